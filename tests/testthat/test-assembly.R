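## Mood backpropagation, two-level centering and the model-table transforms.

test_that("mood ratings are backpropagated to the preceding interval", {
  base <- as.Date("2020-01-06")
  moods <- data.frame(subject_id = "A", date = base + c(6, 13),
                      hdrs17 = c(4L, 9L))
  dt <- function(day) data.frame(subject_id = "A",
                                 timestamp_ms = (as.numeric(base) + day - 1) *
                                   MS_D + 12 * MS_H)
  ## test on day 10 falls in (day 7, day 14] -> the day-14 score
  expect_equal(backpropagate_mood(moods, dt(10))$hdrs17, 9)
  ## a rating's own day is covered by it
  expect_equal(backpropagate_mood(moods, dt(7))$hdrs17, 4)
  ## before the first rating -> first; after the last -> last
  expect_equal(backpropagate_mood(moods, dt(2))$hdrs17, 4)
  expect_equal(backpropagate_mood(moods, dt(40))$hdrs17, 9)
  ## single rating covers everything
  m1 <- moods[1, ]
  expect_equal(backpropagate_mood(m1, dt(1))$hdrs17, 4)
  expect_equal(backpropagate_mood(m1, dt(30))$hdrs17, 4)
})

test_that("backpropagation equals a linear-scan search on random calendars", {
  set.seed(11)
  base <- 18300
  for (rep in 1:20) {
    rating_days <- sort(sample(1:60, sample(2:8, 1)))
    scores <- sample(0:30, length(rating_days), replace = TRUE)
    moods <- data.frame(subject_id = "A",
                        date = as.Date(base + rating_days - 1,
                                       origin = "1970-01-01"),
                        hdrs17 = scores)
    test_days <- sample(1:60, 15, replace = FALSE)
    dtmts <- data.frame(subject_id = "A",
                        timestamp_ms = (base + test_days - 1) * MS_D +
                          9 * MS_H)
    got <- backpropagate_mood(moods, dtmts)$hdrs17
    want <- vapply(test_days, function(d) {
      at_or_after <- rating_days >= d
      if (any(at_or_after)) scores[which(at_or_after)[1]]
      else scores[length(scores)]     # after the last rating
    }, numeric(1))
    expect_equal(got, want)
  }
})

test_that("subjects with tests but no ratings are flagged", {
  moods <- data.frame(subject_id = "A", date = as.Date("2020-01-12"),
                      hdrs17 = 5L)
  dtmts <- data.frame(subject_id = c("A", "B"),
                      timestamp_ms = as.numeric(as.Date("2020-01-10")) *
                        MS_D + 9 * MS_H)
  expect_warning(res <- backpropagate_mood(moods, dtmts), "B")
  expect_equal(res$hdrs17, c(5, NA))
})

test_that("two-level centering splits into between and within parts", {
  r <- two_level_center(rep("A", 3), c(2, 4, 6))
  expect_equal(r$level2, rep(0, 3))           # own mean is the grand mean
  expect_equal(r$level1, c(-2, 0, 2))
  r2 <- two_level_center(c("A", "A", "B", "B"), c(1, 1, 3, 3))
  expect_equal(r2$level2, c(-1, -1, 1, 1))
  expect_equal(r2$level1, rep(0, 4))
  expect_error(two_level_center(character(0), numeric(0)), "empty")
})

test_that("centering reconstructs the data and level-1 sums to zero", {
  set.seed(21)
  ids <- rep(sprintf("S%d", 1:5), times = sample(2:6, 5, replace = TRUE))
  x <- rnorm(length(ids), 10, 4)
  r <- two_level_center(ids, x)
  expect_equal(r$grand_mean + r$level2 + r$level1, x, tolerance = 1e-12)
  within_sums <- tapply(r$level1, ids, sum)
  expect_true(all(abs(within_sums) < 1e-9))
})

## A 4-row hand-built input: one subject, two tests on each of two days,
## days 1 and 45 (one per period). Expected values computed by hand below.
test_that("model table matches a hand-computed fixture", {
  base <- 18300   # day number of study day 1
  mk_ts <- function(day, hour) (base + day - 1) * MS_D + hour * MS_H
  dtmts <- data.frame(
    subject_id = "A",
    timestamp_ms = c(mk_ts(1, 9), mk_ts(1, 21), mk_ts(45, 9), mk_ts(45, 21)),
    completion_time_s = c(20, 18, 15, 16),
    wrong_moves = c(1L, 0L, 2L, 0L),
    variant_id = 1L,
    slot = c("morning", "evening", "morning", "evening"))
  windows <- data.frame(
    subject_id = "A", dtmt_timestamp_ms = dtmts$timestamp_ms,
    window_start_ms = dtmts$timestamp_ms - MS_H,
    window_end_ms = dtmts$timestamp_ms + MS_H,
    n_keypresses = 30L, n_valid_transitions = 25L,
    median_ikd_s = c(0.20, 0.25, 0.30, 0.25))
  moods <- data.frame(subject_id = "A",
                      date = as.Date(c(base + 6, base + 48),
                                     origin = "1970-01-01"),
                      hdrs17 = c(6L, 10L))
  roster <- data.frame(subject_id = "A", age = 50, diagnosis = "bipolar",
                       gender = "female")
  tab <- suppressWarnings(   # single subject: several constant columns
    build_model_table(windows, dtmts, moods, roster))

  expect_equal(tab$log_dtmt_time, log(c(20, 18, 15, 16)))
  ## wrong moves: ln(x + 1), then z-scored
  lw <- log(c(1, 0, 2, 0) + 1)
  expect_equal(tab$log_wrong_moves_z, (lw - mean(lw)) / sd(lw))
  ## practice: ln(day within period), day 1 in each period -> ln(1) = 0
  pr <- log(c(1, 1, 1, 1))
  expect_equal(tab$practice_z, rep(0, 4))   # constant -> zeros with warning
  ## period: 0, 0, 1, 1 z-scored
  per <- c(0, 0, 1, 1)
  expect_equal(tab$period_z, (per - 0.5) / sd(per))
  ## time of day: morning 0, evening 1, z-scored
  tod <- c(0, 1, 0, 1)
  expect_equal(tab$time_of_day_z, (tod - 0.5) / sd(tod))
  ## mood: day-7 rating covers days 1-7, day-49 covers 45; one subject so
  ## the grand-centered part is constant zero and within-part z-scored
  hd <- c(6, 6, 10, 10)
  expect_equal(tab$hdrs_grand_z, rep(0, 4))
  dev <- hd - mean(hd)
  expect_equal(tab$hdrs_subject_z, dev / sd(dev))
  ## typing: same structure
  ik <- c(0.20, 0.25, 0.30, 0.25)
  expect_equal(tab$ikd_grand_z, rep(0, 4))
  ikd_dev <- ik - mean(ik)
  expect_equal(tab$ikd_subject_z, ikd_dev / sd(ikd_dev))
  ## ymrs columns exist but are all-NA without ymrs ratings
  expect_true(all(is.na(tab$ymrs_grand_z)))
})

test_that("consistency of response transform with the printed intercept scale", {
  ## exp(2.898) seconds has log-time 2.898: the response is natural log
  expect_equal(log(exp(2.898)), 2.898)
  base <- 18300
  dtmts <- data.frame(subject_id = c("A", "A", "B", "B"),
                      timestamp_ms = (base + c(1, 2, 1, 2) - 1) * MS_D +
                        9 * MS_H,
                      completion_time_s = exp(2.898),
                      wrong_moves = 0L, variant_id = 1L, slot = "morning")
  windows <- data.frame(subject_id = dtmts$subject_id,
                        dtmt_timestamp_ms = dtmts$timestamp_ms,
                        window_start_ms = dtmts$timestamp_ms - MS_H,
                        window_end_ms = dtmts$timestamp_ms + MS_H,
                        n_keypresses = 30L, n_valid_transitions = 25L,
                        median_ikd_s = c(0.2, 0.3, 0.25, 0.35))
  moods <- data.frame(subject_id = c("A", "B"),
                      date = as.Date(base + 6, origin = "1970-01-01"),
                      hdrs17 = c(3L, 8L))
  roster <- data.frame(subject_id = c("A", "B"), age = c(40, 50),
                       diagnosis = c("control", "bipolar"),
                       gender = c("male", "female"))
  tab <- suppressWarnings(build_model_table(windows, dtmts, moods, roster))
  expect_equal(tab$log_dtmt_time, rep(2.898, 4))
  expect_equal(log(0 + 1), 0)    # zero wrong moves transform to exactly 0
})

test_that("z-scored columns have mean 0 and sd 1 over the table", {
  co <- generate_cohort(generator_config(seed = 9, n_control = 4,
                                         n_bipolar = 5))
  tab <- attr(co, "model_table")
  zcols <- c("age_z", "log_wrong_moves_z", "time_of_day_z", "practice_z",
             "period_z", "practice_period_z", "diagnosis_z", "hdrs_grand_z",
             "hdrs_subject_z", "ikd_grand_z", "ikd_subject_z")
  for (cl in zcols) {
    expect_equal(mean(tab[[cl]]), 0, tolerance = 1e-9)
    expect_equal(sd(tab[[cl]]), 1, tolerance = 1e-9)
  }
  ## ymrs columns are z-scored over bipolar rows only
  bi <- !is.na(tab$ymrs_grand_z)
  expect_gt(sum(bi), 0)
  expect_equal(mean(tab$ymrs_grand_z[bi]), 0, tolerance = 1e-9)
  expect_equal(sd(tab$ymrs_subject_z[bi]), 1, tolerance = 1e-9)
})

test_that("re-running the table builder on its own output is rejected", {
  co <- generate_cohort(generator_config(seed = 9, n_control = 3,
                                         n_bipolar = 3))
  tab <- attr(co, "model_table")
  expect_error(build_model_table(tab, co$dtmt, co$mood, co$roster),
               "refusing")
})

test_that("tests outside both periods are a validation error", {
  base <- 18300
  dtmts <- data.frame(subject_id = "A",
                      timestamp_ms = (base + 30 - 1) * MS_D + 9 * MS_H,
                      completion_time_s = 20, wrong_moves = 0L,
                      variant_id = 1L, slot = "morning")
  windows <- data.frame(subject_id = "A",
                        dtmt_timestamp_ms = dtmts$timestamp_ms,
                        window_start_ms = dtmts$timestamp_ms - MS_H,
                        window_end_ms = dtmts$timestamp_ms + MS_H,
                        n_keypresses = 30L, n_valid_transitions = 25L,
                        median_ikd_s = 0.2)
  moods <- data.frame(subject_id = "A", date = as.Date("2020-02-01"),
                      hdrs17 = 1L)
  roster <- data.frame(subject_id = "A", age = 30, diagnosis = "control",
                       gender = "male")
  expect_error(suppressWarnings(
    build_model_table(windows, dtmts, moods, roster,
                      list(study_start_date = as.Date(base,
                                                      origin = "1970-01-01")))),
    "neither period")
})
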