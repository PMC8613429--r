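#' Backpropagate weekly mood ratings to dTMT-B administrations
#'
#' A rating dated `d` covers every test whose calendar date lies in
#' `(previous_rating_date, d]`; tests after the last rating receive the last
#' rating and tests before the first rating receive the first.
#'
#' @param moods data frame `subject_id`, `date` (`Date` or ISO string),
#'   `hdrs17`, optional `ymrs`.
#' @param dtmts data frame `subject_id`, `timestamp_ms`.
#' @param tz timezone for deriving test dates.
#' @return data frame aligned with `dtmts` rows: `hdrs17`, `ymrs` (`NA` when
#'   absent). Subjects with tests but no ratings get `NA` with a warning; the
#'   caller drops those rows.
#' @export
backpropagate_mood <- function(moods, dtmts, tz = "UTC") {
  moods$date <- as.Date(moods$date)
  if (anyDuplicated(paste(moods$subject_id, moods$date))) {
    stop_validation("duplicate mood rating for a (subject, date)")
  }
  test_day <- day_number(dtmts$timestamp_ms, tz)
  hdrs <- rep(NA_real_, nrow(dtmts))
  ymrs <- rep(NA_real_, nrow(dtmts))
  has_ymrs <- "ymrs" %in% names(moods)
  unrated <- character(0)
  for (sid in unique(dtmts$subject_id)) {
    di <- which(dtmts$subject_id == sid)
    mi <- which(moods$subject_id == sid)
    if (length(mi) == 0L) {
      unrated <- c(unrated, sid)
      next
    }
    mi <- mi[order(moods$date[mi])]
    rd <- as.numeric(moods$date[mi])
    ## first rating date >= test date, else the last rating
    pos <- findInterval(test_day[di] - 1, rd) + 1L
    pos[pos > length(rd)] <- length(rd)
    hdrs[di] <- moods$hdrs17[mi][pos]
    if (has_ymrs) ymrs[di] <- moods$ymrs[mi][pos]
  }
  if (length(unrated) > 0L) {
    warning(sprintf("subject(s) with dTMT-Bs but no mood ratings excluded: %s",
                    paste(unrated, collapse = ", ")), call. = FALSE)
  }
  data.frame(hdrs17 = hdrs, ymrs = ymrs)
}

#' Two-level (grand-mean / within-subject) centering
#'
#' Splits a repeatedly measured covariate into a level-2 between-person part
#' (the subject mean centered at the unweighted grand mean of subject means)
#' and a level-1 within-person part (deviation from the own subject mean,
#' summing to zero within subject).
#'
#' @param subject_id vector of subject ids, one per observation.
#' @param x numeric vector of observations.
#' @return list with `grand_mean` (scalar), `subject_means` (named),
#'   `level2` (per-row between-person value) and `level1` (per-row deviation).
#' @export
two_level_center <- function(subject_id, x) {
  if (length(x) == 0L) stop_validation("two_level_center: empty input")
  if (length(subject_id) != length(x)) {
    stop_validation("two_level_center: subject_id and x lengths differ")
  }
  if (anyNA(x)) stop_validation("two_level_center: missing values in x")
  means <- tapply(x, subject_id, mean)
  grand <- mean(means)
  sm <- means[as.character(subject_id)]
  list(grand_mean = grand,
       subject_means = means,
       level2 = as.numeric(sm - grand),
       level1 = as.numeric(x - sm))
}

default_assembly_options <- function() {
  list(tz = "UTC",
       period1_days = c(1L, 17L),
       period2_days = c(45L, 56L),
       study_start_date = NULL,   # default: earliest test date in the data
       z_score_dummies = TRUE,
       practice_units = "calendar")  # days since period start; "index" counts tests
}

#' Build the analysis-ready model table
#'
#' Merges typing features, mood ratings, test records and the roster into one
#' observation per retained dTMT-B, applying the analysis transforms:
#' natural-log response `ln(completion_time_s)`, `ln(wrong_moves + 1)`,
#' log practice days (day 1 at each period start, so `ln(1) = 0`), a 0/1
#' period indicator with its practice interaction, 0/1 codes for time of day
#' and diagnosis, two-level centering of HDRS-17 and median IKD (and YMRS over
#' bipolar rows), and finally z-scoring of every fixed term over the final
#' table.
#'
#' @param windows filtered windows (from [apply_inclusion_filters()]) with
#'   `median_ikd_s`.
#' @param dtmts dTMT-B records (`subject_id`, `timestamp_ms`,
#'   `completion_time_s`, `wrong_moves`, `slot`).
#' @param moods weekly mood ratings.
#' @param roster subject roster (`subject_id`, `age`, `diagnosis`, `gender`).
#' @param options list of overrides of the defaults: `tz`, `period1_days`,
#'   `period2_days`, `study_start_date`, `z_score_dummies` (z-score 0/1 codes
#'   too, the default), `practice_units`.
#' @return data frame of model rows; attribute `"drop_log"` records row
#'   accounting (rows in = rows out + dropped, by reason).
#' @export
build_model_table <- function(windows, dtmts, moods, roster, options = list()) {
  opt <- merge_options(default_assembly_options(), options, "assembly options")
  guard <- c("log_dtmt_time", "practice_z", "ikd_grand_z")
  if (any(guard %in% names(windows)) || any(guard %in% names(dtmts))) {
    stop_validation("input already looks like a model table; refusing to re-transform")
  }
  key_w <- paste(windows$subject_id, windows$dtmt_timestamp_ms)
  key_d <- paste(dtmts$subject_id, dtmts$timestamp_ms)
  m <- match(key_w, key_d)
  if (anyNA(m)) stop_validation("window without a matching dTMT-B record")
  tab <- data.frame(subject_id = windows$subject_id,
                    dtmt_timestamp_ms = windows$dtmt_timestamp_ms,
                    median_ikd_s = windows$median_ikd_s,
                    completion_time_s = dtmts$completion_time_s[m],
                    wrong_moves = dtmts$wrong_moves[m],
                    slot = dtmts$slot[m],
                    stringsAsFactors = FALSE)
  n_in <- nrow(tab)

  mood_cols <- backpropagate_mood(
    moods, data.frame(subject_id = tab$subject_id,
                      timestamp_ms = tab$dtmt_timestamp_ms), opt$tz)
  tab$hdrs17 <- mood_cols$hdrs17
  tab$ymrs <- mood_cols$ymrs

  drop_ikd <- is.na(tab$median_ikd_s)
  drop_mood <- is.na(tab$hdrs17)
  keep <- !(drop_ikd | drop_mood)
  drop_log <- list(rows_in = n_in,
                   dropped_missing_ikd = sum(drop_ikd),
                   dropped_missing_mood = sum(drop_mood & !drop_ikd))
  tab <- tab[keep, , drop = FALSE]

  rmatch <- match(tab$subject_id, roster$subject_id)
  if (anyNA(rmatch)) stop_validation("model rows reference subjects missing from roster")
  tab$age <- roster$age[rmatch]
  tab$diagnosis01 <- as.numeric(roster$diagnosis[rmatch] == "bipolar")

  test_day <- day_number(tab$dtmt_timestamp_ms, opt$tz)
  start_day <- if (is.null(opt$study_start_date)) min(test_day)
               else as.numeric(as.Date(opt$study_start_date))
  study_day <- test_day - start_day + 1
  p1 <- opt$period1_days; p2 <- opt$period2_days
  in_p1 <- study_day >= p1[1] & study_day <= p1[2]
  in_p2 <- study_day >= p2[1] & study_day <= p2[2]
  if (any(!in_p1 & !in_p2)) {
    bad <- which(!in_p1 & !in_p2)[1L]
    stop_validation("dTMT-B for subject '%s' on study day %d lies in neither period",
                    tab$subject_id[bad], as.integer(study_day[bad]))
  }
  tab$period01 <- as.numeric(in_p2)
  day_within <- ifelse(in_p2, study_day - p2[1] + 1, study_day - p1[1] + 1)
  if (identical(opt$practice_units, "index")) {
    day_within <- stats::ave(tab$dtmt_timestamp_ms,
                             tab$subject_id, tab$period01,
                             FUN = function(z) rank(z, ties.method = "first"))
  }
  tab$practice_log <- log(day_within)
  tab$tod01 <- as.numeric(tab$slot == "evening")

  tab$log_dtmt_time <- log(tab$completion_time_s)
  tab$log_wrong_moves <- log(tab$wrong_moves + 1)
  interaction_raw <- tab$practice_log * tab$period01

  hd <- two_level_center(tab$subject_id, tab$hdrs17)
  ik <- two_level_center(tab$subject_id, tab$median_ikd_s)

  zs <- function(x) z_score(x)
  zd <- if (isTRUE(opt$z_score_dummies)) zs else identity
  tab$age_z <- zs(tab$age)
  tab$log_wrong_moves_z <- zs(tab$log_wrong_moves)
  tab$time_of_day_z <- zd(tab$tod01)
  tab$practice_z <- zs(tab$practice_log)
  tab$period_z <- zd(tab$period01)
  tab$practice_period_z <- zs(interaction_raw)
  tab$diagnosis_z <- zd(tab$diagnosis01)
  tab$hdrs_grand_z <- zs(hd$level2)
  tab$hdrs_subject_z <- zs(hd$level1)
  tab$ikd_grand_z <- zs(ik$level2)
  tab$ikd_subject_z <- zs(ik$level1)

  tab$ymrs_grand_z <- NA_real_
  tab$ymrs_subject_z <- NA_real_
  bi <- tab$diagnosis01 == 1 & !is.na(tab$ymrs)
  if (any(bi)) {
    ym <- two_level_center(tab$subject_id[bi], tab$ymrs[bi])
    tab$ymrs_grand_z[bi] <- zs(ym$level2)
    tab$ymrs_subject_z[bi] <- zs(ym$level1)
  }

  drop_log$rows_out <- nrow(tab)
  out_cols <- c("subject_id", "dtmt_timestamp_ms", "log_dtmt_time",
                "age_z", "log_wrong_moves_z", "time_of_day_z", "practice_z",
                "period_z", "practice_period_z", "diagnosis_z",
                "hdrs_grand_z", "hdrs_subject_z", "ikd_grand_z",
                "ikd_subject_z", "ymrs_grand_z", "ymrs_subject_z")
  out <- tab[, out_cols]
  rownames(out) <- NULL
  attr(out, "drop_log") <- drop_log
  out
}
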