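#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions: 8 controls and 11 individuals with
#' bipolar disorder, twice-daily dTMT-B administrations at preset morning and
#' evening times (09:00 and 21:00 local, +/- 30 min jitter) over study days
#' 1-17 and 45-56 separated by a four-week gap, weekly HDRS-17 (and, for the
#' bipolar group, YMRS) phone ratings, naturalistic keypress streams
#' organized in typing sessions, and a skip probability that reproduces the
#' observed ~31 completed tests per subject out of the 58 scheduled.
#' Completion times are generated by inverting the analysis model: the
#' generator builds the same transformed, two-level-centered, z-scored design
#' the pipeline produces and applies the fixed coefficients (defaults: the
#' Model 3 estimates), per-subject random effects and residual noise on the
#' natural-log-seconds scale.
#'
#' @param ... overrides of any default field. Main fields: `n_control`,
#'   `n_bipolar`, `period1_days`, `period2_days`, `gap_weeks`,
#'   `fixed_coeffs` (named, on the transformed/z-scored scale),
#'   `random_variances` (intercept, practice_slope, period_slope,
#'   interaction_slope), `residual_variance`, `hdrs_params`, `ymrs_params`,
#'   `ikd_params`, `age_params`, `wrong_move_params`, `gender_p_male`,
#'   `ptmt_params`, `missingness`, `seed`, `start_date`, `tz`.
#' @return validated config list of class `generator_config`.
#' @export
generator_config <- function(...) {
  cfg <- list(
    n_control = 8L,
    n_bipolar = 11L,
    period1_days = c(1L, 17L),
    period2_days = c(45L, 56L),
    gap_weeks = 4,
    fixed_coeffs = c(intercept = 2.898, age = 0.008, log_wrong_moves = 0.220,
                     time_of_day = 0.013, practice = -0.069, period = -0.039,
                     practice_period = 0.041, diagnosis = -0.180,
                     hdrs_grand = 0.189, hdrs_subject = 0.038,
                     ikd_grand = 0.189, ikd_subject = 0.032),
    random_variances = c(intercept = 0.010, practice_slope = 0.0003,
                         period_slope = 0.002, interaction_slope = 0.002),
    residual_variance = 0.058,
    hdrs_params = list(control_mean = 1.02, control_sd = 1.49,
                       bipolar_mean = 12.68, bipolar_sd = 7.80,
                       ar_rho = 0.6, control_ar_sd = 1, bipolar_ar_sd = 2),
    ymrs_params = list(mean = 6.00, sd = 3.80, ar_rho = 0.6, ar_sd = 1.5),
    ikd_params = list(trait_median = 0.25, trait_sdlog = 0.25,
                      daily_sdlog = 0.10, session_sdlog = 0.5,
                      sessions_per_day = 10L, keys_min = 12L, keys_max = 28L,
                      session_hours = 7L:22L, cutoff = 8),
    age_params = list(control_mean = 46.12, control_sd = 10.72,
                      bipolar_mean = 47.09, bipolar_sd = 10.57, min_age = 20),
    wrong_move_params = list(rate_meanlog = log(1.5), rate_sdlog = 0.5),
    gender_p_male = c(control = 0.375, bipolar = 0.273),
    ptmt_params = list(noise_sdlog = 0.15, shift_log = 0),
    missingness = 0.47,
    seed = 1L,
    start_date = as.Date("2020-01-06"),
    tz = "UTC")
  cfg <- merge_options(cfg, list(...), "generator config")
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_control < 0 || cfg$n_bipolar < 0) {
    stop_config("n_control/n_bipolar", "must be non-negative")
  }
  if (cfg$missingness < 0 || cfg$missingness > 1) {
    stop_config("missingness", "must be a probability in [0, 1]")
  }
  if (any(cfg$random_variances < 0)) {
    stop_config("random_variances", "must be non-negative")
  }
  if (cfg$residual_variance < 0) {
    stop_config("residual_variance", "must be non-negative")
  }
  if (cfg$period1_days[2] >= cfg$period2_days[1]) {
    stop_config("period1_days/period2_days", "period ranges must be disjoint and ordered")
  }
  if (cfg$ikd_params$trait_median <= 0) {
    stop_config("ikd_params$trait_median", "must be positive")
  }
  if (cfg$ikd_params$session_sdlog <= 0) {
    stop_config("ikd_params$session_sdlog", "must be positive")
  }
  need <- c("intercept", "age", "log_wrong_moves", "time_of_day", "practice",
            "period", "practice_period", "diagnosis", "hdrs_grand",
            "hdrs_subject", "ikd_grand", "ikd_subject")
  if (!all(need %in% names(cfg$fixed_coeffs))) {
    stop_config("fixed_coeffs",
                paste("must name:", paste(need, collapse = ", ")))
  }
  invisible(cfg)
}

#' Simulate one dTMT-B completion time from the generative model
#'
#' Returns `exp(eta + eps)` seconds with `eta = x' beta + z' b`, where `x` is
#' the covariate row on the transformed/z-scored analysis scale, `beta` the
#' configured fixed coefficients, `b` the subject's random effects for
#' (intercept, practice, period, interaction) and `eps ~ N(0,
#' residual_variance)`. Logs are natural throughout, so an intercept of 2.898
#' with everything else zero gives exp(2.898) ~ 18.1 s.
#'
#' @param row_covariates named numeric vector (or a matrix with named
#'   columns, one row per observation) of covariates matching
#'   `config$fixed_coeffs` names except `intercept`; missing names are an
#'   error.
#' @param subject_random_effects numeric vector of length 4 (or a matrix with
#'   one row per observation): intercept, practice, period, interaction
#'   effects. The practice/period/interaction random slopes multiply the
#'   `practice`, `period` and `practice_period` covariates.
#' @param config a [generator_config()].
#' @param eps optional fixed residual(s); if `NULL` drawn from
#'   N(0, residual_variance).
#' @return completion time(s) in seconds, strictly positive.
#' @export
simulate_dtmt_time <- function(row_covariates, subject_random_effects, config,
                               eps = NULL) {
  beta <- config$fixed_coeffs
  covnames <- setdiff(names(beta), "intercept")
  if (is.null(dim(row_covariates))) {
    row_covariates <- matrix(row_covariates, nrow = 1,
                             dimnames = list(NULL, names(row_covariates)))
  }
  missing_cov <- setdiff(covnames, colnames(row_covariates))
  if (length(missing_cov) > 0L) {
    stop_validation("row_covariates lacks: %s", paste(missing_cov, collapse = ", "))
  }
  X <- cbind(intercept = 1, row_covariates[, covnames, drop = FALSE])
  eta <- drop(X %*% beta[c("intercept", covnames)])
  if (is.null(dim(subject_random_effects))) {
    subject_random_effects <- matrix(subject_random_effects,
                                     nrow = nrow(X), ncol = 4, byrow = TRUE)
  }
  Z <- cbind(1, row_covariates[, "practice", drop = TRUE],
             row_covariates[, "period", drop = TRUE],
             row_covariates[, "practice_period", drop = TRUE])
  eta <- eta + rowSums(Z * subject_random_effects)
  if (is.null(eps)) {
    eps <- if (config$residual_variance > 0) {
      stats::rnorm(length(eta), 0, sqrt(config$residual_variance))
    } else 0
  }
  unname(exp(eta + eps))
}

#' Simulate one day of naturalistic keypresses for one subject
#'
#' Events come in typing sessions: session start hours are distinct within
#' the day (so between-session gaps exceed the 8 s session cutoff by
#' construction), within-session inter-key delays are lognormal with the
#' given median, truncated below the cutoff, and key categories are drawn
#' from a fixed multinomial. No text content exists.
#'
#' @param params list: `subject_id`, `day_start_ms` (midnight of the day),
#'   `median_ikd` (seconds, > 0), `sdlog`, `n_sessions`, `keys_min`,
#'   `keys_max`, `session_hours` (candidate start hours), `cutoff`.
#' @param seed optional seed (the generator instead relies on one cohort-level
#'   seed).
#' @return data frame `subject_id`, `timestamp_ms`, `category`, sorted by
#'   timestamp.
#' @export
simulate_keypress_stream <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (params$median_ikd <= 0) {
    stop_config("median_ikd", "trait median inter-key delay must be positive")
  }
  n_sessions <- params$n_sessions
  if (n_sessions == 0L) {
    return(data.frame(subject_id = character(), timestamp_ms = numeric(),
                      category = character(), stringsAsFactors = FALSE))
  }
  res <- keypress_day(params)
  data.frame(subject_id = params$subject_id, timestamp_ms = res$ts,
             category = res$category, stringsAsFactors = FALSE)
}

## vector core of simulate_keypress_stream; avoids data-frame overhead when
## called thousands of times by generate_cohort
keypress_day <- function(params) {
  n_sessions <- params$n_sessions
  sh <- params$session_hours
  hours <- sort(sh[sample.int(length(sh), n_sessions)])
  starts <- params$day_start_ms + hours * MS_PER_HOUR +
    round(stats::runif(n_sessions, 0, 44 * 60) * 1000)
  key_range <- seq(params$keys_min, params$keys_max)
  n_keys <- key_range[sample.int(length(key_range), n_sessions,
                                 replace = TRUE)]
  total <- sum(n_keys)
  ## truncated-below-cutoff lognormal delays via inverse CDF
  pmax_ <- stats::plnorm(params$cutoff, log(params$median_ikd), params$sdlog)
  delays <- stats::qlnorm(stats::runif(total - n_sessions) * pmax_,
                          log(params$median_ikd), params$sdlog)
  ts <- numeric(total)
  pos <- 1L
  dpos <- 1L
  for (s in seq_len(n_sessions)) {
    k <- n_keys[s]
    ts[pos:(pos + k - 1L)] <-
      starts[s] + c(0, cumsum(delays[dpos:(dpos + k - 2L)] * 1000))
    pos <- pos + k
    dpos <- dpos + k - 1L
  }
  cats <- sample(KEY_CATEGORIES[1:6], total, replace = TRUE,
                 prob = c(0.70, 0.08, 0.05, 0.12, 0.03, 0.02))
  list(ts = round(ts), category = cats)
}

rnorm_trunc <- function(n, mean, sd, lower, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lower | x > upper
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < lower | x > upper
  }
  x
}

ar1_series <- function(n, rho, sd) {
  if (n == 0L) return(numeric(0))
  e <- stats::rnorm(n, 0, sd)
  x <- numeric(n)
  x[1] <- e[1] / sqrt(max(1 - rho^2, 1e-12))
  for (t in seq_len(n)[-1L]) x[t] <- rho * x[t - 1L] + e[t]
  x
}

#' Generate a complete synthetic cohort
#'
#' Produces the four data streams of the study (subject roster, keypress
#' events, dTMT-B records, weekly mood ratings) plus the paper-test scores,
#' with completion times generated by [simulate_dtmt_time()] applied to the
#' same transformed design the analysis pipeline reconstructs: the generator
#' runs [build_windows()], [compute_window_features()],
#' [apply_inclusion_filters()] and [build_model_table()] on its own raw
#' streams, so applying the pipeline to the output recovers the generating
#' coefficients (up to sampling error). The seed fully determines the output.
#'
#' @param config a [generator_config()].
#' @return list of data frames: `roster`, `keypresses`, `dtmt`, `mood`,
#'   `ptmt`. The attribute `"truth"` records the generating fixed
#'   coefficients, random effects and variances; `"model_table"` the
#'   generator-side analysis table.
#' @export
generate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  set.seed(config$seed)
  n_sub <- config$n_control + config$n_bipolar
  empty <- list(
    roster = data.frame(subject_id = character(), age = numeric(),
                        diagnosis = character(), gender = character(),
                        stringsAsFactors = FALSE),
    keypresses = data.frame(subject_id = character(), timestamp_ms = numeric(),
                            category = character(), stringsAsFactors = FALSE),
    dtmt = data.frame(subject_id = character(), timestamp_ms = numeric(),
                      completion_time_s = numeric(), wrong_moves = integer(),
                      variant_id = integer(), slot = character(),
                      stringsAsFactors = FALSE),
    mood = data.frame(subject_id = character(), date = as.Date(character()),
                      hdrs17 = integer(), ymrs = integer(),
                      stringsAsFactors = FALSE),
    ptmt = data.frame(subject_id = character(), occasion = character(),
                      time_s = numeric(), stringsAsFactors = FALSE))
  if (n_sub == 0L) return(empty)

  ap <- config$age_params
  diagnosis <- c(rep("control", config$n_control),
                 rep("bipolar", config$n_bipolar))
  sid <- sprintf("S%03d", seq_len(n_sub))
  is_bd <- diagnosis == "bipolar"
  age <- numeric(n_sub)
  age[!is_bd] <- rnorm_trunc(sum(!is_bd), ap$control_mean, ap$control_sd,
                             ap$min_age)
  age[is_bd] <- rnorm_trunc(sum(is_bd), ap$bipolar_mean, ap$bipolar_sd,
                            ap$min_age)
  gender <- ifelse(stats::runif(n_sub) <
                     config$gender_p_male[ifelse(is_bd, "bipolar", "control")],
                   "male", "female")
  roster <- data.frame(subject_id = sid, age = round(age, 1),
                       diagnosis = diagnosis, gender = gender,
                       stringsAsFactors = FALSE)

  start_day <- as.numeric(as.Date(config$start_date))
  p1 <- config$period1_days; p2 <- config$period2_days
  active_days <- c(seq(p1[1], p1[2]), seq(p2[1], p2[2]))
  n_days <- length(active_days)
  week_days <- seq(7, p2[2], by = 7)

  ## dTMT-B schedule with missingness
  sched <- expand.grid(day = active_days, slot = c("morning", "evening"),
                       subject_id = sid, stringsAsFactors = FALSE)
  sched <- sched[order(sched$subject_id, sched$day, sched$slot != "morning"), ]
  taken <- stats::runif(nrow(sched)) >= config$missingness
  sched <- sched[taken, , drop = FALSE]
  jitter_min <- stats::runif(nrow(sched), -30, 30)
  hour <- ifelse(sched$slot == "morning", 9, 21)
  sched$timestamp_ms <- (start_day + sched$day - 1) * MS_PER_DAY +
    hour * MS_PER_HOUR + round(jitter_min * 60000)
  wm_rate <- stats::rlnorm(n_sub, config$wrong_move_params$rate_meanlog,
                           config$wrong_move_params$rate_sdlog)
  names(wm_rate) <- sid
  dtmt <- data.frame(subject_id = sched$subject_id,
                     timestamp_ms = sched$timestamp_ms,
                     completion_time_s = 1,   # placeholder until model applied
                     wrong_moves = stats::rpois(nrow(sched),
                                                wm_rate[sched$subject_id]),
                     variant_id = sample(1:12, nrow(sched), replace = TRUE),
                     slot = sched$slot, stringsAsFactors = FALSE)

  ## weekly mood ratings
  hp <- config$hdrs_params; yp <- config$ymrs_params
  mood_list <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    bd <- is_bd[s]
    trait <- rnorm_trunc(1, if (bd) hp$bipolar_mean else hp$control_mean,
                         if (bd) hp$bipolar_sd else hp$control_sd, 0, 52)
    fluct <- ar1_series(length(week_days), hp$ar_rho,
                        if (bd) hp$bipolar_ar_sd else hp$control_ar_sd)
    hdrs <- pmin(pmax(round(trait + fluct), 0), 52)
    ymrs <- rep(NA_integer_, length(week_days))
    if (bd) {
      ytrait <- rnorm_trunc(1, yp$mean, yp$sd, 0, 60)
      ymrs <- pmin(pmax(round(ytrait + ar1_series(length(week_days),
                                                  yp$ar_rho, yp$ar_sd)), 0), 60)
    }
    mood_list[[s]] <- data.frame(
      subject_id = sid[s],
      date = as.Date(start_day + week_days - 1, origin = "1970-01-01"),
      hdrs17 = as.integer(hdrs), ymrs = as.integer(ymrs),
      stringsAsFactors = FALSE)
  }
  mood <- do.call(rbind, mood_list)

  ## keypress streams, one call per subject-day
  ip <- config$ikd_params
  trait_ikd <- stats::rlnorm(n_sub, log(ip$trait_median), ip$trait_sdlog)
  ts_list <- vector("list", n_sub * n_days)
  cat_list <- vector("list", n_sub * n_days)
  k <- 1L
  for (s in seq_len(n_sub)) {
    daily_mult <- stats::rlnorm(n_days, 0, ip$daily_sdlog)
    for (d in seq_len(n_days)) {
      day <- keypress_day(list(
        day_start_ms = (start_day + active_days[d] - 1) * MS_PER_DAY,
        median_ikd = trait_ikd[s] * daily_mult[d],
        sdlog = ip$session_sdlog,
        n_sessions = ip$sessions_per_day,
        keys_min = ip$keys_min, keys_max = ip$keys_max,
        session_hours = ip$session_hours, cutoff = ip$cutoff))
      ts_list[[k]] <- day$ts
      cat_list[[k]] <- day$category
      k <- k + 1L
    }
  }
  n_per <- lengths(ts_list)
  ## days are generated in subject/time order and sessions cannot overlap the
  ## next hour slot, so the stream is already sorted within subject
  keypresses <- data.frame(
    subject_id = rep(rep(sid, each = n_days), n_per),
    timestamp_ms = unlist(ts_list),
    category = unlist(cat_list),
    stringsAsFactors = FALSE)

  ## analysis-side design via the shared pipeline code path
  tab <- NULL
  if (nrow(dtmt) > 0L) {
    win <- build_windows(dtmt, config$tz)
    win <- compute_window_features(win, keypresses, cutoff = ip$cutoff)
    filt <- apply_inclusion_filters(win)
    if (nrow(filt$windows) > 0L) {
      tab <- suppressWarnings(build_model_table(
        filt$windows, dtmt, mood, roster,
        list(tz = config$tz, period1_days = p1, period2_days = p2,
             study_start_date = as.Date(start_day, origin = "1970-01-01"))))
    }
  }

  rv <- config$random_variances
  b <- cbind(stats::rnorm(n_sub, 0, sqrt(rv["intercept"])),
             stats::rnorm(n_sub, 0, sqrt(rv["practice_slope"])),
             stats::rnorm(n_sub, 0, sqrt(rv["period_slope"])),
             stats::rnorm(n_sub, 0, sqrt(rv["interaction_slope"])))
  rownames(b) <- sid

  beta <- config$fixed_coeffs
  eta_grand <- beta["intercept"] + b[, 1]   # subject-level fallback for pTMT
  eta_row <- eta_grand[dtmt$subject_id]     # latent performance per record
  if (!is.null(tab)) {
    Xcov <- cbind(age = tab$age_z, log_wrong_moves = tab$log_wrong_moves_z,
                  time_of_day = tab$time_of_day_z, practice = tab$practice_z,
                  period = tab$period_z,
                  practice_period = tab$practice_period_z,
                  diagnosis = tab$diagnosis_z, hdrs_grand = tab$hdrs_grand_z,
                  hdrs_subject = tab$hdrs_subject_z,
                  ikd_grand = tab$ikd_grand_z, ikd_subject = tab$ikd_subject_z)
    eps <- stats::rnorm(nrow(Xcov), 0, sqrt(config$residual_variance))
    ct <- simulate_dtmt_time(Xcov, b[tab$subject_id, , drop = FALSE], config,
                             eps = eps)
    midx <- match(paste(tab$subject_id, tab$dtmt_timestamp_ms),
                  paste(dtmt$subject_id, dtmt$timestamp_ms))
    dtmt$completion_time_s[midx] <- round(ct, 3)
    tab$log_dtmt_time <- log(round(ct, 3))
    eta_row[midx] <- log(ct) - eps
    ## records outside the analysis table still need plausible times
    rest <- setdiff(seq_len(nrow(dtmt)), midx)
  } else {
    rest <- seq_len(nrow(dtmt))
  }
  if (length(rest) > 0L) {
    eps <- stats::rnorm(length(rest), 0, sqrt(config$residual_variance))
    dtmt$completion_time_s[rest] <-
      round(exp(eta_row[rest] + eps), 3)
  }

  ## paper TMT-B at study start and end: reflects the same momentary
  ## performance (linear predictor) as the subject's first/last digital test,
  ## up to lognormal modality noise
  pp <- config$ptmt_params
  eta_first <- eta_grand
  eta_last <- eta_grand
  if (nrow(dtmt) > 0L) {
    for (s in sid) {
      i <- which(dtmt$subject_id == s)
      if (length(i) > 0L) {
        eta_first[s] <- eta_row[i[which.min(dtmt$timestamp_ms[i])]]
        eta_last[s] <- eta_row[i[which.max(dtmt$timestamp_ms[i])]]
      }
    }
  }
  ptmt <- data.frame(
    subject_id = rep(sid, each = 2),
    occasion = rep(c("first", "last"), n_sub),
    time_s = round(exp(as.vector(rbind(eta_first, eta_last)) + pp$shift_log +
                         stats::rnorm(2 * n_sub, 0, pp$noise_sdlog)), 2),
    stringsAsFactors = FALSE)

  out <- list(roster = roster, keypresses = keypresses, dtmt = dtmt,
              mood = mood, ptmt = ptmt)
  attr(out, "truth") <- list(beta = beta, random_effects = b,
                             random_variances = rv,
                             residual_variance = config$residual_variance,
                             trait_ikd = trait_ikd)
  attr(out, "model_table") <- tab
  out
}
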