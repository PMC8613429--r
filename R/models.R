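#' Standard model specifications for the dTMT-B analysis
#'
#' The forward-fitted hierarchy: Model 1 is the practice model (age, log wrong
#' moves, time of day, log within-period day, study period and their
#' interaction); Model 2 adds diagnosis and the grand-mean- and
#' subject-centered HDRS-17 depression terms; Model 3 adds the grand-mean-
#' and subject-centered median typing speed (median IKD). Models 4 and 5 are
#' the within-bipolar hierarchy: Model 4 is Model 1 plus the HDRS-17 terms,
#' Model 5 adds the YMRS mania terms. All share the random structure:
#' per-subject intercept and slopes of practice, period and their interaction.
#'
#' @param re_covariance random-effect covariance structure passed to
#'   [lmm_spec()].
#' @return named list of [lmm_spec()] objects `model1` .. `model5`.
#' @export
model_specs <- function(re_covariance = "unstructured") {
  base_terms <- c("age_z", "log_wrong_moves_z", "time_of_day_z",
                  "practice_z", "period_z", "practice_period_z")
  mood_terms <- c("diagnosis_z", "hdrs_grand_z", "hdrs_subject_z")
  typing_terms <- c("ikd_grand_z", "ikd_subject_z")
  hdrs_only <- c("hdrs_grand_z", "hdrs_subject_z")
  ymrs_terms <- c("ymrs_grand_z", "ymrs_subject_z")
  mk <- function(terms) lmm_spec("log_dtmt_time", terms,
                                 re_covariance = re_covariance)
  list(model1 = mk(base_terms),
       model2 = mk(c(base_terms, mood_terms)),
       model3 = mk(c(base_terms, mood_terms, typing_terms)),
       model4 = mk(c(base_terms, hdrs_only)),
       model5 = mk(c(base_terms, hdrs_only, ymrs_terms)))
}

check_nested <- function(small, big) {
  identical(small$response, big$response) &&
    identical(small$grouping, big$grouping) &&
    identical(small$random_terms, big$random_terms) &&
    all(small$fixed_terms %in% big$fixed_terms)
}

#' Likelihood-ratio test between two nested ML fits
#'
#' @param fit_small,fit_big [fit_lmm()] results with the smaller model's
#'   fixed terms a subset of the larger's, identical random structure.
#' @return list with `chi_square` (= deviance_small - deviance_big),
#'   `df_change` (difference in number of fixed terms) and `p_value`.
#' @export
lrt <- function(fit_small, fit_big) {
  if (!check_nested(fit_small$spec, fit_big$spec)) {
    stop_validation("models are not nested (fixed terms must be a superset; random structure identical)")
  }
  chi <- fit_small$deviance - fit_big$deviance
  df <- length(fit_big$spec$fixed_terms) - length(fit_small$spec$fixed_terms)
  p <- if (df == 0L) 1 else stats::pchisq(chi, df, lower.tail = FALSE)
  if (df == 0L) chi <- max(chi, 0)
  list(chi_square = chi, df_change = df, p_value = p)
}

#' Forward-fit a nested sequence of mixed models
#'
#' Fits each model in order (each must nest the previous), warm-starting the
#' covariance parameters from the previous fit so the ML deviance is
#' monotone non-increasing along the sequence, and compares consecutive fits
#' with the likelihood-ratio test.
#'
#' @param table model table.
#' @param model_sequence list of [lmm_spec()]s, e.g. `model_specs()[1:3]`.
#' @param options fit options, see [fit_lmm()].
#' @return object of class `lmm_forward`: list with `fits` and `lrt`
#'   (per-step chi-square, df change, p).
#' @export
forward_fit <- function(table, model_sequence, options = list()) {
  stopifnot(length(model_sequence) >= 1L)
  for (k in seq_along(model_sequence)[-1L]) {
    if (!check_nested(model_sequence[[k - 1L]], model_sequence[[k]])) {
      stop_validation("model %d does not nest model %d", k, k - 1L)
    }
  }
  fits <- vector("list", length(model_sequence))
  tests <- vector("list", max(0L, length(model_sequence) - 1L))
  opts <- merge_options(default_fit_options(), options, "fit options")
  for (k in seq_along(model_sequence)) {
    ok <- opts
    if (k > 1L) ok$start <- fits[[k - 1L]]$theta_rel
    fits[[k]] <- fit_lmm(model_sequence[[k]], table, ok)
    if (k > 1L) tests[[k - 1L]] <- lrt(fits[[k - 1L]], fits[[k]])
  }
  names(fits) <- names(model_sequence) %||% paste0("model", seq_along(fits))
  structure(list(fits = fits, lrt = tests), class = "lmm_forward")
}

#' @export
print.lmm_forward <- function(x, ...) {
  cat("Forward-fitted hierarchical mixed models\n\n")
  dev <- vapply(x$fits, function(f) f$deviance, numeric(1))
  tab <- data.frame(Deviance = sprintf("%.2f", dev),
                    `Chi square (df)` = c("", vapply(x$lrt, function(t)
                      sprintf("%.2f (%d)", t$chi_square, t$df_change),
                      character(1))),
                    `p` = c("", vapply(x$lrt, function(t)
                      format.pval(t$p_value, digits = 3), character(1))),
                    check.names = FALSE, row.names = names(x$fits))
  print(tab)
  invisible(x)
}

#' Variance-partition (Nakagawa) R-squared of a mixed-model fit
#'
#' Marginal R2 is the variance of the fixed-effect predictor over the total
#' (fixed + random + residual) variance; conditional R2 adds the
#' random-effect variance to the numerator. The random-effect contribution is
#' the mean over observations of z_i' G z_i, which reduces to the sum of the
#' random-effect variances for an intercept-only structure and extends it to
#' random slopes.
#'
#' @param fit an [fit_lmm()] result.
#' @return named numeric vector `c(marginal = , conditional = )`, both in
#'   `[0, 1]` with marginal <= conditional.
#' @export
r2_nakagawa <- function(fit) {
  des <- fit$design
  eta <- drop(des$X %*% fit$beta)
  var_f <- stats::var(eta)
  var_re <- mean(rowSums((des$Z %*% fit$re_cov) * des$Z))
  total <- var_f + var_re + fit$sigma2
  if (!is.finite(total) || total <= 0) stop_validation("zero total variance")
  c(marginal = var_f / total, conditional = (var_f + var_re) / total)
}

#' Wald fixed-effect table
#'
#' Wald z inference: p = 2 Phi(-|estimate / se|), with standard errors from
#' the inverse fixed-effect information at the ML estimates.
#'
#' @param fit an [fit_lmm()] result.
#' @return data frame with `term`, `estimate`, `se`, `z`, `p`.
#' @export
wald_fixed_effects <- function(fit) {
  data.frame(term = names(fit$beta),
             estimate = unname(fit$beta),
             se = unname(fit$se),
             z = unname(fit$beta / fit$se),
             p = unname(fit$p_values),
             row.names = NULL, stringsAsFactors = FALSE)
}
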