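ICC_LABEL <- "ICC(3,1) two-way mixed, consistency, single measures"

#' Intraclass correlation, consistency form
#'
#' ICC(3,1): two-way mixed effects, consistency, single rater, computed from
#' the two-way ANOVA decomposition of the n x 2 score matrix as
#' `(MS_rows - MS_error) / (MS_rows + (k - 1) MS_error)` with k = 2, plus an
#' F-based confidence interval. The consistency form is invariant to adding a
#' constant to one modality but not to rescaling it.
#'
#' @param pairs data frame with `subject_id`, `score_a`, `score_b` (complete
#'   pairs only).
#' @param alpha confidence level is `1 - alpha` (default 0.05).
#' @return list of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `n_subjects`, `model_label`.
#' @export
icc_consistency <- function(pairs, alpha = 0.05) {
  m <- as.matrix(pairs[, c("score_a", "score_b")])
  if (anyNA(m)) stop_validation("icc_consistency: incomplete pairs")
  n <- nrow(m)
  k <- 2L
  if (n < 3L) stop_validation("icc_consistency: need at least 3 complete pairs")
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  df_rows <- n - 1L
  df_err <- (n - 1L) * (k - 1L)
  msr <- ss_rows / df_rows
  mse <- ss_err / df_err
  if (msr < 1e-12 && ss_rows < 1e-12) {
    warning("zero between-subject variance; ICC set to 0", call. = FALSE)
    return(structure(list(icc = 0, ci_low = 0, ci_high = 0, n_subjects = n,
                          model_label = ICC_LABEL), class = "icc_result"))
  }
  icc <- if (msr + (k - 1) * mse < 1e-300) 1 else
    (msr - mse) / (msr + (k - 1) * mse)
  if (mse < 1e-300) {
    ci <- c(icc, icc)       # perfect consistency: degenerate interval
  } else {
    f_obs <- msr / mse
    fl <- f_obs / stats::qf(1 - alpha / 2, df_rows, df_err)
    fu <- f_obs * stats::qf(1 - alpha / 2, df_err, df_rows)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  structure(list(icc = icc, ci_low = min(ci[1], icc), ci_high = max(ci[2], icc),
                 n_subjects = n, model_label = ICC_LABEL),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("%s\nICC = %.3f, 95%% CI %.3f-%.3f (n = %d)\n",
              x$model_label, x$icc, x$ci_low, x$ci_high, x$n_subjects))
  invisible(x)
}

#' Paired t-test between two score columns
#'
#' t = mean(d) / (sd(d) / sqrt(n)) on the differences d = score_a - score_b,
#' two-sided p from Student's t with n - 1 degrees of freedom. Zero variance
#' of the differences with a nonzero mean yields an infinite t with p = 0,
#' flagged.
#'
#' @param pairs data frame with `score_a`, `score_b`.
#' @return list of class `paired_t_result`: `t`, `df`, `p`, `mean_diff`, `n`,
#'   `degenerate`.
#' @export
paired_t_test <- function(pairs) {
  a <- pairs$score_a
  b <- pairs$score_b
  if (length(a) < 2L) stop_validation("paired_t_test: need at least 2 pairs")
  if (anyNA(a) || anyNA(b)) stop_validation("paired_t_test: incomplete pairs")
  d <- a - b
  n <- length(d)
  md <- mean(d)
  if (stats::sd(d) < 1e-300) {
    if (abs(md) < 1e-300) {
      res <- list(t = 0, df = n - 1L, p = 1, mean_diff = 0, n = n,
                  degenerate = TRUE)
    } else {
      warning("zero variance of paired differences with nonzero mean",
              call. = FALSE)
      res <- list(t = sign(md) * Inf, df = n - 1L, p = 0, mean_diff = md,
                  n = n, degenerate = TRUE)
    }
    return(structure(res, class = "paired_t_result"))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean_diff = md, n = n, degenerate = FALSE),
            class = "paired_t_result")
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat(sprintf("paired t = %.3f, df = %d, p = %.4g (mean difference %.3f, n = %d)\n",
              x$t, x$df, x$p, x$mean_diff, x$n))
  invisible(x)
}

first_last_scores <- function(dtmts) {
  out <- lapply(split(dtmts, dtmts$subject_id), function(d) {
    d <- d[order(d$timestamp_ms), ]
    data.frame(subject_id = d$subject_id[1],
               first = d$completion_time_s[1],
               last = d$completion_time_s[nrow(d)],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross- and within-modality reliability report
#'
#' Computes the four consistency ICCs (first digital vs first paper, last vs
#' last, first vs last within each modality) and the two within-modality
#' paired t-tests (first vs last). Subjects missing either score of a
#' comparison are dropped from that comparison only, with counts recorded.
#'
#' @param dtmts dTMT-B records (`subject_id`, `timestamp_ms`,
#'   `completion_time_s`): first/last are by timestamp (first completed).
#' @param ptmt paper-test scores (`subject_id`, `occasion`
#'   (`"first"`/`"last"`), `time_s`).
#' @param alpha passed to [icc_consistency()].
#' @return object of class `reliability_report`: data frames `icc`
#'   (comparison, icc, ci_low, ci_high, n, model_label) and `ttests`
#'   (comparison, t, df, p, mean_diff, n); attribute `"drop_log"`.
#' @export
reliability_report <- function(dtmts, ptmt, alpha = 0.05) {
  dscores <- first_last_scores(dtmts)
  pw <- ptmt[ptmt$occasion == "first", c("subject_id", "time_s")]
  names(pw)[2] <- "p_first"
  pl <- ptmt[ptmt$occasion == "last", c("subject_id", "time_s")]
  names(pl)[2] <- "p_last"
  scores <- merge(merge(dscores, pw, all = TRUE), pl, all = TRUE)

  comparisons <- list(
    "first pTMT-B vs first dTMT-B" = c("p_first", "first"),
    "last pTMT-B vs last dTMT-B" = c("p_last", "last"),
    "first vs last pTMT-B" = c("p_first", "p_last"),
    "first vs last dTMT-B" = c("first", "last"))
  drop_log <- list()
  icc_rows <- lapply(names(comparisons), function(nm) {
    cols <- comparisons[[nm]]
    ok <- stats::complete.cases(scores[, cols])
    drop_log[[nm]] <<- sum(!ok)
    pr <- data.frame(subject_id = scores$subject_id[ok],
                     score_a = scores[[cols[1]]][ok],
                     score_b = scores[[cols[2]]][ok])
    r <- icc_consistency(pr, alpha)
    data.frame(comparison = nm, icc = r$icc, ci_low = r$ci_low,
               ci_high = r$ci_high, n = r$n_subjects,
               model_label = r$model_label, stringsAsFactors = FALSE)
  })
  tcomp <- list("first vs last pTMT-B" = c("p_first", "p_last"),
                "first vs last dTMT-B" = c("first", "last"))
  t_rows <- lapply(names(tcomp), function(nm) {
    cols <- tcomp[[nm]]
    ok <- stats::complete.cases(scores[, cols])
    pr <- data.frame(score_a = scores[[cols[1]]][ok],
                     score_b = scores[[cols[2]]][ok])
    r <- paired_t_test(pr)
    data.frame(comparison = nm, t = r$t, df = r$df, p = r$p,
               mean_diff = r$mean_diff, n = r$n, stringsAsFactors = FALSE)
  })
  structure(list(icc = do.call(rbind, icc_rows),
                 ttests = do.call(rbind, t_rows)),
            drop_log = drop_log, class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat("Reliability of digital vs paper Trail Making Test part B\n\n")
  icc <- x$icc
  icc$icc <- round(icc$icc, 2)
  icc$ci <- sprintf("%.2f-%.2f", icc$ci_low, icc$ci_high)
  print(icc[, c("comparison", "icc", "ci", "n")], row.names = FALSE)
  cat("\nPaired t-tests (first vs last):\n")
  tt <- x$ttests
  tt$t <- round(tt$t, 2)
  tt$p <- format.pval(tt$p, digits = 3)
  print(tt[, c("comparison", "t", "df", "p", "n")], row.names = FALSE)
  invisible(x)
}
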