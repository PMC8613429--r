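#' Render the human-readable run report
#'
#' Reads the artifacts already written by the pipeline (`fits.json`,
#' `model_comparison.csv`, `coefficients.csv`, `reliability.csv`,
#' `ttests.csv`) and renders text tables in the shapes of the study's
#' reliability, model-comparison and coefficient tables, plus basic
#' practice-curve and effect plots from the final fitted model. The renderer
#' never recomputes: every number is formatted from the artifacts, so the
#' report agrees with `fits.json` by construction. Missing sections are
#' noted, not errors, except the model artifacts which are required.
#'
#' @param dir artifact directory of a [run_pipeline()] run.
#' @return path of the written `report.txt`, invisibly.
#' @export
make_report <- function(dir) {
  fits_path <- file.path(dir, "fits.json")
  if (!file.exists(fits_path)) stop_validation("missing artifact: %s", fits_path)
  fits <- jsonlite::read_json(fits_path, simplifyVector = FALSE)
  lines <- c("typetrail run report", strrep("=", 60), "")

  cmp_path <- file.path(dir, "model_comparison.csv")
  if (file.exists(cmp_path)) {
    cmp <- utils::read.csv(cmp_path)
    lines <- c(lines, "Model fits and successive likelihood-ratio tests", "")
    lines <- c(lines, sprintf("%-8s %10s %18s %10s", "Model", "Deviance",
                              "Chi square (df)", "p"))
    for (i in seq_len(nrow(cmp))) {
      chi <- if (is.na(cmp$chi_square[i])) "" else
        sprintf("%.2f (%d)", cmp$chi_square[i], cmp$df_change[i])
      p <- if (is.na(cmp$p_value[i])) "" else format.pval(cmp$p_value[i], 3)
      lines <- c(lines, sprintf("%-8s %10.2f %18s %10s", cmp$model[i],
                                cmp$deviance[i], chi, p))
    }
    lines <- c(lines, "")
  } else {
    lines <- c(lines, "[model comparison artifact absent]", "")
  }

  lines <- c(lines, "Fixed-effect estimates (scaled)", "")
  for (nm in names(fits)) {
    f <- fits[[nm]]
    lines <- c(lines, sprintf("%s  (log-Likelihood %.3f, marginal/conditional R2 %.3f / %.3f)",
                              nm, f$loglik, f$r2_marginal, f$r2_conditional))
    for (term in names(f$beta)) {
      lines <- c(lines, sprintf("  %-22s %8.3f  (se %.3f, p %s)", term,
                                f$beta[[term]], f$se[[term]],
                                format.pval(f$p[[term]], 3)))
    }
    rv <- vapply(seq_along(f$random_terms), function(j)
      f$re_cov[[j]][[j]], numeric(1))
    lines <- c(lines, sprintf("  random-effect variances: %s; residual %.4g",
                              paste(sprintf("%s %.4g", f$random_terms, rv),
                                    collapse = ", "), f$sigma2), "")
  }

  rel_path <- file.path(dir, "reliability.csv")
  if (file.exists(rel_path)) {
    rel <- utils::read.csv(rel_path)
    lines <- c(lines, "Intraclass correlations (consistency, single measures)", "")
    for (i in seq_len(nrow(rel))) {
      lines <- c(lines, sprintf("  %-30s ICC %5.2f  CI %.2f-%.2f  (n=%d)",
                                rel$comparison[i], rel$icc[i], rel$ci_low[i],
                                rel$ci_high[i], rel$n[i]))
    }
    tt <- utils::read.csv(file.path(dir, "ttests.csv"))
    lines <- c(lines, "", "Paired t-tests:")
    for (i in seq_len(nrow(tt))) {
      lines <- c(lines, sprintf("  %-30s t = %.2f, df = %d, p = %s",
                                tt$comparison[i], tt$t[i], tt$df[i],
                                format.pval(tt$p[i], 3)))
    }
    lines <- c(lines, "")
  } else {
    lines <- c(lines, "[reliability stage not run; section omitted]", "")
  }

  path <- file.path(dir, "report.txt")
  writeLines(lines, path)
  report_plots(dir, fits)
  invisible(path)
}

## practice-curve and effect plots from the last fitted model's estimates
report_plots <- function(dir, fits) {
  f <- fits[[length(fits)]]
  tab_path <- file.path(dir, "model_table.csv")
  if (!file.exists(tab_path)) return(invisible(NULL))
  tab <- utils::read.csv(tab_path)
  pdf_path <- file.path(dir, "report_plots.pdf")
  grDevices::pdf(pdf_path, width = 9, height = 4.5)
  on.exit(grDevices::dev.off())
  beta <- unlist(f$beta)

  graphics::par(mfrow = c(1, 3))
  ## practice curves: predicted log time across practice, per period
  for (per in sort(unique(tab$period_z))) {
    sel <- tab$period_z == per
    o <- order(tab$practice_z[sel])
    eta <- beta["intercept"] + beta["practice_z"] * tab$practice_z[sel] +
      beta["period_z"] * per +
      beta["practice_period_z"] * tab$practice_period_z[sel]
    if (per == sort(unique(tab$period_z))[1]) {
      graphics::plot(tab$practice_z[sel][o], eta[o], type = "l",
                     xlab = "Practice (z of log day)",
                     ylab = "Predicted log dTMT-B time (s)",
                     main = "Practice effect by period",
                     ylim = range(tab$log_dtmt_time))
    } else {
      graphics::lines(tab$practice_z[sel][o], eta[o], lty = 2)
    }
  }
  graphics::points(tab$practice_z, tab$log_dtmt_time,
                   col = grDevices::adjustcolor("grey40", 0.4), pch = 16,
                   cex = 0.5)
  for (term in c("hdrs_grand_z", "ikd_grand_z")) {
    if (!term %in% names(beta) || !term %in% names(tab)) next
    graphics::plot(tab[[term]], tab$log_dtmt_time, pch = 16, cex = 0.5,
                   col = grDevices::adjustcolor("grey40", 0.5),
                   xlab = term, ylab = "log dTMT-B time (s)",
                   main = sprintf("%s (b = %.3f)", term, beta[term]))
    graphics::abline(mean(tab$log_dtmt_time) -
                       beta[term] * mean(tab[[term]]), beta[term])
  }
  invisible(pdf_path)
}
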