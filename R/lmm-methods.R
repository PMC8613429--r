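#' @export
print.lmm_fit <- function(x, digits = 4, ...) {
  cat("Linear mixed model fit by maximum likelihood\n")
  cat(sprintf("  %d observations, %d subjects; log-likelihood %.3f (deviance %.3f)\n",
              x$n_obs, x$n_subjects, x$loglik, x$deviance))
  if (!is.null(x$fallback)) cat("  covariance structure:", x$fallback, "\n")
  cat("Fixed effects:\n")
  print(round(x$beta, digits))
  cat(sprintf("Residual variance: %.4g\n", x$sigma2))
  invisible(x)
}

#' Summary of a linear mixed model fit
#'
#' @param object an [fit_lmm()] result.
#' @param ... unused.
#' @return object of class `summary.lmm_fit` with the coefficient table,
#'   random-effect covariance, residual variance, R-squared and fit indices.
#' @export
summary.lmm_fit <- function(object, ...) {
  structure(list(
    call = object$call,
    coefficients = wald_fixed_effects(object),
    re_cov = object$re_cov,
    sigma2 = object$sigma2,
    loglik = object$loglik,
    deviance = object$deviance,
    r2_marginal = object$r2_marginal,
    r2_conditional = object$r2_conditional,
    n_obs = object$n_obs, n_subjects = object$n_subjects,
    converged = object$converged,
    fallback = object$fallback), class = "summary.lmm_fit")
}

#' @export
print.summary.lmm_fit <- function(x, digits = 4, ...) {
  cat("Linear mixed model (ML)\n\n")
  co <- x$coefficients
  co$estimate <- round(co$estimate, digits)
  co$se <- round(co$se, digits)
  co$z <- round(co$z, 2)
  co$p <- format.pval(co$p, digits = 3, eps = 1e-16)
  print(co, row.names = FALSE)
  cat("\nRandom effects (variances on the diagonal):\n")
  print(round(x$re_cov, 6))
  cat(sprintf("Residual variance: %.4g\n", x$sigma2))
  cat(sprintf("Marginal R2 / conditional R2: %.3f / %.3f\n",
              x$r2_marginal, x$r2_conditional))
  cat(sprintf("log-Likelihood: %.3f   (n = %d, subjects = %d)\n",
              x$loglik, x$n_obs, x$n_subjects))
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
coef.lmm_fit <- function(object, ...) object$beta

#' @export
vcov.lmm_fit <- function(object, ...) object$vcov_beta

#' @export
logLik.lmm_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' @export
nobs.lmm_fit <- function(object, ...) object$n_obs

#' @export
fitted.lmm_fit <- function(object, level = 1, ...) {
  des <- object$design
  eta <- drop(des$X %*% object$beta)
  if (level >= 1) {
    b <- object$ranef[des$group, , drop = FALSE]
    eta <- eta + rowSums(des$Z * b)
  }
  eta
}

#' Predict from a linear mixed model fit
#'
#' @param object an [fit_lmm()] result.
#' @param newdata model table with the spec's columns; defaults to the
#'   training table.
#' @param level 0 for the marginal (fixed-effects only) prediction, 1 to add
#'   the subject BLUPs (subjects unseen at fit time get level-0 predictions).
#' @param ... unused.
#' @return numeric vector of predictions on the response (log-seconds) scale.
#' @export
predict.lmm_fit <- function(object, newdata = NULL, level = 1, ...) {
  if (is.null(newdata)) return(fitted(object, level = level))
  des <- lmm_design(object$spec, newdata)
  eta <- drop(des$X %*% object$beta)
  if (level >= 1) {
    known <- des$group %in% rownames(object$ranef)
    if (any(known)) {
      b <- object$ranef[des$group[known], , drop = FALSE]
      eta[known] <- eta[known] + rowSums(des$Z[known, , drop = FALSE] * b)
    }
  }
  eta
}

#' @export
residuals.lmm_fit <- function(object, type = c("conditional", "marginal"), ...) {
  type <- match.arg(type)
  object$design$y - fitted(object, level = if (type == "conditional") 1 else 0)
}

#' Simulate responses from a fitted mixed model
#'
#' Draws fresh subject random effects from N(0, G) and residuals from
#' N(0, sigma^2) at the estimates, keeping the fixed-effect predictor.
#'
#' @param object an [fit_lmm()] result.
#' @param nsim number of simulated response vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data frame with `nsim` columns of simulated responses (log scale).
#' @export
simulate.lmm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  des <- object$design
  eta <- drop(des$X %*% object$beta)
  q <- ncol(des$Z)
  ## Cholesky-ish factor robust to singular G
  eg <- eigen(object$re_cov, symmetric = TRUE)
  Lg <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), q)
  sims <- replicate(nsim, {
    b <- matrix(stats::rnorm(length(des$subjects) * q), ncol = q) %*% t(Lg)
    rownames(b) <- des$subjects
    eta + rowSums(des$Z * b[des$group, , drop = FALSE]) +
      stats::rnorm(length(eta), 0, sqrt(object$sigma2))
  })
  as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
}

#' Diagnostic plot for a mixed-model fit
#'
#' Conditional residuals against fitted values plus a normal Q-Q panel.
#'
#' @param x an [fit_lmm()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.lmm_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  f <- fitted(x, level = 1)
  r <- residuals(x)
  graphics::plot(f, r, xlab = "Fitted (log s)", ylab = "Conditional residual",
                 main = "Residuals vs fitted", ...)
  graphics::abline(h = 0, lty = 2)
  stats::qqnorm(r, main = "Normal Q-Q")
  stats::qqline(r)
  invisible(x)
}
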