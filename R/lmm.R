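#' Specify a linear mixed model
#'
#' Describes a Gaussian linear mixed model y = X beta + Z_i b_i + e with
#' independent subjects i, b_i ~ N(0, G) and e ~ N(0, sigma^2 I). The fixed
#' design always carries an implicit intercept; the default random structure
#' is the study's: intercept plus the slopes of practice, study period and
#' their interaction per subject.
#'
#' @param response response column name (typically `"log_dtmt_time"`).
#' @param fixed_terms ordered character vector of fixed-effect column names,
#'   or a one-sided/two-sided formula whose term labels are column names (a
#'   two-sided formula also sets `response`).
#' @param random_terms character vector of per-subject random design columns;
#'   `"intercept"` denotes the constant column.
#' @param grouping subject id column name.
#' @param re_covariance `"unstructured"` (full covariance via log-Cholesky
#'   factors) or `"diagonal"` (independent random effects via log-SDs).
#' @return object of class `lmm_spec`.
#' @export
lmm_spec <- function(response, fixed_terms,
                     random_terms = c("intercept", "practice_z", "period_z",
                                      "practice_period_z"),
                     grouping = "subject_id",
                     re_covariance = c("unstructured", "diagonal")) {
  if (inherits(fixed_terms, "formula")) {
    if (length(fixed_terms) == 3L) response <- all.vars(fixed_terms[[2L]])
    fixed_terms <- attr(stats::terms(fixed_terms), "term.labels")
  }
  re_covariance <- match.arg(re_covariance)
  if (length(fixed_terms) == 0L) stop_validation("fixed_terms must be non-empty")
  structure(list(response = response,
                 fixed_terms = as.character(fixed_terms),
                 random_terms = as.character(random_terms),
                 grouping = grouping,
                 re_covariance = re_covariance),
            class = "lmm_spec")
}

#' @export
print.lmm_spec <- function(x, ...) {
  cat("Linear mixed model specification\n")
  cat("  response:", x$response, "\n")
  cat("  fixed:   ", paste(x$fixed_terms, collapse = " + "), "\n")
  cat("  random:  ", paste(x$random_terms, collapse = " + "),
      sprintf("| %s (%s)\n", x$grouping, x$re_covariance))
  invisible(x)
}

## ---- design construction -------------------------------------------------

lmm_design <- function(spec, table) {
  need <- unique(c(spec$response, setdiff(spec$fixed_terms, "intercept"),
                   setdiff(spec$random_terms, "intercept"), spec$grouping))
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0L) {
    stop_validation("model table lacks column(s): %s",
                    paste(missing_cols, collapse = ", "))
  }
  used <- table[, need, drop = FALSE]
  if (anyNA(used)) {
    bad <- names(used)[vapply(used, anyNA, logical(1))]
    stop_validation("missing values in model column(s): %s",
                    paste(bad, collapse = ", "))
  }
  y <- as.numeric(table[[spec$response]])
  n <- length(y)
  col_of <- function(nm) {
    if (nm == "intercept") rep(1, n) else as.numeric(table[[nm]])
  }
  fx <- setdiff(spec$fixed_terms, "intercept")
  X <- if (length(fx) > 0L) {
    cbind(rep(1, n), vapply(fx, col_of, numeric(n)))
  } else {
    matrix(1, n, 1)
  }
  colnames(X) <- c("intercept", fx)
  Z <- vapply(spec$random_terms, col_of, numeric(n))
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = n)
  colnames(Z) <- spec$random_terms
  group <- as.character(table[[spec$grouping]])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop_validation("singular fixed-effect design; collinear column(s): %s",
                    paste(dropped, collapse = ", "))
  }
  list(y = y, X = X, Z = Z, group = group,
       subjects = unique(group))
}

## theta <-> relative Cholesky factor Lambda (G = sigma^2 Lambda Lambda')
theta_template <- function(q, type) {
  if (type == "diagonal") {
    list(n = q, diag_idx = seq_len(q))
  } else {
    idx <- which(lower.tri(matrix(0, q, q), diag = TRUE))
    dpos <- match((seq_len(q) - 1L) * q + seq_len(q), idx)
    list(n = length(idx), lower_idx = idx, diag_idx = dpos)
  }
}

## log_diag: diagonal entries given on the log scale (the absolute-scale
## parameterization of lmm_loglik); the optimizer instead works on the direct
## scale with a zero lower bound so boundary (zero-variance) fits are exact.
theta_to_lambda <- function(theta, q, type, log_diag = TRUE) {
  L <- matrix(0, q, q)
  if (type == "diagonal") {
    diag(L) <- if (log_diag) exp(theta) else theta
  } else {
    tpl <- theta_template(q, type)
    vals <- theta
    if (log_diag) vals[tpl$diag_idx] <- exp(vals[tpl$diag_idx])
    L[tpl$lower_idx] <- vals
  }
  L
}

## absolute-scale theta -> random-effect covariance G
theta_to_G <- function(theta, q, type) {
  L <- theta_to_lambda(theta, q, type)
  tcrossprod(L)
}

## ---- log-likelihood (blockwise, direct parameterization) -----------------

#' Marginal log-likelihood of a linear mixed model
#'
#' Evaluates the marginal Gaussian log-likelihood ln N(y; X beta, Z G Z' +
#' sigma^2 I) blockwise per subject via Cholesky factorization of each
#' subject's marginal covariance. `theta` parameterizes G on the absolute
#' scale: for an unstructured covariance the lower-triangular Cholesky factor
#' (column-wise, diagonal entries on the log scale); for a diagonal one the
#' log standard deviations.
#'
#' @param spec an [lmm_spec()].
#' @param table model table.
#' @param theta covariance parameters (see above).
#' @param beta fixed-effect vector (intercept first).
#' @param sigma2 residual variance, > 0.
#' @return scalar log-likelihood.
#' @export
lmm_loglik <- function(spec, table, theta, beta, sigma2) {
  des <- lmm_design(spec, table)
  q <- ncol(des$Z)
  G <- theta_to_G(theta, q, spec$re_covariance)
  lmm_loglik_G(des, G, beta, sigma2)
}

lmm_loglik_G <- function(des, G, beta, sigma2) {
  if (!is.finite(sigma2) || sigma2 <= 0) {
    stop_validation("sigma2 must be positive; got %g", sigma2)
  }
  r <- des$y - drop(des$X %*% beta)
  ll <- 0
  for (sid in des$subjects) {
    i <- which(des$group == sid)
    Zi <- des$Z[i, , drop = FALSE]
    Sig <- Zi %*% G %*% t(Zi)
    diag(Sig) <- diag(Sig) + sigma2
    R <- tryCatch(chol(Sig), error = function(e) {
      stop_validation(paste0("implied covariance not positive definite for ",
                             "subject '%s' (sigma2 = %g, diag(G) = %s)"),
                      sid, sigma2, paste(signif(diag(G), 4), collapse = ", "))
    })
    u <- backsolve(R, r[i], transpose = TRUE)
    ll <- ll - 0.5 * (length(i) * log(2 * pi) + 2 * sum(log(diag(R))) +
                        sum(u * u))
  }
  ll
}

## ---- profiled deviance machinery -----------------------------------------

## Per-subject sufficient statistics; everything the profiled deviance needs.
lmm_suffstats <- function(des) {
  lapply(des$subjects, function(sid) {
    i <- which(des$group == sid)
    Xi <- des$X[i, , drop = FALSE]
    Zi <- des$Z[i, , drop = FALSE]
    yi <- des$y[i]
    list(n = length(i),
         M = crossprod(Zi),          # Z'Z  (q x q)
         Czx = crossprod(Zi, Xi),    # Z'X  (q x p)
         czy = drop(crossprod(Zi, yi)),
         XtX = crossprod(Xi),
         Xty = drop(crossprod(Xi, yi)),
         yty = sum(yi * yi))
  })
}

## Profiled ML deviance at relative covariance factor Lambda.
## Uses V_i = I + Z_i A Z_i' with A = Lambda Lambda' and the Woodbury
## identity, so each evaluation is q x q / p x p algebra per subject.
profiled_deviance <- function(theta, ss, q, p, type, n_total, details = FALSE) {
  L <- theta_to_lambda(theta, q, type, log_diag = FALSE)
  A <- tcrossprod(L)
  Iq <- diag(q)
  Sxx <- matrix(0, p, p)
  Sxy <- numeric(p)
  Syy <- 0
  logdet <- 0
  Wlist <- if (details) vector("list", length(ss)) else NULL
  for (k in seq_along(ss)) {
    s <- ss[[k]]
    K <- Iq + A %*% s$M
    dt <- determinant(K, logarithm = TRUE)
    if (dt$sign <= 0 || !is.finite(dt$modulus)) return(list(dev = Inf))
    logdet <- logdet + as.numeric(dt$modulus)
    W <- solve(K, A)                       # = (A^-1 + Z'Z)^-1, PSD
    W <- (W + t(W)) / 2
    WC <- W %*% s$Czx
    Sxx <- Sxx + s$XtX - crossprod(s$Czx, WC)
    Sxy <- Sxy + s$Xty - drop(crossprod(WC, s$czy))
    Syy <- Syy + s$yty - drop(crossprod(s$czy, W %*% s$czy))
    if (details) Wlist[[k]] <- W
  }
  beta <- tryCatch(solve(Sxx, Sxy), error = function(e) NULL)
  if (is.null(beta)) return(list(dev = Inf))
  rss <- Syy - 2 * sum(beta * Sxy) + drop(crossprod(beta, Sxx %*% beta))
  if (!is.finite(rss) || rss <= 0) return(list(dev = Inf))
  sigma2 <- rss / n_total
  dev <- n_total * log(2 * pi * sigma2) + logdet + n_total
  if (!details) return(list(dev = dev))
  list(dev = dev, beta = beta, sigma2 = sigma2, A = A, Lambda = L,
       Sxx = Sxx, logdet = logdet, W = Wlist)
}

default_fit_options <- function() {
  list(restarts = 5L, tol = 1e-8, seed = NULL, maxit = 400L,
       start = NULL, singular_tol = 1e-4, diagonal_fallback = TRUE)
}

#' Fit a linear mixed model by maximum likelihood
#'
#' Maximizes the profiled ML deviance over the relative random-effect
#' covariance parameters (fixed effects and residual variance are profiled
#' out in closed form at every candidate), using bounded quasi-Newton
#' (L-BFGS-B) with jittered restarts. Standard errors are Wald, from the
#' fixed-effect information matrix at the optimum; with an unstructured
#' covariance that comes out singular the fit is repeated with a diagonal
#' structure (the study's 19 subjects support 4 variances better than 10
#' covariance parameters).
#'
#' @param spec an [lmm_spec()], or a two-sided formula of column names (then
#'   the default random structure and grouping are used).
#' @param table model table (from [build_model_table()] or equivalent); must
#'   contain every spec column, with at least two subjects.
#' @param options list of overrides: `restarts` (jittered optimizer restarts,
#'   default 5), `tol` (convergence tolerance on the deviance, default 1e-8),
#'   `seed` (for the jitter), `maxit`, `start` (initial theta),
#'   `singular_tol`, `diagonal_fallback`.
#' @return object of class `lmm_fit`; see [summary.lmm_fit()]. Key fields:
#'   `beta`, `se`, `p_values`, `re_cov` (G), `sigma2`, `theta` (absolute-scale
#'   parameters accepted by [lmm_loglik()]), `loglik`, `deviance`,
#'   `r2_marginal`, `r2_conditional`, `converged`, `ranef`.
#' @export
fit_lmm <- function(spec, table, options = list()) {
  if (inherits(spec, "formula")) spec <- lmm_spec(NULL, spec)
  opt <- merge_options(default_fit_options(), options, "fit options")
  des <- lmm_design(spec, table)
  if (length(des$subjects) < 2L) stop_validation("need at least two subjects")
  q <- ncol(des$Z)
  p <- ncol(des$X)
  n <- length(des$y)
  type <- spec$re_covariance
  ss <- lmm_suffstats(des)
  tpl <- theta_template(q, type)

  objective <- function(th) profiled_deviance(th, ss, q, p, type, n)$dev

  ## relative Cholesky entries on the direct scale, diagonal bounded at zero
  theta0 <- numeric(tpl$n)
  theta0[tpl$diag_idx] <- 0.5
  if (!is.null(opt$start)) theta0 <- opt$start
  lower <- rep(-25, tpl$n); lower[tpl$diag_idx] <- 0
  upper <- rep(25, tpl$n)

  if (!is.null(opt$seed)) set.seed(opt$seed)
  starts <- list(theta0)
  if (opt$restarts > 1L) {
    for (r in seq_len(opt$restarts - 1L)) {
      starts[[r + 1L]] <- pmin(pmax(theta0 + stats::rnorm(tpl$n, 0, 0.5),
                                    lower), upper)
    }
  }
  best <- NULL
  any_converged <- FALSE
  for (st in starts) {
    res <- tryCatch(
      stats::optim(st, objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = opt$maxit, factr = opt$tol / 1e-15)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    if (res$convergence == 0) any_converged <- TRUE
    if (is.null(best) || res$value < best$value - 1e-12) best <- res
  }
  if (is.null(best)) stop_validation("optimizer failed on every restart")
  if (!any_converged) {
    warning("fit_lmm: optimizer did not converge after restarts", call. = FALSE)
  }

  fin <- profiled_deviance(best$par, ss, q, p, type, n, details = TRUE)

  ## singularity check: relative SDs collapsing to the boundary
  singular <- any(sqrt(diag(fin$A)) < opt$singular_tol)
  if (type == "unstructured" && singular && isTRUE(opt$diagonal_fallback)) {
    spec2 <- spec
    spec2$re_covariance <- "diagonal"
    opt2 <- opt
    opt2$start <- NULL
    fit <- fit_lmm(spec2, table, opt2)
    fit$fallback <- "diagonal (unstructured fit singular)"
    return(fit)
  }

  sigma2 <- fin$sigma2
  beta <- drop(fin$beta)
  names(beta) <- colnames(des$X)
  G <- sigma2 * fin$A
  dimnames(G) <- list(spec$random_terms, spec$random_terms)

  ## absolute-scale theta: Cholesky factor of G is sigma * Lambda, diagonal
  ## on the log scale (-Inf encodes an exactly-zero variance component)
  theta_abs <- best$par * sqrt(sigma2)
  theta_abs[tpl$diag_idx] <- log(best$par[tpl$diag_idx] * sqrt(sigma2))
  G_used <- theta_to_G(theta_abs, q, type)

  vcov_beta <- sigma2 * solve(fin$Sxx)
  dimnames(vcov_beta) <- list(names(beta), names(beta))
  se <- sqrt(diag(vcov_beta))
  z <- beta / se
  p_values <- 2 * stats::pnorm(-abs(z))

  ## BLUPs: b_i = (A^-1 + Z'Z)^-1 Z'(y_i - X_i beta)  (relative scale cancels)
  ranef <- matrix(vapply(seq_along(ss), function(k) {
    s <- ss[[k]]
    drop(fin$W[[k]] %*% (s$czy - s$Czx %*% beta))
  }, numeric(q)), ncol = q, byrow = TRUE)
  dimnames(ranef) <- list(des$subjects, spec$random_terms)

  ## report the loglik through the independent blockwise path so that
  ## lmm_loglik(spec, table, theta, beta, sigma2) reproduces it exactly
  loglik <- lmm_loglik_G(des, G_used, beta, sigma2)

  fit <- structure(list(
    spec = spec,
    beta = beta, se = se, p_values = p_values,
    vcov_beta = vcov_beta,
    re_cov = G_used, sigma2 = sigma2,
    theta = theta_abs, theta_rel = best$par,
    loglik = loglik, deviance = -2 * loglik,
    converged = any_converged,
    n_obs = n, n_subjects = length(des$subjects),
    n_params = p + tpl$n + 1L,
    ranef = ranef,
    design = des,
    fallback = NULL,
    call = match.call()), class = "lmm_fit")
  r2 <- r2_nakagawa(fit)
  fit$r2_marginal <- r2[["marginal"]]
  fit$r2_conditional <- r2[["conditional"]]
  fit
}
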