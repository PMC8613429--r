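## Independent oracles used across the tests. These re-derive expected
## behaviour by brute force or closed form, never by calling the code paths
## they check.

MS_H <- 3600000
MS_D <- 86400000

## Brute-force classifier: to which test (row index of dtmts, or NA) does a
## single timestamp belong? Rules re-derived independently from the window
## construction: neighbour midpoints when the neighbour is <= 24 h away,
## otherwise calendar-date membership, with pre-morning/post-evening times on
## two-test days unassigned.
classify_ts <- function(ts, dtmts) {
  t <- dtmts$timestamp_ms
  stopifnot(!is.unsorted(t))
  day <- floor(t / MS_D)
  mday <- floor(ts / MS_D)
  prev_i <- findInterval(ts, t)            # largest i with t[i] <= ts
  next_i <- prev_i + 1L
  has_prev <- prev_i >= 1L
  has_next <- next_i <= length(t)
  if (has_prev && has_next && (t[next_i] - t[prev_i]) <= 24 * MS_H) {
    mid <- (t[prev_i] + t[next_i]) / 2
    return(if (ts < mid) prev_i else next_i)
  }
  on_date <- which(day == mday)
  if (length(on_date) == 1L) return(on_date)
  if (length(on_date) == 2L) {
    ## two-test day reached without the midpoint rule: ts is before the
    ## morning test or at/after the evening test; omitted
    return(NA_integer_)
  }
  NA_integer_
}

## expected per-test keypress counts for arbitrary key timestamps
oracle_counts <- function(key_ts, dtmts) {
  cls <- vapply(key_ts, classify_ts, integer(1), dtmts = dtmts)
  tabulate(cls, nbins = nrow(dtmts))
}

## Dense multivariate-normal log-density of the LMM: assembles the full
## block-diagonal covariance and evaluates with determinant() and solve().
dense_lmm_loglik <- function(y, X, Z, group, G, beta, sigma2) {
  n <- length(y)
  Sigma <- matrix(0, n, n)
  for (sid in unique(group)) {
    i <- which(group == sid)
    Zi <- Z[i, , drop = FALSE]
    Sigma[i, i] <- Zi %*% G %*% t(Zi)
  }
  diag(Sigma) <- diag(Sigma) + sigma2
  r <- y - drop(X %*% beta)
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + ld + drop(t(r) %*% solve(Sigma, r)))
}

## random small LMM instance on the absolute-G scale
random_lmm_instance <- function(n_subjects = 5, rows_per = 8, p = 3, q = 4,
                                type = "unstructured") {
  n <- n_subjects * rows_per
  tab <- data.frame(subject_id = rep(sprintf("P%02d", 1:n_subjects),
                                     each = rows_per))
  for (j in seq_len(p)) tab[[paste0("x", j)]] <- rnorm(n)
  for (j in seq_len(q - 1)) tab[[paste0("z", j)]] <- rnorm(n)
  theta_n <- if (type == "diagonal") q else q * (q + 1) / 2
  theta <- rnorm(theta_n, -1, 0.4)
  beta <- rnorm(p + 1)
  sigma2 <- exp(rnorm(1, -1, 0.3))
  tab$y <- rnorm(n, 2, 1)
  spec <- lmm_spec("y", paste0("x", seq_len(p)),
                   random_terms = c("intercept", paste0("z", seq_len(q - 1))),
                   re_covariance = type)
  list(spec = spec, tab = tab, theta = theta, beta = beta, sigma2 = sigma2)
}

## design matrices as fit_lmm builds them, re-derived here for oracles
design_of <- function(spec, tab) {
  X <- cbind(1, as.matrix(tab[, setdiff(spec$fixed_terms, "intercept"),
                              drop = FALSE]))
  Zc <- setdiff(spec$random_terms, "intercept")
  Z <- cbind(1, if (length(Zc)) as.matrix(tab[, Zc, drop = FALSE]))
  list(y = tab[[spec$response]], X = X, Z = Z, group = tab[[spec$grouping]])
}

## absolute theta -> G, re-derived (log-diagonal Cholesky / log-SDs)
oracle_theta_to_G <- function(theta, q, type) {
  if (type == "diagonal") return(diag(exp(theta)^2, q))
  L <- matrix(0, q, q)
  L[lower.tri(L, diag = TRUE)] <- theta
  diag(L) <- exp(diag(L))
  L %*% t(L)
}

## a small schedule with known structure: days as offsets from an epoch day
make_dtmts <- function(subject = "A", day_hour, base_day = 18300) {
  ## day_hour: matrix-like list of c(day, hour) pairs
  ts <- vapply(day_hour, function(dh) {
    (base_day + dh[1] - 1) * MS_D + dh[2] * MS_H
  }, numeric(1))
  slot <- vapply(day_hour, function(dh) {
    if (dh[2] < 15) "morning" else "evening"
  }, character(1))
  data.frame(subject_id = subject, timestamp_ms = ts,
             completion_time_s = 20, wrong_moves = 1L,
             variant_id = 1L, slot = slot, stringsAsFactors = FALSE)
}

## the committed 6-day fixture: two-test days, one-test days, a 3-day gap
six_day_fixture <- function() {
  make_dtmts(day_hour = list(
    c(1, 9), c(1, 21),      # two-test day
    c(2, 21),               # evening only, morning missed
    c(3, 9),                # morning only
    c(6, 9), c(6, 21)))     # two-test day after a >24 h gap
}

## random schedule over two periods with missingness, one subject
random_schedule <- function(p_skip = 0.4, days = c(1:6, 10:14),
                            base_day = 18300) {
  pairs <- list()
  for (d in days) {
    if (runif(1) > p_skip) pairs <- c(pairs, list(c(d, 9 + runif(1))))
    if (runif(1) > p_skip) pairs <- c(pairs, list(c(d, 21 + runif(1) - 0.5)))
  }
  if (length(pairs) == 0L) pairs <- list(c(days[1], 9))
  make_dtmts(day_hour = pairs, base_day = base_day)
}
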