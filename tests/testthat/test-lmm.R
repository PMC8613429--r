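## The mixed-model machinery against independent oracles.

test_that("blockwise log-likelihood matches the dense MVN oracle", {
  set.seed(101)
  for (rep in 1:20) {
    type <- if (rep %% 2 == 0) "diagonal" else "unstructured"
    inst <- random_lmm_instance(n_subjects = 5, rows_per = sample(6:12, 1),
                                p = 3, q = 4, type = type)
    got <- lmm_loglik(inst$spec, inst$tab, inst$theta, inst$beta, inst$sigma2)
    des <- design_of(inst$spec, inst$tab)
    G <- oracle_theta_to_G(inst$theta, 4, type)
    want <- dense_lmm_loglik(des$y, des$X, des$Z, des$group, G, inst$beta,
                             inst$sigma2)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("zero random variance reduces to the iid normal log-likelihood", {
  set.seed(102)
  inst <- random_lmm_instance(type = "diagonal")
  theta0 <- rep(-40, 4)     # SDs exp(-40): numerically zero
  got <- lmm_loglik(inst$spec, inst$tab, theta0, inst$beta, inst$sigma2)
  des <- design_of(inst$spec, inst$tab)
  r <- des$y - drop(des$X %*% inst$beta)
  want <- sum(dnorm(r, 0, sqrt(inst$sigma2), log = TRUE))
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("balanced random-intercept data matches the compound-symmetry closed form", {
  set.seed(103)
  n_sub <- 6; m <- 5
  tau2 <- 0.5; sigma2 <- 0.8
  tab <- data.frame(subject_id = rep(sprintf("S%d", 1:n_sub), each = m),
                    x1 = rnorm(n_sub * m))
  tab$y <- rnorm(n_sub * m, 1 + 0.3 * tab$x1)
  spec <- lmm_spec("y", "x1", random_terms = "intercept",
                   re_covariance = "diagonal")
  beta <- c(1, 0.3)
  got <- lmm_loglik(spec, tab, 0.5 * log(tau2), beta, sigma2)
  ## textbook closed form: V = sigma2 I + tau2 J per subject, eigenvalues
  ## sigma2 (m-1 times) and sigma2 + m tau2; quadratic form splits into the
  ## within-deviation and subject-mean parts
  r <- tab$y - beta[1] - beta[2] * tab$x1
  ll <- 0
  for (s in unique(tab$subject_id)) {
    ri <- r[tab$subject_id == s]
    lam <- sigma2 + m * tau2
    qf <- sum((ri - mean(ri))^2) / sigma2 + m * mean(ri)^2 / lam
    ll <- ll - 0.5 * (m * log(2 * pi) + (m - 1) * log(sigma2) + log(lam) + qf)
  }
  expect_equal(got, ll, tolerance = 1e-8)
})

test_that("non-positive residual variance is rejected", {
  inst <- random_lmm_instance()
  expect_error(lmm_loglik(inst$spec, inst$tab, inst$theta, inst$beta, -1),
               "positive")
})

test_that("with zero random variances the MLE reduces to OLS", {
  set.seed(104)
  n <- 240
  tab <- data.frame(subject_id = rep(sprintf("S%d", 1:12), each = 20),
                    x1 = rnorm(n), x2 = rnorm(n))
  ## noise centered within subject: the ML random-intercept variance sits at
  ## its zero boundary, so the fit must coincide with OLS
  e <- rnorm(n, 0, 0.3)
  e <- e - ave(e, tab$subject_id)
  tab$y <- 2 + 0.5 * tab$x1 - 0.7 * tab$x2 + e
  spec <- lmm_spec("y", c("x1", "x2"), random_terms = "intercept",
                   re_covariance = "diagonal")
  fit <- fit_lmm(spec, tab, list(restarts = 2, seed = 1))
  expect_equal(unname(fit$re_cov[1, 1]), 0, tolerance = 1e-10)
  ols <- coef(lm(y ~ x1 + x2, tab))
  expect_equal(unname(coef(fit)), unname(ols), tolerance = 1e-6)
  ## and the machinery's degenerate limit is exact at theta = 0
  des <- typetrail:::lmm_design(spec, tab)
  pd <- typetrail:::profiled_deviance(0, typetrail:::lmm_suffstats(des),
                                      1, 3, "diagonal", n, details = TRUE)
  expect_equal(unname(drop(pd$beta)), unname(ols), tolerance = 1e-10)
})

test_that("the reported log-likelihood is reproduced by lmm_loglik at the estimates", {
  set.seed(105)
  co <- generate_cohort(generator_config(seed = 55, n_control = 6,
                                         n_bipolar = 6))
  tab <- attr(co, "model_table")
  for (type in c("diagonal", "unstructured")) {
    spec <- model_specs(type)$model1
    fit <- fit_lmm(spec, tab, list(restarts = 1, diagonal_fallback = FALSE))
    relived <- lmm_loglik(fit$spec, tab, fit$theta, fit$beta, fit$sigma2)
    expect_identical(fit$loglik, relived)
    expect_identical(fit$deviance, -2 * fit$loglik)
  }
})

test_that("Wald SEs equal the dense GLS information oracle", {
  set.seed(106)
  co <- generate_cohort(generator_config(seed = 56, n_control = 5,
                                         n_bipolar = 5))
  tab <- attr(co, "model_table")
  spec <- model_specs("diagonal")$model2
  fit <- fit_lmm(spec, tab, list(restarts = 1))
  des <- design_of(spec, tab)
  Sxx <- matrix(0, ncol(des$X), ncol(des$X))
  for (s in unique(des$group)) {
    i <- des$group == s
    Zi <- des$Z[i, , drop = FALSE]
    Sig <- Zi %*% fit$re_cov %*% t(Zi) + diag(fit$sigma2, sum(i))
    Xi <- des$X[i, , drop = FALSE]
    Sxx <- Sxx + t(Xi) %*% solve(Sig, Xi)
  }
  expect_equal(unname(fit$se), unname(sqrt(diag(solve(Sxx)))),
               tolerance = 1e-6)
  ## p = 2 Phi(-|z|)
  expect_equal(fit$p_values,
               2 * pnorm(-abs(fit$beta / fit$se)), tolerance = 1e-12)
  w <- wald_fixed_effects(fit)
  expect_equal(w$p[w$estimate == 0], rep(1, sum(w$estimate == 0)))
})

test_that("Wald p-values hit the textbook normal quantiles", {
  fake <- structure(list(beta = c(a = 0, b = 1.959964), se = c(a = 1, b = 1),
                         p_values = NULL), class = "lmm_fit")
  fake$p_values <- 2 * pnorm(-abs(fake$beta / fake$se))
  tab <- wald_fixed_effects(fake)
  expect_equal(tab$p[1], 1)
  expect_equal(tab$p[2], 0.05, tolerance = 1e-6)
})

test_that("variance-partition R2 matches a literal reimplementation", {
  set.seed(107)
  co <- generate_cohort(generator_config(seed = 57, n_control = 5,
                                         n_bipolar = 5))
  tab <- attr(co, "model_table")
  fit <- fit_lmm(model_specs("diagonal")$model3, tab, list(restarts = 1))
  des <- design_of(fit$spec, tab)
  vf <- var(drop(des$X %*% fit$beta))
  vr <- mean(rowSums((des$Z %*% fit$re_cov) * des$Z))
  denom <- vf + vr + fit$sigma2
  expect_equal(fit$r2_marginal, vf / denom, tolerance = 1e-10)
  expect_equal(fit$r2_conditional, (vf + vr) / denom, tolerance = 1e-10)
  expect_true(fit$r2_marginal >= 0 && fit$r2_conditional <= 1)
  expect_lte(fit$r2_marginal, fit$r2_conditional)
})

test_that("R2 degenerate limits: no random variance, or no slopes", {
  set.seed(108)
  n <- 120
  tab <- data.frame(subject_id = rep(sprintf("S%d", 1:6), each = 20),
                    x1 = rnorm(n))
  ## intercept-only fixed structure: marginal R2 is 0
  tab$y <- rnorm(n, 3, 1)
  spec0 <- lmm_spec("y", "x1", random_terms = "intercept",
                    re_covariance = "diagonal")
  fit0 <- fit_lmm(spec0, tab, list(restarts = 1))
  fake <- fit0
  fake$beta[] <- c(3, 0)           # zero all but intercept
  r2 <- r2_nakagawa(fake)
  expect_equal(unname(r2["marginal"]), 0, tolerance = 1e-12)
  ## zero random variance: marginal == conditional
  fake2 <- fit0
  fake2$re_cov[] <- 0
  r22 <- r2_nakagawa(fake2)
  expect_equal(unname(r22["marginal"]), unname(r22["conditional"]))
})

test_that("singular fixed designs are reported with the offending column", {
  set.seed(109)
  tab <- data.frame(subject_id = rep(c("a", "b", "c"), each = 10),
                    x1 = rnorm(30))
  tab$x2 <- 2 * tab$x1
  tab$y <- rnorm(30)
  spec <- lmm_spec("y", c("x1", "x2"), random_terms = "intercept",
                   re_covariance = "diagonal")
  expect_error(fit_lmm(spec, tab), "collinear.*x2")
})

test_that("identical consecutive specs give a zero-df LRT with p 1", {
  set.seed(110)
  co <- generate_cohort(generator_config(seed = 58, n_control = 4,
                                         n_bipolar = 4))
  tab <- attr(co, "model_table")
  spec <- model_specs("diagonal")$model1
  ff <- forward_fit(tab, list(spec, spec), list(restarts = 1))
  expect_equal(ff$lrt[[1]]$chi_square, 0, tolerance = 1e-6)
  expect_equal(ff$lrt[[1]]$df_change, 0)
  expect_equal(ff$lrt[[1]]$p_value, 1)
})

test_that("non-nested sequences are rejected", {
  sp <- model_specs("diagonal")
  expect_error(forward_fit(data.frame(), list(sp$model3, sp$model1)),
               "nest")
  sp2 <- sp$model1
  sp2$random_terms <- "intercept"
  f1 <- sp$model1
  expect_false(typetrail:::check_nested(f1, sp2))
})

test_that("adding fixed terms never increases the ML deviance", {
  set.seed(111)
  for (rep in 1:5) {
    co <- generate_cohort(generator_config(seed = 200 + rep, n_control = 4,
                                           n_bipolar = 4))
    tab <- attr(co, "model_table")
    ff <- forward_fit(tab, model_specs("diagonal")[1:3],
                      list(restarts = 1))
    dev <- vapply(ff$fits, function(f) f$deviance, numeric(1))
    expect_true(all(diff(dev) <= 1e-6))
    for (t in ff$lrt) expect_gte(t$chi_square, -1e-6)
  }
})

test_that("fitted log-likelihood agrees with an established mixed-model package", {
  set.seed(112)
  co <- generate_cohort(generator_config(seed = 59))
  tab <- attr(co, "model_table")
  spec <- model_specs("diagonal")$model3
  fit <- fit_lmm(spec, tab, list(restarts = 3, seed = 2))
  lf <- lme4::lmer(
    log_dtmt_time ~ age_z + log_wrong_moves_z + time_of_day_z + practice_z +
      period_z + practice_period_z + diagnosis_z + hdrs_grand_z +
      hdrs_subject_z + ikd_grand_z + ikd_subject_z +
      (1 | subject_id) + (0 + practice_z | subject_id) +
      (0 + period_z | subject_id) + (0 + practice_period_z | subject_id),
    data = tab, REML = FALSE)
  expect_equal(fit$loglik, as.numeric(logLik(lf)), tolerance = 1e-3)
  expect_equal(unname(coef(fit)), unname(lme4::fixef(lf)), tolerance = 1e-3)
})

test_that("simulate/predict/residual methods are coherent", {
  set.seed(113)
  co <- generate_cohort(generator_config(seed = 60, n_control = 4,
                                         n_bipolar = 4))
  tab <- attr(co, "model_table")
  fit <- fit_lmm(model_specs("diagonal")$model1, tab, list(restarts = 1))
  expect_equal(predict(fit, tab, level = 0),
               drop(design_of(fit$spec, tab)$X %*% fit$beta))
  expect_equal(fitted(fit) + residuals(fit), tab$log_dtmt_time)
  sims <- simulate(fit, nsim = 3, seed = 4)
  expect_equal(dim(sims), c(nrow(tab), 3L))
  expect_equal(simulate(fit, nsim = 2, seed = 9), simulate(fit, nsim = 2, seed = 9))
  s <- summary(fit)
  expect_s3_class(s, "summary.lmm_fit")
  expect_output(print(s), "Marginal R2")
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), fit$n_params)
})
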