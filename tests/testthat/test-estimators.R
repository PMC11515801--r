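test_that("REML variance components match the lme4 oracle", {
  for (seed in c(11, 22)) {
    tr <- small_trial(seed = seed, tau2 = 1 / 9, cell_size = 30)
    vc <- estimate_variance_components(tr)
    d <- tr$data
    d$period <- factor(d$period)
    oracle <- lme4::lmer(outcome ~ 0 + period + treatment + (1 | cluster),
                         data = d, REML = TRUE)
    ovc <- as.data.frame(lme4::VarCorr(oracle))
    expect_equal(vc$tau2, ovc$vcov[1], tolerance = 1e-4)
    expect_equal(vc$sigma2, ovc$vcov[2], tolerance = 1e-6)
    me <- fit_mixed_effects(tr)
    osum <- coef(summary(oracle))["treatment", ]
    expect_equal(me$delta_hat, unname(osum["Estimate"]), tolerance = 1e-6)
    expect_equal(me$se_delta, unname(osum["Std. Error"]), tolerance = 1e-5)
  }
})

test_that("balanced one-way REML equals the ANOVA moment estimator", {
  dat <- balanced_oneway_trial(I = 8, n_per = 12)
  trial <- as_swct_trial(dat)
  est <- icc_first_period(trial) # intercept + random cluster on period 1
  p1 <- dat[dat$period == 1, ]
  av <- anova(lm(outcome ~ factor(cluster), data = p1))
  msb <- av$`Mean Sq`[1]
  msw <- av$`Mean Sq`[2]
  expect_equal(est$sigma2_hat, msw, tolerance = 1e-6)
  expect_equal(est$tau2_hat, (msb - msw) / 12, tolerance = 1e-6)
})

test_that("REML recovers the variance components at many clusters", {
  cfg <- scenario_config(swct_design(50), delta = 0.5, tau2 = 1 / 9,
                         cell_size_shape = 30, seed = 31)
  vc <- estimate_variance_components(simulate_trial(cfg))
  expect_equal(vc$tau2, 1 / 9, tolerance = 0.3)
  expect_equal(vc$sigma2, 1, tolerance = 0.05)
})

test_that("degenerate all-equal outcomes give a flagged boundary fit", {
  d <- swct_design(3)
  dat <- expand.grid(subject = 1:2, period = 1:4, cluster = 1:3)
  dat$treatment <- d$treatment[cbind(dat$cluster, dat$period)]
  dat$covariate <- 0
  dat$outcome <- 1
  vc <- estimate_variance_components(as_swct_trial(dat))
  expect_true(vc$degenerate)
  expect_equal(vc$tau2, 0)
  expect_equal(vc$sigma2, 0)
})

test_that("mixed-effects GLS equals the dense-matrix evaluation", {
  tr <- small_trial(seed = 99, cell_size = 4)
  me <- fit_mixed_effects(tr)
  oracle <- dense_gls(tr, me$tau2_hat, me$sigma2_hat)
  expect_equal(me$delta_hat, oracle$beta[oracle$c_index], tolerance = 1e-9)
  expect_equal(me$var_delta,
               oracle$Phi[oracle$c_index, oracle$c_index], tolerance = 1e-9)
  expect_equal(unname(me$coefficients), oracle$beta, tolerance = 1e-9)
  # covariate-adjusted variant against the same oracle
  tr2 <- small_trial(seed = 103, cell_size = 4,
                     scenario_type = "chance_imbalance", xi = 0.3)
  me2 <- fit_mixed_effects(tr2, adjust_covariate = TRUE)
  o2 <- dense_gls(tr2, me2$tau2_hat, me2$sigma2_hat, adjust_covariate = TRUE)
  expect_equal(me2$delta_hat, o2$beta[o2$c_index], tolerance = 1e-9)
})

test_that("noise-free trials are fitted exactly", {
  cfg <- scenario_config(swct_design(3), delta = 0.5, period_slope = 0.2,
                         tau2 = 0, sigma2_w = 1e-12, cell_size_shape = 10,
                         seed = 41)
  tr <- simulate_trial(cfg)
  expect_equal(fit_mixed_effects(tr)$delta_hat, 0.5, tolerance = 1e-4)
  expect_equal(fit_fixed_effects(tr)$delta_hat, 0.5, tolerance = 1e-6)
})

test_that("fixed-effects OLS equals the pseudo-inverse oracle", {
  tr <- small_trial(seed = 55, cell_size = 6)
  fe <- fit_fixed_effects(tr)
  d <- tr$data
  J <- tr$design$n_periods
  I <- tr$design$n_clusters
  Z <- cbind(outer(d$period, 2:J, `==`) * 1, d$treatment,
             outer(d$cluster, seq_len(I), `==`) * 1)
  beta <- MASS::ginv(crossprod(Z)) %*% crossprod(Z, d$outcome)
  expect_equal(unname(fe$coefficients), as.vector(beta), tolerance = 1e-8)
  s2 <- sum((d$outcome - Z %*% beta)^2) / (nrow(d) - ncol(Z))
  expect_equal(fe$sigma2_hat, s2, tolerance = 1e-8)
  expect_equal(fe$var_delta, s2 * MASS::ginv(crossprod(Z))[J, J],
               tolerance = 1e-8)
})

test_that("fixed-effects estimate is invariant to cluster-level shifts", {
  tr <- small_trial(seed = 56)
  fe1 <- fit_fixed_effects(tr)
  tr$data$outcome[tr$data$cluster == 2] <-
    tr$data$outcome[tr$data$cluster == 2] + 5
  fe2 <- fit_fixed_effects(tr)
  expect_equal(fe2$delta_hat, fe1$delta_hat, tolerance = 1e-9)
  expect_true(is.na(fe2$tau2_hat))
})

test_that("the mixed model interpolates between pooled OLS and the
           within estimator as the plugged-in tau2 varies", {
  tr <- small_trial(seed = 77, cell_size = 8)
  fe <- fit_fixed_effects(tr)
  d <- tr$data
  J <- tr$design$n_periods
  sigma2 <- 1
  # tau2 = 0: GLS reduces to pooled OLS on period dummies + treatment
  g0 <- dense_gls(tr, 0, sigma2)
  Z <- cbind(outer(d$period, seq_len(J), `==`) * 1, d$treatment)
  ols <- qr.solve(Z, d$outcome)
  expect_equal(g0$beta, as.vector(ols), tolerance = 1e-8)
  # tau2 -> large: GLS treatment effect converges to the FE estimate
  deltas <- vapply(c(1, 10, 1e3, 1e6), function(tau2) {
    dense_gls(tr, tau2, sigma2)$beta[J + 1]
  }, 1)
  gaps <- abs(deltas - fe$delta_hat)
  expect_true(all(diff(gaps) <= 1e-8))
  expect_lt(gaps[length(gaps)], 1e-6)
})

test_that("aggregated fitting matches fits on individual-level data", {
  # random small instances: jitter the data so cells are unbalanced
  for (seed in c(201, 202, 203)) {
    tr <- small_trial(seed = seed, n_sequences = 4, cell_size = 5)
    me <- fit_mixed_effects(tr)
    oracle <- dense_gls(tr, me$tau2_hat, me$sigma2_hat)
    expect_equal(me$delta_hat, oracle$beta[oracle$c_index], tolerance = 1e-8)
    expect_equal(me$se_delta,
                 sqrt(oracle$Phi[oracle$c_index, oracle$c_index]),
                 tolerance = 1e-8)
  }
})

test_that("rank-deficient fits raise informative errors", {
  tr <- small_trial(seed = 61)
  tr$data$covariate <- 0
  tr$covariate <- rep(0, 3)
  expect_error(fit_mixed_effects(tr, adjust_covariate = TRUE),
               "covariate.*constant", ignore.case = TRUE)
  expect_error(estimate_variance_components(tr, adjust_covariate = TRUE),
               "covariate")
  # single-period data: treatment is confounded with the cluster dummies
  one <- tr$data[tr$data$period == 2, ]
  one$period <- 1
  expect_error(fit_fixed_effects(as_swct_trial(one)), "collinear")
})

test_that("satterthwaite df reduces to n - 1 for a one-sample mean", {
  # classical reduction asserted on the df kernel: v = sigma2/n with
  # gradient 1/n over sigma2, and Var(sigma2_hat) = 2 sigma4/(n - 1)
  for (n in c(5, 20)) {
    sigma2 <- 1.7
    df <- swctsim:::satterthwaite_df_core(
      var_c = sigma2 / n, grad = 1 / n,
      vcov_vc = matrix(2 * sigma2^2 / (n - 1))
    )
    expect_equal(df, n - 1, tolerance = 1e-12)
  }
})

test_that("satterthwaite df agrees with the lmerTest oracle", {
  for (seed in c(11, 33)) {
    tr <- small_trial(seed = seed, tau2 = 1 / 9, cell_size = 30)
    me <- fit_mixed_effects(tr)
    df <- satterthwaite_df(me)
    d <- tr$data
    d$period <- factor(d$period)
    oracle <- lmerTest::lmer(outcome ~ 0 + period + treatment + (1 | cluster),
                             data = d, REML = TRUE)
    odf <- coef(summary(oracle))["treatment", "df"]
    # expected vs finite-difference observed information: close, not equal
    expect_equal(df, odf, tolerance = 0.05)
  }
})

test_that("satterthwaite df grows with the number of clusters", {
  df3 <- mean(vapply(1:10, function(r) {
    satterthwaite_df(fit_mixed_effects(
      small_trial(seed = derive_seed(500, r), n_sequences = 3,
                  tau2 = 1 / 4, cell_size = 30)))
  }, 1))
  df6 <- mean(vapply(1:10, function(r) {
    satterthwaite_df(fit_mixed_effects(
      small_trial(seed = derive_seed(500, r), n_sequences = 6,
                  tau2 = 1 / 4, cell_size = 30)))
  }, 1))
  expect_gt(df6, df3)
})

test_that("satterthwaite and kenward-roger refuse non-mixed fits", {
  fe <- fit_fixed_effects(small_trial(seed = 71))
  expect_error(satterthwaite_df(fe), "mixed-effects fits only")
  expect_error(kenward_roger_adjust(fe), "mixed-effects fits only")
})

test_that("kenward-roger with known variance components changes nothing", {
  me <- fit_mixed_effects(small_trial(seed = 81))
  adj <- kenward_roger_adjust(me, vc_cov = matrix(0, 2, 2))
  expect_equal(adj$kr_se, me$se_delta, tolerance = 1e-12)
})

test_that("kenward-roger never deflates the standard error", {
  for (r in 1:100) {
    tr <- small_trial(seed = derive_seed(900, r),
                      n_sequences = sample(3:5, 1),
                      tau2 = sample(c(1 / 99, 1 / 19, 1 / 9, 1 / 4), 1),
                      cell_size = sample(c(5, 10, 30), 1))
    me <- kenward_roger_adjust(fit_mixed_effects(tr))
    expect_gte(me$kr_se, me$se_delta * (1 - 1e-10))
  }
})

test_that("wald intervals follow the chosen reference distribution", {
  fit <- structure(
    list(model_label = "ME", delta_hat = 0.5, se_delta = 0.1,
         var_delta = 0.01, satterthwaite_df = NULL, kr_se = NULL),
    class = "swct_fit"
  )
  ci <- wald_interval(fit, level = 0.95, df_policy = "normal")
  expect_equal(ci$lower, 0.5 - 1.959964 * 0.1, tolerance = 1e-6)
  expect_equal(ci$upper, 0.5 + 1.959964 * 0.1, tolerance = 1e-6)
  expect_true(ci$reject_null)
  # null estimate never rejects
  fit0 <- fit
  fit0$delta_hat <- 0
  ci0 <- wald_interval(fit0, df_policy = "normal")
  expect_false(ci0$reject_null)
  expect_true(ci0$lower < 0 && ci0$upper > 0)
  # t with huge df reproduces the normal interval
  fit$satterthwaite_df <- 1e9
  cit <- wald_interval(fit, df_policy = "satterthwaite")
  expect_equal(cit$lower, ci$lower, tolerance = 1e-6)
  expect_error(wald_interval(fit, df_policy = "kenward_roger"),
               "Kenward-Roger")
  expect_error(wald_interval(fit, level = 1.2), "level")
})

test_that("hausman statistic follows the printed scalar form", {
  fe <- structure(list(model_label = "FE", delta_hat = 0.6, var_delta = 0.02,
                       n_obs = 100, n_clusters = 3), class = "swct_fit")
  me <- structure(list(model_label = "ME", delta_hat = 0.5, var_delta = 0.01,
                       n_obs = 100, n_clusters = 3), class = "swct_fit")
  h <- hausman_test(fe, me)
  expect_equal(h$statistic, 1.0)
  expect_equal(h$p_value, pchisq(1, 1, lower.tail = FALSE))
  me$delta_hat <- 0.6
  h0 <- hausman_test(fe, me)
  expect_equal(h0$statistic, 0)
  expect_equal(h0$p_value, 1)
  # non-positive variance difference: flagged non-result
  me$var_delta <- 0.03
  hbad <- hausman_test(fe, me)
  expect_false(hbad$valid)
  expect_true(is.na(hbad$statistic))
  me$n_obs <- 99
  expect_error(hausman_test(fe, me), "same trial")
})

test_that("mixed-model precision dominates FE precision absent confounding", {
  # matched replicates, no confounding: average var(ME) <= average var(FE)
  cfg <- scenario_config(swct_design(4), delta = 0.5, tau2 = 1 / 19,
                         cell_size_shape = 30, seed = 1001)
  vars <- t(vapply(1:50, function(r) {
    cfg$seed <- derive_seed(1001, r)
    tr <- simulate_trial(cfg)
    c(me = fit_mixed_effects(tr)$var_delta,
      fe = fit_fixed_effects(tr)$var_delta)
  }, c(me = 1, fe = 1)))
  expect_lte(mean(vars[, "me"]), mean(vars[, "fe"]))
})
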