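# Shared fixture builders for the test suite. All fixtures are generated in
# code under fixed seeds.

# A small simulated trial for estimator tests.
small_trial <- function(seed = 101, n_sequences = 3, delta = 0.5,
                        tau2 = 1 / 9, cell_size = 10,
                        scenario_type = "none", xi = 0) {
  cfg <- scenario_config(
    swct_design(n_sequences), delta = delta, xi = xi, tau2 = tau2,
    cell_size_shape = cell_size, scenario_type = scenario_type, seed = seed
  )
  simulate_trial(cfg)
}

# A balanced one-way layout (single period, equal cluster sizes) expressed
# as a trial table, for the ANOVA variance-component oracle.
balanced_oneway_trial <- function(I = 8, n_per = 12, tau2 = 0.5,
                                  sigma2 = 1, seed = 5) {
  set.seed(seed)
  alpha <- rnorm(I, 0, sqrt(tau2))
  dat <- data.frame(
    cluster = rep(seq_len(I), each = 2 * n_per),
    period = rep(rep(1:2, each = n_per), times = I),
    subject = rep(seq_len(n_per), times = 2 * I),
    covariate = 0
  )
  # make period 1 the balanced layout of interest; period 2 exists only so
  # the staircase validator is satisfied when needed
  dat$treatment <- as.integer(dat$period == 2)
  dat$outcome <- alpha[dat$cluster] + rnorm(nrow(dat), 0, sqrt(sigma2))
  dat
}

# Dense-matrix GLS evaluation of the mixed model at given variance
# components: the individual-level oracle.
dense_gls <- function(trial, tau2, sigma2, adjust_covariate = FALSE) {
  d <- trial$data
  J <- trial$design$n_periods
  Z <- cbind(outer(d$period, seq_len(J), `==`) * 1, d$treatment)
  if (adjust_covariate) Z <- cbind(Z, d$covariate)
  V <- matrix(0, nrow(d), nrow(d))
  for (i in seq_len(trial$design$n_clusters)) {
    idx <- which(d$cluster == i)
    V[idx, idx] <- tau2
  }
  diag(V) <- diag(V) + sigma2
  Vi <- solve(V)
  Phi <- solve(t(Z) %*% Vi %*% Z)
  beta <- Phi %*% t(Z) %*% Vi %*% d$outcome
  list(beta = as.vector(beta), Phi = Phi, c_index = J + 1L)
}
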