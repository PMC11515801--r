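# Restricted-maximum-likelihood engine for the random-intercept model on
# cluster-period cell statistics.
#
# All model fitting in this package runs on sufficient statistics of the
# cluster-period cells rather than on individual rows. With an exchangeable
# within-cluster covariance V_i = sigma2 * I + tau2 * J and fixed-effect
# covariates that are constant within a cell, every quantity needed for
# GLS, the REML criterion, the expected information of the variance
# components, and the Kenward-Roger adjustment reduces to per-cluster
# combinations of cell sizes n_ij, cell means, within-cell sums of squares,
# and the weighted cell-level design matrix. Writing
# V_i^{-1} = a I - b J with a = 1/sigma2, b = tau2 / (sigma2 (sigma2 + m tau2))
# (m = cluster total size) and d = a - b m = 1/(sigma2 + m tau2), powers of
# V_i^{-1} have the spectral form a^k I - c_k J with
# c_k = (a^k - d^k)/m, which is what the helpers below exploit.

# Aggregate a long trial table into cluster-period cell statistics.
# Returns a data frame ordered by (cluster, period) with empty cells dropped.
cell_stats <- function(dat) {
  J <- max(dat$period)
  key <- (dat$cluster - 1L) * J + dat$period
  n <- tabulate(key, nbins = max(key))
  keep <- which(n > 0L)
  sumy <- rowsum(dat$outcome, key)[, 1]
  sumy2 <- rowsum(dat$outcome^2, key)[, 1]
  idx <- match(keep, sort(unique(key)))
  cluster <- (keep - 1L) %/% J + 1L
  period <- (keep - 1L) %% J + 1L
  ybar <- sumy[idx] / n[keep]
  treatment <- rowsum(dat$treatment, key)[idx, 1] / n[keep]
  covariate <- rowsum(dat$covariate, key)[idx, 1] / n[keep]
  data.frame(
    cluster = cluster, period = period, n = n[keep], ybar = ybar,
    ssw = sumy2[idx] - n[keep] * ybar^2,
    treatment = treatment, covariate = covariate
  )
}

# Per-cluster arrays used by the REML criterion and the variance-component
# information: S (q x I matrix of weighted covariate sums s_i), the global
# X'WX and X'W ybar, cluster sizes m_i, cluster outcome totals T_i, and
# per-cluster raw sums of squares yy_i = ssw_i + sum_j n_ij ybar_ij^2.
me_ingredients <- function(cells, X) {
  cl <- factor(cells$cluster)
  n <- cells$n
  Xn <- X * n
  S <- t(rowsum(Xn, cl))
  m <- as.vector(rowsum(n, cl))
  Tt <- as.vector(rowsum(n * cells$ybar, cl))
  yy <- as.vector(rowsum(cells$ssw + n * cells$ybar^2, cl))
  list(
    X = X, S = S, m = m, T = Tt, yy = yy,
    XtWX = crossprod(X, Xn),
    XtWy = crossprod(X, n * cells$ybar),
    N = sum(n), q = ncol(X), I = nlevels(cl),
    ssw_total = sum(cells$ssw)
  )
}

# Profiled -2 * restricted log-likelihood (up to a constant) at variance
# ratio lambda = tau2/sigma2, together with the GLS pieces at that lambda.
reml_pieces <- function(ing, lambda) {
  b <- lambda / (1 + ing$m * lambda)
  G <- ing$XtWX - ing$S %*% (b * t(ing$S))
  R <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  r <- ing$XtWy - ing$S %*% (b * ing$T)
  beta <- backsolve(R, backsolve(R, r, transpose = TRUE))
  yPy <- sum(ing$yy) - sum(b * ing$T^2) - sum(r * beta)
  list(G = G, chol = R, beta = as.vector(beta), yPy = max(yPy, 0),
       logdetG = 2 * sum(log(diag(R))),
       logdetSigma = sum(log(1 + ing$m * lambda)))
}

reml_objective <- function(ing, lambda) {
  p <- reml_pieces(ing, lambda)
  if (is.null(p)) return(Inf)
  df <- ing$N - ing$q
  if (p$yPy <= 0) return(-.Machine$double.xmax) # degenerate: perfect fit
  df * log(p$yPy) + p$logdetSigma + p$logdetG
}

# REML fit of the random-intercept model on cell statistics. The profiled
# criterion is one-dimensional in lambda = tau2/sigma2; it is minimised by
# golden-section/Brent search on log(lambda) and compared against the
# tau2 = 0 boundary, which is where the estimate is truncated.
reml_fit <- function(cells, X) {
  ing <- me_ingredients(cells, X)
  if (ing$N <= ing$q) {
    stop("not enough observations to estimate variance components",
         call. = FALSE)
  }
  f0 <- reml_objective(ing, 0)
  opt <- stats::optimize(function(u) reml_objective(ing, exp(u)),
                         interval = c(-13, 13), tol = 1e-9)
  if (is.finite(f0) || is.finite(opt$objective)) {
    lambda <- if (opt$objective < f0) exp(opt$minimum) else 0
  } else {
    lambda <- 0
  }
  p <- reml_pieces(ing, lambda)
  if (is.null(p)) {
    stop("singular fixed-effects design in mixed-model fit", call. = FALSE)
  }
  df <- ing$N - ing$q
  sigma2 <- p$yPy / df
  degenerate <- sigma2 <= 1e-10 * max(1, mean(abs(ing$yy)) / max(ing$N, 1))
  if (degenerate) {
    return(list(ing = ing, lambda = 0, tau2 = 0, sigma2 = 0,
                beta = p$beta, Phi = NULL, degenerate = TRUE,
                m2logREML = NA_real_))
  }
  Phi <- sigma2 * chol2inv(p$chol)
  list(
    ing = ing, lambda = lambda, tau2 = lambda * sigma2, sigma2 = sigma2,
    beta = p$beta, Phi = Phi, degenerate = FALSE,
    m2logREML = df * log(sigma2) + p$logdetSigma + p$logdetG + df
  )
}

# Expected-information machinery for the variance components (tau2, sigma2)
# and the derived small-sample quantities for a scalar contrast c (given by
# its column index): the Satterthwaite denominator df
# df = 2 v^2 / Var(v_hat), with Var(v_hat) from the delta method over the
# inverse expected REML information, and the Kenward-Roger first-order
# adjusted covariance of the fixed effects. The covariance is linear in
# (tau2, sigma2), so the second-derivative term of the Kenward-Roger
# expansion vanishes. For a rank-1 contrast the Kenward-Roger denominator
# df collapses algebraically to the Satterthwaite df and the F scale factor
# is exactly 1 (see the methods vignette), so the adjustment acts through
# the inflated standard error.
vc_small_sample <- function(ing, tau2, sigma2, c_index, vc_cov = NULL) {
  a <- 1 / sigma2
  m <- ing$m
  d <- 1 / (sigma2 + m * tau2)
  S <- ing$S
  c2 <- (a^2 - d^2) / m
  c3 <- (a^3 - d^3) / m

  G <- a * ing$XtWX - S %*% ((a - d) / m * t(S))
  Phi <- solve(G)
  Pt <- S %*% (d^2 * t(S))
  Ps <- a^2 * ing$XtWX - S %*% (c2 * t(S))
  Qtt <- S %*% (d^3 * m * t(S))
  Qts <- S %*% (d^3 * t(S))
  Qss <- a^3 * ing$XtWX - S %*% (c3 * t(S))

  if (is.null(vc_cov)) {
    tr_tt <- sum(d^2 * m^2)
    tr_ts <- sum(d^2 * m)
    tr_ss <- sum((m - 1) * a^2 + d^2)
    trPP <- function(tr_vv, Qrs, Pr, Ps_) {
      tr_vv - 2 * sum(Phi * t(Qrs)) + sum((Phi %*% Pr) * t(Phi %*% Ps_))
    }
    info <- matrix(c(
      trPP(tr_tt, Qtt, Pt, Pt), trPP(tr_ts, Qts, Pt, Ps),
      trPP(tr_ts, Qts, Pt, Ps), trPP(tr_ss, Qss, Ps, Ps)
    ), 2, 2) / 2
    vc_cov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, 2, 2))
  }

  v <- Phi[c_index, c_index]
  grad <- c(
    (Phi %*% Pt %*% Phi)[c_index, c_index],
    (Phi %*% Ps %*% Phi)[c_index, c_index]
  )
  var_v <- as.numeric(t(grad) %*% vc_cov %*% grad)
  satt_df <- if (is.finite(var_v) && var_v > 0) 2 * v^2 / var_v else Inf

  # Kenward-Roger adjusted covariance (linear covariance structure)
  W <- vc_cov
  Lambda <- W[1, 1] * (Qtt - Pt %*% Phi %*% Pt) +
    W[1, 2] * (Qts - Pt %*% Phi %*% Ps) +
    W[2, 1] * (t(Qts) - Ps %*% Phi %*% Pt) +
    W[2, 2] * (Qss - Ps %*% Phi %*% Ps)
  PhiA <- if (all(is.finite(Lambda))) Phi + 2 * (Phi %*% Lambda %*% Phi) else Phi

  list(
    var_delta = v, grad = grad, vc_cov = vc_cov, satt_df = satt_df,
    kr_var = PhiA[c_index, c_index], kr_df = satt_df, PhiA = PhiA
  )
}

# Satterthwaite denominator degrees of freedom from its ingredients:
# a contrast variance, its gradient with respect to the variance
# components, and the covariance of the variance-component estimates.
satterthwaite_df_core <- function(var_c, grad, vcov_vc) {
  var_v <- as.numeric(t(grad) %*% vcov_vc %*% grad)
  if (!is.finite(var_v) || var_v <= 0) return(Inf)
  2 * var_c^2 / var_v
}
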