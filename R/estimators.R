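# Treatment-effect estimators: the Hussey-Hughes mixed-effects model
# (REML variance components + block-exchangeable GLS), the within-cluster
# fixed-effects model (OLS), small-sample corrections, Wald intervals, and
# the Hausman specification test.

trial_data <- function(trial) {
  if (inherits(trial, "swct_trial")) return(trial)
  if (is.data.frame(trial)) return(as_swct_trial(trial))
  stop("`trial` must be an `swct_trial` or a long-format data frame",
       call. = FALSE)
}

# Cell-level design matrix for the mixed-effects model: one dummy per
# period (no global intercept) plus the treatment indicator, optionally the
# cluster-level covariate.
build_X_me <- function(cells, J, adjust_covariate) {
  P <- outer(cells$period, seq_len(J), `==`) * 1
  colnames(P) <- paste0("period_", seq_len(J))
  X <- cbind(P, treatment = cells$treatment)
  if (adjust_covariate) X <- cbind(X, covariate = cells$covariate)
  X
}

# Cell-level design matrix for the fixed-effects model: period dummies for
# periods 2..J, the treatment indicator, and one dummy per cluster (no
# global intercept).
build_X_fe <- function(cells, I, J) {
  Cl <- outer(cells$cluster, seq_len(I), `==`) * 1
  colnames(Cl) <- paste0("cluster_", seq_len(I))
  if (J < 2L) return(cbind(treatment = cells$treatment, Cl))
  P <- outer(cells$period, 2:J, `==`) * 1
  colnames(P) <- paste0("period_", 2:J)
  cbind(P, treatment = cells$treatment, Cl)
}

new_swct_fit <- function(model_label, delta_hat, var_delta, tau2_hat,
                         sigma2_hat, xi_hat, coefficients, n_obs, n_clusters,
                         n_periods, degenerate = FALSE, internal = NULL) {
  structure(
    list(
      model_label = model_label, delta_hat = delta_hat,
      se_delta = sqrt(var_delta), var_delta = var_delta,
      tau2_hat = tau2_hat, sigma2_hat = sigma2_hat, xi_hat = xi_hat,
      coefficients = coefficients, satterthwaite_df = NULL, kr_df = NULL,
      kr_se = NULL, n_obs = n_obs, n_clusters = n_clusters,
      n_periods = n_periods, degenerate = degenerate, internal = internal
    ),
    class = "swct_fit"
  )
}

#' @export
print.swct_fit <- function(x, ...) {
  cat(sprintf("%s fit: delta_hat = %.4f (SE %.4f)\n",
              x$model_label, x$delta_hat, x$se_delta))
  if (!is.na(x$tau2_hat)) {
    cat(sprintf("  variance components: tau2 = %.5f, sigma2 = %.5f\n",
                x$tau2_hat, x$sigma2_hat))
  } else {
    cat(sprintf("  residual variance: sigma2 = %.5f\n", x$sigma2_hat))
  }
  if (!is.null(x$kr_se)) {
    cat(sprintf("  Kenward-Roger: SE %.4f, df %.2f\n", x$kr_se, x$kr_df))
  }
  if (!is.null(x$satterthwaite_df)) {
    cat(sprintf("  Satterthwaite df: %.2f\n", x$satterthwaite_df))
  }
  invisible(x)
}

check_covariate_estimable <- function(trial) {
  if (length(unique(trial$covariate)) < 2L) {
    stop(paste0(
      "rank deficiency: cluster-level covariate `covariate` is constant ",
      "across clusters and collinear with the period effects"
    ), call. = FALSE)
  }
}

#' Estimate the variance components of the random-intercept model
#'
#' REML estimates of the between-cluster variance `tau2` and residual
#' variance `sigma2` for the mixed-effects working model with period fixed
#' effects, the treatment indicator and (optionally) the cluster-level
#' covariate. The `tau2` estimate is truncated at zero at the boundary.
#'
#' @param trial An `swct_trial` or long-format data frame.
#' @param adjust_covariate Include the cluster-level covariate among the
#'   fixed effects?
#' @return A list with `tau2`, `sigma2` and a `degenerate` flag (`TRUE` when
#'   the fit is on the all-zero-residual boundary, in which case both
#'   components are reported as 0).
#' @export
estimate_variance_components <- function(trial, adjust_covariate = FALSE) {
  trial <- trial_data(trial)
  if (trial$design$n_clusters < 2L) {
    stop("at least 2 clusters are required", call. = FALSE)
  }
  if (adjust_covariate) check_covariate_estimable(trial)
  cells <- cell_stats(trial$data)
  X <- build_X_me(cells, trial$design$n_periods, adjust_covariate)
  fit <- reml_fit(cells, X)
  list(tau2 = fit$tau2, sigma2 = fit$sigma2, degenerate = fit$degenerate)
}

#' Fit the mixed-effects (Hussey-Hughes) model
#'
#' Estimates the variance components by REML, plugs them into the
#' block-exchangeable covariance `V` and solves the generalized
#' least-squares equations `(Z'V^-1 Z)^-1 Z'V^-1 Y` for the period effects,
#' the treatment effect and (optionally) the covariate effect. The
#' computation runs on cluster-period cell statistics and never forms a
#' dense N-by-N covariance; the treatment-effect variance is the
#' corresponding diagonal entry of `(Z'V^-1 Z)^-1`.
#'
#' @inheritParams estimate_variance_components
#' @return An `swct_fit` with `model_label` `"ME"` or `"ME_adj"`.
#' @seealso [satterthwaite_df()], [kenward_roger_adjust()], [wald_interval()]
#' @export
fit_mixed_effects <- function(trial, adjust_covariate = FALSE) {
  trial <- trial_data(trial)
  if (adjust_covariate) check_covariate_estimable(trial)
  J <- trial$design$n_periods
  cells <- cell_stats(trial$data)
  X <- build_X_me(cells, J, adjust_covariate)
  fit <- reml_fit(cells, X)
  beta <- fit$beta
  names(beta) <- colnames(X)
  c_index <- J + 1L
  if (fit$degenerate) {
    return(new_swct_fit(
      model_label = if (adjust_covariate) "ME_adj" else "ME",
      delta_hat = beta[["treatment"]], var_delta = NaN, tau2_hat = 0,
      sigma2_hat = 0,
      xi_hat = if (adjust_covariate) beta[["covariate"]] else NA_real_,
      coefficients = beta, n_obs = fit$ing$N,
      n_clusters = trial$design$n_clusters, n_periods = J,
      degenerate = TRUE,
      internal = list(ing = fit$ing, c_index = c_index)
    ))
  }
  new_swct_fit(
    model_label = if (adjust_covariate) "ME_adj" else "ME",
    delta_hat = beta[["treatment"]],
    var_delta = fit$Phi[c_index, c_index],
    tau2_hat = fit$tau2, sigma2_hat = fit$sigma2,
    xi_hat = if (adjust_covariate) beta[["covariate"]] else NA_real_,
    coefficients = beta, n_obs = fit$ing$N,
    n_clusters = trial$design$n_clusters, n_periods = J,
    internal = list(ing = fit$ing, c_index = c_index)
  )
}

#' Fit the fixed-effects (within-cluster) model
#'
#' Ordinary least squares with period dummies for periods 2..J, the
#' treatment indicator and one fixed dummy per cluster (no global
#' intercept). The cluster dummies absorb every time-invariant cluster-level
#' covariate, measured or not. The residual variance uses the unbiased
#' denominator `N - (I + J)` (the column count of the design), and the
#' treatment-effect variance is the corresponding diagonal entry of
#' `sigma2_hat * (Z'Z)^-1`. Fitting is performed on cluster-period means
#' weighted by cell sizes, which reproduces the individual-level OLS fit
#' exactly.
#'
#' @inheritParams estimate_variance_components
#' @return An `swct_fit` with `model_label` `"FE"` and `tau2_hat = NA` (the
#'   between-cluster variance is absorbed, not estimated).
#' @export
fit_fixed_effects <- function(trial) {
  trial <- trial_data(trial)
  I <- trial$design$n_clusters
  J <- trial$design$n_periods
  cells <- cell_stats(trial$data)
  if (length(unique(cells$cluster)) < I) {
    stop("every cluster needs at least one observation", call. = FALSE)
  }
  X <- build_X_fe(cells, I, J)
  n <- cells$n
  XtWX <- crossprod(X, X * n)
  R <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(R)) {
    stop(paste0(
      "rank deficiency: treatment column is collinear with the cluster and ",
      "period dummies for this design"
    ), call. = FALSE)
  }
  beta <- backsolve(R, backsolve(R, crossprod(X, n * cells$ybar),
                                 transpose = TRUE))[, 1]
  names(beta) <- colnames(X)
  resid_cells <- cells$ybar - as.vector(X %*% beta)
  N <- sum(n)
  rss <- sum(cells$ssw) + sum(n * resid_cells^2)
  dfree <- N - ncol(X)
  sigma2 <- rss / dfree
  XtWXinv <- chol2inv(R)
  c_index <- which(colnames(X) == "treatment")
  new_swct_fit(
    model_label = "FE", delta_hat = beta[["treatment"]],
    var_delta = sigma2 * XtWXinv[c_index, c_index],
    tau2_hat = NA_real_, sigma2_hat = sigma2, xi_hat = NA_real_,
    coefficients = beta, n_obs = N, n_clusters = I, n_periods = J,
    internal = list(df_residual = dfree)
  )
}

small_sample_pieces <- function(fit, vc_cov = NULL) {
  if (!fit$model_label %in% c("ME", "ME_adj")) {
    stop("small-sample corrections apply to mixed-effects fits only",
         call. = FALSE)
  }
  if (is.null(fit$internal$ing)) {
    stop("fit does not carry REML machinery", call. = FALSE)
  }
  sigma2 <- if (fit$degenerate) NA_real_ else fit$sigma2_hat
  if (fit$degenerate || !is.finite(sigma2) || sigma2 <= 0) {
    # boundary fit: adjustment evaluated at a floor residual variance
    sigma2 <- max(fit$sigma2_hat, .Machine$double.eps)
  }
  vc_small_sample(fit$internal$ing, fit$tau2_hat, sigma2,
                  fit$internal$c_index, vc_cov = vc_cov)
}

#' Satterthwaite degrees of freedom for the treatment effect
#'
#' Approximate denominator degrees of freedom for the Wald t-test of the
#' treatment effect in a mixed-effects fit:
#' `df = 2 v^2 / Var(v_hat)`, where `v` is the estimated variance of the
#' treatment-effect estimator and `Var(v_hat)` is obtained by the delta
#' method over the inverse expected REML information of
#' `(tau2, sigma2)`.
#'
#' @param fit An `swct_fit` from [fit_mixed_effects()].
#' @return The approximate degrees of freedom (a positive scalar).
#' @export
satterthwaite_df <- function(fit) {
  small_sample_pieces(fit)$satt_df
}

#' Kenward-Roger adjustment for the treatment effect
#'
#' First-order Kenward-Roger adjusted covariance of the fixed effects
#' (the covariance is linear in the variance components, so the
#' second-derivative term vanishes) and the matching denominator degrees of
#' freedom for the scalar treatment contrast. For a rank-1 contrast the
#' Kenward-Roger degrees of freedom coincide with the Satterthwaite value
#' and the F scale factor is exactly 1, so the correction acts through the
#' inflated standard error `kr_se >= se_delta`.
#'
#' @param fit An `swct_fit` from [fit_mixed_effects()].
#' @param vc_cov Optional 2x2 covariance matrix of `(tau2_hat, sigma2_hat)`
#'   overriding the inverse expected information (a zero matrix reproduces
#'   the unadjusted fit; used to represent known variance components).
#' @return The fit augmented with `kr_se`, `kr_df` and `satterthwaite_df`.
#' @export
kenward_roger_adjust <- function(fit, vc_cov = NULL) {
  ss <- small_sample_pieces(fit, vc_cov = vc_cov)
  fit$satterthwaite_df <- ss$satt_df
  fit$kr_df <- ss$kr_df
  fit$kr_se <- sqrt(ss$kr_var)
  fit
}

#' Wald confidence interval and test for the treatment effect
#'
#' Builds `delta_hat +/- q * SE` with `q` the standard-normal quantile
#' (policy `"normal"`, the uncorrected approach) or the t quantile at the
#' Satterthwaite or Kenward-Roger degrees of freedom; under
#' `"kenward_roger"` the adjusted standard error is used. Reports whether
#' the interval excludes 0 (the test of no treatment effect) and, when
#' `true_delta` is supplied, whether it covers the true effect.
#'
#' @param fit An `swct_fit`; for the t policies it must carry the
#'   corresponding degrees of freedom (see [kenward_roger_adjust()]).
#' @param level Confidence level in (0, 1).
#' @param df_policy One of `"normal"`, `"satterthwaite"`, `"kenward_roger"`.
#' @param true_delta Optional true effect for coverage bookkeeping.
#' @return A list with `lower`, `upper`, `reject_null`, `covers` (`NA` if
#'   `true_delta` is missing), `se`, `df`.
#' @export
wald_interval <- function(fit, level = 0.95, df_policy = "normal",
                          true_delta = NULL) {
  stopifnot(level > 0, level < 1)
  df_policy <- match.arg(df_policy,
                         c("normal", "satterthwaite", "kenward_roger"))
  alpha <- 1 - level
  if (df_policy == "normal") {
    se <- fit$se_delta
    df <- Inf
    q <- stats::qnorm(1 - alpha / 2)
  } else if (df_policy == "satterthwaite") {
    df <- fit$satterthwaite_df
    if (is.null(df)) {
      stop("no Satterthwaite df on this fit; run kenward_roger_adjust() or ",
           "satterthwaite_df() first", call. = FALSE)
    }
    se <- fit$se_delta
    q <- stats::qt(1 - alpha / 2, df)
  } else {
    if (is.null(fit$kr_se)) {
      stop("no Kenward-Roger adjustment on this fit; run ",
           "kenward_roger_adjust() first", call. = FALSE)
    }
    se <- fit$kr_se
    df <- fit$kr_df
    q <- stats::qt(1 - alpha / 2, df)
  }
  lower <- fit$delta_hat - q * se
  upper <- fit$delta_hat + q * se
  list(
    lower = lower, upper = upper,
    reject_null = (lower > 0) || (upper < 0),
    covers = if (is.null(true_delta)) NA else
      (lower <= true_delta && true_delta <= upper),
    se = se, df = df
  )
}

#' Hausman specification test on the treatment effect
#'
#' Scalar Hausman statistic comparing the fixed-effects (consistent under
#' cluster-level confounding) and mixed-effects (efficient under no
#' confounding) estimates:
#' `H = (delta_FE - delta_ME)^2 / (var_FE - var_ME)`, referred to a
#' chi-squared distribution with 1 degree of freedom. When the variance
#' difference is not positive the statistic is undefined and returned as
#' `NA` with `valid = FALSE` rather than truncated.
#'
#' @param fe An `swct_fit` with `model_label` `"FE"`.
#' @param me An `swct_fit` with `model_label` `"ME"` or `"ME_adj"`.
#' @return A list with `statistic`, `p_value`, `valid`.
#' @export
hausman_test <- function(fe, me) {
  stopifnot(inherits(fe, "swct_fit"), inherits(me, "swct_fit"))
  if (fe$model_label != "FE" || !me$model_label %in% c("ME", "ME_adj")) {
    stop("`fe` must be a fixed-effects fit and `me` a mixed-effects fit",
         call. = FALSE)
  }
  if (fe$n_obs != me$n_obs || fe$n_clusters != me$n_clusters) {
    stop("fits must come from the same trial", call. = FALSE)
  }
  dvar <- fe$var_delta - me$var_delta
  if (!is.finite(dvar) || dvar <= 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, valid = FALSE))
  }
  H <- (fe$delta_hat - me$delta_hat)^2 / dvar
  list(statistic = H, p_value = stats::pchisq(H, df = 1, lower.tail = FALSE),
       valid = TRUE)
}
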