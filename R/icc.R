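# Separate-step estimation of the intracluster correlation coefficient,
# usable alongside a fixed-effects treatment-effect analysis (which absorbs
# the between-cluster variance and so does not estimate the ICC itself).

#' Intracluster correlation from variance components
#'
#' `ICC = tau2 / (tau2 + sigma2)`: the correlation between the outcomes of
#' two individuals in the same cluster under an exchangeable structure.
#'
#' @param tau2 Between-cluster variance (non-negative).
#' @param sigma2 Within-cluster residual variance (positive).
#' @return The ICC, a value in `[0, 1)`.
#' @examples
#' icc_from_components(1 / 4, 1) # 0.2
#' @export
icc_from_components <- function(tau2, sigma2) {
  if (!is.numeric(sigma2) || any(sigma2 <= 0)) {
    stop("`sigma2` must be positive", call. = FALSE)
  }
  if (!is.numeric(tau2) || any(tau2 < 0)) {
    stop("`tau2` must be non-negative", call. = FALSE)
  }
  tau2 / (tau2 + sigma2)
}

new_icc_estimate <- function(method, fit, fixed_effects) {
  sigma2 <- fit$sigma2
  icc <- if (sigma2 > 0) icc_from_components(fit$tau2, sigma2) else 0
  structure(
    list(method = method, tau2_hat = fit$tau2, sigma2_hat = sigma2,
         icc = icc, fixed_effects = fixed_effects,
         degenerate = fit$degenerate),
    class = "swct_icc"
  )
}

#' @export
print.swct_icc <- function(x, ...) {
  cat(sprintf("ICC estimate (%s): %.4f  [tau2 = %.5f, sigma2 = %.5f]\n",
              x$method, x$icc, x$tau2_hat, x$sigma2_hat))
  invisible(x)
}

icc_subset_fit <- function(trial, periods, method) {
  trial <- trial_data(trial)
  dat <- trial$data[trial$data$period %in% periods, , drop = FALSE]
  if (length(unique(dat$cluster)) < 2L) {
    stop("need observations from at least 2 clusters in the selected periods",
         call. = FALSE)
  }
  cells <- cell_stats(dat)
  X <- if (length(periods) == 1L) {
    matrix(1, nrow = nrow(cells), ncol = 1, dimnames = list(NULL, "mu"))
  } else {
    P <- outer(cells$period, sort(unique(cells$period)), `==`) * 1
    colnames(P) <- paste0("period_", sort(unique(cells$period)))
    P
  }
  fit <- reml_fit(cells, X)
  beta <- fit$beta
  names(beta) <- colnames(X)
  new_icc_estimate(method, fit, beta)
}

#' Estimate the ICC from the unexposed first period only
#'
#' Fits the random-effects model `Y_i1k = mu + alpha_i + e_i1k` by REML on
#' the period-1 data alone (all clusters are untreated in period 1, so no
#' treatment or period terms are needed) and returns
#' `tau2 / (tau2 + sigma2)`.
#'
#' @param trial An `swct_trial` or long-format data frame.
#' @return An `swct_icc` object with fields `method`, `tau2_hat`,
#'   `sigma2_hat`, `icc` and the estimated fixed effects.
#' @export
icc_first_period <- function(trial) {
  icc_subset_fit(trial, periods = 1L, method = "first_period")
}

#' Estimate the ICC from the first and final periods
#'
#' Fits a mixed-effects model with two period fixed effects and a cluster
#' random intercept on the unexposed first period and the always-exposed
#' final period. No treatment term is included: because every cluster is
#' treated in the final period, a constant treatment effect is absorbed by
#' the final-period fixed effect (this implicitly assumes the treatment
#' effect is constant within the final period).
#'
#' @inheritParams icc_first_period
#' @return An `swct_icc` object.
#' @export
icc_first_last <- function(trial) {
  trial <- trial_data(trial)
  icc_subset_fit(trial, periods = c(1L, trial$design$n_periods),
                 method = "first_last")
}

#' Estimate the ICC from the full mixed-effects model
#'
#' Uses the REML variance components of the full Hussey-Hughes model
#' (period fixed effects plus treatment) on all trial data. This uses the
#' most information and has the lowest Monte Carlo standard error of the
#' three separate-step approaches.
#'
#' @inheritParams icc_first_period
#' @return An `swct_icc` object.
#' @export
icc_full <- function(trial) {
  trial <- trial_data(trial)
  cells <- cell_stats(trial$data)
  X <- build_X_me(cells, trial$design$n_periods, adjust_covariate = FALSE)
  fit <- reml_fit(cells, X)
  beta <- fit$beta
  names(beta) <- colnames(X)
  new_icc_estimate("full", fit, beta)
}
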