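# Monte Carlo harness: replicated simulation per scenario, operating
# characteristics, the quantile-stratified bias experiment, and tidy result
# tables.

results_columns <- c(
  "scenario_type", "n_clusters", "n_periods", "icc_true", "cell_size",
  "delta_true", "model", "correction", "quantile", "reps", "bias",
  "rel_bias_pct", "precision", "power", "coverage", "rmse", "mcse",
  "n_failed"
)

#' Summarise replicate-level estimates into operating characteristics
#'
#' Computes the Monte Carlo operating characteristics over `S` replicates:
#' bias `mean(delta_hat) - delta`; relative bias
#' `100 * |bias| / delta` (only when `delta != 0`); precision, the
#' reciprocal of the average estimated variance; power (or type I error when
#' `delta = 0`), the proportion of replicates rejecting `delta = 0`;
#' coverage, the proportion of intervals containing the true effect; RMSE
#' `sqrt(mean((delta_hat - delta)^2))` (denominator `S`); and the Monte
#' Carlo standard error, the sample standard deviation of the estimates
#' (denominator `S - 1`).
#'
#' @param estimates Numeric vector of treatment-effect estimates.
#' @param variances Numeric vector of estimated variances.
#' @param reject_flags Logical vector: interval excludes 0.
#' @param cover_flags Logical vector: interval contains `true_delta`.
#' @param true_delta The true effect.
#' @param ... Identifier columns (e.g. scenario descriptors) recycled into
#'   the output row.
#' @return A one-row data frame (a `MetricsSummary`).
#' @export
summarize_estimates <- function(estimates, variances, reject_flags,
                                cover_flags, true_delta, ...) {
  S <- length(estimates)
  stopifnot(S >= 2, length(variances) == S, length(reject_flags) == S,
            length(cover_flags) == S)
  bias <- mean(estimates) - true_delta
  out <- data.frame(
    ...,
    reps = S,
    bias = bias,
    rel_bias_pct = if (true_delta != 0) 100 * abs(bias) / true_delta
                   else NA_real_,
    precision = 1 / mean(variances),
    power = mean(reject_flags),
    coverage = mean(cover_flags),
    rmse = sqrt(mean((estimates - true_delta)^2)),
    mcse = stats::sd(estimates),
    stringsAsFactors = FALSE
  )
  out
}

fit_one_model <- function(trial, model) {
  switch(model,
    fe = fit_fixed_effects(trial),
    me = fit_mixed_effects(trial, adjust_covariate = FALSE),
    me_adj = fit_mixed_effects(trial, adjust_covariate = TRUE),
    stop("unknown model: ", model, call. = FALSE)
  )
}

policy_name <- c(normal = "none", satterthwaite = "satterthwaite",
                 kenward_roger = "kr")

# One replicate: simulate and fit each requested model under each policy.
# Returns a list of rows (model, correction, estimate, variance, reject,
# cover) plus bookkeeping flags, or an error condition to be counted by the
# caller.
replicate_fits <- function(config, models, policies, level) {
  trial <- simulate_trial(config)
  rows <- list()
  degenerate_cov <- FALSE
  for (model in models) {
    fit <- if (model == "me_adj" &&
               length(unique(trial$covariate)) < 2L) {
      # aliased covariate: the adjusted model collapses to the unadjusted
      # one (the covariate column carries no information); counted below
      degenerate_cov <- TRUE
      f <- fit_mixed_effects(trial, adjust_covariate = FALSE)
      f$model_label <- "ME_adj"
      f
    } else {
      fit_one_model(trial, model)
    }
    pol <- if (model == "fe") "normal" else policies
    if (model != "fe" && any(pol != "normal")) {
      fit <- kenward_roger_adjust(fit)
    }
    for (p in pol) {
      ci <- wald_interval(fit, level = level, df_policy = p,
                          true_delta = config$delta)
      rows[[paste(model, p, sep = ".")]] <- list(
        model = model, correction = policy_name[[p]],
        estimate = fit$delta_hat,
        variance = if (p == "kenward_roger") fit$kr_se^2 else fit$var_delta,
        reject = ci$reject_null, cover = ci$covers
      )
    }
  }
  list(rows = rows, trial = trial, degenerate_cov = degenerate_cov)
}

#' Run the Monte Carlo study for one scenario
#'
#' Simulates `reps` independent trials from a scenario (replicate `r` uses
#' the child seed `derive_seed(seed, r)`, so results are reproducible and
#' independent of any execution order), fits each requested model, applies
#' each inference policy, and summarises the operating characteristics per
#' model and policy. Small-sample corrections apply to the mixed-effects
#' fits only; the fixed-effects model always uses the normal-approximation
#' interval.
#'
#' Replicates whose fit fails are excluded and counted; if more than 1% of
#' replicates fail the scenario errors out. A replicate in which the
#' covariate-adjusted model has an aliased (cluster-constant) covariate is
#' fitted without the inestimable covariate column and counted separately
#' in the `n_degenerate_covariate` attribute.
#'
#' @param config An `swct_scenario`.
#' @param reps Number of replicates (at least 2).
#' @param models Subset of `c("fe", "me", "me_adj")`.
#' @param policies Subset of `c("normal", "satterthwaite", "kenward_roger")`
#'   applied to mixed-effects fits.
#' @param seed Base seed for the scenario; defaults to `config$seed`.
#' @param level Confidence level.
#' @return A data frame with one row per model-policy combination (columns
#'   as in [write_results()]).
#' @export
run_scenario <- function(config, reps, models = c("fe", "me", "me_adj"),
                         policies = "normal", seed = NULL, level = 0.95) {
  stopifnot(inherits(config, "swct_scenario"), reps >= 2)
  models <- match.arg(models, c("fe", "me", "me_adj"), several.ok = TRUE)
  policies <- match.arg(policies,
                        c("normal", "satterthwaite", "kenward_roger"),
                        several.ok = TRUE)
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) {
    stop("no seed: supply `seed` or a scenario with a seed", call. = FALSE)
  }
  acc <- list()
  n_failed <- 0L
  n_degenerate_cov <- 0L
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$seed <- derive_seed(seed, r)
    res <- tryCatch(replicate_fits(cfg, models, policies, level),
                    error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      if (n_failed > max(1, 0.01 * reps)) {
        stop("more than 1% of replicates failed; last error: ",
             conditionMessage(res), call. = FALSE)
      }
      next
    }
    if (res$degenerate_cov) n_degenerate_cov <- n_degenerate_cov + 1L
    for (nm in names(res$rows)) acc[[nm]][[length(acc[[nm]]) + 1L]] <-
        res$rows[[nm]]
  }
  out <- do.call(rbind, lapply(names(acc), function(nm) {
    rows <- acc[[nm]]
    summarize_estimates(
      estimates = vapply(rows, `[[`, 0, "estimate"),
      variances = vapply(rows, `[[`, 0, "variance"),
      reject_flags = vapply(rows, `[[`, TRUE, "reject"),
      cover_flags = vapply(rows, `[[`, TRUE, "cover"),
      true_delta = config$delta,
      scenario_type = config$scenario_type,
      n_clusters = config$design$n_clusters,
      n_periods = config$design$n_periods,
      icc_true = config$icc,
      cell_size = config$cell_size_shape * config$cell_size_scale,
      delta_true = config$delta,
      model = rows[[1]]$model,
      correction = rows[[1]]$correction,
      quantile = NA_character_
    )
  }))
  out$n_failed <- n_failed
  out <- out[, results_columns]
  attr(out, "n_degenerate_covariate") <- n_degenerate_cov
  out
}

#' Quantile-stratified bias experiment
#'
#' For the three-cluster chance-imbalance condition, runs replicated
#' simulations, classifies each replicate's covariate triple into the
#' imbalance-severity quantiles Q1-Q3 (dropping the excluded constant
#' allocations), and summarises bias and the other operating
#' characteristics per model within each quantile.
#'
#' @inheritParams run_scenario
#' @return A data frame with one row per model-quantile combination.
#' @export
run_quantile_stratified <- function(config, reps,
                                    models = c("fe", "me", "me_adj"),
                                    seed = NULL, level = 0.95) {
  stopifnot(inherits(config, "swct_scenario"), reps >= 2)
  if (config$design$n_clusters != 3L) {
    stop("the quantile experiment is defined for the 3-cluster design",
         call. = FALSE)
  }
  if (config$scenario_type != "chance_imbalance" || config$xi == 0) {
    stop("the quantile experiment requires the chance-imbalance scenario ",
         "with a non-zero covariate effect", call. = FALSE)
  }
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) {
    stop("no seed: supply `seed` or a scenario with a seed", call. = FALSE)
  }
  acc <- list()
  n_failed <- 0L
  n_excluded <- 0L
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$seed <- derive_seed(seed, r)
    res <- tryCatch(replicate_fits(cfg, models, "normal", level),
                    error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      if (n_failed > max(1, 0.01 * reps)) {
        stop("more than 1% of replicates failed; last error: ",
             conditionMessage(res), call. = FALSE)
      }
      next
    }
    qt <- classify_imbalance_quantile(res$trial$covariate)
    if (qt == "excluded") {
      n_excluded <- n_excluded + 1L
      next
    }
    for (nm in names(res$rows)) {
      key <- paste(nm, qt, sep = ".")
      acc[[key]][[length(acc[[key]]) + 1L]] <- c(res$rows[[nm]],
                                                 quantile = qt)
    }
  }
  out <- do.call(rbind, lapply(sort(names(acc)), function(key) {
    rows <- acc[[key]]
    summarize_estimates(
      estimates = vapply(rows, `[[`, 0, "estimate"),
      variances = vapply(rows, `[[`, 0, "variance"),
      reject_flags = vapply(rows, `[[`, TRUE, "reject"),
      cover_flags = vapply(rows, `[[`, TRUE, "cover"),
      true_delta = config$delta,
      scenario_type = config$scenario_type,
      n_clusters = config$design$n_clusters,
      n_periods = config$design$n_periods,
      icc_true = config$icc,
      cell_size = config$cell_size_shape * config$cell_size_scale,
      delta_true = config$delta,
      model = rows[[1]]$model,
      correction = rows[[1]]$correction,
      quantile = rows[[1]]$quantile
    )
  }))
  out$n_failed <- n_failed
  out <- out[, results_columns]
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Write or read result tables
#'
#' Tidy CSV with a fixed column order, one row per
#' (scenario, model, correction, quantile); `read_results` round-trips
#' losslessly up to floating-point formatting.
#'
#' @param summaries A data frame of metric rows (from [run_scenario()] or
#'   [run_quantile_stratified()], possibly row-bound).
#' @param path File path.
#' @return `write_results` returns `path` invisibly; `read_results` returns
#'   the data frame.
#' @export
write_results <- function(summaries, path) {
  if (is.null(summaries) || !is.data.frame(summaries) ||
      nrow(summaries) == 0L) {
    stop("no summaries to write", call. = FALSE)
  }
  miss <- setdiff(results_columns, names(summaries))
  if (length(miss)) {
    stop("missing result columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(summaries[, results_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$quantile <- as.character(out$quantile)
  out$correction <- as.character(out$correction)
  out
}
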