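# Standard stepped-wedge designs and simulation scenario grids.

#' Build a standard stepped-wedge design
#'
#' Constructs the standard staircase stepped-wedge layout with one cluster per
#' sequence: `n_sequences` clusters observed over `n_sequences + 1` periods,
#' all clusters untreated in period 1, cluster `i` first treated in period
#' `i + 1`, and all clusters treated in the final period.
#'
#' @param n_sequences Number of crossover sequences (and clusters); a positive
#'   integer.
#'
#' @return An object of class `swct_design`: a list with elements
#'   `n_clusters`, `n_periods`, `treatment` (the cluster-by-period 0/1
#'   indicator matrix) and `sequence_of_cluster`.
#'
#' @examples
#' d <- swct_design(3)
#' d$treatment
#' @export
swct_design <- function(n_sequences) {
  if (length(n_sequences) != 1L || !is.finite(n_sequences) ||
      n_sequences < 1 || n_sequences != round(n_sequences)) {
    stop("`n_sequences` must be a single positive integer", call. = FALSE)
  }
  I <- as.integer(n_sequences)
  J <- I + 1L
  treatment <- matrix(0L, nrow = I, ncol = J)
  for (i in seq_len(I)) treatment[i, (i + 1L):J] <- 1L
  structure(
    list(
      n_clusters = I,
      n_periods = J,
      treatment = treatment,
      sequence_of_cluster = seq_len(I)
    ),
    class = "swct_design"
  )
}

#' @export
print.swct_design <- function(x, ...) {
  cat("Stepped-wedge design:", x$n_clusters, "clusters (one per sequence),",
      x$n_periods, "periods\n")
  print(x$treatment)
  invisible(x)
}

valid_scenario_types <- c("none", "chance_imbalance",
                          "covariate_confounding", "complete_confounding")

#' Define a single simulation scenario
#'
#' A scenario is one point of the simulation grid: a design plus the
#' parameters of the data-generating process for a cross-sectional
#' stepped-wedge trial with continuous outcomes
#' `Y = phi_j + X_ij * delta + C_i * xi + alpha_i + e_ijk`.
#'
#' @param design A [swct_design()] object.
#' @param delta True intervention effect.
#' @param period_slope Per-period increment of the secular trend; period `j`
#'   has fixed effect `period_slope * (j - 1)` (anchored at 0 in period 1).
#' @param xi Effect of the binary cluster-level covariate.
#' @param tau2 Between-cluster variance of the random intercepts
#'   (non-negative).
#' @param sigma2_w Within-cluster residual variance (positive).
#' @param cell_size_shape Gamma shape `k` for the mean cluster-period size;
#'   with `cell_size_scale = 1` this is the expected cell size.
#' @param cell_size_scale Gamma scale `theta`.
#' @param scenario_type One of `"none"`, `"chance_imbalance"`,
#'   `"covariate_confounding"`, `"complete_confounding"`.
#' @param seed Optional integer seed attached to the scenario.
#'
#' @return An object of class `swct_scenario`.
#' @export
scenario_config <- function(design, delta = 0, period_slope = 0.2, xi = 0,
                            tau2 = 1 / 99, sigma2_w = 1,
                            cell_size_shape = 30, cell_size_scale = 1,
                            scenario_type = "none", seed = NULL) {
  stopifnot(inherits(design, "swct_design"))
  if (!is.numeric(tau2) || tau2 < 0) {
    stop("`tau2` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(sigma2_w) || sigma2_w <= 0) {
    stop("`sigma2_w` must be positive", call. = FALSE)
  }
  if (cell_size_shape <= 0 || cell_size_scale <= 0) {
    stop("gamma cell-size parameters must be positive", call. = FALSE)
  }
  scenario_type <- match.arg(scenario_type, valid_scenario_types)
  icc <- tau2 / (tau2 + sigma2_w)
  stopifnot(icc >= 0, icc < 1)
  structure(
    list(
      design = design, delta = delta, period_slope = period_slope, xi = xi,
      tau2 = tau2, sigma2_w = sigma2_w,
      cell_size_shape = cell_size_shape, cell_size_scale = cell_size_scale,
      scenario_type = scenario_type, seed = seed, icc = icc
    ),
    class = "swct_scenario"
  )
}

#' @export
print.swct_scenario <- function(x, ...) {
  cat(sprintf(
    "SW-CT scenario [%s]: %d clusters, delta=%g, ICC=%.3g, mean cell size=%g\n",
    x$scenario_type, x$design$n_clusters, x$delta, x$icc,
    x$cell_size_shape * x$cell_size_scale
  ))
  invisible(x)
}

#' Define a scenario grid
#'
#' Describes a Cartesian product of simulation conditions. The default
#' arguments give the full 320-scenario study grid: designs with 3, 4, 5, 6
#' and 10 sequences, null and medium intervention effects, four
#' between-cluster variances (ICC 0.01, 0.05, 0.1, 0.2), two mean
#' cluster-period sizes and four imbalance/confounding conditions.
#'
#' The covariate effect is scenario-type policy, not a grid axis: `xi = 0`
#' under `"none"` and `"complete_confounding"` (where the retained covariate
#' is a proxy indicator only) and `xi = xi_imbalance` under
#' `"chance_imbalance"` and `"covariate_confounding"`.
#'
#' @param designs Integer vector of sequence counts.
#' @param deltas Numeric vector of intervention effects.
#' @param tau2s Numeric vector of between-cluster variances.
#' @param cell_sizes Numeric vector of gamma shapes `k` (mean cell sizes at
#'   `theta = 1`).
#' @param scenario_types Character vector of scenario types.
#' @param period_slope,sigma2_w,theta Fixed parameters shared by all
#'   scenarios.
#' @param xi_imbalance Covariate effect applied in imbalance/confounding
#'   scenario types.
#' @param base_seed Base seed from which per-scenario seeds are derived.
#'
#' @return An object of class `swct_grid`.
#' @seealso [enumerate_scenarios()], [read_scenario_grid()]
#' @export
scenario_grid <- function(designs = c(3, 4, 5, 6, 10),
                          deltas = c(0, 0.5),
                          tau2s = c(1 / 99, 1 / 19, 1 / 9, 1 / 4),
                          cell_sizes = c(30, 100),
                          scenario_types = valid_scenario_types,
                          period_slope = 0.2, sigma2_w = 1, theta = 1,
                          xi_imbalance = 0.3, base_seed = 1L) {
  axes <- list(designs = designs, deltas = deltas, tau2s = tau2s,
               cell_sizes = cell_sizes, scenario_types = scenario_types)
  empty <- vapply(axes, length, 1L) == 0L
  if (any(empty)) {
    stop("empty grid axis: ", paste(names(axes)[empty], collapse = ", "),
         call. = FALSE)
  }
  scenario_types <- vapply(scenario_types, function(s)
    match.arg(s, valid_scenario_types), character(1), USE.NAMES = FALSE)
  structure(
    list(designs = designs, deltas = deltas, tau2s = tau2s,
         cell_sizes = cell_sizes, scenario_types = scenario_types,
         period_slope = period_slope, sigma2_w = sigma2_w, theta = theta,
         xi_imbalance = xi_imbalance, base_seed = as.integer(base_seed)),
    class = "swct_grid"
  )
}

#' Enumerate all scenarios of a grid
#'
#' Expands a [scenario_grid()] into the full Cartesian product of scenario
#' configurations in a fixed, reproducible order: row-major over
#' (scenario type, design, delta, tau2, cell size), with scenario type the
#' slowest axis. Each scenario receives a deterministic seed derived from the
#' grid's base seed and the scenario's position, so replicate streams are
#' reproducible.
#'
#' @param grid An `swct_grid` object.
#' @return A list of `swct_scenario` objects whose length is the product of
#'   the axis lengths.
#' @examples
#' length(enumerate_scenarios(scenario_grid())) # 320
#' @export
enumerate_scenarios <- function(grid) {
  stopifnot(inherits(grid, "swct_grid"))
  combos <- expand.grid(
    cell_size = grid$cell_sizes, tau2 = grid$tau2s, delta = grid$deltas,
    design = grid$designs, scenario_type = grid$scenario_types,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  designs <- lapply(unique(grid$designs), swct_design)
  names(designs) <- as.character(unique(grid$designs))
  lapply(seq_len(nrow(combos)), function(idx) {
    row <- combos[idx, ]
    xi <- if (row$scenario_type %in% c("chance_imbalance",
                                       "covariate_confounding")) {
      grid$xi_imbalance
    } else 0
    scenario_config(
      design = designs[[as.character(row$design)]],
      delta = row$delta, period_slope = grid$period_slope, xi = xi,
      tau2 = row$tau2, sigma2_w = grid$sigma2_w,
      cell_size_shape = row$cell_size, cell_size_scale = grid$theta,
      scenario_type = row$scenario_type,
      seed = derive_seed(grid$base_seed, idx)
    )
  })
}

#' Read a scenario grid from a YAML or JSON configuration file
#'
#' Keys mirror the arguments of [scenario_grid()]. Missing keys fall back to
#' the bundled default grid (the 320-scenario study grid, also shipped at
#' `system.file("extdata", "default_grid.yaml", package = "swctsim")`).
#'
#' @param path Path to a YAML (or JSON, which YAML subsumes) file.
#' @return An `swct_grid` object.
#' @export
read_scenario_grid <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(scenario_grid))
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop("unknown grid keys: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  do.call(scenario_grid, cfg)
}
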