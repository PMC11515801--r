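# Data-generating process for cross-sectional stepped-wedge trials:
# gamma-Poisson cluster-period sizes, cluster-level covariate imbalance /
# confounding, and assembly of individual-level outcomes.

#' Draw cluster-period sample sizes
#'
#' Mean cluster-period sizes are drawn once per cluster,
#' `nbar_i ~ Gamma(shape = k, scale = theta)`, and realized cell sizes
#' independently per period, `n_ij ~ Poisson(nbar_i)`, so the sample size
#' varies between periods within a cluster. Zero cells are kept (their
#' probability is negligible at the study's cell sizes, but downstream
#' estimators tolerate empty cells).
#'
#' Uses R's global random number generator; call `set.seed()` for
#' reproducibility.
#'
#' @param k Gamma shape (positive); the mean cell size when `theta = 1`.
#' @param theta Gamma scale (positive).
#' @param design An [swct_design()].
#' @return An integer matrix of cell sizes with one row per cluster and one
#'   column per period.
#' @export
draw_cluster_period_sizes <- function(k, theta, design) {
  stopifnot(inherits(design, "swct_design"))
  if (!is.numeric(k) || k <= 0 || !is.numeric(theta) || theta <= 0) {
    stop("`k` and `theta` must be positive", call. = FALSE)
  }
  I <- design$n_clusters
  J <- design$n_periods
  nbar <- stats::rgamma(I, shape = k, scale = theta)
  matrix(stats::rpois(I * J, rep(nbar, times = J)), nrow = I, ncol = J)
}

#' Draw the cluster-level covariate and the cluster-to-sequence ordering
#'
#' Implements the four imbalance/confounding conditions. `ordering[s]` gives
#' the index (into `latent_alpha` and the raw covariate draws) of the cluster
#' assigned to sequence `s`; sequence `s` crosses over at period `s + 1`.
#'
#' * `none` / `chance_imbalance`: `C_i ~ Bernoulli(0.5)` independently of
#'   sequence; identity ordering. (Under `none` the covariate effect is
#'   forced to zero downstream.)
#' * `covariate_confounding`: covariates are drawn `Bernoulli(0.5)` and the
#'   clusters are then ordered so that every covariate-positive cluster
#'   occupies the latest sequences (treated last). Degenerate all-0/all-1
#'   draws are retained as drawn, yielding no confounding that replicate.
#' * `complete_confounding`: clusters are ordered by ascending latent effect
#'   `alpha_i`, so the lowest-alpha cluster crosses over first; the covariate
#'   is drawn and sorted the same way as under `covariate_confounding` but
#'   acts only as a proxy indicator (its effect is forced to zero downstream).
#'
#' @param config An `swct_scenario`.
#' @param latent_alpha Numeric vector of latent cluster effects, one per
#'   cluster.
#' @return A list with `covariate` (the covariate vector in sequence order)
#'   and `ordering` (the permutation of clusters onto sequences).
#' @export
draw_covariate_and_order <- function(config, latent_alpha) {
  stopifnot(inherits(config, "swct_scenario"))
  I <- config$design$n_clusters
  if (length(latent_alpha) != I) {
    stop("`latent_alpha` must have one entry per cluster", call. = FALSE)
  }
  C_raw <- stats::rbinom(I, 1L, 0.5)
  ordering <- switch(
    config$scenario_type,
    none = seq_len(I),
    chance_imbalance = seq_len(I),
    covariate_confounding = order(C_raw),       # C=1 clusters to latest sequences
    complete_confounding = order(latent_alpha)  # lowest alpha treated earliest
  )
  covariate <- if (config$scenario_type == "complete_confounding") {
    sort(C_raw)  # proxy indicator: latest-treated clusters carry it
  } else {
    C_raw[ordering]
  }
  list(covariate = covariate, ordering = ordering)
}

#' Simulate one stepped-wedge trial
#'
#' Generates individual outcomes
#' `Y_ijk = phi_j + X_ij * delta + C_i * xi + alpha_i + e_ijk` with
#' `alpha_i ~ N(0, tau2)`, `e_ijk ~ N(0, sigma2_w)` and
#' `phi_j = period_slope * (j - 1)`, after applying the scenario's
#' covariate/ordering rule. Covariate effects are applied as dictated by the
#' scenario type: `xi` is forced to zero under `none` and
#' `complete_confounding`.
#'
#' Draw order within a replicate is fixed (alpha, mean cell sizes, cell
#' sizes, covariate, residuals) so a given seed is bit-reproducible.
#'
#' @param config An `swct_scenario`. If `config$seed` is set it is applied
#'   via `set.seed()` before drawing; otherwise the current RNG state is
#'   used.
#' @return An object of class `swct_trial`: a list with the long-format
#'   `data` (columns `cluster`, `period`, `subject`, `treatment`,
#'   `covariate`, `outcome`; 1-based indices, cluster indexed by sequence),
#'   `cell_sizes`, `latent_alpha` (in sequence order), `n_total`, `design`
#'   and `config`.
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "swct_scenario"))
  if (!is.null(config$seed)) set.seed(config$seed)
  design <- config$design
  I <- design$n_clusters
  J <- design$n_periods

  alpha <- stats::rnorm(I, 0, sqrt(config$tau2))
  sizes <- draw_cluster_period_sizes(config$cell_size_shape,
                                     config$cell_size_scale, design)
  alloc <- draw_covariate_and_order(config, alpha)
  alpha_seq <- alpha[alloc$ordering]
  C_seq <- alloc$covariate

  xi_eff <- if (config$scenario_type %in% c("none", "complete_confounding"))
    0 else config$xi

  cl <- rep(rep(seq_len(I), times = J), times = as.vector(sizes))
  pd <- rep(rep(seq_len(J), each = I), times = as.vector(sizes))
  n_total <- length(cl)
  treatment <- design$treatment[cbind(cl, pd)]
  covariate <- C_seq[cl]
  phi <- config$period_slope * (pd - 1)
  e <- stats::rnorm(n_total, 0, sqrt(config$sigma2_w))
  outcome <- phi + treatment * config$delta + covariate * xi_eff +
    alpha_seq[cl] + e

  ord <- order(cl, pd)
  dat <- data.frame(
    cluster = cl[ord], period = pd[ord],
    subject = stats::ave(cl[ord], cl[ord], pd[ord], FUN = seq_along),
    treatment = treatment[ord], covariate = covariate[ord],
    outcome = outcome[ord]
  )
  structure(
    list(data = dat, cell_sizes = sizes, latent_alpha = alpha_seq,
         covariate = C_seq, n_total = n_total, design = design,
         config = config),
    class = "swct_trial"
  )
}

#' @export
print.swct_trial <- function(x, ...) {
  cat(sprintf(
    "Simulated SW-CT [%s]: %d clusters x %d periods, N = %d\n",
    x$config$scenario_type, x$design$n_clusters, x$design$n_periods,
    x$n_total
  ))
  invisible(x)
}

#' Classify a 3-cluster covariate allocation into imbalance quantiles
#'
#' For the three-cluster, four-period design the eight possible binary
#' covariate triples `(C_1, C_2, C_3)` (in sequence order, earliest-treated
#' first) partition into the high negative imbalance quantile
#' Q1 = \{(0,0,1), (0,1,1)\} (covariate concentrated in late-treated
#' clusters), the balanced quantile Q2 = \{(0,1,0), (1,0,1)\}, the high
#' positive imbalance quantile Q3 = \{(1,0,0), (1,1,0)\}, and the excluded
#' constant allocations (0,0,0) and (1,1,1).
#'
#' @param covariate A binary vector of length 3.
#' @return One of `"Q1"`, `"Q2"`, `"Q3"`, `"excluded"`.
#' @export
classify_imbalance_quantile <- function(covariate) {
  if (length(covariate) != 3L || !all(covariate %in% c(0, 1))) {
    stop("`covariate` must be a binary triple", call. = FALSE)
  }
  key <- paste(as.integer(covariate), collapse = "")
  switch(key,
    "001" = , "011" = "Q1",
    "010" = , "101" = "Q2",
    "100" = , "110" = "Q3",
    "excluded"
  )
}

#' Write or read a simulated trial as long-format CSV
#'
#' The on-disk schema is the long table with header
#' `cluster,period,subject,treatment,covariate,outcome` and 1-based cluster
#' and period indices. Reading reconstructs cell sizes from the table;
#' latent cluster effects are not part of the interchange format and are
#' `NA` after a round trip.
#'
#' @param trial An `swct_trial` (or a data frame with the schema columns).
#' @param path File path.
#' @return `write_trial` returns `path` invisibly; `read_trial` returns an
#'   `swct_trial`.
#' @export
write_trial <- function(trial, path) {
  dat <- if (inherits(trial, "swct_trial")) trial$data else trial
  need <- c("cluster", "period", "subject", "treatment", "covariate", "outcome")
  if (!all(need %in% names(dat))) {
    stop("trial table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(dat[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  dat <- utils::read.csv(path)
  as_swct_trial(dat)
}

#' Coerce a long-format table to an `swct_trial`
#'
#' Validates the schema, checks the treatment indicator is non-decreasing
#' within each cluster, and rebuilds the design and cell-size matrix from the
#' data. Used for user-supplied trial tables.
#'
#' @param dat A data frame with columns `cluster`, `period`, `subject`,
#'   `treatment`, `covariate`, `outcome`.
#' @return An `swct_trial`.
#' @export
as_swct_trial <- function(dat) {
  need <- c("cluster", "period", "subject", "treatment", "covariate", "outcome")
  miss <- setdiff(need, names(dat))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  I <- max(dat$cluster)
  J <- max(dat$period)
  treatment <- matrix(0L, I, J)
  agg <- unique(dat[, c("cluster", "period", "treatment")])
  if (anyDuplicated(agg[, c("cluster", "period")])) {
    stop("treatment indicator varies within a cluster-period cell",
         call. = FALSE)
  }
  treatment[cbind(agg$cluster, agg$period)] <- agg$treatment
  if (any(apply(treatment, 1, function(r) any(diff(r) < 0)))) {
    stop("treatment must be non-decreasing over periods within each cluster",
         call. = FALSE)
  }
  sizes <- matrix(0L, I, J)
  tab <- table(factor(dat$cluster, levels = seq_len(I)),
               factor(dat$period, levels = seq_len(J)))
  sizes[] <- as.integer(tab)
  design <- structure(
    list(n_clusters = I, n_periods = J, treatment = treatment,
         sequence_of_cluster = seq_len(I)),
    class = "swct_design"
  )
  Cseq <- vapply(seq_len(I), function(i) {
    ci <- unique(dat$covariate[dat$cluster == i])
    if (length(ci) != 1L) {
      stop("covariate must be constant within cluster", call. = FALSE)
    }
    as.numeric(ci)
  }, numeric(1))
  structure(
    list(data = dat, cell_sizes = sizes, latent_alpha = rep(NA_real_, I),
         covariate = Cseq, n_total = nrow(dat), design = design,
         config = NULL),
    class = "swct_trial"
  )
}
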