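#' Simulation configuration
#'
#' Parameters of the synthetic longitudinal benchmark: a case/control
#' cohort observed over the time domain [0, 10], with features randomly
#' assigned to three taxon archetypes (constant high-abundance, periodic
#' medium-abundance with group-dependent amplitude, and sigmoid-increase
#' low-abundance in cases only), Gaussian observation noise with
#' taxon-specific variances, optional per-subject random time grids, and
#' a fixed fraction of values set to zero to emulate sparsity.
#'
#' @param n_case,n_control group sizes (default 50 each).
#' @param n_timepoints observations per subject (default 10).
#' @param n_features number of microbial features (default 200).
#' @param domain_end end of the time domain (default 10).
#' @param sparsity fraction of observed values set to 0 (default 0).
#' @param time_mode \code{"aligned"} (shared evenly spaced grid) or
#'   \code{"misaligned"} (per-subject random grids).
#' @param misaligned_sampling for misaligned grids: \code{"stratified"}
#'   draws one uniform time per equal-width subinterval (default, giving
#'   one observation per unit band when n_timepoints = 10);
#'   \code{"uniform"} draws all times i.i.d. uniform on the domain.
#' @param noise_variances Gaussian noise variances for the three taxon
#'   types (default c(3, 5, 9)).
#' @param taxon_probs assignment probabilities of the three taxon types
#'   (default uniform).
#' @param taxon2_variant \code{"literal"} (default): the case-group
#'   periodic mean adds a sigmoid term to the oscillation;
#'   \code{"amplitude"}: the sigmoid multiplies the oscillation so the
#'   swing grows over time.
#' @param seed RNG seed (default 0).
#' @export
sim_config <- function(n_case = 50L, n_control = 50L, n_timepoints = 10L,
                       n_features = 200L, domain_end = 10,
                       sparsity = 0,
                       time_mode = c("aligned", "misaligned"),
                       misaligned_sampling = c("stratified", "uniform"),
                       noise_variances = c(3, 5, 9),
                       taxon_probs = c(1, 1, 1) / 3,
                       taxon2_variant = c("literal", "amplitude"),
                       seed = 0L) {
  time_mode <- match.arg(time_mode)
  misaligned_sampling <- match.arg(misaligned_sampling)
  taxon2_variant <- match.arg(taxon2_variant)
  if (n_case < 1L || n_control < 1L) stop("group sizes must be >= 1", call. = FALSE)
  if (n_timepoints < 3L) stop("n_timepoints must be >= 3", call. = FALSE)
  if (sparsity < 0 || sparsity >= 1) stop("sparsity must be in [0, 1)", call. = FALSE)
  if (abs(sum(taxon_probs) - 1) > 1e-8) stop("taxon_probs must sum to 1", call. = FALSE)
  if (length(noise_variances) != 3L || any(noise_variances < 0)) {
    stop("noise_variances must be 3 nonnegative numbers", call. = FALSE)
  }
  structure(list(n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 n_timepoints = as.integer(n_timepoints),
                 n_features = as.integer(n_features),
                 domain_end = domain_end,
                 sparsity = sparsity,
                 time_mode = time_mode,
                 misaligned_sampling = misaligned_sampling,
                 noise_variances = noise_variances,
                 taxon_probs = taxon_probs,
                 taxon2_variant = taxon2_variant,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Taxon mean trajectories
#'
#' Noise-free mean abundance of the three simulated taxon archetypes.
#' Taxon 1 is constant at 10 in both groups. Taxon 2 oscillates around a
#' high baseline; in the case group a sigmoid term raises (literal form)
#' or amplifies (amplitude form) the oscillation. Taxon 3 is constant at
#' 30 in controls and rises in cases along a sigmoid centered at t = 5,
#' from 10 toward 50.
#'
#' @param t time in [0, 10] (vectorized).
#' @param group \code{"case"} or \code{"control"}.
#' @param variant taxon-2 case formula: \code{"literal"} or
#'   \code{"amplitude"}.
#' @export
taxon1_mean <- function(t, group = c("case", "control")) {
  group <- match.arg(group)
  rep(10, length(t))
}

#' @rdname taxon1_mean
#' @export
taxon2_mean <- function(t, group = c("case", "control"),
                        variant = c("literal", "amplitude")) {
  group <- match.arg(group)
  variant <- match.arg(variant)
  osc <- sin(pi * t + 0.5 * pi)
  if (group == "control") {
    10 * (osc + 10)
  } else if (variant == "literal") {
    10 * (pi / (1 + exp(-t)) + 4 * osc + 10)
  } else {
    10 * ((pi / (1 + exp(-t))) * 4 * osc + 10)
  }
}

#' @rdname taxon1_mean
#' @export
taxon3_mean <- function(t, group = c("case", "control")) {
  group <- match.arg(group)
  if (group == "control") {
    rep(30, length(t))
  } else {
    40 * (1 / (1 + exp(-(t - 5))) + 0.25)
  }
}

taxon_mean <- function(taxon, t, group, variant = "literal") {
  switch(taxon,
         taxon1_mean(t, group),
         taxon2_mean(t, group, variant),
         taxon3_mean(t, group))
}

#' Sampling-time grids for a simulated cohort
#'
#' Aligned mode gives every subject the same evenly spaced grid spanning
#' the domain. Misaligned mode gives each subject its own random grid:
#' by default one uniform draw per equal-width subinterval (so a
#' 10-point grid has exactly one time in each unit band), or fully
#' i.i.d. uniform times when \code{misaligned_sampling = "uniform"}.
#' Uses the current RNG stream; seed externally for reproducibility.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a list of sorted time vectors, one per subject.
#' @export
sample_time_grid <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_case + config$n_control
  n_t <- config$n_timepoints
  T_end <- config$domain_end
  if (config$time_mode == "aligned") {
    grid <- seq(0, T_end, length.out = n_t)
    return(rep(list(grid), n))
  }
  lapply(seq_len(n), function(i) {
    if (config$misaligned_sampling == "stratified") {
      width <- T_end / n_t
      (seq_len(n_t) - 1) * width + stats::runif(n_t) * width
    } else {
      sort(stats::runif(n_t, 0, T_end))
    }
  })
}

#' Simulate a longitudinal case/control dataset
#'
#' Draws a complete synthetic cohort under \code{config}: features are
#' assigned to taxon types, each subject-feature trajectory is the taxon
#' mean at the subject's sampling times plus Gaussian noise with the
#' taxon's variance, negative draws are floored at 0 (abundances are
#' nonnegative), and the configured fraction of values is set to zero.
#' Deterministic given \code{config$seed}; the global RNG state is
#' restored afterwards.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{table} (a \code{\link{longitudinal_table}}
#'   with group labels attached), \code{labels} (named group vector) and
#'   \code{taxon_assignment} (feature type vector).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)
  n <- config$n_case + config$n_control
  m <- config$n_features
  n_t <- config$n_timepoints
  width <- max(nchar(as.character(n)))
  subjects <- c(sprintf("case%0*d", width, seq_len(config$n_case)),
                sprintf("ctrl%0*d", width, seq_len(config$n_control)))
  group_of <- c(rep("case", config$n_case), rep("control", config$n_control))
  names(group_of) <- subjects
  taxon <- sample.int(3L, m, replace = TRUE, prob = config$taxon_probs)
  features <- sprintf("F%0*d", max(nchar(as.character(m))), seq_len(m))
  grids <- sample_time_grid(config)

  per_subject <- vector("list", n)
  for (i in seq_len(n)) {
    t_i <- grids[[i]]
    mu <- matrix(0, n_t, m)
    for (tx in 1:3) {
      cols <- which(taxon == tx)
      if (length(cols) > 0L) {
        mu[, cols] <- taxon_mean(tx, t_i, group_of[i],
                                 config$taxon2_variant)
      }
    }
    sd_vec <- sqrt(config$noise_variances)[taxon]
    noise <- matrix(stats::rnorm(n_t * m), n_t, m) *
      rep(sd_vec, each = n_t)
    vals <- pmax(mu + noise, 0)
    per_subject[[i]] <- data.frame(
      subject = subjects[i],
      time = rep(t_i, times = m),
      feature = rep(features, each = n_t),
      value = as.vector(vals),
      stringsAsFactors = FALSE
    )
  }
  obs <- do.call(rbind, per_subject)
  table <- longitudinal_table(obs, domain_end = config$domain_end,
                              groups = group_of)
  if (config$sparsity > 0) {
    table <- apply_sparsity(table, config$sparsity, seed = NULL)
  }
  list(table = table, labels = group_of, taxon_assignment = taxon)
}

#' Inject sparsity by zeroing a fixed fraction of values
#'
#' Sets exactly \code{round(fraction * N)} of the table's N observation
#' values to zero, chosen uniformly without replacement. The records
#' themselves are kept (zeros, not missing values), matching the
#' convention that a zero is an observed non-detection.
#'
#' @param table a \code{\link{longitudinal_table}}.
#' @param fraction fraction of observations to zero, in [0, 1).
#' @param seed RNG seed; \code{NULL} uses the current RNG stream.
#' @export
apply_sparsity <- function(table, fraction, seed = 0L) {
  stopifnot(inherits(table, "longitudinal_table"))
  if (fraction < 0 || fraction >= 1) {
    stop("fraction must be in [0, 1)", call. = FALSE)
  }
  if (fraction == 0) return(table)
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  n_zero <- round(fraction * nrow(table))
  idx <- sample.int(nrow(table), n_zero)
  obs <- as.data.frame(table)
  obs$value[idx] <- 0
  rebuild_table(table, obs)
}

#' Replicate power study
#'
#' Runs \code{n_reps} independent replicates of simulate -> lordist ->
#' PERMANOVA and collects the pseudo-F statistics and p-values.
#' Replicate r uses seed \code{config$seed + r} for both data generation
#' and the permutation test.
#'
#' @param config a \code{\link{sim_config}} (its \code{sparsity},
#'   \code{time_mode} etc. define the scenario).
#' @param n_reps number of replicates.
#' @param n_perm PERMANOVA permutations (default 999).
#' @param ... further arguments passed to \code{\link{lordist}}.
#' @return a data.frame (replicate, sparsity, F, p) of class
#'   \code{lordist_replicates}, with a \code{summary} attribute holding
#'   the fraction of replicates with p > 0.05 and the median F.
#' @export
run_replicates <- function(config = sim_config(), n_reps = 20L,
                           n_perm = 999L, ...) {
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  res <- data.frame(replicate = seq_len(n_reps),
                    sparsity = config$sparsity,
                    F = numeric(n_reps), p = numeric(n_reps))
  for (r in seq_len(n_reps)) {
    cfg_r <- config
    cfg_r$seed <- config$seed + r
    sim <- simulate_dataset(cfg_r)
    fit <- lordist(sim$table, keep_fpca = FALSE, ...)
    pm <- permanova(fit$distance,
                    sim$labels[rownames(fit$distance)],
                    n_perm = n_perm, seed = cfg_r$seed)
    res$F[r] <- pm$F
    res$p[r] <- pm$p
  }
  attr(res, "summary") <- list(frac_nonsignificant = mean(res$p > 0.05),
                               median_F = stats::median(res$F))
  class(res) <- c("lordist_replicates", "data.frame")
  res
}

#' @export
print.lordist_replicates <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("%d replicates at sparsity %.0f%%: median F = %.3g, %.1f%% with p > 0.05\n",
              nrow(x), 100 * x$sparsity[1L], s$median_F,
              100 * s$frac_nonsignificant))
  invisible(x)
}
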