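# Synthetic-data generator: stands in for the wet-lab REU measurements so
# every pipeline stage is testable end to end. Component activity is a noisy
# monotone function of the design features; dual controllers scatter within
# a bounded band of the multiplicative prediction; cell contexts shift means
# (+7 REU HEK, +17 REU HepG2); the mAb titer surface peaks at an encoded
# HC:LC ratio of 1:2 and rises with LC strength.

#' Generator configuration
#'
#' Ground-truth parameters of the simulator. The activity truth model is
#' `REU = intercept + beta . (tract_length, tract_count, loop_length)`
#' clipped to `reu_bounds`; replicate measurements add Gaussian noise. The
#' default truth (intercept 145; betas -13, -9, +4 REU per unit) makes the
#' 40-spec default library span roughly 12-103 REU, matching the
#' two-orders-of-magnitude range synthetic G4 libraries are built to cover.
#' Dual-controller noise is uniform and bounded so the +/-12 REU agreement
#' band holds by construction.
#'
#' @param seed Integer seed; every simulator call is deterministic given the
#'   config.
#' @param truth_intercept Baseline REU of a hypothetical feature-free
#'   component.
#' @param truth_betas Length-3 numeric `(tract_length, tract_count,
#'   loop_length)`; the first two must be negative (stronger quadruplexes
#'   inhibit more), the third positive (longer loops destabilize).
#' @param noise_sd Replicate noise SD in REU (default 5).
#' @param n_replicates Replicates per measurement (default 3).
#' @param reu_bounds Truncation bounds for true and observed REU.
#' @param context_shifts Named mean REU shifts relative to CHO.
#' @param dual_noise_halfwidth Half-width of the uniform dual-controller
#'   observation noise (default 10, inside the 12 REU band).
#' @param titer_params List: `peak_ratio` (encoded HC:LC ratio at the planted
#'   optimum), `lc_exponent` (power-law rise of titer with LC strength),
#'   `ratio_penalty` (quadratic penalty away from the optimum ratio),
#'   `noise_frac` (titer noise SD as a fraction of the noiseless peak).
#' @return Object of class `g4_generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             truth_intercept = 145,
                             truth_betas = c(tract_length = -13,
                                             tract_count = -9,
                                             loop_length = 4),
                             noise_sd = 5,
                             n_replicates = 3L,
                             reu_bounds = c(0, 110),
                             context_shifts = c(CHO = 0, HEK = 7, HepG2 = 17),
                             dual_noise_halfwidth = 10,
                             titer_params = list(peak_ratio = 0.5,
                                                 lc_exponent = 1.5,
                                                 ratio_penalty = 10,
                                                 noise_frac = 0.03)) {
  if (length(truth_betas) != 3L) stop("'truth_betas' must have length 3")
  if (!(truth_betas[1] < 0 && truth_betas[2] < 0 && truth_betas[3] > 0)) {
    stop("sign constraints violated: betas for tract_length and tract_count ",
         "must be negative, loop_length positive")
  }
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (n_replicates < 1L) stop("'n_replicates' must be >= 1")
  if (dual_noise_halfwidth < 0) stop("'dual_noise_halfwidth' must be >= 0")
  names(truth_betas) <- c("tract_length", "tract_count", "loop_length")
  structure(
    list(seed = as.integer(seed), truth_intercept = truth_intercept,
         truth_betas = truth_betas, noise_sd = noise_sd,
         n_replicates = as.integer(n_replicates), reu_bounds = reu_bounds,
         context_shifts = context_shifts,
         dual_noise_halfwidth = dual_noise_halfwidth,
         titer_params = titer_params),
    class = "g4_generator_config"
  )
}

.clip <- function(x, bounds) pmin(pmax(x, bounds[1]), bounds[2])

.true_reu <- function(features, config) {
  .clip(config$truth_intercept +
          as.matrix(features) %*% config$truth_betas,
        config$reu_bounds)[, 1]
}

#' Simulate single-component activity measurements
#'
#' For each motif spec, the true REU is the clipped linear truth model;
#' the observed mean is the average of `n_replicates` Gaussian draws
#' truncated at the REU bounds. Components are labelled by their simulated
#' activity with [name_component()] (collisions suffixed in order).
#'
#' @param specs Library data.frame from [enumerate_library()] (columns
#'   `level`, `tract_length`, `tract_count`, `loop_length`).
#' @param config A [generator_config()].
#' @param cell_host,format,system Measurement context recorded on each row.
#' @return Activity table: one row per spec with `component_label`, design
#'   features, context columns, `reu_true`, `reu_mean`, `reu_sd`,
#'   `n_replicates`.
#' @export
simulate_activities <- function(specs, config = generator_config(),
                                cell_host = "CHO", format = "plasmid",
                                system = "transient") {
  stopifnot(inherits(config, "g4_generator_config"))
  feats <- specs[, c("tract_length", "tract_count", "loop_length")]
  true <- .true_reu(feats, config)
  set.seed(config$seed)
  nr <- config$n_replicates
  draws <- matrix(stats::rnorm(length(true) * nr, mean = rep(true, each = nr),
                               sd = config$noise_sd),
                  nrow = length(true), byrow = TRUE)
  draws <- .clip(draws, config$reu_bounds)
  reu_mean <- rowMeans(draws)
  reu_sd <- if (nr > 1L) apply(draws, 1L, stats::sd) else rep(0, length(true))

  labels <- character(length(true))
  for (i in seq_along(true)) {
    labels[i] <- name_component(specs$level[i], reu_mean[i],
                                existing = labels[seq_len(i - 1L)])
  }
  data.frame(
    component_label = labels,
    level = specs$level,
    tract_length = specs$tract_length,
    tract_count = specs$tract_count,
    loop_length = specs$loop_length,
    cell_host = cell_host, format = format, system = system,
    reu_true = true, reu_mean = reu_mean, reu_sd = reu_sd,
    n_replicates = config$n_replicates,
    stringsAsFactors = FALSE
  )
}

#' Simulate a dual-controller observation panel
#'
#' Observations are the multiplicative prediction plus bounded uniform noise
#' `U(-h, h)` with `h = dual_noise_halfwidth`, clipped at 0, so every
#' simulated panel satisfies the +/-12 REU agreement band when `h < 12`.
#'
#' @param dna_set,rna_set Named numeric vectors of single-controller REUs.
#' @param config A [generator_config()].
#' @return Data.frame with `dna_label`, `rna_label`, `reu_observed`, one row
#'   per pair of the Cartesian product.
#' @export
simulate_dual_panel <- function(dna_set, rna_set,
                                config = generator_config()) {
  stopifnot(inherits(config, "g4_generator_config"))
  grid <- evaluate_matrix(dna_set, rna_set)
  set.seed(config$seed)
  h <- config$dual_noise_halfwidth
  obs <- grid$reu_predicted + stats::runif(nrow(grid), -h, h)
  data.frame(dna_label = grid$dna_label, rna_label = grid$rna_label,
             reu_observed = pmax(obs, 0), stringsAsFactors = FALSE)
}

#' Simulate component activities in a new cell context
#'
#' Shifts each component's true REU by the configured context offset and
#' adds one Gaussian noise draw, preserving labels so panels stay paired.
#' The source records must be CHO-context; requesting CHO back is the
#' identity.
#'
#' @param records CHO-context activity table (needs `reu_true`; falls back
#'   to `reu_mean` when absent).
#' @param target_context Name present in `config$context_shifts`
#'   (e.g. `"HEK"`, `"HepG2"`).
#' @param config A [generator_config()].
#' @return Activity table in the target context.
#' @export
simulate_context_panel <- function(records, target_context,
                                   config = generator_config()) {
  stopifnot(inherits(config, "g4_generator_config"))
  if (!"cell_host" %in% names(records) || any(records$cell_host != "CHO")) {
    stop("source records must be in the CHO context")
  }
  if (!target_context %in% names(config$context_shifts)) {
    stop("unknown context '", target_context, "'; configured contexts: ",
         paste(names(config$context_shifts), collapse = ", "))
  }
  if (target_context == "CHO") return(records)
  true <- if ("reu_true" %in% names(records)) records$reu_true else
    records$reu_mean
  shift <- config$context_shifts[[target_context]]
  set.seed(config$seed)
  out <- records
  out$cell_host <- target_context
  out$reu_true <- .clip(true + shift, config$reu_bounds)
  out$reu_mean <- .clip(true + shift +
                          stats::rnorm(length(true), 0, config$noise_sd),
                        config$reu_bounds)
  out
}

#' Simulate a mAb titer surface over an HC:LC design space
#'
#' The noiseless titer (percent of the both-chains-unengineered control) is
#' `100 * raw(hc, lc) / raw(100, 100)` with
#' `raw = (reu_lc / 100)^lc_exponent * exp(-ratio_penalty *
#' (encoded_ratio - peak_ratio)^2)`: titer rises with LC strength and is
#' sharply unimodal in the encoded ratio around the planted optimum.
#' Gaussian noise with SD `noise_frac * peak` is added and the planted
#' ground truth recorded in the result's attributes.
#'
#' @param points Design space from [build_design_space()].
#' @param config A [generator_config()].
#' @param noise_frac Override for `config$titer_params$noise_frac`.
#' @return `points` with `titer` filled in; attributes `true_titer`,
#'   `peak_ratio` (planted optimum), `true_optimum` (noiseless argmax row).
#' @export
simulate_titer_surface <- function(points, config = generator_config(),
                                   noise_frac = NULL) {
  stopifnot(inherits(config, "g4_generator_config"))
  tp <- config$titer_params
  if (is.null(noise_frac)) noise_frac <- tp$noise_frac
  raw <- function(hc, lc) {
    (lc / 100)^tp$lc_exponent *
      exp(-tp$ratio_penalty * (hc / lc - tp$peak_ratio)^2)
  }
  control <- raw(100, 100)
  true_titer <- 100 * raw(points$reu_hc, points$reu_lc) / control
  set.seed(config$seed)
  noise_sd <- noise_frac * max(true_titer)
  points$titer <- pmax(true_titer + stats::rnorm(nrow(points), 0, noise_sd), 0)
  attr(points, "true_titer") <- true_titer
  attr(points, "peak_ratio") <- tp$peak_ratio
  attr(points, "true_optimum") <-
    points[which.max(true_titer), c("reu_hc", "reu_lc", "encoded_ratio")]
  points
}
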