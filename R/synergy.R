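# Two-level (DNA + RNA) dual-controller prediction: constituent components
# act multiplicatively on expression, REU_combined = REU_DNA * REU_RNA / 100.

#' Predict the combined output of a DNA + RNA dual controller
#'
#' The two levels act on sequential stages of biosynthesis (transcription,
#' then translation), so their fractional effects multiply:
#' `REU_combined = REU_DNA * REU_RNA / 100`. The formula is treated as
#' exact; deviations of observations from it are reported downstream, never
#' absorbed into a refit.
#'
#' @param reu_dna,reu_rna Non-negative REU values (vectorized).
#' @return Predicted combined REU.
#' @examples
#' predict_combined(20, 80)  # 16
#' @export
predict_combined <- function(reu_dna, reu_rna) {
  if (any(is.na(reu_dna)) || any(is.na(reu_rna)) ||
      any(reu_dna < 0) || any(reu_rna < 0)) {
    stop("REU inputs must be non-negative")
  }
  reu_dna * reu_rna / 100
}

#' Evaluate a DNA x RNA dual-controller matrix
#'
#' Builds the full Cartesian product of the supplied DNA and RNA component
#' sets, predicts each combination, and (when observations are supplied)
#' reports the deviation of each observation from its prediction and whether
#' it falls within the tolerance band.
#'
#' @param dna_set,rna_set Named numeric vectors (names = component labels,
#'   values = single-controller REUs).
#' @param observations Optional data.frame with `dna_label`, `rna_label`,
#'   `reu_observed` covering every pair; missing pairs are an error.
#' @param tolerance Absolute deviation band in REU (default 12).
#' @return Data.frame of class `g4_dual_panel` with one row per pair:
#'   labels, constituent REUs, `reu_predicted`, and when observed,
#'   `reu_observed`, `deviation`, `within_tolerance`. When observations are
#'   present the attribute `pearson_r` holds the observed-vs-predicted
#'   correlation.
#' @export
evaluate_matrix <- function(dna_set, rna_set, observations = NULL,
                            tolerance = 12) {
  if (is.null(names(dna_set)) || is.null(names(rna_set))) {
    stop("'dna_set' and 'rna_set' must be named numeric vectors")
  }
  grid <- expand.grid(dna_label = names(dna_set), rna_label = names(rna_set),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$reu_dna <- unname(dna_set[grid$dna_label])
  grid$reu_rna <- unname(rna_set[grid$rna_label])
  grid$reu_predicted <- predict_combined(grid$reu_dna, grid$reu_rna)

  if (!is.null(observations)) {
    need <- c("dna_label", "rna_label", "reu_observed")
    if (!all(need %in% names(observations))) {
      stop("observations need columns: ", paste(need, collapse = ", "))
    }
    key_grid <- paste(grid$dna_label, grid$rna_label, sep = "|")
    key_obs <- paste(observations$dna_label, observations$rna_label,
                     sep = "|")
    absent <- setdiff(key_grid, key_obs)
    if (length(absent)) {
      stop("missing observation(s) for pair(s): ",
           paste(absent, collapse = "; "))
    }
    grid$reu_observed <- observations$reu_observed[match(key_grid, key_obs)]
    grid$deviation <- grid$reu_observed - grid$reu_predicted
    grid$within_tolerance <- abs(grid$deviation) <= tolerance
    attr(grid, "pearson_r") <-
      pearson_r(grid$reu_observed, grid$reu_predicted)$r
  }
  attr(grid, "tolerance") <- tolerance
  class(grid) <- c("g4_dual_panel", "data.frame")
  grid
}
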