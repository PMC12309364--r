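# Heavy-chain:light-chain expression-ratio design space for multichain
# products: Cartesian component grids, encoded-ratio bookkeeping, optimum
# extraction and product-specific design rules from titer data.

.ratio_label <- function(reu) {
  ifelse(reu == 100, "BPCU", sprintf("DNA.%gREU", reu))
}

#' Build the HC:LC vector design space
#'
#' Crosses a set of component strength levels for the heavy chain against a
#' set for the light chain. The encoded HC:LC expression ratio of a point is
#' the quotient of the two REUs (gene copy numbers held equal); level 100
#' denotes the unengineered chassis.
#'
#' @param hc_levels,lc_levels Positive REU levels; default
#'   `c(10, 30, 50, 70, 100)` for both chains (25 points).
#' @return Data.frame with `hc_component`, `lc_component`, `reu_hc`,
#'   `reu_lc`, `encoded_ratio` and a `titer` column of `NA` awaiting
#'   measurement or simulation.
#' @export
build_design_space <- function(hc_levels = c(10, 30, 50, 70, 100),
                               lc_levels = hc_levels) {
  for (lv in list(hc = hc_levels, lc = lc_levels)) {
    if (!length(lv) || any(is.na(lv)) || any(lv <= 0)) {
      stop("strength levels must be positive REU values")
    }
  }
  g <- expand.grid(reu_lc = lc_levels, reu_hc = hc_levels,
                   KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(
    hc_component = .ratio_label(g$reu_hc),
    lc_component = .ratio_label(g$reu_lc),
    reu_hc = g$reu_hc,
    reu_lc = g$reu_lc,
    encoded_ratio = g$reu_hc / g$reu_lc,
    titer = NA_real_,
    stringsAsFactors = FALSE
  )
  out[order(out$reu_hc, out$reu_lc), ]
}

#' Locate the titer optimum and extract design rules
#'
#' Returns the argmax-titer design point (ties broken by lowest HC REU, then
#' lowest encoded ratio) along with two product-specific design rules read
#' off the surface: (a) the Pearson correlation of titer with LC strength at
#' each fixed HC level, and (b) the HC level at the titer peak within each
#' fixed LC level.
#'
#' @param points Design space data.frame from [build_design_space()] with a
#'   complete `titer` column.
#' @return List with `best` (one-row data.frame), `lc_correlations`
#'   (data.frame `reu_hc`, `r`), and `hc_peaks` (data.frame `reu_lc`,
#'   `peak_hc`, `peak_ratio`).
#' @export
find_optimum <- function(points) {
  need <- c("reu_hc", "reu_lc", "encoded_ratio", "titer")
  if (!all(need %in% names(points))) {
    stop("points need columns: ", paste(need, collapse = ", "))
  }
  missing_t <- is.na(points$titer)
  if (any(missing_t)) {
    stop("missing titer for point(s): ",
         paste(sprintf("(HC %g, LC %g)", points$reu_hc[missing_t],
                       points$reu_lc[missing_t]), collapse = "; "))
  }
  ord <- order(-points$titer, points$reu_hc, points$encoded_ratio)
  best <- points[ord[1], , drop = FALSE]
  rownames(best) <- NULL

  lc_correlations <- do.call(rbind, lapply(sort(unique(points$reu_hc)),
    function(h) {
      sub <- points[points$reu_hc == h, ]
      r <- if (nrow(sub) >= 3L && stats::var(sub$reu_lc) > 0 &&
               stats::var(sub$titer) > 0) {
        pearson_r(sub$titer, sub$reu_lc)$r
      } else NA_real_
      data.frame(reu_hc = h, r = r)
    }))

  hc_peaks <- do.call(rbind, lapply(sort(unique(points$reu_lc)),
    function(l) {
      sub <- points[points$reu_lc == l, ]
      sub <- sub[order(-sub$titer, sub$reu_hc), ]
      data.frame(reu_lc = l, peak_hc = sub$reu_hc[1],
                 peak_ratio = sub$encoded_ratio[1])
    }))

  list(best = best, lc_correlations = lc_correlations, hc_peaks = hc_peaks)
}
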