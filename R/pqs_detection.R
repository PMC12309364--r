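# Putative quadruplex-forming sequence (PQS) detection and propensity
# scoring. This is a deliberately simple design gate: a sequence is
# PQS-positive when it contains >= min_tracts G-runs of a common length
# >= min_tract separated by loops of 1..max_loop nt. The QGRS G-score it
# stands in for is not reimplemented.

.validate_nucleotides <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop("'sequence' must be a single string")
  }
  s <- toupper(sequence)
  chars <- strsplit(s, "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "U"))
  if (length(bad)) {
    stop("invalid nucleotide '", chars[bad[1]], "' at position ", bad[1],
         " (1-based); sequence must be over {A,C,G,T} or {A,C,G,U}")
  }
  if (any(chars == "T") && any(chars == "U")) {
    stop("sequence mixes T and U alphabets")
  }
  chartr("U", "T", s)
}

#' Scan a sequence for putative quadruplex-forming sequences
#'
#' Finds runs of >= `min_tracts` all-G tract windows of a common length
#' `t >= min_tract`, with consecutive tracts separated by 1..`max_loop` nt.
#' For each tract length, maximal chains are located with a longest-chain
#' dynamic program over candidate tract starts, so a hit is reported
#' whenever any valid tract decomposition exists. Hits at different tract
#' lengths may overlap and are all reported. T- and U-alphabet renderings of
#' a sequence give identical results.
#'
#' @param sequence Single string over \{A,C,G,T\} or \{A,C,G,U\}.
#' @param min_tract Minimum guanines per tract (default 2, the smallest
#'   designed tract).
#' @param max_loop Maximum loop length in nt (default 7).
#' @param min_tracts Minimum number of tracts per hit (default 4).
#' @return A data.frame of class `pqs_hits` with 0-based half-open
#'   coordinates: `start`, `end`, `tract_length`, `n_tracts`,
#'   `tract_starts` (comma-separated 0-based), `loop_lengths`
#'   (comma-separated), `score` (see [propensity_score()]). Ordered by
#'   `start`, then `tract_length`. Zero rows when no PQS is present.
#' @examples
#' find_pqs("GGGGATCGGGGATCGGGGATCGGGG")
#' @export
find_pqs <- function(sequence, min_tract = 2L, max_loop = 7L,
                     min_tracts = 4L) {
  min_tract <- as.integer(min_tract)
  max_loop <- as.integer(max_loop)
  min_tracts <- as.integer(min_tracts)
  if (min_tract < 1L || max_loop < 1L || min_tracts < 1L) {
    stop("detector parameters must be positive integers")
  }
  empty <- data.frame(start = integer(), end = integer(),
                      tract_length = integer(), n_tracts = integer(),
                      tract_starts = character(), loop_lengths = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  class(empty) <- c("pqs_hits", "data.frame")
  s <- .validate_nucleotides(sequence)
  if (!nzchar(s)) return(empty)
  n <- nchar(s)
  isG <- strsplit(s, "")[[1]] == "G"
  if (!any(isG)) return(empty)

  # longest G run bounds the largest tract length worth scanning
  runs <- rle(isG)
  max_run <- max(runs$lengths[runs$values])
  if (max_run < min_tract) return(empty)

  hits <- list()
  for (t in min_tract:max_run) {
    if (t * min_tracts + (min_tracts - 1L) > n) break
    # 1-based candidate starts of all-G windows of width t
    ok <- isG[seq_len(n - t + 1L)]
    if (t > 1L) {
      for (off in 1L:(t - 1L)) ok <- ok & isG[seq_len(n - t + 1L) + off]
    }
    starts <- which(ok)
    if (length(starts) < min_tracts) next

    # L[i]: longest chain beginning at starts[i]; nxt[i]: earliest successor
    # on a longest chain (ties broken 5'-most)
    m <- length(starts)
    L <- integer(m); nxt <- integer(m)
    for (i in m:1) {
      gap_lo <- starts[i] + t + 1L
      gap_hi <- starts[i] + t + max_loop
      succ <- which(starts >= gap_lo & starts <= gap_hi)
      if (!length(succ)) { L[i] <- 1L; nxt[i] <- NA_integer_; next }
      best <- max(L[succ])
      L[i] <- 1L + best
      nxt[i] <- succ[which(L[succ] == best)[1]]
    }
    # left-maximal chain starts: no candidate tract can precede them
    has_pred <- vapply(seq_len(m), function(i) {
      any(starts >= starts[i] - t - max_loop & starts <= starts[i] - t - 1L)
    }, logical(1))
    for (i in which(!has_pred & L >= min_tracts)) {
      chain <- integer(0)
      j <- i
      while (!is.na(j)) { chain <- c(chain, starts[j]); j <- nxt[j] }
      loops <- diff(chain) - t
      hits[[length(hits) + 1L]] <- data.frame(
        start = chain[1] - 1L,
        end = chain[length(chain)] + t - 1L,
        tract_length = t,
        n_tracts = length(chain),
        tract_starts = paste(chain - 1L, collapse = ","),
        loop_lengths = paste(loops, collapse = ","),
        score = propensity_score(t, length(chain), loops),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$tract_length), ]
  rownames(out) <- NULL
  class(out) <- c("pqs_hits", "data.frame")
  out
}

#' Quadruplex propensity score
#'
#' A documented closed form with the monotonicities that track inhibitory
#' strength: the score strictly increases with G-tract length and tract
#' count and strictly decreases with mean loop length,
#' `score = 3 * tract_length + 2 * n_tracts - mean(loop_lengths)`.
#' It is a relative ranking device, not a thermodynamic quantity.
#'
#' @param hit A one-row `pqs_hits` data.frame, or the tract length when the
#'   components are passed separately.
#' @param n_tracts,loop_lengths Used when `hit` is a bare tract length.
#' @return Numeric score (unitless).
#' @export
propensity_score <- function(hit, n_tracts = NULL, loop_lengths = NULL) {
  if (is.data.frame(hit)) {
    tl <- hit$tract_length
    nt <- hit$n_tracts
    ml <- vapply(strsplit(hit$loop_lengths, ","),
                 function(x) mean(as.numeric(x)), numeric(1))
  } else {
    tl <- hit; nt <- n_tracts; ml <- mean(loop_lengths)
  }
  3 * tl + 2 * nt - ml
}

#' Is a sequence PQS-positive?
#'
#' @inheritParams find_pqs
#' @return `TRUE` iff [find_pqs()] reports at least one hit.
#' @export
is_pqs_positive <- function(sequence, min_tract = 2L, max_loop = 7L,
                            min_tracts = 4L) {
  nrow(find_pqs(sequence, min_tract = min_tract, max_loop = max_loop,
                min_tracts = min_tracts)) > 0L
}
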