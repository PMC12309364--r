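# Synthetic G4 motif design: spec construction, full-factorial library
# enumeration, loop-sequence realization, disabled-mutant design, naming.

#' Construct a G4 motif specification
#'
#' A G4 motif is parameterized by the nucleic-acid level it acts at, the
#' number of guanines per G-tract, the number of G-tracts, and the length of
#' each inter-tract loop. These four inputs are the design parameters of the
#' component library.
#'
#' @param level `"DNA"` or `"RNA"` — the level at which the realized motif
#'   operates (transcriptional vs translational control).
#' @param tract_length Integer >= 2, guanines per G-tract (nt).
#' @param tract_count Integer >= 4, number of G-tracts.
#' @param loop_lengths Integer vector of per-loop lengths (nt), one per
#'   inter-tract loop (`tract_count - 1` of them), each >= 1. A single value
#'   is recycled to all loops.
#' @return An object of class `g4_spec`.
#' @examples
#' g4_spec("DNA", tract_length = 4, tract_count = 4, loop_lengths = 3)
#' @export
g4_spec <- function(level, tract_length, tract_count, loop_lengths) {
  level <- match.arg(toupper(level), c("DNA", "RNA"))
  tract_length <- as.integer(tract_length)
  tract_count <- as.integer(tract_count)
  loop_lengths <- as.integer(loop_lengths)
  if (length(loop_lengths) == 1L) {
    loop_lengths <- rep(loop_lengths, tract_count - 1L)
  }
  if (is.na(tract_length) || tract_length < 2L) {
    stop("'tract_length' must be an integer >= 2 (got ", tract_length, ")")
  }
  if (is.na(tract_count) || tract_count < 4L) {
    stop("'tract_count' must be an integer >= 4 (got ", tract_count, ")")
  }
  if (length(loop_lengths) != tract_count - 1L) {
    stop("need ", tract_count - 1L, " loop lengths (one per inter-tract loop), got ",
         length(loop_lengths))
  }
  if (any(is.na(loop_lengths)) || any(loop_lengths < 1L)) {
    stop("every loop length must be an integer >= 1")
  }
  structure(
    list(level = level, tract_length = tract_length, tract_count = tract_count,
         loop_lengths = loop_lengths),
    class = "g4_spec"
  )
}

#' @export
print.g4_spec <- function(x, ...) {
  cat(sprintf("<g4_spec> %s G%d x%d, loops [%s]\n", x$level, x$tract_length,
              x$tract_count, paste(x$loop_lengths, collapse = ",")))
  invisible(x)
}

#' @export
format.g4_spec <- function(x, ...) {
  sprintf("%s:G%dx%d:L%s", x$level, x$tract_length, x$tract_count,
          paste(x$loop_lengths, collapse = "."))
}

#' Enumerate the full-factorial G4 component library
#'
#' Two complementary design strategies generate the library: strategy (i)
#' holds the G-tract number constant and varies G-tract length and loop
#' length; strategy (ii) holds the loop length constant and varies G-tract
#' length and G-tract number. Each strategy contributes its full Cartesian
#' product; exact-duplicate specifications arising where the strategies
#' overlap are removed once, and the union is instantiated at each requested
#' level. With the default parameter ranges this yields 40 distinct
#' specifications per level, i.e. 80 components over both levels.
#'
#' @param strategy_i List with elements `tract_length`, `loop_length`
#'   (integer ranges) and `tract_count` (scalar), or `NULL` to omit the
#'   strategy. Defaults: tract length 2–6, loop length 1–5, 4 tracts.
#' @param strategy_ii List with elements `tract_length`, `tract_count`
#'   (integer ranges) and `loop_length` (scalar), or `NULL` to omit.
#'   Defaults: tract length 2–6, 4–7 tracts, loop length 2.
#' @param levels Character vector of levels to instantiate (`"DNA"`,
#'   `"RNA"`).
#' @return A data.frame with one row per spec and columns `level`,
#'   `strategy`, `tract_length`, `tract_count`, `loop_length`. Rows are
#'   ordered level-major, strategy (i) before (ii), then lexicographically by
#'   (tract_length, loop_length) within (i) and (tract_length, tract_count)
#'   within (ii).
#' @examples
#' lib <- enumerate_library()
#' nrow(lib)  # 80
#' @export
enumerate_library <- function(strategy_i = list(tract_length = 2:6,
                                                loop_length = 1:5,
                                                tract_count = 4L),
                              strategy_ii = list(tract_length = 2:6,
                                                 tract_count = 4:7,
                                                 loop_length = 2L),
                              levels = c("DNA", "RNA")) {
  levels <- vapply(levels, function(l) match.arg(toupper(l), c("DNA", "RNA")),
                   character(1), USE.NAMES = FALSE)
  if (anyDuplicated(levels)) stop("duplicated entries in 'levels'")
  if (is.null(strategy_i) && is.null(strategy_ii)) {
    stop("at least one strategy must be supplied")
  }

  check_range <- function(x, what, lo) {
    x <- as.integer(x)
    if (length(x) == 0L || any(is.na(x)) || any(x < lo)) {
      stop("invalid range for ", what, ": values must be integers >= ", lo)
    }
    sort(unique(x))
  }

  blocks <- list()
  if (!is.null(strategy_i)) {
    tl <- check_range(strategy_i$tract_length, "tract_length", 2L)
    ll <- check_range(strategy_i$loop_length, "loop_length", 1L)
    tc <- check_range(strategy_i$tract_count, "tract_count", 4L)
    if (length(tc) != 1L) stop("strategy (i) holds 'tract_count' at a single value")
    g <- expand.grid(loop_length = ll, tract_length = tl,
                     KEEP.OUT.ATTRS = FALSE)
    g <- g[order(g$tract_length, g$loop_length), ]
    blocks$i <- data.frame(strategy = "i", tract_length = g$tract_length,
                           tract_count = tc, loop_length = g$loop_length)
  }
  if (!is.null(strategy_ii)) {
    tl <- check_range(strategy_ii$tract_length, "tract_length", 2L)
    tc <- check_range(strategy_ii$tract_count, "tract_count", 4L)
    ll <- check_range(strategy_ii$loop_length, "loop_length", 1L)
    if (length(ll) != 1L) stop("strategy (ii) holds 'loop_length' at a single value")
    g <- expand.grid(tract_count = tc, tract_length = tl,
                     KEEP.OUT.ATTRS = FALSE)
    g <- g[order(g$tract_length, g$tract_count), ]
    blocks$ii <- data.frame(strategy = "ii", tract_length = g$tract_length,
                            tract_count = g$tract_count, loop_length = ll)
  }
  per_level <- do.call(rbind, blocks)
  key <- paste(per_level$tract_length, per_level$tract_count,
               per_level$loop_length)
  per_level <- per_level[!duplicated(key), ]

  out <- do.call(rbind, lapply(levels, function(lv) {
    cbind(data.frame(level = lv), per_level)
  }))
  rownames(out) <- NULL
  out
}

#' Convert a library row to a `g4_spec`
#'
#' @param row One-row data.frame as produced by [enumerate_library()].
#' @return A `g4_spec`.
#' @export
spec_from_row <- function(row) {
  g4_spec(row$level, row$tract_length, row$tract_count, row$loop_length)
}

#' Realize loop sequences for a G4 motif specification
#'
#' Loops never contain guanine: they are drawn from \{A, T, C\} at the DNA
#' level and \{A, U, C\} at the RNA level. Under the `balanced` policy the
#' concatenated loop positions are filled by a deterministic cyclic
#' A, T/U, C assignment 5'->3', so the three nucleotides are used in counts
#' differing by at most one (earlier letters receive the extra copies when
#' the total loop length is not divisible by three). Under the `fixed`
#' policy every loop carries the same user-supplied sequence.
#'
#' @param spec A `g4_spec`.
#' @param policy `"balanced"` or `"fixed"`.
#' @param fixed_loop For `policy = "fixed"`: a loop sequence over \{A, T, C\}
#'   (T is converted to U at the RNA level) whose length equals the spec's
#'   loop length.
#' @return An object of class `g4_motif` with elements `spec`, `loop_seqs`,
#'   `sequence` (realized motif in its own alphabet) and `label`
#'   (`NA` until the component is named).
#' @examples
#' m13 <- g4_spec("DNA", 4, 4, 3)
#' assign_loops(m13, "fixed", "ATC")$sequence
#' # "GGGGATCGGGGATCGGGGATCGGGG"
#' @export
assign_loops <- function(spec, policy = c("balanced", "fixed"),
                         fixed_loop = NULL) {
  stopifnot(inherits(spec, "g4_spec"))
  policy <- match.arg(policy)
  alphabet <- if (spec$level == "RNA") c("A", "U", "C") else c("A", "T", "C")

  if (policy == "balanced") {
    total <- sum(spec$loop_lengths)
    filled <- alphabet[(seq_len(total) - 1L) %% 3L + 1L]
    ends <- cumsum(spec$loop_lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    loop_seqs <- vapply(seq_along(ends), function(i) {
      paste(filled[starts[i]:ends[i]], collapse = "")
    }, character(1))
  } else {
    if (is.null(fixed_loop)) stop("'fixed_loop' is required under the fixed policy")
    fixed_loop <- toupper(fixed_loop)
    if (spec$level == "RNA") fixed_loop <- chartr("T", "U", fixed_loop)
    chars <- strsplit(fixed_loop, "")[[1]]
    if (!all(chars %in% alphabet)) {
      stop("'fixed_loop' must use only {", paste(alphabet, collapse = ","),
           "} (no G): got '", fixed_loop, "'")
    }
    if (any(spec$loop_lengths != nchar(fixed_loop))) {
      stop("'fixed_loop' length (", nchar(fixed_loop),
           ") does not match the spec's loop lengths (",
           paste(spec$loop_lengths, collapse = ","), ")")
    }
    loop_seqs <- rep(fixed_loop, spec$tract_count - 1L)
  }

  tract <- strrep("G", spec$tract_length)
  sequence <- paste0(tract,
                     paste0(vapply(loop_seqs, function(l) paste0(l, tract),
                                   character(1)),
                            collapse = ""))
  structure(
    list(spec = spec, loop_seqs = loop_seqs, sequence = sequence,
         policy = policy, label = NA_character_),
    class = "g4_motif"
  )
}

#' @export
print.g4_motif <- function(x, ...) {
  cat(sprintf("<g4_motif> %s %s (%d nt)%s\n  %s\n", x$spec$level,
              format(x$spec), nchar(x$sequence),
              if (!is.na(x$label)) paste0(" ", x$label) else "",
              x$sequence))
  invisible(x)
}

#' Realize every spec in a library manifest
#'
#' @param library_df Data.frame from [enumerate_library()].
#' @param policy,fixed_loop Passed to [assign_loops()].
#' @return List of `g4_motif` objects, one per row.
#' @export
realize_library <- function(library_df, policy = "balanced",
                            fixed_loop = NULL) {
  lapply(seq_len(nrow(library_df)), function(i) {
    assign_loops(spec_from_row(library_df[i, ]), policy, fixed_loop)
  })
}

#' Enumerate all fixed-loop variants of one specification
#'
#' Every possible loop sequence over \{A, T, C\} (\{A, U, C\} at the RNA
#' level) of the spec's loop length is instantiated as a fixed-loop motif.
#' For a 3 nt loop this is the 27-permutation scan used to probe loop
#' nucleotide composition.
#'
#' @param spec A `g4_spec` whose loops all share one length.
#' @return List of `g4_motif`, in lexicographic loop order (A < T/U < C).
#' @export
enumerate_loop_variants <- function(spec) {
  stopifnot(inherits(spec, "g4_spec"))
  len <- unique(spec$loop_lengths)
  if (length(len) != 1L) stop("loop variants require a uniform loop length")
  letters3 <- c("A", "T", "C")
  grid <- expand.grid(rep(list(letters3), len), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  # lexicographic in the written 5'->3' order under alphabet order A < T < C
  ranks <- lapply(grid, function(col) match(col, letters3))
  grid <- grid[do.call(order, ranks), , drop = FALSE]
  loops <- apply(grid, 1L, paste, collapse = "")
  lapply(loops, function(l) assign_loops(spec, "fixed", l))
}

#' Design a minimal G4-disabled mutant
#'
#' Searches for the smallest set of G-to-A substitutions that abolishes PQS
#' detection of the motif while preserving its length, mirroring the design
#' of disabled control elements that retain high sequence similarity to
#' their originators. The search is exhaustive over substitution counts
#' k = 1, 2, ... up to `max_substitutions`; among equally small solutions the
#' 5'-most substitution set (lexicographic position order) is returned.
#'
#' @param motif A `g4_motif` (must be PQS-positive under the detector
#'   parameters).
#' @param min_tract Minimum G-tract length for the detector; defaults to the
#'   parent's designed tract length so that breaking any single tract
#'   removes it from consideration.
#' @param max_loop,min_tracts Detector parameters, see [find_pqs()].
#' @param max_substitutions Search cap; exceeding it is an explicit error,
#'   never a silent partial mutant.
#' @return An object of class `g4_mutant`: `parent`, `sequence`,
#'   `n_substitutions`, `substitution_positions` (0-based).
#' @export
design_mutant <- function(motif, min_tract = NULL, max_loop = 7L,
                          min_tracts = 4L, max_substitutions = 6L) {
  stopifnot(inherits(motif, "g4_motif"))
  if (is.null(min_tract)) min_tract <- motif$spec$tract_length
  seq0 <- motif$sequence
  if (!is_pqs_positive(seq0, min_tract = min_tract, max_loop = max_loop,
                       min_tracts = min_tracts)) {
    stop("motif is not PQS-positive under the given detector parameters; ",
         "nothing to disable")
  }
  chars <- strsplit(chartr("U", "T", seq0), "")[[1]]
  is_rna <- motif$spec$level == "RNA"
  g_pos <- which(chars == "G")  # 1-based

  for (k in seq_len(max_substitutions)) {
    if (k > length(g_pos)) break
    idx <- seq_len(k)  # indices into g_pos, lexicographically first subset
    repeat {
      cand <- chars
      cand[g_pos[idx]] <- "A"
      cand_seq <- paste(cand, collapse = "")
      if (!is_pqs_positive(cand_seq, min_tract = min_tract,
                           max_loop = max_loop, min_tracts = min_tracts)) {
        if (is_rna) cand_seq <- chartr("T", "U", cand_seq)
        return(structure(
          list(parent = motif, sequence = cand_seq, n_substitutions = k,
               substitution_positions = g_pos[idx] - 1L),
          class = "g4_mutant"
        ))
      }
      # advance to the next k-combination of g_pos in lexicographic order
      i <- k
      while (i >= 1L && idx[i] == length(g_pos) - k + i) i <- i - 1L
      if (i < 1L) break
      idx[i] <- idx[i] + 1L
      if (i < k) idx[(i + 1L):k] <- idx[i] + seq_len(k - i)
    }
  }
  stop("no G->A substitution set of size <= ", max_substitutions,
       " abolishes PQS detection; increase 'max_substitutions'")
}

#' @export
print.g4_mutant <- function(x, ...) {
  cat(sprintf("<g4_mutant> %d G->A substitution(s) at [%s] (0-based)\n  %s\n",
              x$n_substitutions,
              paste(x$substitution_positions, collapse = ","), x$sequence))
  invisible(x)
}

#' Name a component after its measured activity
#'
#' Components are named by the level they act at and the relative expression
#' units (REU, percent of the unengineered control) they encode, rounded to
#' the nearest 5 (half rounds up), e.g. `DNA.70REU`. Labels that collide
#' within a library are disambiguated with `.2`, `.3`, ... suffixes in
#' registration order.
#'
#' @param level `"DNA"`/`"RNA"`, or a `g4_motif` (its level is used).
#' @param measured_reu Non-negative measured/simulated REU.
#' @param existing Character vector of labels already registered in the
#'   library (used for collision suffixes).
#' @return The label string.
#' @examples
#' name_component("DNA", 68.7)                    # "DNA.70REU"
#' name_component("DNA", 50, existing = "DNA.50REU")  # "DNA.50REU.2"
#' @export
name_component <- function(level, measured_reu, existing = character()) {
  if (inherits(level, "g4_motif")) level <- level$spec$level
  level <- match.arg(toupper(level), c("DNA", "RNA"))
  if (!is.numeric(measured_reu) || length(measured_reu) != 1L ||
      is.na(measured_reu) || measured_reu < 0) {
    stop("'measured_reu' must be a single non-negative number")
  }
  r5 <- 5L * as.integer(floor(measured_reu / 5 + 0.5))  # half rounds up
  base <- sprintf("%s.%dREU", level, r5)
  n_prev <- sum(existing == base |
                  grepl(paste0("^", base, "\\.[0-9]+$"), existing))
  if (n_prev == 0L) base else paste0(base, ".", n_prev + 1L)
}
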