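# The BPCU chassis (core promoter + 5'UTR) and full expression cassettes:
# strand-aware motif insertion, transcript derivation, upstream start-codon
# screening, and the candidate insertion-site panel.

# 41 bp hCMV-IE1 core promoter (TATA-box region of the widely distributed
# immediate-early promoter; users with a licensed construct should supply
# their exact sequence).
.default_core_promoter <- "TGGGAGGTCTATATAAGCAGAGCTCGTTTAGTGAACCGTCA"

# 57 nt SYNTHETIC PLACEHOLDER 5'UTR. The authentic bioproduction 5'UTR is
# proprietary and is NOT shipped; this stand-in is guanine-free (so it can
# neither form G4s nor gain start codons at motif junctions) and contains no
# ATG. Supply the real sequence via assemble_bpcu(utr = ...) when licensed.
.default_utr <- "ACCACTTCCTCTTCACCACAACCTCCATCACTCCTACTTCCTCAACCACCTCTCACC"

.validate_dna <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("'", what, "' must be a single string")
  }
  s <- toupper(x)
  chars <- strsplit(s, "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad)) {
    stop("'", what, "' is not DNA: invalid character '", chars[bad[1]],
         "' at position ", bad[1])
  }
  s
}

#' Assemble the core promoter + 5'UTR control unit (BPCU)
#'
#' The BPCU is a standardized chassis formed by fusing a minimal 41 bp
#' hCMV-IE1 core promoter to a 57 nt 5'UTR, giving a 98 bp unit whose
#' transcriptional start site (TSS) sits at the promoter/UTR junction.
#' Coordinates used throughout are TSS-relative with no position 0: +1 is
#' the first UTR nucleotide and -1 the last promoter nucleotide. The
#' packaged default UTR is a clearly flagged synthetic placeholder (the
#' authentic bioproduction UTR is proprietary).
#'
#' @param core_promoter Coding-strand DNA; default: packaged 41 bp core.
#' @param utr Coding-strand DNA; default: packaged 57 nt placeholder.
#' @return Object of class `bpcu`: `core_promoter`, `utr`, `tss_index`
#'   (0-based index of the +1 nucleotide, equal to the promoter length) and
#'   `utr_is_placeholder`.
#' @examples
#' nchar(assemble_bpcu()$core_promoter) + nchar(assemble_bpcu()$utr)  # 98
#' @export
assemble_bpcu <- function(core_promoter = NULL, utr = NULL) {
  placeholder <- is.null(utr)
  if (is.null(core_promoter)) core_promoter <- .default_core_promoter
  if (is.null(utr)) utr <- .default_utr
  core_promoter <- .validate_dna(core_promoter, "core_promoter")
  utr <- .validate_dna(utr, "utr")
  if (!nzchar(core_promoter)) stop("'core_promoter' must be non-empty")
  if (!nzchar(utr)) stop("'utr' must be non-empty")
  structure(
    list(core_promoter = core_promoter, utr = utr,
         tss_index = nchar(core_promoter),
         utr_is_placeholder = placeholder),
    class = "bpcu"
  )
}

#' @export
print.bpcu <- function(x, ...) {
  cat(sprintf("<bpcu> %d bp core promoter + %d nt 5'UTR%s (total %d bp), TSS at +1\n",
              nchar(x$core_promoter), nchar(x$utr),
              if (isTRUE(x$utr_is_placeholder)) " [synthetic placeholder UTR]" else "",
              nchar(x$core_promoter) + nchar(x$utr)))
  invisible(x)
}

#' Create an expression cassette around a BPCU
#'
#' @param bpcu A [assemble_bpcu()] object.
#' @param cds Coding sequence (coding-strand DNA, should begin with ATG).
#' @param proximal_promoter Optional upstream proximal promoter DNA.
#' @param utr3 Optional 3'UTR DNA.
#' @return Object of class `expression_cassette` with the assembled
#'   coding-strand sequence and a `segment_map` (data.frame of `name`,
#'   `start`, `end`, 0-based half-open) that tiles it exactly.
#' @export
expression_cassette <- function(bpcu, cds, proximal_promoter = "",
                                utr3 = "") {
  stopifnot(inherits(bpcu, "bpcu"))
  cds <- .validate_dna(cds, "cds")
  if (!nzchar(cds)) stop("'cds' must be non-empty")
  if (nzchar(proximal_promoter)) {
    proximal_promoter <- .validate_dna(proximal_promoter, "proximal_promoter")
  }
  if (nzchar(utr3)) utr3 <- .validate_dna(utr3, "utr3")
  cas <- structure(
    list(proximal_promoter = proximal_promoter, bpcu = bpcu,
         insertions = list(), cds = cds, utr3 = utr3,
         assembled = NULL, segment_map = NULL),
    class = "expression_cassette"
  )
  .reassemble(cas)
}

# split a sequence at insertion records; returns list of (name, seq) pieces.
# `position` here is the number of leading characters kept before the insert.
.splice <- function(seq_name, seq, inserts, prefix_lengths) {
  ord <- order(prefix_lengths)
  inserts <- inserts[ord]
  prefix_lengths <- prefix_lengths[ord]
  pieces <- list()
  cursor <- 0L
  for (i in seq_along(inserts)) {
    p <- prefix_lengths[i]
    if (p > cursor) {
      pieces[[length(pieces) + 1L]] <-
        list(name = seq_name, seq = substr(seq, cursor + 1L, p))
    }
    ins <- inserts[[i]]
    pieces[[length(pieces) + 1L]] <-
      list(name = paste0("insert:", ins$motif_id), seq = ins$inserted_seq)
    cursor <- p
  }
  if (cursor < nchar(seq)) {
    pieces[[length(pieces) + 1L]] <-
      list(name = seq_name, seq = substr(seq, cursor + 1L, nchar(seq)))
  }
  pieces
}

.reassemble <- function(cas) {
  bp <- cas$bpcu
  L <- nchar(bp$core_promoter)
  dna_ins <- Filter(function(x) x$level == "DNA", cas$insertions)
  rna_ins <- Filter(function(x) x$level == "RNA", cas$insertions)

  pieces <- list()
  if (nzchar(cas$proximal_promoter)) {
    pieces[[1]] <- list(name = "proximal_promoter",
                        seq = cas$proximal_promoter)
  }
  # DNA site -k: motif goes immediately 3' of promoter nucleotide -k, which
  # is the (L + position + 1)-th promoter character
  pieces <- c(pieces, .splice("core_promoter", bp$core_promoter, dna_ins,
                              vapply(dna_ins, function(x) L + x$position + 1L,
                                     integer(1))))
  # RNA site +j: motif goes immediately 3' of UTR nucleotide +j
  pieces <- c(pieces, .splice("utr", bp$utr, rna_ins,
                              vapply(rna_ins, function(x) x$position,
                                     integer(1))))
  pieces[[length(pieces) + 1L]] <- list(name = "cds", seq = cas$cds)
  if (nzchar(cas$utr3)) {
    pieces[[length(pieces) + 1L]] <- list(name = "utr3", seq = cas$utr3)
  }

  seqs <- vapply(pieces, `[[`, character(1), "seq")
  lens <- nchar(seqs)
  ends <- cumsum(lens)
  cas$assembled <- paste(seqs, collapse = "")
  cas$segment_map <- data.frame(
    name = vapply(pieces, `[[`, character(1), "name"),
    start = c(0L, head(ends, -1L)),
    end = ends,
    stringsAsFactors = FALSE
  )
  cas
}

#' @export
print.expression_cassette <- function(x, ...) {
  cat(sprintf("<expression_cassette> %d bp assembled, %d insertion(s)\n",
              nchar(x$assembled), length(x$insertions)))
  for (ins in x$insertions) {
    cat(sprintf("  %s-level '%s' at %+d\n", ins$level, ins$motif_id,
                ins$position))
  }
  invisible(x)
}

#' Insert a G4 motif into a cassette
#'
#' DNA-level motifs act on the template strand of the core promoter: the
#' coding strand therefore gains the reverse complement of the motif (the
#' G-rich content resides on the template strand). RNA-level motifs act in
#' the transcript and are inserted verbatim (T alphabet) into the UTR.
#' The motif is placed immediately 3' of the nucleotide at the TSS-relative
#' coordinate `position` (no position 0): `-1` places it between the last
#' promoter base and the TSS; `+6` places it after the sixth UTR base.
#'
#' @param cassette An [expression_cassette()].
#' @param motif A `g4_motif`, `g4_mutant`, or a raw sequence string (then
#'   `level` is required).
#' @param position Signed TSS-relative coordinate; negative (promoter) for
#'   DNA-level motifs, positive (UTR) for RNA-level motifs.
#' @param motif_id Identifier recorded in the segment map; defaults to the
#'   motif's label or its sequence.
#' @param level `"DNA"`/`"RNA"` when `motif` is a bare string.
#' @return The updated cassette.
#' @export
insert_motif <- function(cassette, motif, position, motif_id = NULL,
                         level = NULL) {
  stopifnot(inherits(cassette, "expression_cassette"))
  if (inherits(motif, "g4_mutant")) {
    level <- motif$parent$spec$level
    motif_seq <- motif$sequence
    if (is.null(motif_id)) motif_id <- paste0("mut:", motif_seq)
  } else if (inherits(motif, "g4_motif")) {
    level <- motif$spec$level
    motif_seq <- motif$sequence
    if (is.null(motif_id)) {
      motif_id <- if (!is.na(motif$label)) motif$label else motif_seq
    }
  } else {
    if (is.null(level)) stop("'level' is required when 'motif' is a string")
    level <- match.arg(toupper(level), c("DNA", "RNA"))
    motif_seq <- toupper(motif)
    if (is.null(motif_id)) motif_id <- motif_seq
  }
  position <- as.integer(position)
  if (is.na(position) || position == 0L) {
    stop("'position' is TSS-relative and has no 0")
  }
  bp <- cassette$bpcu
  if (level == "DNA") {
    if (position > 0L) {
      stop("DNA-level motifs insert at negative (promoter) coordinates, got +",
           position)
    }
    if (-position > nchar(bp$core_promoter)) {
      stop("position ", position, " lies outside the ",
           nchar(bp$core_promoter), " bp core promoter")
    }
    dna <- chartr("U", "T", motif_seq)
    inserted <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(dna)))
  } else {
    if (position < 0L) {
      stop("RNA-level motifs insert at positive (UTR) coordinates, got ",
           position)
    }
    if (position > nchar(bp$utr)) {
      stop("position +", position, " lies outside the ", nchar(bp$utr),
           " nt UTR")
    }
    inserted <- chartr("U", "T", motif_seq)
  }
  ids <- vapply(cassette$insertions, `[[`, character(1), "motif_id")
  if (motif_id %in% ids) {
    stop("an insertion with motif_id '", motif_id, "' already exists")
  }
  cassette$insertions[[length(cassette$insertions) + 1L]] <-
    list(level = level, position = position, motif_id = motif_id,
         motif_seq = motif_seq, inserted_seq = inserted)
  .reassemble(cassette)
}

#' Remove an insertion from a cassette
#'
#' Removing an insertion restores the assembled sequence that preceded it
#' byte-identically.
#'
#' @param cassette An [expression_cassette()].
#' @param motif_id Identifier of the insertion to remove.
#' @return The updated cassette.
#' @export
remove_insertion <- function(cassette, motif_id) {
  stopifnot(inherits(cassette, "expression_cassette"))
  ids <- vapply(cassette$insertions, `[[`, character(1), "motif_id")
  hit <- which(ids == motif_id)
  if (!length(hit)) stop("no insertion with motif_id '", motif_id, "'")
  cassette$insertions <- cassette$insertions[-hit[1]]
  .reassemble(cassette)
}

#' Derive the transcript of a cassette
#'
#' The transcript starts at the TSS: it comprises the UTR (with any
#' RNA-level insertions), the CDS, and the 3'UTR if present, in the RNA
#' alphabet. DNA-level insertions sit upstream of the TSS and are excluded.
#'
#' @param cassette An [expression_cassette()].
#' @return A string over \{A,C,G,U\} with attribute `cds_offset`, the
#'   0-based transcript position of the intended start codon.
#' @export
transcript_of <- function(cassette) {
  stopifnot(inherits(cassette, "expression_cassette"))
  sm <- cassette$segment_map
  # everything from the first UTR segment onward is transcribed
  utr_rows <- which(sm$name == "utr")
  first <- if (length(utr_rows)) min(utr_rows) else which(sm$name == "cds")
  tx_dna <- substr(cassette$assembled, sm$start[first] + 1L,
                   nchar(cassette$assembled))
  cds_start <- sm$start[sm$name == "cds"] - sm$start[first]
  tx <- chartr("T", "U", tx_dna)
  attr(tx, "cds_offset") <- as.integer(cds_start)
  tx
}

#' Scan a transcript for upstream start codons
#'
#' Reports every AUG strictly upstream of the intended start codon. Loop
#' sequences ending in `AU` followed by a G-tract are the canonical way a
#' synthetic G4 introduces one.
#'
#' @param transcript RNA-alphabet string (e.g. from [transcript_of()]).
#' @param cds_offset 0-based position of the intended AUG; defaults to the
#'   transcript's `cds_offset` attribute.
#' @return Integer vector of 0-based AUG positions (possibly empty).
#' @export
scan_upstream_starts <- function(transcript,
                                 cds_offset = attr(transcript, "cds_offset")) {
  if (is.null(cds_offset)) stop("'cds_offset' is required")
  s <- chartr("T", "U", toupper(as.character(transcript)))
  m <- gregexpr("AUG", s, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  pos <- as.integer(m) - 1L
  pos[pos < cds_offset]
}

#' Candidate insertion-site panel
#'
#' The default panel holds 7 DNA-level (promoter) and 6 RNA-level (UTR)
#' sites spanning the chassis, including the two optima -1 and +6. Only the
#' optima are fixed by the positioning study; the remaining coordinates are
#' an editable configuration. An explicitly empty config yields the minimal
#' panel of the two optima.
#'
#' @param config `NULL` for the default 13-site panel; an empty list for the
#'   minimal \{-1, +6\} panel; or a list with integer vectors `dna`
#'   (negative) and `rna` (positive).
#' @return Data.frame with columns `level`, `position`.
#' @export
candidate_sites <- function(config = NULL) {
  if (is.null(config)) {
    dna <- c(-36L, -29L, -21L, -14L, -8L, -4L, -1L)
    rna <- c(1L, 6L, 15L, 25L, 40L, 52L)
  } else if (is.list(config) && length(config) == 0L) {
    dna <- -1L
    rna <- 6L
  } else {
    dna <- as.integer(config$dna)
    rna <- as.integer(config$rna)
    if (any(is.na(dna)) || any(dna >= 0L)) {
      stop("DNA-level sites must be negative TSS-relative coordinates")
    }
    if (any(is.na(rna)) || any(rna <= 0L)) {
      stop("RNA-level sites must be positive TSS-relative coordinates")
    }
  }
  data.frame(level = c(rep("DNA", length(dna)), rep("RNA", length(rna))),
             position = c(dna, rna), stringsAsFactors = FALSE)
}
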