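# Shared readers/writers: library manifests (CSV), motif sequences (FASTA),
# activity tables (CSV), fitted models (JSON), PQS hits (BED-like TSV) and a
# minimal GenBank flat-file emitter for cassettes. Writers prefix '#'
# provenance comments that the paired readers skip; every writer round-trips
# through its reader.

.provenance_header <- function(what) {
  c(sprintf("# g4tune %s", what),
    sprintf("# g4tune version %s",
            as.character(utils::packageVersion("g4tune"))))
}

#' Write a motif library manifest to CSV
#'
#' @param motifs List of `g4_motif` (e.g. from [realize_library()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_library_csv <- function(motifs, path) {
  df <- data.frame(
    label = vapply(motifs, function(m)
      if (is.na(m$label)) format(m$spec) else m$label, character(1)),
    level = vapply(motifs, function(m) m$spec$level, character(1)),
    tract_length = vapply(motifs, function(m) m$spec$tract_length, integer(1)),
    tract_count = vapply(motifs, function(m) m$spec$tract_count, integer(1)),
    loop_lengths = vapply(motifs, function(m)
      paste(m$spec$loop_lengths, collapse = ";"), character(1)),
    loop_policy = vapply(motifs, function(m) m$policy, character(1)),
    sequence = vapply(motifs, function(m) m$sequence, character(1)),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header("library manifest"), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a motif library manifest
#'
#' @param path CSV path written by [write_library_csv()].
#' @return Data.frame with the manifest columns.
#' @export
read_library_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write motif sequences as FASTA
#'
#' One record per motif, id = label (falling back to the spec signature),
#' wrapped at 60 columns.
#'
#' @param motifs List of `g4_motif`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_motif_fasta <- function(motifs, path) {
  seqs <- vapply(motifs, function(m) m$sequence, character(1))
  ids <- vapply(motifs, function(m)
    if (is.na(m$label)) format(m$spec) else m$label, character(1))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read motif sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_motif_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' Write an activity table to CSV
#'
#' @param records Activity data.frame (one row per measurement).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header("activity table"), con)
  utils::write.csv(records, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an activity table
#'
#' @param path CSV path written by [write_activity_csv()].
#' @return Data.frame.
#' @export
read_activity_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Serialize a fitted activity model to JSON
#'
#' @param model A [fit_activity_model()] object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "g4_activity_model"))
  payload <- list(
    package = "g4tune",
    version = as.character(utils::packageVersion("g4tune")),
    level = model$level,
    coefficients = as.list(model$coefficients),
    r_squared = model$r_squared,
    f_statistic = model$f_statistic,
    f_pvalue = model$f_pvalue,
    n = model$n,
    sigma = model$sigma
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted activity model from JSON
#'
#' @param path JSON path written by [write_model_json()].
#' @return A `g4_activity_model`.
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(level = p$level, coefficients = unlist(p$coefficients),
         r_squared = p$r_squared, f_statistic = p$f_statistic,
         f_pvalue = p$f_pvalue, n = p$n, sigma = p$sigma),
    class = "g4_activity_model"
  )
}

#' Write PQS hits as a BED-like TSV
#'
#' Columns: seqid, start, end (0-based half-open), score, tract_length,
#' n_tracts, tract_starts, loop_lengths.
#'
#' @param hits `pqs_hits` data.frame from [find_pqs()].
#' @param seqid Sequence identifier for the first column.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pqs_tsv <- function(hits, seqid, path) {
  out <- data.frame(seqid = rep(seqid, nrow(hits)),
                    hits[, c("start", "end", "score", "tract_length",
                             "n_tracts", "tract_starts", "loop_lengths")],
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header("pqs hits (0-based half-open)"), con)
  utils::write.table(out, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an expression cassette as a GenBank flat file
#'
#' Emits a minimal GenBank record with 1-based inclusive feature coordinates
#' derived from the cassette's segment map: promoter segments, the 5'UTR,
#' each insertion as a `misc_feature` (DNA-level insertions annotated on the
#' minus strand, where the G-rich motif resides), the CDS, and the 3'UTR.
#'
#' @param cassette An [expression_cassette()].
#' @param path Output path.
#' @param locus Locus name for the header.
#' @return `path`, invisibly.
#' @export
write_cassette_genbank <- function(cassette, path, locus = "g4_cassette") {
  stopifnot(inherits(cassette, "expression_cassette"))
  sm <- cassette$segment_map
  seq <- tolower(cassette$assembled)
  n <- nchar(seq)
  ins_levels <- stats::setNames(
    vapply(cassette$insertions, `[[`, character(1), "level"),
    vapply(cassette$insertions, `[[`, character(1), "motif_id"))

  feature_for <- function(name, start, end) {
    loc <- sprintf("%d..%d", start + 1L, end)  # 1-based inclusive
    if (startsWith(name, "insert:")) {
      id <- sub("^insert:", "", name)
      strand_minus <- identical(unname(ins_levels[id]), "DNA")
      c(sprintf("     misc_feature    %s",
                if (strand_minus) sprintf("complement(%s)", loc) else loc),
        sprintf("                     /label=\"%s\"", id),
        sprintf("                     /note=\"G4 %s-level insertion\"",
                unname(ins_levels[id])))
    } else {
      key <- switch(name,
                    proximal_promoter = "promoter",
                    core_promoter = "promoter",
                    utr = "5'UTR",
                    utr3 = "3'UTR",
                    cds = "CDS")
      c(sprintf("     %-16s%s",
                if (key %in% c("5'UTR", "3'UTR")) "misc_feature" else key,
                loc),
        sprintf("                     /label=\"%s\"", name))
    }
  }

  lines <- c(
    sprintf("LOCUS       %s %d bp    DNA     linear   SYN", locus, n),
    "DEFINITION  Synthetic G4 expression cassette (g4tune).",
    "FEATURES             Location/Qualifiers",
    unlist(lapply(seq_len(nrow(sm)), function(i)
      feature_for(sm$name[i], sm$start[i], sm$end[i]))),
    "ORIGIN"
  )
  for (i in seq(1L, n, by = 60L)) {
    chunk <- substr(seq, i, min(i + 59L, n))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", i, paste(blocks, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}
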