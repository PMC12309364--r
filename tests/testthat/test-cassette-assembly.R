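cds_stub <- "ATGGTGAGCAAGGGCGAGGAGCTGTTCACC"

test_that("BPCU assembly arithmetic and validation", {
  bp <- assemble_bpcu()
  expect_equal(nchar(bp$core_promoter) + nchar(bp$utr), 98)
  expect_equal(bp$tss_index, 41)
  expect_true(bp$utr_is_placeholder)

  custom <- assemble_bpcu(utr = strrep("ACT", 20))
  expect_equal(nchar(custom$core_promoter) + nchar(custom$utr), 101)
  expect_equal(custom$tss_index, 41)
  expect_false(custom$utr_is_placeholder)

  expect_error(assemble_bpcu(utr = ""), "non-empty")
  expect_error(assemble_bpcu(core_promoter = "ACGX"), "not DNA")
})

test_that("insertion strand semantics follow the level", {
  bp <- assemble_bpcu()
  cas <- expression_cassette(bp, cds_stub)

  # DNA motif at -1: the coding strand gains the reverse complement (all-G
  # content becomes all-C) immediately 5' of the TSS
  gg <- strrep("G", 16)
  cas_d <- insert_motif(cas, gg, -1, motif_id = "g16", level = "DNA")
  expect_identical(substr(cas_d$assembled, 42, 57), strrep("C", 16))
  expect_identical(substr(cas_d$assembled, 1, 41), bp$core_promoter)
  expect_identical(substr(cas_d$assembled, 58, 58 + 56), bp$utr)

  # RNA motif at +6: first 6 UTR nt, then the motif verbatim (T alphabet),
  # then the remaining 51 nt
  rna <- assign_loops(g4_spec("RNA", 4, 4, 3), "fixed", "AUC")
  cas_r <- insert_motif(cas, rna, 6, motif_id = "r13")
  utr_region <- substr(cas_r$assembled, 42, 42 + 57 + 25 - 1)
  expect_identical(utr_region,
                   paste0(substr(bp$utr, 1, 6),
                          chartr("U", "T", rna$sequence),
                          substr(bp$utr, 7, 57)))

  # level/sign rule
  expect_error(insert_motif(cas, gg, 3, level = "DNA"), "negative")
  expect_error(insert_motif(cas, rna, -2), "positive")
  expect_error(insert_motif(cas, gg, -42, level = "DNA"), "outside")
  expect_error(insert_motif(cas, rna, 58), "outside")
  expect_error(insert_motif(cas, gg, 0, level = "DNA"), "no 0")
})

test_that("segment map tiles exactly and insertions round-trip", {
  bp <- assemble_bpcu()
  cas0 <- expression_cassette(bp, cds_stub, proximal_promoter = "TTGACAAG",
                              utr3 = "AATAAAGC")
  dna <- assign_loops(g4_spec("DNA", 4, 4, 3), "fixed", "ATC")
  rna <- assign_loops(g4_spec("RNA", 3, 4, 2), "balanced")
  cas <- insert_motif(cas0, dna, -1, motif_id = "d13")
  cas <- insert_motif(cas, rna, 6, motif_id = "r1")

  sm <- cas$segment_map
  expect_equal(sm$start, c(0L, head(sm$end, -1)))
  expect_equal(sum(sm$end - sm$start), nchar(cas$assembled))
  expect_setequal(c("insert:d13", "insert:r1"),
                  sm$name[startsWith(sm$name, "insert:")])

  # reverse-complement involution: re-extract the template-strand motif
  ins <- cas$insertions[[1]]
  back <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(ins$inserted_seq)))
  expect_identical(back, dna$sequence)

  # removal restores the unengineered assembly byte-identically
  restored <- remove_insertion(remove_insertion(cas, "r1"), "d13")
  expect_identical(restored$assembled, cas0$assembled)
  expect_identical(restored$segment_map, cas0$segment_map)
  expect_error(remove_insertion(cas, "nope"), "no insertion")
})

test_that("length bookkeeping holds for random insertion sets", {
  set.seed(9)
  bp <- assemble_bpcu()
  for (trial in 1:15) {
    cas <- expression_cassette(bp, cds_stub)
    base_len <- nchar(cas$assembled)
    total_ins <- 0L
    n_ins <- sample(1:4, 1)
    dna_pos <- sample(-41:-1, n_ins)
    rna_pos <- sample(1:57, n_ins)
    for (k in seq_len(n_ins)) {
      tc <- sample(4:6, 1)
      d <- assign_loops(g4_spec("DNA", sample(2:5, 1), tc,
                                sample(1:4, tc - 1, replace = TRUE)),
                        "balanced")
      r <- assign_loops(g4_spec("RNA", sample(2:5, 1), 4,
                                sample(1:4, 3, replace = TRUE)), "balanced")
      cas <- insert_motif(cas, d, dna_pos[k], motif_id = paste0("d", k))
      cas <- insert_motif(cas, r, rna_pos[k], motif_id = paste0("r", k))
      total_ins <- total_ins + nchar(d$sequence) + nchar(r$sequence)
    }
    expect_equal(nchar(cas$assembled), base_len + total_ins)
    sm <- cas$segment_map
    expect_equal(sm$start, c(0L, head(sm$end, -1)))
  }
})

test_that("transcripts start at the TSS and carry only RNA-level insertions", {
  bp <- assemble_bpcu()
  cas <- expression_cassette(bp, cds_stub)
  tx0 <- transcript_of(cas)
  expect_identical(as.character(tx0),
                   chartr("T", "U", paste0(bp$utr, cds_stub)))
  expect_equal(attr(tx0, "cds_offset"), 57)

  rna <- assign_loops(g4_spec("RNA", 4, 4, 3), "fixed", "AUC")
  tx_r <- transcript_of(insert_motif(cas, rna, 6, motif_id = "r"))
  expect_identical(substr(as.character(tx_r), 1, 6 + 25),
                   paste0(chartr("T", "U", substr(bp$utr, 1, 6)),
                          rna$sequence))
  expect_equal(attr(tx_r, "cds_offset"), 57 + 25)

  dna <- assign_loops(g4_spec("DNA", 4, 4, 3), "fixed", "ATC")
  tx_d <- transcript_of(insert_motif(cas, dna, -1, motif_id = "d"))
  expect_identical(as.character(tx_d), as.character(tx0))
})

test_that("upstream start-codon screen flags exactly the AU-ending loops", {
  bp <- assemble_bpcu()
  cas <- expression_cassette(bp, cds_stub)
  spec_r <- g4_spec("RNA", 4, 4, 3)

  aau <- insert_motif(cas, assign_loops(spec_r, "fixed", "AAU"), 6,
                      motif_id = "v")
  expect_gt(length(scan_upstream_starts(transcript_of(aau))), 0)
  auc <- insert_motif(cas, assign_loops(spec_r, "fixed", "AUC"), 6,
                      motif_id = "v")
  expect_length(scan_upstream_starts(transcript_of(auc)), 0)

  vars <- enumerate_loop_variants(spec_r)
  flagged <- vapply(vars, function(v) {
    cc <- insert_motif(cas, v, 6, motif_id = "v")
    length(scan_upstream_starts(transcript_of(cc))) > 0
  }, logical(1))
  expect_equal(sum(flagged), 3)
  expect_setequal(vapply(vars[flagged], function(v) v$loop_seqs[1], ""),
                  c("AAU", "UAU", "CAU"))
})

test_that("candidate site panels respect the level/sign rule", {
  expect_equal(nrow(candidate_sites()), 13)
  expect_equal(sum(candidate_sites()$level == "DNA"), 7)
  minimal <- candidate_sites(list())
  expect_equal(nrow(minimal), 2)
  expect_setequal(minimal$position, c(-1L, 6L))
  expect_error(candidate_sites(list(dna = c(-5, 3), rna = 6)), "negative")
  expect_error(candidate_sites(list(dna = -1, rna = -6)), "positive")
})
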