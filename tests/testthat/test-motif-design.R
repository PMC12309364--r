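test_that("spec construction rejects invalid design parameters", {
  expect_error(g4_spec("DNA", 1, 4, 2), "tract_length")
  expect_error(g4_spec("DNA", 4, 3, 2), "tract_count")
  expect_error(g4_spec("DNA", 4, 4, 0), "loop length")
  expect_error(g4_spec("DNA", 4, 4, c(2, 2)), "loop lengths")
  sp <- g4_spec("rna", 4, 5, 3)
  expect_equal(sp$level, "RNA")
  expect_length(sp$loop_lengths, 4)
})

test_that("full-factorial enumeration matches brute-force set arithmetic", {
  lib <- enumerate_library()
  expect_equal(nrow(lib), 80)
  expect_equal(nrow(enumerate_library(strategy_ii = NULL, levels = "DNA")), 25)
  expect_equal(nrow(enumerate_library(strategy_i = NULL, levels = "DNA")), 20)

  # collapsing both strategies to the shared point leaves one spec after dedup
  one <- enumerate_library(
    strategy_i = list(tract_length = 4, loop_length = 2, tract_count = 4),
    strategy_ii = list(tract_length = 4, tract_count = 4, loop_length = 2),
    levels = "DNA")
  expect_equal(nrow(one), 1)

  # |union| = |i| + |ii| - |overlap| for random ranges, against a set oracle
  set.seed(11)
  for (trial in 1:10) {
    tl_i <- sort(sample(2:7, sample(2:4, 1)))
    ll_i <- sort(sample(1:6, sample(2:4, 1)))
    tl_ii <- sort(sample(2:7, sample(2:4, 1)))
    tc_ii <- sort(sample(4:8, sample(2:3, 1)))
    ll_ii <- sample(1:6, 1)
    lib2 <- enumerate_library(
      strategy_i = list(tract_length = tl_i, loop_length = ll_i,
                        tract_count = 4),
      strategy_ii = list(tract_length = tl_ii, tract_count = tc_ii,
                         loop_length = ll_ii),
      levels = "DNA")
    set_i <- unique(apply(expand.grid(tl_i, 4, ll_i), 1, paste, collapse = "|"))
    set_ii <- unique(apply(expand.grid(tl_ii, tc_ii, ll_ii), 1, paste,
                           collapse = "|"))
    expect_equal(nrow(lib2), length(union(set_i, set_ii)))
  }

  expect_error(enumerate_library(
    strategy_i = list(tract_length = 2:6, loop_length = 1:5, tract_count = 3)),
    "tract_count")
  expect_error(enumerate_library(strategy_i = NULL, strategy_ii = NULL),
               "at least one strategy")
})

test_that("enumeration order is deterministic: strategy i first, lexicographic", {
  lib <- enumerate_library(levels = "DNA")
  first_ii <- which(lib$strategy == "ii")[1]
  expect_true(all(lib$strategy[seq_len(first_ii - 1)] == "i"))
  blk_i <- lib[lib$strategy == "i", ]
  expect_false(is.unsorted(blk_i$tract_length))
  expect_identical(lib, enumerate_library(levels = "DNA"))
})

test_that("realized motifs satisfy the structural invariants", {
  set.seed(3)
  for (trial in 1:40) {
    level <- sample(c("DNA", "RNA"), 1)
    tc <- sample(4:7, 1)
    sp <- g4_spec(level, sample(2:6, 1), tc,
                  sample(1:5, tc - 1, replace = TRUE))
    m <- assign_loops(sp, "balanced")
    expect_equal(nchar(m$sequence),
                 sp$tract_count * sp$tract_length + sum(sp$loop_lengths))
    tract <- strrep("G", sp$tract_length)
    # strict tract/loop alternation: rebuilding from parts reproduces it
    rebuilt <- paste0(tract, paste0(vapply(m$loop_seqs, paste0, "", tract),
                                    collapse = ""))
    expect_identical(m$sequence, rebuilt)
    loops <- paste(m$loop_seqs, collapse = "")
    expect_false(grepl("G", loops))
    if (level == "RNA") expect_false(grepl("T", m$sequence))
    counts <- table(factor(strsplit(loops, "")[[1]],
                           levels = if (level == "RNA") c("A", "U", "C")
                                    else c("A", "T", "C")))
    expect_lte(max(counts) - min(counts), 1)
    # determinism
    expect_identical(assign_loops(sp, "balanced")$sequence, m$sequence)
  }
})

test_that("fixed-loop realization and the loop-permutation scan", {
  m13 <- g4_spec("DNA", 4, 4, 3)
  expect_identical(assign_loops(m13, "fixed", "ATC")$sequence,
                   "GGGGATCGGGGATCGGGGATCGGGG")
  # the shorter G3 rendering sometimes quoted for the same architecture
  expect_identical(assign_loops(g4_spec("DNA", 3, 4, 3), "fixed",
                                "ATC")$sequence,
                   "GGGATCGGGATCGGGATCGGG")

  # loops totalling 6 nt balance exactly
  m6 <- assign_loops(g4_spec("DNA", 3, 4, 2), "balanced")
  loops <- strsplit(paste(m6$loop_seqs, collapse = ""), "")[[1]]
  expect_equal(unname(table(loops)[c("A", "T", "C")]),
               c(2L, 2L, 2L), ignore_attr = TRUE)

  vars <- enumerate_loop_variants(m13)
  expect_length(vars, 27)
  expect_equal(anyDuplicated(vapply(vars, function(v) v$sequence, "")), 0)
  # RNA level renders the same permutations in the U alphabet
  vars_r <- enumerate_loop_variants(g4_spec("RNA", 4, 4, 3))
  expect_true(all(grepl("^[GAUC]+$",
                        vapply(vars_r, function(v) v$sequence, ""))))

  expect_error(assign_loops(m13, "fixed", "AGC"), "no G")
  expect_error(assign_loops(m13, "fixed", "AT"), "does not match")
  expect_error(assign_loops(m13, "fixed"), "required")
})

test_that("mutant design finds the minimal G->A substitution set", {
  m4 <- assign_loops(g4_spec("DNA", 2, 4, 3), "fixed", "ATC")
  expect_identical(m4$sequence, "GGATCGGATCGGATCGG")
  mu <- design_mutant(m4, min_tract = 2)
  expect_equal(mu$n_substitutions, 1)
  expect_false(is_pqs_positive(mu$sequence, min_tract = 2))

  m13 <- assign_loops(g4_spec("DNA", 4, 4, 3), "fixed", "ATC")
  mu13 <- design_mutant(m13, min_tract = 3)
  expect_equal(nchar(mu13$sequence), 25)
  p <- strsplit(m13$sequence, "")[[1]]
  q <- strsplit(mu13$sequence, "")[[1]]
  diffs <- which(p != q)
  expect_true(all(p[diffs] == "G" & q[diffs] == "A"))
  expect_setequal(diffs - 1L, mu13$substitution_positions)

  # minimality vs the exhaustive substitution-search oracle
  for (tc in c(5L, 6L)) {
    m <- assign_loops(g4_spec("DNA", 3, tc, 2), "balanced")
    mu <- design_mutant(m)
    expect_equal(mu$n_substitutions,
                 oracle_min_substitutions(m$sequence, min_tract = 3))
    expect_false(is_pqs_positive(mu$sequence, min_tract = 3))
  }

  # PQS-negative input violates the precondition
  neg <- structure(list(spec = g4_spec("DNA", 4, 4, 3), policy = "fixed",
                        loop_seqs = rep("ATC", 3), label = NA_character_,
                        sequence = "AAATCAAATCAAATCAAA"),
                   class = "g4_motif")
  expect_error(design_mutant(neg, min_tract = 4), "not PQS-positive")

  # substitution cap exceeded is an explicit failure
  m5 <- assign_loops(g4_spec("DNA", 2, 5, 2), "balanced")
  expect_error(design_mutant(m5, min_tract = 2, max_substitutions = 1),
               "no G->A substitution set")
})

test_that("component names round to the nearest 5 and disambiguate collisions", {
  expect_identical(name_component("DNA", 68.7), "DNA.70REU")
  expect_identical(name_component("RNA", 0), "RNA.0REU")
  expect_identical(name_component("DNA", 67.5), "DNA.70REU")  # half rounds up
  expect_identical(name_component("DNA", 62.4), "DNA.60REU")
  reg <- c("DNA.50REU", "DNA.50REU.2")
  expect_identical(name_component("DNA", 50, existing = "DNA.50REU"),
                   "DNA.50REU.2")
  expect_identical(name_component("DNA", 51, existing = reg), "DNA.50REU.3")
  expect_error(name_component("DNA", -1), "non-negative")
  m <- assign_loops(g4_spec("RNA", 4, 4, 3), "balanced")
  expect_identical(name_component(m, 24.9), "RNA.25REU")
})
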