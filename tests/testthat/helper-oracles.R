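# Independent oracles used by the tests: a brute-force PQS decomposition
# search, a decomposition validator, random sequence generation, and a
# multiresolution grid-search least-squares fitter.

# Brute-force PQS existence: depth-first search over all uniform-tract-length
# decompositions. Independent of the scanner's dynamic program.
oracle_pqs_positive <- function(sequence, min_tract = 2L, max_loop = 7L,
                                min_tracts = 4L) {
  s <- chartr("U", "T", toupper(sequence))
  n <- nchar(s)
  if (n == 0L) return(FALSE)
  isG <- strsplit(s, "")[[1]] == "G"
  for (t in min_tract:n) {
    if (t * min_tracts + (min_tracts - 1L) > n) break
    ok <- vapply(seq_len(n - t + 1L),
                 function(i) all(isG[i:(i + t - 1L)]), logical(1))
    starts <- which(ok)
    if (length(starts) < min_tracts) next
    extend <- function(s0, depth) {
      if (depth == min_tracts) return(TRUE)
      nxt <- starts[starts - (s0 + t) >= 1L & starts - (s0 + t) <= max_loop]
      for (sn in nxt) if (extend(sn, depth + 1L)) return(TRUE)
      FALSE
    }
    for (s0 in starts) if (extend(s0, 1L)) return(TRUE)
  }
  FALSE
}

# Validate that a reported hit row is a legal decomposition of the sequence.
oracle_valid_hit <- function(sequence, hit, min_tract, max_loop, min_tracts) {
  s <- chartr("U", "T", toupper(sequence))
  chars <- strsplit(s, "")[[1]]
  starts0 <- as.integer(strsplit(hit$tract_starts, ",")[[1]])  # 0-based
  t <- hit$tract_length
  loops <- as.integer(strsplit(hit$loop_lengths, ",")[[1]])
  all(
    t >= min_tract,
    length(starts0) >= min_tracts,
    length(loops) == length(starts0) - 1L,
    all(loops >= 1L & loops <= max_loop),
    all(diff(starts0) == t + loops),
    hit$end - hit$start == length(starts0) * t + sum(loops),
    hit$start == starts0[1],
    all(vapply(starts0, function(p) all(chars[(p + 1):(p + t)] == "G"),
               logical(1)))
  )
}

# Brute-force minimal disabling substitution count: try every k-subset of G
# positions, smallest k first, judging candidates with the brute-force
# existence oracle.
oracle_min_substitutions <- function(sequence, min_tract, max_loop = 7L,
                                     min_tracts = 4L, cap = 6L) {
  chars <- strsplit(sequence, "")[[1]]
  g_pos <- which(chars == "G")
  for (k in seq_len(cap)) {
    subsets <- utils::combn(g_pos, k)
    for (j in seq_len(ncol(subsets))) {
      cand <- chars
      cand[subsets[, j]] <- "A"
      if (!oracle_pqs_positive(paste(cand, collapse = ""), min_tract,
                               max_loop, min_tracts)) {
        return(k)
      }
    }
  }
  NA_integer_
}

random_seq <- function(len, g_prob = 0.35) {
  other <- (1 - g_prob) / 3
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c(other, other, g_prob, other)), collapse = "")
}

# Multiresolution grid search minimizing the residual sum of squares over
# (intercept, beta1..beta3); independent of the normal-equations solver.
grid_search_ls <- function(X, y, center = c(mean(y), 0, 0, 0),
                           width = 128, iterations = 22L) {
  sse <- function(b) sum((y - as.vector(X %*% b))^2)
  best <- center
  best_val <- sse(best)
  for (it in seq_len(iterations)) {
    # pattern-search sweeps at the current resolution until no improvement
    repeat {
      improved <- FALSE
      for (j in seq_along(best)) {
        for (o in c(-width, width)) {
          b <- best; b[j] <- b[j] + o
          v <- sse(b)
          if (v < best_val) { best <- b; best_val <- v; improved <- TRUE }
        }
      }
      if (!improved) break
    }
    width <- width / 2
  }
  best
}
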