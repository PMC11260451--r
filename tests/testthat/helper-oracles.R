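# Independent oracles used to freeze expected values: brute-force set logic,
# hypergeometric tail enumeration, closed-form chi-square, exhaustive
# split-point search, and a plain dynamic-programming local aligner.

oracle_soi <- function(cell, ctdna, coculture) {
  out <- character(0)
  for (k in unique(c(ctdna, coculture))) {
    if (any(ctdna == k) && any(coculture == k) && !any(cell == k))
      out <- c(out, k)
  }
  out
}

# Two-sided exact p for a 2x2 table [[a, b], [c, d]] by enumerating all
# tables with the observed margins and summing hypergeometric probabilities
# not exceeding the observed one.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)), numeric(1))
  obs <- probs[a - lo + 1L]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Pearson chi-square for a 2x2 table, hand-expanded closed form.
oracle_chisq <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Exhaustive split-point oracle: the largest s such that the first s bases
# of the contig occur in the cell genome and the remainder occurs in the
# fragment core. Every split is tested by literal substring search.
oracle_split <- function(contig, cell_seqs, core) {
  L <- nchar(contig)
  best <- NA_integer_
  for (s in seq_len(L - 1L)) {
    prefix <- substr(contig, 1L, s)
    suffix <- substr(contig, s + 1L, L)
    pre_ok <- any(vapply(cell_seqs, function(g) grepl(prefix, g, fixed = TRUE),
                         logical(1)))
    if (!pre_ok) break  # prefix matching is monotone in s
    if (grepl(suffix, core, fixed = TRUE)) best <- s
  }
  best
}

# Affine-gap Smith-Waterman in plain R (match/mismatch scores, gap open paid
# on the first gap base: open + extend, then extend per base).
oracle_sw_score <- function(a, b, match = 2, mismatch = -3, gap_open = 5,
                            gap_extend = 2) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  M <- matrix(0, n + 1, m + 1)   # match/mismatch state
  X <- matrix(-Inf, n + 1, m + 1) # gap in y
  Y <- matrix(-Inf, n + 1, m + 1) # gap in x
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Random variant-key sets for set-logic tests.
random_key_sets <- function(pool_size = 300, n = 100) {
  pool <- sprintf("chr%d:%d:A:G", sample(1:3, pool_size, TRUE),
                  sample.int(1e5, pool_size, TRUE))
  list(cell = sample(pool, n, TRUE), ctdna = sample(pool, n, TRUE),
       coculture = sample(pool, n, TRUE))
}

# Small simulated world shared by several tests (20-kb cell genome).
small_world <- function(seed = 1, n_snvs = 40, n_contigs = 2L,
                        contig_length = 1e4) {
  simulate_genomes(list(n_contigs = n_contigs, contig_length = contig_length,
                        donor_snv_count = n_snvs), seed = seed)
}
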