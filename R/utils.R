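#' @importFrom stats rbinom rnorm rpois runif setNames chisq.test fisher.test
#'   ppois qnorm
#' @importFrom utils head write.table read.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Uniform random DNA string of length n (no Ns).
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Reverse complement of plain character strings (vectorized; fast path for
# equal-length vectors such as read sets).
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  n <- nchar(x)
  comp <- chartr("ACGT", "TGCA", x)
  if (length(unique(n)) == 1L) {
    out <- do.call(paste0, lapply(seq(n[1], 1L), function(i)
      substring(comp, i, i)))
  } else {
    out <- vapply(comp, function(s) {
      paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  names(out) <- names(x)
  out
}

# All k-mers of a string as a character vector (empty when too short).
seq_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(x, starts, starts + k - 1L)
}

# Count mismatching characters between two equal-length strings.
str_mismatches <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# Map a nucleotide string to integer codes A=1 C=2 G=3 T=4 (others 0).
base_ints <- function(x) {
  code <- integer(128)
  code[utf8ToInt("A")] <- 1L
  code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L
  code[utf8ToInt("T")] <- 4L
  code[utf8ToInt(x)]
}

#' Build a unique k-mer index over a set of sequences
#'
#' Internal anchor index used by the read mapper, the transition detector and
#' the discordant-pair caller. Only k-mers occurring exactly once across the
#' whole sequence set are retained, so every anchor placement is unambiguous.
#'
#' @param seqs named character vector of sequences.
#' @param k k-mer length.
#' @return list with `kmers`, parallel `seq_name` and 0-based `pos`, plus `k`.
#' @keywords internal
kmer_index <- function(seqs, k) {
  stopifnot(length(seqs) > 0, !is.null(names(seqs)))
  km <- lapply(unname(seqs), seq_kmers, k = k)
  n_per <- lengths(km)
  km <- unlist(km, use.names = FALSE)
  seq_name <- rep(names(seqs), n_per)
  pos <- unlist(lapply(n_per, function(n) seq_len(n) - 1L), use.names = FALSE)
  dup <- duplicated(km) | duplicated(km, fromLast = TRUE)
  list(kmers = km[!dup], seq_name = seq_name[!dup], pos = pos[!dup], k = k)
}

# Anchor index over fragment cores: k-mers duplicated across different
# sequences keep their first occurrence (overlapping fragments share donor
# sequence and either attribution is valid); k-mers repeated within one
# sequence are dropped as positionally ambiguous.
frag_kmer_index <- function(seqs, k) {
  km <- lapply(unname(seqs), seq_kmers, k = k)
  n_per <- lengths(km)
  km <- unlist(km, use.names = FALSE)
  seq_name <- rep(names(seqs), n_per)
  pos <- unlist(lapply(n_per, function(n) seq_len(n) - 1L), use.names = FALSE)
  within_key <- paste(km, seq_name, sep = "\r")
  bad <- km %in% km[duplicated(within_key)]
  keep <- !bad & !duplicated(km)
  list(kmers = km[keep], seq_name = seq_name[keep], pos = pos[keep], k = k)
}

# Look up k-mers in an index; returns data.frame with NA rows for misses.
kmer_lookup <- function(index, kmers) {
  i <- match(kmers, index$kmers)
  data.frame(seq_name = index$seq_name[i], pos = index$pos[i],
             stringsAsFactors = FALSE)
}

# Derive a bounded stage seed from a master seed (keeps within 32-bit range).
stage_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 10007L) %% 2147483600L
}

# 95% binomial confidence bounds (normal approximation) for a proportion.
binom_bounds95 <- function(p, n) {
  se <- sqrt(p * (1 - p) / n)
  c(lower = p - 1.96 * se, upper = p + 1.96 * se)
}

stop_param <- function(...) stop(..., call. = FALSE)
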