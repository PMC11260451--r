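#' Find discordant read pairs between the cell genome and a cassette
#'
#' A pair is discordant when one mate anchors uniquely on the cell genome
#' and the other anchors uniquely on the transgene cassette — the signature
#' of a cassette integration junction. The cassette is first checked for
#' homology with the cell genome: any shared `anchor_k`-mer is an ambiguous
#' design and a hard error. Pairs with both mates on the cassette (internal
#' pairs) and concordant genome pairs are discarded.
#'
#' @param reads a `read_set`.
#' @param cell_ref cell `genome_sequence`.
#' @param cassette cassette `genome_sequence` (single contig).
#' @param anchor_k anchor k-mer length.
#' @param max_mismatch_frac mapping mismatch tolerance per mate.
#' @return data.frame of class `discordant_pairs` with the genome-side and
#'   cassette-side anchors of each pair.
#' @export
find_discordant_pairs <- function(reads, cell_ref, cassette, anchor_k = 25,
                                  max_mismatch_frac = 0.1) {
  cass_name <- names(cassette$sequences)[1]
  cass_kmers <- unique(c(seq_kmers(cassette$sequences[[1]], anchor_k),
                         seq_kmers(revcomp(cassette$sequences[[1]]), anchor_k)))
  cell_kmers <- unlist(lapply(cell_ref$sequences, seq_kmers, k = anchor_k),
                       use.names = FALSE)
  if (any(cass_kmers %in% cell_kmers))
    stop_param("cassette shares >= ", anchor_k,
               "-mer homology with the cell genome; design is ambiguous")

  rl <- reads$read_length
  cell_1 <- map_single_end(reads$r1, cell_ref, anchor_k, max_mismatch_frac)
  cell_2 <- map_single_end(reads$r2, cell_ref, anchor_k, max_mismatch_frac)
  cass_1 <- map_single_end(reads$r1, cassette, anchor_k, max_mismatch_frac)
  cass_2 <- map_single_end(reads$r2, cassette, anchor_k, max_mismatch_frac)

  rows <- list()
  ids <- names(reads$r1)
  for (cfg in list(list(g = cell_1, c = cass_2, gmate = "R1"),
                   list(g = cell_2, c = cass_1, gmate = "R2"))) {
    sel <- which(!is.na(cfg$g$start) & !is.na(cfg$c$start) &
                 is.na(if (cfg$gmate == "R1") cass_1$start else cass_2$start) &
                 is.na(if (cfg$gmate == "R1") cell_2$start else cell_1$start))
    if (!length(sel)) next
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = ids[sel], genome_mate = cfg$gmate,
      contig = cfg$g$contig[sel], pos = cfg$g$start[sel],
      strand = cfg$g$strand[sel],
      cassette_pos = cfg$c$start[sel], cassette_strand = cfg$c$strand[sel],
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(0), genome_mate = character(0),
               contig = character(0), pos = integer(0), strand = character(0),
               cassette_pos = integer(0), cassette_strand = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$pos, out$read_id), ]
  rownames(out) <- NULL
  attr(out, "n_pairs_total") <- length(reads$r1)
  attr(out, "read_length") <- rl
  class(out) <- c("discordant_pairs", "data.frame")
  out
}

# Map single-end reads by unique k-mer anchor; NA where no confident unique
# placement exists.
map_single_end <- function(v, reference, anchor_k, max_mismatch_frac) {
  idx <- kmer_index(reference$sequences, anchor_k)
  n <- length(v)
  rl <- nchar(v[1])
  lens <- nchar(reference$sequences)
  res <- data.frame(contig = rep(NA_character_, n), start = rep(NA_integer_, n),
                    strand = rep(NA_character_, n), stringsAsFactors = FALSE)
  best_mm <- rep(Inf, n)
  for (orient in c("+", "-")) {
    w <- if (orient == "+") v else revcomp(v)
    for (off in c(0L, rl - anchor_k)) {
      km <- substr(w, off + 1L, off + anchor_k)
      hit <- kmer_lookup(idx, km)
      cand <- which(!is.na(hit$pos))
      if (!length(cand)) next
      start <- hit$pos[cand] - off
      contig <- hit$seq_name[cand]
      ok <- start >= 0L & start + rl <= lens[contig]
      cand <- cand[ok]; start <- start[ok]; contig <- contig[ok]
      if (!length(cand)) next
      refsub <- substring(reference$sequences[contig], start + 1L, start + rl)
      for (j in seq_along(cand)) {
        i <- cand[j]
        mm <- str_mismatches(w[i], refsub[j])
        if (mm < best_mm[i] && mm <= max_mismatch_frac * rl) {
          best_mm[i] <- mm
          res$contig[i] <- contig[j]
          res$start[i] <- start[j]
          res$strand[i] <- orient
        }
      }
    }
  }
  res
}

#' Cluster discordant pairs into transgene insertion sites
#'
#' Single-linkage clustering of genome-side anchors with a gap limit of
#' `insert mean + 3 sd`; clusters below `min_support` pairs are dropped.
#' Confidence is `1 -` the Poisson probability of observing at least the
#' cluster's support under a background discordant-pair rate estimated from
#' the off-cluster discordant density. Frequency is support divided by the
#' expected physical (pair-spanning) coverage of a point, when the total
#' pair count and genome length are known.
#'
#' @param pairs a `discordant_pairs` data.frame.
#' @param insert_model numeric `(mean, sd)` of the library insert size.
#' @param min_support minimum supporting pairs per site (default 3).
#' @param n_pairs_total total read pairs in the library (defaults to the
#'   attribute recorded by [find_discordant_pairs()]).
#' @param genome_length total cell-genome length (for frequency; optional).
#' @return data.frame of class `transgene_sites` with locus, support, side
#'   counts, confidence and frequency.
#' @export
cluster_sites <- function(pairs, insert_model = c(300, 30), min_support = 3,
                          n_pairs_total = attr(pairs, "n_pairs_total"),
                          genome_length = NULL) {
  gap_limit <- insert_model[1] + 3 * insert_model[2]
  rl <- attr(pairs, "read_length")
  if (is.null(rl)) rl <- 150L
  if (!nrow(pairs)) {
    out <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), support = integer(0),
                      left_support = integer(0), right_support = integer(0),
                      confidence = numeric(0), frequency = numeric(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("transgene_sites", "data.frame")
    return(out)
  }
  pairs <- pairs[order(pairs$contig, pairs$pos), ]
  cl <- integer(nrow(pairs))
  cur <- 0L
  for (i in seq_len(nrow(pairs))) {
    if (i == 1 || pairs$contig[i] != pairs$contig[i - 1] ||
        pairs$pos[i] - pairs$pos[i - 1] > gap_limit) cur <- cur + 1L
    cl[i] <- cur
  }
  sizes <- table(cl)
  keep_cl <- as.integer(names(sizes)[sizes >= min_support])
  # background rate from off-cluster pairs
  n_off <- sum(!(cl %in% keep_cl))
  total_len <- if (!is.null(genome_length)) genome_length else
    max(1, sum(tapply(pairs$pos, pairs$contig, max) + rl))
  lambda_bg <- max(n_off / total_len * gap_limit, 1e-8)
  rows <- lapply(keep_cl, function(g) {
    p <- pairs[cl == g, ]
    n <- nrow(p)
    data.frame(contig = p$contig[1], start = min(p$pos),
               end = max(p$pos) + rl, support = n,
               left_support = sum(p$strand == "+"),
               right_support = sum(p$strand == "-"),
               confidence = ppois(n - 1, lambda_bg),
               frequency = if (!is.null(genome_length) &&
                               !is.null(n_pairs_total))
                 n / (n_pairs_total * insert_model[1] / genome_length)
               else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), support = integer(0),
                      left_support = integer(0), right_support = integer(0),
                      confidence = numeric(0), frequency = numeric(0),
                      stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$start), ]
  rownames(out) <- NULL
  class(out) <- c("transgene_sites", "data.frame")
  out
}
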