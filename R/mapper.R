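#' Map a read set to a reference by unique k-mer anchoring
#'
#' Desk-scale read placement: each read is anchored by a k-mer that occurs
#' exactly once in the reference (tried at the read's first and last k-mer,
#' on both strands), placed ungapped, and accepted when its mismatch count is
#' at most `max_mismatch_frac` of the read length. Reads spanning insertion
#' junctions or without a unique anchor are left unmapped, as a conventional
#' aligner would discard or clip them.
#'
#' @param reads a `read_set`.
#' @param reference a `genome_sequence`.
#' @param anchor_k anchor k-mer length.
#' @param max_mismatch_frac maximum tolerated mismatch fraction per read.
#' @return data.frame with `read_id`, `contig`, `start` (0-based), `seq`
#'   (read in reference orientation) and `mismatches`; one row per placed
#'   read. The number of unplaced reads is attached as attribute
#'   `n_unmapped`.
#' @export
map_reads <- function(reads, reference, anchor_k = 21,
                      max_mismatch_frac = 0.1) {
  idx <- kmer_index(reference$sequences, anchor_k)
  rl <- reads$read_length
  v <- c(reads$r1, reads$r2)
  ids <- c(paste0(names(reads$r1), "/1"), paste0(names(reads$r2), "/2"))
  n <- length(v)
  lens <- nchar(reference$sequences)

  best_contig <- rep(NA_character_, n)
  best_start <- rep(NA_integer_, n)
  best_mm <- rep(Inf, n)
  best_seq <- rep(NA_character_, n)

  for (orient in c("fwd", "rc")) {
    w <- if (orient == "fwd") v else revcomp(v)
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
        if (mm < best_mm[i]) {
          best_mm[i] <- mm
          best_contig[i] <- contig[j]
          best_start[i] <- start[j]
          best_seq[i] <- w[i]
        }
      }
    }
  }
  keep <- which(is.finite(best_mm) & best_mm <= max_mismatch_frac * rl)
  out <- data.frame(read_id = ids[keep], contig = best_contig[keep],
                    start = best_start[keep], seq = best_seq[keep],
                    mismatches = best_mm[keep], stringsAsFactors = FALSE)
  attr(out, "n_unmapped") <- n - nrow(out)
  attr(out, "read_length") <- rl
  out
}

#' Build a base-count pileup from mapped reads
#'
#' @param mapped data.frame from [map_reads()].
#' @param reference the `genome_sequence` the reads were mapped to.
#' @return object of class `pileup`: per-contig 4 x L count matrices (rows
#'   A/C/G/T) plus the reference.
#' @export
pileup_from_mapped <- function(mapped, reference) {
  rl <- attr(mapped, "read_length")
  counts <- lapply(reference$sequences, function(s)
    matrix(0L, nrow = 4, ncol = nchar(s), dimnames = list(DNA_BASES, NULL)))
  for (contig in unique(mapped$contig)) {
    rows <- mapped[mapped$contig == contig, ]
    if (!nrow(rows)) next
    bases <- base_ints(paste(rows$seq, collapse = ""))
    pos <- rep(rows$start, each = rl) + seq_len(rl) - 1L  # 0-based
    keep <- bases > 0L
    tab <- tabulate((pos[keep]) * 4L + bases[keep],
                    nbins = 4L * nchar(reference$sequences[[contig]]))
    counts[[contig]] <- matrix(as.integer(tab), nrow = 4,
                               dimnames = list(DNA_BASES, NULL))
  }
  structure(list(counts = counts, reference = reference), class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %d contig(s), mean depth %.1f\n",
              length(x$counts),
              mean(unlist(lapply(x$counts, colSums)))))
  invisible(x)
}

#' Write / read a pileup as TSV
#'
#' Plain-text exchange format for externally produced pileups: columns
#' `contig`, `pos` (1-based), `ref`, `A`, `C`, `G`, `T`. Zero-depth sites may
#' be omitted on ingestion.
#'
#' @param pileup a `pileup` object.
#' @param path TSV file path.
#' @export
write_pileup_tsv <- function(pileup, path) {
  rows <- lapply(names(pileup$counts), function(contig) {
    m <- pileup$counts[[contig]]
    depth <- colSums(m)
    i <- which(depth > 0)
    if (!length(i)) return(NULL)
    data.frame(contig = contig, pos = i,
               ref = substring(pileup$reference$sequences[[contig]], i, i),
               A = m[1, i], C = m[2, i], G = m[3, i], T = m[4, i],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @param reference `genome_sequence` giving contig lengths for the read-back.
#' @export
read_pileup_tsv <- function(path, reference) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c("character", "integer", "character",
                                  "integer", "integer", "integer", "integer"))
  counts <- lapply(reference$sequences, function(s)
    matrix(0L, nrow = 4, ncol = nchar(s), dimnames = list(DNA_BASES, NULL)))
  for (contig in unique(df$contig)) {
    sub <- df[df$contig == contig, ]
    m <- counts[[contig]]
    m[, sub$pos] <- t(as.matrix(sub[, c("A", "C", "G", "T")]))
    counts[[contig]] <- m
  }
  structure(list(counts = counts, reference = reference), class = "pileup")
}
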