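#' Scan sequences for TE consensus hits by local alignment
#'
#' Smith-Waterman-style local alignment of every consensus against each
#' subject, on both strands (match +2, mismatch -3, gap open -5, gap extend
#' -2; configurable). Hits scoring at least `min_score` with percent
#' identity at least `min_identity` are reported; overlapping hits to
#' different elements are resolved by score, then alignment length, then
#' element name, so output is deterministic.
#'
#' @param subjects named character vector of sequences (or a `contig_set` /
#'   `ctdna_fragments`, whose sequences are scanned).
#' @param library a `te_library` data.frame.
#' @param min_score reporting score cutoff (default 40).
#' @param min_identity minimum fractional identity (default 0.8).
#' @param match,mismatch,gap_open,gap_extend alignment scoring parameters.
#' @return data.frame of class `repeat_annotations` with 0-based half-open
#'   subject intervals.
#' @export
scan_repeats <- function(subjects, library, min_score = 40,
                         min_identity = 0.8, match = 2, mismatch = -3,
                         gap_open = 5, gap_extend = 2) {
  if (inherits(subjects, "contig_set"))
    subjects <- setNames(subjects$sequence, subjects$contig_id)
  if (inherits(subjects, "ctdna_fragments"))
    subjects <- setNames(subjects$sequence, subjects$fragment_id)
  if (!nrow(library)) stop_param("TE library is empty")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  # both strands of every consensus aligned in one batched call per subject
  pats <- Biostrings::DNAStringSet(c(library$sequence,
                                     revcomp(library$sequence)))
  pat_name <- rep(library$name, 2)
  pat_class <- rep(library$te_class, 2)
  pat_strand <- rep(c("+", "-"), each = nrow(library))
  rows <- list()
  for (si in seq_along(subjects)) {
    subj <- Biostrings::DNAString(subjects[[si]])
    al <- Biostrings::pairwiseAlignment(
      pats, subj, type = "local", substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend)
    sc <- Biostrings::score(al)
    pid <- Biostrings::pid(al) / 100
    sel <- which(sc >= min_score & pid >= min_identity)
    if (!length(sel)) next
    rng <- Biostrings::subject(al)
    h <- data.frame(
      subject_id = names(subjects)[si],
      te_name = pat_name[sel], te_class = pat_class[sel],
      start = BiocGenerics::start(rng)[sel] - 1L,
      end = BiocGenerics::end(rng)[sel],
      strand = pat_strand[sel], score = sc[sel], pident = pid[sel],
      stringsAsFactors = FALSE)
    # resolve overlaps between different elements: score, length, name
    h <- h[order(-h$score, -(h$end - h$start), h$te_name), ]
    keep <- rep(TRUE, nrow(h))
    for (a in seq_len(nrow(h))) {
      if (!keep[a]) next
      if (a < nrow(h)) for (b in seq(a + 1L, nrow(h))) {
        if (!keep[b]) next
        if (h$te_name[b] != h$te_name[a] &&
            h$start[b] < h$end[a] && h$end[b] > h$start[a])
          keep[b] <- FALSE
      }
    }
    rows[[length(rows) + 1L]] <- h[keep, ]
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(0), te_name = character(0),
               te_class = character(0), start = integer(0), end = integer(0),
               strand = character(0), score = numeric(0), pident = numeric(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$subject_id, out$start, out$te_name), ]
  rownames(out) <- NULL
  class(out) <- c("repeat_annotations", "data.frame")
  out
}

#' Keep TE hits within the transition window on the ctDNA side
#'
#' Applies the transition-window selection rule: only hits whose nearest
#' edge lies within `window` nt (inclusive) of a transition breakpoint, on
#' the ctDNA side of the junction, are retained. When `require_adaptor` is
#' true, transitions without adaptor evidence contribute nothing.
#'
#' @param annotations `repeat_annotations` on contig coordinates.
#' @param transitions `transition_points` sharing the same contigs.
#' @param window window size in nt (default 100, inclusive).
#' @param require_adaptor drop transitions with `adaptor_adjacent = FALSE`.
#' @return the filtered `repeat_annotations`, with `breakpoint_distance`
#'   and `transition_contig` columns added.
#' @export
filter_transition_proximal <- function(annotations, transitions,
                                       window = 100, require_adaptor = TRUE) {
  tr <- transitions
  if (require_adaptor) tr <- tr[tr$adaptor_adjacent, , drop = FALSE]
  keep <- list()
  for (i in seq_len(nrow(tr))) {
    t1 <- tr[i, ]
    ann <- annotations[annotations$subject_id == t1$contig_id, , drop = FALSE]
    if (!nrow(ann)) next
    bp <- t1$breakpoint
    if (t1$orientation == "cell_to_ctdna") {
      side <- ann$end > bp                       # on the ctDNA (right) side
      dist <- pmax(0L, ann$start - bp)
    } else {
      side <- ann$start < bp                     # ctDNA (left) side
      dist <- pmax(0L, bp - ann$end)
    }
    sel <- side & dist <= window
    if (any(sel)) {
      k <- ann[sel, , drop = FALSE]
      k$breakpoint_distance <- dist[sel]
      k$transition_contig <- t1$contig_id
      keep[[length(keep) + 1L]] <- k
    }
  }
  out <- if (length(keep)) unique(do.call(rbind, keep)) else {
    a <- annotations[0, , drop = FALSE]
    a$breakpoint_distance <- integer(0)
    a$transition_contig <- character(0)
    a
  }
  rownames(out) <- NULL
  class(out) <- c("repeat_annotations", "data.frame")
  out
}

#' Chi-square enrichment of TE content in integrated vs non-integrated ctDNA
#'
#' Pearson chi-square test (1 df) on the 2x2 table of TE-positive /
#' TE-negative fragment counts in the integrated and non-integrated arms.
#' Yates continuity correction is off by default and available as a flag.
#' When any expected cell count falls below 5, a warning is emitted and the
#' exact (Fisher) p-value is reported alongside. The odds ratio uses the
#' Haldane 0.5 correction when a zero cell exists.
#'
#' @param integrated logical vector: TE status of each integrated fragment
#'   (or a 2-vector `c(TE+, TE-)` of counts).
#' @param non_integrated same for the non-integrated arm.
#' @param continuity_correction apply the Yates correction.
#' @return object of class `te_enrichment` with the table, chi-square
#'   statistic, df, p-value and odds ratio.
#' @export
enrichment_test <- function(integrated, non_integrated,
                            continuity_correction = FALSE) {
  as_counts <- function(x) {
    if (is.logical(x)) c(sum(x), sum(!x))
    else if (length(x) == 2) as.numeric(x)
    else stop_param("expected a logical vector or a c(TE+, TE-) count pair")
  }
  tab <- rbind(integrated = as_counts(integrated),
               non_integrated = as_counts(non_integrated))
  colnames(tab) <- c("TE+", "TE-")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_param("zero margin: chi-square statistic undefined")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  fisher_p <- NA_real_
  if (any(expected < 5)) {
    warning("expected count < 5; exact test p-value reported alongside")
    fisher_p <- fisher.test(tab)$p.value
  }
  ct <- suppressWarnings(chisq.test(tab, correct = continuity_correction))
  tab_or <- tab
  if (any(tab == 0)) tab_or <- tab + 0.5
  or <- (tab_or[1, 1] * tab_or[2, 2]) / (tab_or[1, 2] * tab_or[2, 1])
  structure(list(table = tab, expected = expected,
                 chi_square = unname(ct$statistic), df = 1L,
                 p_value = unname(ct$p.value), odds_ratio = unname(or),
                 fisher_p = fisher_p,
                 continuity_correction = continuity_correction),
            class = "te_enrichment")
}

#' @export
print.te_enrichment <- function(x, ...) {
  cat("<te_enrichment> chi-square test (1 df",
      if (x$continuity_correction) ", Yates-corrected" else "", ")\n", sep = "")
  print(x$table)
  cat(sprintf("  X-squared = %.4g, p = %.4g, odds ratio = %.3g\n",
              x$chi_square, x$p_value, x$odds_ratio))
  if (!is.na(x$fisher_p))
    cat(sprintf("  exact test p = %.4g (low expected counts)\n", x$fisher_p))
  invisible(x)
}

#' Elements exclusive to matched-coculture insertion sites
#'
#' Selects elements observed at insertion transitions only when donor ctDNA
#' and recipient cell share a tumor type: count > 0 in the matched multiset
#' and 0 in the mismatched multiset, ranked by matched count (ties broken by
#' name).
#'
#' @param matched,mismatched character vectors of element names (one entry
#'   per occurrence; a named count vector/table also works).
#' @return data.frame with `te_name` and `matched_count`, ranked.
#' @export
tissue_specific_elements <- function(matched, mismatched) {
  to_counts <- function(x) {
    if (is.table(x) || (!is.null(names(x)) && is.numeric(x)))
      x <- rep(names(x), as.integer(x))
    table(as.character(x))
  }
  m <- to_counts(matched)
  mm <- to_counts(mismatched)
  excl <- setdiff(names(m), names(mm))
  out <- data.frame(te_name = excl,
                    matched_count = as.integer(m[excl]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$matched_count, out$te_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Proximity statistics of confirmed insertions
#'
#' Fraction of insertion calls landing within `window` bp of the homologous
#' cell locus of their fragment's origin (inter-contig insertions count as
#' non-proximal), plus a per-origin-contig insertion histogram.
#'
#' @param calls an `insertion_calls` data.frame.
#' @param fragments the `ctdna_fragments` (for origin contigs).
#' @param window proximity window in bp.
#' @return list of class `proximity_stats`.
#' @export
proximity_stats <- function(calls, fragments, window = 10000) {
  n <- nrow(calls)
  proximal <- !is.na(calls$distance_to_origin) &
    calls$distance_to_origin <= window
  origin <- fragments$origin_contig[match(calls$fragment_id,
                                          fragments$fragment_id)]
  structure(list(
    n = n,
    proximal_fraction = if (n > 0) mean(proximal) else NA_real_,
    n_inter_contig = sum(is.na(calls$distance_to_origin)),
    origin_histogram = if (n > 0) table(origin) else table(character(0)),
    window = window), class = "proximity_stats")
}

#' @export
print.proximity_stats <- function(x, ...) {
  cat(sprintf("<proximity_stats> %d calls, proximal (<= %d bp): %.1f%%\n",
              x$n, x$window, 100 * x$proximal_fraction))
  if (length(x$origin_histogram)) {
    cat("  insertions by origin contig:\n")
    print(x$origin_histogram)
  }
  invisible(x)
}
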