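#' Build a contig set
#'
#' @param sequences named character vector of contig sequences.
#' @param source one of `"cell"`, `"ctDNA"`, `"coculture"` applied to all
#'   contigs, or a vector.
#' @return data.frame of class `contig_set` with `contig_id`, `sequence`,
#'   `source`.
#' @export
contig_set <- function(sequences, source = "coculture") {
  stopifnot(!is.null(names(sequences)))
  out <- data.frame(contig_id = names(sequences),
                    sequence = unname(sequences),
                    source = rep_len(source, length(sequences)),
                    stringsAsFactors = FALSE)
  class(out) <- c("contig_set", "data.frame")
  out
}

#' Obtain contigs by ingestion, truth-based construction, or greedy assembly
#'
#' Three routes to the contigs the breakpoint analysis consumes:
#' `"ingest"` reads any FASTA (or named character vector); `"perfect"`
#' constructs junction-spanning contigs directly from the simulation truth
#' (each planted insertion/duplication with `flank` bp of cell sequence on
#' each side, plus optional cell-only background windows); `"greedy"` runs a
#' deterministic de Bruijn unitig assembler over a read set, adequate for
#' error-free test data.
#'
#' @param x a FASTA path / named character vector (`ingest`), a
#'   `coculture_truth` (`perfect`), or a `read_set` (`greedy`).
#' @param mode assembly mode.
#' @param source source label for ingested contigs.
#' @param cell,fragments cell genome and `ctdna_fragments` (perfect mode).
#' @param flank flank length around each junction (perfect mode).
#' @param n_background number of cell-only background contigs (perfect mode).
#' @param k k-mer size (greedy mode).
#' @param min_contig minimum emitted contig length (greedy mode).
#' @return a `contig_set`.
#' @export
assemble_or_ingest <- function(x, mode = c("ingest", "perfect", "greedy"),
                               source = "coculture",
                               cell = NULL, fragments = NULL, flank = 500,
                               n_background = 0, k = 31, min_contig = 100) {
  mode <- match.arg(mode)
  if (mode == "ingest") {
    seqs <- if (is.character(x) && length(x) == 1 && file.exists(x)) {
      ss <- Biostrings::readDNAStringSet(x)
      setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
    } else if (is.character(x)) x
    else stop_param("ingest mode expects a FASTA path or named character vector")
    if (!length(seqs)) stop_param("no contigs to ingest")
    return(contig_set(seqs, source))
  }
  if (mode == "perfect") {
    if (is.null(cell)) stop_param("perfect mode requires the cell genome")
    truth <- x
    seqs <- character(0); src <- character(0)
    ins <- truth$planted_insertions
    if (!is.null(ins) && nrow(ins)) {
      if (is.null(fragments)) stop_param("perfect mode requires fragments")
      core <- setNames(fragments$core, fragments$fragment_id)
      for (i in seq_len(nrow(ins))) {
        p <- ins$pos[i]; contig <- ins$contig[i]
        L <- nchar(cell$sequences[[contig]])
        left <- genome_subseq(cell, contig, max(0, p - flank), p)
        right <- genome_subseq(cell, contig, p, min(L, p + flank))
        seqs <- c(seqs, paste0(left, core[[ins$fragment_id[i]]], right))
        src <- c(src, "coculture")
        names(seqs)[length(seqs)] <- sprintf("cc_ins_%03d", i)
      }
    }
    dup <- truth$planted_duplications
    if (!is.null(dup) && nrow(dup)) {
      for (i in seq_len(nrow(dup))) {
        contig <- dup$contig[i]; s <- dup$start[i]; m <- dup$length[i]
        L <- nchar(cell$sequences[[contig]])
        seqs <- c(seqs, paste0(
          genome_subseq(cell, contig, max(0, s - flank), s + m),
          genome_subseq(cell, contig, s, s + m),
          genome_subseq(cell, contig, s + m, min(L, s + m + flank))))
        src <- c(src, "coculture")
        names(seqs)[length(seqs)] <- sprintf("cc_dup_%03d", i)
      }
    }
    if (n_background > 0) {
      contigs <- names(cell$sequences)
      lens <- nchar(cell$sequences)
      for (i in seq_len(n_background)) {
        ci <- 1L + (i - 1L) %% length(contigs)
        w <- 2L * flank
        start <- as.integer((i * 7919L) %% max(1L, lens[ci] - w))
        seqs <- c(seqs, genome_subseq(cell, contigs[ci], start, start + w))
        src <- c(src, "cell")
        names(seqs)[length(seqs)] <- sprintf("cell_bg_%03d", i)
      }
    }
    if (!length(seqs)) stop_param("truth table holds no events to build contigs from")
    return(contig_set(seqs, src))
  }
  # greedy: de Bruijn unitig walk over reads and their reverse complements
  reads <- c(x$r1, x$r2)
  if (!length(reads)) stop_param("empty read set")
  km <- unique(unlist(lapply(c(reads, revcomp(reads)), seq_kmers, k = k),
                      use.names = FALSE))
  km <- sort(km)
  pre <- substr(km, 1L, k - 1L)
  suf <- substr(km, 2L, k)
  succ_of <- function(s) km[match(paste0(s, DNA_BASES), km, nomatch = 0L)]
  succ_count <- rowSums(matrix(paste0(rep(suf, 4), rep(DNA_BASES, each = length(km)))
                               %in% km, ncol = 4))
  pred_count <- rowSums(matrix(paste0(rep(DNA_BASES, each = length(km)),
                                      rep(pre, 4)) %in% km, ncol = 4))
  names(succ_count) <- km; names(pred_count) <- km
  is_start <- pred_count != 1L
  # also start after a branching predecessor
  used <- setNames(rep(FALSE, length(km)), km)
  unitigs <- character(0)
  walk <- function(start) {
    path <- start
    used[start] <<- TRUE
    cur <- start
    repeat {
      if (succ_count[cur] != 1L) break
      nxt <- succ_of(substr(cur, 2L, k))
      nxt <- nxt[nxt != ""][1]
      if (is.na(nxt) || used[nxt] || pred_count[nxt] != 1L) break
      used[nxt] <<- TRUE
      path <- c(path, nxt)
      cur <- nxt
    }
    paste0(path[1], paste(substr(path[-1], k, k), collapse = ""))
  }
  for (s in km[is_start]) if (!used[s]) unitigs <- c(unitigs, walk(s))
  for (s in km) if (!used[s]) unitigs <- c(unitigs, walk(s))  # cycles
  # collapse reverse-complement duplicates (canonical = lexicographic min)
  canon <- pmin(unitigs, revcomp(unitigs))
  unitigs <- unitigs[!duplicated(canon)]
  unitigs <- unitigs[nchar(unitigs) >= min_contig]
  unitigs <- unitigs[order(-nchar(unitigs), unitigs)]
  if (!length(unitigs)) stop_param("assembly produced no contig above min_contig")
  contig_set(setNames(unitigs, sprintf("utg%04d", seq_along(unitigs))),
             source)
}

# ---- anchor blocks ---------------------------------------------------------

# Extend a match ungapped in one direction. A mismatch is crossed only when
# it is followed by >= re_anchor consecutive matches (isolated sequencing
# error) and the 1-per-100-nt budget allows it; boundaries are always trimmed
# to the last matching base, so junctions are located at the first
# junction-inconsistent base.
extend_match <- function(qseq, rseq, q0, r0, dir, tol_per_100, re_anchor = 8L) {
  qn <- nchar(qseq); rn <- nchar(rseq)
  len <- 0L; mm <- 0L; last_good <- 0L
  repeat {
    q <- q0 + dir * (len + 1L)
    r <- r0 + dir * (len + 1L)
    if (q < 1L || q > qn || r < 1L || r > rn) break
    if (substr(qseq, q, q) == substr(rseq, r, r)) {
      len <- len + 1L; last_good <- len
      next
    }
    # candidate isolated error: require a clean run beyond it
    if ((mm + 1L) > max(1L, (len + 1L) %/% 100L) * tol_per_100) break
    ok <- TRUE
    for (a in seq_len(re_anchor)) {
      qa <- q + dir * a; ra <- r + dir * a
      if (qa < 1L || qa > qn || ra < 1L || ra > rn ||
          substr(qseq, qa, qa) != substr(rseq, ra, ra)) { ok <- FALSE; break }
    }
    if (!ok) break
    mm <- mm + 1L
    len <- len + 1L  # cross the mismatch; run continues next iterations
  }
  last_good
}

# Find maximal ungapped alignment blocks of `query` against an anchor index.
# `banned` is a set of k-mers to skip as seeds (cross-reference ambiguity).
# Returns blocks in query-forward coordinates; strand records whether the
# match is to the reverse complement of the query.
anchor_blocks <- function(query, index, refs, banned = character(0),
                          tol_per_100 = 1) {
  k <- index$k
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else revcomp(query)
    kms <- seq_kmers(q, k)
    if (!length(kms)) next
    hit <- match(kms, index$kmers)
    ok <- which(!is.na(hit) & !(kms %in% banned))
    if (!length(ok)) next
    ref_name <- index$seq_name[hit[ok]]
    rpos <- index$pos[hit[ok]]
    cpos <- ok - 1L
    diag <- rpos - cpos
    grp <- paste(ref_name, diag, sep = "@")
    for (g in unique(grp)) {
      sel <- grp == g
      cp <- cpos[sel]
      # split seed runs separated by large gaps on the same diagonal
      ord <- order(cp)
      cp <- cp[ord]
      brk <- c(0L, which(diff(cp) > 200L), length(cp))
      for (b in seq_len(length(brk) - 1L)) {
        cs <- cp[(brk[b] + 1L):brk[b + 1L]]
        c1 <- cs[1]; c2 <- cs[length(cs)] + k - 1L   # 1-based inclusive span
        rn <- ref_name[sel][1]
        d <- diag[sel][1]
        rseq <- refs[[rn]]
        left <- extend_match(q, rseq, c1 + 1L, c1 + d + 1L, -1L, tol_per_100)
        right <- extend_match(q, rseq, c2 + 1L, c2 + d + 1L, +1L, tol_per_100)
        qs <- c1 - left          # 0-based start
        qe <- c2 + right + 1L    # 0-based half-open end
        rs <- qs + d; re <- qe + d
        if (strand == "-") {
          L <- nchar(query)
          tmp <- qs
          qs <- L - qe; qe <- L - tmp
        }
        out[[length(out) + 1L]] <- data.frame(
          qstart = qs, qend = qe, ref = rn, rstart = rs, rend = re,
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(qstart = integer(0), qend = integer(0),
                      ref = character(0), rstart = integer(0),
                      rend = integer(0), strand = character(0)))
  bl <- do.call(rbind, out)
  # merge duplicated/nested blocks on the same (ref, strand, diagonal)
  key <- paste(bl$ref, bl$strand,
               ifelse(bl$strand == "+", bl$rstart - bl$qstart,
                      bl$rstart + bl$qend), sep = "@")
  merged <- lapply(split(bl, key), function(d) {
    d <- d[order(d$qstart), ]
    keep <- list(d[1, ])
    if (nrow(d) > 1) for (i in 2:nrow(d)) {
      last <- keep[[length(keep)]]
      if (d$qstart[i] <= last$qend) {
        last$qend <- max(last$qend, d$qend[i])
        last$rstart <- min(last$rstart, d$rstart[i])
        last$rend <- max(last$rend, d$rend[i])
        keep[[length(keep)]] <- last
      } else keep[[length(keep) + 1L]] <- d[i, ]
    }
    do.call(rbind, keep)
  })
  bl <- do.call(rbind, merged)
  bl <- bl[order(bl$qstart, bl$qend), ]
  rownames(bl) <- NULL
  bl
}

#' Detect cell-to-ctDNA transition points in contigs
#'
#' Contigs are decomposed into maximal ungapped blocks matching either the
#' cell reference or a ctDNA fragment, seeded by k-mers unique to one
#' reference (k-mers occurring in both references are discarded as
#' ambiguous) and extended with a 1-mismatch-per-100-nt tolerance. A
#' transition point is reported wherever a cell block and a ctDNA block abut
#' within `max_gap` nt; the breakpoint is the contig offset of the first
#' base beyond the maximal cell-consistent segment. Both strands are
#' searched. `adaptor_adjacent` is true when the adaptor motif occurs (with
#' at most 1 mismatch, either orientation) within `adaptor_search_window` nt
#' of the breakpoint on the ctDNA side or of the ctDNA-side contig end.
#'
#' @param contigs a `contig_set` (or named character vector).
#' @param cell_ref cell `genome_sequence`.
#' @param fragments `ctdna_fragments` whose cores form the ctDNA reference.
#' @param adaptor adaptor motif.
#' @param anchor_k seed k-mer length (>= 21).
#' @param max_gap maximum unaligned nt at the joint (NHEJ scar allowance).
#' @param adaptor_search_window adaptor search distance (nt).
#' @param mismatch_per_100 extension mismatch tolerance.
#' @param max_overlap maximum block overlap (microhomology) at a junction.
#' @return data.frame of class `transition_points`: one row per junction with
#'   breakpoint, cell segment, fragment segment, orientation, junction gap
#'   and adaptor flag.
#' @export
detect_transitions <- function(contigs, cell_ref, fragments,
                               adaptor = PACBIO_ADAPTOR,
                               anchor_k = 31, max_gap = 20,
                               adaptor_search_window = 30,
                               mismatch_per_100 = 1, max_overlap = 50) {
  if (anchor_k < 21) stop_param("anchor_k must be >= 21")
  if (!inherits(contigs, "contig_set")) contigs <- contig_set(contigs)
  cores <- setNames(fragments$core, fragments$fragment_id)
  cell_idx <- kmer_index(cell_ref$sequences, anchor_k)
  # fragments drawn from overlapping donor loci share k-mers; such k-mers
  # are unambiguous for the cell-vs-ctDNA decision (only the fragment
  # attribution is ambiguous, and overlapping fragments cover the same donor
  # region), so a deterministic representative is kept rather than dropping
  # the seed; k-mers repeated within one core stay excluded
  frag_idx <- frag_kmer_index(cores, anchor_k)
  # ambiguity is judged on the full k-mer content of both references (not
  # the uniqueness-filtered indexes): any k-mer occurring on both sides is
  # discarded as a seed for either
  all_cell <- unique(unlist(lapply(cell_ref$sequences, seq_kmers,
                                   k = anchor_k), use.names = FALSE))
  all_frag <- unique(unlist(lapply(cores, seq_kmers, k = anchor_k),
                            use.names = FALSE))
  shared <- intersect(all_cell, all_frag)

  rows <- list()
  for (i in seq_len(nrow(contigs))) {
    cid <- contigs$contig_id[i]
    cseq <- contigs$sequence[i]
    cb <- anchor_blocks(cseq, cell_idx, cell_ref$sequences, banned = shared,
                        tol_per_100 = mismatch_per_100)
    fb <- anchor_blocks(cseq, frag_idx, as.list(cores), banned = shared,
                        tol_per_100 = mismatch_per_100)
    if (!nrow(cb) || !nrow(fb)) next
    # a block without at least anchor_k bases outside the union of
    # opposite-type blocks is a chance junction-spanning match inside the
    # other reference's territory, not junction evidence
    cb <- cb[exclusive_len(cb, fb) >= anchor_k, , drop = FALSE]
    fb <- fb[exclusive_len(fb, cb) >= anchor_k, , drop = FALSE]
    if (!nrow(cb) || !nrow(fb)) next
    cb$type <- "cell"; fb$type <- "ctdna"
    bl <- rbind(cb, fb)
    bl <- bl[order(bl$qstart, bl$qend), ]
    for (a in seq_len(nrow(bl) - 1L)) for (b in seq(a + 1L, nrow(bl))) {
      x <- bl[a, ]; y <- bl[b, ]
      if (x$type == y$type) next
      gap <- y$qstart - x$qend
      if (gap > max_gap || gap < -max_overlap) next
      # each side must contribute sequence exclusive of the other: a block
      # nested in its partner (a chance junction-spanning match into the
      # origin-homologous region) is not junction evidence
      ov <- max(0L, min(x$qend, y$qend) - max(x$qstart, y$qstart))
      if ((x$qend - x$qstart) - ov < anchor_k ||
          (y$qend - y$qstart) - ov < anchor_k) next
      cellb <- if (x$type == "cell") x else y
      fragb <- if (x$type == "cell") y else x
      orientation <- if (x$type == "cell") "cell_to_ctdna" else "ctdna_to_cell"
      breakpoint <- if (orientation == "cell_to_ctdna") cellb$qend
                    else cellb$qstart
      L <- nchar(cseq)
      ctdna_right <- orientation == "cell_to_ctdna"
      win <- adaptor_search_window + nchar(adaptor)
      near_bp <- if (ctdna_right)
        substr(cseq, breakpoint + 1L, min(L, breakpoint + win))
      else substr(cseq, max(1L, breakpoint - win + 1L), breakpoint)
      near_end <- if (ctdna_right) substr(cseq, max(1L, L - win + 1L), L)
                  else substr(cseq, 1L, min(L, win))
      adj <- motif_present(near_bp, adaptor) || motif_present(near_end, adaptor)
      rows[[length(rows) + 1L]] <- data.frame(
        contig_id = cid, breakpoint = breakpoint,
        orientation = orientation,
        cell_contig = cellb$ref, cell_start = cellb$rstart,
        cell_end = cellb$rend, cell_strand = cellb$strand,
        fragment_id = fragb$ref, frag_start = fragb$rstart,
        frag_end = fragb$rend, frag_strand = fragb$strand,
        junction_gap = max(0L, gap),
        adaptor_adjacent = adj, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig_id = character(0), breakpoint = integer(0),
               orientation = character(0), cell_contig = character(0),
               cell_start = integer(0), cell_end = integer(0),
               cell_strand = character(0), fragment_id = character(0),
               frag_start = integer(0), frag_end = integer(0),
               frag_strand = character(0), junction_gap = integer(0),
               adaptor_adjacent = logical(0), stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  class(out) <- c("transition_points", "data.frame")
  out
}

# Length of each block in `a` not covered by the union of blocks in `b`
# (query coordinates).
exclusive_len <- function(a, b) {
  if (!nrow(b)) return(a$qend - a$qstart)
  iv <- b[order(b$qstart), c("qstart", "qend")]
  merged <- list(c(iv$qstart[1], iv$qend[1]))
  for (i in seq_len(nrow(iv))[-1]) {
    last <- merged[[length(merged)]]
    if (iv$qstart[i] <= last[2])
      merged[[length(merged)]] <- c(last[1], max(last[2], iv$qend[i]))
    else merged[[length(merged) + 1L]] <- c(iv$qstart[i], iv$qend[i])
  }
  vapply(seq_len(nrow(a)), function(i) {
    cov <- sum(vapply(merged, function(m)
      max(0L, min(a$qend[i], m[2]) - max(a$qstart[i], m[1])), numeric(1)))
    a$qend[i] - a$qstart[i] - cov
  }, numeric(1))
}

# Motif present with at most one mismatch, either orientation.
motif_present <- function(region, motif) {
  if (nchar(region) < nchar(motif)) return(FALSE)
  r <- Biostrings::DNAString(region)
  length(Biostrings::matchPattern(motif, r, max.mismatch = 1)) > 0 ||
    length(Biostrings::matchPattern(revcomp(motif), r, max.mismatch = 1)) > 0
}

#' Confirm transitions as ctDNA insertions via private SNVs
#'
#' Pairs of transitions bounding one inserted fragment on a contig are merged
#' into a double-junction call; each call is confirmed when the inserted
#' fragment segment covers at least one ctDNA-private SNV (variant keys in
#' donor coordinates, lifted through the fragment's origin). The insertion
#' locus on the cell genome is the cell-side coordinate at the junction, and
#' `distance_to_origin` is reported when insertion and origin share a
#' reference contig.
#'
#' @param transitions a `transition_points` data.frame.
#' @param ctdna_private character vector of variant keys private to the ctDNA
#'   sample (e.g. `setdiff(ctdna keys, cell keys)`).
#' @param fragments the `ctdna_fragments` used for detection.
#' @return data.frame of class `insertion_calls`; unconfirmed calls are
#'   retained with `status = "unconfirmed"`.
#' @export
confirm_and_call <- function(transitions, ctdna_private, fragments) {
  priv <- parse_variant_key(as_keys(ctdna_private))
  fr <- fragments
  frag_row <- match(transitions$fragment_id, fr$fragment_id)
  rows <- list()
  for (cid in unique(transitions$contig_id)) {
    tr <- transitions[transitions$contig_id == cid, , drop = FALSE]
    tr <- tr[order(tr$breakpoint), , drop = FALSE]
    used <- rep(FALSE, nrow(tr))
    for (i in seq_len(nrow(tr))) {
      if (used[i]) next
      t1 <- tr[i, ]
      t2 <- NULL
      if (t1$orientation == "cell_to_ctdna" && i < nrow(tr)) {
        j <- which(!used & seq_len(nrow(tr)) > i &
                   tr$orientation == "ctdna_to_cell" &
                   tr$fragment_id == t1$fragment_id)
        if (length(j)) { t2 <- tr[j[1], ]; used[j[1]] <- TRUE }
      }
      used[i] <- TRUE
      fi <- match(t1$fragment_id, fr$fragment_id)
      o_contig <- fr$origin_contig[fi]
      o_start <- fr$origin_start[fi]
      fs <- min(t1$frag_start, if (!is.null(t2)) t2$frag_start else Inf)
      fe <- max(t1$frag_end, if (!is.null(t2)) t2$frag_end else -Inf)
      donor_lo <- o_start + fs; donor_hi <- o_start + fe
      conf <- priv[priv$contig == o_contig & priv$pos >= donor_lo &
                   priv$pos < donor_hi, , drop = FALSE]
      cell_pos <- if (t1$orientation == "cell_to_ctdna") t1$cell_end
                  else t1$cell_start
      dist <- if (t1$cell_contig == o_contig) abs(cell_pos - o_start)
              else NA_integer_
      row <- data.frame(
        contig_id = cid, cell_contig = t1$cell_contig, cell_pos = cell_pos,
        fragment_id = t1$fragment_id,
        n_junctions = if (is.null(t2)) 1L else 2L,
        n_private_snvs = nrow(conf),
        distance_to_origin = dist,
        status = if (nrow(conf) > 0) "confirmed" else "unconfirmed",
        stringsAsFactors = FALSE)
      row$confirming_keys <- list(
        variant_key(conf$contig, conf$pos, conf$ref, conf$alt))
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig_id = character(0), cell_contig = character(0),
               cell_pos = integer(0), fragment_id = character(0),
               n_junctions = integer(0), n_private_snvs = integer(0),
               distance_to_origin = integer(0), status = character(0),
               stringsAsFactors = FALSE)
  # one call per distinct insertion locus: overlapping fragments can yield
  # the same junction under two attributions; keep the best-supported call
  if (nrow(out)) {
    out <- out[order(out$status != "confirmed", -out$n_junctions,
                     -out$n_private_snvs, out$cell_contig, out$cell_pos), ]
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))[-1]) {
      prev <- which(keep[seq_len(i - 1L)])
      near <- out$cell_contig[prev] == out$cell_contig[i] &
        abs(out$cell_pos[prev] - out$cell_pos[i]) <= 20L
      if (any(near)) keep[i] <- FALSE
    }
    out <- out[keep, ]
    out <- out[order(out$cell_contig, out$cell_pos), ]
  }
  rownames(out) <- NULL
  class(out) <- c("insertion_calls", "data.frame")
  out
}

#' Detect duplications of the cell reference within contigs
#'
#' Maps each contig to the cell reference as ungapped anchor blocks and
#' reports a duplication wherever two adjacent colinear blocks show a
#' positive diagonal shift: the shift equals the length of reference
#' sequence present in extra copy, a quantity that is exact regardless of
#' chance matching at the junction. Events of length below `min_len` are
#' suppressed. Events also present in cell-source contigs are flagged as not
#' coculture-unique.
#'
#' @param contigs a `contig_set` (coculture contigs; rows with
#'   `source == "cell"` serve as the cell-only comparison set).
#' @param cell_ref cell `genome_sequence`.
#' @param min_len minimum duplication length (default 10, inclusive).
#' @param soi_filter optional variant keys; when given, only events on
#'   contigs whose mapped reference span covers at least one key are kept.
#' @param anchor_k seed k-mer length.
#' @return data.frame of class `duplication_events`.
#' @export
detect_duplications <- function(contigs, cell_ref, min_len = 10,
                                soi_filter = NULL, anchor_k = 31) {
  if (min_len < 2) stop_param("min_len must be >= 2")
  if (!inherits(contigs, "contig_set")) contigs <- contig_set(contigs)
  cell_idx <- kmer_index(cell_ref$sequences, anchor_k)
  find_events <- function(rows) {
    out <- list()
    for (i in seq_len(nrow(rows))) {
      bl <- anchor_blocks(rows$sequence[i], cell_idx, cell_ref$sequences)
      covered <- bl
      for (strand in c("+", "-")) {
        d <- bl[bl$strand == strand, , drop = FALSE]
        if (nrow(d) < 2) next
        d <- d[order(d$qstart), ]
        for (j in seq_len(nrow(d) - 1L)) {
          x <- d[j, ]; y <- d[j + 1L, ]
          if (x$ref != y$ref) next
          shift <- if (strand == "+")
            (x$rstart - x$qstart) - (y$rstart - y$qstart)
          else (y$rstart + y$qend) - (x$rstart + x$qend)
          if (y$qstart - x$qend > 20L) next      # blocks must abut
          if (shift < min_len) next
          # ref intervals must genuinely overlap (an extra copy of the same
          # reference sequence), not merely sit on shifted diagonals
          if (y$rstart >= x$rend || y$rend <= x$rstart) next
          ref_start <- if (strand == "+") y$rstart else x$rstart
          out[[length(out) + 1L]] <- data.frame(
            contig_id = rows$contig_id[i], ref_contig = x$ref,
            ref_start = ref_start, ref_end = ref_start + shift,
            length = shift, strand = strand,
            mapped_span = I(list(covered[, c("ref", "rstart", "rend")])),
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(contig_id = character(0), ref_contig = character(0),
                 ref_start = integer(0), ref_end = integer(0),
                 length = integer(0), strand = character(0))
  }
  cc <- find_events(contigs[contigs$source != "cell", , drop = FALSE])
  base <- find_events(contigs[contigs$source == "cell", , drop = FALSE])
  if (nrow(cc)) {
    cc$coculture_unique <- vapply(seq_len(nrow(cc)), function(i) {
      !any(base$ref_contig == cc$ref_contig[i] &
           abs(base$ref_start - cc$ref_start[i]) <= 50 &
           base$length == cc$length[i])
    }, logical(1))
    if (!is.null(soi_filter)) {
      soi <- parse_variant_key(as_keys(soi_filter))
      keep <- vapply(seq_len(nrow(cc)), function(i) {
        span <- cc$mapped_span[[i]]
        any(vapply(seq_len(nrow(span)), function(s)
          any(soi$contig == span$ref[s] & soi$pos >= span$rstart[s] &
              soi$pos < span$rend[s]), logical(1)))
      }, logical(1))
      cc <- cc[keep, , drop = FALSE]
    }
  } else cc$coculture_unique <- logical(0)
  cc$mapped_span <- NULL
  rownames(cc) <- NULL
  class(cc) <- c("duplication_events", "data.frame")
  cc
}

#' Summarize structural gain under coculture
#'
#' @param calls an `insertion_calls` data.frame.
#' @param duplications a `duplication_events` data.frame.
#' @param proximity_window window (bp) for counting proximal insertions.
#' @return list of class `sv_gain_summary` with per-class event counts.
#' @export
count_structural_gain <- function(calls, duplications,
                                  proximity_window = 10000) {
  out <- list(
    n_insertions = nrow(calls),
    n_confirmed = sum(calls$status == "confirmed"),
    n_duplications = nrow(duplications),
    n_coculture_unique_duplications =
      if (nrow(duplications)) sum(duplications$coculture_unique) else 0L,
    n_proximal = sum(!is.na(calls$distance_to_origin) &
                     calls$distance_to_origin <= proximity_window),
    proximity_window = proximity_window)
  class(out) <- "sv_gain_summary"
  out
}

#' @export
print.sv_gain_summary <- function(x, ...) {
  cat("<sv_gain_summary>\n")
  cat(sprintf("  insertions: %d (confirmed: %d, proximal <= %d bp: %d)\n",
              x$n_insertions, x$n_confirmed, x$proximity_window, x$n_proximal))
  cat(sprintf("  duplications: %d (coculture-unique: %d)\n",
              x$n_duplications, x$n_coculture_unique_duplications))
  invisible(x)
}
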