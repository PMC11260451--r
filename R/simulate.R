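#' PACBIO adaptor sequence ligated to ctDNA fragment ends
#'
#' The 14-nt oligo ligated to both ends of ctDNA fragments before library
#' preparation; it marks fragment 5'/3' termini and is used downstream to
#' require adaptor evidence next to integration transition points.
#' @export
PACBIO_ADAPTOR <- "GCGCTCTGTGTGCT"

#' Default TE consensus element table
#'
#' Synthetic stand-in consensus elements carrying the field's element names,
#' split between a multiple-myeloma (MM) and a pancreatic-cancer (PC) tissue
#' label. Sequences are generated at simulation time; no curated repeat
#' database sequences are bundled.
#'
#' @return data.frame with columns `name`, `te_class`, `tumor_label`.
#' @export
default_te_elements <- function() {
  data.frame(
    name = c("AluSp", "MER11C", "AluJb", "L2a",
             "AluSx", "MIRc", "MTL1J", "THE1A"),
    te_class = c("SINE", "ERVL", "SINE", "LINE",
                 "SINE", "SINE", "LTR", "LTR"),
    tumor_label = c(rep("MM", 4), rep("PC", 4)),
    stringsAsFactors = FALSE
  )
}

#' Simulate the cell genome, donor genome and TE consensus library
#'
#' Generates a haploid recipient ("cell") genome, a ctDNA donor genome that
#' differs from it only by private single-nucleotide substitutions, and a
#' library of mutually non-homologous TE consensus sequences tagged with
#' tissue labels. Donor-private SNV positions are recorded as ground truth.
#'
#' @param config list of generator parameters; see [default_sim_config()].
#' @param seed integer seed; identical `(config, seed)` reproduce identical
#'   output byte-for-byte.
#' @return list with elements `cell`, `donor` (both `genome_sequence`),
#'   `te_library` (a `te_library` data.frame) and `donor_snvs` (data.frame
#'   with 0-based `pos`, `ref`, `alt`).
#' @export
simulate_genomes <- function(config = default_sim_config(), seed = 1) {
  cfg <- utils::modifyList(default_sim_config(), config)
  if (cfg$n_contigs < 1) stop_param("n_contigs must be >= 1")
  if (any(cfg$contig_length < 1e4)) stop_param("contig lengths must be >= 10 kb")
  if (is.null(cfg$donor_snv_count) &&
      (cfg$donor_snv_rate < 0 || cfg$donor_snv_rate > 1))
    stop_param("donor_snv_rate must be in [0, 1]")
  set.seed(seed)

  lens <- rep_len(cfg$contig_length, cfg$n_contigs)
  contig_names <- sprintf("chr%d", seq_len(cfg$n_contigs))
  cell_seqs <- setNames(vapply(lens, random_dna, character(1)), contig_names)
  cell <- genome_sequence("cell", cell_seqs, role = "cell")

  # donor-private substitutions: either an exact count or a per-base rate
  snv_rows <- list()
  donor_seqs <- cell_seqs
  total_len <- sum(lens)
  if (!is.null(cfg$donor_snv_count)) {
    n_snv_total <- as.integer(cfg$donor_snv_count)
    per_contig <- tabulate(
      sample.int(cfg$n_contigs, n_snv_total, replace = TRUE, prob = lens),
      nbins = cfg$n_contigs)
  } else {
    per_contig <- rbinom(cfg$n_contigs, lens, cfg$donor_snv_rate)
  }
  for (i in seq_len(cfg$n_contigs)) {
    n <- per_contig[i]
    if (n == 0) next
    pos <- sort(sample.int(lens[i], n)) - 1L  # 0-based
    ref <- substring(cell_seqs[i], pos + 1L, pos + 1L)
    alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1),
                  character(1), USE.NAMES = FALSE)
    s <- donor_seqs[[i]]
    for (j in seq_along(pos)) substr(s, pos[j] + 1L, pos[j] + 1L) <- alt[j]
    donor_seqs[[i]] <- s
    snv_rows[[i]] <- data.frame(contig = contig_names[i], pos = pos,
                                ref = ref, alt = alt, stringsAsFactors = FALSE)
  }
  donor_snvs <- if (length(snv_rows)) do.call(rbind, snv_rows) else
    data.frame(contig = character(0), pos = integer(0),
               ref = character(0), alt = character(0))
  rownames(donor_snvs) <- NULL
  donor <- genome_sequence("donor", donor_seqs, role = "donor")

  te_library <- simulate_te_library(cfg$te_elements, cfg$te_length,
                                    score_cutoff = cfg$te_score_cutoff)

  list(cell = cell, donor = donor, te_library = te_library,
       donor_snvs = donor_snvs)
}

#' Default generator configuration
#'
#' Two 100-kb contigs keep every downstream stage at desk scale while leaving
#' room for 10-kb proximity windows. The donor SNV rate of 1e-3 gives ctDNA
#' fragments a realistic chance of carrying a confirming private SNV.
#'
#' @return named list of parameters accepted by [simulate_genomes()].
#' @export
default_sim_config <- function() {
  list(
    n_contigs = 2L,
    contig_length = 1e5,
    donor_snv_rate = 1e-3,
    donor_snv_count = NULL,
    te_elements = default_te_elements(),
    te_length = c(80L, 160L),
    te_score_cutoff = 40
  )
}

#' Generate a TE consensus library of mutually non-homologous sequences
#'
#' Random consensus sequences are drawn for each element and checked pairwise
#' by local alignment (same scoring as [scan_repeats()]); any pair scoring at
#' or above `score_cutoff` triggers regeneration so that the library cannot
#' cross-hit during repeat scanning.
#'
#' @param elements data.frame with `name`, `te_class`, `tumor_label`.
#' @param te_length length-2 range of consensus lengths (>= 50).
#' @param score_cutoff local-alignment reporting cutoff that pairs must stay
#'   below.
#' @return data.frame of class `te_library` with a `sequence` column added.
#' @export
simulate_te_library <- function(elements = default_te_elements(),
                                te_length = c(80L, 160L), score_cutoff = 40) {
  stopifnot(!anyDuplicated(elements$name), min(te_length) >= 50)
  n <- nrow(elements)
  lens <- sample(seq(te_length[1], te_length[2]), n, replace = TRUE)
  seqs <- vapply(lens, random_dna, character(1))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  for (attempt in seq_len(25)) {
    bad <- rep(FALSE, n)
    if (n > 1) {
      for (j in seq(2, n)) {
        prev <- seqs[seq_len(j - 1)]
        sc <- Biostrings::pairwiseAlignment(
          Biostrings::DNAStringSet(c(prev, revcomp(prev))),
          Biostrings::DNAString(seqs[j]), type = "local",
          substitutionMatrix = mat, gapOpening = 5, gapExtension = 2,
          scoreOnly = TRUE)
        if (max(sc) >= score_cutoff) bad[j] <- TRUE
      }
    }
    if (!any(bad)) break
    seqs[bad] <- vapply(lens[bad], random_dna, character(1))
    if (attempt == 25)
      stop_param("could not generate non-homologous TE consensi")
  }
  out <- elements
  out$sequence <- seqs
  class(out) <- c("te_library", "data.frame")
  out
}

# Best local alignment score under the repeat-scan scoring scheme.
local_align_score <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                Biostrings::DNAString(b),
                                type = "local", substitutionMatrix = mat,
                                gapOpening = 5, gapExtension = 2,
                                scoreOnly = TRUE)
}

#' Simulate adaptor-ligated ctDNA fragments from the donor genome
#'
#' Fragment cores are substrings of the donor genome drawn with a lognormal
#' size model (median 170 bp by default, the typical cfDNA mode). With
#' probability `te_end_probability` a TE consensus copy is embedded within
#' 100 nt of one fragment end (locally replacing donor sequence). The adaptor
#' is then ligated to both ends of every fragment. Donor-private SNVs falling
#' inside the (non-TE) core are recorded per fragment.
#'
#' @param donor donor `genome_sequence`.
#' @param te_library `te_library` data.frame from [simulate_te_library()].
#' @param n_fragments number of fragments.
#' @param size_model list with `meanlog`, `sdlog` of the lognormal size draw.
#' @param size_range clamp range for fragment core length.
#' @param te_end_probability probability that a fragment carries a TE copy
#'   near an end.
#' @param te_tissue optional tumor label; restricts planted TEs to elements
#'   carrying that label (`NULL` uses the whole library).
#' @param adaptor adaptor sequence ligated to both ends.
#' @param donor_snvs data.frame of donor-private SNVs (from
#'   [simulate_genomes()]); used to record `private_snvs` per fragment.
#' @param min_private_snvs redraw fragment origins until each fragment core
#'   contains at least this many donor-private SNVs (0 disables).
#' @param seed integer seed.
#' @return data.frame of class `ctdna_fragments` with list-columns
#'   `planted_te` and `private_snvs`.
#' @export
simulate_ctdna <- function(donor, te_library, n_fragments,
                           size_model = list(meanlog = log(170), sdlog = 0.45),
                           size_range = c(60, 5000),
                           te_end_probability = 0.5,
                           te_tissue = NULL,
                           adaptor = PACBIO_ADAPTOR,
                           donor_snvs = NULL,
                           min_private_snvs = 0,
                           seed = 1) {
  if (te_end_probability < 0 || te_end_probability > 1)
    stop_param("te_end_probability must be in [0, 1]")
  if (nchar(adaptor) == 0) stop_param("adaptor must be non-empty")
  lens_contig <- nchar(donor$sequences)
  if (size_range[1] > max(lens_contig))
    stop_param("fragment size exceeds every contig length")
  set.seed(seed)

  lib <- te_library
  if (!is.null(te_tissue)) lib <- lib[lib$tumor_label == te_tissue, ]
  if (te_end_probability > 0 && nrow(lib) == 0)
    stop_param("no TE elements available for tissue ", te_tissue)

  contig_names <- names(donor$sequences)
  rows <- vector("list", n_fragments)
  for (i in seq_len(n_fragments)) {
    plant_te <- runif(1) < te_end_probability
    # retries condition jointly on placement and on private SNVs surviving
    # any TE overwrite, so min_private_snvs is a hard guarantee
    for (try in seq_len(500)) {
      core_len <- round(exp(rnorm(1, size_model$meanlog, size_model$sdlog)))
      core_len <- max(size_range[1], min(size_range[2], core_len))
      ci <- sample.int(length(contig_names), 1, prob = lens_contig)
      if (core_len > lens_contig[ci]) next
      start <- sample.int(lens_contig[ci] - core_len + 1L, 1) - 1L
      end <- start + core_len
      snv_in <- if (!is.null(donor_snvs))
        donor_snvs[donor_snvs$contig == contig_names[ci] &
                   donor_snvs$pos >= start & donor_snvs$pos < end, ,
                   drop = FALSE]
      else donor_snvs_empty()
      core <- genome_subseq(donor, contig_names[ci], start, end)
      planted <- te_plant_empty()
      if (plant_te) {
        el <- lib[sample.int(nrow(lib), 1), ]
        te_seq <- el$sequence
        te_len <- min(nchar(te_seq), core_len)
        te_copy <- substr(te_seq, 1, te_len)
        at_5prime <- runif(1) < 0.5
        max_off <- min(100L, core_len - te_len)
        off <- sample.int(max_off + 1L, 1) - 1L
        te_start <- if (at_5prime) off else core_len - te_len - off
        substr(core, te_start + 1L, te_start + te_len) <- te_copy
        planted <- data.frame(te_name = el$name, start = te_start,
                              end = te_start + te_len,
                              stringsAsFactors = FALSE)
        # private SNVs wiped out by the TE overwrite no longer count
        snv_in <- snv_in[snv_in$pos - start < te_start |
                         snv_in$pos - start >= te_start + te_len, ,
                         drop = FALSE]
      }
      if (nrow(snv_in) >= min_private_snvs) break
      if (try == 500) stop_param("could not place fragment with ",
                                 min_private_snvs, " private SNVs")
    }

    rows[[i]] <- data.frame(
      fragment_id = sprintf("frag%04d", i),
      sequence = paste0(adaptor, core, adaptor),
      core = core,
      origin_contig = contig_names[ci],
      origin_start = start, origin_end = end,
      adaptor_5 = TRUE, adaptor_3 = TRUE,
      stringsAsFactors = FALSE)
    rows[[i]]$planted_te <- list(planted)
    rows[[i]]$private_snvs <- list(snv_in)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "adaptor") <- adaptor
  class(out) <- c("ctdna_fragments", "data.frame")
  out
}

te_plant_empty <- function() {
  data.frame(te_name = character(0), start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)
}
donor_snvs_empty <- function() {
  data.frame(contig = character(0), pos = integer(0), ref = character(0),
             alt = character(0), stringsAsFactors = FALSE)
}

#' Simulate the coculture genome with planted ctDNA insertions
#'
#' Builds the coculture genome as the cell genome plus planted fragment cores
#' (adaptors stripped: ligation is a library artifact, the biological insert
#' is the fragment itself) and tandem duplications of length >= 10 bp. A
#' fraction `proximity_bias` of insertions is drawn within
#' `proximity_window` bp of the homologous cell locus of the fragment's
#' origin; the rest land uniformly anywhere. All event coordinates are
#' recorded in cell-genome coordinates in a machine-readable truth table.
#'
#' @param cell cell `genome_sequence`.
#' @param fragments `ctdna_fragments` from [simulate_ctdna()].
#' @param insertion_rate probability that each fragment is inserted.
#' @param proximity_bias fraction of insertions biased to land near the
#'   fragment's locus of origin (default 0.8).
#' @param proximity_window distance (bp) defining "near" (default 10 kb).
#' @param duplication_rate expected duplications per bp (Poisson); ignored
#'   when `n_duplications` is given.
#' @param n_duplications exact number of tandem duplications to plant.
#' @param dup_length_range inclusive range of duplication lengths (>= 10).
#' @param min_event_spacing minimum distance between planted event positions.
#' @param seed integer seed.
#' @return list with `genome` (coculture `genome_sequence`) and `truth`
#'   (a `coculture_truth` object).
#' @export
simulate_coculture <- function(cell, fragments,
                               insertion_rate = 1,
                               proximity_bias = 0.8,
                               proximity_window = 10000,
                               duplication_rate = 0,
                               n_duplications = NULL,
                               dup_length_range = c(10, 50),
                               min_event_spacing = 2000,
                               seed = 1) {
  if (proximity_bias < 0 || proximity_bias > 1)
    stop_param("proximity_bias must be in [0, 1]")
  if (min(dup_length_range) < 10)
    stop_param("duplication lengths must be >= 10")
  set.seed(seed)

  contig_names <- names(cell$sequences)
  lens <- nchar(cell$sequences)
  total_len <- sum(lens)
  edge <- 200L  # keep events away from contig ends

  taken <- lapply(contig_names, function(x) integer(0))
  names(taken) <- contig_names
  place_ok <- function(contig, pos) {
    all(abs(taken[[contig]] - pos) >= min_event_spacing) &&
      pos >= edge && pos <= lens[[contig]] - edge
  }

  ins_idx <- which(runif(nrow(fragments)) < insertion_rate)
  ins_rows <- list()
  for (fi in ins_idx) {
    fr <- fragments[fi, ]
    placed <- FALSE
    # the proximal/background decision is made once per fragment; placement
    # retries redraw only the position, so the realized proximal fraction
    # tracks proximity_bias instead of being deflated by crowded loci; a
    # fragment whose origin neighborhood is saturated falls back to
    # background placement rather than aborting the run
    proximal_mode <- runif(1) < proximity_bias
    for (try in seq_len(500)) {
      if (proximal_mode && try <= 400L) {
        contig <- fr$origin_contig
        pos <- fr$origin_start +
          round(runif(1, -proximity_window, proximity_window))
      } else {
        ci <- sample.int(length(contig_names), 1, prob = lens)
        contig <- contig_names[ci]
        pos <- sample.int(lens[ci], 1) - 1L
      }
      pos <- as.integer(pos)
      if (place_ok(contig, pos)) { placed <- TRUE; break }
    }
    if (!placed) stop_param("could not place insertion after bounded retries")
    taken[[contig]] <- c(taken[[contig]], pos)
    dist <- if (contig == fr$origin_contig) abs(pos - fr$origin_start) else NA_integer_
    ins_rows[[length(ins_rows) + 1L]] <- data.frame(
      contig = contig, pos = pos, fragment_id = fr$fragment_id,
      core_length = nchar(fr$core), distance_to_origin = dist,
      proximal = !is.na(dist) && dist <= proximity_window,
      stringsAsFactors = FALSE)
  }
  planted_insertions <- if (length(ins_rows)) do.call(rbind, ins_rows) else
    data.frame(contig = character(0), pos = integer(0),
               fragment_id = character(0), core_length = integer(0),
               distance_to_origin = integer(0), proximal = logical(0))

  n_dup <- if (!is.null(n_duplications)) n_duplications else
    rpois(1, duplication_rate * total_len)
  dup_rows <- list()
  for (d in seq_len(n_dup)) {
    len <- sample(seq(dup_length_range[1], dup_length_range[2]), 1)
    placed <- FALSE
    for (try in seq_len(500)) {
      ci <- sample.int(length(contig_names), 1, prob = lens)
      contig <- contig_names[ci]
      start <- sample.int(lens[ci] - len, 1) - 1L
      if (place_ok(contig, start)) { placed <- TRUE; break }
    }
    if (!placed) stop_param("could not place duplication after bounded retries")
    taken[[contig]] <- c(taken[[contig]], start)
    dup_rows[[d]] <- data.frame(contig = contig, start = start, length = len,
                                stringsAsFactors = FALSE)
  }
  planted_duplications <- if (length(dup_rows)) do.call(rbind, dup_rows) else
    data.frame(contig = character(0), start = integer(0), length = integer(0))

  # apply edits right-to-left so recorded cell coordinates stay valid
  frag_core <- setNames(fragments$core, fragments$fragment_id)
  cocult <- cell$sequences
  for (contig in contig_names) {
    pi <- planted_insertions[planted_insertions$contig == contig, , drop = FALSE]
    pd <- planted_duplications[planted_duplications$contig == contig, ,
                               drop = FALSE]
    edits <- rbind(
      data.frame(pos = pi$pos, what = rep("ins", nrow(pi)),
                 id = pi$fragment_id, len = rep(0L, nrow(pi)),
                 stringsAsFactors = FALSE),
      data.frame(pos = pd$start, what = rep("dup", nrow(pd)),
                 id = rep(NA_character_, nrow(pd)), len = pd$length,
                 stringsAsFactors = FALSE))
    if (nrow(edits) == 0) next
    edits <- edits[order(-edits$pos), ]
    s <- cocult[[contig]]
    for (e in seq_len(nrow(edits))) {
      p <- edits$pos[e]
      if (edits$what[e] == "ins") {
        ins <- frag_core[[edits$id[e]]]
        s <- paste0(substr(s, 1, p), ins, substr(s, p + 1L, nchar(s)))
      } else {
        seg <- substr(s, p + 1L, p + edits$len[e])
        s <- paste0(substr(s, 1, p + edits$len[e]), seg,
                    substr(s, p + edits$len[e] + 1L, nchar(s)))
      }
    }
    cocult[[contig]] <- s
  }

  genome <- genome_sequence("coculture", cocult, role = "coculture")
  truth <- structure(list(
    planted_insertions = planted_insertions,
    planted_duplications = planted_duplications,
    donor_private_snvs = NULL,
    cassette_sites = data.frame(contig = character(0), pos = integer(0)),
    seed = seed,
    parameters = list(insertion_rate = insertion_rate,
                      proximity_bias = proximity_bias,
                      proximity_window = proximity_window,
                      duplication_rate = duplication_rate,
                      n_duplications = n_duplications,
                      dup_length_range = dup_length_range,
                      min_event_spacing = min_event_spacing)),
    class = "coculture_truth")
  list(genome = genome, truth = truth)
}

#' @export
print.coculture_truth <- function(x, ...) {
  cat("<coculture_truth>\n")
  cat(sprintf("  insertions: %d (proximal: %d)\n",
              nrow(x$planted_insertions), sum(x$planted_insertions$proximal)))
  cat(sprintf("  duplications: %d\n", nrow(x$planted_duplications)))
  cat(sprintf("  cassette sites: %d\n", nrow(x$cassette_sites)))
  invisible(x)
}

#' Simulate paired-end reads over a genome
#'
#' Uniform fragment sampling with a normal insert-size model, forward/reverse
#' mate orientation and per-base substitution errors. Read names encode the
#' true origin (`contig|start|insert|strand`) for debugging and truth checks.
#'
#' @param genome a `genome_sequence`.
#' @param coverage target mean per-base depth (the study design sequences at
#'   50x; tests use scaled-down values).
#' @param read_length read length in bp.
#' @param insert_size numeric `(mean, sd)` of the insert size.
#' @param error_rate per-base substitution error rate (< 0.1).
#' @param name_prefix prefix for read names (use distinct prefixes when
#'   merging read sets).
#' @param seed integer seed.
#' @return object of class `read_set`: list with `r1`, `r2` (named character
#'   vectors), `origin` data.frame, and the simulation parameters.
#' @export
simulate_reads <- function(genome, coverage, read_length = 150,
                           insert_size = c(300, 30), error_rate = 0.001,
                           name_prefix = "rd", seed = 1) {
  if (coverage <= 0) stop_param("coverage must be > 0")
  if (error_rate >= 0.1) stop_param("error_rate must be < 0.1")
  if (read_length >= insert_size[1]) stop_param("read_length must be < insert mean")
  set.seed(seed)

  contigs <- names(genome$sequences)
  lens <- nchar(genome$sequences)
  r1 <- character(0); r2 <- character(0); org <- list()
  counter <- 0L
  for (ci in seq_along(contigs)) {
    L <- lens[ci]
    n_pairs <- max(0L, as.integer(round(L * coverage / (2 * read_length))))
    if (n_pairs == 0) next
    ins <- as.integer(round(rnorm(n_pairs, insert_size[1], insert_size[2])))
    ins <- pmax(read_length + 2L, pmin(ins, L))
    start <- vapply(ins, function(l) sample.int(L - l + 1L, 1) - 1L, integer(1))
    minus <- runif(n_pairs) < 0.5
    frag_fwd <- substring(genome$sequences[ci], start + 1L, start + ins)
    left <- substr(frag_fwd, 1L, read_length)
    right <- revcomp(substring(frag_fwd, ins - read_length + 1L, ins))
    a <- ifelse(minus, right, left)   # R1
    b <- ifelse(minus, left, right)   # R2
    ids <- sprintf("%s%07d|%s|%d|%d|%s", name_prefix, counter + seq_len(n_pairs),
                   contigs[ci], start, ins, ifelse(minus, "-", "+"))
    counter <- counter + n_pairs
    names(a) <- ids; names(b) <- ids
    r1 <- c(r1, a); r2 <- c(r2, b)
    org[[ci]] <- data.frame(read_id = ids, contig = contigs[ci], start = start,
                            insert = ins, strand = ifelse(minus, "-", "+"),
                            stringsAsFactors = FALSE)
  }
  origin <- do.call(rbind, org)
  rownames(origin) <- NULL

  # substitution errors
  if (error_rate > 0) {
    for (nm in c("r1", "r2")) {
      v <- get(nm)
      nerr <- rbinom(length(v), read_length, error_rate)
      for (i in which(nerr > 0)) {
        s <- v[i]
        at <- sample.int(read_length, nerr[i])
        for (p in at) {
          old <- substr(s, p, p)
          substr(s, p, p) <- sample(setdiff(DNA_BASES, old), 1)
        }
        v[i] <- s
      }
      assign(nm, v)
    }
  }
  structure(list(r1 = r1, r2 = r2, origin = origin,
                 read_length = read_length,
                 insert_mean = insert_size[1], insert_sd = insert_size[2],
                 error_rate = error_rate),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d pairs, 2 x %d bp, insert %g +/- %g, error %g\n",
              length(x$r1), x$read_length, x$insert_mean, x$insert_sd,
              x$error_rate))
  invisible(x)
}

#' Merge read sets (e.g. mixture samples)
#'
#' @param ... `read_set` objects with distinct read-name prefixes.
#' @return a merged `read_set`.
#' @export
merge_read_sets <- function(...) {
  sets <- list(...)
  r1 <- do.call(c, lapply(sets, `[[`, "r1"))
  if (anyDuplicated(names(r1)))
    stop_param("read names collide; use distinct name_prefix per set")
  structure(list(r1 = r1,
                 r2 = do.call(c, lapply(sets, `[[`, "r2")),
                 origin = do.call(rbind, lapply(sets, `[[`, "origin")),
                 read_length = sets[[1]]$read_length,
                 insert_mean = sets[[1]]$insert_mean,
                 insert_sd = sets[[1]]$insert_sd,
                 error_rate = max(vapply(sets, `[[`, numeric(1), "error_rate"))),
            class = "read_set")
}

#' Write a read set as gzipped FASTQ (_R1/_R2)
#'
#' @param reads a `read_set`.
#' @param prefix output path prefix; writes `<prefix>_R1.fastq.gz` and
#'   `<prefix>_R2.fastq.gz`.
#' @return invisibly, the two file paths.
#' @export
write_fastq <- function(reads, prefix) {
  paths <- paste0(prefix, c("_R1.fastq.gz", "_R2.fastq.gz"))
  for (i in 1:2) {
    v <- reads[[c("r1", "r2")[i]]]
    qual <- Biostrings::PhredQuality(
      rep(strrep("I", reads$read_length), length(v)))
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(unname(v)), qual)
    names(x) <- names(v)
    Biostrings::writeQualityScaledXStringSet(x, filepath = paths[i],
                                             compress = TRUE)
  }
  invisible(paths)
}

#' Synthesize a transgene cassette free of homology with the cell genome
#'
#' @param length cassette length (>= 500).
#' @param name cassette name.
#' @param cell optional cell `genome_sequence`; the cassette is redrawn until
#'   it shares no `anchor_k`-mer with the cell genome.
#' @param anchor_k homology check k-mer length.
#' @param seed integer seed.
#' @return a `genome_sequence` with role `"cassette"`.
#' @export
synthesize_cassette <- function(length = 1500, name = "CMV-mCherry",
                                cell = NULL, anchor_k = 25, seed = 1) {
  if (length < 500) stop_param("cassette length must be >= 500")
  set.seed(seed)
  cell_kmers <- if (!is.null(cell))
    unique(unlist(lapply(cell$sequences, seq_kmers, k = anchor_k)))
  for (try in seq_len(50)) {
    s <- random_dna(length)
    if (is.null(cell_kmers) ||
        !any(c(seq_kmers(s, anchor_k), seq_kmers(revcomp(s), anchor_k)) %in%
             cell_kmers))
      return(genome_sequence(name, setNames(s, name), role = "cassette"))
  }
  stop_param("could not synthesize a cassette free of cell-genome homology")
}

#' Plant transgene cassette copies into the cell genome
#'
#' Inserts full cassette copies at `n_sites` random positions (recorded in
#' cell coordinates), emulating transgene integration events whose junctions
#' later produce discordant read pairs.
#'
#' @param cell cell `genome_sequence`.
#' @param cassette cassette `genome_sequence` (single contig, >= 500 bp).
#' @param n_sites number of integration sites.
#' @param min_spacing minimum distance between sites.
#' @param seed integer seed.
#' @return list with `genome` (modified `genome_sequence`) and `truth`
#'   (a `coculture_truth` whose `cassette_sites` table holds the sites).
#' @export
simulate_cassette_integration <- function(cell, cassette, n_sites,
                                          min_spacing = 5000, seed = 1) {
  cass_seq <- cassette$sequences[[1]]
  if (nchar(cass_seq) < 500) stop_param("cassette length must be >= 500")
  set.seed(seed)
  contigs <- names(cell$sequences)
  lens <- nchar(cell$sequences)
  edge <- 500L
  if (n_sites > sum(pmax(0, (lens - 2 * edge) %/% max(min_spacing, 1))))
    stop_param("n_sites exceeds placeable loci")
  sites <- list(); taken <- lapply(contigs, function(x) integer(0))
  names(taken) <- contigs
  for (i in seq_len(n_sites)) {
    placed <- FALSE
    for (try in seq_len(500)) {
      ci <- sample.int(length(contigs), 1, prob = lens)
      pos <- sample.int(lens[ci] - 2L * edge, 1) + edge - 1L
      if (all(abs(taken[[contigs[ci]]] - pos) >= min_spacing)) {
        placed <- TRUE; break
      }
    }
    if (!placed) stop_param("could not place cassette site")
    taken[[contigs[ci]]] <- c(taken[[contigs[ci]]], pos)
    sites[[i]] <- data.frame(contig = contigs[ci], pos = pos,
                             stringsAsFactors = FALSE)
  }
  cassette_sites <- if (n_sites > 0) do.call(rbind, sites) else
    data.frame(contig = character(0), pos = integer(0))

  seqs <- cell$sequences
  if (nrow(cassette_sites) > 0) {
    for (contig in unique(cassette_sites$contig)) {
      pp <- sort(cassette_sites$pos[cassette_sites$contig == contig],
                 decreasing = TRUE)
      s <- seqs[[contig]]
      for (p in pp)
        s <- paste0(substr(s, 1, p), cass_seq, substr(s, p + 1L, nchar(s)))
      seqs[[contig]] <- s
    }
  }
  genome <- genome_sequence("cell+cassette", seqs, role = "coculture")
  truth <- structure(list(
    planted_insertions = data.frame(contig = character(0), pos = integer(0),
                                    fragment_id = character(0),
                                    core_length = integer(0),
                                    distance_to_origin = integer(0),
                                    proximal = logical(0)),
    planted_duplications = data.frame(contig = character(0), start = integer(0),
                                      length = integer(0)),
    donor_private_snvs = NULL,
    cassette_sites = cassette_sites,
    seed = seed,
    parameters = list(n_sites = n_sites, min_spacing = min_spacing)),
    class = "coculture_truth")
  list(genome = genome, truth = truth)
}
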