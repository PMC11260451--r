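#' Build a pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis with the documented
#' defaults: allele-frequency threshold 0.01 (inclusive), 100-nt transition
#' window, minimum duplication length 10 bp, the PACBIO adaptor, and an 80%
#' proximity bias within a 10-kb window.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param genome list of genome-generator parameters
#'   (see [default_sim_config()]).
#' @param n_fragments number of ctDNA fragments.
#' @param fragment_size list with `meanlog`, `sdlog` of the size model.
#' @param fragment_size_range clamp range for fragment core length.
#' @param te_end_probability probability a fragment carries a TE near an end.
#' @param te_tissue tissue label of the donor's TE pool (`NULL`: any).
#' @param min_private_snvs minimum donor-private SNVs per fragment.
#' @param insertion_rate,proximity_bias,proximity_window,n_duplications,min_event_spacing
#'   coculture generator parameters.
#' @param coverage,read_length,insert_size,error_rate read simulation.
#' @param af_threshold,min_depth,min_alt_depth,caller_anchor_k SNV caller
#'   parameters.
#' @param anchor_k,max_gap transition detector parameters.
#' @param adaptor adaptor sequence.
#' @param te_window TE transition window (nt).
#' @param require_adaptor require adaptor evidence at transitions for TE
#'   selection (contigs built from the adaptor-stripped coculture genome
#'   carry no adaptor, so this defaults off in simulation runs).
#' @param min_dup_len minimum duplication length (bp).
#' @param flank,n_background_contigs perfect-contig construction.
#' @param outdir optional output directory for stage files.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       genome = list(contig_length = 1.5e5),
                       n_fragments = 30,
                       fragment_size = list(meanlog = log(500), sdlog = 0.25),
                       fragment_size_range = c(250, 1500),
                       te_end_probability = 0.6,
                       te_tissue = "MM",
                       min_private_snvs = 1,
                       insertion_rate = 2 / 3,
                       proximity_bias = 0.8,
                       proximity_window = 10000,
                       n_duplications = 3,
                       min_event_spacing = 2000,
                       coverage = 30,
                       read_length = 150,
                       insert_size = c(300, 30),
                       error_rate = 0.001,
                       af_threshold = 0.01,
                       min_depth = 8,
                       min_alt_depth = 2,
                       caller_anchor_k = 21,
                       anchor_k = 31,
                       max_gap = 20,
                       adaptor = PACBIO_ADAPTOR,
                       te_window = 100,
                       require_adaptor = FALSE,
                       min_dup_len = 10,
                       flank = 500,
                       n_background_contigs = 4,
                       outdir = NULL) {
  cfg <- as.list(environment())
  cfg$genome <- utils::modifyList(default_sim_config(), genome)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full coculture integration analysis
#'
#' Composes all stages: genome/fragment/coculture simulation, paired-end
#' read simulation for the three samples, SNV calling against the cell
#' reference, the three-way set logic, perfect-contig construction,
#' transition detection with private-SNV confirmation, duplication calling,
#' TE annotation with the transition-window filter, TE enrichment in
#' integrated versus non-integrated fragments, proximity statistics and a
#' truth-table evaluation. Deterministic under `(config, seed)`.
#'
#' @param config a `run_config`.
#' @return list of class `ctdna_report`.
#' @export
run_pipeline <- function(config = run_config()) {
  s0 <- config$seed
  gen <- simulate_genomes(config$genome, seed = stage_seed(s0, 1))
  frs <- simulate_ctdna(gen$donor, gen$te_library, config$n_fragments,
                        size_model = config$fragment_size,
                        size_range = config$fragment_size_range,
                        te_end_probability = config$te_end_probability,
                        te_tissue = config$te_tissue,
                        adaptor = config$adaptor,
                        donor_snvs = gen$donor_snvs,
                        min_private_snvs = config$min_private_snvs,
                        seed = stage_seed(s0, 2))
  cc <- simulate_coculture(gen$cell, frs,
                           insertion_rate = config$insertion_rate,
                           proximity_bias = config$proximity_bias,
                           proximity_window = config$proximity_window,
                           n_duplications = config$n_duplications,
                           min_event_spacing = config$min_event_spacing,
                           seed = stage_seed(s0, 3))
  cc$truth$donor_private_snvs <- gen$donor_snvs

  samples <- list(
    cell = simulate_reads(gen$cell, config$coverage, config$read_length,
                          config$insert_size, config$error_rate,
                          name_prefix = "ce", seed = stage_seed(s0, 4)),
    ctDNA = simulate_reads(gen$donor, config$coverage, config$read_length,
                           config$insert_size, config$error_rate,
                           name_prefix = "ct", seed = stage_seed(s0, 5)),
    coculture = simulate_reads(cc$genome, config$coverage, config$read_length,
                               config$insert_size, config$error_rate,
                               name_prefix = "cc", seed = stage_seed(s0, 6)))
  calls <- lapply(names(samples), function(s)
    call_snvs(samples[[s]], gen$cell, af_threshold = config$af_threshold,
              min_depth = config$min_depth,
              min_alt_depth = config$min_alt_depth, sample_label = s,
              anchor_k = config$caller_anchor_k))
  names(calls) <- names(samples)

  venn <- variant_venn(calls$cell, calls$ctDNA, calls$coculture)
  soi <- snvs_of_interest(calls$cell, calls$ctDNA, calls$coculture)
  ctdna_private <- setdiff(as_keys(calls$ctDNA), as_keys(calls$cell))

  contigs <- assemble_or_ingest(cc$truth, "perfect", cell = gen$cell,
                                fragments = frs, flank = config$flank,
                                n_background = config$n_background_contigs)
  transitions <- detect_transitions(contigs, gen$cell, frs,
                                    adaptor = config$adaptor,
                                    anchor_k = config$anchor_k,
                                    max_gap = config$max_gap)
  insertions <- confirm_and_call(transitions, ctdna_private, frs)
  duplications <- detect_duplications(contigs, gen$cell,
                                      min_len = config$min_dup_len,
                                      anchor_k = config$anchor_k)
  # a proximal insertion whose origin falls inside the contig window also
  # duplicates its source interval; junction contigs are counted as
  # insertion evidence, not duplication evidence
  duplications <- duplications[!duplications$contig_id %in%
                                 transitions$contig_id, , drop = FALSE]

  # TE annotation on junction contigs, windowed to the transitions
  junction_ids <- unique(transitions$contig_id)
  te_at_junctions <- NULL
  if (length(junction_ids)) {
    jc <- contigs[contigs$contig_id %in% junction_ids, , drop = FALSE]
    ann <- scan_repeats(jc, gen$te_library)
    te_at_junctions <- filter_transition_proximal(
      ann, transitions, window = config$te_window,
      require_adaptor = config$require_adaptor)
  }

  # TE enrichment: inserted fragments versus non-inserted fragments
  frag_ann <- scan_repeats(frs, gen$te_library)
  te_pos <- frs$fragment_id %in% frag_ann$subject_id
  inserted <- frs$fragment_id %in% cc$truth$planted_insertions$fragment_id
  enrichment <- NULL
  if (any(inserted) && any(!inserted) &&
      length(unique(te_pos)) > 1)
    enrichment <- tryCatch(
      suppressWarnings(enrichment_test(te_pos[inserted], te_pos[!inserted])),
      error = function(e) NULL)

  proximity <- proximity_stats(insertions[insertions$status == "confirmed", ,
                                          drop = FALSE],
                               frs, window = config$proximity_window)
  gain <- count_structural_gain(insertions, duplications,
                                proximity_window = config$proximity_window)
  truth_eval <- compare_to_truth(cc$truth, insertions = insertions,
                                 duplications = duplications)

  report <- structure(list(
    config = config,
    n_donor_snvs = nrow(gen$donor_snvs),
    n_fragments = nrow(frs),
    truth = cc$truth,
    calls = calls,
    venn = venn,
    soi = soi,
    transitions = transitions,
    insertions = insertions,
    duplications = duplications,
    te_at_junctions = te_at_junctions,
    enrichment = enrichment,
    proximity = proximity,
    gain = gain,
    truth_eval = truth_eval), class = "ctdna_report")
  if (!is.null(config$outdir)) write_report_files(report, gen, frs, config$outdir)
  report
}

#' @export
print.ctdna_report <- function(x, ...) {
  cat("== ctDNA coculture integration report ==\n")
  cat(sprintf("donor-private SNVs: %d | ctDNA fragments: %d\n",
              x$n_donor_snvs, x$n_fragments))
  cat(sprintf("SNV calls (cell/ctDNA/coculture): %d / %d / %d\n",
              nrow(x$calls$cell), nrow(x$calls$ctDNA),
              nrow(x$calls$coculture)))
  cat("Venn partition:\n"); print(x$venn)
  cat(sprintf("SNVs of interest: %d\n", length(x$soi)))
  print(x$gain)
  print(x$proximity)
  if (!is.null(x$enrichment)) print(x$enrichment)
  cat("truth evaluation:\n"); print(x$truth_eval)
  invisible(x)
}

#' Compare pipeline calls against the simulation truth table
#'
#' Greedy one-to-one matching by locus distance within `tolerance` bp, per
#' event class. Precision is NA when there are no calls, recall NA when the
#' truth class is empty.
#'
#' @param truth a `coculture_truth`.
#' @param insertions optional `insertion_calls`.
#' @param duplications optional `duplication_events`.
#' @param cassette_sites optional `transgene_sites`.
#' @param tolerance matching tolerance (bp).
#' @return data.frame of class `truth_eval` with one row per event class.
#' @export
compare_to_truth <- function(truth, insertions = NULL, duplications = NULL,
                             cassette_sites = NULL, tolerance = 50) {
  match_count <- function(truth_contig, truth_pos, call_contig, call_pos) {
    used <- rep(FALSE, length(call_pos))
    matched <- 0L
    for (i in seq_along(truth_pos)) {
      d <- ifelse(call_contig == truth_contig[i] & !used,
                  abs(call_pos - truth_pos[i]), Inf)
      j <- which.min(d)
      if (length(j) && is.finite(d[j]) && d[j] <= tolerance) {
        used[j] <- TRUE; matched <- matched + 1L
      }
    }
    matched
  }
  rows <- list()
  if (!is.null(insertions)) {
    ti <- truth$planted_insertions
    m <- match_count(ti$contig, ti$pos, insertions$cell_contig,
                     insertions$cell_pos)
    rows$insertions <- c(n_truth = nrow(ti), n_calls = nrow(insertions),
                         matched = m)
  }
  if (!is.null(duplications)) {
    td <- truth$planted_duplications
    m <- match_count(td$contig, td$start, duplications$ref_contig,
                     duplications$ref_start)
    rows$duplications <- c(n_truth = nrow(td), n_calls = nrow(duplications),
                           matched = m)
  }
  if (!is.null(cassette_sites)) {
    tc <- truth$cassette_sites
    mid <- if (nrow(cassette_sites))
      (cassette_sites$start + cassette_sites$end) / 2 else numeric(0)
    m <- match_count(tc$contig, tc$pos, cassette_sites$contig, mid)
    rows$cassette_sites <- c(n_truth = nrow(tc), n_calls = nrow(cassette_sites),
                             matched = m)
  }
  out <- as.data.frame(do.call(rbind, rows))
  out$class <- names(rows)
  out$precision <- ifelse(out$n_calls > 0, out$matched / out$n_calls, NA)
  out$recall <- ifelse(out$n_truth > 0, out$matched / out$n_truth, NA)
  out <- out[, c("class", "n_truth", "n_calls", "matched", "precision",
                 "recall")]
  rownames(out) <- NULL
  class(out) <- c("truth_eval", "data.frame")
  out
}

#' Matched versus mismatched coculture tissue-specificity experiment
#'
#' Runs two coculture arms over one cell genome: a matched arm whose ctDNA
#' fragments carry TEs of the recipient's tumor type and a mismatched arm
#' carrying the other tissue's TEs. Transition-window TE occurrences from
#' both arms feed [tissue_specific_elements()]; under the generative model
#' the recovered exclusive set should equal the set of matched-tissue
#' elements actually planted at recovered insertions.
#'
#' @param config a `run_config`; `te_tissue` names the matched tissue.
#' @param mismatched_tissue tissue label of the mismatched arm.
#' @param seed overrides `config$seed` when given.
#' @return list with `recovered` (ranked exclusive elements), `planted`
#'   (matched-tissue element names planted at inserted fragments),
#'   `matched_occurrences`, `mismatched_occurrences`.
#' @export
tissue_specificity_experiment <- function(config = run_config(),
                                          mismatched_tissue = "PC",
                                          seed = NULL) {
  if (!is.null(seed)) config$seed <- seed
  s0 <- config$seed
  gen <- simulate_genomes(config$genome, seed = stage_seed(s0, 11))
  arm <- function(tissue, off) {
    frs <- simulate_ctdna(gen$donor, gen$te_library, config$n_fragments,
                          size_model = config$fragment_size,
                          size_range = config$fragment_size_range,
                          te_end_probability = config$te_end_probability,
                          te_tissue = tissue, adaptor = config$adaptor,
                          donor_snvs = gen$donor_snvs,
                          min_private_snvs = max(1, config$min_private_snvs),
                          seed = stage_seed(s0, off))
    cc <- simulate_coculture(gen$cell, frs,
                             insertion_rate = config$insertion_rate,
                             proximity_bias = config$proximity_bias,
                             proximity_window = config$proximity_window,
                             n_duplications = 0,
                             min_event_spacing = config$min_event_spacing,
                             seed = stage_seed(s0, off + 1))
    contigs <- assemble_or_ingest(cc$truth, "perfect", cell = gen$cell,
                                  fragments = frs, flank = config$flank)
    tr <- detect_transitions(contigs, gen$cell, frs,
                             adaptor = config$adaptor,
                             anchor_k = config$anchor_k,
                             max_gap = config$max_gap)
    ann <- scan_repeats(contigs, gen$te_library)
    sel <- filter_transition_proximal(ann, tr, window = config$te_window,
                                      require_adaptor = config$require_adaptor)
    inserted <- frs$fragment_id %in% cc$truth$planted_insertions$fragment_id
    planted <- unlist(lapply(which(inserted), function(i)
      frs$planted_te[[i]]$te_name))
    list(occurrences = sel$te_name, planted = unique(planted))
  }
  matched <- arm(config$te_tissue, 12)
  mismatched <- arm(mismatched_tissue, 21)
  list(recovered = tissue_specific_elements(matched$occurrences,
                                            mismatched$occurrences),
       planted = sort(matched$planted),
       matched_occurrences = matched$occurrences,
       mismatched_occurrences = mismatched$occurrences)
}
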