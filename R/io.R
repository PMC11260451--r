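#' Write analysis tables as TSV / BED
#'
#' TSV output keeps all columns with a header; BED output is 0-based
#' half-open (`contig`, `start`, `end`, name, score). Breakpoints and loci
#' reported in TSV use 1-based coordinates, matching the VCF convention.
#'
#' @param x a `transition_points`, `insertion_calls`, `duplication_events`
#'   or `transgene_sites` data.frame.
#' @param path output file.
#' @export
write_tsv <- function(x, path) {
  y <- as.data.frame(x)
  list_cols <- vapply(y, is.list, logical(1))
  for (cn in names(y)[list_cols])
    y[[cn]] <- vapply(y[[cn]], function(v) paste(unlist(v), collapse = ","),
                      character(1))
  for (cn in intersect(c("breakpoint", "cell_pos", "pos"), names(y)))
    y[[cn]] <- y[[cn]] + 1L
  write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
write_bed <- function(x, path) {
  bed <- if (inherits(x, "insertion_calls"))
    data.frame(x$cell_contig, x$cell_pos, x$cell_pos + 1L,
               paste0(x$fragment_id, ";", x$status), x$n_private_snvs)
  else if (inherits(x, "duplication_events"))
    data.frame(x$ref_contig, x$ref_start, x$ref_end,
               paste0("dup;", x$contig_id), x$length)
  else if (inherits(x, "transgene_sites"))
    data.frame(x$contig, x$start, x$end, "transgene", x$support)
  else if (inherits(x, "transition_points"))
    data.frame(x$cell_contig,
               ifelse(x$orientation == "cell_to_ctdna", x$cell_end,
                      x$cell_start),
               ifelse(x$orientation == "cell_to_ctdna", x$cell_end,
                      x$cell_start) + 1L,
               paste0(x$fragment_id, ";", x$orientation), x$junction_gap)
  else stop_param("no BED layout for class ", class(x)[1])
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write the TE consensus library as FASTA with `name|class|tissue` headers
#'
#' @param library a `te_library`.
#' @param path output FASTA.
#' @export
write_te_fasta <- function(library, path) {
  seqs <- setNames(library$sequence,
                   paste(library$name, library$te_class, library$tumor_label,
                         sep = "|"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}

#' Read a TE consensus library from FASTA
#'
#' @param path FASTA with `name|class|tissue` headers.
#' @return a `te_library` data.frame.
#' @export
read_te_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  parts <- do.call(rbind, strsplit(names(ss), "|", fixed = TRUE))
  out <- data.frame(name = parts[, 1], te_class = parts[, 2],
                    tumor_label = parts[, 3],
                    sequence = as.character(ss), stringsAsFactors = FALSE)
  class(out) <- c("te_library", "data.frame")
  out
}

#' Write a truth table to a directory of TSV files plus a JSON parameters
#' snapshot
#'
#' @param truth a `coculture_truth`.
#' @param dir output directory (created if needed).
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(truth$planted_insertions, file.path(dir, "insertions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth$planted_duplications, file.path(dir, "duplications.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth$cassette_sites, file.path(dir, "cassette_sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth$donor_private_snvs))
    write.table(truth$donor_private_snvs, file.path(dir, "donor_snvs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = truth$seed, parameters = truth$parameters),
                       file.path(dir, "parameters.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}

# Write the per-stage artifacts of a pipeline run.
write_report_files <- function(report, gen, fragments, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(gen$cell, file.path(outdir, "cell.fasta"))
  write_genome_fasta(gen$donor, file.path(outdir, "donor.fasta"))
  write_te_fasta(gen$te_library, file.path(outdir, "te_library.fasta"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(fragments$sequence,
                                      fragments$fragment_id)),
    filepath = file.path(outdir, "ctdna_fragments.fasta"))
  for (s in names(report$calls))
    write_snv_vcf(report$calls[[s]],
                  file.path(outdir, paste0("calls_", s, ".vcf")))
  write_tsv(report$transitions, file.path(outdir, "transitions.tsv"))
  write_tsv(report$insertions, file.path(outdir, "insertions.tsv"))
  write_bed(report$insertions, file.path(outdir, "insertions.bed"))
  write_tsv(report$duplications, file.path(outdir, "duplications.tsv"))
  write_truth(report$truth, file.path(outdir, "truth"))
  jsonlite::write_json(
    list(venn = as.list(report$venn), n_soi = length(report$soi),
         gain = unclass(report$gain),
         proximal_fraction = report$proximity$proximal_fraction),
    file.path(outdir, "summary.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
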