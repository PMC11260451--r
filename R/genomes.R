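#' Construct a genome sequence object
#'
#' A `genome_sequence` is a named haploid sequence set with 0-based half-open
#' coordinates. It is the container for the recipient cell reference, the
#' ctDNA donor genome, the coculture genome and transgene cassettes.
#'
#' @param name identifier for the genome.
#' @param sequences named character vector of contig sequences (A/C/G/T only).
#' @param role one of `"cell"`, `"donor"`, `"coculture"`, `"cassette"`.
#' @return an object of class `genome_sequence`.
#' @export
genome_sequence <- function(name, sequences, role = c("cell", "donor",
                                                      "coculture", "cassette")) {
  role <- match.arg(role)
  if (length(sequences) == 0) stop_param("a genome needs at least one contig")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop_param("contig names must be present and unique")
  if (any(nchar(sequences) == 0)) stop_param("contigs must be non-empty")
  if (any(grepl("[^ACGT]", sequences)))
    stop_param("sequences restricted to A/C/G/T")
  structure(list(name = name, sequences = sequences, role = role),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence> %s (role: %s)\n", x$name, x$role))
  cat(sprintf("  %d contig(s), total %s bp\n", length(x$sequences),
              format(sum(nchar(x$sequences)), big.mark = ",")))
  invisible(x)
}

#' @export
length.genome_sequence <- function(x) sum(nchar(x$sequences))

#' Extract a subsequence from a genome (0-based half-open)
#'
#' @param genome a `genome_sequence`.
#' @param contig contig name.
#' @param start,end 0-based half-open interval.
#' @return character scalar.
#' @export
genome_subseq <- function(genome, contig, start, end) {
  s <- genome$sequences[[contig]]
  if (is.null(s)) stop_param("unknown contig: ", contig)
  if (start < 0 || end > nchar(s) || end < start)
    stop_param("interval out of bounds")
  substr(s, start + 1L, end)
}

#' Write a genome to FASTA
#'
#' @param genome a `genome_sequence` (or named character vector).
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- if (inherits(genome, "genome_sequence")) genome$sequences else genome
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @param name genome name (defaults to file name).
#' @param role genome role.
#' @return a `genome_sequence`.
#' @export
read_genome_fasta <- function(path, name = basename(path), role = "cell") {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  genome_sequence(name, seqs, role)
}
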