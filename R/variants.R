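#' Build a variant key from its components
#'
#' Keys are the exchange atom of the three-way set logic:
#' `"contig:pos:ref:alt"` with a 0-based position.
#'
#' @param contig,pos,ref,alt vectors of equal length (`pos` 0-based).
#' @return character vector of keys.
#' @export
variant_key <- function(contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = ":")
}

#' Parse variant keys back into components
#'
#' @param keys character vector of `"contig:pos:ref:alt"` keys.
#' @return data.frame with `contig`, `pos` (0-based integer), `ref`, `alt`.
#' @export
parse_variant_key <- function(keys) {
  if (!length(keys))
    return(data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0)))
  parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  data.frame(contig = parts[, 1], pos = as.integer(parts[, 2]),
             ref = parts[, 3], alt = parts[, 4], stringsAsFactors = FALSE)
}

#' Call SNVs from reads or a pileup
#'
#' Transparent pileup caller: reads are anchored on the reference with
#' [map_reads()], base counts accumulated per site, and one record is emitted
#' per site/alt allele with allele frequency at or above `af_threshold`
#' (inclusive, matching the study's AF >= 0.01 rule) and total site depth of
#' at least `min_depth`. Multi-allelic sites decompose into one record per
#' alt allele; `af = depth_alt / (depth_ref + depth_alt)`.
#'
#' @param x a `read_set` or a `pileup` object.
#' @param reference `genome_sequence` the calls are made against (ignored
#'   when `x` is already a pileup).
#' @param af_threshold inclusive allele-frequency threshold (default 0.01).
#' @param min_depth minimum total site depth (default 8).
#' @param min_alt_depth minimum reads supporting the alt allele (default 1,
#'   the pure threshold rule; raise to 2+ to suppress isolated sequencing
#'   errors at moderate coverage).
#' @param sample_label one of `"cell"`, `"ctDNA"`, `"coculture"`, `"tumor"`.
#' @param anchor_k,max_mismatch_frac passed to [map_reads()].
#' @return data.frame of class `snv_calls`, sorted by `(contig, pos)`, with
#'   columns `contig`, `pos` (0-based), `ref`, `alt`, `depth_ref`,
#'   `depth_alt`, `af`, `sample_label` and a `key` column.
#' @export
call_snvs <- function(x, reference = NULL, af_threshold = 0.01, min_depth = 8,
                      min_alt_depth = 1, sample_label = "cell", anchor_k = 21,
                      max_mismatch_frac = 0.1) {
  if (af_threshold <= 0 || af_threshold > 1)
    stop_param("af_threshold must be in (0, 1]")
  pe <- if (inherits(x, "pileup")) x else {
    if (is.null(reference)) stop_param("reference required when calling from reads")
    pileup_from_mapped(map_reads(x, reference, anchor_k, max_mismatch_frac),
                       reference)
  }
  reference <- pe$reference
  rows <- list()
  for (contig in names(pe$counts)) {
    m <- pe$counts[[contig]]
    depth <- colSums(m)
    ref_int <- base_ints(reference$sequences[[contig]])
    ref_count <- m[cbind(ref_int, seq_along(ref_int))]
    for (b in 1:4) {
      alt_count <- m[b, ]
      cand <- which(b != ref_int & alt_count >= min_alt_depth &
                    depth >= min_depth)
      if (!length(cand)) next
      af <- alt_count[cand] / (ref_count[cand] + alt_count[cand])
      keep <- af >= af_threshold
      cand <- cand[keep]; af <- af[keep]
      if (!length(cand)) next
      rows[[length(rows) + 1L]] <- data.frame(
        contig = contig, pos = cand - 1L,
        ref = DNA_BASES[ref_int[cand]], alt = DNA_BASES[b],
        depth_ref = ref_count[cand], depth_alt = alt_count[cand],
        af = af, sample_label = sample_label, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(0), pos = integer(0), ref = character(0),
               alt = character(0), depth_ref = integer(0),
               depth_alt = integer(0), af = numeric(0),
               sample_label = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$pos, out$alt), ]
  out$key <- variant_key(out$contig, out$pos, out$ref, out$alt)
  rownames(out) <- NULL
  class(out) <- c("snv_calls", "data.frame")
  out
}

#' SNVs of interest: shared by ctDNA and coculture, absent from the cell
#'
#' The central three-way set operation of the comparative design:
#' `(ctdna` \eqn{\cap} `coculture) \ cell`. Variants shared by all samples
#' (library-preparation artifacts included) are filtered out by the cell
#' term; what remains marks sequence transferred from the ctDNA.
#'
#' @param cell,ctdna,coculture character vectors of variant keys (or
#'   `snv_calls` data.frames, whose `key` columns are used).
#' @return character vector of keys.
#' @seealso [variant_venn()] for the full 7-region partition.
#' @export
snvs_of_interest <- function(cell, ctdna, coculture) {
  k <- lapply(list(cell, ctdna, coculture), as_keys)
  setdiff(intersect(k[[2]], k[[3]]), k[[1]])
}

as_keys <- function(x) {
  if (is.data.frame(x)) unique(x$key) else unique(as.character(x))
}

#' Seven-region Venn partition of the three variant sets
#'
#' @inheritParams snvs_of_interest
#' @return named integer vector over the 7 exclusive regions
#'   (`cell_only`, `ctdna_only`, `coculture_only`, `cell.ctdna`,
#'   `cell.coculture`, `ctdna.coculture`, `all`); the counts sum to
#'   `|cell` \eqn{\cup} `ctdna` \eqn{\cup} `coculture|`.
#' @export
variant_venn <- function(cell, ctdna, coculture) {
  a <- as_keys(cell); b <- as_keys(ctdna); d <- as_keys(coculture)
  u <- unique(c(a, b, d))
  ia <- u %in% a; ib <- u %in% b; id <- u %in% d
  c(cell_only = sum(ia & !ib & !id),
    ctdna_only = sum(!ia & ib & !id),
    coculture_only = sum(!ia & !ib & id),
    cell.ctdna = sum(ia & ib & !id),
    cell.coculture = sum(ia & !ib & id),
    ctdna.coculture = sum(!ia & ib & id),
    all = sum(ia & ib & id))
}

#' VAF shift between cell and coculture at shared sites
#'
#' For each coculture record, reports the allele-frequency change
#' `delta_af = af_coculture - af_cell` and the p-value of a two-sided exact
#' conditional test (Fisher) on the 2x2 allele-depth table
#' `[[ref_cell, alt_cell], [ref_coculture, alt_coculture]]`. A variant absent
#' from the cell calls is treated as `(depth_ref = site depth, depth_alt =
#' 0)`; the cell site depth is taken from `cell_pileup` when given, otherwise
#' the coculture site depth is used as a proxy.
#'
#' @param coculture `snv_calls` for the coculture sample.
#' @param cell `snv_calls` for the cell sample (may be empty).
#' @param cell_pileup optional `pileup` of the cell sample for site depths at
#'   uncalled sites.
#' @return data.frame with `key`, `af_cell`, `af_coculture`, `delta_af`,
#'   `p_value` and a `flagged` column for zero-depth coculture sites.
#' @export
vaf_shift <- function(coculture, cell = NULL, cell_pileup = NULL) {
  n <- nrow(coculture)
  out <- data.frame(key = coculture$key, af_cell = NA_real_,
                    af_coculture = coculture$af, delta_af = NA_real_,
                    p_value = NA_real_, flagged = FALSE,
                    stringsAsFactors = FALSE)
  cell_idx <- if (!is.null(cell) && nrow(cell)) match(coculture$key, cell$key)
  else rep(NA_integer_, n)
  for (i in seq_len(n)) {
    rc <- coculture$depth_ref[i]; ac <- coculture$depth_alt[i]
    if (rc + ac == 0) { out$flagged[i] <- TRUE; next }
    j <- cell_idx[i]
    if (!is.na(j)) {
      r0 <- cell$depth_ref[j]; a0 <- cell$depth_alt[j]
    } else {
      depth0 <- if (!is.null(cell_pileup)) {
        sum(cell_pileup$counts[[coculture$contig[i]]][, coculture$pos[i] + 1L])
      } else rc + ac
      r0 <- depth0; a0 <- 0L
    }
    af0 <- if (r0 + a0 > 0) a0 / (r0 + a0) else 0
    out$af_cell[i] <- af0
    out$delta_af[i] <- coculture$af[i] - af0
    out$p_value[i] <- fisher.test(matrix(c(r0, a0, rc, ac), nrow = 2,
                                         byrow = TRUE))$p.value
  }
  out
}

#' Estimate the tumor-derived fraction of a cfDNA fragment pool
#'
#' A fragment is informative when it overlaps at least one tumor-SNV site;
#' it counts as tumor-derived when it carries the tumor alt allele at any
#' overlapped site. The estimate is
#' `tumor fragments / informative fragments`, the fragment-level reading of
#' "fraction of cfDNA of tumor origin based on tumor SNV presence".
#'
#' @param fragments data.frame with `contig`, `start`, `end` (0-based
#'   half-open, reference coordinates) and `sequence` columns (e.g. cfDNA
#'   fragment cores laid on the reference).
#' @param tumor_snvs data.frame with `contig`, `pos` (0-based), `ref`, `alt`
#'   (or a vector of variant keys).
#' @return the estimated fraction, with attributes `n_informative`,
#'   `n_tumor` and `per_site` (per-site allele tallies).
#' @export
estimate_tumor_fraction <- function(fragments, tumor_snvs) {
  if (is.character(tumor_snvs)) tumor_snvs <- parse_variant_key(tumor_snvs)
  informative <- 0L; tumor <- 0L
  site_alt <- integer(nrow(tumor_snvs)); site_cov <- integer(nrow(tumor_snvs))
  for (i in seq_len(nrow(fragments))) {
    fr <- fragments[i, ]
    hit <- which(tumor_snvs$contig == fr$contig &
                 tumor_snvs$pos >= fr$start & tumor_snvs$pos < fr$end)
    if (!length(hit)) next
    informative <- informative + 1L
    offs <- tumor_snvs$pos[hit] - fr$start + 1L
    base <- substring(fr$sequence, offs, offs)
    is_alt <- base == tumor_snvs$alt[hit]
    site_cov[hit] <- site_cov[hit] + 1L
    site_alt[hit] <- site_alt[hit] + is_alt
    if (any(is_alt)) tumor <- tumor + 1L
  }
  if (informative == 0L)
    stop_param("no fragment overlaps a tumor SNV site; estimate undefined")
  est <- tumor / informative
  attr(est, "n_informative") <- informative
  attr(est, "n_tumor") <- tumor
  attr(est, "per_site") <- data.frame(
    key = variant_key(tumor_snvs$contig, tumor_snvs$pos, tumor_snvs$ref,
                      tumor_snvs$alt),
    fragments = site_cov, alt_fragments = site_alt, stringsAsFactors = FALSE)
  est
}

#' Write SNV calls as VCF v4.2
#'
#' Coordinates shift to 1-based on output; FORMAT carries `AD` (ref,alt
#' depths) and `AF`.
#'
#' @param calls an `snv_calls` data.frame.
#' @param path output `.vcf` path.
#' @param sample sample column name (defaults to the calls' label).
#' @export
write_snv_vcf <- function(calls, path, sample = NULL) {
  if (is.null(sample))
    sample <- if (nrow(calls)) calls$sample_label[1] else "sample"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=ctdnaIntegrate",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")), con)
  if (nrow(calls)) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD:AF\t0/1:%d,%d:%.6g",
                       calls$contig, calls$pos + 1L, calls$ref, calls$alt,
                       calls$depth_ref, calls$depth_alt, calls$af), con)
  }
  invisible(path)
}

#' Read SNV calls from a VCF file
#'
#' Ingests VCF v4.2 with `AD` sample fields (one alt per row after
#' decomposition); coordinates shift back to 0-based. Uses the vcfR parser.
#'
#' @param path VCF path.
#' @param sample_label label to assign to the ingested records.
#' @return an `snv_calls` data.frame.
#' @export
read_snv_vcf <- function(path, sample_label = "cell") {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_param("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = list(NULL, colnames(vcfR::getFIX(v))))
  ad <- vcfR::extract.gt(v, element = "AD")
  dr <- as.integer(sub(",.*$", "", ad[, 1]))
  da <- as.integer(sub("^[^,]*,", "", ad[, 1]))
  out <- data.frame(contig = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]) - 1L,
                    ref = fix[, "REF"], alt = fix[, "ALT"],
                    depth_ref = dr, depth_alt = da,
                    af = ifelse(dr + da > 0, da / (dr + da), NA_real_),
                    sample_label = sample_label, stringsAsFactors = FALSE)
  out$key <- variant_key(out$contig, out$pos, out$ref, out$alt)
  class(out) <- c("snv_calls", "data.frame")
  out
}
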