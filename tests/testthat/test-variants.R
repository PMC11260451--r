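make_pileup <- function(ref_seq, counts_at) {
  # counts_at: list of list(pos (0-based), counts c(A,C,G,T))
  ref <- genome_sequence("ref", c(ctg = ref_seq), role = "cell")
  m <- matrix(0L, 4, nchar(ref_seq), dimnames = list(c("A", "C", "G", "T"),
                                                     NULL))
  for (x in counts_at) m[, x$pos + 1L] <- as.integer(x$counts)
  structure(list(counts = list(ctg = m), reference = ref), class = "pileup")
}

test_that("pileup caller applies depth and inclusive AF thresholds", {
  ref_seq <- strrep("A", 200)
  # ref A; alt depth 0 -> nothing
  pe <- make_pileup(ref_seq, list(list(pos = 10L, counts = c(100, 0, 0, 0))))
  expect_equal(nrow(call_snvs(pe)), 0L)
  # 1 alt in 100 at the inclusive 0.01 boundary
  pe <- make_pileup(ref_seq, list(list(pos = 10L, counts = c(99, 0, 1, 0))))
  calls <- call_snvs(pe, af_threshold = 0.01)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$af, 0.01)
  expect_identical(calls$alt, "G")
  # just below the boundary -> excluded
  pe <- make_pileup(ref_seq, list(list(pos = 10L, counts = c(100, 0, 1, 0))))
  expect_equal(nrow(call_snvs(pe, af_threshold = 0.01)), 0L)
  # min_depth floor
  pe <- make_pileup(ref_seq, list(list(pos = 10L, counts = c(4, 0, 3, 0))))
  expect_equal(nrow(call_snvs(pe, min_depth = 8)), 0L)
  expect_equal(nrow(call_snvs(pe, min_depth = 7)), 1L)
  # multi-allelic decomposition: one record per alt allele
  pe <- make_pileup(ref_seq, list(list(pos = 20L, counts = c(60, 20, 0, 20))))
  calls <- call_snvs(pe)
  expect_equal(nrow(calls), 2L)
  expect_setequal(calls$alt, c("C", "T"))
  expect_equal(calls$af, c(0.25, 0.25))
})

test_that("caller recovers planted SNVs exactly from error-free reads", {
  g <- simulate_genomes(list(n_contigs = 1L, contig_length = 3e4,
                             donor_snv_count = 15L), seed = 21)
  mix <- merge_read_sets(
    simulate_reads(g$cell, coverage = 12, error_rate = 0, name_prefix = "a",
                   seed = 1),
    simulate_reads(g$donor, coverage = 12, error_rate = 0, name_prefix = "b",
                   seed = 2))
  calls <- call_snvs(mix, g$cell, af_threshold = 0.01, min_depth = 8)
  truth_keys <- variant_key(g$donor_snvs$contig, g$donor_snvs$pos,
                            g$donor_snvs$ref, g$donor_snvs$alt)
  expect_setequal(calls$key, truth_keys)   # recall and precision both 1
  expect_true(all(abs(calls$af - 0.5) < 0.35))
  # threshold monotonicity: raising af_threshold never adds calls
  for (thr in c(0.05, 0.2, 0.45)) {
    expect_true(all(call_snvs(mix, g$cell, af_threshold = thr)$key %in%
                    calls$key))
  }
})

test_that("three-way set logic matches the brute-force oracle", {
  # spec examples
  expect_identical(snvs_of_interest(character(0), "A", "A"), "A")
  expect_identical(snvs_of_interest("B", c("A", "B"), c("B", "C")),
                   character(0))
  set.seed(42)
  for (i in 1:60) {
    s <- random_key_sets()
    expect_setequal(snvs_of_interest(s$cell, s$ctdna, s$coculture),
                    oracle_soi(s$cell, s$ctdna, s$coculture))
    v <- variant_venn(s$cell, s$ctdna, s$coculture)
    expect_equal(sum(v),
                 length(unique(c(s$cell, s$ctdna, s$coculture))))
  }
})

snv_row <- function(contig, pos, ref, alt, dr, da, label) {
  out <- data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
                    depth_ref = dr, depth_alt = da, af = da / (dr + da),
                    sample_label = label, stringsAsFactors = FALSE)
  out$key <- variant_key(contig, pos, ref, alt)
  class(out) <- c("snv_calls", "data.frame")
  out
}

test_that("vaf_shift reports delta AF and exact conditional p", {
  cc <- snv_row("chr1", 100L, "A", "G", 90L, 10L, "coculture")
  ce <- snv_row("chr1", 100L, "A", "G", 100L, 0L, "cell")
  sh <- vaf_shift(cc, ce)
  expect_equal(sh$delta_af, 0.10)
  expect_equal(sh$p_value, oracle_fisher_p(100, 0, 90, 10), tolerance = 1e-9)
  # identical depth pairs: null case
  sh0 <- vaf_shift(snv_row("chr1", 5L, "A", "G", 90L, 10L, "coculture"),
                   snv_row("chr1", 5L, "A", "G", 90L, 10L, "cell"))
  expect_equal(sh0$delta_af, 0)
  expect_equal(sh0$p_value, 1)
  # spec table [[50, 0], [40, 10]] against tail enumeration
  sh2 <- vaf_shift(snv_row("chr1", 7L, "A", "T", 40L, 10L, "coculture"),
                   snv_row("chr1", 7L, "A", "T", 50L, 0L, "cell"))
  expect_equal(sh2$p_value, oracle_fisher_p(50, 0, 40, 10), tolerance = 1e-9)
  # absent cell record: depth proxy, alt 0
  sh3 <- vaf_shift(cc, NULL)
  expect_equal(sh3$af_cell, 0)
  expect_equal(sh3$delta_af, 0.10)
})

test_that("tumor fraction estimation is exact in the limits and recovers a
           known mixture", {
  snvs <- data.frame(contig = "chr1", pos = c(10L, 60L), ref = "A",
                     alt = "G", stringsAsFactors = FALSE)
  all_alt <- data.frame(contig = "chr1", start = c(0L, 50L), end = c(30L, 80L),
                        sequence = c(paste0(strrep("A", 10), "G",
                                            strrep("A", 19)),
                                     paste0(strrep("A", 10), "G",
                                            strrep("A", 19))),
                        stringsAsFactors = FALSE)
  expect_equal(as.numeric(estimate_tumor_fraction(all_alt, snvs)), 1.0)
  none <- all_alt; none$sequence <- strrep("A", 30)
  expect_equal(as.numeric(estimate_tumor_fraction(none, snvs)), 0.0)
  off <- data.frame(contig = "chr1", start = 200L, end = 230L,
                    sequence = strrep("A", 30))
  expect_error(estimate_tumor_fraction(off, snvs), "overlaps")

  # 80:20 donor:cell fragment mixture recovers the tumor fraction
  g <- simulate_genomes(list(n_contigs = 1L, contig_length = 2e4,
                             donor_snv_count = 40L), seed = 17)
  set.seed(99)
  n <- 400
  start <- sample.int(2e4 - 200L, n) - 1L
  from_donor <- runif(n) < 0.8
  seqs <- ifelse(from_donor,
                 substring(g$donor$sequences[[1]], start + 1L, start + 200L),
                 substring(g$cell$sequences[[1]], start + 1L, start + 200L))
  frags <- data.frame(contig = "chr1", start = start, end = start + 200L,
                      sequence = seqs, stringsAsFactors = FALSE)
  est <- estimate_tumor_fraction(frags, g$donor_snvs)
  n_inf <- attr(est, "n_informative")
  expect_gt(n_inf, 30)
  b <- binom_bounds95(0.8, n_inf)
  expect_gt(as.numeric(est), b["lower"])
  expect_lt(as.numeric(est), b["upper"])
})

test_that("VCF round-trip preserves records and coordinates", {
  calls <- rbind(snv_row("chr1", 0L, "A", "G", 30L, 10L, "coculture"),
                 snv_row("chr2", 999L, "C", "T", 12L, 4L, "coculture"))
  path <- tempfile(fileext = ".vcf")
  write_snv_vcf(calls, path)
  txt <- readLines(path)
  expect_true(any(grepl("^chr1\t1\t", txt)))  # 1-based on disk
  back <- read_snv_vcf(path, sample_label = "coculture")
  expect_equal(back$contig, calls$contig)
  expect_equal(back$pos, calls$pos)           # 0-based in memory
  expect_equal(back$ref, calls$ref)
  expect_equal(back$alt, calls$alt)
  expect_equal(back$depth_ref, calls$depth_ref)
  expect_equal(back$depth_alt, calls$depth_alt)
  expect_equal(back$af, calls$af, tolerance = 1e-6)
  expect_identical(back$key, calls$key)
})

test_that("pileup TSV round-trips through the ingestion path", {
  g <- simulate_genomes(list(n_contigs = 1L, contig_length = 1e4,
                             donor_snv_count = 5L), seed = 31)
  rs <- simulate_reads(g$donor, coverage = 10, error_rate = 0, seed = 1)
  pe <- pileup_from_mapped(map_reads(rs, g$cell), g$cell)
  path <- tempfile(fileext = ".tsv")
  write_pileup_tsv(pe, path)
  pe2 <- read_pileup_tsv(path, g$cell)
  expect_identical(pe$counts, pe2$counts)
  expect_identical(call_snvs(pe)$key, call_snvs(pe2)$key)
})
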