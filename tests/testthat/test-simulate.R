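test_that("donor genome differs from cell only by the recorded private SNVs", {
  g0 <- simulate_genomes(list(n_contigs = 1L, contig_length = 1e4,
                              donor_snv_rate = 0), seed = 3)
  expect_identical(g0$cell$sequences, g0$donor$sequences)
  expect_equal(nrow(g0$donor_snvs), 0L)

  g <- simulate_genomes(list(n_contigs = 1L, contig_length = 1e5,
                             donor_snv_rate = 0.001), seed = 11)
  # direct sequence diff as the oracle for the truth table
  diff_pos <- which(charToRaw(g$cell$sequences[[1]]) !=
                    charToRaw(g$donor$sequences[[1]])) - 1L
  expect_identical(diff_pos, g$donor_snvs$pos)
  expect_lt(abs(nrow(g$donor_snvs) - 100), 4 * sqrt(1e5 * 0.001 * 0.999))
  expect_true(all(g$donor_snvs$ref != g$donor_snvs$alt))
})

test_that("all generators are byte-deterministic under (config, seed)", {
  g1 <- small_world(seed = 9)
  g2 <- small_world(seed = 9)
  expect_identical(g1, g2)
  f1 <- simulate_ctdna(g1$donor, g1$te_library, 8, donor_snvs = g1$donor_snvs,
                       seed = 4)
  f2 <- simulate_ctdna(g1$donor, g1$te_library, 8, donor_snvs = g1$donor_snvs,
                       seed = 4)
  expect_identical(f1, f2)
  r1 <- simulate_reads(g1$cell, coverage = 5, seed = 2)
  r2 <- simulate_reads(g1$cell, coverage = 5, seed = 2)
  expect_identical(r1, r2)
  tmp <- tempfile()
  p1 <- write_fastq(r1, paste0(tmp, "_a"))
  p2 <- write_fastq(r2, paste0(tmp, "_b"))
  expect_identical(readLines(gzfile(p1[1])), readLines(gzfile(p2[1])))
})

test_that("ctDNA fragments carry adaptors and TE placements near ends", {
  g <- small_world(seed = 5)
  fr0 <- simulate_ctdna(g$donor, g$te_library, 10, te_end_probability = 0,
                        donor_snvs = g$donor_snvs, seed = 1)
  expect_true(all(vapply(fr0$planted_te, nrow, integer(1)) == 0L))

  fr <- simulate_ctdna(g$donor, g$te_library, 20, te_end_probability = 1,
                       size_model = list(meanlog = log(400), sdlog = 0.2),
                       size_range = c(200, 1000),
                       donor_snvs = g$donor_snvs, seed = 2)
  expect_true(all(startsWith(fr$sequence, PACBIO_ADAPTOR)))
  expect_true(all(endsWith(fr$sequence, PACBIO_ADAPTOR)))
  expect_true(all(vapply(fr$planted_te, nrow, integer(1)) >= 1L))
  # every recorded TE lies within 100 nt of a core end, and the repeat
  # scanner (cross-module oracle) finds it there
  ann <- scan_repeats(setNames(fr$core, fr$fragment_id), g$te_library)
  for (i in seq_len(nrow(fr))) {
    te <- fr$planted_te[[i]]
    core_len <- nchar(fr$core[i])
    edge <- min(te$start, core_len - te$end)
    expect_lte(edge, 100)
    hit <- ann[ann$subject_id == fr$fragment_id[i] &
               ann$te_name == te$te_name, ]
    expect_gte(nrow(hit), 1)
    expect_lte(min(hit$start), te$start + 5)
  }
  # fragment cores without a TE are exact donor substrings
  plain <- which(vapply(fr0$planted_te, nrow, integer(1)) == 0L)
  for (i in plain[1:5]) {
    expect_identical(fr0$core[i],
                     genome_subseq(g$donor, fr0$origin_contig[i],
                                   fr0$origin_start[i], fr0$origin_end[i]))
  }
})

test_that("coculture genome conserves length and records recoverable events", {
  g <- small_world(seed = 6)
  fr <- simulate_ctdna(g$donor, g$te_library, 8, donor_snvs = g$donor_snvs,
                       size_model = list(meanlog = log(300), sdlog = 0.2),
                       size_range = c(150, 800), seed = 3)

  null_cc <- simulate_coculture(g$cell, fr, insertion_rate = 0,
                                duplication_rate = 0, seed = 1)
  expect_identical(null_cc$genome$sequences, g$cell$sequences)
  expect_equal(nrow(null_cc$truth$planted_insertions), 0L)
  expect_equal(nrow(null_cc$truth$planted_duplications), 0L)

  cc <- simulate_coculture(g$cell, fr, insertion_rate = 0.6, n_duplications = 2,
                           proximity_window = 2000, min_event_spacing = 1200,
                           seed = 2)
  ins <- cc$truth$planted_insertions
  dup <- cc$truth$planted_duplications
  core_len <- nchar(fr$core)[match(ins$fragment_id, fr$fragment_id)]
  expect_equal(length(cc$genome),
               length(g$cell) + sum(core_len) + sum(dup$length))
  # each planted core is recoverable as an exact substring at its lifted
  # position in the coculture genome
  for (contig in unique(ins$contig)) {
    ev <- rbind(
      data.frame(pos = ins$pos[ins$contig == contig],
                 len = core_len[ins$contig == contig],
                 id = ins$fragment_id[ins$contig == contig]),
      data.frame(pos = dup$start[dup$contig == contig],
                 len = dup$length[dup$contig == contig], id = NA))
    ev <- ev[order(ev$pos), ]
    offset <- 0L
    for (i in seq_len(nrow(ev))) {
      if (!is.na(ev$id[i])) {
        core <- fr$core[fr$fragment_id == ev$id[i]]
        got <- substr(cc$genome$sequences[[contig]],
                      ev$pos[i] + offset + 1L, ev$pos[i] + offset + ev$len[i])
        expect_identical(got, core)
      }
      offset <- offset + ev$len[i]
    }
  }
  expect_true(all(ins$proximal ==
                  (!is.na(ins$distance_to_origin) &
                   ins$distance_to_origin <= 2000)))
})

test_that("read simulator hits requested depth and origins are faithful", {
  g <- simulate_genomes(list(n_contigs = 1L, contig_length = 2e4,
                             donor_snv_rate = 0), seed = 2)
  rs <- simulate_reads(g$cell, coverage = 20, error_rate = 0, seed = 8)
  realized <- 2 * rs$read_length * nrow(rs$origin) / 2e4
  expect_lt(abs(realized - 20) / 20, 0.1)
  # error-free reads substring-match the genome at their recorded origin
  for (i in seq(1, nrow(rs$origin), by = 97)) {
    o <- rs$origin[i, ]
    frag <- genome_subseq(g$cell, o$contig, o$start, o$start + o$insert)
    left <- substr(frag, 1, rs$read_length)
    right <- revcomp(substring(frag, o$insert - rs$read_length + 1, o$insert))
    if (o$strand == "+") {
      expect_identical(unname(rs$r1[o$read_id]), left)
      expect_identical(unname(rs$r2[o$read_id]), right)
    } else {
      expect_identical(unname(rs$r1[o$read_id]), right)
      expect_identical(unname(rs$r2[o$read_id]), left)
    }
  }
  expect_error(simulate_reads(g$cell, coverage = 0), "coverage")
})

test_that("cassette integration bookkeeping is exact", {
  g <- simulate_genomes(list(n_contigs = 1L, contig_length = 3e4,
                             donor_snv_rate = 0), seed = 4)
  cass <- synthesize_cassette(800, cell = g$cell, seed = 1)
  m0 <- simulate_cassette_integration(g$cell, cass, n_sites = 0, seed = 1)
  expect_identical(m0$genome$sequences[[1]], g$cell$sequences[[1]])
  m2 <- simulate_cassette_integration(g$cell, cass, n_sites = 2, seed = 2)
  expect_equal(nrow(m2$truth$cassette_sites), 2L)
  expect_equal(length(m2$genome), length(g$cell) + 2L * 800L)
  # the cassette occurs verbatim at each lifted site
  sites <- m2$truth$cassette_sites[order(m2$truth$cassette_sites$pos), ]
  offset <- 0L
  for (i in seq_len(nrow(sites))) {
    got <- substr(m2$genome$sequences[[sites$contig[i]]],
                  sites$pos[i] + offset + 1L, sites$pos[i] + offset + 800L)
    expect_identical(got, cass$sequences[[1]])
    offset <- offset + 800L
  }
})
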