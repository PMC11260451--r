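# shared fixture: a small world with fragments long enough to anchor
trans_world <- function(seed = 13, n_frags = 6) {
  g <- small_world(seed = seed, n_snvs = 60)
  fr <- simulate_ctdna(g$donor, g$te_library, n_frags,
                       size_model = list(meanlog = log(450), sdlog = 0.2),
                       size_range = c(300, 900),
                       te_end_probability = 0.5, donor_snvs = g$donor_snvs,
                       min_private_snvs = 1, seed = seed + 1)
  list(g = g, fr = fr)
}

test_that("FASTA ingestion returns contigs byte-identical", {
  seqs <- setNames(vapply(c(300, 400, 500), function(n) {
    set.seed(n); random_dna(n)
  }, character(1)), c("c1", "c2", "c3"))
  path <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  cs <- assemble_or_ingest(path, mode = "ingest")
  expect_equal(nrow(cs), 3L)
  expect_identical(setNames(cs$sequence, cs$contig_id), seqs)
})

test_that("constructed chimeras yield one transition with correct adaptor
           flag and breakpoint", {
  w <- trans_world()
  cellwin <- genome_subseq(w$g$cell, "chr1", 4000, 4500)
  core <- w$fr$core[1]
  with_ad <- paste0(cellwin, PACBIO_ADAPTOR, core)
  without <- paste0(cellwin, core)
  pure_cell <- genome_subseq(w$g$cell, "chr2", 100, 1800)

  tr <- detect_transitions(c(chimA = with_ad, chimB = without,
                             pure = pure_cell),
                           w$g$cell, w$fr)
  expect_equal(sum(tr$contig_id == "pure"), 0L)
  a <- tr[tr$contig_id == "chimA", ]
  expect_equal(nrow(a), 1L)
  expect_true(a$adaptor_adjacent)
  expect_identical(a$orientation, "cell_to_ctdna")
  expect_identical(a$fragment_id, w$fr$fragment_id[1])
  # breakpoint equals the exhaustive split-point oracle
  expect_equal(a$breakpoint,
               oracle_split(with_ad, w$g$cell$sequences, w$fr$sequence[1]))
  b <- tr[tr$contig_id == "chimB", ]
  expect_equal(nrow(b), 1L)
  expect_false(b$adaptor_adjacent)
  expect_equal(b$breakpoint,
               oracle_split(without, w$g$cell$sequences, core))
  # junction gap absorbs the adaptor at the joint
  expect_gte(a$junction_gap, nchar(PACBIO_ADAPTOR) - 3L)
  expect_equal(b$junction_gap, 0L)
})

test_that("reverse-complementing a contig mirrors the transition", {
  w <- trans_world(seed = 23)
  chim <- paste0(genome_subseq(w$g$cell, "chr1", 2000, 2600), w$fr$core[2])
  fwd <- detect_transitions(c(x = chim), w$g$cell, w$fr)
  rev <- detect_transitions(c(x = revcomp(chim)), w$g$cell, w$fr)
  expect_equal(nrow(fwd), 1L)
  expect_equal(nrow(rev), 1L)
  expect_identical(rev$orientation, "ctdna_to_cell")
  expect_equal(rev$breakpoint, nchar(chim) - fwd$breakpoint)
  expect_identical(fwd$cell_strand, "+")
  expect_identical(rev$cell_strand, "-")
  expect_equal(rev$cell_start, fwd$cell_start)
  expect_equal(rev$cell_end, fwd$cell_end)
})

test_that("detected breakpoints equal the exhaustive split oracle on random
           chimeras", {
  w <- trans_world(seed = 31)
  set.seed(7)
  for (i in 1:25) {
    fi <- sample(nrow(w$fr), 1)
    contig <- sample(c("chr1", "chr2"), 1)
    a <- sample(500:8000, 1)
    len <- sample(400:1200, 1)
    chim <- paste0(genome_subseq(w$g$cell, contig, a, a + len),
                   w$fr$core[fi])
    tr <- detect_transitions(setNames(chim, "q"), w$g$cell, w$fr)
    tr <- tr[tr$orientation == "cell_to_ctdna", ]
    expect_equal(nrow(tr), 1L)
    expect_equal(tr$breakpoint,
                 oracle_split(chim, w$g$cell$sequences, w$fr$core[fi]))
  }
})

test_that("insertion calls are confirmed by private SNVs and deduplicated", {
  w <- trans_world(seed = 41)
  g <- w$g; fr <- w$fr
  truth_keys <- variant_key(g$donor_snvs$contig, g$donor_snvs$pos,
                            g$donor_snvs$ref, g$donor_snvs$alt)
  cc <- simulate_coculture(g$cell, fr, insertion_rate = 0.7,
                           min_event_spacing = 1500, seed = 3)
  contigs <- assemble_or_ingest(cc$truth, "perfect", cell = g$cell,
                                fragments = fr, n_background = 2)
  tr <- detect_transitions(contigs, g$cell, fr)
  calls <- confirm_and_call(tr, truth_keys, fr)
  ins <- cc$truth$planted_insertions
  expect_gte(nrow(calls), nrow(ins) - 1L)
  expect_true(all(calls$status == "confirmed"))
  expect_true(all(calls$n_private_snvs >= 1L))
  # status <-> confirming keys invariant
  expect_true(all((calls$n_private_snvs > 0) ==
                  (lengths(calls$confirming_keys) > 0)))
  # loci match truth within a small tolerance
  for (i in seq_len(nrow(calls))) {
    t_i <- ins[ins$fragment_id == calls$fragment_id[i], ]
    expect_equal(calls$cell_contig[i], t_i$contig)
    expect_lte(abs(calls$cell_pos[i] - t_i$pos), 20)
    if (!is.na(calls$distance_to_origin[i]))
      expect_lte(abs(calls$distance_to_origin[i] - t_i$distance_to_origin), 20)
  }
  # a transition on a fragment with no private SNV in range -> unconfirmed
  none <- confirm_and_call(tr, character(0), fr)
  expect_true(all(none$status == "unconfirmed"))
  expect_true(all(none$n_private_snvs == 0L))
})

test_that("duplication calling is exact at the 10-bp boundary", {
  set.seed(5)
  ref <- genome_sequence("cell", c(chr1 = random_dna(2e4)), role = "cell")
  make_dup_contig <- function(s, m, flank = 400) {
    paste0(genome_subseq(ref, "chr1", s - flank, s + m),
           genome_subseq(ref, "chr1", s, s + m),
           genome_subseq(ref, "chr1", s + m, s + m + flank))
  }
  d12 <- detect_duplications(c(q = make_dup_contig(5000, 12)), ref)
  expect_equal(nrow(d12), 1L)
  expect_equal(d12$length, 12L)
  expect_true(d12$coculture_unique)
  expect_lte(abs(d12$ref_start - 5000), 5)
  d9 <- detect_duplications(c(q = make_dup_contig(9000, 9)), ref)
  expect_equal(nrow(d9), 0L)
  # min_len monotonicity: raising min_len never adds events
  d13 <- detect_duplications(c(q = make_dup_contig(5000, 12)), ref,
                             min_len = 13)
  expect_equal(nrow(d13), 0L)
  # contig identical to a reference window -> no event
  plain <- detect_duplications(
    c(q = genome_subseq(ref, "chr1", 3000, 4500)), ref)
  expect_equal(nrow(plain), 0L)
  # event also present in a cell-source contig is not coculture-unique
  both <- contig_set(c(cc1 = make_dup_contig(5000, 15),
                       base1 = make_dup_contig(5000, 15)),
                     source = c("coculture", "cell"))
  d <- detect_duplications(both, ref)
  expect_equal(nrow(d), 1L)
  expect_false(d$coculture_unique)
})

test_that("max_gap and soi filters behave monotonically", {
  w <- trans_world(seed = 51)
  chim <- paste0(genome_subseq(w$g$cell, "chr1", 3000, 3600),
                 strrep("N", 0), w$fr$core[3])
  t_small <- detect_transitions(c(q = chim), w$g$cell, w$fr, max_gap = 5)
  t_big <- detect_transitions(c(q = chim), w$g$cell, w$fr, max_gap = 40)
  expect_gte(nrow(t_big), nrow(t_small))
})

test_that("greedy assembly reconstructs an error-free template", {
  set.seed(77)
  template <- random_dna(5000)
  g <- genome_sequence("t", c(tpl = template), role = "cell")
  rs <- simulate_reads(g, coverage = 40, error_rate = 0, seed = 3)
  cs <- assemble_or_ingest(rs, mode = "greedy", k = 31)
  # longest unitig reconstructs the template (ends may lack read coverage)
  big <- cs$sequence[which.max(nchar(cs$sequence))]
  expect_true(grepl(big, template, fixed = TRUE) ||
                grepl(revcomp(big), template, fixed = TRUE))
  expect_gte(nchar(big), 0.98 * nchar(template))
  # deterministic
  cs2 <- assemble_or_ingest(rs, mode = "greedy", k = 31)
  expect_identical(cs$sequence, cs2$sequence)
})

test_that("structural gain summary counts are consistent", {
  empty <- count_structural_gain(
    structure(data.frame(status = character(0),
                         distance_to_origin = integer(0)),
              class = c("insertion_calls", "data.frame")),
    structure(data.frame(coculture_unique = logical(0)),
              class = c("duplication_events", "data.frame")))
  expect_equal(empty$n_insertions, 0L)
  expect_equal(empty$n_duplications, 0L)
  calls <- structure(data.frame(
    status = c("confirmed", "confirmed", "unconfirmed"),
    distance_to_origin = c(100L, NA, 20000L)),
    class = c("insertion_calls", "data.frame"))
  dups <- structure(data.frame(coculture_unique = c(TRUE, FALSE)),
                    class = c("duplication_events", "data.frame"))
  s <- count_structural_gain(calls, dups, proximity_window = 10000)
  expect_equal(s$n_insertions, 3L)
  expect_equal(s$n_confirmed, 2L)
  expect_lte(s$n_confirmed, s$n_insertions)
  expect_equal(s$n_proximal, 1L)
  expect_equal(s$n_duplications, 2L)
  expect_equal(s$n_coculture_unique_duplications, 1L)
})
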