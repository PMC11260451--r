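test_that("repeat scanner finds exact copies on both strands and nothing in
           random sequence", {
  lib <- simulate_te_library()
  # exact copy: full-length hit at identity 1
  el <- lib[lib$name == "AluSp", ]
  hits <- scan_repeats(c(s1 = el$sequence), lib)
  expect_equal(nrow(hits), 1L)
  expect_identical(hits$te_name, "AluSp")
  expect_equal(hits$start, 0L)
  expect_equal(hits$end, nchar(el$sequence))
  expect_equal(hits$pident, 1)
  expect_identical(hits$strand, "+")
  # embedded reverse-complemented copy: same element, minus strand
  set.seed(2)
  subj <- paste0(random_dna(200), revcomp(el$sequence), random_dna(150))
  rc_hits <- scan_repeats(c(s2 = subj), lib)
  rc_hits <- rc_hits[rc_hits$te_name == "AluSp", ]
  expect_equal(nrow(rc_hits), 1L)
  expect_identical(rc_hits$strand, "-")
  expect_equal(rc_hits$start, 200L)
  # random sequence: no hit, confirmed by the independent DP aligner
  set.seed(3)
  rand <- random_dna(600)
  expect_equal(nrow(scan_repeats(c(r = rand), lib)), 0L)
  best <- max(vapply(lib$sequence[1:3], function(te)
    oracle_sw_score(substr(rand, 1, 300), te), numeric(1)))
  expect_lt(best, 40)
  # hit intervals never exceed subject bounds
  all_hits <- scan_repeats(c(s1 = el$sequence, s2 = subj), lib)
  expect_true(all(all_hits$start >= 0))
  expect_true(all(all_hits$end <= nchar(c(s1 = el$sequence, s2 = subj)[
    all_hits$subject_id])))
})

test_that("scanner scoring agrees with the independent DP aligner", {
  set.seed(11)
  for (i in 1:4) {
    a <- random_dna(90)
    b <- paste0(random_dna(30), substr(a, 20, 75), random_dna(25))
    expect_equal(ctdnaIntegrate:::local_align_score(a, b),
                 oracle_sw_score(a, b))
  }
})

fake_transition <- function(contig_id = "c1", breakpoint = 500L,
                            orientation = "cell_to_ctdna",
                            adaptor_adjacent = TRUE) {
  structure(data.frame(
    contig_id = contig_id, breakpoint = breakpoint, orientation = orientation,
    cell_contig = "chr1", cell_start = 0L, cell_end = breakpoint,
    cell_strand = "+", fragment_id = "fragX", frag_start = 0L,
    frag_end = 500L, frag_strand = "+", junction_gap = 0L,
    adaptor_adjacent = adaptor_adjacent, stringsAsFactors = FALSE),
    class = c("transition_points", "data.frame"))
}

fake_hits <- function(starts, width = 80L) {
  structure(data.frame(
    subject_id = "c1", te_name = paste0("te", seq_along(starts)),
    te_class = "SINE", start = as.integer(starts),
    end = as.integer(starts + width), strand = "+", score = 100,
    pident = 1, stringsAsFactors = FALSE),
    class = c("repeat_annotations", "data.frame"))
}

test_that("100-nt transition window keeps hits at 50 and 100, drops 150", {
  tr <- fake_transition(breakpoint = 500L)
  hits <- fake_hits(c(550, 600, 650))   # edge distances 50, 100, 150
  kept <- filter_transition_proximal(hits, tr, window = 100,
                                     require_adaptor = TRUE)
  expect_setequal(kept$breakpoint_distance, c(50L, 100L))
  expect_equal(nrow(kept), 2L)
  # adaptor-absent transitions contribute nothing when required
  tr_noad <- fake_transition(adaptor_adjacent = FALSE)
  expect_equal(nrow(filter_transition_proximal(hits, tr_noad, window = 100,
                                               require_adaptor = TRUE)), 0L)
  expect_equal(nrow(filter_transition_proximal(hits, tr_noad, window = 100,
                                               require_adaptor = FALSE)), 2L)
  # hits on the cell side of the junction are never selected
  cell_side <- fake_hits(c(100))
  expect_equal(nrow(filter_transition_proximal(cell_side, tr, window = 100)),
               0L)
  # window monotonicity: a larger window keeps a superset
  k50 <- filter_transition_proximal(hits, tr, window = 50)
  k200 <- filter_transition_proximal(hits, tr, window = 200)
  expect_true(all(paste(k50$start) %in% paste(k200$start)))
})

test_that("chi-square enrichment matches the closed form and handles
           degenerate tables", {
  r0 <- enrichment_test(c(10, 90), c(10, 90))
  expect_equal(r0$chi_square, 0)
  expect_equal(r0$p_value, 1)
  r1 <- enrichment_test(c(30, 70), c(10, 90))
  expect_equal(r1$chi_square, oracle_chisq(30, 70, 10, 90), tolerance = 1e-12)
  expect_equal(r1$df, 1L)
  expect_gt(r1$odds_ratio, 1)
  # logical-vector interface
  r2 <- enrichment_test(rep(c(TRUE, FALSE), c(30, 70)),
                        rep(c(TRUE, FALSE), c(10, 90)))
  expect_equal(r2$chi_square, r1$chi_square)
  # zero margin is an error
  expect_error(enrichment_test(c(0, 100), c(0, 50)), "margin")
  # zero cell: Haldane-corrected odds ratio is finite
  r3 <- suppressWarnings(enrichment_test(c(12, 8), c(0, 20)))
  expect_true(is.finite(r3$odds_ratio))
  # low expected counts: warning plus exact p alongside
  expect_warning(r4 <- enrichment_test(c(3, 5), c(1, 7)), "expected")
  expect_false(is.na(r4$fisher_p))
  # Yates correction reduces the statistic
  r5 <- enrichment_test(c(30, 70), c(10, 90), continuity_correction = TRUE)
  expect_lt(r5$chi_square, r1$chi_square)
})

test_that("tissue-specific element selection is exclusive and ranked", {
  expect_identical(tissue_specific_elements(c("AluSp", "AluSp", "AluSp"),
                                            character(0))$te_name, "AluSp")
  r <- tissue_specific_elements(c(rep("AluSp", 3), "L2a"), rep("L2a", 2))
  expect_identical(r$te_name, "AluSp")
  # ranking by count, ties by name
  r2 <- tissue_specific_elements(c(rep("B", 2), rep("A", 2), "C"),
                                 character(0))
  expect_identical(r2$te_name, c("A", "B", "C"))
  # exclusivity invariant over random multisets
  set.seed(8)
  for (i in 1:20) {
    m <- sample(LETTERS[1:6], 12, TRUE)
    mm <- sample(LETTERS[1:6], 12, TRUE)
    expect_length(intersect(tissue_specific_elements(m, mm)$te_name,
                            unique(mm)), 0)
  }
})

test_that("proximity statistics cover the limiting cases", {
  calls0 <- structure(data.frame(
    fragment_id = c("f1", "f2"), distance_to_origin = c(0L, 0L),
    status = "confirmed"), class = c("insertion_calls", "data.frame"))
  frs <- data.frame(fragment_id = c("f1", "f2"),
                    origin_contig = c("chr1", "chr2"))
  p <- proximity_stats(calls0, frs, window = 10000)
  expect_equal(p$proximal_fraction, 1.0)
  callsNA <- calls0
  callsNA$distance_to_origin <- NA_integer_
  p2 <- proximity_stats(callsNA, frs, window = 10000)
  expect_equal(p2$proximal_fraction, 0.0)
  expect_equal(p2$n_inter_contig, 2L)
})
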