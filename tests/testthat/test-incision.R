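# Incision records, contribution decomposition, coupling regression,
# shuffle control, HYV profile and composition/information matrices.

mk_records <- function(d5, d3) {
  data.frame(read_id = sprintf("r%04d", seq_along(d5)),
             kind = "single_CT", d5 = d5, d3 = d3, L = d5 + d3 - 1,
             contig = "chrT", lesion_pos = seq_along(d5) * 10L,
             strand = "+", stringsAsFactors = FALSE)
}

test_that("cut-site distances follow the lesion-inclusive convention", {
  reads <- data.frame(read_id = c("s", "t"), contig = "chrT",
                      start = c(100L, 100L), end = c(125L, 125L),
                      strand = c("+", "-"),
                      seq = strrep("A", 26), length = 26L)
  mm <- data.frame(read_id = c("s", "t"), offset5 = c(20L, 20L),
                   rel3 = c(-7L, -7L), ref = c("C", "CC"),
                   alt = c("T", "TT"), context = "NNN",
                   is_tandem = c(FALSE, TRUE))
  rs <- incision_records(reads, mm["1", ], kind = "single_CT")
  expect_equal(rs$d5, 20)
  expect_equal(rs$d3, 7)
  rt <- incision_records(reads, mm["2", ], kind = "tandem_CCTT")
  expect_equal(rt$d5, 20.5)
  expect_equal(rt$d3, 6.5)
  expect_true(all(c(rs$d5 + rs$d3, rt$d5 + rt$d3) == 27))
  # genomic lesion anchor: plus-strand single at start + offset - 1;
  # minus-strand tandem anchored at the pair's 3'-in-read base
  expect_identical(rs$lesion_pos, 100L + 20L - 1L)
  expect_identical(rt$lesion_pos, 125L - 21L + 1L)
})

test_that("contribution decomposition spans its two extremes", {
  # fixed 3' distance: all length variability comes from the 5' side
  cfg <- sim_config(genome_length = 3e4, n_fragments = 4000,
                    coupling = 0, d3_distribution = c("7" = 1),
                    lesion_dinucleotide_mix = c(TC = 1),
                    p_deaminate = 1, seq_error_rate = 0,
                    p_misprime = 0, seed = 21)
  genome <- generate_genome(cfg)
  fr <- generate_fragments(genome, cfg)
  rec <- incision_records(fr$reads, mismatch_table(fr$reads, genome),
                          kind = "single_CT")
  ct <- contribution_decomposition(rec)
  expect_equal(ct$percent_3prime, 0)
  expect_equal(ct$percent_5prime, 100)

  # symmetric generator: both sides vary identically -> ~50/50
  cfgs <- sim_config(genome_length = 3e4, n_fragments = 20000,
                     coupling = 0,
                     d3_distribution = setNames(rep(0.2, 5),
                                                as.character(5:9)),
                     d5_base_distribution = setNames(rep(0.2, 5),
                                                     as.character(15:19)),
                     lesion_dinucleotide_mix = c(TC = 1),
                     p_deaminate = 1, seq_error_rate = 0,
                     p_misprime = 0, seed = 22)
  gs <- generate_genome(cfgs)
  frs <- generate_fragments(gs, cfgs)
  recs <- incision_records(frs$reads, mismatch_table(frs$reads, gs),
                           kind = "single_CT")
  cts <- contribution_decomposition(recs)
  expect_lt(abs(cts$percent_5prime - 50), 3)

  # a single read length cannot be decomposed
  one <- contribution_decomposition(mk_records(rep(20, 5), rep(7, 5)))
  expect_true(is.na(one$percent_5prime))
})

test_that("coupling regression and its exact identities hold", {
  # full compensation: d3 = C - d5
  full <- mk_records(15:24, 30 - (15:24))
  # the fit is exact by construction; lm warns about the perfect fit
  cf <- suppressWarnings(coupling_regression(full, "d3_vs_d5"))
  expect_equal(cf$slope, -1)
  expect_equal(cf$coupling_percent, 100)

  # independence: slope ~ 0, length slope ~ 1
  set.seed(31)
  ind <- mk_records(sample(15:23, 5000, TRUE), sample(5:9, 5000, TRUE))
  ci <- coupling_regression(ind, "d3_vs_d5")
  expect_lt(abs(ci$coupling_percent), 5)
  cl <- coupling_regression(ind, "read_length_vs_d5")
  expect_lt(abs(cl$slope - 1), 0.05)

  # slope(L ~ d5) = 1 + slope(d3 ~ d5), exactly, for any records
  for (s in 1:5) {
    set.seed(s)
    r <- mk_records(sample(15:23, 400, TRUE), sample(5:9, 400, TRUE))
    a <- coupling_regression(r, "read_length_vs_d5")$slope
    b <- coupling_regression(r, "d3_vs_d5")$slope
    expect_equal(a, 1 + b, tolerance = 1e-12)
  }

  expect_error(coupling_regression(mk_records(rep(20, 10), 5:14),
                                   "d3_vs_d5"), "zero variance")
  expect_error(coupling_regression(mk_records(1:2, 2:1)), "at least 3")
})

test_that("shuffle control preserves marginals and breaks coupling", {
  rec <- mk_records(sample(15:23, 1000, TRUE), sample(5:9, 1000, TRUE))
  sh <- shuffle_control(rec, seed = 41)
  expect_identical(sort(sh$d5), sort(rec$d5))
  expect_identical(sh$d3, rec$d3)
  expect_true(all(sh$L == sh$d5 + sh$d3 - 1))

  same <- mk_records(rep(19, 50), sample(5:9, 50, TRUE))
  expect_identical(shuffle_control(same, seed = 42), same)
})

test_that("HYV frequencies respond to the incision-site context", {
  # every read preceded by "AT" and starting with "A": HYV at the cut
  body <- strrep("G", 24)
  unit <- paste0("AT", "A", body, "GGGGG")   # G-rich elsewhere: no HYV
  gseq <- paste0(strrep("G", 30), strrep(unit, 30), strrep("G", 30))
  genome <- literal_genome(gseq)
  starts <- 30 + (seq_len(30) - 1L) * nchar(unit) + 3L
  reads <- data.frame(read_id = sprintf("h%02d", 1:30), contig = "chrT",
                      start = starts, end = starts + 24L, strand = "+",
                      seq = paste0("A", body), length = 25L)
  prof <- hyv_profile(reads, genome, flank = 8)
  expect_equal(prof$frequency[prof$position == 0], 1.0)

  # preceded by GG: impossible (H excludes G, Y excludes G)
  reads_gg <- data.frame(read_id = "g1", contig = "chrT", start = 31L,
                         end = 55L, strand = "+",
                         seq = substr(gseq, 31, 55), length = 25L)
  prof_gg <- hyv_profile(reads_gg, genome, flank = 4)
  expect_equal(prof_gg$frequency[prof_gg$position == 0], 0)

  # i.i.d. gc = 0.5 background: P(H) P(Y) P(V) = 0.75 * 0.5 * 0.75
  cfg <- small_cfg(n_fragments = 1500, lesion_dinucleotide_mix = c(TT = 1))
  g <- generate_genome(cfg)
  fr <- generate_fragments(g, cfg)
  pr <- hyv_profile(fr$reads, g, flank = 10)
  flankpos <- pr$position < -2          # outside the read and lesion zone
  expect_lt(abs(mean(pr$frequency[flankpos]) - 0.28125), 0.03)
})

test_that("information content is relative entropy against GC background", {
  # four reads at four loci; per-position base mixes are designed
  seqs <- c("ACGTACGTAC", "ACTTACGTAC", "ACGTACGAAC", "ACTTACGAAC")
  gseq <- paste0("CCCC", paste(seqs, collapse = "CCCC"), "CCCC")
  genome <- literal_genome(gseq)
  starts <- 5L + (seq_len(4) - 1L) * 14L
  reads <- data.frame(read_id = paste0("c", 1:4), contig = "chrT",
                      start = starts, end = starts + 9L, strand = "+",
                      seq = seqs, length = 10L)
  cm <- composition_matrix(reads, genome, flank = 2, gc = 0.5)
  # first read base is A at all four loci: 2 bits on a uniform background
  expect_equal(cm$information[cm$position == 1], 2)
  # read position 3 is G,T,G,T across loci: f = (0, 0, 1/2, 1/2) -> 1 bit
  p3 <- cm[cm$position == 3, c("A", "C", "G", "T")]
  expect_equal(unname(unlist(p3)), c(0, 0, 0.5, 0.5))
  expect_equal(cm$information[cm$position == 3], 1)
})
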