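# Read-level filters: rule order and conservation, dipyrimidine
# position scores, length-range derivation, and the TGG mispriming
# filter with strand-aware flanks.

fake_aligned <- function(seqs, n_mismatches = 0L, has_indel = FALSE,
                         has_N = NULL) {
  if (is.null(has_N)) has_N <- grepl("N", seqs, fixed = TRUE)
  data.frame(read_id = sprintf("r%03d", seq_along(seqs)),
             contig = "chrT", start = 1L, end = nchar(seqs),
             strand = "+", seq = seqs, length = nchar(seqs),
             n_mismatches = n_mismatches, has_indel = has_indel,
             has_N = has_N, stringsAsFactors = FALSE)
}

test_that("basic filters apply in order and conserve counts", {
  reads <- fake_aligned(
    c(strrep("A", 25),            # kept
      strrep("A", 21),            # too short for the human range
      strrep("A", 31),            # too long
      paste0(strrep("A", 24), "N"),  # contains N
      strrep("A", 26),            # two mismatches
      strrep("A", 27)),           # indel (first failing rule wins)
    n_mismatches = c(0L, 0L, 0L, 0L, 2L, 3L),
    has_indel = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  out <- basic_filters(reads, c(22L, 30L))
  rep <- setNames(out$report$count, out$report$rule)
  expect_identical(rep[["indel"]], 1L)
  expect_identical(rep[["multi_mismatch"]], 1L)
  expect_identical(rep[["N"]], 1L)
  expect_identical(rep[["length_range"]], 2L)
  expect_identical(rep[["retained"]], 1L)
  expect_identical(sum(rep[c("indel", "multi_mismatch", "N",
                             "length_range", "retained")]),
                   rep[["input"]])
  expect_identical(out$kept$read_id, "r001")

  empty <- basic_filters(NULL, c(22L, 30L))
  expect_identical(empty$report$count[empty$report$rule == "input"], 0L)
})

test_that("dipyrimidine profile indexes pairs at their 3' base", {
  # all reads end in TT: frequency 1.0 at position -1
  prof <- dipyrimidine_profile(rep(paste0(strrep("G", 20), "TT"), 5))
  expect_equal(prof$frequency[prof$position == -1], 1.0)
  expect_equal(sum(prof$frequency), 1.0)

  # all-purine reads: 0 everywhere
  prof0 <- dipyrimidine_profile(rep(strrep("GA", 11), 4))
  expect_true(all(prof0$frequency == 0))

  # i.i.d. 50% pyrimidine: expected 0.25 per position
  set.seed(3)
  seqs <- vapply(1:4000, function(i) {
    paste(sample(c("A", "C", "G", "T"), 24, replace = TRUE), collapse = "")
  }, character(1))
  prof5 <- dipyrimidine_profile(seqs)
  expect_lt(max(abs(prof5$frequency - 0.25)),
            5 * sqrt(0.25 * 0.75 / 4000))
})

test_that("length range derivation picks the right run", {
  # single spike
  r1 <- fake_aligned(rep(strrep("T", 26), 50))
  expect_identical(as.integer(derive_length_range(r1)), c(26L, 26L))

  # bimodal: short run has the global maximum, but the expected length
  # sits in the second run
  seqs <- c(rep(strrep("T", 20), 100), rep(strrep("T", 21), 90),
            rep(strrep("GAGA", 6), 60),            # L=24, score 0
            rep(strrep("T", 26), 40), rep(strrep("T", 27), 35))
  r2 <- fake_aligned(seqs)
  expect_identical(as.integer(derive_length_range(r2, expected_length = 26)),
                   c(26L, 27L))
  # without the expectation, the longest run wins; equal spans break
  # toward longer lengths
  expect_identical(as.integer(derive_length_range(r2)), c(26L, 27L))

  expect_error(derive_length_range(NULL), "no reads")
})

test_that("TGG filter removes exactly reads with a TGG 3' flank", {
  #            read (+)              flank
  gseq <- paste0(strrep("A", 30), "CACACATTACCATCTACAATCTCACA", "TGG",
                 strrep("A", 10), "CCA", "CACACATTACCATCTACAATCTCACA",
                 strrep("A", 30))
  genome <- literal_genome(gseq)
  # r_plus: plus-strand read whose 3' flank is TGG -> removed
  # r_tga: same read shifted so its flank is TGA-like -> kept
  # r_minus: minus-strand read whose upstream plus context is CCA
  #          (= TGG in read orientation) -> removed
  s2 <- 30 + 26 + 3 + 10 + 3 + 1
  reads <- data.frame(
    read_id = c("r_plus", "r_tga", "r_minus"),
    contig = "chrT",
    start = c(31L, 30L, s2), end = c(56L, 55L, s2 + 25L),
    strand = c("+", "+", "-"),
    seq = c(substr(gseq, 31, 56), substr(gseq, 30, 55),
            revcomp_test(substr(gseq, s2, s2 + 25))),
    length = 26L)
  out <- tgg_filter(reads, genome)
  expect_setequal(out$removed$read_id, c("r_plus", "r_minus"))
  expect_identical(out$kept$read_id, "r_tga")
})

test_that("flank motif frequencies match the i.i.d. expectation", {
  cfg <- small_cfg(n_fragments = 1200, gc_content = 0.5,
                   lesion_dinucleotide_mix = c(TT = 1))
  genome <- generate_genome(cfg)
  fr <- generate_fragments(genome, cfg)
  prof <- flank_motif_profile(fr$reads, genome, motif = "TGG", flank = 6)
  # genomic flank positions (past either cut site) carry no lesion or
  # fragment-composition bias: frequency ~ P(T) P(G)^2 = 0.25^3
  fl <- prof[prof$position > 0 | prof$position < -max(prof$read_length), ]
  p <- 0.25^3
  agg <- sum(fl$frequency * fl$n_reads) / sum(fl$n_reads)
  expect_lt(abs(agg - p), 4 * sqrt(p * (1 - p) / sum(fl$n_reads)))

  # the two-base "TG" mode is supported
  prof2 <- flank_motif_profile(fr$reads, genome, motif = "TG", flank = 3)
  expect_true(all(prof2$frequency >= 0 & prof2$frequency <= 1))
})

test_that("truncated reads show the motif right past the 3' cut site", {
  fx <- engineered_tgg_fixture(n_frags = 60)
  cfgm <- sim_config(p_misprime = 1, length_range = c(22L, 30L))
  set.seed(2)
  mp <- apply_mispriming(fx$reads, cfgm)
  prof <- flank_motif_profile(mp$reads, fx$genome, motif = "TGG",
                              flank = 4)
  trunc_len <- unique(mp$reads$length[mp$truncated])
  at1 <- prof[prof$read_length == trunc_len & prof$position == 1, ]
  expect_equal(at1$frequency, 1.0)
})
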