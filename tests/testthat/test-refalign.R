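# Index queries, unique-placement alignment, mismatch extraction and
# strand-aware context, checked against scalar brute-force oracles.

test_that("index locates unique queries on both strands", {
  cfg <- small_cfg()
  genome <- generate_genome(cfg)
  idx <- build_index(genome)
  q <- as.character(Biostrings::subseq(genome[[1]], 501, 520))
  hit <- locate_query(idx, q)
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$start, 501L)
  expect_identical(hit$strand, "+")

  rcq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(q)))
  hit2 <- locate_query(idx, rcq)
  expect_identical(nrow(hit2), 1L)
  expect_identical(hit2$start, 501L)
  expect_identical(hit2$strand, "-")

  expect_identical(count_query(idx, strrep("ACGT", 5)), 0L)
  expect_error(locate_query(idx, "ACGTACG"), ">= 10")
})

test_that("reads align uniquely with mismatches matching brute force", {
  cfg <- small_cfg()
  genome <- generate_genome(cfg)
  gseq <- as.character(genome[[1]])
  idx <- build_index(genome)

  read <- substr(gseq, 1001, 1025)
  a0 <- align_read(read, idx, id = "r0")
  expect_true(a0$aligned)
  expect_identical(a0$read$start, 1001L)
  expect_identical(a0$read$n_mismatches, 0L)

  mut <- read
  old <- substr(mut, 12, 12)
  substr(mut, 12, 12) <- setdiff(c("A", "C", "G", "T"), old)[1]
  a1 <- align_read(mut, idx, id = "r1")
  expect_true(a1$aligned)
  expect_identical(a1$read$start, 1001L)
  expect_identical(a1$read$n_mismatches, 1L)
  orc <- oracle_mismatches(mut, gseq, 1001, 1025, "+")
  expect_equal(a1$mismatches$offset5, orc$offset5)
  expect_equal(a1$mismatches$ref, orc$ref)
  expect_equal(a1$mismatches$alt, orc$alt)

  # a duplicated locus makes the read ambiguous
  dup <- paste0(gseq, substr(gseq, 2001, 2030))
  idx2 <- build_index(literal_genome(dup))
  a2 <- align_read(substr(gseq, 2001, 2025), idx2)
  expect_false(a2$aligned)
  expect_identical(a2$reason, "ambiguous")
})

test_that("internal aligner recovers the simulator's true loci", {
  cfg <- small_cfg(n_fragments = 150, p_deaminate = 0.6)
  genome <- generate_genome(cfg)
  fr <- generate_fragments(genome, cfg)
  idx <- build_index(genome)
  aln <- align_reads(fr$reads$seq, idx, ids = fr$reads$read_id)
  tr <- fr$truth[match(aln$reads$read_id, fr$truth$read_id), ]
  expect_gt(nrow(aln$reads) / nrow(fr$reads), 0.95)
  expect_true(all(aln$reads$start == tr$frag_start))
  expect_true(all(aln$reads$strand == tr$strand))
})

test_that("mismatch extraction is identical to the brute-force oracle", {
  cfg <- small_cfg(n_fragments = 1000, p_deaminate = 0.7,
                   seq_error_rate = 0.01,
                   lesion_dinucleotide_mix = c(TT = 0.4, CT = 0.2,
                                               TC = 0.2, CC = 0.2))
  genome <- generate_genome(cfg)
  gseq <- as.character(genome[[1]])
  fr <- generate_fragments(genome, cfg)
  mm <- mismatch_table(fr$reads, genome)
  by_read <- split(mm, mm$read_id)
  for (i in seq_len(nrow(fr$reads))) {
    r <- fr$reads[i, ]
    orc <- oracle_mismatches(r$seq, gseq, r$start, r$end, r$strand)
    got <- by_read[[r$read_id]]
    if (is.null(orc)) {
      expect_true(is.null(got))
    } else {
      expect_false(is.null(got))
      expect_equal(got$offset5, orc$offset5)
      expect_equal(got$rel3, orc$rel3)
      expect_equal(got$ref, orc$ref)
      expect_equal(got$alt, orc$alt)
      expect_equal(got$context, orc$context)
    }
  }
})

test_that("flanked context is strand aware and N-padded at edges", {
  gseq <- paste0("GGA", "ACGTACGTACGTACGTACGTACGTA", "TGC", "TTTT")
  genome <- literal_genome(gseq)
  reads <- data.frame(
    read_id = c("p", "m", "edge"),
    contig = "chrT",
    start = c(4L, 4L, 1L), end = c(28L, 28L, 12L),
    strand = c("+", "-", "+"),
    seq = c(substr(gseq, 4, 28),
            revcomp_test(substr(gseq, 4, 28)),
            substr(gseq, 1, 12)),
    length = c(25L, 25L, 12L))
  ctx <- extract_context(reads, genome, flank = 3)
  expect_identical(ctx[1], paste0("GGA", substr(gseq, 4, 28), "TGC"))
  # minus strand: last 3 bases are past the read's 3' end in read
  # orientation, i.e. the reverse complement of the plus-strand upstream
  expect_identical(ctx[2], revcomp_test(paste0("GGA", substr(gseq, 4, 28),
                                               "TGC")))
  expect_identical(substr(ctx[3], 1, 3), "NNN")
})

test_that("SAM round trip preserves placements and read orientation", {
  cfg <- small_cfg(n_fragments = 60, p_deaminate = 0.8)
  genome <- generate_genome(cfg)
  fr <- generate_fragments(genome, cfg)
  path <- tempfile(fileext = ".sam")
  write_sam(fr$reads, genome, path)
  imp <- import_sam(path, genome)
  expect_identical(imp$reads$start, fr$reads$start)
  expect_identical(imp$reads$strand, fr$reads$strand)
  expect_identical(imp$reads$seq, fr$reads$seq)
  # mismatch offsets count from the read's 5' end, matching the
  # internal aligner on the same reads
  mm_direct <- mismatch_table(fr$reads, genome)
  expect_equal(imp$mismatches$offset5, mm_direct$offset5)

  # an independent reader agrees with what we wrote
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  sc <- Rsamtools::scanBam(bam)[[1]]
  ord <- match(fr$reads$read_id, sc$qname)
  expect_identical(as.integer(sc$pos[ord]), fr$reads$start)
  expect_identical(as.character(sc$strand[ord]),
                   fr$reads$strand)
})

test_that("SAM records with indel CIGARs are flagged", {
  genome <- literal_genome(strrep("ACGTT", 20))
  sam <- c("@HD\tVN:1.6",
           "@SQ\tSN:chrT\tLN:100",
           paste0("r1\t0\tchrT\t5\t255\t25M\t*\t0\t0\t",
                  strrep("A", 25), "\tIIIIIIIIIIIIIIIIIIIIIIIII"),
           paste0("r2\t0\tchrT\t5\t255\t10M2I13M\t*\t0\t0\t",
                  strrep("A", 25), "\tIIIIIIIIIIIIIIIIIIIIIIIII"))
  path <- tempfile(fileext = ".sam")
  writeLines(sam, path)
  imp <- import_sam(path, genome)
  expect_identical(imp$reads$start, c(5L, 5L))
  expect_identical(imp$reads$end[1], 29L)   # 1-based closed from POS + 25M
  expect_identical(imp$reads$has_indel, c(FALSE, TRUE))
  expect_true(is.na(imp$reads$n_mismatches[2]))
})
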