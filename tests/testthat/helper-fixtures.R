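# Fixtures and independent oracles shared across the suite.  All data
# are generated in code; nothing is read from disk.

# a small, fast default configuration for unit tests
small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(genome_length = 2e4, n_fragments = 500,
                   seq_error_rate = 0, p_misprime = 0, seed = 11)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# build a DNAStringSet genome from a literal string
literal_genome <- function(seq, name = "chrT") {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- name
  g
}

# Brute-force mismatch oracle: scalar, per-base comparison of one read
# with the reference at its placement, entirely independent of the
# package's byte-matrix path.  Returns offsets (1-based from 5' end),
# rel3, ref, alt and context, like mismatch_table().
oracle_mismatches <- function(read_seq, contig_seq, start, end, strand) {
  ref <- substr(contig_seq, start, end)
  if (strand == "-") {
    comp <- chartr("ACGT", "TGCA", ref)
    ref <- paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }
  rb <- strsplit(read_seq, "")[[1]]
  fb <- strsplit(ref, "")[[1]]
  L <- length(rb)
  out <- NULL
  for (j in seq_len(L)) {
    if (rb[j] != fb[j]) {
      # context from the genome, strand-aware, N-padded
      if (strand == "+") {
        lo <- start + j - 2L; hi <- start + j
        tri <- substr(contig_seq, max(lo, 1L), min(hi, nchar(contig_seq)))
        if (lo < 1L) tri <- paste0("N", tri)
        if (hi > nchar(contig_seq)) tri <- paste0(tri, "N")
      } else {
        hi <- end - j + 2L; lo <- end - j
        tri <- substr(contig_seq, max(lo, 1L), min(hi, nchar(contig_seq)))
        if (hi > nchar(contig_seq)) tri <- paste0("N", tri)
        if (lo < 1L) tri <- paste0(tri, "N")
        comp <- chartr("ACGT", "TGCA", tri)
        tri <- paste(rev(strsplit(comp, "")[[1]]), collapse = "")
      }
      out <- rbind(out, data.frame(
        offset5 = j, rel3 = j - L - 1L, ref = fb[j], alt = rb[j],
        context = tri, stringsAsFactors = FALSE))
    }
  }
  out
}

# reverse complement, written independently of the package's helper
revcomp_test <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Brute-force occurrence scan of a query over one contig, both strands,
# tolerating up to max_mm substitutions; byte-vector Hamming scan.
oracle_scan <- function(contig_seq, query, max_mm = 0) {
  g <- charToRaw(contig_seq)
  scan_one <- function(r) {
    L <- length(r); n <- length(g)
    if (n < L) return(integer(0))
    starts <- seq_len(n - L + 1L)
    mm <- integer(length(starts))
    for (j in seq_len(L)) mm <- mm + (g[starts + j - 1L] != r[j])
    data.frame(start = starts[mm <= max_mm], n_mm = mm[mm <= max_mm])
  }
  plus <- scan_one(charToRaw(query))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(query)))
  minus <- scan_one(charToRaw(rc))
  rbind(
    if (nrow(plus)) cbind(plus, strand = "+") else NULL,
    if (nrow(minus)) cbind(minus, strand = "-") else NULL)
}

# Engineered mispriming fixture: a G-free random genome with plus-strand
# fragment slots; an internal TGG is written into a chosen subset, so a
# TGG 3' flank can only ever arise from truncation at those sites.
engineered_tgg_fixture <- function(n_frags = 40, frag_len = 28,
                                   lmin = 22, seed = 5) {
  set.seed(seed)
  gap <- 40L
  glen <- n_frags * (frag_len + gap) + gap
  gseq <- paste(sample(c("A", "C", "T"), glen, replace = TRUE,
                       prob = c(0.4, 0.3, 0.3)), collapse = "")
  starts <- gap + (seq_len(n_frags) - 1L) * (frag_len + gap) + 1L
  with_tgg <- seq_len(n_frags) %% 2L == 0L
  t_idx <- lmin + 2L                       # TGG start inside the read
  for (i in which(with_tgg)) {
    p <- starts[i] + t_idx - 1L
    substr(gseq, p, p + 2L) <- "TGG"
  }
  genome <- literal_genome(gseq, "chrE")
  reads <- data.frame(
    read_id = sprintf("efrag%03d", seq_len(n_frags)),
    contig = "chrE", start = starts, end = starts + frag_len - 1L,
    strand = "+",
    seq = substring(gseq, starts, starts + frag_len - 1L),
    length = frag_len, stringsAsFactors = FALSE)
  list(genome = genome, reads = reads, with_tgg = with_tgg,
       lmin = lmin)
}

# cache of large tandem-record fixtures used by several tests
.tandem_cache <- new.env(parent = emptyenv())

tandem_records_fixture <- function(coupling, n = 1e5, seed = 101) {
  key <- sprintf("c%s_n%d_s%d", coupling, n, seed)
  if (!is.null(.tandem_cache[[key]])) return(.tandem_cache[[key]])
  cfg <- sim_config(genome_length = 2e5, n_fragments = n,
                    coupling = coupling,
                    lesion_dinucleotide_mix = c(CC = 1),
                    p_deaminate = 1, p_tandem = 1,
                    seq_error_rate = 0, p_misprime = 0, seed = seed)
  genome <- generate_genome(cfg)
  fr <- generate_fragments(genome, cfg)
  mm <- collapse_tandem(mismatch_table(fr$reads, genome))
  rec <- incision_records(fr$reads, mm, kind = "tandem_CCTT")
  .tandem_cache[[key]] <- list(records = rec, truth = fr$truth)
  .tandem_cache[[key]]
}
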