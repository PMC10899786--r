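# Synthetic XR-seq fragment simulator with full ground truth.
#
# The generator emulates the data-generating process the analysis assumes:
# an excised NER fragment whose lesion (a dipyrimidine) sits a short,
# sampled distance from the 3' end; a 5' cut-site distance drawn from its
# own distribution; partial coupling by which the 3' incision compensates
# deviations of the 5' draw; per-lesion cytosine deamination (single C>T
# or tandem CC>TT); sparse background sequencing errors; and mispriming
# truncation at adapter-homologous TGG sites inside the fragment.

#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by
#' [generate_genome()], [generate_fragments()] and [apply_mispriming()].
#'
#' Cut-site distances use the lesion-inclusive convention: `d5` is the
#' number of bases from the 5' read end to the lesion anchor inclusive,
#' `d3` from the anchor to the 3' end inclusive, so the fragment length is
#' `L = d5 + d3 - 1`.  The simulator anchors the sampled distances at the
#' 3' base of the lesion dinucleotide; measured distances for tandem
#' CC>TT calls refer to the half-base between the two cytosines and are
#' therefore half-integers obeying `d5 + d3 = L + 1`.
#'
#' Coupling: after drawing `d5`, the 3' distance is set to
#' `d3_base - coupling * (d5 - mean(d5))`, stochastically rounded (so the
#' configured coupling is exactly the slope of `E[d3 | d5]`) and clipped
#' to >= 1.  `coupling = 0` gives independent incisions; `coupling = 1`
#' full compensation (constant fragment length when no rounding is
#' needed).
#'
#' @param genome_length contig length in bp (>= 1000).
#' @param gc_content GC fraction of the i.i.d. genome, in `[0, 1]`.
#' @param n_fragments number of fragments to simulate.
#' @param length_range integer `c(Lmin, Lmax)`, inclusive; `Lmin` also
#'   bounds how short a mispriming truncation may leave a read.
#' @param d3_distribution named numeric vector: probabilities over 3'
#'   cut-site distances (names are the distances, in nt).
#' @param d5_base_distribution named numeric vector: probabilities over
#'   5' cut-site distances before any boundary modulation.
#' @param coupling fraction in `[0, 1]`: each +1 nt of 5' distance above
#'   its mean shifts the 3' distance by `-coupling` nt on average.
#' @param p_deaminate per-lesion probability that a lesion cytosine
#'   deaminates to T (for CC lesions: probability of a single deamination
#'   given no tandem event).
#' @param p_tandem probability that both cytosines of a CC lesion
#'   deaminate (tandem CC>TT).
#' @param seq_error_rate per-base substitution probability outside the
#'   lesion dinucleotide.
#' @param p_misprime probability that a fragment is subject to mispriming
#'   rescue, truncating it at its 3'-most eligible internal TGG.
#' @param lesion_dinucleotide_mix named numeric vector of frequencies over
#'   `TT`, `CT`, `TC`, `CC`.
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_fragments = 100, seed = 1)
#' sim <- simulate_xrseq(cfg)
#' head(sim$truth)
sim_config <- function(genome_length = 1e5,
                       gc_content = 0.5,
                       n_fragments = 1e4,
                       length_range = c(22L, 30L),
                       d3_distribution = c(
                         "5" = 0.10, "6" = 0.25, "7" = 0.30,
                         "8" = 0.25, "9" = 0.10),
                       d5_base_distribution = c(
                         "15" = 0.03, "16" = 0.06, "17" = 0.10,
                         "18" = 0.15, "19" = 0.20, "20" = 0.18,
                         "21" = 0.13, "22" = 0.09, "23" = 0.06),
                       coupling = 0.46,
                       p_deaminate = 0.5,
                       p_tandem = 0.15,
                       seq_error_rate = 0.001,
                       p_misprime = 0.1,
                       lesion_dinucleotide_mix = c(
                         TT = 0.53, CT = 0.17, TC = 0.20, CC = 0.10),
                       seed = NULL) {
  stopifnot_prob(gc_content, "gc_content")
  stopifnot_prob(coupling, "coupling")
  stopifnot_prob(p_deaminate, "p_deaminate")
  stopifnot_prob(p_tandem, "p_tandem")
  stopifnot_prob(seq_error_rate, "seq_error_rate")
  stopifnot_prob(p_misprime, "p_misprime")
  if (genome_length < 1000) stop("genome_length must be >= 1000")
  if (length(length_range) != 2L || length_range[1] < 1 ||
      length_range[1] > length_range[2]) {
    stop("length_range must be c(Lmin, Lmax) with 1 <= Lmin <= Lmax")
  }
  for (nm in c("d3_distribution", "d5_base_distribution",
               "lesion_dinucleotide_mix")) {
    d <- get(nm)
    if (is.null(names(d)) || any(d < 0) || sum(d) <= 0) {
      stop(sprintf("'%s' must be a named non-negative vector", nm))
    }
  }
  if (!all(names(lesion_dinucleotide_mix) %in% c("TT", "CT", "TC", "CC"))) {
    stop("lesion_dinucleotide_mix names must be among TT, CT, TC, CC")
  }
  d3_distribution <- d3_distribution / sum(d3_distribution)
  d5_base_distribution <- d5_base_distribution / sum(d5_base_distribution)
  lesion_dinucleotide_mix <-
    lesion_dinucleotide_mix / sum(lesion_dinucleotide_mix)
  structure(list(
    genome_length = as.integer(genome_length),
    gc_content = gc_content,
    n_fragments = as.integer(n_fragments),
    length_range = as.integer(length_range),
    d3_distribution = d3_distribution,
    d5_base_distribution = d5_base_distribution,
    coupling = coupling,
    p_deaminate = p_deaminate,
    p_tandem = p_tandem,
    seq_error_rate = seq_error_rate,
    p_misprime = p_misprime,
    lesion_dinucleotide_mix = lesion_dinucleotide_mix,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_config")
}

#' Generate an i.i.d. random genome
#'
#' Bases are drawn independently with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1 - gc)/2`.
#'
#' @param cfg a [sim_config()] object.
#' @param contig_name name of the single contig.
#' @return a [Biostrings::DNAStringSet] with one named contig.
#' @export
generate_genome <- function(cfg, contig_name = "chrS") {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  gc <- cfg$gc_content
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- paste(sample(BASES, cfg$genome_length, replace = TRUE, prob = p),
               collapse = "")
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- contig_name
  g
}

# Anchor positions (genome coordinate of the lesion dinucleotide's
# 3'-in-read-orientation base) for one dinucleotide type on one strand.
dinuc_anchor_sites <- function(genome, dinuc, strand, margin) {
  out <- lapply(seq_along(genome), function(i) {
    pat <- if (strand == "+") dinuc else revcomp(dinuc)
    m <- Biostrings::matchPattern(pat, genome[[i]])
    anchor <- if (strand == "+") IRanges::start(m) + 1L
              else IRanges::start(m)
    len <- length(genome[[i]])
    anchor <- anchor[anchor > margin & anchor <= len - margin]
    if (!length(anchor)) return(NULL)
    data.frame(contig = names(genome)[i], anchor = anchor)
  })
  do.call(rbind, out)
}

#' Simulate XR-seq fragments with ground truth
#'
#' For each fragment a genomic dipyrimidine of the configured type is
#' chosen on a random strand; 3' and 5' cut-site distances are sampled
#' (the 3' one compensated for the 5' draw according to the coupling
#' fraction); the excised sequence is emitted in read orientation; lesion
#' deamination, background sequencing errors (never touching the lesion
#' dinucleotide, so truth labels stay unambiguous) and mispriming
#' truncation are applied; and everything is recorded in a truth table.
#'
#' @param genome a [Biostrings::DNAStringSet], typically from
#'   [generate_genome()].
#' @param cfg a [sim_config()] object.
#' @param dyads optional data frame (`contig`, `pos`) from
#'   [generate_dyads()]; only needed when `boundary_shift != 0`.
#' @param boundary_shift additive shift (nt) applied to the 5' cut-site
#'   distance of fragments whose lesion lies within `boundary_band` of a
#'   dyad, emulating incision modulation at nucleosome boundaries.  The 3'
#'   distance compensates through the usual coupling rule.
#' @param boundary_band length-2 vector: the band of absolute
#'   lesion-to-dyad distances (bp) receiving the shift.
#'
#' @return a list with elements `reads` (data frame: `read_id`, `contig`,
#'   `start`, `end` 1-based inclusive, `strand`, `seq`, `length`) and
#'   `truth` (per-fragment ground truth; see Details in the package
#'   vignette).  Reads reflect truncation; `truth` keeps the original
#'   excised interval and true distances.
#' @export
generate_fragments <- function(genome, cfg, dyads = NULL,
                               boundary_shift = 0,
                               boundary_band = c(60, 73)) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 1L)
  n <- cfg$n_fragments
  mix <- cfg$lesion_dinucleotide_mix
  d3v <- as.numeric(names(cfg$d3_distribution))
  d5v <- as.numeric(names(cfg$d5_base_distribution))
  margin <- max(d5v) + max(d3v) + abs(boundary_shift) +
    ceiling(max(d5v) - min(d5v)) + 12L

  types <- sample(names(mix), n, replace = TRUE, prob = mix)
  strands <- sample(c("+", "-"), n, replace = TRUE)

  anchor <- integer(n)
  contig <- character(n)
  for (ty in unique(types)) {
    for (st in c("+", "-")) {
      sel <- which(types == ty & strands == st)
      if (!length(sel)) next
      sites <- dinuc_anchor_sites(genome, ty, st, margin)
      if (is.null(sites) || !nrow(sites)) {
        stop(sprintf(
          "no usable %s dipyrimidine site on strand %s of the genome", ty, st))
      }
      idx <- sample.int(nrow(sites), length(sel), replace = TRUE)
      anchor[sel] <- sites$anchor[idx]
      contig[sel] <- sites$contig[idx]
    }
  }

  d3_base <- as.integer(sample_categorical(n, cfg$d3_distribution))
  d5 <- as.integer(sample_categorical(n, cfg$d5_base_distribution))

  if (boundary_shift != 0) {
    if (is.null(dyads)) stop("boundary_shift != 0 requires 'dyads'")
    signed <- dyad_signed_distance(contig, anchor, strands, dyads,
                                   max_dist = max(abs(boundary_band)))
    in_band <- vapply(signed, function(s) {
      any(abs(s) >= min(boundary_band) & abs(s) <= max(boundary_band))
    }, logical(1))
    d5 <- d5 + ifelse(in_band, boundary_shift, 0)
  }

  mean_d5 <- categorical_mean(cfg$d5_base_distribution)
  d3 <- as.integer(pmax(1, rand_round(d3_base - cfg$coupling *
                                        (d5 - mean_d5))))
  L <- d5 + d3 - 1L

  on_plus <- strands == "+"
  start <- as.integer(ifelse(on_plus, anchor - d5 + 1L, anchor - d3 + 1L))
  end <- as.integer(ifelse(on_plus, anchor + d3 - 1L, anchor + d5 - 1L))

  seqs <- character(n)
  for (ct in unique(contig)) {
    sel <- which(contig == ct)
    ss <- as.character(Biostrings::extractAt(
      genome[[ct]], IRanges::IRanges(start[sel], end[sel])))
    neg <- !on_plus[sel]
    if (any(neg)) ss[neg] <- revcomp(ss[neg])
    seqs[sel] <- ss
  }

  # lesion dinucleotide occupies read indices (d5 - 1, d5)
  deam <- rep("none", n)
  u <- stats::runif(n)
  v <- stats::runif(n)
  w <- stats::runif(n)
  is_cc <- types == "CC"
  deam[is_cc & u < cfg$p_tandem] <- "tandem"
  single_cc <- is_cc & u >= cfg$p_tandem & v < cfg$p_deaminate
  deam[single_cc & w < 0.5] <- "single_5prime_C"
  deam[single_cc & w >= 0.5] <- "single_3prime_C"
  deam[types == "CT" & v < cfg$p_deaminate] <- "single_5prime_C"
  deam[types == "TC" & v < cfg$p_deaminate] <- "single_3prime_C"

  hit5 <- deam %in% c("single_5prime_C", "tandem")
  hit3 <- deam %in% c("single_3prime_C", "tandem")
  substr(seqs[hit5], d5[hit5] - 1L, d5[hit5] - 1L) <- "T"
  substr(seqs[hit3], d5[hit3], d5[hit3]) <- "T"

  # background errors, sparing the lesion dinucleotide
  error_offsets <- vector("list", n)
  if (cfg$seq_error_rate > 0) {
    k <- stats::rbinom(n, L, cfg$seq_error_rate)
    for (i in which(k > 0)) {
      cand <- setdiff(seq_len(L[i]), c(d5[i] - 1L, d5[i]))
      pos <- sample(cand, min(k[i], length(cand)))
      for (p in pos) {
        old <- substr(seqs[i], p, p)
        substr(seqs[i], p, p) <- sample(setdiff(BASES, old), 1L)
      }
      error_offsets[[i]] <- sort(pos)
    }
  }

  reads <- data.frame(
    read_id = sprintf("frag%06d", seq_len(n)),
    contig = contig, start = start, end = end, strand = strands,
    seq = seqs, length = L, stringsAsFactors = FALSE)

  mp <- apply_mispriming(reads, cfg)
  reads <- mp$reads

  truth <- data.frame(
    read_id = reads$read_id,
    contig = contig, strand = strands,
    frag_start = start, frag_end = end,
    lesion_start = as.integer(ifelse(on_plus, anchor - 1L, anchor)),
    lesion_end = as.integer(ifelse(on_plus, anchor, anchor + 1L)),
    anchor = as.integer(anchor),
    lesion_type = types,
    deamination = deam,
    d5 = d5, d3 = d3, length = L,
    truncated = mp$truncated,
    truncation_offset = mp$truncation_offset,
    n_errors = lengths(error_offsets),
    error_offsets = vapply(error_offsets, function(x) {
      paste(x, collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE)

  list(reads = reads, truth = truth)
}

#' Apply mispriming truncation to simulated reads
#'
#' With probability `cfg$p_misprime` per read, if the read contains a TGG
#' (read orientation) whose removal -- truncating immediately 5' of it --
#' leaves at least `Lmin` bases, the read is truncated at the 3'-most such
#' TGG.  This emulates PCR rescue of fragments lacking a 3' adapter via an
#' adapter-homologous internal TGG: after in-silico adapter trimming the
#' read ends just before the TGG, and the TGG becomes its genomic 3'
#' flank.
#'
#' @param reads data frame of placed reads (as from
#'   [generate_fragments()]).
#' @param cfg a [sim_config()] object (`p_misprime`, `length_range`).
#' @return a list: `reads` (updated coordinates/sequences), logical
#'   `truncated`, integer `truncation_offset` (nt removed from the 3'
#'   end).
#' @export
apply_mispriming <- function(reads, cfg) {
  n <- nrow(reads)
  truncated <- rep(FALSE, n)
  offset <- rep(0L, n)
  lmin <- cfg$length_range[1]
  cand <- which(stats::runif(n) < cfg$p_misprime)
  for (i in cand) {
    hits <- gregexpr("(?=TGG)", reads$seq[i], perl = TRUE)[[1]]
    if (hits[1] == -1L) next
    # truncating 5' of a TGG starting at t leaves t - 1 bases
    elig <- hits[hits - 1L >= lmin & hits + 2L <= reads$length[i]]
    if (!length(elig)) next
    t <- max(elig)
    removed <- reads$length[i] - (t - 1L)
    reads$seq[i] <- substr(reads$seq[i], 1L, t - 1L)
    if (reads$strand[i] == "+") {
      reads$end[i] <- reads$end[i] - removed
    } else {
      reads$start[i] <- reads$start[i] + removed
    }
    reads$length[i] <- t - 1L
    truncated[i] <- TRUE
    offset[i] <- removed
  }
  list(reads = reads, truncated = truncated, truncation_offset = offset)
}

#' Generate nucleosome dyad positions
#'
#' Dyads are tiled along each contig at the given spacing with uniform
#' jitter, emulating a genome-wide dyad map at regular nucleosome repeat
#' length.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param spacing nucleosome repeat length in bp (> 147).
#' @param jitter maximum absolute uniform displacement (bp) of each dyad
#'   from its grid point.
#' @param seed optional RNG seed.
#' @return data frame with columns `contig`, `pos` (1-based dyad
#'   coordinate).
#' @export
generate_dyads <- function(genome, spacing = 200, jitter = 20,
                           seed = NULL) {
  if (spacing <= 147) stop("spacing must exceed the 147 bp nucleosome core")
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_along(genome), function(i) {
    len <- length(genome[[i]])
    grid <- seq(from = spacing %/% 2, to = len - 74L, by = spacing)
    pos <- grid + sample(seq(-jitter, jitter), length(grid), replace = TRUE)
    pos <- pmin(pmax(pos, 74L), len - 74L)
    data.frame(contig = names(genome)[i], pos = as.integer(pos))
  })
  do.call(rbind, out)
}

#' Generate random blacklist regions
#'
#' Produces a handful of synthetic excludable intervals for exercising
#' [blacklist_filter()].
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param n_regions regions per contig.
#' @param width region width in bp.
#' @param seed optional RNG seed.
#' @return data frame `contig`, `start`, `end` (1-based inclusive).
#' @export
generate_blacklist <- function(genome, n_regions = 5, width = 500,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_along(genome), function(i) {
    len <- length(genome[[i]])
    start <- sort(sample.int(len - width, n_regions))
    data.frame(contig = names(genome)[i], start = start,
               end = start + width - 1L)
  })
  do.call(rbind, out)
}

#' Run the simulator end to end
#'
#' Convenience wrapper: genome, fragments (+truth), dyads and blacklist
#' under one configuration.
#'
#' @inheritParams generate_fragments
#' @param dyad_spacing,dyad_jitter passed to [generate_dyads()].
#' @return list with `genome`, `reads`, `truth`, `dyads`, `blacklist`,
#'   `cfg`.
#' @export
simulate_xrseq <- function(cfg, dyad_spacing = 200, dyad_jitter = 20,
                           boundary_shift = 0, boundary_band = c(60, 73)) {
  genome <- generate_genome(cfg)
  dseed <- if (is.null(cfg$seed)) NULL else cfg$seed + 2L
  dyads <- generate_dyads(genome, dyad_spacing, dyad_jitter, seed = dseed)
  frags <- generate_fragments(genome, cfg, dyads = dyads,
                              boundary_shift = boundary_shift,
                              boundary_band = boundary_band)
  bseed <- if (is.null(cfg$seed)) NULL else cfg$seed + 3L
  blacklist <- generate_blacklist(genome, seed = bseed)
  c(list(genome = genome, dyads = dyads, blacklist = blacklist, cfg = cfg),
    frags)
}

#' Write simulator outputs to disk
#'
#' Genome FASTA, reads FASTQ (constant dummy qualities), optional SAM of
#' the true placements, dyads and blacklist BED (0-based half-open), and
#' the truth table TSV.
#'
#' @param sim result of [simulate_xrseq()].
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
write_sim_outputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    reads = file.path(dir, "reads.fastq"),
    sam = file.path(dir, "reads.sam"),
    dyads = file.path(dir, "dyads.bed"),
    blacklist = file.path(dir, "blacklist.bed"),
    truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(sim$genome, paths["genome"])
  rs <- Biostrings::DNAStringSet(sim$reads$seq)
  names(rs) <- sim$reads$read_id
  Biostrings::writeXStringSet(
    rs, paths["reads"], format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", nchar(sim$reads$seq))))
  write_sam(sim$reads, sim$genome, paths["sam"])
  write_bed_points(sim$dyads, paths["dyads"])
  write_bed_intervals(sim$blacklist, paths["blacklist"])
  write_tsv(sim$truth, paths["truth"])
  invisible(paths)
}

# strand-aligned signed lesion-to-dyad distances; returns a list (one
# numeric vector per record) of distances to all dyads within max_dist.
dyad_signed_distance <- function(contig, pos, strand, dyads, max_dist) {
  out <- vector("list", length(pos))
  for (ct in unique(contig)) {
    sel <- which(contig == ct)
    dp <- dyads$pos[dyads$contig == ct]
    if (!length(dp)) {
      out[sel] <- list(numeric(0))
      next
    }
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(pos[sel] - max_dist, pos[sel] + max_dist),
      IRanges::IRanges(dp, dp))
    q <- S4Vectors::queryHits(ov)
    s <- S4Vectors::subjectHits(ov)
    raw <- pos[sel][q] - dp[s]
    signed <- ifelse(strand[sel][q] == "+", raw, -raw)
    out[sel] <- split(signed, factor(q, levels = seq_along(sel)))
  }
  out
}

write_bed_points <- function(df, path) {
  gr <- GenomicRanges::GRanges(df$contig, IRanges::IRanges(df$pos, df$pos))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

write_bed_intervals <- function(df, path) {
  gr <- GenomicRanges::GRanges(df$contig, IRanges::IRanges(df$start, df$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
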