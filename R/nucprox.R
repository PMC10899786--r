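# Cut-site distances as a function of lesion position relative to
# nucleosome dyads: blacklist filtering of the dyad map, strand-aligned
# binning of lesion-dyad distances, and per-bin significance against the
# grand mean.

as_granges_intervals <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(rtracklayer::import(x))
  }
  if (is.data.frame(x)) {
    return(GenomicRanges::GRanges(
      x$contig, IRanges::IRanges(x$start, x$end)))
  }
  stop("expected a GRanges, a BED path, or a contig/start/end data frame")
}

#' Read dyad positions from a BED file
#'
#' BED is 0-based half-open; dyads are single positions, returned
#' 1-based.
#'
#' @param path BED file path.
#' @return data frame `contig`, `pos`.
#' @export
read_dyads_bed <- function(path) {
  gr <- rtracklayer::import(path)
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             pos = GenomicRanges::start(gr))
}

#' Exclude dyads near blacklisted regions
#'
#' Each dyad is extended by `half_width` bases on either side (the
#' nucleosome core footprint) and excluded iff the extension overlaps
#' any blacklist interval.
#'
#' @param dyads data frame `contig`, `pos` (1-based).
#' @param blacklist a GRanges, a BED path, or a 1-based
#'   `contig`/`start`/`end` data frame.
#' @param half_width extension in bp on either side of the dyad.
#' @return the retained subset of `dyads`.
#' @export
blacklist_filter <- function(dyads, blacklist, half_width = 73) {
  bl <- as_granges_intervals(blacklist)
  if (!length(bl)) return(dyads)
  ext <- GenomicRanges::GRanges(
    dyads$contig,
    IRanges::IRanges(dyads$pos - half_width, dyads$pos + half_width))
  ov <- GenomicRanges::findOverlaps(ext, bl)
  drop <- unique(S4Vectors::queryHits(ov))
  if (length(drop)) dyads[-drop, , drop = FALSE] else dyads
}

#' Cut-site distances binned by lesion position relative to dyads
#'
#' Every (lesion, dyad) pair within `max_dist` bp contributes the
#' record's `d5` and `d3` to the bin at the strand-aligned signed
#' distance: `lesion - dyad` for plus-strand reads, `dyad - lesion` for
#' minus-strand reads, so the 5' incision always lies in the negative
#' direction from the lesion.  A lesion near two dyads contributes to
#' both bins; the grand means, however, count each record once
#' (`grand_per_pair = TRUE` switches to per-pair averaging).
#'
#' @param records incision records with `contig`, `lesion_pos`,
#'   `strand`, `d5`, `d3`.
#' @param dyads data frame `contig`, `pos`, typically after
#'   [blacklist_filter()].
#' @param max_dist half-width of the profile in bp.
#' @param grand_per_pair count multi-binned records once (default) or
#'   per pair in the grand means.
#' @return object of class `dyad_profile`: list `profile` (data frame
#'   `bin`, `n`, `mean_d5`, `mean_d3`), `pairs` (per-pair `bin`, `d5`,
#'   `d3`), `grand_mean_d5`, `grand_mean_d3`.
#' @export
dyad_profile <- function(records, dyads, max_dist = 500,
                         grand_per_pair = FALSE) {
  pairs <- list()
  for (ct in unique(records$contig)) {
    rsel <- which(records$contig == ct)
    dp <- dyads$pos[dyads$contig == ct]
    if (!length(dp) || !length(rsel)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(records$lesion_pos[rsel] - max_dist,
                       records$lesion_pos[rsel] + max_dist),
      IRanges::IRanges(dp, dp))
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    if (!length(q)) next
    raw <- records$lesion_pos[rsel][q] - dp[s]
    bin <- ifelse(records$strand[rsel][q] == "+", raw, -raw)
    pairs[[length(pairs) + 1L]] <- data.frame(
      record = rsel[q], bin = bin,
      d5 = records$d5[rsel][q], d3 = records$d3[rsel][q])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(record = integer(0), bin = integer(0), d5 = numeric(0),
               d3 = numeric(0))
  if (nrow(pairs)) {
    prof <- do.call(rbind, lapply(split(pairs, pairs$bin), function(d) {
      data.frame(bin = d$bin[1L], n = nrow(d),
                 mean_d5 = mean(d$d5), mean_d3 = mean(d$d3))
    }))
    prof <- prof[order(prof$bin), ]
    rownames(prof) <- NULL
  } else {
    prof <- data.frame(bin = integer(0), n = integer(0),
                       mean_d5 = numeric(0), mean_d3 = numeric(0))
  }
  if (grand_per_pair || !nrow(pairs)) {
    gm5 <- mean(pairs$d5); gm3 <- mean(pairs$d3)
  } else {
    once <- !duplicated(pairs$record)
    gm5 <- mean(pairs$d5[once]); gm3 <- mean(pairs$d3[once])
  }
  structure(list(profile = prof, pairs = pairs,
                 grand_mean_d5 = gm5, grand_mean_d3 = gm3),
            class = "dyad_profile")
}

# closed-form one-sample two-tailed t-test of x against scalar mu;
# returns p (0 when the sample is constant but off the reference).
t_p_value <- function(x, mu) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  s <- stats::sd(x)
  if (s == 0) return(if (mean(x) == mu) 1 else 0)
  tt <- (mean(x) - mu) / (s / sqrt(n))
  2 * stats::pt(-abs(tt), df = n - 1L)
}

#' Flag dyad-profile bins with unusual cut-site distances
#'
#' Each bin's distance sample is compared to the scalar grand mean by a
#' one-sample two-tailed t-test, separately for the 5' and 3'
#' distances; bins with `p < alpha` are flagged.  No multiple-testing
#' correction is applied (the cutoff is already stringent).  A
#' zero-variance bin away from the grand mean is flagged with p
#' reported as 0.
#'
#' @param dp a [dyad_profile()] object.
#' @param alpha significance cutoff.
#' @param min_n smallest bin size tested.
#' @return the profile data frame with `p_d5`, `p_d3`, `sig_d5`,
#'   `sig_d3` columns.
#' @export
bin_significance <- function(dp, alpha = 5e-5, min_n = 2) {
  prof <- dp$profile
  by_bin <- split(dp$pairs, dp$pairs$bin)
  prof$p_d5 <- NA_real_
  prof$p_d3 <- NA_real_
  for (i in seq_len(nrow(prof))) {
    d <- by_bin[[as.character(prof$bin[i])]]
    if (nrow(d) < min_n) next
    prof$p_d5[i] <- t_p_value(d$d5, dp$grand_mean_d5)
    prof$p_d3[i] <- t_p_value(d$d3, dp$grand_mean_d3)
  }
  prof$sig_d5 <- !is.na(prof$p_d5) & prof$p_d5 < alpha
  prof$sig_d3 <- !is.na(prof$p_d3) & prof$p_d3 < alpha
  prof
}
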