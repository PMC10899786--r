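# Incision-site statistics from lesion-anchored reads: cut-site
# distances, 5'/3' contribution decomposition, HYV motif profiles,
# GC-normalised composition/information matrices, the coupling
# regression and its shuffle control.
#
# Distance convention (lesion-inclusive): d5 = bases from the 5' read
# end to the lesion inclusive, d3 = lesion to the 3' end inclusive, so
# d5 + d3 = L + 1.  Tandem CC>TT lesions are anchored at the half-base
# between the two cytosines, giving half-integer distances under the
# same identity.

#' Build incision records from mismatch calls
#'
#' For a single mismatch at 1-based read offset `j` in a length-`L`
#' read: `d5 = j`, `d3 = L - j + 1`.  For a tandem pair at offsets
#' `(j, j+1)`: `d5 = j + 0.5`, `d3 = L - j + 0.5`.  Control mode treats
#' any single non-C>T mismatch as if it were the lesion; it can be
#' restricted to mismatch positions the C>T channel calls enriched.
#'
#' @param reads placement data frame.
#' @param mm mismatch table (see [mismatch_table()], tandem rows
#'   collapsed via [collapse_tandem()]); only reads with exactly one
#'   record enter.
#' @param kind lesion channel: `single_CT` keeps C>T rows,
#'   `tandem_CCTT` keeps tandem rows, `control_mismatch` keeps single
#'   non-C>T rows.
#' @param enriched optional [call_enriched_positions()] result (3' axis)
#'   used to filter control-mode records to C>T-enriched positions.
#' @return data frame `read_id`, `kind`, `d5`, `d3`, `L`, `contig`,
#'   `lesion_pos` (genomic coordinate of the lesion's 3'-in-read base),
#'   `strand`.
#' @export
incision_records <- function(reads, mm,
                             kind = c("single_CT", "tandem_CCTT",
                                      "control_mismatch"),
                             enriched = NULL) {
  kind <- match.arg(kind)
  one <- names(which(table(mm$read_id) == 1L))
  mm <- mm[mm$read_id %in% one, , drop = FALSE]
  mm <- switch(kind,
    single_CT = mm[!mm$is_tandem & mm$ref == "C" & mm$alt == "T", ,
                   drop = FALSE],
    tandem_CCTT = mm[mm$is_tandem & mm$ref == "CC" & mm$alt == "TT", ,
                     drop = FALSE],
    control_mismatch = mm[!mm$is_tandem &
                            !(mm$ref == "C" & mm$alt == "T"), ,
                          drop = FALSE])
  idx <- match(mm$read_id, reads$read_id)
  L <- nchar(reads$seq)[idx]
  half <- ifelse(mm$is_tandem, 0.5, 0)
  d5 <- mm$offset5 + half
  d3 <- L - mm$offset5 + ifelse(mm$is_tandem, 0.5, 1)
  off_anchor <- mm$offset5 + ifelse(mm$is_tandem, 1L, 0L)
  lesion_pos <- ifelse(reads$strand[idx] == "+",
                       reads$start[idx] + off_anchor - 1L,
                       reads$end[idx] - off_anchor + 1L)
  rec <- data.frame(read_id = mm$read_id, kind = kind, d5 = d5, d3 = d3,
                    L = L, contig = reads$contig[idx],
                    lesion_pos = lesion_pos,
                    strand = reads$strand[idx],
                    stringsAsFactors = FALSE)
  if (kind == "control_mismatch" && !is.null(enriched)) {
    keep <- mapply(function(l, p) {
      any(enriched$read_length == l & enriched$position == p &
            enriched$called)
    }, rec$L, -rec$d3)
    rec <- rec[keep, , drop = FALSE]
  }
  rownames(rec) <- NULL
  rec
}

#' 5'/3' contributions to read length variability
#'
#' For each incision side, the mean cut-site distance is computed at
#' every read length; the "position difference" at length `l` is that
#' mean minus the mean at the minimum length.  Differences are weighted
#' by the relative frequency of each read length and summed per side;
#' the two sums are normalised to percentages.  (Since
#' `d5 + d3 = L + 1`, the two sums always total the mean length excess
#' over the minimum length, so the percentages sum to 100.)
#'
#' @param records incision record data frame.
#' @return list `by_length` (data frame `read_length`, `n`, `weight`,
#'   `mean_d5`, `mean_d3`, `diff_d5`, `diff_d3`), `sum_5prime`,
#'   `sum_3prime`, `percent_5prime`, `percent_3prime`.  With a single
#'   read length the percentages are `NA` (no variability to
#'   decompose).
#' @export
contribution_decomposition <- function(records) {
  lens <- sort(unique(records$L))
  by_len <- do.call(rbind, lapply(lens, function(l) {
    d <- records[records$L == l, ]
    data.frame(read_length = l, n = nrow(d),
               mean_d5 = mean(d$d5), mean_d3 = mean(d$d3))
  }))
  by_len$weight <- by_len$n / sum(by_len$n)
  by_len$diff_d5 <- by_len$mean_d5 - by_len$mean_d5[1L]
  by_len$diff_d3 <- by_len$mean_d3 - by_len$mean_d3[1L]
  if (length(lens) < 2L) {
    return(list(by_length = by_len, sum_5prime = NA_real_,
                sum_3prime = NA_real_, percent_5prime = NA_real_,
                percent_3prime = NA_real_))
  }
  s5 <- sum(by_len$weight * by_len$diff_d5)
  s3 <- sum(by_len$weight * by_len$diff_d3)
  list(by_length = by_len, sum_5prime = s5, sum_3prime = s3,
       percent_5prime = 100 * s5 / (s5 + s3),
       percent_3prime = 100 * s3 / (s5 + s3))
}

#' Incision coupling regression
#'
#' Ordinary least squares of the chosen response on the 5' cut-site
#' distance.  For `d3_vs_d5` the coupling percentage is defined as
#' `-100` times the slope: the fraction of a 1 nt shift of the 5'
#' incision that the 3' incision compensates.  Because
#' `L = d5 + d3 - 1`, the identity
#' `slope(L ~ d5) = 1 + slope(d3 ~ d5)` holds exactly.
#'
#' @param records incision record data frame (>= 3 rows).
#' @param target `"d3_vs_d5"` or `"read_length_vs_d5"`.
#' @return one-row data frame `target`, `slope`, `intercept`,
#'   `p_value` (two-sided, on the slope), `coupling_percent` (`NA`
#'   unless `d3_vs_d5`), `n`.
#' @export
coupling_regression <- function(records,
                                target = c("d3_vs_d5",
                                           "read_length_vs_d5")) {
  target <- match.arg(target)
  if (nrow(records) < 3L) stop("need at least 3 records")
  x <- records$d5
  if (stats::var(x) == 0) stop("zero variance in d5: slope undefined")
  y <- if (target == "d3_vs_d5") records$d3 else records$L
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  data.frame(target = target,
             slope = unname(coef(fit)[2L]),
             intercept = unname(coef(fit)[1L]),
             p_value = unname(sm[2L, 4L]),
             coupling_percent = if (target == "d3_vs_d5")
               -100 * unname(coef(fit)[2L]) else NA_real_,
             n = nrow(records))
}

#' Shuffle control for the coupling regression
#'
#' Permutes the 5' cut-site distances across records without
#' replacement, keeps each record's 3' distance, and recomputes the
#' fragment length as `d5 + d3 - 1`.  The multisets of `d5` and of `d3`
#' are unchanged; any coupling is destroyed, so the regression of the
#' recomputed length on the shuffled `d5` has slope 1 in expectation.
#'
#' @param records incision record data frame.
#' @param seed optional RNG seed.
#' @return records with shuffled `d5` and recomputed `L`.
#' @export
shuffle_control <- function(records, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  records$d5 <- sample(records$d5)
  records$L <- records$d5 + records$d3 - 1
  records
}

hyv_match <- function(m) {
  # m: byte matrix of flanked sequences
  H <- m != charToRaw("G")[1] & m != charToRaw("N")[1]
  Y <- m == charToRaw("C")[1] | m == charToRaw("T")[1]
  V <- m != charToRaw("T")[1] & m != charToRaw("N")[1]
  list(H = H, Y = Y, V = V)
}

#' HYV motif frequency around the 5' incision site
#'
#' HYV (H = not G, Y = C or T, V = not T) is the sequence context the 5'
#' endonuclease prefers, the incision falling between Y and V.  An
#' occurrence at position `p` means bases `(p-1, p, p+1)` match
#' `(H, Y, V)`; it is reported at the Y base, in coordinates where `+1`
#' is the first read base, so the incision-proximal signal sits at
#' `p = 0` (Y = last base before the read, V = first read base).
#' Significance uses the familiar four-standard-deviation rule with the
#' six 5'-most profile positions as background.
#'
#' With `records` supplied, the profile is additionally stratified by 5'
#' cut-site distance, and positions within `omit_window` of the lesion
#' are masked (`NA`): dipyrimidine-forming sequences bias composition
#' there.
#'
#' @param reads placement data frame.
#' @param genome a [Biostrings::DNAStringSet].
#' @param flank flank width (nt) used for context extraction.
#' @param records optional incision records for stratification.
#' @param omit_window half-width (nt) of the masked window around the
#'   lesion in stratified profiles.
#' @param k enrichment threshold in background standard deviations.
#' @return data frame `stratum` (`"all"` or the d5 value), `position`,
#'   `frequency`, `n_reads`, `bg_mean`, `bg_sd`, `called`.
#' @export
hyv_profile <- function(reads, genome, flank = 10, records = NULL,
                        omit_window = 2, k = 4) {
  strata <- list(all = seq_len(nrow(reads)))
  if (!is.null(records)) {
    idx <- match(records$read_id, reads$read_id)
    strata <- c(strata,
                split(idx, paste0("d5=", records$d5)))
  }
  ctx <- extract_context(reads, genome, flank = flank)
  len <- nchar(reads$seq)
  out <- list()
  for (snm in names(strata)) {
    sel <- strata[[snm]]
    if (!length(sel)) next
    minL <- min(len[sel])
    qmax <- minL + flank - 1L
    qs <- seq(2L - flank, qmax)
    freq <- numeric(length(qs))
    for (w in unique(len[sel])) {
      ss <- ctx[sel][len[sel] == w]
      m <- seq_byte_matrix(ss)
      hv <- hyv_match(m)
      kk <- qs + flank                      # flanked column of the Y base
      f <- vapply(kk, function(col) {
        mean(hv$H[, col - 1L] & hv$Y[, col] & hv$V[, col + 1L])
      }, numeric(1))
      freq <- freq + f * length(ss)
    }
    freq <- freq / length(sel)
    if (snm != "all") {
      d5val <- as.numeric(sub("^d5=", "", snm))
      mask <- abs(qs - d5val) <= omit_window
      freq[mask] <- NA_real_
    }
    bg <- freq[seq_len(6L)]
    mu <- mean(bg, na.rm = TRUE)
    sdv <- stats::sd(bg, na.rm = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      stratum = snm, position = qs, frequency = freq,
      n_reads = length(sel), bg_mean = mu, bg_sd = sdv,
      called = !is.na(freq) & sdv > 0 & (freq - mu) / sdv >= k)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Positional base composition and GC-normalised information content
#'
#' Per-position nucleotide frequencies over flanked read contexts,
#' anchored at the 5' end (`+1` = first read base), restricted to
#' positions every read covers.  The information content is the relative
#' entropy `sum_b f_b log2(f_b / q_b)` in bits against a background
#' taken from the input's own GC content
#' (`q_G = q_C = GC/2`, `q_A = q_T = (1 - GC)/2`) -- the normalisation a
#' GC-aware sequence logo applies.  No small-sample correction is used.
#'
#' @param reads placement data frame.
#' @param genome a [Biostrings::DNAStringSet].
#' @param flank flank width in nt.
#' @param gc optional background GC fraction; computed from the input
#'   contexts when `NULL`.
#' @return data frame `position`, `A`, `C`, `G`, `T`, `coverage`,
#'   `information`, with the background GC as attribute `"gc"`.
#' @export
composition_matrix <- function(reads, genome, flank = 10, gc = NULL) {
  ctx <- extract_context(reads, genome, flank = flank)
  len <- nchar(reads$seq)
  minL <- min(len)
  qs <- seq(1L - flank, minL + flank)
  counts <- matrix(0, nrow = length(qs), ncol = 4L,
                   dimnames = list(NULL, BASES))
  for (w in unique(len)) {
    ss <- ctx[len == w]
    m <- seq_byte_matrix(ss)[, qs + flank, drop = FALSE]
    for (b in BASES) counts[, b] <- counts[, b] +
        colSums(m == charToRaw(b)[1])
  }
  cov <- rowSums(counts)
  freq <- counts / ifelse(cov == 0, NA, cov)
  if (is.null(gc)) {
    gc <- sum(counts[, c("C", "G")]) / sum(counts)
  }
  q <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  info <- vapply(seq_along(qs), function(i) {
    f <- freq[i, ]
    if (anyNA(f)) return(NA_real_)
    nz <- f > 0
    sum(f[nz] * log2(f[nz] / q[BASES][nz]))
  }, numeric(1))
  out <- data.frame(position = qs, freq, coverage = cov,
                    information = info)
  attr(out, "gc") <- gc
  out
}
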