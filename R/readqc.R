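# Read-level quality filters: indel / multi-mismatch / N / length-range
# rules, data-driven species read length ranges from dipyrimidine
# position scores, and the 3' TGG mispriming filter.

#' Basic read filters
#'
#' Applies, in this fixed order: (i) reads with insertions or deletions
#' removed; (ii) reads with more than one mismatch removed (they are the
#' input to the tandem revertant path, not discarded information);
#' (iii) reads containing N removed; (iv) reads outside the read length
#' range removed.  A read failing several rules is counted once, under
#' the first failing rule.
#'
#' @param reads placement data frame with `n_mismatches`, `has_indel`,
#'   `has_N` (as from [align_reads()] post-processing or [import_sam()]).
#' @param length_range integer `c(Lmin, Lmax)`, inclusive.
#' @return list `kept` (data frame), `report` (data frame `rule`,
#'   `removed`, plus rows `retained` and `input`).
#' @export
basic_filters <- function(reads, length_range) {
  n_input <- if (is.null(reads)) 0L else nrow(reads)
  if (n_input == 0L) {
    report <- data.frame(
      rule = c("indel", "multi_mismatch", "N", "length_range",
               "retained", "input"),
      count = c(0L, 0L, 0L, 0L, 0L, 0L))
    return(list(kept = reads, report = report))
  }
  indel <- reads$has_indel %in% TRUE
  multi <- !indel & !is.na(reads$n_mismatches) & reads$n_mismatches > 1L
  hasn <- !indel & !multi & reads$has_N %in% TRUE
  len <- nchar(reads$seq)
  badlen <- !indel & !multi & !hasn &
    (len < length_range[1] | len > length_range[2])
  removed <- indel | multi | hasn | badlen
  report <- data.frame(
    rule = c("indel", "multi_mismatch", "N", "length_range",
             "retained", "input"),
    count = c(sum(indel), sum(multi), sum(hasn), sum(badlen),
              sum(!removed), n_input))
  list(kept = reads[!removed, , drop = FALSE], report = report)
}

#' Dipyrimidine frequency by position relative to the 3' end
#'
#' For reads of a single length `L`, the frequency at position
#' `p` (`p = -1, ..., -(L-1)`) is the fraction of reads whose bases at
#' `p - 1` and `p` are both pyrimidines.  A pair occupying positions
#' `(p-1, p)` is indexed at `p`, its 3' base -- the anchor the lesion
#' position is plotted against.
#'
#' @param seqs character vector of equal-length read sequences.
#' @return data frame `position` (negative, from `-1`), `frequency`.
#' @export
dipyrimidine_profile <- function(seqs) {
  if (!length(seqs)) stop("no reads")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("reads must share one length")
  m <- seq_byte_matrix(seqs)
  py <- m == charToRaw("C")[1] | m == charToRaw("T")[1]
  freq <- vapply(seq(2L, L), function(j) mean(py[, j - 1L] & py[, j]),
                 numeric(1))
  data.frame(position = seq(2L, L) - L - 1L, frequency = freq)
}

#' Per-length dipyrimidine position scores
#'
#' For each read length: the position (relative to the 3' end) with the
#' highest dipyrimidine frequency, that frequency, the number of reads,
#' and the score `best_frequency * n_reads`.
#'
#' @param reads placement data frame (or any data frame with a `seq`
#'   column).
#' @return data frame `read_length`, `best_position`, `best_frequency`,
#'   `n_reads`, `score`.
#' @export
length_score_table <- function(reads) {
  len <- nchar(reads$seq)
  out <- lapply(sort(unique(len)), function(L) {
    s <- reads$seq[len == L]
    prof <- dipyrimidine_profile(s)
    best <- which.max(prof$frequency)
    data.frame(read_length = L,
               best_position = prof$position[best],
               best_frequency = prof$frequency[best],
               n_reads = length(s),
               score = prof$frequency[best] * length(s))
  })
  do.call(rbind, out)
}

#' Derive a species read length range from dipyrimidine scores
#'
#' Lengths qualify while their score stays at or above
#' `decline_fraction` of the maximum score; the range returned is a
#' maximal contiguous run of qualifying lengths.  When several disjoint
#' runs qualify, the run containing `expected_length` wins; among equally
#' long candidate runs without an expectation, longer read lengths are
#' favoured (shorter fragments may reflect degradation).
#'
#' @param reads placement data frame.
#' @param expected_length optional expected read length from prior
#'   experimental work, used to pick among disjoint runs.
#' @param decline_fraction score fraction below which lengths are deemed
#'   to have "declined sharply" (a documented heuristic; the borders were
#'   originally set by inspection).
#' @return integer `c(Lmin, Lmax)`, with the score table attached as
#'   attribute `"scores"`.
#' @export
derive_length_range <- function(reads, expected_length = NULL,
                                decline_fraction = 0.2) {
  if (is.null(reads) || nrow(reads) == 0L) stop("no reads")
  tab <- length_score_table(reads)
  # place scores on a dense grid of lengths so runs mean contiguity in nt
  lens <- seq(min(tab$read_length), max(tab$read_length))
  score <- setNames(rep(0, length(lens)), lens)
  score[as.character(tab$read_length)] <- tab$score
  qual <- score >= decline_fraction * max(score)
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(from = lens[starts[r$values]],
                     to = lens[ends[r$values]])
  pick <- NULL
  if (!is.null(expected_length)) {
    inrun <- which(runs$from <= expected_length & runs$to >= expected_length)
    if (length(inrun)) pick <- inrun[1L]
  }
  if (is.null(pick)) {
    span <- runs$to - runs$from
    pick <- which(span == max(span))
    if (length(pick) > 1L) pick <- pick[which.max(runs$to[pick])]
  }
  out <- c(runs$from[pick], runs$to[pick])
  attr(out, "scores") <- tab
  out
}

#' Filter reads with a 3'-flanking mispriming motif
#'
#' A read is removed iff the bases immediately past its 3' end, in read
#' orientation, equal `motif` exactly (default `TGG`, the start of the
#' 3' sequencing adapter; `"TG"` gives the stricter two-base variant).
#' Reads whose flank runs off the contig are kept with a warning.
#'
#' @param reads placement data frame.
#' @param genome a [Biostrings::DNAStringSet].
#' @param motif flank motif to remove on.
#' @return list `kept`, `removed` (data frames).
#' @export
tgg_filter <- function(reads, genome, motif = "TGG") {
  k <- nchar(motif)
  ctx <- extract_context(reads, genome, flank = k)
  flank3 <- substr(ctx, nchar(ctx) - k + 1L, nchar(ctx))
  off <- grepl("N", flank3, fixed = TRUE)
  if (any(off)) {
    warning(sum(off), " read(s) with 3' flank off the contig were kept")
  }
  remove <- flank3 == motif & !off
  list(kept = reads[!remove, , drop = FALSE],
       removed = reads[remove, , drop = FALSE])
}

#' Motif frequency around reads, by position and read length
#'
#' For every read length, the fraction of reads whose flanked context
#' contains `motif` starting at each position.  Positions use the 3'-end
#' convention of the lesion-position plots: `-1` is the last read base,
#' `+1` the first base past the 3' cut site; the motif is indexed at its
#' first base.  Flanking positions beyond both cut sites are included.
#'
#' @param reads placement data frame.
#' @param genome a [Biostrings::DNAStringSet].
#' @param motif motif to scan for (overlapping occurrences counted).
#' @param flank context width on either side of the read.
#' @return data frame `read_length`, `position`, `frequency`, `n_reads`.
#' @export
flank_motif_profile <- function(reads, genome, motif = "TGG", flank = 10) {
  ctx <- extract_context(reads, genome, flank = flank)
  len <- nchar(reads$seq)
  k <- nchar(motif)
  pat <- paste0("(?=", motif, ")")
  out <- lapply(sort(unique(len)), function(L) {
    sel <- which(len == L)
    counts <- integer(L + 2L * flank - k + 1L)
    for (s in ctx[sel]) {
      h <- gregexpr(pat, s, perl = TRUE)[[1]]
      if (h[1] != -1L) counts[h] <- counts[h] + 1L
    }
    r <- seq_along(counts) - flank          # 1-based read index of motif start
    position <- ifelse(r <= L, r - L - 1L, r - L)  # -1 = last read base
    data.frame(read_length = L, position = position,
               frequency = counts / length(sel), n_reads = length(sel))
  })
  do.call(rbind, out)
}
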