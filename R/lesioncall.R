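# Lesion calling from mismatch positions: substitution and trinucleotide
# context spectra, read-length-stratified position frequency matrices,
# and the 4-standard-deviation enrichment rule against a 5'-anchored
# background (where no CPD is expected).

#' Single-nucleotide mismatch spectrum
#'
#' Counts the 12 substitution types among non-tandem mismatch records,
#' in read-strand orientation.
#'
#' @param mm mismatch table (see [mismatch_table()]).
#' @return data frame `type` (e.g. `"C>T"`), `count`, `frequency`, over
#'   all 12 types.
#' @export
mismatch_spectrum <- function(mm) {
  mm <- mm[!mm$is_tandem, , drop = FALSE]
  types <- as.vector(outer(BASES, BASES, function(a, b) paste0(a, ">", b)))
  types <- types[substr(types, 1, 1) != substr(types, 3, 3)]
  obs <- paste0(mm$ref, ">", mm$alt)
  counts <- table(factor(obs, levels = sort(types)))
  data.frame(type = names(counts), count = as.integer(counts),
             frequency = as.numeric(counts) / max(1L, sum(counts)))
}

#' Trinucleotide context spectrum of C>T mismatches
#'
#' Tabulates the 16 `N[C]N` reference contexts of single C>T mismatches
#' and the dipyrimidine fraction: the fraction of mismatches with a
#' pyrimidine immediately 5' or 3' of the mismatched reference base.
#' Contexts use the genomic flank when the mismatch sits at a read edge,
#' so no record is dropped.
#'
#' @param mm mismatch table; rows other than single C>T are ignored.
#' @return list `contexts` (data frame `context`, `count`, `frequency`)
#'   and `dipyrimidine_fraction`.
#' @export
context_spectrum <- function(mm) {
  ct <- mm[!mm$is_tandem & mm$ref == "C" & mm$alt == "T", , drop = FALSE]
  lv <- as.vector(outer(BASES, BASES, function(a, b) paste0(a, "C", b)))
  counts <- table(factor(ct$context, levels = sort(lv)))
  up <- substr(ct$context, 1, 1)
  down <- substr(ct$context, 3, 3)
  dipy <- mean(up %in% PYRIMIDINES | down %in% PYRIMIDINES)
  list(contexts = data.frame(context = names(counts),
                             count = as.integer(counts),
                             frequency = as.numeric(counts) /
                               max(1L, sum(counts))),
       dipyrimidine_fraction = dipy)
}

#' Mismatch position frequency matrix, stratified by read length
#'
#' Position convention: on the 3' axis, `-1` is the first nucleotide
#' before the 3' cut site (the last read base); on the 5' axis, `+1` the
#' first nucleotide after the 5' cut site (the first read base).  A
#' mismatch at 1-based read offset `j` in a length-`L` read sits at
#' `j - L - 1` on the 3' axis and `+j` on the 5' axis.  Tandem records
#' contribute at their half-base position (`j + 0.5` from the 5' end).
#'
#' @param reads placement data frame (for read lengths).
#' @param mm mismatch table, usually restricted to the lesion channel of
#'   interest (e.g. single C>T).
#' @param anchor `"3prime"` or `"5prime"`.
#' @return data frame `read_length`, `position`, `count`, `frequency`
#'   (frequencies sum to 1 within each read length), of class
#'   `position_matrix` with the anchor stored as an attribute.
#' @export
position_matrix <- function(reads, mm, anchor = c("3prime", "5prime")) {
  anchor <- match.arg(anchor)
  len <- setNames(nchar(reads$seq), reads$read_id)
  L <- len[mm$read_id]
  off <- mm$offset5 + ifelse(mm$is_tandem, 0.5, 0)
  pos <- if (anchor == "3prime") off - L - 1 else off
  key <- paste(L, pos)
  counts <- table(key)
  parts <- strsplit(names(counts), " ", fixed = TRUE)
  out <- data.frame(
    read_length = as.integer(vapply(parts, `[[`, "", 1L)),
    position = as.numeric(vapply(parts, `[[`, "", 2L)),
    count = as.integer(counts))
  out <- out[order(out$read_length, out$position), ]
  tot <- tapply(out$count, out$read_length, sum)
  out$frequency <- out$count / as.numeric(tot[as.character(out$read_length)])
  rownames(out) <- NULL
  structure(out, anchor = anchor, class = c("position_matrix",
                                            "data.frame"))
}

#' Call lesion-enriched positions against a 5'-anchored background
#'
#' Within each read length's frequency vector the background is the
#' `n_background` positions closest to the 5' incision site, where no
#' CPD is expected; their mean and sample (n-1) standard deviation give
#' the null.  A position is called when its frequency is at least
#' `k` standard deviations above the background mean (and non-zero).  A
#' degenerate zero-variance background is flagged and requires a strict
#' excess over the mean.  The occupied position grid is completed with
#' zero-frequency cells first, so absences count as evidence.
#'
#' @param pm a [position_matrix()] result.
#' @param n_background background positions per read length.
#' @param k number of standard deviations (the two-sided normal tail at
#'   `k = 4` is 6.3e-5).
#' @return data frame `read_length`, `position`, `frequency`, `bg_mean`,
#'   `bg_sd`, `z`, `called`, `degenerate_bg`.  Read lengths with fewer
#'   than `n_background + 1` positions are skipped with a warning.
#' @export
call_enriched_positions <- function(pm, n_background = 10, k = 4) {
  anchor <- attr(pm, "anchor")
  out <- list()
  for (L in unique(pm$read_length)) {
    d <- pm[pm$read_length == L, , drop = FALSE]
    grid <- if (anchor == "3prime") seq(-L, -1) else seq(1, L)
    # complete integer grid; keep any half-integer (tandem) cells as-is
    full <- merge(data.frame(position = grid),
                  d[, c("position", "frequency")],
                  by = "position", all = TRUE)
    full$frequency[is.na(full$frequency)] <- 0
    if (nrow(full) < n_background + 1L) {
      warning("read length ", L, " has too few positions; skipped")
      next
    }
    # order from the 5' end: ascending works for both anchors
    # (3' axis: -L is the 5'-most base; 5' axis: +1 is)
    full <- full[order(full$position), , drop = FALSE]
    bg <- full$frequency[seq_len(n_background)]
    mu <- mean(bg)
    sdv <- stats::sd(bg)
    degen <- sdv == 0
    z <- if (degen) ifelse(full$frequency > mu, Inf, -Inf) else
      (full$frequency - mu) / sdv
    called <- if (degen) full$frequency > mu & full$frequency > 0 else
      z >= k & full$frequency > 0
    out[[length(out) + 1L]] <- data.frame(
      read_length = L, position = full$position,
      frequency = full$frequency, bg_mean = mu, bg_sd = sdv,
      z = z, called = called, degenerate_bg = degen)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
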