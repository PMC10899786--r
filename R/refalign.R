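# Read placement on the reference and per-read mismatch extraction.
#
# The internal placer is a deliberately small stand-in for a production
# aligner at synthetic-genome scale: exact occurrence search on both
# strands, falling back to a unique <=1-mismatch placement.  Reads whose
# best-scoring placement is not unique are reported unaligned
# ("ambiguous") -- reproducibility is preferred over recall.  Reads
# needing >= 2 mismatches (tandem CC>TT deamination) are handled by the
# revertant-sequence path (see tandem.R), not here.

#' Build a genome search index
#'
#' Wraps the genome and its reverse complement for strand-aware exact and
#' one-mismatch occurrence queries.  Queries shorter than 10 nt are
#' rejected (too unspecific to be meaningful for XR-seq fragments).
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @return an object of class `genome_index`.
#' @export
build_index <- function(genome) {
  if (is.null(names(genome))) names(genome) <- paste0("contig", seq_along(genome))
  structure(list(genome = genome,
                 rc = Biostrings::reverseComplement(genome)),
            class = "genome_index")
}

#' Locate occurrences of a query on both strands
#'
#' @param index a [build_index()] object.
#' @param query character or DNAString, length >= 10.
#' @param max_mismatches 0 or 1.
#' @return data frame `contig`, `start`, `end` (1-based inclusive, plus
#'   strand coordinates), `strand`, `n_mismatches`.
#' @export
locate_query <- function(index, query, max_mismatches = 0) {
  query <- as.character(query)
  if (nchar(query) < 10) stop("queries must be >= 10 nt")
  w <- nchar(query)
  pat <- Biostrings::DNAString(query)
  hits <- list()
  for (i in seq_along(index$genome)) {
    n <- length(index$genome[[i]])
    for (st in c("+", "-")) {
      subj <- if (st == "+") index$genome[[i]] else index$rc[[i]]
      m <- Biostrings::matchPattern(pat, subj,
                                    max.mismatch = max_mismatches)
      if (!length(m)) next
      s <- IRanges::start(m)
      nm <- vapply(seq_along(m), function(j) {
        Biostrings::neditAt(pat, subj, at = s[j])
      }, integer(1))
      keep <- nm <= max_mismatches
      if (!any(keep)) next
      s <- s[keep]
      start_plus <- if (st == "+") s else n - (s + w - 1L) + 1L
      hits[[length(hits) + 1L]] <- data.frame(
        contig = names(index$genome)[i],
        start = start_plus, end = start_plus + w - 1L,
        strand = st, n_mismatches = nm[keep])
    }
  }
  if (!length(hits)) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_mismatches = integer(0)))
  }
  do.call(rbind, hits)
}

#' Count exact occurrences of a query (both strands)
#'
#' @inheritParams locate_query
#' @return integer occurrence count.
#' @export
count_query <- function(index, query) {
  nrow(locate_query(index, query, max_mismatches = 0))
}

#' Place one read on the reference
#'
#' An exact hit is preferred over a 1-mismatch hit; within the best score
#' the placement must be unique, otherwise the read is reported unaligned
#' with reason `"ambiguous"`.
#'
#' @param seq read sequence (read orientation), >= 10 nt.
#' @param index a [build_index()] object.
#' @param max_mismatches at most 1 substitution tolerated.
#' @param id read identifier carried into the result.
#' @return list with `aligned` (logical), `reason` (when unaligned), and
#'   on success `read` (one-row placement data frame) and `mismatches`
#'   (data frame as from [mismatch_table()]).
#' @export
align_read <- function(seq, index, max_mismatches = 1, id = "read") {
  exact <- locate_query(index, seq, max_mismatches = 0)
  best <- exact
  if (nrow(exact) == 0L && max_mismatches >= 1) {
    one <- locate_query(index, seq, max_mismatches = 1)
    best <- one[one$n_mismatches == 1L, , drop = FALSE]
  }
  if (nrow(best) == 0L) {
    return(list(aligned = FALSE, reason = "no_hit"))
  }
  if (nrow(best) > 1L) {
    return(list(aligned = FALSE, reason = "ambiguous"))
  }
  read <- data.frame(read_id = id, contig = best$contig,
                     start = best$start, end = best$end,
                     strand = best$strand, seq = seq,
                     length = nchar(seq), stringsAsFactors = FALSE)
  mm <- mismatch_table(read, index$genome)
  read$n_mismatches <- nrow(mm)
  read$has_indel <- FALSE
  read$has_N <- grepl("N", seq, fixed = TRUE)
  list(aligned = TRUE, read = read, mismatches = mm)
}

#' Place many reads
#'
#' @param seqs character vector of read sequences.
#' @param index a [build_index()] object.
#' @param ids read identifiers.
#' @param max_mismatches at most 1.
#' @return list: `reads` (placements), `mismatches`, `unaligned` (data
#'   frame `read_id`, `reason`).
#' @export
align_reads <- function(seqs, index, ids = NULL, max_mismatches = 1) {
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(seqs))
  reads <- list(); mms <- list(); un <- list()
  for (i in seq_along(seqs)) {
    r <- align_read(seqs[i], index, max_mismatches, id = ids[i])
    if (r$aligned) {
      reads[[length(reads) + 1L]] <- r$read
      if (nrow(r$mismatches)) mms[[length(mms) + 1L]] <- r$mismatches
    } else {
      un[[length(un) + 1L]] <- data.frame(read_id = ids[i],
                                          reason = r$reason)
    }
  }
  empty_mm <- mismatch_table(
    data.frame(read_id = character(0), contig = character(0),
               start = integer(0), end = integer(0),
               strand = character(0), seq = character(0),
               length = integer(0)), index$genome)
  list(
    reads = if (length(reads)) do.call(rbind, reads) else NULL,
    mismatches = if (length(mms)) do.call(rbind, mms) else empty_mm,
    unaligned = if (length(un)) do.call(rbind, un) else
      data.frame(read_id = character(0), reason = character(0)))
}

#' Extract mismatches of placed reads against the reference
#'
#' Base-wise comparison of each read (read orientation) with the
#' reference interval it is placed on.  Offsets are 1-based from the 5'
#' read end; `rel3` counts from the 3' end, `-1` being the last read
#' base.  The trinucleotide context is the reference 3-mer centred on the
#' mismatched base, in read-strand orientation (N-padded at contig
#' edges).  Adjacent C>T pairs with reference CC are additionally
#' collapsed into tandem records by [collapse_tandem()].
#'
#' @param reads placement data frame (`read_id`, `contig`, `start`,
#'   `end`, `strand`, `seq`).
#' @param genome a [Biostrings::DNAStringSet].
#' @return data frame `read_id`, `offset5`, `rel3`, `ref`, `alt`,
#'   `context`, `is_tandem` (all `FALSE` here; see [collapse_tandem()]).
#' @export
mismatch_table <- function(reads, genome) {
  empty <- data.frame(read_id = character(0), offset5 = integer(0),
                      rel3 = integer(0), ref = character(0),
                      alt = character(0), context = character(0),
                      is_tandem = logical(0), stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) return(empty)
  refs <- reference_spans(reads, genome, flank = 1L)
  out <- list()
  widths <- nchar(reads$seq)
  for (w in unique(widths)) {
    sel <- which(widths == w)
    rd <- seq_byte_matrix(reads$seq[sel])
    rf <- seq_byte_matrix(refs[sel])          # width w + 2 (1-nt flanks)
    core <- rf[, 2:(w + 1L), drop = FALSE]
    diff <- which(rd != core, arr.ind = TRUE)
    if (!nrow(diff)) next
    i <- diff[, 1L]; j <- diff[, 2L]
    ctx <- substr(refs[sel][i], j, j + 2L)  # ref 3-mer centred on base j
    out[[length(out) + 1L]] <- data.frame(
      read_id = reads$read_id[sel][i],
      offset5 = as.integer(j),
      rel3 = as.integer(j) - w - 1L,
      ref = rawToChar(core[diff], multiple = TRUE),
      alt = rawToChar(rd[diff], multiple = TRUE),
      context = ctx,
      is_tandem = FALSE,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  mm <- do.call(rbind, out)
  mm <- mm[order(match(mm$read_id, reads$read_id), mm$offset5), ]
  rownames(mm) <- NULL
  mm
}

#' Collapse adjacent CC>TT mismatch pairs into tandem records
#'
#' Two mismatches at consecutive read offsets, both C in the reference
#' and T in the read, are replaced by a single record with `ref = "CC"`,
#' `alt = "TT"`, `is_tandem = TRUE`, anchored at the 5' base of the pair.
#'
#' @param mm mismatch table from [mismatch_table()].
#' @return mismatch table with tandem rows collapsed.
#' @export
collapse_tandem <- function(mm) {
  if (nrow(mm) < 2L) return(mm)
  mm <- mm[order(mm$read_id, mm$offset5), , drop = FALSE]
  n <- nrow(mm)
  # row i can start a tandem pair with row i + 1
  can_pair <- c(
    mm$read_id[-n] == mm$read_id[-1L] &
      mm$offset5[-1L] == mm$offset5[-n] + 1L &
      mm$ref[-n] == "C" & mm$ref[-1L] == "C" &
      mm$alt[-n] == "T" & mm$alt[-1L] == "T",
    FALSE)
  # greedy left-to-right pairing within runs (a CCC>TTT chain pairs the
  # first two mismatches and leaves the third single)
  r <- rle(can_pair)
  run_start <- cumsum(r$lengths) - r$lengths + 1L
  first <- unlist(mapply(function(st, len, val) {
    if (val) seq.int(st, st + len - 1L, by = 2L) else integer(0)
  }, run_start, r$lengths, r$values, SIMPLIFY = FALSE), use.names = FALSE)
  if (length(first)) {
    mm$ref[first] <- "CC"
    mm$alt[first] <- "TT"
    mm$is_tandem[first] <- TRUE
    mm <- mm[-(first + 1L), , drop = FALSE]
  }
  rownames(mm) <- NULL
  mm
}

# Reference sequence spanning each read plus `flank` nt on either side,
# in read orientation, N-padded beyond contig ends.
reference_spans <- function(reads, genome, flank = 0L) {
  n <- nrow(reads)
  out <- character(n)
  for (ct in unique(reads$contig)) {
    sel <- which(reads$contig == ct)
    len <- length(genome[[ct]])
    s <- pmax(reads$start[sel] - flank, 1L)
    e <- pmin(reads$end[sel] + flank, len)
    ss <- as.character(Biostrings::extractAt(genome[[ct]],
                                             IRanges::IRanges(s, e)))
    padl <- pmax(flank - (reads$start[sel] - 1L), 0L)
    padr <- pmax(flank - (len - reads$end[sel]), 0L)
    ss <- paste0(strrep("N", padl), ss, strrep("N", padr))
    neg <- reads$strand[sel] == "-"
    if (any(neg)) ss[neg] <- revcomp(ss[neg])
    out[sel] <- ss
  }
  out
}

#' Strand-aware flanked read context
#'
#' Returns each read's sequence context expanded by `flank` genomic bases
#' on either side, in read orientation: for minus-strand reads the
#' reverse complement of the expanded interval, so the last `flank` bases
#' are always past the read's 3' end.  Positions beyond contig ends are
#' N-padded.  The *reference* sequence is used across the read body (the
#' context describes the genome, not the possibly deaminated read).
#'
#' @param reads placement data frame.
#' @param genome a [Biostrings::DNAStringSet].
#' @param flank flank width in nt.
#' @return character vector of width `length + 2 * flank`.
#' @export
extract_context <- function(reads, genome, flank = 10) {
  reference_spans(reads, genome, flank = as.integer(flank))
}
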