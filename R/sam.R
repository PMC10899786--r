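# Minimal SAM dialect: header (@HD/@SQ), one record per line with
# QNAME FLAG RNAME POS MAPQ CIGAR RNEXT PNEXT TLEN SEQ QUAL.
# Only the FLAG 0x10 strand bit is interpreted; CIGARs other than pure
# nM mark the record has_indel (unsupported ops are flagged, not parsed),
# and such reads are excluded by the basic filters downstream.

#' Import alignments from a SAM file
#'
#' Coordinates are converted to this package's 1-based closed intervals;
#' minus-strand records are re-expressed in read orientation (mismatch
#' offsets count from the read's 5' end).  Mismatches are extracted by
#' reference lookup, so `genome` must be the assembly the file was
#' aligned to.
#'
#' @param path SAM file path.
#' @param genome a [Biostrings::DNAStringSet].
#' @return list `reads` (placements with `n_mismatches`, `has_indel`,
#'   `has_N`), `mismatches` (for indel-free reads).
#' @export
import_sam <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(list(reads = NULL,
                mismatches = mismatch_table(
                  data.frame(read_id = character(0), contig = character(0),
                             start = integer(0), end = integer(0),
                             strand = character(0), seq = character(0)),
                  genome)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L)) stop("SAM record with fewer than 11 fields")
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  pos <- as.integer(vapply(f, `[[`, "", 4L))
  cigar <- vapply(f, `[[`, "", 6L)
  seq_plus <- vapply(f, `[[`, "", 10L)
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
  has_indel <- !grepl("^[0-9]+M$", cigar)
  width <- nchar(seq_plus)
  seq_read <- seq_plus
  neg <- strand == "-"
  if (any(neg)) seq_read[neg] <- revcomp(seq_plus[neg])
  reads <- data.frame(
    read_id = vapply(f, `[[`, "", 1L),
    contig = vapply(f, `[[`, "", 3L),
    start = pos, end = pos + width - 1L,
    strand = strand, seq = seq_read, length = width,
    has_indel = has_indel,
    has_N = grepl("N", seq_read, fixed = TRUE),
    stringsAsFactors = FALSE)
  ok <- !has_indel
  mm <- mismatch_table(reads[ok, , drop = FALSE], genome)
  nmm <- table(factor(mm$read_id, levels = reads$read_id))
  reads$n_mismatches <- as.integer(nmm[reads$read_id])
  reads$n_mismatches[has_indel] <- NA_integer_
  list(reads = reads, mismatches = mm)
}

#' Write placements as SAM
#'
#' @param reads placement data frame (`read_id`, `contig`, `start`,
#'   `end`, `strand`, `seq` in read orientation).
#' @param genome a [Biostrings::DNAStringSet] (for `@SQ` lines).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_sam <- function(reads, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                   vapply(seq_along(genome),
                          function(i) length(genome[[i]]), integer(1))))
  seq_plus <- reads$seq
  neg <- reads$strand == "-"
  if (any(neg)) seq_plus[neg] <- revcomp(reads$seq[neg])
  w <- nchar(reads$seq)
  rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s",
                 reads$read_id, ifelse(neg, 16L, 0L), reads$contig,
                 reads$start, w, seq_plus, strrep("I", w))
  writeLines(c(hdr, rec), path)
  invisible(path)
}
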