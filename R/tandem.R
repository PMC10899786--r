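# Revertant-sequence alignment of reads carrying tandem CC>TT
# deamination.  A seeded aligner that tolerates at most one mismatch
# drops these reads; restoring each TT to CC one at a time and asking
# which (if any) restored variant matches the genome exactly recovers
# them, with the tandem event located at the dinucleotide that
# distinguished the matching variant.

#' Enumerate revertant variants of a read
#'
#' Every occurrence of `from` (overlapping occurrences included: `"TTT"`
#' yields offsets 1 and 2) is replaced by `to` in turn.
#'
#' @param seq read sequence.
#' @param from,to dinucleotides; defaults reverse a tandem deamination
#'   (`TT` back to `CC`); `from = "GG", to = "AA"` gives the control
#'   mode.
#' @return data frame `offset` (1-based position of the replaced
#'   dinucleotide's 5' base), `variant`.
#' @export
enumerate_revertants <- function(seq, from = "TT", to = "CC") {
  if (nchar(seq) < 2L) stop("read must be at least 2 nt")
  hits <- gregexpr(paste0("(?=", from, ")"), seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) {
    return(data.frame(offset = integer(0), variant = character(0)))
  }
  variants <- vapply(hits, function(o) {
    v <- seq
    substr(v, o, o + 1L) <- to
    v
  }, character(1))
  data.frame(offset = as.integer(hits), variant = variants,
             stringsAsFactors = FALSE)
}

#' Adjudicate the revertants of one read
#'
#' A tandem call is issued iff (i) exactly one revertant variant has an
#' exact genomic occurrence, (ii) that variant occurs exactly once, and
#' (iii) the original read sequence has no exact occurrence.  Otherwise
#' the reason is one of `no_variant_hit`, `multi_variant_hit`,
#' `variant_multimapped`, `original_aligned`.  Occurrences are counted
#' over both strands.
#'
#' @param seq original read sequence.
#' @param index a [build_index()] object.
#' @param from,to as in [enumerate_revertants()].
#' @param id read identifier.
#' @return list with `called` (logical) and either `call` (one-row data
#'   frame: placement, `offset`, `lesion_halfbase`) or `reason`.
#' @export
adjudicate <- function(seq, index, from = "TT", to = "CC", id = "read") {
  if (count_query(index, seq) > 0L) {
    return(list(called = FALSE, reason = "original_aligned"))
  }
  rev <- enumerate_revertants(seq, from, to)
  if (!nrow(rev)) return(list(called = FALSE, reason = "no_variant_hit"))
  hits <- lapply(rev$variant, locate_query, index = index,
                 max_mismatches = 0)
  nhit <- vapply(hits, nrow, integer(1))
  if (sum(nhit > 0L) == 0L) {
    return(list(called = FALSE, reason = "no_variant_hit"))
  }
  if (sum(nhit > 0L) > 1L) {
    return(list(called = FALSE, reason = "multi_variant_hit"))
  }
  which_v <- which(nhit > 0L)
  if (nhit[which_v] > 1L) {
    return(list(called = FALSE, reason = "variant_multimapped"))
  }
  h <- hits[[which_v]]
  call <- data.frame(read_id = id, contig = h$contig, start = h$start,
                     end = h$end, strand = h$strand, seq = seq,
                     length = nchar(seq),
                     offset = rev$offset[which_v],
                     lesion_halfbase = rev$offset[which_v] + 0.5,
                     stringsAsFactors = FALSE)
  list(called = TRUE, call = call)
}

#' Tandem deamination calling pipeline
#'
#' Runs [adjudicate()] over candidate reads (typically those that failed
#' single-mismatch alignment or carry two mismatches), then subjects the
#' calls to the same read-length and 3'-TGG-flank constraints as the
#' single-mismatch channel, and emits incision records with half-integer
#' cut-site distances (`d5 + d3 = L + 1`).
#'
#' @param seqs character vector of candidate read sequences.
#' @param index a [build_index()] object.
#' @param genome a [Biostrings::DNAStringSet] (for the TGG filter); the
#'   index's genome by default.
#' @param length_range optional `c(Lmin, Lmax)` filter on read length.
#' @param motif 3' flank motif for the mispriming filter.
#' @param from,to dinucleotide mode (control modes supported).
#' @param ids read identifiers.
#' @return list `calls` (placements with `offset`, `lesion_halfbase`),
#'   `records` (incision records, see [incision_records()]),
#'   `rejections` (data frame `read_id`, `reason`).
#' @export
tandem_pipeline <- function(seqs, index, genome = index$genome,
                            length_range = NULL, motif = "TGG",
                            from = "TT", to = "CC", ids = NULL) {
  if (is.null(ids)) ids <- sprintf("tandem%06d", seq_along(seqs))
  calls <- list(); rej <- list()
  for (i in seq_along(seqs)) {
    a <- adjudicate(seqs[i], index, from = from, to = to, id = ids[i])
    if (a$called) {
      calls[[length(calls) + 1L]] <- a$call
    } else {
      rej[[length(rej) + 1L]] <- data.frame(read_id = ids[i],
                                            reason = a$reason)
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else NULL
  rejections <- if (length(rej)) do.call(rbind, rej) else
    data.frame(read_id = character(0), reason = character(0))
  if (!is.null(calls) && !is.null(length_range)) {
    drop <- calls$length < length_range[1] | calls$length > length_range[2]
    if (any(drop)) {
      rejections <- rbind(rejections,
                          data.frame(read_id = calls$read_id[drop],
                                     reason = "length_range"))
      calls <- calls[!drop, , drop = FALSE]
    }
  }
  if (!is.null(calls) && nrow(calls) && !is.null(motif)) {
    tf <- tgg_filter(calls, genome, motif = motif)
    if (nrow(tf$removed)) {
      rejections <- rbind(rejections,
                          data.frame(read_id = tf$removed$read_id,
                                     reason = "tgg_flank"))
    }
    calls <- tf$kept
  }
  records <- if (!is.null(calls) && nrow(calls)) {
    data.frame(read_id = calls$read_id, kind = "tandem_CCTT",
               d5 = calls$offset + 0.5,
               d3 = calls$length - calls$offset + 0.5,
               L = calls$length,
               contig = calls$contig,
               lesion_pos = lesion_genomic_position(calls),
               strand = calls$strand,
               stringsAsFactors = FALSE)
  } else NULL
  list(calls = calls, records = records, rejections = rejections)
}

# genomic coordinate of the lesion anchor for tandem calls: the 3'-in-
# read-orientation base of the CC pair (integer bookkeeping for the
# nucleosome profile; the half-base sits between the pair).
lesion_genomic_position <- function(calls) {
  off3 <- calls$offset + 1L                    # 3' base of the pair
  ifelse(calls$strand == "+",
         calls$start + off3 - 1L,
         calls$end - off3 + 1L)
}
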