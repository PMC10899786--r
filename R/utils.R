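# Small shared helpers.  Read coordinates throughout the package are
# 1-based and intervals are closed ([start, end]), following the
# IRanges/GRanges convention; BED input/output converts at the boundary.

PYRIMIDINES <- c("C", "T")
BASES <- c("A", "C", "G", "T")

#' Stochastic (unbiased) rounding
#'
#' Rounds `x` to an integer such that `E[round] = x` exactly:
#' `floor(x + U)` with `U ~ Uniform(0, 1)`.  Used when the simulator
#' compensates the 3' cut-site distance for the 5' draw, so that the
#' configured coupling equals the regression slope in expectation.
#' Integers are returned unchanged.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
#' @noRd
rand_round <- function(x) {
  floor(x + stats::runif(length(x)))
}

#' Reverse complement of character sequences
#' @param x character vector of DNA sequences (may contain N).
#' @return character vector.
#' @keywords internal
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Draw n values from a categorical distribution given as a named numeric
# vector of probabilities (names coerced to numeric when values = NULL).
sample_categorical <- function(n, dist) {
  vals <- as.numeric(names(dist))
  if (anyNA(vals)) stop("categorical distribution must have numeric names")
  vals[sample.int(length(vals), n, replace = TRUE, prob = dist)]
}

categorical_mean <- function(dist) {
  vals <- as.numeric(names(dist))
  sum(vals * dist / sum(dist))
}

stopifnot_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", what))
  }
}

# Split character sequences of equal width into a byte matrix
# (n_seqs x width); the workhorse for vectorised per-position operations.
seq_byte_matrix <- function(seqs) {
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("sequences must have equal width")
  matrix(unlist(lapply(seqs, charToRaw), use.names = FALSE),
         ncol = w, byrow = TRUE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
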