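# Shared low-level helpers. All genomic intervals inside the package are
# 0-based half-open [start, end); conversion to/from 1-based inclusive happens
# only at the file-format boundary (GFF3, SAM, BED handled by rtracklayer).

PHRED_OFFSET <- 33L

#' Convert a Phred+33 quality string to integer scores
#' @param qual character vector of quality strings
#' @return list of integer vectors, one per input string
#' @keywords internal
phred_ints <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - PHRED_OFFSET)
}

#' @keywords internal
phred_string <- function(scores) {
  vapply(scores, function(s) intToUtf8(pmin(s, 93L) + PHRED_OFFSET), "")
}

#' Reverse-complement a character vector of DNA sequences
#' @keywords internal
revcomp_chr <- function(x) {
  out <- character(length(x))
  nz <- nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out
}

#' Random DNA sequence of given length
#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Hamming distance between equal-length strings, vectorised over pairs
#' @keywords internal
count_mismatches <- function(a, b) {
  stopifnot(length(a) == length(b))
  vapply(seq_along(a), function(i) {
    ra <- charToRaw(a[[i]])
    rb <- charToRaw(b[[i]])
    if (length(ra) != length(rb)) {
      stop("count_mismatches: sequences of unequal length", call. = FALSE)
    }
    sum(ra != rb)
  }, integer(1))
}

# Seed handling: every stochastic entry point takes `seed`; NULL leaves the
# RNG stream untouched so callers can manage it themselves.
#' @keywords internal
set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x
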