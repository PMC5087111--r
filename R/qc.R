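#' Quality-processing parameters
#'
#' Reads are truncated at the first base whose Phred score falls below
#' `phred_floor`, and a pair is removed when either truncated mate is shorter
#' than `min_read_len`.
#'
#' @param phred_floor minimum Phred score; truncation happens strictly before
#'   the first base below it (default 20)
#' @param min_read_len minimum post-truncation mate length to keep a pair
#'   (default 16)
#' @return list of class `sagscope_qc_params`
#' @export
qc_params <- function(phred_floor = 20L, min_read_len = 16L) {
  stopifnot(phred_floor >= 0, min_read_len >= 1)
  structure(list(phred_floor = as.integer(phred_floor),
                 min_read_len = as.integer(min_read_len)),
            class = "sagscope_qc_params")
}

#' Truncate reads at the first low-quality base
#'
#' Returns the prefix strictly before the first base with Phred <
#' `phred_floor`; a first base below the floor yields an empty read. The
#' operation is idempotent.
#'
#' @param seq,qual character vectors of equal-length sequence and Phred+33
#'   quality strings
#' @param phred_floor integer Phred floor
#' @return list with truncated `seq` and `qual` character vectors
#' @export
quality_truncate <- function(seq, qual, phred_floor = 20L) {
  stopifnot(length(seq) == length(qual))
  if (any(nchar(seq) != nchar(qual))) {
    stop("sequence and quality strings differ in length")
  }
  cut <- vapply(qual, function(q) {
    if (!nzchar(q)) return(0L)
    s <- utf8ToInt(q) - PHRED_OFFSET
    bad <- which(s < phred_floor)
    if (length(bad)) bad[1L] - 1L else length(s)
  }, integer(1), USE.NAMES = FALSE)
  list(seq = substring(seq, 1L, cut), qual = substring(qual, 1L, cut))
}

#' Quality-process read pairs: truncation plus short-pair removal
#'
#' Applies [quality_truncate()] to both mates, then removes pairs in which
#' either mate ended up shorter than `min_read_len`, recording the removal.
#'
#' @param pairs pair tibble from [read_pairs()] (or the `fragments` table of a
#'   simulation)
#' @param qc a [qc_params()]
#' @return list with `pairs` (kept, truncated) and `removed` (tibble:
#'   fragment_id, mate1_len, mate2_len, reason)
#' @export
qc_pairs <- function(pairs, qc = qc_params()) {
  t1 <- quality_truncate(pairs$mate1_seq, pairs$mate1_qual, qc$phred_floor)
  t2 <- quality_truncate(pairs$mate2_seq, pairs$mate2_qual, qc$phred_floor)
  out <- pairs
  out$mate1_seq <- t1$seq; out$mate1_qual <- t1$qual
  out$mate2_seq <- t2$seq; out$mate2_qual <- t2$qual
  short <- nchar(out$mate1_seq) < qc$min_read_len |
    nchar(out$mate2_seq) < qc$min_read_len
  removed <- tibble::tibble(
    fragment_id = out$fragment_id[short],
    mate1_len = nchar(out$mate1_seq[short]),
    mate2_len = nchar(out$mate2_seq[short]),
    reason = rep("short_read", sum(short))
  )
  list(pairs = out[!short, , drop = FALSE], removed = removed)
}
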