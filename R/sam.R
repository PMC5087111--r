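#' Write uniquely assigned pairs as SAM
#'
#' Emits a valid SAM file (header with @HD/@SQ lines, one record per mate)
#' for the uniquely placed pairs of an assignment table. Flags carry
#' paired/proper-pair/strand/first-last information; TLEN is signed per the
#' SAM convention (positive on the leftmost mate). Alignments are ungapped,
#' so CIGAR is always `<len>M`. Mate sequences/qualities are included when
#' the originating pair table is supplied, otherwise `*`.
#'
#' @param assignments assignment tibble from [assign_pairs()]
#' @param refset a [refset()]
#' @param path output path
#' @param pairs optional pair tibble to source SEQ/QUAL from
#' @return invisible `path`
#' @export
write_sam <- function(assignments, refset, path, pairs = NULL) {
  info <- refset$contig_info
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", info$contig_id, info$length),
    "@PG\tID:sagscope\tPN:sagscope"
  )
  u <- assignments[assignments$status == "unique", , drop = FALSE]
  recs <- character(0)
  if (nrow(u) > 0) {
    if (!is.null(pairs)) {
      m <- match(u$fragment_id, pairs$fragment_id)
      s1 <- pairs$mate1_seq[m]; q1 <- pairs$mate1_qual[m]
      s2 <- pairs$mate2_seq[m]; q2 <- pairs$mate2_qual[m]
      # SAM stores reverse-strand reads as their forward-strand image
      rev1 <- u$strand == "-"
      s1[rev1] <- revcomp_chr(s1[rev1])
      q1[rev1] <- vapply(strsplit(q1[rev1], ""), function(x)
        paste(rev(x), collapse = ""), "")
      rev2 <- u$strand == "+"
      s2[rev2] <- revcomp_chr(s2[rev2])
      q2[rev2] <- vapply(strsplit(q2[rev2], ""), function(x)
        paste(rev(x), collapse = ""), "")
    } else {
      s1 <- s2 <- q1 <- q2 <- rep("*", nrow(u))
    }
    l1 <- u$m1_end - u$m1_start
    l2 <- u$m2_end - u$m2_start
    m1_left <- u$m1_start <= u$m2_start
    tlen1 <- ifelse(m1_left, u$frag_len, -u$frag_len)
    flag1 <- 1L + 2L + 64L + ifelse(u$strand == "-", 16L, 0L) +
      ifelse(u$strand == "+", 32L, 0L)
    flag2 <- 1L + 2L + 128L + ifelse(u$strand == "+", 16L, 0L) +
      ifelse(u$strand == "-", 32L, 0L)
    rec <- function(flag, pos, cig_len, mpos, tlen, seq, qual) {
      sprintf("%s\t%d\t%s\t%d\t255\t%dM\t=\t%d\t%d\t%s\t%s\tNM:i:%d",
              u$fragment_id, flag, u$contig_id, pos, cig_len, mpos, tlen,
              seq, qual, u$n_mismatch)
    }
    recs <- c(rec(flag1, u$m1_start + 1L, l1, u$m2_start + 1L, tlen1, s1, q1),
              rec(flag2, u$m2_start + 1L, l2, u$m1_start + 1L, -tlen1, s2, q2))
  }
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Import externally mapped read pairs from SAM into an assignment table
#'
#' Reads a SAM file (e.g. from an external mapper) via Rsamtools and
#' reconstructs the pair-assignment layout used throughout the package.
#' Primary, properly paired records are treated as unique placements;
#' reference span is derived from the CIGAR (M/D/N/=/X operations).
#'
#' @param path SAM file path
#' @param refset a [refset()] supplying the contig-to-genome map
#' @return assignment tibble in the [assign_pairs()] layout (mapped pairs
#'   only)
#' @export
read_sam_assignments <- function(path, refset) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("Rsamtools is required to import SAM files")
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"),
    flag = Rsamtools::scanBamFlag(isPaired = TRUE, isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE)
  )
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  if (length(b$qname) == 0) return(empty_assignment_table(character(0)))
  span <- cigar_ref_span(b$cigar)
  first <- bitwAnd(b$flag, 64L) != 0L
  rev <- bitwAnd(b$flag, 16L) != 0L
  d <- data.table::data.table(
    fragment_id = b$qname, first = first,
    contig_id = as.character(b$rname),
    start = b$pos - 1L, end = b$pos - 1L + span,
    strand = ifelse(rev, "-", "+")
  )
  m1 <- d[first == TRUE][!duplicated(fragment_id)]
  m2 <- d[first == FALSE][!duplicated(fragment_id)]
  both <- merge(m1, m2, by = "fragment_id", suffixes = c("_1", "_2"))
  gmap <- stats::setNames(refset$contig_info$genome_id,
                          refset$contig_info$contig_id)
  tibble::tibble(
    fragment_id = both$fragment_id,
    status = rep("unique", nrow(both)),
    genome_id = unname(gmap[both$contig_id_1]),
    contig_id = both$contig_id_1,
    m1_start = both$start_1, m1_end = both$end_1,
    m2_start = both$start_2, m2_end = both$end_2,
    strand = both$strand_1,
    n_mismatch = rep(NA_integer_, nrow(both)),
    frag_len = pmax(both$end_1, both$end_2) - pmin(both$start_1, both$start_2)
  )
}

# Reference-space width of simple CIGAR strings (sums M/D/N/=/X lengths).
#' @keywords internal
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    sum(vapply(toks, function(t) {
      op <- substring(t, nchar(t))
      n <- as.integer(substring(t, 1, nchar(t) - 1L))
      if (op %in% c("M", "D", "N", "=", "X")) n else 0L
    }, integer(1)))
  }, integer(1), USE.NAMES = FALSE)
}
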