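#' Count uniquely assigned fragments per CDS (union mode, non-stranded)
#'
#' Implements union-mode fragment counting: the feature set of a pair is the
#' union, over both aligned mates, of all CDS overlapping the mate interval
#' by at least one base (the unsequenced inner gap of the fragment does not
#' contribute). Exactly one feature increments that CDS; none increments
#' `__no_feature`; more than one increments `__ambiguous`. Non-unique pairs
#' (`multi`) go to `__not_unique`, out-of-bounds pairs to `__out_of_bounds`,
#' unmapped pairs to `__not_aligned`, QC-removed pairs to `__qc_removed`, so
#' per-CDS counts plus class tallies always equal the number of input pairs.
#'
#' @param assignments assignment tibble (any statuses)
#' @param cds CDS tibble (as in a [refset()]); ids must be unique
#' @param stranded if `TRUE`, a mate only overlaps CDS on the fragment's
#'   transcript strand; default `FALSE` (non-strand-specific libraries)
#' @return object of class `sagscope_counts`: list with `counts` (tibble:
#'   cds_id, genome_id, length_bp, count), `tallies` (named integer vector),
#'   `n_pairs`
#' @export
count_fragments <- function(assignments, cds, stranded = FALSE) {
  if (anyDuplicated(cds$cds_id)) stop("CDS id collision in feature table")
  n_pairs <- nrow(assignments)
  u <- assignments[assignments$status == "unique", , drop = FALSE]
  tall <- c(
    no_feature = 0L, ambiguous = 0L,
    not_unique = sum(assignments$status == "multi"),
    out_of_bounds = sum(assignments$status == "frag_out_of_bounds"),
    not_aligned = sum(assignments$status == "unmapped"),
    qc_removed = sum(assignments$status == "qc_removed")
  )
  counts <- tibble::tibble(cds_id = cds$cds_id, genome_id = cds$genome_id,
                           length_bp = cds$length_bp,
                           count = integer(nrow(cds)))
  if (nrow(u) > 0 && nrow(cds) > 0) {
    feats <- GenomicRanges::GRanges(
      seqnames = cds$contig_id,
      ranges = IRanges::IRanges(start = cds$start + 1L, end = cds$end),
      strand = cds$strand
    )
    mates <- GenomicRanges::GRanges(
      seqnames = c(u$contig_id, u$contig_id),
      ranges = IRanges::IRanges(
        start = c(u$m1_start, u$m2_start) + 1L,
        end = c(u$m1_end, u$m2_end)
      ),
      strand = rep(u$strand, 2L)  # transcript strand = strand of mate 1
    )
    ov <- GenomicRanges::findOverlaps(mates, feats,
                                      ignore.strand = !stranded,
                                      minoverlap = 1L)
    pair_of_mate <- rep(seq_len(nrow(u)), 2L)
    hits <- unique(data.table::data.table(
      pair = pair_of_mate[S4Vectors::queryHits(ov)],
      feat = S4Vectors::subjectHits(ov)
    ))
    nf <- hits[, .N, by = pair]
    single <- nf[N == 1L, pair]
    tall[["ambiguous"]] <- nrow(nf[N > 1L])
    tall[["no_feature"]] <- nrow(u) - nrow(nf)
    if (length(single)) {
      fidx <- hits[pair %in% single, feat]
      tb <- tabulate(fidx, nbins = nrow(cds))
      counts$count <- as.integer(tb)
    }
  } else {
    tall[["no_feature"]] <- nrow(u)
  }
  structure(list(counts = counts, tallies = tall, n_pairs = n_pairs),
            class = "sagscope_counts")
}

#' @export
print.sagscope_counts <- function(x, ...) {
  cat(sprintf("<sagscope_counts> %d CDS, %d pairs, %d assigned\n",
              nrow(x$counts), x$n_pairs, sum(x$counts$count)))
  print(x$tallies)
  invisible(x)
}

#' Brute-force union-mode counting oracle
#'
#' Independent reference implementation: loops over every pair and every CDS
#' with manual interval-overlap arithmetic. For validating
#' [count_fragments()] on small fixtures.
#' @inheritParams count_fragments
#' @return a `sagscope_counts`
#' @export
count_oracle <- function(assignments, cds, stranded = FALSE) {
  tall <- c(no_feature = 0L, ambiguous = 0L, not_unique = 0L,
            out_of_bounds = 0L, not_aligned = 0L, qc_removed = 0L)
  cnt <- stats::setNames(integer(nrow(cds)), cds$cds_id)
  for (i in seq_len(nrow(assignments))) {
    st <- assignments$status[i]
    if (st != "unique") {
      key <- switch(st, multi = "not_unique",
                    frag_out_of_bounds = "out_of_bounds",
                    unmapped = "not_aligned", qc_removed = "qc_removed")
      tall[[key]] <- tall[[key]] + 1L
      next
    }
    feat <- character(0)
    for (j in seq_len(nrow(cds))) {
      if (cds$contig_id[j] != assignments$contig_id[i]) next
      if (stranded && cds$strand[j] != assignments$strand[i]) next
      ov1 <- min(cds$end[j], assignments$m1_end[i]) -
        max(cds$start[j], assignments$m1_start[i])
      ov2 <- min(cds$end[j], assignments$m2_end[i]) -
        max(cds$start[j], assignments$m2_start[i])
      if (ov1 > 0 || ov2 > 0) feat <- c(feat, cds$cds_id[j])
    }
    if (length(feat) == 0) {
      tall[["no_feature"]] <- tall[["no_feature"]] + 1L
    } else if (length(feat) > 1) {
      tall[["ambiguous"]] <- tall[["ambiguous"]] + 1L
    } else {
      cnt[[feat]] <- cnt[[feat]] + 1L
    }
  }
  counts <- tibble::tibble(cds_id = cds$cds_id, genome_id = cds$genome_id,
                           length_bp = cds$length_bp,
                           count = unname(cnt))
  structure(list(counts = counts, tallies = tall,
                 n_pairs = nrow(assignments)),
            class = "sagscope_counts")
}

#' Fraction of a genome's CDS represented by at least one fragment
#'
#' @param counts a `sagscope_counts`
#' @param genome_id restrict the denominator to one genome's CDS (default:
#'   all CDS in the table)
#' @return fraction in `[0, 1]`
#' @export
representation_fraction <- function(counts, genome_id = NULL) {
  tab <- counts$counts
  if (!is.null(genome_id)) tab <- tab[tab$genome_id %in% genome_id, ]
  if (nrow(tab) == 0) stop("no CDS in the requested denominator")
  mean(tab$count >= 1L)
}

#' Write/read a count table in the htseq-count TSV dialect
#'
#' Two tab-separated columns (cds_id, count), followed by the class tallies
#' with reserved `__`-prefixed ids.
#' @param counts a `sagscope_counts`
#' @param path output path
#' @return invisible `path`
#' @export
write_counts <- function(counts, path) {
  lines <- c(
    sprintf("%s\t%d", counts$counts$cds_id, counts$counts$count),
    sprintf("__%s\t%d", names(counts$tallies), counts$tallies)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_counts
#' @param cds optional CDS tibble to re-attach genome ids and lengths
#' @return for `read_counts`, a `sagscope_counts`
#' @export
read_counts <- function(path, cds = NULL) {
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                         col.names = c("cds_id", "count"))
  is_tally <- startsWith(d$cds_id, "__")
  tall <- stats::setNames(as.integer(d$count[is_tally]),
                          sub("^__", "", d$cds_id[is_tally]))
  tab <- d[!is_tally, , drop = FALSE]
  counts <- tibble::tibble(
    cds_id = tab$cds_id,
    genome_id = NA_character_, length_bp = NA_integer_,
    count = as.integer(tab$count)
  )
  if (!is.null(cds)) {
    m <- match(counts$cds_id, cds$cds_id)
    counts$genome_id <- cds$genome_id[m]
    counts$length_bp <- cds$length_bp[m]
  }
  structure(list(counts = counts, tallies = tall,
                 n_pairs = sum(counts$count) + sum(tall)),
            class = "sagscope_counts")
}
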