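#' Per-base coverage track from unique pair placements
#'
#' Each aligned mate interval contributes 1 to every base it covers
#' (read-based coverage: the unsequenced inner fragment gap stays uncovered,
#' and overlapping mates of one pair count twice, matching genome-browser
#' read pileups). A fragment-span mode covering the whole outer interval
#' once per pair is available behind `mode = "fragment"`.
#'
#' @param assignments assignment tibble; only `unique` rows are used
#' @param contig_id contig to compute coverage for
#' @param contig_length contig length in bp
#' @param mode `"read"` (default) or `"fragment"`
#' @return object of class `sagscope_coverage`: list with `contig_id` and
#'   `coverage` (integer vector of length `contig_length`; position i is
#'   base i-1 in 0-based coordinates)
#' @export
coverage_track <- function(assignments, contig_id, contig_length,
                           mode = c("read", "fragment")) {
  mode <- match.arg(mode)
  u <- assignments[assignments$status == "unique" &
                     assignments$contig_id == contig_id, , drop = FALSE]
  if (mode == "read") {
    starts <- c(u$m1_start, u$m2_start)
    ends <- c(u$m1_end, u$m2_end)
  } else {
    starts <- pmin(u$m1_start, u$m2_start)
    ends <- pmax(u$m1_end, u$m2_end)
  }
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) && (min(starts) < 0 || max(ends) > contig_length)) {
    stop("aligned interval outside the contig")
  }
  cov <- as.integer(IRanges::coverage(
    IRanges::IRanges(start = starts + 1L, end = ends),
    width = contig_length
  ))
  structure(list(contig_id = contig_id, coverage = cov),
            class = "sagscope_coverage")
}

#' Maximal zero-coverage intervals of a track
#'
#' @param track a `sagscope_coverage` (or bare integer vector)
#' @param min_depth bases with coverage below this count as uncovered
#'   (default 1, the literal zero-coverage reading)
#' @return tibble of maximal, disjoint, sorted 0-based half-open intervals
#'   `start`, `end` whose union is exactly the uncovered bases
#' @export
zero_runs <- function(track, min_depth = 1L) {
  cov <- if (inherits(track, "sagscope_coverage")) track$coverage else track
  if (length(cov) == 0) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  r <- rle(cov < min_depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  tibble::tibble(start = starts[r$values], end = ends[r$values])
}

#' Call candidate polycistrons from coverage and CDS layout
#'
#' Scans the CDS of one contig in genomic order and merges consecutive CDS
#' into one call when (a) they lie on the same strand (when
#' `same_strand_required`) and (b) no base strictly between them is
#' uncovered (coverage below `min_depth`). CDS without a single covered base
#' are excluded from calls entirely; every covered CDS belongs to exactly
#' one call. For each call, flags report whether an uncovered base exists
#' within `flank_window` bases outside the call span on either side
#' (evidence of transcript boundaries, not a requirement; `NA` when the call
#' touches the contig edge).
#'
#' @param track a `sagscope_coverage` for the contig
#' @param cds CDS tibble rows of that contig, sorted by `start` (input error
#'   otherwise)
#' @param same_strand_required merge only same-strand neighbours (default
#'   TRUE, operon biology)
#' @param min_depth coverage threshold defining "covered" (default 1)
#' @param flank_window width in bp of the flank inspected for uncovered
#'   bases (default 100)
#' @return tibble of calls: `call_id`, `members` (comma-joined cds ids in
#'   genomic order), `n_members`, `start`, `end` (span, 0-based half-open),
#'   `strand`, `left_flank_zero`, `right_flank_zero`
#' @export
call_polycistrons <- function(track, cds, same_strand_required = TRUE,
                              min_depth = 1L, flank_window = 100L) {
  cov <- track$coverage
  if (nrow(cds) == 0) return(empty_call_table())
  if (any(cds$contig_id != track$contig_id)) {
    stop("CDS rows do not all belong to the track's contig")
  }
  if (is.unsorted(cds$start, strictly = FALSE)) {
    stop("CDS must be sorted by start position")
  }
  covered_base <- cov >= min_depth
  has_cov <- vapply(seq_len(nrow(cds)), function(i) {
    any(covered_base[(cds$start[i] + 1L):cds$end[i]])
  }, logical(1))
  cds <- cds[has_cov, , drop = FALSE]
  if (nrow(cds) == 0) return(empty_call_table())

  # group consecutive CDS whose gaps are fully covered
  grp <- integer(nrow(cds))
  grp[1] <- 1L
  for (i in seq_len(nrow(cds))[-1]) {
    gap_ok <- gap_fully_covered(covered_base, cds$end[i - 1], cds$start[i])
    strand_ok <- !same_strand_required || cds$strand[i] == cds$strand[i - 1]
    grp[i] <- if (gap_ok && strand_ok) grp[i - 1] else grp[i - 1] + 1L
  }
  calls <- lapply(split(seq_len(nrow(cds)), grp), function(ix) {
    span_start <- cds$start[ix[1]]
    span_end <- cds$end[ix[length(ix)]]
    lw <- max(0L, span_start - flank_window)
    left <- if (span_start == 0L) NA else
      any(!covered_base[(lw + 1L):span_start])
    rw <- min(length(cov), span_end + flank_window)
    right <- if (span_end == length(cov)) NA else
      any(!covered_base[(span_end + 1L):rw])
    tibble::tibble(
      members = paste(cds$cds_id[ix], collapse = ","),
      n_members = length(ix),
      start = span_start, end = span_end,
      strand = if (length(unique(cds$strand[ix])) == 1)
        cds$strand[ix[1]] else "*",
      left_flank_zero = left, right_flank_zero = right
    )
  })
  out <- dplyr::bind_rows(calls)
  out <- dplyr::bind_cols(
    tibble::tibble(call_id = sprintf("%s_pc%02d", track$contig_id,
                                     seq_len(nrow(out)))),
    out
  )
  out
}

# TRUE when every base strictly between prev_end and next_start is covered
# (empty/negative gaps, i.e. adjacent or overlapping CDS, are trivially OK).
#' @keywords internal
gap_fully_covered <- function(covered_base, prev_end, next_start) {
  if (next_start <= prev_end) return(TRUE)
  all(covered_base[(prev_end + 1L):next_start])
}

#' @keywords internal
empty_call_table <- function() {
  tibble::tibble(call_id = character(), members = character(),
                 n_members = integer(), start = integer(), end = integer(),
                 strand = character(), left_flank_zero = logical(),
                 right_flank_zero = logical())
}

#' Exhaustive gap-scan polycistron oracle
#'
#' Independent reference implementation of [call_polycistrons()]: for every
#' pair of consecutive covered CDS it scans the intergenic bases one by one.
#' @inheritParams call_polycistrons
#' @return tibble in the [call_polycistrons()] layout minus flank flags
#' @export
polycistron_oracle <- function(track, cds, same_strand_required = TRUE,
                               min_depth = 1L) {
  cov <- track$coverage
  keep <- logical(nrow(cds))
  for (i in seq_len(nrow(cds))) {
    keep[i] <- FALSE
    for (p in (cds$start[i] + 1L):cds$end[i]) {
      if (cov[p] >= min_depth) { keep[i] <- TRUE; break }
    }
  }
  cds <- cds[keep, , drop = FALSE]
  if (nrow(cds) == 0) return(empty_call_table()[, 2:6])
  runs <- list(c(1L))
  for (i in seq_len(nrow(cds))[-1]) {
    merged <- TRUE
    if (same_strand_required && cds$strand[i] != cds$strand[i - 1]) {
      merged <- FALSE
    }
    if (merged && cds$start[i] > cds$end[i - 1]) {
      for (p in (cds$end[i - 1] + 1L):cds$start[i]) {
        if (cov[p] < min_depth) { merged <- FALSE; break }
      }
    }
    if (merged) {
      runs[[length(runs)]] <- c(runs[[length(runs)]], i)
    } else {
      runs[[length(runs) + 1L]] <- i
    }
  }
  dplyr::bind_rows(lapply(runs, function(ix) tibble::tibble(
    members = paste(cds$cds_id[ix], collapse = ","),
    n_members = length(ix),
    start = cds$start[ix[1]], end = cds$end[ix[length(ix)]],
    strand = if (length(unique(cds$strand[ix])) == 1)
      cds$strand[ix[1]] else "*"
  )))
}

#' Export a coverage track as bedGraph
#' @param track a `sagscope_coverage`
#' @param path output path
#' @return invisible `path`
#' @export
export_bedgraph <- function(track, path) {
  r <- rle(track$coverage)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  gr <- GenomicRanges::GRanges(
    seqnames = track$contig_id,
    ranges = IRanges::IRanges(start = starts + 1L, end = ends),
    score = r$values
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Export polycistron calls as BED
#'
#' One record per call (0-based half-open on disk), member CDS ids joined in
#' the name field.
#' @param calls tibble from [call_polycistrons()]
#' @param contig_id contig the calls belong to
#' @param path output path
#' @return invisible `path`
#' @export
export_calls_bed <- function(calls, contig_id, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = rep(contig_id, nrow(calls)),
    ranges = IRanges::IRanges(start = calls$start + 1L, end = calls$end),
    strand = ifelse(calls$strand == "*", "*", calls$strand)
  )
  gr$name <- calls$members
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
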