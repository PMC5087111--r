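#' Per-CDS FPKM from a count table
#'
#' FPKM (fragments per kilobase of CDS per million assigned fragments):
#' `FPKM_g = count_g / ((length_g/1e3) * (N/1e6))`, where `N` is the total
#' number of fragments assigned to the target genome's CDS in this replicate
#' (not the whole metatranscriptome). All FPKM are 0 when `N = 0`. The
#' conservation identity `sum(FPKM_g * length_g/1e3) = 1e6` holds whenever
#' `N > 0`.
#'
#' @param counts a `sagscope_counts`
#' @param genome_id genome whose CDS form the FPKM universe (default: all
#'   CDS in the table, treated as one genome)
#' @return tibble: cds_id, genome_id, length_bp, count, fpkm
#' @export
compute_fpkm <- function(counts, genome_id = NULL) {
  tab <- counts$counts
  if (!is.null(genome_id)) tab <- tab[tab$genome_id %in% genome_id, ]
  if (any(is.na(tab$length_bp)) || any(tab$length_bp <= 0)) {
    stop("missing or non-positive CDS length for a counted CDS")
  }
  n_total <- sum(tab$count)
  tab$fpkm <- if (n_total == 0) 0 else
    tab$count / ((tab$length_bp / 1e3) * (n_total / 1e6))
  tab
}

#' Housekeeping baseline FPKM
#'
#' Arithmetic mean of (replicate-averaged) FPKM over the housekeeping CDS.
#' @param fpkm named numeric vector of mean FPKM (names = cds_id)
#' @param housekeeping_ids non-empty character vector of housekeeping CDS ids
#' @return scalar baseline FPKM
#' @export
hk_baseline <- function(fpkm, housekeeping_ids) {
  if (length(housekeeping_ids) == 0) stop("empty housekeeping set")
  miss <- setdiff(housekeeping_ids, names(fpkm))
  if (length(miss)) {
    stop("housekeeping ids absent from the FPKM table: ",
         paste(utils::head(miss, 3), collapse = ", "))
  }
  mean(fpkm[housekeeping_ids])
}

#' Classify highly expressed CDS against the housekeeping baseline
#'
#' A CDS is highly expressed iff its mean FPKM strictly exceeds the
#' housekeeping baseline (fold over baseline, FPKM_HK, > 1); a gene sitting
#' exactly at the baseline is excluded.
#' @param fpkm named numeric vector of mean FPKM
#' @param baseline housekeeping baseline from [hk_baseline()]
#' @return list with `high_ids` (character), `fold_hk` (named numeric),
#'   `n_high`
#' @export
classify_high_expression <- function(fpkm, baseline) {
  stopifnot(baseline > 0)
  fold <- fpkm / baseline
  high <- names(fpkm)[fold > 1]
  list(high_ids = high, fold_hk = fold, n_high = length(high))
}

#' Annotation proportions inside and outside the highly expressed set
#'
#' @param high_ids character vector of highly expressed CDS ids
#' @param cds CDS tibble with `annotated` flags (restricted by the caller to
#'   the genome of interest)
#' @return list: `prop_high`, `prop_rest` (proportions annotated; `NA` with
#'   `undefined = TRUE` when a denominator is empty)
#' @export
annotation_contrast <- function(high_ids, cds) {
  if (any(is.na(cds$annotated))) stop("annotation flags missing")
  in_high <- cds$cds_id %in% high_ids
  prop <- function(x) if (length(x) == 0) NA_real_ else mean(x)
  list(
    prop_high = prop(cds$annotated[in_high]),
    prop_rest = prop(cds$annotated[!in_high]),
    undefined = sum(in_high) == 0 || sum(!in_high) == 0
  )
}

#' Pairwise Pearson correlation of replicate FPKM profiles
#'
#' @param fpkm_matrix numeric matrix, CDS in rows, replicates in columns
#'   (>= 2 columns)
#' @return list: `pairwise` (tibble rep_a, rep_b, r), `mean_r`,
#'   `undefined` (TRUE when some replicate has zero variance; affected pairs
#'   are NA and excluded from the mean)
#' @export
replicate_correlation <- function(fpkm_matrix) {
  stopifnot(is.matrix(fpkm_matrix), ncol(fpkm_matrix) >= 2)
  reps <- colnames(fpkm_matrix) %||% paste0("rep", seq_len(ncol(fpkm_matrix)))
  cmb <- utils::combn(ncol(fpkm_matrix), 2)
  r <- apply(cmb, 2, function(ij) {
    x <- fpkm_matrix[, ij[1]]; y <- fpkm_matrix[, ij[2]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = "pearson")
  })
  list(
    pairwise = tibble::tibble(rep_a = reps[cmb[1, ]], rep_b = reps[cmb[2, ]],
                              r = r),
    mean_r = mean(r, na.rm = TRUE),
    undefined = anyNA(r)
  )
}

#' Percentile rank of each CDS's FPKM within its genome
#'
#' Percentile of a value = fraction of CDS with a strictly smaller value,
#' times 100; ties share a percentile (all-equal profiles get 0).
#' @param fpkm numeric vector of (mean) FPKM
#' @return numeric vector of percentiles in `[0, 100)`
#' @export
fpkm_percentiles <- function(fpkm) {
  stopifnot(length(fpkm) >= 1)
  100 * (rank(fpkm, ties.method = "min") - 1L) / length(fpkm)
}

#' Full expression profile across replicates
#'
#' Combines per-replicate count tables of one target genome into the profile
#' table: per-CDS FPKM per replicate, replicate-mean FPKM, housekeeping
#' baseline, fold over baseline (FPKM_HK), highly expressed flag and FPKM
#' percentile, plus replicate concordance.
#'
#' @param count_list list of `sagscope_counts`, one per biological replicate
#' @param housekeeping_ids housekeeping CDS ids (non-empty)
#' @param genome_id target genome (default: all CDS)
#' @param cds optional CDS tibble to attach `annotated` flags
#' @return object of class `sagscope_expression`: list with `profile`
#'   (tibble), `hk_baseline`, `replicate_cor`, `n_high`, `high_ids`
#' @export
expression_profile <- function(count_list, housekeeping_ids,
                               genome_id = NULL, cds = NULL) {
  stopifnot(length(count_list) >= 1)
  fpkms <- lapply(count_list, compute_fpkm, genome_id = genome_id)
  ids <- fpkms[[1]]$cds_id
  for (f in fpkms) stopifnot(identical(f$cds_id, ids))
  mat <- do.call(cbind, lapply(fpkms, `[[`, "fpkm"))
  colnames(mat) <- paste0("fpkm_rep", seq_along(fpkms))
  rownames(mat) <- ids
  mean_fpkm <- stats::setNames(rowMeans(mat), ids)
  base <- hk_baseline(mean_fpkm, housekeeping_ids)
  cls <- classify_high_expression(mean_fpkm, base)
  prof <- tibble::tibble(
    cds_id = ids,
    genome_id = fpkms[[1]]$genome_id,
    length_bp = fpkms[[1]]$length_bp
  )
  prof <- dplyr::bind_cols(prof, tibble::as_tibble(mat))
  prof$mean_fpkm <- unname(mean_fpkm)
  prof$fold_hk <- unname(cls$fold_hk)
  prof$highly_expressed <- prof$fold_hk > 1
  prof$percentile <- fpkm_percentiles(prof$mean_fpkm)
  if (!is.null(cds)) {
    prof$annotated <- cds$annotated[match(prof$cds_id, cds$cds_id)]
  }
  rc <- if (length(count_list) >= 2) replicate_correlation(mat) else NULL
  structure(
    list(profile = prof, hk_baseline = base, replicate_cor = rc,
         n_high = cls$n_high, high_ids = cls$high_ids,
         housekeeping_ids = housekeeping_ids),
    class = "sagscope_expression"
  )
}

#' @export
print.sagscope_expression <- function(x, ...) {
  cat(sprintf(
    "<sagscope_expression> %d CDS; HK baseline %.2f FPKM; %d highly expressed\n",
    nrow(x$profile), x$hk_baseline, x$n_high))
  if (!is.null(x$replicate_cor)) {
    cat(sprintf("  mean replicate Pearson r = %.3f\n", x$replicate_cor$mean_r))
  }
  invisible(x)
}

#' Write an expression profile as TSV
#' @param profile a `sagscope_expression`
#' @param path output path
#' @return invisible `path`
#' @export
write_expression <- function(profile, path) {
  utils::write.table(profile$profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
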