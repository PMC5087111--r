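#' Evaluate retrieval against simulation ground truth
#'
#' A pair counts as a true positive for genome g when it was uniquely
#' assigned to g and truly originates from g; a false positive when uniquely
#' assigned to g but from elsewhere; a false negative when from g but not
#' uniquely assigned to g. Precision = TP/(TP+FP) and recall = TP/(TP+FN),
#' with 0/0 defined as 1. A confusion table of true origin by assignment
#' outcome (assigned genome, or the discard class) is returned; its counts
#' sum to the number of input pairs.
#'
#' @param assignments assignment tibble from [assign_pairs()] (rows for
#'   QC-removed pairs may be included with status `"qc_removed"`)
#' @param truth truth tibble from [simulate_fragments()]/[read_truth()];
#'   every assignment `fragment_id` must appear in it
#' @param target_genomes genomes to score (default: all genomes in truth)
#' @return object of class `sagscope_retrieval_metrics`: list with
#'   `per_genome` (tibble: genome_id, tp, fp, fn, precision, recall, f1),
#'   `micro` (one-row tibble over all target genomes), `confusion`
#'   (tibble: true_genome, assigned, n), `n_pairs`
#' @export
evaluate_retrieval <- function(assignments, truth, target_genomes = NULL) {
  miss <- setdiff(assignments$fragment_id, truth$fragment_id)
  if (length(miss)) {
    stop("assignments contain fragment ids absent from the truth table: ",
         paste(utils::head(miss, 3), collapse = ", "))
  }
  tr <- truth[match(assignments$fragment_id, truth$fragment_id), ]
  true_g <- tr$genome_id
  assigned <- ifelse(assignments$status == "unique",
                     assignments$genome_id, assignments$status)
  if (is.null(target_genomes)) target_genomes <- sort(unique(true_g))

  per <- lapply(target_genomes, function(g) {
    uniq_g <- assignments$status == "unique" & assignments$genome_id == g
    tp <- sum(uniq_g & true_g == g)
    fp <- sum(uniq_g & true_g != g)
    fn <- sum(true_g == g & !(uniq_g))
    tibble::tibble(genome_id = g, tp = tp, fp = fp, fn = fn,
                   precision = safe_ratio(tp, tp + fp),
                   recall = safe_ratio(tp, tp + fn))
  })
  per <- dplyr::bind_rows(per)
  per$f1 <- ifelse(per$precision + per$recall == 0, 0,
                   2 * per$precision * per$recall /
                     (per$precision + per$recall))
  tp <- sum(per$tp); fp <- sum(per$fp); fn <- sum(per$fn)
  micro <- tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    precision = safe_ratio(tp, tp + fp),
    recall = safe_ratio(tp, tp + fn)
  )
  micro$f1 <- ifelse(micro$precision + micro$recall == 0, 0,
                     2 * micro$precision * micro$recall /
                       (micro$precision + micro$recall))
  conf <- tibble::as_tibble(as.data.frame(table(
    true_genome = true_g, assigned = assigned
  ), responseName = "n"))
  conf <- conf[conf$n > 0, ]
  structure(list(per_genome = per, micro = micro, confusion = conf,
                 n_pairs = nrow(assignments)),
            class = "sagscope_retrieval_metrics")
}

#' @keywords internal
safe_ratio <- function(num, den) if (den == 0) 1 else num / den

#' @export
print.sagscope_retrieval_metrics <- function(x, ...) {
  cat(sprintf("<retrieval metrics> %d pairs; micro P=%.4f R=%.4f F1=%.4f\n",
              x$n_pairs, x$micro$precision, x$micro$recall, x$micro$f1))
  print(x$per_genome)
  invisible(x)
}

#' Percentage share of assigned fragments per genome
#'
#' The per-genome share of all fragments assigned across the reference
#' genomes, in percent — the summary used to report how much of the
#' community-assigned signal a single reference captures.
#'
#' @param counts named numeric vector of assigned-fragment counts per genome
#' @return named numeric vector of percentages summing to 100
#' @export
genome_share <- function(counts) {
  stopifnot(length(counts) > 0, all(counts >= 0), sum(counts) > 0)
  100 * counts / sum(counts)
}

#' Exhaustive evaluation of assignment parameters over a grid
#'
#' Runs QC + assignment + [evaluate_retrieval()] for every row of
#' `param_grid` and tabulates micro precision/recall/F1. Rows are evaluated
#' and reported in grid order (deterministic); the best row by micro F1
#' (first on ties) is attached as attribute `"best"`.
#'
#' @param pairs raw pair tibble (QC is applied here)
#' @param truth simulation truth tibble
#' @param refset a [refset()]
#' @param param_grid data frame with any of the columns `seed_k`,
#'   `max_mismatch`, `min_frag`, `max_frag`; missing columns take the
#'   [assign_params()] defaults
#' @param qc a [qc_params()]
#' @param target_genomes genomes to score
#' @return tibble, one row per grid row, with the parameters, `n_unique`,
#'   micro `precision`, `recall`, `f1`
#' @export
grid_search <- function(pairs, truth, refset, param_grid,
                        qc = qc_params(), target_genomes = NULL) {
  param_grid <- as.data.frame(param_grid)
  if (nrow(param_grid) == 0) stop("empty parameter grid")
  defaults <- assign_params()
  for (col in c("seed_k", "max_mismatch", "min_frag", "max_frag")) {
    if (is.null(param_grid[[col]])) param_grid[[col]] <- defaults[[col]]
  }
  proc <- qc_pairs(pairs, qc)
  indexes <- new.env()
  rows <- lapply(seq_len(nrow(param_grid)), function(i) {
    p <- assign_params(seed_k = param_grid$seed_k[i],
                       max_mismatch = param_grid$max_mismatch[i],
                       min_frag = param_grid$min_frag[i],
                       max_frag = param_grid$max_frag[i])
    key <- as.character(p$seed_k)
    if (is.null(indexes[[key]])) {
      indexes[[key]] <- build_index(refset, p$seed_k)
    }
    asn <- assign_pairs(proc$pairs, indexes[[key]], p)
    asn <- add_removed(asn, proc$removed)
    m <- evaluate_retrieval(asn, truth, target_genomes)
    tibble::tibble(
      seed_k = p$seed_k, max_mismatch = p$max_mismatch,
      min_frag = p$min_frag, max_frag = p$max_frag,
      n_unique = sum(asn$status == "unique"),
      precision = m$micro$precision, recall = m$micro$recall,
      f1 = m$micro$f1
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "best") <- out[which.max(out$f1), ]
  out
}

#' Append QC-removed pairs to an assignment table
#'
#' Keeps the conservation invariant (every input pair accounted for) by
#' adding `qc_removed` rows for pairs dropped during quality processing.
#' @param assignments assignment tibble
#' @param removed `removed` tibble from [qc_pairs()]
#' @return assignment tibble with the extra rows
#' @export
add_removed <- function(assignments, removed) {
  if (nrow(removed) == 0) return(assignments)
  extra <- empty_assignment_table(removed$fragment_id)
  extra$status <- rep("qc_removed", nrow(extra))
  dplyr::bind_rows(assignments, extra)
}

#' One-call retrieval pipeline: QC, index, assign
#'
#' @param pairs raw pair tibble
#' @param refset a [refset()]
#' @param params an [assign_params()]
#' @param qc a [qc_params()]
#' @return assignment tibble including `qc_removed` rows
#' @export
retrieve_pairs <- function(pairs, refset, params = assign_params(),
                           qc = qc_params()) {
  proc <- qc_pairs(pairs, qc)
  idx <- build_index(refset, params$seed_k)
  add_removed(assign_pairs(proc$pairs, idx, params), proc$removed)
}
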