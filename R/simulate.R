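#' Sample per-CDS relative transcription weights
#'
#' Draws heavy-tailed (log-normal) expression weights over the whole
#' community, normalised to sum to 1. A log-normal captures the empirical
#' shape of prokaryotic expression: most genes moderate, a long upper tail of
#' highly transcribed genes, so a "highly expressed" set exists to recover.
#' `lognormal_sigma = 0` gives equal weights.
#'
#' @param refset a [refset()]
#' @param lognormal_mu,lognormal_sigma log-scale mean and sd (natural log)
#' @param seed integer seed or `NULL`
#' @return named numeric vector (names = cds_id), non-negative, summing to 1
#' @export
sample_expression <- function(refset, lognormal_mu = 0, lognormal_sigma = 1.5,
                              seed = NULL) {
  stopifnot(lognormal_sigma >= 0)
  set_seed_if(seed)
  ids <- refset$cds$cds_id
  if (length(ids) == 0) return(stats::setNames(numeric(0), character(0)))
  w <- if (lognormal_sigma == 0) {
    rep(exp(lognormal_mu), length(ids))
  } else {
    rlnorm(length(ids), meanlog = lognormal_mu, sdlog = lognormal_sigma)
  }
  stats::setNames(w / sum(w), ids)
}

#' Simulate ground-truthed paired-end metatranscriptome fragments
#'
#' Emulates an Illumina-style non-stranded mRNA library over a community
#' reference: each fragment picks a CDS with probability proportional to its
#' expression weight, an insert length from `N(insert_mean, insert_sd)`
#' (rounded; clipped into `[1, CDS length]`), and a uniform start within the
#' CDS. Mate 1 reads the fragment's 5' end on the transcript (CDS) strand,
#' mate 2 the 3' end on the opposite strand (FR orientation). Reads are
#' `min(read_len, insert)` long, so short inserts yield read-through-shortened
#' mates and CDS shorter than `read_len` yield reads spanning the whole CDS —
#' reads are always genomic substrings. Each read base is substituted
#' independently with probability `error_rate`; every fragment's true origin
#' is recorded.
#'
#' @param refset a [refset()]
#' @param weights named per-CDS weights from [sample_expression()]
#' @param n_fragments number of read pairs to simulate
#' @param read_len read length in bp (101 mirrors HiSeq 2000 output)
#' @param insert_mean,insert_sd insert-size distribution (bp); defaults 149/30
#' @param error_rate per-base substitution probability in `[0, 1)`
#' @param qual_model `"constant"` (flat Phred) or `"decay"` (linear quality
#'   drop after a random per-read breakpoint, to exercise quality truncation)
#' @param qual_phred baseline Phred score
#' @param decay_rate Phred lost per base after the breakpoint (decay model)
#' @param background_rate probability that a fragment originates from
#'   untargeted background transcription instead of a CDS: placed uniformly
#'   on a random contig (length-weighted), random strand, `cds_id` recorded
#'   as `NA`. Default 0 (all fragments transcript-derived); a nonzero rate
#'   exercises no-feature counting and coverage between genes.
#' @param seed integer seed or `NULL`
#' @return object of class `sagscope_fragments`: a list with `fragments`
#'   (tibble: fragment_id, genome_id, cds_id, contig_id, frag_start,
#'   frag_end, insert_size, n_errors, mate seqs/quals) and the simulation
#'   parameters
#' @export
simulate_fragments <- function(refset, weights, n_fragments,
                               read_len = 101L, insert_mean = 149,
                               insert_sd = 30, error_rate = 0,
                               qual_model = c("constant", "decay"),
                               qual_phred = 38L, decay_rate = 2L,
                               background_rate = 0, seed = NULL) {
  qual_model <- match.arg(qual_model)
  stopifnot(n_fragments >= 0, error_rate >= 0, error_rate < 1, read_len >= 1,
            background_rate >= 0, background_rate < 1)
  set_seed_if(seed)
  cds <- refset$cds
  if (n_fragments > 0 && nrow(cds) == 0 && background_rate == 0) {
    stop("cannot simulate fragments from a reference set without CDS")
  }
  if (n_fragments == 0) {
    return(new_fragments(empty_fragment_table(), read_len, insert_mean,
                         insert_sd, error_rate, qual_model))
  }
  is_bg <- runif(n_fragments) < background_rate
  n_cds_frag <- sum(!is_bg)
  if (n_cds_frag > 0) stopifnot(all(cds$cds_id %in% names(weights)))
  w <- if (nrow(cds)) weights[cds$cds_id] else numeric(0)

  # origin units: a CDS (transcript-derived) or a whole contig (background)
  origin_cds <- rep(NA_integer_, n_fragments)
  if (n_cds_frag > 0) {
    origin_cds[!is_bg] <- sample.int(nrow(cds), n_cds_frag, replace = TRUE,
                                     prob = w)
  }
  info <- refset$contig_info
  origin_contig <- rep(NA_integer_, n_fragments)
  if (any(is_bg)) {
    origin_contig[is_bg] <- sample.int(nrow(info), sum(is_bg),
                                       replace = TRUE, prob = info$length)
  }
  unit_start <- ifelse(is_bg, 0L, cds$start[origin_cds])
  unit_len <- ifelse(is_bg, info$length[origin_contig],
                     cds$length_bp[origin_cds])
  unit_strand <- ifelse(is_bg, sample(c("+", "-"), n_fragments, TRUE),
                        cds$strand[origin_cds])
  contig <- ifelse(is_bg, info$contig_id[origin_contig],
                   cds$contig_id[origin_cds])

  cl <- unit_len
  isize <- as.integer(round(rnorm(n_fragments, insert_mean, insert_sd)))
  isize <- pmin(pmax(isize, 1L), cl)
  offset <- floor(runif(n_fragments) * (cl - isize + 1L))
  fs <- unit_start + as.integer(offset)
  fe <- fs + isize
  rl <- pmin(read_len, isize)

  seqs <- as.character(refset$contigs)
  fwd <- substring(seqs[contig], fs + 1L, fs + rl)       # 5' end, + strand
  rev <- revcomp_chr(substring(seqs[contig], fe - rl + 1L, fe))
  plus <- unit_strand == "+"
  # mate1 reads the transcript 5' end: on "-" CDS that is the fragment's
  # right edge read on the reverse strand
  mate1 <- ifelse(plus, fwd, revcomp_chr(substring(seqs[contig],
                                                   fe - rl + 1L, fe)))
  mate2 <- ifelse(plus, rev, substring(seqs[contig], fs + 1L, fs + rl))

  e1 <- apply_errors(mate1, error_rate)
  e2 <- apply_errors(mate2, error_rate)

  q1 <- make_quals(nchar(mate1), qual_model, qual_phred, decay_rate)
  q2 <- make_quals(nchar(mate2), qual_model, qual_phred, decay_rate)

  genome <- ifelse(is_bg, info$genome_id[origin_contig],
                   cds$genome_id[origin_cds])
  unit_id <- ifelse(is_bg, NA_character_, cds$cds_id[origin_cds])
  frags <- tibble::tibble(
    fragment_id = sprintf("%s:%s:%06d", genome,
                          ifelse(is_bg, "bg", unit_id),
                          seq_len(n_fragments)),
    genome_id = genome,
    cds_id = unit_id,
    contig_id = contig,
    frag_start = as.integer(fs),
    frag_end = as.integer(fe),
    insert_size = isize,
    cds_strand = unit_strand,
    n_errors = e1$n + e2$n,
    mate1_seq = e1$seq, mate2_seq = e2$seq,
    mate1_qual = q1, mate2_qual = q2
  )
  new_fragments(frags, read_len, insert_mean, insert_sd, error_rate,
                qual_model)
}

#' @keywords internal
new_fragments <- function(frags, read_len, insert_mean, insert_sd,
                          error_rate, qual_model) {
  structure(
    list(fragments = frags,
         params = list(read_len = read_len, insert_mean = insert_mean,
                       insert_sd = insert_sd, error_rate = error_rate,
                       qual_model = qual_model)),
    class = "sagscope_fragments"
  )
}

#' @keywords internal
empty_fragment_table <- function() {
  tibble::tibble(
    fragment_id = character(), genome_id = character(), cds_id = character(),
    contig_id = character(), frag_start = integer(), frag_end = integer(),
    insert_size = integer(), cds_strand = character(), n_errors = integer(),
    mate1_seq = character(), mate2_seq = character(),
    mate1_qual = character(), mate2_qual = character()
  )
}

#' @export
print.sagscope_fragments <- function(x, ...) {
  cat(sprintf(
    "<sagscope_fragments> %d pairs, read_len %d, insert %s+-%s, error %.3g\n",
    nrow(x$fragments), x$params$read_len, x$params$insert_mean,
    x$params$insert_sd, x$params$error_rate
  ))
  invisible(x)
}

# Substitution errors: draw the per-read error count Binomial(len, rate),
# then mutate that many distinct positions (cheap when rate is small).
#' @keywords internal
apply_errors <- function(seqs, error_rate) {
  n <- length(seqs)
  if (error_rate == 0 || n == 0) {
    return(list(seq = seqs, n = integer(n)))
  }
  lens <- nchar(seqs)
  k <- rbinom(n, lens, error_rate)
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  for (i in which(k > 0)) {
    s <- seqs[[i]]
    posn <- sample.int(lens[i], k[i])
    for (p in posn) {
      b <- substring(s, p, p)
      substring(s, p, p) <- sample(alt[[b]], 1L)
    }
    seqs[[i]] <- s
  }
  list(seq = seqs, n = as.integer(k))
}

# Quality strings: constant Phred, or linear decay after a uniform breakpoint
# in the second half of the read (emulating 3' quality drop-off).
#' @keywords internal
make_quals <- function(lens, qual_model, qual_phred, decay_rate) {
  if (qual_model == "constant") {
    return(strrep(intToUtf8(qual_phred + PHRED_OFFSET), lens))
  }
  vapply(lens, function(L) {
    bp <- sample(seq(max(1L, L %/% 2L), L), 1L)
    q <- rep(qual_phred, L)
    if (bp < L) {
      drop <- seq_len(L - bp) * decay_rate
      q[(bp + 1L):L] <- pmax(qual_phred - drop, 2L)
    }
    intToUtf8(q + PHRED_OFFSET)
  }, "")
}

#' Write simulated fragments as a FASTQ pair plus a truth table
#'
#' FASTQ is Phred+33; read names are the fragment ids (which encode
#' genome:cds:serial provenance), but the tab-separated truth table is the
#' contract: columns `fragment_id`, `genome_id`, `cds_id`, `contig_id`,
#' `frag_start`, `frag_end` (0-based half-open), `insert_size`, `n_errors`.
#'
#' @param frags a `sagscope_fragments`
#' @param dir output directory
#' @param prefix file name prefix
#' @return invisible named vector of paths (`fastq1`, `fastq2`, `truth`)
#' @export
write_fragments <- function(frags, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- frags$fragments
  paths <- c(
    fastq1 = file.path(dir, paste0(prefix, "_1.fastq")),
    fastq2 = file.path(dir, paste0(prefix, "_2.fastq")),
    truth = file.path(dir, paste0(prefix, "_truth.tsv"))
  )
  write_fastq(f$fragment_id, f$mate1_seq, f$mate1_qual, paths[["fastq1"]])
  write_fastq(f$fragment_id, f$mate2_seq, f$mate2_qual, paths[["fastq2"]])
  truth <- f[, c("fragment_id", "genome_id", "cds_id", "contig_id",
                 "frag_start", "frag_end", "insert_size", "n_errors")]
  utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' @keywords internal
write_fastq <- function(ids, seqs, quals, path) {
  if (length(ids) == 0) {
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

#' Read a FASTQ mate pair into the pair table the QC/assignment steps expect
#'
#' @param fastq1,fastq2 mate FASTQ paths (Phred+33); records must be in the
#'   same order with matching ids
#' @return tibble with `fragment_id`, `mate1_seq`, `mate1_qual`,
#'   `mate2_seq`, `mate2_qual`
#' @export
read_pairs <- function(fastq1, fastq2) {
  r1 <- read_fastq(fastq1)
  r2 <- read_fastq(fastq2)
  if (!identical(r1$id, r2$id)) {
    stop("mate FASTQ files disagree on read ids/order")
  }
  tibble::tibble(fragment_id = r1$id,
                 mate1_seq = r1$seq, mate1_qual = r1$qual,
                 mate2_seq = r2$seq, mate2_qual = r2$qual)
}

#' @keywords internal
read_fastq <- function(path) {
  if (file.info(path)$size == 0) {
    return(list(id = character(), seq = character(), qual = character()))
  }
  # Biostrings warns about dropping its own metadata columns here; harmless
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  list(id = sub("\\s.*$", "", names(x)),
       seq = unname(as.character(x)),
       qual = unname(as.character(Biostrings::quality(x))))
}

#' Read a fragment truth table written by [write_fragments()]
#' @param path truth TSV path
#' @return tibble of the truth columns
#' @export
read_truth <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Ground-truth pair placements for mapping-free validation
#'
#' Converts simulated fragments into the assignment table an ideal aligner
#' would produce (every pair `unique` at its true locus). Used to exercise
#' counting, expression and coverage logic independently of the mapper.
#'
#' @param frags a `sagscope_fragments`
#' @return assignment tibble as produced by [assign_pairs()]
#' @export
perfect_assignments <- function(frags) {
  f <- frags$fragments
  l1 <- nchar(f$mate1_seq)
  l2 <- nchar(f$mate2_seq)
  plus <- f$cds_strand == "+"
  m1s <- ifelse(plus, f$frag_start, f$frag_end - l1)
  m1e <- ifelse(plus, f$frag_start + l1, f$frag_end)
  m2s <- ifelse(plus, f$frag_end - l2, f$frag_start)
  m2e <- ifelse(plus, f$frag_end, f$frag_start + l2)
  tibble::tibble(
    fragment_id = f$fragment_id,
    status = rep("unique", nrow(f)),
    genome_id = f$genome_id,
    contig_id = f$contig_id,
    m1_start = as.integer(m1s), m1_end = as.integer(m1e),
    m2_start = as.integer(m2s), m2_end = as.integer(m2e),
    strand = ifelse(plus, "+", "-"),
    n_mismatch = f$n_errors,
    frag_len = f$insert_size
  )
}
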