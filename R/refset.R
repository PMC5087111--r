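#' Reference set: genomes, CDS annotations and housekeeping flags
#'
#' A `sagscope_refset` bundles the mapping target and counting universe:
#' contig sequences (as a [Biostrings::DNAStringSet] named by globally unique
#' contig ids), a CDS table and the set of housekeeping CDS ids.
#'
#' The CDS table has columns `cds_id`, `genome_id`, `contig_id`, `start`,
#' `end` (0-based half-open), `strand` (`+`/`-`), `annotated` (has a
#' functional annotation) and `length_bp = end - start`. CDS of one contig
#' never overlap (a generator guarantee, not enforced on read).
#'
#' @param contigs [Biostrings::DNAStringSet] named by contig id
#' @param contig_info tibble with `contig_id`, `genome_id`, `length`
#' @param cds CDS tibble (see Details)
#' @param housekeeping_ids character vector of CDS ids
#' @return object of class `sagscope_refset`
#' @export
refset <- function(contigs, contig_info, cds, housekeeping_ids = character()) {
  obj <- structure(
    list(
      contigs = contigs,
      contig_info = tibble::as_tibble(contig_info),
      cds = tibble::as_tibble(cds),
      housekeeping_ids = unique(as.character(housekeeping_ids))
    ),
    class = "sagscope_refset"
  )
  validate_refset(obj)
  obj
}

#' Validate a reference set's structural invariants
#'
#' Checks that CDS intervals lie within their contig, that CDS ids are unique
#' across the set, and that every housekeeping id names an existing CDS.
#' @param x a `sagscope_refset`
#' @return `x`, invisibly; stops on violation
#' @export
validate_refset <- function(x) {
  cds <- x$cds
  if (anyDuplicated(cds$cds_id)) stop("duplicate cds_id in reference set")
  if (anyDuplicated(names(x$contigs))) stop("duplicate contig ids")
  if (nrow(cds) > 0) {
    clen <- stats::setNames(x$contig_info$length, x$contig_info$contig_id)
    if (!all(cds$contig_id %in% names(clen))) {
      stop("CDS reference a contig absent from the set")
    }
    bad <- cds$start < 0 | cds$end > clen[cds$contig_id] | cds$start >= cds$end
    if (any(bad)) stop("CDS interval outside its contig or empty")
    if (!all(cds$length_bp == cds$end - cds$start)) {
      stop("length_bp inconsistent with start/end")
    }
  }
  if (!all(x$housekeeping_ids %in% cds$cds_id)) {
    stop("housekeeping id does not name an existing CDS")
  }
  invisible(x)
}

#' @export
print.sagscope_refset <- function(x, ...) {
  cat(sprintf(
    "<sagscope_refset> %d genome(s), %d contig(s), %d CDS (%d housekeeping)\n",
    length(unique(x$contig_info$genome_id)), length(x$contigs),
    nrow(x$cds), length(x$housekeeping_ids)
  ))
  invisible(x)
}

#' Generate reference genomes with non-overlapping CDS annotations
#'
#' Builds a synthetic community reference: random nucleotide contigs carrying
#' non-overlapping CDS on random strands. Per genome, exactly
#' `floor(hk_fraction * n_cds_per_genome)` CDS are flagged housekeeping and
#' `round(annotated_fraction * n_cds_per_genome)` carry a functional
#' annotation. Deterministic for a fixed seed.
#'
#' @param n_genomes number of genomes (0 gives a valid empty set)
#' @param contig_lengths contig length(s); a single number (one contig per
#'   genome), a vector recycled across genomes, or a list with one vector of
#'   contig lengths per genome
#' @param n_cds_per_genome CDS count per genome
#' @param hk_fraction fraction of CDS flagged housekeeping (floor applied)
#' @param annotated_fraction fraction of CDS with functional annotation
#' @param cds_len_range min/max CDS length (bp), sampled uniformly
#' @param intergenic_min minimum gap between consecutive CDS (bp)
#' @param genome_prefix prefix for genome ids (`<prefix>1`, `<prefix>2`, ...)
#' @param seed integer seed; `NULL` uses the current RNG stream
#' @return a [refset()]
#' @export
generate_references <- function(n_genomes,
                                contig_lengths = 20000L,
                                n_cds_per_genome = 40L,
                                hk_fraction = 0.1,
                                annotated_fraction = 0.7,
                                cds_len_range = c(300L, 1500L),
                                intergenic_min = 20L,
                                genome_prefix = "genome",
                                seed = NULL) {
  set_seed_if(seed)
  stopifnot(n_genomes >= 0, n_cds_per_genome >= 0,
            hk_fraction >= 0, hk_fraction <= 1,
            annotated_fraction >= 0, annotated_fraction <= 1)
  if (n_genomes == 0) {
    return(refset(
      Biostrings::DNAStringSet(),
      tibble::tibble(contig_id = character(), genome_id = character(),
                     length = integer()),
      empty_cds_table()
    ))
  }
  if (!is.list(contig_lengths)) {
    contig_lengths <- as.list(rep_len(as.integer(contig_lengths), n_genomes))
  }
  stopifnot(length(contig_lengths) == n_genomes)

  seqs <- character(0)
  info <- list()
  cds_rows <- list()
  hk_ids <- character(0)
  for (g in seq_len(n_genomes)) {
    gid <- paste0(genome_prefix, g)
    lens <- as.integer(contig_lengths[[g]])
    cids <- sprintf("%s_c%d", gid, seq_along(lens))
    gseqs <- vapply(lens, random_dna, "")
    names(gseqs) <- cids
    seqs <- c(seqs, gseqs)
    info[[g]] <- tibble::tibble(contig_id = cids, genome_id = gid,
                                length = lens)
    if (n_cds_per_genome > 0) {
      cds_rows[[g]] <- place_cds(gid, cids, lens, n_cds_per_genome,
                                 cds_len_range, intergenic_min,
                                 annotated_fraction)
      n_hk <- floor(hk_fraction * n_cds_per_genome)
      if (n_hk > 0) {
        hk_ids <- c(hk_ids, sample(cds_rows[[g]]$cds_id, n_hk))
      }
    }
  }
  cds <- if (length(cds_rows)) dplyr::bind_rows(cds_rows) else empty_cds_table()
  refset(Biostrings::DNAStringSet(seqs), dplyr::bind_rows(info), cds, hk_ids)
}

#' @keywords internal
empty_cds_table <- function() {
  tibble::tibble(cds_id = character(), genome_id = character(),
                 contig_id = character(), start = integer(), end = integer(),
                 strand = character(), annotated = logical(),
                 length_bp = integer())
}

# Place n CDS across a genome's contigs without overlap: CDS lengths are drawn
# first, contigs filled proportionally to length, then the per-contig slack is
# spread over the gaps. Errors out when the contig cannot host its share.
#' @keywords internal
place_cds <- function(genome_id, contig_ids, contig_lens, n_cds,
                      cds_len_range, intergenic_min, annotated_fraction) {
  # allot CDS to contigs proportionally to contig length
  alloc <- floor(n_cds * contig_lens / sum(contig_lens))
  rem <- n_cds - sum(alloc)
  if (rem > 0) {
    ord <- order(contig_lens, decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1L
  }
  rows <- list()
  serial <- 0L
  for (ci in seq_along(contig_ids)) {
    k <- alloc[ci]
    if (k == 0) next
    lens <- sample(seq(cds_len_range[1], cds_len_range[2]), k, replace = TRUE)
    need <- sum(lens) + (k + 1L) * intergenic_min
    if (need > contig_lens[ci]) {
      stop(sprintf(
        "capacity error: contig %s (%d bp) cannot host %d CDS totalling %d bp",
        contig_ids[ci], contig_lens[ci], k, need
      ), call. = FALSE)
    }
    slack <- contig_lens[ci] - sum(lens) - (k + 1L) * intergenic_min
    # random split of slack over the k+1 gaps
    cuts <- sort(sample(0:slack, k, replace = TRUE))
    extra <- diff(c(0L, cuts, slack))
    gap <- intergenic_min + extra
    starts <- cumsum(gap[seq_len(k)]) + c(0L, cumsum(lens))[seq_len(k)]
    ids <- sprintf("%s_cds%03d", genome_id, serial + seq_len(k))
    serial <- serial + k
    ann <- rep(FALSE, k)
    n_ann <- round(annotated_fraction * k)
    if (n_ann > 0) ann[sample(k, min(n_ann, k))] <- TRUE
    rows[[ci]] <- tibble::tibble(
      cds_id = ids, genome_id = genome_id, contig_id = contig_ids[ci],
      start = as.integer(starts), end = as.integer(starts + lens),
      strand = sample(c("+", "-"), k, replace = TRUE),
      annotated = ann, length_bp = as.integer(lens)
    )
  }
  dplyr::bind_rows(rows)
}

#' Combine reference sets into one community reference
#'
#' Used to append e.g. a host "genome" to a symbiont reference set. Contig and
#' CDS ids must not collide.
#' @param ... `sagscope_refset` objects
#' @return a single [refset()]
#' @export
combine_refsets <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) > 0)
  refset(
    do.call(c, lapply(parts, `[[`, "contigs")),
    dplyr::bind_rows(lapply(parts, `[[`, "contig_info")),
    dplyr::bind_rows(lapply(parts, `[[`, "cds")),
    unlist(lapply(parts, `[[`, "housekeeping_ids"))
  )
}

#' Enforce global uniqueness of seed k-mers across a reference set
#'
#' Deterministically point-mutates repeated occurrences of any canonical
#' k-mer (a k-mer and its reverse complement are one key) until every k-mer
#' occurs exactly once in the whole set. Guarantees that error-free reads of
#' length >= k re-locate uniquely, which underpins the exact
#' precision = recall = 1 property of the retrieval validation.
#'
#' @param refset a [refset()]
#' @param k seed k-mer size
#' @param max_iter safety cap on mutation rounds
#' @return the modified `sagscope_refset`
#' @export
enforce_unique_kmers <- function(refset, k, max_iter = 50L) {
  seqs <- as.character(refset$contigs)
  for (iter in seq_len(max_iter)) {
    km <- data.table::rbindlist(lapply(names(seqs), function(cid) {
      s <- seqs[[cid]]
      n <- nchar(s)
      if (n < k) return(NULL)
      pos <- seq_len(n - k + 1L)
      data.table::data.table(contig = cid, pos = pos,
                             kmer = substring(s, pos, pos + k - 1L))
    }))
    if (nrow(km) == 0) break
    rc <- revcomp_chr(km$kmer)
    km[, canon := pmin(kmer, rc)]
    dup <- km[, .N, by = canon][N > 1L, canon]
    if (length(dup) == 0) break
    # mutate the middle base of every occurrence after the first
    fix <- km[canon %in% dup][, utils::tail(.SD, -1L), by = canon]
    shift <- c(A = "C", C = "G", G = "T", T = "A")
    for (i in seq_len(nrow(fix))) {
      p <- fix$pos[i] + (k %/% 2L)
      s <- seqs[[fix$contig[i]]]
      substring(s, p, p) <- shift[[substring(s, p, p)]]
      seqs[[fix$contig[i]]] <- s
    }
  }
  refset$contigs <- Biostrings::DNAStringSet(seqs)
  refset
}

#' Write a reference set as FASTA + GFF3 (+ housekeeping list)
#'
#' GFF3 CDS records are 1-based inclusive on disk (converted from the 0-based
#' half-open internal convention) and carry `ID`, `genome_id` and `annotated`
#' attributes. The housekeeping set goes to a one-id-per-line text file.
#'
#' @param refset a [refset()]
#' @param dir output directory (created if missing)
#' @param prefix file name prefix
#' @return invisible named character vector of the paths written
#' @export
write_refset <- function(refset, dir, prefix = "reference") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, paste0(prefix, ".fasta")),
    gff3 = file.path(dir, paste0(prefix, ".gff3")),
    housekeeping = file.path(dir, paste0(prefix, "_housekeeping.txt"))
  )
  Biostrings::writeXStringSet(refset$contigs, paths[["fasta"]])
  cds <- refset$cds
  if (nrow(cds) == 0) {
    writeLines("##gff-version 3", paths[["gff3"]])
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = cds$contig_id,
      ranges = IRanges::IRanges(start = cds$start + 1L, end = cds$end),
      strand = cds$strand,
      type = rep("CDS", nrow(cds)),
      phase = rep(0L, nrow(cds)),
      ID = cds$cds_id,
      genome_id = cds$genome_id,
      annotated = tolower(as.character(cds$annotated))
    )
    rtracklayer::export(gr, paths[["gff3"]], format = "gff3")
  }
  writeLines(refset$housekeeping_ids, paths[["housekeeping"]])
  invisible(paths)
}

#' Read a reference set from FASTA + GFF3 (+ housekeeping list)
#'
#' Inverse of [write_refset()]; genome ids default to the contig id when the
#' GFF3 lacks a `genome_id` attribute.
#' @param fasta,gff3 file paths
#' @param housekeeping optional path to a one-id-per-line housekeeping list
#' @return a [refset()]
#' @export
read_refset <- function(fasta, gff3, housekeeping = NULL) {
  contigs <- Biostrings::readDNAStringSet(fasta)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  gr <- rtracklayer::import(gff3, format = "gff3")
  if (length(gr) > 0) gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0) {
    info <- tibble::tibble(contig_id = names(contigs),
                           genome_id = names(contigs),
                           length = Biostrings::width(contigs))
    return(refset(contigs, info, empty_cds_table()))
  }
  ann <- if (!is.null(gr$annotated)) gr$annotated == "true" else
    rep(NA, length(gr))
  gid <- if (!is.null(gr$genome_id)) gr$genome_id else
    as.character(GenomicRanges::seqnames(gr))
  cds <- tibble::tibble(
    cds_id = as.character(gr$ID),
    genome_id = as.character(gid),
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    annotated = ann,
    length_bp = GenomicRanges::width(gr)
  )
  info <- tibble::tibble(
    contig_id = names(contigs),
    genome_id = vapply(names(contigs), function(cid) {
      hit <- match(cid, cds$contig_id)
      if (is.na(hit)) cid else cds$genome_id[hit]
    }, ""),
    length = Biostrings::width(contigs)
  )
  hk <- if (!is.null(housekeeping) && file.exists(housekeeping)) {
    readLines(housekeeping)
  } else character()
  refset(contigs, info, cds, hk[nzchar(hk)])
}
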