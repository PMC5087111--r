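# Fixtures are generated in code at test time; no binary data on disk.

# A small simulation-ready community: k-mer-disjoint symbiont genomes plus a
# host background genome excluded from the retrieval targets.
make_community <- function(n_genomes = 2, contig_len = 8000,
                           n_cds = 8, n_fragments = 400,
                           error_rate = 0, seed = 42, seed_k = 15,
                           host = FALSE, sigma = 1.5,
                           cds_len = c(200, 500)) {
  rs <- generate_references(n_genomes, contig_len, n_cds_per_genome = n_cds,
                            cds_len_range = cds_len, seed = seed)
  if (host) {
    hg <- generate_references(1, contig_len, n_cds_per_genome = n_cds,
                              cds_len_range = cds_len,
                              genome_prefix = "host", seed = seed + 1)
    rs <- combine_refsets(rs, hg)
  }
  rs <- enforce_unique_kmers(rs, seed_k)
  w <- sample_expression(rs, lognormal_sigma = sigma, seed = seed + 2)
  fr <- simulate_fragments(rs, w, n_fragments, error_rate = error_rate,
                           seed = seed + 3)
  list(refset = rs, weights = w, frags = fr,
       targets = paste0("genome", seq_len(n_genomes)))
}

# Hand-built assignment row for counting/coverage fixtures (0-based
# half-open mate intervals).
make_assignment <- function(fragment_id, contig_id, m1, m2,
                            status = "unique", genome_id = "genome1",
                            strand = "+") {
  tibble::tibble(
    fragment_id = fragment_id, status = status, genome_id = genome_id,
    contig_id = contig_id,
    m1_start = m1[1], m1_end = m1[2], m2_start = m2[1], m2_end = m2[2],
    strand = strand, n_mismatch = 0L,
    frag_len = max(m1[2], m2[2]) - min(m1[1], m2[1])
  )
}

# Minimal CDS table on one contig.
make_cds <- function(starts, ends, strand = "+", contig = "c1",
                     genome = "genome1", annotated = TRUE) {
  n <- length(starts)
  tibble::tibble(
    cds_id = sprintf("cds%02d", seq_len(n)), genome_id = genome,
    contig_id = contig, start = as.integer(starts), end = as.integer(ends),
    strand = rep_len(strand, n), annotated = rep_len(annotated, n),
    length_bp = as.integer(ends - starts)
  )
}

# Counts object straight from per-CDS counts (bypassing assignment).
make_counts <- function(counts, lengths, genome = "genome1") {
  n <- length(counts)
  structure(list(
    counts = tibble::tibble(
      cds_id = names(counts) %||% sprintf("cds%03d", seq_len(n)),
      genome_id = genome, length_bp = as.integer(lengths),
      count = as.integer(counts)
    ),
    tallies = c(no_feature = 0L, ambiguous = 0L, not_unique = 0L,
                out_of_bounds = 0L, not_aligned = 0L, qc_removed = 0L),
    n_pairs = sum(counts)
  ), class = "sagscope_counts")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
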