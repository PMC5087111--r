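test_that("the seed index enumerates every contig position", {
  rs <- refset(
    Biostrings::DNAStringSet(c(c1 = "ACGTACGT")),
    tibble::tibble(contig_id = "c1", genome_id = "g1", length = 8L),
    make_cds(integer(0), integer(0))[0, ]
  )
  idx <- build_index(rs, 4)
  expect_equal(nrow(idx$kmers), 5)  # 8 - 4 + 1
  expect_equal(query_index(idx, "ACGT")$pos, c(0, 4))
  expect_equal(nrow(query_index(idx, "TTTT")), 0)
})

test_that("index content is a set: independent of contig insertion order", {
  s <- c(c1 = "ACGTTGCAAC", c2 = "GGGCCCATAT")
  mk <- function(ord) build_index(refset(
    Biostrings::DNAStringSet(s[ord]),
    tibble::tibble(contig_id = names(s)[ord], genome_id = "g1",
                   length = nchar(s)[ord]),
    make_cds(integer(0), integer(0))[0, ]
  ), 4)
  a <- mk(1:2); b <- mk(2:1)
  expect_identical(
    data.table::setorder(data.table::copy(a$kmers), kmer, contig_id, pos),
    data.table::setorder(data.table::copy(b$kmers), kmer, contig_id, pos)
  )
})

test_that("error-free planted pairs are recovered uniquely at their locus", {
  cm <- make_community(n_genomes = 2, n_fragments = 150, seed = 101)
  asn <- retrieve_pairs(cm$frags$fragments, cm$refset)
  expect_true(all(asn$status == "unique"))
  pa <- perfect_assignments(cm$frags)
  j <- match(asn$fragment_id, pa$fragment_id)
  expect_equal(asn$m1_start, pa$m1_start[j])
  expect_equal(asn$m2_end, pa$m2_end[j])
  expect_equal(asn$genome_id, pa$genome_id[j])
  expect_equal(asn$frag_len, pa$frag_len[j])
})

test_that("fragment-length bounds gate placements at the boundary", {
  set.seed(9)
  contig <- paste(sample(c("A", "C", "G", "T"), 1200, TRUE), collapse = "")
  rs <- refset(
    Biostrings::DNAStringSet(c(c1 = contig)),
    tibble::tibble(contig_id = "c1", genome_id = "g1", length = 1200L),
    make_cds(integer(0), integer(0))[0, ]
  )
  rs <- enforce_unique_kmers(rs, 15)
  contig <- as.character(rs$contigs[["c1"]])
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  mk_pair <- function(frag_len) tibble::tibble(
    fragment_id = "p1",
    mate1_seq = substring(contig, 101, 201),          # starts at 0-based 100
    mate1_qual = strrep("I", 101),
    mate2_seq = rc(substring(contig, 100 + frag_len - 100, 100 + frag_len)),
    mate2_qual = strrep("I", 101)
  )
  idx <- build_index(rs, 15)
  # outer distance exactly 450: in bounds
  a450 <- assign_pairs(mk_pair(450), idx, assign_params(max_frag = 450))
  expect_equal(a450$status, "unique")
  expect_equal(a450$frag_len, 450L)
  # outer distance 451 with max_frag 450: rejected as out of bounds
  a451 <- assign_pairs(mk_pair(451), idx, assign_params(max_frag = 450))
  expect_equal(a451$status, "frag_out_of_bounds")
  # ...and accepted once the bound is widened
  a451b <- assign_pairs(mk_pair(451), idx, assign_params(max_frag = 500))
  expect_equal(a451b$status, "unique")
})

test_that("pairs mapping equally well to duplicated references are multi", {
  rs <- generate_references(1, 5000, n_cds_per_genome = 4,
                            cds_len_range = c(300, 700), seed = 71)
  dup <- refset(
    Biostrings::DNAStringSet(c(g1_c1 = as.character(rs$contigs[[1]]),
                               g2_c1 = as.character(rs$contigs[[1]]))),
    tibble::tibble(contig_id = c("g1_c1", "g2_c1"),
                   genome_id = c("g1", "g2"), length = rep(5000L, 2)),
    make_cds(integer(0), integer(0))[0, ]
  )
  w <- sample_expression(rs, seed = 72)
  fr <- simulate_fragments(rs, w, 60, seed = 73)
  asn <- retrieve_pairs(fr$fragments, dup)
  expect_true(all(asn$status == "multi"))
})

test_that("seed-and-extend agrees with the all-positions oracle", {
  cm <- make_community(n_genomes = 1, contig_len = 1500, n_cds = 2,
                       n_fragments = 40, error_rate = 0.02, seed = 81)
  p <- assign_params(max_mismatch = 3)
  fast <- retrieve_pairs(cm$frags$fragments, cm$refset, p)
  slow <- align_bruteforce(cm$frags$fragments, cm$refset, p)
  expect_equal(fast$status, slow$status)
  u <- fast$status == "unique"
  expect_equal(fast$m1_start[u], slow$m1_start[u])
  expect_equal(fast$m2_end[u], slow$m2_end[u])
  expect_equal(fast$n_mismatch[u], slow$n_mismatch[u])
})

test_that("SAM round-trip reproduces placements and the resulting counts", {
  skip_if_not_installed("Rsamtools")
  cm <- make_community(n_genomes = 2, n_fragments = 120, seed = 91)
  asn <- retrieve_pairs(cm$frags$fragments, cm$refset)
  sam <- file.path(withr::local_tempdir(), "out.sam")
  write_sam(asn, cm$refset, sam, pairs = cm$frags$fragments)
  back <- read_sam_assignments(sam, cm$refset)
  j <- match(asn$fragment_id[asn$status == "unique"], back$fragment_id)
  expect_false(anyNA(j))
  u <- asn[asn$status == "unique", ]
  expect_equal(back$m1_start[j], u$m1_start)
  expect_equal(back$m2_end[j], u$m2_end)
  expect_equal(back$contig_id[j], u$contig_id)
  c1 <- count_fragments(asn, cm$refset$cds)
  c2 <- count_fragments(back, cm$refset$cds)
  expect_equal(c1$counts$count, c2$counts$count)
})

test_that("retrieval metrics follow the confusion-count arithmetic", {
  # 90 correct + 10 wrong unique assignments to genome A, 100 truly from A
  truth <- tibble::tibble(
    fragment_id = sprintf("f%03d", 1:110),
    genome_id = c(rep("A", 100), rep("B", 10))
  )
  asn <- tibble::tibble(
    fragment_id = truth$fragment_id,
    status = c(rep("unique", 90), rep("unmapped", 10), rep("unique", 10)),
    genome_id = c(rep("A", 90), rep(NA, 10), rep("A", 10))
  )
  m <- evaluate_retrieval(asn, truth, target_genomes = "A")
  expect_equal(m$per_genome$precision, 0.9)
  expect_equal(m$per_genome$recall, 0.9)
  # confusion counts conserve the input pairs
  expect_equal(sum(m$confusion$n), 110)
  # perfect assignment: precision = recall = 1 everywhere
  asn2 <- tibble::tibble(fragment_id = truth$fragment_id, status = "unique",
                         genome_id = truth$genome_id)
  m2 <- evaluate_retrieval(asn2, truth)
  expect_true(all(m2$per_genome$precision == 1))
  expect_true(all(m2$per_genome$recall == 1))
  # unknown fragment id is an input error
  expect_error(
    evaluate_retrieval(dplyr::mutate(asn2, fragment_id = paste0("x", fragment_id)),
                       truth),
    "absent"
  )
})

test_that("duplicated references give recall 0 but well-defined precision 1", {
  rs <- generate_references(1, 5000, n_cds_per_genome = 4,
                            cds_len_range = c(300, 700), seed = 71)
  dup <- refset(
    Biostrings::DNAStringSet(c(g1_c1 = as.character(rs$contigs[[1]]),
                               g2_c1 = as.character(rs$contigs[[1]]))),
    tibble::tibble(contig_id = c("g1_c1", "g2_c1"),
                   genome_id = c("genome1", "g2"), length = rep(5000L, 2)),
    make_cds(integer(0), integer(0))[0, ]
  )
  w <- sample_expression(rs, seed = 72)
  fr <- simulate_fragments(rs, w, 40, seed = 74)
  asn <- retrieve_pairs(fr$fragments, dup)
  m <- evaluate_retrieval(asn, fr$fragments, target_genomes = "genome1")
  expect_equal(m$per_genome$recall, 0)
  expect_equal(m$per_genome$precision, 1)  # 0/0 defined as 1
})

test_that("grid search is exhaustive, deterministic and monotone where
           theory says it must be", {
  cm <- make_community(n_genomes = 2, n_fragments = 250, seed = 111)
  # grid of size 1 equals a direct evaluation
  g1 <- grid_search(cm$frags$fragments, cm$frags$fragments, cm$refset,
                    data.frame(max_mismatch = 0))
  asn <- retrieve_pairs(cm$frags$fragments, cm$refset,
                        assign_params(max_mismatch = 0))
  m <- evaluate_retrieval(asn, cm$frags$fragments)
  expect_equal(nrow(g1), 1)
  expect_equal(g1$recall, m$micro$recall)
  expect_equal(g1$n_unique, sum(asn$status == "unique"))
  # widening max_frag never loses unique assignments on error-free data
  gf <- grid_search(cm$frags$fragments, cm$frags$fragments, cm$refset,
                    data.frame(max_frag = c(200, 300, 450)))
  expect_true(all(diff(gf$n_unique) >= 0))
  # raising max_mismatch on noisy data raises recall
  noisy <- make_community(n_genomes = 2, n_fragments = 250,
                          error_rate = 0.01, seed = 112)
  gm <- grid_search(noisy$frags$fragments, noisy$frags$fragments,
                    noisy$refset, data.frame(max_mismatch = c(0, 2)))
  expect_gt(gm$recall[2], gm$recall[1])
  expect_equal(attr(gm, "best")$max_mismatch, 2)
})

test_that("per-genome share of assigned reads is plain percentage arithmetic", {
  sh <- genome_share(c(g3 = 2345508, rest = 2995024 - 2345508))
  expect_equal(round(unname(sh["g3"]), 1), 78.3)
  expect_equal(sum(sh), 100)
})
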