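test_that("empty and degenerate reference sets are valid", {
  rs <- generate_references(0)
  expect_s3_class(rs, "sagscope_refset")
  expect_equal(length(rs$contigs), 0)
  expect_equal(nrow(rs$cds), 0)
  d <- withr::local_tempdir()
  paths <- write_refset(rs, d)
  expect_true(all(file.exists(paths)))
  rt <- read_refset(paths[["fasta"]], paths[["gff3"]], paths[["housekeeping"]])
  expect_equal(nrow(rt$cds), 0)
})

test_that("reference generation is reproducible and round-trips", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  rs1 <- generate_references(2, 6000, n_cds_per_genome = 6, seed = 11)
  rs2 <- generate_references(2, 6000, n_cds_per_genome = 6, seed = 11)
  p1 <- write_refset(rs1, d1); p2 <- write_refset(rs2, d2)
  expect_identical(readLines(p1[["fasta"]]), readLines(p2[["fasta"]]))
  expect_identical(readLines(p1[["gff3"]]), readLines(p2[["gff3"]]))
  rt <- read_refset(p1[["fasta"]], p1[["gff3"]], p1[["housekeeping"]])
  expect_identical(as.character(rt$contigs), as.character(rs1$contigs))
  expect_equal(rt$cds[order(rt$cds$cds_id), ]$start,
               rs1$cds[order(rs1$cds$cds_id), ]$start)
  expect_setequal(rt$housekeeping_ids, rs1$housekeeping_ids)
})

test_that("housekeeping flagging takes the floor of the requested fraction", {
  rs <- generate_references(3, 6000, n_cds_per_genome = 5, hk_fraction = 0.4,
                            seed = 5)
  # brute-force count over the generated annotation, per genome
  for (g in unique(rs$cds$genome_id)) {
    ids <- rs$cds$cds_id[rs$cds$genome_id == g]
    expect_equal(sum(rs$housekeeping_ids %in% ids), 2)  # floor(0.4 * 5)
  }
})

test_that("generated CDS never overlap and stay inside their contig", {
  rs <- generate_references(2, 10000, n_cds_per_genome = 10,
                            cds_len_range = c(300, 600), seed = 21)
  for (cid in unique(rs$cds$contig_id)) {
    sub <- rs$cds[rs$cds$contig_id == cid, ]
    sub <- sub[order(sub$start), ]
    expect_true(all(sub$start >= 0 & sub$end <= 10000))
    if (nrow(sub) > 1) {
      expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
    }
  }
  expect_error(generate_references(1, 1000, n_cds_per_genome = 10,
                                   cds_len_range = c(300, 400), seed = 1),
               "capacity")
})

test_that("expression weights are normalised, symmetric at sigma 0, and
           recover the requested dispersion", {
  rs <- generate_references(1, 4000, n_cds_per_genome = 4, seed = 3)
  w0 <- sample_expression(rs, lognormal_sigma = 0)
  expect_equal(unname(w0), rep(0.25, 4))
  for (s in c(1, 2, 3)) {
    w <- sample_expression(rs, lognormal_sigma = 1.5, seed = s)
    expect_equal(sum(w), 1, tolerance = 1e-9)
    expect_true(all(w >= 0))
  }
  big <- generate_references(1, 300000, n_cds_per_genome = 1000,
                             cds_len_range = c(200, 250), seed = 4)
  w <- sample_expression(big, lognormal_sigma = 1.5, seed = 9)
  expect_equal(sd(log(w)), 1.5, tolerance = 0.15)
})

test_that("zero-fragment simulation writes empty outputs", {
  cm <- make_community(n_fragments = 0)
  expect_equal(nrow(cm$frags$fragments), 0)
  d <- withr::local_tempdir()
  paths <- write_fragments(cm$frags, d)
  expect_true(file.exists(paths[["fastq1"]]))
  expect_equal(file.info(paths[["fastq1"]])$size, 0)
  expect_equal(nrow(read_truth(paths[["truth"]])), 0)
})

test_that("error-free reads are exact genomic substrings in FR orientation", {
  cm <- make_community(n_fragments = 200, seed = 77)
  f <- cm$frags$fragments
  seqs <- as.character(cm$refset$contigs)
  for (i in seq_len(nrow(f))) {
    frag <- substring(seqs[[f$contig_id[i]]], f$frag_start[i] + 1,
                      f$frag_end[i])
    if (f$cds_strand[i] == "+") {
      expect_identical(f$mate1_seq[i],
                       substring(frag, 1, nchar(f$mate1_seq[i])))
    } else {
      expect_identical(
        f$mate2_seq[i], substring(frag, 1, nchar(f$mate2_seq[i]))
      )
    }
  }
  # mate2 is the reverse-complement strand of mate1's fragment
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  i <- which(f$insert_size == nchar(f$mate1_seq))[1]
  if (!is.na(i)) {
    expect_identical(f$mate2_seq[i], rc(f$mate1_seq[i]))
  }
})

test_that("fragment counts per CDS follow the multinomial sampling model", {
  rs <- generate_references(1, 30000, n_cds_per_genome = 20, seed = 13)
  w <- sample_expression(rs, lognormal_sigma = 0.5, seed = 14)
  fr <- simulate_fragments(rs, w, 10000, seed = 15)
  obs <- table(factor(fr$fragments$cds_id, levels = names(w)))
  p <- suppressWarnings(stats::chisq.test(as.integer(obs), p = w))$p.value
  expect_gt(p, 0.001)
})

test_that("observed insert sizes match the requested distribution", {
  cm <- make_community(n_genomes = 2, contig_len = 20000, n_cds = 15,
                       n_fragments = 10000, seed = 31)
  ins <- cm$frags$fragments$insert_size
  se <- sd(ins) / sqrt(length(ins))
  expect_lt(abs(mean(ins) - 149), 3 * se)
})

test_that("simulation outputs are byte-identical for a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    rs <- generate_references(1, 6000, n_cds_per_genome = 5, seed = 8)
    w <- sample_expression(rs, seed = 9)
    fr <- simulate_fragments(rs, w, 100, error_rate = 0.01,
                             qual_model = "decay", seed = 10)
    write_fragments(fr, d)
  }
  for (f in c("sim_1.fastq", "sim_2.fastq", "sim_truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("FASTQ pair and truth table round-trip through files", {
  cm <- make_community(n_fragments = 50, seed = 19)
  d <- withr::local_tempdir()
  paths <- write_fragments(cm$frags, d)
  pr <- read_pairs(paths[["fastq1"]], paths[["fastq2"]])
  expect_equal(pr$fragment_id, cm$frags$fragments$fragment_id)
  expect_equal(pr$mate1_seq, cm$frags$fragments$mate1_seq)
  expect_equal(pr$mate2_qual, cm$frags$fragments$mate2_qual)
  tr <- read_truth(paths[["truth"]])
  expect_equal(tr$frag_start, cm$frags$fragments$frag_start)
})

test_that("background transcription yields intergenic fragments outside CDS", {
  rs <- generate_references(1, 20000, n_cds_per_genome = 5,
                            cds_len_range = c(300, 600), seed = 171)
  w <- sample_expression(rs, seed = 172)
  fr <- simulate_fragments(rs, w, 2000, background_rate = 0.3, seed = 173)
  f <- fr$fragments
  n_bg <- sum(is.na(f$cds_id))
  expect_gt(n_bg, 0.2 * 2000)
  expect_lt(n_bg, 0.4 * 2000)
  # background reads are still genomic substrings and count as no_feature
  # unless they happen to overlap a CDS
  ct <- count_fragments(perfect_assignments(fr), rs$cds)
  expect_gt(ct$tallies[["no_feature"]], 0)
  expect_equal(sum(ct$counts$count) + sum(ct$tallies), 2000)
  seqs <- as.character(rs$contigs)
  i <- which(is.na(f$cds_id))[1]
  frag <- substring(seqs[[f$contig_id[i]]], f$frag_start[i] + 1, f$frag_end[i])
  if (f$cds_strand[i] == "+") {
    expect_identical(f$mate1_seq[i], substring(frag, 1, nchar(f$mate1_seq[i])))
  }
})

test_that("enforce_unique_kmers leaves every canonical seed k-mer unique", {
  rs <- generate_references(3, 3000, n_cds_per_genome = 3,
                            cds_len_range = c(300, 500), seed = 55)
  rs <- enforce_unique_kmers(rs, 11)
  seqs <- as.character(rs$contigs)
  kms <- unlist(lapply(seqs, function(s) {
    p <- seq_len(nchar(s) - 10)
    substring(s, p, p + 10)
  }), use.names = FALSE)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kms)))
  expect_false(any(duplicated(pmin(kms, rc))))
})
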