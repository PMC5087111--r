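#!/usr/bin/env Rscript
# Step 4 — coverage-based polycistron inference: per-base read coverage of
# the target genome, zero-coverage loci, and candidate polycistron calls
# (runs of consecutive same-strand CDS with no uncovered intergenic base),
# cross-checked against the exhaustive gap-scan oracle.

suppressPackageStartupMessages(library(sagscope))
simdir <- "results/sim"
outdir <- "results/polycistrons"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

community <- read_refset(file.path(simdir, "community.fasta"),
                         file.path(simdir, "community.gff3"),
                         file.path(simdir, "community_housekeeping.txt"))
pairs <- read_pairs(file.path(simdir, "rep1_1.fastq"),
                    file.path(simdir, "rep1_2.fastq"))
asn <- retrieve_pairs(pairs, community, assign_params(max_mismatch = 2))

cid <- "genome1_c1"
clen <- community$contig_info$length[community$contig_info$contig_id == cid]
track <- coverage_track(asn, cid, clen)
export_bedgraph(track, file.path(outdir, paste0(cid, ".bedGraph")))

zr <- zero_runs(track)
message(sprintf("%s: %d zero-coverage loci covering %d bp", cid, nrow(zr),
                sum(zr$end - zr$start)))

cds <- community$cds[community$cds$contig_id == cid, ]
cds <- cds[order(cds$start), ]
calls <- call_polycistrons(track, cds)
stopifnot(identical(calls$members,
                    polycistron_oracle(track, cds)$members))
multi <- calls[calls$n_members > 1, ]
message(sprintf("%d calls, of which %d multi-gene (candidate polycistrons)",
                nrow(calls), nrow(multi)))
print(calls[, c("call_id", "members", "n_members",
                "left_flank_zero", "right_flank_zero")])
export_calls_bed(calls, cid, file.path(outdir, paste0(cid, "_calls.bed")))
write.table(calls, file.path(outdir, "polycistron_calls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("note: the simulator transcribes each CDS on its own, so every gap ",
        "is uncovered and singleton calls are the correct outcome here.")

# Planted co-transcription: two transcribed blocks (genes 1-3 and 4-5 with
# covered gaps) separated and flanked by zero-coverage loci, the pattern a
# genuine polycistronic region leaves in read coverage.
starts <- c(50, 160, 270, 450, 560)
opcds <- tibble::tibble(
  cds_id = sprintf("op%02d", 1:5), genome_id = "sag", contig_id = "op_c1",
  start = starts, end = starts + 100L, strand = "+", annotated = TRUE,
  length_bp = 100L
)
opcov <- rep(0L, 700); opcov[51:370] <- 3L; opcov[451:660] <- 2L
optrack <- structure(list(contig_id = "op_c1", coverage = opcov),
                     class = "sagscope_coverage")
opcalls <- call_polycistrons(optrack, opcds)
stopifnot(identical(opcalls$members,
                    polycistron_oracle(optrack, opcds)$members))
message("planted co-transcribed blocks are merged into multi-gene calls:")
print(opcalls[, c("members", "n_members", "left_flank_zero",
                  "right_flank_zero")])
write.table(opcalls, file.path(outdir, "planted_operon_calls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote ", outdir)
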