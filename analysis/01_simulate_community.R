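#!/usr/bin/env Rscript
# Step 1 — build the synthetic study system: four symbiont genomes with CDS
# annotations and housekeeping flags, one host "genome" as metatranscriptome
# background, per-CDS expression weights, and three replicate ground-truthed
# paired-end libraries (101 bp reads, ~149 bp inserts, 0.5% substitution
# errors, decaying 3' qualities).

suppressPackageStartupMessages(library(sagscope))
outdir <- "results/sim"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
seed <- 20160318

symbionts <- generate_references(4, 20000, n_cds_per_genome = 12,
                                 cds_len_range = c(300, 1200),
                                 hk_fraction = 0.25, seed = seed)
host <- generate_references(1, 40000, n_cds_per_genome = 20,
                            cds_len_range = c(300, 1200),
                            genome_prefix = "host", seed = seed + 1)
community <- enforce_unique_kmers(combine_refsets(symbionts, host), 15)
write_refset(community, outdir, "community")
message("reference community: ", length(community$contigs), " contigs, ",
        nrow(community$cds), " CDS (",
        length(community$housekeeping_ids), " housekeeping)")

weights <- sample_expression(community, lognormal_sigma = 1.5,
                             seed = seed + 2)
for (r in 1:3) {
  fr <- simulate_fragments(community, weights, 20000,
                           error_rate = 0.005, qual_model = "decay",
                           seed = seed + 10 + r)
  write_fragments(fr, outdir, sprintf("rep%d", r))
  message(sprintf("replicate %d: %d pairs, mean insert %.1f bp", r,
                  nrow(fr$fragments), mean(fr$fragments$insert_size)))
}
write.table(data.frame(cds_id = names(weights), weight = weights),
            file.path(outdir, "expression_weights.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote ", outdir)
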