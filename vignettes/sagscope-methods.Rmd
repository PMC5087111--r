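---
title: "Retrieving a symbiont's transcriptome from host metatranscriptomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrieving a symbiont's transcriptome from host metatranscriptomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sagscope)
```

## The problem

Uncultivated bacterial symbionts — such as the Poribacteria that densely
populate the mesohyl of marine sponges — cannot be profiled by ordinary
RNA-seq: their transcripts arrive mixed with host mRNA and with transcripts
of every other community member. When single amplified genomes (SAGs) of the
taxon exist, its transcriptome can be *retrieved computationally*: map the
bulk metatranscriptome reads against the SAGs, keep only confident
assignments, and quantify expression per gene. The catch is that the
retrieval step itself needs validation — reads from close relatives or the
host can mis-map, and the mapping parameters (fragment-length bounds,
mismatch tolerance, uniqueness requirement) trade recall against precision.

`sagscope` implements this workflow end to end at desk scale, together with
the simulation harness needed to validate it, and the quantitative
microscopy summaries (FISH probe co-localization, IHC positivity, 3D
granule morphometry) used to ground the transcriptional findings in
cellular structure.

## The simulator defines the study conditions

`generate_references()` builds random-nucleotide genomes carrying
non-overlapping CDS on random strands; a host "genome" generated the same
way but excluded from the retrieval targets stands in for sponge mRNA
background. `sample_expression()` draws per-CDS weights from a log-normal
(default `sdlog = 1.5`), the standard heavy-tailed model of prokaryotic
expression — it guarantees a genuine "highly expressed" tail for the
classification step to find. Weights are normalised to sum to one and act
as multinomial sampling probabilities for fragments.

`simulate_fragments()` emulates an Illumina HiSeq-style non-stranded paired
library: 101 bp reads, insert sizes `N(149, 30)` rounded and clipped into
`[1, CDS length]`, uniform fragment placement within the sampled CDS, FR
orientation with mate 1 on the transcript strand. Reads are
`min(101, insert)` long, so short inserts produce read-through-shortened
mates and CDS shorter than a read yield reads spanning the whole CDS —
every simulated read is an exact genomic substring before errors.
Substitution errors are independent per base (no indels, matching the
ungapped aligner); qualities are constant Phred 38 or, in `"decay"` mode,
drop linearly after a random breakpoint to exercise quality truncation.
An optional `background_rate` places a fraction of fragments uniformly on
the genome outside any transcript model. Every fragment's origin is
recorded in a truth table; read ids encode provenance too, but the TSV is
the contract.

What the generator does **not** emulate: rRNA carry-over, amplification
bias, indels, strand-specific library chemistry, or shared sequence between
community genomes (see below). Passing tests therefore demonstrate the
correctness of the pipeline's logic under its stated error model, not
robustness to every artefact of real libraries.

## Retrieval: QC, assignment, validation

Quality processing mirrors the standard two-step rule: truncate each read
strictly before its first base with Phred < 20, then drop pairs in which
either mate is shorter than 16 bp (`qc_params()` exposes both thresholds).
Truncation is idempotent.

`assign_pairs()` is a deliberately transparent seed-and-extend aligner:
exact k-mer seeds (default `seed_k = 15`, all non-overlapping windows of
each mate in both orientations) propose candidate loci, which are extended
ungapped while counting mismatches (budget `max_mismatch` per mate). Mates
are paired under forward–reverse orientation with the inferred fragment
length — the outer distance, the SAM `TLEN` magnitude — inside
`[min_frag, max_frag]` (defaults 20 and 450, the conventional `-I/-X`
bounds for this library type). A pair is `unique` only when exactly one
best-scoring placement survives; tied placements are reported `multi` and
discarded downstream, never broken randomly, because downstream counting
admits only unambiguous evidence. `frag_out_of_bounds` and `unmapped`
complete the status set, so every input pair is accounted for. The aligner
is validated against `align_bruteforce()`, an independent all-positions
oracle, on small instances.

Two constructive guarantees make the validation exact rather than
probabilistic: `enforce_unique_kmers()` point-mutates the generated genomes
until every canonical seed k-mer occurs exactly once across the community,
so error-free reads cannot multi-map; under those conditions per-genome
precision and recall are exactly 1, and the test suite asserts equality,
not closeness. With 1% substitution errors and `max_mismatch = 0`, recall
collapses to roughly `0.99^202` (both mates error-free) and recovers
monotonically as the budget grows — the behaviour `grid_search()` tabulates
over a parameter grid, reporting the best row by F1 deterministically.

Real-data use goes through SAM: `write_sam()` emits the unique pairs with
proper flags and signed TLEN, and `read_sam_assignments()` imports an
external mapper's SAM into the same assignment layout.

## Counting and expression

`count_fragments()` reimplements union-mode, non-strand-specific fragment
counting: the feature set of a pair is the union over both aligned mates of
all CDS overlapping at least one aligned base. The unsequenced inner gap of
the fragment contributes nothing — counting is read-based, which is also
why coverage tracks are read-based (below). One feature increments that
CDS; none or several increment `no_feature` / `ambiguous`; non-unique,
out-of-bounds, unmapped and QC-removed pairs each have their own tally, so
counts plus tallies always equal the number of input pairs. A pair is one
fragment: both mates in the same CDS count once. An exhaustive
interval-overlap oracle (`count_oracle()`) backs the implementation in
tests.

FPKM is computed per target genome:
`FPKM_g = count_g / ((len_g/10^3) * (N/10^6))` with `N` the fragments
assigned to that genome's CDS in that replicate. Using the per-genome `N`
(rather than the whole metatranscriptome) is the reading consistent with
per-SAG expression tables; it makes the conservation identity
`sum(FPKM * len_kb) = 10^6` hold exactly per replicate, which the tests
assert to numerical precision. Expression is summarised relative to a
user-supplied housekeeping set: the baseline is the arithmetic mean of
replicate-averaged FPKM over housekeeping CDS (replicate-mean-then-gene-mean
order), a gene is *highly expressed* iff its mean FPKM strictly exceeds the
baseline (fold `FPKM_HK > 1`; a gene exactly at baseline is excluded), and
percentile ranks use the strictly-smaller-fraction definition, so ties
share a percentile and a constant profile ranks everything at 0. Replicate
concordance is plain Pearson correlation on per-CDS FPKM vectors;
zero-variance replicates are flagged rather than propagated as errors.

## Polycistron inference

Transcribed operons leave a characteristic footprint: uninterrupted read
coverage across intergenic gaps, bounded by uncovered loci.
`coverage_track()` accumulates per-base depth from unique placements
(read-based; a fragment-span mode exists behind a flag),
`zero_runs()` extracts maximal uncovered intervals, and
`call_polycistrons()` merges consecutive CDS into one call when no base
strictly between them falls below `min_depth` (default 1 — the literal
zero-coverage reading; raise it for noisy data). Same-strand adjacency is
required by default on operon-biology grounds, though it is configurable
since coverage alone cannot prove co-orientation for a non-stranded
library. CDS without a single covered base are excluded from calls, and
every covered CDS belongs to exactly one call. Flanking zero-coverage is
reported as evidence flags (within a configurable window, default 100 bp)
rather than required, since transcript boundaries outside the window are
common. An exhaustive gap-scan oracle validates the caller.

Because the simulator transcribes each CDS independently, simulated data
correctly produce singleton calls; the analysis scripts therefore also
demonstrate the merge behaviour on planted two-block coverage patterns
(three genes co-covered, a zero gap, two genes co-covered), the footprint a
genuine polycistronic region produces.

## Quantitative microscopy

The microscopy arm consumes already-labelled masks — segmentation and
registration of raw micrographs are upstream, out of scope. A 2D
`label_field()` holds prokaryote-scale DAPI object labels, host cell
labels, and binary probe/protein masks at a known pixel size. An object is
probe-positive when at least `min_overlap_fraction` (default 0.25) of *its
own* pixels fall on the probe mask — a fraction-of-object rule chosen over
any-pixel overlap for robustness to mask dilation; the threshold is
configurable because no standard rule exists. Protein (IHC) positivity
applies the same rule with the probe-positive objects as denominator.
Summaries are reported both pooled (ratios of summed counts) and as
per-area means with n−1 standard deviations; the two disagree whenever
fields differ in size, so both are first-class outputs.

A 3D `voxel_model()` holds cell and granule voxel masks with anisotropic
voxel sizes (z defaults to 0.1 µm, the serial-section spacing). Volume is
voxel count × voxel volume; equivalent spherical diameter is
`(6V/π)^(1/3)`; the bipolarity score projects granule centroids onto the
cell's principal axis (first principal component of the cell voxel
coordinates in physical units) and scores 1 iff the two largest granules
fall in opposite axial halves — a minimal operationalisation of "bipolar",
which has no established metric. Digitised-sphere fixtures converge to the
analytic volume as voxels shrink; tests require 3% agreement at 10 nm
voxels for a 168 nm sphere. Note that a 168 nm-diameter sphere has volume
2.48×10⁻³ µm³; reported granule volumes and diameters are computed
independently from the voxel data, never derived from one another.

The fixture generators place objects on jittered grids (2D) or as
digitised ellipsoids/spheres (3D) with exact requested counts, so the
generator–quantifier loop closes exactly; capacity violations are errors,
not silent truncation.

## Numerical and interface conventions

* All intervals are 0-based half-open internally; GFF3/SAM/BED conversion
  happens only at the file boundary (via `rtracklayer`/`Biostrings`).
* Every stochastic entry point takes an integer `seed`; fixed seeds give
  byte-identical FASTA/FASTQ/GFF3/TSV outputs.
* Ratios with empty denominators are defined once, centrally: precision and
  recall use 0/0 = 1 (a genome with no assignments has made no mistakes);
  empty-denominator percentages in microscopy are `NA` with an `undefined`
  flag.
* Problem sizes in the tests and analysis scripts (4 × 20 kb genomes,
  10⁴–10⁵ fragments, 220-CDS expression recovery) were chosen as the
  smallest scales at which every validated property is stably observable;
  all results regenerate in minutes on one core.

## Known limitations

* The aligner is mismatch-only and ungapped; indels in real data shift
  placements and must be handled by an external mapper via the SAM import
  path.
* Random genomes carry no homology, so cross-mapping between related
  community members — the hard case for real SAG references — is
  represented only by the duplicated-reference worst case in the tests.
* Replicates simulated from shared weights measure technical (sampling)
  noise only; biological replicate divergence is not modelled, so simulated
  replicate correlations run higher than real ones.
* FPKM inherits its known incomparability across samples with different
  library compositions; no TPM or count-model normalisation is provided.
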