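---
title: "svscout: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{svscout: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

svscout calls germline structural variants (SVs) — deletions (DEL),
insertions (INS), tandem duplications (DUP), inversions (INV) and
translocations (TRA) of 50 bp and larger — from coordinate-sorted long-read
BAM files. This vignette explains the model and the procedure, the
parameters that matter, what the built-in simulator does and does not
emulate, and the design choices made where more than one reasonable option
existed.

## Pipeline overview

1. **Feature extraction.** For every reference position, ten alignment-derived
   counts are collected separately for forward- and reverse-strand reads
   (20 channels): aligned depth; coverage by CIGAR deletions ≥ `min_op`;
   insertion anchors (I ≥ `min_op`); left and right clips ≥ 20 bp; split-read
   junction counts in four flavours (colinear, inverted, backward-jump/
   duplication-like, inter-contig, all derived from SA tags of primary
   alignments); and coverage by reads whose substitution rate exceeds twice
   the regional mean. Only primary alignments with mapping quality ≥ 20
   contribute; supplementary alignments enter solely through SA tags so no
   junction is double-counted.
2. **Window classification.** The per-site matrix is tiled into 2000 bp
   windows of ten 200 bp submatrices. A small CNN with channel and spatial
   attention embeds each submatrix; a transformer encoder with sinusoidal
   positional encodings lets the ten embeddings of a window exchange
   information; a linear head scores each submatrix for SV content.
   Submatrices above the probability threshold are merged (touching or
   overlapping intervals collapse to `[min(starts), max(ends))`) into
   candidate regions.
3. **Signature extraction.** Within candidate regions (extended by the
   largest clustering bandwidth), reads are re-scanned: CIGAR D/I operations
   ≥ `min_op` give DEL/INS signatures; adjacent split-alignment segment
   pairs give DEL, INS, DUP (backward reference jump), INV (strand flip) or
   BND (contig change) signatures, with junction coordinates derived from
   the strand-aware segment ends.
4. **Clustering.** Per SV type and contig, breakpoint positions are grouped
   by mean shift under a Gaussian kernel density estimate. The bandwidth is
   1000 bp for DEL, 300 bp for INS and 500 bp for DUP and INV; when the
   sample's mean read error rate is below 0.10 it is raised to 1500 bp for
   all types, since precise reads scatter breakpoints less and sparser,
   wider gathering is safe. Clusters are refined into subclusters of similar
   length: members are sorted by length and a new subcluster opens when a
   member differs from the opener of the current one by at least
   `median(length) × 0.7`. Breakends are not density-clustered; two BNDs are
   paired when both ends lie on the same contig pair within 1000 bp.
5. **Support filtering.** A subcluster becomes a PASS call when its distinct
   supporting reads reach
   `ceil(mu * C_global^phi * (1 + rho * tanh((C_local - C_global)/C_global)))`,
   clamped below at 2. Defaults are `mu = 1.0`, `phi = 0.6`, `rho = 0.4`;
   when the error rate is ≥ 0.10 or global coverage is below 10×, the
   relaxed pair `mu = 0.8`, `rho = 0.3` is used. These defaults put the
   threshold in the 2–10 read range conventional for 5–70× long-read
   calling (e.g. 8 reads at 30×); all are exposed in `support_params()`.
6. **Genotyping.** Reads spanning the locus (±50 bp) without a matching
   signature count as reference support. Three genotypers run on the
   (ref, alt) counts under a binomial model with per-read variant
   observation probability ε (0/0), ½ (0/1), 1−ε (1/1): a Bayesian call
   with priors (0.40, 0.40, 0.20); an EM iteration over genotype weights;
   and the support-ratio rule (reference fraction > 0.7 → 0/0, variant
   fraction > 0.7 → 1/1, otherwise 0/1). The majority vote wins; a
   three-way tie falls back to the Bayesian call because it integrates the
   prior and is deterministic. The plain likelihood argmax is recorded
   alongside for diagnostics.
7. **Output.** Calls are written as VCF 4.2 with symbolic ALT alleles;
   SVLEN is negative for DEL and positive otherwise; a TRA becomes two
   mated BND records in bracket notation. Internally all coordinates are
   0-based half-open; conversion to 1-based happens only at VCF emission.

## The window model

The classifier is implemented on a small reverse-mode automatic
differentiation engine over base-R matrices (`R/autograd.R`): dense matrix
products, broadcast add/multiply, ReLU/sigmoid/softmax/layer norm, block
pooling, im2col-based 1-D convolution, a fused scaled-dot-product attention
and a weighted logistic loss, optimised with Adam. Every operation's
gradient is validated against central finite differences in the test suite,
as is the full model end to end for all three variants.

Default architecture (all in `sv_model_config()`): input max-pool by 2 along
positions, two 1-D convolutions (kernel 5, channels 16 then 32) with a
max-pool of 4 between them; channel attention (reduction 8, shared MLP over
mean- and max-pooled descriptors) followed by spatial attention (kernel 7
over the per-position mean/max channel profile); global mean **and** max
pooling concatenated and projected to a 128-dimensional embedding; a
2-layer, 4-head pre-norm transformer (feed-forward width 256, dropout 0.1)
over the ten submatrix slots; a per-submatrix linear head. Max pooling at
the readout matters: insertion anchors, clips and split junctions occupy a
single position in a 200 bp submatrix, and a mean-only readout dilutes them
by two orders of magnitude. Counts are divided by the sample's global mean
coverage before entering the network, which makes a model trained at 30×
transfer to other depths without retraining.

Training minimises binary cross-entropy with a positive-class weight equal
to the negative/positive label ratio (SV submatrices are rare), for at most
a fixed number of epochs with early stopping on validation loss
(patience 3); the best-validation parameters are kept. One seed controls
initialisation, the train/validation split and shuffling; the split is
drawn before parameter initialisation so that every model variant trained
with the same seed sees the identical split. The transformer's
residual-branch output projections start at zero, making the untrained
transformer the identity: the combined model begins on the CNN encoder's
solution path and learns cross-submatrix context on top, which removes the
slow-start the combined architecture otherwise shows in short schedules.

With the weighted loss the classifier is deliberately recall-heavy at the
0.5 threshold: candidate regions are cheap to verify downstream, while a
missed region is unrecoverable, so the submatrix-level false positives it
admits are cleaned up by signature extraction and the support filter.
Because 0.5 is therefore not a meaningful summary operating point, a
trained model also records calibrated validation scores (`$val_scores`):
the threshold maximising F1 on the training split, evaluated on the
held-out split. Region proposal keeps the 0.5 threshold.

Three variants support the ablation harness: `full`, `cnn_only` (encoder +
head, no transformer) and `transformer_only` (linear patch embedding
replacing the CNN). Per-submatrix binary output was chosen over a
window-level softmax; the submatrix is the unit the region merger consumes.

## The simulator

`sv_simulate()` generates uniform-random contigs, implants SVs and
constructs aligned reads analytically — no external aligner is involved, so
the alignments are exactly consistent with the implanted truth and fully
deterministic per seed. Donor haplotypes are block lists over the
reference; heterozygous variants (fraction 0.5 by default) go to one random
haplotype. Reads sampled from a haplotype are walked through the blocks:
colinear stretches become M/D/I CIGAR runs, while duplication, inversion
and translocation junctions split the read into supplementary alignments
with SA tags and correct strands, for both sequencing orientations.
Substitution errors are injected at the configured rate and reflected in NM.

Default benchmark conditions: two 1 Mb contigs, 20 SVs per type of
60–2000 bp, heterozygous fraction 0.5, 30× coverage, 10 kb ± 2 kb reads,
10% substitution error. A translocation is modelled as an inter-chromosomal
segment insertion (2–5 kb copied from the partner contig), which keeps all
other truth coordinates fixed; each event contributes its two junctions as
two TRA truth entries, so the configured TRA count is in junctions and must
be even. Placement uses randomised slots that keep events at least two
maximal SV lengths apart.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: alignment ambiguity in repeats and low-complexity
sequence, reference bias, platform-specific error profiles (homopolymer
indels, chimeras), small-indel sequencing noise in CIGARs, nested or
overlapping SVs, and quality strings. Results on it are an upper bound on
real-data behaviour; the pipeline's robustness knobs (error-rate-dependent
bandwidth, the relaxed support regime) exist precisely for signals the
simulator renders cleanly.

## Numerical choices and degenerate inputs

* Mean shift iterates until the largest shift is below 1 bp or 200
  iterations; converged modes closer than half a bandwidth merge, with ties
  broken toward the smaller coordinate. Agreement with an exhaustive
  grid-KDE hill-climbing oracle is asserted on random instances in the
  tests.
* Length refinement compares each member against the first (shortest)
  member of the open subcluster, scanning in sorted order — a deterministic
  reading of the pairwise rule.
* The EM genotyper starts from uniform weights; its E-step responsibilities
  are proportional to prior-weight × binomial likelihood, so its argmax
  equals the flat-prior Bayesian argmax from the first iteration onwards
  and the iteration converges geometrically (tolerance 1e-6, cap 100).
  Zero total support yields `./.` rather than a genotype.
* Empty inputs are contracts, not errors: an empty region gives an all-zero
  feature matrix, an empty matrix no windows, no signatures no clusters,
  and an empty call set a header-only (still parseable) VCF.
* `min_support` clamps at a floor of 2 reads; `tanh` bounds the local
  adjustment to ±rho, so the threshold always lies within
  `mu*C^phi*(1±rho)`.

## Problem sizes used by the shipped checks

The acceptance script and test suite train on a 2 × 600 kb simulation
(20 SVs/type, 30×) under the fixed 20-epoch schedule with early-stopping
patience 5, and benchmark on the default 2 × 1 Mb sample; the negative
control is an SV-free 2 × 500 kb sample at 30×. These sizes give several
hundred positive submatrices — enough for the classifier to converge —
while keeping a full run in the minutes range on a single CPU. The model
ablation (full vs `cnn_only` vs `transformer_only`) is scored by submatrix
F1 on the benchmark genome's labelled windows rather than on the
training-side validation split: the independent sample carries roughly five
times as many positive submatrices, which is what it takes to resolve the
variant ordering above the noise of a few borderline submatrices. The
combined model also converges markedly more slowly than the CNN-only
variant (best validation loss near the end of the schedule versus around
epoch 13), which is why the schedule is run to its fixed length rather than
stopped at the CNN's plateau. Larger genomes train the same way via
`sv_train()`; per-contig work is independent and merged in deterministic
contig order.

## Known limitations

* The ten feature channels are this package's own concrete instantiation of
  a per-site alignment summary; they cover the five signature classes but
  are defined behind a single constructor (`extract_site_features()`) so the
  set can be revised without touching the model.
* Somatic variants, nested SVs (e.g. INV within INV) and overlapping SVs on
  homologous chromosomes are out of scope.
* The EM and Bayesian genotypers share the binomial emission model; they
  differ only through the prior, so the vote's diversity comes mainly from
  the ratio rule at low support.
* Training on one CPU is minutes-scale for desk-sized genomes but the
  engine is not suited to whole-genome training; the architecture is
  intentionally small.
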