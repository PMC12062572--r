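# svscout

Structural variant (SV) calling from long-read alignments: deletions (DEL),
insertions (INS), tandem duplications (DUP), inversions (INV) and
translocations (TRA) of 50 bp and larger, from a coordinate-sorted, indexed
BAM. svscout is aimed at method development and teaching at desk scale: it
ships its own alignment simulator, so the entire pipeline — training
included — runs end to end on a laptop with no external data.

## Method

svscout detects SVs in three stages:

1. **Learned region proposal.** For each reference position, 10 alignment
   features are counted per strand (depth, long CIGAR deletion/insertion
   events, clips, four classes of split-read junctions from SA tags, and
   low-identity coverage), giving a 20-channel matrix. 2000 bp windows of
   ten 200 bp submatrices are scored by a CNN with channel/spatial
   attention whose submatrix embeddings are contextualised by a transformer
   encoder; adjacent positive submatrices merge into candidate regions
   \[min(starts), max(ends)).
2. **Breakpoint clustering.** Read-level signatures (CIGAR D/I operations
   and split-read junctions) are extracted inside candidate regions and
   clustered by KDE mean shift over breakpoint position, with bandwidths of
   1000 bp (DEL), 300 bp (INS) and 500 bp (DUP/INV), raised to 1500 bp for
   low-error samples (< 10% mean read error); clusters are split into
   subclusters of similar length via the median-length rule (ratio 0.7).
   Breakends are paired positionally into TRA clusters.
3. **Filtering and genotyping.** A subcluster passes when its distinct
   supporting reads reach the coverage-adaptive minimum

   min_support = ceil( mu * C_global^phi * (1 + rho * tanh((C_local − C_global) / C_global)) )

   (defaults mu = 1, phi = 0.6, rho = 0.4, floor 2; relaxed to mu = 0.8,
   rho = 0.3 for high-error or < 10x samples). Genotypes (0/0, 0/1, 1/1)
   come from a majority vote over Bayesian, expectation–maximisation and
   read-support-ratio genotypers under a binomial read-observation model.
   Calls are written as VCF 4.2 (symbolic ALTs; TRA as mated BND records).

The window model is trained with Adam on weighted binary cross-entropy; the
package carries its own small reverse-mode autodiff engine over base-R
matrices, with every operator gradient verified against finite differences
in the test suite. See `vignettes/svscout-methods.Rmd` for the full account.

## Worked example

Simulate a diploid sample, train the classifier on an independently seeded
simulation, call, and evaluate:

```r
library(svscout)

train <- sv_simulate(sim_config(ref_length = 600000, seed = 1001), "sim_train")
model <- sv_train(train$bam, train$truth, sv_model_config(seed = 8),
                  epochs = 20, patience = 5)

bench <- sv_simulate(sim_config(seed = 1), "sim_bench")   # 2 x 1 Mb, 20 SVs/type, 30x
res   <- sv_call(bench$bam, model, output_vcf = "calls.vcf",
                 reference = bench$ref_fasta)
pass  <- res$calls[res$calls$filter == "PASS", ]
evaluate_calls(pass, bench$truth)$per_type
```

Output from this run:

```
  svtype n_truth n_calls tp precision recall f1
1    DEL      20      20 20         1      1  1
2    DUP      20      20 20         1      1  1
3    INS      20      20 20         1      1  1
4    INV      20      20 20         1      1  1
5    TRA      20      20 20         1      1  1
```

Every implanted variant is recovered with no false positives; because the
simulator constructs alignments analytically, called breakpoints typically
sit exactly on the truth coordinates. On real aligner output, repeat-driven
ambiguity would lower these numbers — the simulator's scope is discussed in
the methods vignette.

The same workflow is available from the shell via the installed `svscout`
script (subcommands `simulate`, `train`, `call`, `evaluate`).

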