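# methylSD

Signal-detection analysis of whole-genome bisulfite sequencing (WGBS)
methylomes in R.

## The problem

Per-cytosine methylation counts are intrinsically stochastic: spontaneous
epimutations and sampling noise produce large methylation differences
between biological replicates of the *same* condition. The prevalent
analysis recipe — a per-site Fisher exact test (or logistic/beta-binomial
regression) followed by an arbitrary methylation-difference cutoff and
fixed-window DMR binning — has no model of that background variation, so
its calls mix treatment-associated signal with stochastic fluctuation, and
its window-based density rules discard sparse but genuine signal.

`methylSD` implements the alternative signal-detection strategy for users
analysing plant (or other) WGBS experiments with replicated controls:

1. **Centroid reference.** Control replicates (at least three) are pooled
   by element-wise count summation; the pooled methylome is the reference
   that captures background variation.
2. **Divergence.** For every sample *s* (controls included) and every
   cytosine, the divergence between the sample and reference Bernoulli
   methylation distributions is computed as the squared Hellinger
   divergence
   *H(p, q) = (√p − √q)² + (√(1−p) − √(1−q))²* ∈ [0, 2],
   its coverage-weighted form *w·H* with *w = 2n₁n₂/(n₁+n₂)*, and the
   total variation distance *|p − q|*.
3. **Generalized gamma model.** Each sample × context divergence
   distribution is fitted by maximum likelihood with the generalized gamma
   family
   *f(x; α, ψ, δ) = δ/(ψΓ(α)) (x/ψ)^(αδ−1) e^(−(x/ψ)^δ)*,
   which nests the gamma (δ = 1), Weibull (α = 1) and exponential members.
   Candidate DMPs are sites above the fitted 95th percentile.
4. **Learned cutoff.** The classification cutoff separating control
   candidates (background) from treatment candidates is learned by an
   exhaustive threshold sweep maximizing Youden's J; each replicate's DMPs
   are then assessed against its own fitted distribution.
5. **Gene-level GLM.** Per-sample DMP counts in annotated genes
   (≥ 3 treatment DMPs and ≥ 3 DMPs / 10 kbp) are tested with a
   Poisson / negative-binomial likelihood-ratio test; genes with BH-adjusted
   p < 0.05 and log₂ fold change > 1 are DMGs.

The package also ships the prevalent **baseline pipeline** (pooled Fisher
exact test, 20% level-difference cutoff, 100-bp window DMRs) for
side-by-side comparison, **downstream analysis** (hypergeometric term fold
enrichment; k-means core-hub detection on six network centrality metrics),
and a **simulator** of bisulfite count experiments with planted signal and
ground truth.

## Worked example

```r
library(methylSD)

# a synthetic 3v3 experiment: 200 kbp genome, 100 genes, ~10,000 cytosines,
# 20 signal genes shifted by 0.4 in the treatment replicates
exp <- simulate_experiment(genome_spec(),
                           sim_design(n_signal_genes = 20, effect_size = 0.4,
                                      seed = 7))
res <- run_signal_detection(exp$samples, exp$genes)

res$cutoffs$CG
#> <cutoff_model CG> cutoff=6.423 (youden)  acc=0.975 sens=1.000 spec=0.928 fdr=0.038 youden=0.928

res$models[["trt_1.CG"]]
#> <divfit gamma3p> alpha=1.885 psi=0.08342 delta=0.3477  logLik=-1869.47 AIC=3744.93 n=2470 (6 zeros dropped, KS=0.026)

res$dmg_table[order(p_adjusted)][1:5]
#>     gene_id family_used mean_ctl mean_trt log2fc lrt_stat p_adjusted is_dmg
#> 1: GENE0050     poisson     9.67     81.7   3.08      195   6.65e-43   TRUE
#> 2: GENE0074     poisson     4.33     61.0   3.82      176   4.05e-39   TRUE
#> 3: GENE0011     poisson     4.00     56.3   3.82      163   2.34e-36   TRUE
#> 4: GENE0036     poisson     4.67     55.3   3.57      151   5.61e-34   TRUE
#> 5: GENE0076     poisson     8.67     63.7   2.88      142   5.10e-32   TRUE
```

The learned CG cutoff separates control from treatment candidates almost
perfectly (Youden 0.93); the top genes are planted signal genes with
treatment DMP counts an order of magnitude above their control counts. On
this run the pipeline calls 19 DMGs: 19 of the 20 planted genes and no
false calls. Contrasting with the baseline pipeline:

```r
bl  <- run_baseline(exp$samples, exp$genes)
cmp <- run_compare(res$dmgs, bl$dmgs)
#> signal-only 0 | overlap 19 | baseline-only 6 | Jaccard 0.760
```

Real inputs enter the same way: a tab-separated sample sheet
(`sample_id`, `path`, `group`) pointing at Bismark-style CX reports, plus a
GFF3 annotation — `run_signal_detection("samples.tsv", "genes.gff3",
out_dir = "run1")`. A command-line wrapper with `simulate`, `detect`,
`baseline` and `compare` subcommands is installed at
`system.file("cli", "methylsd", package = "methylSD")`.

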