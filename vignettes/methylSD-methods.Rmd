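---
title: "Methods: signal-detection methylome analysis in methylSD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal-detection methylome analysis in methylSD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylSD)
```

# The model

WGBS yields, for every cytosine, a pair of counts (methylated,
unmethylated) whose ratio estimates the methylation level of that site in
that replicate. Two sources of variation ride on top of any treatment
effect: binomial sampling noise at finite read depth, and spontaneous
epimutation — stochastic level changes that occur in every replicate of
every group. A calling method that has no model of this background will
attribute part of it to the treatment.

`methylSD` treats calling as a signal-detection problem:

1. **Reference methylome.** The control replicates are pooled by
   element-wise count summation over the union of site keys. Summation
   (rather than averaging proportions) makes the reference level at a site
   the coverage-weighted mean of the control levels and preserves read
   depth for the weighted divergence. Because pooling fewer replicates
   cannot represent background variation, fewer than three controls is an
   error unless `strict = FALSE`.

2. **Divergence.** At each site shared between a sample and the reference
   (both passing the coverage filter), with levels $q$ (sample) and $p$
   (reference), the package records the squared Hellinger divergence
   $H = (\sqrt p - \sqrt q)^2 + (\sqrt{1-p} - \sqrt{1-q})^2 \in [0,2]$,
   its coverage-weighted form $w\,H$ with $w = 2 n_1 n_2/(n_1+n_2)$ (the
   harmonic-mean depth), and the total variation distance $|p - q|$.
   Controls are deliberately included among the compared samples: their
   divergences against the pooled reference are the empirical null used
   later for cutoff learning.

3. **Distribution model.** Within each sample and context, the positive
   divergences are fitted with the generalized gamma family
   $$f(x;\alpha,\psi,\delta) = \frac{\delta}{\psi\,\Gamma(\alpha)}
     \left(\frac{x}{\psi}\right)^{\alpha\delta-1}
     e^{-(x/\psi)^\delta},$$
   which nests the gamma ($\delta=1$), Weibull ($\alpha=1$) and
   exponential members. Sites whose divergence exceeds the fitted 95th
   percentile of their own sample's model are *candidate* DMPs — in
   controls these measure background, in treatments background plus
   signal.

4. **Cutoff learning.** The divergence threshold that best separates
   control candidates (label 0) from treatment candidates (label 1) is
   found by an exhaustive sweep over all observed candidate divergences
   under the rule "divergence ≥ cutoff → treatment", maximizing Youden's
   J (accuracy is available). This is deliberately a deterministic 1-D
   optimal-threshold learner, not a fitted classifier: the decision
   variable is one-dimensional and monotone, so a threshold is the
   complete family of monotone classifiers, and determinism makes every
   run reproducible. A `scorer` hook accepts alternative learners.

5. **Per-replicate assessment.** The learned cutoff is a raw divergence
   value. Because each control contributes its own counts to the pooled
   reference, control divergences are structurally smaller than treatment
   divergences even in the complete absence of treatment effect (with
   three pooled controls the level-difference variance is
   $\tfrac{2}{3}\sigma^2$ for a control versus $\tfrac{4}{3}\sigma^2$ for
   a treatment replicate). Applying one absolute threshold to both groups
   would therefore count systematically more treatment DMPs under a true
   null. The pipeline instead assesses each candidate against its own
   replicate's fitted distribution: the learned cutoff is converted to
   the probability level $u^\*$ it occupies under the treatment-sample
   models (mean CDF), and each sample applies its own quantile
   $Q_s(u^\*)$ as cutoff. For treatment replicates this applied cutoff
   is essentially the learned one; for controls it is the
   background-scale equivalent. Hypo- and hyper-methylated DMPs are kept
   equally; direction is annotated, never filtered.

6. **Gene-level test.** DMPs are counted per sample within annotated
   genes (1-based inclusive boundaries, strand ignored, overlapping genes
   both counted). Genes with at least `dmg_min_dmps = 3` pooled treatment
   DMPs and a density of at least `dmg_min_density = 3` per 10 kbp are
   tested: intercept-only versus group-effect GLM, Poisson always,
   negative binomial additionally when the pooled counts are
   overdispersed (variance > mean; otherwise NB degenerates to Poisson),
   family chosen by AIC on the group model, likelihood-ratio statistic
   against $\chi^2_1$, Benjamini–Hochberg adjustment, and the DMG rule
   adjusted $p < 0.05$ and $\log_2$ fold change $> 1$ (one-sided by
   default, matching the count-increase reading of the fold-change gate;
   two-sided available).

## The baseline pipeline

For comparison the package implements the prevalent recipe faithfully,
including its arbitrary constants: replicates pooled within group, a
two-sided Fisher exact test per shared site (the "probability mass ≤
observed" convention, computed by direct hypergeometric enumeration), BH
adjustment, a methylation-difference cutoff of 20% (`>=` at the boundary;
published cutoffs range from 10 to 40%), and non-overlapping 100-bp tiles
reported as DMRs when they hold ≥ 3 DMPs. A gene is a baseline DMG iff it
intersects a DMR. Logistic and beta-binomial variants and sliding windows
are intentionally out of scope.

## Downstream analysis

*Enrichment.* For a term with $K$ annotated genes among $N$ population
genes and $k$ hits among $n$ study genes, fold enrichment is
$(k/n)/(K/N)$ and the p-value the hypergeometric upper tail
$P(X \ge k)$; results are BH-adjusted and filtered to fold strictly above
`min_fold` (fourfold and tenfold are typical working thresholds).
No ontology-graph propagation is performed.

*Network hubs.* After single-pass removal of nodes with fewer than 2
edges (cascading removal is available but off by default, matching
network-viewer semantics), six per-node metrics are computed: unnormalized
betweenness (unordered pairs, endpoints excluded), closeness
$(n_c-1)/\sum d$, average shortest path length $\sum d/(n_c-1)$, local
clustering coefficient, degree, and eccentricity — distance metrics per
connected component, isolated nodes receiving 0 by convention. Closeness
and average path length are reciprocally related; both are kept as
separate features because the clustering procedure is defined over that
six-metric list. Metrics are z-standardized before k-means (their raw
scales differ by orders of magnitude; unstandardized Euclidean distance
would be degree-dominated), then Lloyd's algorithm runs with $k = 3$ and
up to 500 iterations from a seeded draw of $k$ distinct profiles. The
*core hub* is the cluster with the highest mean standardized
degree + betweenness — "highest centrality" operationalized through the
two metrics that dominate connectivity scores; any single metric can be
selected via configuration.

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `min_coverage` | 4 | reads | Field-conventional floor; deliberately mild. Surfaced in config and logs because it is arbitrary. |
| `prior` | (0.5, 0.5) | pseudo-counts | Jeffreys-type; avoids undefined levels and extreme $\sqrt{}$ terms at low coverage. Applied only when computing levels, never stored. |
| `divergence` | `hdiv_w` | — | Coverage-weighted divergence carries read-depth information; `hdiv` available for closed-form work. |
| `prob` | 0.95 | probability | The fitted-distribution percentile defining candidate DMPs. |
| `criterion` | `youden` | — | Cutoff-learning objective; `accuracy` available. |
| `min_tv` | unset | level difference | Optional extra TV floor on candidates. |
| `dmg_min_dmps`, `dmg_min_density` | 3, 3/10 kbp | counts | Gene gates applied to pooled treatment-group DMPs (per-sample gating is a config choice away). |
| `dmg_alpha`, `dmg_lfc_min` | 0.05, 1 | — | DMG thresholds. |
| `baseline_min_diff` | 0.20 | level difference | The baseline's arbitrary cutoff, kept faithful. |
| `baseline_window`, `baseline_min_dmps` | 100 bp, 3 | — | Fixed, non-overlapping DMR tiles. |

# Numerical choices

* **Generalized gamma MLE.** For fixed $\delta$, $x^\delta$ is gamma
  distributed, so the inner $(\alpha,\psi)$ maximization is solved
  exactly by Newton iteration on the shape (closed-form start), and only
  $\delta$ is profiled by 1-D search on $\log\delta \in
  [\log 0.05, \log 20]$. The fit is exactly deterministic given the data
  — no random restarts. Zeros are excluded (the model describes positive
  divergence) and counted; fewer than 30 positive values or all-equal
  values are errors. AIC plus a Kolmogorov–Smirnov statistic are reported
  but never gate the pipeline.
* **Model selection.** Lowest AIC wins; exact ties break toward fewer
  parameters; candidates that fail to fit are dropped.
* **Cutoff sweep.** The Youden objective is compared in exact integer
  arithmetic ($\mathrm{TP}\cdot n_0 - \mathrm{FP}\cdot n_1$), so ties
  between mathematically equal cutoffs are resolved deterministically
  toward the smallest cutoff rather than by floating-point noise.
* **Fisher two-sided p.** Hypergeometric enumeration with the standard
  one-sided relative tolerance ($1+10^{-7}$) against floating ties, and a
  final clamp at 1.
* **Level-difference boundary.** `delta_filter` subtracts $10^{-12}$ from
  the cutoff so a difference exactly at 20% passes despite binary
  representation ($0.6 - 0.4 < 0.2$ in doubles).
* **Degenerate inputs.** Empty site intersections warn and return empty
  tables; an empty candidate class falls back to the percentile threshold
  alone (logged); all-identical centrality profiles collapse $k$ with a
  warning; genes whose GLM fails in both families are reported with
  $p = 1$ and a note rather than dropped.

# Open design decisions taken

* The divergence formula (the source methodology names the quantity but
  not the estimator): squared Hellinger divergence between Bernoulli
  distributions, with the harmonic-mean-depth weight available as
  `hdiv_w`; downstream modeling uses the weighted form by default.
* Distribution fits are per sample × context — matching per-replicate
  assessment — rather than per group or pooled.
* One cutoff is learned per context across all replicates (not per
  replicate); candidates from *all* treatment replicates and *all*
  controls enter the sweep.
* Controls are compared against the full self-inclusive pooled reference;
  the structural divergence-scale difference this induces is corrected at
  the DMP-counting stage by the quantile-matched per-replicate cutoffs
  described above.
* The GLM response is per-sample DMP counts per gene (not raw methylation
  count sums); the fold change is computed on those counts. This is the
  most direct reading of a count-based gene test with an "at least three
  DMPs" gate, and is documented as interpretive.
* Count/density gene gates use pooled treatment-group DMPs.

# The simulator

`simulate_experiment()` emulates the statistical structure the pipeline
assumes, at desk scale:

* **Genome.** One 200-kbp chromosome, 100 non-overlapping genes of
  1–3 kbp, ~10,000 cytosines mixed 60% CHH / 25% CG / 15% CHG — a
  plant-like context mix. The defaults pack genes densely; a drawn length
  vector that cannot be placed without overlap is rescaled proportionally
  to fit with a minimal gap budget.
* **Levels.** Context-specific baselines: CG bimodal concentrated near 0
  and 1 (beta mixture), CHG intermediate, CHH low — the canonical plant
  pattern.
* **Noise.** Each site in each replicate (both groups) redraws its level
  from the context distribution with probability `epimutation_rate`
  (default 0.01 — an order of magnitude above per-generation germline
  epimutation rates, standing in for cumulative somatic and measurement
  stochasticity).
* **Signal.** A chosen set of genes shifts the level of a
  `signal_site_fraction` share of its cytosines by `effect_size`
  (default 0.4), clamped to [0, 1], in treatment replicates only;
  direction is mixed 50/50 across signal genes. Fractions below 1 plant
  *sparse* signal that defeats window-based density rules while remaining
  detectable at gene level.
* **Counts.** Coverage is negative-binomial (mean 20, dispersion 5,
  emulating WGBS depth variability); observed methylated counts are
  binomial in the replicate's level.

Everything derives from one seed; identical seeds give byte-identical
output files, and a truth table records all underlying levels and planted
genes.

What the simulator does **not** model — and what passing tests therefore
do not demonstrate about real data: linkage between neighbouring
cytosines (real methylation is spatially autocorrelated, especially CG),
strand-symmetric CpG coupling, bisulfite conversion error, mapping bias,
transgenerational epimutation inheritance, and context-dependent coverage.
Type-I control and recovery results on simulated data are statements about
the pipeline's behaviour under its own assumptions.

# Test problem sizes

The suite exercises the statistical properties at sizes chosen to make
the checks sharp while keeping a full run in minutes: parameter recovery
at 20 replicates of $n = 5000$; the cutoff learner against an exhaustive
sweep on 500 random instances ($n \le 200$ per class); Fisher p against
enumeration over all 2×2 tables with margins ≤ 15; BH against brute force
on 1000 random vectors; centralities against brute-force all-pairs
shortest paths on 200 random graphs of ≤ 8 nodes; and the type-I /
recovery simulations on a 2-Mbp, 500-gene genome with 40,000 cytosines at
3v3 replication.

# Known limitations

* Gene-level calling only; exon- or transposable-element-level features
  are not yet supported.
* The Fisher baseline's logistic and beta-binomial siblings are not
  implemented; comparisons are against the Fisher variant.
* No smoothing across neighbouring sites, by design: kernel assumptions
  valid for CG/CHG do not hold for CHH.
* `log2fc` is $+\infty$ when a gene has treatment DMPs but zero control
  DMPs in every control replicate; such genes pass the fold gate whenever
  they pass significance.
* The learned cutoff assumes at least some candidate DMPs in both groups;
  severely underpowered designs fall back to the percentile threshold.
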