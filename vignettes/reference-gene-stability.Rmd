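---
title: "Selecting RT-qPCR reference genes: models and methods in refstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting RT-qPCR reference genes: models and methods in refstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Relative quantification by RT-qPCR normalises a target gene's expression
against one or more reference genes, on the assumption that the reference is
expressed at a constant level across all samples and conditions. That
assumption fails often enough — reference-gene stability is tissue- and
species-specific — that a dedicated selection study is the accepted first
step before any quantitative expression work in a new system. `refstab`
implements that selection study as a pipeline: quantification-cycle (Cq)
preprocessing, four independent stability algorithms, and a comprehensive
rank aggregation, together with a synthetic-data generator that makes every
stage testable against a known ground truth.

The packaged example data come from a blood reference-gene study in beluga
whales: 13 candidate housekeeping genes (*ACTB*, *B2M*, *GAPDH*, *HPRT1*,
*LDHB*, *PGK1*, *RPL4*, *RPL8*, *RPL18*, *RPS9*, *RPS18*, *TFRC*, *YWHAZ*)
measured in 60 blood samples from four animals spanning healthy,
inflammation, skin-lesion and internal-disease states, plus a 30-sample
random subset (`beluga_stability_table()`, `beluga_efficiencies()`).

## Preprocessing model

**Replicate collapsing.** Reactions run in technical triplicate are averaged
when the triplicate SD (n−1 denominator throughout the package) is below 0.5
cycles; noisier sets are flagged and their cell becomes missing. A singleton
replicate is kept with SD defined as 0 — data are never discarded silently.
Because the stability algorithms need a complete matrix, samples with any
missing cell are dropped up front with a warning naming them; the flag rate
is monotone non-increasing in the threshold, which the tests assert.

**Plate controls.** An identical reaction on every plate monitors inter-plate
drift; plates may be pooled into one data set when the plate-control Cq SD is
below 0.5 cycles (`plate_control_qc()`).

**Amplification efficiency.** A five-point, 10-fold dilution series is fit
by ordinary least squares of Cq on log10 relative dilution, and efficiency
derived from the slope as \(E = (10^{-1/slope} - 1) \times 100\%\). Assays
are gated at 95–105% efficiency with \(R^2 > 0.99\). Per-gene efficiencies
are usually the mean of several curve fits; the package accepts a
precomputed efficiency table as the normal input path.

**Efficiency-corrected Cq.** With amplification factor \(b = 1 + E/100\) and
per-gene calibrator \(Cq_{min}\) (the lowest observed Cq of that gene, i.e.
its most expressed sample), raw Cq is re-expressed on an ideal-doubling
scale:
\[ Cq_{corr} = Cq_{min} + \Delta Cq \cdot \log_2 b, \qquad
   \Delta Cq = Cq - Cq_{min}. \]
This is the unique affine transform with the property
\(2^{-\Delta Cq_{corr}} = b^{-\Delta Cq}\): base-2 relative quantities
computed from corrected Cq equal true-efficiency relative quantities
computed from raw Cq. It is the identity at \(E = 100\%\), preserves each
gene's minimum and the within-gene ordering for any \(E > 0\). When a subset
of samples is analysed, \(Cq_{min}\) is recomputed within the subset so the
analysis is self-contained.

## The four stability algorithms

All four return per-gene values with "lower = more stable", ranked by
competition ranking (ties share the best rank: 1, 1, 3).

**Comparative ΔCt** (`delta_ct_stability()`). For every gene pair, the SD
across samples of the pairwise Cq difference; a gene's score is the mean of
its pair SDs. Shared sample-to-sample shifts cancel in the differences.

**geNorm** (`genorm()`). Works on relative quantities
\(Q_{ig} = b^{Cq_{min,g} - Cq_{ig}}\) (base 2 on corrected Cq, since
efficiency is already folded in). A gene's M value is the mean over partners
of the SD of \(\log_2(Q_g/Q_k)\); the worst gene is excluded and M
recomputed until two remain, which share the final M and rank 1 (next rank
3) — the 1, 1, 3 pattern visible in the packaged tables. With base 2 the
first-step M equals the comparative ΔCt score gene for gene, a cross-check
the test suite enforces to 1e-10 on random matrices. The pairwise-variation
series \(V_{n/n+1}\) — SD across samples of the log-ratio of normalization
factors built from the n and n+1 top genes — determines how many reference
genes are needed: the smallest n with \(V < 0.15\)
(`recommend_gene_count()`). M below 1.5 is the conventional acceptability
cut-off. Within-step ties on the worst M exclude the alphabetically last
gene, a deterministic package convention.

**NormFinder** (`normfinder_stability()`). A model-based approach: log-scale
expression \(y_{ig} = -Cq_{ig}\) is modelled as
\(y_{ig} = \alpha_g + \beta_i + \epsilon_{ig}\), where the sample effect
\(\beta_i\) absorbs RNA-input and RT-yield variation, and the gene-specific
noise SD \(\sigma_g\) is the stability value. The single-group moment
estimator uses the doubly-centered residuals \(r_{ig}\): with \(v_g\) their
sample variance over samples,
\[ \hat\sigma^2_g = \Big(v_g - \frac{\sum_k v_k}{G(G-1)}\Big)\frac{G}{G-2},
   \quad \text{floored at } 0. \]
This is unbiased under the model up to \(O(1/n)\) terms (the test suite
verifies the mean of \(\hat\sigma^2\) over 500 simulated data sets at
n = 200, G = 8 to within 5%). When condition groups are supplied, the same
estimator is applied within groups and pooled by degrees of freedom; the
full multi-group intergroup-variation term is deliberately out of scope, as
one ranking per sample set is the reporting convention here.

**BestKeeper** (`bestkeeper()`). Per-gene dispersion of Cq itself — sample
SD by default, mean absolute deviation about the mean as the `"mad"` option
(the original tool's descriptor; the default matches the "SD" column label
of the published tables). Because it works on Cq rather than relative
quantities, shared sample loading counts against every gene — the one
algorithm that is *not* invariant to per-sample shifts, which the property
tests assert in both directions. Dispersion below 1 cycle is the
conventional "stably expressed" gate. The BestKeeper index (per-sample
geometric mean of Cq) and each gene's Pearson correlation with it are
reported but do not enter the ranking.

## Comprehensive ranking

Each algorithm contributes one rank column; a gene's comprehensive score is
the geometric mean of its four ranks and the final order is ascending in
that score (`comprehensive_rank()`). The geometric mean lies between the
best and worst single rank, and a gene ranked last by all four lands last
with score G. The published tables do not show geomean ties; for
determinism, ties are broken by the best single-algorithm rank, then by
gene name. Geomeans are conventionally printed to 2 decimals; full precision
is kept internally.

Genes can carry an advisory "unsuitable" flag (e.g. a gene whose expression
tracks leukocyte counts is a poor reference for immunology work even if
numerically stable); flags annotate the recommendation text and never move
ranks. The expression summary classes genes as high (mean Cq < 25) or low
expression — the boundary Cq = 25 is assigned to "low", since one side must
own it — supporting the practice of pairing reference genes with targets of
similar expression level.

## Synthetic data and what it does (not) show

`generate_cq_dataset()` draws
\[ Cq_{ig} = \mu_g + \delta_i + \Delta_{c(i),g} + \epsilon_{ig}, \qquad
   \delta_i \sim N(0, \tau), \; \epsilon_{ig} \sim N(0, \sigma_g), \]
with triplicate noise and optional +2-cycle outlier replicates on top. The
sample shift \(\delta_i\) has loading 1 on every gene — it models shared RNA
input, exactly the variation the relative-quantity methods are built to
ignore, giving a sharp discriminating test against BestKeeper. Defaults
mirror the blood-panel design the package ships data for: 13 genes with
baselines spread over Cq 22–31, noise SDs spanning 0.05–0.8 cycles (the
implied true stability order), shift SD τ = 0.5, four animals, condition
classes in 30:6:9:15 proportions, triplicates, 100% true efficiency.

Property tests built on the generator show parameter recovery (Spearman
≥ 0.9 between the true σ order and each relative-quantity ranking at 13
genes × 60 samples, averaged over 20 seeds) and that a condition-regulated
pseudo-housekeeper sinks into the bottom half of the ranking. What passing
these tests does *not* show: real blood Cq data have non-Gaussian tails,
gene–gene correlation beyond the shared shift (co-regulation, which the
pairwise methods are known to reward), and plate batch structure; the
generator emulates none of these beyond the plate-control hook.

## Numerical choices and problem sizes

All SDs use the n−1 denominator; all logs in the stability algorithms are
base 2. Simulation-backed tests use fixed seeds and sizes chosen to keep the
full suite under a few minutes on one CPU: the unbiasedness check at
n = 200, G = 8 with 500 replicates; the equivalence check on 100 random
matrices; recovery at 60 samples over 20 seeds; monotonicity at n = 500.
Degenerate inputs are contracts, not crashes: singleton replicates are kept,
flagged cells become missing, matrices with missing cells are refused by the
algorithms with advice to drop incomplete samples, fewer than three genes is
an error for geNorm (stepwise exclusion undefined) and NormFinder (variance
separation impossible), and a non-negative standard-curve slope marks the
curve invalid rather than producing a nonsense efficiency.

One design question the data leave open is whether published stability
tables of this kind were computed from raw or corrected Cq, and whether the
BestKeeper column is SD or MAD; the pipeline defaults to corrected Cq and SD
and exposes both as switches (`input_scale`, `dispersion`).

## A worked run

```{r example}
sim <- generate_cq_dataset(synthetic_truth(seed = 42), n_samples = 60)
corrected <- correct_cq(sim$matrix, data.frame(
  gene = sim$truth$genes, efficiency_percent = unname(sim$truth$efficiency)))
fit <- ref_stability(corrected)
fit
summary(fit)
```

The comprehensive ranking tracks the generator's ascending-σ truth; the
V series typically recommends two reference genes at the default noise
levels, matching the behaviour seen in well-behaved blood panels.

```{r published}
tab <- beluga_stability_table(60)
res <- comprehensive_rank(tab[, c("gene", "delta_ct_rank", "bestkeeper_rank",
                                  "normfinder_rank", "genorm_rank")])
head(as.data.frame(res), 4)
```

## Limitations

The multi-group NormFinder intergroup term, geNorm's normalization-factor
export for downstream target quantification, BestKeeper's regression
p-values, and any handling of raw fluorescence (baseline/threshold
determination) are out of scope. The advisory-exclusion mechanism is
metadata only. Rankings from 13 genes and 30–60 samples carry sampling
noise of their own: the packaged 60- and 30-sample tables disagree in rank
detail while agreeing on the top group, which is the realistic resolution
of a study this size.
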