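---
title: "Methods: mRNA stabilome analysis from actinomycin-D chase RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mRNA stabilome analysis from actinomycin-D chase RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The experimental design

A transcription-shutoff ("chase") experiment estimates mRNA decay without
metabolic labeling: cells are stimulated (here with TNF) for a time $t$,
actinomycin D (ActD) is added to arrest transcription, and expression is
re-measured a fixed interval $t_c$ later (3 h by default). For gene $i$ at
stimulation time $t$ the **stability ratio**

$$ S_{t,i} \;=\; \frac{\bar{x}^{\,\mathrm{TNF+ActD}}_{t,i}}{\bar{x}^{\,\mathrm{TNF}}_{t,i}} $$

compares mean expression (RPKM or normalized counts, replicates averaged
per arm **before** the ratio) with and without the chase. Under complete
shutoff and first-order decay with rate $\lambda_{t,i}$,
$\mathbb{E}[S_{t,i}] \approx e^{-\lambda_{t,i} t_c}$, so $S$ near 1 marks a
stable transcript and $S$ near 0 an unstable one. Ratios are clipped to
$[0,1]$ for classification (the raw value is retained) and binned into five
equal-width classes of 0.2: class 1 ($S < 0.2$, very unstable) through
class 5 ($S \ge 0.8$, very stable). The bin width is inferred from the
published 0.2 / 0.8 thresholds for "very unstable" and "very stable"
transcripts; it is a configurable default, not a printed constant.

# The dependent-ratio GLM for differential stabilization

Chase-arm counts are statistically dependent on the no-chase counts of the
same gene, so comparing stability between an early ($C=0$, default 1 h) and
a late ($C=1$, default 72 h) stimulation time is a *ratio-of-ratios*
problem. Each gene's eight libraries (2 arms × 2 times × 2 replicates) are
modeled as NB with log link and log size-factor offsets:

$$ \log \mu^{i}_{\mathrm{TNF},C} = \beta^i_C + \beta^i_{\mathrm{TNF}},
\qquad
\log \mu^{i}_{\mathrm{TNF+ActD},C} = \beta^i_C + \beta^i_{\mathrm{TNF+ActD}}
 + \beta^i_{\Delta,C} $$

with $\beta_{\Delta,0} \equiv 0$. The interaction $\beta_{\Delta,1}$ is the
natural-log ratio-of-ratios — the change in the chase/no-chase ratio from
early to late. Differential stabilization is the likelihood-ratio test of
$\beta_{\Delta,1}=0$ (4 vs 3 free coefficients), referred to
$\chi^2_1$, with Benjamini–Hochberg adjustment across tested genes. The
**stabilization degree** reported alongside is
$\log_2(S_\mathrm{late}/S_\mathrm{early})$ computed from mean normalized
counts with pseudocount 0.5, so it is finite even for zero cells; ranking
sorts by degree, then adjusted p, then gene id.

The alternative model is saturated (four cells, four coefficients), so its
MLE is computed exactly from per-cell mean fits; the null model is fitted
by iteratively reweighted least squares (IRLS) with Fisher weights
$\mu/(1+k\mu)$, deviance tolerance $10^{-8}$, at most 100 iterations,
step-halving when the likelihood decreases, and a BFGS fallback with
analytic score on non-convergence. Non-convergent fits are flagged,
excluded from multiple testing and logged. LRT statistics that come out
negative within $10^{-6}$ (numerical noise) are set to 0; larger negatives
are flagged.

# Normalization and an identifiability caveat

Libraries are normalized with median-of-ratios size factors estimated
**jointly** across all arms and times and rescaled to geometric mean 1; the
reference uses genes positive in every sample (a positive-count fallback is
available via `pseudo_ref = TRUE`). Joint estimation keeps the chase and
no-chase arms on one scale, which the dependent-ratio model requires.

A consequence every user of chase RNA-seq should know: **depth
normalization cannot see a decay shift shared by all genes**. If every
transcript decayed identically during the chase, median-of-ratios (and
RPKM alike) would absorb the loss into the library scale and all stability
ratios would read ~1. Real stabilomes are dominated by stable transcripts,
which anchor the chase-arm factors, but measured ratios are always relative
to that anchor. For the same reason, validation simulations in which every
gene shares one decay rate are run with the known simulated library factors
— with estimated factors the target signal would be unidentifiable by
construction, not by implementation defect.

# Dispersion estimation

One NB dispersion per gene is shared across all design cells. Raw per-gene
dispersions maximize the profile likelihood of the saturated group-mean
model over a 45-point log-spaced grid ($10^{-8}$ to 30) with parabolic
refinement. The profile likelihood is **Cox–Reid adjusted by default**
(subtracting $\tfrac12\log\det X^\top W X$, which for the cell-mean model
is $\tfrac12\sum_g \log \sum_i w_{gi}$). With two replicates per cell,
profiling out four cell means biases the unadjusted MLE low by roughly a
factor of two, which makes the downstream LRT strongly anti-conservative;
with the adjustment the test suite's null-calibration criterion holds. The
adjustment therefore defaults to on (`cox_reid = FALSE` restores the plain
profile MLE).

The mean–dispersion trend is a gamma GLM with identity link and mean
function $k = a_0 + a_1/\bar\mu$ fitted to the raw dispersions of genes
with mean normalized count ≥ 1 and raw dispersion above $10^{-6}$,
with iterative trimming of estimates more than $10^4$-fold off the trend
(at most 10 passes) and non-negativity constraints on $a_0, a_1$. The
**final** per-gene dispersion is the trend prediction, floored at
$10^{-8}$ — no empirical-Bayes shrinkage toward the gene-wise value, since
at $n=2$ the trend is far more stable than any per-gene estimate. The cost
of trend-only dispersions is mild miscalibration for genes whose true
dispersion sits off the trend: with log-normal dispersion scatter (sd 0.3
in the simulator) the null p-value distribution is slightly conservative at
low counts, which the calibration test tolerates but a strict
goodness-of-uniformity test can detect. Essentially-Poisson data (fewer
than 10 positive raw dispersions) fall back to a flat floor-level trend
with a warning.

# Filters and thresholds

| parameter | default | role |
|---|---|---|
| `min_counts` | 100 | raw TNF-arm counts required for the two-group tests |
| `min_norm_counts` | 10 | mean normalized TNF-arm count required at both times for the stabilization GLM |
| `padj` | 0.1 | BH-adjusted significance threshold throughout |
| `fold_induced` | 2 | induced-gene threshold for the temporal-switch summary |
| `fold_highly_induced` | 5 | selection for kinetic clustering |
| `top_fraction` | 0.10 | top-expressed slice |
| `n_classes` | 5 | stability classes (bin width 0.2) |
| `k_clusters` | 6 | kinetic clusters |
| `early_h`, `late_h` | 1, 72 | stabilization comparison times |

The published count filters name "TNF treated conditions" without fixing
the aggregation; here the raw-count filter is the **sum over the TNF-arm
replicates at the tested time point**, and the normalized-count filter is
the **mean over TNF-arm replicates, required at both compared times**.
Both are parameters.

# Two-step workflow

Step 1 selects genes significantly down-regulated by ActD at the early
time (unstable candidates). Step 2 keeps those still expressed at the late
time and compares chase log2 fold changes: movement toward 0 = stabilized,
away = destabilized. Whether the original analysis additionally required
significance of the late-time test is not stated, so the summary reports
both variants (`sign_only` and `sign_and_late_significant`); genes lost at
the late time are logged with the reason.

# Induction kinetics and clustering

Induction at each time is the same two-group NB LRT against the
unstimulated controls; fold changes use pseudocount 0.5 on normalized
means. The `induced_2fold` / `induced_5fold` flags are fold-only (so they
are monotone in the threshold); significance is a separate column, and the
pipeline's cluster selection requires both, mirroring a "DESeq2-identified,
≥5-fold" selection.

Time-course profiles (controls at 0 h, TNF arm afterwards) are z-scored
per gene so shape outweighs magnitude; the distance is 1 − Pearson
correlation with average linkage, and the tree is cut at `k`. Neither the
distance nor the expression unit of the original clustering is published;
this combination is declared as the default because the reference heatmap
is row-normalized. Clusters are renumbered by the peak time of the mean
profile (ties by the profile's time centroid), which makes labels
deterministic and invariant to input order. Genes with constant profiles
are dropped with a warning (correlation is undefined).

# The synthetic-data generator

The generator emulates the study design: times {0, 1, 3, 24, 72} h, a 3 h
chase arm per stimulated time, 2 replicates, unstimulated controls at 0 h
(18 libraries). Five archetypes are mixed (defaults: early_transient 0.10,
intermediate 0.10, late_sustained 0.15, constitutive 0.60, silent 0.05):

* **early_transient** — induction peaking 16-fold at 1 h, decaying to
  baseline by 72 h; very unstable ($S = 0.1$). Half of these genes (the
  `frac_stabilized` default 0.5) get TNF-induced stabilization, $S$ rising
  0.1 → 0.8 across the time course — the stabilization phenomenon under
  study, with true $\beta_\Delta = \ln 8$ between 1 and 72 h.
* **intermediate** — peak at 24 h, $S = 0.5$.
* **late_sustained** — monotone rise to 10-fold at 72 h, $S = 0.9$.
* **constitutive** — no induction; $S$ drawn from a class mixture
  (0.05, 0.05, 0.10, 0.15, 0.65) dominated by very stable transcripts, as
  observed for expressed genes in fibroblast-like synoviocytes.
* **silent** — basal mean below 0.5, filtered out downstream.

Basal means are log-uniform on [5, 5000]; dispersions follow the trend
$0.01 + 2/\mu$ with log-normal scatter (sd 0.3, mean-unbiased); decay
rates get log-normal jitter (sd 0.15). Counts are NB
($\mathrm{Var} = \mu + k\mu^2$; Poisson at $k=0$), chase-arm means are the
TNF-arm means times $(1-\ell)e^{-\lambda t_c} + \ell$ with transcription
leakage $\ell = 0$ by default (complete shutoff, per the primary-transcript
controls in the source experiment; $\ell$ is exposed for robustness
checks). Library factors are log-normal (sd 0.1, geometric mean 1). A
single seed fully determines the output.

What the generator does **not** emulate: gene-length effects (RPKM inputs
are exercised with user-supplied lengths), batch or donor effects,
isoform switching, count outliers, or correlated genes. A green test
therefore establishes correctness of the estimators under the stated NB
world, not robustness to those artifacts.

# Known limitations

* Stability ratios are relative to the library anchor (see the
  identifiability caveat); absolute decay rates require spike-ins or
  metabolic labeling, both out of scope.
* Single-interval chase data cannot separate first-order from more complex
  decay kinetics; $S$ is a summary, not a half-life fit.
* With 2 replicates, per-gene dispersion information is minimal; the
  trend-only choice trades per-gene adaptivity for stability.
* The five-class boundaries and the clustering recipe are declared
  defaults where the original publication is silent; both are parameters.
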