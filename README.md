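# stabilome

Genome-wide mRNA stability analysis from actinomycin-D (ActD)
transcription-shutoff RNA-seq.

Inflammatory stimuli such as TNF shape gene expression not only through
transcription but through mRNA decay: in TNF-stimulated fibroblast-like
synoviocytes the inducible transcriptome switches from unstable transcripts
early to very stable (and actively *stabilized*) transcripts late in the
response. This package implements that analysis for anyone with gene-level
count tables from a chase design — stimulate, add ActD to arrest
transcription, re-sequence after a fixed interval — and provides a
ground-truth simulator so every stage can be validated end to end.

## What it computes

For gene *i* at stimulation time *t*, the **stability ratio**

    S(t, i) = mean expression(TNF + ActD) / mean expression(TNF)

is ~1 for stable and ~0 for unstable transcripts (under first-order decay,
`E[S] = exp(-lambda * t_chase)`). Genes are binned into five stability
classes of width 0.2 (class 1 very unstable, class 5 very stable).

**Differential stabilization** between an early and a late time is tested
with a dependent-ratio negative-binomial GLM. Per gene, the eight
libraries (two arms x two times x two replicates) are modeled with log
link and size-factor offsets:

    log mu[TNF, C]      = beta_C + beta_TNF
    log mu[TNF+ActD, C] = beta_C + beta_ActD + beta_Delta[C]

with `beta_Delta[early] = 0`. The likelihood-ratio test of
`beta_Delta[late] = 0` is referred to chi-squared(1) and BH-adjusted;
`beta_Delta` is the natural-log ratio-of-ratios, and genes are ranked by
the stabilization degree `log2(S_late / S_early)`. Dispersions are
per-gene Cox-Reid-adjusted profile MLEs smoothed by a gamma-regression
trend `k = a0 + a1/mean`. The package also provides the two-step
stabilized/destabilized workflow, TNF-induction tests against unstimulated
controls, temporal-switch stability densities of the induced sets,
top-expressed stability composition, and hierarchical clustering of
induction kinetics (1 - Pearson correlation, average linkage, z-scored
profiles).

## Worked example

```r
library(stabilome)

truth <- make_truth(2000, seed = 1)                  # known ground truth
sim   <- simulate_counts(truth, sim_design(seed = 2))# 2000 genes x 18 libraries

sf   <- size_factors(sim$counts)
expr <- normalized_counts(sim$counts, sf)

## stabilome composition at 1 h of TNF
st <- stability_ratio(expr, sim$sheet, time_h = 1, min_expr = 10)
stabilome_composition(st$stability_class[!st$excluded])
#>   class count   fraction
#> 1     1   224 0.13038417
#> 2     2    84 0.04889406
#> 3     3   129 0.07508731
#> 4     4   202 0.11757858
#> 5     5  1079 0.62805588

## differential stabilization, 1 h vs 72 h
res <- differential_stability_test(sim$counts, sim$sheet,
                                   early_h = 1, late_h = 72)
rank_stabilized(res, 5)[, c("gene_id", "beta_delta",
                            "stabilization_degree", "padj", "direction")]
#>     gene_id beta_delta stabilization_degree         padj  direction
#> 1 gene00019   3.162974             4.574001 1.016541e-27 stabilized
#> 2 gene00002   3.167505             4.541182 2.452931e-28 stabilized
#> 3 gene00029   3.108627             4.485273 2.896209e-76 stabilized
#> 4 gene00013   3.024015             4.358430 1.269653e-63 stabilized
#> 5 gene00099   2.937850             4.239685 5.158553e-67 stabilized
```

At 1 h, 13% of expressed genes are very unstable and 63% very stable; the
top-ranked genes are the simulator's stabilized early-transient archetype
(stability ratio rising 0.1 to 0.8, true `beta_Delta = ln 8 ~ 2.08`; the
reported estimates also carry each gene's decay-rate jitter and the
library-anchor shift discussed in the methods vignette). On this dataset
96.7% of the truly stabilized genes tested are called stabilized at
adjusted p < 0.1, with 9 false destabilized calls among 1651 tested genes.

## Command line

```sh
Rscript inst/cli/stabilome all --out results --ngenes 12000 --seed 1
Rscript inst/cli/stabilome simulate|stabilome|diffstab|kinetics \
    --config cfg.json [--counts counts.tsv --sheet sheet.tsv] [--seed N]
```

`all` simulates (when no counts are given) and writes every output table
(TSV with headers), a verbatim `config.json`, an `exclusions.tsv` log with
per-gene reasons, and a `manifest.json` (package version, seed, config,
input MD5s) sufficient to reproduce the run.

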