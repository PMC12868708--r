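---
title: "Mapping hereditary haemochromatosis risk: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping hereditary haemochromatosis risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfeRisk)
```

## The scientific problem

Hereditary haemochromatosis (ICD-10 E83.1) is a recessive iron-overload
disorder driven almost entirely, in European-heritage populations, by two
missense variants in *HFE*: p.Cys282Tyr (C282Y, chr6:26092913 G>A, GRCh38)
and p.His63Asp (H63D, chr6:26090951 C>G). The major risk genotype is the
C282Y homozygote; the C282Y/H63D compound heterozygote carries roughly
ten-fold lower risk; other genotypes are treated as risk-free here. Because
the allele frequency of C282Y varies several-fold across the British Isles,
the *population* risk of haemochromatosis is strongly regional — and
comparing genetically predicted risk with the prevalence of clinical
diagnoses in health records highlights regions where the condition appears
under-diagnosed.

`hfeRisk` implements that comparison end to end. The centre of the package
is `fit_hfe_risk()`, which behaves like a classical R model-fitting
function: it consumes a cohort of per-individual two-site genotypes with
region labels (plus, optionally, a diagnosis-count registry) and returns an
`hfe_risk` object with `print`, `summary`, `coef`, `predict`, `plot`,
`simulate` and `residuals` methods.

## The model

**Triallelic Hardy-Weinberg prediction.** The two variants are modelled as
three alleles (WT, C, H) of one locus with frequencies
$p_{wt} + p_C + p_H = 1$. The six genotype classes then have the usual HWE
probabilities; in particular the homozygote frequency is $q^2 = p_C^2$ and
the compound heterozygote $2\,p_C\,p_H$. Predicting genotype frequencies
from allele frequencies is far more precise than counting observed
homozygotes, because heterozygotes are more than twenty-fold more numerous.
The single-locus model ignores the possibility of a C282Y–H63D cis
haplotype; in practice the two variants essentially never co-occur on one
haplotype, and the triallelic form is what makes $2 p_C p_H$ the exact
compound-heterozygote frequency.

**Penetrance weighting.** The combined genetic risk of a region is
$$\mathrm{risk} = \pi_{hom}\, p_C^2 + \pi_{cmpd}\, 2 p_C p_H ,$$
the product of genotype frequencies and penetrances summed over the two
risk genotypes. The default `penetrance_model()` uses the male cumulative
incidences to age 80, $\pi_{hom} = 0.56$ and $\pi_{cmpd} = 0.06$. No female
default is shipped: published female penetrance is materially lower and
sex-mixing silently would be worse than requiring an explicit model, so the
label of the penetrance model is carried into every report.

**Prevalence and discrepancy.** Prevalence is raw: $100\,c/d$ percent for a
diagnosis count $c$ over denominator $d$, with "1 in
$\mathrm{round}(d/c)$". No age or sex standardisation is applied, matching
how national EHR feasibility counts are reported. The discrepancy statistic
is the ratio risk/prevalence; regions are ranked by it and the top-$k$
flagged as candidate under-diagnosis areas. The interpretation assumes
penetrance is uniform across regions — an assumption, stated in reports,
that dietary iron or diagnostic practice could violate.

```{r example}
r <- combined_risk(hfe_frequencies(0.0780, 0.1510))
r$risk_pct   # 0.482 % of males predicted to develop the condition by 80
```

## Statistical tests

* `hwe_chisq()` — Pearson goodness of fit of the 0/1/2-copy genotype counts
  of one variant (the third allele collapsed into the reference class)
  against HWE at the sample allele frequency; 1 df because one frequency is
  estimated. The test is direct $\sum (O-E)^2/E$ arithmetic; any expected
  class of zero is a degenerate-input error rather than a silent `NaN`.
* `compare_frequencies_chisq()` — 2×2 Pearson chi-square on allele counts
  (not genotype counts), no continuity correction, 1 df. Sources describing
  these regional comparisons do not define their one-sided convention, so
  the package adopts the direction-matching half-p rule: the one-sided p is
  half the two-sided p when the observed direction matches the alternative,
  and its complement otherwise. Allele counting (rather than
  homozygote-vs-rest) was chosen as the conventional single-df comparison;
  this is a documented design choice, not a reproduction claim.

## Ancestry assignment

Two stages mirror how population groups are isolated before frequency
estimation:

* **DBSCAN on top-2 PC coordinates** (`dbscan_points()`, hand-implemented
  since no density-clustering package is available here): Euclidean, with
  `min_pts` counting the point itself. Border points reachable from two
  clusters join the cluster expanded first in index order — an explicit,
  reproducible tie-break, verified in tests against a brute-force
  density-reachability oracle. `select_core_cluster()` keeps the cluster
  holding the plurality of a seed group (e.g. people born in the target
  country).
* **IBD-graph community detection.** `build_ibd_graph()` keeps segments
  strictly between 3 and 30 cM (short segments are unreliable, long ones
  reflect recent relatedness, not population structure) and sums lengths
  per pair into edge weights. `detect_communities()` is a Leiden-style
  optimiser of weighted modularity (local moving, refinement, aggregation,
  iterated; a final stabilising pass at the node level guarantees no single
  node move can improve the returned partition). The resolution parameter
  defaults to 1.0 — the source analyses do not report theirs — and the
  returned objective is re-computable with `graph_modularity()` (and
  cross-checked against igraph in the tests). `annotate_communities()`
  names communities by majority vote of reference labels, with ties joined
  and logged.

## The synthetic-data generator

Real inputs are access-controlled, so `simulate_genotypes()`,
`simulate_diagnoses()`, `simulate_pc_cloud()` and `simulate_ibd_segments()`
generate data with the structure the analysis assumes:

* genotypes are exact six-class multinomial draws at the declared region
  frequencies (so HWE holds by construction);
* each individual is diagnosed with probability
  penetrance(genotype) × ascertainment(region), and counts are rounded to
  increments of 5 as disclosure control does (`round_to_5 = TRUE`), which
  perturbs any count by at most 2.5;
* IBD segment counts per pair are Poisson (`within_rate` vs
  `between_rate`); lengths follow a truncated exponential (rate 0.25/cM) on
  the open interval (3, 30) cM so every simulated segment survives the
  filter. The default demo plants 5 communities of 60 with rates 2.0/0.05,
  a regime the detector should resolve essentially perfectly.

What the generator does **not** emulate: linkage disequilibrium, genotyping
error, imputation uncertainty, age/sex structure of incidence, non-HFE
genes, or migration between regions. A green test therefore establishes
that the pipeline arithmetic and algorithms are correct under the stated
model — not that the model captures every feature of real biobank or EHR
data.

There is no quantitative ascertainment model in the source material; the
`ascertainment` parameter exists so that a *known* under-ascertainment can
be planted and recovered: with ascertainment 0.5 everywhere, the fitted
risk/prevalence ratio converges to 2 (a property test asserts this within
Monte-Carlo error).

## Numerical and formatting conventions

* Ratios and prevalences are computed at full precision and rounded only
  for display (prevalence 4 decimals in ethnicity-style tables, 3 in
  regional ones; ratios 2 decimals).
* "one in N" uses `round(1/f)`; N ≥ 1000 prints at two significant figures
  with "k", N ≥ 10^6 with "M"; zero frequency yields an `Inf` sentinel.
* All stochastic functions take an explicit seed and restore the caller's
  RNG state; pipeline reports are byte-identical across runs for a fixed
  config and seed. Config files are JSON (no YAML parser is available in
  the target environment).
* Known limitation: reproducing published regional "1 in N" risk values
  exactly requires unrounded allele frequencies that are only published as
  supplementary data; the package verifies the arithmetic on the printed
  main-text values instead.

## Worked pipeline run

```{r pipeline, eval = FALSE}
res <- run_pipeline(demo_config(seed = 7))
summary(res$fit)       # frequencies, HWE checks, risk and discrepancy tables
res$partition          # 5 planted IBD communities recovered
```
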