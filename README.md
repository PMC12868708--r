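# hfeRisk

Regional genetic risk and diagnosed prevalence of hereditary
haemochromatosis.

Hereditary haemochromatosis (ICD-10 E83.1) is a recessive iron-overload
disorder caused, in European-heritage populations, almost entirely by two
*HFE* variants: p.Cys282Tyr (C282Y, chr6:26092913 G>A) and p.His63Asp
(H63D, chr6:26090951 C>G). Because the C282Y allele frequency varies
several-fold across regions of the British Isles, so does population risk —
and comparing genetically predicted risk with the prevalence of clinical
diagnoses in health records points to regions where the condition may be
under-diagnosed. `hfeRisk` is aimed at population geneticists and public
health analysts who want to run or stress-test that comparison.

## The model

Treating WT, C282Y and H63D as three alleles of one locus with frequencies
`p_wt + p_C + p_H = 1`, Hardy–Weinberg equilibrium gives the two risk
genotypes frequencies `q² = p_C²` (C282Y homozygote) and `2·p_C·p_H`
(compound heterozygote). With genotype penetrances `π_hom` and `π_cmpd`
(defaults: male cumulative incidence to age 80, 0.56 and 0.06), the
combined genetic risk of a region is

```
risk = π_hom · p_C² + π_cmpd · 2 p_C p_H
```

Observed prevalence in a stratum is `100·count/denominator` percent, and
the discrepancy statistic is `ratio = risk% / prevalence%`: regions with
the highest ratios have markedly fewer diagnoses than their genetics
predicts.

The package also implements the ancestry-assignment stages used upstream
of frequency estimation: DBSCAN core-cluster selection on top-2
principal-component coordinates, and Leiden-style community detection on an
identity-by-descent sharing graph (segments strictly between 3 and 30 cM,
summed per pair). Individual-level biobank data are access-controlled, so a
synthetic-data module generates cohorts, diagnosis registries (with
counts disclosure-rounded to increments of 5), PC clouds and IBD segments
with the statistical structure the analysis assumes.

## Worked example

```r
library(hfeRisk)

# a population with the printed genomically-British allele frequencies
g <- predict_genotypes(hfe_frequencies(0.0780, 0.1510))
g$hom_c282y     # 0.006084  -> about 1 in 164 carry the major risk genotype
g$one_in_hom    # "164"
g$cmpd_het      # 0.023556  -> about 1 in 42 are C282Y/H63D

combined_risk(hfe_frequencies(0.0780, 0.1510))$risk_pct
# 0.48204  -> 0.482 % of males predicted to develop iron overload by age 80

prevalence(1355, 225320)$one_in   # 166: diagnosed prevalence, White Irish
round(risk_prevalence_ratio(0.427, 0.127), 2)  # 3.36: most under-diagnosed

# end-to-end on synthetic data: four regions spanning the reported
# frequency range, ascertainment 0.5, planted IBD communities
res <- run_pipeline(demo_config(seed = 7))
summary(res$fit)
#>   risk range 0.376% (S England) to 1.313% (NW Irish)
#>   Risk vs prevalence (r = 0.99; uniform penetrance assumed):
#>            region prevalence_pct risk_pct ratio flagged
#>          NW Irish          0.625    1.313  2.10    TRUE
#>       SW Scotland          0.350    0.673  1.92    TRUE
#>    Outer Hebrides          0.600    1.121  1.87   FALSE
#>         S England          0.250    0.376  1.50   FALSE
res$partition
#> <ibd_partition> 300 nodes in 5 communities, modularity 0.7068
```

Every ratio hovers near 2 because the demo plants an ascertainment of 0.5:
half the clinically affected are never coded, and the model recovers
exactly that factor. The fitted object also exposes `coef()` (allele
frequencies), `predict()` (risk for new frequencies), `residuals()`
(log prevalence − log risk; negative = under-diagnosed), `simulate()`
(parametric re-simulation) and `plot()` (risk vs prevalence with the
flagged regions highlighted).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the full pipeline — synthetic cohort, risk model fit, prevalence and
discrepancy tables, IBD community detection — under the given seed,
prints the model summary, and writes the JSON result summary to `--out`.
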