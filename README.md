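# sseqtl — two-stage discovery of sex-interacting expression QTLs

`sseqtl` is an R package for mapping *sex-interacting* cis expression
quantitative trait loci (ss-eQTLs): variants whose effect on a transcript's
expression differs between males and females. It is aimed at analysts
working with population transcriptome cohorts (genotypes in VCF, a
normalized expression matrix, sample sex and population PCs) who want a
tested, reproducible interaction scan rather than ad-hoc scripts.

## The method

**Stage 1 — interaction screen.** For every variant within ±1 Mb of a
feature anchor (TSS or miRNA locus), ordinary least squares fits

```
y = β0 + β1·SNP + β2·sex + β3·sex×SNP + β4·PC1 + β5·PC2 + β6·PC3 + e
```

with dosage-coded genotypes (0/1/2; X-chromosome males hemizygous, coded
0/2) and sex coded 0 = male / 1 = female. The two-sided t-test of the
interaction coefficient β3 is screened by Benjamini–Hochberg FDR at
q = 0.05, and the largest rejected p-value is reported as the run's
equivalent p-value threshold.

**Stage 2 — robust sex-stratified validation.** Each candidate is refit
separately in males and females with `y = β0 + β1·SNP + Σ βk·PCk + e`
using a Huber M-estimator (IWLS, k = 1.345, MAD scale), so outlying
expression values cannot manufacture a sex-specific slope. β1 is tested
with a robust Wald test; a genotype-block filter requires ≥ 5 samples in
every genotype-by-sex cell; stratum p-values are BH-screened at q = 0.05;
and a pair is called an ss-eQTL when either sex stratum (or both) passes.

Supporting modules provide MAF filtering (folded, X-aware), cis-window
pairing, analytic power calculations (noncentral F for the interaction
ANOVA; noncentral t for single-eQTL detection), LD-r² annotation of calls
against a trait-association catalog, and a synthetic-data generator that
reproduces the generative model above so the whole pipeline is testable
without external data. See the vignette
(`vignettes/two-stage-sseqtl.Rmd`) for the full model account.

## Worked example

Simulate a 334-sample cohort (174 male / 160 female) with one planted
sex-interaction effect (β3 = 1 at a common variant) and run the full
pipeline:

```r
library(sseqtl)
run <- run_pipeline(list(
  sim = list(n_variants = 150, n_features = 30, seed = 5,
             maf_range = c(0.2, 0.5),
             effects = list(feature = 1, beta0 = 0, beta1 = 0,
                            beta2 = 0, beta3 = 1.0))))
run
#> sseqtl pipeline run (config 5c542897 )
#>   867 cis pairs -> 1 stage-1 candidates -> 1 ss-eQTL calls
#>   stage-1 equivalent p threshold: 3.029923e-12

run$calls[, c("variant_id", "feature_id", "beta1_male", "p_male",
              "beta1_female", "p_female", "which_stratum")]
#>   variant_id feature_id  beta1_male    p_male beta1_female     p_female which_stratum
#> 1   var00002   feat0001 -0.02577137 0.8292622     1.128277 5.085865e-17        female
```

The planted effect acts only in females (sex is coded 0/1, so β3 adds to
the female slope): the pipeline finds exactly the planted pair, the male
genotype slope is null (−0.03, p = 0.83) and the female slope ≈ 1.13 with
p ≈ 5e-17 — the call is driven by the female stratum, as designed.

Analytic power for the interaction stage at this sample size:

```r
anova_power(c(0.1, 0.2), n_total = 334)
#> [1] 0.2417755 0.8108307
```

i.e. power 0.24 for a small interaction effect (Cohen's f = 0.1) and 0.81
for f = 0.2. Stage-2 detection power rises steeply with MAF at a stratum
size of 176:

```r
eqtl_power(c(0.05, 0.15, 0.3), n = 176, slope = 0.5)
#> [1] 0.5292287 0.9148310 0.9896944
```

With real files, replace `sim` with `vcf`, `expression`, `samples`,
`features` (and optionally `catalog`) paths — formats are documented in
`?run_pipeline` and the reader functions (`?read_genotypes`,
`?read_expression`, `?read_samples`, `?read_features`).

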