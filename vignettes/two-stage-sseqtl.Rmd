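---
title: "Two-stage discovery of sex-interacting eQTLs: models and methods"
author: "sseqtl package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage discovery of sex-interacting eQTLs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sseqtl)
```

## The scientific problem

Many human traits are sexually dimorphic, and part of that dimorphism is
thought to act through sex-dependent gene regulation. An expression
quantitative trait locus (eQTL) is a variant whose genotype associates with
a transcript's expression; a *sex-interacting* eQTL (ss-eQTL) is one whose
genotype–expression slope differs between males and females. Detecting
interactions is statistically much harder than detecting main effects —
roughly four times the sample size is needed for equivalent power — so an
ss-eQTL scan at a few hundred samples must spend its error budget carefully.

`sseqtl` implements a two-stage design for cis ss-eQTL discovery:

1. **Stage 1 (screen).** For every cis variant–feature pair (variant within
   ±1 Mb of the feature anchor, inclusive), fit by ordinary least squares

   $$y = \beta_0 + \beta_1\,\mathrm{SNP} + \beta_2\,\mathrm{sex}
     + \beta_3\,\mathrm{sex}{\times}\mathrm{SNP}
     + \textstyle\sum_k \beta_{\mathrm{PC}_k} \mathrm{PC}_k + e$$

   where $y$ is normalized expression, SNP is the alternate-allele dosage
   (0/1/2), sex is coded 0 = male / 1 = female, and the PCs adjust for
   population structure. The two-sided $t$-test p-value of $\hat\beta_3$ is
   screened with the Benjamini–Hochberg (BH) step-up at $q = 0.05$, run
   separately per analysis (e.g. an mRNA run and an miRNA run each get
   their own threshold). The largest rejected p-value is reported as the
   run's *equivalent p-value threshold*.

2. **Stage 2 (validate).** Each stage-1 candidate is refit separately in
   males and in females with the covariates-only model
   $y = \beta_0 + \beta_1\,\mathrm{SNP} + \sum_k \beta_{\mathrm{PC}_k}
   \mathrm{PC}_k + e$, using a Huber M-estimator (IWLS) so single outlying
   expression values cannot manufacture a sex-specific slope. The genotype
   slope is tested with a robust Wald test; all stratum p-values are
   BH-screened at $q = 0.05$; and a pair is *called* when either stratum
   (or both) passes — the interaction claims the slopes differ, and a real
   difference should be visible as a genotype effect in at least one sex.

Before stage-2 testing, a genotype-block filter requires every
genotype-by-sex cell to contain at least 5 samples with all genotype
classes present, so a stratum slope can never rest on a handful of rare
homozygotes.

## Coding and filtering conventions

* **Dosage** is the count of alternate alleles. On the X chromosome males
  are hemizygous: male genotypes are coded 0/2 (one expressed copy weighed
  against X inactivation in females), females 0/1/2. A diploid-format
  heterozygous male X call is a genotyping artifact and is set missing with
  a logged count.
* **MAF** is folded (≤ 0.5) and computed on the analysis samples after
  intersection with the expression data, counting one allele per male and
  two per female on X. Variants below 1% MAF are removed.
* **Cis window**: ±1 Mb of the feature anchor, boundary inclusive. The
  anchor is the TSS — the start coordinate on the + strand, the end
  coordinate on the − strand; when strand is unknown the start is used and
  a warning emitted.
* **Missing dosages** drop the sample for that pair only (complete-case per
  test); nothing is imputed.
* **Untestable pairs** (constant genotype, single-sex data, collinear or
  exact-fit designs) are flagged with a reason code and excluded from the
  BH test count, never silently given a p-value.
* **X-chromosome QC**: the all-three-genotypes block rule cannot hold for
  hemizygous males, so on X the filter requires the realizable blocks —
  male {0, 2} and female {0, 1, 2} — each with ≥ 5 samples.

## The robust stage in detail

Stage 2 uses the Huber M-estimator with tuning constant $k = 1.345$ (95%
efficiency at the gaussian) fitted by iterated reweighted least squares:
residuals at the current coefficients give a scale estimate
$\hat\sigma = 1.4826 \cdot \mathrm{median}|r_i|$, Huber weights
$w_i = \min(1, k\hat\sigma/|r_i|)$, and a weighted least-squares solve;
iteration stops when the largest coefficient change falls below
$10^{-8}(1 + \max|\hat\beta|)$ or 50 iterations. Robust standard errors use
the classical M-estimation covariance with Huber's small-sample correction

$$\widehat{\mathrm{var}}(\hat\beta) = \kappa^2\,
  \frac{\hat\sigma^2 \sum_i \psi(u_i)^2/(n-p)}
       {\left[\overline{\psi'(u)}\right]^2}\,(X^\top X)^{-1},
  \qquad
  \kappa = 1 + \frac{p}{n}\frac{\mathrm{var}(\psi'(u))}
                              {\left[\overline{\psi'(u)}\right]^2},$$

the same formula the standard robust-regression summaries use, and the
Wald statistic $\hat\beta_1/\widehat{se}(\hat\beta_1)$ is referred to a
$t_{n-p}$ distribution. The test suite cross-checks coefficients, scale and
standard errors against `MASS::rlm` as an independent implementation.

Two numerical caveats are deliberate design choices. An exact fit (median
absolute residual numerically zero) has no defined robust scale; such fits
are flagged `scale_degenerate` and carry no p-value. Non-convergent fits
are treated as QC failures of the pair, with a logged count — a
non-converged estimate is not evidence.

A property worth stating precisely: on *clean gaussian* data the Huber
estimate does **not** coincide with OLS — about 18% of gaussian residuals
exceed $k\hat\sigma$ and get downweighted — so the two agree only to
sampling precision ($O(n^{-1/2})$). Exact agreement holds when no residual
exceeds $k\hat\sigma$ (bounded noise), and the tests check both regimes
separately.

## Stage-2 BH pooling

The two-stage design fixes per-stage FDR levels but leaves open which set
of p-values stage-2 BH runs over. The package pools both sex strata of all
candidates into one BH run (2 p-values per candidate), which directly
matches the either-sex OR call logic; a `pool = "per_stratum"` switch
screens males and females separately for sensitivity analyses. This
pooling choice is recorded in every run's manifest.

## The synthetic-data generator

The generator (`simulate_dataset()`) emulates the statistical structure the
pipeline assumes, so every stage is testable without access to a real
cohort:

* **Samples**: 174 males and 160 females by default — the post-QC sample
  sizes of the motivating mRNA analysis (the cohort is also describable as
  162/176 pre-QC; per-sex counts are free parameters). Three iid standard
  normal PCs by default; a `sex_pc_cor` knob adds a sex-dependent PC1 shift
  for confounding experiments.
* **Genotypes**: biallelic SNPs under Hardy–Weinberg equilibrium — dosages
  iid Binomial(2, p) with p uniform on `maf_range` (default 0.01–0.5,
  matching the 1% MAF filter floor); on X, males Binomial(1, p) recoded
  0/2. Positions are uniform on a 10 Mb synthetic chromosome so the ±1 Mb
  window produces non-trivial pairings. Variants are independent: **no
  linkage disequilibrium is simulated** (LD tests construct correlated
  pairs explicitly).
* **Expression**: generated directly from the stage-1 model on the
  normalized scale with configurable coefficients per feature; the
  generative variant defaults to the variant nearest the feature's anchor.
  Noise is gaussian($\sigma$) or a contaminated mixture (a fraction of
  errors at $\sigma \times$ `outlier_scale`) to exercise the robust stage.
  No read-count or library-size structure is simulated — the pipeline
  consumes already-normalized expression.
* **Reproducibility**: one master seed; per-component and per-variant
  streams are derived deterministically, so the same configuration
  reproduces the dataset bit-for-bit and a variant subset is reproducible
  independent of the total variant count.

Because the generator samples genotypes under HWE with no LD, no batch
effects, and exactly the model the pipeline fits, passing tests demonstrate
the statistical machinery is correct *under its own assumptions*; they do
not certify behaviour under model misspecification (LD between cis
variants, non-normalized expression, population substructure beyond three
PCs).

## Power analyses

Two analytic calculators mirror the questions one asks before running such
a study:

* `anova_power()` — power of the interaction stage treated as an omnibus
  fixed-effects one-way ANOVA over the 6 genotype-by-sex cells, with
  noncentral-F distribution, $\lambda = f^2 N$ for Cohen's $f$. At
  $N = 334$, $\alpha = 0.05$: $f = 0.1$ gives power 0.24 and $f = 0.2$
  gives 0.81 — small interaction effects are out of reach at this sample
  size, moderate ones are well powered. The convention (6 cells, $N$ total,
  $\alpha = 0.05$, $\lambda = f^2N$) is the classical calculator default;
  all four parameters are arguments. Because the real analysis is a
  covariate-adjusted regression rather than a pure cell-means ANOVA, this
  is an optimistic bound.
* `eqtl_power()` — power of the stage-2 single-stratum slope test: a
  noncentral-$t$ computation with $\delta = \mathrm{slope}\sqrt{n \cdot
  2\,\mathrm{maf}(1-\mathrm{maf})}/\sigma$ and $n-2$ df. The noncentral-$t$
  form (not a normal approximation) matters because per-sex strata are
  moderate ($n \approx 160$–176). Power rises steeply with MAF; at stratum
  sizes near 170, common variants (MAF > 0.15) are comfortably detectable
  for unit-scale slopes.

Both calculators are validated against Monte-Carlo simulation of the exact
tests they describe. The eQTL-power oracle fixes the genotype vector at an
exact-HWE design (MAF 0.25, $n$ = 176, counts 99/66/11, for which
$\sum(g-\bar g)^2 = 2n\,\mathrm{maf}(1-\mathrm{maf})$ exactly), because the
analytic formula conditions on the design variance; redrawing genotypes
each replicate adds a small Jensen-gap bias that is not part of the claim
being tested.

## LD annotation

Called variants are annotated against a user-supplied trait-association
catalog (SNP id, trait, p-value): a call co-localizes with a catalog entry
when the two variants are within 1 Mb, their dosage correlation satisfies
$r^2 > 0.8$ (strict), and the catalog association has $p < 0.05$ (strict).
$r^2$ is composite LD — the squared Pearson correlation of unphased
dosages — because the pipeline never sees phase; a call variant that is
itself in the catalog self-annotates at $r^2 = 1$.

## Choices made where the design was open

* **Window boundary** inclusive at exactly 1 Mb.
* **Stage-1 BH test count** excludes untestable pairs (with logged counts).
* **Stage-2 BH pool** is both strata pooled (see above).
* **Equivalent p threshold** when nothing is rejected is reported as
  "none" (`NA`), not 0.
* **TSS for − strand** features is the annotated end coordinate.
* **Male heterozygous X calls** become missing rather than erroring the
  run.
* **Robust SE formula** is the weighted/corrected M-estimation covariance
  above; a full sandwich estimator would be a drop-in alternative at the
  single point where the covariance is formed.

## Experiment sizes used by the validation suite

The packaged checks run at desk scale, chosen to give stable Monte-Carlo
estimates while staying lightweight: null calibration uses 200 complete-null
datasets of 2000 cis pairs at $n = 334$ (zero-call rate and pooled p-value
uniformity); planted-effect recovery uses $\beta_3 = 1$, $\sigma = 1$ with
the planted variant common (MAF 0.2–0.5) across 100 seeds — common, because
a rare planted variant fails the 5-per-block QC for reasons of genotype
availability, not power; the robustness comparison uses 500 replicate
datasets of 20 stratum fits each at 5% contamination with 10σ outliers,
comparing mean absolute slope error of the Huber and OLS fits per
replicate. A single contaminated fit beats OLS head-to-head only about
three times out of four (the outlier perturbation to the OLS slope is only
~2× the clean sampling noise at this contamination level), while the
stage-level aggregate comparison is essentially always won — which is the
operationally relevant guarantee for a scan.

## Worked example

```{r example, eval = FALSE}
cfg <- list(
  sim = list(n_variants = 150, n_features = 30, seed = 5,
             maf_range = c(0.2, 0.5),
             effects = list(feature = 1, beta0 = 0, beta1 = 0,
                            beta2 = 0, beta3 = 1.0)),
  out_dir = "sseqtl_demo"
)
run <- run_pipeline(cfg)
run           # pair counts, candidates, calls, equivalent p threshold
run$calls     # per-sex slopes, robust Wald p-values, which stratum drove the call
```

## Known limitations

* No permutation-based calibration: p-values are parametric, as in the
  two-stage design itself.
* LD is estimated from dosage correlation, not haplotype frequencies; with
  unphased data this composite estimate is standard but can differ from
  haplotype $r^2$ under departures from HWE.
* The generator does not simulate LD, so the pipeline's behaviour when many
  cis variants tag one causal signal (correlated tests within a feature) is
  not covered by the packaged simulations.
* Expression normalization, batch correction and PC computation are
  upstream concerns; the package consumes their outputs.
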