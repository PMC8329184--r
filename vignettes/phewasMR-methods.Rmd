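---
title: "Dissecting a metabolite's genetic architecture: methods and design choices"
author: "phewasMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting a metabolite's genetic architecture: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phewasMR)
```

## The virtual-biomarker design

A circulating metabolite such as plasma kynurenine can associate with disease
for several distinct reasons: the metabolite causally influences disease,
disease (or a shared exposure) influences the metabolite, or a genetic locus
influences both through separate pathways (horizontal pleiotropy). phewasMR
implements the "virtual biomarker study" that separates these explanations
using only genetic data:

1. **Instruments.** Variants robustly associated with the metabolite are
   selected from GWAS summary statistics (genome-wide significance
   `p < 5e-8`), reduced to an independent set by greedy LD clumping
   (`r^2 < 0.05` within 1000 kb against a reference panel), and carried
   through cohort-level QC (imputation quality `info >= 0.3`; one member of
   each related pair with `pi-hat > 0.2` removed at random).
2. **Phenome scanning.** Each instrument, and a polygenic score combining
   all of them, is tested against every phecode-defined phenotype in an
   EHR-derived cohort by logistic regression adjusted for sex, age (or birth
   decade) and five genetic principal components.
3. **Synthesis.** Per-cohort scans are combined by METAL-style
   sample-size-weighted z meta-analysis, and discoveries are declared at
   Benjamini–Hochberg `q < 0.05` within each scan.
4. **Mendelian randomization.** Bi-directional two-sample MR quantifies the
   causal contribution of the metabolite to any correlated trait, with
   estimators of graded robustness to pleiotropy.

A variant whose PheWAS signal is strong while the polygenic-score scan and
MR are null is behaving like a pleiotropic locus — it moves both metabolite
and disease through pathways that do not run *through* the metabolite. That
contrast is the package's central testable output, and the synthetic-data
generator exists to create ground-truth instances of it.

## Statistical models

### Association engine

Logistic fits are maximum-likelihood via iteratively reweighted least
squares: at most 25 iterations, convergence declared when the largest score
(gradient) component falls below `1e-8`, Wald two-sided p-values. A constant
outcome yields a flagged degenerate result rather than an error;
quasi-separation is flagged when any |coefficient| exceeds 15 or the fit
fails to converge. Rank-deficient designs are an error naming the collinear
columns, because silently dropping covariates in a scan would change the
adjustment set. Linear fits are QR least squares with classical SEs. The
test suite requires agreement with R's `glm`/`lm` to 1e-6 relative error on
randomized designs; the engines are independent implementations so that
convergence behaviour and flags stay under the package's control across a
scan of hundreds of phenotypes.

### Genetic encodings and the polygenic score

Dosages count the alt allele in [0, 2]. The additive encoding is the dosage
itself; the recessive encoding is an indicator of effect-allele
homozygosity, with imputed dosages hard-called at 1.5 (round to nearest).
The polygenic score is the weighted allele-dosage sum
\(s_i = \sum_j g_{ij}\beta_j\) using discovery-study betas for all
instrument SNPs (no further p-value thresholding), after aligning each
weight's effect allele to the dosage matrix; effects reported per SD of the
score. Missing dosages are mean-imputed within the cohort by default
(configurable to drop the person): mean imputation keeps the score defined
for every person and is the standard choice for score construction.

### Phecode cohorts

Cases for a phecode are persons with at least two *distinct-date* instances
of a mapping code; a person with exactly one instance is excluded from both
groups, as is any control candidate carrying a code in the phecode's
exclusion range. Counting distinct dates rather than raw rows prevents
same-day duplicate billing from inflating case status (raw-row counting is
available). Controls are additionally restricted to the age range (or
birth-decade set) observed among cases — range matching, not 1:1 pairing,
which is what "matched to the age ranges among the cases" describes.
Phenotypes with fewer than 300 cases, or restricted to a single sex, are
dropped from the scan set. Controls are required to be free of
*exclusion-range* codes only, not of all codes.

### Two-sample MR estimators

With per-variant exposure effects \(b_{Xj}\) (SE \(s_{Xj}\)) and outcome
effects \(b_{Yj}\) (SE \(s_{Yj}\)):

* **IVW** is the zero-intercept weighted regression of \(b_Y\) on \(b_X\)
  with first-order weights \(1/s_{Yj}^2\):
  \(\hat\theta = \sum_j b_{Xj}b_{Yj}/s_{Yj}^2 \big/ \sum_j b_{Xj}^2/s_{Yj}^2\),
  \(SE = (\sum_j b_{Xj}^2/s_{Yj}^2)^{-1/2}\). Fixed-effect by default;
  multiplicative random-effects SE scaling by
  \(\max(1,\sqrt{Q/(m-1)})\) is a flag. For a single variant it reduces to
  the Wald ratio \(b_Y/b_X\) with delta-method SE \(s_Y/|b_X|\).
* **Cochran's Q**, \(\sum_j (b_{Yj}-\hat\theta b_{Xj})^2/s_{Yj}^2\) on
  \(m-1\) df, accompanies every IVW fit; inflation flags heterogeneity and
  hence possible pleiotropy.
* **MR-Egger** adds an intercept to the weighted regression after orienting
  every variant to \(b_{Xj}>0\) (required by the InSIDE framing); the
  intercept estimates average directional pleiotropy. SEs carry the usual
  overdispersion factor \(\max(1,\sqrt{RSS_w/(m-2)})\).
* **Weighted median**: ratio estimates \(r_j=b_{Yj}/b_{Xj}\) weighted by
  \(w_j \propto b_{Xj}^2/s_{Yj}^2\); the estimate interpolates the ordered
  ratios at cumulative percentile 0.5 and is consistent when valid
  instruments carry at least half the weight. Its SE is a seeded parametric
  bootstrap (default 1000 draws) resampling both betas from their sampling
  distributions, mirroring the reference approach to this estimator's SE.

Egger and the weighted median require at least three instruments; below
that they are skipped with a warning rather than silently approximated.

### Harmonization

Exposure and outcome tables are intersected on variant id and the outcome
flipped to the exposure's effect allele. Alleles that match only after
complementing both outcome alleles (A↔T, C↔G) are treated as a strand
recoding. Palindromic variants (A/T, C/G) are kept only when the MAF is
below 0.42 in *both* studies and the frequencies agree in orientation;
otherwise they are dropped with a logged reason. The 0.42 default is the
conservative community convention — near 0.5 the allele frequency cannot
identify the strand. A palindromic variant with missing frequency is
dropped (nothing can orient it); a non-palindromic one is kept because the
letters alone fix the orientation. Indels are accepted but never treated as
palindromic. The original studies do not state their orientation policy, so
this one is a documented default, not a reconstruction.

### Meta-analysis and FDR

The default cross-cohort scheme is METAL's default: sample-size-weighted
z-combination \(z = \sum_i z_i\sqrt{n_i} / \sqrt{\sum_i n_i}\) with a
per-study direction string. Inverse-variance effect-size combination is
provided as the alternative. FDR is Benjamini–Hochberg, applied per scan
(one predictor against one phenome) — combining several scans into one
family is a caller decision. Ties in p are handled by a stable sort.

## The synthetic-data generator

The generator stands in for the GWAS discovery cohort, the LD reference and
the EHR biobanks, and gives every pipeline stage a known truth.

* **Genotypes**: two haplotypes per person from a thresholded latent
  Gaussian with block-diagonal AR correlation; the latent correlation is
  pre-adjusted by a tetrachoric-style inversion so that the configured
  `rho` is realized between allele indicators *after* thresholding, i.e. on
  the haplotype LD-r scale a user expects. Marginal Hardy–Weinberg holds by
  construction. Blocks sit 10 Mb apart (variants 5 kb apart within a
  block), so the default 1000-kb clumping window separates blocks. This is
  desk-scale LD, not coalescent realism.
* **Metabolite**: \(y_i = \sum_j \gamma_j g_{ij} + \delta C_i +
  \varepsilon_i\) with residual variance set so the marginal variance is 1;
  \(C\) is a standard-normal confounder shared with the disease model.
* **Diseases and ICD events**:
  \(\mathrm{logit}\,P(D_d=1) = \alpha_d + \theta_d y + \sum_j \pi_{jd} g_{ij}
  + \lambda_d C\), with \(\alpha_d\) anchored at the configured base rate.
  Cases emit at least two mapped ICD events on distinct dates in a 10-year
  window; everyone emits Poisson-distributed unmapped noise codes; true
  controls never receive exclusion-range codes. One phecode per disease,
  mapped from two ICD-9-CM codes and one ICD-10 code with non-overlapping
  exclusion ranges.
* **Two-sample summary statistics**: two non-overlapping simulated samples;
  per-variant betas and SEs come from the simulated regressions themselves,
  not asymptotic formulas, so SE calibration is an honest property of the
  output (verified to track the replicate-to-replicate spread of betas
  within 10%).

The configuration defaults mirror the published kynurenine instrument
architecture: six variants in four LD blocks at effect-allele frequencies
(0.37, 0.02, 0.48, 0.43, 0.64, 0.21) with per-allele effects (−0.010,
0.081, 0.015, 0.012, 0.014, 0.026) SD. All randomness derives from the
mandatory seed; identical configurations give byte-identical outputs.

What the generator does **not** emulate: real ICD ontologies and coding
practice, phecode hierarchies beyond the supplied map, population structure
and relatedness in genotypes (principal components are simulated as pure
noise covariates), ascertainment into a biobank, and time-varying disease
risk. Passing tests therefore demonstrate the *statistical machinery* under
the stated generative model, not robustness to the full messiness of EHR
data.

## Problem sizes and decision rules in the checks

The package's own verification (test suite and `scripts/acceptance.R`) uses
these study sizes, chosen to give tight Monte-Carlo error at desk scale:
causal-effect recovery with 50 instruments, 5000 persons per sample, true
\(\theta = 0.2\), 500 replicates (the mean IVW estimate must sit within
0.02 of the truth; at 5000 persons per sample the mean instrument F-statistic
is large enough that weak-instrument attenuation is well inside that
budget); directional-pleiotropy and 40%-invalid scenarios with 200
replicates each, where MR-Egger and the weighted median respectively must
beat IVW on absolute bias; Cochran's Q and per-phenotype type-I error
checked against exact binomial 95% envelopes (500 and 1000 replicates); and
FDR checked as mean realized false-discovery proportion ≤ 0.075 over 200
replicates of a 900-null/100-alternative phenome.

The end-to-end contrast simulates the pleiotropic-locus scenario: one
variant with a direct log-odds effect (0.35 per allele) on one disease,
zero metabolite→disease causation, 10&nbsp;000 persons, 20 phecodes, the
default six-variant instrument set. Across six seeded replicates the
single-SNP scan must flag the pleiotropic disease at `q < 0.05` every time,
while the PRS scan must be discovery-free in the majority of replicates and
produce fewer discoveries overall. The decision rule is deliberately
majority-based rather than per-replicate: the pleiotropic variant is *part
of* the score, so a diluted shadow of its signal (attenuated by the
variant's modest weight relative to the score's SD) occasionally clears the
BH threshold in any single replicate, and under the global null the BH
procedure itself has a ~5% chance of some discovery. The contrast —
strong, repeatable single-SNP signal versus a near-null score scan — is the
scientifically meaningful statement.

## Numerical and degenerate-input choices

* Clumping ties in p are broken by (chromosome, position, variant id), so
  results do not depend on input row order; the window is measured
  center-to-center from the index variant; LD uses pairwise-complete
  observations; a monomorphic reference variant is an error, not a silent
  r² of zero.
* `info` QC is strict (`< 0.3` dropped); records with missing `info` are
  kept and counted, since directly genotyped variants have no imputation
  score.
* Relatedness pruning removes a seeded-random member of each offending
  pair, iterating until no retained pair exceeds the threshold — matching
  "one participant from each related pair randomly excluded" while staying
  reproducible.
* A PRS with zero variance (e.g. all-zero weights) flags standardization
  rather than dividing by zero; a scan phenotype whose fit fails yields a
  flagged row and the scan continues.
* The quantitative-outcome scale of recessive-model fits is caller-defined;
  the package does not assume a particular metabolite transformation.

## Limitations

Estimates are not corrected for winner's curse in instrument selection;
there is no MR-PRESSO outlier removal, multivariable MR or Steiger
filtering (out of scope by design); mixed-model and saddlepoint association
tests and Firth correction are not provided — rare-phenotype fits are
flagged instead; the phecode machinery performs no hierarchy rollup beyond
the supplied map. Pi-hat is consumed, not estimated from genotypes.
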