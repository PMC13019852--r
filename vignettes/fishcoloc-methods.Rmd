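---
title: "Quantifying OXTR/ChAT colocalization and its cohort statistics"
author: "fishcoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying OXTR/ChAT colocalization and its cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishcoloc)
```

## The problem

Duplex fluorescence in situ hybridization (RNAScope-style) visualizes two
mRNA species as punctate signal on a tissue section. In the basal forebrain,
*ChAT* mRNA marks the magnocellular cholinergic neurons whose condensed
clusters define the nucleus basalis of Meynert (NBM), while the adjacent
ventral pallidum (VP) carries *OXTR* signal without condensed cholinergic
regions. The scientific questions this package serves are: how much *OXTR*
signal colocalizes with the cholinergic regions; whether area-based *OXTR*
metrics differ between autistic (ASD) and allistic (AST) donors; whether
mRNA tracks receptor binding density measured on adjacent sections; whether
genotype at three *OXTR* SNPs (rs2268491, rs2268495, rs237885; note some
sources print the second as rs2266495) predicts either phenotype; and how
mRNA relates to donor age.

All computation is area-based at the image level — no cell segmentation, no
puncta-per-cell counting. That matches a macroscopic quantification design
whose unit of analysis is the specimen, and sidesteps the resolution limits
of 20× imaging of postmortem tissue.

## Quantification model

**Thresholding macro.** Commercial analyzers expose "sensitivity/tolerance"
dials that an operator tunes once on a representative image and then freezes
as a macro for the whole dataset. We map this to three transparent
parameters per channel: `threshold_fraction` (of a calibration reference
intensity), `tolerance_px` (merge radius when counting nearby objects), and
`min_object_px` (speckle rejection). The reference intensity is the maximum
over a dataset-wide calibration set — never a per-image maximum, since
per-image normalization would shrink exactly the group differences the study
measures. Brightness is the mean intensity over the thresholded mask; whether
the original instrument averaged over the mask or the whole image is not
knowable from outside, so mean-over-mask is the default and the alternative
is a configuration choice.

**Condensed cholinergic regions.** Thresholded *ChAT* signal shows cracks
(1–2 px gaps) inside what is anatomically one neuron cluster. "Filling
cracks" is implemented as binary closing with a disk of radius 2 px followed
by hole filling; the radius is a config knob chosen to bridge the crack
widths the generator produces. Closing with a disk containing the origin is
extensive (never shrinks the mask) and idempotent, and both properties are
enforced and tested bit-exactly.

**Partition and metrics.** The *OXTR* mask is split by the cholinergic
region into inside/outside parts; because pixel membership is binary, the
partition is exact: `in + out = total` in integer pixel counts. Areas are
pixel counts × pixel_size². The *ChAT*+ and *ChAT*− *OXTR* areas are divided
by the crack-filled region area (the extraction target, which we take as the
normalizer — the unnormalized raw ChAT mask area is the other defensible
reading) to account for how much cholinergic tissue each image contains.
Images with no cholinergic region contribute *missing* values to
ChAT-normalized metrics, not zeros: 0/0 is undefined.

**Percent colocalization** is computed by summing *OXTR*-in-ChAT and total
*OXTR* areas across a specimen's images *before* taking the ratio. The
mean-of-ratios estimator is a different statistic (87.5 vs 80 on the
two-image example with (in,total) = (30,40) and (10,10)) and is deliberately
not used; the sum-then-ratio form is additive, hence invariant to tiling an
image into pieces.

**QC.** NBM images require a cholinergic region fraction above
`tau_chat_nbm` (default 1% of the image); VP images require *OXTR* signal
and a ChAT fraction below `tau_chat_vp` (default 0.5%); every image's
recorded exposure must equal the dataset-wide declared settings. Exclusions
carry machine-readable reasons. A one-way ANOVA of per-channel brightness
across assay batches guards against batch effects; a zero-variance
(degenerate) design reports F = 0, p = 1 with a flag so that clean synthetic
runs complete.

## Group statistics

Each metric is regressed on neurotype by OLS. The named assumptions —
normality and homoskedasticity of residuals — are checked by Shapiro–Wilk
and a Breusch–Pagan test. A square-root transform is adopted when either
test rejects at 0.05 on the identity fit and the sqrt refit improves both
diagnostics (a diagnostic that passed and still passes does not veto).
Data-driven selection can be pinned per metric via configuration. Estimated
marginal means come from the model via **emmeans**; under the sqrt transform
the reporting-scale mean and CI bounds are the *squares* of the model-scale
values (squaring is monotone on nonnegative values, so CI order is
preserved), the SE stays on the model scale, and the convention is recorded
in the output table. In a balanced two-group identity-scale design the EMMs
equal the raw group means and the neurotype p-value equals the equal-variance
two-sample t-test — both are tested exactly. No covariates enter the model.

## SNP association

**D′.** Pairwise haplotype frequencies are estimated from unphased
genotypes by EM (the double heterozygote is the only ambiguous class);
D = p₁₁ − p₁·p·₁ and D′ = |D|/Dmax with the usual sign-dependent Dmax. The
EM log-likelihood is non-decreasing and the result is checked against a
brute-force likelihood grid search. In-sample D′ replaces any external
reference-panel lookup, so small-n estimates scatter widely — which is
precisely the multicollinearity motivation for ridge.

**Ridge.** Genotypes are standardized, the intercept is unpenalized, and the
objective is `(1/2n)‖y − b0 − Xb‖² + (λ/2)‖b‖²`, giving the closed form
`(XᵀX/n + λI)⁻¹Xᵀy/n`. λ is selected on a 100-point log grid spanning
`[1e-4, 1e4] × max|Xᵀy|/n` by five-fold CV (random folds under the stage
seed; ties go to the smaller λ). Permutation p-values permute the response B
= 1000 times with λ **fixed** at the observed CV choice — re-selecting λ per
permutation is available behind a flag but is not the default, since the
fixed-λ null is the conventional and cheaper test of the same hypothesis.
The statistic is |β| on the standardized scale (two-sided); p = (1+b)/(1+B)
never reaches zero. FDR correction is Benjamini–Hochberg within each model's
three locus p-values (per-model families; a global family is available but
off by default). Missing genotypes are mean-imputed per locus within the
analysis stratum; strata under n = 6 are skipped with a logged warning.

## Age correlations

Pearson correlations of age with each metric, overall and by neurotype,
keeping each metric's region-specific sample. The sensitivity analysis
removes the k oldest donors (k = 1, 2) *within each metric's non-missing
rows* — so n drops by exactly k per metric — with age ties broken by
specimen id for reproducibility. Verdicts use 0.05 (significant) and 0.10
(trending).

## The synthetic-data generator

The generator is first-class, tested code that encodes the study conditions:

* **Cohort**: 12 ASD / 18 AST specimens with NBM tissue, VP available for
  7/12 and 14/18, ages uniform on 2–67 years, three assay batches.
* **Effects**: multiplicative neurotype effects per metric taken from the
  reported group-mean ratios (ChAT+ 31.3/18.7 ≈ 1.67, VP 6831/2292,
  NBM 12409/6972, ChAT− 1.163/0.619). The ChAT+ and VP effects are the two
  the group comparison is powered for; the NBM and ChAT− effects are exposed
  as parameters too because every metric needs a latent level, with defaults
  from the same mean ratios.
* **Noise**: specimen-level log-normal with CV 0.5 — multiplicative because
  areas are nonnegative and right-skewed, which is what makes the sqrt
  transform path realistic rather than decorative.
* **Binding**: one value per specimen per region, coupled to the latent
  mRNA (ChAT+ for NBM, total for VP) at target Pearson correlations +0.39
  and −0.42 via a standardized-latent construction whose sample correlation
  converges to the target (checked at n = 500 within ±0.1).
* **Age**: per-year proportional slope 0.04 in ASD, 0 in AST, so the
  positive age association is ASD-driven.
* **Genotypes**: individuals are two independent haplotypes drawn from a
  three-locus haplotype distribution built by iterative proportional
  fitting to the two-way margins implied by the MAFs (0.25, 0.30, 0.40) and
  pairwise D′ targets (0.33, 0.63, 0.50 — inside the 0.328–0.625 band that
  motivates ridge). D′ is therefore a real property of the data and is
  EM-recoverable (±0.08 at n = 2000). Jointly incompatible margins raise a
  parameter error.
* **Images**: 2–5 per specimen per region. NBM recipes render 6
  magnocellular blobs (radius ~15 µm) with deliberate 1–2 px cracks; VP
  recipes render none. *OXTR* puncta are Poisson-placed at 30 per 1000 µm²
  inside blobs and 3 outside, scaled by the specimen's latent level;
  Gaussian PSF blur (σ = 0.6 µm) and Poisson-Gaussian noise follow. Ground
  truth (masks, counts) is returned for oracle tests. The default desk-scale
  field is 160 × 160 px at 0.75 µm/px — large enough for several blobs and
  hundreds of puncta while keeping a full synthetic run under a minute.
* **Batch effects** default to zero (matching a no-batch-difference
  finding) but are parameterizable to exercise the batch ANOVA. The
  within-specimen image-to-image variance of the metrics is not pinned by
  any published value; it emerges from Poisson puncta placement and is
  deliberately left as a recipe-level knob.

What passing tests show — and what they do not: the generator produces
geometrically simple blobs and puncta with stationary background. It does
not emulate lipofuscin autofluorescence, optical aberrations, z-structure,
white-matter intrusions, or segmentation-adversarial morphology, so green
tests certify the pipeline's arithmetic, invariances, and statistical
calibration, not robustness to every histological artifact.

## Numerical choices and degenerate inputs

* Masks are binary on 0-based, row-major, half-open pixel grids; no partial
  pixels. Partition identities are asserted in integer pixel counts (float
  area sums can differ in the last ulp depending on summation order).
* Empty thresholded masks are flagged, not errors; brightness is 0 with a
  flag. Monomorphic loci give undefined D′ with a flag. Constant-data
  t-tests and correlations return flagged NA rather than erroring.
* The EM convergence tolerance is 1e-12 on the log-likelihood; the IPF
  margin tolerance is 1e-10 with a 1e-6 feasibility cutoff.
* CV ties break to the smallest λ; "oldest" ties break by specimen id; the
  permutation statistic is |β| (the signed-β variant is a one-line change
  but is not exposed).
* One master seed is fanned to stages by a deterministic hash
  (`stage_seed`), keeping all derived seeds below 2³¹; every seed is
  recorded in the run manifest, and the manifest hash (MD5 over sorted
  per-table MD5s) is identical across reruns.

## Problem sizes used in the shipped checks

Unit and acceptance tests run the quantification oracles on ≤64×64 rasters
(200 random partition pairs, 100 random closing masks), full synthetic runs
on the default 30-specimen cohort with 160×160 images, sign-recovery over
100 simulated cohorts at n = 12/18, type-I calibration at 200–400 replicates
(ridge permutations at B = 200), D′ recovery at n = 2000, and the ridge/EM
oracles on dozens of random problems. These sizes were chosen so the whole
suite completes in a few minutes while leaving the statistical bands
(±0.03 on type-I error, ±0.08 on D′) wide enough to be stable across seeds.

## Known limitations

* Area-based metrics cannot see per-cell expression changes; a shift from
  many dim puncta to few bright ones can leave areas unchanged.
* The brightness analogues inherit whatever nonlinearity the acquisition
  applied; only identical settings across images make them comparable.
* In-sample D′ from ~30 diplotypes is a noisy stand-in for reference-panel
  LD; it is reported alongside the association results, not as a population
  estimate.
* The back-transformed sqrt-scale EMM is a median-type quantity on the raw
  scale, not the raw-scale mean; both conventions are emitted so either can
  be compared downstream.
* Permutation p-values with fixed λ condition on the observed-data model
  selection; the re-selection variant is available when that conditioning
  is a concern.
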