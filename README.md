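# fishcoloc

Area-based quantification and downstream statistics for duplex fluorescence
in situ hybridization (fISH) studies of *OXTR* expression in the human basal
forebrain — built for the postmortem-cohort setting where *OXTR* mRNA is
visualized together with *ChAT* mRNA (the cholinergic marker that defines the
nucleus basalis of Meynert, NBM), and compared between autistic (ASD) and
allistic (AST) donors, against receptor autoradiography, against genotype at
three *OXTR* SNPs, and against donor age.

Because postmortem tissue and its images cannot be redistributed, the package
ships a synthetic-data generator that emulates the full study — three-channel
TIFF image stacks, a cohort table, binding densities, and genotypes in
linkage disequilibrium — so every stage of the pipeline is exercised and
tested end to end without any external data.

## What it computes

**Quantification.** Each image (DAPI / *OXTR* / *ChAT*) is thresholded with a
single frozen macro (threshold = a fraction of a dataset-wide calibration
intensity; speckle rejection; never per-image normalization, which would
silently equalize group differences). Condensed cholinergic regions are built
from the *ChAT* mask by crack filling (morphological closing with a disk,
radius 2 px by default, plus hole filling), and the *OXTR* mask is partitioned
exactly into signal inside and outside those regions. Per specimen this
yields four mRNA metrics — total NBM *OXTR* area, *ChAT*+ *OXTR* area and
*ChAT*− *OXTR* area (both normalized by the cholinergic region area), and VP
*OXTR* area — plus brightness analogues and percent colocalization

    %coloc = 100 × Σ_images OXTR∩ChAT+ area / Σ_images OXTR area,

the ratio of sample-wise sums, not the mean of per-image ratios.

**Statistics.** OLS of each metric on neurotype with data-driven square-root
transform selection (Shapiro–Wilk + Breusch–Pagan residual diagnostics) and
estimated marginal means back-transformed by squaring; Pearson correlations
of mRNA with binding density and with age (with leave-out-oldest
sensitivity); pairwise D′ between SNPs by two-locus haplotype EM; and — since
the loci are in medium-to-high LD — ridge regression of each phenotype on the
three genotypes with five-fold CV λ selection, permutation p-values
((1+b)/(1+B), B = 1000), and per-model Benjamini–Hochberg FDR correction.

## Worked example

```r
library(fishcoloc)

data_dir <- file.path(tempdir(), "demo")
write_fixture_set(cohort_spec(n_asd = 6L, n_ast = 8L, seed = 42L),
                  outdir = data_dir)
res <- run_pipeline(run_config(data_dir, file.path(tempdir(), "demo_out"),
                               seed = 42L, B = 200L))

coloc <- res$group$coloc$overall
cat(sprintf("NBM percent colocalization: %.1f +- %.1f%% (n = %d)\n",
            coloc$mean, coloc$sem, coloc$n))
#> NBM percent colocalization: 84.6 +- 0.9% (n = 14)

subset(res$group$emm, metric == "chatplus_oxtr_area",
       c(neurotype, mean, ci_lo, ci_hi))
#>   neurotype       mean      ci_lo      ci_hi
#> 3       AST 0.02883786 0.00333344 0.07946665
#> 4       ASD 0.22959463 0.12231817 0.37037025

res$group$model_summary
#>                metric transform p_neurotype  n
#> 1       nbm_oxtr_area      sqrt 0.001865986 14
#> 2  chatplus_oxtr_area      sqrt 0.001974403 14
#> 3 chatminus_oxtr_area      sqrt 0.005396250 14
#> 4        vp_oxtr_area  identity 0.058188394 10

round(res$snp$ld$dprime, 2)
#>           rs2268491 rs2268495 rs237885
#> rs2268491        NA      0.37     0.17
#> rs2268495      0.37        NA     0.25
#> rs237885       0.17      0.25       NA
```

Here most *OXTR* signal in NBM images falls inside the crack-filled *ChAT*+
regions (the generator places puncta ten times denser inside cholinergic
blobs); the *ChAT*+ *OXTR* area metric (OXTR-in-ChAT area divided by
cholinergic region area) is higher in the simulated ASD group, which the
group model detects after a square-root transform; and the in-sample D′
estimates at n = 14 scatter widely around the generating values, which is why
the association stage uses ridge rather than per-SNP OLS.

The same stages are available as a stepwise workflow under `analysis/`
(`01_simulate.R` → `05_age.R`), each writing its tables under `results/`.

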