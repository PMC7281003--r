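# herdnmr

Fixed-effect correction and chemometrics for large, multi-farm 1D ¹H NMR
serum metabolomics of early-lactation dairy cattle.

When hundreds of cows from many farms are profiled together, herd of
origin (diet, management, sample handling) can explain more spectral
variance than the animals themselves — fatal for metabotype discovery,
where the goal is inter-animal variation free of environmental
confounding. `herdnmr` removes such systematic effects the way
quantitative geneticists do: the intensity at every chemical shift is
treated as a separate phenotype and residualised by OLS on categorical
fixed effects,

```
y_ijkl = mu + WIM_i + P_j + H_k + e_ijkl
```

with WIM the week of lactation (4 levels), P parity (1, 2, 3, 4+) and H
herd (13 levels by default). The residual matrix is the *corrected*
spectrum set; per-shift R² vectors show where each effect acts; the same
design corrects the reference phenotype (serum β-hydroxybutyrate, BHBA,
mmol/L). Correcting for one factor is exactly class centering — the
linear model generalises it to several factors at once.

Around that core the package provides:

* **`synthetic_cohort`** — a generator for multi-herd serum-like spectra
  with known, configurable effect structure (13 herds of 9–248 cows,
  707 total; Lorentzian metabolite templates; herd-dominated phenolics;
  a deviant high-BHBA farm; jitter, baseline, noise, assay error), so
  every downstream stage is testable without any data download.
* **`preprocess`** — region excision, correlation optimised warping
  (exact dynamic programme), total-area normalisation, asymmetric
  weighted least squares baseline removal, mean centering.
* **`pca_analysis`** — SVD-based PCA with deterministic loading signs,
  Hotelling T² outlier screening, and |Pearson| correlations between PC
  scores of corrected vs uncorrected datasets.
* **`effect_inference`** — conditional Wald F tests (each factor fitted
  last) on PC scores, and ASCA with restricted permutation testing.
* **`opls_regression`** — single-response OPLS with VIP scores,
  venetian-blinds CV, leave-one-farm-out external validation, and
  rank/Wilcoxon permutation significance.
* **`run_study()`** — the end-to-end orchestration with seeded,
  byte-identical outputs and provenance headers.

## Worked example

```r
library(herdnmr)

coh <- generate_cohort(cohort_config(grid_size = 2048, seed = 1))
pp  <- preprocess_pipeline(coh$spectra)

des <- encode_design(coh$metadata, c("wim", "parity", "herd"))
cr  <- correct_matrix(pp, des)
cr
#> <correction_result> model: wim+parity+herd; 707 x 1591; mean R2 = 0.177

# How much does herd explain at the hippurate aromatic peaks?
crh <- correct_matrix(pp, encode_design(coh$metadata, "herd"))
mean(crh$r2[peak_columns(pp, c(7.55, 7.64, 7.84))])
#> [1] 0.651551

# Which factor drives PC1?
conditional_wald_f(fit_pca(pp, k = 3)$scores[, 1], coh$metadata)
#>   factor          f df1 df2         p
#> 1    wim   1.045366   3 688  3.72e-01
#> 2 parity  13.891790   3 688  8.38e-09
#> 3   herd 110.812004  12 688  9.48e-152

# ASCA before and after herd correction
asca_decompose(pp, coh$metadata, c("wim", "parity", "herd"))$magnitudes
#>       wim    parity      herd
#> 0.7926390 2.6460496 50.241367
asca_decompose(crh$residuals, coh$metadata,
               c("wim", "parity", "herd"))$magnitudes
#>          wim       parity         herd
#> 6.638413e-01 4.699071e+00 4.816216e-29
```

Herd explains ~50% of the centred spectral sum of squares and ~65% of the
intensity variance at the hippurate peak tops in this quick 2,048-point,
area-normalised run (area normalisation couples every column to the
fluctuating total, and the coarse grid is jitter-sensitive; on the
default 4,096-point grid without normalisation the measured share is
~0.78 against a configured 0.80 — see the vignette). Residualising on
herd removes its ASCA magnitude to numerical zero while parity and
week-of-lactation effects are retained. A full seeded study (`run_study`) additionally
writes the five-PCA score-correlation matrices, the three-way OPLS
comparison (reference farm / all uncorrected / all corrected) and the
leave-one-farm-out validation table, in which the deviant farm H01 shows
by far the largest external RMSE.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main study from scratch at the given seed: it
simulates the default 707-cow, 13-herd cohort on a reduced grid, runs
preprocessing, all four correction models, PCA, Wald F, permutation ASCA,
the three OPLS comparisons and the leave-one-farm-out validation, writes
every stage table under `results/study_seed<seed>/`, and writes the
results JSON to `--out`. A few minutes on one CPU.
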