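---
title: "Correcting multi-herd 1H NMR serum spectra for fixed effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting multi-herd 1H NMR serum spectra for fixed effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdnmr)
```

## The problem

Serum metabolomics in livestock usually works with small, homogeneous
cohorts: one farm, one breed, one diet. Biomarkers found that way are
fragile. Assembling a large cohort across many farms fixes the power
problem but imports a confounder: herd of origin bundles diet, management
and sample handling, and can dominate the spectral variance. For
management-oriented prediction (e.g. predicting serum
beta-hydroxybutyrate, BHBA, the standard ketosis biomarker) that
environmental signal is part of the phenotype and should be kept. For
metabotype discovery — inter-animal variation free of environmental
confounding, intended for genetic selection — it must be removed.

`herdnmr` implements the removal as quantitative geneticists do it: treat
the signal intensity at every chemical shift as a separate phenotype and
residualise it on categorical fixed effects with ordinary least squares,

$$y_{ijkl} = \mu + \mathrm{WIM}_i + P_j + H_k + e_{ijkl},$$

where WIM is week of lactation (4 levels), $P$ parity (1, 2, 3, 4+), and
$H$ herd (13 levels by default). The matrix of residuals is the
*corrected* spectrum set, and the per-shift $R^2$ vector says how much
variation each effect set explains where. Correcting for a single factor
is exactly class centering; the linear-model formulation generalises it to
several simultaneous factors and to phenotype correction (corrected BHBA
is the residual of the reference assay value on the same design —
negative values are legitimate; it is a relative ranking).

Downstream, the package quantifies what the correction did: PCA on
corrected and uncorrected data with absolute Pearson correlations between
their PC scores, conditional Wald F tests of each factor on the leading PC
scores (each term fitted last), ASCA with restricted permutation testing,
and OPLS regression of BHBA with venetian-blinds cross-validation,
leave-one-farm-out external validation and permutation significance.

## The synthetic cohort: a stated world

No spectral data are deposited with the study this package models, so the
generator is a first-class module, not a fixture. Its defaults state one
fixed world:

* 13 herds of sizes 129, 11, 12, 11, 18, 248, 9, 24, 33, 27, 50, 123, 12
  (707 cows), days in milk uniform on 1–30, `WIM = min(ceiling(DIM/7), 4)`
  so days 29–30 fold into class 4, parity sampled to a mean near 2.5.
* 14 metabolite templates at their literature shift assignments (lactate,
  BHBA, acetate, glucose, glycine, creatine, betaine, pyruvate, hippurate,
  an unassigned aromatic singlet at 7.22 ppm, alanine, valine, isoleucine,
  leucine), rendered as Lorentzian multiplets with component heights
  proportional to proton counts.
* Fixed effects act additively on log-concentration, so concentrations
  stay positive. Herd dominates the diet-driven phenolics (hippurate
  target share 0.8, the unassigned aromatic 0.6) and matters for the
  energy metabolites (0.3–0.5); parity shifts glucose, acetate and BHBA by
  around 10–15%; WIM effects are small (<5%). A latent per-animal
  energy-balance factor loads positively on BHBA and acetate and
  negatively on lactate and glucose, giving the biologically expected
  correlation structure.
* Herd 1 is deviant: crossbred, with a BHBA log-mean shift of +0.85 and
  extra within-herd BHBA spread — the one farm whose withheld data should
  be hardest to predict.
* Measurement: rigid per-sample chemical-shift jitter (sd 0.0015 ppm), a
  slow positive sinusoidal baseline (amplitude 0.05), iid spectral noise
  (sd 0.005), a broad residual-water surrogate in 4.68–5.00 ppm and a
  methanol artifact near 3.34 ppm (so excision is exercised), and a BHBA
  reference assay with sd 0.030 mmol/L — an uncertainty of ±0.060 mmol/L
  read as a 95% half-interval.

### Calibration choices worth spelling out

**What "herd fraction 0.8" means.** Effects are log-additive, but a
per-shift linear model measures variance shares on the natural intensity
scale, and for log-normal data the two differ (a log-scale share of 0.80
corresponds to roughly 0.78 on the natural scale at these spreads).
`herd_frac` therefore targets the *natural-scale* share — the quantity the
correction module estimates — and the drawn herd-effect shape is rescaled
by a one-dimensional root-find until the realized one-way variance
fraction of the simulated concentrations equals the target exactly. With
only 13 herds the share of a raw draw has about 40% relative standard
deviation, so without this step a "configured" fraction would be
decorative. If a small target sits below the one-way noise floor of a
tiny cohort, the herd effect is set to zero. When an explicit
`herd_effect_sd` is supplied instead, the draw is rescaled to that
between-herd log-sd and no fraction targeting happens.

**Linewidth follows the grid.** The full-resolution acquisition grid this
emulates (31,313 points over 10.6 ppm) samples a real serum line of
~0.003 ppm FWHM with about nine points. At the desk-scale default of
4,096 points, keeping the physical linewidth would leave one point per
FWHM: peak-top intensities would be numerically meaningless and collapse
under sub-point misalignment. The default Lorentzian HWHM of 0.010 ppm
preserves the *sampling geometry* (~8 grid points per FWHM) rather than
the absolute Hz width — the same trade apodization makes at reduced
digital resolution. The cost is that J-coupling structure narrower than
~0.02 ppm is unresolved; doublets render as single lumps. The
31,313-point grid remains available through `grid_size`.

**Jitter is sub-point by design.** After internal referencing to DSS the
remaining rigid drift of a serum spectrum is of order 1 Hz, i.e.
~0.0015 ppm, and that is the default. The physically larger local,
pH-dependent shifts that alignment fights in practice are outside the
generator's rigid-shift model (one global shift per sample is enough to
exercise the warping stage; local warps are not emulated).

**What a green test does not establish.** The generator has independent
log-normal metabolites plus one shared latent factor, no lipoprotein broad
signals, no vendor artefacts, no local warping and no global dilution
factor. Recovery of a configured fraction here shows the estimator chain
is unbiased in this world; it says nothing about, e.g., peak overlap with
macromolecular baselines in real serum.

## Preprocessing

Stages run in the study's order: water excision (4.68–5.00 ppm),
correlation optimised warping, total-area normalisation, post-
normalisation excisions (methanol 3.32–3.36 ppm; the upfield reference
region read as [-0.60, 0.40]; everything above — not including —
9.00 ppm), asymmetric weighted least squares baseline removal, mean
centering. Excision intervals are closed on both ends. The retained
column count is recorded in the provenance attribute rather than forced to
any particular value: the original study's retained count is not exactly
derivable from a uniform grid under any single boundary convention, so the
package trusts its own arithmetic.

COW details that matter:

* Segments are near-equal splits with shared endpoints (default 50
  points); interior boundaries may shift by up to the slack (default 5
  points); boundary offsets are integers chosen by dynamic programming to
  maximise the summed per-segment Pearson correlation with the reference.
  The DP is exact — a property test checks it against exhaustive path
  enumeration on 64-point instances.
* The reference defaults to the sample with maximal mean correlation to
  all others ("median" mode).
* The DP objective is the per-segment sum, but the no-degradation
  guarantee users care about is whole-spectrum: any sample whose overall
  correlation with the reference would decrease keeps its identity path.
  A constant (zero-variance) segment contributes correlation 0, with a
  warning.
* Integer boundary offsets cannot remove sub-grid-point shifts; with the
  default jitter most samples are already within half a point and the
  identity path is common. That is expected, not a failure.

Baseline removal minimises
$\sum_i w_i (y_i - z_i)^2 + \lambda \sum (\Delta^2 z)^2$ with weight
`asym_p` (default 0.001) above the current baseline and `1 - asym_p`
below, iterating until the weight assignment stabilises (default cap 20).
The default $\lambda = 10^7$ is matched to drift periods of thousands of
points, as on full-width spectra; the penalty scales with the fourth power
of drift frequency, so short-period test fixtures need a smaller
$\lambda$. Non-convergence returns the current estimate and reports a
count.

Normalisation targets row sum 1 (relative areas). Note one deliberate
asymmetry: the generator simulates no global dilution factor, so on
synthetic cohorts area normalisation only re-introduces cross-feature
coupling (every column acquires the fluctuation of the total). The
parameter-recovery acceptance check therefore runs without it, while the
full `run_study` pipeline keeps it, as the study design prescribes.

## Correction and inference: numerical choices

* One shared QR projection corrects all columns; a property test pins it
  to naive per-column `lm()` fits at 1e-10. Zero-variance columns get
  residual 0 and $R^2 = 0$ instead of errors.
* Treatment coding with sorted levels; residuals are invariant to the
  coding, so only effect reporting depends on it.
* Corrected spectra are not re-centred before PCA: residuals of a design
  with an intercept are already column-centred.
* $R^2$ is a fraction internally, a percentage only in presentation.
* PCA is an SVD of the centred matrix; each loading's largest-magnitude
  element is made positive (scores flipped accordingly) so results are
  reproducible across linear-algebra backends. Between-model score
  comparisons use |Pearson r| because PC signs are arbitrary; output
  headers say so.
* The Hotelling $T^2$ screen on the first two PCs flags samples against
  the $n_{pc}(n-1)/(n-n_{pc})\,F_{1-\alpha}$ limit; flagged samples are
  for manual inspection, mirroring how the outlier was actually handled in
  the study this models — removal is never automatic.
* Conditional Wald F is the exact drop-one-term OLS F (the REML
  conditional Wald F of mixed-model software reduces to this for a
  fixed-effects-only model), with denominator df $n - \mathrm{rank}$.
* ASCA uses the simplest published variant: per-factor level means of the
  globally centred matrix, magnitudes as % of centred total SSQ. For
  unbalanced designs the effect matrices are not mutually orthogonal and
  percentages need not add up — the balanced-design additivity is tested,
  the unbalanced caveat is documented here and in output headers. The
  printed effect sizes of the original study are on an unstated scale; no
  attempt is made to match them.
* Permutation p-values use the $(b+1)/(m+1)$ estimator (no zero
  p-values); with 50 permutations the floor is $1/51 \approx 0.02$.
  Permutations shuffle one factor's labels and keep the others attached to
  their samples.

## OPLS

Single-response OPLS: predictive weight $w \propto X^\top y$, orthogonal
components peeled from the X-loading of the current predictive score, then
a one-component regression on the filtered matrix. "LV" counts in reports
mean 1 predictive + $(LV-1)$ orthogonal components. Key conventions:

* With zero orthogonal components the model is exactly PLS1, and with $k$
  orthogonal components it explains the same y-variance as PLS1 with
  $k+1$ components — both are oracle-tested against an independent NIPALS
  implementation.
* VIP is computed from the predictive component only, so the mean of
  squared VIPs is exactly 1 and VIP > 1 marks influential variables.
* Venetian-blinds CV assigns every $n_{splits}$-th sample (input order) to
  a fold; deterministic by default.
* External $R^2$ in leave-one-farm-out validation uses the validation
  set's own mean in the total sum of squares, and is undefined (NA) for a
  constant withheld response.
* The orthogonal-component count is selected by CV-RMSE with a
  one-standard-error parsimony rule (SE of the RMSE estimated from the
  spread of squared errors); deterministic.
* Permutation significance reports the rank-based p as primary (floor
  $1/(n_{perm}+1)$) and, secondarily, the median over permutations of a
  paired Wilcoxon signed-rank test on absolute CV residuals — the
  composite mirrors "cross-validated, Wilcoxon" permutation testing as
  practised, whose exact recipe is not published.

## Orchestration

`run_study()` runs the whole design: simulate (or ingest), preprocess,
Models 1–4, five PCAs, score-correlation matrices, Wald F on PC1–3, ASCA
on all five datasets, the three OPLS comparisons (single reference farm;
all farms uncorrected; all farms corrected, with the phenotype corrected
identically), and leave-one-farm-out validation. One global seed fans out
to per-stage seeds by fixed offsets; every output table carries a
provenance header (package version, seed, config MD5) and a seeded run is
byte-identical when repeated. The deterministic sanity checks in the test
suite run a reduced cohort; the full 707-cow, reduced-grid study runs in
a few minutes on one CPU via `scripts/acceptance.R`.

## Known limitations

Rigid-shift jitter only; no local warping, so COW's segment machinery is
exercised mostly by explicit test shifts. No lipoprotein/macromolecule
broad signals, no J-coupling fine structure at the default grid, no
inter-metabolite overlap beyond what the shift assignments imply (the
hippurate CH2 at 3.97 ppm genuinely overlaps betaine/creatine at the
default linewidth — effect-recovery checks use its clean aromatic
multiplets). ASCA is main-effects-only; no interactions, no
covariate-adjusted (ASCA+/LiMM-PCA) variants; OPLS is single-response.
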