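---
title: "Stress testing Centiloid pipelines: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress testing Centiloid pipelines: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`centistress` studies how the design of a Centiloid (CL) quantification
pipeline — reference region, mask provenance, cortical target definition,
quantification space — together with tracer, age, brain atrophy and image
resolution, shifts CL values.  Because real multi-cohort PET data are
access-controlled, the package pairs the statistical battery with a
synthetic phantom cohort whose ground truth is fully known.  This vignette
explains the models, the tunable parameters and their defaults, what the
simulator does and does not emulate, the numerical choices, and the known
limitations.

## 1. The phantom and its geometry

The phantom replaces anatomy with nested ellipsoids on a regular isotropic
grid (default 96 voxels at 2 mm for the standalone template; the cohort
default is a 48-cube, chosen so a 60-subject cohort simulates and
quantifies in a few minutes on one CPU).  What the geometry preserves is
*adjacency*, because adjacency is what drives partial-volume spill-in:

* a cortical grey-matter ribbon wrapped around a cerebral white-matter
  core (with a small deep-grey nucleus inside the core);
* a cerebellum with a grey shell over a white core — so the cerebellar-grey
  reference region borders hot white matter on the inside;
* a pons/brainstem column touching the cerebellum and the cerebral white
  matter — an almost purely white-matter reference region.

Background (scalp, CSF) is given a nonzero uptake of 0.30 relative to the
whole-cerebellum mean.  Real scans show nonzero extracerebral signal, and a
zero background would make every boundary loss dominate every white-matter
gain on curved shells, suppressing the inward spill-in the package exists
to study.  All seven compartments must be non-empty and must not touch the
grid boundary; violations raise a geometry error.

## 2. Uptake model

Intensities are piecewise-constant per compartment, scaled so the
whole-cerebellum (WCB) mean is exactly 1:

* cortical target: the tracer's SUVr at the subject's true amyloid load,
  linear between `suvr_yc` (0 CL) and `suvr_ad100` (100 CL), extrapolated
  outside;
* all white matter (cerebral, cerebellar, pons):
  `wm_uptake_base + wm_age_slope * (age - 70)`;
* cerebellar grey: solves the WCB normalisation;
* deep grey: 1; background: 0.30.

Noise is multiplicative Gaussian *per region* (default SD 1.5%).  The
piecewise-constant choice is deliberate: it keeps the ideal SUVr an exact
affine function of true CL, so the whole measurement chain has closed-form
oracles — with zero noise, zero smoothing, no atrophy and no age slope, all
32 pipelines return the true CL to machine precision, and the tests assert
exactly that.

Age enters *only* through white-matter uptake.  This mirrors the
attribution in the amyloid-PET literature (white-matter binding rises with
age and differs by tracer) and makes age effects interpretable: any
age–ΔCL correlation in the output is traceable to the injected slope.

### Tracer profiles

| tracer | suvr_yc | suvr_ad100 | wm_uptake_base | wm_age_slope /yr |
|--------|---------|------------|----------------|------------------|
| PiB    | 1.05    | 2.08       | 1.70           | 0.000            |
| FMM    | 1.00    | 1.61       | 2.20           | 0.004            |
| FBB    | 1.00    | 1.76       | 2.00           | 0.020            |
| FBP    | 1.00    | 1.67       | 1.80           | 0.010            |

The 18F profiles have compressed dynamic ranges and high white-matter
binding relative to PiB, as in practice.  The age slopes are ordered
FBB > FBP > FMM so that the pons-referenced bias across tracers has the
ordering reported for real cohorts (largest for florbetaben); the
*magnitudes* of the resulting ΔCL values are emergent configuration, not
calibrated reproductions, and no test asserts them.

## 3. Atrophy

A subject's `atrophy` parameter is the grey-matter volume retained relative
to the template — equivalently GM/TIV normalised to the template's GM/TIV,
since the intracranial volume is fixed.  (The raw GM/TIV of any phantom is
a geometry constant, so "atrophy = 1 leaves the template unchanged" forces
the normalised reading.)  Erosion removes boundary voxels of each
grey-matter compartment (seeded random order among boundary voxels, so
thinning is spatially unbiased) until the voxel count matches, and eroded
voxels become background/CSF.  The realised fraction is exact up to
per-compartment rounding; `atrophy < 0.05` or an emptied compartment raises
a degenerate-subject error.

Defaults couple atrophy to diagnosis (SCD 0.95 ± 0.03, MCI 0.90 ± 0.04,
dementia 0.85 ± 0.05, clamped to [0.70, 1]) — a typical memory-clinic
gradient.

## 4. Resolution and harmonisation

`apply_psf()` convolves with an isotropic Gaussian via FFT circular
convolution.  The kernel is the sampled, renormalised discrete Gaussian, so
the DC gain is exactly 1 and **total intensity is conserved to machine
precision for any image**; wraparound is physically negligible because the
anatomy keeps a margin from the grid boundary.  `harmonize_image()` applies
the quadrature-complement kernel `sqrt(target^2 - effective^2)` (default
target 8 mm) and refuses to sharpen.  Two-stage smoothing agrees with the
one-shot kernel up to kernel-sampling error (about 1e-6 relative on the
default grids), which is why the corresponding test uses a 1e-5 tolerance
rather than machine precision.

Native scanner FWHM is drawn uniformly from 5–8 mm; harmonised images are
always at 8 mm.  Subjects of the FMM/FBB subsample keep both image
versions (64 measurements each); FBP subjects are harmonised-only
(32 measurements), mirroring the asymmetry of the cohorts the design
emulates.

## 5. Masks, pipelines and calibration

GAAIN-style masks are template masks, with the cortical target dilated one
voxel into white matter — emulating a fixed template ROI that overlaps WM.
Subject-based masks are the subject's own tissue labels, undilated.  This
is an acknowledged abstraction of the real template-vs-segmentation
difference; it reproduces the two mechanisms that matter (white-matter
fraction inside the ROI; atrophy mismatch between template and subject)
with a single controllable knob.

MNI-space quantification resamples the image to the template grid
(trilinear) through the recorded rigid subject–template transform; native
space resamples masks instead (nearest-neighbour).  Interpolation smoothing
is accepted as part of the Space effect, which is minor.

Calibration simulates noise-free young-control (0 CL, age 65) and
typical-AD (100 CL, age 70) groups without atrophy or misalignment,
processed at the harmonised resolution, for every tracer and pipeline.  PiB
anchors define the scale; each 18F tracer gets a level-2 PiB-on-tracer OLS
conversion validated against the standard criteria (R² > 0.70, positive
slope, minimum pairs).  By construction the calibration groups map to
exactly 0 and 100 CL in every pipeline — the anchor-exactness test asserts
|error| < 1e-9.  Because the groups are noise-free their members are
identical; group size (default 5) is nominal and only enters the pair
count.  The young-control group being younger than the cohort (65 vs
~71 ± 7) is itself part of the design: it is what converts the white-matter
age slope into a pons-referenced bias.

## 6. The statistical battery

**Bias models.**  Gaussian identity-link GEEs clustered by subject fit the
long table; the main model regresses CL on diagnosis, tracer and the four
design factors plus tracer interactions, and the secondary models add age,
atrophy or harmonisation status with their design-factor interactions.
Choices the source material leaves open, decided here: exchangeable working
correlation (repeated measures within subject; an independence switch is
provided), robust sandwich covariance for all inference (model-based
covariance retained for diagnostics), and sum-to-zero contrasts so the
Type III Wald tests are invariant to level ordering.  Marginal means use a
balanced reference grid (equal weights over all factor-level combinations,
covariates at their means); pairwise ΔCL against the standard design
(WCB/GAAIN/GAAIN/MNI) carries the 3-CL relevance threshold, the estimated
test–retest variability of amyloid PET.  The standard sandwich is mildly
liberal at finite cluster counts; at 300 clusters the simulated type-I
error of a null Type III test sits near 0.04–0.07 against the nominal
0.05, which is the accepted behaviour of the uncorrected estimator.

**Stratification** assigns each subject wholly to the amyloid-negative or
-positive stratum by their standard-pipeline harmonised CL, positive iff
CL > 24 (strict).  Harmonised measurements are used because every subject
has them; which version the original analyses used is not stated.

**Precision.**  The within/between-pipeline decomposition is the two-way
additive model `CL_ip = mu + s_i + pi_p + e_ip`: between-pipeline SD is the
SD of the 32 pipeline effects, within-pipeline SD the mean-square residual
SD (unbiased for an injected residual sigma), and 95% half-widths are
1.96 SD.  How to extract these two numbers from a `CL ~ pipeline` GEE is
not uniquely determined; this transparent, oracle-testable decomposition
is the chosen operationalisation, with a GEE-marginal-means route provided
as a cross-check mode.  CI interpolation anchors at the stratum mean CLs
(computed from the data at hand — the anchors are not printed quantities)
and evaluates linearly at 12 and 24 CL, flagging extrapolation.  ICC is
fixed to ICC(2,1) (two-way random effects, absolute agreement, single
measurement); Bland–Altman differences are oriented harmonised − original
throughout.

**Missing cells** in the decomposition are imputed from subject + pipeline
means with a warning, or rejected in strict mode.  Degenerate correlations
(constant differences) report a flagged zero rather than NA propagation.

## 7. What the simulator shows — and what it cannot

Passing tests on the phantom cohort demonstrate that the *machinery* is
correct (exact anchors, oracle-equal GEEs, recovered injected effects) and
that the *mechanistic directions* emerge from the injected physics:
smoothing spills white-matter signal into the cerebellar-grey reference;
harmonisation raises pons-referenced CL and lowers CGM-referenced CL;
template targets underestimate CL in atrophic positives; positive-stratum
CL is noisier than negative-stratum CL.

They do not show that the phantom's effect *sizes* match real cohorts.
Real anatomy, voxelwise texture, nonlinear registration error, scanner
nonuniformities and visual-read ground truth are all outside the model.
Two specific caveats:

* The sign of the age correlation of pons-referenced ΔCL depends on the
  age composition of the calibration groups relative to the cohort.  The
  simulator's mechanism (young calibration controls, older cohort) gives
  CL_pons falling with age; real calibration datasets with elderly
  amyloid-negative members can reverse the printed sign.  Tests therefore
  assert consistency with the injected mechanism, not with any published
  coefficient.
* At the default evaluation scale (60 subjects, ~30 per stratum) the
  positive-minus-negative gap in within-pipeline CI is real but modest, and
  the stratum tracer composition fluctuates; at some seeds the direction
  check would not replicate.  The packaged test evaluates it at a fixed
  seed; larger cohorts sharpen the contrast at proportional cost.

The amyloid mixture defaults (negative N(2, 8) CL, positive N(75, 20) CL,
50/50 mix, age N(71, 6.7) clamped to 55–90, diagnosis mix 32/45/23%,
tracer mix 39/23/38%) are stated assumptions of a plausible memory-clinic
cohort — the true-CL distributions of the source cohorts are not published
and these values are not estimates of them.

## 8. Reproducibility

Every stochastic operation takes a seed; cohorts derive per-subject child
seeds by stable integer hashing of the subject id, so any subject subset
reproduces bit-identically.  `run_pipeline()` writes a manifest with the
seed, a configuration hash and per-stage row counts; identical
configuration and seed give identical table hashes.  `scripts/acceptance.R`
recomputes the headline quantities from scratch under a caller-supplied
seed.
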