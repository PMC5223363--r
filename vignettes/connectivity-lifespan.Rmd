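---
title: "Methods: lifespan functional connectivity with connlife"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifespan functional connectivity with connlife}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models, the numerical
choices, and what the synthetic cohort does and does not establish about real
data. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The scientific object

The quantity under study is the Pearson correlation `r` between the resting
BOLD time courses of two brain regions, variance-stabilised by the Fisher
transform `z(r) = ½ ln[(1+r)/(1−r)]`. Regions are 42 spheres (6 mm radius by
default) at fixed MNI coordinates, grouped into seven intrinsic connectivity
networks and split into two classes: cognitive (DMN, SN, DAN, FPCN) and
sensorimotor (AN, VN, MN). Node order is fixed by the ROI table and asserted
by a hash everywhere, so the 861 node pairs (109 within-network, 752
between-network) are identically indexed for every subject.

Two statistical layers sit on top of the per-subject z matrices:

* **Edge level** — for each node pair, a Welch two-sample t test compares
  the subject z values of two age groups; p values are corrected jointly
  over all pairs by a false-discovery-rate step-up. The default is
  Benjamini–Yekutieli because the pairs of a correlation matrix are
  arbitrarily dependent and BY is valid with no dependence assumptions;
  Benjamini–Hochberg is available (`fdr_method = "BH"`) and is the more
  powerful choice under the positive-dependence conditions that usually hold
  here. The difference convention is earlier minus later group ("Y−M" =
  mean(young) − mean(middle)) throughout.
* **Network level** — each subject's mean z over a network's within-network
  pairs becomes the response of a mixed ANCOVA:
  `mean_z ~ network * age_group * gender + FD + DVARS + thickness +
  (1|center) + (1|subject)`, REML, with independent random intercepts
  (variance-components structure). Because a model with many factorial
  interactions is fragile under strong imbalance, groups are first matched
  in size by random subsampling to the smallest group
  (`matched_subsample()`).

Pre-planned contrasts are built from the least-squares means (LSM) of the
network × age-group cells: `C1(k) = LSM(young,k) − 2·LSM(middle,k) +
LSM(old,k)` contrasts the young-to-middle transition against the
middle-to-old transition within network k (positive C1 = early decline with
late plateau/rebound); `C2(c,s) = C1(c) − C1(s)` asks whether a cognitive
network's transition pattern differs from a sensorimotor one's. Family-wise
multiplicity is corrected by Monte-Carlo max-|t|: the observed |t| of each
contrast is referred to the distribution of the maximum |t| over its family
under the estimated contrast correlation, estimated from 10^5
multivariate-normal draws. The two families (7 within-network contrasts; 12
class-pair contrasts) are corrected separately, mirroring how the two
contrast sets are reported as separate analyses.

## Least-squares means and degrees of freedom

LSM are computed directly from the fixed-effect estimates: the model matrix
is evaluated on a reference grid holding covariates (FD, DVARS, thickness) at
their sample means and averaging the gender factor with equal weights within
each network × age-group cell. A test cross-checks this construction against
the independent `emmeans` implementation.

Fixed-effect F tests are type III. Two denominator-df methods are exposed:
Satterthwaite (via lmerTest; the default for data analysis) and a
large-sample Wald chi-square/F (`ddf = "asymptotic"`), which is an order of
magnitude faster and indistinguishable at the designs used here (hundreds to
thousands of denominator df) — the simulation studies in the test suite use
it. The Monte-Carlo max-|t| adjustment uses a multivariate-normal
approximation to the joint t distribution; at the df of every design in this
package the difference from a multivariate t is negligible, and adjusted p
values are floored at the raw p value.

## The synthetic cohort

The generator is the package's ground-truth instrument, not a fixture. A
`cohort_config()` fixes: group sizes (default 106 per group — the matched
design size; the study-scale 543/238/106 imbalance is reproduced by
generating at those sizes and matching down), age bounds (21–40, 41–60,
61–85, uniform within groups), a multi-center table (default four sites, TR
2–3 s, 119–175 frames; the first site is 120 frames at TR 2.5 s, matching
the largest typical site), an MNI-aligned grid (default 4 mm isotropic,
46 × 55 × 46), voxel noise SD, a motion scale, and the planted effects.

The *effect ledger* expands per-network, per-age-group target correlations
(plus optional between-network targets) into one full 42 × 42 target
correlation matrix per age group. Every matrix must be positive
semi-definite; a violating target is rejected naming the offending group,
with an opt-in repair (`psd_repair = TRUE`) that clips negative eigenvalues
and rescales to unit diagonal. The default planted pattern encodes the
lifespan hypothesis the pipeline is designed to detect — cognitive networks
decline early then plateau, AN/VN decline across both transitions, MN rises
then falls — so that default runs exercise every downstream contrast.

Latent network signals are white Gaussian vectors transformed by the
symmetric square root of the target matrix, then hard low-passed below
0.08 Hz and rescaled to unit variance, making them low-frequency dominated
like resting BOLD so the pipeline's own filter preserves the planted
structure. Sphere voxels receive their node's latent series plus white
voxel noise (a voxel inside two overlapping spheres is assigned to the
nearer centre; the only overlapping standard pair is the two anterior
cingulate nodes); all brain voxels share a global fluctuation; ventricle and
deep-white-matter boxes carry their own slow drifts; masks are procedural
(ellipsoid brain, interior boxes) since real data would use standard
atlases. Motion traces are smoothed Gaussian random walks scaled by
`motion_scale`; they feed FD/DVARS and the nuisance design but do not
displace the simulated volumes — rigid-body realignment is out of scope, and
its parameters are taken as inputs.

Two consequences of band-limiting are worth stating. First, filtering
reduces the effective number of independent time points to roughly the
retained band fraction, so the sampling SD of a null Fisher z is wider than
the white-noise value `1/√(T−3)`; the classical law is therefore verified on
white series (`band_limited = FALSE`), and all group-level inference uses
empirical between-subject variance, which is insensitive to this. Second,
expected correlations are unchanged by common filtering, so planted targets
are recovered without bias (verified at long runs in the tests).

A fast path, `simulate_cohort_connectivity()`, draws the latent ROI series
directly — identical in law to what the sphere voxels carry — and skips the
voxel lattice. Cohort-scale experiments (FDR calibration over hundreds of
cohorts, effect-recovery curves) use it; a test confirms the two routes
agree on the same subject. What the synthetic cohort does *not* emulate:
scanner artifacts, slice timing, susceptibility distortion, cardiac and
respiratory cycles, spatially structured noise, realistic age-related
atrophy (thickness is a generated covariate with mild linear thinning), or
arousal/eye-state differences. Green tests therefore certify the statistical
machinery, not robustness to those phenomena.

## Preprocessing: numerical choices

* **Order** — smoothing, then detrend/low-pass, then nuisance regression;
  the order is recorded in the output log and configurable
  (`smooth_first = FALSE` filters before smoothing; the two commute only
  approximately at mask boundaries).
* **Filter** — removal of the constant and least-squares linear trend,
  then a zero-phase hard low-pass in the FFT domain keeping frequencies
  strictly below the cutoff, then re-detrending so the output contract
  (exactly zero mean and trend) holds. A hard FFT mask makes the passband
  and stopband exactly testable; at 120 frames and TR 2.5 s a 0.1 Hz
  sinusoid lands on an integer bin and is annihilated.
* **Filtered regressors** — the nuisance columns are passed through the
  identical filter before regression (`filter_regressors = TRUE`).
  Regressing unfiltered nuisance series out of filtered data can reintroduce
  stopband variance; matching the spectra avoids that. The filter
  annihilates the linear-trend column, which is then dropped as numerically
  zero; the constant column is never filtered.
* **Smoothing** — separable per-axis Gaussian with σ = FWHM/(2√(2 ln 2))
  scaled by each axis's voxel size (anisotropic voxels handled per axis),
  kernel truncated at 3σ and renormalised row-wise, so a constant volume is
  reproduced exactly and frame sums are conserved away from boundaries.
* **Derivatives** — backward differences with d[1] = 0.
* **Degenerate designs** — pivoted QR drops rank-deficient columns and logs
  them; a design whose data-driven columns all vanish (zero motion, constant
  volumes) keeps its constant and linear columns (rank 2) and warns.
* **GSR** — a design toggle only; filtering and smoothing are unaffected, so
  with/without-GSR comparisons isolate the regressor set.

## Motion QC choices

Rotations are converted to mm as arc length at a 50 mm head radius (the
conventional value; the generator produces rotations in radians and the
conversion happens only in QC). DVARS is standardized by its predicted null
value, computed from per-voxel robust lag-1 difference SDs (IQR/1.349), so
white data yield ≈ 1 and the measure is scale-free. Screening uses
mean FD < 0.5 mm (strict) and mean standardized DVARS in the closed interval
[0.7, 1.5]; these describe a retained sample, so the default behaviour is to
flag, not drop (`enforce_qc = TRUE` drops). No frame censoring is performed;
motion enters the group model as per-subject covariates.

## Voxelwise group maps

The map-level two-sample test controls family-wise error by group-label
permutation of the maximum |t| (≥ 1000 permutations recommended), which is
exact under exchangeability at any map size and replaces parametric
random-field corrections that require smoothness estimation.

## Problem sizes used by the tests and acceptance script

Chosen as the package's own desk-scale study conditions: FDR calibration
uses 200 null cohorts of 30 subjects per group (42-node atlas, 120 frames,
TR 2.5 s); effect recovery uses Δz = 0.2 within DMN at 40 per group over 20
seeds; ANCOVA operating characteristics use the matched 106-per-group design
over 10 balanced centers, 100 pattern runs and 200 null runs with the
asymptotic df path; variance-component recovery uses 30 centers × 10
subjects. Voxel-level tests run on 4–6 mm grids with 48–200 frames and a
handful of subjects; the full default grid is exercised, the full default
cohort size is not.

## Known limitations

* Subject random effects are intercepts only; no network-specific subject
  covariance (the variance-components structure is the only one
  implemented, plus the residual).
* The max-|t| adjustment is normal-based; at very small designs (few
  centers, few subjects) it will be slightly anticonservative relative to a
  multivariate-t simulation.
* Seed-to-voxel maps clamp |r| at 1 − 1e−7 before the Fisher transform so
  seed voxels stay finite.
* The generator's realism gaps listed above mean real-data robustness
  (vascular confounds, site-specific artifacts) is untested here by design.
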