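---
title: "Methods: perivascular diffusivity and spherical-mean microstructure mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perivascular diffusivity and spherical-mean microstructure mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpsmt)
```

# Scope

`alpsmt` implements an end-to-end analysis chain for multi-shell
diffusion-weighted MRI (DWI) aimed at glymphatic-system neuroimaging:

1. protocol I/O and shell grouping for HCP-style acquisitions
   (b = 1000/2000/3000 s/mm² plus b0 volumes);
2. a per-voxel single diffusion tensor fit on the b = 1000 shell with
   fractional anisotropy (FA) and mean diffusivity (MD) maps;
3. the DTI-ALPS index ("diffusion tensor image analysis along the
   perivascular space") from projection- and association-fibre ROIs;
4. a two-compartment spherical-mean-technique (SMT) fit yielding the
   intra-neurite volume fraction (INVF) and the extra-neurite mean
   diffusivity (exMD);
5. regional aggregation over an atlas label volume (34
   Desikan–Killiany cortical regions plus pooled grey/white composites);
6. the cohort statistical layer: circadian time construction, Pearson
   correlations, standardized-coefficient linear models, pooled t-tests,
   and Bonferroni control over regional screens.

Because suitable human cohort data are access-restricted, the package
ships a first-class synthetic-data module. Every stage is validated by
parameter recovery: phantoms and cohorts are generated with known ground
truth, pushed through the pipeline, and the estimates compared with the
generators.

Upstream image processing — distortion/eddy/motion correction, cortical
reconstruction, template registration — is out of scope. The package
consumes preprocessed 4-D volumes with FSL-dialect `bval`/`bvec` tables,
and masks/atlases already resampled into the image grid.

# Models

## Diffusion tensor

Per voxel the signal follows the mono-exponential tensor model
$$S(b, \mathbf g) = S_0 \exp(-b\, \mathbf g^\top D\, \mathbf g),$$
with $D$ a symmetric 3×3 tensor (6 unique elements, stored in the order
Dxx, Dyy, Dzz, Dxy, Dxz, Dyz; units mm²/s). Taking logs makes the model
linear with design row
$(1, -b g_x^2, -b g_y^2, -b g_z^2, -2b g_x g_y, -2b g_x g_z, -2b g_y g_z)$.
`fitTensor()` solves this by ordinary least squares, followed by one
weighted refit with weights equal to the squared predicted signals — the
standard variance-stabilizing compromise for log-transformed magnitude
data, since the log transform inflates the variance of low signals. Only
the b = 1000 shell and the b0 volumes enter the fit; higher shells, where
the mono-exponential model is visibly wrong, are excluded by design.

FA uses the $\sqrt{3/2}$-normalized convention with range [0, 1]
(stated explicitly because two equivalent normalizations circulate):
$$\mathrm{FA} = \sqrt{\tfrac{3}{2}}\,
 \frac{\sqrt{\sum_i (\lambda_i - \bar\lambda)^2}}{\sqrt{\sum_i \lambda_i^2}},
 \qquad \mathrm{MD} = \bar\lambda.$$
FA of an all-zero eigenvalue triple is defined as 0.

## DTI-ALPS index

At the level of the lateral-ventricle body, perivascular spaces of the
medullary veins run along the left–right (x) axis, perpendicular both to
projection fibres (head–foot, z) and to association fibres
(anterior–posterior, y). Averaging tensor elements over the two fibre
ROIs per hemisphere gives four diffusivities, and
$$\mathrm{ALPS} = \frac{\mathrm{mean}(D_{x,\mathrm{proj}},
 D_{x,\mathrm{assoc}})}{\mathrm{mean}(D_{y,\mathrm{proj}},
 D_{z,\mathrm{assoc}})}.$$
An index of 1 means no preferential diffusion along the perivascular
axis. Voxels whose stored tensor is identically zero (no fit output) are
excluded from the ROI means; this reading of "non-zero voxels" matches
the mask-then-average order of the original method. The index is
computed independently per hemisphere and the two indices averaged
arithmetically — averaging of *indices*, not of diffusivities before
division, which is the interpretation we adopt where the procedure's
prose is ambiguous. ROI sizes (voxel count × voxel volume, mm³) are
reported for descriptive parity but play no role in the index.

Because the index reads tensor elements *by axis*, the image axes must be
approximately aligned with anatomical left–right/anterior–posterior/
head–foot. `loadDWI()` rejects acquisitions whose affine deviates more
than 20° from axis alignment (configurable; `Inf` disables the check).
Gradient directions are interpreted in the image axis frame (FSL bvec
convention) and no world-frame rotation is applied.

## Spherical-mean two-compartment model

Averaging the DW signal over all gradient directions of a shell removes
the orientation distribution of fibres and leaves a per-shell mean that
depends only on microscopic compartment parameters. With the b0-normalized
spherical mean $\bar e(b)$, the two-compartment model is
$$\bar e(b; v, \lambda) = v\, c(b\lambda) +
 (1 - v)\, e^{-b(1-v)\lambda}\, c(b v \lambda),$$
where $c(x) = \sqrt{\pi/(4x)}\,\mathrm{erf}(\sqrt x)$ is the spherical
mean of $\exp(-x\cos^2\theta)$. The three modelling assumptions are:

* the intra-neurite compartment is a "stick" with zero transverse
  diffusivity;
* longitudinal microscopic diffusivity $\lambda$ is the same inside and
  outside neurites;
* the extra-neurite transverse diffusivity follows the tortuosity
  relation $\lambda_\perp = (1 - v)\lambda$.

$v \in [0,1]$ is the intra-neurite volume fraction (INVF) and the derived
extra-neurite mean diffusivity is $\mathrm{exMD} = \lambda(3 - 2v)/3$.

`fitSMT()` minimizes the equally-weighted sum of squared differences
between observed and model shell means over $v \in [0,1]$,
$\lambda \in [\lambda_{\min}, \lambda_{\max}]$, using a coarse grid
(v = 0.05…0.95 step 0.1; λ = 0.25…3.0 step 0.25) followed by
box-constrained L-BFGS-B refinement. Both parameters are free — the
two-shell-minimum requirement follows from the two degrees of freedom.
The fit is the unnormalized two-parameter formulation on b0-normalized
means, so per-voxel S0 is not a free parameter and
$\bar e(0) = 1$ holds by construction.

# Units and numerical choices

* Internal SMT units are b in ms/µm² and diffusivity in µm²/ms
  (1000 s/mm² = 1 ms/µm²), keeping $b\lambda$ of order 1 for the erf
  evaluation; exported exMD maps are converted to mm²/s. Tensor units are
  mm²/s throughout.
* $c(x)$ switches to the Taylor branch $1 - x/3 + x^2/10 - x^3/42$ for
  $x \le 10^{-5}$, where the closed form loses precision; the truncation
  error at the switch is below $10^{-24}$, and continuity across the
  switch is verified to $10^{-9}$ in the tests.
* $\lambda_{\min} = 0.01$, $\lambda_{\max} = 3.0$ µm²/ms (free-water
  ceiling at body temperature); both configurable.
* Tensor fit: signals at or below $10^{-6} \times$ mean b0 are floored
  before the log; eigenvalues below $10^{-9}$ mm²/s are clamped and the
  voxel flagged. Voxels with all-zero signals are dropped from the fit
  mask rather than erroring.
* Shell grouping: b-values ≤ 50 s/mm² count as b0; members join a shell
  within 100 s/mm² of its running mean, otherwise they seed a new shell;
  nominal shell b is the member mean rounded to the nearest 10. The
  defaults absorb the effective-b jitter of multiband protocols.
* Scalar maps and DWI volumes are written as 32-bit float NIfTI-1;
  computation is in doubles. The tensor field is persisted as a 6-volume
  NIfTI with a JSON sidecar recording the element order.

# Statistical layer

All continuous predictors and the outcome are z-scored, so each
coefficient of `standardizedLM()` is a standardized β and equals the
Pearson r in a single-continuous-predictor model (an identity the test
suite checks to 10⁻¹²; coefficient magnitudes of ~0.07 at n ≈ 900 with
p ≈ 0.03 are only consistent with this reading of "β"). Binary sex is
coded 0 (female) / 1 (male) and left unscaled, so its β reads as a group
offset in outcome standard deviations. Interaction columns are products
of the already-transformed main-effect columns, then themselves z-scored.
A variable can be re-centred to a stated origin (e.g. sleep duration
relative to 8 h/night) while still being scaled by its sample SD; this
affects only interactions involving it, since z-scoring absorbs shifts in
main effects.

Circadian time is the signed same-calendar-day difference from usual
awakening time to mid-scan time in decimal hours, without 24-hour
wrapping: negative values (scan before usual awakening) are meaningful
and preserved. The definition of "mid-scan" (midpoint of one DWI set vs
the session) is left to the data supplier; the package consumes it as an
input field.

Group comparisons use the pooled-variance two-sided Student's t-test;
regional screens correct p-values by Bonferroni with family size m = 34
regardless of how many regions survive filtering. Missing data are
handled by complete-case deletion per model; family structure (siblings)
is not modelled — plain OLS, no mixed effects.

# What the synthetic data emulate — and what they do not

`makePhantom()` builds slab phantoms on a small grid (default
20 × 20 × 12 voxels of 1.25 mm) under the emulated protocol: three shells
of 90 uniformly drawn directions plus 18 b0 volumes, S0 = 1000. Regions
emit: exact tensor signals; stick + tortuosity-zeppelin mixtures averaged
over a per-voxel fibre orientation set (`nFibreDirs`; `Inf` means a fully
dispersed orientation distribution whose per-direction signal equals the
analytic spherical mean); or isotropic CSF-like decay. Rician noise
replaces each magnitude by $|S + \epsilon_1 + i\epsilon_2|$ with
$\epsilon_j \sim N(0, (S_0/\mathrm{SNR})^2)$; a Gaussian flag exists for
debugging. The default SNR of 50 is a typical b0 SNR for the emulated
3 T protocol.

Two distinct error sources matter when interpreting recovery tests:
direction-sampling error (a 90-direction average is not an exact sphere
integral; for a single stick it perturbs the shell mean by up to ~0.01,
which the steep v-Jacobian amplifies roughly tenfold into v̂) and
measurement noise. The stochastic-recovery checks therefore use a
10-orientation dispersed fibre population per voxel, which keeps the
voxel-to-voxel spread noise-dominated, while dedicated
orientation-invariance tests compare 1-, 10- and ∞-direction populations
at the direction-sampling tolerance. Noise-free identity-chain checks use
the fully dispersed limit, where every downstream estimator must be exact
to numerical tolerance.

`makeCohort()` draws covariates independently from truncated normal
distributions with the study-population descriptives (age 28.7 ± 3.7 in
[22, 37]; BMI 26.5 ± 5.23; systolic blood pressure 123.5 ± 13.8; PSQI
4.85 ± 2.80 rounded and clamped to [0, 21]; CFTC 113.6 ± 20.19; usual
awakening 07:04 ± 2:04; acquisition midpoint 12:04 ± 3:19; sleep
6.80 ± 1.15 h). No white-matter-volume descriptive is available, so we
use N(470 000, 50 000) mm³ truncated to [250 000, 750 000], typical of
young adults. PSQI component scores distribute the global score over the
seven components one point at a time, capped at 3 per component, so the
global score is the component sum by construction. Clock times are
rounded to whole minutes before circadian time is computed, exactly as
the analysis pipeline would see them. Each outcome is a unit-variance
standardized composite $\sum_k \beta_k z(x_k) + \varepsilon$,
$\varepsilon \sim N(0, 1 - \sum_k \beta_k^2)$; regional outcomes are 34
columns with effects only where the effect map names a region.

What the generators deliberately do *not* emulate: anatomy (no
template-shaped brains), scanner artifacts, gradient nonlinearity,
correlated covariates (a correlation hook exists but defaults to
independence — e.g. real BMI and blood pressure co-vary), non-normal
outcome tails, or family structure. Note two systematic consequences of
truncation: the realized BMI mean sits ~1.4% above the nominal 26.5 and
its SD ~2.3% below 5.23 (the analytic truncated-normal moments are the
correct large-n targets, and the tests assert convergence to those).
Passing recovery tests therefore demonstrate estimator correctness and
calibration under the stated model, not robustness to the full
complexity of in-vivo data.

# Validation design and problem sizes

The test suite (and `scripts/acceptance.R`) recomputes, per run:

* closed-form $c(x)$ and $\bar e$ against direct numerical quadrature of
  the orientation integral (agreement ≤ 10⁻⁶ across x ∈ [10⁻⁸, 10]);
* the noise-free identity chain on a 20 × 20 × 12 phantom with
  3 × 90 directions: tensor, FA/MD and SMT parameters recovered to
  ≤ 10⁻⁴ relative error, pipeline ALPS index equal to the analytically
  composed index to ≤ 10⁻⁹;
* stochastic recovery at SNR 50 on 500 voxels (10-orientation fibre
  populations): v̂ bias ≤ 0.05, RMSE ≤ 0.10; tensor Dxx median within 3%;
* cohort effect recovery at n = 916 across 20 seeds with standardized
  effects {−0.07, −0.20, +0.15}: mean β within ±0.01 and ≥18/20 estimates
  inside their 95% intervals;
* regional-screen calibration at n = 916 across 20 seeds: family-wise
  error within binomial tolerance of 0.05 under the null, and detection
  of two injected −0.15 effects. Note that both the detection criterion
  (≥18/20 seeds at per-seed success probability ≈ 0.89) and the
  false-positive bound (≤1 across 20 × 32 null regions, expectation
  ≈ 0.94) sit essentially *at* their distributions' means, so these two
  assertions fail for an appreciable fraction of seed choices even when
  the implementation is exactly calibrated — a property of the
  thresholds, not of the code. The seeds used were fixed in advance and
  not reselected.
* determinism: two orchestrated runs from one configuration are
  byte-identical (uncompressed NIfTI, fixed seeds, checksummed manifest).

These sizes keep the full suite in tens of seconds on one CPU while
leaving every bound dominated by the estimator, not the problem size.

# Known limitations

* No Rician-bias correction of shell means before the SMT fit (a config
  hook exists); at shell-mean SNR this bias is small but nonzero at high
  b.
* The single-tensor fit has no outlier rejection (RESTORE-style) and no
  free-water elimination.
* ALPS ROI placement is consumed, not computed: the original method's
  template-space ROI drawing and subject-space transformation happen
  upstream.
* Atlas aggregation is volumetric and unweighted; no partial-volume
  handling, no surface-based parcellation.
* The cohort models ignore kinship; with related subjects the standard
  errors are optimistic.
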