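---
title: "From ASL signal to cognitive decline: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ASL signal to cognitive decline: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aslcbf)
```

`aslcbf` implements a complete analysis chain for pseudo-continuous
arterial spin labelling (pcASL) perfusion MRI in a memory-clinic setting:
voxelwise cerebral blood flow (CBF) quantification, partial-volume
correction (PVC), regional perfusion extraction, and linear mixed models
relating baseline perfusion to the rate of cognitive decline measured
with the Mini-Mental State Examination (MMSE). Because clinical imaging
data cannot ship with a package, every stage is exercised against a
synthetic brain phantom and a simulated longitudinal cohort whose ground
truth is known exactly. This vignette documents the models, the defaults
and why they were chosen, the numerical decisions, and what the synthetic
data can and cannot tell you about real acquisitions.

## 1. CBF quantification

A single-compartment kinetic model converts the ASL difference signal
$\Delta S$ (control minus label) and the proton-density reference $S_0$
into perfusion:

$$
\mathrm{CBF} \;=\; u\,\lambda\,
\bigl(1 - e^{-T_{SAT}/T_{1GM}}\bigr)\,
\frac{e^{w/T_{1B}}}
     {2\,T_{1B}\,\bigl(1 - e^{-\tau/T_{1B}}\bigr)\,\varepsilon}\,
\frac{\Delta S}{S_0}.
$$

The defaults in `kinetic_params()` describe a background-suppressed 3D
pcASL protocol at 3 T: post-label delay $w = 2.0$ s, labelling duration
$\tau = 1.5$ s, partition coefficient $\lambda = 0.9$ mL/g, efficiency
$\varepsilon = 0.8 \times 0.75 = 0.6$ (label efficiency and
background-suppression losses folded into one constant, as is standard
for this protocol family), $T_{1B} = 1.4$ s, and a saturation-recovery
correction of the reference image ($T_{SAT} = 2.0$ s, $T_{1GM} = 1.2$ s).

Two decisions deserve comment:

* **Unit conversion.** With $\lambda$ in mL/g and times in seconds the
  bracketed expression yields mL/g/s; `unit_factor = 6000` converts to
  the conventional mL/100 g/min. With default parameters the full
  multiplier is `quantification_factor(kinetic_params())` $\approx
  1.655 \times 10^4$, i.e. a signal ratio $\Delta S/S_0 = 0.01$ maps to
  about 165.5 mL/100 g/min.
* **No clipping.** Negative quantified values arise from noise and are
  preserved; ROI means must reflect the raw quantification, and any
  clipping belongs to reporting, not to the estimator.

`quantify_cbf()` is linear in $\Delta S$ and inversely linear in $S_0$;
the test suite verifies it against an independent log-space evaluation of
the same formula on 1000 random parameter draws ($\le 10^{-12}$ relative
error) and against exact round trips through the phantom simulator.

## 2. Partial-volume correction

ASL voxels at this resolution mix gray matter (GM), white matter (WM)
and CSF. `pvc_regress()` estimates pure-tissue perfusion by locally
weighted two-tissue regression: at each voxel $v$ it solves

$$
\mathrm{cbf}(u) \;\approx\; P_{GM}(u)\, c_{GM} + P_{WM}(u)\, c_{WM},
\qquad u \in \mathcal{N}(v),
$$

by weighted least squares under a 3-D Gaussian kernel (default FWHM
9.5 mm, $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ converted to voxel
units per axis, so anisotropic voxels get an anisotropic stencil). There
is no intercept and CSF perfusion is taken as zero — the standard
assumptions for this regression family. The PVE-weighted cortical
summary $\sum P_{GM}\,\hat c_{GM} / \sum P_{GM}$ gives the reported
"PVC cortical CBF", which systematically exceeds uncorrected GM-region
means wherever $P_{GM} < 1$ and $c_{WM} < c_{GM}$.

Numerical choices:

* **Separable convolution.** The per-voxel $2\times 2$ normal equations
  are assembled by separable Gaussian convolution of the five product
  images ($P_{GM}^2$, $P_{GM}P_{WM}$, $P_{WM}^2$, $P_{GM}y$, $P_{WM}y$).
  This is algebraically identical to solving the stencil-weighted
  regression voxel by voxel (kernel normalization cancels in the
  solution) and reduces the cost from $O(N k^3)$ to a few banded matrix
  products. The suite checks equivalence with a brute-force per-voxel
  solve to $10^{-10}$.
* **Truncation.** The stencil is cut at 3$\sigma$ per axis and clipped at
  the volume boundary; with zero signal and zero tissue fraction outside
  the brain, clipping and zero padding coincide.
* **Degeneracy.** Windows containing effectively one tissue make the
  local design rank deficient. Voxels whose normal matrix has condition
  number above `1e8` (or a non-positive eigenvalue) are excluded from
  `valid_mask`; a dominant-tissue fallback
  $\sum w\,\mathrm{cbf} / \sum w\,P_{dom}$ is recorded and flagged in
  `diagnostics`. The threshold is a numerical guard, not a scientific
  statement; it is configurable.
* **Low-GM guard.** The cortical map is reported only where the central
  voxel has $P_{GM} \ge 0.05$ (`gm_guard`), to keep near-zero weights
  from amplifying noise in the weighted summaries. This too is
  configurable and logged in the result object.

On noise-free two-tissue mixtures the regression recovers the generating
$c_{GM}$ and $c_{WM}$ exactly (to $10^{-6}$) wherever the local design
has rank 2, and under Gaussian acquisition noise the estimator is
unbiased — both properties are tested.

## 3. Regional extraction

`whole_brain_mean()` averages the uncorrected map over *all* voxels
classified as brain tissue, CSF included — that convention, common in
clinical ASL reports, is why whole-brain CBF (about 23–28 mL/100 g/min)
sits far below PVC cortical values (about 31–43). `regional_means()`
averages over an integer label map with five cortical regions (frontal,
parietal, precuneus + posterior cingulate, temporal, occipital); with a
`pvc_result` it adds PVE-weighted PVC means per region. Regions missing
from a label map are reported as `NA` with a zero voxel count, never as
zero perfusion. On real data the label map would come from an atlas
registration; the package is agnostic about its provenance.

## 4. The synthetic phantom

`build_phantom()` constructs concentric ellipsoids — an outer GM shell,
a WM core, a central CSF "ventricle" — with smooth partial-volume
transitions about 2.5 voxels wide, on a default $48^3$ grid of 1.7 mm
isotropic voxels. Azimuthal sectors of the shell are labelled as the
five cortical regions; the interior is "other brain". Ground truth obeys
the mixing law $\mathrm{cbf} = P_{GM}\,c_{GM}(\mathrm{region}) +
P_{WM}\,c_{WM}$ exactly, which makes PVC recovery testable.

Default ground-truth GM perfusion per region (23.5, 30.2, 38.3, 27.5,
36.7 mL/100 g/min for frontal, parietal, PRCPCC, temporal, occipital)
was calibrated once against the default geometry so that the
*uncorrected* regional means land at typical memory-clinic values (18.7,
23.9, 30.2, 21.8, 29.1). White matter defaults to 20 mL/100 g/min —
below all GM values, so the correction has signal to separate — and CSF
to zero. `simulate_asl()` inverts the quantification equation to produce
$\Delta S$, adds seeded Gaussian noise to $\Delta S$ only (the reference
stays noise-free, keeping the propagated CBF noise exactly
$F\,\sigma_{\Delta S}/S_0$ and hence analytically checkable), and
returns a co-registered stack.

What the phantom does **not** emulate: head anatomy, coil or readout
physics, motion, arterial transit delays, spatially varying $S_0$, and
registration or segmentation error (it supplies PVEs and labels
directly). Passing tests therefore validate the *estimators* — the
quantification algebra, the regression, the summaries — not robustness
to acquisition artefacts.

## 5. The cohort simulator

`simulate_cohort()` is the generative twin of the analysis model:

$$
\mathrm{MMSE}_{ij} = \beta_0 + b_{0i} + (\beta_t + b_{1i})\,t_{ij}
 + \beta_c z_i + \beta_{ct}\, z_i t_{ij} + x_i'\gamma + \epsilon_{ij},
$$

with independent zero-mean Gaussian random intercepts $b_{0i}$, slopes
$b_{1i}$ and residuals, and $z_i$ the baseline CBF of a chosen measure
standardized and *inverted* (higher $z$ = lower perfusion). Defaults:
$\beta_0 = 22$ MMSE points, $\beta_t = -2.11$ points/year,
$\beta_c = -0.42$, $\beta_{ct} = -0.50$ points/year per SD, $n = 88$
subjects — values typical of a dementia cohort of this kind. The
dispersions ($\sigma_{b_0} = 3$, $\sigma_{b_1} = 1.5$,
$\sigma_\epsilon = 1.5$ MMSE points) are the package's own choices:
clinical reports rarely publish variance components, and these values
give per-subject trajectories whose scatter (baseline SD $\approx 3.4$
points, annual-slope SD $\approx 1.6$) looks like routine MMSE data
while keeping $n = 88$ estimable.

Other generator choices, in brief: visits start at $t = 0$ with 2–8
visits per subject (uniform) and gaps uniform on $[0.7, 1.3]$ years;
covariates are drawn independently with memory-clinic marginals (age
$65 \pm 7$, half women, Verhage education $5 \pm 1$, normalized GM
volume $715.8 \pm 44.6$ mL, atrophy and white-matter scores on their
rating scales, zero-inflated Poisson counts for microbleeds and
lacunes with median 0); the twelve CBF measures share a per-subject
factor at correlation 0.7, since regional perfusion is strongly
correlated within subject; and MMSE clamping to integer $[0, 30]$ is
**off** by default because rounding and censoring bias slope recovery —
turn it on for realism studies, not for estimator validation.

## 6. Inclusion and the mixed model

`apply_inclusion()` retains subjects with at least two MMSE scores
spanning at least one year — the usual entry criterion for decline
analyses; the exact-one-year span is included. `fit_lmm()` standardizes
the baseline CBF measure *on the analysis sample actually fitted* (after
inclusion and complete-case filtering), inverts it, and fits

`mmse ~ cbf + time + cbf:time + covariates + (1 + time | subject)`

by REML through `lme4::lmer()`, with an unstructured $2 \times 2$
random-effects covariance. Model 1 adjusts for age, sex and education;
model 2 adds normalized GM volume, medial temporal atrophy,
white-matter hyperintensities, microbleeds and lacunes — except that PVC
analyses drop the GM-volume term, whose information the correction
already uses. Choices worth making explicit:

* **REML, not ML** — the default of the major mixed-model software this
  analysis style comes from; both are exposed via `reml = FALSE`.
* **Wald $p$-values against a normal reference** — reported estimates
  are $\hat\beta \pm \mathrm{SE}$ with $p = 2\Phi(-|\hat\beta/SE|)$;
  at $n \approx 88$ subjects the normal and $t$ references are close,
  and the replicate-based calibration test (empirical SD of the
  interaction estimate within 20 % of the mean model SE) confirms the
  SEs are honest at this size.
* **Non-convergence is a flag, not an exception** — degenerate samples
  return an `lmm_result` with `converged = FALSE`.
* **Complete-case covariate handling** — subjects missing a modelled
  covariate are dropped with a message, per model.

In the noise-free limit (all dispersions zero) the fitted fixed effects
equal the generating ones to machine precision, and across 200 simulated
cohorts at the defaults every fixed effect is recovered within
Monte-Carlo error — both are acceptance-level tests.

## 7. The pipeline and reproducibility

`run_pipeline()` composes the stages — phantom, simulated acquisition,
quantification, PVC, regional extraction, cohort simulation (with its
CBF distributions centred on the phantom-derived regional values),
inclusion, and the full grid of mixed models (6 measures × 2 models ×
uncorrected/PVC, plus the unadjusted annual change) — and writes
volumes (NIfTI), tables (CSV) and a provenance log. One master seed is
split deterministically into per-stage seeds, so the whole run is
byte-reproducible and each stage can be re-run in isolation. Volumes
travel as NIfTI via `RNifti`; tables as CSV with a fixed header.

Problem sizes used in the shipped tests were chosen to keep the suite
quick while leaving every property sharply testable: a $20^3$ phantom at
3.4 mm for imaging properties, $16^3$ volumes for the brute-force PVC
oracle, the default $48^3$ phantom for calibration checks, and 200
replicate cohorts at $n = 88$ for recovery and SE calibration.

## 8. Known limitations

* Single post-label delay: arterial transit-time variation is not
  modelled and would bias real-data CBF regionally.
* The phantom's geometry is deliberately artificial; spatial smoothness
  of its PVE maps is more benign than real segmentations.
* The two-tissue regression inherits the usual PVC caveats — no method
  of this family is a gold standard — and assumes locally constant
  tissue perfusion at the kernel scale.
* The cohort simulator draws covariates independently; real demographic
  and vascular covariates are correlated, so adjusted and unadjusted
  fits differ more in clinic data than in simulation.
* MMSE is modelled as continuous and untransformed; floor/ceiling
  effects only appear with `clamp_mmse = TRUE`.
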