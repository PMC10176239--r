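---
title: "Methods: the DTI-ALPS glymphatic index, PVS quantification, and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the DTI-ALPS glymphatic index, PVS quantification, and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtialps)
```

## The measurement model

The glymphatic system exchanges CSF and interstitial fluid along perivascular
spaces (PVS). At the level of the lateral ventricles, medullary veins — and
the PVS sheathing them — run right–left (the image x axis), orthogonal to the
two dominant white-matter fibre systems there: projection fibres
(inferior–superior, z) and association fibres (anterior–posterior, y).
Because water diffusion inside a fibre tract is strongly anisotropic along
the tract, the x-axis diffusivity measured *within* those tracts is not
driven by the axons; any excess x diffusivity is attributed to fluid motion
along the x-oriented perivascular channels. The ALPS index condenses this
into a ratio of scanner-frame diagonal tensor elements,

$$\mathrm{ALPS} \;=\; \frac{\mathrm{mean}(D_{xx,\mathrm{proj}},\, D_{xx,\mathrm{assoc}})}
                         {\mathrm{mean}(D_{yy,\mathrm{proj}},\, D_{zz,\mathrm{assoc}})},$$

computed per hemisphere from ROI-mean diffusivities and averaged across
hemispheres. Isotropic diffusion gives exactly 1; higher values indicate
greater perivascular diffusivity. We use the tensor's diagonal elements in
the scanner frame (the standard ALPS convention); an alternative reading —
diffusivity along projected eigensystem axes — is not implemented because
the ratio is defined on the fixed anatomical axes, which is what makes it
sensitive to the vein-parallel component.

The ratio is computed from ROI means, not as a mean of voxelwise ratios,
matching the index's published structure; it is therefore invariant to a
global rescaling of the tensor field.

## Tensor estimation

Tensors are fitted per voxel from the log-linear model
$\ln S = \ln S_0 - b\, g^\top D g$ by ordinary least squares followed by one
reweighted pass with weights equal to the squared predicted signal — the
standard weighted-least-squares correction for the heteroscedasticity
introduced by log-transforming magnitude MRI data. $S_0$ is the fit's
intercept rather than a separate b = 0 average, so all volumes inform it.
Both shells (b = 1500 and 3000 s/mm²) enter one fit by default; a `shells`
switch restricts to the lower shell. Non-positive measurements are excluded
per voxel; voxels left with fewer than 7 usable volumes are flagged
unfitted, never silently zeroed. Negative eigenvalues are clamped to
1e-6 mm²/s and the clamp count recorded. A rank check on the design matrix
rejects gradient schemes that cannot identify all six tensor components.

## Automatic ROI placement

The conventional procedure places 5 mm square ROIs manually on a
direction-encoded colour FA map ("at the level of the lateral ventricle").
Automation has to make three choices, each configurable and overridable by
manual coordinates:

* **Axial level.** The slice with the most CSF-like voxels. A voxel is
  CSF-like when its fitted MD leaves the plausible parenchyma band
  (MD > 1.5e-3 or MD < 0.3e-3 mm²/s). The lower tail matters at finite SNR:
  the high-b CSF signal sits at the Rician noise floor, is flat across b,
  and therefore fits to a *near-zero* MD rather than a high one.
* **Candidate voxels.** Fibre dominance: |v1 component| > 0.7 along z
  (projection) or y (association), within each hemisphere, excluding a
  1-voxel midline band.
* **Centre.** The ROI position maximising the ROI-*mean* dominance score
  |v1·axis|·FA (box-filtered score). Centring on the single best voxel is
  biased at realistic SNR — the argmax selects FA noise extremes and
  depressed transverse diffusivities, which we measured as a ~19% ALPS
  underestimate at SNR 20; maximising the ROI-mean score is identical on
  noise-free phantoms and keeps the mean ALPS within 1% of the noise-free
  value at SNR 20. Ties (homogeneous blocks) resolve to the candidate
  closest to the tie-set centroid, which centres the ROI in the tract.

The "5-mm-diameter square" is read as a 5 mm in-plane square on one axial
slice, rounded to the nearest odd voxel count so the centre voxel is well
defined (3 voxels at the default 1.5 mm resolution).

## The synthetic phantom

The phantom emulates exactly the geometry the index relies on: bilateral
projection blocks (tensor eigenvalues λ∥ = 1.5e-3 along z, λ⊥ = 0.4e-3
transverse), bilateral association blocks (λ∥ along y), a central CSF slab
(isotropic 3.0e-3) as the ventricle landmark, and isotropic background
tissue (0.7e-3). In both fibre blocks a perivascular diffusivity
`d_perivascular` is added to the tensor's xx element, so the ground-truth
index is analytically

$$\mathrm{ALPS}_{\mathrm{truth}} = \frac{\lambda_\perp + d_{\mathrm{peri}}}{\lambda_\perp},$$

which is the oracle for the whole pipeline (e.g. d = 0.3e-3 with
λ⊥ = 0.4e-3 gives 1.75). The default d = 1.4e-4 corresponds to ALPS = 1.35,
the magnitude reported for adult clinical cohorts. Signals follow
$S = S_0 e^{-b\,g^\top D g}$ on two shells (b = 1500, 3000; 98
spherical-Fibonacci directions per shell) plus one b = 0 baseline — the
acquisitions it mimics do not state their b = 0 count, so it is a
configurable choice; one baseline suffices because $S_0$ is a fit
parameter. Rician noise is applied as
$S' = \sqrt{(S+n_1)^2 + n_2^2}$, $n_i \sim N(0, \sigma S_0)$, with an
explicit seed; `noise_sigma = 0.05` corresponds to SNR 20 at b = 0.

The default grid is 40×40×20 voxels at 1.5 mm — deliberately desk-scale.
What the phantom does *not* emulate: susceptibility and eddy distortion,
motion, partial-volume mixtures, crossing fibres, or any biophysical flow
model (d_perivascular is a phenomenological dial). Passing tests therefore
demonstrate the correctness of the estimator chain, not robustness to
real-scanner artefacts.

## PVS quantification

The T2w/T1w pair is combined into an enhanced-contrast volume by dividing
denoised T2w by denoised T1w (PVS are bright on T2w and dark on T1w, so the
division multiplies the contrasts; the denominator is floored at 5% of the
median positive T1w intensity). Denoising uses a *selective* median filter:
a voxel is replaced by its 3×3×3 median only when the deviation is within 3
robust noise SDs. A plain median filter — the obvious edge-preserving
choice — erases 1-voxel-thin tubules outright (their enhanced contrast fell
to background in our measurements); the selective variant removes
noise-scale deviations while structures with real contrast survive, and it
is exactly the identity on noise-free volumes.

Segmentation applies a multiscale Hessian tubularity (Frangi-type
vesselness for bright tubes, scales 1 and 1.6 voxels, α = β = 0.5,
structure sensitivity at half the per-scale maximum Hessian norm),
thresholds at 0.08 inside the white-matter mask, and removes 26-connected
components below 5 voxels. The threshold is the filter's operating point on
its intended contrast, chosen from the clean-phantom response distribution
(truth-voxel responses 0.06–0.28 vs background ≤ 0.11 at the 99th
percentile). The outermost 1-voxel rim of the WM mask is excluded:
partial-volume CSF edges at the ventricle wall and cortical boundary
produce spurious tubular responses there — standard practice in PVS
pipelines.

Volume is voxel count × voxel volume, reported both in mL and as % of
intracranial volume (the unit of the published summary statistic is
ambiguous, so both are kept). The slice count is the number of in-plane
8-connected components on the axial slice one above the ventricle's
superior extent — counts depend on the connectivity convention, which is
why it is fixed and documented (8 in-plane, 26 in 3D). The severity score
uses the common visual-rating bins 0 / 1–10 / 11–20 / 21–40 / >40
(configurable), which by construction is monotone in the count.

## Cohort statistics

The statistical battery mirrors a two-group glymphatic study analysed in
SPSS:

* **Pearson correlations** with pairwise deletion and t-distribution
  p-values (n − 2 df), n reported per pair.
* **ANCOVA**: OLS of outcome ~ group + age with partial (Type-III) F tests
  by nested-model RSS comparison. For a two-level group with continuous
  covariates and no interactions this equals the SPSS Type-III table.
  Adjusted means are model predictions at the covariate grand means.
  Exact separation of residuals (a pure group shift with zero noise) is
  reported as F = ∞ rather than a misleading large number.
* **Multiple regression** of NfL on ALPS, PVS volume and age with listwise
  deletion, standardized coefficients via b·SD(x)/SD(y) (the SPSS "Beta";
  published b values of this design are interpreted as standardized, and
  both scales are always reported to remove the ambiguity), and
  added-variable residual pairs for partial-regression plots.
* All tests two-sided at α = 0.05, no multiplicity correction (matching
  the analysis style this reproduces).

The cohort generator draws each subject's ALPS parameter around a group
mean (defaults 1.336 TBI / 1.389 control) with a linear age decline
(−0.005/yr around age 55) and residual SD 0.14 (total SD ≈ the reported
0.16 scale); NfL = 60 − 30·ALPS + 0.4·age + N(0, 8) pg/mL, giving a
standardized ALPS coefficient near the reported −0.4 to −0.5 magnitude.
The generative age coefficient on NfL is positive — plasma NfL rises with
age — even though the published standardized age coefficient in this model
family is negative; only the ALPS coefficient's sign is treated as a
recoverable effect. PVS burden is Poisson (rate 25, mild age effect), with
volume proportional to count plus 10% noise so the volume–count correlation
reproduces the reported R ≈ 0.9. Subject counts, age ranges, sex ratios,
days-since-injury and GCS distributions follow the published cohort table,
including missing GCS for roughly half the TBI group.

### What the simulations can and cannot show

With a generative group difference of 0.05 ALPS units, SD 0.16 and a 37/13
split, the standard error of the adjusted difference is ≈ 0.052, so even a
perfect estimator recovers the *sign* of the effect in only
Φ(0.05/0.052) ≈ 83% of cohorts, and the ANCOVA rejects at roughly the
published borderline rate. The simulation suite verifies what is
statistically attainable: nominal type-I error (3–7% at α = 0.05),
unbiased recovery of the adjusted difference, 95% CI coverage, and
near-certain recovery of the *negative sign* of the standardized ALPS→NfL
coefficient, which is far better powered (|β| ≈ 0.4 at n = 37).

## Numerical choices and degenerate inputs

* Eigenvalue clamp floor 1e-6 mm²/s; clamped voxels counted, not hidden.
* Design-matrix rank < 7 → error naming the unidentifiable components.
* ROI contracts: four non-empty disjoint squares, bilateral, fully inside
  the fitted mask; any ROI-mean diffusivity ≤ 0 is an error.
* An all-isotropic volume cannot pass the dominance threshold; the error
  directs the user to manual coordinates (this is also how the isotropy
  calibration is evaluated).
* Tubule placement uses bounded retries (200 per tubule) with a 1-voxel
  clearance so 26-connected components equal the tubule count; failure is
  an explicit error, not a silent shortfall.
* Pipeline subject failures are isolated and logged; the run aborts only
  if every subject fails. Per-subject seeds are master seed + index, so a
  cohort prefix is stable when the cohort grows.

## Problem sizes used by the test-suite

Property tests run on 24×24×12 phantoms with 24 directions/shell (each
tensor fit well under a second); segmentation-fidelity checks use the full
40×40×20 grid; statistical calibration uses 1000 simulated cohorts for
type-I error and 200 for effect-direction and parameter recovery. These
sizes were chosen so the whole suite documents the estimators' behaviour at
interactive timescales.

## Known limitations

* ALPS automation assumes the phantom-like situation of one dominant fibre
  system per search region; real data with white-matter damage near the
  ROIs requires the manual-coordinate path (as in rater-driven practice).
* The PVS operator chain is a documented, testable analog of published
  T1/T2-combination pipelines, not a replication of any specific one.
* No registration, bias-field correction or tissue segmentation: inputs
  are assumed co-registered with masks supplied.
* The NfL model is linear-Gaussian; real plasma NfL is right-skewed.
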