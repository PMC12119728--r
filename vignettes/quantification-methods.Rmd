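---
title: "Models and numerical choices behind petmrquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices behind petmrquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

petmrquant quantifies simultaneous dynamic PET and multiparametric MRI of
intracranial tumours: static uptake metrics and contour segmentation,
tracer-kinetic modelling for an irreversibly trapped PET tracer, DCE/DSC
perfusion-permeability MRI, ASL and DWI, and the downstream statistics that
turn per-lesion parameters into cohort comparisons, a LASSO biomarker
vector, survival splits and a metabolomics screen. Because patient images
from such studies are rarely shareable, the package carries a synthetic-data
module that generates every input from known ground truth; each quantifier
is validated by recovering the parameters that generated its input.

## Data model

A `dynamic_image` is a 4-D voxel array with a `frame_schedule` (start and
duration per frame, seconds from injection; contiguity is enforced). All
kinetic fitting uses frame mid-times in minutes, the standard abscissa for
frame-integrated PET data. ROI masks live in voxel-index space on the image
grid; the hybrid acquisition is simultaneous, so masks are assumed
co-registered and no world-coordinate resampling is attempted (registration
is out of scope). NIfTI-1 is the on-disk format, with a JSON sidecar
(`FrameTimesStart`, `FrameDuration`, `Units`, `DecayCorrected`) mirroring
common PET-BIDS vocabulary so that real data can be adapted. Region curves
are arithmetic means over mask voxels; max-based statistics (SUVmax) are
computed from voxel values, never from the averaged curve. Decay correction
to injection time is tracked by a flag on each curve so it can be applied
to simulator output that is deliberately uncorrected, and double correction
is an error.

## Input function

The population input is a tri-exponential bolus,
$C(t) = (A_1 t - A_2 - A_3)e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t} +
A_3 e^{-\lambda_3 t}$, which starts at zero at injection. The package
defaults (`default_aif_params()`: $A_1 = 30$, $A_2 = 6$, $A_3 = 2$ kBq/mL,
$\lambda_1 = 1.2$, $\lambda_2 = 0.01$, $\lambda_3 = 0.35$ /min) describe a
curve peaking near 1 min with a peak-to-tail ratio of about 4.5 — the
dispersed shape of a venous, sagittal-sinus-normalised blood curve rather
than a sharp arterial bolus. The intermediate washout rate was chosen well
above typical tissue efflux rates so that, for trapping-range kinetics,
the Patlak plot is linear by 15–20 min; a slowly decaying intermediate
component comparable to $k_2+k_3$ would leave a curvature transient in the
20–30 min window that is a property of the input shape, not of the
quantifier. These parameters are data, not logic: `scale_population_input`
rescales the shape by a single factor matching its area to a measured
whole-blood curve over a stated window, evaluated on the blood curve's own
time samples so that a blood curve that is an exact multiple of the shape
returns the exact factor. Plasma is derived from whole blood by one
configurable ratio (default 1; tracer plasma partitioning is generally
unpublished).

## PET kinetics

The tracer is modelled as irreversibly trapped: a two-tissue compartment
model with $k_4 = 0$,
$$\frac{dC_1}{dt} = K_1 C_p - (k_2 + k_3) C_1, \qquad
  \frac{dC_2}{dt} = k_3 C_1,$$
measured as $C_t = (1 - v_b)(C_1 + C_2) + v_b C_b$. The blood-volume
fraction multiplies *whole blood*, since it represents blood-signal
contamination of the tissue voxel. The forward model is evaluated exactly
for a piecewise-linear input: the convolution splits into a trapped term
($\propto \int C_p$) and a reversible term, the latter computed by a
first-order recursive filter that is the closed-form solution of the
exponential kernel on each interval; predictions are then averaged over
each frame interval, avoiding bias from the long late frames. `fit_2tcm`
runs bounded Levenberg–Marquardt least squares ($K_1,k_2,k_3 \in [0,5]$,
$v_b \in [0, 0.2]$) from a documented five-point start lattice with
best-residual selection, and reports the macro constant
$K_i = K_1 k_3 / (k_2 + k_3)$.

`patlak_standard` regresses $C_t(t)/C_p(t)$ on
$\int_0^t C_p \, du / C_p(t)$ for frames at or after $t^\ast$ (default
20 min, configurable; equilibration can be judged from the returned
$R^2$). Two conventions deserve note. First, the Patlak slope of the
*measured* curve is $(1 - v_b) K_i$, not $K_i$; at $v_b = 0.03$ that is a
3% difference inherent to the measurement model, so slope-accuracy checks
are made on curves generated with $v_b = 0$. Second, a residual
equilibration transient of order a few tenths of a percent remains at
$t^\ast = 20$ min and decays by 30 min; properties that compare two Patlak
variants to each other are asserted at $t^\ast = 30$ min where both are
past the transient. `patlak_modified` is the generalized (efflux-term)
graphical form
$y = K_i x + v_0 - k_{loss} \int_0^t C_t \, du / C_p(t)$, fitted by
multiple regression with a collinearity flag — the original study's
modified formulation is defined in an external reference, so the package
commits to this documented choice behind a single interface where an
alternative could be swapped in. Uniform weighting is the default, with
frame-duration weighting optional.

## DCE-MRI

Signal is modelled with the spoiled-gradient-echo steady state;
`signal_to_concentration` estimates the equilibrium scale from the
pre-bolus baseline and the known pre-contrast $R_{10}$, inverts the signal
equation per sample (un-invertible samples are flagged, not fatal), and
maps $C = (R_1 - R_{10})/r_1$. Extended-Tofts kinetics,
$C_t = v_p C_p + K^{trans} \int_0^t C_p(u) e^{-k_{ep}(t-u)} du$, use the
same exact exponential-kernel recursion as the PET side, so no convolution
grid has to be chosen. Defaults ($r_1 = 5.0$ L mmol$^{-1}$ s$^{-1}$ for
gadobutrol at 3 T, hematocrit 0.42, $p_i = 0.8$, $R_{1i} = R_{10}$) are
configuration values — the acquisition parameters of any particular study
belong in `dce_acquisition()`.

The shutter-speed model adds finite transcytolemmal water exchange: two
longitudinal magnetisation pools (intracellular population $p_i$,
extracellular $p_o = 1 - p_i$) exchange with rates $1/\tau_i$ and
$1/\tau_o = (p_i/p_o)/\tau_i$ (detailed balance), while the contrast agent
raises only the extracellular rate,
$R_{1o}(t) = R_{10o} + r_1 C_t(t)/p_o$. The observed signal is the exact
two-pool SPGR steady state, computed from the closed-form eigendecomposition
of the 2×2 exchange-relaxation matrix, vectorised over time (the numeric
matrix exponential serves as an independent oracle in the tests, agreeing
to 1e-14). As $\tau_i \to 0$ the signal reduces to the fast-exchange
(extended-Tofts) signal; the nesting is asserted numerically at
$\tau_i = 2\times10^{-6}$ min, which still exercises the two-pool code
path. `fit_shutter_speed` fits $K^{trans}, v_e, v_p, \tau_i$ with
$\tau_i \in [0, 10]$ min. With long lifetimes and strong leakage $\tau_i$
becomes weakly identified — a flat residual surface is a property of the
model, and the tests treat the reported value accordingly (convergence and
signal fidelity, not a point estimate).

## DSC-MRI

$\Delta R_2^*(t) = -\ln(S/S_0)/TE$ with $S_0$ from the pre-bolus baseline.
Leakage follows the linear two-parameter model
$\Delta R_2^{*,tissue} \approx k_1 \Delta R_2^{*,ref} -
k_2 \int_0^t \Delta R_2^{*,ref}$, fitted against a non-leaky reference
curve (in phantoms, the background average); the corrected curve adds back
the $k_2$ term and integrates to CBVlc. $k_2$ is reported signed, so both
T1-dominant (post-bolus overshoot, $k_2 > 0$) and T2*-dominant leakage are
representable. CBV is the tissue/AIF integral ratio. CBF comes from
truncated-SVD deconvolution of the Volterra system $C_t = CBF (AIF
\circledast R)$; the convolution matrix uses trapezoid quadrature (half
weights at the interval ends), whose $O(\Delta t^2)$ discretisation error
keeps MTT $= $ CBV/CBF accurate to under 1% at a 1.5 s sampling interval
where a rectangle-rule matrix is biased by $\Delta t/2 \approx 15\%$. The
truncation threshold defaults to $\lambda = 0.2$ of the largest singular
value (standard sSVD practice); the deconvolution tests use
$\lambda = 10^{-4}$ on noiseless data. TTP is the tissue-curve peak time
relative to bolus arrival (first sample above baseline + 3 SD), with ties
resolved to the earliest index.

## ASL and DWI

ASL uses the single-compartment QUIPSS II pulsed-ASL expression
$CBF = 6000\,\lambda\,\Delta M e^{TI/T_{1b}} / (2\alpha M_0 TI_1)$
(mL/100 g/min), with consensus 3 T defaults $\lambda = 0.9$ mL/g,
$T_{1b} = 1650$ ms, $\alpha = 0.98$. ADC is fitted log-linearly
(deterministic, exact on noiseless mono-exponential data) and reported in
$10^{-6}$ mm$^2$/s to match conventional magnitudes.

## Static PET and segmentation

SUV = tissue concentration / (injected activity / body weight); TBR
divides lesion statistics by an equal-volume contralateral white-matter
region. The SUV30/SUV40 contours grow the 26-connected component of voxels
at or above 30%/40% of SUVmax that contains the SUVmax voxel, with SUVmax
searched inside a seed region (an anatomical mask dilated by a default
5 mm) so a second lesion cannot capture the contour. Ties at exactly the
threshold are included, which makes the mask deterministic and invariant
to positive rescaling; whether the original contour implementation used
face or full 26-connectivity is not public, so the choice is recorded
here. Dice is $2|A \cap B|/(|A|+|B|)$ by exhaustive voxel counting.

## Downstream statistics

Cohort comparisons are two-sided Wilcoxon rank-sum tests per variable
(exact tails for small untied samples), reported with per-group
mean ± SD. The grade-predictive vector is an L1-penalised logistic
regression over a 100-point penalty grid spanning four decades, with
seeded, class-stratified k-fold cross-validation and minimum-deviance
penalty selection ("1se" selectable); the CV record and coefficient path
are retained, weights live on the standardised scale, and the stored
standardisation lets a vector trained on one cohort score unseen lesions
unchanged. ROC/AUC use the empirical curve and trapezoid rule (equal to
the Mann–Whitney concordance), with accuracy at the Youden threshold.
Published vectors can be loaded verbatim from JSON since the original
weights appear only in figure annotations.

Survival is dichotomised at a marker cutoff (e.g. SUVmax ≥ 2.0);
Kaplan–Meier curves and medians come from the product-limit estimator, and
the groups are compared both by a two-tailed Mann–Whitney test on observed
times — the comparison reported alongside the cutoff in the source
analyses, which is unusual under censoring — and by the conventional
log-rank test, always side by side rather than silently substituted.
Multiple lesions per patient are treated as independent rows by default,
matching the lesion-level source analysis.

The metabolomics screen runs Welch's unequal-variance t-test per
metabolite and group pair on log abundances (assumed already normalised to
tissue mass), Benjamini–Hochberg q-values within each pair (a Storey-type
estimator was considered; BH is monotone and assumption-light, and the
choice is recorded in the output), geometric-mean fold-changes, and the
shading categories: significant at p ≤ 0.05, trend at 0.05 < p < 0.10,
direction from the fold-change. PCA reports component scores and percent
variance of the leading components.

## The synthetic-data module

Every simulator is a deterministic function of (parameters, seed); seeds
are applied per operation and the caller's RNG state is restored. PET
frame noise is zero-mean Gaussian with SD proportional to
value/\(\sqrt{\text{frame duration}}\) (the stated level is the relative SD
at the mean frame duration), emulating count statistics; MRI magnitude
noise is Rician by default with a Gaussian option for analytic checks. The
central design property is that the noiseless output of each simulator is
exactly inverted by its quantifier — parameter recovery is the test of the
whole chain, not a coincidence of tuning.

What the generator does *not* emulate: anatomy beyond spheres-in-boxes,
scanner and reconstruction physics (point-spread, attenuation, motion),
registration error, arterial dispersion/delay differences between tissue
and input, or partial-volume effects. Passing recovery tests therefore
demonstrates correctness of the numerical inversions under the stated
models, not robustness to the physics the models omit.

The demo study (`run_phantom_study`) simulates two cohorts of lesions —
treatment-naive and treated — whose generating parameters differ in
delivery/trapping ($K_1, k_3$), permeability ($K^{trans}$ roughly halved
in the treated cohort, the pattern reported for irradiated metastases) and
diffusion; per-lesion heterogeneity is lognormal (SD 0.10–0.20 in log
space). Background white-matter kinetics were set so the
tumour-to-background ratio lands in the 3–4 range reported for this
tracer class. Default sizes (8 lesions per cohort, 100 noisy replicates in
the recovery studies, 1000 subjects per survival arm, 10 000 null
replicates for test calibration, 200–4000 metabolites) were chosen so the
whole suite runs in minutes on one core while keeping Monte-Carlo error
well inside the asserted tolerances. Survival times are exponential with a
proportional-hazards link to SUVmax and independent uniform censoring; the
metabolite matrix is lognormal with a designated acyl-carnitine-like block
elevated in the two higher-grade groups.

## Known limitations

ROI-level quantification only (no voxelwise parametric maps); no $k_4 > 0$
compartment models; no B1 or bolus-arrival-time correction beyond a
configurable shift; no contrast-agent preload modelling or absolute CBF
calibration; no DICOM ingestion. The table of printed units in the source
literature contains two inconsistencies ($K_1$ under 1/min, CBV under a
flow unit); outputs here are labelled with dimensionally consistent units
(mL/g/min for $K_1$ and $K_i$, relative volume for CBV).
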