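# petmrquant

Quantification pipeline for simultaneous dynamic PET and multiparametric
MRI studies of intracranial tumours — the setting where a short-chain
fatty-acid PET tracer is irreversibly trapped in tissue, lesions are
characterised by static uptake (SUV, TBR), tracer kinetics (Patlak,
two-tissue compartment model), and perfusion/permeability/diffusion MRI
(DCE, DSC, ASL, DWI), and those per-lesion parameters feed cohort
statistics, a LASSO "grade-predictive vector", survival dichotomisation
and a tissue metabolomics screen.

Patient images from such studies are generally not shareable, so the
package is built around a synthetic-data module that generates every input
the pipeline consumes from known ground truth. Each quantifier is
validated by parameter recovery against its own forward model and against
independent oracles (ODE integration, matrix exponentials, brute-force
voxel scans, pair-counting statistics).

## What is implemented

| Stage | Functions |
| --- | --- |
| Data model & I/O | `dynamic_image`, `frame_schedule`, `roi_mask`, NIfTI + JSON sidecar readers/writers, `extract_tac`, `decay_correct` |
| Input function | `make_population_aif` (tri-exponential bolus), `scale_population_input` (AUC-matched to a sagittal-sinus blood curve) |
| Static PET | `compute_suv`, `compute_tbr`, `threshold_segment` (SUV30/SUV40 contours, 26-connected), `mask_overlap` (Dice, volumes) |
| PET kinetics | `patlak_standard`, `patlak_modified` (efflux term), `fit_2tcm` (irreversible 2TCM, k4 = 0); `Ki = K1 k3/(k2+k3)` |
| DCE-MRI | `signal_to_concentration` (SPGR), `fit_extended_tofts`, `forward_two_site_exchange` + `fit_shutter_speed` (water-exchange τi) |
| DSC-MRI | `delta_r2star`, `leakage_correct` (CBVlc), `compute_cbv`, `deconvolve_cbf` (truncated SVD; CBF, MTT, TTP) |
| ASL / DWI | `asl_cbf` (QUIPSS II pASL), `fit_adc` (log-linear) |
| Biomarker vector | `assemble_features`, `fit_lasso_classifier`, `compute_gpv`, `evaluate_classifier` (ROC/AUC), JSON model serialisation |
| Outcome statistics | `compare_groups` (rank-sum), `km_estimate`, `dichotomise_survival` (Mann–Whitney + log-rank), `metabolite_screen` (Welch t, BH q), `pca_overview` |
| Synthetic data | `simulate_2tcm_tac`, `simulate_dce_signal`, `simulate_dsc_signal`, `simulate_asl_pair`, `simulate_dwi_series`, `make_lesion_phantom`, `simulate_feature_table`, `simulate_survival`, `simulate_metabolomics` |
| Driver | `run_phantom_study` — the full simulate → quantify → statistics loop |

## Worked example

Simulate a lesion time-activity curve on the 28-frame dynamic scheme
(10×15 s, 3×60 s, 5×120 s, 9×300 s, 1×360 s — ending at 66.5 min), add
frame-weighted 5% noise, and fit the kinetic models:

```r
library(petmrquant)
sch <- frame_schedule_from_counts(c(10, 3, 5, 9, 1), c(15, 60, 120, 300, 360))
input <- make_population_aif(schedule = sch)
tac <- simulate_2tcm_tac(input, list(k1 = 0.1, k2 = 0.15, k3 = 0.02, vb = 0.03),
                         sch, noise = noise_spec("gaussian", 0.05, seed = 7))
fit_2tcm(tac, input)
#> <tcm_result> K1 = 0.1316 mL/g/min, k2 = 0.2098, k3 = 0.02128 /min, vb = 0.0001993
#>   Ki(macro) = 0.01212 mL/g/min, residual norm 1.063, converged: TRUE
patlak_standard(tac, input, t_star = 20)
#> <patlak_result> standard: Ki = 0.011473 mL/g/min, v0 = 0.5846 (t* = 20 min, R^2 = 0.9821)
```

The generating macro constant is K1·k3/(k2+k3) = 0.01176 mL/g/min; with 5%
frame noise the compartmental fit returns 0.01212 (+3%) and the Patlak
slope 0.01147 — the graphical estimate sits slightly low because the
measured curve carries the (1 − vb) tissue fraction. On noiseless curves
both recover the truth to well under 1%.

The end-to-end phantom study simulates two cohorts (treatment-naive vs
irradiated), quantifies every modality per lesion, and runs the downstream
statistics:

```r
ps <- run_phantom_study(seed = 1)
ps
#> <phantom_study> 16 lesions (SRS: 8 / TN: 8), seed 1
#>   GpV: 3 selected features, AUC 1.000, accuracy 1.000
#>   survival at SUVmax >= 2: median 0.276 v 10.7 months (MW p = 0.129)
#>   metabolomics: 42 pair-tests at q <= 0.05; PC1 12.4% variance
head(subset(ps$group_comparison, select = -test), 4)
#>   variable mean_SRS  sd_SRS mean_TN   sd_TN  p_value
#> 1   SUVmax  0.80340 0.17121  1.5945 0.32898 0.000155
#> 2  SUVmean  0.60723 0.12505  1.2022 0.26342 0.000155
#> 3   TBRmax  1.85938 0.44638  3.7696 0.79848 0.000155
#> 4  TBRmean  1.59951 0.36649  3.2154 0.71493 0.000155
ps$gpv$model
#> <gpv_model> GpVd: 3 features at lambda = 0.09637 (min rule)
#>   Ki_std     +1.4050
#>   Kep        +0.8403
#>   k3         +0.0380
#>   intercept +0.0988
```

The rank-sum table reads like a two-cohort parameter summary: the treated
cohort shows roughly half the uptake and Ktrans of the naive cohort (as
built into the generator), and the LASSO vector picks kinetic uptake and
permeability features to separate the cohorts. The survival split at
SUVmax ≥ 2.0 puts only a few lesions in the high group — at this cohort
size the split is illustrative, not powered.

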