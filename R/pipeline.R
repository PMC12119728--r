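# End-to-end phantom study: simulate a two-cohort lesion population with
# known ground truth, quantify every modality, assemble the per-lesion
# feature table, and run the downstream statistics (cohort comparison,
# grade-predictive vector, survival dichotomisation, metabolomics screen).

# Cohort-level generating parameters. The treated cohort has lower tracer
# delivery/trapping and roughly halved Ktrans (the treatment-effect pattern
# the downstream statistics are meant to detect); per-lesion heterogeneity
# is lognormal around these means.
default_cohort_truth <- function() {
  list(
    TN = list(tcm = list(k1 = 0.10, k2 = 0.15, k3 = 0.020, vb = 0.03),
              dce = list(ktrans = 0.25, ve = 0.30, vp = 0.03, taui = 1.0),
              dsc = list(cbv_rel = 0.040, k1_leak = 1.0, k2_leak = 0.010),
              asl_cbf = 45, adc_e6 = 1000, suv_het = 1.35),
    SRS = list(tcm = list(k1 = 0.07, k2 = 0.15, k3 = 0.012, vb = 0.03),
               dce = list(ktrans = 0.125, ve = 0.30, vp = 0.03, taui = 1.5),
               dsc = list(cbv_rel = 0.035, k1_leak = 1.0, k2_leak = 0.010),
               asl_cbf = 40, adc_e6 = 1200, suv_het = 1.35))
}

jitter_lognormal <- function(x, sdlog) x * exp(rnorm(length(x), 0, sdlog))

# Quantify one lesion end to end from its generating truth. Returns a named
# row of the feature-table inventory.
quantify_one_lesion <- function(truth, input, schedule, meta, dce_t, dce_cp,
                                acq_dce, dsc_t, pet_noise, mri_noise,
                                lesion_seed) {
  # --- dynamic PET -> static SUV/TBR + Patlak + 2TCM
  tac <- simulate_2tcm_tac(input, truth$tcm, schedule,
                           noise = noise_spec("gaussian", pet_noise,
                                              seed = lesion_seed))
  bg_truth <- list(k1 = 0.06, k2 = 0.17, k3 = 0.006, vb = 0.02)
  bg_tac <- simulate_2tcm_tac(input, bg_truth, schedule,
                              noise = noise_spec("gaussian", pet_noise,
                                                 seed = lesion_seed + 1L))
  last_les <- tail(tac$value, 1L); last_bg <- tail(bg_tac$value, 1L)
  # voxelwise spread of late-frame uptake within the region gives the
  # max-vs-mean statistics
  n_vox <- 257L
  vox_les <- pmax(rnorm(n_vox, last_les, (truth$suv_het - 1) / 3 * last_les),
                  0.05 * last_les)
  vox_bg <- pmax(rnorm(n_vox, last_bg, 0.05 * last_bg), 0.5 * last_bg)
  suv_les <- compute_suv(vox_les, meta); suv_bg <- compute_suv(vox_bg, meta)
  pk <- patlak_standard(tac, input, t_star = 20)
  pkm <- patlak_modified(tac, input, t_star = 20)
  tcm <- fit_2tcm(tac, input)
  # --- DCE (shutter-speed signal, shutter-speed + Tofts quantification)
  dce_sig <- simulate_dce_signal(truth$dce, dce_t, dce_cp, acq_dce,
                                 noise = noise_spec("rician", mri_noise,
                                                    seed = lesion_seed + 2L))
  ss <- fit_shutter_speed(as.numeric(dce_sig), dce_t, dce_cp, acq_dce,
                          starts = cbind(tofts_start_lattice()[1:2, ,
                                                               drop = FALSE],
                                         taui = c(1, 0.3)))
  # --- DSC
  dsc <- simulate_dsc_signal(truth$dsc, dsc_t,
                             noise = noise_spec("gaussian", mri_noise,
                                                seed = lesion_seed + 3L))
  dscq <- quantify_dsc(dsc$signal, dsc_t, te_ms = 30, aif_dr2 = dsc$aif_dr2,
                       ref_dr2 = dsc$ref_dr2)
  # --- ASL + DWI
  asl <- simulate_asl_pair(truth$asl_cbf,
                           noise = noise_spec("gaussian", mri_noise,
                                              seed = lesion_seed + 4L))
  aslq <- asl_cbf(asl$control, asl$label, asl$m0, asl_acquisition())
  dwi <- simulate_dwi_series(truth$adc_e6,
                             noise = noise_spec("rician", mri_noise / 4,
                                                seed = lesion_seed + 5L))
  adc <- fit_adc(dwi, c(0, 500, 1000))
  data.frame(
    SUVmax = max(suv_les), SUVmean = mean(suv_les),
    TBRmax = max(suv_les) / max(suv_bg),
    TBRmean = mean(suv_les) / mean(suv_bg),
    Ki_std = pk$ki, Ki_mod = pkm$ki,
    K1 = tcm$k1, k2 = tcm$k2, k3 = tcm$k3, vb = tcm$vb,
    Ktrans = ss$ktrans, Kep = ss$kep, Ve = ss$ve, Vp = ss$vp,
    Taui = ss$taui,
    CBF = dscq$cbf, CBV = dscq$cbv, CBVlc = dscq$cbv_lc,
    MTT = dscq$mtt_s, TTP = dscq$ttp_s,
    ASL_CBF = aslq, ADC = adc$adc)
}

#' Run the full phantom study
#'
#' Simulates a two-cohort lesion population (treatment-naive vs treated)
#' from known ground truth, quantifies every modality per lesion, and runs
#' the downstream statistics: per-variable cohort comparison, LASSO
#' grade-predictive vector with ROC evaluation, SUVmax-dichotomised
#' survival, and the metabolomics screen with PCA.
#'
#' @param seed master seed; every stage derives its stream from it.
#' @param n_per_cohort lesions per cohort (default 8).
#' @param pet_noise,mri_noise relative noise levels (default 0.05, 0.02).
#' @param suv_cutoff survival dichotomisation threshold on SUVmax
#'   (default 2.0).
#' @param cohort_truth generating parameters; see
#'   \code{default_cohort_truth()}.
#' @return list of class \code{phantom_study}: feature_table (with cohort),
#'   group_comparison, gpv (model, scores, evaluation), survival
#'   (records, split), metabolomics (screen, pca), truth.
#' @export
run_phantom_study <- function(seed = 1, n_per_cohort = 8,
                              pet_noise = 0.05, mri_noise = 0.02,
                              suv_cutoff = 2.0,
                              cohort_truth = default_cohort_truth()) {
  if (n_per_cohort < 3L)
    stop("n_per_cohort must be >= 3 (cross-validated penalty selection ",
         "needs at least 3 folds)")
  schedule <- frame_schedule_from_counts(c(10, 3, 5, 9, 1),
                                         c(15, 60, 120, 300, 360))
  input <- make_population_aif(schedule = schedule)
  meta <- subject_meta(injected_activity = 346.4, body_weight = 75)
  acq_dce <- dce_acquisition()
  dce_t <- seq(0, 5, by = acq_dce$dt_s / 60)
  dce_cp <- 5 * gamma_variate(dce_t * 60, t0 = 55, alpha = 3, beta = 6) +
    2.5 * pmin(pmax(dce_t - 55 / 60, 0) / 0.5, 1) * exp(-0.08 * dce_t)
  dsc_t <- seq(0, 90, by = 1.5)

  rows <- list(); cohorts <- character(0)
  truths <- list()
  i <- 0L
  for (coh in names(cohort_truth)) {
    base <- cohort_truth[[coh]]
    for (k in seq_len(n_per_cohort)) {
      i <- i + 1L
      lesion_seed <- seed * 1000L + i * 10L
      truth <- with_seed(lesion_seed + 7L, {
        tr <- base
        tr$tcm[c("k1", "k3")] <- lapply(tr$tcm[c("k1", "k3")],
                                        jitter_lognormal, sdlog = 0.20)
        tr$dce$ktrans <- jitter_lognormal(tr$dce$ktrans, 0.20)
        tr$dce$taui <- jitter_lognormal(tr$dce$taui, 0.15)
        tr$dsc$cbv_rel <- jitter_lognormal(tr$dsc$cbv_rel, 0.15)
        tr$asl_cbf <- jitter_lognormal(tr$asl_cbf, 0.10)
        tr$adc_e6 <- jitter_lognormal(tr$adc_e6, 0.10)
        tr
      })
      truths[[i]] <- truth
      rows[[i]] <- with_seed(lesion_seed + 8L,
        quantify_one_lesion(truth, input, schedule, meta, dce_t, dce_cp,
                            acq_dce, dsc_t, pet_noise, mri_noise,
                            lesion_seed))
      cohorts[i] <- coh
    }
  }
  ft <- do.call(rbind, rows)
  ft$cohort <- cohorts

  comparison <- compare_groups(ft, ft$cohort,
                               variables = setdiff(names(ft), "cohort"))

  tab <- assemble_features(ft, variant = "GpVd")
  labels <- as.integer(cohorts == names(cohort_truth)[1L])
  gpv <- suppressWarnings(
    fit_lasso_classifier(tab, labels, n_folds = min(4L, n_per_cohort),
                         seed = seed))
  scores <- compute_gpv(tab, gpv)
  gpv_eval <- evaluate_classifier(scores, labels)

  # survival linked to SUVmax through a proportional hazard
  surv <- simulate_survival(n = nrow(ft), rate = log(2) / 15,
                            linked_feature = ft$SUVmax, beta = 1.0,
                            censoring_rate = 0.15, seed = seed + 11L)
  split <- tryCatch(dichotomise_survival(surv, ft$SUVmax, suv_cutoff),
                    error = function(e) NULL)

  met <- simulate_metabolomics(seed = seed + 13L)
  screen <- metabolite_screen(met$matrix, met$groups)
  pca <- pca_overview(met$matrix)

  structure(list(feature_table = ft, group_comparison = comparison,
                 gpv = list(model = gpv, scores = scores,
                            evaluation = gpv_eval),
                 survival = list(records = surv, split = split,
                                 cutoff = suv_cutoff),
                 metabolomics = list(screen = screen, pca = pca,
                                     truth = met[c("block",
                                                   "fold_changes")]),
                 truth = truths, seed = seed),
            class = "phantom_study")
}

#' @export
print.phantom_study <- function(x, ...) {
  cat(sprintf("<phantom_study> %d lesions (%s), seed %d\n",
              nrow(x$feature_table),
              paste(names(table(x$feature_table$cohort)),
                    table(x$feature_table$cohort), collapse = " / ",
                    sep = ": "), x$seed))
  cat(sprintf("  GpV: %d selected features, AUC %.3f, accuracy %.3f\n",
              length(x$gpv$model$selected_features), x$gpv$evaluation$auc,
              x$gpv$evaluation$accuracy))
  if (!is.null(x$survival$split))
    cat(sprintf("  survival at SUVmax >= %g: median %.3g v %.3g months (MW p = %.3g)\n",
                x$survival$cutoff, x$survival$split$median_high,
                x$survival$split$median_low,
                x$survival$split$p_mann_whitney))
  nsig <- sum(x$metabolomics$screen$q <= 0.05, na.rm = TRUE)
  cat(sprintf("  metabolomics: %d pair-tests at q <= 0.05; PC1 %.1f%% variance\n",
              nsig, x$metabolomics$pca$percent_variance[1L]))
  invisible(x)
}
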