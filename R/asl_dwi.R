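# ASL CBF quantification (single-compartment pulsed-ASL, QUIPSS II timing)
# and mono-exponential ADC estimation from multi-b diffusion data.

#' Pulsed-ASL acquisition parameters
#'
#' Defaults follow consensus recommendations for 3 T pASL: blood-brain
#' partition coefficient 0.9 mL/g, blood T1 1650 ms, labelling efficiency
#' 0.98.
#'
#' @param ti_ms inversion time (ms); ti1_ms bolus duration (ms).
#' @param ti1_ms bolus duration (ms).
#' @param t1_blood_ms longitudinal relaxation time of blood (ms).
#' @param labeling_efficiency fraction in (0, 1].
#' @param lambda_partition mL/g.
#' @export
asl_acquisition <- function(ti_ms = 1800, ti1_ms = 800, t1_blood_ms = 1650,
                            labeling_efficiency = 0.98,
                            lambda_partition = 0.9) {
  for (nm in c("ti_ms", "ti1_ms", "t1_blood_ms", "lambda_partition"))
    stop_if_not_scalar_pos(get(nm), nm)
  if (labeling_efficiency <= 0 || labeling_efficiency > 1)
    stop("labeling efficiency must be in (0, 1]")
  structure(list(ti_ms = ti_ms, ti1_ms = ti1_ms, t1_blood_ms = t1_blood_ms,
                 labeling_efficiency = labeling_efficiency,
                 lambda_partition = lambda_partition),
            class = "asl_acquisition")
}

#' CBF from a pASL control/label pair
#'
#' Single-compartment QUIPSS II model:
#' \eqn{CBF = 6000 \lambda \Delta M e^{TI/T_{1b}} / (2 \alpha M_0 TI_1)}
#' with \eqn{\Delta M} = control - label and TI1 in seconds, giving
#' mL/100 g/min. Linear in \eqn{\Delta M}; accepts scalars or voxel arrays.
#'
#' @param control,label signal (scalar or array).
#' @param m0 equilibrium magnetisation signal (> 0).
#' @param acq an \code{asl_acquisition}.
#' @export
asl_cbf <- function(control, label, m0, acq) {
  stopifnot(inherits(acq, "asl_acquisition"))
  if (any(m0 <= 0)) stop("M0 must be positive")
  dm <- control - label
  6000 * acq$lambda_partition * dm * exp(acq$ti_ms / acq$t1_blood_ms) /
    (2 * acq$labeling_efficiency * m0 * (acq$ti1_ms / 1e3))
}

#' Simulate a pASL control/label pair from a known CBF
#'
#' Inverts the \code{asl_cbf} expression so that noiseless quantification
#' recovers the generating CBF exactly.
#'
#' @param cbf mL/100 g/min (scalar or array).
#' @param m0 equilibrium signal.
#' @param acq an \code{asl_acquisition}.
#' @param noise a \code{noise_spec} or NULL (applied to both members).
#' @return list(control, label, m0).
#' @export
simulate_asl_pair <- function(cbf, m0 = 1000, acq = asl_acquisition(),
                              noise = NULL) {
  dm <- cbf * 2 * acq$labeling_efficiency * m0 * (acq$ti1_ms / 1e3) /
    (6000 * acq$lambda_partition * exp(acq$ti_ms / acq$t1_blood_ms))
  control <- rep(m0, length(dm)) + 0 * dm
  label <- control - dm
  if (!is.null(noise) && noise$level > 0) {
    control <- apply_mri_noise(control, noise, reference = m0)
    label <- apply_mri_noise(
      label, noise_spec(noise$model, noise$level,
                        if (is.null(noise$seed)) NULL else noise$seed + 1L),
      reference = m0)
  }
  list(control = control, label = label, m0 = m0)
}

#' Simulate a mono-exponential DWI decay series
#'
#' \eqn{S(b) = S_0 e^{-b \cdot ADC}} with ADC given in 1e-6 mm^2/s and b in
#' s/mm^2.
#'
#' @param adc_e6 ADC in 1e-6 mm^2/s (e.g. 800).
#' @param b_values s/mm^2, distinct.
#' @param s0 signal at b = 0.
#' @param noise a \code{noise_spec} or NULL.
#' @export
simulate_dwi_series <- function(adc_e6, b_values = c(0, 500, 1000),
                                s0 = 1000, noise = NULL) {
  if (anyDuplicated(b_values)) stop("b-values must be distinct")
  s <- s0 * exp(-b_values * adc_e6 * 1e-6)
  apply_mri_noise(s, noise, reference = s0)
}

#' Apparent diffusion coefficient by log-linear least squares
#'
#' Fits \eqn{\ln S = \ln S_0 - b \cdot ADC} over all usable (positive)
#' signal samples; exact on noiseless mono-exponential input.
#'
#' @param signals signal per b-value.
#' @param b_values s/mm^2, >= 2 distinct usable values.
#' @return an \code{adc_result}: adc (1e-6 mm^2/s), s0, r_squared,
#'   n_excluded.
#' @export
fit_adc <- function(signals, b_values) {
  if (length(signals) != length(b_values))
    stop("signals and b_values must match in length")
  ok <- is.finite(signals) & signals > 0
  if (sum(ok) < 2L || length(unique(b_values[ok])) < 2L)
    stop("need >= 2 distinct b-values with positive signal")
  fit <- lm(ls ~ b, data = data.frame(ls = log(signals[ok]),
                                      b = b_values[ok]))
  structure(list(adc = -unname(coef(fit)[2L]) * 1e6,
                 s0 = exp(unname(coef(fit)[1L])),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n_excluded = sum(!ok)),
            class = "adc_result")
}

#' @export
print.adc_result <- function(x, ...) {
  cat(sprintf("<adc_result> ADC = %.4g x1e-6 mm^2/s (S0 = %.4g, R^2 = %.4f, %d excluded)\n",
              x$adc, x$s0, x$r_squared, x$n_excluded))
  invisible(x)
}
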