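# DCE-MRI quantification: spoiled-gradient-echo signal <-> concentration,
# extended-Tofts fitting, and the two-site water-exchange (shutter-speed)
# model yielding the mean intracellular water lifetime tau_i.

#' DCE acquisition parameters
#'
#' @param tr_ms repetition time, ms.
#' @param flip_deg flip angle, degrees, in (0, 90].
#' @param r1 contrast-agent longitudinal relaxivity, 1/(mM s); default 5.0
#'   (gadobutrol at 3 T).
#' @param r10_tissue,r10_blood pre-contrast R1, 1/s.
#' @param hematocrit fraction in (0, 1); converts blood to plasma
#'   concentration. Default 0.42.
#' @param baseline_frames number of pre-bolus frames used to estimate the
#'   equilibrium signal scale.
#' @param dt_s frame spacing, seconds.
#' @export
dce_acquisition <- function(tr_ms = 5, flip_deg = 15, r1 = 5.0,
                            r10_tissue = 1.0, r10_blood = 0.61,
                            hematocrit = 0.42, baseline_frames = 10,
                            dt_s = 5) {
  if (flip_deg <= 0 || flip_deg > 90)
    stop("flip angle must be in (0, 90] degrees")
  if (hematocrit <= 0 || hematocrit >= 1) stop("hematocrit must be in (0,1)")
  for (nm in c("tr_ms", "r1", "r10_tissue", "r10_blood", "dt_s"))
    stop_if_not_scalar_pos(get(nm), nm)
  structure(list(tr_ms = tr_ms, flip_deg = flip_deg, r1 = r1,
                 r10_tissue = r10_tissue, r10_blood = r10_blood,
                 hematocrit = hematocrit,
                 baseline_frames = as.integer(baseline_frames), dt_s = dt_s),
            class = "dce_acquisition")
}

# SPGR steady-state signal for longitudinal rate R1 (1/s).
spgr_signal <- function(r1_per_s, m0, tr_ms, flip_deg) {
  a <- flip_deg * pi / 180
  e1 <- exp(-tr_ms / 1e3 * r1_per_s)
  m0 * sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

# Invert SPGR for R1 given the signal; returns NA outside invertible range.
spgr_invert <- function(signal, m0, tr_ms, flip_deg) {
  a <- flip_deg * pi / 180
  e1 <- (m0 * sin(a) - signal) / (m0 * sin(a) - signal * cos(a))
  out <- rep(NA_real_, length(signal))
  ok <- is.finite(e1) & e1 > 0 & e1 < 1
  out[ok] <- -log(e1[ok]) / (tr_ms / 1e3)
  out
}

# Exact convolution of a piecewise-linear curve cp(t) with exp(-k (t - u)),
# i.e. int_0^t cp(u) exp(-k (t-u)) du, on an increasing grid (minutes; k in
# 1/min). The interval recursion is exact for piecewise-linear cp; on a
# uniform grid it is evaluated as a first-order recursive filter.
exp_conv <- function(t, cp, k) {
  n <- length(t)
  if (k < 1e-12) return(cumtrapz_int(t, cp))
  dts <- diff(t)
  if (max(abs(dts - dts[1L])) < 1e-12 * dts[1L]) {
    dt <- dts[1L]
    e <- exp(-k * dt)
    f1 <- (1 - e) / k
    f2 <- (1 - (1 + k * dt) * e) / (k^2 * dt)
    u <- f1 * cp + f2 * (c(cp[1L], cp[-n]) - cp)
    u[1L] <- 0
    as.numeric(stats::filter(u, e, method = "recursive"))
  } else {
    out <- numeric(n)
    for (i in 2:n) {
      dt <- t[i] - t[i - 1L]
      e <- exp(-k * dt)
      f1 <- (1 - e) / k
      f2 <- (1 - (1 + k * dt) * e) / (k^2 * dt)
      out[i] <- out[i - 1L] * e + cp[i] * f1 + (cp[i - 1L] - cp[i]) * f2
    }
    out
  }
}

#' Extended-Tofts tissue concentration
#'
#' \eqn{C_t(t) = v_p C_p(t) + K^{trans} \int_0^t C_p(u) e^{-k_{ep}(t-u)} du}
#' with \eqn{k_{ep} = K^{trans}/v_e}; evaluated on the acquisition grid with
#' an exponential-kernel recursion that is exact for piecewise-linear
#' \eqn{C_p}.
#'
#' @param t minutes.
#' @param cp plasma concentration, mM.
#' @param ktrans 1/min; ve, vp fractions.
#' @export
tofts_concentration <- function(t, cp, ktrans, ve, vp) {
  if (ve <= 0 || ve > 1 || vp < 0 || vp >= 1) stop("invalid ve/vp")
  kep <- ktrans / ve
  vp * cp + ktrans * exp_conv(t, cp, kep)
}

#' Convert a DCE signal curve to tissue concentration
#'
#' Estimates the equilibrium signal scale from the pre-bolus baseline and
#' the known pre-contrast R1, inverts the SPGR signal equation per sample,
#' and maps \eqn{C(t) = (R_1(t) - R_{10}) / r_1}. Samples outside the
#' invertible signal range are returned as NA and flagged, never a crash.
#'
#' @param signal DCE signal samples.
#' @param acq a \code{dce_acquisition}.
#' @param r10 pre-contrast R1 (1/s); default the acquisition's tissue R10.
#' @return numeric concentration (mM) with attribute \code{invalid} giving
#'   the indices that could not be inverted.
#' @export
signal_to_concentration <- function(signal, acq, r10 = acq$r10_tissue) {
  stopifnot(inherits(acq, "dce_acquisition"))
  nb <- min(acq$baseline_frames, length(signal))
  s_base <- mean(signal[seq_len(nb)])
  a <- acq$flip_deg * pi / 180
  e10 <- exp(-acq$tr_ms / 1e3 * r10)
  m0 <- s_base * (1 - cos(a) * e10) / (sin(a) * (1 - e10))
  r1t <- spgr_invert(signal, m0, acq$tr_ms, acq$flip_deg)
  conc <- (r1t - r10) / acq$r1
  attr(conc, "invalid") <- which(!is.finite(conc))
  conc
}

# Fast-exchange SPGR signal for a tissue concentration curve.
fast_exchange_signal <- function(t, ct, acq, m0 = 1000,
                                 r10 = acq$r10_tissue) {
  spgr_signal(r10 + acq$r1 * ct, m0, acq$tr_ms, acq$flip_deg)
}

#' Two-site water-exchange (shutter-speed) forward signal
#'
#' Longitudinal magnetisation of the intracellular (population
#' \code{pi_fraction}, relaxation \code{r1i}) and extracellular water pools
#' evolves under the 2x2 exchange-relaxation matrix with rates
#' \eqn{1/\tau_i} (intra-to-extra) and \eqn{1/\tau_o},
#' \eqn{\tau_o = \tau_i p_o / p_i} (detailed balance). The contrast agent is
#' confined to the extracellular space, whose water pool sees
#' \eqn{R_{1o}(t) = R_{10o} + r_1 C_t(t)/p_o}; the observed signal is the
#' exact two-pool SPGR steady state (both eigencomponents through the
#' readout). As \eqn{\tau_i \to 0} this reduces to the fast-exchange
#' (extended-Tofts) signal.
#'
#' @param params list: ktrans (1/min), ve, vp, taui (min), and optionally
#'   pi_fraction (default 0.8) and r1i (default the tissue R10).
#' @param t minutes; cp plasma concentration (mM).
#' @param acq a \code{dce_acquisition}.
#' @param m0 equilibrium signal scale.
#' @export
forward_two_site_exchange <- function(params, t, cp, acq, m0 = 1000) {
  p <- params
  pi_f <- if (is.null(p$pi_fraction)) 0.8 else p$pi_fraction
  if (pi_f <= 0 || pi_f >= 1) stop("pi_fraction must be in (0, 1)")
  r1i <- if (is.null(p$r1i)) acq$r10_tissue else p$r1i
  po <- 1 - pi_f
  # pre-contrast extracellular R1 chosen so the population-weighted baseline
  # equals the tissue R10 (the fast-exchange pre-contrast rate)
  r10o <- (acq$r10_tissue - pi_f * r1i) / po
  ct <- tofts_concentration(t, cp, p$ktrans, p$ve, p$vp)
  if (p$taui < 1e-6) {
    r1fx <- pi_f * r1i + po * (r10o + acq$r1 * ct / po)
    return(spgr_signal(r1fx, m0, acq$tr_ms, acq$flip_deg))
  }
  kie <- 1 / (p$taui * 60)          # 1/s
  kei <- kie * pi_f / po            # detailed balance
  a_ <- acq$flip_deg * pi / 180
  tr <- acq$tr_ms / 1e3
  cosa <- cos(a_); sina <- sin(a_)
  # Exchange-relaxation matrix L = [[R1i+kie, -kei], [-kie, R1o+kei]];
  # everything below is the closed-form 2x2 eigendecomposition of
  # E = exp(-L TR) and the two-pool SPGR steady state, vectorised over time.
  l11 <- r1i + kie; l12 <- -kei; l21 <- -kie
  r1o <- r10o + acq$r1 * ct / po
  l22 <- r1o + kei
  b1 <- r1i * pi_f * m0; b2 <- r1o * po * m0
  detL <- l11 * l22 - l12 * l21
  minf1 <- (l22 * b1 - l12 * b2) / detL
  minf2 <- (-l21 * b1 + l11 * b2) / detL
  disc <- sqrt(pmax((l11 - l22)^2 + 4 * l12 * l21, 0))
  lam1 <- (l11 + l22 + disc) / 2
  lam2 <- (l11 + l22 - disc) / 2
  e1 <- exp(-lam1 * tr); e2 <- exp(-lam2 * tr)
  dl <- lam1 - lam2 # >= 2 sqrt(kie kei) > 0 whenever taui > 0
  E11 <- (e1 * (l11 - lam2) - e2 * (l11 - lam1)) / dl
  E12 <- (e1 - e2) * l12 / dl
  E21 <- (e1 - e2) * l21 / dl
  E22 <- (e1 * (l22 - lam2) - e2 * (l22 - lam1)) / dl
  # steady state: (I - cosa E) mss = (I - E) minf
  r1_ <- (1 - E11) * minf1 - E12 * minf2
  r2_ <- -E21 * minf1 + (1 - E22) * minf2
  m11 <- 1 - cosa * E11; m12 <- -cosa * E12
  m21 <- -cosa * E21; m22 <- 1 - cosa * E22
  detM <- m11 * m22 - m12 * m21
  mss1 <- (m22 * r1_ - m12 * r2_) / detM
  mss2 <- (-m21 * r1_ + m11 * r2_) / detM
  sina * (mss1 + mss2)
}

#' Simulate a DCE signal curve
#'
#' Extended-Tofts kinetics through the SPGR readout; with \code{taui > 0}
#' the two-site water-exchange signal model is used.
#'
#' @param truth list with ktrans, ve, vp, taui (0 for fast exchange), and
#'   optionally pi_fraction, r1i.
#' @param t minutes; cp plasma concentration (mM).
#' @param acq a \code{dce_acquisition}.
#' @param m0 equilibrium signal scale.
#' @param noise a \code{noise_spec} or NULL.
#' @return signal vector with attributes \code{truth} and \code{ct} (the
#'   noiseless tissue concentration).
#' @export
simulate_dce_signal <- function(truth, t, cp, acq, m0 = 1000, noise = NULL) {
  truth <- as.list(truth)
  if (is.null(truth$taui)) truth$taui <- 0
  sig <- forward_two_site_exchange(truth, t, cp, acq, m0 = m0)
  sig <- apply_mri_noise(sig, noise, reference = mean(sig))
  attr(sig, "truth") <- truth
  attr(sig, "ct") <- tofts_concentration(t, cp, truth$ktrans, truth$ve,
                                         truth$vp)
  sig
}

new_dce_result <- function(p, model, residual_norm, converged) {
  structure(list(ktrans = p[["ktrans"]], ve = p[["ve"]], vp = p[["vp"]],
                 kep = p[["ktrans"]] / p[["ve"]],
                 taui = if ("taui" %in% names(p)) p[["taui"]] else NA_real_,
                 residual_norm = residual_norm, converged = converged,
                 model = model),
            class = "dce_result")
}

#' @export
print.dce_result <- function(x, ...) {
  cat(sprintf(
    "<dce_result> %s: Ktrans = %.4g /min, kep = %.4g /min, ve = %.4g, vp = %.4g%s\n  residual norm %.4g, converged: %s\n",
    x$model, x$ktrans, x$kep, x$ve, x$vp,
    if (!is.na(x$taui)) sprintf(", taui = %.4g min", x$taui) else "",
    x$residual_norm, x$converged))
  invisible(x)
}

#' @export
coef.dce_result <- function(object, ...) {
  c(ktrans = object$ktrans, kep = object$kep, ve = object$ve,
    vp = object$vp, taui = object$taui)
}

tofts_start_lattice <- function() {
  rbind(c(0.25, 0.30, 0.03),
        c(0.05, 0.15, 0.01),
        c(0.60, 0.50, 0.05),
        c(0.02, 0.40, 0.10),
        c(1.00, 0.20, 0.02))
}

#' Fit the extended-Tofts model to a tissue concentration curve
#'
#' Bounded nonlinear least squares with a documented multi-start lattice;
#' \code{kep} is reported as \code{ktrans / ve}.
#'
#' @param ct tissue concentration (mM); t minutes; cp plasma concentration.
#' @param t,cp model grid and plasma input.
#' @param starts start matrix (columns ktrans, ve, vp).
#' @param lower,upper bounds: Ktrans in [0,5] 1/min, ve in (0,1],
#'   vp in [0,0.5].
#' @return a \code{dce_result} with \code{model = "tofts-extended"}.
#' @export
fit_extended_tofts <- function(ct, t, cp, starts = tofts_start_lattice(),
                               lower = c(0, 1e-4, 0),
                               upper = c(5, 1, 0.5)) {
  if (any(!is.finite(ct)) || any(!is.finite(cp)))
    stop("non-finite inputs")
  resid_fun <- function(p)
    tofts_concentration(t, cp, p[1L], p[2L], p[3L]) - ct
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best)) stop("all extended-Tofts starts failed")
  p <- unname(best$fit$par)
  new_dce_result(c(ktrans = p[1L], ve = p[2L], vp = p[3L]),
                 "tofts-extended", best$rn, best$fit$info %in% 1:4)
}

#' Fit the shutter-speed (two-site water-exchange) model
#'
#' Fits Ktrans, ve, vp and the mean intracellular water lifetime tau_i by
#' bounded nonlinear least squares against
#' \code{forward_two_site_exchange}; the water population fraction and
#' intracellular R1 are fixed inputs, not fitted.
#'
#' @param signal measured DCE signal curve.
#' @param t,cp model grid (min) and plasma concentration (mM).
#' @param acq a \code{dce_acquisition}.
#' @param pi_fraction intracellular water population fraction (default 0.8).
#' @param r1i intracellular R1 (default tissue R10).
#' @param m0 equilibrium signal scale; estimated from the baseline when NULL.
#' @param starts start matrix (columns ktrans, ve, vp, taui).
#' @param lower,upper bounds; taui in [0, 10] min.
#' @return a \code{dce_result} with \code{model = "shutter-speed"}.
#' @export
fit_shutter_speed <- function(signal, t, cp, acq, pi_fraction = 0.8,
                              r1i = acq$r10_tissue, m0 = NULL,
                              starts = cbind(tofts_start_lattice(),
                                             taui = c(0.5, 1, 2, 0.1, 5)),
                              lower = c(0, 1e-4, 0, 0),
                              upper = c(5, 1, 0.5, 10)) {
  if (any(!is.finite(signal))) stop("non-finite signal")
  if (is.null(m0)) {
    nb <- min(acq$baseline_frames, length(signal))
    s_base <- mean(signal[seq_len(nb)])
    a <- acq$flip_deg * pi / 180
    e10 <- exp(-acq$tr_ms / 1e3 * acq$r10_tissue)
    m0 <- s_base * (1 - cos(a) * e10) / (sin(a) * (1 - e10))
  }
  resid_fun <- function(p)
    forward_two_site_exchange(list(ktrans = p[1L], ve = p[2L], vp = p[3L],
                                   taui = p[4L], pi_fraction = pi_fraction,
                                   r1i = r1i), t, cp, acq, m0 = m0) - signal
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best)) stop("all shutter-speed starts failed")
  p <- unname(best$fit$par)
  new_dce_result(c(ktrans = p[1L], ve = p[2L], vp = p[3L], taui = p[4L]),
                 "shutter-speed", best$rn, best$fit$info %in% 1:4)
}
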