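# Dynamic PET tracer-kinetic modelling for an irreversibly trapped tracer:
# standard Patlak graphical analysis, a generalized (efflux-term) Patlak
# variant, and full nonlinear fitting of the irreversible two-tissue
# compartment model.

# Patlak transform: x(t) = int_0^t Cp / Cp(t), y(t) = Ct / Cp(t) at frame
# mid-times at or after t_star. The input function's fine grid supplies the
# integral; Ct comes from the frame-averaged TAC.
patlak_points <- function(tac, input, t_star) {
  cum_cp <- cumtrapz_int(input$time, input$cp)
  sel <- tac$time >= t_star - 1e-9
  tm <- tac$time[sel]
  cp_t <- approx(input$time, input$cp, xout = tm, rule = 2)$y
  if (any(cp_t <= 0))
    stop("plasma input is zero at an included frame mid-time")
  x <- approx(input$time, cum_cp, xout = tm, rule = 2)$y / cp_t
  list(x = x, y = tac$value[sel] / cp_t, t = tm, cp = cp_t)
}

new_patlak_result <- function(ki, v0, k_loss, t_star, r2, variant, fit) {
  structure(list(ki = ki, v0 = v0, k_loss = k_loss, t_star = t_star,
                 r_squared = r2, variant = variant, fit = fit),
            class = "patlak_result")
}

#' @export
print.patlak_result <- function(x, ...) {
  cat(sprintf("<patlak_result> %s: Ki = %.5g mL/g/min, v0 = %.4g%s (t* = %g min, R^2 = %.4f)\n",
              x$variant, x$ki, x$v0,
              if (!is.na(x$k_loss)) sprintf(", k_loss = %.4g /min", x$k_loss)
              else "", x$t_star, x$r_squared))
  invisible(x)
}

#' @export
coef.patlak_result <- function(object, ...) {
  c(ki = object$ki, v0 = object$v0, k_loss = object$k_loss)
}

#' Standard Patlak graphical analysis
#'
#' Ordinary least squares on the Patlak-transformed points for frames with
#' mid-time at or after the equilibration time t*; the slope is the net
#' irreversible uptake constant Ki (macro form K1 k3/(k2+k3)) and the
#' intercept the effective distribution volume term.
#'
#' @param tac a \code{time_activity_curve} (tissue).
#' @param input an \code{input_function}.
#' @param t_star equilibration time, minutes (default 20).
#' @return a \code{patlak_result} with \code{variant = "standard"}.
#' @export
patlak_standard <- function(tac, input, t_star = 20) {
  stopifnot(inherits(tac, "time_activity_curve"),
            inherits(input, "input_function"))
  pts <- patlak_points(tac, input, t_star)
  if (length(pts$x) < 3L)
    stop("fewer than 3 frames at or after t_star")
  fit <- lm(y ~ x, data = data.frame(x = pts$x, y = pts$y))
  r2 <- suppressWarnings(summary(fit)$r.squared)
  new_patlak_result(ki = unname(coef(fit)[2L]), v0 = unname(coef(fit)[1L]),
                    k_loss = NA_real_, t_star = t_star,
                    r2 = r2, variant = "standard", fit = fit)
}

#' Generalized (efflux-term) Patlak analysis
#'
#' Extends the Patlak regression with a loss regressor,
#' \eqn{y = K_i x + v_0 - k_{loss} \int_0^t C_t / C_p(t)}, solved by
#' multiple linear regression; with no efflux in the data the fit collapses
#' to the standard Patlak estimate. Near-collinear regressors are flagged in
#' the result, never silently dropped.
#'
#' @inheritParams patlak_standard
#' @return a \code{patlak_result} with \code{variant = "modified"} and a
#'   \code{collinear} flag.
#' @export
patlak_modified <- function(tac, input, t_star = 20) {
  stopifnot(inherits(tac, "time_activity_curve"),
            inherits(input, "input_function"))
  pts <- patlak_points(tac, input, t_star)
  if (length(pts$x) < 4L)
    stop("fewer than 4 frames at or after t_star")
  cum_ct <- cumtrapz_int(c(0, tac$time), c(0, tac$value))[-1L]
  z <- cum_ct[tac$time >= t_star - 1e-9] / pts$cp
  X <- cbind(1, pts$x, -z)
  kappa <- kappa(scale(X[, -1L], center = TRUE, scale = TRUE), exact = TRUE)
  fit <- lm(y ~ x + mz, data = data.frame(x = pts$x, mz = -z, y = pts$y))
  cf <- coef(fit)
  if (anyNA(cf)) stop("collinear Patlak regressors: fit is degenerate")
  out <- new_patlak_result(ki = unname(cf[2L]), v0 = unname(cf[1L]),
                           k_loss = unname(cf[3L]), t_star = t_star,
                           r2 = suppressWarnings(summary(fit)$r.squared),
                           variant = "modified", fit = fit)
  out$collinear <- is.finite(kappa) && kappa > 1e6
  out
}

# Documented multi-start lattice for the 2TCM fit (K1, k2, k3, vb).
tcm_start_lattice <- function() {
  rbind(c(0.10, 0.15, 0.02, 0.03),
        c(0.05, 0.30, 0.01, 0.05),
        c(0.30, 0.60, 0.05, 0.02),
        c(0.02, 0.05, 0.005, 0.10),
        c(0.50, 1.00, 0.10, 0.05))
}

#' Fit the irreversible two-tissue compartment model
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of the
#' frame-averaged 2TCM prediction
#' \eqn{C_t = (1-v_b)(C_1+C_2) + v_b C_b} with
#' \eqn{dC_1/dt = K_1 C_p - (k_2+k_3) C_1}, \eqn{dC_2/dt = k_3 C_1},
#' \eqn{k_4 = 0}, against a tissue TAC; multiple documented starting points
#' with best-residual selection. vb multiplies whole blood, not plasma.
#'
#' @param tac tissue \code{time_activity_curve}.
#' @param input an \code{input_function} on a fine grid.
#' @param starts numeric matrix of starting points (columns K1, k2, k3, vb);
#'   default \code{tcm_start_lattice()}.
#' @param lower,upper parameter bounds; defaults [0,5]^3 x [0,0.2].
#' @param weights per-frame weights: "uniform" or "frame-duration".
#' @return a \code{tcm_result} with k1, k2, k3, vb, the macro constant
#'   \code{ki_macro}, residual norm and convergence flag.
#' @export
fit_2tcm <- function(tac, input, starts = tcm_start_lattice(),
                     lower = c(0, 0, 0, 0), upper = c(5, 5, 5, 0.2),
                     weights = c("uniform", "frame-duration")) {
  stopifnot(inherits(tac, "time_activity_curve"),
            inherits(input, "input_function"))
  if (any(!is.finite(tac$value))) stop("TAC contains non-finite values")
  weights <- match.arg(weights)
  sch <- attr(tac, "schedule")
  if (is.null(sch))
    stop("TAC must carry its acquisition schedule; see set_tac_schedule()")
  w <- if (weights == "uniform") rep(1, length(tac$value))
       else sqrt(sch$frame_duration / mean(sch$frame_duration))
  resid_fun <- function(p) {
    w * (forward_2tcm_frames(p[1L], p[2L], p[3L], p[4L], input, sch) -
           tac$value)
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(starts[i, ], lower), upper),
                         lower = lower, upper = upper, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best))
    return(structure(list(k1 = NA_real_, k2 = NA_real_, k3 = NA_real_,
                          vb = NA_real_, ki_macro = NA_real_,
                          residual_norm = NA_real_, converged = FALSE),
                     class = "tcm_result"))
  p <- best$fit$par
  ki <- if (p[2L] + p[3L] > 0) p[1L] * p[3L] / (p[2L] + p[3L]) else p[1L]
  structure(list(k1 = p[1L], k2 = p[2L], k3 = p[3L], vb = p[4L],
                 ki_macro = ki, residual_norm = best$rn,
                 converged = best$fit$info %in% 1:4,
                 n_starts = nrow(starts)),
            class = "tcm_result")
}

#' @export
print.tcm_result <- function(x, ...) {
  cat(sprintf(
    "<tcm_result> K1 = %.4g mL/g/min, k2 = %.4g, k3 = %.4g /min, vb = %.4g\n  Ki(macro) = %.5g mL/g/min, residual norm %.4g, converged: %s\n",
    x$k1, x$k2, x$k3, x$vb, x$ki_macro, x$residual_norm, x$converged))
  invisible(x)
}

#' @export
coef.tcm_result <- function(object, ...) {
  c(k1 = object$k1, k2 = object$k2, k3 = object$k3, vb = object$vb,
    ki_macro = object$ki_macro)
}

# Attach an acquisition schedule to a TAC so fitters can frame-average with
# the true durations (mid-times alone do not determine them).
#' Attach the acquisition frame schedule to a TAC
#' @param tac a \code{time_activity_curve}.
#' @param schedule the acquisition \code{frame_schedule}.
#' @export
set_tac_schedule <- function(tac, schedule) {
  stopifnot(inherits(tac, "time_activity_curve"),
            inherits(schedule, "frame_schedule"))
  if (length(schedule$frame_start) != length(tac$time))
    stop("schedule length does not match TAC")
  attr(tac, "schedule") <- schedule
  tac
}
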