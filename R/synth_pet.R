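# Synthetic dynamic PET: irreversible two-tissue-compartment forward model,
# frame-realistic noise, and a sphere-in-box lesion phantom with lesion /
# background / blood-pool masks.

#' Noise specification for simulators
#'
#' PET frame noise is zero-mean Gaussian with SD proportional to
#' value/sqrt(frame duration), emulating count statistics (the stated
#' \code{level} is the relative SD at the mean frame duration). MRI
#' magnitude noise is Rician by default with Gaussian available for
#' analytic checks.
#'
#' @param model "gaussian", "rician" or "frame-gaussian".
#' @param level relative noise SD (>= 0); 0 disables noise.
#' @param seed integer seed for this noise stream, or NULL.
#' @export
noise_spec <- function(model = c("gaussian", "rician", "frame-gaussian"),
                       level = 0, seed = NULL) {
  model <- match.arg(model)
  if (!is.numeric(level) || level < 0) stop("noise level must be >= 0")
  structure(list(model = model, level = level, seed = seed),
            class = "noise_spec")
}

# Trapezoid-rule convolution of two curves sampled on a shared uniform grid
# with step dt (minutes): returns integral_0^t h(t - u) g(u) du at each node.
conv_trapz <- function(h, g, dt) {
  n <- length(h)
  stopifnot(length(g) == n)
  full <- convolve(h, rev(g), type = "open")[seq_len(n)]
  (full - 0.5 * h[1L] * g - 0.5 * g[1L] * h) * dt
}

# Impulse response of the irreversible 2TCM (k4 = 0):
# h(t) = K1 * [k3/(k2+k3) + k2/(k2+k3) exp(-(k2+k3) t)]; degenerates to K1
# when k2 + k3 = 0 (all delivered tracer retained).
tcm_impulse_response <- function(t, k1, k2, k3) {
  s <- k2 + k3
  if (s <= 0) return(rep(k1, length(t)))
  k1 * (k3 / s + (k2 / s) * exp(-s * t))
}

# Average fine-grid samples over each frame interval (trapezoid / duration).
frame_average <- function(t_min, v, schedule) {
  start <- schedule$frame_start / 60
  end <- (schedule$frame_start + schedule$frame_duration) / 60
  vapply(seq_along(start), function(i) {
    sel <- t_min >= start[i] - 1e-9 & t_min <= end[i] + 1e-9
    if (sum(sel) < 2L)
      return(approx(t_min, v, xout = (start[i] + end[i]) / 2, rule = 2)$y)
    trapz_int(t_min[sel], v[sel]) / (t_min[sel][sum(sel)] - t_min[sel][1L])
  }, numeric(1L))
}

# Noiseless frame-averaged tissue curve for the irreversible 2TCM.
# C_t = (1 - vb) * (h conv Cp) + vb * Cb, frame-averaged over each interval.
# The convolution splits into a trapped term K1 k3/s * int Cp and a
# reversible term K1 k2/s * (Cp conv exp(-s t)), both evaluated exactly for
# piecewise-linear Cp (no FFT).
forward_2tcm_frames <- function(k1, k2, k3, vb, input, schedule) {
  s <- k2 + k3
  conv <- if (s <= 0) {
    k1 * cumtrapz_int(input$time, input$cp)
  } else {
    k1 * (k3 / s) * cumtrapz_int(input$time, input$cp) +
      k1 * (k2 / s) * exp_conv(input$time, input$cp, s)
  }
  frame_average(input$time, (1 - vb) * conv + vb * input$cb, schedule)
}

apply_pet_frame_noise <- function(values, schedule, noise) {
  if (is.null(noise) || noise$level == 0) return(values)
  dur <- schedule$frame_duration
  sdv <- noise$level * abs(values) * sqrt(mean(dur) / dur)
  with_seed(noise$seed, values + rnorm(length(values), 0, sdv))
}

apply_mri_noise <- function(signal, noise, reference = NULL) {
  if (is.null(noise) || noise$level == 0) return(signal)
  if (is.null(reference)) reference <- mean(abs(signal))
  sdv <- noise$level * reference
  with_seed(noise$seed, {
    if (noise$model == "rician") {
      sqrt((signal + rnorm(length(signal), 0, sdv))^2 +
             rnorm(length(signal), 0, sdv)^2)
    } else {
      signal + rnorm(length(signal), 0, sdv)
    }
  })
}

#' Simulate a tissue time-activity curve from the irreversible 2TCM
#'
#' Convolves the two-tissue impulse response (k4 = 0, irreversible
#' trapping) with the plasma input on the input function's fine grid,
#' adds the whole-blood spillover term vb*Cb, averages over each frame
#' interval, and applies frame-duration-weighted Gaussian noise.
#'
#' @param input an \code{input_function}.
#' @param truth named list/vector with k1 (mL/g/min), k2, k3 (1/min),
#'   vb (fraction in [0, 1]).
#' @param schedule a \code{frame_schedule}.
#' @param noise a \code{noise_spec} or NULL.
#' @param label curve label.
#' @return a \code{time_activity_curve} with attribute \code{truth}
#'   (including the macro uptake constant \code{ki_macro = K1 k3/(k2+k3)}).
#' @export
simulate_2tcm_tac <- function(input, truth, schedule, noise = NULL,
                              label = "lesion") {
  truth <- as.list(truth)
  for (nm in c("k1", "k2", "k3", "vb"))
    if (is.null(truth[[nm]])) stop(sprintf("truth$%s missing", nm))
  if (any(unlist(truth[c("k1", "k2", "k3")]) < 0))
    stop("rate constants must be nonnegative")
  if (truth$vb < 0 || truth$vb > 1) stop("vb must be in [0, 1]")
  v <- forward_2tcm_frames(truth$k1, truth$k2, truth$k3, truth$vb,
                           input, schedule)
  v <- apply_pet_frame_noise(v, schedule, noise)
  out <- time_activity_curve(frame_mid_times(schedule), v, label = label)
  attr(out, "schedule") <- schedule
  truth$ki_macro <- if (truth$k2 + truth$k3 > 0)
    truth$k1 * truth$k3 / (truth$k2 + truth$k3) else truth$k1
  attr(out, "truth") <- truth
  out
}

# Sphere helper: logical mask of voxels within radius (voxel units) of
# center on a grid of dimension dims.
sphere_mask <- function(dims, center, radius) {
  ax <- lapply(seq_len(3L), function(i) (seq_len(dims[i]) - center[i])^2)
  d2 <- outer(outer(ax[[1L]], ax[[2L]], "+"), ax[[3L]], "+")
  array(d2 <= radius^2 + 1e-9, dim = dims)
}

#' Sphere-in-box dynamic lesion phantom
#'
#' Builds a 4-D dynamic image where lesion voxels follow a high-uptake 2TCM
#' curve, background voxels a low-uptake curve, and a blood-pool region the
#' whole-blood input curve; returns the image together with the lesion,
#' background (contralateral), blood and contrast-enhancement masks and the
#' generating ground truth. The CE mask radius may differ from the PET-avid
#' radius to emulate PET volumes extending beyond contrast enhancement.
#'
#' @param dims grid size, default c(32, 32, 32).
#' @param voxel_size mm, default 2.
#' @param lesion_radius PET-avid lesion radius in voxels.
#' @param ce_radius contrast-enhancing radius in voxels (default = lesion).
#' @param lesion_truth,background_truth 2TCM parameter lists.
#' @param input an \code{input_function}.
#' @param schedule a \code{frame_schedule}.
#' @param noise a \code{noise_spec} applied voxelwise, or NULL.
#' @param seed seed for voxel noise.
#' @export
make_lesion_phantom <- function(dims = c(32L, 32L, 32L), voxel_size = 2,
                                lesion_radius = 5, ce_radius = lesion_radius,
                                lesion_truth = list(k1 = 0.10, k2 = 0.15,
                                                    k3 = 0.02, vb = 0.03),
                                background_truth = list(k1 = 0.06, k2 = 0.17,
                                                        k3 = 0.006, vb = 0.02),
                                input, schedule, noise = NULL, seed = NULL) {
  if (lesion_radius <= 0) stop("lesion radius must be positive")
  center_lesion <- c(ceiling(dims[1L] * 0.3), dims[2L] %/% 2, dims[3L] %/% 2)
  if (lesion_radius > min(dims) / 2 - 1) stop("lesion larger than grid")
  lesion <- sphere_mask(dims, center_lesion, lesion_radius)
  ce <- sphere_mask(dims, center_lesion, ce_radius)
  center_cwm <- c(dims[1L] - center_lesion[1L] + 1L, center_lesion[2L],
                  center_lesion[3L])
  cwm <- sphere_mask(dims, center_cwm, lesion_radius)
  blood <- array(FALSE, dims)
  blood[(dims[1L] %/% 2 - 1L):(dims[1L] %/% 2 + 1L),
        (dims[2L] %/% 2 - 1L):(dims[2L] %/% 2 + 1L),
        dims[3L] - 3L] <- TRUE

  les_tac <- simulate_2tcm_tac(input, lesion_truth, schedule)
  bg_tac <- simulate_2tcm_tac(input, background_truth, schedule)
  cb_frames <- frame_average(input$time, input$cb, schedule)
  nf <- length(schedule$frame_start)
  vox <- array(rep(bg_tac$value, each = prod(dims)), dim = c(dims, nf))
  for (f in seq_len(nf)) {
    sl <- vox[, , , f]
    sl[lesion] <- les_tac$value[f]
    sl[blood] <- cb_frames[f]
    vox[, , , f] <- sl
  }
  if (!is.null(noise) && noise$level > 0) {
    dur <- schedule$frame_duration
    vox <- with_seed(if (is.null(noise$seed)) seed else noise$seed, {
      sdv <- noise$level * abs(vox) *
        rep(sqrt(mean(dur) / dur), each = prod(dims))
      vox + array(rnorm(length(vox), 0, as.numeric(sdv)), dim = dim(vox))
    })
  }
  list(image = dynamic_image(vox, voxel_size = voxel_size,
                             schedule = schedule, value_unit = "kBq/mL"),
       lesion_mask = roi_mask(lesion, "lesion"),
       ce_mask = roi_mask(ce, "ce-mri"),
       cwm_mask = roi_mask(cwm, "contralateral-white-matter"),
       blood_mask = roi_mask(blood, "sagittal-sinus"),
       truth = list(lesion = attr(les_tac, "truth"),
                    background = attr(bg_tac, "truth"),
                    lesion_radius = lesion_radius, ce_radius = ce_radius))
}
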