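# Data model and I/O for dynamic volumes, frame schedules, ROI masks and
# region time-activity extraction. All geometry is in voxel-index space;
# masks are assumed co-registered with their companion image (simultaneous
# hybrid acquisition), so no world-coordinate resampling is done here.

#' Frame schedule for a dynamic acquisition
#'
#' Describes when each reconstructed frame starts and how long it lasts,
#' in seconds from tracer injection. Frames must be contiguous,
#' non-overlapping and of positive duration.
#'
#' @param frame_start numeric vector, frame start times in seconds.
#' @param frame_duration numeric vector, frame durations in seconds.
#' @return An object of class \code{frame_schedule}.
#' @examples
#' sch <- frame_schedule_from_counts(c(10, 3, 5, 9, 1),
#'                                   c(15, 60, 120, 300, 360))
#' frame_mid_times(sch)
#' @export
frame_schedule <- function(frame_start, frame_duration) {
  frame_start <- as.numeric(frame_start)
  frame_duration <- as.numeric(frame_duration)
  if (length(frame_start) != length(frame_duration))
    stop("frame_start and frame_duration must have equal length")
  if (length(frame_start) == 0L) stop("schedule must contain >= 1 frame")
  if (any(!is.finite(frame_start)) || any(!is.finite(frame_duration)))
    stop("schedule entries must be finite")
  if (any(frame_duration <= 0)) stop("frame durations must be positive")
  if (frame_start[1L] < 0) stop("first frame start must be >= 0")
  if (length(frame_start) > 1L) {
    gap <- frame_start[-1L] - (frame_start[-length(frame_start)] +
                                 frame_duration[-length(frame_duration)])
    if (any(abs(gap) > 1e-9))
      stop("frames must be contiguous and non-overlapping")
  }
  structure(list(frame_start = frame_start, frame_duration = frame_duration),
            class = "frame_schedule")
}

#' @rdname frame_schedule
#' @param n_frames integer vector: number of frames per block.
#' @param durations numeric vector: frame duration (s) per block.
#' @export
frame_schedule_from_counts <- function(n_frames, durations) {
  if (length(n_frames) != length(durations))
    stop("n_frames and durations must have equal length")
  dur <- rep(durations, times = n_frames)
  start <- cumsum(c(0, dur[-length(dur)]))
  frame_schedule(start, dur)
}

#' Frame mid-times in minutes
#'
#' Mid-frame time is the abscissa used by all kinetic fitting on
#' frame-integrated data.
#'
#' @param schedule a \code{frame_schedule}.
#' @return numeric vector of mid-times in minutes, with attribute
#'   \code{end_min} giving the end of the last frame in minutes.
#' @export
frame_mid_times <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  mid <- (schedule$frame_start + schedule$frame_duration / 2) / 60
  attr(mid, "end_min") <- (schedule$frame_start[length(schedule$frame_start)] +
    schedule$frame_duration[length(schedule$frame_duration)]) / 60
  mid
}

#' @rdname frame_mid_times
#' @export
schedule_end_min <- function(schedule) {
  attr(frame_mid_times(schedule), "end_min")
}

#' Dynamic (or static) image container
#'
#' A 4-D voxel array (x, y, z, frame) with its frame schedule, voxel size
#' and value unit; 3-D arrays are accepted as static volumes with
#' \code{schedule = NULL}.
#'
#' @param voxels 3-D or 4-D numeric array.
#' @param voxel_size numeric length-3, mm per axis.
#' @param schedule a \code{frame_schedule} or NULL for static volumes.
#' @param value_unit one of \code{"kBq/mL"}, \code{"arbitrary-signal"},
#'   \code{"unitless"}.
#' @param decay_corrected logical: whether values are already decay-corrected
#'   to injection time.
#' @return An object of class \code{dynamic_image}.
#' @export
dynamic_image <- function(voxels, voxel_size = c(1, 1, 1), schedule = NULL,
                          value_unit = c("kBq/mL", "arbitrary-signal",
                                         "unitless"),
                          decay_corrected = TRUE) {
  value_unit <- match.arg(value_unit)
  nd <- length(dim(voxels))
  if (!nd %in% c(3L, 4L)) stop("voxels must be a 3-D or 4-D array")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  if (nd == 4L) {
    if (is.null(schedule))
      stop("4-D image requires a frame schedule")
    if (dim(voxels)[4L] != length(schedule$frame_start))
      stop(sprintf("frame count mismatch: image has %d frames, schedule %d",
                   dim(voxels)[4L], length(schedule$frame_start)))
  } else if (!is.null(schedule)) {
    stop("3-D image must not carry a frame schedule")
  }
  structure(list(voxels = voxels, voxel_size = as.numeric(voxel_size),
                 schedule = schedule, value_unit = value_unit,
                 decay_corrected = isTRUE(decay_corrected)),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<dynamic_image> %s [%s] voxel %s mm, unit %s%s\n",
              if (length(d) == 4L) "dynamic" else "static",
              paste(d, collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x"),
              x$value_unit,
              if (length(d) == 4L)
                sprintf(", %d frames ending %.1f min", d[4L],
                        schedule_end_min(x$schedule)) else ""))
  invisible(x)
}

#' Binary region-of-interest mask
#'
#' @param voxels 3-D logical (or coercible) array on the same grid as the
#'   companion image.
#' @param label text label, e.g. "lesion", "contralateral-white-matter",
#'   "sagittal-sinus".
#' @export
roi_mask <- function(voxels, label = "roi") {
  if (length(dim(voxels)) != 3L) stop("mask must be a 3-D array")
  structure(list(voxels = array(as.logical(voxels), dim = dim(voxels)),
                 label = as.character(label)[1L]),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s': %d voxels on [%s]\n", x$label,
              sum(x$voxels), paste(dim(x$voxels), collapse = "x")))
  invisible(x)
}

#' Region time-activity curve
#'
#' Frame mid-time-stamped mean concentration for a region: the unit of all
#' kinetic fitting.
#'
#' @param time numeric, frame mid-times in minutes (strictly increasing).
#' @param value numeric, mean region concentration per frame.
#' @param n_voxels voxel count the mean was taken over.
#' @param label region label.
#' @param decay_corrected whether values are decay-corrected to injection.
#' @export
time_activity_curve <- function(time, value, n_voxels = NA_integer_,
                                label = "region", decay_corrected = TRUE) {
  time <- as.numeric(time); value <- as.numeric(value)
  if (length(time) != length(value))
    stop("time and value must have equal length")
  if (length(time) > 1L && any(diff(time) <= 0))
    stop("time must be strictly increasing")
  structure(list(time = time, value = value,
                 n_voxels = as.integer(n_voxels),
                 label = as.character(label)[1L],
                 decay_corrected = isTRUE(decay_corrected)),
            class = "time_activity_curve")
}

#' @export
print.time_activity_curve <- function(x, ...) {
  cat(sprintf("<time_activity_curve> '%s': %d frames, %.3g-%.3g min, peak %.4g\n",
              x$label, length(x$time), min(x$time), max(x$time),
              max(x$value)))
  invisible(x)
}

#' @export
as.data.frame.time_activity_curve <- function(x, ...) {
  data.frame(time_min = x$time, value = x$value, n_voxels = x$n_voxels)
}

#' Per-subject tracer administration metadata
#'
#' @param injected_activity MBq.
#' @param body_weight kg.
#' @param isotope_half_life minutes; default 109.77 (fluorine-18).
#' @export
subject_meta <- function(injected_activity, body_weight,
                         isotope_half_life = 109.77) {
  stop_if_not_scalar_pos(injected_activity, "injected_activity")
  stop_if_not_scalar_pos(body_weight, "body_weight")
  stop_if_not_scalar_pos(isotope_half_life, "isotope_half_life")
  structure(list(injected_activity = injected_activity,
                 body_weight = body_weight,
                 isotope_half_life = isotope_half_life),
            class = "subject_meta")
}

# ---- NIfTI + JSON sidecar I/O -------------------------------------------
# Sidecar keys mirror the common PET-BIDS vocabulary so real data can be
# adapted: FrameTimesStart (s), FrameDuration (s), Units, DecayCorrected.

#' Write a dynamic image as NIfTI plus JSON sidecar
#'
#' @param image a \code{dynamic_image}.
#' @param image_path output .nii/.nii.gz path.
#' @param sidecar_path output .json path; defaults to image path with .json.
#' @return invisibly, the image path.
#' @export
write_dynamic_image <- function(image, image_path, sidecar_path = NULL) {
  stopifnot(inherits(image, "dynamic_image"))
  nif <- RNifti::asNifti(image$voxels)
  RNifti::pixdim(nif) <- c(image$voxel_size,
                           if (length(dim(image$voxels)) == 4L) 1 else NULL)
  RNifti::writeNifti(nif, image_path)
  if (!is.null(image$schedule)) {
    if (is.null(sidecar_path))
      sidecar_path <- sub("\\.nii(\\.gz)?$", ".json", image_path)
    jsonlite::write_json(
      list(FrameTimesStart = image$schedule$frame_start,
           FrameDuration = image$schedule$frame_duration,
           Units = image$value_unit,
           DecayCorrected = image$decay_corrected),
      sidecar_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(image_path)
}

#' Load a dynamic image from NIfTI plus JSON sidecar
#'
#' A 4-D image requires a sidecar declaring frame timing; a 3-D image loads
#' as a static volume with no schedule.
#'
#' @param image_path NIfTI path.
#' @param sidecar_path JSON sidecar path (required for 4-D input).
#' @return a \code{dynamic_image}.
#' @export
load_dynamic_image <- function(image_path, sidecar_path = NULL) {
  nif <- RNifti::readNifti(image_path)
  vox <- array(as.numeric(nif), dim = dim(nif))
  pd <- RNifti::pixdim(nif)[seq_len(3L)]
  if (length(dim(vox)) == 4L) {
    if (is.null(sidecar_path) || !file.exists(sidecar_path))
      stop("4-D image requires a JSON timing sidecar")
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    for (key in c("FrameTimesStart", "FrameDuration"))
      if (is.null(sc[[key]]))
        stop(sprintf("sidecar missing required key '%s'", key))
    sch <- frame_schedule(sc$FrameTimesStart, sc$FrameDuration)
    if (length(sch$frame_start) != dim(vox)[4L])
      stop(sprintf("frame count mismatch: sidecar has %d entries, image %d frames",
                   length(sch$frame_start), dim(vox)[4L]))
    dynamic_image(vox, voxel_size = pd, schedule = sch,
                  value_unit = if (!is.null(sc$Units)) sc$Units else "unitless",
                  decay_corrected = !isFALSE(sc$DecayCorrected))
  } else {
    dynamic_image(vox, voxel_size = pd, schedule = NULL,
                  value_unit = "unitless")
  }
}

#' Write / read a binary ROI mask as NIfTI
#' @param mask a \code{roi_mask}.
#' @param path NIfTI path.
#' @export
write_roi_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask$voxels),
                                           dim = dim(mask$voxels))), path)
  invisible(path)
}

#' @rdname write_roi_mask
#' @param label label for the loaded mask.
#' @export
read_roi_mask <- function(path, label = "roi") {
  nif <- RNifti::readNifti(path)
  roi_mask(array(as.numeric(nif), dim = dim(nif)) > 0.5, label = label)
}

# ---- TAC extraction and decay handling ----------------------------------

#' Extract a region time-activity curve
#'
#' Per-frame arithmetic mean of the image over the mask voxels. Max-based
#' statistics are computed from voxel values by the static-PET metrics, not
#' from the TAC.
#'
#' @param image a \code{dynamic_image}.
#' @param mask a \code{roi_mask} on the same grid.
#' @return a \code{time_activity_curve} (for static images, a single-sample
#'   curve at time 0 with no schedule semantics).
#' @export
extract_tac <- function(image, mask) {
  stopifnot(inherits(image, "dynamic_image"), inherits(mask, "roi_mask"))
  d <- dim(image$voxels)
  if (!identical(dim(mask$voxels), d[seq_len(3L)]))
    stop("mask grid does not match image grid")
  idx <- which(mask$voxels)
  if (length(idx) == 0L) stop("mask is empty")
  if (length(d) == 4L) {
    nvox3 <- prod(d[seq_len(3L)])
    mat <- matrix(image$voxels, nrow = nvox3, ncol = d[4L])
    vals <- colMeans(mat[idx, , drop = FALSE])
    out <- time_activity_curve(frame_mid_times(image$schedule), vals,
                               n_voxels = length(idx), label = mask$label,
                               decay_corrected = image$decay_corrected)
    attr(out, "schedule") <- image$schedule
    out
  } else {
    time_activity_curve(0, mean(image$voxels[idx]),
                        n_voxels = length(idx), label = mask$label,
                        decay_corrected = image$decay_corrected)
  }
}

#' Radioactive-decay correction of a time-activity curve
#'
#' Correcting to injection time multiplies each frame value by
#' \eqn{2^{t/T_{1/2}}} at its mid-time; \code{target = "none"} undoes a
#' previous correction. The corrected/uncorrected state is tracked on the
#' curve, and re-applying the same correction is an error.
#'
#' @param tac a \code{time_activity_curve}.
#' @param meta a \code{subject_meta} (supplies the isotope half-life, min).
#' @param target \code{"injection_time"} (correct) or \code{"none"} (undo).
#' @export
decay_correct <- function(tac, meta, target = c("injection_time", "none")) {
  stopifnot(inherits(tac, "time_activity_curve"),
            inherits(meta, "subject_meta"))
  target <- match.arg(target)
  fac <- exp(log(2) * tac$time / meta$isotope_half_life)
  if (target == "injection_time") {
    if (tac$decay_corrected)
      stop("curve is already decay-corrected to injection time")
    out <- tac
    out$value <- tac$value * fac
    out$decay_corrected <- TRUE
  } else {
    if (!tac$decay_corrected)
      stop("curve is already uncorrected")
    out <- tac
    out$value <- tac$value / fac
    out$decay_corrected <- FALSE
  }
  out
}

#' Write / read a TAC as CSV (columns time_min, value, n_voxels)
#' @param tac a \code{time_activity_curve}.
#' @param path CSV path.
#' @export
write_tac_csv <- function(tac, path) {
  write.csv(as.data.frame(tac), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac_csv
#' @param label label for the loaded curve.
#' @export
read_tac_csv <- function(path, label = "region") {
  df <- read.csv(path)
  time_activity_curve(df$time_min, df$value,
                      n_voxels = if ("n_voxels" %in% names(df))
                        df$n_voxels[1L] else NA_integer_,
                      label = label)
}
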