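# Static PET metrics on the late uptake frame: SUV, tumour-to-background
# ratio against contralateral white matter, fractional-SUVmax contour
# segmentation, and mask volume/overlap statistics.

#' Standardised uptake value
#'
#' SUV = tissue activity concentration / (injected activity / body weight).
#' With concentration in kBq/mL, activity in MBq and weight in kg the units
#' cancel to the conventional g/mL scale (1 mL of tissue taken as 1 g).
#'
#' @param value activity concentration in kBq/mL (scalar, vector or array —
#'   e.g. the last dynamic frame, the static-uptake frame).
#' @param meta a \code{subject_meta}.
#' @return SUV on the same shape as \code{value}.
#' @export
compute_suv <- function(value, meta) {
  stopifnot(inherits(meta, "subject_meta"))
  # injected MBq -> kBq, weight kg -> g: (1e3 * MBq) / (1e3 * kg) = MBq/kg
  value / (meta$injected_activity * 1e3 / (meta$body_weight * 1e3))
}

#' Last dynamic frame as the static-uptake volume
#'
#' The final reconstructed frame is the conventional late-uptake volume for
#' static visualisation and SUV metrics.
#'
#' @param image a dynamic \code{dynamic_image}.
#' @return a static \code{dynamic_image} (3-D).
#' @export
static_uptake_frame <- function(image) {
  stopifnot(inherits(image, "dynamic_image"))
  d <- dim(image$voxels)
  if (length(d) != 4L) stop("image is already static")
  dynamic_image(array(image$voxels[, , , d[4L]], dim = d[seq_len(3L)]),
                voxel_size = image$voxel_size, value_unit = image$value_unit,
                decay_corrected = image$decay_corrected)
}

#' Region SUV statistics
#'
#' @param suv_volume static 3-D \code{dynamic_image} of SUV values (or raw
#'   concentration; interpretation is the caller's).
#' @param mask a \code{roi_mask}.
#' @return list with suv_max, suv_mean, n_voxels, volume_ml and the label.
#' @export
region_suv_stats <- function(suv_volume, mask) {
  stopifnot(inherits(suv_volume, "dynamic_image"), inherits(mask, "roi_mask"))
  if (!identical(dim(mask$voxels), dim(suv_volume$voxels)))
    stop("mask grid does not match volume grid")
  idx <- which(mask$voxels)
  if (length(idx) == 0L) stop("mask is empty")
  v <- suv_volume$voxels[idx]
  list(suv_max = max(v), suv_mean = mean(v), n_voxels = length(idx),
       volume_ml = length(idx) * prod(suv_volume$voxel_size) / 1e3,
       mask_label = mask$label)
}

#' Tumour-to-background ratio
#'
#' Lesion SUV statistics divided by those of an equal-volume contralateral
#' white-matter region.
#'
#' @param lesion_stat,background_stat outputs of \code{region_suv_stats}.
#' @return list with tbr_max and tbr_mean.
#' @export
compute_tbr <- function(lesion_stat, background_stat) {
  if (background_stat$suv_mean <= 0 || background_stat$suv_max <= 0)
    stop("background uptake must be positive")
  list(tbr_max = lesion_stat$suv_max / background_stat$suv_max,
       tbr_mean = lesion_stat$suv_mean / background_stat$suv_mean)
}

# 26-connected component of `candidate` containing `seed_index`, by
# breadth-first frontier expansion on the voxel grid.
connected_component_26 <- function(candidate, seed_index) {
  dims <- dim(candidate)
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]
  offsets <- nb[, 1L] + nb[, 2L] * dims[1L] + nb[, 3L] * dims[1L] * dims[2L]
  # coordinates needed to reject neighbours that wrap across grid edges
  coord <- arrayInd(seq_len(prod(dims)), dims)
  visited <- array(FALSE, dims)
  visited[seed_index] <- TRUE
  frontier <- seed_index
  while (length(frontier) > 0L) {
    cand <- rep(frontier, each = nrow(nb)) + rep(offsets, length(frontier))
    src <- rep(frontier, each = nrow(nb))
    ok <- cand >= 1L & cand <= prod(dims)
    cand <- cand[ok]; src <- src[ok]
    # neighbour must differ by <= 1 in every axis (no wrap-around)
    keep <- abs(coord[cand, 1L] - coord[src, 1L]) <= 1L &
      abs(coord[cand, 2L] - coord[src, 2L]) <= 1L &
      abs(coord[cand, 3L] - coord[src, 3L]) <= 1L
    cand <- unique(cand[keep])
    cand <- cand[candidate[cand] & !visited[cand]]
    visited[cand] <- TRUE
    frontier <- cand
  }
  visited
}

#' Fractional-SUVmax contour segmentation
#'
#' Finds the SUVmax voxel within a seed region and grows the 26-connected
#' component of voxels at or above \code{fraction * SUVmax} that contains
#' it — the SUV30/SUV40 contour masks at fractions 0.30/0.40. Ties at
#' exactly the threshold are included, so the mask is deterministic and
#' invariant to positive rescaling of the image.
#'
#' @param suv_volume static 3-D \code{dynamic_image}.
#' @param seed_region \code{roi_mask} localising the lesion (e.g. the T1
#'   mask dilated by a margin); SUVmax is searched within it.
#' @param fraction threshold as a fraction of SUVmax (0.30, 0.40, ...).
#' @return a \code{roi_mask} labelled \code{"SUV<percent>"}.
#' @export
threshold_segment <- function(suv_volume, seed_region, fraction = 0.40) {
  stopifnot(inherits(suv_volume, "dynamic_image"),
            inherits(seed_region, "roi_mask"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (!identical(dim(seed_region$voxels), dim(suv_volume$voxels)))
    stop("seed region grid does not match volume")
  seed_idx <- which(seed_region$voxels)
  if (length(seed_idx) == 0L) stop("seed region is empty")
  vmax_idx <- seed_idx[which.max(suv_volume$voxels[seed_idx])]
  vmax <- suv_volume$voxels[vmax_idx]
  candidate <- suv_volume$voxels >= fraction * vmax - 1e-12 * abs(vmax)
  comp <- connected_component_26(candidate, vmax_idx)
  roi_mask(comp, label = sprintf("SUV%d", round(fraction * 100)))
}

#' Dilate a binary mask by a margin (mm)
#'
#' Adds every voxel whose centre lies within \code{margin_mm} of a mask
#' voxel centre; used to turn an anatomical lesion mask into a
#' SUVmax-search seed region.
#'
#' @param mask a \code{roi_mask}.
#' @param margin_mm dilation margin in mm (default 5).
#' @param voxel_size mm per axis.
#' @export
dilate_mask <- function(mask, margin_mm = 5, voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(mask, "roi_mask"))
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  r <- floor(margin_mm / voxel_size)
  dims <- dim(mask$voxels)
  offs <- expand.grid(dx = -r[1L]:r[1L], dy = -r[2L]:r[2L], dz = -r[3L]:r[3L])
  d_mm <- sqrt((offs$dx * voxel_size[1L])^2 + (offs$dy * voxel_size[2L])^2 +
                 (offs$dz * voxel_size[3L])^2)
  offs <- offs[d_mm <= margin_mm, , drop = FALSE]
  idx <- which(mask$voxels)
  coord <- arrayInd(idx, dims)
  out <- array(FALSE, dims)
  for (i in seq_len(nrow(offs))) {
    x <- coord[, 1L] + offs$dx[i]; y <- coord[, 2L] + offs$dy[i]
    z <- coord[, 3L] + offs$dz[i]
    ok <- x >= 1L & x <= dims[1L] & y >= 1L & y <= dims[2L] &
      z >= 1L & z <= dims[3L]
    out[cbind(x[ok], y[ok], z[ok])] <- TRUE
  }
  roi_mask(out, label = mask$label)
}

#' Mask volume and overlap statistics
#'
#' Dice similarity coefficient \eqn{2|A \cap B| / (|A| + |B|)}, per-mask
#' volumes, and the percent volume difference \eqn{100 (V_A - V_B) / V_B}.
#'
#' @param mask_a,mask_b \code{roi_mask}s on the same grid.
#' @param voxel_size mm per axis.
#' @return list dice, volume_a_ml, volume_b_ml, percent_volume_difference.
#' @export
mask_overlap <- function(mask_a, mask_b, voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(mask_a, "roi_mask"), inherits(mask_b, "roi_mask"))
  if (!identical(dim(mask_a$voxels), dim(mask_b$voxels)))
    stop("masks are on different grids")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  na <- sum(mask_a$voxels); nb <- sum(mask_b$voxels)
  ninter <- sum(mask_a$voxels & mask_b$voxels)
  vml <- prod(voxel_size) / 1e3
  list(dice = if (na + nb == 0L) NA_real_ else 2 * ninter / (na + nb),
       volume_a_ml = na * vml, volume_b_ml = nb * vml,
       percent_volume_difference = if (nb == 0L) NA_real_
       else 100 * (na - nb) / nb)
}
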