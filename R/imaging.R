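# PET/CT preprocessing and the three standard PET parameters.

#' CT display window specification
#'
#' Narrow soft-tissue window used before feeding CT into a CNN; defaults to
#' center 70 HU, width 200 HU.
#'
#' @param center window center in HU.
#' @param width window width in HU (> 0).
#' @return object of class `window_spec`.
#' @export
window_spec <- function(center = 70, width = 200) {
  if (width <= 0) stop("window width must be > 0")
  structure(list(center = center, width = width), class = "window_spec")
}

#' Window a CT volume and scale to \[0, 1\]
#'
#' Clips HU to `[center - width/2, center + width/2]` then maps the window
#' affinely onto \[0, 1\]. Idempotent on already-windowed input re-expressed
#' in HU.
#'
#' @param ct 3D array of HU values.
#' @param spec a [window_spec()].
#' @return array of the same shape with values in \[0, 1\].
#' @export
window_ct <- function(ct, spec = window_spec()) {
  lo <- spec$center - spec$width / 2
  hi <- spec$center + spec$width / 2
  (pmin(pmax(ct, lo), hi) - lo) / (hi - lo)
}

#' Clip PET at an SUV cut-off and scale to \[0, 1\]
#'
#' @param pet nonnegative 3D array of SUVs.
#' @param cutoff SUV cut-off (> 0); default 25, the training-cohort value
#'   derived from the 95th percentile of per-patient SUV max.
#' @return array with values `min(v, cutoff) / cutoff`.
#' @export
clip_scale_pet <- function(pet, cutoff = 25) {
  if (cutoff <= 0) stop("SUV cutoff must be > 0")
  pmin(pet, cutoff) / cutoff
}

#' Derive the SUV cut-off from a training cohort
#'
#' The 95th percentile (linear-interpolation convention, `quantile`
#' type 7) of the per-patient SUV max over the training cohort.
#'
#' @param suv_max numeric vector of per-patient SUV max values, or a
#'   `phantom_cohort` whose patients supply them.
#' @param prob percentile in (0, 1\].
#' @return the SUV cut-off.
#' @export
derive_suv_cutoff <- function(suv_max, prob = 0.95) {
  if (inherits(suv_max, "phantom_cohort")) {
    suv_max <- vapply(suv_max$patients, function(p) max(p$pet), numeric(1))
  }
  if (length(suv_max) < 2L) stop("need at least two patients to derive a cutoff")
  unname(quantile(suv_max, prob, type = 7))
}

#' Crop volumes and masks to a fixed physical volume of interest
#'
#' The VOI is centered on the centroid of GTVp union GTVn, clamped so it
#' stays on the grid; where the VOI extends past the grid the output is
#' zero-padded (padding is reported). All volumes are cropped identically.
#'
#' @param volumes named list of 3D arrays (e.g. `pet`, `ct`).
#' @param masks named list of binary arrays; must contain `gtvp`.
#' @param voi_mm physical extent of the VOI per axis in mm; default the
#'   head-and-neck 191 x 265 x 173 mm box.
#' @param spacing voxel size in mm.
#' @return list with cropped `volumes`, `masks`, and `padding` (voxels
#'   added per axis, low/high).
#' @export
crop_voi <- function(volumes, masks, voi_mm = c(191, 265, 173), spacing = 1) {
  spacing <- rep(spacing, length.out = 3L)
  d <- dim(volumes[[1]])
  for (v in c(volumes, masks)) stopifnot(identical(dim(v), d))
  out_shape <- as.integer(round(voi_mm / spacing))
  union <- masks$gtvp
  if (!is.null(masks$gtvn)) union <- pmax(union, masks$gtvn)
  idx <- which(union > 0, arr.ind = TRUE)
  centroid <- round(colMeans(idx))

  starts <- integer(3); pad_lo <- integer(3); pad_hi <- integer(3)
  take <- vector("list", 3)
  for (a in 1:3) {
    s <- centroid[a] - out_shape[a] %/% 2L
    # clamp so as much of the VOI as possible lies on the grid
    s <- min(max(s, 1L), max(d[a] - out_shape[a] + 1L, 1L))
    e <- s + out_shape[a] - 1L
    pad_hi[a] <- max(0L, e - d[a])
    take[[a]] <- s:min(e, d[a])
    starts[a] <- s
  }
  crop1 <- function(v) {
    out <- array(0, out_shape)
    out[seq_along(take[[1]]), seq_along(take[[2]]), seq_along(take[[3]])] <-
      v[take[[1]], take[[2]], take[[3]]]
    out
  }
  volumes <- lapply(volumes, crop1)
  masks <- lapply(masks, crop1)
  if (sum(masks$gtvp) == 0) stop("GTVp lost entirely by the VOI crop")
  list(volumes = volumes, masks = masks,
       padding = cbind(low = pad_lo, high = pad_hi))
}

# Integer sphere offsets (voxel units) whose centers lie within radius r_mm.
sphere_offsets <- function(spacing, r_mm) {
  reach <- ceiling(r_mm / spacing)
  off <- as.matrix(expand.grid(dx = -reach[1]:reach[1],
                               dy = -reach[2]:reach[2],
                               dz = -reach[3]:reach[3]))
  phys <- sweep(off, 2, spacing, "*")
  off[rowSums(phys^2) <= r_mm^2, , drop = FALSE]
}

#' SUV peak: maximum 1 cm3 sphere-mean SUV centered in the GTVp
#'
#' For every voxel center inside the GTVp, averages the PET values of all
#' grid voxels whose centers lie within the radius of a 1 cm3 sphere
#' (r = (3000 / 4 pi)^(1/3) ~ 6.204 mm) of that center, and returns the
#' maximum. The sphere may extend beyond the GTVp; voxels beyond the image
#' grid are excluded from the mean.
#'
#' @param pet 3D SUV array.
#' @param gtvp_mask binary mask (nonempty).
#' @param spacing voxel size in mm.
#' @param sphere_volume_mm3 sphere volume (default 1000 mm3 = 1 cm3).
#' @return SUV peak (scalar).
#' @export
suv_peak <- function(pet, gtvp_mask, spacing = 1,
                     sphere_volume_mm3 = 1000) {
  spacing <- rep(spacing, length.out = 3L)
  centers <- which(gtvp_mask > 0, arr.ind = TRUE)
  if (nrow(centers) == 0L) stop("GTVp mask is empty")
  r <- (3 * sphere_volume_mm3 / (4 * pi))^(1 / 3)
  off <- sphere_offsets(spacing, r)
  d <- dim(pet)
  best <- -Inf
  for (i in seq_len(nrow(centers))) {
    pos <- sweep(off, 2, centers[i, ], "+")
    ok <- pos[, 1] >= 1 & pos[, 1] <= d[1] &
          pos[, 2] >= 1 & pos[, 2] <= d[2] &
          pos[, 3] >= 1 & pos[, 3] <= d[3]
    vals <- pet[pos[ok, , drop = FALSE]]
    m <- mean(vals)
    if (m > best) best <- m
  }
  best
}

#' Metabolic tumor volume
#'
#' Volume (cm3) of GTVp voxels with SUV at or above 50% of the SUV peak.
#'
#' @param pet 3D SUV array.
#' @param gtvp_mask binary mask.
#' @param suv_peak_value SUV peak (> 0).
#' @param spacing voxel size in mm.
#' @param fraction threshold fraction of the SUV peak (default 0.5).
#' @return MTV in cm3.
#' @export
mtv <- function(pet, gtvp_mask, suv_peak_value, spacing = 1, fraction = 0.5) {
  if (suv_peak_value <= 0) stop("suv_peak_value must be > 0")
  spacing <- rep(spacing, length.out = 3L)
  thr <- fraction * suv_peak_value
  sum(pet[gtvp_mask > 0] >= thr) * prod(spacing) / 1000
}

#' Total lesion glycolysis
#'
#' `MTV x SUV mean`, with the SUV mean taken over the whole GTVp.
#'
#' @param mtv_value MTV in cm3 (>= 0).
#' @param suv_mean_gtvp mean SUV within the GTVp (>= 0).
#' @return TLG in cm3 * SUV.
#' @export
tlg <- function(mtv_value, suv_mean_gtvp) {
  stopifnot(mtv_value >= 0, suv_mean_gtvp >= 0)
  mtv_value * suv_mean_gtvp
}

#' Standard PET parameters for one patient
#'
#' @param pet 3D SUV array.
#' @param gtvp_mask binary mask.
#' @param spacing voxel size in mm.
#' @return named list: `suv_peak`, `suv_mean`, `suv_max`, `mtv` (cm3),
#'   `tlg` (cm3 * SUV).
#' @export
pet_params <- function(pet, gtvp_mask, spacing = 1) {
  sp <- suv_peak(pet, gtvp_mask, spacing)
  sm <- mean(pet[gtvp_mask > 0])
  mt <- mtv(pet, gtvp_mask, sp, spacing)
  list(suv_peak = sp, suv_mean = sm, suv_max = max(pet[gtvp_mask > 0]),
       mtv = mt, tlg = tlg(mt, sm))
}
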