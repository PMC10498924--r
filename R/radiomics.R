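# Radiomics features: the named first-order, shape, GLCM, GLSZM, GLRLM and
# 3D LBP subset surfaced by the study, computed within the GTVp. Texture
# matrices follow IBSI conventions: symmetric co-occurrences at distance 1
# over the 13 unique 3D directions, 26-connected zones, per-direction
# feature averaging.

#' Discretize in-mask intensities to gray levels
#'
#' @param vol 3D numeric array.
#' @param mask binary mask.
#' @param bins number of gray levels for `"fixed_bin_count"` mode.
#' @param mode `"fixed_bin_count"` (default) or `"fixed_bin_width"`.
#' @param bin_width bin width for `"fixed_bin_width"` mode.
#' @return integer array with levels 1..Ng inside the mask and `NA`
#'   outside; attributes `n_levels` and `bin_mid` (bin midpoint values).
#' @export
discretize_volume <- function(vol, mask, bins = 32L,
                              mode = c("fixed_bin_count", "fixed_bin_width"),
                              bin_width = NULL) {
  mode <- match.arg(mode)
  vals <- vol[mask > 0]
  out <- array(NA_integer_, dim(vol))
  if (mode == "fixed_bin_count") {
    if (bins < 2L) stop("need at least 2 bins")
    lo <- min(vals); hi <- max(vals)
    if (hi == lo) {
      lev <- rep(1L, length(vals))
      ng <- 1L
      mids <- lo
    } else {
      w <- (hi - lo) / bins
      lev <- pmin(as.integer(floor((vals - lo) / w)) + 1L, as.integer(bins))
      ng <- as.integer(bins)
      mids <- lo + (seq_len(ng) - 0.5) * w
    }
  } else {
    if (is.null(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
    lo <- min(vals)
    lev <- as.integer(floor((vals - lo) / bin_width)) + 1L
    ng <- max(lev)
    mids <- lo + (seq_len(ng) - 0.5) * bin_width
  }
  out[mask > 0] <- lev
  attr(out, "n_levels") <- ng
  attr(out, "bin_mid") <- mids
  out
}

#' Shape features of a binary mask
#'
#' Sphericity is `pi^(1/3) (6V)^(2/3) / A` with surface area `A` and volume
#' `V` measured on a triangle mesh: the mask is zero-padded, smoothed with a
#' 3x3x3 mean filter (anti-aliasing, see the methods vignette) and
#' iso-surfaced at 0.5 by marching tetrahedra. Elongation is
#' `sqrt(lambda2 / lambda1)` of the physical voxel-coordinate covariance
#' eigenvalues, major axis length `4 sqrt(lambda1)`, and the maximum 3D
#' diameter the largest pairwise distance between surface voxel centers.
#'
#' @param mask binary 3D array (nonempty).
#' @param spacing voxel size in mm.
#' @return named list: `sphericity`, `elongation`, `major_axis_length`,
#'   `max_3d_diameter`, `mesh_volume`, `mesh_area`.
#' @export
shape_features <- function(mask, spacing = 1) {
  spacing <- rep(spacing, length.out = 3L)
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty")
  d <- dim(mask)

  padded <- array(0, d + 2L)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  field <- mean_filter3d(padded, 3L)
  av <- .mesh_area_volume(field, dim(field), spacing, 0.5)
  if (av[1] == 0) {
    # degenerate region (e.g. a single voxel) vanishes under smoothing:
    # mesh the raw binary field instead
    av <- .mesh_area_volume(padded, dim(padded), spacing, 0.5)
  }
  area <- av[1]; volume <- av[2]
  sphericity <- pi^(1 / 3) * (6 * volume)^(2 / 3) / area

  if (nrow(idx) == 1L) {
    elongation <- 1          # degenerate single-voxel convention
    major <- 0
  } else {
    phys <- sweep(idx, 2, spacing, "*")
    cv <- crossprod(sweep(phys, 2, colMeans(phys))) / nrow(phys)
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev[ev < 0] <- 0
    elongation <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
    major <- 4 * sqrt(ev[1])
  }

  surf <- is_surface_voxel(mask)
  sidx <- which(surf, arr.ind = TRUE)
  maxdiam <- .max_pairwise_dist(sweep(sidx, 2, spacing, "*"))

  list(sphericity = sphericity, elongation = elongation,
       major_axis_length = major, max_3d_diameter = maxdiam,
       mesh_volume = volume, mesh_area = area)
}

# mask voxels with at least one 6-neighbor outside the mask (or on the
# image border)
is_surface_voxel <- function(mask) {
  d <- dim(mask)
  shift <- function(ax, by) {
    out <- array(0, d)
    src <- lapply(d, seq_len); dst <- src
    if (by > 0) { dst[[ax]] <- (1 + by):d[ax]; src[[ax]] <- 1:(d[ax] - by) }
    else { dst[[ax]] <- 1:(d[ax] + by); src[[ax]] <- (1 - by):d[ax] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
    out
  }
  nb <- shift(1, 1) + shift(1, -1) + shift(2, 1) + shift(2, -1) +
        shift(3, 1) + shift(3, -1)
  mask > 0 & nb < 6
}

#' First-order intensity features
#'
#' Fixed documented list computed from the raw in-mask intensities, with
#' entropy and the maximum discretized value computed on a fixed-bin-count
#' histogram. Variance and the higher moments use the population (1/N)
#' convention; skewness/kurtosis of a constant region are 0 by convention
#' and kurtosis is not excess-corrected.
#'
#' @param values numeric vector of in-mask intensities (>= 1 voxel).
#' @param n_bins histogram bins for entropy / maximum-discretized.
#' @return named numeric vector: mean, median, min, max,
#'   maximum_discretized, range, variance, skewness, kurtosis, entropy,
#'   energy, p10, p90, iqr, robust_mad.
#' @export
first_order_features <- function(values, n_bins = 32L) {
  stopifnot(length(values) >= 1L)
  n <- length(values)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 else 0
  if (diff(range(values)) == 0) {
    p <- 1
    max_disc <- values[1]
  } else {
    w <- diff(range(values)) / n_bins
    lev <- pmin(floor((values - min(values)) / w) + 1, n_bins)
    p <- tabulate(lev, n_bins) / n
    p <- p[p > 0]
    max_disc <- min(values) + (max(lev) - 0.5) * w
  }
  q <- quantile(values, c(0.1, 0.25, 0.75, 0.9), names = FALSE, type = 7)
  inner <- values[values >= q[1] & values <= q[4]]
  c(mean = mu, median = median(values), min = min(values), max = max(values),
    maximum_discretized = max_disc, range = diff(range(values)),
    variance = m2, skewness = skew, kurtosis = kurt,
    entropy = -sum(p * log2(p)), energy = sum(values^2),
    p10 = q[1], p90 = q[4], iqr = q[3] - q[2],
    robust_mad = mean(abs(inner - mean(inner))))
}

#' GLCM features: joint average, sum average, cluster shade
#'
#' Symmetric gray-level co-occurrence matrices at distance 1 over the 13
#' unique 3D directions, each normalized; features averaged over directions
#' containing at least one pair.
#'
#' @param disc discretized volume from [discretize_volume()].
#' @param mask binary mask (>= 2 voxels).
#' @return named numeric vector: `joint_average`, `sum_average`,
#'   `cluster_shade`.
#' @export
glcm_features <- function(disc, mask) {
  if (sum(mask > 0) < 2L) stop("GLCM needs at least 2 in-mask voxels")
  ng <- attr(disc, "n_levels")
  counts <- .glcm_counts(disc, dim(disc), ng)
  i_idx <- matrix(seq_len(ng), ng, ng)
  j_idx <- t(i_idx)
  ja <- sa <- cs <- numeric(0)
  for (k in seq_len(dim(counts)[3])) {
    cm <- counts[, , k]
    tot <- sum(cm)
    if (tot == 0) next
    p <- cm / tot
    mu <- sum(i_idx * p)
    ja <- c(ja, mu)
    sa <- c(sa, sum((i_idx + j_idx) * p))
    cs <- c(cs, sum((i_idx + j_idx - 2 * mu)^3 * p))
  }
  c(joint_average = mean(ja), sum_average = mean(sa),
    cluster_shade = mean(cs))
}

#' GLSZM features: small area low gray level emphasis, gray level
#' non-uniformity normalized
#'
#' Zones are 26-connected constant-level regions of the discretized volume.
#'
#' @inheritParams glcm_features
#' @return named numeric vector: `small_area_low_gray_level_emphasis`,
#'   `gray_level_nonuniformity_normalized`.
#' @export
glszm_features <- function(disc, mask) {
  zones <- glszm_zones(disc)
  nz <- nrow(zones)
  salgle <- sum(1 / (zones$level^2 * zones$size^2)) / nz
  glnn <- sum(tapply(rep(1, nz), zones$level, sum)^2) / nz^2
  c(small_area_low_gray_level_emphasis = salgle,
    gray_level_nonuniformity_normalized = glnn)
}

# zone table (level, size) from 26-connected labeling of equal levels
glszm_zones <- function(disc) {
  labels <- .label_components26(disc, dim(disc))
  pos <- labels > 0
  data.frame(level = as.vector(tapply(disc[pos], labels[pos], function(v) v[1])),
             size = as.vector(table(labels[pos])))
}

#' GLRLM feature: high gray level run emphasis
#'
#' Run-length matrices over the 13 unique 3D directions, feature averaged
#' over directions: `HGLRE = sum p(g, r) g^2` with `p` the normalized run
#' matrix.
#'
#' @inheritParams glcm_features
#' @return named numeric vector: `high_gray_level_run_emphasis`.
#' @export
glrlm_features <- function(disc, mask) {
  ng <- attr(disc, "n_levels")
  counts <- .glrlm_counts(disc, dim(disc), ng)
  g2 <- (seq_len(ng))^2
  vals <- numeric(0)
  for (k in seq_len(dim(counts)[3])) {
    rm <- counts[, , k, drop = TRUE]
    rm <- matrix(rm, nrow = ng)
    nr <- sum(rm)
    if (nr == 0) next
    vals <- c(vals, sum(rowSums(rm) * g2) / nr)
  }
  c(high_gray_level_run_emphasis = mean(vals))
}

# sampling directions for the 3D LBP code: octahedron vertices for
# n_points = 6, otherwise a Fibonacci sphere
lbp_sample_points <- function(n_points, radius) {
  if (n_points == 6L) {
    pts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    i <- seq_len(n_points) - 0.5
    phi <- acos(1 - 2 * i / n_points)
    theta <- pi * (1 + sqrt(5)) * i
    pts <- cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
  }
  pts * radius
}

# trilinear interpolation at (x, y, z) voxel coordinates with replicate
# (clamped) edge handling
trilinear <- function(vol, x, y, z) {
  d <- dim(vol)
  cl <- function(v, n) pmin(pmax(v, 1), n)
  x0 <- cl(floor(x), d[1]); x1 <- cl(x0 + 1, d[1])
  y0 <- cl(floor(y), d[2]); y1 <- cl(y0 + 1, d[2])
  z0 <- cl(floor(z), d[3]); z1 <- cl(z0 + 1, d[3])
  fx <- cl(x, d[1]) - x0; fy <- cl(y, d[2]) - y0; fz <- cl(z, d[3]) - z0
  at <- function(i, j, k) vol[cbind(i, j, k)]
  (1 - fz) * ((1 - fy) * ((1 - fx) * at(x0, y0, z0) + fx * at(x1, y0, z0)) +
              fy * ((1 - fx) * at(x0, y1, z0) + fx * at(x1, y1, z0))) +
  fz * ((1 - fy) * ((1 - fx) * at(x0, y0, z1) + fx * at(x1, y0, z1)) +
        fy * ((1 - fx) * at(x0, y1, z1) + fx * at(x1, y1, z1)))
}

#' 3D local binary pattern histogram features
#'
#' For each in-mask voxel, `n_points` neighbors are sampled on a sphere of
#' the given radius (trilinear interpolation, replicate edge handling) and
#' thresholded at the center value; a neighbor equal to the center counts
#' as 1 (tie rule). The normalized histogram of the resulting codes is
#' returned, one feature per code bin.
#'
#' @param vol 3D numeric array.
#' @param mask binary mask.
#' @param n_points neighbors per voxel (code has `2^n_points` bins).
#' @param radius sampling radius in voxels (>= 1).
#' @return named numeric vector `LBP_000 ...` summing to 1.
#' @export
lbp3d_features <- function(vol, mask, n_points = 6L, radius = 1) {
  if (radius < 1) stop("LBP radius must be >= 1 voxel")
  idx <- which(mask > 0, arr.ind = TRUE)
  stopifnot(nrow(idx) >= 1L)
  pts <- lbp_sample_points(n_points, radius)
  center <- vol[mask > 0]
  code <- rep(0, nrow(idx))
  for (k in seq_len(n_points)) {
    nb <- trilinear(vol, idx[, 1] + pts[k, 1], idx[, 2] + pts[k, 2],
                    idx[, 3] + pts[k, 3])
    code <- code + (nb >= center) * 2^(k - 1)
  }
  h <- tabulate(code + 1, nbins = 2^n_points)
  h <- h / sum(h)
  names(h) <- sprintf("LBP_%03d", seq_len(2^n_points) - 1L)
  h
}

#' Drop exactly duplicated feature columns
#'
#' Keeps the first occurrence of each distinct value vector; columns equal
#' only up to floating-point noise are kept (exact-equality rule).
#'
#' @param m numeric matrix with column names.
#' @return matrix without duplicated columns; attribute `dropped` lists the
#'   removed names.
#' @export
dedupe_features <- function(m) {
  dup <- duplicated(t(m))
  out <- m[, !dup, drop = FALSE]
  attr(out, "dropped") <- colnames(m)[dup]
  out
}

#' Extract the radiomics feature vector for one patient
#'
#' Shape features from the GTVp mask plus, for each modality (PET on SUV,
#' CT on raw HU) and each binning setting: first-order, GLCM, GLSZM, GLRLM
#' and LBP features within the GTVp.
#'
#' @param pet,ct 3D arrays (SUV / HU).
#' @param gtvp binary mask.
#' @param spacing voxel size in mm.
#' @param bins vector of fixed-bin-count settings (one block per setting).
#' @param lbp_points,lbp_radius LBP sampling parameters.
#' @return named numeric vector; attribute `provenance` is a data frame
#'   with columns feature, modality, family, discretization.
#' @export
extract_radiomics <- function(pet, ct, gtvp, spacing = 1, bins = 32L,
                              lbp_points = 6L, lbp_radius = 1) {
  sf <- shape_features(gtvp, spacing)
  out <- c(shape_sphericity = sf$sphericity,
           shape_elongation = sf$elongation,
           shape_major_axis_length = sf$major_axis_length,
           shape_max_3d_diameter = sf$max_3d_diameter)
  prov <- data.frame(feature = names(out), modality = "mask",
                     family = "shape", discretization = NA_character_)
  for (mod in c("PET", "CT")) {
    vol <- if (mod == "PET") pet else ct
    fo <- first_order_features(vol[gtvp > 0])
    names(fo) <- paste0(mod, "_fo_", names(fo))
    out <- c(out, fo)
    prov <- rbind(prov, data.frame(feature = names(fo), modality = mod,
                                   family = "firstorder",
                                   discretization = NA_character_))
    lbp <- lbp3d_features(vol, gtvp, lbp_points, lbp_radius)
    names(lbp) <- paste0(mod, "_", names(lbp))
    out <- c(out, lbp)
    prov <- rbind(prov, data.frame(feature = names(lbp), modality = mod,
                                   family = "lbp",
                                   discretization = NA_character_))
    for (b in bins) {
      disc <- discretize_volume(vol, gtvp, bins = b)
      tex <- c(glcm_features(disc, gtvp), glszm_features(disc, gtvp),
               glrlm_features(disc, gtvp))
      fam <- c(rep("glcm", 3L), rep("glszm", 2L), rep("glrlm", 1L))
      names(tex) <- paste0(mod, "_", fam, "_", names(tex), "_b", b)
      out <- c(out, tex)
      prov <- rbind(prov, data.frame(feature = names(tex), modality = mod,
                                     family = fam,
                                     discretization = paste0("fbc", b)))
    }
  }
  attr(out, "provenance") <- prov
  out
}

#' Radiomics feature matrix (D2) for a cohort
#'
#' Applies [extract_radiomics()] per patient and removes exactly duplicated
#' columns.
#'
#' @param cohort a `phantom_cohort` (or list of patient records).
#' @param ... passed to [extract_radiomics()].
#' @return patients x features matrix with patient ids as row names;
#'   attributes `provenance` and `dropped`.
#' @export
radiomics_matrix <- function(cohort, ...) {
  patients <- if (inherits(cohort, "phantom_cohort")) cohort$patients else cohort
  rows <- lapply(patients, function(p)
    extract_radiomics(p$pet, p$ct, p$gtvp_mask, p$spacing[1], ...))
  m <- do.call(rbind, lapply(rows, as.numeric))
  colnames(m) <- names(rows[[1]])
  rownames(m) <- vapply(patients, `[[`, "", "patient_id")
  prov <- attr(rows[[1]], "provenance")
  m <- dedupe_features(m)
  attr(m, "provenance") <- prov[prov$feature %in% colnames(m), ]
  m
}
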