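# VarGrad explainability: gradient saliency under input noise, and the
# quantitative stratification of heatmaps by SUV, HU and tumor/node/other
# location.

#' Gradient saliency map
#'
#' Gradient of the scalar class-1 output with respect to every input
#' voxel/channel (CNN) or feature (FCNN). The default target is the sigmoid
#' probability; `target = "logit"` differentiates the pre-sigmoid output.
#' Non-differentiable models (e.g. the M2 forest) raise an error.
#'
#' @param model fitted model.
#' @param input one input volume `[D, H, W, C]` (CNN), feature row matrix
#'   (FCNN/affine).
#' @param target `"probability"` or `"logit"`.
#' @param ... unused.
#' @return gradient array shaped like `input`.
#' @export
saliency <- function(model, input, target = c("probability", "logit"), ...) {
  UseMethod("saliency")
}

#' @export
saliency.petrad_cnn <- function(model, input,
                                target = c("probability", "logit"), ...) {
  cnn_input_gradient(model, input, match.arg(target))
}

#' @export
saliency.petrad_fcnn <- function(model, input,
                                 target = c("probability", "logit"), ...) {
  fcnn_input_gradient(model, input, match.arg(target))
}

#' @export
saliency.default <- function(model, input, ...) {
  stop("saliency is undefined for models of class ",
       paste(class(model), collapse = "/"),
       " (model must be differentiable; e.g. the M2 forest is not)")
}

#' Affine image model (analytic saliency reference)
#'
#' A linear scoring model `p = bias + sum(w * x)` whose output is used as a
#' probability directly (identity link). Its gradient is the weight volume
#' everywhere, so its VarGrad map is identically zero -- the analytic
#' degenerate case of the method.
#'
#' @param weights array of weights shaped like the input.
#' @param bias scalar offset.
#' @return object of class `petrad_affine`.
#' @export
make_affine_model <- function(weights, bias = 0) {
  structure(list(weights = weights, bias = bias), class = "petrad_affine")
}

#' @export
predict_proba.petrad_affine <- function(model, newdata, ...) {
  sum(model$weights * newdata) + model$bias
}

#' @export
saliency.petrad_affine <- function(model, input, ...) {
  model$weights + 0 * input
}

#' VarGrad heatmap
#'
#' Perturbs the input with Gaussian noise, computes the saliency map, and
#' repeats `n_repeats` times (20 by default); the per-voxel variance over
#' the repeats, normalized by its global maximum, is the heatmap.
#'
#' @param model differentiable fitted model.
#' @param input one input volume `[D, H, W, C]`.
#' @param n_repeats number of noisy repeats (>= 2).
#' @param noise_sd noise standard deviation; default 0.05 x the input's
#'   dynamic range per channel.
#' @param seed RNG seed.
#' @param target saliency target, see [saliency()].
#' @return object of class `vargrad_map`: `heatmap` (nonnegative array in
#'   \[0, 1\], same shape as input), `n_repeats`, `noise_sd`, `raw_max`
#'   (normalization constant).
#' @export
vargrad <- function(model, input, n_repeats = 20L, noise_sd = NULL,
                    seed = NULL, target = "probability") {
  if (n_repeats < 2L) stop("VarGrad needs at least 2 repeats")
  d <- dim(input)
  nc <- d[length(d)]
  if (is.null(noise_sd)) {
    rng <- vapply(seq_len(nc), function(c)
      diff(range(slice_channel(input, c))), numeric(1))
    noise_sd <- 0.05 * pmax(rng, 1e-8)
  }
  noise_sd <- rep(noise_sd, length.out = nc)
  if (any(noise_sd <= 0)) stop("noise_sd must be positive")
  with_seed(seed, {
    maps <- vector("list", n_repeats)
    for (r in seq_len(n_repeats)) {
      noisy <- input
      for (c in seq_len(nc)) {
        sl <- slice_channel(noisy, c)
        sl <- sl + array(rnorm(length(sl), 0, noise_sd[c]), dim(sl))
        noisy <- assign_channel(noisy, c, sl)
      }
      maps[[r]] <- saliency(model, noisy, target = target)
    }
    # shifted two-pass variance: exactly zero for input-independent
    # gradients (all deviations from the first map vanish identically)
    devs <- lapply(maps, function(g) g - maps[[1]])
    dbar <- Reduce(`+`, devs) / n_repeats
    v <- Reduce(`+`, lapply(devs, function(g) (g - dbar)^2)) / n_repeats
    mx <- max(v)
    structure(list(heatmap = if (mx > 0) v / mx else v,
                   n_repeats = as.integer(n_repeats), noise_sd = noise_sd,
                   raw_max = mx),
              class = "vargrad_map")
  })
}

slice_channel <- function(x, c) {
  d <- dim(x)
  if (length(d) == 4L) x[, , , c] else x[, c]
}
assign_channel <- function(x, c, value) {
  if (length(dim(x)) == 4L) x[, , , c] <- value else x[, c] <- value
  x
}

#' Stratify heatmap importance by SUV, HU and region
#'
#' Mean heatmap value within SUV bins, HU bins (edges relative to the CT
#' window center) and the tumor/node/other regions; overlapping masks
#' resolve with tumor precedence. Multi-channel maps are reduced to one
#' spatial map by the across-channel maximum. Empty strata are reported as
#' `NA` (absent), not 0.
#'
#' @param map a [vargrad()] result (or a bare heatmap array).
#' @param pet,ct SUV / HU volumes aligned with the map.
#' @param gtvp,gtvn binary masks (gtvn may be `NULL`).
#' @param suv_bins SUV bin edges (default `c(0, 2, 10, Inf)`).
#' @param hu_bins HU bin edges relative to the window center
#'   (default `c(-Inf, -50, 0, 50, Inf)`).
#' @param hu_center CT window center (default 70 HU).
#' @return object of class `stratified_importance`: data frames `suv`,
#'   `hu`, `region` with stratum, voxel count and mean importance.
#' @export
stratify_importance <- function(map, pet, ct, gtvp, gtvn = NULL,
                                suv_bins = c(0, 2, 10, Inf),
                                hu_bins = c(-Inf, -50, 0, 50, Inf),
                                hu_center = 70) {
  h <- if (inherits(map, "vargrad_map")) map$heatmap else map
  if (length(dim(h)) == 4L) h <- apply(h, 1:3, max)
  stopifnot(identical(dim(h), dim(pet)), identical(dim(h), dim(ct)))
  if (is.null(gtvn)) gtvn <- array(0, dim(pet))

  strat <- function(values, edges, labels) {
    bin <- cut(as.vector(values), edges, labels = labels,
               include.lowest = TRUE, right = FALSE)
    cnt <- tapply(rep(1, length(bin)), bin, sum)
    mn <- tapply(as.vector(h), bin, mean)
    data.frame(stratum = levels(bin), n_voxels = as.integer(ifelse(is.na(cnt), 0L, cnt)),
               mean_importance = as.numeric(mn), row.names = NULL)
  }
  suv_lab <- paste0("SUV[", head_fmt(suv_bins), ")")
  hu_lab <- paste0("HU-center[", head_fmt(hu_bins), ")")
  region <- array("other", dim(pet))
  region[gtvn > 0] <- "node"
  region[gtvp > 0] <- "tumor"         # tumor precedence over node
  reg <- factor(region, levels = c("tumor", "node", "other"))
  reg_cnt <- tapply(rep(1, length(reg)), reg, sum)
  reg_mean <- tapply(as.vector(h), reg, mean)
  structure(list(
    suv = strat(pet, suv_bins, suv_lab),
    hu = strat(ct - hu_center, hu_bins, hu_lab),
    region = data.frame(stratum = levels(reg),
                        n_voxels = as.integer(ifelse(is.na(reg_cnt), 0L, reg_cnt)),
                        mean_importance = as.numeric(reg_mean),
                        row.names = NULL)),
    class = "stratified_importance")
}

head_fmt <- function(edges) {
  paste0(format(edges[-length(edges)], trim = TRUE), ",",
         format(edges[-1], trim = TRUE))
}

#' Render a heatmap overlay on a fused PET/CT slice
#'
#' Produces an RGB raster of one axial slice: grayscale fused PET/CT base,
#' heatmap in red shown only where it exceeds the display threshold, and
#' mask contours (GTVp green, GTVn blue).
#'
#' @param map a [vargrad()] result or heatmap array (normalized).
#' @param pet,ct volumes.
#' @param masks list with `gtvp` and optionally `gtvn`.
#' @param slice axial slice index (third axis); default the GTVp centroid.
#' @param display_threshold show heatmap only above this value
#'   (default 0.25).
#' @param suv_cutoff,wspec preprocessing for the base image.
#' @return `D x H x 3` RGB array in \[0, 1\] (invisible); also plotted if
#'   `plot = TRUE`.
#' @param plot draw the raster on the active graphics device?
#' @export
render_heatmap_overlay <- function(map, pet, ct, masks, slice = NULL,
                                   display_threshold = 0.25,
                                   suv_cutoff = 25, wspec = window_spec(),
                                   plot = FALSE) {
  h <- if (inherits(map, "vargrad_map")) map$heatmap else map
  if (length(dim(h)) == 4L) h <- apply(h, 1:3, max)
  if (is.null(slice)) {
    idx <- which(masks$gtvp > 0, arr.ind = TRUE)
    slice <- round(mean(idx[, 3]))
  }
  base <- 0.5 * clip_scale_pet(pet[, , slice], suv_cutoff) +
          0.5 * window_ct(ct[, , slice], wspec)
  hs <- h[, , slice]
  show <- hs > display_threshold
  rgb <- array(rep(base, 3L), c(dim(base), 3L))
  rgb[, , 1][show] <- pmin(1, base[show] * 0.3 + hs[show])
  rgb[, , 2][show] <- base[show] * 0.3
  rgb[, , 3][show] <- base[show] * 0.3
  gp <- contour_mask(masks$gtvp[, , slice])
  rgb[, , 2][gp] <- 1
  if (!is.null(masks$gtvn)) {
    gn <- contour_mask(masks$gtvn[, , slice])
    rgb[, , 3][gn] <- 1
  }
  if (plot) {
    op <- graphics::par(mar = c(0, 0, 0, 0)); on.exit(graphics::par(op))
    graphics::plot.new()
    graphics::rasterImage(grDevices::as.raster(aperm(rgb, c(2, 1, 3))),
                          0, 0, 1, 1)
  }
  invisible(rgb)
}

# boundary pixels of a 2D binary mask (4-neighborhood)
contour_mask <- function(m) {
  d <- dim(m)
  inner <- m > 0
  nb <- array(0L, d)
  nb[-1, ] <- nb[-1, ] + (m[-d[1], ] > 0)
  nb[-d[1], ] <- nb[-d[1], ] + (m[-1, ] > 0)
  nb[, -1] <- nb[, -1] + (m[, -d[2]] > 0)
  nb[, -d[2]] <- nb[, -d[2]] + (m[, -1] > 0)
  inner & nb < 4L
}
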