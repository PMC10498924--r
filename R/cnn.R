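# M5-M7: a downscaled 3D squeeze-excitation CNN in the EfficientNet mold
# (stem convolution, mobile-inverted-bottleneck blocks with SE, global
# pooling, dropout, sigmoid head). Forward and backward passes are written
# out explicitly on top of the compiled conv3d kernels; the default "tiny"
# profile trains on one CPU for 32^3 inputs.
#
# Volume layout: one sample is a 4D array [D, H, W, C]; a dataset is a 5D
# array [D, H, W, C, N]. Channels follow the study's convention:
# (PET, CT) for M5, + GTVp for M6, + GTVn for M7.

conv_out <- function(n, k = 3L, s = 1L, p = 1L) (n + 2L * p - k) %/% s + 1L

#' CNN architecture specification
#'
#' @param in_channels input channels; 2 (PET+CT, M5), 3 (+GTVp, M6) or
#'   4 (+GTVn, M7).
#' @param width stem output channels (width scaling knob).
#' @param block_channels output channels per mobile-inverted-bottleneck
#'   block (depth scaling knob).
#' @param block_strides stride per block (2 halves the grid).
#' @param expand expansion ratio inside each block.
#' @param se_ratio squeeze-excitation reduction ratio.
#' @param dropout dropout rate on the pooled feature vector.
#' @param loss `"bce"` or `"focal"`.
#' @return object of class `cnn_spec`.
#' @export
cnn_spec <- function(in_channels = 2L, width = 8L,
                     block_channels = c(16L, 16L),
                     block_strides = c(2L, 1L),
                     expand = 2L, se_ratio = 4L, dropout = 0.2,
                     loss = c("bce", "focal")) {
  loss <- match.arg(loss)
  if (!in_channels %in% 2:4)
    stop("in_channels must be 2 (M5), 3 (M6) or 4 (M7)")
  stopifnot(length(block_channels) == length(block_strides))
  structure(list(in_channels = as.integer(in_channels),
                 width = as.integer(width),
                 block_channels = as.integer(block_channels),
                 block_strides = as.integer(block_strides),
                 expand = as.integer(expand), se_ratio = as.integer(se_ratio),
                 dropout = dropout, loss = loss),
            class = "cnn_spec")
}

cnn_init_params <- function(spec) {
  he <- function(fan_in, n) rnorm(n, 0, sqrt(2 / fan_in))
  p <- list()
  k3 <- 27L
  p$stem_w <- array(he(k3 * spec$in_channels,
                       k3 * spec$in_channels * spec$width),
                    c(3L, 3L, 3L, spec$in_channels, spec$width))
  p$stem_b <- rep(0, spec$width)
  cin <- spec$width
  for (i in seq_along(spec$block_channels)) {
    ce <- cin * spec$expand
    r <- max(1L, ce %/% spec$se_ratio)
    cout <- spec$block_channels[i]
    nm <- function(s) paste0("b", i, "_", s)
    p[[nm("we")]] <- matrix(he(cin, cin * ce), cin, ce)
    p[[nm("be")]] <- rep(0, ce)
    p[[nm("wd")]] <- array(he(k3, k3 * ce), c(3L, 3L, 3L, 1L, ce))
    p[[nm("bd")]] <- rep(0, ce)
    p[[nm("se_w1")]] <- matrix(he(ce, ce * r), ce, r)
    p[[nm("se_b1")]] <- rep(0.1, r)    # keep the SE bottleneck live at init
    p[[nm("se_w2")]] <- matrix(he(r, r * ce), r, ce)
    p[[nm("se_b2")]] <- rep(0, ce)
    p[[nm("wp")]] <- matrix(he(ce, ce * cout), ce, cout)
    p[[nm("bp")]] <- rep(0, cout)
    cin <- cout
  }
  p$head_w <- he(cin, cin)
  p$head_b <- 0
  p
}

# forward pass for one sample; returns caches when `keep` for backprop
cnn_forward_one <- function(params, spec, x, keep = FALSE,
                            drop_mask = NULL) {
  cache <- list(x = x)
  d <- dim(x)
  h <- .conv3d_forward(x, d, params$stem_w, dim(params$stem_w),
                       params$stem_b, 2L, 1L, 1L)
  hr <- pmax(h, 0)
  if (keep) { cache$stem_pre <- h }
  cur <- hr
  for (i in seq_along(spec$block_channels)) {
    nm <- function(s) paste0("b", i, "_", s)
    din <- dim(cur)
    nv <- prod(din[1:3])
    M <- matrix(cur, nv, din[4])
    te_pre <- sweep(M %*% params[[nm("we")]], 2, params[[nm("be")]], "+")
    te <- pmax(te_pre, 0)
    ce <- ncol(te)
    te_arr <- array(te, c(din[1:3], ce))
    s <- spec$block_strides[i]
    dpre <- .conv3d_forward(te_arr, dim(te_arr), params[[nm("wd")]],
                            dim(params[[nm("wd")]]), params[[nm("bd")]],
                            s, 1L, ce)
    dr <- pmax(dpre, 0)
    dd <- dim(dpre)
    nv2 <- prod(dd[1:3])
    DrM <- matrix(dr, nv2, ce)
    z <- colMeans(DrM)
    s1_pre <- as.vector(z %*% params[[nm("se_w1")]]) + params[[nm("se_b1")]]
    s1 <- pmax(s1_pre, 0)
    g <- sigmoid(as.vector(s1 %*% params[[nm("se_w2")]]) + params[[nm("se_b2")]])
    Ym <- sweep(DrM, 2, g, "*")
    out <- sweep(Ym %*% params[[nm("wp")]], 2, params[[nm("bp")]], "+")
    resid <- s == 1L && din[4] == ncol(out)
    if (resid) out <- out + matrix(cur, nv, din[4])
    if (keep) {
      cache[[nm("in")]] <- cur; cache[[nm("M")]] <- M
      cache[[nm("te")]] <- te; cache[[nm("dpre")]] <- dpre
      cache[[nm("dr")]] <- DrM; cache[[nm("z")]] <- z
      cache[[nm("s1")]] <- s1; cache[[nm("g")]] <- g
      cache[[nm("Ym")]] <- Ym; cache[[nm("resid")]] <- resid
      cache[[nm("dims")]] <- list(din = din, dd = dd)
    }
    cur <- array(out, c(dd[1:3], ncol(out)))
  }
  dh <- dim(cur)
  v <- colMeans(matrix(cur, prod(dh[1:3]), dh[4]))
  if (!is.null(drop_mask)) v <- v * drop_mask
  logit <- sum(v * params$head_w) + params$head_b
  if (!keep) return(sigmoid(logit))
  cache$hr <- hr
  cache$final <- cur
  cache$v <- v
  cache$drop_mask <- drop_mask
  cache$logit <- logit
  cache$p <- sigmoid(logit)
  cache
}

# backward pass for one sample; dlogit is the scalar loss gradient at the
# logit. Returns parameter gradients and (optionally) the input gradient.
cnn_backward_one <- function(params, spec, cache, dlogit,
                             want_input = FALSE) {
  grads <- list()
  v <- cache$v
  dv <- dlogit * params$head_w
  if (!is.null(cache$drop_mask)) dv <- dv * cache$drop_mask
  grads$head_w <- dlogit * v
  grads$head_b <- dlogit
  dh <- dim(cache$final)
  nv <- prod(dh[1:3])
  dout <- matrix(rep(dv / nv, each = nv), nv, dh[4])

  for (i in rev(seq_along(spec$block_channels))) {
    nm <- function(s) paste0("b", i, "_", s)
    dims <- cache[[nm("dims")]]
    din <- dims$din; dd <- dims$dd
    nv1 <- prod(din[1:3]); nv2 <- prod(dd[1:3])
    ce <- ncol(cache[[nm("te")]])
    dskip <- if (cache[[nm("resid")]]) dout else NULL

    grads[[nm("wp")]] <- crossprod(cache[[nm("Ym")]], dout)
    grads[[nm("bp")]] <- colSums(dout)
    dY <- dout %*% t(params[[nm("wp")]])
    g <- cache[[nm("g")]]
    DrM <- cache[[nm("dr")]]
    ddr <- sweep(dY, 2, g, "*")
    dg <- colSums(dY * DrM)
    du <- dg * g * (1 - g)
    grads[[nm("se_w2")]] <- outer(cache[[nm("s1")]], du)
    grads[[nm("se_b2")]] <- du
    ds1 <- as.vector(params[[nm("se_w2")]] %*% du) * (cache[[nm("s1")]] > 0)
    grads[[nm("se_w1")]] <- outer(cache[[nm("z")]], ds1)
    grads[[nm("se_b1")]] <- ds1
    dz <- as.vector(params[[nm("se_w1")]] %*% ds1)
    ddr <- ddr + matrix(rep(dz / nv2, each = nv2), nv2, ce)
    dd_pre <- ddr * (matrix(cache[[nm("dpre")]], nv2, ce) > 0)
    dd_arr <- array(dd_pre, dd)
    s <- spec$block_strides[i]
    te_arr <- array(cache[[nm("te")]], c(din[1:3], ce))
    wshape <- dim(params[[nm("wd")]])
    wb <- .conv3d_backward_weight(te_arr, dim(te_arr), dd_arr, wshape,
                                  s, 1L, ce)
    grads[[nm("wd")]] <- wb$dw
    grads[[nm("bd")]] <- wb$db
    dte <- .conv3d_backward_input(dd_arr, dim(te_arr), params[[nm("wd")]],
                                  wshape, s, 1L, ce)
    dte_m <- matrix(dte, nv1, ce) * (cache[[nm("te")]] > 0)
    grads[[nm("we")]] <- crossprod(cache[[nm("M")]], dte_m)
    grads[[nm("be")]] <- colSums(dte_m)
    dM <- dte_m %*% t(params[[nm("we")]])
    if (!is.null(dskip)) dM <- dM + dskip
    dout <- dM
  }
  # stem
  hr_dims <- dim(cache$stem_pre)
  dstem <- array(dout, hr_dims) * (cache$stem_pre > 0)
  wb <- .conv3d_backward_weight(cache$x, dim(cache$x), dstem,
                                dim(params$stem_w), 2L, 1L, 1L)
  grads$stem_w <- wb$dw
  grads$stem_b <- wb$db
  dx <- NULL
  if (want_input) {
    dx <- .conv3d_backward_input(dstem, dim(cache$x), params$stem_w,
                                 dim(params$stem_w), 2L, 1L, 1L)
  }
  list(grads = grads, dx = dx)
}

#' Fit the 3D squeeze-excitation CNN (M5-M7)
#'
#' Trains with Adam on mini-batches; inputs must be preprocessed channels
#' in \[0, 1\] (scaled PET, windowed CT, optional binary masks).
#'
#' @param volumes 5D array `[D, H, W, C, N]`.
#' @param y binary outcome of length N.
#' @param spec a [cnn_spec()]; its `in_channels` must match `C`.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size.
#' @param seed RNG seed (init, shuffling, dropout).
#' @param verbose print the running loss once per `verbose` epochs (0 = quiet).
#' @return object of class `petrad_cnn`.
#' @export
fit_cnn <- function(volumes, y, spec = cnn_spec(), epochs = 20L, lr = 1e-3,
                    batch_size = 16L, seed = NULL, verbose = 0L) {
  stopifnot(length(dim(volumes)) == 5L)
  y <- stopifnot_binary(y)
  n <- dim(volumes)[5]
  stopifnot(length(y) == n)
  if (dim(volumes)[4] != spec$in_channels)
    stop(sprintf("input has %d channels but the spec expects %d",
                 dim(volumes)[4], spec$in_channels))
  with_seed(seed, {
    st <- adam_init(cnn_init_params(spec))
    nb <- ncol_head <- length(st$params$head_w)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        acc <- NULL
        for (s in idx) {
          x <- volumes[, , , , s, drop = FALSE]
          dim(x) <- dim(volumes)[1:4]
          dm <- if (spec$dropout > 0)
            (runif(ncol_head) >= spec$dropout) / (1 - spec$dropout) else NULL
          cache <- cnn_forward_one(st$params, spec, x, keep = TRUE,
                                   drop_mask = dm)
          p <- cache$p
          if (!is.finite(p)) stop("divergent CNN loss (non-finite output)")
          eps <- 1e-12
          ep_loss <- ep_loss - (y[s] * log(p + eps) +
                                  (1 - y[s]) * log(1 - p + eps))
          dlogit <- if (spec$loss == "bce") (p - y[s]) / length(idx)
                    else focal_grad(p, y[s]) * length(y[s]) / length(idx)
          bw <- cnn_backward_one(st$params, spec, cache, dlogit)
          acc <- if (is.null(acc)) bw$grads
                 else mapply(`+`, acc, bw$grads, SIMPLIFY = FALSE)
        }
        st <- adam_step(st, acc, lr)
      }
      if (verbose > 0 && ep %% verbose == 0)
        iso_log("epoch %d/%d loss %.4f", ep, epochs, ep_loss / n)
    }
    structure(list(params = st$params, spec = spec), class = "petrad_cnn")
  })
}

#' @export
predict_proba.petrad_cnn <- function(model, newdata, ...) {
  if (length(dim(newdata)) == 4L) {
    dim(newdata) <- c(dim(newdata), 1L)
  }
  n <- dim(newdata)[5]
  vapply(seq_len(n), function(s) {
    x <- newdata[, , , , s, drop = FALSE]
    dim(x) <- dim(newdata)[1:4]
    cnn_forward_one(model$params, model$spec, x)
  }, numeric(1))
}

# gradient of the class-1 probability (or logit) w.r.t. one input volume
cnn_input_gradient <- function(model, x, target = c("probability", "logit")) {
  target <- match.arg(target)
  cache <- cnn_forward_one(model$params, model$spec, x, keep = TRUE)
  dlogit <- if (target == "probability") cache$p * (1 - cache$p) else 1
  bw <- cnn_backward_one(model$params, model$spec, cache, dlogit,
                         want_input = TRUE)
  array(bw$dx, dim(x))
}

#' Stack preprocessed channels for the CNN models
#'
#' Builds the `[D, H, W, C]` channel stack for one patient: clipped/scaled
#' PET, windowed CT, and optionally the GTVp and GTVn masks (M5: neither,
#' M6: GTVp, M7: both).
#'
#' @param patient a `patient_record`.
#' @param channels 2, 3 or 4.
#' @param suv_cutoff SUV cut-off for [clip_scale_pet()].
#' @param wspec CT [window_spec()].
#' @return 4D array.
#' @export
cnn_input_stack <- function(patient, channels = 2L, suv_cutoff = 25,
                            wspec = window_spec()) {
  chans <- list(clip_scale_pet(patient$pet, suv_cutoff),
                window_ct(patient$ct, wspec))
  if (channels >= 3L) chans <- c(chans, list(patient$gtvp_mask))
  if (channels >= 4L) chans <- c(chans, list(patient$gtvn_mask))
  arr <- array(0, c(dim(patient$pet), length(chans)))
  for (i in seq_along(chans)) arr[, , , i] <- chans[[i]]
  arr
}
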