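test_that("saliency of an affine model is its weight volume", {
  set.seed(1)
  w <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  m <- make_affine_model(w, bias = 0.1)
  x <- array(runif(length(w)), dim(w))
  expect_equal(saliency(m, x), w)

  # a model ignoring the CT channel has zero CT-channel gradient
  w2 <- w
  w2[, , , 2] <- 0
  m2 <- make_affine_model(w2)
  g2 <- saliency(m2, x)
  expect_true(all(g2[, , , 2] == 0))
})

test_that("saliency errors on non-differentiable models", {
  xo <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2,
               dimnames = list(NULL, c("a", "b")))
  m2 <- fit_m2_forest(xo, c(0, 1, 1, 0), n_estimators = 5, seed = 1)
  expect_error(saliency(m2, xo), "petrad_m2")
})

test_that("CNN saliency matches finite differences on random voxels", {
  set.seed(2)
  spec <- cnn_spec(in_channels = 2, width = 4, block_channels = 6,
                   block_strides = 2, dropout = 0)
  vols <- array(runif(8^3 * 2 * 6), c(8, 8, 8, 2, 6))
  y <- rep(c(0, 1), 3)
  m <- fit_cnn(vols, y, spec, epochs = 2, seed = 1)
  x <- array(runif(8^3 * 2), c(8, 8, 8, 2))
  g <- saliency(m, x, target = "probability")
  eps <- 1e-4
  for (i in sample(length(x), 5)) {
    x2 <- x
    x2[i] <- x2[i] + eps
    up <- predict_proba(m, x2)
    x2[i] <- x2[i] - 2 * eps
    dn <- predict_proba(m, x2)
    expect_equal(g[i], (up - dn) / (2 * eps), tolerance = 1e-3)
  }
})

test_that("VarGrad: affine models give identically zero maps; defaults and
           determinism hold", {
  set.seed(3)
  w <- array(rnorm(5 * 5 * 5 * 2), c(5, 5, 5, 2))
  m <- make_affine_model(w)
  x <- array(runif(length(w)), dim(w))
  vg <- vargrad(m, x, seed = 1)
  expect_equal(vg$n_repeats, 20L)                  # protocol default
  expect_true(all(vg$heatmap == 0))                # exact analytic limit

  spec <- cnn_spec(in_channels = 2, width = 4, block_channels = 6,
                   block_strides = 2, dropout = 0)
  vols <- array(runif(8^3 * 2 * 4), c(8, 8, 8, 2, 4))
  cm <- fit_cnn(vols, c(0, 1, 0, 1), spec, epochs = 2, seed = 2)
  xc <- array(runif(8^3 * 2), c(8, 8, 8, 2))
  v1 <- vargrad(cm, xc, n_repeats = 5, seed = 7)
  v2 <- vargrad(cm, xc, n_repeats = 5, seed = 7)
  expect_identical(v1$heatmap, v2$heatmap)
  expect_true(all(v1$heatmap >= 0))
  expect_equal(max(v1$heatmap), 1)
  expect_error(vargrad(cm, xc, n_repeats = 1), "repeats")
  expect_error(vargrad(cm, xc, noise_sd = 0), "noise_sd")
})

test_that("stratified importance equals masked means and flags empty strata", {
  d <- c(10, 10, 10)
  gtvp <- array(0, d); gtvp[3:5, 3:5, 3:5] <- 1
  gtvn <- array(0, d); gtvn[7:8, 7:8, 7:8] <- 1
  pet <- array(1, d); pet[gtvp > 0] <- 12; pet[gtvn > 0] <- 5
  ct <- array(45, d)

  h <- array(0, d); h[gtvp > 0] <- 1
  st <- stratify_importance(h, pet, ct, gtvp, gtvn)
  reg <- st$region
  expect_equal(reg$mean_importance[reg$stratum == "tumor"], 1)
  expect_equal(reg$mean_importance[reg$stratum == "node"], 0)
  expect_equal(reg$mean_importance[reg$stratum == "other"], 0)

  hu <- array(0.4, d)
  st2 <- stratify_importance(hu, pet, ct, gtvp, gtvn)
  nonempty <- st2$suv$n_voxels > 0
  expect_true(all(abs(st2$suv$mean_importance[nonempty] - 0.4) < 1e-12))
  expect_true(all(is.na(st2$suv$mean_importance[!nonempty])))

  set.seed(4)
  hr <- array(runif(prod(d)), d)
  st3 <- stratify_importance(hr, pet, ct, gtvp, gtvn,
                             suv_bins = c(0, 2, 10, Inf))
  expect_equal(st3$region$mean_importance[1], mean(hr[gtvp > 0]))
  expect_equal(st3$region$mean_importance[2],
               mean(hr[gtvn > 0 & gtvp == 0]))
  expect_equal(st3$suv$mean_importance[3], mean(hr[pet >= 10]))
  # strata partition the volume
  expect_equal(sum(st3$suv$n_voxels), prod(d))
  expect_equal(sum(st3$region$n_voxels), prod(d))

  # tumor precedence for overlapping masks
  st4 <- stratify_importance(h, pet, ct, gtvp, gtvp)
  expect_equal(st4$region$n_voxels[st4$region$stratum == "node"], 0L)
})

test_that("heatmap overlay honours the display threshold", {
  d <- c(12, 12, 12)
  gtvp <- array(0, d); gtvp[5:8, 5:8, 5:8] <- 1
  pet <- array(2, d); ct <- array(45, d)
  h <- array(0.6, d)
  base <- render_heatmap_overlay(array(0, d), pet, ct, list(gtvp = gtvp),
                                 slice = 6, display_threshold = 0)
  full <- render_heatmap_overlay(h, pet, ct, list(gtvp = gtvp), slice = 6,
                                 display_threshold = 0.25)
  none <- render_heatmap_overlay(h, pet, ct, list(gtvp = gtvp), slice = 6,
                                 display_threshold = 1)
  expect_equal(dim(full), c(12, 12, 3))
  expect_identical(none, base)          # everything below threshold: base image
  expect_gt(mean(full[, , 1]), mean(none[, , 1]))   # red channel lit
  expect_true(all(full >= 0 & full <= 1))
})
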