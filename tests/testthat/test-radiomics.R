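make_disc <- function(levels, ng) {
  attr(levels, "n_levels") <- ng
  levels
}

test_that("shape features hit the analytic ball and ellipsoid values", {
  ball <- generate_tumor_mask(c(15, 15, 15), c(40, 40, 40))$mask
  sf <- shape_features(ball)
  expect_gte(sf$sphericity, 0.97)
  expect_lte(sf$sphericity, 1.01)
  expect_gte(sf$elongation, 0.98)
  expect_lte(sf$elongation, 1.0)
  expect_lt(abs(sf$max_3d_diameter - 30), sqrt(3))

  ell <- generate_tumor_mask(c(20, 10, 10), c(48, 48, 48))$mask
  expect_lt(abs(shape_features(ell)$elongation - 0.5), 0.03)

  single <- array(0, c(5, 5, 5)); single[3, 3, 3] <- 1
  sf1 <- shape_features(single)
  expect_equal(sf1$elongation, 1)
  expect_equal(sf1$max_3d_diameter, 0)
  expect_gt(sf1$mesh_area, 0)
})

test_that("shape features are invariant to translation and axis permutation", {
  base <- generate_tumor_mask(c(8, 6, 5), c(30, 30, 30))$mask
  sf <- shape_features(base)
  shifted <- array(0, c(30, 30, 30))
  shifted[4:30, 1:27, 2:30] <- base[1:27, 4:30, 1:29]
  sf2 <- shape_features(shifted)
  for (f in c("sphericity", "elongation", "major_axis_length",
              "max_3d_diameter")) {
    expect_equal(sf2[[f]], sf[[f]], tolerance = 1e-9)
  }
  sf3 <- shape_features(aperm(base, c(3, 1, 2)))
  for (f in c("sphericity", "elongation", "major_axis_length",
              "max_3d_diameter")) {
    expect_equal(sf3[[f]], sf[[f]], tolerance = 1e-9)
  }
})

test_that("first-order features match direct formulas", {
  fo <- first_order_features(rep(7, 20))
  expect_equal(unname(fo[c("mean", "variance", "entropy")]), c(7, 0, 0))
  expect_equal(unname(fo["skewness"]), 0)

  fo2 <- first_order_features(c(1, 2, 3, 4))
  expect_equal(unname(fo2["mean"]), 2.5)
  expect_equal(unname(fo2["range"]), 3)
  expect_equal(unname(fo2["energy"]), 30)

  set.seed(7)
  v <- rnorm(500)
  fo3 <- first_order_features(v)
  mu <- mean(v); m2 <- mean((v - mu)^2)
  expect_equal(unname(fo3["skewness"]), mean((v - mu)^3) / m2^1.5)
  expect_equal(unname(fo3["kurtosis"]), mean((v - mu)^4) / m2^2)
  expect_equal(unname(fo3["p10"]), unname(quantile(v, 0.1)))
})

test_that("GLCM features: degenerate forms, hand-counted grid, identities", {
  # constant region at one level
  lv <- array(NA_integer_, c(3, 3, 3)); lv[1:2, 1:2, 1:2] <- 2L
  msk <- array(0, c(3, 3, 3)); msk[1:2, 1:2, 1:2] <- 1
  g <- glcm_features(make_disc(lv, 4L), msk)
  expect_equal(unname(g["joint_average"]), 2)
  expect_equal(unname(g["sum_average"]), 4)
  expect_equal(unname(g["cluster_shade"]), 0)

  # hand-built 3x3x1 two-level grid vs the pair-counting oracle
  lv2 <- array(c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L), c(3, 3, 1))
  msk2 <- array(1, c(3, 3, 1))
  disc2 <- make_disc(lv2, 2L)
  counts <- petrad:::.glcm_counts(disc2, dim(disc2), 2L)
  expect_equal(unclass(counts), unclass(oracle_glcm(lv2, 2L)),
               ignore_attr = TRUE)
  g2 <- glcm_features(disc2, msk2)
  expect_equal(unname(g2["sum_average"]), 2 * unname(g2["joint_average"]))
  expect_error(glcm_features(make_disc(lv, 4L), array(0, c(3, 3, 3))),
               "2 in-mask")
})

test_that("GLSZM features: constant region, checkerboard, zone oracle", {
  lv <- array(NA_integer_, c(4, 3, 2)); lv[1:3, 1:2, 1] <- 3L
  msk <- (!is.na(lv)) * 1
  z <- glszm_features(make_disc(lv, 4L), msk)
  expect_equal(unname(z["gray_level_nonuniformity_normalized"]), 1)
  expect_equal(unname(z["small_area_low_gray_level_emphasis"]),
               1 / (9 * 36))

  # 2D checkerboard: all zones size 1 (diagonal adjacency joins same-level
  # cells in 3D, so use a 1-thick slab with 4-phase labels to avoid it)
  ck <- array(NA_integer_, c(4, 4, 1))
  for (i in 1:4) for (j in 1:4) ck[i, j, 1] <- ((i + j) %% 2L) + 1L
  zz <- petrad:::glszm_zones(make_disc(ck, 2L))
  orz <- oracle_zones(ck)
  expect_equal(nrow(zz), nrow(orz))
  expect_equal(sort(zz$size), sort(orz[, "size"]))
  expect_equal(sum(zz$size), sum(!is.na(ck)))
})

test_that("GLRLM features: single run, alternating runs, g^2 weighting", {
  line <- array(3L, c(1, 1, 4))
  d1 <- make_disc(line, 3L)
  # a 1x1x4 line: direction (0,0,1) has one run of length 4 -> HGLRE 9;
  # the other 12 directions see four runs of length 1 -> HGLRE 9 as well
  expect_equal(unname(glrlm_features(d1, array(1, c(1, 1, 4)))), 9)

  alt <- array(c(1L, 2L, 1L, 2L, 1L), c(5, 1, 1))
  d2 <- make_disc(alt, 2L)
  # all runs length 1; per direction HGLRE = weighted mean of g^2
  expect_equal(unname(glrlm_features(d2, array(1, c(5, 1, 1)))),
               oracle_hglre(alt))
  # permuting gray-level labels rescales by the g^2 weighting
  alt_perm <- array(c(2L, 1L, 2L, 1L, 2L), c(5, 1, 1))
  expect_equal(unname(glrlm_features(make_disc(alt_perm, 2L),
                                     array(1, c(5, 1, 1)))),
               oracle_hglre(alt_perm))
})

test_that("texture features equal brute-force enumeration on random grids", {
  for (s in 1:25) {
    rg <- random_grid(s)
    disc <- make_disc(rg$levels, rg$ng)
    counts <- petrad:::.glcm_counts(disc, dim(disc), rg$ng)
    expect_equal(unclass(counts), unclass(oracle_glcm(rg$levels, rg$ng)),
                 ignore_attr = TRUE)
    zz <- petrad:::glszm_zones(disc)
    orz <- oracle_zones(rg$levels)
    expect_equal(sort(zz$size), sort(orz[, "size"]))
    expect_equal(unname(glrlm_features(disc, rg$mask)),
                 oracle_hglre(rg$levels))
  }
})

test_that("LBP codes follow the tie rule and match the per-voxel oracle", {
  cst <- array(5, c(4, 4, 4))
  msk <- array(1, c(4, 4, 4))
  h <- lbp3d_features(cst, msk)
  expect_equal(sum(h), 1)
  expect_equal(unname(h["LBP_063"]), 1)   # ties count as 1 -> all-ones code

  set.seed(9)
  vol <- array(cumsum(runif(5^3))^0.7, c(5, 5, 5))  # monotone-ish ramp
  msk2 <- array(rbinom(5^3, 1, 0.7), c(5, 5, 5))
  msk2[1] <- 1
  h2 <- lbp3d_features(vol, msk2, n_points = 6L, radius = 1)
  expect_equal(sum(h2), 1)
  pts <- petrad:::lbp_sample_points(6L, 1)
  codes <- oracle_lbp_codes(vol, msk2, pts)
  href <- tabulate(codes + 1, 64) / length(codes)
  expect_equal(unname(h2), href)
  expect_error(lbp3d_features(vol, msk2, radius = 0.5), "radius")
})

test_that("discretization and deduplication behave as documented", {
  set.seed(1)
  vol <- array(runif(27), c(3, 3, 3))
  msk <- array(1, c(3, 3, 3))
  disc <- discretize_volume(vol, msk, bins = 4)
  expect_true(all(disc[msk > 0] %in% 1:4))
  expect_equal(attr(disc, "n_levels"), 4L)
  cst <- discretize_volume(array(3, c(2, 2, 2)), array(1, c(2, 2, 2)))
  expect_true(all(cst[] == 1L))

  m <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3 + 1e-12))
  dd <- dedupe_features(m)
  expect_equal(colnames(dd), c("a", "c"))
  expect_equal(attr(dd, "dropped"), "b")
  m2 <- cbind(x = 1:3, y = 4:6)
  expect_equal(dim(dedupe_features(m2)), dim(m2))
})

test_that("extract_radiomics returns a named, deterministic feature vector", {
  coh <- generate_cohort(phantom_spec(n_patients = 2,
                                      grid_shape = c(28, 28, 28), seed = 2))
  p <- coh$patients[[1]]
  f1 <- extract_radiomics(p$pet, p$ct, p$gtvp_mask, 1)
  f2 <- extract_radiomics(p$pet, p$ct, p$gtvp_mask, 1)
  expect_identical(f1, f2)
  expect_true(all(c("shape_sphericity", "PET_glcm_cluster_shade_b32",
                    "CT_glszm_small_area_low_gray_level_emphasis_b32",
                    "PET_glrlm_high_gray_level_run_emphasis_b32",
                    "PET_LBP_000", "CT_fo_maximum_discretized") %in%
                    names(f1)))
  prov <- attr(f1, "provenance")
  expect_equal(nrow(prov), length(f1))
  m <- radiomics_matrix(coh)
  expect_equal(nrow(m), 2L)
  expect_false(any(duplicated(t(m))))
})
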