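test_that("CT windowing maps the 70/200 window onto [0,1]", {
  ws <- window_spec()
  expect_equal(window_ct(array(-30, c(1, 1, 1)), ws)[1], 0)
  expect_equal(window_ct(array(170, c(1, 1, 1)), ws)[1], 1)
  expect_equal(window_ct(array(70, c(1, 1, 1)), ws)[1], 0.5)
  expect_equal(window_ct(array(1000, c(1, 1, 1)), ws)[1], 1)
  ct <- array(70, c(4, 4, 4))
  expect_true(all(window_ct(ct, ws) == 0.5))
  expect_error(window_spec(width = 0), "width")
})

test_that("PET clip/scale is exact at the cutoff and monotone", {
  expect_equal(clip_scale_pet(array(c(25, 50, 12.5, 0), c(4, 1, 1)))[, 1, 1],
               c(1, 1, 0.5, 0))
  set.seed(1)
  v1 <- array(runif(64, 0, 40), c(4, 4, 4))
  v2 <- v1 + runif(64, 0, 5)
  expect_true(all(clip_scale_pet(v2) >= clip_scale_pet(v1)))
  expect_error(clip_scale_pet(v1, cutoff = 0), "cutoff")
})

test_that("window/clip are idempotent once in processed units", {
  set.seed(2)
  pet <- array(runif(27, 0, 40), c(3, 3, 3))
  p1 <- clip_scale_pet(pet)
  expect_equal(clip_scale_pet(p1 * 25) / 1, p1)   # re-expressed in SUV
  ct <- array(runif(27, -100, 300), c(3, 3, 3))
  c1 <- window_ct(ct)
  expect_equal(window_ct(c1 * 200 + (70 - 100)), c1)
})

test_that("SUV cutoff derivation follows the documented percentile rule", {
  expect_equal(derive_suv_cutoff(1:20), unname(quantile(1:20, 0.95)))
  expect_equal(derive_suv_cutoff(rep(12, 5)), 12)
  set.seed(3)
  v <- runif(50, 5, 40)
  expect_lte(derive_suv_cutoff(v), max(v))
  expect_error(derive_suv_cutoff(3), "two patients")
})

test_that("VOI cropping is identity at full extent and keeps the GTVp", {
  msk <- generate_tumor_mask(c(6, 6, 6), c(24, 24, 24))$mask
  pet <- array(1, c(24, 24, 24))
  out <- crop_voi(list(pet = pet), list(gtvp = msk), voi_mm = c(24, 24, 24))
  expect_identical(out$volumes$pet, pet)
  expect_identical(out$masks$gtvp, msk)

  out2 <- crop_voi(list(pet = pet), list(gtvp = msk), voi_mm = c(16, 12, 20))
  expect_equal(dim(out2$volumes$pet), c(16L, 12L, 20L))
  expect_gt(sum(out2$masks$gtvp), 0)
  # GTVp centroid stays inside the VOI by the placement rule
  ctr <- colMeans(which(out2$masks$gtvp > 0, arr.ind = TRUE))
  expect_true(all(ctr >= 1 & ctr <= c(16, 12, 20)))
})

test_that("the default VOI crops a 300 mm grid to 191 x 265 x 173 voxels", {
  d <- c(300L, 300L, 300L)
  pet <- array(0, d)
  msk <- array(0, d)
  msk[140:160, 140:160, 140:160] <- 1
  out <- crop_voi(list(pet = pet), list(gtvp = msk))
  expect_equal(dim(out$volumes$pet), c(191L, 265L, 173L))
  expect_equal(sum(out$masks$gtvp), sum(msk))
})

test_that("SUV peak matches uniform and single-voxel closed forms", {
  msk <- generate_tumor_mask(c(12, 12, 12), c(32, 32, 32))$mask
  pet <- array(0.5, c(32, 32, 32))
  pet[msk > 0] <- 10
  # GTVp much larger than the sphere: interior spheres are all-tumor
  expect_equal(suv_peak(pet, msk), 10)

  single <- array(0, c(15, 15, 15))
  single[8, 8, 8] <- 1
  pet2 <- array(2, c(15, 15, 15))
  off <- petrad:::sphere_offsets(c(1, 1, 1), (3000 / (4 * pi))^(1 / 3))
  expect_equal(suv_peak(pet2, single), 2)
  expect_error(suv_peak(pet2, array(0, c(15, 15, 15))), "empty")
})

test_that("SUV peak equals the brute-force sphere search on random phantoms", {
  for (s in 1:5) {
    set.seed(s)
    d <- c(14, 12, 13)
    pet <- array(runif(prod(d), 0, 20), d)
    msk <- array(0, d)
    msk[5:9, 4:8, 5:9] <- 1
    expect_equal(suv_peak(pet, msk), oracle_suv_peak(pet, msk),
                 tolerance = 1e-12)
  }
})

test_that("SUV peak, MTV and TLG are axis-permutation invariant", {
  set.seed(4)
  d <- c(12, 12, 12)
  pet <- array(runif(prod(d), 0, 15), d)
  msk <- array(0, d)
  msk[4:8, 5:9, 3:7] <- 1
  sp <- suv_peak(pet, msk)
  mt <- mtv(pet, msk, sp)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    pp <- aperm(pet, perm)
    mm <- aperm(msk, perm)
    expect_equal(suv_peak(pp, mm), sp, tolerance = 1e-12)
    expect_equal(mtv(pp, mm, sp), mt)
  }
})

test_that("MTV thresholds at half the SUV peak and TLG multiplies", {
  msk <- array(0, c(25, 25, 25))
  msk[1:20, 1:25, 1:10] <- 1             # 5000 voxels
  pet <- array(0, c(25, 25, 25))
  pet[msk > 0] <- 10
  expect_equal(mtv(pet, msk, 10), 5)
  half <- pet
  ix <- which(msk > 0)
  half[ix[1:2500]] <- 2
  expect_equal(mtv(half, msk, 10), 2.5)
  # brute-force voxel count oracle on a random phantom
  set.seed(5)
  pet2 <- array(runif(25^3, 0, 12), c(25, 25, 25))
  sp <- 9
  expect_equal(mtv(pet2, msk, sp),
               sum(pet2[msk > 0] >= 4.5) / 1000)
  expect_equal(tlg(5, 10), 50)
  expect_equal(tlg(0, 7), 0)
})

test_that("pet_params ties the pieces together on a uniform phantom", {
  msk <- generate_tumor_mask(c(10, 10, 10), c(28, 28, 28))$mask
  pet <- array(0, c(28, 28, 28))
  pet[msk > 0] <- 6
  pp <- pet_params(pet, msk)
  expect_equal(pp$suv_mean, 6)
  expect_equal(pp$suv_max, 6)
  expect_equal(pp$mtv, sum(msk) / 1000)
  expect_equal(pp$tlg, pp$mtv * 6)
  expect_lte(pp$suv_peak, pp$suv_max)
})
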