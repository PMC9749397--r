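# Normalization and grid-standardization operators.

test_that("mask dilation is exact Euclidean dilation in millimetres", {
  m <- newVolume(array(0, c(24, 24, 24)))
  m[12, 12, 12] <- 1
  expect_identical(dilateMask(m, 0), newVolume((m > 0) * 1))
  d10 <- dilateMask(m, 10)
  # lattice oracle: integer offsets with ||v|| <= 10
  offs <- as.matrix(expand.grid(-10:10, -10:10, -10:10))
  nBall <- sum(rowSums(offs^2) <= 100)
  expect_equal(sum(d10), nBall)
  # 2 mm spacing: 10 mm equals a 5-voxel ball
  m2 <- newVolume(array(0, c(16, 16, 16)), spacing = c(2, 2, 2))
  m2[8, 8, 8] <- 1
  offs5 <- as.matrix(expand.grid(-5:5, -5:5, -5:5))
  expect_equal(sum(dilateMask(m2, 10)), sum(rowSums(offs5^2) <= 25))
  expect_error(dilateMask(newVolume(array(0, c(4, 4, 4))), 2), "empty")
})

test_that("dilation matches brute-force distance thresholding", {
  set.seed(42)
  for (i in 1:3) {
    m <- newVolume(array(runif(16^3) < 0.03, c(16, 16, 16)) * 1)
    d2 <- bruteDistSq(m)
    for (r in c(2.5, 4)) {
      expect_identical(as.vector(dilateMask(m, r)),
                       as.vector((d2 <= r^2) * 1))
    }
  }
})

test_that("MRI z-normalization uses only tissue voxels (population SD)", {
  g <- array(0, c(4, 4, 4))
  mri <- array(0, c(4, 4, 4))
  g[1:4, 1, 1] <- 1
  mri[1:4, 1, 1] <- 1:4
  wm <- array(0, c(4, 4, 4))
  dil <- array(1, c(4, 4, 4))
  z <- znormalizeMri(newVolume(mri), g, wm, dil)
  expect_equal(z[1:4, 1, 1],
               c(-1.3416408, -0.4472136, 0.4472136, 1.3416408),
               tolerance = 1e-6)
  # sentinel outside the dilated mask, exactly
  dil2 <- array(0, c(4, 4, 4))
  dil2[1:4, 1, 1] <- 1
  z2 <- znormalizeMri(newVolume(mri), g, wm, dil2, sentinel = -7)
  expect_true(all(z2[dil2 == 0] == -7))
  # degenerate cases
  mriC <- array(5, c(4, 4, 4))
  expect_error(znormalizeMri(newVolume(mriC), g, wm, dil), "degenerate")
  expect_error(znormalizeMri(newVolume(mri), array(0, c(4, 4, 4)), wm, dil),
               "matter")
})

test_that("z-normalized tissue voxels have mean 0 and SD 1", {
  ns <- fixtureNormalized("noisy64")
  tiss <- (ns@gm + ns@wm) > 0.5
  v <- ns@mriZ[tiss]
  expect_lt(abs(mean(v)), 1e-9)
  expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-9)
})

test_that("PET normalization divides by the top-2% GM/WM mean", {
  g <- array(0, c(5, 5, 5))
  pet <- array(0, c(5, 5, 5))
  g[1:100] <- 1
  pet[1:100] <- 1:100
  pet[101] <- 199      # outside GM: not part of the constant
  out <- normalizePet(newVolume(pet), g, array(0, c(5, 5, 5)),
                      blurFwhmMm = 0)
  expect_equal(out$constant, 99.5)
  expect_equal(out$pet[101], 2.0)
  # constant PET: c = k, output identically one on the support
  petC <- array(7, c(5, 5, 5))
  outC <- normalizePet(newVolume(petC), g, array(0, c(5, 5, 5)),
                       blurFwhmMm = 0)
  expect_equal(outC$constant, 7)
  expect_true(all(outC$pet == 1))
  # scale equivariance
  out2 <- normalizePet(newVolume(2 * pet), g, array(0, c(5, 5, 5)),
                       blurFwhmMm = 0)
  expect_equal(out2$constant, 2 * out$constant)
  expect_equal(as.vector(out2$pet), as.vector(out$pet))
  expect_error(normalizePet(newVolume(array(0, c(5, 5, 5))), g,
                            array(0, c(5, 5, 5))), "constant|positive")
})

test_that("recomputing the PET constant on normalized output gives 1", {
  ns <- fixtureNormalized("noisy64")
  rn <- normalizePet(newVolume(ns@petN, ns@spacing, ns@affine), ns@gm,
                     ns@wm)
  expect_lt(abs(rn$constant - 1), 1e-9)
})

test_that("crop/pad centres the volume and preserves world coordinates", {
  v <- newVolume(array(rnorm(10 * 12 * 9), c(10, 12, 9)))
  # axis 2 crops 12 -> 10 removing one low / one high slab; axis 3 pads
  # 9 -> 10 with the extra slab on the high-index side
  out10 <- cropPadToCube(v, 10)
  expect_equal(as.vector(out10[, , 1:9]), as.vector(v[, 2:11, ]))
  expect_true(all(out10[, , 10] == 0))
  # identity when already cubic
  c16 <- cropPadToCube(newVolume(array(1:64, c(4, 4, 4))), 4)
  expect_equal(as.vector(c16), as.numeric(1:64))
  # the standard-space case: 197 x 233 x 189 -> 192^3
  big <- newVolume(array(0, c(197, 233, 189)))
  big[3, 21, 1] <- 5   # first retained voxel given the centering rule
  out <- cropPadToCube(big, 192)
  expect_identical(dim(out), rep(192L, 3))
  expect_equal(out[1, 1, 2], 5)
  af <- voxelAffine(out)
  # world position of output voxel (1,1,2) equals input voxel (3,21,1)
  expect_equal(as.vector(af %*% c(0, 0, 1, 1))[1:3], c(2, 20, 0))
  # round trip: pad then crop back recovers the original
  small <- newVolume(array(rnorm(6^3), c(6, 6, 6)))
  rt <- cropPadToCube(cropPadToCube(small, 10, fill = -1), 6)
  expect_equal(as.vector(rt), as.vector(small))
})

test_that("Gaussian blur has the right width and preserves constants", {
  v <- newVolume(array(0, c(33, 33, 33)))
  v[17, 17, 17] <- 1
  fwhm <- 6
  b <- gaussianBlur(v, fwhm)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  prof <- apply(b, 1, sum)
  m2 <- sum(prof * ((1:33) - 17)^2) / sum(prof)
  expect_equal(m2, sigma^2, tolerance = 0.02 * sigma^2)
  expect_identical(gaussianBlur(v, 0), v)
  vc <- newVolume(array(3.5, c(9, 9, 9)))
  expect_equal(as.vector(gaussianBlur(vc, 4)), rep(3.5, 9^3))
  # anisotropic spacing is honoured (sigma in voxels differs per axis)
  va <- newVolume(array(0, c(21, 21, 21)), spacing = c(1, 2, 1))
  va[11, 11, 11] <- 1
  ba <- gaussianBlur(va, 6)
  sx <- sum(apply(ba, 1, sum) * ((1:21) - 11)^2)
  sy <- sum(apply(ba, 2, sum) * ((1:21) - 11)^2)
  expect_gt(sx / sy, 2)   # narrower in voxel units along the coarse axis
  expect_identical(voxelSpacing(ba), c(1, 2, 1))
})
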