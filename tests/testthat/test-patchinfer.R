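# Patch tiling, fusion weights, weighted overlap blending and whole-volume
# synthesis plumbing.

test_that("patch positions give stride-1 full coverage", {
  expect_identical(patchPositions(32, 32), 1L)
  expect_identical(patchPositions(34, 32), 1:3)
  pos <- patchPositions(192, 32)
  expect_length(pos, 161)
  covered <- rep(FALSE, 192)
  for (p in pos) covered[p:(p + 31)] <- TRUE
  expect_true(all(covered))
  # the edge convention that trades one uncovered slice for a round count
  expect_length(patchPositions(192, 32, dropLast = TRUE), 160)
  expect_error(patchPositions(16, 32), "width")
})

test_that("triangular fusion profile is positive, symmetric, centre-peaked", {
  expect_equal(fusionWeightProfile(1), 1)
  w4 <- fusionWeightProfile(4)
  expect_equal(w4, c(1, 2, 2, 1))
  for (w in c(2, 5, 8, 32)) {
    prof <- fusionWeightProfile(w)
    expect_true(all(prof > 0))
    expect_equal(prof, rev(prof))
    expect_equal(prof[1], prof[w])
    expect_equal(which.min(prof), 1L)
    half <- prof[seq_len(ceiling(w / 2))]
    expect_true(all(diff(half) > 0) || w <= 2)
  }
  expect_equal(fusionWeightProfile(5, "uniform"), rep(1, 5))
})

test_that("fusion is a weighted per-voxel average", {
  set.seed(30)
  # a single covering patch passes through unchanged
  p <- array(rnorm(4 * 3 * 3), c(4, 3, 3))
  expect_equal(fusePatches(list(p), 1L, fusionWeightProfile(4), 4), p)
  # constant patches fuse to the constant
  S <- 10
  pos <- patchPositions(S, 4)
  patches <- lapply(pos, function(i) array(2.5, c(4, 3, 3)))
  expect_equal(fusePatches(patches, pos, fusionWeightProfile(4), S),
               array(2.5, c(S, 3, 3)))
  # random patches match the brute-force oracle
  S <- 12
  pos <- patchPositions(S, 4)
  patches <- lapply(pos, function(i) array(rnorm(4 * 2 * 2), c(4, 2, 2)))
  prof <- fusionWeightProfile(4)
  expect_equal(max(abs(fusePatches(patches, pos, prof, S) -
                         bruteFuse(patches, pos, prof, S))), 0,
               tolerance = 1e-12)
  # order invariance
  ord <- sample(seq_along(pos))
  expect_equal(fusePatches(patches[ord], pos[ord], prof, S),
               fusePatches(patches, pos, prof, S))
  # uniform weights reduce to the plain mean of covering patches
  expect_equal(fusePatches(patches, pos, rep(1, 4), S),
               bruteFuse(patches, pos, rep(1, 4), S))
  expect_error(fusePatches(patches[-1], pos, prof, S), "one patch")
  expect_error(fusePatches(patches[1], pos[1], prof, 40), "uncovered")
})

test_that("extract-then-fuse reproduces the volume for any profile", {
  set.seed(31)
  for (i in 1:5) {
    S <- sample(8:40, 1)
    w <- sample(2:min(S, 16), 1)
    vol <- array(rnorm(S * 5 * 4), c(S, 5, 4))
    pos <- patchPositions(S, w)
    patches <- lapply(pos, function(p) vol[p:(p + w - 1), , , drop = FALSE])
    for (shape in c("triangular", "gaussian", "uniform")) {
      fused <- fusePatches(patches, pos, fusionWeightProfile(w, shape), S)
      expect_lt(max(abs(fused - vol)), 1e-12)
    }
  }
})

test_that("volume synthesis stitches generator outputs correctly", {
  ns <- fixtureNormalized("noisy64")
  mz <- newVolume(ns@mriZ, ns@spacing, ns@affine)
  # identity stub: the sbPET equals the masked, clamped normalized MRI
  idStub <- list(sketcher = function(p) p)
  sb <- synthesizeVolume(mz, ns@mask, idStub, patchWidth = 32)
  expect_equal(as.vector(sb), as.vector(pmax(ns@mriZ, 0) * ns@mask),
               tolerance = 1e-12)
  # constant stub: one inside the mask, zero outside
  oneStub <- list(sketcher = function(p) array(1, dim = dim(p)),
                  refiner = function(mri, sk) sk)
  sb1 <- synthesizeVolume(mz, ns@mask, oneStub, patchWidth = 32)
  expect_true(all(sb1[ns@mask > 0] == 1))
  expect_true(all(sb1[ns@mask == 0] == 0))
  # an untrained real model produces the right shape and respects the mask
  arch <- archConfig(genChannels = c(2L, 4L), discChannels = c(2L, 4L),
                     discPrepool = 1L, patchSlices = 32L)
  sbM <- synthesizeVolume(mz, ns@mask, createModel(arch, seed = 2L))
  expect_identical(dim(sbM), dim(ns@mriZ))
  expect_true(all(sbM >= 0))
  expect_true(all(sbM[ns@mask == 0] == 0))
  expect_error(synthesizeVolume(mz, ns@mask, idStub, patchWidth = 100),
               "exceeds")
})
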