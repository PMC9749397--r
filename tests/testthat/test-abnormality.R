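# Personalized abnormality mapping: healthy-region extraction, sbPET
# post-normalization, the Z% map, regional summaries and group averages.

test_that("healthy region captures the top-2% GM/WM uptake", {
  g <- array(0, c(5, 5, 5))
  pet <- array(0, c(5, 5, 5))
  g[1:100] <- 1
  pet[1:100] <- 1:100
  region <- healthyRegionMask(newVolume(pet), g, array(0, c(5, 5, 5)),
                              blurFwhmMm = 0)
  expect_identical(which(region > 0), 99:100L)
  # tie convention: a constant PET selects every GM/WM voxel
  petC <- array(0, c(5, 5, 5))
  petC[1:100] <- 4
  regC <- healthyRegionMask(newVolume(petC), g, array(0, c(5, 5, 5)),
                            blurFwhmMm = 0)
  expect_equal(sum(regC), 100)
  # continuous phantom: selected fraction is close to 2%
  ns <- fixtureNormalized("noisy64")
  reg <- healthyRegionMask(newVolume(ns@petN, ns@spacing, ns@affine),
                           ns@gm, ns@wm)
  frac <- sum(reg) / sum((ns@gm + ns@wm) > 0.5)
  expect_gt(frac, 0.015)
  expect_lt(frac, 0.06)
})

test_that("post-normalization equalizes healthy-region means", {
  set.seed(50)
  pet <- newVolume(array(runif(64, 0.5, 2), c(4, 4, 4)))
  region <- array(runif(64) > 0.5, c(4, 4, 4)) * 1
  pn1 <- postNormalizeSbpet(pet, pet, region)
  expect_equal(pn1$factor, 1)
  expect_equal(pn1$sbpet, pet)
  pn2 <- postNormalizeSbpet(2 * pet, pet, region)
  expect_equal(pn2$factor, 0.5)
  expect_equal(as.vector(pn2$sbpet), as.vector(pet), tolerance = 1e-12)
  # joint rescaling cancels
  pn3 <- postNormalizeSbpet(2 * 7 * pet, 7 * pet, region)
  expect_equal(pn3$factor, pn2$factor)
  expect_error(postNormalizeSbpet(0 * pet, pet, region), "positive")
})

test_that("Z% equals the relative percent deviation from the baseline", {
  y <- newVolume(array(1, c(3, 3, 3)))
  m <- array(1, c(3, 3, 3))
  z0 <- zmap(y, y, m, blurFwhmMm = 0)
  expect_true(all(z0@zPct == 0))
  yh <- newVolume(array(1, c(3, 3, 3)))
  y2 <- newVolume(array(0.8, c(3, 3, 3)))
  z <- zmap(y2, yh, m, blurFwhmMm = 0)
  expect_true(all(abs(z@zPct + 20) < 1e-12))
  # outside the mask the map is undefined
  m2 <- m
  m2[1, 1, 1] <- 0
  z2 <- zmap(y2, yh, m2, blurFwhmMm = 0)
  expect_true(is.na(z2@zPct[1, 1, 1]))
  # joint rescaling of both volumes leaves Z% unchanged
  set.seed(51)
  ya <- newVolume(array(runif(27, 0.5, 2), c(3, 3, 3)))
  yb <- newVolume(array(runif(27, 0.5, 2), c(3, 3, 3)))
  za <- zmap(ya, yb, m, blurFwhmMm = 0)
  zb <- zmap(newVolume(3 * ya), newVolume(3 * yb), m, blurFwhmMm = 0)
  expect_equal(za@zPct, zb@zPct, tolerance = 1e-12)
})

test_that("a known lesion is recovered at its injected magnitude", {
  healthy <- fixturePhantom("clean64")
  lesioned <- injectLesion(healthy,
                           lesionSpec(c(54, 32, 32), radiusMm = 7,
                                      reduction = 0.3))
  geom <- function(v) newVolume(v, healthy@spacing, healthy@affine)
  map <- abnormalityAnalysis(geom(lesioned@pet), geom(healthy@pet),
                             lesioned@mask, lesioned@gm, lesioned@wm,
                             blurFwhmMm = 0)
  core <- lesionCoreMask(lesioned)
  expect_equal(mean(map@zPct[core], na.rm = TRUE), -30, tolerance = 0.1 / 30)
  # healthy tissue far from the lesion shows no abnormality
  away <- healthy@mask > 0 & lesioned@lesion == 0
  expect_lt(max(abs(map@zPct[away]), na.rm = TRUE), 1e-6)
})

test_that("regional summaries aggregate defined voxels per label", {
  z <- array(NA_real_, c(2, 2, 1))
  z[1, 1, 1] <- -10
  z[2, 1, 1] <- 10
  z[1, 2, 1] <- 30
  atlas <- array(c(1, 2, 2, 3), c(2, 2, 1))
  map <- new("AbnormalityMap", zPct = z, postNormFactor = 1,
             healthyRegion = array(0, c(2, 2, 1)), summary = data.frame(),
             spacing = c(1, 1, 1), affine = diag(4))
  tab <- regionalSummary(map, atlas)
  expect_equal(tab$mean_z_pct[tab$region == 1], -10)
  expect_equal(tab$mean_z_pct[tab$region == 2], 20)
  # label 3 has only an undefined voxel: empty, not zero
  expect_true(is.na(tab$mean_z_pct[tab$region == 3]))
  expect_equal(tab$n_voxels[tab$region == 3], 0L)
  expect_error(regionalSummary(map, array(1, c(3, 3, 3))), "match")
  # random map against a brute-force per-label loop
  set.seed(52)
  zr <- array(rnorm(64), c(4, 4, 4))
  ar <- array(sample(0:3, 64, TRUE), c(4, 4, 4))
  mapr <- new("AbnormalityMap", zPct = zr, postNormFactor = 1,
              healthyRegion = array(0, c(4, 4, 4)), summary = data.frame(),
              spacing = c(1, 1, 1), affine = diag(4))
  tabr <- regionalSummary(mapr, ar)
  for (lab in 1:3) {
    expect_equal(tabr$mean_z_pct[tabr$region == lab], mean(zr[ar == lab]))
    expect_equal(tabr$sd_z_pct[tabr$region == lab], sd(zr[ar == lab]))
  }
})

test_that("healthy-group abnormality vanishes as noise vanishes", {
  groupMean <- function(noiseSd) {
    maps <- lapply(1:3, function(i) {
      clean <- generatePhantom(phantomParams(gridSize = 48, noiseSd = 0,
                                             biasAmplitude = 0,
                                             seed = 300 + i))
      noisy <- generatePhantom(phantomParams(gridSize = 48,
                                             noiseSd = noiseSd,
                                             biasAmplitude = 0,
                                             seed = 300 + i))
      geom <- function(v) newVolume(v, clean@spacing, clean@affine)
      abnormalityAnalysis(geom(noisy@pet), geom(clean@pet), noisy@mask,
                          noisy@gm, noisy@wm)
    })
    g <- groupMeanMap(maps)
    mean(abs(g), na.rm = TRUE)
  }
  m0 <- groupMean(0)
  m1 <- groupMean(0.02)
  m2 <- groupMean(0.06)
  expect_identical(m0, 0)      # exact at zero noise
  expect_lt(m1, m2)            # shrinks with the noise level
  expect_lt(m2, 1)             # small at the standard noise level
})

test_that("group averaging counts only defined voxels", {
  mk <- function(z) new("AbnormalityMap", zPct = z, postNormFactor = 1,
                        healthyRegion = array(0, dim(z)),
                        summary = data.frame(), spacing = c(1, 1, 1),
                        affine = diag(4))
  a <- array(c(1, NA, 3, NA), c(2, 2, 1))
  b <- array(c(5, 7, NA, NA), c(2, 2, 1))
  expect_equal(as.vector(groupMeanMap(list(mk(a)))), as.vector(a))
  g <- groupMeanMap(list(mk(a), mk(b)))
  expect_equal(g[1, 1, 1], 3)        # both defined: mean
  expect_equal(g[2, 1, 1], 7)        # defined in one map only
  expect_equal(g[1, 2, 1], 3)
  expect_true(is.na(g[2, 2, 1]))     # defined in no map
  expect_error(groupMeanMap(list(mk(a), mk(array(1, c(3, 3, 1))))),
               "mismatch")
})
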