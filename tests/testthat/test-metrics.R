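# Synthesis-accuracy metrics: closed-form examples, brute-force oracle
# equivalence on random volumes, and the stated scale invariance.

test_that("PSNR matches the closed form and is scale invariant", {
  y <- newVolume(array(1, c(3, 3, 3)))
  yh <- y + 0.1
  m <- array(1, c(3, 3, 3))
  expect_equal(psnr(y, yh, m), 20)
  expect_equal(psnr(2 * y, 2 * yh, m), psnr(y, yh, m), tolerance = 1e-12)
  expect_error(psnr(y, y, m), "infinite")
  expect_error(psnr(y, yh, array(0, c(3, 3, 3))), "empty")
})

test_that("RD% expresses signed bias with the true uptake denominator", {
  m <- array(1, c(2, 1, 1))
  y <- array(1, c(2, 1, 1))
  expect_equal(rdPercent(y, y, m), 0)
  expect_equal(rdPercent(y, array(c(1.1, 0.9), c(2, 1, 1)), m), 0)
  y3 <- array(runif(27, 0.5, 2), c(3, 3, 3))
  m3 <- array(1, c(3, 3, 3))
  expect_equal(rdPercent(y3, 1.2 * y3, m3), 20)
  b <- 0.37
  expect_equal(rdPercent(y3, (1 + b) * y3, m3), 100 * b)
})

test_that("Abs% expresses deviation magnitude and stays non-negative", {
  m <- array(1, c(2, 1, 1))
  y <- array(1, c(2, 1, 1))
  expect_equal(absPercent(y, array(c(1.1, 0.9), c(2, 1, 1)), m), 10)
  set.seed(40)
  y3 <- array(runif(27, 0.5, 2), c(3, 3, 3))
  yh3 <- y3 + rnorm(27, 0, 0.2)
  expect_gte(absPercent(y3, yh3, m <- array(1, c(3, 3, 3))), 0)
  expect_equal(absPercent(0.1 * y3, 0.1 * yh3, m),
               absPercent(y3, yh3, m), tolerance = 1e-9)
})

test_that("metrics agree with brute-force loop oracles", {
  set.seed(41)
  for (i in 1:5) {
    y <- array(runif(512, 0.5, 2), c(8, 8, 8))
    yh <- y * (1 + rnorm(512, 0, 0.1))
    m <- array(runif(512) > 0.3, c(8, 8, 8)) * 1
    expect_equal(psnr(y, yh, m), brutePsnr(y, yh, m), tolerance = 1e-10)
    expect_equal(rdPercent(y, yh, m), bruteRelMean(y, yh, m, FALSE),
                 tolerance = 1e-10)
    expect_equal(absPercent(y, yh, m), bruteRelMean(y, yh, m, TRUE),
                 tolerance = 1e-10)
    f <- jointFit(y, yh, m)
    fb <- bruteFit(y, yh, m)
    expect_equal(f$slope, fb$slope, tolerance = 1e-10)
    expect_equal(f$intercept, fb$intercept, tolerance = 1e-10)
    expect_equal(f$r2, fb$r2, tolerance = 1e-10)
  }
})

test_that("regional metrics localize errors and recombine to whole-brain", {
  atlas <- array(rep(1:2, each = 32), c(4, 4, 4))
  y <- array(runif(64, 1, 2), c(4, 4, 4))
  yh <- y
  yh[atlas == 2] <- yh[atlas == 2] + 0.5
  m <- array(1, c(4, 4, 4))
  tab <- regionalMetrics(y, yh, atlas, mask = m)
  expect_equal(tab$rd_pct[tab$region == 1], 0)
  expect_gt(tab$rd_pct[tab$region == 2], 0)
  combined <- sum(tab$rd_pct * tab$n_voxels) / sum(tab$n_voxels)
  expect_equal(combined, rdPercent(y, yh, m), tolerance = 1e-10)
  expect_error(regionalMetrics(y, yh, atlas, regions = 9, mask = m),
               "unknown")
})

test_that("the joint fit recovers exact linear relations", {
  y <- array(runif(27, 0.5, 2), c(3, 3, 3))
  m <- array(1, c(3, 3, 3))
  f1 <- jointFit(y, y, m)
  expect_equal(f1$slope, 1, tolerance = 1e-12)
  expect_equal(f1$intercept, 0, tolerance = 1e-12)
  expect_equal(f1$r2, 1, tolerance = 1e-12)
  f2 <- jointFit(y, 2 * y + 3, m)
  expect_equal(f2$slope, 2, tolerance = 1e-12)
  expect_equal(f2$intercept, 3, tolerance = 1e-12)
  expect_error(jointFit(array(1, c(2, 2, 2)), y <- array(1, c(2, 2, 2)),
                        array(1, c(2, 2, 2))), "degenerate")
})

test_that("denormalization undoes the PET intensity normalization", {
  v <- newVolume(array(runif(27), c(3, 3, 3)))
  expect_equal(as.vector(denormalize(v / 3.7, 3.7)), as.vector(v),
               tolerance = 1e-12)
  expect_identical(denormalize(v, 1), v)
  expect_equal(as.vector(denormalize(2 * v, 3)),
               2 * as.vector(denormalize(v, 3)))
  expect_error(denormalize(v, 0), "positive|> 0")
})

test_that("evaluateSynthesis assembles a coherent report", {
  ns <- fixtureNormalized("noisy64")
  yh <- ns@petN * 1.05
  rep <- evaluateSynthesis(ns@petN, yh, ns@mask, ns@atlas)
  expect_s4_class(rep, "MetricsReport")
  expect_equal(rep@rdPct, 5, tolerance = 1e-9)
  expect_equal(rep@fit$slope, 1.05, tolerance = 1e-9)
  expect_equal(rep@fit$r2, 1, tolerance = 1e-9)
  expect_equal(nrow(rep@perRegion), 8)
  expect_output(show(rep), "PSNR")
})
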