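# Adversarial core: losses and their gradients, schedule, augmentations,
# architecture bookkeeping, and small training runs.

test_that("masked L1 is confined to the mask", {
  p <- array(c(1, 3, 100), c(3, 1, 1))
  t <- array(c(2, 5, 0), c(3, 1, 1))
  m <- array(c(1, 1, 0), c(3, 1, 1))
  expect_equal(maskedL1(p, t, m), 1.5)
  expect_equal(maskedL1(t, t, m), 0)
  p2 <- p
  p2[3] <- p2[3] + 1e6   # out-of-mask perturbation
  expect_equal(maskedL1(p2, t, m), maskedL1(p, t, m))
  expect_error(maskedL1(p, t, array(0, c(3, 1, 1))), "mask")
})

test_that("masked L1 analytic gradient matches finite differences", {
  set.seed(4)
  pred <- array(rnorm(64), c(4, 4, 4))
  target <- array(rnorm(64), c(4, 4, 4))
  mask <- array(runif(64) > 0.4, c(4, 4, 4)) * 1
  g <- sbpet:::l1Grad(pred, target, mask)
  eps <- 1e-6
  for (i in c(1, 9, 33, 64)) {
    pp <- pred; pp[i] <- pp[i] + eps
    pm <- pred; pm[i] <- pm[i] - eps
    fd <- (maskedL1(pp, target, mask) - maskedL1(pm, target, mask)) /
      (2 * eps)
    expect_equal(g[i], fd, tolerance = 1e-5)
  }
})

test_that("adversarial BCE matches the closed forms", {
  half <- array(0.5, c(2, 2))
  expect_equal(adversarialBce(half, "real"), log(2), tolerance = 1e-12)
  expect_equal(adversarialBce(half, "fake"), log(2), tolerance = 1e-12)
  ones <- array(1, c(2, 2))
  expect_lt(adversarialBce(ones, "real"), 1e-6)
  expect_gt(adversarialBce(ones, "fake"), -log(1e-6))
  expect_equal(discriminatorLoss(half, half), log(2), tolerance = 1e-12)
  expect_lt(discriminatorLoss(ones, 1 - ones), 1e-6)
  expect_gt(discriminatorLoss(1 - ones, ones), 15)
  expect_error(discriminatorLoss(half, ones[1]), "shape")
})

test_that("generator losses compose sketcher and refiner terms", {
  pred <- array(runif(27), c(3, 3, 3))
  mask <- array(1, c(3, 3, 3))
  gm <- array(c(rep(1, 10), rep(0, 17)), c(3, 3, 3))
  half <- array(0.5, c(2, 2))
  w <- lossWeights(lambdaAdv = 1, lambdaL1Brain = 100, lambdaL1Gm = 50)
  expect_equal(generatorLoss("sketcher", half, pred, pred, mask, w = w),
               log(2), tolerance = 1e-12)
  w0 <- lossWeights(lambdaAdv = 0, lambdaL1Brain = 10)
  target <- pred + 0.2
  expect_equal(generatorLoss("sketcher", half, pred, target, mask, w = w0),
               10 * maskedL1(pred, target, mask))
  wg0 <- lossWeights(lambdaL1Gm = 0)
  expect_equal(
    generatorLoss("refiner", half, pred, target, mask, gm, wg0),
    generatorLoss("sketcher", half, pred, target, mask, w = wg0))
  expect_error(generatorLoss("refiner", half, pred, target, mask, w = w),
               "gray-matter")
})

test_that("learning rate schedule matches the production decays", {
  sched <- trainSchedule()
  expect_equal(lrAtStep(0, sched), 1e-4)
  expect_equal(lrAtStep(19999, sched), 1e-4)
  expect_equal(lrAtStep(20000, sched), 1e-5)
  expect_equal(lrAtStep(49999, sched), 1e-5)
  expect_equal(lrAtStep(50000, sched), 1e-6)
  expect_equal(lrAtStep(90000, sched), 1e-6)
  expect_error(lrAtStep(-1, sched), "schedule")
  expect_error(trainSchedule(decaySteps = c(50000L, 20000L)), "decay")
  expect_error(trainSchedule(totalSteps = 100L,
                             decaySteps = c(20000L, 50000L)), "decay")
})

test_that("augmentations transform every volume identically and safely", {
  ns <- fixtureNormalized("noisy64")
  # all randomness off -> identity
  cfgId <- augmentConfig(pMirror = 0, pAffine = 1, pBias = 0,
                         scaleRange = c(1, 1), rotRangeDeg = c(0, 0))
  set.seed(1)
  a <- augmentSample(ns, cfgId)
  expect_equal(a@mriZ, ns@mriZ, tolerance = 1e-12)
  expect_equal(a@petN, ns@petN, tolerance = 1e-12)
  # mirroring twice restores the original
  cfgM <- augmentConfig(pMirror = 1, pAffine = 0, pBias = 0)
  set.seed(2)
  m1 <- augmentSample(ns, cfgM)
  set.seed(3)
  m2 <- augmentSample(m1, cfgM)
  expect_identical(m2@mriZ, ns@mriZ)
  expect_false(identical(m1@mriZ, ns@mriZ))
  # generic draw: masks stay binary, PET stays non-negative,
  # out-of-field MRI takes the sentinel
  set.seed(7)
  g <- augmentSample(ns, augmentConfig())
  expect_true(all(g@mask %in% c(0, 1)))
  expect_true(all(g@dilatedMask %in% c(0, 1)))
  expect_true(all(g@petN >= 0))
  expect_true(all(g@mriZ[g@dilatedMask == 0] <= max(ns@mriZ)))
  # restricting the transformed slots does not change the draws
  set.seed(7)
  gLight <- augmentSample(ns, augmentConfig(),
                          slots = c("mriZ", "petN", "mask", "gm"))
  expect_identical(gLight@mriZ, g@mriZ)
  expect_identical(gLight@gm, g@gm)
})

test_that("parameter counts match the instantiated engine", {
  arch <- archConfig("desk")
  nets <- sbpet:::buildNets(arch, seed = 1L)
  engineCount <- sbpet:::.nn_unet_nparams(nets$sketcherG) +
    sbpet:::.nn_unet_nparams(nets$refinerG) +
    sbpet:::.nn_disc_nparams(nets$sketcherD) +
    sbpet:::.nn_disc_nparams(nets$refinerD)
  expect_equal(countParameters(arch), engineCount)
})

test_that("generator forward equals a double-precision reference", {
  ne <- asNamespace("sbpet")
  ch <- c(2L, 3L, 4L)
  dm <- c(8L, 8L, 8L)
  set.seed(10)
  x <- rnorm(prod(dm))
  net <- ne$.nn_unet_create(1L, ch, 99L)
  yc <- ne$.nn_unet_forward(net, x, dm, FALSE)
  yr <- refUnet(ne$.nn_unet_get_weights(net), 1L, ch, x, dm)
  expect_equal(yc, yr, tolerance = 1e-5)
  # output shape equals the input patch shape
  expect_length(yc, prod(dm))
})

test_that("engine gradients match finite differences on the reference", {
  ne <- asNamespace("sbpet")
  ch <- c(2L, 3L)
  dm <- c(4L, 4L, 4L)
  set.seed(11)
  x <- rnorm(prod(dm))
  target <- rnorm(prod(dm))
  net <- ne$.nn_unet_create(1L, ch, 42L)
  y <- ne$.nn_unet_forward(net, x, dm, TRUE)
  ne$.nn_unet_backward(net, 2 * (y - target) / length(y))
  g <- ne$.nn_unet_get_grads(net)
  wts <- ne$.nn_unet_get_weights(net)
  set.seed(12)
  dirs <- lapply(wts, function(v) rnorm(length(v)))
  analytic <- sum(mapply(function(gi, di) sum(gi * di), g, dirs))
  lossR <- function(w) mean((refUnet(w, 1L, ch, x, dm) - target)^2)
  eps <- 1e-6
  fd <- (lossR(mapply(function(v, d) v + eps * d, wts, dirs,
                      SIMPLIFY = FALSE)) -
           lossR(mapply(function(v, d) v - eps * d, wts, dirs,
                        SIMPLIFY = FALSE))) / (2 * eps)
  expect_equal(analytic, fd, tolerance = 1e-4)
})

test_that("tiny training runs are deterministic and finite", {
  subs <- lapply(1:3, function(i) preprocessSubject(generatePhantom(
    phantomParams(gridSize = 32, seed = 20 + i))))
  arch <- archConfig(genChannels = c(2L, 4L), discChannels = c(2L, 4L),
                     discPrepool = 1L, patchSlices = 16L)
  sched <- deskSchedule("pretrain", totalSteps = 12L, seed = 5L)
  m1 <- trainStage(subs, arch, sched = sched, valSubjects = subs[3])
  m2 <- trainStage(subs, arch, sched = sched, valSubjects = subs[3])
  expect_identical(m1@history, m2@history)
  expect_identical(m1@sketcherG, m2@sketcherG)
  expect_true(all(is.finite(unlist(m1@history[, -1]))))
  expect_error(trainStage(subs, arch,
                          sched = deskSchedule("finetune", 5L)),
               "initial model")
  # transfer: finetuning resumes from the given weights without error
  m3 <- trainStage(subs, arch,
                   sched = deskSchedule("finetune", 4L, seed = 6L),
                   init = m1, valSubjects = subs[3])
  expect_identical(m3@stage, "finetune")
})
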