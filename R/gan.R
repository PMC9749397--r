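# Sketcher-refiner adversarial core: architecture presets, masked losses,
# training augmentations, the learning-rate schedule and the two-stage
# (pretrain / finetune) optimization loop.
#
# Both generators share one U-Net architecture and both discriminators one
# PatchGAN architecture. The sketcher maps an MRI patch to a preliminary PET
# patch; the refiner consumes the MRI patch concatenated with the (detached)
# sketch and produces the final patch. Each stage keeps its own
# discriminator, shown (MRI, candidate-PET) channel pairs.

#' Architecture configuration presets
#'
#' `"desk"` is sized to train on one CPU at a 64-voxel grid; `"full"` follows
#' the production-scale plan with a trainable-parameter count near 2e8 across
#' the two generators and two discriminators.
#'
#' @param preset `"desk"` or `"full"`; ignored when `genChannels` is given.
#' @param genChannels,discChannels,discPrepool,patchSlices custom overrides,
#'   see [ArchConfig-class].
#' @return an [ArchConfig-class].
#' @export
archConfig <- function(preset = c("desk", "full"), genChannels = NULL,
                       discChannels = NULL, discPrepool = NULL,
                       patchSlices = 32L) {
  if (is.null(genChannels)) {
    preset <- match.arg(preset)
    if (preset == "desk") {
      genChannels <- c(2L, 8L, 16L)
      discChannels <- c(4L, 8L)
      discPrepool <- 1L
    } else {
      genChannels <- as.integer(64 * 2^(0:5))
      discChannels <- c(64L, 128L, 256L)
      discPrepool <- 1L
    }
  } else {
    preset <- "custom"
    if (is.null(discChannels)) discChannels <- c(4L, 8L)
    if (is.null(discPrepool)) discPrepool <- 1L
  }
  new("ArchConfig", scalePreset = preset,
      genChannels = as.integer(genChannels),
      discChannels = as.integer(discChannels),
      discPrepool = as.integer(discPrepool),
      patchSlices = as.integer(patchSlices))
}

unetParamCount <- function(cin, ch) {
  L <- length(ch)
  n <- 27 * cin * ch[1] + ch[1]
  if (L > 1) {
    n <- n + sum(27 * ch[-L] * ch[-1] + ch[-1])
    for (i in seq_len(L - 1)) {
      n <- n + (ch[i + 1] + ch[i]) * ch[i] + ch[i]   # 1x1 reduce
      n <- n + 27 * ch[i]^2 + ch[i]                  # 3x3x3 conv
    }
  }
  n + ch[1] + 1                                      # 1x1 head
}

discParamCount <- function(cin, ch) {
  n <- 27 * cin * ch[1] + ch[1]
  if (length(ch) > 1)
    n <- n + sum(27 * ch[-length(ch)] * ch[-1] + ch[-1])
  n + ch[length(ch)] + 1
}

#' Trainable parameter count of an architecture
#'
#' Sums the weights and biases of the sketcher and refiner generators and
#' their discriminators, computed from layer shapes without allocating the
#' model.
#'
#' @param arch an [ArchConfig-class].
#' @return total number of trainable parameters.
#' @export
countParameters <- function(arch) {
  unetParamCount(1L, arch@genChannels) +          # sketcher G (MRI in)
    unetParamCount(2L, arch@genChannels) +        # refiner G (MRI + sketch)
    2 * discParamCount(2L, arch@discChannels)     # two conditioned Ds
}

# ---- losses ----------------------------------------------------------------

#' Brain-mask-confined L1 loss
#'
#' Mean absolute difference over mask-positive voxels only; values outside
#' the mask (including sentinel voxels) cannot influence the loss.
#'
#' @param pred,target numeric arrays of equal shape.
#' @param mask binary array; must contain at least one positive voxel.
#' @return scalar loss.
#' @export
maskedL1 <- function(pred, target, mask) {
  idx <- which(mask > 0)
  if (!length(idx)) stop("mask has no positive voxels")
  mean(abs(pred[idx] - target[idx]))
}

BCE_EPS <- 1e-7

#' Adversarial binary cross-entropy
#'
#' Mean BCE of a discriminator's (post-sigmoid) patch-probability field
#' against a constant real/fake label map. Probabilities are clamped away
#' from 0 and 1 by a small epsilon for numerical safety.
#'
#' @param dOut discriminator output probabilities.
#' @param label `"real"` or `"fake"`.
#' @param eps clamp width.
#' @return non-negative scalar.
#' @export
adversarialBce <- function(dOut, label = c("real", "fake"), eps = BCE_EPS) {
  label <- match.arg(label)
  p <- pmin(pmax(dOut, eps), 1 - eps)
  if (label == "real") mean(-log(p)) else mean(-log(1 - p))
}

#' Generator objective
#'
#' `lambdaAdv * BCE(dOutFake, real) + lambdaL1Brain * L1(pred, target | brain)`
#' plus, for the refiner only, the additional gray-matter-masked L1 term that
#' emphasizes tissue relevant to neurodegenerative disease.
#'
#' @param which `"sketcher"` or `"refiner"`.
#' @param dOutFake discriminator probabilities for the candidate patch.
#' @param pred,target predicted and true PET patches.
#' @param brainMask binary brain mask patch.
#' @param gmMask binary gray-matter mask patch (required for the refiner).
#' @param w a [LossWeights-class].
#' @return scalar loss.
#' @export
generatorLoss <- function(which = c("sketcher", "refiner"), dOutFake, pred,
                          target, brainMask, gmMask = NULL,
                          w = lossWeights()) {
  which <- match.arg(which)
  loss <- w@lambdaAdv * adversarialBce(dOutFake, "real") +
    w@lambdaL1Brain * maskedL1(pred, target, brainMask)
  if (which == "refiner") {
    if (is.null(gmMask)) stop("refiner loss requires a gray-matter mask")
    loss <- loss + w@lambdaL1Gm * maskedL1(pred, target, gmMask)
  }
  loss
}

#' Discriminator objective
#'
#' `0.5 * (BCE(dOutReal, real) + BCE(dOutFake, fake))`.
#'
#' @param dOutReal,dOutFake discriminator probability fields of equal shape.
#' @return scalar loss.
#' @export
discriminatorLoss <- function(dOutReal, dOutFake) {
  if (length(dOutReal) != length(dOutFake)) stop("output shape mismatch")
  0.5 * (adversarialBce(dOutReal, "real") + adversarialBce(dOutFake, "fake"))
}

#' Learning rate at a step
#'
#' Piecewise-constant schedule: `lr0 * decayFactor^k` where `k` is the number
#' of decay steps at or below `step`.
#'
#' @param step optimization step (0-based, as counted by the schedule).
#' @param sched a [TrainSchedule-class].
#' @return learning rate.
#' @export
lrAtStep <- function(step, sched) {
  if (step < 0 || step > sched@totalSteps) stop("step outside the schedule")
  sched@lr0 * sched@decayFactor^sum(sched@decaySteps <= step)
}

# ---- augmentation ----------------------------------------------------------

#' Default training augmentation configuration
#'
#' Random sagittal mirroring (p = 0.5), random per-axis affine
#' transformations (scale ~ U(0.9, 1.1), rotation ~ U(-10, 10) degrees,
#' p = 1) and random multiplicative MRI bias fields (p = 0.5).
#'
#' @param pMirror,pAffine,pBias application probabilities.
#' @param scaleRange,rotRangeDeg per-axis uniform draw ranges.
#' @param biasAmplitude peak bias deviation.
#' @return configuration list.
#' @export
augmentConfig <- function(pMirror = 0.5, pAffine = 1, pBias = 0.5,
                          scaleRange = c(0.9, 1.1),
                          rotRangeDeg = c(-10, 10), biasAmplitude = 0.2) {
  list(pMirror = pMirror, pAffine = pAffine, pBias = pBias,
       scaleRange = scaleRange, rotRangeDeg = rotRangeDeg,
       biasAmplitude = biasAmplitude)
}

rotMat <- function(degs) {
  r <- degs * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

resampleAffine <- function(vol, M, nearest, fill) {
  d <- dim(vol)
  ctr <- (d - 1) / 2
  off <- ctr - M %*% ctr
  out <- .cpp_resample_affine(as.vector(vol), d, M, as.vector(off),
                              if (nearest) 1L else 0L, fill)
  withGeom(out, vol)
}

#' Apply training augmentations to a normalized subject
#'
#' One identical geometric transform (mirror and/or affine) is applied to
#' every volume of the subject — images with trilinear and masks with
#' nearest-neighbour resampling — and a random multiplicative bias field is
#' applied to the MRI only, inside the brain. Parameters are drawn from the
#' configured distributions using the current RNG state, so the result is
#' deterministic given the seed.
#'
#' @param subject a [NormalizedSubject-class].
#' @param cfg configuration from [augmentConfig()].
#' @param slots volumes to transform (default: all); restricting the set does
#'   not change the random draws, so a restricted call sees the same
#'   transform as a full one.
#' @return the augmented [NormalizedSubject-class].
#' @export
augmentSample <- function(subject, cfg = augmentConfig(), slots = NULL) {
  s <- subject
  sentinel <- if (!is.null(s@provenance$sentinel)) s@provenance$sentinel
              else -7
  doMirror <- runif(1) < cfg$pMirror
  doAffine <- runif(1) < cfg$pAffine
  scl <- runif(3, cfg$scaleRange[1], cfg$scaleRange[2])
  rot <- runif(3, cfg$rotRangeDeg[1], cfg$rotRangeDeg[2])
  doBias <- runif(1) < cfg$pBias

  imgSlots <- c(mriZ = sentinel, petN = 0)
  mskSlots <- c("dilatedMask", "mask", "gm", "wm")
  doOpt <- is.null(slots)
  if (!is.null(slots)) {
    imgSlots <- imgSlots[names(imgSlots) %in% slots]
    mskSlots <- mskSlots[mskSlots %in% slots]
  }

  if (doMirror) {
    rev1 <- function(v) v[rev(seq_len(dim(v)[1])), , , drop = FALSE]
    for (nm in c(names(imgSlots), mskSlots))
      slot(s, nm) <- stripExtra(rev1(slot(s, nm)))
    if (doOpt && !is.null(s@atlas)) s@atlas <- stripExtra(rev1(s@atlas))
    if (doOpt && !is.null(s@lesion)) s@lesion <- stripExtra(rev1(s@lesion))
  }
  if (doAffine) {
    M <- solve(rotMat(rot) %*% diag(scl))
    geo <- function(v, near, fill)
      stripExtra(resampleAffine(newVolume(v, s@spacing, s@affine), M, near,
                                fill))
    for (nm in names(imgSlots))
      slot(s, nm) <- geo(slot(s, nm), FALSE, imgSlots[[nm]])
    for (nm in mskSlots) {
      v <- geo(slot(s, nm), nm %in% c("dilatedMask", "mask"), 0)
      if (nm %in% c("dilatedMask", "mask")) v <- (v > 0.5) * 1
      slot(s, nm) <- v
    }
    if (doOpt && !is.null(s@atlas)) s@atlas <- geo(s@atlas, TRUE, 0)
    if (doOpt && !is.null(s@lesion)) s@lesion <- geo(s@lesion, TRUE, 0)
  }
  if (doBias && cfg$biasAmplitude > 0) {
    g <- dim(s@mriZ)[1]
    if (all(dim(s@mriZ) == g)) {
      field <- biasFieldDraw(g, cfg$biasAmplitude)
      inb <- s@mask > 0
      s@mriZ[inb] <- s@mriZ[inb] * field[inb]
    }
  }
  s
}

# ---- engine plumbing -------------------------------------------------------

# create the four networks; optionally load weights from a ModelBundle
buildNets <- function(arch, seed, weights = NULL) {
  nets <- list(
    sketcherG = .nn_unet_create(1L, arch@genChannels, seed + 101L),
    refinerG = .nn_unet_create(2L, arch@genChannels, seed + 202L),
    sketcherD = .nn_disc_create(2L, arch@discChannels, arch@discPrepool,
                                seed + 303L),
    refinerD = .nn_disc_create(2L, arch@discChannels, arch@discPrepool,
                               seed + 404L))
  if (!is.null(weights) && length(weights@sketcherG)) {
    .nn_unet_set_weights(nets$sketcherG, weights@sketcherG)
    .nn_unet_set_weights(nets$refinerG, weights@refinerG)
    .nn_disc_set_weights(nets$sketcherD, weights@sketcherD)
    .nn_disc_set_weights(nets$refinerD, weights@refinerD)
  }
  nets
}

netsToBundle <- function(nets, arch, stage, step, seed, history) {
  new("ModelBundle", arch = arch,
      sketcherG = .nn_unet_get_weights(nets$sketcherG),
      sketcherD = .nn_disc_get_weights(nets$sketcherD),
      refinerG = .nn_unet_get_weights(nets$refinerG),
      refinerD = .nn_disc_get_weights(nets$refinerD),
      stage = stage, step = as.integer(step), seed = as.integer(seed),
      history = history)
}

#' Create an untrained model bundle
#'
#' Freshly initialized sketcher/refiner weights for an architecture; the
#' natural baseline against which training improvement is measured.
#'
#' @param arch an [ArchConfig-class].
#' @param seed weight-initialization seed.
#' @return a [ModelBundle-class] with stage `"init"`.
#' @export
createModel <- function(arch, seed = 1L) {
  nets <- buildNets(arch, as.integer(seed))
  netsToBundle(nets, arch, "init", 0L, seed, emptyHistory())
}

emptyHistory <- function() {
  data.frame(step = integer(), lr = numeric(), d_sketch = numeric(),
             d_refine = numeric(), g_sketch = numeric(),
             g_refine = numeric(), val_l1 = numeric())
}

# ---- training --------------------------------------------------------------

# gradient of mean BCE w.r.t. the (clamped) probabilities
bceGrad <- function(p, label, eps = BCE_EPS) {
  pc <- pmin(pmax(p, eps), 1 - eps)
  n <- length(p)
  if (label == "real") -1 / pc / n else 1 / (1 - pc) / n
}

l1Grad <- function(pred, target, mask) {
  idx <- mask > 0
  g <- numeric(length(pred))
  g[idx] <- sign(pred[idx] - target[idx]) / sum(idx)
  g
}

samplePatch <- function(s, w) {
  d <- dim(s@mriZ)
  pos <- sample(patchPositions(d[1], w), 1L)
  idx <- pos:(pos + w - 1L)
  list(mri = as.vector(s@mriZ[idx, , , drop = FALSE]),
       pet = as.vector(s@petN[idx, , , drop = FALSE]),
       brain = as.vector(s@mask[idx, , , drop = FALSE]),
       gm = as.vector((s@gm[idx, , , drop = FALSE] > GMWM_THRESHOLD) * 1),
       dims = c(w, d[2], d[3]))
}

centralPatch <- function(s, w) {
  d <- dim(s@mriZ)
  pos <- max(1L, (d[1] - w) %/% 2L + 1L)
  idx <- pos:(pos + w - 1L)
  list(mri = as.vector(s@mriZ[idx, , , drop = FALSE]),
       pet = as.vector(s@petN[idx, , , drop = FALSE]),
       brain = as.vector(s@mask[idx, , , drop = FALSE]),
       dims = c(w, d[2], d[3]))
}

validationL1 <- function(nets, valSubjects, w) {
  mean(vapply(valSubjects, function(s) {
    p <- centralPatch(s, w)
    sk <- .nn_unet_forward(nets$sketcherG, p$mri, p$dims, FALSE)
    rf <- .nn_unet_forward(nets$refinerG,
                           as.vector(rbind(p$mri, sk)), p$dims, FALSE)
    maskedL1(rf, p$pet, p$brain)
  }, numeric(1)))
}

#' Train one stage of the sketcher-refiner model
#'
#' Alternates discriminator and generator updates each step, for the sketcher
#' and then the refiner; the refiner consumes the sketcher's (detached)
#' output patch. A holdout split provides a validation L1 that selects the
#' returned checkpoint (early stopping on the validation curve). Training is
#' deterministic on CPU given the schedule seed.
#'
#' @param subjects list of [NormalizedSubject-class] training subjects.
#' @param arch an [ArchConfig-class].
#' @param w a [LossWeights-class].
#' @param sched a [TrainSchedule-class]; `stage = "finetune"` requires
#'   `init`.
#' @param init optional [ModelBundle-class] to start from (transfer
#'   learning).
#' @param valSubjects optional explicit validation subjects; by default a
#'   fraction `valFrac` of `subjects` is held out.
#' @param valFrac fraction held out for validation when `valSubjects` is
#'   `NULL`.
#' @param augment apply the training augmentations of [augmentSample()].
#' @param augmentCfg augmentation configuration.
#' @param verbose print progress lines.
#' @return a trained [ModelBundle-class] with its loss history.
#' @export
trainStage <- function(subjects, arch, w = lossWeights(),
                       sched = trainSchedule(), init = NULL,
                       valSubjects = NULL, valFrac = 0.15, augment = TRUE,
                       augmentCfg = augmentConfig(), verbose = FALSE) {
  if (!length(subjects)) stop("training set is empty")
  if (sched@stage == "finetune" && is.null(init))
    stop("finetune stage requires an initial model")
  set.seed(sched@seed)
  if (is.null(valSubjects)) {
    if (length(subjects) >= 4L) {
      nv <- max(1L, round(valFrac * length(subjects)))
      vi <- sample(seq_along(subjects), nv)
      valSubjects <- subjects[vi]
      subjects <- subjects[-vi]
    } else {
      valSubjects <- subjects
    }
  }
  nets <- buildNets(arch, sched@seed, weights = init)
  pw <- arch@patchSlices
  lw <- w
  hist <- emptyHistory()
  best <- NULL
  bestVal <- Inf
  lastLoss <- c(d_sketch = NA_real_, d_refine = NA_real_,
                g_sketch = NA_real_, g_refine = NA_real_)

  for (step in seq_len(sched@totalSteps)) {
    lr <- lrAtStep(step, sched)
    batch <- lapply(seq_len(sched@batchSize), function(i) {
      s <- subjects[[sample(length(subjects), 1L)]]
      if (augment) s <- augmentSample(s, augmentCfg,
                                      slots = c("mriZ", "petN", "mask", "gm"))
      samplePatch(s, pw)
    })
    scale <- 1 / sched@batchSize
    # At batch size 1 the generator forwards computed here keep their caches
    # valid through the discriminator updates (which touch only the D nets),
    # so the generator phase below can reuse them without re-forwarding.
    fuse1 <- sched@batchSize == 1L

    # --- discriminator phase ----------------------------------------------
    fakes <- vector("list", length(batch))
    for (i in seq_along(batch)) {
      p <- batch[[i]]
      sk <- .nn_unet_forward(nets$sketcherG, p$mri, p$dims, fuse1)
      rf <- .nn_unet_forward(nets$refinerG, as.vector(rbind(p$mri, sk)),
                             p$dims, fuse1)
      fakes[[i]] <- list(sk = sk, rf = rf)
      for (which in c("sketcherD", "refinerD")) {
        cand <- if (which == "sketcherD") sk else rf
        dr <- .nn_disc_forward(nets[[which]],
                               as.vector(rbind(p$mri, p$pet)), p$dims, TRUE)
        .nn_disc_backward(nets[[which]], 0.5 * bceGrad(dr, "real"), FALSE,
                          TRUE)
        df <- .nn_disc_forward(nets[[which]],
                               as.vector(rbind(p$mri, cand)), p$dims, TRUE)
        .nn_disc_backward(nets[[which]], 0.5 * bceGrad(df, "fake"), FALSE,
                          TRUE)
        if (i == length(batch))
          lastLoss[[if (which == "sketcherD") "d_sketch" else "d_refine"]] <-
            discriminatorLoss(dr, df)
      }
    }
    .nn_disc_step(nets$sketcherD, lr, scale)
    .nn_disc_step(nets$refinerD, lr, scale)

    # --- generator phase --------------------------------------------------
    for (i in seq_along(batch)) {
      p <- batch[[i]]
      sk <- if (fuse1) fakes[[i]]$sk
            else .nn_unet_forward(nets$sketcherG, p$mri, p$dims, TRUE)
      dsf <- .nn_disc_forward(nets$sketcherD,
                              as.vector(rbind(p$mri, sk)), p$dims, TRUE)
      dIn <- .nn_disc_backward(nets$sketcherD,
                               lw@lambdaAdv * bceGrad(dsf, "real"), TRUE,
                               FALSE)
      dPet <- matrix(dIn, nrow = 2)[2, ]
      dSketch <- dPet + lw@lambdaL1Brain * l1Grad(sk, p$pet, p$brain)
      .nn_unet_backward(nets$sketcherG, dSketch)
      if (i == length(batch))
        lastLoss[["g_sketch"]] <- generatorLoss("sketcher", dsf, sk, p$pet,
                                                p$brain, w = lw)

      rf <- if (fuse1) fakes[[i]]$rf
            else .nn_unet_forward(nets$refinerG,
                                  as.vector(rbind(p$mri, sk)),  # detached
                                  p$dims, TRUE)
      drf <- .nn_disc_forward(nets$refinerD,
                              as.vector(rbind(p$mri, rf)), p$dims, TRUE)
      dInR <- .nn_disc_backward(nets$refinerD,
                                lw@lambdaAdv * bceGrad(drf, "real"), TRUE,
                                FALSE)
      dPetR <- matrix(dInR, nrow = 2)[2, ]
      dRef <- dPetR + lw@lambdaL1Brain * l1Grad(rf, p$pet, p$brain) +
        lw@lambdaL1Gm * l1Grad(rf, p$pet, p$gm)
      .nn_unet_backward(nets$refinerG, dRef)
      if (i == length(batch))
        lastLoss[["g_refine"]] <- generatorLoss("refiner", drf, rf, p$pet,
                                                p$brain, p$gm, lw)
    }
    .nn_unet_step(nets$sketcherG, lr, scale)
    .nn_unet_step(nets$refinerG, lr, scale)

    if (any(!is.finite(unlist(lastLoss))))
      stop(sprintf("training diverged at step %d (non-finite loss)", step))

    doVal <- step %% sched@valEvery == 0L || step == sched@totalSteps
    if (doVal) {
      vl <- validationL1(nets, valSubjects, pw)
      if (vl < bestVal) {
        bestVal <- vl
        best <- netsToBundle(nets, arch, sched@stage, step, sched@seed,
                             emptyHistory())
      }
      if (verbose)
        message(sprintf("step %d: lr %.2g val L1 %.5f", step, lr, vl))
    }
    if (step %% sched@logEvery == 0L || step == sched@totalSteps) {
      hist <- rbind(hist, data.frame(
        step = step, lr = lr, d_sketch = lastLoss[["d_sketch"]],
        d_refine = lastLoss[["d_refine"]],
        g_sketch = lastLoss[["g_sketch"]],
        g_refine = lastLoss[["g_refine"]],
        val_l1 = if (doVal) vl else NA_real_))
    }
  }
  if (is.null(best))
    best <- netsToBundle(nets, arch, sched@stage, sched@totalSteps,
                         sched@seed, emptyHistory())
  best@history <- hist
  best
}
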