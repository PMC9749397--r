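# S4 containers for the pipeline. Voxel data inside the slots are plain 3D
# arrays with geometry attributes (see volume.R).

setClassUnion("arrayOrNULL", c("array", "NULL"))
setClassUnion("listOrNULL", c("list", "NULL"))

#' Hypometabolic lesion specification
#'
#' A spherical region in which simulated FDG uptake is multiplied by
#' `1 - reduction`, emulating focal hypometabolism with known ground truth.
#'
#' @slot center numeric length-3, voxel coordinate (1-based) of the centre.
#' @slot radiusMm positive sphere radius in mm.
#' @slot reduction fraction in (0, 1]; uptake becomes `uptake * (1 - reduction)`.
#' @slot tissueRestrict logical; if `TRUE` the lesion only affects voxels with
#'   gray-matter probability above 0.5.
#' @export
setClass("LesionSpec", representation(
  center = "numeric", radiusMm = "numeric", reduction = "numeric",
  tissueRestrict = "logical"
), validity = function(object) {
  if (length(object@center) != 3L) return("center must have length 3")
  if (object@radiusMm <= 0) return("radiusMm must be > 0")
  if (object@reduction <= 0 || object@reduction > 1)
    return("reduction must be in (0, 1]")
  TRUE
})

#' @param center,radiusMm,reduction,tissueRestrict see slots of
#'   [LesionSpec-class].
#' @rdname LesionSpec-class
#' @export
lesionSpec <- function(center, radiusMm, reduction, tissueRestrict = TRUE) {
  new("LesionSpec", center = as.numeric(center), radiusMm = radiusMm,
      reduction = reduction, tissueRestrict = tissueRestrict)
}

#' Phantom generation parameters
#'
#' Controls the paired pseudo-MRI / pseudo-PET brain phantom: grid, anatomy
#' (atrophy), per-tissue uptake and MRI intensity, bias field, noise and
#' lesions. The defaults define the simulated study conditions used by the
#' package's tests and examples.
#'
#' @slot gridSize voxels per axis (cube), at least 16.
#' @slot spacingMm isotropic voxel size in mm.
#' @slot atrophy scalar in [0,1]: 0 = none, 1 = maximal ventricular
#'   enlargement and cortical thinning.
#' @slot lesions list of [LesionSpec-class] objects.
#' @slot uptakeRatios GM:WM:CSF relative uptake, strictly positive.
#' @slot mriMeans,mriSds per-tissue (GM, WM, CSF) pseudo-T1w intensity mean
#'   and within-tissue SD.
#' @slot noiseSd additive Gaussian noise SD applied to both modalities.
#' @slot biasAmplitude peak multiplicative MRI bias deviation, in [0,1).
#' @slot seed integer RNG seed; generation is deterministic given the seed.
#' @export
setClass("PhantomParams", representation(
  gridSize = "integer", spacingMm = "numeric", atrophy = "numeric",
  lesions = "list", uptakeRatios = "numeric", mriMeans = "numeric",
  mriSds = "numeric", noiseSd = "numeric", biasAmplitude = "numeric",
  seed = "integer"
), validity = function(object) {
  if (object@gridSize < 16L) return("gridSize must be >= 16")
  if (any(object@uptakeRatios <= 0)) return("uptake ratios must be > 0")
  if (object@atrophy < 0 || object@atrophy > 1)
    return("atrophy must be in [0, 1]")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@biasAmplitude < 0 || object@biasAmplitude >= 1)
    return("biasAmplitude must be in [0, 1)")
  if (!all(vapply(object@lesions, function(l) is(l, "LesionSpec"), TRUE)))
    return("lesions must be LesionSpec objects")
  TRUE
})

#' @param gridSize,spacingMm,atrophy,lesions,uptakeRatios,mriMeans,mriSds,noiseSd,biasAmplitude,seed
#'   see slots of [PhantomParams-class].
#' @rdname PhantomParams-class
#' @export
phantomParams <- function(gridSize = 64L, spacingMm = 1.0, atrophy = 0,
                          lesions = list(),
                          uptakeRatios = c(gm = 3.0, wm = 1.0, csf = 0.2),
                          mriMeans = c(gm = 0.55, wm = 0.85, csf = 0.2),
                          mriSds = c(gm = 0.02, wm = 0.02, csf = 0.02),
                          noiseSd = 0.06, biasAmplitude = 0.1,
                          seed = 1L) {
  new("PhantomParams", gridSize = as.integer(gridSize), spacingMm = spacingMm,
      atrophy = atrophy, lesions = lesions,
      uptakeRatios = as.numeric(uptakeRatios), mriMeans = as.numeric(mriMeans),
      mriSds = as.numeric(mriSds), noiseSd = noiseSd,
      biasAmplitude = biasAmplitude, seed = as.integer(seed))
}

#' Aligned subject bundle
#'
#' One subject's co-registered, skull-stripped volumes: T1w-like MRI, FDG-like
#' PET, binary brain mask, GM/WM/CSF probability maps, and (optionally) an
#' integer atlas-label volume and a ground-truth lesion mask (phantoms only).
#'
#' @slot mri,pet,mask,gm,wm,csf 3D arrays on a shared grid.
#' @slot atlas,lesion optional 3D arrays (`NULL` when absent).
#' @slot spacing voxel size (mm); @slot affine voxel-to-world matrix.
#' @slot group free-text group label (e.g. "CN", "AD").
#' @slot params the [PhantomParams-class] used to generate the subject, or
#'   `NULL` for externally loaded data.
#' @export
setClass("SubjectRecord", representation(
  mri = "array", pet = "array", mask = "array", gm = "array", wm = "array",
  csf = "array", atlas = "arrayOrNULL", lesion = "arrayOrNULL",
  spacing = "numeric", affine = "matrix", group = "character",
  params = "ANY"
), validity = function(object) {
  d <- dim(object@mri)
  for (nm in c("pet", "mask", "gm", "wm", "csf")) {
    if (!identical(dim(slot(object, nm)), d))
      return(sprintf("volume '%s' does not match the MRI grid", nm))
  }
  for (nm in c("atlas", "lesion")) {
    v <- slot(object, nm)
    if (!is.null(v) && !identical(dim(v), d))
      return(sprintf("volume '%s' does not match the MRI grid", nm))
  }
  if (any(object@pet < 0)) return("PET uptake must be non-negative")
  TRUE
})

#' Normalized subject ready for model training/inference
#'
#' @slot mriZ z-scored MRI with the out-of-dilated-mask sentinel applied.
#' @slot petN PET divided by the top-2% GM/WM constant.
#' @slot petNormConstant the scalar divisor (original units per normalized
#'   unit); multiplying `petN` by it recovers the original scale.
#' @slot dilatedMask the dilated brain mask used for the sentinel.
#' @slot mask,gm,wm original brain mask and tissue probability maps.
#' @slot atlas,lesion carried through from the subject when present.
#' @slot provenance list of the normalization parameters used
#'   (sentinel, dilation radius, blur FWHM, top percent, mu, sigma).
#' @export
setClass("NormalizedSubject", representation(
  mriZ = "array", petN = "array", petNormConstant = "numeric",
  dilatedMask = "array", mask = "array", gm = "array", wm = "array",
  atlas = "arrayOrNULL", lesion = "arrayOrNULL", spacing = "numeric",
  affine = "matrix", group = "character", provenance = "list"
), validity = function(object) {
  if (object@petNormConstant <= 0) return("petNormConstant must be > 0")
  sent <- object@provenance$sentinel
  if (!is.null(sent)) {
    outside <- object@mriZ[object@dilatedMask == 0]
    if (length(outside) && any(outside != sent))
      return("voxels outside the dilated mask must equal the sentinel")
  }
  TRUE
})

#' Model architecture configuration
#'
#' Channel plan for the shared U-Net generator and PatchGAN discriminator
#' architectures. `scalePreset` selects either the CPU-sized `"desk"` preset
#' or the `"full"` preset whose trainable parameter count sits near 2e8.
#'
#' @slot scalePreset `"desk"`, `"full"` or `"custom"`.
#' @slot genChannels integer vector of U-Net channels per resolution level
#'   (level 1 = full resolution).
#' @slot discChannels integer vector of discriminator conv channels.
#' @slot discPrepool number of 2x average-poolings applied to the
#'   discriminator input before its conv stack.
#' @slot patchSlices sagittal patch width (number of slices per patch).
#' @export
setClass("ArchConfig", representation(
  scalePreset = "character", genChannels = "integer",
  discChannels = "integer", discPrepool = "integer", patchSlices = "integer"
), validity = function(object) {
  if (length(object@genChannels) < 2L) return("need at least 2 U-Net levels")
  if (any(object@genChannels <= 0) || any(object@discChannels <= 0))
    return("channel counts must be positive")
  if (object@patchSlices < 2L) return("patchSlices must be >= 2")
  TRUE
})

#' Adversarial loss weights
#'
#' @slot lambdaAdv weight of the adversarial BCE term.
#' @slot lambdaL1Brain weight of the brain-masked L1 recognition term.
#' @slot lambdaL1Gm weight of the additional gray-matter-masked L1 term
#'   (refiner generator only; ignored for the sketcher).
#' @export
setClass("LossWeights", representation(
  lambdaAdv = "numeric", lambdaL1Brain = "numeric", lambdaL1Gm = "numeric"
), validity = function(object) {
  if (object@lambdaAdv < 0 || object@lambdaL1Brain < 0 ||
      object@lambdaL1Gm < 0) return("loss weights must be >= 0")
  TRUE
})

#' @param lambdaAdv,lambdaL1Brain,lambdaL1Gm see slots.
#' @rdname LossWeights-class
#' @export
lossWeights <- function(lambdaAdv = 1, lambdaL1Brain = 100,
                        lambdaL1Gm = 100) {
  new("LossWeights", lambdaAdv = lambdaAdv, lambdaL1Brain = lambdaL1Brain,
      lambdaL1Gm = lambdaL1Gm)
}

#' Optimization schedule for one training stage
#'
#' ADAM with a piecewise-constant learning rate: `lr0` multiplied by
#' `decayFactor` at each step in `decaySteps`.
#'
#' @slot stage `"pretrain"` or `"finetune"`.
#' @slot totalSteps number of optimization steps.
#' @slot lr0 initial learning rate (generators and discriminators).
#' @slot decaySteps strictly increasing steps (< `totalSteps`) at which the
#'   rate is multiplied by `decayFactor`.
#' @slot decayFactor multiplicative decay, e.g. 0.1 for 10-fold.
#' @slot batchSize samples per optimization step.
#' @slot seed RNG seed for sampling, augmentation and weight init.
#' @slot valEvery,logEvery cadence (steps) of holdout validation / logging.
#' @export
setClass("TrainSchedule", representation(
  stage = "character", totalSteps = "integer", lr0 = "numeric",
  decaySteps = "integer", decayFactor = "numeric", batchSize = "integer",
  seed = "integer", valEvery = "integer", logEvery = "integer"
), validity = function(object) {
  if (!object@stage %in% c("pretrain", "finetune"))
    return("stage must be 'pretrain' or 'finetune'")
  if (object@lr0 <= 0) return("lr0 must be > 0")
  ds <- object@decaySteps
  if (length(ds) && (any(diff(ds) <= 0) || any(ds >= object@totalSteps)))
    return("decaySteps must be strictly increasing and < totalSteps")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  TRUE
})

#' @param stage,totalSteps,lr0,decaySteps,decayFactor,batchSize,seed,valEvery,logEvery
#'   see slots.
#' @rdname TrainSchedule-class
#' @export
trainSchedule <- function(stage = "pretrain", totalSteps = 90000L,
                          lr0 = 1e-4, decaySteps = c(20000L, 50000L),
                          decayFactor = 0.1, batchSize = 2L, seed = 1L,
                          valEvery = max(1L, as.integer(totalSteps %/% 10)),
                          logEvery = max(1L, as.integer(totalSteps %/% 40))) {
  new("TrainSchedule", stage = stage, totalSteps = as.integer(totalSteps),
      lr0 = lr0, decaySteps = as.integer(decaySteps),
      decayFactor = decayFactor, batchSize = as.integer(batchSize),
      seed = as.integer(seed), valEvery = as.integer(valEvery),
      logEvery = as.integer(logEvery))
}

#' Trained sketcher-refiner model bundle
#'
#' Self-describing checkpoint: architecture configuration, the weights of the
#' sketcher/refiner generators and their discriminators, and training
#' provenance (stage, step, seed, loss history).
#'
#' @slot arch an [ArchConfig-class].
#' @slot sketcherG,sketcherD,refinerG,refinerD weight lists as produced by the
#'   engine (alternating kernel/bias vectors per layer).
#' @slot stage `"init"`, `"pretrain"` or `"finetune"`.
#' @slot step last completed optimization step.
#' @slot seed seed the stage was run with.
#' @slot history data.frame log (step, lr, loss terms, validation L1).
#' @export
setClass("ModelBundle", representation(
  arch = "ArchConfig", sketcherG = "list", sketcherD = "list",
  refinerG = "list", refinerD = "list", stage = "character",
  step = "integer", seed = "integer", history = "data.frame"
))

#' Personalized abnormality map
#'
#' Voxel-wise relative percent difference, Z%, of the true PET from the
#' post-normalized synthetic baseline. Negative values indicate
#' hypometabolism, positive hypermetabolism. Voxels where the baseline is
#' (near) zero, or outside the brain mask, are `NA` (undefined).
#'
#' @slot zPct 3D array of Z% values (percent) with `NA` where undefined.
#' @slot postNormFactor scalar the sbPET was multiplied by.
#' @slot healthyRegion binary volume of the healthy-uptake normalization
#'   region derived from the true PET.
#' @slot summary per-region summary table (may be empty when no atlas).
#' @export
setClass("AbnormalityMap", representation(
  zPct = "array", postNormFactor = "numeric", healthyRegion = "array",
  summary = "data.frame", spacing = "numeric", affine = "matrix"
), validity = function(object) {
  if (object@postNormFactor <= 0) return("postNormFactor must be > 0")
  TRUE
})

#' Synthesis-accuracy report
#'
#' @slot psnr peak signal-to-noise ratio in dB over the brain mask.
#' @slot rdPct mean relative percent difference (bias; signed).
#' @slot absPct mean absolute relative percent difference (uncertainty).
#' @slot perRegion per-atlas-region RD%/Abs% table.
#' @slot fit list(slope, intercept, r2) of the joint-uptake linear fit.
#' @slot nVoxels voxels entering the whole-brain metrics.
#' @export
setClass("MetricsReport", representation(
  psnr = "numeric", rdPct = "numeric", absPct = "numeric",
  perRegion = "data.frame", fit = "list", nVoxels = "integer"
))

# ---- show methods ----------------------------------------------------------

setMethod("show", "PhantomParams", function(object) {
  cat(sprintf(
    "PhantomParams: %d^3 grid @ %.2f mm, atrophy %.2f, %d lesion(s)\n",
    object@gridSize, object@spacingMm, object@atrophy,
    length(object@lesions)))
  cat(sprintf("  uptake GM:WM:CSF = %s, noise SD %.3f, bias %.2f, seed %d\n",
              paste(format(object@uptakeRatios), collapse = ":"),
              object@noiseSd, object@biasAmplitude, object@seed))
})

setMethod("show", "SubjectRecord", function(object) {
  d <- dim(object@mri)
  cat(sprintf("SubjectRecord [%s]: %dx%dx%d @ %s mm, brain %d voxels\n",
              object@group, d[1], d[2], d[3],
              paste(format(object@spacing), collapse = "x"),
              sum(object@mask > 0)))
  cat(sprintf("  atlas: %s, lesion: %s\n",
              if (is.null(object@atlas)) "none" else
                sprintf("%d regions", length(setdiff(unique(as.vector(
                  object@atlas[object@mask > 0])), 0))),
              if (is.null(object@lesion)) "none" else
                sprintf("%d voxels", sum(object@lesion > 0))))
})

setMethod("show", "NormalizedSubject", function(object) {
  d <- dim(object@mriZ)
  cat(sprintf(
    "NormalizedSubject [%s]: %dx%dx%d, PET norm constant %.4g\n",
    object@group, d[1], d[2], d[3], object@petNormConstant))
})

setMethod("show", "ArchConfig", function(object) {
  cat(sprintf("ArchConfig '%s': U-Net channels (%s), disc (%s, prepool %d),\n",
              object@scalePreset,
              paste(object@genChannels, collapse = ", "),
              paste(object@discChannels, collapse = ", "),
              object@discPrepool))
  cat(sprintf("  patch = %d sagittal slices; ~%.3g trainable parameters\n",
              object@patchSlices, countParameters(object)))
})

setMethod("show", "ModelBundle", function(object) {
  cat(sprintf("ModelBundle: stage '%s', step %d, seed %d (%s preset)\n",
              object@stage, object@step, object@seed,
              object@arch@scalePreset))
  if (nrow(object@history))
    cat(sprintf("  last logged losses: %s\n",
                paste(sprintf("%s=%.4g",
                              names(object@history)[-1],
                              as.numeric(object@history[
                                nrow(object@history), -1])),
                      collapse = ", ")))
})

setMethod("show", "AbnormalityMap", function(object) {
  z <- object@zPct[!is.na(object@zPct)]
  cat(sprintf(
    "AbnormalityMap: %d defined voxels, mean Z%% %.2f, range [%.1f, %.1f]\n",
    length(z), mean(z), min(z), max(z)))
  cat(sprintf("  post-normalization factor %.4f\n", object@postNormFactor))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    "MetricsReport: PSNR %.2f dB, RD%% %.2f, Abs%% %.2f (n = %d voxels)\n",
    object@psnr, object@rdPct, object@absPct, object@nVoxels))
  if (length(object@fit))
    cat(sprintf("  joint fit: slope %.3f, intercept %.3f, R2 %.3f\n",
                object@fit$slope, object@fit$intercept, object@fit$r2))
})

# ---- accessors -------------------------------------------------------------

#' Accessors for subject bundles and result objects
#'
#' @param x an object of the matching class.
#' @param tissue one of "gm", "wm", "csf".
#' @name accessors
NULL

#' @rdname accessors
#' @export
mriVolume <- function(x) asVol(x, "mri", "mriZ")
#' @rdname accessors
#' @export
petVolume <- function(x) asVol(x, "pet", "petN")
#' @rdname accessors
#' @export
brainMask <- function(x) asVol(x, "mask", "mask")
#' @rdname accessors
#' @export
tissueProb <- function(x, tissue = c("gm", "wm", "csf")) {
  tissue <- match.arg(tissue)
  asVol(x, tissue, tissue)
}
#' @rdname accessors
#' @export
atlasLabels <- function(x) {
  v <- slot(x, "atlas")
  if (is.null(v)) NULL else newVolume(v, x@spacing, x@affine)
}
#' @rdname accessors
#' @export
lesionMask <- function(x) {
  v <- slot(x, "lesion")
  if (is.null(v)) NULL else newVolume(v, x@spacing, x@affine)
}
#' @rdname accessors
#' @export
petNormConstant <- function(x) x@petNormConstant
#' @rdname accessors
#' @export
zPercentMap <- function(x) newVolume(x@zPct, x@spacing, x@affine)
#' @rdname accessors
#' @export
postNormFactor <- function(x) x@postNormFactor
#' @rdname accessors
#' @export
regionalTable <- function(x) {
  if (is(x, "AbnormalityMap")) x@summary else x@perRegion
}

asVol <- function(x, rawSlot, normSlot) {
  nm <- if (rawSlot %in% slotNames(class(x))) rawSlot else normSlot
  newVolume(slot(x, nm), x@spacing, x@affine)
}
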