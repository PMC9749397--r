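# Paired pseudo-MRI / pseudo-PET brain phantom simulator.
#
# Anatomy is a set of concentric, randomly deformed ellipsoidal shells:
# a CSF ventricle core, a WM shell, a cortical GM ribbon and a thin outer
# (sulcal) CSF band, all expressed through a perturbed normalized radius.
# Tissue probabilities ramp linearly over ~2 voxels at every interface, so
# partial-volume voxels exist by construction. Atrophy scales the ventricle
# outward and thins the GM ribbon, both linearly in the atrophy scalar.

# evaluate phantom with an already-seeded RNG stream; draw order is fixed and
# independent of atrophy/lesions so regeneration under a changed atrophy keeps
# the same morphological noise.
phantomFields <- function(params) {
  g <- params@gridSize
  sp <- params@spacingMm
  jitter <- 1 + 0.03 * rnorm(3)
  delta <- smoothField3(g, coarse = 5L)
  texture <- array(rnorm(g^3), dim = c(g, g, g))
  bias <- biasFieldDraw(g, params@biasAmplitude)
  mriNoise <- array(rnorm(g^3), dim = c(g, g, g))
  petNoise <- array(rnorm(g^3), dim = c(g, g, g))

  ax <- c(0.42, 0.40, 0.38) * g * jitter
  ctr <- (g + 1) / 2
  x <- (seq_len(g) - ctr)
  rho0 <- sqrt(
    outer(outer((x / ax[1])^2, (x / ax[2])^2, "+"), (x / ax[3])^2, "+"))
  damp <- 0.06
  m <- max(abs(delta))
  if (m > 0) delta <- delta / m * damp
  rho <- rho0 * (1 + delta)

  a <- params@atrophy
  vVent <- 0.22 * (1 + 1.2 * a)    # ventricular enlargement
  wOut <- 0.78 + 0.10 * a          # cortical thinning: WM/GM interface moves out
  gOut <- 0.94
  h <- 2 / mean(ax)                # ~2-voxel partial-volume ramp

  ramp <- function(t) pmin(pmax((t + h / 2 - rho) / h, 0), 1)
  mask <- (rho <= 1) * 1
  fV <- ramp(vVent); fW <- ramp(wOut); fG <- ramp(gOut); fB <- ramp(1)
  pVent <- fV * mask
  pWm <- (fW - fV) * mask
  pGm <- (fG - fW) * mask
  pCsf <- (pVent + (fB - fG) * mask)

  u <- params@uptakeRatios
  pet <- u[1] * pGm + u[2] * pWm + u[3] * pCsf

  mm <- params@mriMeans
  ms <- params@mriSds
  mri <- (mm[1] * pGm + mm[2] * pWm + mm[3] * pCsf +
            texture * sqrt(ms[1]^2 * pGm + ms[2]^2 * pWm +
                             ms[3]^2 * pCsf)) * bias
  mri <- (mri + params@noiseSd * mriNoise) * mask

  list(mask = mask, pGm = pGm, pWm = pWm, pCsf = pCsf, pet = pet, mri = mri,
       petNoise = petNoise, ctr = ctr)
}

smoothField3 <- function(g, coarse = 5L) {
  cg <- array(rnorm(coarse^3), dim = rep(coarse, 3L))
  up <- trilinearUpsample(cg, g)
  up - mean(up)
}

# trilinear upsampling of a small k^3 array onto a g^3 grid spanning it
trilinearUpsample <- function(cg, g) {
  k <- dim(cg)[1]
  u <- (seq_len(g) - 1) / (g - 1) * (k - 1)
  i0 <- pmin(floor(u), k - 2)
  f <- u - i0
  i0 <- i0 + 1L
  out <- array(0, dim = c(g, g, g))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- outer(outer(if (dx) f else 1 - f, if (dy) f else 1 - f),
               if (dz) f else 1 - f)
    out <- out + cg[i0 + dx, i0 + dy, i0 + dz] * w
  }
  out
}

biasFieldDraw <- function(g, amplitude) {
  if (amplitude == 0) return(array(1, dim = c(g, g, g)))
  up <- smoothField3(g, coarse = 4L)
  m <- max(abs(up))
  if (m == 0) return(array(1, dim = c(g, g, g)))
  1 + amplitude * up / m
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a paired MRI/PET brain phantom
#'
#' Produces an aligned [SubjectRecord-class] with pseudo-T1w MRI, pseudo-FDG
#' PET, a binary brain mask, GM/WM/CSF probability maps (summing to at most 1
#' per voxel inside the mask), an octant atlas-label volume and, when lesions
#' are specified, a ground-truth lesion mask. Noise-free tissue-pure PET
#' voxels equal the configured uptake ratios, scaled by `1 - reduction`
#' inside lesions. Deterministic given `params@seed`.
#'
#' @param params a [PhantomParams-class] object.
#' @return a [SubjectRecord-class].
#' @examples
#' ph <- generatePhantom(phantomParams(gridSize = 32, noiseSd = 0))
#' ph
#' @export
generatePhantom <- function(params) {
  validObject(params)
  g <- params@gridSize
  fl <- withSeed(params@seed, phantomFields(params))

  pet <- fl$pet
  lesionMask <- NULL
  for (les in params@lesions) {
    lm <- lesionVoxels(les, fl$mask, fl$pGm, g, params@spacingMm)
    pet[lm] <- pet[lm] * (1 - les@reduction)
    if (is.null(lesionMask)) lesionMask <- array(0, dim = dim(pet))
    lesionMask[lm] <- 1
  }
  pet <- pmax(pet + params@noiseSd * fl$petNoise, 0) * fl$mask

  ctr <- fl$ctr
  atlas <- octantAtlas(g, ctr) * fl$mask

  sp <- rep(params@spacingMm, 3)
  new("SubjectRecord",
      mri = fl$mri, pet = pet, mask = fl$mask, gm = fl$pGm, wm = fl$pWm,
      csf = fl$pCsf, atlas = atlas, lesion = lesionMask,
      spacing = sp, affine = diag(c(sp, 1)), group = "phantom",
      params = params)
}

octantAtlas <- function(g, ctr) {
  ix <- (seq_len(g) > ctr) * 1
  1 + outer(outer(ix, 2 * ix, "+"), 4 * ix, "+")
}

lesionVoxels <- function(les, mask, pGm, g, spacingMm) {
  x1 <- (seq_len(g) - les@center[1])^2
  x2 <- (seq_len(g) - les@center[2])^2
  x3 <- (seq_len(g) - les@center[3])^2
  d2 <- outer(outer(x1, x2, "+"), x3, "+") * spacingMm^2
  lm <- d2 <= les@radiusMm^2
  if (les@tissueRestrict) lm <- lm & (pGm > 0.5)
  lm <- lm & (mask > 0)
  if (!any(lm)) stop("lesion sphere does not intersect the brain")
  lm
}

#' Regenerate a phantom at a different atrophy level
#'
#' Rebuilds the subject from its stored generation parameters with the
#' atrophy scalar replaced; the RNG seed and hence the subject's morphological
#' noise, bias field and noise draws are unchanged. Ventricular CSF volume is
#' non-decreasing and cortical GM volume non-increasing in `atrophy`; the PET
#' uptake field is regenerated consistently with the deformed tissue maps.
#'
#' @param record a phantom [SubjectRecord-class] (must carry its params).
#' @param atrophy scalar in [0, 1].
#' @return a new [SubjectRecord-class].
#' @export
applyAtrophy <- function(record, atrophy) {
  if (atrophy < 0 || atrophy > 1) stop("atrophy must be in [0, 1]")
  if (!is(record@params, "PhantomParams"))
    stop("record does not carry phantom parameters")
  p <- record@params
  if (atrophy == p@atrophy) return(record)
  p@atrophy <- atrophy
  generatePhantom(p)
}

#' Inject a hypometabolic lesion into a subject
#'
#' Multiplies PET uptake by `1 - reduction` inside the lesion sphere
#' (restricted to GM voxels when `tissueRestrict`), leaving the MRI unchanged:
#' an AD-like metabolic change without structural change. The lesion mask is
#' recorded on the returned subject.
#'
#' @param record a [SubjectRecord-class].
#' @param lesion a [LesionSpec-class].
#' @return the modified [SubjectRecord-class].
#' @export
injectLesion <- function(record, lesion) {
  validObject(lesion)
  g <- dim(record@pet)[1]
  lm <- lesionVoxels(lesion, record@mask, record@gm, g, record@spacing[1])
  record@pet[lm] <- record@pet[lm] * (1 - lesion@reduction)
  if (is.null(record@lesion)) record@lesion <- array(0, dim = dim(record@pet))
  record@lesion[lm] <- 1
  if (is(record@params, "PhantomParams"))
    record@params@lesions <- c(record@params@lesions, lesion)
  record
}

#' Core voxels of the injected lesions
#'
#' Lesion voxels at least `marginMm` inside the sphere boundary; used to read
#' out lesion-core abnormality without partial-volume and blur edge effects.
#'
#' @param record a lesioned phantom [SubjectRecord-class].
#' @param marginMm margin in mm eroded from each lesion sphere.
#' @return logical array marking the core voxels.
#' @export
lesionCoreMask <- function(record, marginMm = 2) {
  if (!is(record@params, "PhantomParams") ||
      length(record@params@lesions) == 0L)
    stop("record has no lesion specifications")
  g <- dim(record@pet)[1]
  core <- array(FALSE, dim = dim(record@pet))
  for (les in record@params@lesions) {
    shrunk <- les
    shrunk@radiusMm <- max(les@radiusMm - marginMm, record@spacing[1])
    core <- core | lesionVoxels(shrunk, record@mask, record@gm, g,
                                record@spacing[1])
  }
  core
}

#' Sample a smooth multiplicative bias field
#'
#' Low-frequency field obtained by trilinear upsampling of a coarse Gaussian
#' grid, centred and rescaled so values lie in `[1 - amplitude, 1 + amplitude]`
#' with mean 1 over the grid. Used both by the phantom simulator and by the
#' training augmentation pipeline.
#'
#' @param gridSize voxels per axis.
#' @param amplitude peak deviation, in [0, 1).
#' @param seed RNG seed; the field is deterministic given the seed.
#' @return 3D array of multiplicative factors.
#' @export
sampleBiasField <- function(gridSize, amplitude, seed) {
  if (amplitude < 0 || amplitude >= 1) stop("amplitude must be in [0, 1)")
  withSeed(seed, biasFieldDraw(as.integer(gridSize), amplitude))
}
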