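# Normalization and grid-standardization operators for already-registered,
# skull-stripped volumes: millimetre mask dilation, tissue-referenced MRI
# z-normalization with an out-of-mask sentinel, top-2% PET normalization, and
# centred crop/pad to an isometric cube.

GMWM_THRESHOLD <- 0.5  # a voxel "depicts" GM or WM when gm + wm > 0.5
FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Dilate a binary mask by a millimetre radius
#'
#' Exact Euclidean dilation: the output contains precisely the voxels whose
#' centre lies within `radiusMm` of some mask-voxel centre, honouring
#' (possibly anisotropic) voxel spacing. Computed via an exact distance
#' transform, so it equals brute-force distance thresholding.
#'
#' @param mask binary volume.
#' @param radiusMm dilation radius in mm (0 returns the input).
#' @return binary volume of the same geometry.
#' @export
dilateMask <- function(mask, radiusMm) {
  if (radiusMm < 0) stop("radiusMm must be >= 0")
  if (!any(mask > 0)) stop("mask is empty")
  if (radiusMm == 0) return(withGeom((mask > 0) * 1, mask))
  d2 <- .cpp_edt_sq(as.vector(mask > 0), dim(mask), voxelSpacing(mask))
  withGeom((d2 <= radiusMm^2 + 1e-9) * 1, mask)
}

#' Z-normalize MRI intensities against gray/white matter
#'
#' Centres and scales the MRI by the mean and population standard deviation
#' computed only over voxels depicting gray or white matter
#' (`gm + wm > 0.5`), which keeps the normalization stable under varying
#' degrees of atrophy. Every voxel outside the dilated brain mask is set to
#' the sentinel value exactly, so unmasked voxels are distinguishable from
#' tissue.
#'
#' @param mri MRI volume.
#' @param gm,wm tissue probability volumes.
#' @param dilatedMask binary volume (e.g. from [dilateMask()]).
#' @param sentinel value assigned outside `dilatedMask` (default -7).
#' @return z-scored volume; attributes `mu` and `sigma` record the constants.
#' @export
znormalizeMri <- function(mri, gm, wm, dilatedMask, sentinel = -7) {
  tiss <- (gm + wm) > GMWM_THRESHOLD
  if (sum(tiss) < 2L) stop("fewer than 2 gray/white-matter voxels")
  v <- mri[tiss]
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))  # population SD
  if (sigma == 0) stop("degenerate intensity distribution (zero tissue SD)")
  out <- (mri - mu) / sigma
  out[dilatedMask == 0] <- sentinel
  out <- withGeom(out, mri)
  attr(out, "mu") <- mu
  attr(out, "sigma") <- sigma
  out
}

# mean of the top-`topPct`% (by value) of x: values at or above the
# (100 - topPct)th percentile, ties included
topFractionMean <- function(x, topPct = 2) {
  thr <- quantile(x, probs = 1 - topPct / 100, names = FALSE, type = 7)
  mean(x[x >= thr])
}

#' Normalize PET to a common intensity space
#'
#' Divides the PET by the average of its top-2% gray/white-matter voxels,
#' computed after a Gaussian blur (default 3 mm FWHM). The blur enters only
#' the constant; the returned volume is the unblurred PET divided by it.
#'
#' @param pet non-negative PET volume.
#' @param gm,wm tissue probability volumes.
#' @param blurFwhmMm blur FWHM in mm used when computing the constant
#'   (0 disables the blur).
#' @param topPct top percentage of GM/WM voxels averaged (default 2).
#' @return list with `pet` (normalized volume) and `constant` (the divisor,
#'   in original units per normalized unit).
#' @export
normalizePet <- function(pet, gm, wm, blurFwhmMm = 3, topPct = 2) {
  tiss <- (gm + wm) > GMWM_THRESHOLD
  if (!any(tiss)) stop("no gray/white-matter voxels")
  if (any(pet < 0)) stop("PET must be non-negative")
  blurred <- if (blurFwhmMm > 0) gaussianBlur(pet, blurFwhmMm) else pet
  const <- topFractionMean(blurred[tiss], topPct)
  if (const <= 0) stop("PET normalization constant is not positive")
  list(pet = withGeom(pet / const, pet), constant = const)
}

#' Gaussian blur with a millimetre FWHM
#'
#' Separable Gaussian filter with per-axis sigma `fwhm / (2 sqrt(2 ln 2))`
#' converted to voxels via the spacing. The kernel is renormalised over its
#' in-bounds support at the edges, so constant volumes are unchanged.
#' `fwhmMm = 0` is the identity.
#'
#' @param vol a volume.
#' @param fwhmMm full width at half maximum in mm.
#' @return blurred volume of the same geometry.
#' @export
gaussianBlur <- function(vol, fwhmMm) {
  if (fwhmMm < 0) stop("fwhmMm must be >= 0")
  if (fwhmMm == 0) return(vol)
  sigmaVox <- fwhmMm * FWHM_TO_SIGMA / voxelSpacing(vol)
  withGeom(.cpp_gauss_blur(as.vector(vol), dim(vol), sigmaVox), vol)
}

# per-axis start index (1-based) of a centred crop of n down to size:
# the larger remainder is removed from the high-index side
cropStart <- function(n, size) floor((n - size) / 2) + 1L
# padding placed on the low-index side when growing n up to size
padLow <- function(n, size) floor((size - n) / 2)

#' Crop and/or pad a volume to a cube
#'
#' Centred crop and symmetric pad per axis to `size^3`. When the split is
#' uneven the larger share goes to the high-index side. Padding voxels take
#' `fill`; the voxel-to-world affine is updated so retained voxels keep their
#' world coordinates, making the operation invertible on the retained region.
#'
#' @param vol a volume.
#' @param size target edge length in voxels.
#' @param fill value for padded voxels.
#' @return `size^3` volume.
#' @export
cropPadToCube <- function(vol, size, fill = 0) {
  size <- as.integer(size)
  if (size < 1L) stop("size must be >= 1")
  d <- dim(vol)
  out <- array(fill, dim = rep(size, 3L))
  srcStart <- integer(3)
  dstStart <- integer(3)
  len <- integer(3)
  for (ax in 1:3) {
    if (d[ax] >= size) {
      srcStart[ax] <- cropStart(d[ax], size)
      dstStart[ax] <- 1L
      len[ax] <- size
    } else {
      srcStart[ax] <- 1L
      dstStart[ax] <- padLow(d[ax], size) + 1L
      len[ax] <- d[ax]
    }
  }
  out[dstStart[1]:(dstStart[1] + len[1] - 1),
      dstStart[2]:(dstStart[2] + len[2] - 1),
      dstStart[3]:(dstStart[3] + len[3] - 1)] <-
    vol[srcStart[1]:(srcStart[1] + len[1] - 1),
        srcStart[2]:(srcStart[2] + len[2] - 1),
        srcStart[3]:(srcStart[3] + len[3] - 1)]
  af <- voxelAffine(vol)
  # world position of the new voxel (1,1,1): shift by (src - dst) in voxels
  shift <- (srcStart - dstStart)
  af[1:3, 4] <- af[1:3, 4] + af[1:3, 1:3] %*% shift
  newVolume(out, voxelSpacing(vol), af)
}

#' Preprocess a subject for model training and inference
#'
#' Applies the full normalization chain: brain-mask dilation, MRI
#' z-normalization with sentinel, and top-2% PET normalization. Optionally
#' standardizes the grid to `size^3` first.
#'
#' @param record a [SubjectRecord-class].
#' @param size optional target cube edge (default: keep the native grid).
#' @param sentinel out-of-dilated-mask MRI value.
#' @param dilateMm mask dilation radius in mm.
#' @param blurFwhmMm blur used for the PET normalization constant.
#' @param topPct top-percentage used for the PET normalization constant.
#' @return a [NormalizedSubject-class].
#' @export
preprocessSubject <- function(record, size = NULL, sentinel = -7,
                              dilateMm = 10, blurFwhmMm = 3, topPct = 2) {
  vols <- list(mri = record@mri, pet = record@pet, mask = record@mask,
               gm = record@gm, wm = record@wm, atlas = record@atlas,
               lesion = record@lesion)
  geom <- function(v) newVolume(v, record@spacing, record@affine)
  vols[!vapply(vols, is.null, TRUE)] <-
    lapply(vols[!vapply(vols, is.null, TRUE)], geom)
  if (!is.null(size)) {
    vols$mri <- cropPadToCube(vols$mri, size, fill = 0)
    for (nm in setdiff(names(vols), "mri")) {
      if (!is.null(vols[[nm]])) {
        vols[[nm]] <- cropPadToCube(vols[[nm]], size, fill = 0)
      }
    }
  }
  dil <- dilateMask(vols$mask, dilateMm)
  mriZ <- znormalizeMri(vols$mri, vols$gm, vols$wm, dil, sentinel)
  petn <- normalizePet(vols$pet, vols$gm, vols$wm, blurFwhmMm, topPct)
  new("NormalizedSubject",
      mriZ = stripExtra(mriZ), petN = stripExtra(petn$pet),
      petNormConstant = petn$constant, dilatedMask = stripExtra(dil),
      mask = stripExtra(vols$mask), gm = stripExtra(vols$gm),
      wm = stripExtra(vols$wm),
      atlas = if (is.null(vols$atlas)) NULL else stripExtra(vols$atlas),
      lesion = if (is.null(vols$lesion)) NULL else stripExtra(vols$lesion),
      spacing = voxelSpacing(vols$mri), affine = voxelAffine(vols$mri),
      group = record@group,
      provenance = list(sentinel = sentinel, dilateMm = dilateMm,
                        blurFwhmMm = blurFwhmMm, topPct = topPct,
                        mu = attr(mriZ, "mu"), sigma = attr(mriZ, "sigma"),
                        petNormConstant = petn$constant))
}

# drop geometry/bookkeeping attributes before storing in S4 slots
stripExtra <- function(v) {
  array(as.vector(v), dim = dim(v))
}
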