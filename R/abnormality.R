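# Personalized abnormality analysis: sbPET post-normalization against a
# healthy-uptake region defined by the true PET, the voxel-wise Z% map,
# per-region summaries and group averaging.

#' Healthy-uptake region mask
#'
#' Gray/white-matter voxels whose (blurred) true-PET value lies in the top
#' `topPct` percent of GM/WM uptake: value at or above the
#' `(100 - topPct)`th percentile of the blurred PET over GM/WM voxels, ties
#' included.
#'
#' @param pet true PET volume.
#' @param gm,wm tissue probability volumes.
#' @param blurFwhmMm Gaussian blur FWHM in mm (0 disables).
#' @param topPct top uptake percentage captured.
#' @return binary volume.
#' @export
healthyRegionMask <- function(pet, gm, wm, blurFwhmMm = 3, topPct = 2) {
  tiss <- (gm + wm) > GMWM_THRESHOLD
  if (!any(tiss)) stop("no gray/white-matter voxels")
  blurred <- if (blurFwhmMm > 0) gaussianBlur(pet, blurFwhmMm) else pet
  thr <- quantile(blurred[tiss], probs = 1 - topPct / 100, names = FALSE)
  region <- (tiss & (blurred >= thr)) * 1
  if (!any(region > 0)) stop("degenerate PET: empty healthy region")
  withGeom(region, pet)
}

#' Post-normalize the synthetic baseline to the true PET
#'
#' Rescales the sbPET by `f = mean(pet over region) / mean(sbpet over
#' region)` so that the two volumes agree, on average, over the
#' healthy-uptake region. Invariant to joint rescaling of both inputs.
#'
#' @param sbpet synthetic baseline PET volume.
#' @param pet true PET volume.
#' @param region binary healthy-region volume (see [healthyRegionMask()]).
#' @return list with `sbpet` (rescaled volume) and `factor`.
#' @export
postNormalizeSbpet <- function(sbpet, pet, region) {
  idx <- which(region > 0)
  if (!length(idx)) stop("empty healthy region")
  ms <- mean(sbpet[idx])
  if (ms <= 0) stop("sbPET mean over the healthy region is not positive")
  f <- mean(pet[idx]) / ms
  list(sbpet = withGeom(sbpet * f, sbpet), factor = f)
}

#' Voxel-wise Z% abnormality map
#'
#' Blurs the true PET `Y` and the post-normalized baseline `Yhat` (default
#' 3 mm FWHM) and computes, inside the brain mask,
#' `Z%(x) = 100 (Y(x) - Yhat(x)) / Yhat(x)`:
#' the relative percent deviation of the subject's uptake from the
#' personalized healthy baseline. Negative values indicate hypometabolism,
#' positive hypermetabolism. Voxels with `Yhat <= eps` (and all voxels
#' outside the mask) are undefined (`NA`).
#'
#' @param pet true PET volume.
#' @param sbpetPost post-normalized sbPET (from [postNormalizeSbpet()]).
#' @param mask binary brain mask.
#' @param blurFwhmMm blur applied to both volumes (0 disables).
#' @param eps denominator guard; default `1e-6 *` mean baseline uptake in
#'   the mask.
#' @param postNormFactor factor recorded on the returned map.
#' @param healthyRegion region recorded on the returned map.
#' @return an [AbnormalityMap-class].
#' @export
zmap <- function(pet, sbpetPost, mask, blurFwhmMm = 3, eps = NULL,
                 postNormFactor = 1,
                 healthyRegion = array(0, dim = dim(pet))) {
  if (!identical(dim(pet), dim(sbpetPost)) ||
      !identical(dim(pet), dim(mask))) stop("volumes are not aligned")
  y <- if (blurFwhmMm > 0) gaussianBlur(withGeom(pet, pet), blurFwhmMm)
       else pet
  yh <- if (blurFwhmMm > 0)
          gaussianBlur(withGeom(sbpetPost, sbpetPost), blurFwhmMm)
        else sbpetPost
  if (is.null(eps)) eps <- 1e-6 * mean(yh[mask > 0])
  z <- array(NA_real_, dim = dim(pet))
  ok <- (mask > 0) & (yh > eps)
  z[ok] <- 100 * (y[ok] - yh[ok]) / yh[ok]
  new("AbnormalityMap", zPct = z, postNormFactor = postNormFactor,
      healthyRegion = stripExtra((healthyRegion > 0) * 1),
      summary = data.frame(), spacing = voxelSpacing(pet),
      affine = voxelAffine(pet))
}

#' Full abnormality analysis for one subject
#'
#' Chains [healthyRegionMask()], [postNormalizeSbpet()] and [zmap()], and
#' attaches a per-region summary when an atlas is given. The sbPET is
#' post-normalized first; both volumes are blurred afterwards, then divided.
#'
#' @param pet,sbpet true and synthetic PET volumes (same normalized space).
#' @param mask binary brain mask.
#' @param gm,wm tissue probability volumes.
#' @param atlas optional integer label volume.
#' @param blurFwhmMm blur FWHM for both the region mask and the map.
#' @param topPct healthy-region top-uptake percentage.
#' @return an [AbnormalityMap-class].
#' @export
abnormalityAnalysis <- function(pet, sbpet, mask, gm, wm, atlas = NULL,
                                blurFwhmMm = 3, topPct = 2) {
  region <- healthyRegionMask(pet, gm, wm, blurFwhmMm, topPct)
  pn <- postNormalizeSbpet(sbpet, pet, region)
  m <- zmap(pet, pn$sbpet, mask, blurFwhmMm, postNormFactor = pn$factor,
            healthyRegion = region)
  if (!is.null(atlas)) m@summary <- regionalSummary(m, atlas)
  m
}

#' Per-region summary of an abnormality map
#'
#' Mean, SD and voxel count of the defined Z% voxels within each atlas
#' label. Regions without defined voxels are reported with `NA` mean/SD and
#' a zero count (empty, not zero).
#'
#' @param map an [AbnormalityMap-class].
#' @param atlas integer label volume aligned with the map.
#' @return data.frame with columns region, mean_z_pct, sd_z_pct, n_voxels.
#' @export
regionalSummary <- function(map, atlas) {
  if (!identical(dim(atlas), dim(map@zPct)))
    stop("atlas grid does not match the abnormality map")
  labs <- setdiff(sort(unique(as.vector(atlas))), 0)
  if (!length(labs)) stop("atlas has no labelled regions")
  rows <- lapply(labs, function(lab) {
    z <- map@zPct[atlas == lab]
    z <- z[!is.na(z)]
    if (!length(z))
      return(data.frame(region = lab, mean_z_pct = NA_real_,
                        sd_z_pct = NA_real_, n_voxels = 0L))
    data.frame(region = lab, mean_z_pct = mean(z),
               sd_z_pct = if (length(z) > 1) sd(z) else 0,
               n_voxels = length(z))
  })
  do.call(rbind, rows)
}

#' Group-average abnormality map
#'
#' Voxel-wise mean Z% over subjects sharing one grid, counting only voxels
#' defined in each contributing map; voxels defined in no map remain
#' undefined.
#'
#' @param maps list of [AbnormalityMap-class] objects on identical grids.
#' @return volume of group-mean Z% values with `NA` where undefined.
#' @export
groupMeanMap <- function(maps) {
  if (!length(maps)) stop("need at least one map")
  d <- dim(maps[[1]]@zPct)
  num <- array(0, dim = d)
  cnt <- array(0L, dim = d)
  for (m in maps) {
    if (!identical(dim(m@zPct), d)) stop("abnormality-map grid mismatch")
    ok <- !is.na(m@zPct)
    num[ok] <- num[ok] + m@zPct[ok]
    cnt[ok] <- cnt[ok] + 1L
  }
  out <- array(NA_real_, dim = d)
  out[cnt > 0] <- num[cnt > 0] / cnt[cnt > 0]
  newVolume(out, maps[[1]]@spacing, maps[[1]]@affine)
}
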