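# Synthesis-accuracy metrics. All three headline metrics (PSNR, RD%, Abs%)
# are invariant to joint positive rescaling of the true and synthetic
# volumes, and hence to the PET normalization scheme.

metricMaskIdx <- function(y, mask) {
  idx <- which(mask > 0)
  if (!length(idx)) stop("mask is empty")
  idx
}

# default denominator floor: 1% of the mask-mean true uptake, guarding
# against near-zero CSF denominators
defaultFloor <- function(y, idx) 0.01 * mean(y[idx])

#' Peak signal-to-noise ratio within a mask
#'
#' `10 log10(MAX^2 / MSE)` with `MAX` the maximum of the true volume over the
#' mask and the MSE over mask voxels. Joint rescaling of both volumes leaves
#' the value unchanged.
#'
#' @param y true volume.
#' @param yhat synthetic volume.
#' @param mask binary volume.
#' @return PSNR in dB.
#' @export
psnr <- function(y, yhat, mask) {
  idx <- metricMaskIdx(y, mask)
  mse <- mean((y[idx] - yhat[idx])^2)
  if (mse == 0) stop("identical volumes: PSNR is infinite")
  10 * log10(max(y[idx])^2 / mse)
}

#' Mean relative percent difference (bias)
#'
#' `100 * mean((yhat - y) / y)` over mask voxels with `y` above the floor.
#' Positive values mean the synthetic volume overestimates true uptake.
#'
#' @inheritParams psnr
#' @param floor denominator floor; voxels with `y <= floor` are excluded.
#'   Default: 1% of the mask-mean of `y`.
#' @return signed percentage.
#' @export
rdPercent <- function(y, yhat, mask, floor = NULL) {
  idx <- metricMaskIdx(y, mask)
  if (is.null(floor)) floor <- defaultFloor(y, idx)
  idx <- idx[y[idx] > floor]
  if (!length(idx)) stop("no voxels above the denominator floor")
  100 * mean((yhat[idx] - y[idx]) / y[idx])
}

#' Mean absolute relative percent difference (uncertainty)
#'
#' `100 * mean(|yhat - y| / y)` over the same eligible voxels as
#' [rdPercent()]; the average magnitude of deviation between synthetic and
#' true uptake.
#'
#' @inheritParams rdPercent
#' @return non-negative percentage.
#' @export
absPercent <- function(y, yhat, mask, floor = NULL) {
  idx <- metricMaskIdx(y, mask)
  if (is.null(floor)) floor <- defaultFloor(y, idx)
  idx <- idx[y[idx] > floor]
  if (!length(idx)) stop("no voxels above the denominator floor")
  100 * mean(abs(yhat[idx] - y[idx]) / y[idx])
}

#' Region-wise RD% and Abs%
#'
#' Computes [rdPercent()] and [absPercent()] restricted to each atlas label,
#' using one global denominator floor (1% of the whole-mask mean of `y`)
#' so the whole-brain RD% is the voxel-count-weighted combination of the
#' regional values.
#'
#' @inheritParams psnr
#' @param atlas integer label volume (0 = background).
#' @param regions labels to evaluate (default: all positive labels present).
#' @param mask optional binary volume intersected with each region.
#' @return data.frame with columns region, rd_pct, abs_pct, n_voxels.
#' @export
regionalMetrics <- function(y, yhat, atlas, regions = NULL, mask = NULL) {
  if (!identical(dim(atlas), dim(y))) stop("atlas grid mismatch")
  if (is.null(mask)) mask <- array(1, dim = dim(y))
  present <- setdiff(sort(unique(as.vector(atlas[mask > 0]))), 0)
  if (is.null(regions)) regions <- present
  unknown <- setdiff(regions, present)
  if (length(unknown))
    stop("unknown atlas label(s): ", paste(unknown, collapse = ", "))
  floor <- defaultFloor(y, metricMaskIdx(y, mask))
  rows <- lapply(regions, function(lab) {
    rmask <- (atlas == lab) & (mask > 0)
    idx <- which(rmask & (y > floor))
    if (!length(idx))
      return(data.frame(region = lab, rd_pct = NA_real_,
                        abs_pct = NA_real_, n_voxels = 0L))
    rel <- (yhat[idx] - y[idx]) / y[idx]
    data.frame(region = lab, rd_pct = 100 * mean(rel),
               abs_pct = 100 * mean(abs(rel)), n_voxels = length(idx))
  })
  do.call(rbind, rows)
}

#' Linear fit of the joint uptake distribution
#'
#' Ordinary least squares of synthetic on true uptake over mask voxels;
#' `r2` is the squared Pearson correlation (the explained variance of the
#' fit with intercept).
#'
#' @inheritParams psnr
#' @return list with `slope`, `intercept`, `r2`.
#' @export
jointFit <- function(y, yhat, mask) {
  idx <- metricMaskIdx(y, mask)
  yv <- y[idx]
  yh <- yhat[idx]
  if (length(unique(yv)) < 2L || sd(yv) == 0)
    stop("degenerate variance in true volume")
  fit <- lm(yh ~ yv)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = unname(cor(yv, yh)^2))
}

#' Undo the PET intensity normalization
#'
#' Multiplies a normalized volume by its stored normalization constant,
#' recovering the original (e.g. MBq/ml) scale.
#'
#' @param vol normalized volume.
#' @param constant the positive normalization constant.
#' @return rescaled volume.
#' @export
denormalize <- function(vol, constant) {
  if (constant <= 0) stop("normalization constant must be > 0")
  withGeom(vol * constant, vol)
}

#' Evaluate synthesis accuracy for one subject
#'
#' Whole-brain PSNR, RD% and Abs%, region-wise scores when an atlas is given,
#' and the joint-uptake linear fit.
#'
#' @inheritParams psnr
#' @param atlas optional label volume.
#' @return a [MetricsReport-class].
#' @export
evaluateSynthesis <- function(y, yhat, mask, atlas = NULL) {
  idx <- metricMaskIdx(y, mask)
  floor <- defaultFloor(y, idx)
  per <- if (is.null(atlas)) {
    data.frame(region = integer(), rd_pct = numeric(), abs_pct = numeric(),
               n_voxels = integer())
  } else {
    regionalMetrics(y, yhat, atlas, mask = mask)
  }
  new("MetricsReport",
      psnr = psnr(y, yhat, mask),
      rdPct = rdPercent(y, yhat, mask),
      absPct = absPercent(y, yhat, mask),
      perRegion = per,
      fit = jointFit(y, yhat, mask),
      nVoxels = length(idx[y[idx] > floor]))
}
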