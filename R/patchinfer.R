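# Whole-volume synthesis by tiling patches of neighbouring full sagittal
# slices through the generators and fusing the overlaps with a weighted
# average in which a slice's influence decreases with its sagittal distance
# to the centre of the originating patch.

#' Sagittal patch start positions
#'
#' Stride-1 start positions (1-based) covering every sagittal slice:
#' `1 ... S - w + 1`. With `dropLast = TRUE` the final position is omitted,
#' giving `S - w` positions (one uncovered edge slice); coverage is then no
#' longer guaranteed.
#'
#' @param S number of sagittal slices.
#' @param w patch width in slices.
#' @param dropLast omit the last start position.
#' @return integer vector of start positions.
#' @export
patchPositions <- function(S, w, dropLast = FALSE) {
  if (w < 1 || w > S) stop("patch width must satisfy 1 <= w <= S")
  pos <- seq_len(S - w + 1L)
  if (dropLast && length(pos) > 1L) pos <- pos[-length(pos)]
  pos
}

#' Triangular fusion weight profile
#'
#' Per-offset weights of length `w`: `(w/2 + 0.5) - |offset - (w - 1)/2|`
#' for offsets `0 ... w-1`. Strictly positive, symmetric, maximal at the
#' centre and strictly decreasing towards the patch edges.
#'
#' @param w patch width.
#' @param shape `"triangular"` (default), `"gaussian"` (sigma = w/4) or
#'   `"uniform"`.
#' @return numeric weight vector of length `w`.
#' @export
fusionWeightProfile <- function(w, shape = c("triangular", "gaussian",
                                             "uniform")) {
  if (w < 1) stop("w must be >= 1")
  shape <- match.arg(shape)
  off <- seq_len(w) - 1
  switch(shape,
         triangular = (w / 2 + 0.5) - abs(off - (w - 1) / 2),
         gaussian = exp(-0.5 * ((off - (w - 1) / 2) / (w / 4))^2),
         uniform = rep(1, w))
}

#' Fuse overlapping sagittal patches into a volume
#'
#' Per-voxel weighted average: `sum_p weight_p(x) patch_p(x) / sum_p
#' weight_p(x)`, where a patch's weight at a slice depends only on the
#' slice's offset within that patch. Every slice must be covered by at least
#' one patch.
#'
#' @param patches list of arrays, each `w x H x W`.
#' @param positions 1-based start slice of each patch.
#' @param profile per-offset weights (length `w`), strictly positive.
#' @param S number of sagittal slices of the output.
#' @return fused `S x H x W` array.
#' @export
fusePatches <- function(patches, positions, profile, S) {
  if (length(patches) != length(positions))
    stop("one patch per position required")
  w <- length(profile)
  if (any(profile <= 0)) stop("weight profile must be strictly positive")
  hw <- dim(patches[[1]])[2:3]
  num <- array(0, dim = c(S, hw))
  den <- numeric(S)
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    if (!identical(dim(p), c(w, hw)) && !identical(dim(p), as.integer(c(w, hw))))
      stop("patch shape mismatch")
    sl <- positions[i]:(positions[i] + w - 1L)
    if (positions[i] < 1L || max(sl) > S) stop("patch exceeds the volume")
    num[sl, , ] <- num[sl, , ] + profile * as.vector(p)
    den[sl] <- den[sl] + profile
  }
  if (any(den == 0)) stop("uncovered sagittal slice(s): ",
                          paste(which(den == 0), collapse = ", "))
  num / den
}

extractPatch <- function(vol, pos, w) {
  vol[pos:(pos + w - 1L), , , drop = FALSE]
}

#' Synthesize a baseline PET volume from a normalized MRI
#'
#' Extracts all stride-1 sagittal patches, runs each through the sketcher and
#' then the refiner generator, and fuses the refined patches with the
#' distance-weighted scheme. The output is clamped non-negative and set to 0
#' outside the brain mask.
#'
#' @param mriZ z-normalized MRI volume (sentinel applied).
#' @param mask binary brain mask on the same grid.
#' @param model a [ModelBundle-class], or a list with function elements
#'   `sketcher(mriPatch)` and `refiner(mriPatch, sketchPatch)` (stub models
#'   for plumbing checks).
#' @param weightShape fusion profile shape, see [fusionWeightProfile()].
#' @param patchWidth override of the model's sagittal patch width.
#' @param dropLast see [patchPositions()].
#' @return synthetic baseline PET volume (sbPET).
#' @export
synthesizeVolume <- function(mriZ, mask, model,
                             weightShape = "triangular",
                             patchWidth = NULL, dropLast = FALSE) {
  d <- dim(mriZ)
  w <- if (!is.null(patchWidth)) as.integer(patchWidth)
       else if (is(model, "ModelBundle")) model@arch@patchSlices
       else 32L
  if (w > d[1]) stop("patch width exceeds the sagittal extent")
  runner <- patchRunner(model, c(w, d[2], d[3]))
  positions <- patchPositions(d[1], w, dropLast)
  profile <- fusionWeightProfile(w, weightShape)
  patches <- lapply(positions, function(pos) {
    runner(extractPatch(mriZ, pos, w))
  })
  fused <- fusePatches(patches, positions, profile, d[1])
  fused <- pmax(fused, 0)
  fused[mask == 0] <- 0
  withGeom(fused, mriZ)
}

# build a patch -> refined-patch function from a model specification
patchRunner <- function(model, pdim) {
  if (is.list(model) && is.function(model$sketcher)) {
    sk <- model$sketcher
    rf <- if (is.function(model$refiner)) model$refiner else
      function(mri, sketch) sketch
    return(function(p) {
      s <- sk(p)
      array(rf(p, s), dim = dim(p))
    })
  }
  if (!is(model, "ModelBundle")) stop("unsupported model specification")
  nets <- buildNets(model@arch, seed = model@seed, weights = model)
  function(p) {
    n <- length(p)
    s <- .nn_unet_forward(nets$sketcherG, as.vector(p), dim(p), FALSE)
    rin <- rbind(as.vector(p), s)
    r <- .nn_unet_forward(nets$refinerG, as.vector(rin), dim(p), FALSE)
    array(r, dim = dim(p))
  }
}
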