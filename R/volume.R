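# Volumes are plain 3D numeric arrays carrying geometry as attributes:
#   "spacing" - voxel size in mm per axis
#   "affine"  - 4x4 voxel-to-world matrix (RAS+, 0-based voxel indices)
# Keeping them as arrays keeps voxel arithmetic idiomatic; the S4 surface of
# the package lives in the subject/model/report bundles.

#' Create a volume
#'
#' Attaches voxel spacing and a voxel-to-world affine to a 3D numeric array.
#' All image operators in the package preserve these attributes.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, voxel size in mm.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `spacing` with the origin at voxel (1,1,1).
#' @return the array with `spacing` and `affine` attributes.
#' @export
newVolume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L, length(spacing) == 3L)
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  attr(data, "spacing") <- as.numeric(spacing)
  attr(data, "affine") <- affine
  data
}

#' Voxel spacing of a volume
#' @param vol a volume (see [newVolume()]).
#' @return numeric length-3 spacing in mm (1 mm isotropic if unset).
#' @export
voxelSpacing <- function(vol) {
  sp <- attr(vol, "spacing")
  if (is.null(sp)) c(1, 1, 1) else sp
}

#' Voxel-to-world affine of a volume
#' @param vol a volume.
#' @return 4x4 matrix mapping 0-based voxel indices to world mm.
#' @export
voxelAffine <- function(vol) {
  af <- attr(vol, "affine")
  if (is.null(af)) diag(c(voxelSpacing(vol), 1)) else af
}

# copy geometry attributes from a reference volume onto a data array
withGeom <- function(data, ref) {
  dim(data) <- dim(ref)
  attr(data, "spacing") <- voxelSpacing(ref)
  attr(data, "affine") <- voxelAffine(ref)
  data
}

sameGrid <- function(a, b, tol = 1e-4) {
  identical(dim(a), dim(b)) &&
    max(abs(voxelSpacing(a) - voxelSpacing(b))) < tol &&
    max(abs(voxelAffine(a) - voxelAffine(b))) < tol
}
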