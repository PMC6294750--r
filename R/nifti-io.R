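## NIfTI I/O. World space is RAS millimetres throughout; the affine read from
## (or written to) the header maps 0-based voxel indices to voxel-centre
## world coordinates, the usual neuroimaging convention.

.writeNifti <- function(data, affine, path) {
  im <- RNifti::asNifti(unname(data))
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  nd <- length(dim(data))
  RNifti::pixdim(im) <- c(vs, rep(1, max(0L, nd - 3L)))
  aff <- structure(unname(affine), code = 2L)
  RNifti::sform(im) <- aff
  RNifti::qform(im) <- aff
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Load a 4-D diffusion-weighted volume
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param gtab the matching [GradientTable-class]; its length must equal the
#'   4th image dimension.
#' @return a [DWIVolume-class] with the affine taken from the header.
#' @export
loadDWI <- function(path, gtab) {
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) != 4L)
    stop("DWI format error: expected a 4-D image, got ", length(d), "-D")
  if (d[4] != length(gtab@bvals))
    stop("DWI format error: 4th dimension (", d[4],
         ") does not match gradient table length (", length(gtab@bvals), ")")
  aff <- unclass(RNifti::xform(im))
  attributes(aff) <- list(dim = c(4L, 4L))
  arr <- array(as.numeric(im), dim = d)
  arr[arr < 0] <- 0
  new("DWIVolume", data = arr, affine = aff, gtab = gtab)
}

#' Write a DWIVolume (and optionally its gradient table) to disk
#'
#' @param dwi a [DWIVolume-class].
#' @param path output NIfTI path.
#' @return invisibly, the path.
#' @export
saveDWI <- function(dwi, path) {
  .writeNifti(dwi@data, dwi@affine, path)
}

#' Load a label mask on the grid of a reference volume
#'
#' Float masks holding integral values are cast losslessly; the mask must
#' share grid shape and affine (within 1e-4) with the reference.
#'
#' @param path NIfTI file.
#' @param ref the companion [DWIVolume-class] (or [LabelMask-class]).
#' @param tol affine agreement tolerance.
#' @return a [LabelMask-class].
#' @export
loadMask <- function(path, ref, tol = 1e-4) {
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) == 4L && d[4] == 1L) { d <- d[1:3]; im <- array(im, d) }
  if (length(d) != 3L) stop("mask format error: expected a 3-D image")
  refDim <- dim(ref@data)[1:3]
  if (!all(d == refDim))
    stop("mask geometry error: grid ", paste(d, collapse = "x"),
         " does not match reference ", paste(refDim, collapse = "x"))
  aff <- unclass(RNifti::xform(im))
  attributes(aff) <- list(dim = c(4L, 4L))
  if (max(abs(aff - ref@affine)) > tol)
    stop("mask geometry error: affine differs from reference beyond ", tol)
  vals <- as.numeric(im)
  if (max(abs(vals - round(vals))) > 1e-6)
    stop("mask format error: non-integer label values")
  labelMask(array(round(vals), d), ref@affine)
}

#' Write a label mask to disk
#'
#' @param mask a [LabelMask-class].
#' @param path output NIfTI path.
#' @return invisibly, the path.
#' @export
saveMask <- function(mask, path) {
  .writeNifti(mask@data, mask@affine, path)
}

#' Write a scalar or RGB map to disk
#'
#' @param map 3-D (scalar) or 4-D (e.g. RGB) array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param path output NIfTI path.
#' @return invisibly, the path.
#' @export
saveMap <- function(map, affine, path) {
  .writeNifti(map, affine, path)
}
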