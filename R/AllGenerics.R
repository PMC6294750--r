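#' @rdname tracts
#' @export
setGeneric("tracts", function(x) standardGeneric("tracts"))

#' @rdname tracts
#' @export
setGeneric("bundleLabels", function(x) standardGeneric("bundleLabels"))

#' @rdname tracts
#' @export
setGeneric("bundleLabels<-", function(x, value) standardGeneric("bundleLabels<-"))

#' @rdname affine
#' @export
setGeneric("affine", function(x) standardGeneric("affine"))

#' @rdname gradientTable
#' @export
setGeneric("gradientTable", function(x) standardGeneric("gradientTable"))

#' @rdname faMap
#' @export
setGeneric("faMap", function(x) standardGeneric("faMap"))

#' Number of tracts, particles or acquisitions in a container
#'
#' `nTracts` counts streamlines in a [TractSet-class]; `nParticles` counts
#' segment particles in a [SegmentConfiguration-class].
#'
#' @param x the container.
#' @return an integer count.
#' @export
setGeneric("nTracts", function(x) standardGeneric("nTracts"))

#' @rdname nTracts
#' @export
setGeneric("nParticles", function(x) standardGeneric("nParticles"))

## -- accessors ---------------------------------------------------------------

#' Tracts and bundle labels of a TractSet
#'
#' @param x a [TractSet-class].
#' @param value integer vector of labels, one per tract.
#' @return `tracts()` the list of point matrices; `bundleLabels()` the integer
#'   label vector.
#' @aliases tracts bundleLabels bundleLabels<-
#' @export
setMethod("tracts", "TractSet", function(x) x@tracts)

#' @rdname tracts
setMethod("bundleLabels", "TractSet", function(x) x@labels)

#' @rdname tracts
setMethod("bundleLabels<-", "TractSet", function(x, value) {
  x@labels <- as.integer(value)
  validObject(x)
  x
})

#' Voxel-to-world affine of an image container
#'
#' @param x a [DWIVolume-class], [LabelMask-class] or [TensorField-class].
#' @return the 4x4 voxel-index-to-world-mm matrix (0-based voxel indices,
#'   voxel-centre convention).
#' @aliases affine
#' @export
setMethod("affine", "DWIVolume", function(x) x@affine)

#' @rdname affine
setMethod("affine", "LabelMask", function(x) x@affine)

#' @rdname affine
setMethod("affine", "TensorField", function(x) x@affine)

#' Gradient table of a DWI volume
#'
#' @param x a [DWIVolume-class].
#' @return the [GradientTable-class].
#' @aliases gradientTable
#' @export
setMethod("gradientTable", "DWIVolume", function(x) x@gtab)

#' Fractional anisotropy map of a tensor field
#'
#' @param x a [TensorField-class].
#' @return 3-D array of FA values (0 outside the valid mask).
#' @aliases faMap
#' @export
setMethod("faMap", "TensorField", function(x) x@fa)

setMethod("nTracts", "TractSet", function(x) length(x@tracts))

setMethod("nParticles", "SegmentConfiguration", function(x) nrow(x@particles))

setMethod("length", "GradientTable", function(x) length(x@bvals))

## -- show --------------------------------------------------------------------

setMethod("show", "GradientTable", function(object) {
  cat(sprintf("GradientTable: %d acquisitions (%d b0, %d diffusion-weighted)\n",
              length(object@bvals), sum(object@b0), sum(!object@b0)))
  if (any(!object@b0))
    cat(sprintf("  b-values: %s s/mm^2\n",
                paste(unique(round(object@bvals[!object@b0], 1)), collapse = ", ")))
})

setMethod("show", "DWIVolume", function(object) {
  d <- dim(object@data)
  vs <- sqrt(colSums(object@affine[1:3, 1:3]^2))
  cat(sprintf("DWIVolume: %d x %d x %d grid, %d acquisitions, voxels %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], d[4], vs[1], vs[2], vs[3]))
})

setMethod("show", "LabelMask", function(object) {
  labs <- sort(unique(object@data[object@data > 0]))
  cat(sprintf("LabelMask: %s grid, %d labelled voxels, labels {%s}\n",
              paste(dim(object@data), collapse = " x "),
              sum(object@data > 0), paste(labs, collapse = ", ")))
})

setMethod("show", "TractSet", function(object) {
  np <- if (length(object@tracts)) vapply(object@tracts, nrow, 1L) else integer()
  cat(sprintf("TractSet: %d tracts (%s points/tract), space %s\n",
              length(object@tracts),
              if (length(np)) sprintf("%d-%d", min(np), max(np)) else "-",
              object@space))
  labs <- object@labels[!is.na(object@labels)]
  if (length(labs))
    cat(sprintf("  bundle labels: %s\n",
                paste(sprintf("%d (n=%d)", sort(unique(labs)),
                              tabulate(factor(labs))), collapse = ", ")))
})

setMethod("show", "TensorField", function(object) {
  cat(sprintf("TensorField: %s grid, %d valid voxels, FA range [%.3f, %.3f]\n",
              paste(dim(object@fa), collapse = " x "), sum(object@valid),
              min(object@fa[object@valid]), max(object@fa[object@valid])))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: kind '%s', grid %s at %s mm, SNR %s, seed %d\n",
              object@geometryKind, paste(object@gridShape, collapse = "x"),
              paste(object@voxelSize, collapse = "x"),
              format(object@targetB0SNR), object@seed))
})

setMethod("show", "SegmentConfiguration", function(object) {
  nb <- sum(object@linkPartner > 0)
  cat(sprintf("SegmentConfiguration: %d particles, %d bound endpoints, segment length %.3f mm\n",
              nrow(object@particles), nb, object@segmentLength))
})

setMethod("show", "CosineCurve", function(object) {
  cat(sprintf("CosineCurve: order %d, rmse (%s) mm\n", object@order,
              paste(sprintf("%.3g", object@rmse), collapse = ", ")))
})
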