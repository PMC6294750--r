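#' @useDynLib myotract, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Diffusion gradient table
#'
#' Per-acquisition diffusion encoding: b-values, unit gradient directions and
#' a flag marking baseline (b0) acquisitions.
#'
#' @slot bvals numeric vector of b-values (s/mm^2).
#' @slot bvecs numeric matrix, one row per acquisition, columns x/y/z.
#'   Non-baseline rows are unit vectors; baseline rows may be zero.
#' @slot b0 logical vector flagging baseline acquisitions.
#'
#' @seealso [loadGradientTable()], [makeGradientScheme()]
#' @export
setClass("GradientTable",
  representation(bvals = "numeric", bvecs = "matrix", b0 = "logical"))

setValidity("GradientTable", function(object) {
  n <- length(object@bvals)
  if (nrow(object@bvecs) != n || length(object@b0) != n)
    return("bvals, bvecs rows and b0 flags must have equal length")
  if (ncol(object@bvecs) != 3L)
    return("bvecs must have 3 columns")
  if (!any(object@b0))
    return("at least one baseline (b0) acquisition is required")
  nrm <- sqrt(rowSums(object@bvecs^2))
  bad <- !object@b0 & abs(nrm - 1) > 1e-8
  if (any(bad))
    return("every non-b0 gradient direction must have unit norm (within 1e-8)")
  TRUE
})

#' 4-D diffusion-weighted MRI volume
#'
#' Signal intensities indexed (i, j, k, acquisition), a voxel-to-world affine
#' and the matching [GradientTable-class]. Voxel indices are 0-based and a
#' voxel's world position (RAS millimetres) is the centre of its cell.
#'
#' @slot data 4-D numeric array of non-negative signal intensities.
#' @slot affine 4x4 voxel-index-to-world-mm matrix.
#' @slot gtab the diffusion encoding, a [GradientTable-class].
#'
#' @seealso [loadDWI()], [simulateDWI()]
#' @export
setClass("DWIVolume",
  representation(data = "array", affine = "matrix", gtab = "GradientTable"))

setValidity("DWIVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be a 4-D array")
  if (d[4] != length(object@gtab@bvals))
    return("4th dimension must equal the gradient-table length")
  if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
  if (abs(det(object@affine)) < 1e-12) return("affine must be invertible")
  if (any(object@data < 0)) return("signal must be non-negative")
  TRUE
})

#' Integer label mask on a DWI grid
#'
#' 3-D integer array with 0 = background and labels >= 1 marking regions of
#' interest, sharing grid shape and affine with a companion volume.
#'
#' @slot data 3-D integer array.
#' @slot affine 4x4 voxel-index-to-world-mm matrix.
#' @slot labelNames named character vector mapping label to name (optional).
#'
#' @seealso [loadMask()]
#' @export
setClass("LabelMask",
  representation(data = "array", affine = "matrix", labelNames = "character"))

setValidity("LabelMask", function(object) {
  if (length(dim(object@data)) != 3L) return("mask data must be 3-D")
  if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
  if (any(object@data != round(object@data)))
    return("mask labels must be integer-valued")
  if (any(object@data < 0)) return("mask labels must be >= 0")
  TRUE
})

#' A set of fiber tracts
#'
#' An ordered collection of streamlines, each an n x 3 matrix of world-mm
#' (RAS) coordinates, with optional per-tract bundle labels (ground truth or
#' cluster assignment; NA when unknown).
#'
#' @slot tracts list of numeric matrices (n_i x 3), each with >= 2 points and
#'   no repeated consecutive point.
#' @slot labels integer vector of bundle labels (NA allowed), one per tract.
#' @slot space character space tag; always \code{"world-mm-RAS"}.
#'
#' @seealso [tractSet()], [saveTracts()], [loadTracts()]
#' @export
setClass("TractSet",
  representation(tracts = "list", labels = "integer", space = "character"))

setValidity("TractSet", function(object) {
  if (length(object@labels) != length(object@tracts))
    return("one label per tract required (use NA when unknown)")
  if (!identical(object@space, "world-mm-RAS"))
    return("space tag must be 'world-mm-RAS'")
  for (tr in object@tracts) {
    if (!is.matrix(tr) || ncol(tr) != 3L || nrow(tr) < 2L)
      return("each tract must be a matrix with 3 columns and >= 2 points")
    if (any(rowSums((tr[-1, , drop = FALSE] - tr[-nrow(tr), , drop = FALSE])^2) == 0))
      return("consecutive tract points must be distinct")
  }
  TRUE
})

#' Per-voxel diffusion tensor field
#'
#' Result of voxel-wise tensor estimation: the 3x3 symmetric tensor, its
#' eigen-system, the baseline estimate, fractional anisotropy and a validity
#' mask.
#'
#' @slot tensors 5-D array (nx, ny, nz, 3, 3) of tensors (mm^2/s).
#' @slot s0 3-D array of baseline signal estimates.
#' @slot evals 4-D array (nx, ny, nz, 3), eigenvalues sorted descending.
#' @slot evecs 5-D array (nx, ny, nz, 3, 3); \code{[,,,,m]} is the
#'   eigenvector of eigenvalue m (columns of the orthonormal triad).
#' @slot fa 3-D array of fractional anisotropy in [0, 1] (0 where invalid).
#' @slot valid 3-D logical array of voxels with a successful fit.
#' @slot clamped 3-D logical array flagging voxels whose negative eigenvalues
#'   were clamped to zero.
#' @slot affine 4x4 voxel-index-to-world-mm matrix.
#'
#' @seealso [fitTensor()]
#' @export
setClass("TensorField",
  representation(tensors = "array", s0 = "array", evals = "array",
                 evecs = "array", fa = "array", valid = "array",
                 clamped = "array", affine = "matrix"))

setValidity("TensorField", function(object) {
  d <- dim(object@fa)
  if (length(d) != 3L) return("fa must be 3-D")
  if (!identical(dim(object@evals), c(d, 3L))) return("evals must be (grid, 3)")
  if (!identical(dim(object@evecs), c(d, 3L, 3L))) return("evecs must be (grid, 3, 3)")
  if (any(object@fa < -1e-9 | object@fa > 1 + 1e-9))
    return("fa must lie in [0, 1]")
  TRUE
})

#' Synthetic phantom specification
#'
#' Declarative description of a synthetic crossing-fiber phantom: grid,
#' fiber geometry, stick-mixture signal model and Rician noise level.
#'
#' @slot gridShape integer (nx, ny, nz) voxels.
#' @slot voxelSize numeric mm per axis (length 3).
#' @slot geometryKind one of \code{"straight"}, \code{"arc"},
#'   \code{"crossing"}, \code{"purse_string"}.
#' @slot geometryParams named list of kind-specific parameters
#'   (\code{bundleRadius} mm, \code{arcRadius} mm, \code{crossingAngle}
#'   degrees, \code{midlineGap} mm).
#' @slot nTruthTracts integer, ground-truth streamlines per bundle.
#' @slot b0Intensity baseline signal (arbitrary units).
#' @slot stickDiffusivity mm^2/s along a fiber stick.
#' @slot isoDiffusivity mm^2/s of the isotropic compartment.
#' @slot isoFraction isotropic volume fraction in [0, 1].
#' @slot targetB0SNR target baseline signal-to-noise ratio (Inf = noiseless).
#' @slot seed integer RNG seed.
#'
#' @seealso [phantomSpec()], [makeGeometry()], [simulateDWI()]
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSize = "numeric",
                 geometryKind = "character", geometryParams = "list",
                 nTruthTracts = "integer", b0Intensity = "numeric",
                 stickDiffusivity = "numeric", isoDiffusivity = "numeric",
                 isoFraction = "numeric", targetB0SNR = "numeric",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    return("gridShape must be 3 positive integers")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive values (mm)")
  if (!object@geometryKind %in% c("straight", "arc", "crossing", "purse_string"))
    return("unknown geometry kind")
  if (object@isoFraction < 0 || object@isoFraction > 1)
    return("isoFraction must lie in [0, 1]")
  if (!(object@targetB0SNR > 0))
    return("targetB0SNR must be positive (Inf for noiseless)")
  TRUE
})

#' Ground truth of a synthetic phantom
#'
#' Truth streamlines with bundle labels, plus the per-voxel fiber
#' orientations and volume fractions that generated the signal.
#'
#' @slot tracts [TractSet-class] with bundle labels.
#' @slot voxels data.frame with columns i, j, k (0-based voxel index),
#'   nx, ny, nz (unit stick orientation), fraction (stick volume fraction)
#'   and bundle (label); one row per voxel-bundle pair.
#' @slot spec the generating [PhantomSpec-class].
#'
#' @seealso [makeGeometry()]
#' @export
setClass("PhantomTruth",
  representation(tracts = "TractSet", voxels = "data.frame",
                 spec = "PhantomSpec"))

setValidity("PhantomTruth", function(object) {
  v <- object@voxels
  need <- c("i", "j", "k", "nx", "ny", "nz", "fraction", "bundle")
  if (!all(need %in% names(v))) return("voxels must have columns i j k nx ny nz fraction bundle")
  if (nrow(v)) {
    tot <- tapply(v$fraction, paste(v$i, v$j, v$k), sum)
    if (any(tot > 1 + 1e-9)) return("per-voxel volume fractions must sum to <= 1")
  }
  TRUE
})

#' FACT tracking parameters
#'
#' Gates and step controls for deterministic FACT streamline tracking.
#' Defaults follow the midpoints of the ranges used for low-anisotropy
#' muscle: FA threshold 0.10, angular threshold 60 degrees; the minimum
#' track length used at acquisition scale is 40 mm.
#'
#' @slot faThreshold unitless FA gate in [0, 1].
#' @slot angleThreshold degrees, maximum turning angle per step.
#' @slot minLength mm, minimum emitted polyline arc length.
#' @slot stepSize mm per propagation step.
#' @slot maxSteps maximum steps per direction from a seed.
#' @slot seedsPerVoxel seeds placed per seed-mask voxel.
#'
#' @seealso [factParams()], [factTrack()]
#' @export
setClass("FactParams",
  representation(faThreshold = "numeric", angleThreshold = "numeric",
                 minLength = "numeric", stepSize = "numeric",
                 maxSteps = "integer", seedsPerVoxel = "integer"))

setValidity("FactParams", function(object) {
  if (object@faThreshold < 0 || object@faThreshold > 1)
    return("faThreshold must lie in [0, 1]")
  if (object@angleThreshold <= 0 || object@angleThreshold >= 180)
    return("angleThreshold must lie in (0, 180)")
  if (!is.na(object@minLength) && object@minLength <= 0)
    return("minLength must be positive")
  if (!is.na(object@stepSize) && object@stepSize <= 0)
    return("stepSize must be positive")
  TRUE
})

#' Gibbs global tractography parameters
#'
#' Parameters of the segment point process and its simulated-annealing
#' optimization. Segment geometry and prior weights default to the values
#' used for perineal muscle at acquisition scale: segment length 1.172 mm,
#' width 0.3 mm, signal weight 0.096 and density penalty 0.2, with start/end
#' temperatures 0.1 and 0.001. The desk-scale default iteration count is
#' 2e5; acquisition-scale runs use on the order of 5e8.
#'
#' @slot nIterations Metropolis steps.
#' @slot tStart,tEnd start and end temperatures (tStart > tEnd > 0).
#' @slot segmentLength mm, full length of a segment particle.
#' @slot segmentWidth mm, kernel width for voxel apportionment.
#' @slot segmentWeight per-particle signal contribution (normalized signal
#'   units).
#' @slot densityPenalty prior cost per free (unbound) segment endpoint; the
#'   termination drive that pushes chains to continue and bridge.
#' @slot particlePotential prior cost per segment endpoint, charged whether
#'   bound or not; bounds the particle count by data support.
#' @slot connectionStrength depth of the endpoint binding potential at the
#'   start of the run.
#' @slot connectionStrengthEnd depth at the end of the run (the binding
#'   prior is annealed linearly alongside the temperature; NA = constant).
#' @slot badBondPenalty cost of a geometrically incompatible junction.
#' @slot sigmaGap gap scale of the binding potential (mm).
#' @slot sigmaBend bend scale of the binding potential (radians), measured
#'   between directed endpoint orientations so fold-backs are forbidden.
#' @slot rC mm, connection search radius.
#' @slot muBirth reference mass of the birth/death move (NA = number of mask
#'   voxels, set at run time).
#' @slot moveProbabilities named numeric over birth, death, shift, rotate,
#'   connect, disconnect, extend, retract; must sum to 1.
#' @slot shiftSigma mm, positional proposal scale.
#' @slot rotateSigma radians, orientation proposal scale.
#' @slot extendRadius mm, ball radius of the chain-extension position
#'   proposal.
#' @slot extendAngle radians, cone half-angle of the chain-extension
#'   orientation proposal.
#' @slot minChain minimum particles per emitted streamline.
#' @slot rngSeed integer seed.
#'
#' @seealso [gibbsParams()], [anneal()], [gibbsTrack()]
#' @export
setClass("GibbsParams",
  representation(nIterations = "numeric", tStart = "numeric", tEnd = "numeric",
                 segmentLength = "numeric", segmentWidth = "numeric",
                 segmentWeight = "numeric", densityPenalty = "numeric",
                 particlePotential = "numeric",
                 connectionStrength = "numeric",
                 connectionStrengthEnd = "numeric",
                 badBondPenalty = "numeric", sigmaGap = "numeric",
                 sigmaBend = "numeric", rC = "numeric", muBirth = "numeric",
                 moveProbabilities = "numeric", shiftSigma = "numeric",
                 rotateSigma = "numeric", extendRadius = "numeric",
                 extendAngle = "numeric", minChain = "integer",
                 rngSeed = "integer"))

setValidity("GibbsParams", function(object) {
  if (!(object@tStart > object@tEnd && object@tEnd > 0))
    return("temperatures must satisfy tStart > tEnd > 0")
  mv <- object@moveProbabilities
  need <- c("birth", "death", "shift", "rotate", "connect", "disconnect",
            "extend", "retract")
  if (!identical(sort(names(mv)), sort(need)))
    return(paste("moveProbabilities must be named", paste(need, collapse = " ")))
  if (abs(sum(mv) - 1) > 1e-9) return("move probabilities must sum to 1")
  if (any(mv < 0)) return("move probabilities must be non-negative")
  if (object@segmentLength <= 0) return("segmentLength must be positive")
  TRUE
})

#' Configuration of segment particles
#'
#' The state of the Gibbs model: oriented line segments with endpoint
#' connections. With h = segmentLength / 2, endpoint 1 of a particle sits at
#' position - h * orientation and endpoint 2 at position + h * orientation.
#'
#' @slot particles numeric matrix n x 6: columns px, py, pz (world mm) and
#'   nx, ny, nz (unit orientation, antipodal class).
#' @slot linkPartner integer matrix n x 2; \code{linkPartner[i, e]} is the
#'   particle bound to endpoint e of particle i, or 0 when free.
#' @slot linkEnd integer matrix n x 2; which endpoint (1 or 2) of the partner
#'   is bound, or 0 when free.
#' @slot segmentLength mm, shared full segment length.
#' @slot segmentWeight shared per-particle signal weight.
#'
#' @seealso [segmentConfiguration()], [anneal()], [extractStreamlines()]
#' @export
setClass("SegmentConfiguration",
  representation(particles = "matrix", linkPartner = "matrix",
                 linkEnd = "matrix", segmentLength = "numeric",
                 segmentWeight = "numeric"))

setValidity("SegmentConfiguration", function(object) {
  n <- nrow(object@particles)
  if (n && ncol(object@particles) != 6L)
    return("particles must have 6 columns (position, orientation)")
  if (!identical(dim(object@linkPartner), dim(object@linkEnd)) ||
      (n && !identical(dim(object@linkPartner), c(n, 2L))))
    return("link matrices must be n x 2")
  if (n) {
    nrm <- sqrt(rowSums(object@particles[, 4:6, drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-8)) return("orientations must be unit vectors")
    for (i in seq_len(n)) for (e in 1:2) {
      j <- object@linkPartner[i, e]
      if (j > 0) {
        f <- object@linkEnd[i, e]
        if (j == i) return("a particle may not bind to itself")
        if (object@linkPartner[j, f] != i || object@linkEnd[j, f] != e)
          return("endpoint links must be symmetric")
      }
    }
  }
  TRUE
})

#' Cosine-series parametrization of a curve
#'
#' Per-axis cosine series x(t) = sum_k c_k cos(pi k t) on t in [0, 1], with
#' t the normalized cumulative arc length of the source tract.
#'
#' @slot coef numeric matrix (order + 1) x 3 of coefficients (mm); row k + 1
#'   holds c_k for the three axes.
#' @slot order integer series order K.
#' @slot rmse per-axis residual RMSE of the fit (mm); NA when constructed
#'   directly.
#'
#' @seealso [fitCosineSeries()], [headingCurvature()]
#' @export
setClass("CosineCurve",
  representation(coef = "matrix", order = "integer", rmse = "numeric"))

setValidity("CosineCurve", function(object) {
  if (ncol(object@coef) != 3L) return("coef must have 3 columns")
  if (nrow(object@coef) != object@order + 1L)
    return("coef must have order + 1 rows")
  if (any(!is.finite(object@coef))) return("coefficients must be finite")
  TRUE
})
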