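## Synthetic crossing-fiber phantoms. Geometry is built in world mm with the
## grid centred on the origin; the midline is the plane x = 0. Signal follows
## the stick-mixture model and noise is Rician (magnitude of two independent
## Gaussian channels with a single global sigma = S0 / target SNR).

#' Construct a phantom specification
#'
#' Defaults emulate the acquisition the package targets at desk scale: a
#' 32 x 32 x 12 grid of 1.5-mm isotropic voxels (bundles stay resolvable at
#' this size; acquisition-like 3-mm anisotropic voxels can be requested),
#' stick diffusivity 1.5e-3 mm^2/s, isotropic diffusivity 2.0e-3 mm^2/s and
#' a 10\% isotropic fraction, physiologic values for muscle and interstitial
#' fluid.
#'
#' @param geometryKind \code{"straight"}, \code{"arc"}, \code{"crossing"}
#'   (two straight bundles, default angle 90 degrees) or
#'   \code{"purse_string"} (two point-mirrored arcs interdigitating around
#'   the midline, emulating fibers that cross the perineal body and continue
#'   contralaterally).
#' @param gridShape,voxelSize grid geometry.
#' @param geometryParams overrides for \code{bundleRadius} (mm),
#'   \code{arcRadius} (mm), \code{crossingAngle} (degrees),
#'   \code{midlineGap} (mm, z-separation of the two bundles),
#'   \code{apexOffset} (mm, contralateral overshoot of each purse-string
#'   arc).
#' @param nTruthTracts ground-truth streamlines per bundle.
#' @param b0Intensity,stickDiffusivity,isoDiffusivity,isoFraction signal
#'   model; see [simulateDWI()].
#' @param targetB0SNR baseline SNR of the Rician noise (Inf = noiseless).
#' @param seed integer RNG seed (noise only; geometry is deterministic).
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(geometryKind = "crossing",
                        gridShape = c(32L, 32L, 12L),
                        voxelSize = c(1.5, 1.5, 1.5),
                        geometryParams = list(),
                        nTruthTracts = 25L,
                        b0Intensity = 1000,
                        stickDiffusivity = 1.5e-3,
                        isoDiffusivity = 2.0e-3,
                        isoFraction = 0.1,
                        targetB0SNR = Inf,
                        seed = 1L) {
  defaults <- list(bundleRadius = 4, arcRadius = 18, crossingAngle = 90,
                   midlineGap = 0, apexOffset = 4, arcSweep = 110)
  gp <- utils::modifyList(defaults, geometryParams)
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSize = as.numeric(voxelSize), geometryKind = geometryKind,
      geometryParams = gp, nTruthTracts = as.integer(nTruthTracts),
      b0Intensity = b0Intensity, stickDiffusivity = stickDiffusivity,
      isoDiffusivity = isoDiffusivity, isoFraction = isoFraction,
      targetB0SNR = targetB0SNR, seed = as.integer(seed))
}

#' Voxel-to-world affine of a phantom grid
#'
#' @param spec a [PhantomSpec-class].
#' @return 4x4 matrix placing the grid centre at the world origin.
#' @export
phantomAffine <- function(spec) {
  aff <- diag(4)
  diag(aff)[1:3] <- spec@voxelSize
  aff[1:3, 4] <- -(spec@gridShape - 1) / 2 * spec@voxelSize
  aff
}

## internal: dense centerlines per bundle.
## Returns a list of bundles; each has points (M x 3), tangents (M x 3) and
## frame vectors e1, e2 (M x 3 each) spanning the cross-sectional plane.
.bundleCenterlines <- function(spec) {
  gp <- spec@geometryParams
  half <- spec@gridShape * spec@voxelSize / 2
  M <- 400L
  frame <- function(pts, tans) {
    e1 <- cbind(-tans[, 2], tans[, 1], 0)         # in-plane normal
    nz <- sqrt(rowSums(e1^2))
    flat <- nz < 1e-8
    if (any(flat)) e1[flat, ] <- matrix(c(1, 0, 0), sum(flat), 3, byrow = TRUE)
    e1 <- e1 / sqrt(rowSums(e1^2))
    e2 <- cbind(tans[, 2] * e1[, 3] - tans[, 3] * e1[, 2],
                tans[, 3] * e1[, 1] - tans[, 1] * e1[, 3],
                tans[, 1] * e1[, 2] - tans[, 2] * e1[, 1])
    list(points = pts, tangents = tans, e1 = e1, e2 = e2)
  }
  line <- function(dir, zoff, extent) {
    dir <- unitize(dir)
    s <- seq(-extent, extent, length.out = M)
    pts <- outer(s, dir) + matrix(c(0, 0, zoff), M, 3, byrow = TRUE)
    frame(pts, matrix(dir, M, 3, byrow = TRUE))
  }
  arc <- function(R, sweepDeg, apex, bow = +1, zoff = 0) {
    ## circle arc in the x-y plane; apex = (x, y) of the extremum, bowing
    ## toward +y when bow = +1; traversed left-to-right when bow = +1 and
    ## right-to-left when bow = -1 (point inversion).
    phi <- seq(-sweepDeg, sweepDeg, length.out = M) * pi / 180
    x <- apex[1] + bow * R * sin(phi)
    y <- apex[2] - bow * R * (1 - cos(phi))
    pts <- cbind(x, y, zoff)
    ## tangent = d(pts)/dphi, normalized; traversal follows increasing phi
    tans <- cbind(bow * cos(phi), -bow * sin(phi), 0)
    frame(pts, tans)
  }
  kind <- spec@geometryKind
  if (kind == "straight") {
    list(line(c(1, 0, 0), 0, 0.9 * half[1]))
  } else if (kind == "arc") {
    R <- gp$arcRadius
    sweep <- min(gp$arcSweep / 2, asin(min(0.95, 0.85 * half[1] / R)) * 180 / pi)
    list(arc(R, sweep, c(0, R * (1 - cos(sweep * pi / 180)) / 2)))
  } else if (kind == "crossing") {
    th <- gp$crossingAngle * pi / 180
    g <- gp$midlineGap
    list(line(c(1, 0, 0), +g / 2, 0.9 * half[1]),
         line(c(cos(th), sin(th), 0), -g / 2,
              0.9 * min(half[1:2] / pmax(abs(c(cos(th), sin(th))), 1e-9))))
  } else if (kind == "purse_string") {
    R <- gp$arcRadius
    a <- gp$apexOffset
    g <- gp$midlineGap
    sweep <- min(55, asin(min(0.95, (0.9 * half[1] - a) / R)) * 180 / pi)
    bowY <- min(4, 0.3 * half[2])
    A <- arc(R, sweep, c(+a, +bowY), bow = +1, zoff = +g / 2)
    B <- arc(R, sweep, c(-a, -bowY), bow = -1, zoff = -g / 2)
    list(A, B)
  } else stop("unknown geometry kind")
}

#' Build phantom geometry and ground truth
#'
#' Constructs the bundle centerlines for the requested geometry, derives
#' ground-truth streamlines (parallel offset curves filling each bundle
#' tube) and the per-voxel stick orientations and volume fractions obtained
#' by supersampling every voxel 3x per axis against the tube geometry.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [PhantomTruth-class].
#' @export
makeGeometry <- function(spec) {
  bundles <- .bundleCenterlines(spec)
  gp <- spec@geometryParams
  r <- gp$bundleRadius
  half <- spec@gridShape * spec@voxelSize / 2
  aff <- phantomAffine(spec)

  ## ground-truth tracts: sunflower-packed parallel offsets within the tube
  nT <- spec@nTruthTracts
  golden <- pi * (3 - sqrt(5))
  tracts <- list()
  labels <- integer()
  keep <- seq(1L, 400L, by = 5L)                    # ~80 points per tract
  for (b in seq_along(bundles)) {
    bd <- bundles[[b]]
    for (t in seq_len(nT)) {
      rad <- if (nT == 1L) 0 else 0.85 * r * sqrt((t - 1) / (nT - 1))
      th <- (t - 1) * golden
      off <- rad * (cos(th) * bd$e1 + sin(th) * bd$e2)
      pts <- (bd$points + off)[keep, , drop = FALSE]
      if (any(abs(pts[, 1]) > half[1] | abs(pts[, 2]) > half[2] |
              abs(pts[, 3]) > half[3]))
        stop("phantom geometry error: bundle ", b, " leaves the grid")
      tracts[[length(tracts) + 1L]] <- pts
      labels <- c(labels, b)
    }
  }

  ## per-voxel occupancy and orientation by 3x3x3 supersampling
  dims <- spec@gridShape
  sub <- (seq_len(3) - 2) / 3                       # -1/3, 0, 1/3 voxel
  subOff <- as.matrix(expand.grid(sub, sub, sub))
  rows <- list()
  for (b in seq_along(bundles)) {
    bd <- bundles[[b]]
    cl <- bd$points
    ## candidate voxels: centres within r + voxel diagonal of the centerline
    loV <- floor(worldToVoxel(matrix(apply(cl, 2, min) - r - max(spec@voxelSize), 1), aff))
    hiV <- ceiling(worldToVoxel(matrix(apply(cl, 2, max) + r + max(spec@voxelSize), 1), aff))
    loV <- pmax(loV, 0); hiV <- pmin(hiV, dims - 1)
    if (any(loV > hiV)) next
    idx <- as.matrix(expand.grid(i = loV[1]:hiV[1], j = loV[2]:hiV[2],
                                 k = loV[3]:hiV[3]))
    ctr <- voxelToWorld(idx, aff)
    ## coarse filter on voxel centres
    dctr <- .minDistToPolyline(ctr, cl)
    near <- dctr$dist <= r + max(spec@voxelSize) * sqrt(3) / 2
    if (!any(near)) next
    idx <- idx[near, , drop = FALSE]
    ctr <- ctr[near, , drop = FALSE]
    nearest <- dctr$index[near]
    occ <- numeric(nrow(idx))
    for (s in seq_len(nrow(subOff))) {
      pts <- ctr + matrix(subOff[s, ] * spec@voxelSize, nrow(ctr), 3,
                          byrow = TRUE)
      occ <- occ + (.minDistToPolyline(pts, cl)$dist <= r)
    }
    occ <- occ / nrow(subOff)
    inside <- occ > 0
    if (!any(inside)) next
    tans <- bd$tangents[nearest[inside], , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      i = idx[inside, 1], j = idx[inside, 2], k = idx[inside, 3],
      nx = tans[, 1], ny = tans[, 2], nz = tans[, 3],
      fraction = occ[inside], bundle = b)
  }
  vox <- if (length(rows)) do.call(rbind, rows) else
    data.frame(i = integer(), j = integer(), k = integer(), nx = numeric(),
               ny = numeric(), nz = numeric(), fraction = numeric(),
               bundle = integer())
  ## cap per-voxel totals at 1 (proportional rescale where bundles overlap)
  if (nrow(vox)) {
    key <- paste(vox$i, vox$j, vox$k)
    tot <- tapply(vox$fraction, key, sum)[key]
    over <- tot > 1
    vox$fraction[over] <- vox$fraction[over] / tot[over]
  }
  new("PhantomTruth", tracts = tractSet(tracts, labels), voxels = vox,
      spec = spec)
}

## internal: minimum distance from each point to a dense polyline,
## chunked so the distance matrix stays small.
.minDistToPolyline <- function(pts, poly) {
  n <- nrow(pts)
  dist <- numeric(n); index <- integer(n)
  polySq <- rowSums(poly^2)
  chunk <- max(1L, floor(2e6 / nrow(poly)))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    p <- pts[s:e, , drop = FALSE]
    d2 <- outer(rowSums(p^2), polySq, `+`) - 2 * p %*% t(poly)
    wm <- max.col(-d2, ties.method = "first")
    index[s:e] <- wm
    dist[s:e] <- sqrt(pmax(0, d2[cbind(seq_len(e - s + 1L), wm)]))
  }
  list(dist = dist, index = index)
}

#' Simulate the diffusion-weighted signal of a phantom
#'
#' Noise-free per-voxel signal follows the stick-mixture model
#' \deqn{S(g) = S_0 [\, f_{iso}\,\tau\, e^{-b d_{iso}} +
#'   \sum_f v_f\, e^{-b d_{stick} (g \cdot n_f)^2} ]}
#' with \eqn{\tau} the tissue occupancy of the voxel and
#' \eqn{v_f = (1 - f_{iso})\,\mathrm{occ}_f} the stick volume fractions.
#' Rician noise is applied as the magnitude of two independent Gaussian
#' channels with \eqn{\sigma = S_0 / \mathrm{SNR}}; the result is
#' deterministic given the spec seed.
#'
#' @param truth a [PhantomTruth-class] from [makeGeometry()].
#' @param spec the generating [PhantomSpec-class] (defaults to the one
#'   stored in \code{truth}).
#' @param gtab a [GradientTable-class] with at least 6 non-b0 directions.
#' @return a [DWIVolume-class].
#' @export
simulateDWI <- function(truth, spec = truth@spec,
                        gtab = makeGradientScheme()) {
  if (sum(!gtab@b0) < 6L)
    stop("at least 6 non-b0 directions are required")
  dims <- spec@gridShape
  nAcq <- length(gtab@bvals)
  nVox <- prod(dims)
  sig <- matrix(0, nVox, nAcq)
  v <- truth@voxels
  if (nrow(v)) {
    lin <- 1L + v$i + dims[1] * (v$j + dims[2] * v$k)
    ## stick attenuation per (row, acquisition)
    dot <- cbind(v$nx, v$ny, v$nz) %*% t(gtab@bvecs)
    att <- exp(-outer(rep(1, nrow(v)), gtab@bvals) * spec@stickDiffusivity *
               dot^2)
    vf <- (1 - spec@isoFraction) * v$fraction
    acc <- rowsum(att * vf, lin)               # stick contributions per voxel
    sig[as.integer(rownames(acc)), ] <- acc
    ## isotropic compartment scaled by tissue occupancy
    tau <- rowsum(v$fraction, lin)
    isoAtt <- exp(-gtab@bvals * spec@isoDiffusivity)
    sig[as.integer(rownames(tau)), ] <-
      sig[as.integer(rownames(tau)), , drop = FALSE] +
      outer(as.numeric(tau), isoAtt) * spec@isoFraction
  }
  sig <- sig * spec@b0Intensity
  if (is.finite(spec@targetB0SNR)) {
    sigma <- spec@b0Intensity / spec@targetB0SNR
    sig <- .withSeed(spec@seed, {
      e1 <- matrix(stats::rnorm(length(sig), sd = sigma), nVox, nAcq)
      e2 <- matrix(stats::rnorm(length(sig), sd = sigma), nVox, nAcq)
      sqrt((sig + e1)^2 + e2^2)
    })
  }
  new("DWIVolume", data = array(sig, c(dims, nAcq)),
      affine = phantomAffine(spec), gtab = gtab)
}

#' Whole-bundle label mask of a phantom
#'
#' Labels each voxel by its dominant bundle (0 = background).
#'
#' @param truth a [PhantomTruth-class].
#' @return a [LabelMask-class].
#' @export
phantomMask <- function(truth) {
  spec <- truth@spec
  dims <- spec@gridShape
  lab <- array(0L, dims)
  v <- truth@voxels
  if (nrow(v)) {
    ord <- order(v$fraction)        # later (larger) assignments win
    for (r in ord)
      lab[v$i[r] + 1L, v$j[r] + 1L, v$k[r] + 1L] <- v$bundle[r]
  }
  labelMask(lab, phantomAffine(spec))
}

#' Write a phantom to disk
#'
#' Emits the DWI NIfTI, bval/bvec files, the whole-bundle label mask, the
#' ground-truth tracts (TCK + JSON bundle labels) and a YAML echo of the
#' spec. Re-loading the DWI reproduces [simulateDWI()] output bit-exactly
#' for the same seed.
#'
#' @param spec a [PhantomSpec-class].
#' @param outDir output directory (created if missing).
#' @param gtab gradient table (default [makeGradientScheme()]).
#' @return named list of file paths.
#' @export
writePhantom <- function(spec, outDir, gtab = makeGradientScheme()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  truth <- makeGeometry(spec)
  dwi <- simulateDWI(truth, spec, gtab)
  paths <- list(
    dwi = file.path(outDir, "dwi.nii.gz"),
    bval = file.path(outDir, "dwi.bval"),
    bvec = file.path(outDir, "dwi.bvec"),
    mask = file.path(outDir, "mask.nii.gz"),
    tracts = file.path(outDir, "truth.tck"),
    labels = file.path(outDir, "truth.tck.json"),
    spec = file.path(outDir, "phantom.yaml"))
  saveDWI(dwi, paths$dwi)
  saveGradientTable(gtab, paths$bval, paths$bvec)
  saveMask(phantomMask(truth), paths$mask)
  saveTracts(truth@tracts, paths$tracts)
  yaml::write_yaml(list(
    geometry_kind = spec@geometryKind,
    grid_shape = as.integer(spec@gridShape),
    voxel_size = as.numeric(spec@voxelSize),
    geometry_params = spec@geometryParams,
    n_truth_tracts = spec@nTruthTracts,
    b0_intensity = spec@b0Intensity,
    stick_diffusivity = spec@stickDiffusivity,
    iso_diffusivity = spec@isoDiffusivity,
    iso_fraction = spec@isoFraction,
    target_b0_snr = if (is.finite(spec@targetB0SNR)) spec@targetB0SNR else "Inf",
    seed = spec@seed), paths$spec)
  paths
}
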