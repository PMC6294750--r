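#' Construct FACT tracking parameters
#'
#' @param faThreshold FA gate; tracking stops on entering a voxel below it.
#'   Default 0.10, the midpoint of the 0.08-0.15 range appropriate for
#'   low-anisotropy muscle.
#' @param angleThreshold maximum turning angle in degrees (default 60, the
#'   midpoint of 50-70).
#' @param minLength minimum emitted arc length in mm; NA (default) resolves
#'   at tracking time to 0.25 x the grid diagonal, the desk-scale analogue
#'   of the 40-mm acquisition-scale cutoff.
#' @param stepSize mm; NA resolves to half the smallest voxel dimension.
#' @param maxSteps per-direction step cap.
#' @param seedsPerVoxel seeds per seed-mask voxel (1 = voxel centre; more
#'   are jittered uniformly within the cell).
#' @return a [FactParams-class].
#' @export
factParams <- function(faThreshold = 0.10, angleThreshold = 60,
                       minLength = NA_real_, stepSize = NA_real_,
                       maxSteps = 2000L, seedsPerVoxel = 1L) {
  new("FactParams", faThreshold = faThreshold,
      angleThreshold = angleThreshold,
      minLength = if (is.na(minLength)) NA_real_ else minLength,
      stepSize = if (is.na(stepSize)) NA_real_ else stepSize,
      maxSteps = as.integer(maxSteps),
      seedsPerVoxel = as.integer(seedsPerVoxel))
}

#' Deterministic FACT streamline tracking
#'
#' From every seed, propagates bidirectionally along the nearest-voxel
#' principal eigenvector (re-sampled at each step, sign-aligned with the
#' incoming direction; no interpolation, the defining FACT behaviour). A
#' step terminates on entering a voxel with FA below the threshold or
#' without a valid fit, when the turning angle between consecutive steps
#' (after antipodal alignment) exceeds the angular threshold, when leaving
#' the grid, or at the step cap. The two half-tracks are concatenated and
#' tracks shorter than the minimum length are discarded.
#'
#' @param tf a [TensorField-class].
#' @param seedMask a [LabelMask-class]; voxels with label >= 1 seed tracks.
#' @param p a [FactParams-class].
#' @param seed RNG seed for seed jitter (used when seedsPerVoxel > 1).
#' @return a [TractSet-class].
#' @export
factTrack <- function(tf, seedMask, p = factParams(), seed = 1L) {
  dims <- dim(tf@fa)
  aff <- tf@affine
  vs <- sqrt(colSums(aff[1:3, 1:3]^2))
  stepSize <- if (is.na(p@stepSize)) min(vs) / 2 else p@stepSize
  minLength <- if (is.na(p@minLength))
    0.25 * sqrt(sum((dims * vs)^2)) else p@minLength

  ## principal-direction field (antipodal representative), FA gate
  ok <- tf@valid & tf@fa >= p@faThreshold
  dirs <- array(NA_real_, c(dims, 3L))
  for (v in which(ok)) {
    vox <- arrayInd(v, dims)
    dirs[vox[1], vox[2], vox[3], ] <-
      .antipodalRep(tf@evecs[vox[1], vox[2], vox[3], , 1L])
  }
  inv <- solve(aff)
  toVox <- function(x) round(inv[1:3, 1:3] %*% x + inv[1:3, 4])
  cosThr <- cos(p@angleThreshold * pi / 180)

  march <- function(x0, d0) {
    pts <- list()
    x <- x0; d <- d0
    for (s in seq_len(p@maxSteps)) {
      xn <- x + stepSize * d
      v <- toVox(xn)
      if (any(v < 0) || any(v >= dims)) break
      dn <- dirs[v[1] + 1, v[2] + 1, v[3] + 1, ]
      if (any(is.na(dn))) break                      # FA gate / invalid fit
      if (sum(dn * d) < 0) dn <- -dn                 # antipodal alignment
      if (sum(dn * d) < cosThr) break                # turning-angle gate
      pts[[s]] <- xn
      x <- xn; d <- dn
    }
    pts
  }

  seedVox <- which(seedMask@data >= 1, arr.ind = TRUE) - 1L
  tracts <- .withSeed(seed, {
    out <- list()
    if (nrow(seedVox)) for (r in seq_len(nrow(seedVox))) {
      sv <- seedVox[r, ]
      d0full <- dirs[sv[1] + 1, sv[2] + 1, sv[3] + 1, ]
      if (any(is.na(d0full))) next
      for (sdx in seq_len(p@seedsPerVoxel)) {
        jitter <- if (p@seedsPerVoxel == 1L) c(0, 0, 0) else
          stats::runif(3, -0.5, 0.5)
        x0 <- as.numeric(voxelToWorld(matrix(sv + jitter, 1), aff))
        fwd <- march(x0, d0full)
        bwd <- march(x0, -d0full)
        pts <- rbind(do.call(rbind, rev(bwd)),
                     matrix(x0, 1), do.call(rbind, fwd))
        if (nrow(pts) >= 2L) out[[length(out) + 1L]] <- pts
      }
    }
    out
  })
  filterByLength(tractSet(tracts), minLength)
}

#' Discard tracts below a minimum arc length
#'
#' Keeps tracts whose polyline arc length is at least \code{minLength};
#' at acquisition scale the cutoff used to eliminate fiber fragments is
#' 40 mm.
#'
#' @param ts a [TractSet-class].
#' @param minLength mm.
#' @return the filtered [TractSet-class].
#' @export
filterByLength <- function(ts, minLength) {
  if (!length(ts@tracts)) return(ts)
  keep <- tractLength(ts) >= minLength
  tractSet(ts@tracts[keep], ts@labels[keep])
}
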