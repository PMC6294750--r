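## Recovery metrics scoring reconstructions against phantom ground truth.

#' Through-crossing continuation rate
#'
#' For a crossing phantom, the fraction of tracts that, having entered the
#' central crossing zone, continue straight through it into the same
#' bundle's far side (both endpoints beyond the zone on opposite sides of
#' one bundle axis). Local trackers stall or veer in the low-anisotropy
#' crossing, global tracking should not.
#'
#' @param ts a [TractSet-class].
#' @param halfWidth half-size of the crossing zone in mm (use the bundle
#'   radius).
#' @param center zone centre, world mm (default origin).
#' @param axes candidate bundle axes as a list of axis indices (default
#'   x and y, the crossing-phantom bundles).
#' @return list with \code{rate}, \code{nEntering} and \code{nThrough}.
#' @export
throughCrossingRate <- function(ts, halfWidth, center = c(0, 0, 0),
                                axes = list(1L, 2L)) {
  entering <- 0L; through <- 0L
  for (p in ts@tracts) {
    rel <- p - matrix(center, nrow(p), 3, byrow = TRUE)
    inZone <- abs(rel[, 1]) <= halfWidth & abs(rel[, 2]) <= halfWidth
    if (!any(inZone)) next
    entering <- entering + 1L
    e1 <- rel[1, ]; e2 <- rel[nrow(rel), ]
    ok <- any(vapply(axes, function(a)
      e1[a] < -halfWidth && e2[a] > halfWidth ||
      e1[a] > halfWidth && e2[a] < -halfWidth, TRUE))
    if (ok) through <- through + 1L
  }
  list(rate = if (entering) through / entering else NA_real_,
       nEntering = entering, nThrough = through)
}

#' Opposite-lateral-half endpoint rate
#'
#' Fraction of tracts whose two endpoints lie on opposite sides of the
#' midline plane — the purse-string topology signature of fibers crossing
#' the perineal body and continuing contralaterally.
#'
#' @param ts a [TractSet-class].
#' @param axis midline axis (default 1, x).
#' @param midline plane position in mm (default 0).
#' @return fraction in [0, 1] (NA for an empty set).
#' @export
oppositeHalfRate <- function(ts, axis = 1L, midline = 0) {
  if (!length(ts@tracts)) return(NA_real_)
  mean(vapply(ts@tracts, function(p)
    (p[1, axis] - midline) * (p[nrow(p), axis] - midline) < 0, TRUE))
}

#' Mean angular error of particle orientations against phantom truth
#'
#' Each particle is compared with the stick orientation of the truth voxel
#' it sits in (antipodal angle); particles in voxels without truth
#' orientation are skipped.
#'
#' @param cfg a [SegmentConfiguration-class].
#' @param truth a [PhantomTruth-class].
#' @return list with \code{meanError} (degrees) and \code{n} particles
#'   scored.
#' @export
particleOrientationError <- function(cfg, truth) {
  spec <- truth@spec
  aff <- phantomAffine(spec)
  v <- truth@voxels
  if (!nrow(v) || !nrow(cfg@particles))
    return(list(meanError = NA_real_, n = 0L))
  ## dominant orientation per voxel
  key <- paste(v$i, v$j, v$k)
  best <- tapply(seq_len(nrow(v)), key, function(r) r[which.max(v$fraction[r])])
  lookup <- v[unlist(best), ]
  lkey <- paste(lookup$i, lookup$j, lookup$k)
  vox <- floor(worldToVoxel(cfg@particles[, 1:3, drop = FALSE], aff) + 0.5)
  pkey <- paste(vox[, 1], vox[, 2], vox[, 3])
  m <- match(pkey, lkey)
  ok <- !is.na(m)
  if (!any(ok)) return(list(meanError = NA_real_, n = 0L))
  tr <- as.matrix(lookup[m[ok], c("nx", "ny", "nz")])
  dots <- abs(rowSums(cfg@particles[ok, 4:6, drop = FALSE] * tr))
  ang <- acos(pmin(1, dots)) * 180 / pi
  list(meanError = mean(ang), n = sum(ok))
}

#' Mean angular error of tract tangents against phantom truth
#'
#' Per polyline segment, the antipodal angle between the segment direction
#' and the truth orientation of the voxel the segment midpoint falls in;
#' averaged over all segments of all tracts.
#'
#' @param ts a [TractSet-class].
#' @param truth a [PhantomTruth-class].
#' @return list with \code{meanError} (degrees) and \code{n} segments
#'   scored.
#' @export
tangentError <- function(ts, truth) {
  spec <- truth@spec
  aff <- phantomAffine(spec)
  v <- truth@voxels
  key <- paste(v$i, v$j, v$k)
  best <- tapply(seq_len(nrow(v)), key, function(r) r[which.max(v$fraction[r])])
  lookup <- v[unlist(best), ]
  lkey <- paste(lookup$i, lookup$j, lookup$k)
  errs <- c(); n <- 0L
  for (p in ts@tracts) {
    mid <- (p[-1, , drop = FALSE] + p[-nrow(p), , drop = FALSE]) / 2
    d <- diff(p)
    d <- d / sqrt(rowSums(d^2))
    vox <- floor(worldToVoxel(mid, aff) + 0.5)
    m <- match(paste(vox[, 1], vox[, 2], vox[, 3]), lkey)
    ok <- !is.na(m)
    if (!any(ok)) next
    tr <- as.matrix(lookup[m[ok], c("nx", "ny", "nz")])
    ang <- acos(pmin(1, abs(rowSums(d[ok, , drop = FALSE] * tr)))) * 180 / pi
    errs <- c(errs, ang)
    n <- n + sum(ok)
  }
  list(meanError = if (n) mean(errs) else NA_real_, n = n)
}
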