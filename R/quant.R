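#' Construct a slicing plane
#'
#' @param origin 3-vector, world mm.
#' @param normal 3-vector; normalized internally.
#' @return list with unit \code{normal} and \code{origin}.
#' @export
slicePlane <- function(origin, normal) {
  list(origin = as.numeric(origin), normal = unitize(as.numeric(normal)))
}

#' Intersect tracts with a plane
#'
#' Finds every transversal crossing of each tract polyline through the
#' plane (sign change of the signed distance; points exactly on the plane
#' are counted with the positive side). Crossing points are linearly
#' interpolated; the local direction is the normalized polyline segment at
#' the crossing.
#'
#' @param ts a [TractSet-class].
#' @param plane a [slicePlane()].
#' @return data.frame with columns x, y, z (crossing point), dx, dy, dz
#'   (local direction) and tract (index into \code{ts}).
#' @export
sliceTracts <- function(ts, plane) {
  out <- list()
  for (m in seq_along(ts@tracts)) {
    p <- ts@tracts[[m]]
    d <- as.numeric((p - matrix(plane$origin, nrow(p), 3, byrow = TRUE)) %*%
                    plane$normal)
    d[d == 0] <- .Machine$double.xmin
    i <- which(d[-length(d)] * d[-1] < 0)
    if (!length(i)) next
    w <- d[i] / (d[i] - d[i + 1])
    pt <- p[i, , drop = FALSE] + w * (p[i + 1, , drop = FALSE] - p[i, , drop = FALSE])
    dir <- p[i + 1, , drop = FALSE] - p[i, , drop = FALSE]
    dir <- dir / sqrt(rowSums(dir^2))
    out[[length(out) + 1L]] <- data.frame(
      x = pt[, 1], y = pt[, 2], z = pt[, 3],
      dx = dir[, 1], dy = dir[, 2], dz = dir[, 3], tract = m)
  }
  if (!length(out))
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      dx = numeric(), dy = numeric(), dz = numeric(),
                      tract = integer()))
  do.call(rbind, out)
}

#' Fit a cosine-series parametrization to a tract
#'
#' Per axis, least-squares fit of x(t) = sum_{k=0..K} c_k cos(pi k t) with
#' t the normalized cumulative arc length of the polyline. The constant
#' term c_0 absorbs rigid translation; the fit is exact for curves that are
#' themselves order-K cosine series.
#'
#' @param tract an n x 3 point matrix or single-tract [TractSet-class]
#'   element.
#' @param order series order K; the tract must have more than K + 1 points.
#' @param t optional per-point parameter values in [0, 1]; by default the
#'   normalized cumulative arc length (sampling-density independent).
#' @return a [CosineCurve-class] with per-axis residual RMSE.
#' @export
fitCosineSeries <- function(tract, order = 9L, t = NULL) {
  p <- rbind3(tract)
  n <- nrow(p)
  if (n <= order + 1L)
    stop("cosine series order ", order, " requires more than ", order + 1L,
         " points (got ", n, ")")
  if (is.null(t)) {
    s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
    t <- s / s[length(s)]
  }
  B <- cos(pi * outer(t, 0:order))
  qrB <- qr(B)
  coef <- qr.coef(qrB, p)
  res <- p - B %*% coef
  new("CosineCurve", coef = unname(coef), order = as.integer(order),
      rmse = sqrt(colMeans(res^2)))
}

#' Evaluate a cosine curve and its derivatives
#'
#' @param curve a [CosineCurve-class].
#' @param t parameter values in [0, 1].
#' @param deriv derivative order (0, 1 or 2), with respect to t.
#' @return length(t) x 3 matrix.
#' @export
evalCosineCurve <- function(curve, t, deriv = 0L) {
  k <- 0:curve@order
  ang <- pi * outer(t, k)
  B <- switch(as.character(deriv),
    "0" = cos(ang),
    "1" = -sin(ang) * matrix(pi * k, length(t), length(k), byrow = TRUE),
    "2" = -cos(ang) * matrix((pi * k)^2, length(t), length(k), byrow = TRUE),
    stop("deriv must be 0, 1 or 2"))
  B %*% curve@coef
}

#' Curvature from first and second derivatives
#'
#' kappa = ||x' x x''|| / ||x'||^3, invariant to the parametrization speed.
#' Samples with a vanishing tangent are flagged NA.
#'
#' @param d1,d2 n x 3 matrices of first and second derivatives.
#' @return numeric vector of curvatures (1/mm).
#' @export
curvatureFromDerivatives <- function(d1, d2) {
  d1 <- rbind3(d1); d2 <- rbind3(d2)
  cr <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
              d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
              d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  sp <- sqrt(rowSums(d1^2))
  kappa <- sqrt(rowSums(cr^2)) / sp^3
  kappa[sp < 1e-12] <- NA_real_
  kappa
}

#' Heading-direction and curvature profile of a cosine curve
#'
#' Samples the analytic derivative of the cosine series at n interior
#' points (the even extension pins the derivative to zero at the exact
#' endpoints, so those are excluded). The
#' heading direction is the trajectory tangent; its angle against each
#' world axis is reported in the oriented convention,
#' arccos(tangent . axis / ||tangent||) in [0, 180] degrees (flipping the
#' tract maps every angle to 180 - angle). Curvature is
#' ||x' x x''|| / ||x'||^3.
#'
#' @param curve a [CosineCurve-class] of order >= 1.
#' @param nSamples number of samples over t in [0, 1].
#' @return data.frame with t, angleX, angleY, angleZ (degrees) and
#'   curvature (1/mm; NA where the tangent vanishes).
#' @export
headingCurvature <- function(curve, nSamples = 100L) {
  if (curve@order < 1L) stop("order >= 1 required for a nonzero tangent")
  # interior sampling: the even (cosine) extension forces a vanishing
  # derivative exactly at t = 0 and t = 1, where tangents are undefined
  t <- seq(0.5 / nSamples, 1 - 0.5 / nSamples, length.out = nSamples)
  d1 <- evalCosineCurve(curve, t, 1L)
  d2 <- evalCosineCurve(curve, t, 2L)
  sp <- sqrt(rowSums(d1^2))
  ang <- function(ax) {
    ct <- d1[, ax] / sp
    ct[sp < 1e-12] <- NA_real_
    acos(pmin(1, pmax(-1, ct))) * 180 / pi
  }
  data.frame(t = t, angleX = ang(1), angleY = ang(2), angleZ = ang(3),
             curvature = curvatureFromDerivatives(d1, d2))
}

#' Mean oriented heading angle of tracts
#'
#' The length-weighted mean over polyline segments of the oriented tangent
#' angle against a world axis, in [0, 180] degrees.
#'
#' @param ts a [TractSet-class].
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return numeric vector, one mean angle per tract.
#' @export
tractMeanHeading <- function(ts, axis = 1L) {
  vapply(ts@tracts, function(p) {
    d <- diff(p)
    len <- sqrt(rowSums(d^2))
    ang <- acos(pmin(1, pmax(-1, d[, axis] / len))) * 180 / pi
    sum(ang * len) / sum(len)
  }, 0)
}

#' Canonicalize tract orientation for heading statistics
#'
#' Oriented heading angles depend on traversal direction, so mirrored
#' bundles are only comparable after a consistent orientation convention.
#' Each tract is oriented along the midline axis in the direction given by
#' the sign of its bow — the mean coordinate on the bow axis minus the
#' chord midpoint, i.e. the side its apex bulges to, which is invariant to
#' parallel offsets within a bundle: point-mirrored arc pairs then receive
#' exactly opposite tangent fields, which makes their heading distributions
#' reflectively symmetric about 90 degrees. Tracts with no bow or no
#' midline extent keep their stored order.
#'
#' @param ts a [TractSet-class].
#' @param midlineAxis axis crossed at the midline (default 1, x).
#' @param bowAxis axis of the bundle's bow (default 2, y).
#' @return the re-oriented [TractSet-class].
#' @export
canonicalizeHeading <- function(ts, midlineAxis = 1L, bowAxis = 2L) {
  flip <- function(p) {
    dx <- p[nrow(p), midlineAxis] - p[1, midlineAxis]
    bow <- mean(p[, bowAxis]) - (p[1, bowAxis] + p[nrow(p), bowAxis]) / 2
    if (abs(bow) > 1e-9 && abs(dx) > 1e-9 && sign(dx) != sign(bow))
      p[nrow(p):1, , drop = FALSE] else p
  }
  tractSet(lapply(ts@tracts, flip), ts@labels)
}

#' Histogram of tract-mean heading angles
#'
#' One entry per tract: its mean oriented heading angle against the axis,
#' binned over [0, 180] degrees. Apply [canonicalizeHeading()] first when
#' comparing mirrored bundles.
#'
#' @param ts a non-empty [TractSet-class].
#' @param axis world axis (1, 2, 3).
#' @param binWidth degrees (default 10).
#' @return list with \code{angles} (per tract), \code{breaks} and
#'   \code{counts}.
#' @export
headingHistogram <- function(ts, axis = 1L, binWidth = 10) {
  if (!length(ts@tracts)) stop("empty TractSet")
  ang <- tractMeanHeading(ts, axis)
  breaks <- seq(0, 180, by = binWidth)
  if (breaks[length(breaks)] < 180) breaks <- c(breaks, 180)
  h <- graphics::hist(ang, breaks = breaks, plot = FALSE)
  list(angles = ang, breaks = breaks, counts = h$counts)
}

#' Reflective-symmetry statistic of heading distributions
#'
#' For two mirrored bundles the mean heading angles should sit symmetric
#' about 90 degrees on every axis. With bundle labels the statistic per
#' axis is |mean of the per-bundle mean angles - 90|; without labels it is
#' |grand mean - 90|.
#'
#' @param ts a [TractSet-class], already passed through
#'   [canonicalizeHeading()].
#' @param labels optional bundle labels (default: the set's own).
#' @return list with \code{bundleMeans} (axis x bundle matrix, degrees) and
#'   \code{deviation} (per-axis deviation from 90, degrees).
#' @export
headingSymmetry <- function(ts, labels = bundleLabels(ts)) {
  angles <- vapply(1:3, function(a) tractMeanHeading(ts, a),
                   numeric(length(ts@tracts)))
  angles <- matrix(angles, ncol = 3)
  if (!is.null(labels) && any(!is.na(labels)) &&
      length(unique(stats::na.omit(labels))) >= 2) {
    bm <- apply(angles, 2, function(col) tapply(col, labels, mean))
    dev <- abs(colMeans(bm) - 90)
    list(bundleMeans = t(bm), deviation = stats::setNames(dev, c("x", "y", "z")))
  } else {
    dev <- abs(colMeans(angles) - 90)
    list(bundleMeans = t(colMeans(angles)),
         deviation = stats::setNames(dev, c("x", "y", "z")))
  }
}
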