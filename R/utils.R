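## Coordinate contract: voxel indices are 0-based, a voxel's world position
## (RAS mm) is the centre of its cell, world = affine %*% c(ijk, 1).

#' Convert between voxel indices and world coordinates
#'
#' @param ijk numeric matrix (n x 3) of 0-based voxel indices (may be
#'   fractional).
#' @param xyz numeric matrix (n x 3) of world-mm coordinates.
#' @param affine 4x4 voxel-to-world matrix.
#' @return an n x 3 matrix in the other frame.
#' @export
voxelToWorld <- function(ijk, affine) {
  ijk <- rbind3(ijk)
  t(affine[1:3, 1:3] %*% t(ijk) + affine[1:3, 4])
}

#' @rdname voxelToWorld
#' @export
worldToVoxel <- function(xyz, affine) {
  xyz <- rbind3(xyz)
  inv <- solve(affine)
  t(inv[1:3, 1:3] %*% t(xyz) + inv[1:3, 4])
}

rbind3 <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3L) else x
}

unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

#' Construct a TractSet
#'
#' @param tracts list of n x 3 numeric matrices of world-mm points.
#' @param labels optional integer bundle labels (recycled NA otherwise).
#' @return a [TractSet-class].
#' @export
tractSet <- function(tracts = list(), labels = NULL) {
  tracts <- lapply(tracts, function(m) {
    m <- unname(as.matrix(m))
    storage.mode(m) <- "double"
    m
  })
  if (is.null(labels)) labels <- rep(NA_integer_, length(tracts))
  new("TractSet", tracts = tracts, labels = as.integer(labels),
      space = "world-mm-RAS")
}

#' Polyline arc length of a tract
#'
#' @param points an n x 3 matrix of world-mm points, or a [TractSet-class]
#'   (then a vector of lengths is returned).
#' @return arc length(s) in mm.
#' @export
tractLength <- function(points) {
  if (is(points, "TractSet"))
    return(vapply(points@tracts, tractLength, 0))
  d <- diff(points)
  sum(sqrt(rowSums(d^2)))
}

#' Resample a polyline at equidistant arc-length positions
#'
#' @param points n x 3 matrix.
#' @param n number of output points.
#' @return n x 3 matrix with the same endpoints.
#' @export
resampleTract <- function(points, n = 20L) {
  s <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
  total <- s[length(s)]
  if (total == 0) stop("degenerate tract of zero length")
  ts <- seq(0, total, length.out = n)
  cbind(stats::approx(s, points[, 1], ts)$y,
        stats::approx(s, points[, 2], ts)$y,
        stats::approx(s, points[, 3], ts)$y)
}

## internal: default label names
.maskLabelNames <- function(data) {
  labs <- sort(unique(as.integer(data[data > 0])))
  stats::setNames(sprintf("roi%d", labs), labs)
}

#' Construct a LabelMask
#'
#' @param data 3-D integer-valued array (0 background).
#' @param affine 4x4 voxel-to-world matrix.
#' @param labelNames optional named character vector (names are labels).
#' @return a [LabelMask-class].
#' @export
labelMask <- function(data, affine, labelNames = NULL) {
  data <- round(data)
  storage.mode(data) <- "integer"
  if (is.null(labelNames)) labelNames <- .maskLabelNames(data)
  new("LabelMask", data = unname(data), affine = unname(affine),
      labelNames = labelNames)
}

#' Construct a SegmentConfiguration
#'
#' @param particles n x 6 matrix (position, unit orientation).
#' @param linkPartner,linkEnd n x 2 integer matrices (0 = free endpoint); see
#'   [SegmentConfiguration-class].
#' @param segmentLength full segment length (mm).
#' @param segmentWeight per-particle signal weight.
#' @return a [SegmentConfiguration-class].
#' @export
segmentConfiguration <- function(particles,
                                 linkPartner = NULL, linkEnd = NULL,
                                 segmentLength = 1.172,
                                 segmentWeight = 0.096) {
  particles <- rbind3(particles)
  if (ncol(particles) == 3L) stop("particles need 6 columns (position, orientation)")
  n <- nrow(particles)
  if (is.null(linkPartner)) linkPartner <- matrix(0L, n, 2)
  if (is.null(linkEnd)) linkEnd <- matrix(0L, n, 2)
  storage.mode(linkPartner) <- "integer"
  storage.mode(linkEnd) <- "integer"
  new("SegmentConfiguration", particles = unname(particles),
      linkPartner = unname(linkPartner), linkEnd = unname(linkEnd),
      segmentLength = segmentLength, segmentWeight = segmentWeight)
}

## internal: seed R's RNG reproducibly from an integer, keeping values in range
.withSeed <- function(seed, expr) {
  if (!is.null(seed) && !is.na(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483647))
  }
  force(expr)
}
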