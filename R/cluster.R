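#' Pairwise tract shape distance
#'
#' Symmetrized mean-closest-point distance: the mean over points of a of
#' the distance to the nearest point of b, averaged with the reverse. Both
#' tracts are resampled to a common point count first. A pseudo-metric:
#' non-negative, symmetric, zero on identical curves.
#'
#' @param a,b n x 3 point matrices.
#' @param nPoints resampling count (default 20).
#' @return distance in mm.
#' @export
tractDistance <- function(a, b, nPoints = 20L) {
  pa <- resampleTract(rbind3(a), nPoints)
  pb <- resampleTract(rbind3(b), nPoints)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  (mean(sqrt(apply(d2, 1, min))) + mean(sqrt(apply(d2, 2, min)))) / 2
}

#' Pairwise distance and affinity matrices of a TractSet
#'
#' Affinity = exp(-d^2 / sigma^2); by default sigma is the median
#' off-diagonal distance (the median heuristic, scale-free).
#'
#' @param ts a [TractSet-class].
#' @param sigma affinity bandwidth in mm, or NA for the median heuristic.
#' @param nPoints resampling count for [tractDistance()].
#' @return list with \code{distance}, \code{affinity} and \code{sigma}.
#' @export
tractAffinity <- function(ts, sigma = NA_real_, nPoints = 20L) {
  n <- length(ts@tracts)
  rs <- lapply(ts@tracts, resampleTract, n = nPoints)
  sq <- lapply(rs, function(m) rowSums(m^2))
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i == n) break
    pa <- rs[[i]]; sa <- sq[[i]]
    for (j in seq(i + 1L, n)) {
      d2 <- outer(sa, sq[[j]], `+`) - 2 * pa %*% t(rs[[j]])
      d2[d2 < 0] <- 0
      D[i, j] <- D[j, i] <-
        (mean(sqrt(apply(d2, 1, min))) + mean(sqrt(apply(d2, 2, min)))) / 2
    }
  }
  if (is.na(sigma)) {
    off <- D[upper.tri(D)]
    sigma <- if (length(off)) stats::median(off) else 1
    if (sigma == 0) sigma <- 1
  }
  A <- exp(-D^2 / sigma^2)
  list(distance = D, affinity = A, sigma = sigma)
}

#' Spectral embedding of tracts into 2-D shape space
#'
#' Embeds each tract as a point in the plane spanned by eigenvectors 2 and
#' 3 of the symmetric-normalized affinity matrix D^(-1/2) A D^(-1/2),
#' scaled by their eigenvalues (diffusion-map convention), so that distance
#' in the embedding reflects shape similarity and identical tracts collapse
#' onto one point. Eigenvector signs are fixed by making each vector's
#' largest-magnitude entry positive.
#'
#' @param ts a [TractSet-class] with >= 3 tracts.
#' @param sigma affinity bandwidth (NA = median heuristic).
#' @return list with \code{coords} (n x 2), \code{eigenvalues} (the ones
#'   used) and \code{sigma}.
#' @export
spectralEmbed <- function(ts, sigma = NA_real_) {
  n <- length(ts@tracts)
  if (n < 3L) stop("at least 3 tracts are required for a 2-D embedding")
  aff <- tractAffinity(ts, sigma)
  A <- aff$affinity
  deg <- rowSums(A)
  if (all(A[upper.tri(A)] < 1e-12))
    warning("affinity graph is disconnected (all off-diagonal ~ 0)")
  Dn <- 1 / sqrt(pmax(deg, 1e-300))
  L <- A * outer(Dn, Dn)
  es <- eigen((L + t(L)) / 2, symmetric = TRUE)
  coords <- es$vectors[, 2:3, drop = FALSE] %*% diag(es$values[2:3], 2)
  for (c in 1:2) {
    m <- which.max(abs(coords[, c]))
    if (coords[m, c] < 0) coords[, c] <- -coords[, c]
  }
  list(coords = coords, eigenvalues = es$values[2:3], sigma = aff$sigma)
}

#' Cluster embedded tracts into k bundles
#'
#' Iterative centroid assignment (k-means with multiple deterministic
#' restarts) on the 2-D spectral embedding.
#'
#' @param embedding output of [spectralEmbed()] (or an n x 2 matrix).
#' @param k number of clusters (>= 1).
#' @param seed RNG seed; the result is deterministic given it.
#' @return integer vector of per-tract labels in 1..k.
#' @export
clusterTracts <- function(embedding, k = 2L, seed = 1L) {
  if (k < 1L) stop("k must be >= 1")
  coords <- if (is.list(embedding)) embedding$coords else rbind3(embedding)
  if (k > nrow(coords)) stop("k exceeds the number of tracts")
  if (k == 1L) return(rep(1L, nrow(coords)))
  ## collapse exact duplicates to keep kmeans well-posed
  .withSeed(seed, {
    km <- suppressWarnings(
      stats::kmeans(coords, centers = k, nstart = 10L, iter.max = 100L))
    as.integer(km$cluster)
  })
}

#' Cluster a TractSet by shape
#'
#' Convenience wrapper: [spectralEmbed()] then [clusterTracts()], returning
#' the TractSet with labels set.
#'
#' @param ts a [TractSet-class].
#' @param k number of bundles (default 2, the left/right use case).
#' @param sigma affinity bandwidth (NA = median heuristic).
#' @param seed RNG seed.
#' @return the labelled [TractSet-class].
#' @export
clusterTractSet <- function(ts, k = 2L, sigma = NA_real_, seed = 1L) {
  emb <- spectralEmbed(ts, sigma)
  labs <- clusterTracts(emb, k, seed)
  bundleLabels(ts) <- labs
  ts
}

#' Cluster purity against reference labels
#'
#' Each cluster votes for its dominant reference label; purity is the
#' fraction of tracts matching their cluster's vote.
#'
#' @param labels cluster labels.
#' @param truth reference labels of equal length.
#' @return purity in [0, 1].
#' @export
clusterPurity <- function(labels, truth) {
  stopifnot(length(labels) == length(truth))
  if (!length(labels)) return(NA_real_)
  hit <- 0L
  for (c in unique(labels)) {
    sub <- truth[labels == c]
    hit <- hit + max(table(sub))
  }
  hit / length(labels)
}

#' Assign reconstructed tracts to truth bundles
#'
#' Labels each tract with the bundle of its nearest ground-truth tract
#' (mean-closest-point distance), the scoring link between reconstructions
#' and generator truth.
#'
#' @param ts reconstructed [TractSet-class].
#' @param truth a [PhantomTruth-class] or labelled [TractSet-class].
#' @param nPoints resampling count for the distance computation.
#' @return integer vector of bundle labels.
#' @export
matchToTruth <- function(ts, truth, nPoints = 20L) {
  tt <- if (is(truth, "PhantomTruth")) truth@tracts else truth
  rsA <- lapply(ts@tracts, resampleTract, n = nPoints)
  rsB <- lapply(tt@tracts, resampleTract, n = nPoints)
  sqB <- lapply(rsB, function(m) rowSums(m^2))
  vapply(seq_along(rsA), function(i) {
    pa <- rsA[[i]]
    sa <- rowSums(pa^2)
    d <- vapply(seq_along(rsB), function(j) {
      d2 <- outer(sa, sqB[[j]], `+`) - 2 * pa %*% t(rsB[[j]])
      d2[d2 < 0] <- 0
      (mean(sqrt(apply(d2, 1, min))) + mean(sqrt(apply(d2, 2, min)))) / 2
    }, 0)
    tt@labels[which.min(d)]
  }, 1L)
}
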