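#' Fractional anisotropy from tensor eigenvalues
#'
#' FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||, by convention 0
#' for an all-zero input.
#'
#' @param eigenvalues numeric vector of 3 non-negative eigenvalues, or a
#'   matrix with 3 columns (one row per voxel).
#' @return FA value(s) in [0, 1].
#' @export
fractionalAnisotropy <- function(eigenvalues) {
  ev <- if (is.null(dim(eigenvalues))) matrix(eigenvalues, ncol = 3L)
        else as.matrix(eigenvalues)
  if (ncol(ev) != 3L) stop("three eigenvalues per voxel are required")
  if (any(ev < 0)) stop("negative eigenvalue passed to fractionalAnisotropy")
  nrm <- sqrt(rowSums(ev^2))
  dev <- ev - rowMeans(ev)
  fa <- ifelse(nrm > 0, sqrt(1.5) * sqrt(rowSums(dev^2)) / nrm, 0)
  if (is.null(dim(eigenvalues))) fa[1] else fa
}

#' Fit a diffusion tensor per voxel
#'
#' Ordinary log-linear least squares of
#' log S(g) = log S0 - b g' D g per masked voxel. The fit is exact on
#' noise-free single-tensor data. Negative eigenvalues are clamped to zero
#' and the voxel flagged in the \code{clamped} slot. Voxels outside the mask,
#' with non-positive signal in any acquisition, or below the background
#' intensity threshold are marked invalid (FA reported as 0).
#'
#' @param dwi a [DWIVolume-class] with >= 6 non-b0 directions and >= 1 b0.
#' @param mask optional [LabelMask-class]; voxels with label >= 1 are fit.
#'   When NULL all voxels above the background threshold are fit.
#' @param backgroundThreshold intensity threshold separating tissue from
#'   noise background in the b0 image, as a multiple of the background
#'   standard deviation estimated from the lowest-intensity half of the
#'   volume; default 3. Set to 0 to disable.
#' @return a [TensorField-class].
#' @export
fitTensor <- function(dwi, mask = NULL, backgroundThreshold = 3) {
  gtab <- dwi@gtab
  if (sum(!gtab@b0) < 6L) stop("at least 6 non-b0 directions are required")
  if (!any(gtab@b0)) stop("at least one b0 acquisition is required")
  dims <- dim(dwi@data)[1:3]
  nVox <- prod(dims)
  nAcq <- length(gtab@bvals)
  S <- matrix(dwi@data, nVox, nAcq)

  b0mean <- rowMeans(S[, gtab@b0, drop = FALSE])
  inMask <- if (is.null(mask)) rep(TRUE, nVox) else as.logical(mask@data >= 1)
  if (backgroundThreshold > 0) {
    bg <- b0mean[b0mean <= stats::median(b0mean)]
    thr <- backgroundThreshold * stats::sd(bg)
    if (is.finite(thr)) inMask <- inMask & b0mean > thr
  }
  positive <- rowSums(S <= 0) == 0L
  fit <- which(inMask & positive)

  tensors <- array(0, c(dims, 3L, 3L))
  evals <- array(0, c(dims, 3L))
  evecs <- array(0, c(dims, 3L, 3L))
  fa <- array(0, dims)
  s0 <- array(b0mean, dims)
  valid <- array(FALSE, dims)
  clamped <- array(FALSE, dims)

  if (length(fit)) {
    g <- gtab@bvecs
    b <- gtab@bvals
    X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
               -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
               -2 * b * g[, 2] * g[, 3])
    beta <- qr.coef(qr(X), t(log(S[fit, , drop = FALSE])))  # 7 x nfit
    s0v <- exp(beta[1, ])
    ev3 <- matrix(0, length(fit), 3L)
    for (m in seq_along(fit)) {
      D <- matrix(c(beta[2, m], beta[5, m], beta[6, m],
                    beta[5, m], beta[3, m], beta[7, m],
                    beta[6, m], beta[7, m], beta[4, m]), 3L, 3L)
      es <- eigen(D, symmetric = TRUE)       # eigenvalues descending
      lam <- es$values
      if (any(lam < 0)) {
        clamped[fit[m]] <- TRUE
        lam <- pmax(lam, 0)
      }
      vox <- arrayInd(fit[m], dims)
      tensors[vox[1], vox[2], vox[3], , ] <- D
      evals[vox[1], vox[2], vox[3], ] <- lam
      evecs[vox[1], vox[2], vox[3], , ] <- es$vectors
      ev3[m, ] <- lam
    }
    fa[fit] <- fractionalAnisotropy(ev3)
    s0[fit] <- s0v
    valid[fit] <- TRUE
  }
  new("TensorField", tensors = tensors, s0 = s0, evals = evals,
      evecs = evecs, fa = fa, valid = valid, clamped = clamped,
      affine = dwi@affine)
}

## internal: antipodal representative with non-negative first nonzero entry
.antipodalRep <- function(v) {
  nz <- which(abs(v) > 1e-12)
  if (length(nz) && v[nz[1]] < 0) v <- -v
  v
}

#' Principal diffusion direction at a voxel
#'
#' The eigenvector of the largest eigenvalue, sign-normalized so that its
#' first nonzero component is positive (the antipodal representative). A
#' degenerate lambda1 == lambda2 is broken deterministically: among the tied
#' eigenvectors the one most aligned with the lowest world axis is chosen.
#'
#' @param tf a [TensorField-class].
#' @param voxel integer (i, j, k), 0-based.
#' @return unit 3-vector.
#' @export
principalDirection <- function(tf, voxel) {
  i <- voxel[1] + 1L; j <- voxel[2] + 1L; k <- voxel[3] + 1L
  if (!tf@valid[i, j, k])
    stop("principal direction queried at an invalid voxel")
  lam <- tf@evals[i, j, k, ]
  tied <- which(lam >= lam[1] - 1e-9 * max(lam[1], 1e-30))
  V <- tf@evecs[i, j, k, , tied, drop = FALSE]
  dim(V) <- c(3L, length(tied))
  if (length(tied) == 1L) return(.antipodalRep(V[, 1]))
  # degenerate leading eigenvalue: pick, within the tied subspace, the
  # direction closest to the lowest-index world axis
  P <- V %*% t(V)
  for (a in 1:3) {
    v <- P[, a]
    if (sqrt(sum(v^2)) > 1e-6) return(.antipodalRep(v / sqrt(sum(v^2))))
  }
  .antipodalRep(V[, 1])
}

#' Direction-encoded color FA map
#'
#' Per-voxel RGB = FA * |principal direction| with, in world RAS axes,
#' red mapped to the right-left (x) component, green to antero-posterior
#' (y) and blue to cranio-caudal (z). The channel order is configurable.
#'
#' @param tf a [TensorField-class].
#' @param channels integer permutation mapping world axes (x, y, z) to
#'   (R, G, B); default \code{c(1, 2, 3)}.
#' @return 4-D array (grid, 3) with values in [0, 1]; black where invalid.
#' @export
colorFAMap <- function(tf, channels = c(1L, 2L, 3L)) {
  dims <- dim(tf@fa)
  rgb <- array(0, c(dims, 3L))
  idx <- which(tf@valid)
  for (v in idx) {
    vox <- arrayInd(v, dims)
    d <- abs(tf@evecs[vox[1], vox[2], vox[3], , 1L])
    rgb[vox[1], vox[2], vox[3], ] <- pmin(1, tf@fa[v] * d[channels])
  }
  rgb
}

#' Measure baseline SNR from tissue and background ROIs
#'
#' The ratio of the mean b0 intensity over a tissue ROI to the standard
#' deviation of the b0 intensity over a background ROI placed outside the
#' anatomy. Multiple b0 volumes are averaged first.
#'
#' @param dwi a [DWIVolume-class].
#' @param tissueROI,backgroundROI [LabelMask-class] objects (label >= 1 =
#'   in ROI); both must be non-empty.
#' @return unitless SNR; Inf (with a warning) when the background standard
#'   deviation is zero.
#' @export
measureSNR <- function(dwi, tissueROI, backgroundROI) {
  gtab <- dwi@gtab
  if (!any(gtab@b0)) stop("no b0 volume present")
  dims <- dim(dwi@data)[1:3]
  b0 <- array(rowMeans(matrix(dwi@data, prod(dims),
                              length(gtab@bvals))[, gtab@b0, drop = FALSE]),
              dims)
  tIdx <- tissueROI@data >= 1
  bIdx <- backgroundROI@data >= 1
  if (!any(tIdx) || !any(bIdx)) stop("both ROIs must be non-empty")
  m <- mean(b0[tIdx])
  s <- stats::sd(b0[bIdx])
  if (s == 0) {
    warning("background ROI has zero standard deviation; SNR is undefined")
    return(Inf)
  }
  m / s
}
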