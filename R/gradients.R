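#' Construct a GradientTable
#'
#' Non-baseline directions are normalized to unit length; entries with
#' b <= b0Threshold are flagged as baseline acquisitions.
#'
#' @param bvals numeric b-values (s/mm^2).
#' @param bvecs n x 3 matrix of gradient directions.
#' @param b0Threshold b-values at or below this are treated as baseline
#'   (default 50 s/mm^2, tolerant of vendor jitter and unambiguous at
#'   b = 400).
#' @return a [GradientTable-class].
#' @export
GradientTable <- function(bvals, bvecs, b0Threshold = 50) {
  bvecs <- rbind3(bvecs)
  if (length(bvals) != nrow(bvecs))
    stop("gradient table format error: ", length(bvals), " b-values but ",
         nrow(bvecs), " direction vectors")
  b0 <- bvals <= b0Threshold
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(!b0 & nrm == 0))
    stop("zero-norm direction vector for a non-b0 acquisition")
  scale <- ifelse(nrm > 0, 1 / nrm, 0)
  bvecs <- bvecs * scale
  bvecs[b0 & nrm == 0, ] <- 0
  new("GradientTable", bvals = as.numeric(bvals), bvecs = unname(bvecs),
      b0 = b0)
}

#' Read a gradient table from FSL-style bval/bvec text files
#'
#' Both bvec dialects are accepted: 3 rows x N columns and N rows x 3
#' columns, auto-detected from the shape (a 3 x 3 file is read as
#' row-per-acquisition).
#'
#' @param bvalPath path to the whitespace-separated b-value file.
#' @param bvecPath path to the whitespace-separated direction file.
#' @param b0Threshold see [GradientTable()].
#' @return a [GradientTable-class].
#' @export
loadGradientTable <- function(bvalPath, bvecPath, b0Threshold = 50) {
  bvals <- scan(bvalPath, quiet = TRUE)
  rows <- lapply(strsplit(trimws(readLines(bvecPath)), "\\s+"), as.numeric)
  rows <- rows[vapply(rows, length, 0L) > 0]
  lens <- vapply(rows, length, 0L)
  if (length(unique(lens)) != 1L)
    stop("gradient table format error: ragged bvec file")
  m <- do.call(rbind, rows)
  if (nrow(m) == 3L && ncol(m) != 3L) m <- t(m)           # 3 x N dialect
  if (ncol(m) != 3L) stop("gradient table format error: bvec needs 3 components")
  if (nrow(m) != length(bvals))
    stop("gradient table format error: ", length(bvals), " b-values but ",
         nrow(m), " directions")
  GradientTable(bvals, m, b0Threshold)
}

#' Write a gradient table as bval/bvec text files
#'
#' @param gtab a [GradientTable-class].
#' @param bvalPath,bvecPath output paths; bvec is written in the 3 x N
#'   dialect.
#' @return invisibly, the two paths.
#' @export
saveGradientTable <- function(gtab, bvalPath, bvecPath) {
  writeLines(paste(format(gtab@bvals, scientific = FALSE, trim = TRUE),
                   collapse = " "), bvalPath)
  m <- t(gtab@bvecs)
  writeLines(apply(m, 1, function(r)
    paste(sprintf("%.10f", r), collapse = " ")), bvecPath)
  invisible(c(bvalPath, bvecPath))
}

#' Generate an n-direction gradient scheme by electrostatic repulsion
#'
#' Places n directions on the half-sphere by minimizing the Coulomb energy of
#' the antipodally symmetrized point set, then prepends one baseline
#' acquisition. The default mirrors the acquisition protocol the package
#' targets: 1 baseline plus 32 non-collinear directions at b = 400 s/mm^2.
#' The optimization is deterministic.
#'
#' @param n number of diffusion-weighted directions.
#' @param b b-value of the weighted acquisitions (s/mm^2).
#' @param nIter repulsion iterations.
#' @return a [GradientTable-class] of length n + 1.
#' @export
makeGradientScheme <- function(n = 32L, b = 400, nIter = 400L) {
  # deterministic quasi-uniform start: Fibonacci sphere
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - i / n                         # upper half-ish sphere
  r <- sqrt(pmax(0, 1 - z^2))
  v <- cbind(r * cos(phi), r * sin(phi), z)
  step <- 0.05
  for (it in seq_len(nIter)) {
    g <- matrix(0, n, 3)
    for (a in seq_len(n)) {
      d <- v[-a, , drop = FALSE]
      for (s in c(1, -1)) {              # antipodal pairs repel too
        diff <- matrix(v[a, ], n - 1, 3, byrow = TRUE) - s * d
        r2 <- rowSums(diff^2)
        r2[r2 < 1e-12] <- 1e-12
        g[a, ] <- g[a, ] + colSums(diff / r2^1.5)
      }
    }
    v <- v + step * g / n
    v <- v / sqrt(rowSums(v^2))
    step <- step * 0.99
  }
  GradientTable(c(0, rep(b, n)), rbind(c(0, 0, 0), v))
}
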