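# Shared fixtures, built once per test run. All phantoms are generated in
# code; nothing is read from disk.

fixtureEnv <- new.env()

# default 33-entry gradient scheme (1 b0 + 32 directions at b = 400)
fixGtab <- function() {
  if (is.null(fixtureEnv$gtab)) fixtureEnv$gtab <- makeGradientScheme()
  fixtureEnv$gtab
}

# compact noiseless straight-bundle phantom (grid matched to short anneals)
fixStraight <- function() {
  if (is.null(fixtureEnv$straight)) {
    spec <- phantomSpec("straight", gridShape = c(12L, 12L, 6L),
                        targetB0SNR = Inf,
                        geometryParams = list(bundleRadius = 2.5))
    truth <- makeGeometry(spec)
    dwi <- simulateDWI(truth, spec, fixGtab())
    fixtureEnv$straight <- list(spec = spec, truth = truth, dwi = dwi,
                                mask = phantomMask(truth))
  }
  fixtureEnv$straight
}

# orthogonal crossing phantom at SNR 30
fixCrossing <- function() {
  if (is.null(fixtureEnv$crossing)) {
    spec <- phantomSpec("crossing", targetB0SNR = 30)
    truth <- makeGeometry(spec)
    dwi <- simulateDWI(truth, spec, fixGtab())
    fixtureEnv$crossing <- list(spec = spec, truth = truth, dwi = dwi,
                                mask = phantomMask(truth))
  }
  fixtureEnv$crossing
}

# helical test curve sampled densely (mm)
fixHelix <- function(n = 200L, radius = 10, pitch = 4, turns = 0.75) {
  th <- seq(0, turns * 2 * pi, length.out = n)
  cbind(radius * cos(th), radius * sin(th), pitch * th / (2 * pi))
}

# a simple single-tensor DWI volume synthesized directly from D (no sticks)
fixTensorSignal <- function(D, dims = c(4L, 4L, 3L), s0 = 900,
                            gtab = fixGtab()) {
  b <- gtab@bvals
  g <- gtab@bvecs
  quad <- rowSums((g %*% D) * g)
  sig <- s0 * exp(-b * quad)
  arr <- array(rep(sig, each = prod(dims)), c(dims, length(b)))
  aff <- diag(c(1.5, 1.5, 1.5, 1))
  aff[1:3, 4] <- -(dims - 1) / 2 * 1.5
  new("DWIVolume", data = arr, affine = aff, gtab = gtab)
}
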