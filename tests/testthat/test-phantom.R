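test_that("straight geometry has uniform +x truth tangents", {
  fx <- fixStraight()
  v <- fx$truth@voxels
  expect_gt(nrow(v), 0)
  expect_true(all(abs(abs(v$nx) - 1) < 1e-9))
  expect_true(all(abs(v$ny) < 1e-9 & abs(v$nz) < 1e-9))
  expect_true(all(tapply(v$fraction, paste(v$i, v$j, v$k), sum) <= 1 + 1e-9))
})

test_that("crossing geometry produces two bundles at the stated angle", {
  fx <- fixCrossing()
  labs <- bundleLabels(fx$truth@tracts)
  expect_setequal(unique(labs), c(1L, 2L))
  v <- fx$truth@voxels
  # voxels near the centre hold both bundles at ~90 degrees
  ctr <- v[abs(v$i - 15.5) < 2 & abs(v$j - 15.5) < 2, ]
  expect_setequal(unique(ctr$bundle), c(1L, 2L))
  n1 <- colMeans(ctr[ctr$bundle == 1, c("nx", "ny", "nz")])
  n2 <- colMeans(ctr[ctr$bundle == 2, c("nx", "ny", "nz")])
  n1 <- n1 / sqrt(sum(n1^2)); n2 <- n2 / sqrt(sum(n2^2))
  ang <- acos(abs(sum(n1 * n2))) * 180 / pi
  expect_lt(abs(ang - 90), 1)
})

test_that("purse-string tracts cross the midline into the opposite half", {
  spec <- phantomSpec("purse_string")
  truth <- makeGeometry(spec)
  expect_equal(nTracts(truth@tracts), 2L * spec@nTruthTracts)
  for (p in truth@tracts@tracts)
    expect_lt(p[1, 1] * p[nrow(p), 1], 0)
  # two mirrored bundles
  expect_setequal(unique(bundleLabels(truth@tracts)), c(1L, 2L))
})

test_that("a bundle larger than the grid raises a geometry error", {
  spec <- phantomSpec("arc", gridShape = c(8L, 8L, 4L),
                      geometryParams = list(arcRadius = 30, bundleRadius = 6))
  expect_error(makeGeometry(spec), "geometry error")
})

test_that("noise-free stick signal matches the closed form", {
  gtab <- GradientTable(c(0, 400, 400),
                        rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  spec <- phantomSpec("straight", gridShape = c(9L, 9L, 5L),
                      targetB0SNR = Inf, isoFraction = 0,
                      geometryParams = list(bundleRadius = 2))
  truth <- makeGeometry(spec)
  dwi <- suppressWarnings(tryCatch(simulateDWI(truth, spec, gtab),
                                   error = function(e) e))
  # fewer than 6 directions is a precondition failure
  expect_s3_class(dwi, "error")

  gtab6 <- fixGtab()
  dwi <- simulateDWI(truth, spec, gtab6)
  v <- truth@voxels
  full <- v[v$fraction > 0.999, ][1, ]
  sig <- dwi@data[full$i + 1, full$j + 1, full$k + 1, ]
  s0 <- sig[gtab6@b0][1]
  # along the stick: S = S0 exp(-b d); perpendicular: S = S0
  along <- which(abs(abs(gtab6@bvecs %*% c(1, 0, 0)) - 1) < 0.05 & !gtab6@b0)
  perp <- which(abs(gtab6@bvecs %*% c(1, 0, 0)) < 0.05 & !gtab6@b0)
  if (length(along))
    expect_equal(sig[along[1]] / s0,
                 exp(-400 * spec@stickDiffusivity *
                     sum(gtab6@bvecs[along[1], ] * c(1, 0, 0))^2),
                 tolerance = 1e-10)
  expect_true(all(abs(sig[perp] / s0 - 1) < 0.01))
})

test_that("Rician noise realizes the target baseline SNR", {
  # oracle: sample statistics of the Rician generator at large n
  spec <- phantomSpec("straight", gridShape = c(16L, 16L, 8L),
                      targetB0SNR = 30, seed = 42L)
  truth <- makeGeometry(spec)
  dwi <- simulateDWI(truth, spec, fixGtab())
  mask <- phantomMask(truth)
  b0 <- dwi@data[, , , which(fixGtab()@b0)[1]]
  # background-free voxels: fully occupied by the bundle (tau = 1)
  v <- truth@voxels
  full <- v[v$fraction > 0.999, ]
  tissue <- b0[cbind(full$i + 1, full$j + 1, full$k + 1)]
  bgVox <- mask@data == 0
  bg <- b0[bgVox]
  sigmaHat <- sqrt(mean(bg^2) / 2)        # Rayleigh: E[x^2] = 2 sigma^2
  expect_lt(abs(mean(tissue) / sigmaHat - 30) / 30, 0.1)

  # measureSNR divides by the background STANDARD DEVIATION, which for
  # Rayleigh-distributed magnitude background is sigma * sqrt(2 - pi/2);
  # the measured ratio therefore sits above the channel-sigma SNR by the
  # factor 1 / sqrt(2 - pi/2) ~ 1.526
  tArr <- array(0L, dim(mask@data))
  tArr[cbind(full$i + 1, full$j + 1, full$k + 1)] <- 1L
  tROI <- labelMask(tArr, mask@affine)
  bROI <- labelMask(array(as.integer(bgVox), dim(mask@data)), mask@affine)
  expected <- 30 / sqrt(2 - pi / 2)
  expect_lt(abs(measureSNR(dwi, tROI, bROI) - expected) / expected, 0.1)
})

test_that("simulation is deterministic given the seed", {
  spec <- phantomSpec("straight", gridShape = c(8L, 8L, 4L),
                      targetB0SNR = 20, seed = 7L,
                      geometryParams = list(bundleRadius = 2))
  truth <- makeGeometry(spec)
  d1 <- simulateDWI(truth, spec, fixGtab())
  d2 <- simulateDWI(truth, spec, fixGtab())
  expect_identical(d1@data, d2@data)
})

test_that("stick signal is antipodally symmetric and monotone in b", {
  gtabs <- lapply(c(200, 400, 800), function(b) makeGradientScheme(b = b))
  spec <- phantomSpec("straight", gridShape = c(8L, 8L, 4L),
                      targetB0SNR = Inf,
                      geometryParams = list(bundleRadius = 2))
  truth <- makeGeometry(spec)
  # flipping every stick direction leaves the signal unchanged
  flipped <- truth
  flipped@voxels$nx <- -flipped@voxels$nx
  flipped@voxels$ny <- -flipped@voxels$ny
  flipped@voxels$nz <- -flipped@voxels$nz
  expect_equal(simulateDWI(truth, spec, gtabs[[2]])@data,
               simulateDWI(flipped, spec, gtabs[[2]])@data)
  # increasing b never increases the noise-free signal where g.n != 0
  sigs <- lapply(gtabs, function(g) simulateDWI(truth, spec, g)@data)
  v <- truth@voxels[1, ]
  dirs <- which(!gtabs[[1]]@b0 & abs(gtabs[[1]]@bvecs %*% c(1, 0, 0)) > 0.1)
  for (g in dirs[1:5]) {
    s <- vapply(sigs, function(x) x[v$i + 1, v$j + 1, v$k + 1, g], 0)
    expect_true(all(diff(s) <= 1e-9))
  }
})

test_that("crossing voxels have lower tensor-fit FA than single-stick voxels", {
  fxS <- fixStraight()
  tfS <- fitTensor(fxS$dwi, fxS$mask)
  vS <- fxS$truth@voxels
  fullS <- vS[vS$fraction > 0.999, ][1, ]
  faSingle <- tfS@fa[fullS$i + 1, fullS$j + 1, fullS$k + 1]

  spec <- phantomSpec("crossing", targetB0SNR = Inf)
  truth <- makeGeometry(spec)
  dwi <- simulateDWI(truth, spec, fixGtab())
  tf <- fitTensor(dwi, phantomMask(truth))
  v <- truth@voxels
  key <- paste(v$i, v$j, v$k)
  both <- names(which(table(key) == 2))
  tot <- tapply(v$fraction, key, sum)
  bal <- both[sapply(both, function(k) {
    r <- v[key == k, ]; tot[k] > 0.9 && min(r$fraction) > 0.4
  })]
  expect_gt(length(bal), 0)
  r <- v[key == bal[1], ][1, ]
  faCross <- tf@fa[r$i + 1, r$j + 1, r$k + 1]
  expect_lt(faCross, faSingle)
})

test_that("writePhantom emits a complete, reloadable artifact set", {
  d <- withr::local_tempdir()
  spec <- phantomSpec("crossing", gridShape = c(16L, 16L, 6L),
                      targetB0SNR = 25, seed = 3L,
                      geometryParams = list(bundleRadius = 3))
  paths <- writePhantom(spec, d)
  expect_true(all(file.exists(unlist(paths))))
  gtab <- loadGradientTable(paths$bval, paths$bvec)
  dwi <- loadDWI(paths$dwi, gtab)
  truth <- makeGeometry(spec)
  ref <- simulateDWI(truth, spec, makeGradientScheme())
  expect_equal(dwi@data, ref@data)                 # bit-exact for same seed
  mask <- loadMask(paths$mask, dwi)
  expect_setequal(unique(as.integer(mask@data[mask@data > 0])), c(1L, 2L))
  ts <- loadTracts(paths$tracts)
  expect_equal(nTracts(ts), 2L * spec@nTruthTracts)
  expect_setequal(unique(bundleLabels(ts)), c(1L, 2L))
})
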