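test_that("fractional anisotropy matches its closed form", {
  expect_equal(fractionalAnisotropy(c(1, 1, 1)), 0)
  expect_equal(fractionalAnisotropy(c(1, 0, 0)), 1)
  # independent evaluation of the closed-form expression for (2, 1, 1):
  # sqrt(3/2) * ||(2,1,1) - 4/3|| / ||(2,1,1)|| = sqrt(1.5)/3 = 0.4082483
  lam <- c(2, 1, 1)
  oracle <- sqrt(1.5) * sqrt(sum((lam - mean(lam))^2)) / sqrt(sum(lam^2))
  expect_equal(oracle, 0.40824829, tolerance = 1e-7)
  expect_equal(fractionalAnisotropy(lam), oracle, tolerance = 1e-12)
  expect_error(fractionalAnisotropy(c(1, -0.1, 0)), "negative")
  # scale invariance
  for (c in c(0.3, 2, 1e4))
    expect_equal(fractionalAnisotropy(c * c(1.7, 0.4, 0.2)),
                 fractionalAnisotropy(c(1.7, 0.4, 0.2)), tolerance = 1e-12)
})

test_that("log-linear fit recovers a noise-free tensor exactly", {
  D <- diag(c(1.5, 0.3, 0.3)) * 1e-3
  dwi <- fixTensorSignal(D)
  tf <- fitTensor(dwi, backgroundThreshold = 0)
  ctr <- c(2, 2, 2)
  Dhat <- tf@tensors[ctr[1], ctr[2], ctr[3], , ]
  expect_lt(max(abs(Dhat - D)) / max(abs(D)), 1e-10)
  expect_equal(principalDirection(tf, ctr - 1), c(1, 0, 0), tolerance = 1e-8)
  expect_equal(tf@s0[ctr[1], ctr[2], ctr[3]], 900, tolerance = 1e-8)

  # rotated tensor: FA invariant, principal direction rotates with it
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tfR <- fitTensor(fixTensorSignal(R %*% D %*% t(R)), backgroundThreshold = 0)
  expect_equal(tfR@fa[2, 2, 2], tf@fa[2, 2, 2], tolerance = 1e-8)
  v <- principalDirection(tfR, ctr - 1)
  expect_equal(abs(sum(v * (R %*% c(1, 0, 0)))), 1, tolerance = 1e-8)
})

test_that("constant signal yields an isotropic tensor with zero FA", {
  D <- diag(c(1, 1, 1)) * 1e-3
  tf <- fitTensor(fixTensorSignal(D), backgroundThreshold = 0)
  expect_equal(tf@fa[2, 2, 2], 0, tolerance = 1e-7)
})

test_that("masked-out and degenerate voxels are flagged, not fatal", {
  D <- diag(c(1.5, 0.3, 0.3)) * 1e-3
  dwi <- fixTensorSignal(D)
  dwi@data[1, 1, 1, ] <- 0                       # dead voxel
  mask <- labelMask(array(c(0L, rep(1L, prod(dim(dwi@data)[1:3]) - 1L)),
                          dim(dwi@data)[1:3]), dwi@affine)
  tf <- fitTensor(dwi, mask, backgroundThreshold = 0)
  expect_false(tf@valid[1, 1, 1])                # outside mask
  expect_equal(tf@fa[1, 1, 1], 0)
  expect_error(principalDirection(tf, c(0, 0, 0)), "invalid")
})

test_that("antipodal and degenerate principal directions are canonical", {
  D <- diag(c(1.5, 0.3, 0.3)) * 1e-3
  tf <- fitTensor(fixTensorSignal(D), backgroundThreshold = 0)
  # a tensor built from -v gives the same representative
  v <- c(-1, 0, 0)
  D2 <- 1.5e-3 * outer(v, v) + 0.3e-3 * (diag(3) - outer(v, v))
  tf2 <- fitTensor(fixTensorSignal(D2), backgroundThreshold = 0)
  expect_equal(principalDirection(tf, c(1, 1, 1)),
               principalDirection(tf2, c(1, 1, 1)), tolerance = 1e-8)
  # oblate (lambda1 == lambda2): deterministic lowest-axis tie-break
  D3 <- diag(c(1, 1, 0.2)) * 1e-3
  tf3 <- fitTensor(fixTensorSignal(D3), backgroundThreshold = 0)
  pd <- principalDirection(tf3, c(1, 1, 1))
  expect_equal(abs(pd[1]), 1, tolerance = 1e-6)
})

test_that("color FA map follows the RAS channel convention", {
  D <- diag(c(1.5, 0.3, 0.3)) * 1e-3              # right-left fiber
  tf <- fitTensor(fixTensorSignal(D), backgroundThreshold = 0)
  rgb <- colorFAMap(tf)
  fa <- tf@fa[2, 2, 2]
  expect_equal(rgb[2, 2, 2, ], c(fa, 0, 0), tolerance = 1e-6)
  # cranio-caudal fiber lights only the blue channel
  Dz <- diag(c(0.3, 0.3, 1.5)) * 1e-3
  tfz <- fitTensor(fixTensorSignal(Dz), backgroundThreshold = 0)
  rgbz <- colorFAMap(tfz)
  expect_equal(rgbz[2, 2, 2, 1:2], c(0, 0), tolerance = 1e-6)
  expect_gt(rgbz[2, 2, 2, 3], 0.5)
  # invalid voxels are black
  dwi <- fixTensorSignal(D)
  mask <- labelMask(array(0L, dim(dwi@data)[1:3]), dwi@affine)
  tfb <- fitTensor(dwi, mask, backgroundThreshold = 0)
  expect_true(all(colorFAMap(tfb) == 0))
})

test_that("measureSNR implements the ROI ratio definition", {
  dims <- c(6L, 6L, 3L)
  arr <- array(0, c(dims, length(fixGtab()@bvals)))
  arr[1:3, , , ] <- 50                              # tissue
  set.seed(2)
  arr[4:6, , , ] <- abs(rnorm(prod(c(3L, dims[2:3], length(fixGtab()@bvals)))))
  aff <- diag(4)
  dwi <- new("DWIVolume", data = arr, affine = aff, gtab = fixGtab())
  tROI <- labelMask(array(rep(c(1L, 0L), times = c(3, 3)), dims), aff)
  bROI <- labelMask(array(rep(c(0L, 1L), times = c(3, 3)), dims), aff)
  b0 <- arr[, , , which(fixGtab()@b0)[1]]
  expect_equal(measureSNR(dwi, tROI, bROI), 50 / sd(b0[4:6, , ]))
  # zero tissue signal -> 0; zero background spread -> Inf with warning
  arr0 <- arr; arr0[1:3, , , ] <- 0
  dwi0 <- new("DWIVolume", data = arr0, affine = aff, gtab = fixGtab())
  expect_equal(measureSNR(dwi0, tROI, bROI), 0)
  arrC <- arr; arrC[4:6, , , ] <- 1
  dwiC <- new("DWIVolume", data = arrC, affine = aff, gtab = fixGtab())
  expect_warning(snr <- measureSNR(dwiC, tROI, bROI), "undefined")
  expect_identical(snr, Inf)
})
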