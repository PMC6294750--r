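test_that("gradient tables load, normalize and round-trip", {
  d <- withr::local_tempdir()
  bval <- file.path(d, "a.bval"); bvec <- file.path(d, "a.bvec")
  gt0 <- fixGtab()
  saveGradientTable(gt0, bval, bvec)
  gt <- loadGradientTable(bval, bvec)
  expect_equal(sum(gt@b0), 1L)
  expect_equal(sum(!gt@b0), 32L)
  expect_equal(gt@bvecs, gt0@bvecs, tolerance = 1e-8)
  expect_equal(gt@bvals, gt0@bvals)

  # un-normalized input vectors are stored unit length
  gt2 <- GradientTable(c(0, 400), rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(gt2@bvecs[2, ], c(1, 0, 0))

  # both bvec dialects are accepted
  writeLines("0 400 400 400", bval)
  writeLines(c("0 1 0 0", "0 0 1 0", "0 0 0 1"), bvec)     # 3 x N
  gt3 <- loadGradientTable(bval, bvec)
  expect_equal(gt3@bvecs[2, ], c(1, 0, 0))
  writeLines(c("0 0 0", "1 0 0", "0 1 0", "0 0 1"), bvec)  # N x 3
  gt4 <- loadGradientTable(bval, bvec)
  expect_equal(gt4@bvecs[3, ], c(0, 1, 0))
})

test_that("gradient table errors on malformed input", {
  d <- withr::local_tempdir()
  bval <- file.path(d, "a.bval"); bvec <- file.path(d, "a.bvec")
  writeLines("0 400 400", bval)
  writeLines(c("0 1", "0 0", "0 0"), bvec)
  expect_error(loadGradientTable(bval, bvec), "format error")
  expect_error(GradientTable(c(0, 400), rbind(c(0, 0, 0), c(0, 0, 0))),
               "zero-norm")
})

test_that("DWI volumes round-trip through NIfTI with affine preserved", {
  d <- withr::local_tempdir()
  fx <- fixStraight()
  p <- file.path(d, "dwi.nii.gz")
  saveDWI(fx$dwi, p)
  dwi2 <- loadDWI(p, fixGtab())
  expect_identical(dim(dwi2@data), dim(fx$dwi@data))
  expect_equal(dwi2@data, fx$dwi@data)            # float64 on disk: bit-exact
  expect_equal(dwi2@affine, fx$dwi@affine, tolerance = 1e-5)
})

test_that("loadDWI rejects wrong dimensionality and gradient mismatch", {
  d <- withr::local_tempdir()
  im3 <- array(1, c(4, 4, 4))
  RNifti::writeNifti(RNifti::asNifti(im3), file.path(d, "a.nii.gz"))
  expect_error(loadDWI(file.path(d, "a.nii.gz"), fixGtab()), "4-D")
  im4 <- array(1, c(4, 4, 4, 30))
  RNifti::writeNifti(RNifti::asNifti(im4), file.path(d, "b.nii.gz"))
  expect_error(loadDWI(file.path(d, "b.nii.gz"), fixGtab()),
               "gradient table")
})

test_that("masks load with integer labels and geometry checks", {
  d <- withr::local_tempdir()
  fx <- fixStraight()
  mp <- file.path(d, "mask.nii.gz")
  saveMask(fx$mask, mp)
  m <- loadMask(mp, fx$dwi)
  expect_identical(m@data, fx$mask@data)

  # float 0/1 volumes are cast losslessly
  fl <- array(as.numeric(fx$mask@data > 0), dim(fx$mask@data))
  .ignore <- myotract:::.writeNifti(fl, fx$mask@affine, mp)
  m2 <- loadMask(mp, fx$dwi)
  expect_true(all(m2@data %in% c(0L, 1L)))

  # shifted affine is a geometry error
  aff <- fx$mask@affine; aff[1, 4] <- aff[1, 4] + 1
  myotract:::.writeNifti(fx$mask@data, aff, mp)
  expect_error(loadMask(mp, fx$dwi), "geometry error")
})

test_that("streamlines round-trip through TCK and TRK within 1e-4 mm", {
  d <- withr::local_tempdir()
  set.seed(11)
  ts <- tractSet(lapply(1:2, function(i) {
    apply(matrix(rnorm(15, sd = 4), 5, 3), 2, cumsum)
  }), labels = c(1L, 2L))
  for (ext in c("tck", "trk")) {
    p <- file.path(d, paste0("t.", ext))
    saveTracts(ts, p, refAffine = diag(c(1.5, 1.5, 1.5, 1)),
               refDim = c(10L, 10L, 10L))
    ts2 <- loadTracts(p)
    expect_equal(nTracts(ts2), 2L)
    for (i in 1:2)
      expect_equal(ts2@tracts[[i]], ts@tracts[[i]], tolerance = 1e-4)
    expect_identical(bundleLabels(ts2), c(1L, 2L))   # via JSON sidecar
  }
  # empty sets are valid files with zero streamlines
  p0 <- file.path(d, "empty.tck")
  saveTracts(tractSet(), p0)
  expect_equal(nTracts(loadTracts(p0)), 0L)
  expect_error(saveTracts(ts, file.path(d, "t.xyz")), "format error")
})

test_that("axis-permuted affines leave world-space results unchanged", {
  fx <- fixStraight()
  dwi <- fx$dwi
  # permute x and y axes of the stored array and compensate in the affine
  perm <- aperm(dwi@data, c(2, 1, 3, 4))
  P <- rbind(c(0, 1, 0, 0), c(1, 0, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1))
  affP <- dwi@affine %*% P
  dwiP <- new("DWIVolume", data = perm, affine = affP, gtab = dwi@gtab)
  maskP <- labelMask(aperm(fx$mask@data, c(2, 1, 3)), affP)

  tf <- fitTensor(dwi, fx$mask)
  tfP <- fitTensor(dwiP, maskP)
  # FA fields agree voxel-for-voxel after the same permutation
  expect_equal(aperm(tf@fa, c(2, 1, 3)), tfP@fa, tolerance = 1e-8)

  ts <- factTrack(tf, fx$mask, factParams())
  tsP <- factTrack(tfP, maskP, factParams())
  expect_equal(nTracts(ts), nTracts(tsP))
  # world-space endpoints agree within tolerance
  e1 <- sort(vapply(ts@tracts, function(p) p[1, 1], 0))
  e2 <- sort(vapply(tsP@tracts, function(p) p[1, 1], 0))
  expect_equal(e1, e2, tolerance = 1e-3)
})
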