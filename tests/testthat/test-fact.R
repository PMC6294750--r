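test_that("FACT tracks a uniform field straight through the mask", {
  fx <- fixStraight()
  tf <- fitTensor(fx$dwi, fx$mask)
  ts <- factTrack(tf, fx$mask, factParams())
  expect_gt(nTracts(ts), 0)
  # every tangent is (1, 0, 0) up to antipodal sign
  for (p in ts@tracts[1:min(10, nTracts(ts))]) {
    d <- diff(p); d <- d / sqrt(rowSums(d^2))
    expect_true(all(abs(abs(d[, 1]) - 1) < 1e-6))
  }
  # mean angular error vs truth below 2 degrees at infinite SNR
  te <- tangentError(ts, fx$truth)
  expect_lt(te$meanError, 2)
})

test_that("FACT terminates below the FA threshold and on sharp turns", {
  fx <- fixStraight()
  tf <- fitTensor(fx$dwi, fx$mask)
  # an FA threshold above the phantom's FA suppresses all tracts
  ts <- factTrack(tf, fx$mask, factParams(faThreshold = 0.99))
  expect_equal(nTracts(ts), 0L)
  # empty seed mask gives an empty TractSet
  empty <- labelMask(array(0L, dim(fx$mask@data)), fx$mask@affine)
  expect_equal(nTracts(factTrack(tf, empty, factParams())), 0L)
})

test_that("emitted tracts respect the FACT gates", {
  fx <- fixCrossing()
  tf <- fitTensor(fx$dwi, fx$mask)
  p <- factParams(faThreshold = 0.10, angleThreshold = 60)
  ts <- factTrack(tf, fx$mask, p, seed = 5L)
  expect_gt(nTracts(ts), 0)
  minLen <- 0.25 * sqrt(sum((dim(tf@fa) * 1.5)^2))
  for (tr in ts@tracts[seq_len(min(25, nTracts(ts)))]) {
    expect_gte(tractLength(tr), minLen)
    d <- diff(tr); d <- d / sqrt(rowSums(d^2))
    turn <- acos(pmin(1, abs(rowSums(d[-1, , drop = FALSE] *
                                     d[-nrow(d), , drop = FALSE]))))
    expect_true(all(turn <= (p@angleThreshold + 1e-6) * pi / 180))
  }
})

test_that("tracking is reproducible given the seed", {
  fx <- fixStraight()
  tf <- fitTensor(fx$dwi, fx$mask)
  p <- factParams(seedsPerVoxel = 2L)
  t1 <- factTrack(tf, fx$mask, p, seed = 9L)
  t2 <- factTrack(tf, fx$mask, p, seed = 9L)
  expect_equal(t1@tracts, t2@tracts)
})

test_that("the length filter keeps exactly the tracts at or above threshold", {
  # 10 straight tracts of arc lengths 35..44 mm; threshold 40 keeps 5
  ts <- tractSet(lapply(35:44, function(L)
    cbind(seq(0, L, length.out = 20L), 0, 0)))
  kept <- filterByLength(ts, 40)
  expect_equal(nTracts(kept), 5L)
  expect_true(all(tractLength(kept) >= 40))
  # boundary behaviour: 39 mm removed, 41 mm kept
  expect_equal(nTracts(filterByLength(tractSet(list(
    cbind(seq(0, 39, length.out = 10L), 0, 0))), 40)), 0L)
  expect_equal(nTracts(filterByLength(tractSet(list(
    cbind(seq(0, 41, length.out = 10L), 0, 0))), 40)), 1L)
  expect_equal(nTracts(filterByLength(tractSet(), 40)), 0L)
})
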