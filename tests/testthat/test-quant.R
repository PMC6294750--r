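test_that("plane slicing counts transversal crossings exactly", {
  pl <- slicePlane(c(0, 0, 0), c(1, 0, 0))
  # straight tract perpendicular to the plane: one crossing along the normal
  straight <- tractSet(list(cbind(seq(-5, 5, 1), 0, 0)))
  rec <- sliceTracts(straight, pl)
  expect_equal(nrow(rec), 1L)
  expect_equal(abs(rec$dx), 1)
  expect_equal(rec$x, 0, tolerance = 1e-12)
  # tract entirely on one side: no crossings
  oneSide <- tractSet(list(cbind(seq(1, 5, 1), 0, 0)))
  expect_equal(nrow(sliceTracts(oneSide, pl)), 0L)
  # S-shaped tract crossing three times (interior zeros of cos(1.5 t))
  t <- seq(0, 2 * pi, length.out = 200)
  sshape <- tractSet(list(cbind(cos(1.5 * t), t, 0)))
  expect_equal(nrow(sliceTracts(sshape, pl)), 3L)
})

test_that("slice crossing counts match a brute-force sign-change oracle", {
  set.seed(31)
  pl <- slicePlane(c(0.3, -0.2, 0.1), c(1, 2, -0.5))
  for (rep in 1:10) {
    p <- apply(matrix(rnorm(60), 20, 3), 2, cumsum)
    d <- as.numeric((p - matrix(pl$origin, 20, 3, TRUE)) %*% pl$normal)
    oracle <- sum(d[-20] * d[-1] < 0)
    expect_equal(nrow(sliceTracts(tractSet(list(p)), pl)), oracle)
  }
})

test_that("cosine fits recover exact cosine curves and translations", {
  tpar <- seq(0, 1, length.out = 60)
  # axes that are constant along the curve are captured by c0 alone
  line <- cbind(3 + 2 * tpar, -1, 5)
  fit <- fitCosineSeries(line, 6L)
  expect_lt(max(fit@rmse[2:3]), 1e-10)
  expect_equal(fit@coef[1, 2:3], c(-1, 5), tolerance = 1e-10)
  expect_lt(max(abs(fit@coef[-1, 2:3])), 1e-8)
  # a curve synthesized exactly as an order-2 series is recovered at K = 2
  # when fit with the synthesis parametrization
  cf <- rbind(c(1, -4, 2), c(8, 1, 0), c(-3, 2, 1))
  curve <- new("CosineCurve", coef = cf, order = 2L, rmse = rep(NA_real_, 3))
  pts <- evalCosineCurve(curve, tpar)
  fit2 <- fitCosineSeries(pts, 2L, t = tpar)
  expect_lt(max(abs(fit2@coef - cf)), 1e-8)
  expect_lt(max(fit2@rmse), 1e-10)
  # translation is absorbed by c0: residual invariant
  fit3 <- fitCosineSeries(pts + matrix(c(10, -20, 5), nrow(pts), 3, TRUE),
                          2L, t = tpar)
  expect_equal(fit3@rmse, fit2@rmse, tolerance = 1e-9)
  expect_equal(fit3@coef[1, ] - fit2@coef[1, ], c(10, -20, 5),
               tolerance = 1e-6)
  expect_error(fitCosineSeries(line[1:5, ], 9L), "order")
})

test_that("cosine residual is non-increasing in the series order", {
  helix <- fixHelix()
  rmse <- vapply(c(1L, 3L, 5L, 9L), function(k)
    mean(fitCosineSeries(helix, k)@rmse), 0)
  expect_true(all(diff(rmse) <= 1e-9))
})

test_that("resampling density does not move the fitted coefficients", {
  helix <- fixHelix(150L)
  dense <- resampleTract(helix, 300L)
  c1 <- fitCosineSeries(helix, 7L)@coef
  c2 <- fitCosineSeries(dense, 7L)@coef
  expect_lt(max(abs(c1 - c2)), 1e-2)
})

test_that("heading angles and curvature follow the analytic forms", {
  # straight line along +x: angle 0 vs x, 90 vs y, curvature 0
  line <- cbind(seq(0, 30, length.out = 40), 0, 0)
  hp <- headingCurvature(fitCosineSeries(line, 3L))
  expect_lt(max(abs(hp$angleX)), 0.5)
  expect_true(all(abs(hp$angleY - 90) < 0.5))
  expect_lt(max(hp$curvature, na.rm = TRUE), 1e-6)

  # a 10-mm circle has curvature 0.1/mm: closed form via the derivative
  # operator (the cosine basis cannot represent a circle exactly)
  th <- seq(0, 2 * pi, length.out = 100)
  d1 <- cbind(-10 * sin(th), 10 * cos(th), 0)
  d2 <- cbind(-10 * cos(th), -10 * sin(th), 0)
  expect_equal(curvatureFromDerivatives(d1, d2), rep(0.1, 100),
               tolerance = 1e-12)

  # analytic curvature of a fitted smooth curve agrees with finite
  # differences within 1%
  helix <- fixHelix(400L)
  fit <- fitCosineSeries(helix, 9L)
  hp2 <- headingCurvature(fit, 200L)
  t <- hp2$t
  pts <- evalCosineCurve(fit, t)
  h <- t[2] - t[1]
  fd1 <- (pts[-(1:2), ] - pts[1:(nrow(pts) - 2), ]) / (2 * h)
  fd2 <- (pts[-(1:2), ] - 2 * pts[2:(nrow(pts) - 1), ] +
          pts[1:(nrow(pts) - 2), ]) / h^2
  kfd <- curvatureFromDerivatives(fd1, fd2)
  mid <- 30:170
  expect_lt(max(abs(kfd[mid - 1] - hp2$curvature[mid]) / hp2$curvature[mid]),
            0.01)
})

test_that("mirroring a curve reflects its oriented heading about 90 deg", {
  helix <- fixHelix()
  mir <- helix; mir[, 1] <- -mir[, 1]
  a <- headingCurvature(fitCosineSeries(helix, 9L))$angleX
  b <- headingCurvature(fitCosineSeries(mir, 9L))$angleX
  expect_equal(a, 180 - b, tolerance = 1e-6)
})

test_that("heading histograms bin tract-mean angles over [0, 180]", {
  bundle <- tractSet(lapply(1:5, function(i)
    cbind(seq(0, 20, 2), i, 0)))
  h <- headingHistogram(bundle, axis = 1L)
  expect_equal(sum(h$counts), 5L)
  expect_equal(h$counts[1], 5L)                 # all at 0 degrees
  # a bundle plus its mirror is symmetric about 90 within binning
  mir <- tractSet(lapply(bundle@tracts, function(p) {
    q <- p; q[, 1] <- -q[, 1]; q
  }))
  both <- tractSet(c(bundle@tracts, mir@tracts))
  h2 <- headingHistogram(both, axis = 1L)
  expect_equal(h2$counts, rev(h2$counts))
  expect_error(headingHistogram(tractSet(), 1L), "empty")
})

test_that("mirrored purse-string bundles are symmetric about 90 degrees", {
  # oracle: the truth tracts of the generator
  truth <- makeGeometry(phantomSpec("purse_string"))
  ts <- canonicalizeHeading(truth@tracts)
  sym <- headingSymmetry(ts)
  expect_true(all(sym$deviation < 10))
  # the two bundle means mirror each other on the midline axis
  expect_equal(sum(sym$bundleMeans[1, c(1, 2)]), 180, tolerance = 2)
})
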