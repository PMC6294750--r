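test_that("predicted stick signal follows the closed form and linearity", {
  gtab <- fixGtab()
  dims <- c(3L, 3L, 3L)
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- -2
  # empty configuration predicts zero everywhere
  cfg0 <- segmentConfiguration(matrix(numeric(0), 0, 6))
  expect_true(all(predictSignal(cfg0, dims, aff, gtab) == 0))

  # one particle fully inside the centre voxel, raw kernel (no demeaning):
  # perpendicular gradients see the full weight, parallel ones the
  # attenuated weight exp(-b d)
  cfg1 <- segmentConfiguration(cbind(0, 0, 0, 1, 0, 0),
                               segmentLength = 1.0, segmentWeight = 0.096)
  pred <- predictSignal(cfg1, dims, aff, gtab, dStick = 1.5e-3,
                        demean = FALSE)
  ctr <- 1L + 1L + 3L * (1L + 3L * 1L)
  g <- gtab@bvecs[!gtab@b0, , drop = FALSE]
  b <- gtab@bvals[!gtab@b0]
  expect_equal(pred[ctr, ], 0.096 * exp(-b * 1.5e-3 * (g %*% c(1, 0, 0))^2)[, 1],
               tolerance = 1e-12)
  perp <- which(abs(g %*% c(1, 0, 0)) < 1e-6)
  if (length(perp)) expect_equal(pred[ctr, perp[1]], 0.096)
  # all other voxels untouched
  expect_true(all(pred[-ctr, ] == 0))

  # two coincident particles predict exactly twice one
  cfg2 <- segmentConfiguration(rbind(cbind(0, 0, 0, 1, 0, 0),
                                     cbind(0, 0, 0, 1, 0, 0)),
                               segmentLength = 1.0, segmentWeight = 0.096)
  expect_equal(predictSignal(cfg2, dims, aff, gtab),
               2 * predictSignal(cfg1, dims, aff, gtab), tolerance = 1e-12)
})

test_that("a particle's contribution is apportioned by traversed length", {
  gtab <- fixGtab()
  dims <- c(2L, 1L, 1L)
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-1, 0, 0)
  # segment of length 1 centred on the voxel boundary: half in each voxel
  cfg <- segmentConfiguration(cbind(0, 0, 0, 1, 0, 0),
                              segmentLength = 1.0, segmentWeight = 0.1)
  pred <- predictSignal(cfg, dims, aff, gtab, demean = FALSE)
  expect_equal(pred[1, ], pred[2, ], tolerance = 1e-12)
  perp <- which(abs(gtab@bvecs[!gtab@b0, ] %*% c(1, 0, 0)) < 1e-6)
  if (length(perp)) expect_equal(pred[1, perp[1]], 0.05, tolerance = 1e-12)
})

test_that("external energy is zero iff prediction equals observation", {
  gtab <- fixGtab()
  dims <- c(3L, 3L, 3L)
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- -2
  cfg <- segmentConfiguration(cbind(0, 0, 0, 0, 1, 0), segmentLength = 1)
  obs <- predictSignal(cfg, dims, aff, gtab)
  expect_equal(externalEnergy(cfg, obs, dims, aff, gtab), 0)
  # energy strictly increases when a particle lands in an empty-signal region
  cfg2 <- segmentConfiguration(rbind(cbind(0, 0, 0, 0, 1, 0),
                                     cbind(0, 0, 2, 1, 0, 0)),
                               segmentLength = 1)
  expect_gt(externalEnergy(cfg2, obs, dims, aff, gtab), 0)
  # enumeration order does not change the energy
  cfg3 <- segmentConfiguration(cfg2@particles[2:1, ], segmentLength = 1)
  expect_equal(externalEnergy(cfg3, obs, dims, aff, gtab),
               externalEnergy(cfg2, obs, dims, aff, gtab), tolerance = 1e-12)
})

test_that("internal energy counts endpoints and rewards smooth junctions", {
  p <- gibbsParams()
  len <- p@segmentLength
  # a single unbound particle costs its two endpoint charges
  one <- segmentConfiguration(cbind(0, 0, 0, 1, 0, 0))
  expect_equal(internalEnergy(one, p),
               2 * (p@particlePotential + p@densityPenalty))
  # two perfectly abutting collinear particles: bound strictly below unbound
  two <- rbind(cbind(0, 0, 0, 1, 0, 0), cbind(len, 0, 0, 1, 0, 0))
  free2 <- segmentConfiguration(two)
  lp <- rbind(c(0L, 2L), c(1L, 0L)); le <- rbind(c(0L, 1L), c(2L, 0L))
  bound2 <- segmentConfiguration(two, lp, le)
  expect_lt(internalEnergy(bound2, p), internalEnergy(free2, p))
  # the perfect-junction refund has its closed-form depth
  csEnd <- p@connectionStrengthEnd
  expect_equal(internalEnergy(bound2, p) - internalEnergy(free2, p),
               p@badBondPenalty - (2 * p@densityPenalty + p@badBondPenalty +
                                   csEnd), tolerance = 1e-9)
  # a fold-back junction (parallel particles bound at facing ends) earns
  # nothing: it costs the full bad-bond penalty
  hair <- rbind(cbind(0, 0, 0, 1, 0, 0), cbind(0, 1e-6, 0, 1, 0, 0))
  lpH <- rbind(c(0L, 2L), c(0L, 1L)); leH <- rbind(c(0L, 2L), c(0L, 2L))
  hairpin <- segmentConfiguration(hair, lpH, leH)
  expect_equal(internalEnergy(hairpin, p) - internalEnergy(free2, p),
               p@badBondPenalty, tolerance = 1e-6)
  # three-particle chain: 6 endpoint charges + 2 junction terms
  three <- rbind(cbind(0, 0, 0, 1, 0, 0), cbind(len, 0, 0, 1, 0, 0),
                 cbind(2 * len, 0, 0, 1, 0, 0))
  lp3 <- rbind(c(0L, 2L), c(1L, 3L), c(2L, 0L))
  le3 <- rbind(c(0L, 1L), c(2L, 1L), c(2L, 0L))
  chain3 <- segmentConfiguration(three, lp3, le3)
  bondTerm <- p@badBondPenalty - (2 * p@densityPenalty + p@badBondPenalty + csEnd)
  expect_equal(internalEnergy(chain3, p),
               6 * (p@particlePotential + p@densityPenalty) + 2 * bondTerm,
               tolerance = 1e-9)
  # asymmetric links are an integrity error
  bad <- chain3
  slot(bad, "linkPartner", check = FALSE) <-
    rbind(c(0L, 2L), c(0L, 0L), c(0L, 0L))
  slot(bad, "linkEnd", check = FALSE) <-
    rbind(c(0L, 1L), c(0L, 0L), c(0L, 0L))
  expect_error(internalEnergy(bad, p), "integrity")
})

test_that("streamline extraction walks chains and breaks cycles", {
  len <- 1
  # a 5-particle collinear chain emits one tract of 6 points
  pts <- cbind((0:4) * len, 0, 0, 1, 0, 0)
  lp <- cbind(c(0L, 1:4), c(2:5, 0L))
  le <- cbind(c(0L, rep(2L, 4)), c(rep(1L, 4), 0L))
  cfg <- segmentConfiguration(pts, lp, le, segmentLength = len)
  ts <- extractStreamlines(cfg, minChain = 2L)
  expect_equal(nTracts(ts), 1L)
  expect_equal(nrow(ts@tracts[[1]]), 6L)
  expect_equal(tractLength(ts), 5, tolerance = 1e-9)
  # each particle appears in exactly one tract (total points conserved)
  # all particles unbound: nothing at minChain 2
  loose <- segmentConfiguration(pts)
  expect_equal(nTracts(extractStreamlines(loose, 2L)), 0L)
  # a 4-cycle is broken at the largest bend and emitted once
  sq <- rbind(cbind(0.5, 0, 0, 1, 0, 0),
              cbind(1, 0.5, 0, 0, 1, 0),
              cbind(0.5, 1, 0, -1, 0, 0),
              cbind(0, 0.5, 0, 0, -1, 0))
  lpC <- cbind(c(4L, 1L, 2L, 3L), c(2L, 3L, 4L, 1L))
  leC <- cbind(c(2L, 2L, 2L, 2L), c(1L, 1L, 1L, 1L))
  cyc <- segmentConfiguration(sq, lpC, leC, segmentLength = len)
  tsC <- extractStreamlines(cyc, minChain = 2L)
  expect_equal(nTracts(tsC), 1L)
  expect_equal(nrow(tsC@tracts[[1]]), 5L)
})

test_that("annealing is deterministic and descends in energy", {
  fx <- fixStraight()
  p <- gibbsParams(nIterations = 5e4, rngSeed = 21L)
  r1 <- anneal(fx$dwi, fx$mask, p)
  r2 <- anneal(fx$dwi, fx$mask, p)
  expect_identical(r1$config@particles, r2$config@particles)
  expect_identical(r1$config@linkPartner, r2$config@linkPartner)
  tr <- r1$trace
  n10 <- max(1L, floor(length(tr) / 10))
  expect_lt(mean(tr[seq(length(tr) - n10 + 1L, length(tr))]),
            mean(tr[seq_len(n10)]))
})

test_that("incremental energies match a full recomputation", {
  fx <- fixStraight()
  p <- gibbsParams(nIterations = 5e4, rngSeed = 3L)
  res <- anneal(fx$dwi, fx$mask, p)
  eb <- energyBreakdown(res$config, res$observed, dim(fx$dwi@data)[1:3],
                        affine(fx$dwi), fixGtab(), p,
                        noiseSigma = res$noiseSigma)
  expect_lt(abs(eb$external - res$externalEnergy) /
            max(abs(eb$external), 1e-12), 1e-6)
  expect_lt(abs(eb$internal - res$internalEnergy) /
            max(abs(eb$internal), 1e-12), 1e-6)
})

test_that("the toy sampler respects state-space bounds and determinism", {
  ori <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  gtab <- fixGtab()
  obs <- as.numeric(myotract:::.toyKernels(ori[1, , drop = FALSE], gtab,
                                           gibbsParams(), 1.5e-3)) * 5
  s <- toySample(ori, obs, gtab, nSteps = 2e4, thin = 10L,
                 maxParticles = 2L, seed = 4L)
  expect_true(all(rowSums(s) <= 2L))
  expect_true(all(s >= 0L))
  s2 <- toySample(ori, obs, gtab, nSteps = 2e4, thin = 10L,
                  maxParticles = 2L, seed = 4L)
  expect_identical(s, s2)
})
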