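#' Construct Gibbs tractography parameters
#'
#' Segment geometry and prior weights default to the values used for
#' perineal-muscle reconstructions at acquisition scale (segment length
#' 1.172 mm, width 0.3 mm, signal weight 0.096, density penalty 0.2;
#' temperatures 0.1 to 0.001). The iteration default of 2e5 is the
#' desk-scale budget used for phantoms; acquisition-scale runs use on the
#' order of 5e8.
#'
#' @param nIterations Metropolis steps.
#' @param tStart,tEnd annealing start/end temperatures (exponential
#'   schedule).
#' @param segmentLength,segmentWidth segment geometry in mm; the width
#'   enters only through voxel apportionment and is immaterial below the
#'   voxel size.
#' @param segmentWeight per-particle contribution to the normalized signal.
#' @param densityPenalty prior cost of a free segment endpoint (the
#'   termination drive: dangling chain ends are expensive, so chains
#'   continue through and bridge low-anisotropy regions).
#' @param particlePotential prior cost per segment endpoint, bound or not
#'   (default 0.2); this chemical-potential term keeps the particle count
#'   bounded by data support.
#' @param connectionStrength depth of the endpoint binding potential at
#'   the start of the run (default 0.3).
#' @param connectionStrengthEnd binding depth at the end of the run
#'   (default 0.9). The binding prior is annealed linearly alongside the
#'   temperature: weak early bonds let segments align to the data before
#'   committing, strong late bonds fuse chain fragments and push them
#'   through ambiguous (crossing) regions. NA keeps it constant.
#' @param badBondPenalty cost of a geometrically incompatible junction
#'   (default 0.5): binding a pair with poor gap/bend compatibility is
#'   worse than leaving both ends free, which keeps the chain topology
#'   from weaving or folding back.
#' @param sigmaGap gap scale of the binding potential (mm); default
#'   segmentLength / 2.
#' @param sigmaBend bend scale of the binding potential (radians, between
#'   directed endpoint orientations; default 0.3). Gradual veering across
#'   junctions and fold-backs are both penalized through this term.
#' @param rC connection search radius; default segmentLength.
#' @param muBirth reference mass of birth/death moves; NA resolves to the
#'   number of mask voxels at run time.
#' @param moveProbabilities named vector over birth, death, shift, rotate,
#'   connect, disconnect, extend, retract. Extension/retraction grow and
#'   prune chains at their ends (a birth-and-bind reversible-jump pair);
#'   they are what makes chain growth kinetically feasible at desk-scale
#'   iteration budgets.
#' @param shiftSigma,rotateSigma proposal scales (mm, radians); defaults
#'   segmentLength / 8 and 0.1.
#' @param extendRadius,extendAngle extension proposal geometry: the bound
#'   endpoint of a proposed chain-end particle is uniform in a ball of this
#'   radius (mm) around the free endpoint, its axis uniform in a cone of
#'   this half-angle (radians) around the chain direction.
#' @param minChain minimum particles per emitted streamline (default 10;
#'   shorter chains are reconstruction fragments).
#' @param rngSeed integer seed.
#' @return a [GibbsParams-class].
#' @export
gibbsParams <- function(nIterations = 2e5, tStart = 0.1, tEnd = 0.001,
                        segmentLength = 1.172, segmentWidth = 0.3,
                        segmentWeight = 0.096, densityPenalty = 0.2,
                        particlePotential = 0.2,
                        connectionStrength = 0.3,
                        connectionStrengthEnd = 1.2,
                        badBondPenalty = 0.35,
                        sigmaGap = segmentLength / 2, sigmaBend = 0.3,
                        rC = segmentLength,
                        muBirth = NA_real_,
                        moveProbabilities = c(birth = 0.04, death = 0.04,
                                              shift = 0.34, rotate = 0.3,
                                              connect = 0.06,
                                              disconnect = 0.03,
                                              extend = 0.13,
                                              retract = 0.06),
                        shiftSigma = segmentLength / 8, rotateSigma = 0.1,
                        extendRadius = 0.3, extendAngle = 30 * pi / 180,
                        minChain = 10L, rngSeed = 1L) {
  new("GibbsParams", nIterations = nIterations, tStart = tStart, tEnd = tEnd,
      segmentLength = segmentLength, segmentWidth = segmentWidth,
      segmentWeight = segmentWeight, densityPenalty = densityPenalty,
      particlePotential = particlePotential,
      connectionStrength = connectionStrength,
      connectionStrengthEnd = if (is.na(connectionStrengthEnd))
        connectionStrength else connectionStrengthEnd,
      badBondPenalty = badBondPenalty, sigmaGap = sigmaGap,
      sigmaBend = sigmaBend, rC = rC,
      muBirth = muBirth, moveProbabilities = moveProbabilities,
      shiftSigma = shiftSigma, rotateSigma = rotateSigma,
      extendRadius = extendRadius, extendAngle = extendAngle,
      minChain = as.integer(minChain), rngSeed = as.integer(rngSeed))
}

## add segmentWidth slot default handling: width is carried for provenance
setMethod("show", "GibbsParams", function(object) {
  cat(sprintf(paste0("GibbsParams: %g iterations, T %g -> %g, segment %.3f mm",
                     " (weight %g), density penalty %g\n"),
              object@nIterations, object@tStart, object@tEnd,
              object@segmentLength, object@segmentWeight,
              object@densityPenalty))
})

#' Observed anisotropic signal for the global tracker
#'
#' Normalizes each voxel's diffusion-weighted signal by its measured
#' baseline and removes the direction-independent (isotropic) part by
#' subtracting the per-voxel mean over non-b0 directions, so that what
#' remains is the directional modulation the segment model must explain.
#' Voxels with baseline below the background threshold are zeroed.
#'
#' @param dwi a [DWIVolume-class].
#' @param backgroundThreshold background cut as a multiple of the noise
#'   standard deviation estimated from the low half of the b0 image
#'   (default 3; 0 disables).
#' @return matrix (nvox x n non-b0 directions) of demeaned normalized
#'   signal, voxels in column-major grid order.
#' @export
observedAnisotropy <- function(dwi, backgroundThreshold = 3) {
  gtab <- dwi@gtab
  dims <- dim(dwi@data)[1:3]
  S <- matrix(dwi@data, prod(dims), length(gtab@bvals))
  b0 <- rowMeans(S[, gtab@b0, drop = FALSE])
  keep <- b0 > 0
  if (backgroundThreshold > 0) {
    bgsd <- stats::sd(b0[b0 <= stats::median(b0)])
    if (is.finite(bgsd) && bgsd > 0) keep <- b0 > backgroundThreshold * bgsd
  }
  Sw <- S[, !gtab@b0, drop = FALSE]
  obs <- matrix(0, nrow(S), ncol(Sw))
  if (any(keep)) {
    r <- Sw[keep, , drop = FALSE] / b0[keep]
    obs[keep, ] <- r - rowMeans(r)
  }
  obs
}

#' Predicted anisotropic signal of a segment configuration
#'
#' Each particle contributes weight * exp(-b d_stick (g . n)^2) to the
#' voxels its axis traverses, apportioned by traversed length (8
#' sub-segments). With \code{demean = TRUE} (the form entering the external
#' energy) the directional mean of the stick kernel is subtracted, matching
#' [observedAnisotropy()].
#'
#' @param cfg a [SegmentConfiguration-class].
#' @param dims integer grid shape (nx, ny, nz).
#' @param affine 4x4 voxel-to-world matrix.
#' @param gtab a [GradientTable-class] (non-b0 entries are used).
#' @param dStick stick diffusivity (mm^2/s).
#' @param demean subtract the per-orientation directional mean.
#' @return matrix (nvox x n non-b0 directions).
#' @export
predictSignal <- function(cfg, dims, affine, gtab, dStick = 1.5e-3,
                          demean = TRUE) {
  cpp_predict_signal(cfg@particles, as.integer(dims), affine,
                     gtab@bvals[!gtab@b0], gtab@bvecs[!gtab@b0, , drop = FALSE],
                     dStick, cfg@segmentLength, cfg@segmentWeight, demean)
}

#' Estimate the relative noise level of the normalized signal
#'
#' Estimates the Rician channel sigma from the background of the b0 image
#' (Rayleigh mean = sigma * sqrt(pi/2)) and expresses it relative to the
#' median tissue baseline, giving the standard deviation of the
#' S/S0-normalized signal that the external energy is measured against.
#'
#' @param dwi a [DWIVolume-class].
#' @param floor lower bound on the returned sigma (default 0.01), the
#'   effective data-confidence cap for noise-free data.
#' @return relative noise sigma (unitless).
#' @export
estimateNoiseSigma <- function(dwi, floor = 0.01) {
  gtab <- dwi@gtab
  dims <- dim(dwi@data)[1:3]
  b0 <- rowMeans(matrix(dwi@data, prod(dims),
                        length(gtab@bvals))[, gtab@b0, drop = FALSE])
  bg <- b0[b0 <= stats::median(b0)]
  sigmaRaw <- mean(bg) / sqrt(pi / 2)
  tissue <- b0[b0 > 3 * max(stats::sd(bg), 1e-12)]
  s0 <- if (length(tissue)) stats::median(tissue) else max(b0)
  if (s0 <= 0) return(floor)
  max(floor, sigmaRaw / s0)
}

#' External (data-mismatch) energy of a configuration
#'
#' Sum of squared differences between the predicted and observed demeaned
#' normalized signal over all voxels and non-b0 directions, scaled by
#' 1/(2 sigma^2) so the energy is measured in units of the noise variance.
#' This is the from-scratch recomputation path, used to audit the
#' incremental bookkeeping of [anneal()].
#'
#' @param cfg a [SegmentConfiguration-class].
#' @param observed matrix from [observedAnisotropy()].
#' @param dims,affine,gtab,dStick as in [predictSignal()].
#' @param noiseSigma relative noise level (see [estimateNoiseSigma()]);
#'   the default 1/sqrt(2) gives an unscaled sum of squares.
#' @return scalar energy.
#' @export
externalEnergy <- function(cfg, observed, dims, affine, gtab,
                           dStick = 1.5e-3, noiseSigma = 1 / sqrt(2)) {
  pred <- predictSignal(cfg, dims, affine, gtab, dStick, demean = TRUE)
  sum((pred - observed)^2) / (2 * noiseSigma^2)
}

#' Internal (prior) energy of a configuration
#'
#' Every segment endpoint contributes +(particlePotential +
#' densityPenalty); each bound endpoint pair contributes
#' badBondPenalty - (2 densityPenalty + badBondPenalty +
#' connectionStrength) * B with
#' B = exp(-gap^2/sigmaGap^2 - bend^2/sigmaBend^2), where gap is the
#' distance between the bound endpoints (mm) and bend the angle (radians)
#' between the directed chain orientations at the junction (the outgoing
#' direction of one particle against the incoming direction of the other,
#' so fold-backs earn nothing). Dangling ends are thereby expensive, but
#' only smooth junctions are rewarded. Asymmetric links raise an integrity
#' error.
#'
#' @param cfg a [SegmentConfiguration-class].
#' @param p a [GibbsParams-class] supplying the prior constants.
#' @return scalar energy (lower is better).
#' @export
internalEnergy <- function(cfg, p = gibbsParams()) {
  n <- nrow(cfg@particles)
  if (!n) return(0)
  csFinal <- if (is.na(p@connectionStrengthEnd)) p@connectionStrength else
    p@connectionStrengthEnd
  cpp_internal_energy(cfg@particles, cfg@linkPartner, cfg@linkEnd,
                      cfg@segmentLength, p@densityPenalty,
                      p@particlePotential, csFinal,
                      p@badBondPenalty, p@sigmaGap, p@sigmaBend)
}

#' Total energy breakdown of a configuration
#'
#' @inheritParams externalEnergy
#' @param p a [GibbsParams-class].
#' @return list with components \code{external}, \code{internal} and
#'   \code{total}.
#' @export
energyBreakdown <- function(cfg, observed, dims, affine, gtab, p = gibbsParams(),
                            dStick = 1.5e-3, noiseSigma = 1 / sqrt(2)) {
  ext <- externalEnergy(cfg, observed, dims, affine, gtab, dStick, noiseSigma)
  int <- internalEnergy(cfg, p)
  list(external = ext, internal = int, total = ext + int)
}

#' Optimize a segment configuration by simulated annealing
#'
#' Runs the reversible-jump Metropolis sampler (birth, death, shift,
#' rotate, connect, disconnect moves) for \code{p@nIterations} steps under
#' an exponential temperature schedule from \code{tStart} to \code{tEnd}.
#' Deterministic given \code{p@rngSeed}.
#'
#' @param dwi a [DWIVolume-class].
#' @param mask a [LabelMask-class]; particles live in voxels with
#'   label >= 1.
#' @param p a [GibbsParams-class].
#' @param dStick stick diffusivity of the data model (mm^2/s).
#' @param noiseSigma scale of the data term in units of the normalized
#'   signal: the external energy is SSE / (2 noiseSigma^2). This is a
#'   regularization constant balancing data against the prior, not a
#'   noise estimate: because the low-b stick kernel is close to a pure
#'   rank-2 profile, weighting the data at the raw noise level rewards
#'   half-aligned segments and overfills the volume. The default 0.2
#'   makes one segment's aligned signal gain O(1) against the endpoint
#'   penalties, which is what gives orientation selectivity.
#' @param init optional starting [SegmentConfiguration-class].
#' @return list with \code{config} (final [SegmentConfiguration-class]),
#'   \code{externalEnergy}, \code{internalEnergy} (incrementally maintained
#'   values), \code{trace} (energy sampled ~1000 times along the run),
#'   \code{attempted} and \code{accepted} per move type, \code{observed}
#'   (the precomputed data term) and \code{noiseSigma} (the value used).
#' @export
anneal <- function(dwi, mask, p = gibbsParams(), dStick = 1.5e-3,
                   noiseSigma = 0.2, init = NULL) {
  dims <- dim(dwi@data)[1:3]
  obs <- observedAnisotropy(dwi)
  maskIdx <- which(as.logical(mask@data >= 1)) - 1L
  if (!length(maskIdx)) stop("empty mask")
  par <- list(
    dataWeight = 1 / (2 * noiseSigma^2),
    nIterations = p@nIterations, tStart = p@tStart, tEnd = p@tEnd,
    segmentLength = p@segmentLength, segmentWeight = p@segmentWeight,
    densityPenalty = p@densityPenalty,
    particlePotential = p@particlePotential,
    connectionStrength = p@connectionStrength,
    connectionStrengthEnd = p@connectionStrengthEnd,
    badBondPenalty = p@badBondPenalty, sigmaGap = p@sigmaGap,
    sigmaBend = p@sigmaBend, rC = p@rC,
    muBirth = if (is.na(p@muBirth)) as.numeric(length(maskIdx)) else p@muBirth,
    shiftSigma = p@shiftSigma, rotateSigma = p@rotateSigma,
    extendRadius = p@extendRadius, extendAngle = p@extendAngle,
    moveProbabilities = as.numeric(p@moveProbabilities[
      c("birth", "death", "shift", "rotate", "connect", "disconnect",
        "extend", "retract")]))
  if (is.null(init))
    init <- segmentConfiguration(matrix(0, 0, 6),
                                 segmentLength = p@segmentLength,
                                 segmentWeight = p@segmentWeight)
  gtab <- dwi@gtab
  res <- .withSeed(p@rngSeed,
    cpp_anneal(obs, as.integer(dims), dwi@affine, maskIdx,
               gtab@bvals[!gtab@b0], gtab@bvecs[!gtab@b0, , drop = FALSE],
               dStick, par, init@particles, init@linkPartner, init@linkEnd))
  cfg <- segmentConfiguration(res$particles, res$linkPartner, res$linkEnd,
                              segmentLength = p@segmentLength,
                              segmentWeight = p@segmentWeight)
  moves <- c("birth", "death", "shift", "rotate", "connect", "disconnect",
             "extend", "retract")
  list(config = cfg,
       externalEnergy = res$externalEnergy,
       internalEnergy = res$internalEnergy,
       trace = res$trace,
       attempted = stats::setNames(res$attempted, moves),
       accepted = stats::setNames(res$accepted, moves),
       observed = obs, noiseSigma = noiseSigma)
}

#' Read out streamlines from a segment configuration
#'
#' Bound particles form chains; each chain is traversed from a free end
#' (cycles are broken at the link with the largest bend angle) and emitted
#' as a polyline through the outer endpoints and the midpoints of bound
#' endpoint pairs, so a chain of k particles yields k + 1 points. Each
#' particle appears in exactly one tract.
#'
#' @param cfg a [SegmentConfiguration-class].
#' @param minChain minimum number of particles per emitted tract.
#' @return a [TractSet-class].
#' @export
extractStreamlines <- function(cfg, minChain = 2L) {
  n <- nrow(cfg@particles)
  if (!n) return(tractSet())
  h <- cfg@segmentLength / 2
  P <- cfg@particles[, 1:3, drop = FALSE]
  O <- cfg@particles[, 4:6, drop = FALSE]
  lp <- cfg@linkPartner
  le <- cfg@linkEnd
  ## validate link symmetry
  for (i in seq_len(n)) for (e in 1:2) {
    j <- lp[i, e]
    if (j > 0) {
      f <- le[i, e]
      if (j == i || lp[j, f] != i || le[j, f] != e)
        stop("link integrity error: asymmetric endpoint links")
    }
  }
  ep <- function(i, e) P[i, ] + (if (e == 1L) -h else h) * O[i, ]
  visited <- rep(FALSE, n)
  tracts <- list()

  walk <- function(i, enterEnd) {
    ## returns list(points, particles) following the chain from endpoint
    pts <- list(ep(i, enterEnd))
    chain <- integer()
    repeat {
      visited[i] <<- TRUE
      chain <- c(chain, i)
      other <- 3L - enterEnd
      j <- lp[i, other]
      if (j == 0L || visited[j]) {
        pts[[length(pts) + 1L]] <- ep(i, other)
        break
      }
      f <- le[i, other]
      pts[[length(pts) + 1L]] <- (ep(i, other) + ep(j, f)) / 2
      i <- j; enterEnd <- f
    }
    list(points = do.call(rbind, pts), chain = chain)
  }

  ## chains with a free end
  for (i in seq_len(n)) {
    if (visited[i]) next
    freeEnd <- which(lp[i, ] == 0L)
    if (!length(freeEnd)) next
    w <- walk(i, freeEnd[1])
    if (length(w$chain) >= minChain) tracts[[length(tracts) + 1L]] <- w$points
  }
  ## remaining particles form cycles: break at the largest-bend link
  for (i in seq_len(n)) {
    if (visited[i]) next
    ## collect the cycle
    cyc <- integer(); ends <- integer()
    cur <- i; enter <- 1L
    repeat {
      cyc <- c(cyc, cur); ends <- c(ends, enter)
      nxt <- lp[cur, 3L - enter]
      if (nxt == i && length(cyc) > 1L) break
      enter <- le[cur, 3L - enter]
      cur <- nxt
      if (cur == i) break
    }
    bends <- vapply(seq_along(cyc), function(m) {
      a <- cyc[m]; b <- cyc[m %% length(cyc) + 1L]
      acos(min(1, abs(sum(O[a, ] * O[b, ]))))
    }, 0)
    cut <- which.max(bends)               # break between cyc[cut], cyc[cut+1]
    start <- cyc[cut %% length(cyc) + 1L]
    enterEnd <- le[cyc[cut], 3L - ends[cut]]
    w <- walkCycle(start, enterEnd, cyc, lp, le, ep)
    visited[cyc] <- TRUE
    if (length(cyc) >= minChain) tracts[[length(tracts) + 1L]] <- w
  }
  tractSet(tracts)
}

## internal: linear walk over a known cycle starting at `start`
walkCycle <- function(start, enterEnd, cyc, lp, le, ep) {
  pts <- list(ep(start, enterEnd))
  i <- start; enter <- enterEnd
  for (step in seq_along(cyc)) {
    other <- 3L - enter
    j <- lp[i, other]
    if (step == length(cyc)) {
      pts[[length(pts) + 1L]] <- ep(i, other)
      break
    }
    f <- le[i, other]
    pts[[length(pts) + 1L]] <- (ep(i, other) + ep(j, f)) / 2
    i <- j; enter <- f
  }
  do.call(rbind, pts)
}

#' Global tractography: anneal and extract streamlines
#'
#' Convenience wrapper running [anneal()] followed by
#' [extractStreamlines()] with the parameter set's \code{minChain}.
#'
#' @inheritParams anneal
#' @return list with \code{tracts} (a [TractSet-class]) and all [anneal()]
#'   outputs.
#' @export
gibbsTrack <- function(dwi, mask, p = gibbsParams(), dStick = 1.5e-3,
                       noiseSigma = 0.2) {
  res <- anneal(dwi, mask, p, dStick, noiseSigma)
  res$tracts <- extractStreamlines(res$config, minChain = p@minChain)
  res
}

#' Fixed-temperature sampling of the single-voxel toy model
#'
#' Runs the package's Metropolis birth/death rule on an enumerable model:
#' one voxel, up to \code{maxParticles} particles, each taking one of a
#' small set of discrete orientations. The stationary distribution of this
#' chain is the Boltzmann distribution over occupancy states, which can be
#' computed exactly by enumeration — the statistical-correctness anchor of
#' the sampler.
#'
#' @param orientations K x 3 matrix of unit orientations.
#' @param observed demeaned observed profile over the non-b0 directions of
#'   \code{gtab}.
#' @param gtab a [GradientTable-class].
#' @param p a [GibbsParams-class] (segment weight and density penalty are
#'   used).
#' @param temperature fixed sampling temperature.
#' @param nSteps Metropolis steps.
#' @param thin record every \code{thin}-th state.
#' @param maxParticles state-space cap on the particle count.
#' @param dStick stick diffusivity.
#' @param seed RNG seed.
#' @return integer matrix (nSteps/thin x K) of orientation occupancies.
#' @export
toySample <- function(orientations, observed, gtab, p = gibbsParams(),
                      temperature = 0.05, nSteps = 1e6, thin = 10L,
                      maxParticles = 3L, dStick = 1.5e-3, seed = 1L) {
  kern <- .toyKernels(orientations, gtab, p, dStick)
  .withSeed(seed,
    cpp_toy_sample(kern, observed, p@densityPenalty, temperature,
                   nSteps, as.integer(thin), as.integer(maxParticles)))
}

## internal: weight-scaled demeaned stick kernels of the toy orientations
.toyKernels <- function(orientations, gtab, p, dStick) {
  b <- gtab@bvals[!gtab@b0]
  g <- gtab@bvecs[!gtab@b0, , drop = FALSE]
  k <- exp(-outer(rep(1, nrow(orientations)), b) * dStick *
             (orientations %*% t(g))^2)
  p@segmentWeight * (k - rowMeans(k))
}

#' Exact Boltzmann distribution of the toy model
#'
#' Enumerates every occupancy state of the single-voxel toy model and
#' returns exp(-E/T) normalized, with E computed from the same stick
#' kernels and density penalty as [toySample()].
#'
#' @inheritParams toySample
#' @return data.frame with one row per state: the K occupancy counts,
#'   \code{energy} and \code{prob}.
#' @export
toyBoltzmannExact <- function(orientations, observed, gtab,
                              p = gibbsParams(), temperature = 0.05,
                              maxParticles = 3L, dStick = 1.5e-3) {
  K <- nrow(orientations)
  kern <- .toyKernels(orientations, gtab, p, dStick)
  states <- .toyStates(K, maxParticles)
  E <- apply(states, 1, function(m) {
    pred <- colSums(kern * m)
    sum((pred - observed)^2) + 2 * p@densityPenalty * sum(m)
  })
  w <- exp(-(E - min(E)) / temperature)
  data.frame(states, energy = E, prob = w / sum(w))
}

## internal: all occupancy vectors with sum <= maxParticles
.toyStates <- function(K, maxParticles) {
  grid <- do.call(expand.grid, rep(list(0:maxParticles), K))
  grid <- as.matrix(grid[rowSums(grid) <= maxParticles, , drop = FALSE])
  colnames(grid) <- paste0("o", seq_len(K))
  rownames(grid) <- NULL
  grid
}
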