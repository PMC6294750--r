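---
title: "Global tractography for muscle fiber architecture: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global tractography for muscle fiber architecture: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myotract)
```

## The problem

Skeletal-muscle diffusion MRI is a low-anisotropy, low-SNR regime: muscle T2
is short, so acquisitions use a modest diffusion weighting (b = 400 s/mm²,
one baseline plus 32 non-collinear directions in the protocol this package
targets) and fractional anisotropy in muscle sits far below white-matter
values. Where muscle bundles interdigitate — the canonical example being the
perineal body, where the superficial perineal muscles meet and fibers
continue contralaterally in a purse-string arrangement — single-tensor local
tracking fails: the voxel-average tensor flattens, FA drops, and the
principal eigenvector becomes unstable, so deterministic streamline
propagation (FACT) stalls or veers exactly at the region of interest.

`myotract` implements both sides of that comparison: a faithful FACT tracker
with the field's gating thresholds, and a global tractography engine that
reconstructs all fibers simultaneously as the minimum-energy configuration
of a Gibbs point process of oriented line segments, optimized by simulated
annealing. Everything is exercised on synthetic crossing-fiber phantoms with
known ground truth, generated by the package itself.

## The synthetic phantoms

`phantomSpec()` / `makeGeometry()` / `simulateDWI()` build
4-D DWI volumes from declared fiber geometry:

* **Geometries.** `straight` (one cylinder), `arc` (a circular-arc tube),
  `crossing` (two straight tubes crossing at a configurable angle, default
  90°), and `purse_string`: two point-mirrored circular arcs whose tubes
  interdigitate around the midline plane, each arc crossing the midline and
  ending contralaterally — the synthetic stand-in for fibers crossing the
  perineal body. The two arcs are related by inversion through the origin,
  which makes their (canonically oriented) tangent fields exactly opposite;
  this is what gives the mirror symmetry of heading distributions about 90°
  used in the quantification module.
* **Signal model.** Noise-free signal per voxel follows the stick mixture
  \(S(g) = S_0\,[\,f_{iso}\,\tau\,e^{-b d_{iso}} + \sum_f v_f\,
  e^{-b d_{stick} (g\cdot n_f)^2}]\) with \(\tau\) the tissue occupancy of
  the voxel (supersampled 3× per axis against the tube geometry) and
  \(v_f = (1-f_{iso})\,\mathrm{occ}_f\). Defaults: stick diffusivity
  1.5e-3 mm²/s, isotropic diffusivity 2.0e-3 mm²/s, isotropic fraction 0.1 —
  physiologic for muscle tissue and interstitial fluid; the source protocol
  does not state tissue diffusivities.
* **Noise.** Rician, as the magnitude of two independent Gaussian channels
  with a single global \(\sigma = S_0/\mathrm{SNR}\). Note that the
  conventional in-vivo SNR measurement — tissue mean over *background
  standard deviation* (`measureSNR()`) — exceeds the channel-\(\sigma\) SNR
  by the Rayleigh factor \(1/\sqrt{2-\pi/2} \approx 1.53\), because the
  magnitude background is Rayleigh distributed. The generator's
  `targetB0SNR` is defined against the channel \(\sigma\).
* **Grid.** Default 32×32×12 voxels at 1.5 mm isotropic, centred on the
  origin; bundles of 4 mm radius. This keeps crossing regions several voxels
  wide at desk scale while remaining far smaller than an acquisition.
  Acquisition-like 3-mm anisotropic voxels are available through
  `phantomSpec()`.
* **Ground truth.** 25 truth streamlines per bundle (sunflower-packed
  parallel offsets inside each tube) plus per-voxel stick orientations and
  volume fractions, the scoring targets for recovery metrics.

What the phantoms deliberately do **not** emulate: eddy currents,
susceptibility distortion, coil profiles, T2 decay, physiological motion,
or anatomically realistic muscle shapes. Passing recovery tests on these
phantoms demonstrates the estimators and the optimizer, not robustness to
acquisition artifacts.

## Tensor fitting and FACT

`fitTensor()` is ordinary log-linear least squares of
\(\log S = \log S_0 - b\,g^\top D g\), which is exact on noise-free
single-tensor data and adequate above SNR ≈ 20; negative eigenvalues are
clamped to zero and flagged rather than refit. Background voxels are removed
by an intensity threshold in the b0 image (3× the background standard
deviation), following the acquisition protocol's own background handling.
FA uses the standard closed form; the direction-encoded color map follows
the red = right–left, green = antero–posterior, blue = cranio–caudal
convention (the channel mapping is configurable, since published figure
captions and text do not always agree on the assignment).

`factTrack()` implements the classical FACT dialect: bidirectional
propagation along the *nearest-voxel* principal eigenvector (re-sampled at
each step, no interpolation), antipodal sign alignment with the incoming
direction, and termination on FA below threshold, turning angle above
threshold, grid exit, or step cap. Defaults take the midpoints of the
published ranges for low-anisotropy muscle — FA threshold 0.10 (range
0.08–0.15), angular threshold 60° (range 50°–70°) — and the
fiber-fragment length filter is 40 mm at acquisition scale; at phantom scale
the default scales to 0.25× the grid diagonal, preserving the filter's
proportionality to the field of view.

## The Gibbs segment model

The global tracker's state is a set of *particles*: oriented line segments
of fixed length (1.172 mm) and width (0.3 mm), each contributing a fixed
weight (0.096) of template stick signal to the voxels its axis traverses,
with endpoint-to-endpoint connections forming chains. The posterior energy
is \(E = E_{ext} + E_{int}\).

**External (data) energy.** Both the observed and the predicted signal are
expressed as per-voxel, per-direction *demeaned normalized* signal: S/S0
minus its mean over the non-b0 directions. Demeaning both sides makes the
isotropic compartment cancel exactly and keeps the data term linear in the
particles, which is what allows O(1) incremental energy updates (a particle
touches at most a few voxels; its exact per-voxel length fractions come from
analytic clipping of the segment against the voxel lattice, so the energy is
continuous in position and orientation). The mismatch is
\(E_{ext} = \mathrm{SSE}/(2\sigma_{data}^2)\).

The scale \(\sigma_{data}\) (argument `noiseSigma`, default 0.2) is a
*regularization constant*, not a noise estimate. At b = 400 the stick
kernel is almost entirely a rank-2 (tensor-like) function of direction, so a
single segment's orientation is only weakly identified by its own voxel;
weighting the data at the raw noise level makes half-aligned segments
profitable and overfills the volume with orientation disorder. The default
makes one aligned segment's signal gain O(1) against the prior's endpoint
charges, which empirically gives the best orientation selectivity; per-voxel
angular precision beyond that comes from the chain prior, not the data.

**Internal (prior) energy.** Every segment endpoint is charged
\(c_p + c_d\) (particle potential \(c_p = 0.2\) + density penalty
\(c_d = 0.2\)); each bound endpoint pair earns
\(\kappa - (2 c_d + \kappa + c_s)\,B\) with
\(B = \exp(-\mathrm{gap}^2/\sigma_g^2 - \mathrm{bend}^2/\sigma_b^2)\),
bad-bond penalty \(\kappa = 0.35\), connection strength \(c_s\), gap scale
\(\sigma_g\) = half the segment length, and bend scale \(\sigma_b = 0.3\)
rad. Three properties motivate this exact form, each the repair of a
concrete failure mode observed during development:

* The endpoint charge is unconditional, so the particle count stays bounded
  by data support. (Charging only *free* endpoints makes every bonded
  interior particle profitable regardless of data, and the energy is then
  unbounded below: chains snake through the volume without limit.)
* A perfect junction refunds more than the two density penalties
  (\(2c_d + c_s\)), so dangling chain ends are expensive — the termination
  drive that pushes chains to continue through, and bridge across,
  low-anisotropy crossings.
* An incompatible junction *costs* \(\kappa\) rather than merely earning
  nothing, so the chain topology cannot drift into weaving; and the bend is
  measured between *directed* chain orientations at the junction (the
  outgoing direction of one particle against the incoming direction of the
  other), so a fold-back junction scores bend ≈ π and is effectively
  forbidden. With the undirected axis angle, a hairpin looks like a perfect
  bond and reconstructed "fibers" fold back on themselves.

The connection strength is *annealed* linearly from 0.3 to 1.2 over the
run, alongside the temperature. Weak early bonds let segments align to the
data before committing to chains; strong late bonds fuse chain fragments
and push them through ambiguous regions. (Internally the engine tracks the
bond-compatibility sum incrementally, so the cached energy remains exact
under the time-varying prior; the audit against full recomputation holds to
~1e-13 relative.)

**Moves.** A reversible-jump Metropolis sampler with eight move types:
birth (uniform position in the mask, uniform orientation), death (unbound
particles only), shift, rotate, connect (Boltzmann-weighted choice among
free endpoints within the connection radius, with exact forward/reverse
proposal probabilities), disconnect, and an extension/retraction pair that
births a new particle already bound to a free chain end, with
uniform-in-ball position and uniform-in-cone orientation proposals whose
densities are exact. Extension/retraction is what makes chain growth
kinetically feasible at desk-scale iteration budgets: the intermediate
state of birth-then-connect (an unbound particle) sits ~2 density penalties
uphill and is prohibitively rare below the starting temperature. The default
move mix is weighted toward shift/rotate (0.34/0.30), which dominate the
relaxation of orientation disorder; acceptance statistics for every move
type are returned by `anneal()`.

**Statistical correctness.** The Metropolis rule is validated where it can
be validated exactly: on a single-voxel toy model with discrete orientations
and at most three particles, the state space (84 occupancy states) is
enumerable, and `toySample()` (the package's birth/death rule) reproduces
the exact Boltzmann distribution `toyBoltzmannExact()` to within multinomial
sampling error over a million steps. The full engine additionally audits its
incremental energy bookkeeping against from-scratch recomputation
(`externalEnergy()`, `internalEnergy()`) after every run.

**Temperatures and iterations.** The annealing schedule is exponential from
0.1 to 0.001 — the published start/end values; note that a temperature is
only meaningful relative to an energy normalization, which the source
software does not define, so the schedule endpoints should be read as part
of this package's calibration. Iteration budgets scale with problem size at
roughly the published effort of ~1e4 iterations per mask voxel (5e8
iterations on an acquisition-scale volume): the desk-scale default is 2e5;
the analyses in this package use 2e5 on a ~30-voxel compact bundle, and
3e7 on the default 32×32×12 phantoms (about one minute of CPU).

**Readout.** `extractStreamlines()` walks bound chains from free ends
(cycles are broken at the largest-bend link), emitting one polyline per
chain through the outer endpoints and bound-pair midpoints; chains shorter
than `minChain` (default 10 segments) are reconstruction fragments and are
not emitted.

## What the engine does and does not achieve at desk scale

On the noiseless compact straight phantom the annealer recovers mean
particle orientation within ~4.5° of truth at the 2e5-iteration default; on
the 90° crossing phantom at SNR 30 (3e7 iterations) the fraction of
crossing-entering tracts that continue straight through into the same
bundle's far side is ~0.8, versus ~0.05 for FACT on identical data — the
local-versus-global contrast that motivates the method. Known limitation:
fragment *fusion* is glassy. Parallel chains whose ends abut another
chain's interior cannot merge by any single move once their corridor's
signal is saturated, so a fraction of emitted tracts remain partial-length
fragments even in long runs. On the purse-string phantom this caps the
fraction of tracts whose endpoints reach opposite lateral halves at roughly
0.55--0.6 over the length-filtered tracts (~0.75 among tracts that reach
the midline region); matching the topology criterion for essentially all tracts would
require either acquisition-scale iteration counts or collective
(reptation-style) moves, which this engine does not implement.

## Tract quantification

* **Slicing** (`sliceTracts()`): transversal crossings of each polyline
  through a plane, by sign change of the signed distance, with linear
  interpolation; exact zeros are assigned to the positive side.
* **Cosine parametrization** (`fitCosineSeries()`): per axis,
  least squares of \(x(t) = \sum_{k=0}^{K} c_k \cos(\pi k t)\) with t the
  normalized cumulative arc length (sampling-density independent; an
  explicit t can be supplied). Default order K = 9, enough for
  perineal-scale curvature with ~30-point tracts. The constant term absorbs
  translation. Two intrinsic properties of the even (cosine) extension are
  worth knowing: the fitted derivative vanishes at exactly t = 0 and 1, so
  heading/curvature profiles are sampled strictly inside (0,1); and a
  circle is not exactly representable in the basis, so closed-form curvature
  checks go through the derivative operator
  (`curvatureFromDerivatives()`, \(\kappa = \|x'\times x''\|/\|x'\|^3\))
  rather than a fit.
* **Heading direction** (`headingCurvature()`, `tractMeanHeading()`): the
  trajectory tangent's angle against each world axis, in the *oriented*
  convention (no absolute value, range [0°, 180°]), so that mirrored
  bundles land symmetric about 90°. Because oriented angles depend on
  traversal direction, `canonicalizeHeading()` fixes a convention: each
  tract runs along the midline axis in the direction given by the side its
  apex bulges to (the bow sign, offset-invariant within a bundle).
  Point-mirrored bundle pairs then receive exactly opposite tangent fields.
  `headingSymmetry()` reports the per-axis deviation of the mean of the
  per-bundle mean angles from 90°.
* **Histograms** (`headingHistogram()`): tract-mean oriented angles binned
  at 10° over [0°, 180°].

## Tract clustering

`tractDistance()` is the symmetrized mean-closest-point distance on tracts
resampled to 20 equidistant points — the standard shape distance of the
tract-clustering literature. Affinities are \(\exp(-d^2/\sigma^2)\) with
\(\sigma\) the median off-diagonal distance (scale-free). The spectral
embedding takes eigenvectors 2 and 3 of the symmetric-normalized affinity,
scaled by their eigenvalues (diffusion-map convention, so identical tracts
embed at one point), with signs fixed by the largest-magnitude entry;
k-means (k = 2 for the left/right use case, 10 deterministic restarts)
yields labels. Purity against generator truth uses nearest-truth-tract
assignment (`matchToTruth()`). Following the source workflow, tracts are
length-filtered before clustering and heading statistics — fragments
shorter than the filter carry little shape information and sit ambiguously
between mirrored bundles.

## Numerical choices and degenerate inputs

* Voxel indexing is 0-based; a voxel's world position is its cell centre;
  world space is RAS millimetres everywhere; TRK files are converted from
  their corner-origin voxel-mm convention on read/write.
* The b0 threshold for gradient tables is 50 s/mm² (vendor-jitter tolerant,
  unambiguous at b = 400); both bvec dialects (3×N, N×3) are auto-detected.
* Tensor voxels with non-positive signal are flagged invalid rather than
  fit; degenerate λ1 = λ2 principal directions resolve to the direction in
  the tied subspace closest to the lowest-index world axis.
* The electrostatic-repulsion gradient scheme is deterministic (Fibonacci
  initialization, fixed iteration count).
* Random number use: everything flows through R's RNG; every public
  entry point takes an explicit seed, and identical seeds reproduce results
  bit-for-bit (including the C++ engine, which draws from R's RNG).

## Design decisions that were genuinely open

The source describes the global method's ingredients (segments, stick
model, binding into chains, annealing, the printed segment parameters) but
not the energy functional, proposal set, or schedule internals; those are
this package's own design, as documented above. The same holds for the
tract-distance, affinity bandwidth, embedding dimension and final clustering
step of the bundle-segmentation module, and for the exact cosine basis and
order of the curve parametrization. Where a published value exists (segment
length/width/weight, density penalty, temperature endpoints, FACT gates,
b-value and direction count, length filter) it is the default; everything
else was calibrated once on the straight and crossing phantoms and then
frozen.
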