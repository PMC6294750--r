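// Gibbs point-process engine for global tractography.
//
// The model state is a set of oriented line segments ("particles") with
// endpoint-to-endpoint connections. The posterior energy is
//   E = E_ext + E_int
// with E_ext the summed squared mismatch between the predicted and observed
// direction-demeaned diffusion signal (stick model), and E_int the prior:
// +(particlePotential + densityPenalty) per segment endpoint, and per
// bound endpoint pair
//   badBondPenalty - (2*densityPenalty + badBondPenalty +
//                     connectionStrength) * B,
//   B = exp(-gap^2/sigmaGap^2 - bend^2/sigmaBend^2)
// with the bend measured between directed chain orientations at the
// junction. Dangling ends are expensive (the termination drive that pushes
// chains through ambiguous regions), smooth junctions are rewarded, and
// geometrically incompatible junctions cost more than leaving the ends
// free, so chains cannot weave or fold back. A
// reversible-jump Metropolis sampler with birth / death / shift / rotate /
// connect / disconnect moves is run under an exponential simulated-annealing
// temperature schedule. Energies are maintained incrementally; R-level
// helpers recompute them from scratch for integrity checks.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int NSUB = 8;  // capacity for voxels hit by one segment

// demeaned stick attenuation kernel for orientation n
static void stickKernel(const double n[3], const std::vector<double>& bv,
                        const std::vector<double>& gx,
                        const std::vector<double>& gy,
                        const std::vector<double>& gz,
                        double dstick, std::vector<double>& out,
                        bool demean = true) {
  int nd = (int)bv.size();
  double mean = 0.0;
  for (int g = 0; g < nd; ++g) {
    double dot = gx[g] * n[0] + gy[g] * n[1] + gz[g] * n[2];
    out[g] = std::exp(-bv[g] * dstick * dot * dot);
    mean += out[g];
  }
  mean /= nd;
  if (demean)
    for (int g = 0; g < nd; ++g) out[g] -= mean;
}

struct Engine {
  // grid and signal
  int nx, ny, nz, nvox, ndir;
  std::vector<double> obs, pred;           // nvox * ndir, index v*ndir+g
  std::vector<double> bv, gx, gy, gz;
  double A[12], Ainv[12];                  // vox->world, world->vox (3x4)
  std::vector<char> inMask;                // per voxel
  std::vector<int> maskIdx;
  // model parameters
  double dstick, segLen, halfLen, segWgt;
  double densPen, partPot, connStr, badBond, sigmaG2, sigmaB2, rC, muBirth;
  double shiftSigma, rotSigma;
  // particles (slot arrays; slots stable, reused via free list)
  std::vector<double> px, py, pz, ox, oy, oz;
  std::vector<int> lp0, lp1, le0, le1;     // partner slot (-1 free), end
  std::vector<char> alive;
  std::vector<int> aliveList, posInAlive, freeSlots;
  // free endpoints (code = 2*slot + end)
  std::vector<int> freeEnds, posInFree;    // posInFree indexed by code
  // terminal particles (exactly one endpoint bound), for retract moves
  std::vector<int> termList, posInTerm;    // posInTerm indexed by slot
  // extension proposal geometry
  double extRho, extCone, lambda;          // ball radius, cone half-angle,
                                           // reference intensity (per mm^3 sr)
  // bound pairs (stored as code of lower endpoint)
  std::vector<int> pairList;
  std::unordered_map<int, int> pairPos;
  // spatial hash of free endpoints
  double cell;
  std::unordered_map<long long, std::vector<int>> grid;
  // cached energies; Eint is derived from counts so that the connection
  // strength may be annealed without invalidating the bookkeeping
  double Eext;
  double sumB = 0.0;  // sum of bond compatibilities B over bound pairs
  double dataWeight = 1.0;  // 1/(2 sigma^2) scaling of the data term
  bool demean = true;  // subtract the directional mean from stick kernels

  int nAlive() const { return (int)aliveList.size(); }

  int partner(int i, int e) const { return e == 0 ? lp0[i] : lp1[i]; }
  int partnerEnd(int i, int e) const { return e == 0 ? le0[i] : le1[i]; }
  void setLink(int i, int e, int j, int f) {
    if (e == 0) { lp0[i] = j; le0[i] = f; } else { lp1[i] = j; le1[i] = f; }
  }

  void endpoint(int i, int e, double out[3]) const {
    double s = (e == 0) ? -halfLen : halfLen;
    out[0] = px[i] + s * ox[i];
    out[1] = py[i] + s * oy[i];
    out[2] = pz[i] + s * oz[i];
  }

  // ---- spatial hash ----
  long long key(double x, double y, double z) const {
    long long qx = (long long)std::floor(x / cell) + 1024;
    long long qy = (long long)std::floor(y / cell) + 1024;
    long long qz = (long long)std::floor(z / cell) + 1024;
    return qx + 2048LL * (qy + 2048LL * qz);
  }
  void hashAdd(int code) {
    int i = code >> 1, e = code & 1;
    double p[3]; endpoint(i, e, p);
    grid[key(p[0], p[1], p[2])].push_back(code);
  }
  void hashRemove(int code) {
    int i = code >> 1, e = code & 1;
    double p[3]; endpoint(i, e, p);
    auto it = grid.find(key(p[0], p[1], p[2]));
    if (it == grid.end()) stop("spatial index corrupted");
    std::vector<int>& v = it->second;
    for (size_t m = 0; m < v.size(); ++m)
      if (v[m] == code) { v[m] = v.back(); v.pop_back(); return; }
    stop("spatial index corrupted (endpoint missing)");
  }

  // ---- free endpoint list ----
  void freeAdd(int code) {
    if ((int)posInFree.size() <= code) posInFree.resize(code + 1, -1);
    posInFree[code] = (int)freeEnds.size();
    freeEnds.push_back(code);
    hashAdd(code);
  }
  void freeRemove(int code) {
    hashRemove(code);
    int p = posInFree[code];
    int last = freeEnds.back();
    freeEnds[p] = last; posInFree[last] = p;
    freeEnds.pop_back(); posInFree[code] = -1;
  }

  // ---- voxel apportionment ----
  // voxels traversed by the segment axis, with exact length fractions
  // (analytic clipping of the segment against the voxel lattice, so the
  // energy is a continuous function of position and orientation)
  int traverse(int i, int vox[NSUB], double frac[NSUB]) const {
    double p0[3] = { px[i], py[i], pz[i] };
    double n[3] = { ox[i], oy[i], oz[i] };
    return traverseAt(p0, n, vox, frac);
  }
  int traverseAt(const double p0[3], const double n[3],
                 int vox[NSUB], double frac[NSUB]) const {
    // endpoints in continuous voxel coordinates (centres at integers,
    // boundaries at half-integers)
    double va[3], vb[3];
    for (int r = 0; r < 3; ++r) {
      double wa0 = p0[0] - halfLen * n[0], wa1 = p0[1] - halfLen * n[1],
             wa2 = p0[2] - halfLen * n[2];
      double wb0 = p0[0] + halfLen * n[0], wb1 = p0[1] + halfLen * n[1],
             wb2 = p0[2] + halfLen * n[2];
      va[r] = Ainv[4 * r] * wa0 + Ainv[4 * r + 1] * wa1 +
              Ainv[4 * r + 2] * wa2 + Ainv[4 * r + 3];
      vb[r] = Ainv[4 * r] * wb0 + Ainv[4 * r + 1] * wb1 +
              Ainv[4 * r + 2] * wb2 + Ainv[4 * r + 3];
    }
    // parameter values t in (0,1) where the line crosses a boundary plane
    double ts[16];
    int nts = 0;
    ts[nts++] = 0.0;
    for (int r = 0; r < 3 && nts < 13; ++r) {
      double d = vb[r] - va[r];
      if (std::fabs(d) < 1e-12) continue;
      double lo = std::min(va[r], vb[r]), hi = std::max(va[r], vb[r]);
      for (double bnd = std::floor(lo + 0.5) + 0.5; bnd < hi && nts < 13;
           bnd += 1.0) {
        double t = (bnd - va[r]) / d;
        if (t > 1e-12 && t < 1.0 - 1e-12) ts[nts++] = t;
      }
    }
    ts[nts++] = 1.0;
    // insertion sort (nts is tiny)
    for (int a = 1; a < nts; ++a) {
      double key = ts[a];
      int b = a - 1;
      while (b >= 0 && ts[b] > key) { ts[b + 1] = ts[b]; --b; }
      ts[b + 1] = key;
    }
    int cnt = 0;
    for (int a = 0; a + 1 < nts; ++a) {
      double dt = ts[a + 1] - ts[a];
      if (dt <= 0) continue;
      double tm = (ts[a] + ts[a + 1]) / 2;
      int ii = (int)std::floor(va[0] + tm * (vb[0] - va[0]) + 0.5);
      int jj = (int)std::floor(va[1] + tm * (vb[1] - va[1]) + 0.5);
      int kk = (int)std::floor(va[2] + tm * (vb[2] - va[2]) + 0.5);
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;  // outside the grid: contribution dropped
      int lin = ii + nx * (jj + ny * kk);
      bool found = false;
      for (int m = 0; m < cnt; ++m)
        if (vox[m] == lin) { frac[m] += dt; found = true; break; }
      if (!found && cnt < NSUB) { vox[cnt] = lin; frac[cnt] = dt; ++cnt; }
    }
    return cnt;
  }

  // add (sign=+1) or remove (sign=-1) particle i's signal contribution;
  // returns the external-energy change and updates pred
  double applySignal(int i, int sign) {
    double p0[3] = { px[i], py[i], pz[i] };
    double n[3] = { ox[i], oy[i], oz[i] };
    return applySignalAt(p0, n, sign);
  }
  double applySignalAt(const double p0[3], const double n[3], int sign) {
    static thread_local std::vector<double> kern;
    kern.resize(ndir);
    stickKernel(n, bv, gx, gy, gz, dstick, kern, demean);
    int vox[NSUB]; double frac[NSUB];
    int cnt = traverseAt(p0, n, vox, frac);
    double dE = 0.0;
    for (int m = 0; m < cnt; ++m) {
      double w = segWgt * frac[m];
      double* P = &pred[(size_t)vox[m] * ndir];
      const double* O = &obs[(size_t)vox[m] * ndir];
      for (int g = 0; g < ndir; ++g) {
        double a = sign * w * kern[g];
        dE += a * (a + 2.0 * (P[g] - O[g]));
        P[g] += a;
      }
    }
    return dataWeight * dE;
  }

  // ---- connection potential ----
  // The bend is measured between DIRECTED orientations: the chain leaves
  // particle i along its outward endpoint direction and must enter j
  // against j's outward direction. A fold-back (hairpin) junction scores
  // bend ~ pi and is effectively forbidden, so chains represent smooth
  // fiber paths rather than arbitrary matchings.
  double bondB(int i, int e, int j, int f) const {
    double pi_[3], pj_[3];
    endpoint(i, e, pi_); endpoint(j, f, pj_);
    double dx = pi_[0] - pj_[0], dy = pi_[1] - pj_[1], dz = pi_[2] - pj_[2];
    double gap2 = dx * dx + dy * dy + dz * dz;
    double si = (e == 0) ? -1.0 : 1.0;   // outward direction signs
    double sj = (f == 0) ? -1.0 : 1.0;
    double dot = -si * sj *
                 (ox[i] * ox[j] + oy[i] * oy[j] + oz[i] * oz[j]);
    if (dot > 1.0) dot = 1.0;
    if (dot < -1.0) dot = -1.0;
    double bend = std::acos(dot);
    return std::exp(-gap2 / sigmaG2 - bend * bend / sigmaB2);
  }
  double bondEnergyFromB(double B) const {
    return badBond - (2.0 * densPen + badBond + connStr) * B;
  }
  double bondEnergy(int i, int e, int j, int f) const {
    return bondEnergyFromB(bondB(i, e, j, f));
  }
  // internal energy derived from counts (exact under annealed connStr)
  double eint() const {
    return 2.0 * (partPot + densPen) * nAlive() +
           badBond * (double)pairList.size() -
           (2.0 * densPen + badBond + connStr) * sumB;
  }
  double bondsBOf(int i) const {
    double s = 0.0;
    for (int e = 0; e < 2; ++e) {
      int j = partner(i, e);
      if (j >= 0) s += bondB(i, e, j, partnerEnd(i, e));
    }
    return s;
  }

  // ---- candidate search for connect ----
  // free endpoints within rC of endpoint (i,e), excluding particle i
  void candidates(int i, int e, std::vector<int>& out) const {
    out.clear();
    double p[3]; endpoint(i, e, p);
    long long bx = (long long)std::floor(p[0] / cell);
    long long by = (long long)std::floor(p[1] / cell);
    long long bz = (long long)std::floor(p[2] / cell);
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          long long k = (bx + dx + 1024) +
                        2048LL * ((by + dy + 1024) + 2048LL * (bz + dz + 1024));
          auto it = grid.find(k);
          if (it == grid.end()) continue;
          for (int code : it->second) {
            int j = code >> 1;
            if (j == i) continue;
            double q[3]; endpoint(j, code & 1, q);
            double d2 = (p[0] - q[0]) * (p[0] - q[0]) +
                        (p[1] - q[1]) * (p[1] - q[1]) +
                        (p[2] - q[2]) * (p[2] - q[2]);
            if (d2 <= rC * rC) out.push_back(code);
          }
        }
  }

  // Boltzmann selection probability of candidate `target` among the
  // candidates of (i,e) at temperature T; returns 0 if absent
  double selectProb(int i, int e, int target, double T,
                    std::vector<int>& cand) const {
    candidates(i, e, cand);
    if (cand.empty()) return 0.0;
    double xmax = -1e300;
    std::vector<double> x(cand.size());
    for (size_t m = 0; m < cand.size(); ++m) {
      x[m] = -bondEnergy(i, e, cand[m] >> 1, cand[m] & 1) / T;
      if (x[m] > xmax) xmax = x[m];
    }
    double Z = 0.0, xt = 0.0;
    bool present = false;
    for (size_t m = 0; m < cand.size(); ++m) {
      double w = std::exp(x[m] - xmax);
      Z += w;
      if (cand[m] == target) { xt = w; present = true; }
    }
    return present ? xt / Z : 0.0;
  }

  // sample a candidate by Boltzmann weight; returns chosen code or -1
  int sampleCandidate(int i, int e, double T, double& prob,
                      std::vector<int>& cand) const {
    candidates(i, e, cand);
    if (cand.empty()) return -1;
    double xmax = -1e300;
    std::vector<double> x(cand.size());
    for (size_t m = 0; m < cand.size(); ++m) {
      x[m] = -bondEnergy(i, e, cand[m] >> 1, cand[m] & 1) / T;
      if (x[m] > xmax) xmax = x[m];
    }
    double Z = 0.0;
    for (size_t m = 0; m < cand.size(); ++m) { x[m] = std::exp(x[m] - xmax); Z += x[m]; }
    double u = unif_rand() * Z, c = 0.0;
    for (size_t m = 0; m < cand.size(); ++m) {
      c += x[m];
      if (u <= c) { prob = x[m] / Z; return cand[m]; }
    }
    prob = x.back() / Z;
    return cand.back();
  }

  // ---- terminal list ----
  int degree(int i) const {
    return (partner(i, 0) >= 0) + (partner(i, 1) >= 0);
  }
  void termAdd(int i) {
    if ((int)posInTerm.size() <= i) posInTerm.resize(i + 1, -1);
    posInTerm[i] = (int)termList.size();
    termList.push_back(i);
  }
  void termRemove(int i) {
    int p = posInTerm[i], last = termList.back();
    termList[p] = last; posInTerm[last] = p;
    termList.pop_back(); posInTerm[i] = -1;
  }

  // ---- particle bookkeeping ----
  int addParticle(double x, double y, double z,
                  double nxv, double nyv, double nzv) {
    int i;
    if (!freeSlots.empty()) { i = freeSlots.back(); freeSlots.pop_back(); }
    else {
      i = (int)px.size();
      px.push_back(0); py.push_back(0); pz.push_back(0);
      ox.push_back(0); oy.push_back(0); oz.push_back(0);
      lp0.push_back(-1); lp1.push_back(-1);
      le0.push_back(0); le1.push_back(0);
      alive.push_back(0);
      posInAlive.push_back(-1);
    }
    px[i] = x; py[i] = y; pz[i] = z;
    ox[i] = nxv; oy[i] = nyv; oz[i] = nzv;
    lp0[i] = lp1[i] = -1; le0[i] = le1[i] = 0;
    alive[i] = 1;
    posInAlive[i] = (int)aliveList.size();
    aliveList.push_back(i);
    freeAdd(2 * i); freeAdd(2 * i + 1);
    return i;
  }
  void removeParticle(int i) {  // must be unbound
    freeRemove(2 * i); freeRemove(2 * i + 1);
    int p = posInAlive[i], last = aliveList.back();
    aliveList[p] = last; posInAlive[last] = p;
    aliveList.pop_back(); posInAlive[i] = -1;
    alive[i] = 0;
    freeSlots.push_back(i);
  }
  void link(int i, int e, int j, int f) {
    freeRemove(2 * i + e); freeRemove(2 * j + f);
    int di = degree(i), dj = degree(j);
    setLink(i, e, j, f); setLink(j, f, i, e);
    if (di == 0) termAdd(i); else termRemove(i);   // 0->1 or 1->2
    if (dj == 0) termAdd(j); else termRemove(j);
    int code = std::min(2 * i + e, 2 * j + f);
    pairPos[code] = (int)pairList.size();
    pairList.push_back(code);
  }
  void unlink(int i, int e) {
    int j = partner(i, e), f = partnerEnd(i, e);
    int code = std::min(2 * i + e, 2 * j + f);
    auto it = pairPos.find(code);
    int p = it->second, lastCode = pairList.back();
    pairList[p] = lastCode; pairPos[lastCode] = p;
    pairList.pop_back(); pairPos.erase(it);
    setLink(i, e, -1, 0); setLink(j, f, -1, 0);
    if (degree(i) == 0) termRemove(i); else termAdd(i);  // 1->0 or 2->1
    if (degree(j) == 0) termRemove(j); else termAdd(j);
    freeAdd(2 * i + e); freeAdd(2 * j + f);
  }

  bool inMaskWorld(double x, double y, double z) const {
    double vc[3];
    double w[3] = { x, y, z };
    for (int r = 0; r < 3; ++r)
      vc[r] = Ainv[4 * r] * w[0] + Ainv[4 * r + 1] * w[1] +
              Ainv[4 * r + 2] * w[2] + Ainv[4 * r + 3];
    int ii = (int)std::floor(vc[0] + 0.5);
    int jj = (int)std::floor(vc[1] + 0.5);
    int kk = (int)std::floor(vc[2] + 0.5);
    if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
      return false;
    return inMask[ii + nx * (jj + ny * kk)] != 0;
  }
};

static void fillAffine(const NumericMatrix& aff, double out[12]) {
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 4; ++c) out[4 * r + c] = aff(r, c);
}

// invert a 4x4 affine (rotation+scale+translation part)
static NumericMatrix invertAffine(const NumericMatrix& aff) {
  // delegate to R would be simpler; done here to keep the engine
  // self-contained: solve the 3x3 block by cofactors
  double a[9];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) a[3 * r + c] = aff(r, c);
  double det = a[0] * (a[4] * a[8] - a[5] * a[7]) -
               a[1] * (a[3] * a[8] - a[5] * a[6]) +
               a[2] * (a[3] * a[7] - a[4] * a[6]);
  if (std::fabs(det) < 1e-15) stop("affine is singular");
  double inv[9] = {
    (a[4] * a[8] - a[5] * a[7]) / det, (a[2] * a[7] - a[1] * a[8]) / det,
    (a[1] * a[5] - a[2] * a[4]) / det, (a[5] * a[6] - a[3] * a[8]) / det,
    (a[0] * a[8] - a[2] * a[6]) / det, (a[2] * a[3] - a[0] * a[5]) / det,
    (a[3] * a[7] - a[4] * a[6]) / det, (a[1] * a[6] - a[0] * a[7]) / det,
    (a[0] * a[4] - a[1] * a[3]) / det };
  NumericMatrix out(4, 4);
  for (int r = 0; r < 3; ++r) {
    double t = 0.0;
    for (int c = 0; c < 3; ++c) {
      out(r, c) = inv[3 * r + c];
      t -= inv[3 * r + c] * aff(c, 3);
    }
    out(r, 3) = t;
  }
  out(3, 3) = 1.0;
  return out;
}

static void setupEngine(Engine& E, const NumericMatrix& obs, IntegerVector dims,
                        const NumericMatrix& affine, IntegerVector maskIdx,
                        NumericVector bvals, const NumericMatrix& bvecs,
                        double dstick, List par) {
  E.nx = dims[0]; E.ny = dims[1]; E.nz = dims[2];
  E.nvox = E.nx * E.ny * E.nz;
  E.ndir = bvecs.nrow();
  if (obs.nrow() != E.nvox || obs.ncol() != E.ndir)
    stop("observed signal must be nvox x ndir");
  E.obs.assign(E.nvox * (size_t)E.ndir, 0.0);
  for (int v = 0; v < E.nvox; ++v)
    for (int g = 0; g < E.ndir; ++g)
      E.obs[(size_t)v * E.ndir + g] = obs(v, g);
  E.pred.assign(E.nvox * (size_t)E.ndir, 0.0);
  E.bv.resize(E.ndir); E.gx.resize(E.ndir); E.gy.resize(E.ndir); E.gz.resize(E.ndir);
  for (int g = 0; g < E.ndir; ++g) {
    E.bv[g] = bvals[g];
    E.gx[g] = bvecs(g, 0); E.gy[g] = bvecs(g, 1); E.gz[g] = bvecs(g, 2);
  }
  fillAffine(affine, E.A);
  NumericMatrix ainv = invertAffine(affine);
  fillAffine(ainv, E.Ainv);
  E.inMask.assign(E.nvox, 0);
  for (int m = 0; m < maskIdx.size(); ++m) {
    int v = maskIdx[m];
    if (v < 0 || v >= E.nvox) stop("mask index out of range");
    E.inMask[v] = 1;
    E.maskIdx.push_back(v);
  }
  E.dstick = dstick;
  E.segLen = as<double>(par["segmentLength"]);
  E.halfLen = E.segLen / 2.0;
  E.segWgt = as<double>(par["segmentWeight"]);
  E.densPen = as<double>(par["densityPenalty"]);
  E.partPot = as<double>(par["particlePotential"]);
  E.connStr = as<double>(par["connectionStrength"]);
  E.badBond = as<double>(par["badBondPenalty"]);
  double sg = as<double>(par["sigmaGap"]);
  double sb = as<double>(par["sigmaBend"]);
  E.sigmaG2 = sg * sg;
  E.sigmaB2 = sb * sb;
  E.rC = as<double>(par["rC"]);
  E.muBirth = as<double>(par["muBirth"]);
  E.shiftSigma = as<double>(par["shiftSigma"]);
  E.rotSigma = as<double>(par["rotateSigma"]);
  E.extRho = as<double>(par["extendRadius"]);
  E.extCone = as<double>(par["extendAngle"]);
  E.dataWeight = as<double>(par["dataWeight"]);
  // reference intensity of the point process implied by muBirth over the
  // mask volume and the orientation sphere
  {
    double det = affine(0, 0) * (affine(1, 1) * affine(2, 2) - affine(1, 2) * affine(2, 1)) -
                 affine(0, 1) * (affine(1, 0) * affine(2, 2) - affine(1, 2) * affine(2, 0)) +
                 affine(0, 2) * (affine(1, 0) * affine(2, 1) - affine(1, 1) * affine(2, 0));
    double vmask = std::fabs(det) * std::max((size_t)1, (size_t)maskIdx.size());
    E.lambda = E.muBirth / (vmask * 4.0 * M_PI);
  }
  E.cell = std::max(E.rC, 0.5);
  E.Eext = 0.0;
  for (size_t m = 0; m < E.obs.size(); ++m) E.Eext += E.obs[m] * E.obs[m];
  E.Eext *= E.dataWeight;
}

static void loadConfiguration(Engine& E, const NumericMatrix& particles,
                              const IntegerMatrix& linkPartner,
                              const IntegerMatrix& linkEnd) {
  int n = particles.nrow();
  for (int i = 0; i < n; ++i) {
    E.addParticle(particles(i, 0), particles(i, 1), particles(i, 2),
                  particles(i, 3), particles(i, 4), particles(i, 5));
    E.Eext += E.applySignal(i, +1);
  }
  for (int i = 0; i < n; ++i)
    for (int e = 0; e < 2; ++e) {
      int j = linkPartner(i, e) - 1;            // 1-based from R, 0 = free
      if (j >= i) continue;                     // each pair once (j < i)
      if (j >= 0) {
        int f = linkEnd(i, e) - 1;
        E.link(i, e, j, f);
        E.sumB += E.bondB(i, e, j, f);
      }
    }
}

// [[Rcpp::export]]
NumericMatrix cpp_predict_signal(NumericMatrix particles, IntegerVector dims,
                                 NumericMatrix affine, NumericVector bvals,
                                 NumericMatrix bvecs, double dstick,
                                 double segLen, double segWgt,
                                 bool demean = true) {
  Engine E;
  E.demean = demean;
  NumericMatrix zero(dims[0] * dims[1] * dims[2], bvecs.nrow());
  List par = List::create(
    _["segmentLength"] = segLen, _["segmentWeight"] = segWgt,
    _["densityPenalty"] = 0.0, _["particlePotential"] = 0.0,
    _["connectionStrength"] = 0.0, _["badBondPenalty"] = 0.0,
    _["sigmaGap"] = 1.0, _["sigmaBend"] = 1.0, _["rC"] = segLen,
    _["muBirth"] = 1.0,
    _["shiftSigma"] = 1.0, _["rotateSigma"] = 1.0,
    _["extendRadius"] = 0.3, _["extendAngle"] = 0.5,
    _["dataWeight"] = 1.0);
  IntegerVector noMask(0);
  setupEngine(E, zero, dims, affine, noMask, bvals, bvecs, dstick, par);
  for (int i = 0; i < particles.nrow(); ++i) {
    E.addParticle(particles(i, 0), particles(i, 1), particles(i, 2),
                  particles(i, 3), particles(i, 4), particles(i, 5));
    E.applySignal(i, +1);
  }
  NumericMatrix out(E.nvox, E.ndir);
  for (int v = 0; v < E.nvox; ++v)
    for (int g = 0; g < E.ndir; ++g) out(v, g) = E.pred[(size_t)v * E.ndir + g];
  return out;
}

// [[Rcpp::export]]
double cpp_internal_energy(NumericMatrix particles, IntegerMatrix linkPartner,
                           IntegerMatrix linkEnd, double segLen,
                           double densityPenalty, double particlePotential,
                           double connectionStrength, double badBondPenalty,
                           double sigmaGap, double sigmaBend) {
  int n = particles.nrow();
  Engine E;
  E.halfLen = segLen / 2.0;
  E.densPen = densityPenalty;
  E.connStr = connectionStrength;
  E.badBond = badBondPenalty;
  E.sigmaG2 = sigmaGap * sigmaGap;
  E.sigmaB2 = sigmaBend * sigmaBend;
  E.px.resize(n); E.py.resize(n); E.pz.resize(n);
  E.ox.resize(n); E.oy.resize(n); E.oz.resize(n);
  for (int i = 0; i < n; ++i) {
    E.px[i] = particles(i, 0); E.py[i] = particles(i, 1); E.pz[i] = particles(i, 2);
    E.ox[i] = particles(i, 3); E.oy[i] = particles(i, 4); E.oz[i] = particles(i, 5);
  }
  double energy = 0.0;
  for (int i = 0; i < n; ++i)
    for (int e = 0; e < 2; ++e) {
      energy += particlePotential + densityPenalty;  // every endpoint
      int j = linkPartner(i, e) - 1;
      int f = linkEnd(i, e) - 1;
      if (j < 0) continue;
      if (j == i) stop("link integrity error: self-link");
      if (linkPartner(j, f) - 1 != i || linkEnd(j, f) - 1 != e)
        stop("link integrity error: asymmetric endpoint links");
      if (j > i) energy += E.bondEnergy(i, e, j, f);  // each pair once
    }
  return energy;
}

// [[Rcpp::export]]
List cpp_anneal(NumericMatrix obs, IntegerVector dims, NumericMatrix affine,
                IntegerVector maskIdx, NumericVector bvals,
                NumericMatrix bvecs, double dstick, List par,
                NumericMatrix initParticles, IntegerMatrix initLinkPartner,
                IntegerMatrix initLinkEnd) {
  Engine E;
  setupEngine(E, obs, dims, affine, maskIdx, bvals, bvecs, dstick, par);
  loadConfiguration(E, initParticles, initLinkPartner, initLinkEnd);

  double nIter = as<double>(par["nIterations"]);
  double tStart = as<double>(par["tStart"]);
  double tEnd = as<double>(par["tEnd"]);
  double csStart = as<double>(par["connectionStrength"]);
  double csEnd = as<double>(par["connectionStrengthEnd"]);
  // move order: birth death shift rotate connect disconnect extend retract
  NumericVector mv = par["moveProbabilities"];
  const int NMOVE = 8;
  double cum[NMOVE];
  double c = 0.0;
  for (int m = 0; m < NMOVE; ++m) { c += mv[m]; cum[m] = c; }
  long long N = (long long)nIter;
  int traceEvery = std::max(1LL, N / 1000);
  std::vector<double> trace;
  std::vector<int> att(NMOVE, 0), acc(NMOVE, 0);
  std::vector<int> cand, cand2;

  if (E.maskIdx.empty()) stop("empty mask");
  double lograt = std::log(tEnd / tStart);

  for (long long it = 0; it < N; ++it) {
    double frac = N > 1 ? (double)it / (N - 1) : 1.0;
    double T = tStart * std::exp(lograt * frac);
    E.connStr = csStart + (csEnd - csStart) * frac;
    double u = unif_rand() * cum[NMOVE - 1];
    int mtype = 0;
    while (mtype < NMOVE - 1 && u > cum[mtype]) ++mtype;
    ++att[mtype];
    bool accepted = false;

    if (mtype == 0) {  // birth
      int vix = E.maskIdx[(int)(unif_rand() * E.maskIdx.size())];
      int kk = vix / (E.nx * E.ny);
      int jj = (vix - kk * E.nx * E.ny) / E.nx;
      int ii = vix % E.nx;
      double vc[3] = { ii + unif_rand() - 0.5, jj + unif_rand() - 0.5,
                       kk + unif_rand() - 0.5 };
      double w[3];
      for (int r = 0; r < 3; ++r)
        w[r] = E.A[4 * r] * vc[0] + E.A[4 * r + 1] * vc[1] +
               E.A[4 * r + 2] * vc[2] + E.A[4 * r + 3];
      double z = 2.0 * unif_rand() - 1.0, ph = 2.0 * M_PI * unif_rand();
      double rxy = std::sqrt(std::max(0.0, 1.0 - z * z));
      double n[3] = { rxy * std::cos(ph), rxy * std::sin(ph), z };
      double dEext = E.applySignalAt(w, n, +1);
      double dEint = 2.0 * (E.partPot + E.densPen);
      int nAfter = E.nAlive() + 1;
      double a = std::exp(-(dEext + dEint) / T) *
                 (mv[1] * E.muBirth) / (mv[0] * nAfter);
      if (unif_rand() < a) {
        int i = E.addParticle(w[0], w[1], w[2], n[0], n[1], n[2]);
        (void)i;
        E.Eext += dEext;
        accepted = true;
      } else {
        E.applySignalAt(w, n, -1);  // roll back prediction
      }
    } else if (mtype == 1) {  // death (uniform particle; null if bound)
      int n = E.nAlive();
      if (n > 0) {
        int i = E.aliveList[(int)(unif_rand() * n)];
        if (E.partner(i, 0) < 0 && E.partner(i, 1) < 0) {
          double dEext = E.applySignal(i, -1);
          double dEint = -2.0 * (E.partPot + E.densPen);
          double a = std::exp(-(dEext + dEint) / T) *
                     (mv[0] * n) / (mv[1] * E.muBirth);
          if (unif_rand() < a) {
            E.removeParticle(i);
            E.Eext += dEext;
            accepted = true;
          } else {
            E.applySignal(i, +1);
          }
        }
      }
    } else if (mtype == 2 || mtype == 3) {  // shift / rotate
      int n = E.nAlive();
      if (n > 0) {
        int i = E.aliveList[(int)(unif_rand() * n)];
        double oldP[3] = { E.px[i], E.py[i], E.pz[i] };
        double oldN[3] = { E.ox[i], E.oy[i], E.oz[i] };
        double newP[3] = { oldP[0], oldP[1], oldP[2] };
        double newN[3] = { oldN[0], oldN[1], oldN[2] };
        if (mtype == 2)
          for (int r = 0; r < 3; ++r) newP[r] += E.shiftSigma * norm_rand();
        for (int r = 0; r < 3; ++r) newN[r] += E.rotSigma * norm_rand();
        double nn = std::sqrt(newN[0] * newN[0] + newN[1] * newN[1] +
                              newN[2] * newN[2]);
        if (nn > 1e-12 && E.inMaskWorld(newP[0], newP[1], newP[2])) {
          for (int r = 0; r < 3; ++r) newN[r] /= nn;
          double bondsBOld = E.bondsBOf(i);
          double dEext = E.applySignal(i, -1);
          // free endpoints must be re-hashed around the geometry change
          bool f0 = E.partner(i, 0) < 0, f1 = E.partner(i, 1) < 0;
          if (f0) E.hashRemove(2 * i);
          if (f1) E.hashRemove(2 * i + 1);
          E.px[i] = newP[0]; E.py[i] = newP[1]; E.pz[i] = newP[2];
          E.ox[i] = newN[0]; E.oy[i] = newN[1]; E.oz[i] = newN[2];
          if (f0) E.hashAdd(2 * i);
          if (f1) E.hashAdd(2 * i + 1);
          dEext += E.applySignal(i, +1);
          double bondsBNew = E.bondsBOf(i);
          double dEint = -(2.0 * E.densPen + E.badBond + E.connStr) *
                         (bondsBNew - bondsBOld);
          double a = std::exp(-(dEext + dEint) / T);
          if (unif_rand() < a) {
            E.Eext += dEext;
            E.sumB += bondsBNew - bondsBOld;
            accepted = true;
          } else {
            E.applySignal(i, -1);
            if (f0) E.hashRemove(2 * i);
            if (f1) E.hashRemove(2 * i + 1);
            E.px[i] = oldP[0]; E.py[i] = oldP[1]; E.pz[i] = oldP[2];
            E.ox[i] = oldN[0]; E.oy[i] = oldN[1]; E.oz[i] = oldN[2];
            if (f0) E.hashAdd(2 * i);
            if (f1) E.hashAdd(2 * i + 1);
            E.applySignal(i, +1);
          }
        }
      }
    } else if (mtype == 4) {  // connect
      int nf = (int)E.freeEnds.size();
      if (nf > 0) {
        int codeI = E.freeEnds[(int)(unif_rand() * nf)];
        int i = codeI >> 1, e = codeI & 1;
        double probIJ = 0.0;
        int codeJ = E.sampleCandidate(i, e, T, probIJ, cand);
        if (codeJ >= 0) {
          int j = codeJ >> 1, f = codeJ & 1;
          double probJI = E.selectProb(j, f, codeI, T, cand2);
          double B = E.bondB(i, e, j, f);
          double dEint = E.bondEnergyFromB(B);
          double qFwd = (mv[4] / nf) * (probIJ + probJI);
          double qRev = mv[5] / (double)(E.pairList.size() + 1);
          double a = std::exp(-dEint / T) * qRev / qFwd;
          if (unif_rand() < a) {
            E.link(i, e, j, f);
            E.sumB += B;
            accepted = true;
          }
        }
      }
    } else if (mtype == 5) {  // disconnect
      int np = (int)E.pairList.size();
      if (np > 0) {
        int code = E.pairList[(int)(unif_rand() * np)];
        int i = code >> 1, e = code & 1;
        int j = E.partner(i, e), f = E.partnerEnd(i, e);
        double B = E.bondB(i, e, j, f);
        double dEint = -E.bondEnergyFromB(B);
        E.unlink(i, e);  // tentatively apply to evaluate the reverse move
        int nfAfter = (int)E.freeEnds.size();
        double probIJ = E.selectProb(i, e, 2 * j + f, T, cand);
        double probJI = E.selectProb(j, f, 2 * i + e, T, cand2);
        double qFwd = mv[5] / (double)np;
        double qRev = (mv[4] / nfAfter) * (probIJ + probJI);
        double a = std::exp(-dEint / T) * qRev / qFwd;
        if (unif_rand() < a) {
          E.sumB -= B;
          accepted = true;
        } else {
          E.link(i, e, j, f);
        }
      }
    } else if (mtype == 6) {  // extend: chain-end birth + bind
      int nf = (int)E.freeEnds.size();
      if (nf > 0) {
        int codeP = E.freeEnds[(int)(unif_rand() * nf)];
        int i = codeP >> 1, e = codeP & 1;
        double epP[3]; E.endpoint(i, e, epP);
        double s = (e == 0) ? -1.0 : 1.0;  // outward direction of endpoint e
        double d[3] = { s * E.ox[i], s * E.oy[i], s * E.oz[i] };
        // near endpoint: uniform in a ball of radius extRho around epP
        double r[3];
        {
          double z = 2.0 * unif_rand() - 1.0, ph = 2.0 * M_PI * unif_rand();
          double rad = E.extRho * std::cbrt(unif_rand());
          double rxy = std::sqrt(std::max(0.0, 1.0 - z * z));
          r[0] = epP[0] + rad * rxy * std::cos(ph);
          r[1] = epP[1] + rad * rxy * std::sin(ph);
          r[2] = epP[2] + rad * z;
        }
        // orientation: uniform in the cone of half-angle extCone around d
        double n[3];
        {
          double ca = 1.0 - unif_rand() * (1.0 - std::cos(E.extCone));
          double sa = std::sqrt(std::max(0.0, 1.0 - ca * ca));
          double ph = 2.0 * M_PI * unif_rand();
          // orthonormal basis (u, v) perpendicular to d
          double u1[3];
          if (std::fabs(d[0]) < 0.9) { u1[0] = 0; u1[1] = -d[2]; u1[2] = d[1]; }
          else { u1[0] = -d[1]; u1[1] = d[0]; u1[2] = 0; }
          double nu = std::sqrt(u1[0]*u1[0] + u1[1]*u1[1] + u1[2]*u1[2]);
          for (int q = 0; q < 3; ++q) u1[q] /= nu;
          double v1[3] = { d[1]*u1[2] - d[2]*u1[1],
                           d[2]*u1[0] - d[0]*u1[2],
                           d[0]*u1[1] - d[1]*u1[0] };
          for (int q = 0; q < 3; ++q)
            n[q] = ca * d[q] + sa * (std::cos(ph) * u1[q] + std::sin(ph) * v1[q]);
        }
        // new particle: the bound endpoint sits at r and the segment runs
        // along +n away from the parent; the stored (orientation, bound
        // end) representation of that physical state is chosen with
        // probability 1/2 each (antipodal class), with the matching 1/2
        // in the proposal density
        double ctr[3] = { r[0] + E.halfLen * n[0], r[1] + E.halfLen * n[1],
                          r[2] + E.halfLen * n[2] };
        int bindEnd = 0;
        if (unif_rand() < 0.5) {
          bindEnd = 1;
          n[0] = -n[0]; n[1] = -n[1]; n[2] = -n[2];
        }
        if (E.inMaskWorld(ctr[0], ctr[1], ctr[2])) {
          double dEext = E.applySignalAt(ctr, n, +1);
          int iNew = E.addParticle(ctr[0], ctr[1], ctr[2], n[0], n[1], n[2]);
          double B = E.bondB(i, e, iNew, bindEnd);
          double dEint = 2.0 * (E.partPot + E.densPen) + E.bondEnergyFromB(B);
          double vball = 4.0 / 3.0 * M_PI * E.extRho * E.extRho * E.extRho;
          // orientation proposal density is 1/(2 * cap area) per
          // representation of the antipodal class
          double acap2 = 4.0 * M_PI * (1.0 - std::cos(E.extCone));
          // new particle becomes terminal (+1); parent goes 0->1 (+1) or
          // 1->2 (-1)
          int nTermAfter = (E.degree(i) == 0) ? (int)E.termList.size() + 2
                                              : (int)E.termList.size();
          double a = std::exp(-(dEext + dEint) / T) * E.lambda * vball * acap2 *
                     (mv[7] * nf) / (mv[6] * nTermAfter);
          if (unif_rand() < a) {
            E.link(i, e, iNew, bindEnd);
            E.Eext += dEext;
            E.sumB += B;
            accepted = true;
          } else {
            E.applySignal(iNew, -1);
            E.removeParticle(iNew);
          }
        }
      }
    } else {  // retract: unbind + delete a terminal particle
      int nt = (int)E.termList.size();
      if (nt > 0) {
        int t = E.termList[(int)(unif_rand() * nt)];
        int eb = (E.partner(t, 0) >= 0) ? 0 : 1;
        int j = E.partner(t, eb), f = E.partnerEnd(t, eb);
        // reverse (extend) feasibility: gap within the ball, bend within
        // the cone
        double epT[3], epJ[3];
        E.endpoint(t, eb, epT); E.endpoint(j, f, epJ);
        double g2 = (epT[0]-epJ[0])*(epT[0]-epJ[0]) +
                    (epT[1]-epJ[1])*(epT[1]-epJ[1]) +
                    (epT[2]-epJ[2])*(epT[2]-epJ[2]);
        double sT = (eb == 0) ? 1.0 : -1.0;   // axis pointing away from bond
        double sJ = (f == 0) ? -1.0 : 1.0;    // outward direction of parent
        double dot = sT * sJ * (E.ox[t]*E.ox[j] + E.oy[t]*E.oy[j] +
                                E.oz[t]*E.oz[j]);
        if (g2 <= E.extRho * E.extRho && dot >= std::cos(E.extCone)) {
          double B = E.bondB(t, eb, j, f);
          E.unlink(t, eb);
          double dEext = E.applySignal(t, -1);
          double dEint = -2.0 * (E.partPot + E.densPen) - E.bondEnergyFromB(B);
          double vball = 4.0 / 3.0 * M_PI * E.extRho * E.extRho * E.extRho;
          double acap2 = 4.0 * M_PI * (1.0 - std::cos(E.extCone));
          int nfAfter = (int)E.freeEnds.size() - 2;  // after deleting t
          double a = std::exp(-(dEext + dEint) / T) *
                     (mv[6] * nt) /
                     (mv[7] * nfAfter * E.lambda * vball * acap2);
          if (unif_rand() < a) {
            E.removeParticle(t);
            E.Eext += dEext;
            E.sumB -= B;
            accepted = true;
          } else {
            E.applySignal(t, +1);
            E.link(t, eb, j, f);
          }
        }
      }
    }

    if (accepted) ++acc[mtype];
    if (it % traceEvery == 0) trace.push_back(E.Eext + E.eint());
  }

  // export configuration (compacted)
  int n = E.nAlive();
  NumericMatrix particles(n, 6);
  IntegerMatrix linkPartner(n, 2), linkEnd(n, 2);
  std::vector<int> newIdx(E.px.size(), -1);
  for (int m = 0; m < n; ++m) newIdx[E.aliveList[m]] = m;
  for (int m = 0; m < n; ++m) {
    int i = E.aliveList[m];
    particles(m, 0) = E.px[i]; particles(m, 1) = E.py[i]; particles(m, 2) = E.pz[i];
    particles(m, 3) = E.ox[i]; particles(m, 4) = E.oy[i]; particles(m, 5) = E.oz[i];
    for (int e = 0; e < 2; ++e) {
      int j = E.partner(i, e);
      linkPartner(m, e) = j < 0 ? 0 : newIdx[j] + 1;
      linkEnd(m, e) = j < 0 ? 0 : E.partnerEnd(i, e) + 1;
    }
  }
  return List::create(
    _["particles"] = particles,
    _["linkPartner"] = linkPartner,
    _["linkEnd"] = linkEnd,
    _["externalEnergy"] = E.Eext,
    _["internalEnergy"] = E.eint(),
    _["trace"] = NumericVector(trace.begin(), trace.end()),
    _["attempted"] = IntegerVector(att.begin(), att.end()),
    _["accepted"] = IntegerVector(acc.begin(), acc.end()));
}

// Fixed-temperature birth/death sampler on the single-voxel toy model with
// discrete orientations, used to validate the Metropolis rule against exact
// Boltzmann weights. kernels: K x ndir matrix of per-particle (weight-scaled,
// demeaned) signal contributions; obs: observed demeaned profile.
// [[Rcpp::export]]
IntegerMatrix cpp_toy_sample(NumericMatrix kernels, NumericVector obs,
                             double densityPenalty, double temperature,
                             double nSteps, int thin, int maxParticles) {
  int K = kernels.nrow(), nd = kernels.ncol();
  std::vector<int> m(K, 0);
  int k = 0;
  std::vector<double> P(nd, 0.0);
  long long N = (long long)nSteps;
  int nOut = (int)(N / thin);
  IntegerMatrix out(nOut, K);
  int row = 0;
  const double pb = 0.5, pd = 0.5;
  for (long long it = 0; it < N; ++it) {
    if (unif_rand() < pb) {  // birth
      if (k < maxParticles) {
        int o = (int)(unif_rand() * K);
        double dE = 2.0 * densityPenalty;
        for (int g = 0; g < nd; ++g) {
          double a = kernels(o, g);
          dE += a * (a + 2.0 * (P[g] - obs[g]));
        }
        double a = std::exp(-dE / temperature) *
                   (pd * K * (m[o] + 1.0)) / (pb * (k + 1.0));
        if (unif_rand() < a) {
          ++m[o]; ++k;
          for (int g = 0; g < nd; ++g) P[g] += kernels(o, g);
        }
      }
    } else {  // death
      if (k > 0) {
        double u = unif_rand() * k;
        int o = 0; double c = m[0];
        while (o < K - 1 && u > c) c += m[++o];
        double dE = -2.0 * densityPenalty;
        for (int g = 0; g < nd; ++g) {
          double a = -kernels(o, g);
          dE += a * (a + 2.0 * (P[g] - obs[g]));
        }
        double a = std::exp(-dE / temperature) *
                   (pb * k) / (pd * K * (double)m[o]);
        if (unif_rand() < a) {
          --m[o]; --k;
          for (int g = 0; g < nd; ++g) P[g] -= kernels(o, g);
        }
      }
    }
    if ((it + 1) % thin == 0 && row < nOut) {
      for (int o = 0; o < K; ++o) out(row, o) = m[o];
      ++row;
    }
  }
  return out;
}
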