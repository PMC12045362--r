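// Particle Gibbs with ancestor sampling over the biophysical bouton model,
// plus a linear AR(2) generative baseline. The sensor master equation is
// advanced with exact per-lobe matrix-exponential propagators cached on a
// log-spaced calcium grid (kinetic rates are fixed within a sweep); the
// calcium scalars take one midpoint (RK2) step per bin. All randomness goes
// through R's RNG so results are reproducible with set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct CellPars {
  double kB, pumpKm, storeInVmax, storeInKm, storeOutVmax, storeOutKm;
  double storeCaBasal, slowFrac, slowK, caBasal;
};

struct Theta {
  double aCa, gTotal, pumpVmax, Rf, sigma, rateHz, driftScale;
};

struct SensorCtx {
  arma::cube PNf, PCf;        // fine-substep propagators (h = dt / nFine)
  arma::cube PNc, PCc;        // coarse-substep propagators (h = dt / nCoarse)
  arma::vec caGrid;           // grid (uM), caGrid(0) == 0
  double phi0, phiSat, phiBasal;
  int nCa, nFine, nCoarse, relaxBins;
  double lcaMin, lcaStep;     // log-grid bookkeeping (grid index 1..G-1)
  int G;
};

inline double mm(double vmax, double km, double ca) {
  return vmax * ca / (km + ca);
}

// Linearly interpolated per-lobe propagators at the current calcium.
inline void lobeProps(const SensorCtx& sc, const arma::cube& PN,
                      const arma::cube& PC, double ca, arma::mat33& pn,
                      arma::mat33& pc) {
  if (ca <= sc.caGrid(1)) {
    double w = ca / sc.caGrid(1);
    pn = (1 - w) * PN.slice(0) + w * PN.slice(1);
    pc = (1 - w) * PC.slice(0) + w * PC.slice(1);
    return;
  }
  double li = (std::log(ca) - sc.lcaMin) / sc.lcaStep + 1.0;
  int i0 = (int)std::floor(li);
  if (i0 >= sc.G - 1) { pn = PN.slice(sc.G - 1); pc = PC.slice(sc.G - 1); return; }
  double w = li - i0;
  pn = (1 - w) * PN.slice(i0) + w * PN.slice(i0 + 1);
  pc = (1 - w) * PC.slice(i0) + w * PC.slice(i0 + 1);
}

// One bin of the biophysical latent dynamics. state = [ca, caSlow,
// caStore, x0..x8, binsSinceSpike] with x stored C-lobe-fastest as a 3x3
// matrix X(c, n). Strang-split substeps: fine resolution while the
// spike-evoked calcium transient is fast, coarse afterwards.
inline void advanceBio(double* s, bool spike, const Theta& th,
                       const CellPars& cp, const SensorCtx& sc, double dt,
                       double leak) {
  if (spike) {
    s[0] += th.aCa / (1.0 + cp.kB);
    s[12] = 0.0;
  } else {
    s[12] += 1.0;
  }
  bool fine = s[12] < sc.relaxBins;
  int nSub = fine ? sc.nFine : sc.nCoarse;
  const arma::cube& PN = fine ? sc.PNf : sc.PNc;
  const arma::cube& PC = fine ? sc.PCf : sc.PCc;
  double h = dt / nSub;
  double vr = cp.slowFrac > 0 ? cp.slowFrac / (1.0 - cp.slowFrac) : 0.0;
  auto deriv = [&](const double* y, double* d) {
    double ca = y[0] > 0 ? y[0] : 0, sl = y[1], st = y[2];
    double jTot = leak - mm(th.pumpVmax, cp.pumpKm, ca) +
      mm(cp.storeOutVmax, cp.storeOutKm, st) -
      mm(cp.storeInVmax, cp.storeInKm, ca) +
      cp.slowK * vr * (sl - ca);
    d[0] = jTot / (1.0 + cp.kB);
    d[1] = cp.slowK * (ca - sl);
    d[2] = mm(cp.storeInVmax, cp.storeInKm, ca) -
      mm(cp.storeOutVmax, cp.storeOutKm, st);
  };
  arma::mat X(s + 3, 3, 3, false, true);
  arma::mat33 pn, pc;
  double d1[3], ymid[3], d2[3];
  for (int sub = 0; sub < nSub; ++sub) {
    // half-step of the calcium scalars (midpoint)
    deriv(s, d1);
    for (int k = 0; k < 3; ++k) ymid[k] = s[k] + 0.25 * h * d1[k];
    deriv(ymid, d2);
    for (int k = 0; k < 3; ++k) s[k] += 0.5 * h * d2[k];
    if (s[0] < 0) s[0] = 0;
    // full sensor step at the midpoint calcium, with calcium uptake
    lobeProps(sc, PN, PC, s[0], pn, pc);
    double boundBefore = 2.0 - arma::accu(X.col(0)) - arma::accu(X.row(0));
    X = pc * X * pn.t();
    double boundAfter = 2.0 - arma::accu(X.col(0)) - arma::accu(X.row(0));
    s[0] -= th.gTotal * sc.nCa * (boundAfter - boundBefore) / (1.0 + cp.kB);
    // second half-step of the scalars
    deriv(s, d1);
    for (int k = 0; k < 3; ++k) ymid[k] = s[k] + 0.25 * h * d1[k];
    deriv(ymid, d2);
    for (int k = 0; k < 3; ++k) s[k] += 0.5 * h * d2[k];
    if (s[0] < 0) s[0] = 0;
    if (s[1] < 0) s[1] = 0;
    if (s[2] < 0) s[2] = 0;
  }
}

inline double dffBio(const double* s, const Theta& th, const SensorCtx& sc) {
  const arma::mat X(const_cast<double*>(s) + 3, 3, 3, false, true);
  double phi = arma::accu(X.row(2)) + arma::accu(X.col(2)) - X(2, 2);
  double u = (phi - sc.phi0) / (sc.phiSat - sc.phi0);
  double ub = (sc.phiBasal - sc.phi0) / (sc.phiSat - sc.phi0);
  double F = 1.0 + (th.Rf - 1.0) * u;
  double Fb = 1.0 + (th.Rf - 1.0) * ub;
  return F / Fb - 1.0;
}

CellPars cellFromList(const List& cl) {
  CellPars cp;
  cp.kB = cl["kappaB"]; cp.pumpKm = cl["pumpKm"];
  cp.storeInVmax = cl["storeInVmax"]; cp.storeInKm = cl["storeInKm"];
  cp.storeOutVmax = cl["storeOutVmax"]; cp.storeOutKm = cl["storeOutKm"];
  cp.storeCaBasal = cl["storeCaBasal"]; cp.slowFrac = cl["slowFrac"];
  cp.slowK = cl["slowK"]; cp.caBasal = cl["caBasal"];
  return cp;
}

Theta thetaFromList(const List& tl) {
  Theta th;
  th.aCa = tl["aCa"]; th.gTotal = tl["gTotal"];
  th.pumpVmax = tl["pumpVmax"]; th.Rf = tl["Rf"]; th.sigma = tl["sigma"];
  th.rateHz = tl["rateHz"]; th.driftScale = tl["driftScale"];
  return th;
}

SensorCtx ctxFromList(const List& sl) {
  SensorCtx sc;
  sc.PNf = as<arma::cube>(sl["PNf"]);
  sc.PCf = as<arma::cube>(sl["PCf"]);
  sc.PNc = as<arma::cube>(sl["PNc"]);
  sc.PCc = as<arma::cube>(sl["PCc"]);
  sc.caGrid = as<arma::vec>(sl["caGrid"]);
  sc.phi0 = sl["phi0"]; sc.phiSat = sl["phiSat"];
  sc.phiBasal = sl["phiBasal"]; sc.nCa = sl["nCa"];
  sc.nFine = sl["nFine"]; sc.nCoarse = sl["nCoarse"];
  sc.relaxBins = sl["relaxBins"];
  sc.G = sc.caGrid.n_elem;
  sc.lcaMin = std::log(sc.caGrid(1));
  sc.lcaStep = (std::log(sc.caGrid(sc.G - 1)) - sc.lcaMin) / (sc.G - 2);
  return sc;
}

double leakOf(const Theta& th, const CellPars& cp) {
  return mm(th.pumpVmax, cp.pumpKm, cp.caBasal) +
    mm(cp.storeInVmax, cp.storeInKm, cp.caBasal) -
    mm(cp.storeOutVmax, cp.storeOutKm, cp.storeCaBasal);
}

inline double logdnorm(double x, double sd) {
  return -0.5 * std::log(2.0 * M_PI * sd * sd) - 0.5 * x * x / (sd * sd);
}

}  // namespace

// Build per-lobe propagator tables on {0} + log-spaced calcium grid,
// at the fine and coarse substep durations.
// [[Rcpp::export(name = ".cppBuildTable")]]
List cppBuildTable(List lobeN, List lobeC, double dt, int nGrid,
                   double caMin, double caMax, int nFine, int nCoarse) {
  arma::vec grid(nGrid);
  grid(0) = 0.0;
  for (int i = 1; i < nGrid; ++i)
    grid(i) = std::exp(std::log(caMin) + (std::log(caMax) - std::log(caMin)) *
                       (i - 1.0) / (nGrid - 2.0));
  auto build = [&](const List& l, double h) {
    double koff = l["koffCa"], Ka = l["Ka"], hh = l["hill"];
    double kpon = l["konPep"], kpoff = l["koffPep"];
    arma::cube P(3, 3, nGrid);
    for (int i = 0; i < nGrid; ++i) {
      double kon = koff * std::pow(grid(i) / Ka, hh);
      arma::mat G = {{-kon, koff, 0.0},
                     {kon, -(koff + kpon), kpoff},
                     {0.0, kpon, -kpoff}};
      P.slice(i) = arma::expmat(G * h);
    }
    return P;
  };
  return List::create(
      _["PNf"] = build(lobeN, dt / nFine), _["PCf"] = build(lobeC, dt / nFine),
      _["PNc"] = build(lobeN, dt / nCoarse),
      _["PCc"] = build(lobeC, dt / nCoarse),
      _["caGrid"] = grid, _["nFine"] = nFine, _["nCoarse"] = nCoarse);
}

// Deterministic binned simulation of dF/F given a binary spike vector.
// [[Rcpp::export(name = ".cppSimBins")]]
arma::vec cppSimBins(const arma::ivec& spikes, List theta, List cell,
                     List ctx, const arma::vec& x0, double dt) {
  Theta th = thetaFromList(theta);
  CellPars cp = cellFromList(cell);
  SensorCtx sc = ctxFromList(ctx);
  double leak = leakOf(th, cp);
  int T = spikes.n_elem;
  arma::vec out(T);
  double s[13];
  s[0] = cp.caBasal; s[1] = cp.caBasal; s[2] = cp.storeCaBasal;
  for (int k = 0; k < 9; ++k) s[3 + k] = x0(k);
  s[12] = 1e9;  // long since any spike
  for (int t = 0; t < T; ++t) {
    advanceBio(s, spikes(t) > 0, th, cp, sc, dt, leak);
    out(t) = dffBio(s, th, sc);
  }
  return out;
}

// Conditional SMC sweep with ancestor sampling (biophysical model).
// Particle 0 follows the reference (spikes, baseline); returns one
// trajectory drawn from the particle genealogy.
// [[Rcpp::export(name = ".cppCSMC")]]
List cppCSMC(const arma::vec& y, List theta, List cell, List ctx,
             const arma::vec& x0, const arma::ivec& refSpikes,
             const arma::vec& refBase, int nParticles, double dt) {
  RNGScope scope;
  Theta th = thetaFromList(theta);
  CellPars cp = cellFromList(cell);
  SensorCtx sc = ctxFromList(ctx);
  double leak = leakOf(th, cp);
  const int T = y.n_elem, N = nParticles;
  double pSpike = std::min(th.rateHz * dt, 0.95);
  double driftSd = th.driftScale * std::sqrt(dt);

  arma::mat state(13, N), newState(13, N);
  for (int i = 0; i < N; ++i) {
    state(0, i) = cp.caBasal; state(1, i) = cp.caBasal;
    state(2, i) = cp.storeCaBasal;
    for (int k = 0; k < 9; ++k) state(3 + k, i) = x0(k);
    state(12, i) = 1e9;
  }
  arma::vec base(N, arma::fill::zeros), newBase(N);
  double b0Sd = std::max(th.driftScale * 0.5, 1e-4);
  arma::imat spMat(N, T);
  arma::imat ancMat(N, T);
  arma::mat baseMat(N, T);
  arma::vec logw(N, arma::fill::zeros), prevLogw(N, arma::fill::zeros);

  for (int t = 0; t < T; ++t) {
    // ancestor indices
    arma::ivec anc(N);
    if (t == 0) {
      for (int i = 0; i < N; ++i) anc(i) = i;
    } else {
      arma::vec w = arma::exp(prevLogw - prevLogw.max());
      double wsum = arma::accu(w);
      if (!std::isfinite(wsum) || wsum <= 0)
        stop("particle weight degeneracy at bin %d", t);
      w /= wsum;
      arma::vec cw = arma::cumsum(w);
      for (int i = 1; i < N; ++i) {
        double u = R::runif(0, 1);
        int k = 0;
        while (k < N - 1 && cw(k) < u) ++k;
        anc(i) = k;
      }
      // ancestor sampling for the reference particle: transition +
      // one-step-lookahead likelihood under the reference continuation
      arma::vec lasw(N);
      for (int i = 0; i < N; ++i) {
        double tmp[13];
        std::memcpy(tmp, state.colptr(i), sizeof(tmp));
        advanceBio(tmp, refSpikes(t) > 0, th, cp, sc, dt, leak);
        double ll = logdnorm(y(t) - refBase(t) - dffBio(tmp, th, sc),
                             th.sigma);
        double lb = logdnorm(refBase(t) - base(i), driftSd);
        double lsp = refSpikes(t) > 0 ? std::log(pSpike)
                                      : std::log1p(-pSpike);
        lasw(i) = prevLogw(i) + lb + lsp + ll;
      }
      arma::vec aw = arma::exp(lasw - lasw.max());
      aw /= arma::accu(aw);
      arma::vec caw = arma::cumsum(aw);
      double u0 = R::runif(0, 1);
      int k0 = 0;
      while (k0 < N - 1 && caw(k0) < u0) ++k0;
      anc(0) = k0;
    }
    // propagate
    for (int i = 0; i < N; ++i) {
      int a = anc(i);
      std::memcpy(newState.colptr(i), state.colptr(a), 13 * sizeof(double));
      bool spike;
      double b;
      if (i == 0) {
        spike = refSpikes(t) > 0;
        b = refBase(t);
      } else {
        spike = R::unif_rand() < pSpike;
        b = (t == 0 ? R::norm_rand() * b0Sd
                    : base(a) + R::norm_rand() * driftSd);
      }
      advanceBio(newState.colptr(i), spike, th, cp, sc, dt, leak);
      newBase(i) = b;
      spMat(i, t) = spike ? 1 : 0;
      ancMat(i, t) = a;
      baseMat(i, t) = b;
      logw(i) = logdnorm(y(t) - b - dffBio(newState.colptr(i), th, sc),
                         th.sigma);
    }
    state = newState;
    base = newBase;
    prevLogw = logw;
  }
  // draw one trajectory from the final weights and backtrack
  arma::vec w = arma::exp(prevLogw - prevLogw.max());
  w /= arma::accu(w);
  arma::vec cw = arma::cumsum(w);
  double u = R::runif(0, 1);
  int k = 0;
  while (k < N - 1 && cw(k) < u) ++k;
  arma::ivec outSp(T);
  arma::vec outBase(T);
  for (int t = T - 1; t >= 0; --t) {
    outSp(t) = spMat(k, t);
    outBase(t) = baseMat(k, t);
    k = ancMat(k, t);
  }
  return List::create(_["spikes"] = outSp, _["baseline"] = outBase);
}

// ---- Linear AR(2) generative model ------------------------------------
// c_t = a1 c_{t-1} + a2 c_{t-2} + A s_t ; prediction = c_t.

// [[Rcpp::export(name = ".cppSimBinsAr")]]
arma::vec cppSimBinsAr(const arma::ivec& spikes, double A, double a1,
                       double a2) {
  int T = spikes.n_elem;
  arma::vec out(T);
  double c1 = 0, c2 = 0;
  for (int t = 0; t < T; ++t) {
    double c = a1 * c1 + a2 * c2 + A * (spikes(t) > 0 ? 1.0 : 0.0);
    out(t) = c;
    c2 = c1; c1 = c;
  }
  return out;
}

// [[Rcpp::export(name = ".cppCSMCAr")]]
List cppCSMCAr(const arma::vec& y, double A, double a1, double a2,
               double rateHz, double driftScale, double sigma,
               const arma::ivec& refSpikes, const arma::vec& refBase,
               int nParticles, double dt) {
  RNGScope scope;
  const int T = y.n_elem, N = nParticles;
  double pSpike = std::min(rateHz * dt, 0.95);
  double driftSd = driftScale * std::sqrt(dt);
  double b0Sd = std::max(driftScale * 0.5, 1e-4);
  arma::mat c1(1, N, arma::fill::zeros), c2(1, N, arma::fill::zeros);
  arma::vec base(N, arma::fill::zeros);
  arma::vec logw(N, arma::fill::zeros), prevLogw(N, arma::fill::zeros);
  arma::imat spMat(N, T), ancMat(N, T);
  arma::mat baseMat(N, T), c1Mat(N, T), c2Mat(N, T);

  for (int t = 0; t < T; ++t) {
    arma::ivec anc(N);
    if (t == 0) {
      for (int i = 0; i < N; ++i) anc(i) = i;
    } else {
      arma::vec w = arma::exp(prevLogw - prevLogw.max());
      double wsum = arma::accu(w);
      if (!std::isfinite(wsum) || wsum <= 0)
        stop("particle weight degeneracy at bin %d", t);
      w /= wsum;
      arma::vec cw = arma::cumsum(w);
      for (int i = 1; i < N; ++i) {
        double u = R::runif(0, 1);
        int k = 0;
        while (k < N - 1 && cw(k) < u) ++k;
        anc(i) = k;
      }
      arma::vec lasw(N);
      for (int i = 0; i < N; ++i) {
        double c = a1 * c1(0, i) + a2 * c2(0, i) +
          A * (refSpikes(t) > 0 ? 1.0 : 0.0);
        double ll = logdnorm(y(t) - refBase(t) - c, sigma);
        double lb = logdnorm(refBase(t) - base(i), driftSd);
        double lsp = refSpikes(t) > 0 ? std::log(pSpike)
                                      : std::log1p(-pSpike);
        lasw(i) = prevLogw(i) + lb + lsp + ll;
      }
      arma::vec aw = arma::exp(lasw - lasw.max());
      aw /= arma::accu(aw);
      arma::vec caw = arma::cumsum(aw);
      double u0 = R::runif(0, 1);
      int k0 = 0;
      while (k0 < N - 1 && caw(k0) < u0) ++k0;
      anc(0) = k0;
    }
    arma::rowvec nc1(N), nc2(N);
    arma::vec nbase(N);
    for (int i = 0; i < N; ++i) {
      int a = anc(i);
      bool spike;
      double b;
      if (i == 0) {
        spike = refSpikes(t) > 0;
        b = refBase(t);
      } else {
        spike = R::unif_rand() < pSpike;
        b = (t == 0 ? R::norm_rand() * b0Sd
                    : base(a) + R::norm_rand() * driftSd);
      }
      double c = a1 * c1(0, a) + a2 * c2(0, a) + A * (spike ? 1.0 : 0.0);
      nc1(i) = c; nc2(i) = c1(0, a);
      nbase(i) = b;
      spMat(i, t) = spike ? 1 : 0;
      ancMat(i, t) = a;
      baseMat(i, t) = b;
      c1Mat(i, t) = c; c2Mat(i, t) = c1(0, a);
      logw(i) = logdnorm(y(t) - b - c, sigma);
    }
    c1.row(0) = nc1; c2.row(0) = nc2;
    base = nbase;
    prevLogw = logw;
  }
  arma::vec w = arma::exp(prevLogw - prevLogw.max());
  w /= arma::accu(w);
  arma::vec cw = arma::cumsum(w);
  double u = R::runif(0, 1);
  int k = 0;
  while (k < N - 1 && cw(k) < u) ++k;
  arma::ivec outSp(T);
  arma::vec outBase(T);
  for (int t = T - 1; t >= 0; --t) {
    outSp(t) = spMat(k, t);
    outBase(t) = baseMat(k, t);
    k = ancMat(k, t);
  }
  return List::create(_["spikes"] = outSp, _["baseline"] = outBase);
}
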