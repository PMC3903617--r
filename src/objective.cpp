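// Inner loops of the side-chain relaxation: nonbonded (Coulomb + 12-6
// Lennard-Jones) pair energies plus harmonic distance restraints with
// analytic Cartesian gradients, and the preconditioned L-BFGS descent
// (Armijo backtracking, monotone accepted-step trace). Mirrors the R
// reference implementation (min_objective_ref) exactly.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct PairData {
  std::vector<int> ni, nj, ri, rj, mov;
  std::vector<double> qq, epsij, rmin, rk, r0;
  double dielectric;
};

// energy + gradient over movable atoms; returns false on a zero-distance
// clash (energy set to +inf)
static bool obj_grad(const std::vector<double>& X, int n, const PairData& pd,
                     double& E, std::vector<double>& G) {
  // X is n x 3 column-major (x block, y block, z block)
  std::vector<double> gx(n, 0.0), gy(n, 0.0), gz(n, 0.0);
  E = 0.0;
  const int np = (int)pd.ni.size();
  for (int p = 0; p < np; ++p) {
    const int i = pd.ni[p] - 1, j = pd.nj[p] - 1;
    const double dx = X[i] - X[j];
    const double dy = X[n + i] - X[n + j];
    const double dz = X[2 * n + i] - X[2 * n + j];
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < 1e-12) { E = R_PosInf; return false; }
    const double r = std::sqrt(r2);
    const double s2 = (pd.rmin[p] * pd.rmin[p]) / r2;
    const double s6 = s2 * s2 * s2;
    E += pd.qq[p] / (pd.dielectric * r) + pd.epsij[p] * (s6 * s6 - 2.0 * s6);
    const double dEdr = -pd.qq[p] / (pd.dielectric * r2)
      - pd.epsij[p] * (12.0 / r) * (s6 * s6 - s6);
    const double f = dEdr / r;
    gx[i] += f * dx; gy[i] += f * dy; gz[i] += f * dz;
    gx[j] -= f * dx; gy[j] -= f * dy; gz[j] -= f * dz;
  }
  const int nr = (int)pd.ri.size();
  for (int p = 0; p < nr; ++p) {
    const int i = pd.ri[p] - 1, j = pd.rj[p] - 1;
    const double dx = X[i] - X[j];
    const double dy = X[n + i] - X[n + j];
    const double dz = X[2 * n + i] - X[2 * n + j];
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    const double dev = r - pd.r0[p];
    E += pd.rk[p] * dev * dev;
    const double f = (r < 1e-12) ? 0.0 : 2.0 * pd.rk[p] * dev / r;
    gx[i] += f * dx; gy[i] += f * dy; gz[i] += f * dz;
    gx[j] -= f * dx; gy[j] -= f * dy; gz[j] -= f * dz;
  }
  const int m = (int)pd.mov.size();
  for (int k = 0; k < m; ++k) {
    const int a = pd.mov[k] - 1;
    G[k] = gx[a]; G[m + k] = gy[a]; G[2 * m + k] = gz[a];
  }
  return true;
}

static PairData make_pairdata(IntegerVector ni, IntegerVector nj,
                              NumericVector qq, NumericVector epsij,
                              NumericVector rmin, IntegerVector ri,
                              IntegerVector rj, NumericVector rk,
                              NumericVector r0, IntegerVector movable,
                              double dielectric) {
  PairData pd;
  pd.ni.assign(ni.begin(), ni.end());
  pd.nj.assign(nj.begin(), nj.end());
  pd.qq.assign(qq.begin(), qq.end());
  pd.epsij.assign(epsij.begin(), epsij.end());
  pd.rmin.assign(rmin.begin(), rmin.end());
  pd.ri.assign(ri.begin(), ri.end());
  pd.rj.assign(rj.begin(), rj.end());
  pd.rk.assign(rk.begin(), rk.end());
  pd.r0.assign(r0.begin(), r0.end());
  pd.mov.assign(movable.begin(), movable.end());
  pd.dielectric = dielectric;
  return pd;
}

// [[Rcpp::export(name = ".obj_grad_cpp")]]
List obj_grad_cpp(NumericMatrix xyz,
                  IntegerVector ni, IntegerVector nj,
                  NumericVector qq, NumericVector epsij, NumericVector rmin,
                  IntegerVector ri, IntegerVector rj,
                  NumericVector rk, NumericVector r0,
                  IntegerVector movable, double dielectric) {
  const int n = xyz.nrow();
  PairData pd = make_pairdata(ni, nj, qq, epsij, rmin, ri, rj, rk, r0,
                              movable, dielectric);
  std::vector<double> X(xyz.begin(), xyz.end());
  const int m = (int)pd.mov.size();
  std::vector<double> G(3 * m, 0.0);
  double E;
  if (!obj_grad(X, n, pd, E, G))
    return List::create(_["E"] = R_PosInf, _["G"] = R_NilValue);
  NumericMatrix Gm(m, 3);
  std::copy(G.begin(), G.end(), Gm.begin());
  return List::create(_["E"] = E, _["G"] = Gm);
}

// [[Rcpp::export(name = ".lbfgs_cpp")]]
List lbfgs_cpp(NumericMatrix xyz,
               IntegerVector ni, IntegerVector nj,
               NumericVector qq, NumericVector epsij, NumericVector rmin,
               IntegerVector ri, IntegerVector rj,
               NumericVector rk, NumericVector r0,
               IntegerVector movable, NumericVector pdiag,
               double dielectric, double threshold, int max_steps) {
  const int n = xyz.nrow();
  PairData pd = make_pairdata(ni, nj, qq, epsij, rmin, ri, rj, rk, r0,
                              movable, dielectric);
  std::vector<double> X(xyz.begin(), xyz.end());
  const int m = (int)pd.mov.size();
  const int d = 3 * m;
  std::vector<double> g(d), gn(d), x(d), xn(d), p(d), q(d), rdir(d);
  // pack movable coordinates
  for (int k = 0; k < m; ++k) {
    const int a = pd.mov[k] - 1;
    x[k] = X[a]; x[m + k] = X[n + a]; x[2 * m + k] = X[2 * n + a];
  }
  auto unpack = [&](const std::vector<double>& xx) {
    for (int k = 0; k < m; ++k) {
      const int a = pd.mov[k] - 1;
      X[a] = xx[k]; X[n + a] = xx[m + k]; X[2 * n + a] = xx[2 * m + k];
    }
  };
  double f;
  unpack(x);
  if (!obj_grad(X, n, pd, f, g) || !std::isfinite(f)) {
    NumericMatrix out(n, 3);
    std::copy(X.begin(), X.end(), out.begin());
    return List::create(_["xyz"] = out, _["trace"] = NumericVector::create(f),
                        _["converged"] = false, _["n_steps"] = 0,
                        _["rms_grad"] = R_PosInf);
  }
  std::vector<double> trace;
  trace.push_back(f);
  const int mem = 10;
  std::vector<std::vector<double>> S, Y;
  std::vector<double> RHO;
  double gamma = 1.0;
  int n_steps = 0;
  auto rmsg = [&](const std::vector<double>& gg) {
    double s = 0; for (double v : gg) s += v * v;
    return std::sqrt(s / d);
  };
  double rms = rmsg(g);
  while (rms >= threshold && n_steps < max_steps) {
    // two-loop recursion with diagonal preconditioner
    q = g;
    const int kk = (int)S.size();
    std::vector<double> alpha(kk);
    for (int i = kk - 1; i >= 0; --i) {
      double sq = 0; for (int t = 0; t < d; ++t) sq += S[i][t] * q[t];
      alpha[i] = RHO[i] * sq;
      for (int t = 0; t < d; ++t) q[t] -= alpha[i] * Y[i][t];
    }
    for (int t = 0; t < d; ++t) rdir[t] = gamma * pdiag[t] * q[t];
    for (int i = 0; i < kk; ++i) {
      double yr = 0; for (int t = 0; t < d; ++t) yr += Y[i][t] * rdir[t];
      const double beta = RHO[i] * yr;
      for (int t = 0; t < d; ++t) rdir[t] += S[i][t] * (alpha[i] - beta);
    }
    for (int t = 0; t < d; ++t) p[t] = -rdir[t];
    double gp = 0; for (int t = 0; t < d; ++t) gp += g[t] * p[t];
    if (gp >= 0) {
      for (int t = 0; t < d; ++t) p[t] = -g[t];
      gp = 0; for (int t = 0; t < d; ++t) gp += g[t] * p[t];
    }
    // cap the first trial step so a clash start cannot explode
    double pmax = 0; for (int t = 0; t < d; ++t) pmax = std::max(pmax, std::fabs(p[t]));
    double tstep = std::min(1.0, 0.5 / std::max(pmax, 1e-12));
    bool ok = false;
    double fn = f;
    for (int ls = 0; ls < 40; ++ls) {
      for (int t = 0; t < d; ++t) xn[t] = x[t] + tstep * p[t];
      unpack(xn);
      if (obj_grad(X, n, pd, fn, gn) && std::isfinite(fn) &&
          fn <= f + 1e-4 * tstep * gp) { ok = true; break; }
      tstep *= 0.5;
    }
    if (!ok) break;
    double sy = 0, yy = 0;
    std::vector<double> s(d), y(d);
    for (int t = 0; t < d; ++t) {
      s[t] = xn[t] - x[t];
      y[t] = gn[t] - g[t];
      sy += s[t] * y[t];
      yy += y[t] * pdiag[t] * y[t];
    }
    if (sy > 1e-12) {
      S.push_back(s); Y.push_back(y); RHO.push_back(1.0 / sy);
      if ((int)S.size() > mem) {
        S.erase(S.begin()); Y.erase(Y.begin()); RHO.erase(RHO.begin());
      }
      gamma = sy / yy;
    }
    x = xn; f = fn; g = gn;
    trace.push_back(f);
    rms = rmsg(g);
    ++n_steps;
  }
  unpack(x);
  NumericMatrix out(n, 3);
  std::copy(X.begin(), X.end(), out.begin());
  return List::create(_["xyz"] = out,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["converged"] = rms < threshold,
                      _["n_steps"] = n_steps,
                      _["rms_grad"] = rms);
}
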