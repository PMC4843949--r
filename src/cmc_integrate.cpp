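#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Fixed-step RK4 integration of the delayed canonical-microcircuit network.
//
// Each source has four populations (ss, sp, ii, dp), each with a voltage v
// and current i obeying second-order synaptic dynamics
//   v' = i,  i' = (u - 2 i - v / T_p) / T_p
// where u is the gain-weighted presynaptic firing afferent to the
// population.  Delayed firing enters through linear interpolation of a
// firing-rate history buffer; all couplings are delayed (>= 1 ms), so
// within one RK4 step the afferent drive is an exogenous function of time
// and the stage equations stay explicit.  Extrinsic couplings are
// converted to sparse edge lists once at entry.
//
// G      : ns x 10 intrinsic strengths (sp_sp already gain-scaled)
// Tms    : 4 time constants (ms), order ss, sp, ii, dp
// Hpop   : 4 synaptic gain multipliers per population
// R      : sigmoid slope
// WFss, WFdp : ns x ns extrinsic weights (target row, source col) from
//              presynaptic sp, entering ss / dp (forward + lateral)
// WBsp, WBii : ns x ns weights from presynaptic dp entering sp (applied
//              with negative sign) and ii (positive)
// Uamp   : ns input gains
// ut     : exogenous input on the half-step grid, length 2*nsteps + 1
// dint, dext : delays in units of dt; dt in ms
//
// Returns vsp, vdp: ns x (nsteps+1) voltage matrices.

struct Edge {
  int t, s;
  double w1, w2;
};

static inline double sigm(double v, double R) {
  return 1.0 / (1.0 + std::exp(-R * v)) - 0.5;
}

// [[Rcpp::export]]
List cmc_integrate_cpp(NumericMatrix G, NumericVector Tms, NumericVector Hpop,
                       double R, NumericMatrix WFss, NumericMatrix WFdp,
                       NumericMatrix WBsp, NumericMatrix WBii,
                       NumericVector Uamp, NumericVector ut,
                       double dint, double dext, double dt, int nsteps) {
  const int ns = G.nrow();
  const int np = ns * 4;
  const int nt = nsteps + 1;

  std::vector<Edge> fwd, bwd;
  for (int t = 0; t < ns; ++t) {
    for (int s = 0; s < ns; ++s) {
      if (WFss(t, s) != 0.0 || WFdp(t, s) != 0.0) {
        fwd.push_back({t, s, WFss(t, s), WFdp(t, s)});
      }
      if (WBsp(t, s) != 0.0 || WBii(t, s) != 0.0) {
        bwd.push_back({t, s, WBsp(t, s), WBii(t, s)});
      }
    }
  }
  std::vector<double> Gc(ns * 10), Ua(ns), Tv(4), Hv(4);
  for (int s = 0; s < ns; ++s) {
    for (int j = 0; j < 10; ++j) Gc[s * 10 + j] = G(s, j);
    Ua[s] = Uamp[s];
  }
  for (int p = 0; p < 4; ++p) {
    Tv[p] = Tms[p];
    Hv[p] = Hpop[p];
  }

  std::vector<double> v(np, 0.0), cur(np, 0.0);
  std::vector<double> Sh((size_t)nt * np, 0.0);     // firing history
  NumericMatrix vsp(ns, nt), vdp(ns, nt);

  const double *sh = Sh.data();
  auto hist = [sh, np](double tidx, int s, int p) -> double {
    if (tidx <= 0.0) return 0.0;
    int i0 = (int)tidx;
    double f = tidx - i0;
    double a = sh[(size_t)i0 * np + s * 4 + p];
    if (f == 0.0) return a;
    double b = sh[(size_t)(i0 + 1) * np + s * 4 + p];
    return a + f * (b - a);
  };

  std::vector<double> u1(np), u2(np), u3(np);
  auto afferents = [&](double tidx, double uin, std::vector<double> &aff) {
    double ti = tidx - dint;
    double te = tidx - dext;
    for (int s = 0; s < ns; ++s) {
      const double *g = &Gc[s * 10];
      double Sss = hist(ti, s, 0);
      double Ssp = hist(ti, s, 1);
      double Sii = hist(ti, s, 2);
      double Sdp = hist(ti, s, 3);
      aff[s * 4 + 0] = -g[0] * Sss - g[1] * Ssp - g[2] * Sii + Ua[s] * uin;
      aff[s * 4 + 1] = g[7] * Sss - g[6] * Ssp;
      aff[s * 4 + 2] = g[4] * Sss + g[5] * Sdp - g[3] * Sii;
      aff[s * 4 + 3] = -g[8] * Sii - g[9] * Sdp;
    }
    for (const Edge &e : fwd) {
      double Se = hist(te, e.s, 1);
      aff[e.t * 4 + 0] += e.w1 * Se;
      aff[e.t * 4 + 3] += e.w2 * Se;
    }
    for (const Edge &e : bwd) {
      double Se = hist(te, e.s, 3);
      aff[e.t * 4 + 1] -= e.w1 * Se;
      aff[e.t * 4 + 2] += e.w2 * Se;
    }
    for (int s = 0; s < ns; ++s) {
      for (int p = 0; p < 4; ++p) aff[s * 4 + p] *= Hv[p];
    }
  };

  for (int k = 0; k < nsteps; ++k) {
    afferents((double)k, ut[2 * k], u1);
    afferents(k + 0.5, ut[2 * k + 1], u2);
    afferents((double)(k + 1), ut[2 * k + 2], u3);

    bool bad = false;
    for (int s = 0; s < ns; ++s) {
      for (int p = 0; p < 4; ++p) {
        const double T = Tv[p];
        const int ix = s * 4 + p;
        double vv = v[ix], ii = cur[ix];
        double k1v = ii;
        double k1i = (u1[ix] - 2.0 * ii - vv / T) / T;
        double v2 = vv + 0.5 * dt * k1v, i2 = ii + 0.5 * dt * k1i;
        double k2v = i2;
        double k2i = (u2[ix] - 2.0 * i2 - v2 / T) / T;
        double v3 = vv + 0.5 * dt * k2v, i3 = ii + 0.5 * dt * k2i;
        double k3v = i3;
        double k3i = (u2[ix] - 2.0 * i3 - v3 / T) / T;
        double v4 = vv + dt * k3v, i4 = ii + dt * k3i;
        double k4v = i4;
        double k4i = (u3[ix] - 2.0 * i4 - v4 / T) / T;
        v[ix] = vv + dt / 6.0 * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
        cur[ix] = ii + dt / 6.0 * (k1i + 2.0 * k2i + 2.0 * k3i + k4i);
        if (!std::isfinite(v[ix]) || std::fabs(v[ix]) > 1e3) bad = true;
      }
    }
    if (bad) {
      stop("numerical blow-up during integration (|v| > 1e3 mV at "
           "t = %f ms); consider rescaling parameters",
           (k + 1) * dt);
    }
    double *shk = &Sh[(size_t)(k + 1) * np];
    for (int ix = 0; ix < np; ++ix) shk[ix] = sigm(v[ix], R);
    for (int s = 0; s < ns; ++s) {
      vsp(s, k + 1) = v[s * 4 + 1];
      vdp(s, k + 1) = v[s * 4 + 3];
    }
  }
  return List::create(_["vsp"] = vsp, _["vdp"] = vdp);
}
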