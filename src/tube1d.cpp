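// 1D cross-section-averaged compliant-tube network solver.
//
// Per segment: conservative MacCormack (predictor/corrector) update of
// (A, Q) with the affine tube law P = pref + k(x) (A - A0(x)), the
// momentum friction source 8 pi mu Q / (rho A), and the pressure
// gradient treated as a forward/backward-biased source consistent with
// the flux bias.  Boundary/junction closure by Riemann invariants
// W+- = u +- 2 c,  c = sqrt(k A / rho).
//
// Nodes are either prescribed-pressure (time series, linearly
// interpolated within the outer step) or junctions (static-pressure
// continuity + mass conservation, solved per substep by safeguarded
// Newton).  The outer step is sub-cycled under a CFL guard.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Seg {
  int n;                // cells
  double dx, pref;
  std::vector<double> A, Q, A0, k;
  int node0, node1;     // node index at x = 0 / x = l
  // ghost states (recomputed each substep)
  double Agl, Qgl, Agr, Qgr;
  double reff_acc = 0.0;
};

struct Inc { int seg; int end; };  // end: 0 = x=0 side, 1 = x=l side

struct Node {
  int type;             // 0 = pressure, 1 = junction
  int pcol;             // column in pbc (type 0)
  std::vector<Inc> inc;
};

static inline double wavec(double k, double A, double rho) {
  return std::sqrt(k * A / rho);
}

// area from pressure through the affine tube law at a segment end cell
static inline double area_from_p(const Seg& s, int cell, double P) {
  return s.A0[cell] + (P - s.pref) / s.k[cell];
}

// Outgoing invariant at a segment end (from the adjacent interior cell).
// end 0: W- = u - 2c propagates out; end 1: W+ = u + 2c.
static inline double out_invariant(const Seg& s, int end, double rho) {
  int c = (end == 0) ? 0 : s.n - 1;
  double u = s.Q[c] / s.A[c];
  double cc = wavec(s.k[c], s.A[c], rho);
  return (end == 0) ? u - 2.0 * cc : u + 2.0 * cc;
}

// boundary velocity given boundary area and the outgoing invariant
static inline double bnd_u(const Seg& s, int end, double Ab, double W,
                           double rho) {
  int c = (end == 0) ? 0 : s.n - 1;
  double cb = wavec(s.k[c], Ab, rho);
  return (end == 0) ? W + 2.0 * cb : W - 2.0 * cb;
}

// signed flux into the node from one incidence, and its dP derivative
static inline void junc_flux(const Seg& s, int end, double P, double W,
                             double rho, double& g, double& dg) {
  int c = (end == 0) ? 0 : s.n - 1;
  double Ab = area_from_p(s, c, P);
  if (Ab <= 0) { g = NA_REAL; dg = NA_REAL; return; }
  double cb = wavec(s.k[c], Ab, rho);
  double u = (end == 0) ? W + 2.0 * cb : W - 2.0 * cb;
  double sgn = (end == 1) ? 1.0 : -1.0;     // end 1 flows into the node
  g = sgn * Ab * u;
  double dA = 1.0 / s.k[c];
  double du = ((end == 0) ? 1.0 : -1.0) / (cb * rho);
  dg = sgn * (dA * u + Ab * du);
}

static double solve_junction(const std::vector<Seg>& segs,
                             const Node& nd, double rho) {
  // initial guess: mean of incident end pressures
  double P = 0.0;
  std::vector<double> W(nd.inc.size());
  for (size_t m = 0; m < nd.inc.size(); ++m) {
    const Seg& s = segs[nd.inc[m].seg];
    int c = (nd.inc[m].end == 0) ? 0 : s.n - 1;
    P += s.pref + s.k[c] * (s.A[c] - s.A0[c]);
    W[m] = out_invariant(s, nd.inc[m].end, rho);
  }
  P /= nd.inc.size();
  double scale = 0.0;
  for (size_t m = 0; m < nd.inc.size(); ++m) {
    const Seg& s = segs[nd.inc[m].seg];
    int c = (nd.inc[m].end == 0) ? 0 : s.n - 1;
    scale += s.A[c] * wavec(s.k[c], s.A[c], rho);
  }
  double tol = 1e-12 * scale;
  for (int it = 0; it < 60; ++it) {
    double g = 0.0, dg = 0.0;
    for (size_t m = 0; m < nd.inc.size(); ++m) {
      double gm, dgm;
      junc_flux(segs[nd.inc[m].seg], nd.inc[m].end, P, W[m], rho, gm, dgm);
      if (!std::isfinite(gm)) stop("junction solve: nonpositive area");
      g += gm; dg += dgm;
    }
    if (std::fabs(g) < tol) return P;
    if (dg == 0.0) break;
    double step = g / dg;
    if (std::fabs(step) > 5000.0) step = (step > 0 ? 5000.0 : -5000.0);
    P -= step;
  }
  // bisection fallback
  double lo = P - 3e4, hi = P + 3e4;
  auto G = [&](double p) {
    double g = 0.0, dgm, gm;
    for (size_t m = 0; m < nd.inc.size(); ++m) {
      junc_flux(segs[nd.inc[m].seg], nd.inc[m].end, p, W[m], rho, gm, dgm);
      g += gm;
    }
    return g;
  };
  double glo = G(lo), ghi = G(hi);
  if (glo * ghi > 0) stop("junction Newton solve non-convergent");
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (lo + hi), gm = G(mid);
    if (std::fabs(gm) < tol || hi - lo < 1e-10) return mid;
    if (glo * gm <= 0) { hi = mid; ghi = gm; } else { lo = mid; glo = gm; }
  }
  return 0.5 * (lo + hi);
}

// [[Rcpp::export]]
List tube1d_run_cpp(List segments, List nodes, NumericMatrix pbc,
                    double dt_outer, double mu, double rho,
                    double cfl = 0.9, int max_substeps = 20000,
                    int record = 1) {
  int S = segments.size();
  std::vector<Seg> segs(S);
  for (int s = 0; s < S; ++s) {
    List L = segments[s];
    Seg& sg = segs[s];
    sg.A = as<std::vector<double>>(L["A"]);
    sg.Q = as<std::vector<double>>(L["Q"]);
    sg.A0 = as<std::vector<double>>(L["A0"]);
    sg.k = as<std::vector<double>>(L["k"]);
    sg.n = sg.A.size();
    sg.dx = as<double>(L["dx"]);
    sg.pref = as<double>(L["pref"]);
    sg.node0 = as<int>(L["node0"]);
    sg.node1 = as<int>(L["node1"]);
    if (sg.n < 3) stop("segment with fewer than 3 cells");
  }
  int NN = nodes.size();
  std::vector<Node> nds(NN);
  for (int j = 0; j < NN; ++j) {
    List L = nodes[j];
    nds[j].type = as<int>(L["type"]);
    nds[j].pcol = as<int>(L["pcol"]);
    IntegerMatrix inc = L["inc"];
    for (int r = 0; r < inc.nrow(); ++r)
      nds[j].inc.push_back({inc(r, 0), inc(r, 1)});
  }
  int n_steps = pbc.nrow() - 1;
  int n_rec = (record > 0) ? n_steps : 0;
  NumericMatrix Qmid(n_rec, S), Amid(n_rec, S), Qleft(n_rec, S),
    Qright(n_rec, S);
  NumericVector reff(S);
  double fr = 8.0 * M_PI * mu / rho;
  long total_sub = 0;

  std::vector<double> As, Qs, Ps, F2s;  // predictor scratch

  for (int step = 0; step < n_steps; ++step) {
    // CFL: choose substep count from current wave speeds
    double rate = 0.0;
    for (int s = 0; s < S; ++s) {
      Seg& sg = segs[s];
      double m = 0.0;
      for (int i = 0; i < sg.n; ++i) {
        if (sg.A[i] <= 0) stop("nonpositive area in segment %d", s + 1);
        double lam = std::fabs(sg.Q[i] / sg.A[i]) +
          wavec(sg.k[i], sg.A[i], rho);
        if (lam > m) m = lam;
      }
      double r = m / (cfl * sg.dx);
      if (r > rate) rate = r;
    }
    int nsub = (int)std::ceil(dt_outer * rate);
    if (nsub < 1) nsub = 1;
    if (nsub > max_substeps)
      stop("CFL violation: would need %d substeps per outer step; "
           "reduce dt or stiffen walls", nsub);
    double dt = dt_outer / nsub;
    total_sub += nsub;

    for (int sub = 0; sub < nsub; ++sub) {
      double frac = (sub + 0.5) / nsub;   // midpoint-in-time BC sampling
      // ghosts from boundary/junction closure
      for (int j = 0; j < NN; ++j) {
        Node& nd = nds[j];
        double P;
        if (nd.type == 0) {
          P = (1.0 - frac) * pbc(step, nd.pcol) + frac * pbc(step + 1, nd.pcol);
        } else {
          P = solve_junction(segs, nd, rho);
        }
        for (size_t m = 0; m < nd.inc.size(); ++m) {
          Seg& sg = segs[nd.inc[m].seg];
          int end = nd.inc[m].end;
          int c = (end == 0) ? 0 : sg.n - 1;
          double Ab = area_from_p(sg, c, P);
          if (Ab <= 0)
            stop("nonpositive boundary area (node pressure %g Pa)", P);
          double W = out_invariant(sg, end, rho);
          double u = bnd_u(sg, end, Ab, W, rho);
          // linear extrapolation through the boundary face so the
          // condition acts at x = 0 / l, not at the ghost centre
          double Ag = 2.0 * Ab - sg.A[c];
          double Qg = 2.0 * Ab * u - sg.Q[c];
          if (Ag <= 0) Ag = Ab;
          if (end == 0) { sg.Agl = Ag; sg.Qgl = Qg; }
          else { sg.Agr = Ag; sg.Qgr = Qg; }
        }
      }
      // MacCormack per segment with ghost cells
      for (int s = 0; s < S; ++s) {
        Seg& sg = segs[s];
        int n = sg.n;
        double lam = dt / sg.dx;
        As.assign(n + 2, 0.0); Qs.assign(n + 2, 0.0);
        Ps.assign(n + 2, 0.0); F2s.assign(n + 2, 0.0);
        // extended arrays with ghosts at [0] and [n+1]
        std::vector<double> Ae(n + 2), Qe(n + 2), Pe(n + 2), F2e(n + 2);
        Ae[0] = sg.Agl; Qe[0] = sg.Qgl;
        Ae[n + 1] = sg.Agr; Qe[n + 1] = sg.Qgr;
        for (int i = 0; i < n; ++i) { Ae[i + 1] = sg.A[i]; Qe[i + 1] = sg.Q[i]; }
        Pe[0] = sg.pref + sg.k[0] * (Ae[0] - sg.A0[0]);
        Pe[n + 1] = sg.pref + sg.k[n - 1] * (Ae[n + 1] - sg.A0[n - 1]);
        for (int i = 0; i < n; ++i)
          Pe[i + 1] = sg.pref + sg.k[i] * (Ae[i + 1] - sg.A0[i]);
        for (int i = 0; i < n + 2; ++i) F2e[i] = Qe[i] * Qe[i] / Ae[i];
        // predictor (forward differences); ghosts held fixed
        for (int i = 0; i < n + 2; ++i) { As[i] = Ae[i]; Qs[i] = Qe[i]; }
        for (int i = 1; i <= n; ++i) {
          As[i] = Ae[i] - lam * (Qe[i + 1] - Qe[i]);
          Qs[i] = Qe[i] - lam * (F2e[i + 1] - F2e[i])
            - lam * (Ae[i] / rho) * (Pe[i + 1] - Pe[i])
            - dt * fr * Qe[i] / Ae[i];
          if (As[i] <= 0) stop("nonpositive area (predictor), segment %d", s + 1);
        }
        int a0i;
        for (int i = 0; i < n + 2; ++i) {
          a0i = std::min(std::max(i - 1, 0), n - 1);
          Ps[i] = sg.pref + sg.k[a0i] * (As[i] - sg.A0[a0i]);
          F2s[i] = Qs[i] * Qs[i] / As[i];
        }
        // corrector (backward differences)
        for (int i = 1; i <= n; ++i) {
          double Anew = 0.5 * (Ae[i] + As[i] - lam * (Qs[i] - Qs[i - 1]));
          double Qnew = 0.5 * (Qe[i] + Qs[i]
                               - lam * (F2s[i] - F2s[i - 1])
                               - lam * (As[i] / rho) * (Ps[i] - Ps[i - 1])
                               - dt * fr * Qs[i] / As[i]);
          sg.A[i - 1] = Anew;
          sg.Q[i - 1] = Qnew;
          if (Anew <= 0) stop("nonpositive area (corrector), segment %d", s + 1);
        }
      }
    }
    if (record > 0) {
      for (int s = 0; s < S; ++s) {
        Seg& sg = segs[s];
        int mid = sg.n / 2;
        Qmid(step, s) = sg.Q[mid];
        Amid(step, s) = sg.A[mid];
        Qleft(step, s) = sg.Qgl;
        Qright(step, s) = sg.Qgr;
        double acc = 0.0;
        for (int i = 0; i < sg.n; ++i)
          acc += 8.0 * M_PI * mu / (sg.A[i] * sg.A[i]) * sg.dx;
        sg.reff_acc += acc;
      }
    }
  }
  List Aout(S), Qout(S);
  for (int s = 0; s < S; ++s) {
    Aout[s] = wrap(segs[s].A);
    Qout[s] = wrap(segs[s].Q);
    reff[s] = (n_rec > 0) ? segs[s].reff_acc / n_rec : NA_REAL;
  }
  return List::create(_["Qmid"] = Qmid, _["Amid"] = Amid,
                      _["Qleft"] = Qleft, _["Qright"] = Qright,
                      _["reff"] = reff, _["A"] = Aout, _["Q"] = Qout,
                      _["n_substeps"] = (double)total_sub);
}
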