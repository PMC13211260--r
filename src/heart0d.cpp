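// RK4 time stepper for the closed-loop lumped heart.  Mirrors the R
// reference step (step_heart) exactly: same RHS, same lagged
// viscoelastic term, same post-step aortic-valve clamp.  Elastance
// waveforms are passed as half-step-sampled tables (2*nt+1 entries per
// cycle) so any R-level waveform remains usable.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct HP {
  double ea[4], eb[4], v0[4];   // ra, rv, la, lv
  double sv, rav, bav, lav, rtv, rmv, rpv;
  double cao, cpa, cvn, rpul, rvc;
};

// y: Vra Vrv Vla Vlv Qav Vao Vpa Vvn
static void rhs(const double* y, const HP& p, double ev, double ea,
                double la, double lb, const double* dvp, double* dy,
                double* pao_out, double* plv_out) {
  double P[4];
  for (int c = 0; c < 4; ++c) {
    double e = (c == 1 || c == 3) ? ev : ea;   // ventricles vs atria
    P[c] = (p.ea[c] * e + p.eb[c]) * (y[c] - p.v0[c]) + p.sv * dvp[c];
  }
  double pao = y[5] / p.cao, ppa = y[6] / p.cpa, pvn = y[7] / p.cvn;
  double qtv = (P[0] > P[1]) ? (P[0] - P[1]) / p.rtv : 0.0;
  double qpv = (P[1] > ppa) ? (P[1] - ppa) / p.rpv : 0.0;
  double qmv = (P[2] > P[3]) ? (P[2] - P[3]) / p.rmv : 0.0;
  double qpul = (ppa - P[2]) / p.rpul;
  double qvc = (pvn - P[0]) / p.rvc;
  double qload = la + lb * pao;
  double qav = y[4];
  double dqav = 0.0;
  if (P[3] > pao)
    dqav = (P[3] - pao - p.rav * qav - p.bav * qav * std::fabs(qav)) / p.lav;
  dy[0] = qvc - qtv;
  dy[1] = qtv - qpv;
  dy[2] = qpul - qmv;
  dy[3] = qmv - qav;
  dy[4] = dqav;
  dy[5] = qav - qload;
  dy[6] = qpv - qpul;
  dy[7] = qload - qvc;
  *pao_out = pao;
  *plv_out = P[3];
}

// [[Rcpp::export]]
List heart_run_cpp(NumericVector y0, NumericVector dv0, List params,
                   NumericVector ev_tab, NumericVector ea_tab,
                   double dt, int nt, int n_cycles,
                   double load_a, double load_b) {
  HP p;
  NumericVector ea = params["ea"], eb = params["eb"], v0 = params["v0"];
  for (int c = 0; c < 4; ++c) { p.ea[c] = ea[c]; p.eb[c] = eb[c]; p.v0[c] = v0[c]; }
  p.sv = params["sv"]; p.rav = params["rav"]; p.bav = params["bav"];
  p.lav = params["lav"]; p.rtv = params["rtv"]; p.rmv = params["rmv"];
  p.rpv = params["rpv"]; p.cao = params["cao"]; p.cpa = params["cpa"];
  p.cvn = params["cvn"]; p.rpul = params["rpul"]; p.rvc = params["rvc"];

  double y[8], dvp[4], k1[8], k2[8], k3[8], k4[8], yt[8];
  for (int i = 0; i < 8; ++i) y[i] = y0[i];
  for (int i = 0; i < 4; ++i) dvp[i] = dv0[i];

  NumericVector pao(nt), qav(nt), plv(nt);
  NumericMatrix pao_cycles(nt, n_cycles);
  double po, pl;
  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    for (int i = 0; i < nt; ++i) {
      double yold[4] = {y[0], y[1], y[2], y[3]};
      int i2 = 2 * i;
      rhs(y, p, ev_tab[i2], ea_tab[i2], load_a, load_b, dvp, k1, &po, &pl);
      for (int j = 0; j < 8; ++j) yt[j] = y[j] + 0.5 * dt * k1[j];
      rhs(yt, p, ev_tab[i2 + 1], ea_tab[i2 + 1], load_a, load_b, dvp, k2,
          &po, &pl);
      for (int j = 0; j < 8; ++j) yt[j] = y[j] + 0.5 * dt * k2[j];
      rhs(yt, p, ev_tab[i2 + 1], ea_tab[i2 + 1], load_a, load_b, dvp, k3,
          &po, &pl);
      for (int j = 0; j < 8; ++j) yt[j] = y[j] + dt * k3[j];
      rhs(yt, p, ev_tab[i2 + 2], ea_tab[i2 + 2], load_a, load_b, dvp, k4,
          &po, &pl);
      for (int j = 0; j < 8; ++j)
        y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      // algebra at the new state (lagged dv), then valve clamp
      double dy[8];
      rhs(y, p, ev_tab[i2 + 2], ea_tab[i2 + 2], load_a, load_b, dvp, dy,
          &po, &pl);
      if (pl <= po || y[4] < 0) y[4] = 0.0;
      for (int j = 0; j < 4; ++j) dvp[j] = (y[j] - yold[j]) / dt;
      for (int j = 0; j < 8; ++j)
        if (j != 4 && y[j] < 0)
          stop("integration instability: negative volume; reduce dt");
      pao[i] = po; qav[i] = y[4]; plv[i] = pl;
      pao_cycles(i, cyc) = po;
    }
  }
  NumericVector yout(8), dvout(4);
  for (int i = 0; i < 8; ++i) yout[i] = y[i];
  for (int i = 0; i < 4; ++i) dvout[i] = dvp[i];
  return List::create(_["state"] = yout, _["dv"] = dvout, _["pao"] = pao,
                      _["qav"] = qav, _["plv"] = plv,
                      _["pao_cycles"] = pao_cycles);
}
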