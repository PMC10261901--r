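// 29-state clock + photosynthetic-gene ODE right-hand side and the
// fixed-step classical RK4 integrator with piecewise light forcing.
//
// State order (0-based) — must stay in lock-step with clock_states() in R:
//  0 MCL   1 CL    2 MP97  3 P97   4 MP51  5 P51
//  6 MEL   7 EL    8 MGI   9 GI   10 MRVE8 11 RVE8
// 12 EC   13 RL   14 ZG   15 ZTL  16 COP1c 17 COP1n 18 COP1d 19 HY5
// 20 P
// 21 MLhcb1 22 Lhcb1 23 MpsbA 24 psbA 25 MRbcS1 26 RbcS1 27 MatpA 28 atpA
//
// Parameter order (0-based) — must stay in lock-step with param_registry():
// see the PIDX enum below.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

enum PIDX {
  v1 = 0, q1, K1, K2, K3, a1, K4, m1, m1d, p1, d1,
  v2, q2, K5, K6, m2, p2, d2,
  v3, K7, K15, c3, K8, m3, p3, d3, d3z,
  v4, q4, K9, c4, K10, m4, m4l, p4, d4,
  v5, K11, K12, K13, m5, m5l, p5, d5,
  v6, q6, K14, m6, p6, d6, d6d,
  c_ec, K_ec, d_ec, g_ec,
  c_rl, d_rl,
  g_zg, q_zg, r_zg, d_zg,
  v_zt, d_zt,
  v_cc, d_cc, k_cn,
  k_nd, k_dn, d_cn, d_cd,
  v_hy, d_hy, g_hy,
  s_p, d_p,
  v7, K17, K18, k7, p7, d7,
  v8, K19, k8, p8, d8,
  v9, K20, k9, p9, d9,
  v10, K21, k10, p10, d10,
  I_A, I_B, I_C,
  hill,
  NPAR
};

static const int NSTATE = 29;

static inline double hact(double x, double K, double h) {
  // Hill activation x^h / (K^h + x^h); x, K >= 0
  double xn = std::pow(x, h), Kn = std::pow(K, h);
  return xn / (Kn + xn);
}
static inline double hrep(double x, double K, double h) {
  double xn = std::pow(x, h), Kn = std::pow(K, h);
  return Kn / (Kn + xn);
}

// variant: 0 = extended Lhcb1 model (CL activation x GI inhibition),
//          1 = control (CL activation only)
static void model_rhs(const double* y, const double* p,
                      double L, double D, double f, int variant,
                      double* dy) {
  const double h = p[hill];
  const double MCL = y[0],  CL  = y[1],  MP97 = y[2],  P97 = y[3];
  const double MP51 = y[4], P51 = y[5],  MEL = y[6],   EL  = y[7];
  const double MGI = y[8],  GI  = y[9],  MRVE8 = y[10], RVE8 = y[11];
  const double EC = y[12],  RL  = y[13], ZG = y[14],   ZTL = y[15];
  const double C1c = y[16], C1n = y[17], C1d = y[18],  HY5 = y[19];
  const double P = y[20];
  const double ML = y[21],  Lh = y[22],  MpA = y[23],  pA = y[24];
  const double MRb = y[25], Rb = y[26],  MaA = y[27],  aA = y[28];

  const double lightP = f * L * P;   // acute dawn activation input
  const double fl = f * L;           // intensity-scaled light gate

  // --- core oscillator mRNAs ---
  dy[0] = p[v1] * hrep(CL, p[K1], h) * hrep(P97, p[K2], h) *
            hrep(P51, p[K3], h) * (1.0 + p[a1] * hact(HY5, p[K4], h)) +
          p[q1] * lightP - (p[m1] + p[m1d] * D) * MCL;
  dy[1] = p[p1] * MCL - p[d1] * CL;

  dy[2] = p[v2] * hrep(CL, p[K5], h) * hrep(EC, p[K6], h) +
          p[q2] * lightP - p[m2] * MP97;
  dy[3] = p[p2] * MP97 - p[d2] * P97;

  dy[4] = p[v3] * hrep(CL, p[K7], h) * hrep(EC, p[K15], h) *
            (p[c3] + (1.0 - p[c3]) * hact(RL, p[K8], h)) -
          p[m3] * MP51;
  dy[5] = p[p3] * MP51 - (p[d3] + p[d3z] * D * ZG) * P51;

  dy[6] = p[v4] * hrep(CL, p[K9], h) *
            (p[c4] + (1.0 - p[c4]) * hact(RL, p[K10], h)) +
          p[q4] * lightP - (p[m4] + p[m4l] * fl) * MEL;
  dy[7] = p[p4] * MEL - p[d4] * EL;

  dy[8] = p[v5] * hrep(CL, p[K11], h) * hrep(P97, p[K12], h) *
            hrep(P51, p[K13], h) - (p[m5] + p[m5l] * fl) * MGI;
  const double zg_form = p[g_zg] * ZTL * GI * (1.0 + p[q_zg] * fl);
  dy[9] = p[p5] * MGI - p[d5] * GI - zg_form + p[r_zg] * ZG;

  dy[10] = p[v6] * hrep(P51, p[K14], h) + p[q6] * lightP - p[m6] * MRVE8;
  dy[11] = p[p6] * MRVE8 - (p[d6] + p[d6d] * D) * RVE8;

  // --- complexes / active proteins ---
  dy[12] = p[c_ec] * hact(EL, p[K_ec], h) - p[d_ec] * EC - p[g_ec] * C1n * EC;
  dy[13] = p[c_rl] * RVE8 - p[d_rl] * RL;
  dy[14] = zg_form - (p[r_zg] + p[d_zg]) * ZG;
  dy[15] = p[v_zt] - p[d_zt] * ZTL - zg_form + p[r_zg] * ZG;
  dy[16] = p[v_cc] - (p[d_cc] + p[k_cn]) * C1c;
  dy[17] = p[k_cn] * C1c - p[k_nd] * fl * C1n + p[k_dn] * D * C1d -
           p[d_cn] * C1n;
  dy[18] = p[k_nd] * fl * C1n - p[k_dn] * D * C1d - p[d_cd] * C1d;
  dy[19] = p[v_hy] - p[d_hy] * HY5 - p[g_hy] * C1n * D * HY5;

  // --- light-sensitive protein: accumulates in dark, degraded in light ---
  dy[20] = p[s_p] * D * (1.0 - P) - p[d_p] * fl * P;

  // --- photosynthetic genes ---
  double lhcb_act = hact(CL, p[K17], h);
  if (variant == 0) lhcb_act *= hrep(GI, p[K18], h);
  dy[21] = p[v7] * lhcb_act - p[k7] * ML;
  dy[22] = p[p7] * ML - p[d7] * Lh;

  dy[23] = p[v8] * hrep(CL, p[K19], h) - p[k8] * MpA;
  dy[24] = p[p8] * MpA - p[d8] * pA;

  dy[25] = p[v9] * hrep(CL, p[K20], h) - p[k9] * MRb;
  dy[26] = p[p9] * MRb - p[d9] * Rb;

  dy[27] = p[v10] * hrep(CL, p[K21], h) - p[k10] * MaA;
  dy[28] = p[p10] * MaA - p[d10] * aA;
}

// [[Rcpp::export(name = ".clock_rhs_cpp")]]
NumericVector clock_rhs_cpp(NumericVector y, NumericVector params,
                            double L, double D, double f,
                            int variant = 0) {
  if (y.size() != NSTATE) stop("state vector must have length 29");
  if (params.size() != NPAR) stop("parameter vector must have length 100");
  NumericVector dy(NSTATE);
  model_rhs(y.begin(), params.begin(), L, D, f, variant, dy.begin());
  return dy;
}

// Light lookup along a protocol. Segments matrix columns:
// 0 t0, 1 t1, 2 hours_light, 3 hours_dark, 4 intensity.
// Right-continuous: the value at a switch time is the new regime.
static inline void light_at(const double* seg, int nseg, double t,
                            double* L, double* D, double* I) {
  int k = -1;
  for (int i = 0; i < nseg; ++i) {
    if (t >= seg[i] - 1e-9 && t < seg[i + nseg] - 1e-9) { k = i; break; }
  }
  if (k < 0 && std::fabs(t - seg[2 * nseg - 1]) < 1e-6) k = nseg - 1;
  if (k < 0) stop("time %f outside the light protocol", t);
  double hl = seg[2 * nseg + k], hd = seg[3 * nseg + k];
  *I = seg[4 * nseg + k];
  if (hd <= 0.0) { *L = 1.0; *D = 0.0; return; }   // constant light
  double cyc = hl + hd;
  double rel = t - seg[k];
  double local = rel - cyc * std::floor(rel / cyc);
  if (local < hl - 1e-9) { *L = 1.0; *D = 0.0; }
  else { *L = 0.0; *D = 1.0; }
}

// [[Rcpp::export(name = ".light_gate_cpp")]]
NumericVector light_gate_cpp(double t, NumericMatrix segments) {
  double L, D, I;
  light_at(segments.begin(), segments.nrow(), t, &L, &D, &I);
  return NumericVector::create(L, D, I);
}

// [[Rcpp::export(name = ".integrate_cpp")]]
List integrate_cpp(NumericVector y0, NumericVector params,
                   NumericMatrix segments, double t0, double t_end,
                   double dt, int stride, int variant = 0) {
  if (y0.size() != NSTATE) stop("y0 must have length 29");
  if (params.size() != NPAR) stop("parameter vector must have length 100");
  if (dt <= 0) stop("dt must be positive");
  const double* p = params.begin();
  const double* seg = segments.begin();
  const int nseg = segments.nrow();
  const long nstep = (long) std::llround((t_end - t0) / dt);
  if (nstep < 0) stop("t_end must be >= t0");
  const long nrec = nstep / stride + 1;

  NumericMatrix out(nrec, NSTATE);
  NumericVector tout(nrec);

  double y[NSTATE], k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE],
         tmp[NSTATE];
  for (int i = 0; i < NSTATE; ++i) y[i] = y0[i];
  for (int i = 0; i < NSTATE; ++i) out(0, i) = y[i];
  tout[0] = t0;

  double L, D, I, f;
  long irec = 1;
  for (long s = 0; s < nstep; ++s) {
    double t = t0 + s * dt;

    // light switches are grid-aligned, so the whole step lies in one
    // regime; freeze light at the step midpoint (never on a switch) to
    // keep the per-step vector field smooth
    light_at(seg, nseg, t + 0.5 * dt, &L, &D, &I);
    f = I / (p[I_A] * I * I + p[I_B] * I + p[I_C]);
    model_rhs(y, p, L, D, f, variant, k1);
    for (int i = 0; i < NSTATE; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
    model_rhs(tmp, p, L, D, f, variant, k2);
    for (int i = 0; i < NSTATE; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
    model_rhs(tmp, p, L, D, f, variant, k3);
    double t1 = t + dt;
    for (int i = 0; i < NSTATE; ++i) tmp[i] = y[i] + dt * k3[i];
    model_rhs(tmp, p, L, D, f, variant, k4);

    for (int i = 0; i < NSTATE; ++i) {
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (!std::isfinite(y[i]))
        stop("integration failure: non-finite state '%d' at t = %f",
             i + 1, t1);
      if (y[i] < 0) {
        if (y[i] < -1e-8)
          stop("integration failure: state %d went negative (%.3e) at t = %f",
               i + 1, y[i], t1);
        y[i] = 0.0;   // round-off undershoot
      }
    }
    if (y[20] > 1.0) {
      if (y[20] > 1.0 + 1e-8)
        stop("integration failure: P exceeded 1 at t = %f", t1);
      y[20] = 1.0;
    }

    if ((s + 1) % stride == 0) {
      for (int i = 0; i < NSTATE; ++i) out(irec, i) = y[i];
      tout[irec] = t1;
      ++irec;
    }
  }

  return List::create(_["time"] = tout, _["states"] = out);
}
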