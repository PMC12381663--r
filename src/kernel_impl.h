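// Batch forward-Euler integration of the phenomenological AP models.
//
// This header is included several times from kernels.cpp, each time inside a
// different namespace and (via GCC target pragmas) for a different SIMD
// instruction set.  Everything here must therefore be `static inline` plain
// C++ with no external dependencies; the Rcpp layer and runtime dispatch live
// in kernels.cpp.
//
// Layout conventions (shared with the R wrappers):
//  * parameter matrix `par` is column-major P x d (R matrix), one row per
//    particle, columns in the model's canonical roster order;
//  * `init` is column-major P x state_dim;
//  * `out` is column-major P x S with S = n_rec * spc / sps voltage samples;
//  * `fin` is column-major P x state_dim and receives the final state;
//  * `bad[p]` is set to 1 if any recorded sample of particle p is non-finite.
//
// Particles are processed in blocks of KBLK with the time loop innermost, so
// state and parameters stay in registers; the per-particle lane loops are the
// ones the compiler vectorizes.

#define KBLK 16

// exp(x) for |x| <= ~60, accurate to ~5e-9 relative: Cody-Waite range
// reduction to 2^n * e^r with |r| <= ln(2)/2 and a degree-7 Taylor kernel.
// Written branch-free so it vectorizes; the 2^n scaling uses the standard
// round-to-int-via-magic-constant bit trick.
static inline double k_exp(double x) {
  const double log2e = 1.4426950408889634074;
  const double ln2hi = 6.93147180369123816490e-01;
  const double ln2lo = 1.90821492927058770002e-10;
  const double magic = 6755399441055744.0; // 1.5 * 2^52
  double sh = x * log2e + magic;
  double fn = sh - magic;
  double r = (x - fn * ln2hi) - fn * ln2lo;
  double p = 1.0 / 5040.0;
  p = p * r + 1.0 / 720.0;
  p = p * r + 1.0 / 120.0;
  p = p * r + 1.0 / 24.0;
  p = p * r + 1.0 / 6.0;
  p = p * r + 0.5;
  p = p * r + 1.0;
  p = p * r + 1.0;
  unsigned long long bits;
  __builtin_memcpy(&bits, &sh, 8);
  bits = (bits + 1023ULL) << 52; // 2^n; n is in the low bits of sh
  double sc;
  __builtin_memcpy(&sc, &bits, 8);
  return p * sc;
}

// tanh(x) via exp, clamped where tanh is 1 to double precision.
static inline double k_tanh(double x) {
  double ax = x < 0 ? -x : x;
  if (ax > 19.0) ax = 19.0; // tanh(19) = 1 - 6e-17
  double em = k_exp(-2.0 * ax);
  double t = (1.0 - em) / (1.0 + em);
  return x < 0 ? -t : t;
}

// ---- Mitchell-Schaeffer ----------------------------------------------------
// par columns: tau_in, tau_out, tau_open, tau_close, v_gate
static void sim_ms(const double* par, int P, const double* init,
                   const double* stim, int spc, int n_pre, int n_rec, int sps,
                   double dt, double* out, double* fin, int* bad) {
  for (int p0 = 0; p0 < P; p0 += KBLK) {
    int klim = P - p0 < KBLK ? P - p0 : KBLK;
    double u[KBLK], h[KBLK], itin[KBLK], itout[KBLK], itop[KBLK], itcl[KBLK],
        vg[KBLK];
    int fl[KBLK];
    for (int k = 0; k < KBLK; k++) {
      int p = p0 + k < P ? p0 + k : P - 1;
      u[k] = init[p];
      h[k] = init[P + p];
      itin[k] = 1.0 / par[p];
      itout[k] = 1.0 / par[P + p];
      itop[k] = 1.0 / par[2 * P + p];
      itcl[k] = 1.0 / par[3 * P + p];
      vg[k] = par[4 * P + p];
      fl[k] = 0;
    }
    for (int cyc = 0; cyc < n_pre + n_rec; cyc++) {
      int rec = cyc >= n_pre;
      long col0 = rec ? (long)(cyc - n_pre) * (spc / sps) : 0;
      for (int s = 0; s < spc; s++) {
        if (rec && s % sps == 0) {
          long col = col0 + s / sps;
          for (int k = 0; k < klim; k++) {
            out[col * P + p0 + k] = u[k];
            fl[k] |= !(u[k] - u[k] == 0.0);
          }
        }
        double ist = stim[s];
        for (int k = 0; k < KBLK; k++) {
          double uu = u[k], hh = h[k];
          double du = hh * uu * uu * (1.0 - uu) * itin[k] - uu * itout[k] + ist;
          double dh = uu < vg[k] ? (1.0 - hh) * itop[k] : -hh * itcl[k];
          u[k] = uu + dt * du;
          h[k] = hh + dt * dh;
        }
      }
    }
    for (int k = 0; k < klim; k++) {
      fin[p0 + k] = u[k];
      fin[P + p0 + k] = h[k];
      bad[p0 + k] = fl[k];
    }
  }
}

// ---- modified Mitchell-Schaeffer -------------------------------------------
// Cubic inward current gated above v_gate and outward current gated by the
// closed fraction (1 - h).  par columns as MS.
static void sim_mms(const double* par, int P, const double* init,
                    const double* stim, int spc, int n_pre, int n_rec, int sps,
                    double dt, double* out, double* fin, int* bad) {
  for (int p0 = 0; p0 < P; p0 += KBLK) {
    int klim = P - p0 < KBLK ? P - p0 : KBLK;
    double u[KBLK], h[KBLK], itin[KBLK], itout[KBLK], itop[KBLK], itcl[KBLK],
        vg[KBLK];
    int fl[KBLK];
    for (int k = 0; k < KBLK; k++) {
      int p = p0 + k < P ? p0 + k : P - 1;
      u[k] = init[p];
      h[k] = init[P + p];
      itin[k] = 1.0 / par[p];
      itout[k] = 1.0 / par[P + p];
      itop[k] = 1.0 / par[2 * P + p];
      itcl[k] = 1.0 / par[3 * P + p];
      vg[k] = par[4 * P + p];
      fl[k] = 0;
    }
    for (int cyc = 0; cyc < n_pre + n_rec; cyc++) {
      int rec = cyc >= n_pre;
      long col0 = rec ? (long)(cyc - n_pre) * (spc / sps) : 0;
      for (int s = 0; s < spc; s++) {
        if (rec && s % sps == 0) {
          long col = col0 + s / sps;
          for (int k = 0; k < klim; k++) {
            out[col * P + p0 + k] = u[k];
            fl[k] |= !(u[k] - u[k] == 0.0);
          }
        }
        double ist = stim[s];
        for (int k = 0; k < KBLK; k++) {
          double uu = u[k], hh = h[k];
          double du = hh * uu * (uu - vg[k]) * (1.0 - uu) * itin[k] -
                      (1.0 - hh) * uu * itout[k] + ist;
          double dh = uu < vg[k] ? (1.0 - hh) * itop[k] : -hh * itcl[k];
          u[k] = uu + dt * du;
          h[k] = hh + dt * dh;
        }
      }
    }
    for (int k = 0; k < klim; k++) {
      fin[p0 + k] = u[k];
      fin[P + p0 + k] = h[k];
      bad[p0 + k] = fl[k];
    }
  }
}

// ---- modified FitzHugh-Nagumo ----------------------------------------------
// Cubic excitation with linear recovery variable.
// par columns: a, b, c1, c2, d
static void sim_mfhn(const double* par, int P, const double* init,
                     const double* stim, int spc, int n_pre, int n_rec,
                     int sps, double dt, double* out, double* fin, int* bad) {
  for (int p0 = 0; p0 < P; p0 += KBLK) {
    int klim = P - p0 < KBLK ? P - p0 : KBLK;
    double u[KBLK], v[KBLK], a[KBLK], b[KBLK], c1[KBLK], c2[KBLK], d[KBLK];
    int fl[KBLK];
    for (int k = 0; k < KBLK; k++) {
      int p = p0 + k < P ? p0 + k : P - 1;
      u[k] = init[p];
      v[k] = init[P + p];
      a[k] = par[p];
      b[k] = par[P + p];
      c1[k] = par[2 * P + p];
      c2[k] = par[3 * P + p];
      d[k] = par[4 * P + p];
      fl[k] = 0;
    }
    for (int cyc = 0; cyc < n_pre + n_rec; cyc++) {
      int rec = cyc >= n_pre;
      long col0 = rec ? (long)(cyc - n_pre) * (spc / sps) : 0;
      for (int s = 0; s < spc; s++) {
        if (rec && s % sps == 0) {
          long col = col0 + s / sps;
          for (int k = 0; k < klim; k++) {
            out[col * P + p0 + k] = u[k];
            fl[k] |= !(u[k] - u[k] == 0.0);
          }
        }
        double ist = stim[s];
        for (int k = 0; k < KBLK; k++) {
          double uu = u[k], vv = v[k];
          double du =
              c1[k] * uu * (uu - a[k]) * (1.0 - uu) - c2[k] * uu * vv + ist;
          double dv = b[k] * (uu - d[k] * vv);
          u[k] = uu + dt * du;
          v[k] = vv + dt * dv;
        }
      }
    }
    for (int k = 0; k < klim; k++) {
      fin[p0 + k] = u[k];
      fin[P + p0 + k] = v[k];
      bad[p0 + k] = fl[k];
    }
  }
}

// ---- Fenton-Karma ----------------------------------------------------------
// Three currents (fast inward, slow outward, slow inward) with gates v and w.
// Gate regimes switch at u_c; the v-gate recovery time constant switches at
// u_v (tau_v1_minus above u_v, tau_v2_minus below).
// par columns: tau_d, tau_r, tau_si, tau_0, tau_v_plus, tau_v1_minus,
//              tau_v2_minus, tau_w_plus, tau_w_minus, u_c, u_v, u_csi, k
static void sim_fk(const double* par, int P, const double* init,
                   const double* stim, int spc, int n_pre, int n_rec, int sps,
                   double dt, double* out, double* fin, int* bad) {
  for (int p0 = 0; p0 < P; p0 += KBLK) {
    int klim = P - p0 < KBLK ? P - p0 : KBLK;
    double u[KBLK], v[KBLK], w[KBLK];
    double itd[KBLK], itr[KBLK], hitsi[KBLK], it0[KBLK], itvp[KBLK],
        itv1m[KBLK], itv2m[KBLK], itwp[KBLK], itwm[KBLK], uc[KBLK], uv[KBLK],
        ucsi[KBLK], kk[KBLK];
    int fl[KBLK];
    for (int k = 0; k < KBLK; k++) {
      int p = p0 + k < P ? p0 + k : P - 1;
      u[k] = init[p];
      v[k] = init[P + p];
      w[k] = init[2 * P + p];
      itd[k] = 1.0 / par[p];
      itr[k] = 1.0 / par[P + p];
      hitsi[k] = 0.5 / par[2 * P + p];
      it0[k] = 1.0 / par[3 * P + p];
      itvp[k] = 1.0 / par[4 * P + p];
      itv1m[k] = 1.0 / par[5 * P + p];
      itv2m[k] = 1.0 / par[6 * P + p];
      itwp[k] = 1.0 / par[7 * P + p];
      itwm[k] = 1.0 / par[8 * P + p];
      uc[k] = par[9 * P + p];
      uv[k] = par[10 * P + p];
      ucsi[k] = par[11 * P + p];
      kk[k] = par[12 * P + p];
      fl[k] = 0;
    }
    for (int cyc = 0; cyc < n_pre + n_rec; cyc++) {
      int rec = cyc >= n_pre;
      long col0 = rec ? (long)(cyc - n_pre) * (spc / sps) : 0;
      for (int s = 0; s < spc; s++) {
        if (rec && s % sps == 0) {
          long col = col0 + s / sps;
          for (int k = 0; k < klim; k++) {
            out[col * P + p0 + k] = u[k];
            fl[k] |= !(u[k] - u[k] == 0.0);
          }
        }
        double ist = stim[s];
        for (int k = 0; k < KBLK; k++) {
          double uu = u[k], vv = v[k], ww = w[k];
          bool pg = uu >= uc[k];
          double itvm = uu >= uv[k] ? itv1m[k] : itv2m[k];
          double jfi = pg ? -vv * (1.0 - uu) * (uu - uc[k]) * itd[k] : 0.0;
          double jso = pg ? itr[k] : uu * it0[k];
          double jsi = -ww * (1.0 + k_tanh(kk[k] * (uu - ucsi[k]))) * hitsi[k];
          double dv = pg ? -vv * itvp[k] : (1.0 - vv) * itvm;
          double dw = pg ? -ww * itwp[k] : (1.0 - ww) * itwm[k];
          u[k] = uu + dt * (-(jfi + jso + jsi) + ist);
          v[k] = vv + dt * dv;
          w[k] = ww + dt * dw;
        }
      }
    }
    for (int k = 0; k < klim; k++) {
      fin[p0 + k] = u[k];
      fin[P + p0 + k] = v[k];
      fin[2 * P + p0 + k] = w[k];
      bad[p0 + k] = fl[k];
    }
  }
}

// ---- Bueno-Orovio-Cherry-Fenton minimal model (and Brugada variant) --------
// Four variables u, v, w, s.  The resting offset u_o of the original
// formulation is fixed at 0 and is not part of the fittable roster.
// BOCF par columns:
//   0 u_u, 1 theta_v, 2 theta_w, 3 theta_v_minus, 4 theta_o,
//   5 tau_v1_minus, 6 tau_v2_minus, 7 tau_v_plus, 8 tau_w1_minus,
//   9 tau_w2_minus, 10 k_w_minus, 11 u_w_minus, 12 tau_w_plus, 13 tau_fi,
//   14 tau_o1, 15 tau_o2, 16 tau_so1, 17 tau_so2, 18 k_so, 19 u_so,
//   20 tau_s1, 21 tau_s2, 22 k_s, 23 u_s, 24 tau_si, 25 tau_w_inf,
//   26 w_inf_star
// BBOCF replaces tau_w_plus by a sigmoidal blend tau_w1_plus/tau_w2_plus
// (steepness k_w_plus around u_w_plus) and tau_si by tau_si1/tau_si2 blended
// in the gate s around s_c with steepness k_si:
//   ... 12 tau_w1_plus, 13 tau_w2_plus, 14 k_w_plus, 15 u_w_plus, 16 tau_fi,
//   17 tau_o1, 18 tau_o2, 19 tau_so1, 20 tau_so2, 21 k_so, 22 u_so,
//   23 tau_s1, 24 tau_s2, 25 k_s, 26 u_s, 27 tau_si1, 28 tau_si2, 29 k_si,
//   30 s_c, 31 tau_w_inf, 32 w_inf_star
template <bool BB>
static void sim_bocf(const double* par, int P, const double* init,
                     const double* stim, int spc, int n_pre, int n_rec,
                     int sps, double dt, double* out, double* fin, int* bad) {
  const int q = BB ? 3 : 0; // net column shift after the tau_w_plus slot(s)
  for (int p0 = 0; p0 < P; p0 += KBLK) {
    int klim = P - p0 < KBLK ? P - p0 : KBLK;
    double u[KBLK], v[KBLK], w[KBLK], sg[KBLK];
    double uu_[KBLK], thv[KBLK], thw[KBLK], thvm[KBLK], tho[KBLK];
    double itv1m[KBLK], itv2m[KBLK], itvp[KBLK];
    double tw1m[KBLK], tw2m[KBLK], kwm[KBLK], uwm[KBLK];
    double itwp1[KBLK], twp2m1[KBLK], kwp[KBLK], uwp[KBLK];
    double itfi[KBLK], ito1[KBLK], ito2[KBLK];
    double tso1[KBLK], tso2[KBLK], kso[KBLK], uso[KBLK];
    double its1[KBLK], its2[KBLK], ks[KBLK], us[KBLK];
    double tsi1[KBLK], tsi2m1[KBLK], ksi[KBLK], sc[KBLK];
    double itwinf[KBLK], winfs[KBLK];
    int fl[KBLK];
    for (int k = 0; k < KBLK; k++) {
      int p = p0 + k < P ? p0 + k : P - 1;
      u[k] = init[p];
      v[k] = init[P + p];
      w[k] = init[2 * P + p];
      sg[k] = init[3 * P + p];
      uu_[k] = par[p];
      thv[k] = par[P + p];
      thw[k] = par[2 * P + p];
      thvm[k] = par[3 * P + p];
      tho[k] = par[4 * P + p];
      itv1m[k] = 1.0 / par[5 * P + p];
      itv2m[k] = 1.0 / par[6 * P + p];
      itvp[k] = 1.0 / par[7 * P + p];
      tw1m[k] = par[8 * P + p];
      tw2m[k] = par[9 * P + p];
      kwm[k] = par[10 * P + p];
      uwm[k] = par[11 * P + p];
      if (BB) {
        itwp1[k] = par[12 * P + p];           // tau_w1_plus (not inverted)
        twp2m1[k] = par[13 * P + p] - itwp1[k]; // tau_w2_plus - tau_w1_plus
        kwp[k] = par[14 * P + p];
        uwp[k] = par[15 * P + p];
      } else {
        itwp1[k] = 1.0 / par[12 * P + p];
        twp2m1[k] = 0.0;
        kwp[k] = 0.0;
        uwp[k] = 0.0;
      }
      itfi[k] = 1.0 / par[(13 + q) * P + p];
      ito1[k] = 1.0 / par[(14 + q) * P + p];
      ito2[k] = 1.0 / par[(15 + q) * P + p];
      tso1[k] = par[(16 + q) * P + p];
      tso2[k] = par[(17 + q) * P + p];
      kso[k] = par[(18 + q) * P + p];
      uso[k] = par[(19 + q) * P + p];
      its1[k] = 1.0 / par[(20 + q) * P + p];
      its2[k] = 1.0 / par[(21 + q) * P + p];
      ks[k] = par[(22 + q) * P + p];
      us[k] = par[(23 + q) * P + p];
      if (BB) {
        tsi1[k] = par[27 * P + p];
        tsi2m1[k] = par[28 * P + p] - tsi1[k];
        ksi[k] = par[29 * P + p];
        sc[k] = par[30 * P + p];
        itwinf[k] = 1.0 / par[31 * P + p];
        winfs[k] = par[32 * P + p];
      } else {
        tsi1[k] = par[24 * P + p];
        tsi2m1[k] = 0.0;
        ksi[k] = 0.0;
        sc[k] = 0.0;
        itwinf[k] = 1.0 / par[25 * P + p];
        winfs[k] = par[26 * P + p];
      }
      fl[k] = 0;
    }
    for (int cyc = 0; cyc < n_pre + n_rec; cyc++) {
      int rec = cyc >= n_pre;
      long col0 = rec ? (long)(cyc - n_pre) * (spc / sps) : 0;
      for (int s = 0; s < spc; s++) {
        if (rec && s % sps == 0) {
          long col = col0 + s / sps;
          for (int k = 0; k < klim; k++) {
            out[col * P + p0 + k] = u[k];
            fl[k] |= !(u[k] - u[k] == 0.0);
          }
        }
        double ist = stim[s];
        for (int k = 0; k < KBLK; k++) {
          double uu = u[k], vv = v[k], ww = w[k], ss = sg[k];
          bool hv = uu >= thv[k];
          bool hw = uu >= thw[k];
          bool ho = uu >= tho[k];
          double itvm = uu >= thvm[k] ? itv2m[k] : itv1m[k];
          double twm =
              tw1m[k] +
              (tw2m[k] - tw1m[k]) * 0.5 * (1.0 + k_tanh(kwm[k] * (uu - uwm[k])));
          double tso =
              tso1[k] +
              (tso2[k] - tso1[k]) * 0.5 * (1.0 + k_tanh(kso[k] * (uu - uso[k])));
          double vinf = uu < thvm[k] ? 1.0 : 0.0;
          double winf = ho ? winfs[k] : 1.0 - uu * itwinf[k];
          double itsi, itwp;
          if (BB) {
            itsi = 1.0 / (tsi1[k] + tsi2m1[k] * 0.5 *
                                        (1.0 + k_tanh(ksi[k] * (ss - sc[k]))));
            itwp = 1.0 / (itwp1[k] + twp2m1[k] * 0.5 *
                                         (1.0 + k_tanh(kwp[k] * (uu - uwp[k]))));
          } else {
            itsi = 1.0 / tsi1[k];
            itwp = itwp1[k];
          }
          double jfi = hv ? -vv * (uu - thv[k]) * (uu_[k] - uu) * itfi[k] : 0.0;
          double jso = hw ? 1.0 / tso : uu * (ho ? ito2[k] : ito1[k]);
          double jsi = hw ? -ww * ss * itsi : 0.0;
          double dv = hv ? -vv * itvp[k] : (vinf - vv) * itvm;
          double dw = hw ? -ww * itwp : (winf - ww) / twm;
          double sinf = 0.5 * (1.0 + k_tanh(ks[k] * (uu - us[k])));
          double ds = (sinf - ss) * (hw ? its2[k] : its1[k]);
          u[k] = uu + dt * (-(jfi + jso + jsi) + ist);
          v[k] = vv + dt * dv;
          w[k] = ww + dt * dw;
          sg[k] = ss + dt * ds;
        }
      }
    }
    for (int k = 0; k < klim; k++) {
      fin[p0 + k] = u[k];
      fin[P + p0 + k] = v[k];
      fin[2 * P + p0 + k] = w[k];
      fin[3 * P + p0 + k] = sg[k];
      bad[p0 + k] = fl[k];
    }
  }
}

// Single entry point used by the dispatcher in kernels.cpp.
static void sim_dispatch_model(int model_id, const double* par, int P,
                               const double* init, const double* stim, int spc,
                               int n_pre, int n_rec, int sps, double dt,
                               double* out, double* fin, int* bad) {
  switch (model_id) {
    case 0: sim_ms(par, P, init, stim, spc, n_pre, n_rec, sps, dt, out, fin, bad); break;
    case 1: sim_mms(par, P, init, stim, spc, n_pre, n_rec, sps, dt, out, fin, bad); break;
    case 2: sim_mfhn(par, P, init, stim, spc, n_pre, n_rec, sps, dt, out, fin, bad); break;
    case 3: sim_fk(par, P, init, stim, spc, n_pre, n_rec, sps, dt, out, fin, bad); break;
    case 4: sim_bocf<false>(par, P, init, stim, spc, n_pre, n_rec, sps, dt, out, fin, bad); break;
    case 5: sim_bocf<true>(par, P, init, stim, spc, n_pre, n_rec, sps, dt, out, fin, bad); break;
  }
}

#undef KBLK
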