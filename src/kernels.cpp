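// Rcpp interface to the batch Euler kernels plus small compiled helpers for
// the fitness pipeline.  The numerical core in kernel_impl.h is compiled
// three times (portable baseline, AVX2, AVX-512) and selected at run time,
// so no architecture-specific compiler flags are required to build the
// package while still exploiting wide SIMD where the CPU provides it.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>

using namespace Rcpp;

namespace k_base {
#include "kernel_impl.h"
}

#if defined(__x86_64__) || defined(__i386__)
#define APSWARM_X86 1
#pragma GCC push_options
#pragma GCC target("avx2,fma")
namespace k_avx2 {
#include "kernel_impl.h"
}
#pragma GCC pop_options

#pragma GCC push_options
#pragma GCC target("avx512f,fma,prefer-vector-width=512")
namespace k_avx512 {
#include "kernel_impl.h"
}
#pragma GCC pop_options
#endif

// simd: 0 = auto, 1 = force baseline, 2 = force avx2, 3 = force avx512
static int pick_isa(int simd) {
#ifdef APSWARM_X86
  if (simd == 1) return 1;
  if (simd == 2) return 2;
  if (simd == 3) return 3;
  if (__builtin_cpu_supports("avx512f")) return 3;
  if (__builtin_cpu_supports("avx2") && __builtin_cpu_supports("fma")) return 2;
#endif
  return 1;
}

// Stimulus current at a vector of times since stimulus onset (ms).
// shape 0 = square: magnitude for 0 <= t < duration.
// shape 1 = biphasic: a hyperpolarizing phase of half the magnitude over the
// first half of the duration followed by a depolarizing phase of the full
// magnitude, a simple surrogate for the current experienced through diffusive
// coupling (experimental; see the package vignette).
// [[Rcpp::export(name = ".cxx_stimulus_current")]]
NumericVector cxx_stimulus_current(NumericVector t, int shape, double magnitude,
                                   double duration) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    double ti = t[i];
    double v = 0.0;
    if (ti >= 0 && ti < duration) {
      if (shape == 0) {
        v = magnitude;
      } else {
        v = ti < 0.5 * duration ? -0.5 * magnitude : magnitude;
      }
    }
    out[i] = v;
  }
  return out;
}

// Batch pacing simulation.  par: P x d (roster order), init: P x state_dim.
// Returns P x S sample matrix with attributes "ok" (logical) and "state"
// (P x state_dim final state).
// [[Rcpp::export(name = ".cxx_sim_batch")]]
NumericMatrix cxx_sim_batch(int model_id, int state_dim, NumericMatrix par,
                            NumericMatrix init, double cycle_length, int n_pre,
                            int n_rec, double dt, double sample_interval,
                            int stim_shape, double stim_magnitude,
                            double stim_duration, int simd) {
  int P = par.nrow();
  long spc_l = (long)std::llround(cycle_length / dt);
  if (std::fabs(spc_l * dt - cycle_length) > 1e-6)
    stop("cycle_length must be an integer multiple of dt");
  int spc = (int)spc_l;
  long sps_l = (long)std::llround(sample_interval / dt);
  if (std::fabs(sps_l * dt - sample_interval) > 1e-9)
    stop("sample_interval must be an integer multiple of dt");
  int sps = (int)sps_l;
  if (spc % sps != 0)
    stop("cycle_length must be an integer multiple of sample_interval");
  if (init.nrow() != P || init.ncol() != state_dim)
    stop("init must be a P x state_dim matrix");
  long S = (long)n_rec * (spc / sps);
  std::vector<double> stim(spc);
  for (int s = 0; s < spc; s++) {
    double t = s * dt;
    double v = 0.0;
    if (t < stim_duration) {
      if (stim_shape == 0)
        v = stim_magnitude;
      else
        v = t < 0.5 * stim_duration ? -0.5 * stim_magnitude : stim_magnitude;
    }
    stim[s] = v;
  }
  NumericMatrix out(P, (int)S);
  NumericMatrix fin(P, state_dim);
  std::vector<int> bad(P, 0);
  int isa = pick_isa(simd);
#ifdef APSWARM_X86
  if (isa == 3)
    k_avx512::sim_dispatch_model(model_id, par.begin(), P, init.begin(),
                                 stim.data(), spc, n_pre, n_rec, sps, dt,
                                 out.begin(), fin.begin(), bad.data());
  else if (isa == 2)
    k_avx2::sim_dispatch_model(model_id, par.begin(), P, init.begin(),
                               stim.data(), spc, n_pre, n_rec, sps, dt,
                               out.begin(), fin.begin(), bad.data());
  else
#endif
    k_base::sim_dispatch_model(model_id, par.begin(), P, init.begin(),
                               stim.data(), spc, n_pre, n_rec, sps, dt,
                               out.begin(), fin.begin(), bad.data());
  LogicalVector ok(P);
  for (int p = 0; p < P; p++) {
    bool fine = bad[p] == 0;
    if (fine)
      for (int j = 0; j < state_dim; j++)
        if (!R_finite(fin(p, j))) fine = false;
    ok[p] = fine;
  }
  out.attr("ok") = ok;
  out.attr("state") = fin;
  return out;
}

// First upward crossing of `threshold` per row, as a 1-based sample index
// (the index of the first sample at or above threshold with its predecessor
// below); 0 when the row never crosses.  NaN-safe: comparisons with NaN fail.
// [[Rcpp::export(name = ".cxx_upstroke_index")]]
IntegerVector cxx_upstroke_index(NumericMatrix m, double threshold) {
  int P = m.nrow(), S = m.ncol();
  IntegerVector out(P);
  for (int p = 0; p < P; p++) {
    int idx = 0;
    // allow a crossing at the very first sample only if it starts above
    for (int j = 1; j < S; j++) {
      if (m(p, j - 1) < threshold && m(p, j) >= threshold) {
        idx = j + 1;
        break;
      }
    }
    out[p] = idx;
  }
  return out;
}

// Length-weighted squared voltage error per row after applying a per-row
// integer sample offset: model sample (j + offset) is compared with data
// sample j, summing over the overlap and dividing by the number of data
// samples.  offset is in samples; rows with NA offset or empty overlap give
// NA (caller substitutes the worst-case sentinel).  Any non-finite model
// value in the overlap also yields NA.
// [[Rcpp::export(name = ".cxx_voltage_error")]]
NumericVector cxx_voltage_error(NumericMatrix m, NumericVector data,
                                IntegerVector offset) {
  int P = m.nrow(), S = m.ncol(), n = data.size();
  NumericVector out(P);
  for (int p = 0; p < P; p++) {
    if (offset[p] == NA_INTEGER) {
      out[p] = NA_REAL;
      continue;
    }
    int o = offset[p];
    int j0 = o < 0 ? -o : 0;        // first data index (0-based) in overlap
    int j1 = n < S - o ? n : S - o; // one past last data index
    if (j1 <= j0) {
      out[p] = NA_REAL;
      continue;
    }
    double acc = 0.0;
    bool bad = false;
    for (int j = j0; j < j1; j++) {
      double d = m(p, j + o) - data[j];
      acc += d * d;
      if (!R_finite(d)) bad = true;
    }
    out[p] = bad ? NA_REAL : acc / n;
  }
  return out;
}
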