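# Shared fixtures built in code.

# Trapezoidal pulse sampled at 1 ms: linear rise over `rise` ms, flat plateau,
# linear fall; baseline zero before and after.
trapezoid_trace <- function(rise = 2, plateau = 100, fall = 2, pad = 20,
                            amplitude = 1) {
  t <- 0:(pad + rise + plateau + fall + pad)
  v <- numeric(length(t))
  v[t > pad & t <= pad + rise] <- amplitude * (t[t > pad & t <= pad + rise] - pad) / rise
  v[t > pad + rise & t <= pad + rise + plateau] <- amplitude
  idx <- t > pad + rise + plateau & t < pad + rise + plateau + fall
  v[idx] <- amplitude * (pad + rise + plateau + fall - t[idx]) / fall
  ap_trace(v, 1)
}

# Rectangular action potentials: each AP is `width` samples at 1, separated
# by `gap` samples at 0 (APD at half-max is exactly `width` ms).
rect_ap_trace <- function(widths, gap = 50) {
  v <- numeric(0)
  for (w in widths) v <- c(v, rep(0, gap), rep(1, w))
  ap_trace(c(v, rep(0, gap)), 1)
}

# Parameter sets exhibiting APD alternans at a short cycle length while
# pacing 1:1 at a long one (frozen from a restitution scan of the defaults).
alternans_fixture <- function(model) {
  if (model == "FK") {
    p <- default_params("FK")
    p[c("tau_w_minus", "tau_w_plus", "tau_si")] <- c(160, 400, 25)
    list(params = p, cl_short = 300, cl_long = 500)
  } else if (model == "BOCF") {
    list(params = default_params("BOCF"), cl_short = 240, cl_long = 500)
  } else {
    stop("no alternans fixture for ", model)
  }
}

# Small MS fitting problem used by determinism/invariant tests (fast).
tiny_ms_problem <- function() {
  syn <- generate_dataset("MS", cycle_lengths = 300, n_stimuli = 1)
  fit_problem("MS", syn$entries,
    n_stimuli = 1, n_prerecording = 1,
    normalize_to = 0
  )
}
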