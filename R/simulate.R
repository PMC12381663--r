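# Pacing protocols, stimulus waveforms, forward Euler integration and the
# newline-delimited voltage trace dialect.

#' Stimulus specification
#'
#' @param shape `"square"` (constant `magnitude` for `duration` ms) or
#'   `"biphasic"` (a brief hyperpolarizing phase of half the magnitude over
#'   the first half of the duration followed by a depolarizing phase at the
#'   full magnitude; an experimental surrogate for the current a cell
#'   experiences through diffusive coupling).
#' @param magnitude Stimulus amplitude in 1/ms (default 0.2).
#' @param duration Stimulus duration in ms (default 2).
#' @return An object of class `ap_stimulus`.
#' @export
stimulus_spec <- function(shape = c("square", "biphasic"), magnitude = 0.2,
                          duration = 2) {
  shape <- match.arg(shape)
  if (!is.numeric(magnitude) || magnitude <= 0) stop("magnitude must be > 0")
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  structure(
    list(shape = shape, magnitude = magnitude, duration = duration),
    class = "ap_stimulus"
  )
}

#' Stimulus current at a given time since stimulus onset
#'
#' @param stimulus An [stimulus_spec()] object.
#' @param t Time(s) since stimulus onset, in ms (vectorized).
#' @return Stimulus current(s) in 1/ms.
#' @export
stimulus_current <- function(stimulus, t) {
  stopifnot(inherits(stimulus, "ap_stimulus"))
  .cxx_stimulus_current(
    as.numeric(t), if (stimulus$shape == "square") 0L else 1L,
    stimulus$magnitude, stimulus$duration
  )
}

#' Pacing protocol
#'
#' Defines periodic stimulation at a fixed cycle length: `n_prerecording`
#' wash-out beats are simulated first (to reduce the transient effect of the
#' initial conditions), then `n_stimuli` beats are recorded.  The voltage is
#' sampled every `sample_interval` ms starting at the onset of the first
#' recorded stimulus, so a recorded trace has
#' `n_stimuli * cycle_length / sample_interval` samples.
#'
#' @param cycle_length Pacing period in ms.
#' @param n_stimuli Number of recorded beats (default 2).
#' @param n_prerecording Number of wash-out beats before recording (default 0).
#' @param dt Forward Euler time step in ms (default 0.02).
#' @param sample_interval Sampling interval in ms (default 1); must be an
#'   integer multiple of `dt` and divide `cycle_length`.
#' @param stimulus A [stimulus_spec()].
#' @return An object of class `ap_protocol`.
#' @export
pacing_protocol <- function(cycle_length, n_stimuli = 2L, n_prerecording = 0L,
                            dt = 0.02, sample_interval = 1,
                            stimulus = stimulus_spec()) {
  stopifnot(
    is.numeric(cycle_length), cycle_length > 0,
    n_stimuli >= 1, n_prerecording >= 0, dt > 0
  )
  if (cycle_length <= stimulus$duration) {
    stop("cycle_length must exceed the stimulus duration")
  }
  k <- sample_interval / dt
  if (abs(k - round(k)) > 1e-9) {
    stop("sample_interval must be an integer multiple of dt")
  }
  m <- cycle_length / sample_interval
  if (abs(m - round(m)) > 1e-9) {
    stop("cycle_length must be an integer multiple of sample_interval")
  }
  structure(
    list(
      cycle_length = cycle_length, n_stimuli = as.integer(n_stimuli),
      n_prerecording = as.integer(n_prerecording), dt = dt,
      sample_interval = sample_interval, stimulus = stimulus
    ),
    class = "ap_protocol"
  )
}

#' Construct a voltage trace
#'
#' @param values Numeric vector of dimensionless voltage samples.
#' @param sample_interval Sampling interval in ms.
#' @param cycle_length Pacing cycle length in ms (may be `NA` for free-form
#'   recordings).
#' @return An object of class `ap_trace`.
#' @export
ap_trace <- function(values, sample_interval = 1, cycle_length = NA_real_) {
  structure(
    list(
      values = as.numeric(values), sample_interval = sample_interval,
      cycle_length = cycle_length
    ),
    class = "ap_trace"
  )
}

#' @export
print.ap_trace <- function(x, ...) {
  cat(sprintf(
    "<ap_trace: %d samples at %g ms%s, range [%.3g, %.3g]>\n",
    length(x$values), x$sample_interval,
    if (is.na(x$cycle_length)) "" else sprintf(", CL %g ms", x$cycle_length),
    suppressWarnings(min(x$values)), suppressWarnings(max(x$values))
  ))
  invisible(x)
}

#' @export
plot.ap_trace <- function(x, ...) {
  t <- (seq_along(x$values) - 1) * x$sample_interval
  plot(t, x$values,
    type = "l", xlab = "time (ms)", ylab = "voltage (dimensionless)", ...
  )
  invisible(x)
}

.simd_code <- function() {
  switch(getOption("apswarm.simd", "auto"),
    auto = 0L, none = 1L, avx2 = 2L, avx512 = 3L, 0L
  )
}

.sim_batch <- function(model, param_matrix, protocol, init = NULL) {
  model <- ap_model(model)
  d <- nrow(model$parameters)
  if (!is.matrix(param_matrix)) {
    param_matrix <- matrix(param_matrix, nrow = 1)
  }
  if (ncol(param_matrix) != d) {
    stop(sprintf(
      "%s expects %d parameters per row, got %d", model$name, d,
      ncol(param_matrix)
    ))
  }
  P <- nrow(param_matrix)
  if (is.null(init)) {
    # resting gates; for the minimal models the s gate rest depends on k_s, u_s
    init <- matrix(0, P, model$state_dim)
    if (model$name %in% c("MS", "MMS")) {
      init[, 2] <- 1
    } else if (model$name == "FK") {
      nm <- model$parameters$name
      t0 <- param_matrix[, match("tau_0", nm)]
      tsi <- param_matrix[, match("tau_si", nm)]
      kk <- param_matrix[, match("k", nm)]
      ucsi <- param_matrix[, match("u_csi", nm)]
      ur <- numeric(P)
      for (i in 1:4) ur <- t0 * (1 + tanh(kk * (ur - ucsi))) / (2 * tsi)
      init[, 1] <- ur
      init[, 2] <- 1
      init[, 3] <- 1
    } else if (model$name %in% c("BOCF", "BBOCF")) {
      init[, 2] <- 1
      init[, 3] <- 1
      ks <- param_matrix[, match("k_s", model$parameters$name)]
      us <- param_matrix[, match("u_s", model$parameters$name)]
      init[, 4] <- (1 + tanh(-ks * us)) / 2
    }
  } else {
    if (!is.matrix(init)) init <- matrix(init, nrow = P, ncol = model$state_dim, byrow = TRUE)
  }
  .cxx_sim_batch(
    .model_ids[[model$name]], model$state_dim,
    param_matrix, init, protocol$cycle_length,
    protocol$n_prerecording, protocol$n_stimuli, protocol$dt,
    protocol$sample_interval,
    if (protocol$stimulus$shape == "square") 0L else 1L,
    protocol$stimulus$magnitude, protocol$stimulus$duration,
    .simd_code()
  )
}

#' Integrate a model under a pacing protocol
#'
#' Integrates the model with the forward Euler method at the protocol's time
#' step, running `n_prerecording` wash-out beats followed by `n_stimuli`
#' recorded beats, and returns the recorded voltage sampled every
#' `sample_interval` ms.  Integration starts from the resting state unless
#' `init` is supplied.  If the state becomes non-finite (possible under
#' extreme parameter values with an explicit method) the returned trace is
#' flagged invalid via its `ok` attribute rather than raising an error;
#' downstream fitness evaluation treats such traces as worst-case.
#'
#' @param model Model name or `ap_model`.
#' @param params Parameter vector (defaults to the model defaults).
#' @param protocol A [pacing_protocol()].
#' @param init Optional initial state vector (defaults to [rest_state()]).
#' @return An `ap_trace` with attributes `ok` (logical validity flag) and
#'   `state` (final state vector, usable to chain simulations).
#' @examples
#' tr <- integrate_model("MS", protocol = pacing_protocol(500, n_stimuli = 1))
#' max(tr$values)
#' @export
integrate_model <- function(model, params = NULL, protocol, init = NULL) {
  model <- ap_model(model)
  params <- .check_params(model, params)
  m <- .sim_batch(
    model, matrix(params, nrow = 1), protocol,
    init = if (is.null(init)) NULL else matrix(init, nrow = 1)
  )
  tr <- ap_trace(m[1, ], protocol$sample_interval, protocol$cycle_length)
  attr(tr, "ok") <- attr(m, "ok")[1]
  attr(tr, "state") <- stats::setNames(attr(m, "state")[1, ], model$states)
  tr
}

#' Integrate a batch of parameter sets under one protocol
#'
#' Evaluates many candidate parameter sets at once; row `i` of the result is
#' identical (bitwise) to `integrate_model(model, param_matrix[i, ],
#' protocol)`.  This is the evaluation path used by the particle swarm, where
#' each particle's parameter vector is simulated independently.
#'
#' @param model Model name or `ap_model`.
#' @param param_matrix Numeric matrix, one full parameter vector per row.
#' @param protocol A [pacing_protocol()].
#' @param init Optional matrix of initial states (one row per parameter set).
#' @return A numeric matrix (rows = parameter sets, columns = samples) with
#'   attributes `ok` (logical vector) and `state` (final state matrix).
#' @export
integrate_batch <- function(model, param_matrix, protocol, init = NULL) {
  .sim_batch(model, param_matrix, protocol, init = init)
}

#' Write a voltage trace in the newline-delimited dialect
#'
#' One voltage value per line.  With `sidecar = TRUE` a JSON metadata file
#' (`<path>.json`) recording the cycle length and sample interval is written
#' alongside.
#'
#' @param trace An `ap_trace`.
#' @param path Output file path.
#' @param sidecar Write the JSON metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, sidecar = TRUE) {
  stopifnot(inherits(trace, "ap_trace"))
  writeLines(sprintf("%.15g", trace$values), path)
  if (sidecar) {
    jsonlite::write_json(
      list(
        cycle_length = trace$cycle_length,
        sample_interval = trace$sample_interval,
        n_samples = length(trace$values)
      ),
      paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Read a newline-delimited voltage trace
#'
#' @param path File with one voltage value per line.
#' @param cycle_length Pacing cycle length in ms; if `NULL`, taken from the
#'   JSON sidecar `<path>.json` when present.
#' @param sample_interval Sampling interval in ms (default 1, or the sidecar
#'   value).
#' @return An `ap_trace`.
#' @export
read_trace <- function(path, cycle_length = NULL, sample_interval = NULL) {
  values <- as.numeric(readLines(path))
  if (anyNA(values)) stop(sprintf("non-numeric voltage values in %s", path))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  if (is.null(cycle_length)) cycle_length <- meta$cycle_length
  if (is.null(sample_interval)) {
    sample_interval <- if (!is.null(meta$sample_interval)) {
      meta$sample_interval
    } else {
      1
    }
  }
  ap_trace(
    values, sample_interval,
    if (is.null(cycle_length)) NA_real_ else cycle_length
  )
}
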