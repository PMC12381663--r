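# Synthetic dataset generation: pace a model with known parameters to steady
# state at one or more cycle lengths and emit data files in the same
# newline-delimited dialect consumed by the fitting tools, together with a
# truth record of the generating parameters.

#' Generate synthetic voltage datasets from a model
#'
#' Paces the model at each requested cycle length until the action potential
#' duration (measured at half of the trace maximum) stabilizes, then records
#' `n_stimuli` beats sampled at `sample_interval`.  Steady state means the
#' APD of consecutive beats changes by less than `steady_tol` ms; at cycle
#' lengths producing alternans a stable period-2 pattern (beat `k` vs beat
#' `k - 2`) is accepted instead.  If `max_beats` is reached first the trace
#' is recorded anyway with a warning.
#'
#' @param model Model name or `ap_model`.
#' @param params Generating parameter vector (defaults to model defaults).
#' @param cycle_lengths Numeric vector of pacing cycle lengths in ms.
#' @param n_stimuli Recorded beats per cycle length (default 2).
#' @param sample_interval Sampling interval in ms (default 1).
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   recorded samples (default 0, no noise).
#' @param seed Integer seed (used for the noise; generation is otherwise
#'   deterministic).
#' @param steady_tol APD convergence tolerance in ms (default 0.5).
#' @param max_beats Cap on pre-pacing beats per cycle length (default 200).
#' @param dt Euler time step in ms (default 0.02).
#' @param stimulus A [stimulus_spec()].
#' @param dir Optional directory: when given, each trace is written as
#'   `<model>_cl<CL>.txt` (newline-delimited voltages plus a JSON metadata
#'   sidecar) and a `<model>_truth.json` file records the generating
#'   parameters.
#' @return An object of class `ap_synth`: a list with `entries` (one
#'   [voltage_entry()] per cycle length), `params` (the truth), `model`,
#'   `info` (per-CL beats paced, final APDs and whether alternans was
#'   detected) and `files` (paths, when `dir` was given).
#' @examples
#' syn <- generate_dataset("MS", cycle_lengths = c(500, 400), seed = 1)
#' vapply(syn$entries, function(e) length(e$trace$values), 0)
#' @export
generate_dataset <- function(model, params = NULL, cycle_lengths,
                             n_stimuli = 2L, sample_interval = 1,
                             noise_sd = 0, seed = NULL, steady_tol = 0.5,
                             max_beats = 200L, dt = 0.02,
                             stimulus = stimulus_spec(), dir = NULL) {
  model <- ap_model(model)
  params <- .check_params(model, params)
  stopifnot(all(cycle_lengths > 0), steady_tol > 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  one_beat <- function(cl, state) {
    integrate_model(
      model, params,
      pacing_protocol(cl,
        n_stimuli = 1L, n_prerecording = 0L, dt = dt,
        sample_interval = sample_interval, stimulus = stimulus
      ),
      init = state
    )
  }
  entries <- list()
  info <- list()
  files <- character(0)
  for (cl in cycle_lengths) {
    state <- NULL
    apds <- rep(NA_real_, max_beats)
    beat <- 0L
    alternans <- FALSE
    converged <- FALSE
    repeat {
      beat <- beat + 1L
      tr <- one_beat(cl, state)
      if (!isTRUE(attr(tr, "ok"))) {
        stop(sprintf(
          "%s blew up while pacing at CL %g ms", model$name, cl
        ))
      }
      state <- attr(tr, "state")
      peak <- max(tr$values)
      # a genuine action potential must clearly exceed the stimulus artifact
      # (magnitude x duration = 0.4 for the default square pulse)
      a <- if (peak >= 0.45) measure_apds(tr, 0.5 * peak, n_expected = 1L) else numeric(0)
      if (!length(a)) {
        # beats without a measurable AP are tolerated once the model has
        # excited (e.g. the failing beat of a 2:2 alternans rhythm), but a
        # model that never excites is a configuration error
        if (beat >= 5L && !any(is.finite(apds))) {
          stop(sprintf(
            "%s does not produce an action potential at CL %g ms",
            model$name, cl
          ))
        }
        if (beat >= max_beats) break
        next
      }
      apds[beat] <- a[1]
      if (beat >= 2L && is.finite(apds[beat - 1L]) &&
        abs(apds[beat] - apds[beat - 1L]) < steady_tol) {
        converged <- TRUE
        break
      }
      if (beat >= 3L && is.finite(apds[beat - 2L]) &&
        abs(apds[beat] - apds[beat - 2L]) < steady_tol) {
        alternans <- TRUE
        converged <- TRUE
        break
      }
      if (beat >= max_beats) break
    }
    if (!converged) {
      warning(sprintf(
        "CL %g ms: APD not converged to %g ms after %d beats", cl,
        steady_tol, max_beats
      ))
    }
    # for a period-2 rhythm, start the recording on an even phase so that
    # regenerated datasets are phase-consistent
    if (alternans && beat %% 2L == 1L) {
      tr <- one_beat(cl, state)
      state <- attr(tr, "state")
      beat <- beat + 1L
    }
    rec <- integrate_model(
      model, params,
      pacing_protocol(cl,
        n_stimuli = n_stimuli, n_prerecording = 0L, dt = dt,
        sample_interval = sample_interval, stimulus = stimulus
      ),
      init = state
    )
    values <- rec$values
    if (noise_sd > 0) values <- values + stats::rnorm(length(values), 0, noise_sd)
    trace <- ap_trace(values, sample_interval, cl)
    entries[[length(entries) + 1L]] <- voltage_entry(trace, cl)
    info[[as.character(cl)]] <- list(
      beats_paced = beat, alternans = alternans, converged = converged,
      apds = measure_apds(rec, 0.5 * max(rec$values))
    )
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      path <- file.path(dir, sprintf("%s_cl%g.txt", tolower(model$name), cl))
      write_trace(trace, path)
      files <- c(files, path)
    }
  }
  truth <- list(
    model = model$name, params = as.list(params),
    cycle_lengths = cycle_lengths, n_stimuli = n_stimuli,
    sample_interval = sample_interval, noise_sd = noise_sd, seed = seed,
    steady_tol = steady_tol
  )
  if (!is.null(dir)) {
    truth_path <- file.path(dir, sprintf("%s_truth.json", tolower(model$name)))
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
    files <- c(files, truth_path)
  }
  structure(
    list(
      entries = entries, params = params, model = model$name, info = info,
      truth = truth, files = files
    ),
    class = "ap_synth"
  )
}
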