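# Data normalization, upstroke alignment, APD measurement and the weighted
# composite fitness comparing candidate traces with datasets.

#' Normalize a voltage sequence to a target range
#'
#' Affinely maps the input so its minimum is 0 and its maximum equals
#' `target_max`.  A `target_max` of 0 bypasses normalization and returns the
#' input unchanged, for data already on the model's scale.
#'
#' @param values Numeric voltage sequence (or an `ap_trace`).
#' @param target_max Desired maximum after normalization; 0 to bypass.
#' @return The normalized sequence (an `ap_trace` in, an `ap_trace` out).
#' @examples
#' normalize_trace(c(-80, -30, 20), 1)
#' @export
normalize_trace <- function(values, target_max) {
  if (inherits(values, "ap_trace")) {
    out <- values
    out$values <- normalize_trace(values$values, target_max)
    return(out)
  }
  if (!length(values)) stop("empty voltage sequence")
  if (target_max < 0) stop("target_max must be >= 0")
  if (target_max == 0) {
    return(values)
  }
  rng <- range(values)
  if (rng[2] <= rng[1]) {
    stop("cannot normalize a constant voltage sequence")
  }
  (values - rng[1]) / (rng[2] - rng[1]) * target_max
}

#' APD measurement threshold for a repolarization percentage
#'
#' The threshold is the normalized voltage at which the action potential
#' duration is measured: APD at `percent` repolarization on data normalized
#' to `target_max` uses a threshold of `(1 - percent/100) * target_max`, e.g.
#' APD90 on unit-normalized data corresponds to a threshold of 0.1.
#'
#' @param percent Repolarization percentage (e.g. 90 for APD90).
#' @param target_max Normalization maximum of the data (default 1).
#' @return The voltage threshold.
#' @examples
#' apd_threshold(90) # 0.1
#' @export
apd_threshold <- function(percent, target_max = 1) {
  stopifnot(percent > 0, percent < 100, target_max > 0)
  (1 - percent / 100) * target_max
}

#' Align a model trace with a data trace at the first upstroke
#'
#' Finds the integer sample offset such that the first upward crossings of
#' the alignment threshold in the two traces coincide.  The threshold
#' defaults to half the data trace's maximum, which is robust to baseline
#' noise at the foot of the upstroke.  The model trace is then compared with
#' the data over the overlap after shifting by the returned offset.
#'
#' @param model_trace,data_trace `ap_trace` objects sampled at the same
#'   interval (plain numeric vectors are also accepted).
#' @param threshold Alignment threshold; default `0.5 * max(data)`.
#' @return Integer sample offset (model crossing index minus data crossing
#'   index), or `NA` when the model trace never crosses the threshold
#'   (alignment failure; fitness then takes the worst-case value).
#' @export
align_upstroke <- function(model_trace, data_trace, threshold = NULL) {
  mv <- if (inherits(model_trace, "ap_trace")) model_trace$values else model_trace
  dv <- if (inherits(data_trace, "ap_trace")) data_trace$values else data_trace
  if (inherits(model_trace, "ap_trace") && inherits(data_trace, "ap_trace") &&
    !isTRUE(all.equal(model_trace$sample_interval, data_trace$sample_interval))) {
    stop("model and data traces must share the sample interval")
  }
  if (is.null(threshold)) threshold <- 0.5 * max(dv)
  cd <- .cxx_upstroke_index(matrix(dv, nrow = 1), threshold)[1]
  cm <- .cxx_upstroke_index(matrix(mv, nrow = 1), threshold)[1]
  if (cd == 0L) stop("data trace never crosses the alignment threshold")
  if (cm == 0L) {
    return(NA_integer_)
  }
  cm - cd
}

#' Measure action potential durations in a trace
#'
#' For each action potential, the duration from the upward crossing of
#' `threshold` to the next downward crossing, with crossing times linearly
#' interpolated between samples.  Returns up to `n_expected` durations; if
#' fewer complete action potentials are present the result is shorter (the
#' fitness treats missing APDs as maximal error).
#'
#' @param trace An `ap_trace` or numeric vector (sample interval 1 ms).
#' @param threshold Normalized voltage at which the duration is measured
#'   (e.g. [apd_threshold(90)][apd_threshold] for APD90).
#' @param n_expected Maximum number of APDs to return (default all).
#' @return Numeric vector of durations in ms.
#' @examples
#' tri <- ap_trace(c(0, 1, 1, 1, 0)) # 1 ms samples
#' measure_apds(tri, 0.5) # crosses 0.5 at t = 0.5 and t = 3.5
#' @export
measure_apds <- function(trace, threshold, n_expected = Inf) {
  v <- if (inherits(trace, "ap_trace")) trace$values else trace
  si <- if (inherits(trace, "ap_trace")) trace$sample_interval else 1
  stopifnot(threshold > 0)
  n <- length(v)
  if (n < 2) {
    return(numeric(0))
  }
  below <- v[-n] < threshold
  above <- v[-1] >= threshold
  ups <- which(below & above)
  downs <- which(!below & !above)
  frac_t <- function(i) (i - 1) * si + si * (threshold - v[i]) / (v[i + 1] - v[i])
  apds <- numeric(0)
  for (i in ups) {
    j <- downs[downs >= i][1]
    if (is.na(j)) break
    apds <- c(apds, frac_t(j) - frac_t(i))
    if (length(apds) >= n_expected) break
  }
  apds
}

#' Voltage dataset entry
#'
#' @param trace An `ap_trace` (or numeric vector) of the recorded voltage.
#' @param cycle_length Pacing cycle length of the recording in ms.
#' @param weight Fitting weight multiplying this dataset's error in the
#'   composite fitness (default 1).
#' @return An object of class `ap_dataset`.
#' @export
voltage_entry <- function(trace, cycle_length = NULL, weight = 1) {
  if (!inherits(trace, "ap_trace")) trace <- ap_trace(trace)
  if (is.null(cycle_length)) cycle_length <- trace$cycle_length
  if (is.na(cycle_length)) stop("cycle_length is required")
  if (!length(trace$values)) stop("voltage dataset must be non-empty")
  stopifnot(weight > 0)
  structure(
    list(
      kind = "voltage", trace = trace, cycle_length = cycle_length,
      weight = weight
    ),
    class = "ap_dataset"
  )
}

#' APD dataset entry
#'
#' @param apds Numeric vector of action potential durations in ms, one per
#'   recorded stimulus.
#' @param apd_threshold Normalized voltage at which the APDs were measured.
#' @param cycle_length Pacing cycle length in ms.
#' @param weight Fitting weight (default 1).
#' @return An object of class `ap_dataset`.
#' @export
apd_entry <- function(apds, apd_threshold, cycle_length, weight = 1) {
  stopifnot(
    length(apds) >= 1, all(is.finite(apds)), all(apds > 0),
    apd_threshold > 0, cycle_length > 0, weight > 0
  )
  structure(
    list(
      kind = "apd", apds = as.numeric(apds), apd_threshold = apd_threshold,
      cycle_length = cycle_length, weight = weight
    ),
    class = "ap_dataset"
  )
}

#' Worst-case fitness sentinel for a dataset
#'
#' A finite value guaranteed to exceed any error achievable by a valid trace
#' against this dataset, assigned when a candidate's trace is invalid (blew
#' up), never crosses the alignment threshold, or produces no overlap.  Kept
#' finite so that ordering among valid particles is preserved and the swarm
#' update remains well defined.
#'
#' @param entry An `ap_dataset`.
#' @return A positive number.
#' @export
worst_case_error <- function(entry) {
  if (entry$kind == "voltage") {
    10 * (diff(range(entry$trace$values)) + 1)^2
  } else {
    10 * length(entry$apds) * entry$cycle_length^2
  }
}

.apd_row_error <- function(values, sample_interval, entry) {
  apds <- measure_apds(
    ap_trace(values, sample_interval), entry$apd_threshold,
    n_expected = length(entry$apds)
  )
  n <- length(apds)
  err <- if (n) sum((apds - entry$apds[seq_len(n)])^2) else 0
  # each missing AP counts as maximal error, one squared cycle length
  err + (length(entry$apds) - n) * entry$cycle_length^2
}

#' Error of a model trace against one dataset
#'
#' For a voltage dataset: the model and data upstrokes are aligned
#' ([align_upstroke()]), and the sum of squared differences over the
#' overlapping samples is divided by the number of data samples.  This
#' length weighting keeps the error comparable across datasets of different
#' cycle lengths and durations; truncated overlap after shifting is
#' implicitly penalized because the divisor does not shrink.  For an APD
#' dataset: the sum of squared differences between measured and target
#' durations (no length normalization), with each missing action potential
#' contributing one squared cycle length.
#'
#' Fitting weights are not applied here; see [total_fitness()].
#'
#' @param model_trace An `ap_trace` from [integrate_model()], simulated under
#'   the entry's cycle length and stimulus counts.
#' @param entry An `ap_dataset`.
#' @return A non-negative number; the worst-case sentinel on alignment
#'   failure or an invalid trace.
#' @export
dataset_error <- function(model_trace, entry) {
  stopifnot(inherits(entry, "ap_dataset"))
  if (!inherits(model_trace, "ap_trace")) model_trace <- ap_trace(model_trace)
  if (isFALSE(attr(model_trace, "ok"))) {
    return(worst_case_error(entry))
  }
  if (entry$kind == "apd") {
    return(.apd_row_error(model_trace$values, model_trace$sample_interval, entry))
  }
  if (!isTRUE(all.equal(
    model_trace$sample_interval,
    entry$trace$sample_interval
  ))) {
    stop("model trace and dataset have different sample intervals")
  }
  off <- align_upstroke(model_trace, entry$trace)
  if (is.na(off)) {
    return(worst_case_error(entry))
  }
  err <- .cxx_voltage_error(
    matrix(model_trace$values, nrow = 1),
    entry$trace$values, as.integer(off)
  )[1]
  if (is.na(err)) worst_case_error(entry) else err
}

#' Composite weighted fitness over several datasets
#'
#' The error of each dataset is multiplied by its fitting weight and the
#' components are summed.
#'
#' @param traces List of model `ap_trace` objects, one per entry.
#' @param entries List of `ap_dataset` objects.
#' @return A non-negative number.
#' @export
total_fitness <- function(traces, entries) {
  if (inherits(traces, "ap_trace")) traces <- list(traces)
  if (inherits(entries, "ap_dataset")) entries <- list(entries)
  stopifnot(length(traces) == length(entries))
  sum(vapply(
    seq_along(entries),
    function(i) entries[[i]]$weight * dataset_error(traces[[i]], entries[[i]]),
    0
  ))
}

# Batch fitness across particles for one dataset entry.  `sim` is the P x S
# sample matrix from .sim_batch under the entry's protocol; returns a
# P-vector of unweighted dataset errors.
.batch_entry_error <- function(sim, entry, sample_interval) {
  P <- nrow(sim)
  ok <- attr(sim, "ok")
  worst <- worst_case_error(entry)
  if (entry$kind == "voltage") {
    data <- entry$trace$values
    thr <- 0.5 * max(data)
    cd <- .cxx_upstroke_index(matrix(data, nrow = 1), thr)[1]
    cm <- .cxx_upstroke_index(sim, thr)
    offs <- ifelse(cm == 0L | !ok, NA_integer_, cm - cd)
    err <- .cxx_voltage_error(sim, data, as.integer(offs))
    err[is.na(err)] <- worst
  } else {
    err <- vapply(seq_len(P), function(p) {
      if (!ok[p]) {
        return(worst)
      }
      .apd_row_error(sim[p, ], sample_interval, entry)
    }, 0)
  }
  err
}
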