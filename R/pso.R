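# Constriction-coefficient particle swarm optimization over the fittable
# model parameters, and the fitting problem container binding datasets,
# protocol settings and bounds.

#' Clerc constriction coefficient
#'
#' `chi = 2 / (phi - 2 + sqrt(phi^2 - 4 phi))` with `phi = phi1 + phi2`,
#' the damping factor of the velocity update that guarantees swarm
#' convergence for `phi > 4`.  With the default `phi1 = phi2 = 2.05`,
#' `chi` is approximately 0.73.
#'
#' @param phi1,phi2 Acceleration constants; their sum must exceed 4.
#' @return The constriction coefficient.
#' @examples
#' constriction_coefficient(2.05, 2.05)
#' @export
constriction_coefficient <- function(phi1 = 2.05, phi2 = 2.05) {
  phi <- phi1 + phi2
  if (!is.finite(phi) || phi <= 4) {
    stop("phi1 + phi2 must exceed 4 for the constriction coefficient")
  }
  2 / (phi - 2 + sqrt(phi^2 - 4 * phi))
}

#' Particle swarm hyperparameters
#'
#' @param n_particles Number of particles.
#' @param n_iterations Number of swarm update iterations (the initial swarm
#'   is evaluated as well, so a run performs `n_iterations + 1` batch
#'   evaluations).
#' @param phi1,phi2 Acceleration constants toward the personal and global
#'   best positions (defaults 2.05 each).
#' @param gamma Learning rate scaling the position update (default 0.05).
#' @param seed Integer seed for reproducible runs (optional).
#' @return An object of class `ap_pso`; the derived constriction
#'   coefficient is stored in `$chi`.
#' @export
pso_hyperparameters <- function(n_particles, n_iterations, phi1 = 2.05,
                                phi2 = 2.05, gamma = 0.05, seed = NULL) {
  stopifnot(n_particles >= 1, n_iterations >= 1, gamma > 0)
  structure(
    list(
      n_particles = as.integer(n_particles),
      n_iterations = as.integer(n_iterations),
      phi1 = phi1, phi2 = phi2,
      chi = constriction_coefficient(phi1, phi2),
      gamma = gamma, seed = seed
    ),
    class = "ap_pso"
  )
}

#' Initialize a particle swarm
#'
#' Positions are drawn uniformly within the per-parameter bounds; velocities
#' start at zero so the first move is governed purely by the best-attraction
#' terms.  Personal bests are the initial positions; their errors are filled
#' in by the first [update_swarm()] call.  Uses the current R random number
#' generator state (seed it for reproducibility).
#'
#' @param lower,upper Numeric bound vectors, one entry per fitted parameter.
#' @param hyper An [pso_hyperparameters()] object.
#' @return A swarm state list (positions, velocities, personal and global
#'   bests, iteration counter and error history).
#' @export
init_swarm <- function(lower, upper, hyper) {
  d <- length(lower)
  stopifnot(d >= 1, length(upper) == d, all(lower < upper))
  P <- hyper$n_particles
  pos <- matrix(stats::runif(P * d), P, d)
  pos <- sweep(sweep(pos, 2, upper - lower, "*"), 2, lower, "+")
  list(
    positions = pos,
    velocities = matrix(0, P, d),
    personal_bests = pos,
    personal_best_errors = rep(Inf, P),
    global_best = pos[1, ],
    global_best_error = Inf,
    iteration = 0L,
    error_history = numeric(0)
  )
}

#' Advance a particle swarm by one iteration
#'
#' Absorbs the fitness values of the current positions (updating personal
#' and global bests, with ties kept by the incumbent), then applies the
#' constriction velocity update
#' `v <- chi * (v + u(0, phi1) * (pb - p) + u(0, phi2) * (gb - p))`
#' with elementwise uniform draws, advances positions by `gamma * v`, and
#' resets every out-of-range coordinate to a uniform draw within the nearest
#' three-quarters of its range (velocities are not zeroed on reset).
#'
#' @param state Swarm state from [init_swarm()] or a previous update.
#' @param errors Fitness of each current position (length `n_particles`).
#' @param hyper An [pso_hyperparameters()] object.
#' @param lower,upper Per-parameter bounds.
#' @return The updated swarm state; `$error_history` gains the global best
#'   error after absorbing `errors`.
#' @export
update_swarm <- function(state, errors, hyper, lower, upper) {
  state <- .absorb_errors(state, errors)
  pos <- state$positions
  P <- nrow(pos)
  d <- ncol(pos)
  r1 <- matrix(stats::runif(P * d, 0, hyper$phi1), P, d)
  r2 <- matrix(stats::runif(P * d, 0, hyper$phi2), P, d)
  gb <- matrix(state$global_best, P, d, byrow = TRUE)
  vel <- hyper$chi *
    (state$velocities + r1 * (state$personal_bests - pos) + r2 * (gb - pos))
  pos <- pos + hyper$gamma * vel
  rng <- upper - lower
  below <- which(pos < matrix(lower, P, d, byrow = TRUE))
  if (length(below)) {
    j <- ((below - 1) %/% P) + 1
    pos[below] <- lower[j] + 0.75 * rng[j] * stats::runif(length(below))
  }
  above <- which(pos > matrix(upper, P, d, byrow = TRUE))
  if (length(above)) {
    j <- ((above - 1) %/% P) + 1
    pos[above] <- upper[j] - 0.75 * rng[j] * stats::runif(length(above))
  }
  state$velocities <- vel
  state$positions <- pos
  state$iteration <- state$iteration + 1L
  state
}

.absorb_errors <- function(state, errors) {
  stopifnot(length(errors) == nrow(state$positions))
  improved <- errors < state$personal_best_errors
  if (any(improved)) {
    state$personal_bests[improved, ] <- state$positions[improved, , drop = FALSE]
    state$personal_best_errors[improved] <- errors[improved]
  }
  i <- which.min(state$personal_best_errors)
  if (state$personal_best_errors[i] < state$global_best_error) {
    state$global_best <- state$personal_bests[i, ]
    state$global_best_error <- state$personal_best_errors[i]
  }
  state$error_history <- c(state$error_history, state$global_best_error)
  state
}

#' Minimize a batch fitness function with the particle swarm
#'
#' The generic swarm loop used by [run_fit()]: it evaluates the initial
#' swarm, then performs `n_iterations` update-evaluate cycles.  `fn` receives
#' a `n_particles x d` position matrix and must return one fitness value per
#' row; this batch signature is what allows all candidate simulations of an
#' iteration to be evaluated together.
#'
#' @param fn Batch fitness function (matrix in, vector out).
#' @param lower,upper Per-dimension bounds.
#' @param hyper An [pso_hyperparameters()] object; `hyper$seed`, when set,
#'   seeds the R random number generator for the whole run.
#' @return List with `par` (best position), `value` (best fitness),
#'   `error_history` (global best after the initial evaluation and after
#'   each iteration; non-increasing), and `swarm` (final swarm state).
#' @examples
#' sphere <- function(x) rowSums((x - 0.3)^2)
#' fit <- pso_minimize(sphere, c(0, 0), c(1, 1),
#'   pso_hyperparameters(50, 100, seed = 1)
#' )
#' fit$par
#' @export
pso_minimize <- function(fn, lower, upper, hyper) {
  if (!is.null(hyper$seed)) set.seed(hyper$seed)
  state <- init_swarm(lower, upper, hyper)
  for (n in seq_len(hyper$n_iterations)) {
    errors <- fn(state$positions)
    state <- update_swarm(state, errors, hyper, lower, upper)
  }
  state <- .absorb_errors(state, fn(state$positions))
  list(
    par = state$global_best,
    value = state$global_best_error,
    error_history = state$error_history,
    swarm = state
  )
}

#' Define a fitting problem
#'
#' Binds a model, one or more datasets, the shared pacing settings, and the
#' choice of which parameters to fit.  Voltage datasets are normalized here
#' (minimum 0, maximum `normalize_to`; 0 bypasses).  The stimulus counts and
#' sample interval are shared by all datasets; each dataset carries its own
#' cycle length.
#'
#' @param model Model name or `ap_model`.
#' @param entries An `ap_dataset` or list of them ([voltage_entry()],
#'   [apd_entry()]).
#' @param n_stimuli Recorded stimuli per dataset (default 2); APD datasets
#'   must list exactly this many APDs.
#' @param n_prerecording Wash-out stimuli before recording (default 2).
#' @param sample_interval Data sample interval in ms (default 1).
#' @param dt Euler time step in ms (default 0.02).
#' @param stimulus A [stimulus_spec()].
#' @param normalize_to Normalization target for voltage data; defaults to
#'   the model's `default_normalization`; 0 bypasses.
#' @param fit Character vector of parameter names to fit (default: all).
#' @param fixed Named numeric vector of values for parameters not being
#'   fitted (defaults to the model's default values).
#' @param lower,upper Named numeric vectors overriding individual default
#'   bounds.
#' @return An object of class `ap_problem`.
#' @export
fit_problem <- function(model, entries, n_stimuli = 2L, n_prerecording = 2L,
                        sample_interval = 1, dt = 0.02,
                        stimulus = stimulus_spec(), normalize_to = NULL,
                        fit = NULL, fixed = NULL, lower = NULL, upper = NULL) {
  model <- ap_model(model)
  roster <- model$parameters
  if (inherits(entries, "ap_dataset")) entries <- list(entries)
  if (!length(entries)) stop("at least one dataset entry is required")
  if (is.null(normalize_to)) normalize_to <- model$default_normalization
  entries <- lapply(entries, function(e) {
    stopifnot(inherits(e, "ap_dataset"))
    if (e$kind == "voltage") {
      e$trace <- normalize_trace(e$trace, normalize_to)
      expected <- n_stimuli * e$cycle_length / sample_interval
      if (length(e$trace$values) != expected) {
        warning(sprintf(
          "voltage dataset at CL %g has %d samples; expected %g for %d stimuli",
          e$cycle_length, length(e$trace$values), expected, n_stimuli
        ))
      }
    } else if (length(e$apds) != n_stimuli) {
      stop(sprintf(
        "APD dataset at CL %g lists %d APDs but n_stimuli is %d",
        e$cycle_length, length(e$apds), n_stimuli
      ))
    }
    e
  })
  if (is.null(fit)) fit <- roster$name
  bad <- setdiff(fit, roster$name)
  if (length(bad)) {
    stop(sprintf("unknown parameter(s) to fit: %s", paste(bad, collapse = ", ")))
  }
  if (!length(fit)) stop("at least one parameter must be fitted")
  fitted <- roster$name %in% fit
  values <- stats::setNames(roster$default, roster$name)
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), roster$name)
    if (length(bad)) {
      stop(sprintf("unknown fixed parameter(s): %s", paste(bad, collapse = ", ")))
    }
    values[names(fixed)] <- fixed
  }
  lo <- stats::setNames(roster$lower, roster$name)
  hi <- stats::setNames(roster$upper, roster$name)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if (any(lo >= hi)) stop("every lower bound must be below its upper bound")
  structure(
    list(
      model = model, entries = entries, n_stimuli = as.integer(n_stimuli),
      n_prerecording = as.integer(n_prerecording),
      sample_interval = sample_interval, dt = dt, stimulus = stimulus,
      normalize_to = normalize_to, fitted = fitted, values = values,
      lower = lo, upper = hi
    ),
    class = "ap_problem"
  )
}

.problem_protocol <- function(problem, cycle_length) {
  pacing_protocol(
    cycle_length = cycle_length, n_stimuli = problem$n_stimuli,
    n_prerecording = problem$n_prerecording, dt = problem$dt,
    sample_interval = problem$sample_interval, stimulus = problem$stimulus
  )
}

# Batch fitness closure over the fitted coordinates of a problem.
.problem_fitness <- function(problem) {
  model <- problem$model
  d_full <- length(problem$values)
  fitted <- problem$fitted
  protos <- lapply(
    problem$entries,
    function(e) .problem_protocol(problem, e$cycle_length)
  )
  function(pos) {
    P <- nrow(pos)
    full <- matrix(problem$values, P, d_full, byrow = TRUE)
    full[, fitted] <- pos
    total <- numeric(P)
    for (i in seq_along(problem$entries)) {
      sim <- .sim_batch(model, full, protos[[i]])
      total <- total + problem$entries[[i]]$weight *
        .batch_entry_error(sim, problem$entries[[i]], problem$sample_interval)
    }
    total
  }
}

#' Fit a model to data with the particle swarm
#'
#' Runs the constriction-coefficient PSO over the problem's fitted
#' parameters: the swarm is initialized uniformly within bounds, and each
#' iteration simulates every particle under every dataset's pacing protocol
#' (batch forward Euler), evaluates the weighted composite fitness, and
#' applies the velocity/position update.  Re-running with the same seed
#' reproduces the result exactly.
#'
#' @param problem An [fit_problem()].
#' @param hyper An [pso_hyperparameters()].
#' @return An object of class `ap_fit`: `best_params` (full named parameter
#'   vector), `best_error`, `error_history`, `traces` (best-fit model trace
#'   per dataset), plus the problem and hyperparameters.
#' @export
run_fit <- function(problem, hyper) {
  stopifnot(inherits(problem, "ap_problem"), inherits(hyper, "ap_pso"))
  fn <- .problem_fitness(problem)
  res <- pso_minimize(
    fn, problem$lower[problem$fitted], problem$upper[problem$fitted], hyper
  )
  best <- problem$values
  best[problem$fitted] <- res$par
  traces <- lapply(problem$entries, function(e) {
    integrate_model(problem$model, best, .problem_protocol(problem, e$cycle_length))
  })
  structure(
    list(
      best_params = best, best_error = res$value,
      error_history = res$error_history, traces = traces,
      problem = problem, hyper = hyper, seed = hyper$seed
    ),
    class = "ap_fit"
  )
}

#' @export
print.ap_fit <- function(x, ...) {
  cat(sprintf(
    "<ap_fit %s: %d datasets, best error %.6g after %d iterations>\n",
    x$problem$model$name, length(x$problem$entries), x$best_error,
    length(x$error_history) - 1L
  ))
  fitted <- x$problem$fitted
  p <- x$best_params
  cat("  fitted parameters (3 significant digits):\n")
  for (nm in names(p)[fitted]) {
    cat(sprintf("    %-14s %s\n", nm, signif(p[[nm]], 3)))
  }
  if (any(!fitted)) {
    cat(
      "  fixed:",
      paste(sprintf("%s=%g", names(p)[!fitted], p[!fitted]), collapse = ", "),
      "\n"
    )
  }
  invisible(x)
}

#' Normalized RMS voltage error of a fit
#'
#' The root mean squared difference between the best-fit traces and the
#' voltage datasets, pooled over all voltage entries (APD entries are
#' ignored), on the normalized voltage scale.
#'
#' @param fit An `ap_fit`.
#' @return A non-negative number, or `NA` if there are no voltage entries.
#' @export
fit_rms <- function(fit) {
  sse <- 0
  n <- 0
  for (i in seq_along(fit$problem$entries)) {
    e <- fit$problem$entries[[i]]
    if (e$kind != "voltage") next
    ni <- length(e$trace$values)
    sse <- sse + dataset_error(fit$traces[[i]], e) * ni
    n <- n + ni
  }
  if (n == 0) {
    return(NA_real_)
  }
  sqrt(sse / n)
}

#' Save the full-precision results of a fit
#'
#' Writes the run details as JSON (model, bounds, fixed parameters,
#' hyperparameters, seed, per-iteration global best error and the best
#' parameters at full precision) and, optionally, the best parameters as a
#' two-column CSV.
#'
#' @param fit An `ap_fit`.
#' @param path Output JSON path.
#' @param csv Optional path for the parameter CSV.
#' @return `path`, invisibly.
#' @export
save_run_details <- function(fit, path, csv = NULL) {
  problem <- fit$problem
  details <- list(
    model = problem$model$name,
    n_stimuli = problem$n_stimuli,
    n_prerecording = problem$n_prerecording,
    sample_interval = problem$sample_interval,
    dt = problem$dt,
    stimulus = unclass(problem$stimulus),
    normalize_to = problem$normalize_to,
    datasets = lapply(problem$entries, function(e) {
      if (e$kind == "voltage") {
        list(
          kind = "voltage", cycle_length = e$cycle_length,
          n_samples = length(e$trace$values), weight = e$weight
        )
      } else {
        list(
          kind = "apd", cycle_length = e$cycle_length, apds = e$apds,
          apd_threshold = e$apd_threshold, weight = e$weight
        )
      }
    }),
    fitted = names(fit$best_params)[problem$fitted],
    fixed = as.list(fit$best_params[!problem$fitted]),
    lower = as.list(problem$lower),
    upper = as.list(problem$upper),
    hyperparameters = list(
      n_particles = fit$hyper$n_particles,
      n_iterations = fit$hyper$n_iterations,
      phi1 = fit$hyper$phi1, phi2 = fit$hyper$phi2, chi = fit$hyper$chi,
      gamma = fit$hyper$gamma
    ),
    seed = fit$seed,
    best_error = fit$best_error,
    error_history = fit$error_history,
    best_params = as.list(fit$best_params)
  )
  jsonlite::write_json(details, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv)) {
    utils::write.csv(
      data.frame(parameter = names(fit$best_params), value = fit$best_params),
      csv,
      row.names = FALSE
    )
  }
  invisible(path)
}
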