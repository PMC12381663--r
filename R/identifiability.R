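# Repeated independent fits and identifiability statistics: normalized
# parameter distributions, standard-deviation comparisons across dataset
# configurations, and per-parameter two-sample tests.

#' Map parameter values to and from their normalized unit range
#'
#' Affine map of each value from `[lower, upper]` to `[0, 1]`; presenting
#' fitted parameters normalized over their bounds makes spreads comparable
#' across parameters of very different magnitudes.
#'
#' @param values Numeric vector or matrix (columns = parameters).
#' @param lower,upper Bounds (recycled across columns for matrices).
#' @return Object of the same shape on the normalized scale.
#' @export
normalize_parameters <- function(values, lower, upper) {
  stopifnot(all(lower < upper))
  if (is.matrix(values)) {
    sweep(sweep(values, 2, lower, "-"), 2, upper - lower, "/")
  } else {
    (values - lower) / (upper - lower)
  }
}

#' @rdname normalize_parameters
#' @export
denormalize_parameters <- function(values, lower, upper) {
  stopifnot(all(lower < upper))
  if (is.matrix(values)) {
    sweep(sweep(values, 2, upper - lower, "*"), 2, lower, "+")
  } else {
    values * (upper - lower) + lower
  }
}

#' Repeated independent fits of one problem
#'
#' Runs [run_fit()] `R` times with seeds `base_seed`, `base_seed + 1`, ...,
#' collecting the best parameter vector and error of every run.  The spread
#' of each parameter across runs measures how well the data constrain it
#' (identifiability); parameters are also reported normalized over their
#' bounds.  A failed run is recorded and skipped as long as at least two
#' runs succeed.
#'
#' @param problem An [fit_problem()].
#' @param hyper An [pso_hyperparameters()]; its seed field is overridden
#'   per run.
#' @param R Number of runs (at least 2 for standard deviations).
#' @param base_seed First seed.
#' @param truth Optional named vector of generating parameter values, stored
#'   for downstream comparison.
#' @return An object of class `ap_repeated_fits`: `params` (R x d matrix of
#'   fitted values), `normalized`, `errors`, `seeds`, `lower`, `upper`,
#'   `fitted_names`, `truth` and `failures`.
#' @export
repeated_fits <- function(problem, hyper, R, base_seed = 1L, truth = NULL) {
  stopifnot(R >= 1)
  seeds <- base_seed + seq_len(R) - 1L
  fits <- vector("list", R)
  failures <- character(0)
  for (i in seq_len(R)) {
    hyper$seed <- seeds[i]
    fits[[i]] <- tryCatch(run_fit(problem, hyper), error = function(e) e)
    if (inherits(fits[[i]], "error")) {
      failures <- c(failures, sprintf(
        "seed %d: %s", seeds[i],
        conditionMessage(fits[[i]])
      ))
    }
  }
  keep <- !vapply(fits, inherits, TRUE, "error")
  if (sum(keep) < min(2L, R)) {
    stop(paste(c("too many failed runs:", failures), collapse = "\n  "))
  }
  fitted_names <- names(problem$values)[problem$fitted]
  params <- do.call(rbind, lapply(fits[keep], function(f) {
    f$best_params[problem$fitted]
  }))
  rownames(params) <- paste0("seed", seeds[keep])
  lo <- problem$lower[problem$fitted]
  hi <- problem$upper[problem$fitted]
  if (R == 1L) {
    warning("single run: standard deviations are undefined")
  }
  structure(
    list(
      params = params,
      normalized = normalize_parameters(params, lo, hi),
      errors = vapply(fits[keep], `[[`, 0, "best_error"),
      rms = vapply(fits[keep], fit_rms, 0),
      seeds = seeds[keep],
      lower = lo, upper = hi, fitted_names = fitted_names,
      model = problem$model$name,
      truth = truth, failures = failures
    ),
    class = "ap_repeated_fits"
  )
}

#' @export
print.ap_repeated_fits <- function(x, ...) {
  cat(sprintf(
    "<ap_repeated_fits %s: %d runs x %d parameters, best error %.4g>\n",
    x$model, nrow(x$params), ncol(x$params), min(x$errors)
  ))
  print(summary(x))
  invisible(x)
}

#' @export
summary.ap_repeated_fits <- function(object, ...) {
  p <- object$params
  out <- data.frame(
    parameter = object$fitted_names,
    mean = colMeans(p),
    sd = apply(p, 2, stats::sd),
    median = apply(p, 2, stats::median),
    norm_mean = colMeans(object$normalized),
    norm_sd = apply(object$normalized, 2, stats::sd),
    row.names = NULL
  )
  if (!is.null(object$truth)) {
    out$truth <- as.numeric(object$truth[object$fitted_names])
  }
  out
}

#' Export per-run fitted parameters as CSV
#'
#' Long format (run, seed, parameter, value, normalized value, error),
#' suitable for violin plots of parameter distributions.
#'
#' @param x An `ap_repeated_fits`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_repeated_fits <- function(x, path) {
  R <- nrow(x$params)
  d <- ncol(x$params)
  long <- data.frame(
    run = rep(seq_len(R), d),
    seed = rep(x$seeds, d),
    parameter = rep(x$fitted_names, each = R),
    value = as.vector(x$params),
    normalized = as.vector(x$normalized),
    error = rep(x$errors, d)
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

.match_rosters <- function(a, b) {
  if (!identical(a$fitted_names, b$fitted_names)) {
    stop("the two repeated-fit results have different parameter rosters")
  }
}

#' Count parameters whose spread shrank between two configurations
#'
#' Compares the per-parameter standard deviation of fitted values between
#' two repeated-fit results (e.g. fits to a single cycle length versus fits
#' to several) and counts how many parameters have a strictly smaller
#' standard deviation in the second.
#'
#' @param a,b `ap_repeated_fits` objects over the same model and roster.
#' @return Integer count.
#' @export
sd_reduction_count <- function(a, b) {
  .match_rosters(a, b)
  sd_a <- apply(a$params, 2, stats::sd)
  sd_b <- apply(b$params, 2, stats::sd)
  sum(sd_b < sd_a)
}

#' Per-parameter two-sample tests between two repeated-fit results
#'
#' For each fitted parameter, a two-sample t-test on the raw (unnormalized)
#' best values of the two run ensembles, with a three-way verdict:
#' `different` for p below `alpha_strict`, `borderline` for p between
#' `alpha_strict` and `alpha_loose`, otherwise `not_different`.  The strict
#' default of 0.001 compensates for the many parameters and comparisons
#' involved; no further multiplicity correction is applied.  Welch's
#' unequal-variance form is the default; set `var_equal = TRUE` for the
#' pooled-variance test.  When both groups are constant and equal the
#' verdict is `not_different` by convention.
#'
#' @param a,b `ap_repeated_fits` objects over the same roster.
#' @param alpha_strict,alpha_loose Significance bands (defaults 0.001, 0.01).
#' @param var_equal Use the pooled-variance t-test (default `FALSE`, Welch).
#' @return Data frame with columns `parameter`, `mean_a`, `mean_b`,
#'   `p_value`, `verdict`.
#' @export
pairwise_parameter_tests <- function(a, b, alpha_strict = 0.001,
                                     alpha_loose = 0.01, var_equal = FALSE) {
  .match_rosters(a, b)
  stopifnot(alpha_strict < alpha_loose)
  d <- ncol(a$params)
  p_value <- numeric(d)
  for (j in seq_len(d)) {
    xa <- a$params[, j]
    xb <- b$params[, j]
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      p_value[j] <- if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0
    } else {
      p_value[j] <- stats::t.test(xa, xb, var.equal = var_equal)$p.value
    }
  }
  verdict <- ifelse(
    p_value < alpha_strict, "different",
    ifelse(p_value < alpha_loose, "borderline", "not_different")
  )
  data.frame(
    parameter = a$fitted_names,
    mean_a = colMeans(a$params),
    mean_b = colMeans(b$params),
    p_value = p_value,
    verdict = verdict,
    row.names = NULL
  )
}
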