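# Model registry: the phenomenological action potential models, their
# canonical parameter rosters, defaults and default fitting bounds.

.model_ids <- c(MS = 0L, MMS = 1L, MFHN = 2L, FK = 3L, BOCF = 4L, BBOCF = 5L)

.roster <- function(...) {
  rows <- list(...)
  out <- data.frame(
    name = vapply(rows, `[[`, "", 1L),
    default = as.numeric(vapply(rows, `[[`, "", 2L)),
    lower = as.numeric(vapply(rows, `[[`, "", 3L)),
    upper = as.numeric(vapply(rows, `[[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  out
}

.r <- function(name, default, lower, upper) c(name, default, lower, upper)

.model_registry <- local({
  ms <- .roster(
    .r("tau_in", 0.3, 0.05, 1),
    .r("tau_out", 6, 1, 30),
    .r("tau_open", 100, 50, 400),
    .r("tau_close", 120, 50, 400),
    .r("v_gate", 0.13, 0.05, 0.4)
  )
  mfhn <- .roster(
    .r("a", 0.13, 0.05, 0.4),
    .r("b", 0.013, 0.002, 0.05),
    .r("c1", 0.26, 0.05, 1),
    .r("c2", 0.1, 0.02, 0.5),
    .r("d", 1, 0.2, 3)
  )
  fk <- .roster(
    .r("tau_d", 0.25, 0.05, 1),
    .r("tau_r", 33, 5, 100),
    .r("tau_si", 30, 5, 100),
    .r("tau_0", 12.5, 1, 50),
    .r("tau_v_plus", 3.33, 1, 50),
    .r("tau_v1_minus", 1250, 100, 2000),
    .r("tau_v2_minus", 19.6, 5, 100),
    .r("tau_w_plus", 870, 100, 2000),
    .r("tau_w_minus", 41, 5, 300),
    .r("u_c", 0.13, 0.05, 0.5),
    .r("u_v", 0.04, 0.005, 0.2),
    .r("u_csi", 0.85, 0.2, 0.95),
    .r("k", 10, 1, 30)
  )
  bocf_head <- list(
    .r("u_u", 1.55, 1, 2),
    .r("theta_v", 0.3, 0.1, 0.5),
    .r("theta_w", 0.13, 0.05, 0.5),
    .r("theta_v_minus", 0.006, 0.001, 0.3),
    .r("theta_o", 0.006, 0.001, 0.3),
    .r("tau_v1_minus", 60, 10, 300),
    .r("tau_v2_minus", 1150, 100, 2000),
    .r("tau_v_plus", 1.4506, 0.5, 10),
    .r("tau_w1_minus", 60, 10, 300),
    .r("tau_w2_minus", 15, 3, 300),
    .r("k_w_minus", 65, 10, 200),
    .r("u_w_minus", 0.03, 0.005, 0.2)
  )
  bocf_tail <- list(
    .r("tau_fi", 0.11, 0.02, 0.5),
    .r("tau_o1", 400, 50, 600),
    .r("tau_o2", 6, 1, 50),
    .r("tau_so1", 30.0181, 5, 100),
    .r("tau_so2", 0.9957, 0.1, 10),
    .r("k_so", 2.0458, 0.5, 10),
    .r("u_so", 0.65, 0.2, 0.95),
    .r("tau_s1", 2.7342, 0.5, 20),
    .r("tau_s2", 16, 1, 100),
    .r("k_s", 2.0994, 0.5, 10),
    .r("u_s", 0.9087, 0.2, 1.5)
  )
  bocf <- do.call(.roster, c(
    bocf_head,
    list(.r("tau_w_plus", 200, 50, 1000)),
    bocf_tail,
    list(
      .r("tau_si", 1.8875, 0.5, 20),
      .r("tau_w_inf", 0.07, 0.01, 0.5),
      .r("w_inf_star", 0.94, 0.5, 1)
    )
  ))
  bbocf <- do.call(.roster, c(
    bocf_head,
    list(
      .r("tau_w1_plus", 200, 50, 1000),
      .r("tau_w2_plus", 200, 50, 1000),
      .r("k_w_plus", 8, 0.5, 50),
      .r("u_w_plus", 0.13, 0.01, 0.5)
    ),
    bocf_tail,
    list(
      .r("tau_si1", 1.8875, 0.5, 20),
      .r("tau_si2", 1.8875, 0.5, 20),
      .r("k_si", 10, 0.5, 50),
      .r("s_c", 0.5, 0.05, 0.95),
      .r("tau_w_inf", 0.07, 0.01, 0.5),
      .r("w_inf_star", 0.94, 0.5, 1)
    )
  ))
  list(
    MS = list(
      name = "MS", state_dim = 2L, parameters = ms,
      default_normalization = 1,
      states = c("u", "h"),
      description = "Mitchell-Schaeffer two-variable model"
    ),
    MMS = list(
      name = "MMS", state_dim = 2L, parameters = ms,
      default_normalization = 1,
      states = c("u", "h"),
      description = "modified Mitchell-Schaeffer two-variable model"
    ),
    MFHN = list(
      name = "MFHN", state_dim = 2L, parameters = mfhn,
      default_normalization = 1,
      states = c("u", "v"),
      description = "modified FitzHugh-Nagumo two-variable model"
    ),
    FK = list(
      name = "FK", state_dim = 3L, parameters = fk,
      default_normalization = 1,
      states = c("u", "v", "w"),
      description = "Fenton-Karma three-current model"
    ),
    BOCF = list(
      name = "BOCF", state_dim = 4L, parameters = bocf,
      default_normalization = 1.35,
      states = c("u", "v", "w", "s"),
      description = "Bueno-Orovio-Cherry-Fenton minimal model"
    ),
    BBOCF = list(
      name = "BBOCF", state_dim = 4L, parameters = bbocf,
      default_normalization = 1.35,
      states = c("u", "v", "w", "s"),
      description = "Brugada-phenotype variant of the minimal model"
    )
  )
})

#' Available cardiac action potential models
#'
#' @return Character vector of model names understood by [ap_model()].
#' @export
ap_models <- function() names(.model_registry)

#' Look up a cardiac action potential model
#'
#' Returns the model specification: state dimension, canonical parameter
#' roster (name, default, lower bound, upper bound), resting state and the
#' default normalization constant applied to data fitted against the model.
#' Model names are matched case-insensitively.
#'
#' The available models are the Mitchell-Schaeffer (`"MS"`, 5 parameters),
#' modified Mitchell-Schaeffer (`"MMS"`, 5), modified FitzHugh-Nagumo
#' (`"MFHN"`, 5), Fenton-Karma (`"FK"`, 13), Bueno-Orovio-Cherry-Fenton
#' minimal (`"BOCF"`, 27) and Brugada-variant minimal (`"BBOCF"`, 33)
#' models.  All describe a dimensionless voltage `u` driven by a total
#' membrane current plus an external stimulus, with one to three auxiliary
#' gating variables.
#'
#' @param model Model name (string, case-insensitive), or an `ap_model`
#'   object which is returned unchanged.
#' @return An object of class `ap_model`.
#' @examples
#' m <- ap_model("MS")
#' list_parameters(m)
#' @export
ap_model <- function(model) {
  if (inherits(model, "ap_model")) {
    return(model)
  }
  if (!is.character(model) || length(model) != 1L) {
    stop("`model` must be a single model name or an ap_model object")
  }
  key <- toupper(model)
  if (!key %in% names(.model_registry)) {
    stop(sprintf(
      "unknown model '%s'; available models: %s",
      model, paste(names(.model_registry), collapse = ", ")
    ))
  }
  spec <- .model_registry[[key]]
  structure(spec, class = "ap_model")
}

#' @export
print.ap_model <- function(x, ...) {
  cat(sprintf(
    "<ap_model %s: %s>\n  %d state variables (%s), %d parameters\n  default normalization: %g\n",
    x$name, x$description, x$state_dim,
    paste(x$states, collapse = ", "),
    nrow(x$parameters), x$default_normalization
  ))
  invisible(x)
}

#' Parameter roster of a model
#'
#' @param model Model name or `ap_model`.
#' @return A data frame with columns `name`, `default`, `lower`, `upper`, in
#'   the model's canonical (stable) parameter order.
#' @export
list_parameters <- function(model) {
  ap_model(model)$parameters
}

#' Default parameter vector of a model
#'
#' @param model Model name or `ap_model`.
#' @return Named numeric vector of default parameter values.
#' @export
default_params <- function(model) {
  p <- ap_model(model)$parameters
  stats::setNames(p$default, p$name)
}

#' Export a model's parameter roster
#'
#' Writes the roster (name, default, lower, upper) as CSV or JSON for use by
#' external tools.
#'
#' @param model Model name or `ap_model`.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; defaults to the file extension.
#' @return `path`, invisibly.
#' @export
export_parameters <- function(model, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  roster <- list_parameters(model)
  if (format == "csv") {
    utils::write.csv(roster, path, row.names = FALSE)
  } else {
    jsonlite::write_json(roster, path, dataframe = "rows", digits = NA)
  }
  invisible(path)
}

.check_params <- function(model, params) {
  model <- ap_model(model)
  roster <- model$parameters
  if (is.null(params)) {
    return(stats::setNames(roster$default, roster$name))
  }
  if (!is.numeric(params)) stop("`params` must be numeric")
  if (!is.null(names(params)) && all(nzchar(names(params)))) {
    missing <- setdiff(roster$name, names(params))
    if (length(missing)) {
      full <- stats::setNames(roster$default, roster$name)
      full[names(params)[names(params) %in% roster$name]] <-
        params[names(params) %in% roster$name]
      extra <- setdiff(names(params), roster$name)
      if (length(extra)) {
        stop(sprintf(
          "unknown parameter(s) for %s: %s", model$name,
          paste(extra, collapse = ", ")
        ))
      }
      params <- full
    } else {
      params <- params[roster$name]
    }
  } else if (length(params) != nrow(roster)) {
    stop(sprintf(
      "%s expects %d parameters, got %d", model$name, nrow(roster),
      length(params)
    ))
  } else {
    params <- stats::setNames(as.numeric(params), roster$name)
  }
  if (anyNA(params)) stop("parameter vector contains NA")
  params
}

#' Resting equilibrium state of a model
#'
#' The analytic resting state with the voltage at zero and every gate at its
#' zero-voltage steady state.  For the minimal (BOCF-family) models the gate
#' `s` rests at its sigmoidal steady state evaluated at `u = 0`, which depends
#' on `k_s` and `u_s`.
#'
#' @param model Model name or `ap_model`.
#' @param params Optional parameter vector (defaults to the model defaults).
#' @return Named numeric vector of length `state_dim`.
#' @export
rest_state <- function(model, params = NULL) {
  model <- ap_model(model)
  params <- .check_params(model, params)
  out <- switch(model$name,
    MS = ,
    MMS = c(u = 0, h = 1),
    MFHN = c(u = 0, v = 0),
    FK = {
      # the tanh tail of the slow inward current leaves a tiny residual at
      # u = 0, balanced by the outward current at a slightly positive u;
      # a few fixed-point sweeps give the equilibrium to machine precision
      u_r <- 0
      for (i in 1:4) {
        u_r <- params[["tau_0"]] *
          (1 + tanh(params[["k"]] * (u_r - params[["u_csi"]]))) /
          (2 * params[["tau_si"]])
      }
      c(u = u_r, v = 1, w = 1)
    },
    BOCF = ,
    BBOCF = c(
      u = 0, v = 1, w = 1,
      s = (1 + tanh(-params[["k_s"]] * params[["u_s"]])) / 2
    )
  )
  out
}

#' Right-hand side of a model's differential equations
#'
#' Evaluates the time derivative of every state variable at the given state,
#' parameters and stimulus current.  The voltage derivative is the total
#' membrane current plus the stimulus.  This reference implementation in R is
#' intended for inspection, testing and use with general-purpose ODE solvers;
#' pacing simulations use the compiled batch integrator in
#' [integrate_model()].
#'
#' Regime conventions: a regime gated at a threshold applies from the
#' threshold upwards (`u >= threshold`).  In the FK model the v-gate recovery
#' time constant is `tau_v1_minus` for `u >= u_v` and `tau_v2_minus` below;
#' in the BOCF-family models the v-gate recovery constant is `tau_v2_minus`
#' for `u >= theta_v_minus` and `tau_v1_minus` below.
#'
#' @param model Model name or `ap_model`.
#' @param state Numeric state vector of length `state_dim`.
#' @param params Parameter vector (defaults to the model defaults).
#' @param i_stim Stimulus current in 1/ms (default 0).
#' @return Named numeric vector of state derivatives (1/ms).
#' @export
model_rhs <- function(model, state, params = NULL, i_stim = 0) {
  model <- ap_model(model)
  p <- as.list(.check_params(model, params))
  if (length(state) != model$state_dim) {
    stop(sprintf(
      "%s has %d state variables, got state of length %d",
      model$name, model$state_dim, length(state)
    ))
  }
  state <- as.numeric(state)
  u <- state[1]
  out <- switch(model$name,
    MS = {
      h <- state[2]
      du <- h * u^2 * (1 - u) / p$tau_in - u / p$tau_out + i_stim
      dh <- if (u < p$v_gate) (1 - h) / p$tau_open else -h / p$tau_close
      c(du, dh)
    },
    MMS = {
      h <- state[2]
      du <- h * u * (u - p$v_gate) * (1 - u) / p$tau_in -
        (1 - h) * u / p$tau_out + i_stim
      dh <- if (u < p$v_gate) (1 - h) / p$tau_open else -h / p$tau_close
      c(du, dh)
    },
    MFHN = {
      v <- state[2]
      du <- p$c1 * u * (u - p$a) * (1 - u) - p$c2 * u * v + i_stim
      dv <- p$b * (u - p$d * v)
      c(du, dv)
    },
    FK = {
      v <- state[2]
      w <- state[3]
      pg <- u >= p$u_c
      tau_v_minus <- if (u >= p$u_v) p$tau_v1_minus else p$tau_v2_minus
      j_fi <- if (pg) -v * (1 - u) * (u - p$u_c) / p$tau_d else 0
      j_so <- if (pg) 1 / p$tau_r else u / p$tau_0
      j_si <- -w * (1 + tanh(p$k * (u - p$u_csi))) / (2 * p$tau_si)
      du <- -(j_fi + j_so + j_si) + i_stim
      dv <- if (pg) -v / p$tau_v_plus else (1 - v) / tau_v_minus
      dw <- if (pg) -w / p$tau_w_plus else (1 - w) / p$tau_w_minus
      c(du, dv, dw)
    },
    BOCF = ,
    BBOCF = {
      v <- state[2]
      w <- state[3]
      s <- state[4]
      hv <- u >= p$theta_v
      hw <- u >= p$theta_w
      ho <- u >= p$theta_o
      tau_v_minus <- if (u >= p$theta_v_minus) p$tau_v2_minus else p$tau_v1_minus
      tau_w_minus <- p$tau_w1_minus + (p$tau_w2_minus - p$tau_w1_minus) *
        (1 + tanh(p$k_w_minus * (u - p$u_w_minus))) / 2
      tau_so <- p$tau_so1 + (p$tau_so2 - p$tau_so1) *
        (1 + tanh(p$k_so * (u - p$u_so))) / 2
      tau_s <- if (hw) p$tau_s2 else p$tau_s1
      tau_o <- if (ho) p$tau_o2 else p$tau_o1
      v_inf <- if (u < p$theta_v_minus) 1 else 0
      w_inf <- if (ho) p$w_inf_star else 1 - u / p$tau_w_inf
      if (model$name == "BBOCF") {
        tau_w_plus <- p$tau_w1_plus + (p$tau_w2_plus - p$tau_w1_plus) *
          (1 + tanh(p$k_w_plus * (u - p$u_w_plus))) / 2
        tau_si <- p$tau_si1 + (p$tau_si2 - p$tau_si1) *
          (1 + tanh(p$k_si * (s - p$s_c))) / 2
      } else {
        tau_w_plus <- p$tau_w_plus
        tau_si <- p$tau_si
      }
      j_fi <- if (hv) -v * (u - p$theta_v) * (p$u_u - u) / p$tau_fi else 0
      j_so <- if (hw) 1 / tau_so else u / tau_o
      j_si <- if (hw) -w * s / tau_si else 0
      du <- -(j_fi + j_so + j_si) + i_stim
      dv <- if (hv) -v / p$tau_v_plus else (v_inf - v) / tau_v_minus
      dw <- if (hw) -w / tau_w_plus else (w_inf - w) / tau_w_minus
      ds <- ((1 + tanh(p$k_s * (u - p$u_s))) / 2 - s) / tau_s
      c(du, dv, dw, ds)
    }
  )
  stats::setNames(out, model$states)
}
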