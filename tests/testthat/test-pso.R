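test_that("the constriction coefficient follows the closed form", {
  chi <- constriction_coefficient(2.05, 2.05)
  expect_equal(chi, 2 / (4.1 - 2 + sqrt(4.1^2 - 4 * 4.1)), tolerance = 1e-15)
  expect_equal(round(chi, 2), 0.73)
  expect_equal(constriction_coefficient(3, 3), 2 / (4 + sqrt(12)), tolerance = 1e-15)
  # chi -> 1 as phi -> 4 from above
  expect_equal(constriction_coefficient(2, 2 + 1e-10), 1, tolerance = 1e-4)
  expect_error(constriction_coefficient(2, 2), "exceed 4")
  expect_error(constriction_coefficient(1, 2), "exceed 4")
})

test_that("swarm initialization is uniform within bounds and seed-reproducible", {
  hyper <- pso_hyperparameters(200, 10)
  lower <- c(0, -5, 100)
  upper <- c(1, 5, 400)
  for (seed in 1:3) {
    set.seed(seed)
    s <- init_swarm(lower, upper, hyper)
    expect_true(all(sweep(s$positions, 2, lower, ">=")))
    expect_true(all(sweep(s$positions, 2, upper, "<=")))
    expect_true(all(s$velocities == 0))
  }
  set.seed(9)
  a <- init_swarm(lower, upper, hyper)
  set.seed(9)
  b <- init_swarm(lower, upper, hyper)
  expect_identical(a, b)
  # degenerate range collapses to the lower bound
  set.seed(1)
  s <- init_swarm(c(2, 2), c(2 + 1e-9, 3), pso_hyperparameters(50, 1))
  expect_true(all(abs(s$positions[, 1] - 2) <= 1e-9))
  expect_error(init_swarm(c(1), c(1), hyper), "lower < upper")
})

test_that("a particle at the global best with zero velocity is a fixed point", {
  hyper <- pso_hyperparameters(1, 5)
  set.seed(1)
  state <- init_swarm(c(0, 0), c(1, 1), hyper)
  p0 <- state$positions
  state <- update_swarm(state, errors = 0.5, hyper, c(0, 0), c(1, 1))
  expect_identical(state$positions, p0)
  expect_true(all(state$velocities == 0))
  expect_equal(state$global_best, as.numeric(p0))
})

test_that("out-of-range coordinates reset uniformly into the nearest three-quarters", {
  hyper <- pso_hyperparameters(500, 1)
  run_once <- function(vel) {
    set.seed(sample.int(1e6, 1))
    state <- init_swarm(0, 1, hyper)
    state$personal_bests <- state$positions
    state$velocities <- matrix(vel, 500, 1)
    state <- update_swarm(state, errors = rep(1, 500), hyper, 0, 1)
    state$positions[, 1]
  }
  set.seed(42)
  below <- run_once(-1000) # every particle shoots far below 0
  expect_true(all(below >= 0 & below <= 0.75))
  expect_lt(min(below), 0.1) # draws actually spread over [0, 0.75]
  expect_gt(max(below), 0.65)
  above <- run_once(1000)
  expect_true(all(above >= 0.25 & above <= 1))
  expect_lt(min(above), 0.35)
  expect_gt(max(above), 0.9)
})

test_that("the global best error is non-increasing and positions stay in bounds", {
  # a rugged multimodal toy keeps the swarm moving for many iterations
  rugged <- function(x) rowSums((x - 0.37)^2) + 0.05 * rowSums(sin(40 * x)^2)
  hyper <- pso_hyperparameters(30, 60, seed = 4)
  set.seed(4)
  lower <- rep(0, 3)
  upper <- rep(1, 3)
  state <- init_swarm(lower, upper, hyper)
  best <- Inf
  for (i in 1:60) {
    state <- update_swarm(state, rugged(state$positions), hyper, lower, upper)
    expect_true(all(sweep(state$positions, 2, lower, ">=")))
    expect_true(all(sweep(state$positions, 2, upper, "<=")))
    expect_lte(state$global_best_error, best)
    best <- state$global_best_error
  }
  expect_true(!is.unsorted(rev(state$error_history)))
})

test_that("a single particle for a single iteration reports its evaluated position", {
  sphere <- function(x) rowSums((x - 0.5)^2)
  res <- pso_minimize(sphere, c(0, 0), c(1, 1), pso_hyperparameters(1, 1, seed = 2))
  expect_length(res$par, 2)
  expect_equal(res$value, sphere(matrix(res$par, 1)))
  expect_length(res$error_history, 2)
})

test_that("the swarm converges to a known quadratic minimum", {
  target <- c(0.3, 0.6, 0.45)
  sphere <- function(x) rowSums(sweep(x, 2, target)^2)
  res <- pso_minimize(sphere, rep(0, 3), rep(1, 3), pso_hyperparameters(64, 200, seed = 7))
  expect_lt(max(abs(res$par - target)), 1e-3)
  expect_lt(max(abs(colMeans(res$swarm$positions) - target)), 1e-3)
})

test_that("identical seeds reproduce a model fit exactly", {
  problem <- tiny_ms_problem()
  hyper <- pso_hyperparameters(32, 5, seed = 13)
  f1 <- run_fit(problem, hyper)
  f2 <- run_fit(problem, hyper)
  expect_identical(f1$best_params, f2$best_params)
  expect_identical(f1$error_history, f2$error_history)
  f3 <- run_fit(problem, pso_hyperparameters(32, 5, seed = 14))
  expect_false(identical(f1$best_params, f3$best_params))
})

test_that("fitting problems validate their configuration", {
  syn <- generate_dataset("MS", cycle_lengths = 300, n_stimuli = 1)
  expect_error(
    fit_problem("MS", syn$entries, n_stimuli = 1, fit = character(0)),
    "at least one parameter"
  )
  expect_error(
    fit_problem("MS", syn$entries, n_stimuli = 1, fit = "tau_bogus"),
    "unknown parameter"
  )
  expect_error(
    fit_problem("MS", list(apd_entry(c(200, 190), 0.1, 300)), n_stimuli = 1),
    "n_stimuli"
  )
  p <- fit_problem("MS", syn$entries,
    n_stimuli = 1,
    fit = c("tau_in", "tau_close"), fixed = c(tau_out = 7), normalize_to = 0
  )
  expect_identical(sum(p$fitted), 2L)
  expect_equal(p$values[["tau_out"]], 7)
})

test_that("run details are saved at full precision and as CSV", {
  problem <- tiny_ms_problem()
  fit <- run_fit(problem, pso_hyperparameters(16, 3, seed = 1))
  json <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  save_run_details(fit, json, csv = csv)
  details <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(details$seed, 1)
  expect_equal(details$hyperparameters$chi, fit$hyper$chi, tolerance = 1e-12)
  expect_equal(
    details$best_params$tau_close, fit$best_params[["tau_close"]],
    tolerance = 1e-12
  )
  expect_equal(length(details$error_history), 4)
  got <- utils::read.csv(csv)
  expect_equal(got$value, unname(fit$best_params), tolerance = 1e-12)
})
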