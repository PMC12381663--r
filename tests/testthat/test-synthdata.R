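test_that("generated files have the expected lengths and metadata", {
  dir <- withr::local_tempdir()
  syn <- generate_dataset("MS",
    cycle_lengths = c(500, 400, 300), n_stimuli = 2,
    seed = 1, dir = dir
  )
  expect_length(syn$entries, 3)
  expect_equal(
    vapply(syn$entries, function(e) length(e$trace$values), 0),
    c(1000, 800, 600)
  )
  files <- file.path(dir, sprintf("ms_cl%d.txt", c(500, 400, 300)))
  expect_true(all(file.exists(files)))
  expect_equal(length(readLines(files[1])), 1000)
  truth <- jsonlite::read_json(file.path(dir, "ms_truth.json"), simplifyVector = TRUE)
  expect_equal(truth$model, "MS")
  expect_equal(truth$params$tau_close, default_params("MS")[["tau_close"]])
  expect_equal(truth$cycle_lengths, c(500, 400, 300))
})

test_that("generation is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_dataset("MS", cycle_lengths = 400, n_stimuli = 2, seed = 7, dir = d1)
  generate_dataset("MS", cycle_lengths = 400, n_stimuli = 2, seed = 7, dir = d2)
  expect_identical(
    readLines(file.path(d1, "ms_cl400.txt")),
    readLines(file.path(d2, "ms_cl400.txt"))
  )
  # noisy data reproduce with the seed and differ across seeds
  n1 <- generate_dataset("MS", cycle_lengths = 400, noise_sd = 0.01, seed = 3)
  n2 <- generate_dataset("MS", cycle_lengths = 400, noise_sd = 0.01, seed = 3)
  n3 <- generate_dataset("MS", cycle_lengths = 400, noise_sd = 0.01, seed = 4)
  expect_identical(n1$entries[[1]]$trace$values, n2$entries[[1]]$trace$values)
  expect_false(identical(n1$entries[[1]]$trace$values, n3$entries[[1]]$trace$values))
})

test_that("recorded beats are at steady state by construction", {
  syn <- generate_dataset("MS", cycle_lengths = c(500, 300), n_stimuli = 2, steady_tol = 0.5)
  for (cl in c("500", "300")) {
    apds <- syn$info[[cl]]$apds
    expect_length(apds, 2)
    expect_lt(abs(diff(apds)), 0.5)
    expect_true(syn$info[[cl]]$converged)
  }
})

test_that("a model that never excites raises a generation error naming the CL", {
  p <- default_params("MS")
  p["tau_in"] <- 5 # inward current too weak to regenerate an upstroke
  expect_error(
    generate_dataset("MS", p, cycle_lengths = 400),
    "action potential at CL 400"
  )
})

test_that("alternans-capable parameter sets alternate at short CL but not long", {
  for (m in c("FK", "BOCF")) {
    fx <- alternans_fixture(m)
    long_tr <- integrate_model(m, fx$params,
      pacing_protocol(fx$cl_long, n_stimuli = 4, n_prerecording = 60)
    )
    long_apds <- measure_apds(long_tr, 0.5 * max(long_tr$values))
    expect_lt(
      max(abs(diff(long_apds))) / max(long_apds), 0.01,
      label = paste(m, "long CL")
    )
    short_tr <- integrate_model(m, fx$params,
      pacing_protocol(fx$cl_short, n_stimuli = 4, n_prerecording = 60)
    )
    short_apds <- measure_apds(short_tr, 0.5 * max(short_tr$values))
    expect_gte(length(short_apds), 2)
    expect_gt(
      abs(short_apds[2] - short_apds[1]) / max(short_apds[1:2]), 0.10,
      label = paste(m, "short CL alternans")
    )
  }
})

test_that("the generator accepts a stable period-2 rhythm as steady state", {
  fx <- alternans_fixture("FK")
  syn <- generate_dataset("FK", fx$params,
    cycle_lengths = fx$cl_short,
    n_stimuli = 2, max_beats = 120
  )
  info <- syn$info[[as.character(fx$cl_short)]]
  expect_true(info$alternans)
  expect_true(info$converged)
  expect_length(info$apds, 2)
  expect_gt(abs(diff(info$apds)) / max(info$apds), 0.10)
})

test_that("fitting a model to its own synthetic data reaches the mismatch floor", {
  # round trip at reduced scale: with the generating parameters themselves the
  # only error left is the steady-state/wash-out mismatch; the swarm must get
  # at least that close
  syn <- generate_dataset("MS", cycle_lengths = 400, n_stimuli = 2)
  problem <- fit_problem("MS", syn$entries,
    n_stimuli = 2, n_prerecording = 4,
    normalize_to = 0
  )
  floor_err <- apswarm:::.problem_fitness(problem)(matrix(default_params("MS"), 1))
  fit <- run_fit(problem, pso_hyperparameters(256, 40, seed = 2))
  expect_lt(floor_err, 1e-6) # the generating parameters sit at the floor
  expect_lt(fit$best_error, 1e-4) # and the swarm gets within RMS ~ 0.01 of it
  expect_lt(fit_rms(fit), 0.01)
})
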