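test_that("the square stimulus has the documented waveform and charge", {
  sq <- stimulus_spec()
  expect_equal(stimulus_current(sq, 1), 0.2)
  expect_equal(stimulus_current(sq, 0), 0.2)
  expect_equal(stimulus_current(sq, 2.5), 0)
  expect_equal(stimulus_current(sq, 2), 0) # half-open pulse [0, duration)
  # integral over one cycle on the Euler grid: magnitude x duration
  tgrid <- seq(0, 500 - 0.02, by = 0.02)
  expect_equal(sum(stimulus_current(sq, tgrid)) * 0.02, 0.2 * 2, tolerance = 1e-12)
  expect_error(stimulus_spec(magnitude = 0), "magnitude")
  expect_error(stimulus_spec(duration = -1), "duration")
})

test_that("the biphasic stimulus has a hyperpolarizing then depolarizing phase", {
  bi <- stimulus_spec("biphasic", magnitude = 0.2, duration = 2)
  expect_lt(stimulus_current(bi, 0.5), 0)
  expect_gt(stimulus_current(bi, 1.5), 0)
  expect_equal(stimulus_current(bi, 3), 0)
  # net charge is depolarizing, and the model still excites
  tgrid <- seq(0, 10, by = 0.02)
  expect_gt(sum(stimulus_current(bi, tgrid)) * 0.02, 0)
  tr <- integrate_model("MS",
    protocol = pacing_protocol(500,
      n_stimuli = 1,
      stimulus = stimulus_spec("biphasic", magnitude = 0.6, duration = 4)
    )
  )
  expect_gt(max(tr$values), 0.5)
})

test_that("recorded traces have n_stimuli * CL / sample_interval samples", {
  for (cl in c(500, 400, 300)) {
    tr <- integrate_model("MS", protocol = pacing_protocol(cl, n_stimuli = 2))
    expect_length(tr$values, 2 * cl)
  }
  tr <- integrate_model("MS",
    protocol = pacing_protocol(400, n_stimuli = 3, sample_interval = 2)
  )
  expect_length(tr$values, 3 * 400 / 2)
  expect_error(pacing_protocol(500, sample_interval = 0.03), "integer multiple")
  expect_error(pacing_protocol(1.5), "exceed the stimulus")
})

test_that("a sub-threshold stimulus leaves the trace at rest", {
  tr <- integrate_model("MS",
    protocol = pacing_protocol(300,
      n_stimuli = 2,
      stimulus = stimulus_spec(magnitude = 1e-6, duration = 2)
    )
  )
  expect_lt(max(tr$values), 1e-4)
})

test_that("batch integration is bitwise identical to single-trace integration", {
  proto <- pacing_protocol(300, n_stimuli = 2, n_prerecording = 1)
  pm <- matrix(rep(default_params("FK"), each = 5), 5)
  pm[2, 2] <- 40 # perturb one particle
  pm[4, ] <- pm[2, ] # duplicated row
  sim <- integrate_batch("FK", pm, proto)
  for (i in c(1, 2, 3)) {
    one <- integrate_model("FK", pm[i, ], proto)
    expect_identical(as.numeric(sim[i, ]), one$values)
  }
  expect_identical(sim[2, ], sim[4, ])
})

test_that("a large batch completes and stays finite", {
  proto <- pacing_protocol(300, n_stimuli = 1, n_prerecording = 2)
  pm <- matrix(rep(default_params("MS"), each = 4096), 4096)
  sim <- integrate_batch("MS", pm, proto)
  expect_identical(dim(sim), c(4096L, 300L))
  expect_true(all(attr(sim, "ok")))
  expect_true(all(is.finite(sim)))
})

test_that("all SIMD dispatch paths agree", {
  proto <- pacing_protocol(400, n_stimuli = 1, n_prerecording = 1)
  pm <- rbind(default_params("BOCF"), default_params("BOCF") * 1.05)
  res <- lapply(c("none", "avx2", "avx512"), function(s) {
    withr::with_options(list(apswarm.simd = s), integrate_batch("BOCF", pm, proto))
  })
  expect_lt(max(abs(res[[1]] - res[[2]])), 1e-9)
  expect_lt(max(abs(res[[1]] - res[[3]])), 1e-9)
})

test_that("repeated pacing converges to a steady cycle", {
  for (m in ap_models()) {
    tr <- integrate_model(m, protocol = pacing_protocol(500, n_stimuli = 40))
    cyc <- matrix(tr$values, nrow = 500)
    diffs <- apply(abs(cyc[, -1, drop = FALSE] - cyc[, -40, drop = FALSE]), 2, max)
    expect_lt(min(diffs), 1e-3, label = paste(m, "steady pacing"))
    expect_lt(diffs[39], 1e-3, label = paste(m, "still steady at the end"))
  }
})

test_that("default-parameter traces stay within the physiological band", {
  for (m in ap_models()) {
    for (cl in c(400, 300)) {
      tr <- integrate_model(m, protocol = pacing_protocol(cl, n_stimuli = 3, n_prerecording = 5))
      expect_true(all(tr$values > -0.2 & tr$values < 1.5),
        info = sprintf("%s CL %d", m, cl)
      )
    }
  }
})

test_that("non-finite blow-up is flagged instead of raising", {
  p <- default_params("MS")
  p["tau_in"] <- 1e-7 # explicit Euler is violently unstable here
  tr <- integrate_model("MS", p, pacing_protocol(300, n_stimuli = 1))
  expect_false(attr(tr, "ok"))
  e <- voltage_entry(rect_ap_trace(150), 300)
  expect_equal(dataset_error(tr, e), worst_case_error(e))
})

test_that("traces round-trip through the newline-delimited dialect", {
  tr <- integrate_model("MS", protocol = pacing_protocol(300, n_stimuli = 1))
  path <- withr::local_tempfile(fileext = ".txt")
  write_trace(tr, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_trace(path)
  expect_equal(back$values, tr$values, tolerance = 1e-14)
  expect_equal(back$cycle_length, 300)
  expect_equal(back$sample_interval, 1)
  # explicit metadata wins over the sidecar
  back2 <- read_trace(path, cycle_length = 999)
  expect_equal(back2$cycle_length, 999)
})

test_that("the final state chains simulations exactly", {
  proto1 <- pacing_protocol(400, n_stimuli = 1)
  tr1 <- integrate_model("FK", protocol = proto1)
  tr2 <- integrate_model("FK", protocol = proto1, init = attr(tr1, "state"))
  full <- integrate_model("FK", protocol = pacing_protocol(400, n_stimuli = 2))
  expect_identical(c(tr1$values, tr2$values), full$values)
})
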