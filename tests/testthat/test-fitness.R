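test_that("normalization maps the range affinely and 0 bypasses", {
  expect_equal(normalize_trace(c(-80, -30, 20), 1), c(0, 0.5, 1))
  x <- c(0.2, -0.1, 0.7)
  expect_identical(normalize_trace(x, 0), x)
  # the scaling used for minimal-model fits with a 1.35 normalization constant
  expect_equal(normalize_trace(c(0, 0.5, 1), 1.35), c(0, 0.675, 1.35))
  expect_error(normalize_trace(rep(1, 5), 1), "constant")
  expect_error(normalize_trace(numeric(0), 1), "empty")
  tr <- normalize_trace(ap_trace(c(-80, 20), 1, 500), 1)
  expect_s3_class(tr, "ap_trace")
  expect_equal(tr$values, c(0, 1))
})

test_that("APD thresholds follow the repolarization-percentage convention", {
  expect_equal(apd_threshold(90), 0.1)
  expect_equal(apd_threshold(20), 0.8)
  expect_equal(apd_threshold(90, target_max = 1.35), 0.135)
})

test_that("upstroke alignment recovers known lags and flags failures", {
  pulse <- trapezoid_trace()
  expect_identical(align_upstroke(pulse, pulse), 0L)
  for (k in c(3L, 11L)) {
    delayed <- ap_trace(c(rep(0, k), pulse$values[1:(length(pulse$values) - k)]), 1)
    expect_identical(align_upstroke(pulse, delayed), -k)
    expect_identical(align_upstroke(delayed, pulse), k)
  }
  flat <- ap_trace(rep(0, 100), 1)
  expect_identical(align_upstroke(flat, pulse), NA_integer_)
  expect_error(align_upstroke(pulse, flat), "never crosses")
})

test_that("APDs are measured with linear sub-sample interpolation", {
  # trapezoid: rise 0->1 over 2 ms, 100 ms plateau, fall over 2 ms; at
  # threshold 0.5 the crossings are mid-ramp, so APD = 1 + 100 + 1 = 102
  trap <- trapezoid_trace(rise = 2, plateau = 100, fall = 2)
  expect_equal(measure_apds(trap, 0.5), 102)
  expect_identical(measure_apds(ap_trace(rep(0, 200), 1), 0.5), numeric(0))
  # rectangles measure their exact widths
  expect_equal(measure_apds(rect_ap_trace(c(200, 180)), 0.5), c(200, 180))
  expect_equal(measure_apds(rect_ap_trace(c(200, 180)), 0.5, n_expected = 1), 200)
  # sample interval scales the result
  trap2 <- ap_trace(trap$values, 2)
  expect_equal(measure_apds(trap2, 0.5), 204)
})

test_that("voltage dataset error is the length-weighted squared difference", {
  data <- trapezoid_trace()
  expect_equal(dataset_error(data, voltage_entry(data, 500)), 0)
  shifted <- ap_trace(data$values + 0.1, 1)
  # constant offset of 0.1 with unchanged alignment: N * 0.01 / N
  expect_equal(dataset_error(shifted, voltage_entry(data, 500)), 0.01)
  expect_error(
    dataset_error(ap_trace(data$values, 2), voltage_entry(data, 500)),
    "sample interval"
  )
})

test_that("APD dataset error is the raw squared sum with maximal missing-AP penalty", {
  e <- apd_entry(c(210, 180), apd_threshold = 0.5, cycle_length = 300)
  expect_equal(dataset_error(rect_ap_trace(c(200, 180)), e), 100) # 10^2 + 0
  expect_equal(dataset_error(rect_ap_trace(c(210, 180)), e), 0)
  # one missing AP contributes one squared cycle length
  expect_equal(dataset_error(rect_ap_trace(210), e), 300^2)
  expect_equal(dataset_error(ap_trace(rep(0, 600), 1), e), 2 * 300^2)
})

test_that("the composite fitness is linear in the fitting weights", {
  data <- trapezoid_trace()
  model <- ap_trace(data$values + 0.1, 1)
  e1 <- voltage_entry(data, 500, weight = 1)
  expect_equal(total_fitness(model, e1), dataset_error(model, e1))
  e2 <- voltage_entry(data, 500, weight = 2)
  expect_equal(total_fitness(model, e2), 2 * dataset_error(model, e1))
  # hybrid voltage + APD composite with asymmetric weights
  ea <- apd_entry(c(101), apd_threshold = 0.5, cycle_length = 500, weight = 1000)
  ev <- voltage_entry(data, 500, weight = 0.1)
  expect_equal(
    total_fitness(list(model, model), list(ev, ea)),
    0.1 * dataset_error(model, ev) + 1000 * dataset_error(model, ea)
  )
})

test_that("fitness is invariant under a common time shift", {
  data <- trapezoid_trace()
  model <- ap_trace(data$values * 0.95, 1)
  base <- dataset_error(model, voltage_entry(data, 500))
  k <- 7 # rotate within the zero-padded window so lengths stay equal
  shift <- function(tr) {
    n <- length(tr$values)
    ap_trace(c(rep(0, k), tr$values[1:(n - k)]), 1)
  }
  expect_equal(
    dataset_error(shift(model), voltage_entry(shift(data), 500)),
    base,
    tolerance = 1e-9
  )
})

test_that("doubling a dataset by self-concatenation leaves the error unchanged", {
  data <- trapezoid_trace()
  model <- ap_trace(data$values + 0.05, 1)
  base <- dataset_error(model, voltage_entry(data, 500))
  dbl <- function(tr) ap_trace(rep(tr$values, 2), 1)
  expect_equal(
    dataset_error(dbl(model), voltage_entry(dbl(data), 500)),
    base,
    tolerance = 1e-12
  )
})

test_that("invalid candidates receive the finite worst-case sentinel", {
  data <- trapezoid_trace()
  e <- voltage_entry(data, 500)
  flat <- ap_trace(rep(0, length(data$values)), 1)
  expect_equal(dataset_error(flat, e), worst_case_error(e))
  expect_true(is.finite(worst_case_error(e)))
  # the sentinel dominates any achievable error and propagates into the total
  expect_gt(worst_case_error(e), dataset_error(ap_trace(1 - data$values, 1), e))
  expect_equal(
    total_fitness(list(flat, data), list(e, e)),
    worst_case_error(e) + 0
  )
})

test_that("the batch fitness path matches the single-trace path", {
  syn <- generate_dataset("MS", cycle_lengths = 300, n_stimuli = 2)
  entry <- syn$entries[[1]]
  proto <- pacing_protocol(300, n_stimuli = 2, n_prerecording = 2)
  set.seed(5)
  pm <- do.call(rbind, lapply(1:8, function(i) {
    p <- default_params("MS")
    p * stats::runif(5, 0.8, 1.25)
  }))
  sim <- integrate_batch("MS", pm, proto)
  batch <- apswarm:::.batch_entry_error(sim, entry, 1)
  single <- vapply(1:8, function(i) {
    dataset_error(integrate_model("MS", pm[i, ], proto), entry)
  }, 0)
  expect_equal(batch, single, tolerance = 1e-12)
})
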