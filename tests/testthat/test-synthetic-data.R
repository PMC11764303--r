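test_that("the generator produces the requested tonic and bump morphology", {
  flat <- simulate_trace(list(), tonic_baseline = 3.5, noise_sd = 0)
  expect_equal(flat$trace$conductance, rep(3.5, 61))
  expect_identical(nrow(flat$truth), 0L)

  sh <- scr_shape(stimulus_time = 10, latency = 4, amplitude = 1,
                  rise_time = 10, recovery_half_time = 5, shape = "triangular")
  sim <- simulate_trace(list(sh), tonic_baseline = 2, noise_sd = 0)
  # peak falls on a sample (onset 14 + rise 10 = 24 s): exact amplitude
  expect_equal(max(sim$trace$conductance) - 2, 1)
  expect_equal(sim$trace$times[which.max(sim$trace$conductance)], 24)
  expect_equal(sim$truth$onset_time, 14)
  expect_equal(sim$truth$peak_time, 24)
})

test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_trace(list(scr_shape()), tonic_baseline = 4, noise_sd = 0.02,
                      seed = 99)
  b <- simulate_trace(list(scr_shape()), tonic_baseline = 4, noise_sd = 0.02,
                      seed = 99)
  expect_identical(a$trace, b$trace)
  c1 <- simulate_cohort(cohort_spec(4, 2, 1, seed = 17))
  c2 <- simulate_cohort(cohort_spec(4, 2, 1, seed = 17))
  expect_identical(c1, c2)
})

test_that("overlapping bumps violate the spacing rule", {
  shapes <- list(
    scr_shape(stimulus_time = 10, latency = 2, amplitude = 1, rise_time = 10,
              recovery_half_time = 10),
    scr_shape(stimulus_time = 20, latency = 2, amplitude = 1, rise_time = 10,
              recovery_half_time = 10)
  )
  expect_error(simulate_trace(shapes, tonic_baseline = 3, noise_sd = 0),
               "overlapping")
})

test_that("conductance above the physiological ceiling is clipped and flagged", {
  sh <- scr_shape(stimulus_time = 10, latency = 2, amplitude = 5,
                  rise_time = 10, recovery_half_time = 10)
  expect_warning(
    sim <- simulate_trace(list(sh), tonic_baseline = 18, noise_sd = 0),
    "clipping"
  )
  expect_true(sim$clipped)
  expect_lte(max(sim$trace$conductance), 20)
})

test_that("the divider inversion reproduces the worked ADC value", {
  tr <- make_trace(rep(2, 5))
  raw <- conductance_to_au(tr)
  expect_equal(raw$values, rep(512, 5))   # balanced divider
  # enormous conductance shorts the divider: Vx -> 0 -> reading 0
  big <- conductance_to_au(make_trace(rep(1e6, 3)))
  expect_equal(big$values, rep(0, 3))
  expect_error(conductance_to_au(conductance_trace(c(0, 2), c(2, NA))),
               "finite")
})

test_that("conductance -> ADC -> conductance round trips within 1 LSB", {
  set.seed(14)
  dev <- device_params()
  y <- runif(400, 0.5, 20)
  tr <- conductance_trace(seq(0, by = 2, length.out = 400), y)
  raw <- conductance_to_au(tr, dev)
  back <- convert_trace(raw)
  expect_identical(back$times, tr$times)
  # per-sample bound: the conductance change of one ADC step at that code
  au <- raw$values
  step <- abs(subject_conductance(au_to_volts(pmin(au + 1, 1023), dev), dev) -
              subject_conductance(au_to_volts(pmax(au - 1, 1), dev), dev)) / 2
  expect_true(all(abs(back$conductance - y) <= step + 1e-12))
  # and the mapping is idempotent at the codes
  expect_identical(conductance_to_au(back, dev)$values, raw$values)
})

test_that("cohort composition, labels and fault modes are as requested", {
  ch <- simulate_cohort(cohort_spec(36, 12, 3, seed = 7))
  expect_length(ch$traces, 51)
  expect_equal(as.vector(table(ch$truth$label)[c("stressed", "calm", "invalid")]),
               c(36, 12, 3))
  # invalid traces are flat lines; at least one sits below the 1 uS floor
  inv <- ch$traces[ch$truth$label == "invalid"]
  sds <- vapply(inv, function(tr) sd(tr$conductance), numeric(1))
  expect_true(all(sds < 0.005))
  expect_true(any(vapply(inv, function(tr) all(tr$conductance < 1), logical(1))))
  # calm traces pass the validity screen and carry no injected bumps
  calm <- ch$traces[ch$truth$label == "calm"]
  expect_false(any(vapply(calm, function(tr) validity_flags(tr)$trace_invalid,
                          logical(1))))
  expect_true(all(is.na(ch$truth$amplitude[ch$truth$label != "stressed"])))
})

test_that("calm traces rarely trigger the detector at default settings", {
  set.seed(33)
  n_events <- replicate(60, {
    tonic <- runif(1, 2, 8)
    sim <- simulate_trace(list(), tonic_baseline = tonic, noise_sd = 0.02)
    nrow(detect_events(sim$trace))
  })
  expect_gte(mean(n_events == 0), 0.95)
})
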