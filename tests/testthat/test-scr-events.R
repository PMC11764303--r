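test_that("flat traces yield no events", {
  expect_identical(nrow(detect_events(make_trace(rep(3, 40)))), 0L)
})

test_that("a single noiseless bump is detected with its injected parameters", {
  sh <- scr_shape(stimulus_time = 10, latency = 4, amplitude = 1,
                  rise_time = 10, recovery_half_time = 15)
  sim <- simulate_trace(list(sh), tonic_baseline = 2, noise_sd = 0)
  ev <- detect_events(sim$trace)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$amplitude, 1, tolerance = 0.05)
  expect_equal(ev$onset_value, 2, tolerance = 0.01)
  expect_lt(abs(ev$rise_time - 10), 2)        # one sample interval
  expect_lt(abs(ev$onset_time - 14), 2)
  # recovery half-life of the decay is the injected recovery half-time
  expect_false(ev$recovery_censored)
  expect_equal(ev$recovery_time, 15, tolerance = 2)
})

test_that("well-separated bumps give time-ordered events", {
  shapes <- list(
    scr_shape(stimulus_time = 10, latency = 4, amplitude = 1.2,
              rise_time = 10, recovery_half_time = 12),
    scr_shape(stimulus_time = 80, latency = 4, amplitude = 0.8,
              rise_time = 8, recovery_half_time = 10)
  )
  sim <- simulate_trace(shapes, tonic_baseline = 3, noise_sd = 0,
                        duration = 160)
  ev <- detect_events(sim$trace)
  expect_identical(nrow(ev), 2L)
  expect_true(all(diff(ev$onset_time) > 0))
  expect_equal(ev$amplitude, c(1.2, 0.8), tolerance = 0.06)
})

test_that("characterization reproduces the worked stressed recording", {
  tr <- worked_stress_trace()
  onset_idx <- which(tr$times == 20)
  peak_idx <- which(tr$times == 42)
  ev <- characterize(tr, onset_idx, peak_idx, recovery_start_time = 94)
  expect_equal(ev$amplitude, 2.51)             # 6.99 - 4.48 uS
  expect_equal(ev$rise_time, 22)               # 42 - 20 s
  expect_true(ev$recovery_censored)
  expect_equal(ev$recovery_lower_bound, 80)    # 174 - 94 s
  # without a later recovery-phase start the bound runs from the peak
  ev2 <- characterize(tr, onset_idx, peak_idx)
  expect_equal(ev2$recovery_lower_bound, 174 - 42)
  expect_error(characterize(tr, peak_idx, peak_idx + 3), "not an event")
})

test_that("half-recovery and width are exact on a dense triangular bump", {
  tr <- dense_triangle_trace()     # up 10 s, down 10 s, amp 1 atop 2 uS
  onset_idx <- which.min(abs(tr$times - 10))
  peak_idx <- which.min(abs(tr$times - 20))
  ev <- characterize(tr, onset_idx, peak_idx)
  expect_equal(ev$recovery_time, 5, tolerance = 0.02)   # halfway down
  expect_equal(peak_width(tr, ev), 10, tolerance = 0.02)
})

test_that("peak width spans a dense rectangular pulse", {
  dt <- 0.01
  t <- seq(0, 30, by = dt)
  y <- rep(2, length(t)); y[t >= 10 & t < 20] <- 3
  tr <- conductance_trace(t, y)
  onset_idx <- max(which(t < 10))
  peak_idx <- min(which(y == 3))
  ev <- characterize(tr, onset_idx, peak_idx)
  expect_equal(peak_width(tr, ev), 10, tolerance = 2 * dt)
})

test_that("latency classification uses the 1-5 s event-related window", {
  sh <- scr_shape(stimulus_time = 20, latency = 3, amplitude = 1,
                  rise_time = 10, recovery_half_time = 15)
  sim <- simulate_trace(list(sh), tonic_baseline = 2, noise_sd = 0)
  er <- detect_events(sim$trace, stimulus_time = 20)
  expect_identical(er$latency_class, "ER_SCR")
  expect_equal(er$latency, 3, tolerance = 2)
  ns <- detect_events(sim$trace, stimulus_time = 10)  # latency ~13 s
  expect_identical(ns$latency_class, "NS_SCR")
  un <- detect_events(sim$trace)
  expect_identical(un$latency_class, "unknown")
})

test_that("detection is deterministic and rejects unordered timestamps", {
  sim <- simulate_trace(list(scr_shape()), tonic_baseline = 3,
                        noise_sd = 0.02, seed = 21)
  expect_identical(detect_events(sim$trace), detect_events(sim$trace))
  bad <- sim$trace
  bad$times[2] <- bad$times[4]
  expect_error(detect_events(bad), "strictly increasing")
})

test_that("injected amplitudes are recovered and recovery outlasts the rise", {
  set.seed(27)
  n <- 40
  amp_ok <- logical(n); rise_err <- numeric(n)
  rises <- numeric(0); recs <- numeric(0)
  for (i in seq_len(n)) {
    tonic <- runif(1, 2, 8)
    sh <- draw_scr_shape(stimulus_time = runif(1, 5, 15))
    sim <- simulate_trace(list(sh), tonic_baseline = tonic, noise_sd = 0.02)
    ev <- detect_events(sim$trace)
    expect_gt(nrow(ev), 0)
    j <- which.max(ev$amplitude)
    amp_ok[i] <- abs(ev$amplitude[j] - sh$amplitude) / sh$amplitude <= 0.1
    rise_err[i] <- ev$rise_time[j] - sh$rise_time
    expect_true(all(ev$onset_time < ev$peak_time))
    keep <- !ev$recovery_censored
    rises <- c(rises, ev$rise_time[keep])
    recs <- c(recs, ev$recovery_time[keep])
  }
  expect_gte(mean(amp_ok), 0.9)
  # rise-time error: unbiased to within one sample interval in the median
  expect_lte(median(abs(rise_err)), 2)
  # recovery is slower than the rise (uncensored events)
  expect_gt(median(recs), median(rises))
})
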