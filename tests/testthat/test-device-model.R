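test_that("ADC-to-volts conversion matches the divider arithmetic", {
  dev <- device_params()
  expect_identical(au_to_volts(512, dev), 2.5)
  expect_identical(adc_lambda(dev), 5 / 1024)
  expect_identical(au_to_volts(0, dev), 0)
  # hypothetical full scale maps onto the supply by construction
  expect_identical(au_to_volts(1024, dev), 5)
  expect_error(au_to_volts(c(3, 1025), dev), "index 2")
  expect_error(au_to_volts(-1, dev), "out of range")
})

test_that("sensor current follows (V - Vx) / R in microamperes", {
  expect_equal(sensor_current(2.5), 5)   # (5 - 2.5) V / 0.5 MOhm
  expect_equal(sensor_current(0), 10)    # full supply across R
  expect_gt(sensor_current(4.9999), 0)
  expect_lt(sensor_current(4.9999), 0.001)
  expect_error(sensor_current(5), "degenerate")
})

test_that("subject conductance inverts the divider", {
  expect_equal(subject_conductance(2.5), 2)  # X = 500 kOhm -> 2 uS
  # balanced divider: X = R, so Y = 1/R regardless of R
  for (r in c(100, 250, 500, 820)) {
    dev <- device_params(series_resistance_kohm = r)
    expect_equal(subject_conductance(2.5, dev), 1000 / r)
  }
  # higher Vx means higher subject resistance, hence lower conductance
  expect_lt(subject_conductance(4.0), subject_conductance(1.0))
  expect_error(subject_conductance(0), "artifact")
})

test_that("conversion chain is strictly monotone decreasing in AU", {
  dev <- device_params()
  au <- sort(sample.int(1022, 60)) # distinct, in range, nonzero
  y <- subject_conductance(au_to_volts(au, dev), dev)
  expect_true(all(diff(y) < 0))
})

test_that("convert_trace preserves length and timestamps and flags bad samples", {
  dev <- device_params()
  raw <- raw_trace(seq(0, 18, by = 2), rep(512L, 10), dev)
  tr <- convert_trace(raw)
  expect_s3_class(tr, "conductance_trace")
  expect_identical(tr$times, raw$times)
  expect_equal(tr$conductance, rep(2, 10))
  expect_identical(tr$source, "converted")

  raw0 <- raw_trace(c(0, 2, 4), c(512L, 0L, 512L), dev)
  tr0 <- convert_trace(raw0)
  expect_true(is.na(tr0$conductance[2]))
  expect_identical(tr0$flags[2], "zero_voltage")
  expect_identical(tr0$flags[c(1, 3)], c("", ""))

  empty <- convert_trace(raw_trace(numeric(0), numeric(0), dev))
  expect_length(empty$times, 0)
})

test_that("raw traces enforce ADC range and strictly increasing time", {
  expect_error(raw_trace(c(0, 2), c(0, 1024)), "ADC values")
  expect_error(raw_trace(c(0, 0), c(1, 2)), "strictly increasing")
  expect_error(conductance_trace(c(0, 2), c(1, -3)), "> 0")
})

test_that("trace CSV round trips in both dialects", {
  dir <- withr::local_tempdir()
  raw <- raw_trace(seq(0, 8, 2), c(400L, 410L, 420L, 430L, 440L))
  p1 <- file.path(dir, "raw.csv")
  write_trace_csv(raw, p1)
  expect_identical(readLines(p1, n = 1L), "time_s,value_au")
  back <- read_trace_csv(p1)
  expect_s3_class(back, "raw_trace")
  expect_equal(back$values, raw$values)

  tr <- make_trace(c(2, 2.5, 3))
  p2 <- file.path(dir, "us.csv")
  write_trace_csv(tr, p2)
  back2 <- read_trace_csv(p2)
  expect_s3_class(back2, "conductance_trace")
  expect_equal(back2$conductance, tr$conductance)

  p3 <- file.path(dir, "bad.csv")
  writeLines(c("a,b", "1,2"), p3)
  expect_error(read_trace_csv(p3), "unrecognized")
})
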