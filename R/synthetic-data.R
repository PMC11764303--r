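#' Shape of one synthetic skin-conductance response
#'
#' A response is parameterized by the four canonical phases: latency after
#' the stimulus, a rise of duration `rise_time` up to `amplitude`, and a
#' slower recovery whose half-amplitude level is crossed
#' `recovery_half_time` seconds after the peak. The default functional form
#' is a linear rise followed by an exponential decay with half-life
#' `recovery_half_time`, so the half-recovery time is analytically exact; a
#' triangular variant (linear decay reaching zero at `2 * recovery_half_time`
#' after the peak) is also available.
#'
#' @param stimulus_time Stimulus onset, seconds.
#' @param latency Stimulus-to-onset delay, seconds.
#' @param amplitude Response amplitude above the tonic level, microSiemens.
#' @param rise_time Onset-to-peak duration, seconds.
#' @param recovery_half_time Peak-to-half-recovery duration, seconds; slower
#'   than the rise for physiologically shaped responses.
#' @param shape `"linear_rise_exp_decay"` (default) or `"triangular"`.
#' @return An object of class `scr_shape`.
#' @export
scr_shape <- function(stimulus_time = 0, latency = 2, amplitude = 1,
                      rise_time = 10, recovery_half_time = 15,
                      shape = c("linear_rise_exp_decay", "triangular")) {
  shape <- match.arg(shape)
  stopifnot(latency >= 0, amplitude > 0, rise_time > 0, recovery_half_time > 0)
  structure(
    list(stimulus_time = stimulus_time, latency = latency,
         amplitude = amplitude, rise_time = rise_time,
         recovery_half_time = recovery_half_time, shape = shape),
    class = "scr_shape"
  )
}

#' Draw a random response shape from the generator defaults
#'
#' Defaults emulate the morphology reported for stress responses under
#' seconds-scale sampling: latency uniform on 1-5 s, amplitude uniform on
#' 0.2-3 microSiemens, rise time uniform on 5-35 s, and a recovery half-time
#' of 1.2-3 times the rise time, enforcing recovery slower than rise. Uses
#' the current RNG state; seed upstream for reproducibility.
#'
#' @param stimulus_time Stimulus onset, seconds.
#' @param latency_range,amplitude_range,rise_range Uniform draw bounds.
#' @param recovery_factor_range Uniform bounds for the recovery-half-time to
#'   rise-time ratio.
#' @param shape Passed to [scr_shape()].
#' @return An [scr_shape()].
#' @export
draw_scr_shape <- function(stimulus_time = 0,
                           latency_range = c(1, 5),
                           amplitude_range = c(0.2, 3.0),
                           rise_range = c(5, 35),
                           recovery_factor_range = c(1.2, 3.0),
                           shape = "linear_rise_exp_decay") {
  rise <- stats::runif(1, rise_range[1], rise_range[2])
  scr_shape(
    stimulus_time = stimulus_time,
    latency = stats::runif(1, latency_range[1], latency_range[2]),
    amplitude = stats::runif(1, amplitude_range[1], amplitude_range[2]),
    rise_time = rise,
    recovery_half_time = rise * stats::runif(1, recovery_factor_range[1],
                                             recovery_factor_range[2]),
    shape = shape
  )
}

# evaluate one bump at times t (vectorized), relative to a zero baseline
scr_bump_values <- function(t, s) {
  onset <- s$stimulus_time + s$latency
  peak <- onset + s$rise_time
  v <- numeric(length(t))
  rising <- t >= onset & t <= peak
  v[rising] <- s$amplitude * (t[rising] - onset) / s$rise_time
  after <- t > peak
  if (s$shape == "linear_rise_exp_decay") {
    v[after] <- s$amplitude * 2^(-(t[after] - peak) / s$recovery_half_time)
  } else {
    v[after] <- pmax(0, s$amplitude * (1 - (t[after] - peak) / (2 * s$recovery_half_time)))
  }
  v
}

#' Simulate one conductance trace with ground-truth events
#'
#' Tonic baseline plus the sum of the response bumps plus white Gaussian
#' noise, sampled on a regular grid. Bumps must respect the spacing rule
#' (consecutive onsets at least `rise_time + 2 * recovery_half_time` of the
#' earlier bump apart) so that responses do not overlap. Samples pushed above
#' the 20 uS physiological ceiling are clipped and the trace flagged, with a
#' warning.
#'
#' @param shapes List of [scr_shape()] objects (may be empty).
#' @param tonic_baseline Tonic conductance level, microSiemens.
#' @param noise_sd Gaussian noise standard deviation, microSiemens.
#' @param duration Recording length, seconds.
#' @param sample_interval Sampling interval, seconds (default 2 s).
#' @param seed Optional integer seed; when given the trace is reproducible.
#' @return A list with `trace` (a [conductance_trace()], `source =
#'   "synthetic"`), `truth` (data frame of injected onset/peak
#'   times, amplitudes, rise and recovery-half times) and `clipped` (flag).
#' @export
simulate_trace <- function(shapes = list(), tonic_baseline = 4,
                           noise_sd = 0.02, duration = 120,
                           sample_interval = 2, seed = NULL) {
  stopifnot(is.list(shapes), tonic_baseline > 0, noise_sd >= 0,
            duration >= 10 * sample_interval, sample_interval > 0)
  if (!is.null(seed)) set.seed(seed)
  if (length(shapes) > 1) {
    onsets <- vapply(shapes, function(s) s$stimulus_time + s$latency, numeric(1))
    o <- order(onsets)
    shapes <- shapes[o]
    onsets <- onsets[o]
    need <- vapply(shapes, function(s) s$rise_time + 2 * s$recovery_half_time,
                   numeric(1))
    if (any(diff(onsets) < need[-length(need)])) {
      stop(paste(
        "overlapping responses: consecutive onsets must be at least",
        "rise_time + 2 * recovery_half_time of the earlier response apart"
      ), call. = FALSE)
    }
  }
  t <- seq(0, duration, by = sample_interval)
  y <- rep(tonic_baseline, length(t))
  for (s in shapes) y <- y + scr_bump_values(t, s)
  if (noise_sd > 0) y <- y + stats::rnorm(length(t), 0, noise_sd)
  clipped <- any(y > 20)
  if (clipped) {
    warning("simulated conductance exceeds 20 uS; clipping to the physiological ceiling")
    y <- pmin(y, 20)
  }
  y <- pmax(y, 1e-6)  # conductance must stay positive
  truth <- if (length(shapes)) {
    data.frame(
      stimulus_time = vapply(shapes, `[[`, numeric(1), "stimulus_time"),
      onset_time = vapply(shapes, function(s) s$stimulus_time + s$latency, numeric(1)),
      peak_time = vapply(shapes, function(s) s$stimulus_time + s$latency + s$rise_time,
                         numeric(1)),
      amplitude = vapply(shapes, `[[`, numeric(1), "amplitude"),
      rise_time = vapply(shapes, `[[`, numeric(1), "rise_time"),
      recovery_half_time = vapply(shapes, `[[`, numeric(1), "recovery_half_time")
    )
  } else {
    data.frame(stimulus_time = numeric(0), onset_time = numeric(0),
               peak_time = numeric(0), amplitude = numeric(0),
               rise_time = numeric(0), recovery_half_time = numeric(0))
  }
  list(trace = conductance_trace(t, y, source = "synthetic"),
       truth = truth, clipped = clipped)
}

#' Map a conductance trace back to ADC readings
#'
#' Inverse of the divider conversion: `X = 1/Y`, `Vx = V * X / (R + X)`,
#' ADC reading = nearest integer of `Vx / lambda`, clamped to the
#' representable range. Together with [convert_trace()] this round-trips
#' within one ADC quantization step.
#'
#' @param trace A [conductance_trace()] with strictly positive conductance.
#' @param device A [device_params()] object.
#' @return A [raw_trace()].
#' @export
conductance_to_au <- function(trace, device = device_params()) {
  stopifnot(inherits(trace, "conductance_trace"), inherits(device, "device_params"))
  y <- trace$conductance
  if (any(!is.finite(y) | y <= 0)) {
    stop("conductance must be finite and > 0 to invert", call. = FALSE)
  }
  x_kohm <- 1000 / y
  vx <- device$supply_voltage * x_kohm / (device$series_resistance_kohm + x_kohm)
  au <- round(vx / adc_lambda(device))
  au <- pmin(pmax(au, 0), device$adc_levels - 1)
  si <- if (length(trace$times) > 1) stats::median(diff(trace$times)) else 2
  raw_trace(trace$times, au, device = device, sample_interval = si)
}

#' Specification of a synthetic cohort
#'
#' Study conditions for a simulated screening cohort: each recording lasts
#' `duration` seconds sampled every `sample_interval` seconds; tonic
#' baselines are drawn uniformly inside the physiological band
#' (`tonic_range`); stressed subjects carry one stress response drawn by
#' [draw_scr_shape()] with a stimulus 5-15 s into the recording; calm
#' subjects carry none; invalid recordings are flat lines, alternating a
#' constant reading below the 1 uS floor (open contact, air conductivity
#' 0.93 uS) and a constant in-band value (1.99 uS, a stuck reading).
#'
#' @param n_stressed,n_calm,n_invalid Trace counts per true condition.
#' @param tonic_range Uniform bounds for the tonic baseline, microSiemens.
#' @param noise_sd Gaussian noise standard deviation, microSiemens.
#' @param duration Recording length, seconds.
#' @param sample_interval Sampling interval, seconds.
#' @param seed Integer seed for the whole cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_stressed = 36, n_calm = 12, n_invalid = 3,
                        tonic_range = c(2, 8), noise_sd = 0.02,
                        duration = 120, sample_interval = 2, seed = 1) {
  stopifnot(n_stressed >= 0, n_calm >= 0, n_invalid >= 0,
            n_stressed + n_calm + n_invalid >= 1,
            duration >= 10 * sample_interval)
  structure(
    list(n_stressed = as.integer(n_stressed), n_calm = as.integer(n_calm),
         n_invalid = as.integer(n_invalid), tonic_range = tonic_range,
         noise_sd = noise_sd, duration = duration,
         sample_interval = sample_interval, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Simulate a labeled cohort of conductance traces
#'
#' @param spec A [cohort_spec()].
#' @return A list with `traces` (named list of [conductance_trace()]s),
#'   `truth` (data frame: `id`, true `label`, tonic level, injected amplitude
#'   where applicable) and `shapes` (list of injected [scr_shape()]s, `NULL`
#'   for calm/invalid traces).
#' @examples
#' cohort <- simulate_cohort(cohort_spec(4, 2, 1, seed = 7))
#' names(cohort$traces)
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_stressed + spec$n_calm + spec$n_invalid
  labels <- rep(c("stressed", "calm", "invalid"),
                c(spec$n_stressed, spec$n_calm, spec$n_invalid))
  ids <- sprintf("trace_%03d", seq_len(n))
  traces <- vector("list", n)
  shapes <- vector("list", n)
  tonic <- rep(NA_real_, n)
  amplitude <- rep(NA_real_, n)
  invalid_kind <- 0L
  for (i in seq_len(n)) {
    if (labels[i] == "invalid") {
      # alternate the two observed fault modes, both flat lines
      invalid_kind <- invalid_kind + 1L
      level <- if (invalid_kind %% 2L == 1L) 0.93 else 1.99
      sim <- simulate_trace(list(), tonic_baseline = level, noise_sd = 0,
                            duration = spec$duration,
                            sample_interval = spec$sample_interval)
      tonic[i] <- level
    } else {
      tonic[i] <- stats::runif(1, spec$tonic_range[1], spec$tonic_range[2])
      sh <- if (labels[i] == "stressed") {
        list(draw_scr_shape(stimulus_time = stats::runif(1, 5, 15)))
      } else {
        list()
      }
      sim <- simulate_trace(sh, tonic_baseline = tonic[i],
                            noise_sd = spec$noise_sd,
                            duration = spec$duration,
                            sample_interval = spec$sample_interval)
      if (length(sh)) {
        shapes[[i]] <- sh[[1]]
        amplitude[i] <- sh[[1]]$amplitude
      }
    }
    traces[[i]] <- sim$trace
  }
  names(traces) <- ids
  list(
    traces = traces,
    truth = data.frame(id = ids, label = labels, tonic = tonic,
                       amplitude = amplitude),
    shapes = shapes
  )
}
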