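#' Sensor device parameters
#'
#' Describes the acquisition hardware: a GSR finger electrode pair in series
#' with a fixed resistor across the supply rail, read through an ADC. The
#' defaults correspond to a 10-bit, 5 V microcontroller board with a 500 kOhm
#' series resistor.
#'
#' @param supply_voltage Supply voltage across the divider, in volts.
#' @param adc_levels Number of ADC quantization levels (1024 for a 10-bit ADC).
#' @param series_resistance_kohm Fixed series resistance, in kiloohms.
#'
#' @return An object of class `device_params`.
#' @examples
#' dev <- device_params()
#' adc_lambda(dev)  # volts per ADC unit
#' @export
device_params <- function(supply_voltage = 5.0,
                          adc_levels = 1024L,
                          series_resistance_kohm = 500) {
  stopifnot(
    is.numeric(supply_voltage), length(supply_voltage) == 1L, supply_voltage > 0,
    is.numeric(adc_levels), length(adc_levels) == 1L, adc_levels >= 2,
    adc_levels == as.integer(adc_levels),
    is.numeric(series_resistance_kohm), length(series_resistance_kohm) == 1L,
    series_resistance_kohm > 0
  )
  structure(
    list(
      supply_voltage = as.numeric(supply_voltage),
      adc_levels = as.integer(adc_levels),
      series_resistance_kohm = as.numeric(series_resistance_kohm)
    ),
    class = "device_params"
  )
}

#' @export
print.device_params <- function(x, ...) {
  cat(sprintf(
    "<device_params> supply %.3g V, %d ADC levels (lambda = %.10g V/AU), series R %.4g kOhm\n",
    x$supply_voltage, x$adc_levels, adc_lambda(x), x$series_resistance_kohm
  ))
  invisible(x)
}

#' ADC conversion factor (volts per ADC unit)
#'
#' Derived quantity `supply_voltage / adc_levels`; it is computed on demand and
#' never stored, so it cannot drift out of sync with the device parameters.
#' For the default device it equals 5/1024 = 0.0048828125 V/AU.
#'
#' @param device A [device_params()] object.
#' @return Volts per ADC unit.
#' @export
adc_lambda <- function(device) {
  stopifnot(inherits(device, "device_params"))
  device$supply_voltage / device$adc_levels
}

#' Convert ADC readings to volts
#'
#' Multiplies the ADC count by the conversion factor [adc_lambda()]. The full
#' scale value `adc_levels` maps exactly onto the supply voltage, so readings
#' in `[0, adc_levels]` are accepted; a recorded trace is constrained to the
#' representable codes `[0, adc_levels - 1]` by [raw_trace()].
#'
#' @param au Numeric vector of ADC readings ("Arduino Units").
#' @param device A [device_params()] object.
#' @return Voltages, same length as `au`.
#' @examples
#' au_to_volts(512, device_params())  # 2.5 V
#' @export
au_to_volts <- function(au, device = device_params()) {
  stopifnot(inherits(device, "device_params"), is.numeric(au))
  bad <- which(is.finite(au) & (au < 0 | au > device$adc_levels))
  if (length(bad)) {
    stop(sprintf(
      "ADC reading out of range [0, %d] at index %s (value %g)",
      device$adc_levels, bad[1L], au[bad[1L]]
    ), call. = FALSE)
  }
  au * adc_lambda(device)
}

#' Current through the sensor branch
#'
#' With the subject's skin (resistance X) in series with the fixed resistor R
#' across the supply V, the branch current is `I = (V - Vx) / R`, where `Vx`
#' is the voltage measured across the skin. Returned in microamperes.
#'
#' @param vx Measured voltage across the subject, in volts.
#' @param device A [device_params()] object.
#' @return Current in microamperes, same length as `vx`.
#' @examples
#' sensor_current(2.5)  # 5 uA through 500 kOhm under 5 V
#' @export
sensor_current <- function(vx, device = device_params()) {
  stopifnot(inherits(device, "device_params"), is.numeric(vx))
  bad <- which(is.finite(vx) & vx >= device$supply_voltage)
  if (length(bad)) {
    stop(sprintf(
      "measured voltage %g V at index %d is at or above the supply (%g V): degenerate circuit, current would be <= 0",
      vx[bad[1L]], bad[1L], device$supply_voltage
    ), call. = FALSE)
  }
  if (any(is.finite(vx) & vx < 0)) {
    stop("measured voltage must be non-negative", call. = FALSE)
  }
  # V / kOhm = mA; x1000 -> uA
  (device$supply_voltage - vx) / device$series_resistance_kohm * 1000
}

#' Skin conductance from the measured voltage
#'
#' Solves the voltage divider for the subject's resistance `X = Vx / I`
#' (kiloohms) and returns its reciprocal, the skin conductance
#' `Y = 1/X`, in microSiemens. When the divider is balanced (Vx = supply/2)
#' the subject's resistance equals the series resistor.
#'
#' @inheritParams sensor_current
#' @return Conductance in microSiemens, same length as `vx`.
#' @examples
#' subject_conductance(2.5)  # 2 uS (X = 500 kOhm)
#' @export
subject_conductance <- function(vx, device = device_params()) {
  stopifnot(inherits(device, "device_params"), is.numeric(vx))
  if (any(is.finite(vx) & vx == 0)) {
    stop(paste(
      "measured voltage of 0 V implies zero subject resistance",
      "(conductance undefined / infinite): flag as artifact"
    ), call. = FALSE)
  }
  i_ua <- sensor_current(vx, device)     # uA
  x_kohm <- vx / i_ua * 1000             # V / uA = MOhm; x1000 -> kOhm
  1000 / x_kohm                          # 1 / kOhm = mS; x1000 -> uS
}

#' Raw ADC trace
#'
#' A timestamped series of ADC readings together with the device parameters
#' needed to convert it to physical units.
#'
#' @param times Sample times in seconds, strictly increasing.
#' @param values Integer ADC readings in `[0, adc_levels - 1]`.
#' @param device A [device_params()] object.
#' @param sample_interval Nominal sampling interval in seconds (default 2 s).
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(times, values, device = device_params(),
                      sample_interval = 2) {
  stopifnot(
    is.numeric(times), is.numeric(values), length(times) == length(values),
    inherits(device, "device_params"),
    is.numeric(sample_interval), sample_interval > 0
  )
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (any(values != round(values) | values < 0 | values > device$adc_levels - 1)) {
    stop(sprintf("ADC values must be integers in [0, %d]", device$adc_levels - 1),
         call. = FALSE)
  }
  structure(
    list(times = as.numeric(times), values = as.numeric(values),
         device = device, sample_interval = as.numeric(sample_interval)),
    class = "raw_trace"
  )
}

#' Skin-conductance trace
#'
#' @param times Sample times in seconds, strictly increasing.
#' @param conductance Conductance in microSiemens; non-finite entries mark
#'   samples where the conversion failed (see `flags`).
#' @param source One of `"converted"`, `"native"`, `"synthetic"`.
#' @param flags Optional character vector of per-sample flags (`""` = clean).
#' @return An object of class `conductance_trace`.
#' @export
conductance_trace <- function(times, conductance,
                              source = c("native", "converted", "synthetic"),
                              flags = NULL) {
  source <- match.arg(source)
  stopifnot(is.numeric(times), is.numeric(conductance),
            length(times) == length(conductance))
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (is.null(flags)) flags <- rep("", length(times))
  stopifnot(length(flags) == length(times))
  if (any(is.finite(conductance) & conductance <= 0)) {
    stop("conductance must be > 0 wherever finite", call. = FALSE)
  }
  structure(
    list(times = as.numeric(times), conductance = as.numeric(conductance),
         source = source, flags = as.character(flags)),
    class = "conductance_trace"
  )
}

#' @export
print.conductance_trace <- function(x, ...) {
  ok <- sum(is.finite(x$conductance))
  cat(sprintf(
    "<conductance_trace> %d samples (%d finite), %s, %.4g-%.4g s\n",
    length(x$times), ok, x$source,
    if (length(x$times)) min(x$times) else NA, if (length(x$times)) max(x$times) else NA
  ))
  invisible(x)
}

#' Convert a raw ADC trace to a conductance trace
#'
#' Applies [au_to_volts()] then [subject_conductance()] sample by sample.
#' Samples whose reading makes the conversion degenerate (0 V, i.e. zero
#' subject resistance, or a reading at/above the supply voltage) become
#' non-finite and carry a flag instead of aborting the whole recording.
#'
#' @param raw A [raw_trace()].
#' @return A [conductance_trace()] with `source = "converted"`, the same
#'   length and timestamps as the input.
#' @export
convert_trace <- function(raw) {
  stopifnot(inherits(raw, "raw_trace"))
  n <- length(raw$times)
  vx <- au_to_volts(raw$values, raw$device)
  y <- rep(NA_real_, n)
  flags <- rep("", n)
  for (i in seq_len(n)) {
    if (!is.finite(vx[i])) {
      flags[i] <- "non_finite_input"
    } else if (vx[i] == 0) {
      flags[i] <- "zero_voltage"
    } else if (vx[i] >= raw$device$supply_voltage) {
      flags[i] <- "at_supply"
    } else {
      y[i] <- subject_conductance(vx[i], raw$device)
    }
  }
  conductance_trace(raw$times, y, source = "converted", flags = flags)
}

#' Read a trace from CSV
#'
#' Two dialects are recognized by header: `time_s,value_au` (integer ADC
#' readings, returns a [raw_trace()]) and `time_s,value_us` (conductance in
#' microSiemens, returns a [conductance_trace()]). Comma-separated, `.`
#' decimal mark, UTF-8.
#'
#' @param path Path to the CSV file.
#' @param device Device parameters attached to ADC traces.
#' @param sample_interval Nominal sampling interval for ADC traces.
#' @return A `raw_trace` or `conductance_trace`, depending on the header.
#' @export
read_trace_csv <- function(path, device = device_params(), sample_interval = 2) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (identical(names(df), c("time_s", "value_au"))) {
    raw_trace(df$time_s, df$value_au, device = device,
              sample_interval = sample_interval)
  } else if (identical(names(df), c("time_s", "value_us"))) {
    conductance_trace(df$time_s, df$value_us, source = "native")
  } else {
    stop(sprintf(
      "unrecognized trace CSV header in '%s': expected time_s,value_au or time_s,value_us",
      path
    ), call. = FALSE)
  }
}

#' Write a trace to CSV
#'
#' Writes the dialect matching the trace type (`time_s,value_au` for raw ADC
#' traces, `time_s,value_us` for conductance traces).
#'
#' @param trace A `raw_trace` or `conductance_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  if (inherits(trace, "raw_trace")) {
    df <- data.frame(time_s = trace$times, value_au = as.integer(trace$values))
  } else if (inherits(trace, "conductance_trace")) {
    df <- data.frame(time_s = trace$times, value_us = trace$conductance)
  } else {
    stop("trace must be a raw_trace or conductance_trace", call. = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
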