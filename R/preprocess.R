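#' Physiological validity configuration
#'
#' Normal human skin conductance lies between about 1 and 20 microSiemens;
#' readings outside that band usually mean poor electrode contact (an open
#' circuit reads the conductivity of air, below 1 uS).
#'
#' @param min_valid,max_valid Validity band in microSiemens.
#' @param invalid_fraction_threshold A trace is ruled invalid when the
#'   fraction of out-of-band or non-finite samples exceeds this proportion.
#' @return An object of class `validity_config`.
#' @export
validity_config <- function(min_valid = 1.0, max_valid = 20.0,
                            invalid_fraction_threshold = 0.5) {
  stopifnot(min_valid > 0, min_valid < max_valid,
            invalid_fraction_threshold >= 0, invalid_fraction_threshold <= 1)
  structure(
    list(min_valid = min_valid, max_valid = max_valid,
         invalid_fraction_threshold = invalid_fraction_threshold),
    class = "validity_config"
  )
}

#' Screen a trace against the physiological range
#'
#' A sample is valid when it is finite and inside `[min_valid, max_valid]`;
#' the whole trace is ruled invalid when the invalid-sample fraction exceeds
#' the configured threshold.
#'
#' @param trace A [conductance_trace()].
#' @param cfg A [validity_config()].
#' @return A list with `sample_valid` (logical per sample), `invalid_fraction`
#'   and `trace_invalid` (the trace-level verdict).
#' @export
validity_flags <- function(trace, cfg = validity_config()) {
  stopifnot(inherits(trace, "conductance_trace"), inherits(cfg, "validity_config"))
  if (!length(trace$times)) stop("trace is empty", call. = FALSE)
  y <- trace$conductance
  ok <- is.finite(y) & y >= cfg$min_valid & y <= cfg$max_valid
  frac <- mean(!ok)
  list(sample_valid = ok, invalid_fraction = frac,
       trace_invalid = frac > cfg$invalid_fraction_threshold)
}

#' Local baseline of a conductance trace
#'
#' For every sample, the mean (or median) of all samples whose timestamps lie
#' within `+/- half_window` seconds of it. The window is a closed interval,
#' truncated at the trace boundaries; non-finite samples are excluded from
#' the average. Subtracting this from the trace isolates the phasic
#' component.
#'
#' @param trace A [conductance_trace()].
#' @param half_window Half-width of the window, in seconds (default 4 s).
#' @param method `"mean"` (default) or `"median"`.
#' @return Numeric vector of baseline values, one per sample.
#' @export
local_baseline <- function(trace, half_window = 4, method = c("mean", "median")) {
  stopifnot(inherits(trace, "conductance_trace"), half_window > 0)
  method <- match.arg(method)
  t <- trace$times
  y <- trace$conductance
  n <- length(t)
  if (n < 1L) stop("trace must contain at least one sample", call. = FALSE)
  # tolerance so that samples at exactly +/- half_window are kept despite
  # floating-point timestamp arithmetic
  eps <- 1e-9
  lo <- findInterval(t - half_window - eps, t) + 1L
  hi <- findInterval(t + half_window + eps, t)
  stat <- if (method == "mean") mean else stats::median
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- y[lo[i]:hi[i]]
    w <- w[is.finite(w)]
    out[i] <- if (length(w)) stat(w) else NA_real_
  }
  out
}

#' Phasic component by local-baseline subtraction
#'
#' Subtracts the windowed local baseline from the trace; the remainder is the
#' phasic (rapid, event-driven) signal. At every sample
#' `phasic + baseline == raw` by construction.
#'
#' @inheritParams local_baseline
#' @return An object of class `phasic_trace` with fields `times`, `phasic`,
#'   `baseline` and `half_window`.
#' @export
phasic_component <- function(trace, half_window = 4, method = c("mean", "median")) {
  method <- match.arg(method)
  base <- local_baseline(trace, half_window = half_window, method = method)
  structure(
    list(times = trace$times, phasic = trace$conductance - base,
         baseline = base, half_window = half_window, method = method),
    class = "phasic_trace"
  )
}

#' Min-max normalization to [0, 1]
#'
#' Affine rescaling `(v - min) / (max - min)` over the finite entries. A
#' constant input has no scale and maps to all zeros (declared degenerate
#' rule, avoids 0/0); non-finite entries pass through unchanged.
#'
#' @param values Numeric vector.
#' @return Vector of the same length with finite entries in `[0, 1]`.
#' @export
normalize_01 <- function(values) {
  stopifnot(is.numeric(values), length(values) > 0)
  fin <- is.finite(values)
  if (!any(fin)) return(values)
  rng <- range(values[fin])
  if (rng[1] == rng[2]) {
    values[fin] <- 0
    return(values)
  }
  values[fin] <- (values[fin] - rng[1]) / (rng[2] - rng[1])
  values
}
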