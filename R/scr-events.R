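#' SCR detection configuration
#'
#' @param onset_amplitude_criterion Minimum rise above the preceding local
#'   minimum for an onset to be declared, in microSiemens. 0.05 uS is the
#'   conventional strict criterion; 0.01 uS the sensitive one.
#' @param er_latency_window Latency window (seconds after the stimulus) inside
#'   which a response counts as event-related (ER-SCR); responses outside it
#'   are non-specific (NS-SCR).
#' @param min_peak_prominence Events with onset-to-peak amplitude below this
#'   are discarded; also used as the hysteresis drop that closes an event.
#'   Defaults to the onset criterion.
#' @param smooth_samples Odd number of samples for the centered moving mean
#'   on which onsets and peaks are *located* (values are always read from
#'   the raw trace). With seconds-scale sampling a 5-sample window keeps
#'   sample-to-sample noise excursions from masquerading as responses while
#'   leaving the seconds-long SCR flanks intact; 1 disables smoothing.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(onset_amplitude_criterion = 0.05,
                             er_latency_window = c(1, 5),
                             min_peak_prominence = onset_amplitude_criterion,
                             smooth_samples = 5L) {
  stopifnot(onset_amplitude_criterion > 0,
            length(er_latency_window) == 2L,
            er_latency_window[1] >= 0,
            er_latency_window[1] < er_latency_window[2],
            min_peak_prominence > 0,
            smooth_samples >= 1, smooth_samples %% 2 == 1)
  structure(
    list(onset_amplitude_criterion = onset_amplitude_criterion,
         er_latency_window = as.numeric(er_latency_window),
         min_peak_prominence = min_peak_prominence,
         smooth_samples = as.integer(smooth_samples)),
    class = "detection_config"
  )
}

# centered moving mean with truncated edge windows; non-finite samples stay
# non-finite and are excluded from neighbouring windows
moving_mean <- function(y, k) {
  if (k <= 1L) return(y)
  h <- (k - 1L) %/% 2L
  n <- length(y)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!is.finite(y[i])) next
    w <- y[max(1L, i - h):min(n, i + h)]
    out[i] <- mean(w[is.finite(w)])
  }
  out
}

empty_events <- function() {
  data.frame(
    onset_index = integer(0), peak_index = integer(0),
    onset_time = numeric(0), onset_value = numeric(0),
    peak_time = numeric(0), peak_value = numeric(0),
    amplitude = numeric(0), rise_time = numeric(0),
    recovery_time = numeric(0), recovery_censored = logical(0),
    recovery_lower_bound = numeric(0),
    latency = numeric(0), latency_class = character(0)
  )
}

#' Detect skin-conductance responses in a trace
#'
#' Scans a lightly smoothed copy of the signal (centered moving mean over
#' `smooth_samples` samples) with a two-state machine. While searching, the
#' running local minimum is tracked; a response is declared at the first
#' sample whose rising excursion exceeds `onset_amplitude_criterion` above
#' that minimum, and the onset is then placed at the last preceding sample
#' still within half a criterion of the minimum — the point where the curve
#' leaves its pre-response level (the criterion certifies the response;
#' reading the onset at the crossing itself would clip up to one sample's
#' rise plus the criterion off every amplitude). The event then tracks its
#' running maximum and closes when the smoothed signal has fallen by
#' `min_peak_prominence` below it (hysteresis, so sample-to-sample noise
#' during a slow rise does not fragment a response) or the trace ends.
#'
#' Values are always read from the raw trace: the peak sample is the raw
#' maximum among the immediate neighbours of the smoothed argmax, and onset
#' and peak values — hence the amplitude — are raw sample values. Onset and
#' peak *times* are refined off the sample grid by intersecting
#' least-squares lines through the rising flank and the first post-peak
#' samples (see the package vignette); with seconds-scale sampling this
#' removes most of the quantization bias in rise-time estimates. Events
#' whose amplitude is below `min_peak_prominence` are discarded.
#'
#' Detection runs on the raw conductance by default, since the conventional
#' amplitude bookkeeping (onset value, peak value) is in raw microSiemens;
#' set `signal = "phasic"` to scan the baseline-subtracted signal instead
#' (event characterization still reports raw-trace values).
#'
#' @param trace A [conductance_trace()].
#' @param phasic Optional [phasic_component()] of the same trace; required
#'   when `signal = "phasic"`.
#' @param cfg A [detection_config()].
#' @param stimulus_time Optional stimulus onset (seconds). When given, each
#'   event is assigned `latency = onset_time - stimulus_time` and a latency
#'   class: `"ER_SCR"` inside the configured window, `"NS_SCR"` outside.
#' @param signal `"raw"` (default) or `"phasic"`.
#' @return A data frame of class `scr_events`, one row per event, ordered by
#'   onset time, with columns `onset_index`, `peak_index`, `onset_time`,
#'   `onset_value`, `peak_time`, `peak_value`, `amplitude`, `rise_time`,
#'   `recovery_time`, `recovery_censored`, `recovery_lower_bound`, `latency`,
#'   `latency_class`.
#' @export
detect_events <- function(trace, phasic = NULL, cfg = detection_config(),
                          stimulus_time = NULL, signal = c("raw", "phasic")) {
  stopifnot(inherits(trace, "conductance_trace"), inherits(cfg, "detection_config"))
  signal <- match.arg(signal)
  t <- trace$times
  if (length(t) > 1 && any(diff(t) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  y <- if (signal == "phasic") {
    stopifnot(inherits(phasic, "phasic_trace"),
              length(phasic$phasic) == length(t))
    phasic$phasic
  } else {
    trace$conductance
  }
  n <- length(y)
  yr <- trace$conductance           # values are always reported from the raw trace
  ys <- moving_mean(y, cfg$smooth_samples)  # onsets/peaks are located on this
  events <- list()
  in_event <- FALSE
  min_idx <- NA_integer_
  onset_idx <- NA_integer_
  max_idx <- NA_integer_

  close_event <- function(onset_idx, max_idx) {
    if (max_idx <= onset_idx) return(NULL)
    # the smoothed argmax locates the peak; snap to the raw maximum among
    # its immediate neighbours so the reported peak value is not averaged down
    cand <- intersect(seq.int(max_idx - 1L, max_idx + 1L),
                      seq.int(onset_idx + 1L, n))
    cand <- cand[is.finite(yr[cand])]
    if (!length(cand)) return(NULL)
    max_idx <- cand[which.max(yr[cand])]
    amp <- yr[max_idx] - yr[onset_idx]
    if (!is.finite(amp) || amp < cfg$min_peak_prominence) return(NULL)
    ev <- characterize(trace, onset_idx, max_idx)
    # refine the onset time by intersecting the rising flank with the
    # pre-response level: with seconds-scale sampling the trough sample can
    # sit several seconds before the true rise start, so the flank's
    # least-squares line crossing y[onset] is a better estimate of when the
    # response began. Values (onset_value, amplitude) stay sample-exact.
    flank <- if (max_idx - onset_idx >= 3L) {
      seq.int(onset_idx + 1L, max_idx - 1L)
    } else {
      integer(0)
    }
    flank <- flank[is.finite(yr[flank])]
    if (length(flank) >= 2L) {
      slope <- stats::cov(t[flank], yr[flank]) / stats::var(t[flank])
      if (is.finite(slope) && slope > 0) {
        t0 <- mean(t[flank]) - (mean(yr[flank]) - yr[onset_idx]) / slope
        t0 <- min(max(t0, t[onset_idx]), t[max_idx] - 1e-9)
        ev$onset_time <- t0
        # the true peak (the rise/decay corner) usually falls between
        # samples; intersect the rising line with a short line through the
        # first post-peak samples to locate it, constrained to one sample
        # interval around the sampled maximum
        decay <- seq_len(n) > max_idx & seq_len(n) <= max_idx + 4L & is.finite(yr)
        decay <- which(decay)
        if (length(decay) >= 2L) {
          s2 <- stats::cov(t[decay], yr[decay]) / stats::var(t[decay])
          if (is.finite(s2) && s2 < slope) {
            a1 <- mean(yr[flank]) - slope * mean(t[flank])
            a2 <- mean(yr[decay]) - s2 * mean(t[decay])
            tc <- (a2 - a1) / (slope - s2)
            step_before <- t[max_idx] - t[max(onset_idx, max_idx - 1L)]
            step_after <- t[min(n, max_idx + 1L)] - t[max_idx]
            if (is.finite(tc) && tc > t0 &&
                tc >= t[max_idx] - step_before && tc <= t[max_idx] + step_after) {
              shift <- t[max_idx] - tc
              ev$peak_time <- tc
              # recovery is measured from the peak; keep the 50%-crossing
              # and the censored lower bound anchored to the refined peak
              if (!ev$recovery_censored) {
                ev$recovery_time <- ev$recovery_time + shift
              } else if (is.finite(ev$recovery_lower_bound)) {
                ev$recovery_lower_bound <- ev$recovery_lower_bound + shift
              }
            }
          }
        }
        ev$rise_time <- ev$peak_time - ev$onset_time
      }
    }
    ev
  }

  for (i in seq_len(n)) {
    if (!is.finite(ys[i])) {
      # flagged sample: close any open event and restart the search after it
      if (in_event) {
        ev <- close_event(onset_idx, max_idx)
        if (!is.null(ev)) events[[length(events) + 1L]] <- ev
        in_event <- FALSE
      }
      min_idx <- NA_integer_
      next
    }
    if (!in_event) {
      if (is.na(min_idx) || ys[i] < ys[min_idx]) {
        min_idx <- i
      } else if (ys[i] - ys[min_idx] >= cfg$onset_amplitude_criterion) {
        in_event <- TRUE
        # the criterion certifies a response; the onset itself is where the
        # curve leaves the pre-response level, so backtrack from the crossing
        # to the last sample still within half a criterion of the minimum
        onset_idx <- min_idx
        for (k in seq.int(i - 1L, min_idx)) {
          if (is.finite(ys[k]) &&
              ys[k] - ys[min_idx] <= cfg$onset_amplitude_criterion / 2) {
            onset_idx <- k
            break
          }
        }
        max_idx <- i
      }
    } else {
      if (ys[i] > ys[max_idx]) max_idx <- i
      if (ys[max_idx] - ys[i] >= cfg$min_peak_prominence) {
        ev <- close_event(onset_idx, max_idx)
        if (!is.null(ev)) events[[length(events) + 1L]] <- ev
        in_event <- FALSE
        min_idx <- i
      }
    }
  }
  if (in_event) {
    ev <- close_event(onset_idx, max_idx)
    if (!is.null(ev)) events[[length(events) + 1L]] <- ev
  }

  out <- if (length(events)) do.call(rbind, events) else empty_events()
  if (!is.null(stimulus_time) && nrow(out)) {
    out$latency <- out$onset_time - stimulus_time
    win <- cfg$er_latency_window
    out$latency_class <- ifelse(out$latency >= win[1] & out$latency <= win[2],
                                "ER_SCR", "NS_SCR")
  }
  out <- out[order(out$onset_time), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("scr_events", "data.frame")
  out
}

#' Characterize one skin-conductance response
#'
#' Given onset and peak sample indices, computes the response descriptors:
#' amplitude (peak value minus onset value), rise time (peak time minus onset
#' time) and recovery time, the time from the peak until the conductance
#' falls to half the amplitude below the peak. The half-recovery crossing is
#' linearly interpolated between the bracketing samples; onset and peak times
#' snap to sample times. When the recording ends before the half-recovery
#' level is reached, the recovery time is censored and only a lower bound is
#' reported: the time from the start of the recovery phase to the end of the
#' recording.
#'
#' @param trace A [conductance_trace()].
#' @param onset_index,peak_index Sample indices of the onset and the peak
#'   (onset strictly before peak).
#' @param recovery_start_time Start of the recovery phase, used for the
#'   censored lower bound. Defaults to the peak time; recordings in which the
#'   conductance plateaus after the peak may pass the observed start of the
#'   decline instead.
#' @return A one-row data frame with the `scr_events` columns (latency fields
#'   `NA` / `"unknown"`).
#' @export
characterize <- function(trace, onset_index, peak_index,
                         recovery_start_time = NULL) {
  stopifnot(inherits(trace, "conductance_trace"))
  n <- length(trace$times)
  stopifnot(onset_index >= 1L, peak_index <= n, onset_index < peak_index)
  t <- trace$times
  y <- trace$conductance
  onset_value <- y[onset_index]
  peak_value <- y[peak_index]
  if (!is.finite(onset_value) || !is.finite(peak_value) || peak_value <= onset_value) {
    stop("not an event: peak value must exceed onset value", call. = FALSE)
  }
  amplitude <- peak_value - onset_value
  rise_time <- t[peak_index] - t[onset_index]
  if (is.null(recovery_start_time)) recovery_start_time <- t[peak_index]

  # half-recovery: first time after the peak at which y <= peak - amplitude/2
  target <- peak_value - amplitude / 2
  rec_time <- NA_real_
  censored <- TRUE
  if (peak_index < n) {
    after <- seq.int(peak_index + 1L, n)
    hit <- after[which(is.finite(y[after]) & y[after] <= target)]
    if (length(hit)) {
      j <- hit[1L]
      # interpolate between the last sample above target and the crossing one
      k <- j - 1L
      while (k > peak_index && !is.finite(y[k])) k <- k - 1L
      t_cross <- if (k >= peak_index && is.finite(y[k]) && y[k] > target) {
        t[k] + (y[k] - target) / (y[k] - y[j]) * (t[j] - t[k])
      } else {
        t[j]
      }
      rec_time <- t_cross - t[peak_index]
      censored <- FALSE
    }
  }
  data.frame(
    onset_index = as.integer(onset_index), peak_index = as.integer(peak_index),
    onset_time = t[onset_index], onset_value = onset_value,
    peak_time = t[peak_index], peak_value = peak_value,
    amplitude = amplitude, rise_time = rise_time,
    recovery_time = rec_time, recovery_censored = censored,
    recovery_lower_bound = if (censored) t[n] - recovery_start_time else NA_real_,
    latency = NA_real_, latency_class = "unknown"
  )
}

#' Full width at half amplitude of a response
#'
#' Duration for which the conductance stays at or above
#' `onset_value + amplitude / 2` around the peak, with the two flank
#' crossings linearly interpolated between samples. Flanks that never drop
#' below the half level inside the recording are truncated at the trace
#' boundaries.
#'
#' @param trace A [conductance_trace()].
#' @param event A one-row `scr_events` data frame (or a row of one).
#' @return Width in seconds.
#' @export
peak_width <- function(trace, event) {
  stopifnot(inherits(trace, "conductance_trace"), nrow(event) == 1L)
  t <- trace$times
  y <- trace$conductance
  n <- length(t)
  p <- event$peak_index
  level <- event$onset_value + event$amplitude / 2

  # walk left from the peak to the first sample below the level
  i <- p
  while (i > 1L && is.finite(y[i - 1L]) && y[i - 1L] >= level) i <- i - 1L
  t_left <- if (i == 1L || !is.finite(y[i - 1L])) {
    t[i]
  } else {
    t[i - 1L] + (level - y[i - 1L]) / (y[i] - y[i - 1L]) * (t[i] - t[i - 1L])
  }
  # walk right
  j <- p
  while (j < n && is.finite(y[j + 1L]) && y[j + 1L] >= level) j <- j + 1L
  t_right <- if (j == n || !is.finite(y[j + 1L])) {
    t[j]
  } else {
    t[j] + (y[j] - level) / (y[j] - y[j + 1L]) * (t[j + 1L] - t[j])
  }
  t_right - t_left
}

#' Export detected events as CSV
#'
#' Writes one row per event with the header
#' `onset_s,onset_us,peak_s,peak_us,amplitude_us,rise_s,recovery_s,censored,latency_class`.
#'
#' @param events An `scr_events` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  df <- data.frame(
    onset_s = events$onset_time, onset_us = events$onset_value,
    peak_s = events$peak_time, peak_us = events$peak_value,
    amplitude_us = events$amplitude, rise_s = events$rise_time,
    recovery_s = events$recovery_time, censored = events$recovery_censored,
    latency_class = events$latency_class
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
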