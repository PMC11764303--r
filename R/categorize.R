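#' Categorization configuration
#'
#' @param magnitude_margin Minimum event amplitude (microSiemens) for the
#'   peak-phase level to count as meaningfully above the pre-response level.
#'   This operationalizes the "magnitude comparison" rule as a descriptive
#'   margin rather than a hypothesis test.
#' @param flatline_sd Traces whose sample standard deviation falls below this
#'   floor (microSiemens) are ruled invalid as flat-line sensor faults, even
#'   when the constant value lies inside the physiological band.
#' @return An object of class `categorize_config`.
#' @export
categorize_config <- function(magnitude_margin = 0.1, flatline_sd = 0.005) {
  stopifnot(magnitude_margin >= 0, flatline_sd >= 0)
  structure(list(magnitude_margin = magnitude_margin, flatline_sd = flatline_sd),
            class = "categorize_config")
}

#' Rule-based stressed / not-stressed / invalid categorization
#'
#' A trace is **invalid** when the validity screen rules it out of the 1-20 uS
#' physiological band, or when it is a flat line (standard deviation below
#' `flatline_sd`): a constant reading, even inside the band, indicates a
#' sensor fault rather than skin. Otherwise it is **stressed** when at least
#' one detected response shows the canonical onset-peak-recovery pattern
#' (positive rise time) *and* an amplitude at least `magnitude_margin` above
#' the pre-response level; with no such response the subject is **not
#' stressed** (at rest).
#'
#' @param trace A [conductance_trace()].
#' @param events Events from [detect_events()] on the same trace (may be
#'   empty; ignored for invalid traces).
#' @param validity Result of [validity_flags()] for the trace.
#' @param cfg A [categorize_config()].
#' @return An object of class `trace_category`: a list with `label` (one of
#'   `"stressed"`, `"not_stressed"`, `"invalid"`), `n_events`, `pattern_ok`,
#'   `magnitude_ok` and a free-text `evidence` summary.
#' @export
categorize_trace <- function(trace, events, validity, cfg = categorize_config()) {
  stopifnot(inherits(trace, "conductance_trace"), inherits(cfg, "categorize_config"))
  y <- trace$conductance[is.finite(trace$conductance)]
  trace_sd <- if (length(y) > 1) stats::sd(y) else 0

  if (isTRUE(validity$trace_invalid)) {
    return(new_trace_category(
      "invalid", NA_integer_, NA, NA,
      sprintf("%.0f%% of samples outside the physiological band",
              100 * validity$invalid_fraction)
    ))
  }
  if (trace_sd < cfg$flatline_sd) {
    return(new_trace_category(
      "invalid", NA_integer_, NA, NA,
      sprintf("flat line (sd %.4g uS < %.4g uS): sensor fault", trace_sd,
              cfg$flatline_sd)
    ))
  }
  n_events <- if (is.null(events)) 0L else nrow(events)
  if (n_events > 0L) {
    pattern <- events$rise_time > 0 & events$peak_time > events$onset_time
    magnitude <- events$amplitude >= cfg$magnitude_margin
    hit <- pattern & magnitude
    if (any(hit)) {
      best <- which.max(events$amplitude * hit)
      return(new_trace_category(
        "stressed", n_events, TRUE, TRUE,
        sprintf("%d response(s); largest passing amplitude %.3g uS (rise %.3g s)",
                n_events, events$amplitude[best], events$rise_time[best])
      ))
    }
    return(new_trace_category(
      "not_stressed", n_events, any(pattern), any(magnitude),
      sprintf("%d response(s) but none pass both pattern and magnitude checks",
              n_events)
    ))
  }
  new_trace_category("not_stressed", 0L, FALSE, FALSE,
                     "no discernible peaks relative to the local average")
}

new_trace_category <- function(label, n_events, pattern_ok, magnitude_ok, evidence) {
  structure(
    list(label = label, n_events = n_events, pattern_ok = pattern_ok,
         magnitude_ok = magnitude_ok, evidence = evidence),
    class = "trace_category"
  )
}

#' @export
print.trace_category <- function(x, ...) {
  cat(sprintf("<trace_category> %s (%s)\n", x$label, x$evidence))
  invisible(x)
}

# round-half-up to integer (base round() is half-to-even)
round_half_up <- function(x) floor(x + 0.5)

#' Summarize a cohort of trace categories
#'
#' Counts each label and reports integer percentages rounded half-up. Note
#' that half-up-rounded percentages need not sum to exactly 100.
#'
#' @param categories A list of [categorize_trace()] results (or a character
#'   vector of labels).
#' @return An object of class `cohort_summary` with counts `n_total`,
#'   `n_stressed`, `n_not_stressed`, `n_invalid` and integer percentages
#'   `pct_stressed`, `pct_not_stressed`, `pct_invalid`.
#' @examples
#' summarize_cohort(rep(c("stressed", "not_stressed", "invalid"), c(36, 12, 3)))
#' @export
summarize_cohort <- function(categories) {
  labels <- if (is.character(categories)) {
    categories
  } else {
    vapply(categories, function(x) x$label, character(1))
  }
  if (!length(labels)) stop("empty cohort", call. = FALSE)
  bad <- setdiff(unique(labels), c("stressed", "not_stressed", "invalid"))
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  n <- length(labels)
  ns <- sum(labels == "stressed")
  nn <- sum(labels == "not_stressed")
  ni <- sum(labels == "invalid")
  structure(
    list(n_total = n, n_stressed = ns, n_not_stressed = nn, n_invalid = ni,
         pct_stressed = round_half_up(100 * ns / n),
         pct_not_stressed = round_half_up(100 * nn / n),
         pct_invalid = round_half_up(100 * ni / n)),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    "<cohort_summary> n = %d: stressed %d (%d%%), not stressed %d (%d%%), invalid %d (%d%%)\n",
    x$n_total, x$n_stressed, x$pct_stressed, x$n_not_stressed,
    x$pct_not_stressed, x$n_invalid, x$pct_invalid
  ))
  invisible(x)
}
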