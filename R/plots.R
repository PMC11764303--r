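#' Plot a GSR trace
#'
#' The four standard views of a recording:
#' \describe{
#'   \item{`"raw"`}{conductance against time;}
#'   \item{`"phasic"`}{the baseline-subtracted phasic signal;}
#'   \item{`"peaks"`}{the raw signal with detected peaks marked as red
#'     crosses and the mean conductance as a dashed line;}
#'   \item{`"combined"`}{raw and phasic signals overlaid.}
#' }
#'
#' @param trace A [conductance_trace()].
#' @param phasic Its [phasic_component()] (required for `"phasic"` and
#'   `"combined"`).
#' @param events Its [detect_events()] result (used by `"peaks"`).
#' @param type One of `"raw"`, `"phasic"`, `"peaks"`, `"combined"`.
#' @return A ggplot object.
#' @export
plot_gsr <- function(trace, phasic = NULL, events = NULL,
                     type = c("raw", "phasic", "peaks", "combined")) {
  stopifnot(inherits(trace, "conductance_trace"))
  type <- match.arg(type)
  df <- data.frame(time = trace$times, gsr = trace$conductance)
  if (type %in% c("phasic", "combined")) {
    stopifnot(inherits(phasic, "phasic_trace"))
    dfp <- data.frame(time = phasic$times, phasic = phasic$phasic)
  }
  base_labs <- ggplot2::labs(x = "time (s)", y = "conductance (µS)")
  switch(type,
    raw = ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$gsr)) +
      ggplot2::geom_line(color = "steelblue") +
      base_labs + ggplot2::ggtitle("Raw GSR signal"),
    phasic = ggplot2::ggplot(dfp, ggplot2::aes(.data$time, .data$phasic)) +
      ggplot2::geom_line(color = "darkorange") +
      ggplot2::labs(x = "time (s)", y = "phasic (µS)") +
      ggplot2::ggtitle("Phasic GSR signal"),
    peaks = {
      p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$gsr)) +
        ggplot2::geom_line(color = "steelblue") +
        ggplot2::geom_hline(yintercept = mean(df$gsr[is.finite(df$gsr)]),
                            linetype = "dashed", color = "grey40") +
        base_labs + ggplot2::ggtitle("GSR peaks and mean value")
      if (!is.null(events) && nrow(events)) {
        p <- p + ggplot2::geom_point(
          data = data.frame(time = events$peak_time, gsr = events$peak_value),
          shape = 4, color = "red", size = 3, stroke = 1.2
        )
      }
      p
    },
    combined = ggplot2::ggplot() +
      ggplot2::geom_line(data = df, ggplot2::aes(.data$time, .data$gsr),
                         color = "steelblue") +
      ggplot2::geom_line(data = dfp, ggplot2::aes(.data$time, .data$phasic),
                         color = "darkorange") +
      base_labs + ggplot2::ggtitle("Combined raw and phasic GSR")
  )
}

#' Save the four standard plots for one trace
#'
#' Writes `<prefix>_raw.png`, `<prefix>_phasic.png`, `<prefix>_peaks.png`
#' and `<prefix>_combined.png`.
#'
#' @param trace,phasic,events As in [plot_gsr()].
#' @param prefix Output path prefix.
#' @param width,height,dpi Passed to [ggplot2::ggsave()].
#' @return Character vector of the files written, invisibly.
#' @export
save_trace_plots <- function(trace, phasic, events, prefix,
                             width = 6, height = 3.5, dpi = 120) {
  types <- c("raw", "phasic", "peaks", "combined")
  paths <- paste0(prefix, "_", types, ".png")
  for (k in seq_along(types)) {
    p <- plot_gsr(trace, phasic = phasic, events = events, type = types[k])
    ggplot2::ggsave(paths[k], p, width = width, height = height, dpi = dpi)
  }
  invisible(paths)
}
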