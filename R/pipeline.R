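#' Configuration for a full pipeline run
#'
#' Exactly one input source must be given: a directory of trace CSV files
#' (`input_dir`, dialects as in [read_trace_csv()]) or a simulation
#' specification (`cohort`, a [cohort_spec()]).
#'
#' @param input_dir Directory of `*.csv` traces, or `NULL`.
#' @param cohort A [cohort_spec()], or `NULL`.
#' @param device [device_params()] used to convert ADC traces.
#' @param validity [validity_config()].
#' @param detection [detection_config()].
#' @param categorization [categorize_config()].
#' @param half_window Baseline half-window in seconds.
#' @param baseline_method `"mean"` or `"median"`.
#' @param ml Run the clustering + SVM layer (needs at least 4 non-invalid
#'   traces with both pseudo-classes present).
#' @param ml_kernel,ml_nu,ml_folds SVM settings, see [train_classifier()].
#' @param out_dir Output directory for the JSON report, CSV exports and
#'   plots; `NULL` disables file output.
#' @param n_plot_traces Number of traces (from the first) to plot.
#' @param seed Integer seed for the ML layer (and the simulation, unless the
#'   cohort spec carries its own).
#' @return An object of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, cohort = NULL,
                       device = device_params(),
                       validity = validity_config(),
                       detection = detection_config(),
                       categorization = categorize_config(),
                       half_window = 4, baseline_method = "mean",
                       ml = TRUE, ml_kernel = "rbf", ml_nu = NULL,
                       ml_folds = 5,
                       out_dir = NULL, n_plot_traces = 4, seed = 1) {
  if (is.null(input_dir) == is.null(cohort)) {
    stop("exactly one of input_dir or cohort must be given", call. = FALSE)
  }
  structure(
    list(input_dir = input_dir, cohort = cohort, device = device,
         validity = validity, detection = detection,
         categorization = categorization, half_window = half_window,
         baseline_method = baseline_method, ml = ml, ml_kernel = ml_kernel,
         ml_nu = ml_nu, ml_folds = ml_folds, out_dir = out_dir,
         n_plot_traces = n_plot_traces, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key-value document mirroring the module configuration keys:
#' `supply_voltage`, `adc_levels`, `series_resistance_kohm`,
#' `half_window_s`, `baseline_method`, `valid_range_us` (two numbers),
#' `invalid_fraction_threshold`, `onset_amplitude_criterion`,
#' `er_latency_window`, `min_peak_prominence`, `magnitude_margin`,
#' `flatline_sd`, `ml`, `ml_kernel`, `ml_nu`, `ml_folds`, `input_dir`,
#' `out_dir`, `n_plot_traces`, `seed`, and the simulation block
#' `simulate: {n_stressed, n_calm, n_invalid, ...}`. Keys not present keep
#' their defaults; arguments passed in `...` override file values (CLI
#' flags take precedence over the file).
#'
#' @param path Path to the YAML file.
#' @param ... Overrides forwarded to [run_config()].
#' @return A [run_config()].
#' @export
read_run_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  grab <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default
  device <- device_params(
    supply_voltage = grab("supply_voltage", 5.0),
    adc_levels = grab("adc_levels", 1024L),
    series_resistance_kohm = grab("series_resistance_kohm", 500)
  )
  vr <- unlist(grab("valid_range_us", c(1, 20)))
  validity <- validity_config(
    min_valid = vr[1], max_valid = vr[2],
    invalid_fraction_threshold = grab("invalid_fraction_threshold", 0.5)
  )
  crit <- grab("onset_amplitude_criterion", 0.05)
  detection <- detection_config(
    onset_amplitude_criterion = crit,
    er_latency_window = unlist(grab("er_latency_window", c(1, 5))),
    min_peak_prominence = grab("min_peak_prominence", crit)
  )
  categorization <- categorize_config(
    magnitude_margin = grab("magnitude_margin", 0.1),
    flatline_sd = grab("flatline_sd", 0.005)
  )
  cohort <- if (!is.null(cfg$simulate)) {
    s <- cfg$simulate
    cohort_spec(
      n_stressed = s$n_stressed %||% 36, n_calm = s$n_calm %||% 12,
      n_invalid = s$n_invalid %||% 3,
      tonic_range = unlist(s$tonic_range %||% c(2, 8)),
      noise_sd = s$noise_sd %||% 0.02, duration = s$duration %||% 120,
      sample_interval = s$sample_interval %||% 2,
      seed = s$seed %||% grab("seed", 1)
    )
  } else {
    NULL
  }
  base <- list(
    input_dir = grab("input_dir", NULL), cohort = cohort, device = device,
    validity = validity, detection = detection, categorization = categorization,
    half_window = grab("half_window_s", 4),
    baseline_method = grab("baseline_method", "mean"),
    ml = grab("ml", TRUE), ml_kernel = grab("ml_kernel", "rbf"),
    ml_nu = grab("ml_nu", NULL), ml_folds = grab("ml_folds", 5),
    out_dir = grab("out_dir", NULL),
    n_plot_traces = grab("n_plot_traces", 4), seed = grab("seed", 1)
  )
  overrides <- list(...)
  base[names(overrides)] <- overrides
  do.call(run_config, base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Loads or simulates the cohort, converts ADC traces to conductance,
#' screens validity, extracts the phasic component, detects and
#' characterizes responses, categorizes every trace, summarizes the cohort,
#' and (optionally) runs the k-means pseudo-labeling + SVM layer. When
#' `out_dir` is set, writes `report.json`, `features.csv`, per-trace event
#' CSVs and the four standard plot types for the first few traces.
#'
#' Unreadable input files are recorded as per-file errors and the run
#' continues; an empty cohort aborts.
#'
#' @param cfg A [run_config()].
#' @return The run report (a list, also serialized to JSON when `out_dir` is
#'   set) with blocks `meta`, `traces`, `cohort`, `ml` and `errors`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  errors <- list()
  truth <- NULL

  if (!is.null(cfg$cohort)) {
    sim <- simulate_cohort(cfg$cohort)
    traces <- sim$traces
    truth <- sim$truth
  } else {
    files <- list.files(cfg$input_dir, pattern = "\\.csv$", full.names = TRUE)
    traces <- list()
    for (f in files) {
      tr <- tryCatch(read_trace_csv(f, device = cfg$device),
                     error = function(e) e)
      if (inherits(tr, "error")) {
        errors[[basename(f)]] <- conditionMessage(tr)
      } else {
        traces[[tools::file_path_sans_ext(basename(f))]] <- tr
      }
    }
  }
  if (!length(traces)) stop("empty cohort: no readable traces", call. = FALSE)

  per_trace <- vector("list", length(traces))
  names(per_trace) <- names(traces)
  categories <- vector("list", length(traces))
  feature_rows <- vector("list", length(traces))
  analyzed <- vector("list", length(traces))

  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    conv_flagged <- 0L
    if (inherits(tr, "raw_trace")) {
      tr <- convert_trace(tr)
      conv_flagged <- sum(tr$flags != "")
    }
    val <- validity_flags(tr, cfg$validity)
    ph <- phasic_component(tr, half_window = cfg$half_window,
                           method = cfg$baseline_method)
    ev <- if (val$trace_invalid) empty_events() else {
      detect_events(tr, phasic = ph, cfg = cfg$detection)
    }
    cat_i <- categorize_trace(tr, ev, val, cfg$categorization)
    categories[[i]] <- cat_i
    analyzed[[i]] <- list(trace = tr, phasic = ph, events = ev)
    if (cat_i$label != "invalid") {
      feature_rows[[i]] <- extract_features(tr, ph, ev)
    }
    per_trace[[i]] <- list(
      id = names(traces)[i],
      n_samples = length(tr$times),
      conversion = list(n_flagged = conv_flagged),
      validity = list(invalid_fraction = val$invalid_fraction,
                      trace_invalid = val$trace_invalid),
      n_events = nrow(ev),
      events = ev[, setdiff(names(ev), c("onset_index", "peak_index"))],
      category = unclass(cat_i)
    )
  }

  cohort <- summarize_cohort(categories)

  ml <- NULL
  kept <- !vapply(feature_rows, is.null, logical(1))
  if (isTRUE(cfg$ml) && sum(kept) >= 4) {
    feats <- do.call(rbind, feature_rows[kept])
    norm <- normalize_features(feats[, c("peak_amplitude", "phasic_max")])
    ml <- tryCatch({
      km <- kmeans_stress_clusters(norm, seed = cfg$seed)
      clf <- train_classifier(norm, km$labels, kernel = cfg$ml_kernel,
                              nu = cfg$ml_nu, n_folds = cfg$ml_folds,
                              seed = cfg$seed)
      pred <- predict(clf, norm)
      out <- list(
        kernel = cfg$ml_kernel, nu = cfg$ml_nu,
        best = as.list(clf$best),
        pseudo_label_counts = as.list(table(km$labels))
      )
      out$vs_pseudo_labels <- unclass(evaluate_classification(pred, km$labels))
      if (!is.null(truth)) {
        truth_kept <- ifelse(truth$label[kept] == "stressed", "stressed", "relaxed")
        out$vs_truth <- unclass(evaluate_classification(pred, truth_kept))
      }
      out
    }, error = function(e) {
      errors[["ml"]] <<- conditionMessage(e)
      NULL
    })
  }

  report <- list(
    meta = list(
      package = "edastress",
      version = as.character(utils::packageVersion("edastress")),
      seed = cfg$seed,
      n_traces = length(traces),
      half_window_s = cfg$half_window,
      baseline_method = cfg$baseline_method,
      onset_amplitude_criterion = cfg$detection$onset_amplitude_criterion,
      valid_range_us = c(cfg$validity$min_valid, cfg$validity$max_valid),
      magnitude_margin = cfg$categorization$magnitude_margin,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    traces = per_trace,
    cohort = unclass(cohort),
    ml = ml,
    errors = errors
  )

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, na = "null",
                         pretty = TRUE)
    if (any(kept)) {
      write_features_csv(do.call(rbind, feature_rows[kept]),
                         file.path(cfg$out_dir, "features.csv"),
                         ids = names(traces)[kept])
    }
    n_plot <- min(cfg$n_plot_traces, length(traces))
    for (i in seq_len(n_plot)) {
      a <- analyzed[[i]]
      save_trace_plots(a$trace, a$phasic, a$events,
                       file.path(cfg$out_dir, names(traces)[i]))
      if (nrow(a$events)) {
        write_events_csv(a$events,
                         file.path(cfg$out_dir,
                                   paste0(names(traces)[i], "_events.csv")))
      }
    }
  }
  report
}
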