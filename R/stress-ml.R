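#' Extract per-trace features for stress classification
#'
#' Features summarize the response morphology of a single recording: the
#' largest detected response amplitude (`peak_amplitude`, 0 when no response
#' was detected), its full width at half amplitude (`peak_width`, 0 likewise),
#' the mean conductance (`mean_gsr`), the excess of the peak conductance over
#' the mean (`amp_minus_mean`) and the maximum of the phasic signal
#' (`phasic_max`).
#'
#' @param trace A [conductance_trace()].
#' @param phasic Its [phasic_component()].
#' @param events Its [detect_events()] result.
#' @return A one-row data frame with columns `peak_amplitude`, `peak_width`,
#'   `mean_gsr`, `amp_minus_mean`, `phasic_max`.
#' @export
extract_features <- function(trace, phasic, events) {
  stopifnot(inherits(trace, "conductance_trace"), inherits(phasic, "phasic_trace"))
  y <- trace$conductance[is.finite(trace$conductance)]
  mean_gsr <- mean(y)
  ph <- phasic$phasic[is.finite(phasic$phasic)]
  phasic_max <- if (length(ph)) max(ph) else 0
  if (!is.null(events) && nrow(events)) {
    best <- which.max(events$amplitude)
    pa <- events$amplitude[best]
    pw <- peak_width(trace, events[best, , drop = FALSE])
    amm <- events$peak_value[best] - mean_gsr
  } else {
    pa <- 0
    pw <- 0
    amm <- max(y) - mean_gsr
  }
  data.frame(peak_amplitude = pa, peak_width = pw, mean_gsr = mean_gsr,
             amp_minus_mean = amm, phasic_max = phasic_max)
}

#' Min-max normalize feature columns across a cohort
#'
#' Applies [normalize_01()] column-wise, so every feature is comparable on a
#' common `[0, 1]` scale before clustering or classification.
#'
#' @param features Data frame of numeric feature columns (one row per trace).
#' @return Data frame of the same shape with each column normalized.
#' @export
normalize_features <- function(features) {
  stopifnot(is.data.frame(features), nrow(features) > 0)
  as.data.frame(lapply(features, normalize_01))
}

#' K-means pseudo-labeling of stressed vs relaxed traces
#'
#' Partitions the cohort feature matrix into k = 2 clusters by Euclidean
#' distance and assigns the semantic labels: the cluster whose centroid has
#' the larger `peak_amplitude` coordinate is `"stressed"`, the other
#' `"relaxed"`. Deterministic for a given seed.
#'
#' @param features Numeric data frame / matrix of features, one row per
#'   trace; must contain the column named by `amplitude_col`.
#' @param seed Integer seed for the k-means initialization.
#' @param amplitude_col Column used for the semantic cluster assignment.
#' @return A list with `labels` (character vector, `"stressed"`/`"relaxed"`),
#'   `centroids` (2-row matrix) and the underlying [stats::kmeans()] `fit`.
#' @export
kmeans_stress_clusters <- function(features, seed = 1,
                                   amplitude_col = "peak_amplitude") {
  x <- as.matrix(as.data.frame(features))
  stopifnot(is.numeric(x), amplitude_col %in% colnames(x))
  if (nrow(unique(x)) < 2) {
    stop("degenerate clustering: need at least 2 distinct points", call. = FALSE)
  }
  set.seed(seed)
  fit <- stats::kmeans(x, centers = 2, nstart = 10)
  stressed_cluster <- which.max(fit$centers[, amplitude_col])
  labels <- unname(ifelse(fit$cluster == stressed_cluster, "stressed", "relaxed"))
  list(labels = labels, centroids = fit$centers, fit = fit)
}

default_cost_grid <- c(0.01, 0.1, 1, 10, 100)
default_gamma_grid <- c(0.1, 0.5, 1, 2, 5)

#' Train an SVM / NuSVM stress classifier with cross-validated grid search
#'
#' Fits a support-vector classifier on labeled feature vectors. For the
#' standard C-SVM, the cost parameter (and, for the RBF kernel, gamma) is
#' chosen by mean k-fold cross-validation accuracy over a grid; ties go to
#' the smaller cost, then the smaller gamma. Supplying `nu` switches to the
#' Nu-parameterization (nu-classification), in which `nu` bounds the margin
#' -error fraction and is held fixed while gamma is still grid-searched for
#' the RBF kernel. Fold assignment is seeded, so the search is reproducible.
#'
#' @param features Numeric data frame / matrix, one row per observation.
#' @param labels Class labels (two classes required).
#' @param kernel `"linear"` or `"rbf"`.
#' @param cost_grid Candidate C values (C-SVM only).
#' @param gamma_grid Candidate gamma values (RBF kernel only). The
#'   conventional default grid includes gamma = 2.
#' @param nu Optional nu in (0, 1) selecting the NuSVM variant.
#' @param n_folds Number of cross-validation folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `stress_classifier`: list with the fitted
#'   e1071 `model`, `best` parameters, the full `cv_table` of grid-point
#'   accuracies, and the training metadata.
#' @export
train_classifier <- function(features, labels, kernel = c("linear", "rbf"),
                             cost_grid = default_cost_grid,
                             gamma_grid = default_gamma_grid,
                             nu = NULL, n_folds = 5, seed = 1) {
  kernel <- match.arg(kernel)
  x <- as.matrix(as.data.frame(features))
  y <- factor(labels)
  stopifnot(nrow(x) == length(y), n_folds >= 2)
  if (nlevels(y) != 2) {
    stop("need exactly two classes in the training labels", call. = FALSE)
  }
  if (!is.null(nu)) stopifnot(nu > 0, nu < 1)
  svm_kernel <- if (kernel == "rbf") "radial" else "linear"

  grid <- if (is.null(nu)) {
    if (kernel == "rbf") {
      expand.grid(cost = cost_grid, gamma = gamma_grid)
    } else {
      expand.grid(cost = cost_grid, gamma = NA_real_)
    }
  } else {
    if (kernel == "rbf") {
      expand.grid(cost = NA_real_, gamma = gamma_grid)
    } else {
      expand.grid(cost = NA_real_, gamma = NA_real_)
    }
  }

  fit_one <- function(xtr, ytr, cost, gamma) {
    args <- list(x = xtr, y = ytr, kernel = svm_kernel, scale = FALSE)
    if (is.null(nu)) {
      args$type <- "C-classification"
      args$cost <- cost
    } else {
      args$type <- "nu-classification"
      args$nu <- nu
    }
    if (svm_kernel == "radial") args$gamma <- gamma
    do.call(e1071::svm, args)
  }

  set.seed(seed)
  n <- nrow(x)
  fold <- sample(rep(seq_len(n_folds), length.out = n))
  cv_acc <- vapply(seq_len(nrow(grid)), function(g) {
    accs <- vapply(seq_len(n_folds), function(k) {
      tr <- fold != k
      if (nlevels(droplevels(y[tr])) < 2) return(NA_real_)
      m <- tryCatch(fit_one(x[tr, , drop = FALSE], y[tr],
                            grid$cost[g], grid$gamma[g]),
                    error = function(e) NULL)
      if (is.null(m)) return(NA_real_)
      mean(stats::predict(m, x[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  }, numeric(1))
  cv_table <- cbind(grid, cv_accuracy = cv_acc)

  # best by CV accuracy; ties -> smaller cost, then smaller gamma
  ord <- order(-cv_acc, grid$cost, grid$gamma)
  best <- cv_table[ord[1L], , drop = FALSE]
  model <- fit_one(x, y, best$cost, best$gamma)

  structure(
    list(model = model, kernel = kernel, nu = nu, best = best,
         cv_table = cv_table, levels = levels(y),
         feature_names = colnames(x), n_folds = n_folds, seed = seed),
    class = "stress_classifier"
  )
}

#' @export
print.stress_classifier <- function(x, ...) {
  cat(sprintf(
    "<stress_classifier> %s kernel%s; best CV accuracy %.3f (cost = %s, gamma = %s)\n",
    x$kernel,
    if (is.null(x$nu)) "" else sprintf(", nu = %g", x$nu),
    x$best$cv_accuracy,
    format(x$best$cost), format(x$best$gamma)
  ))
  invisible(x)
}

#' Predict stress labels for new feature vectors
#'
#' @param object A [train_classifier()] fit.
#' @param newdata Feature data frame / matrix with the training columns.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.stress_classifier <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata))
  as.character(stats::predict(object$model, x))
}

#' Classification metrics: precision, recall, F1, accuracy
#'
#' Confusion counts are taken with `positive` as the positive class;
#' precision = TP/(TP+FP), recall = TP/(TP+FN), and F1 is their harmonic
#' mean. Metrics whose denominator is zero are reported as 0 (declared
#' convention for degenerate predictions). Class fractions of the
#' *predicted* labels are reported as percentages.
#'
#' @param predicted,truth Equal-length label vectors.
#' @param positive Label treated as the positive (stressed) class.
#' @return An object of class `classification_metrics` with fields `tp`,
#'   `fp`, `fn`, `tn`, `precision`, `recall`, `f1`, `accuracy`,
#'   `pct_stressed`, `pct_unstressed`.
#' @examples
#' evaluate_classification(c("stressed", "relaxed"), c("stressed", "stressed"))
#' @export
evaluate_classification <- function(predicted, truth, positive = "stressed") {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have the same length", call. = FALSE)
  }
  if (!length(truth)) stop("empty label vectors", call. = FALSE)
  tp <- sum(predicted == positive & truth == positive)
  fp <- sum(predicted == positive & truth != positive)
  fn <- sum(predicted != positive & truth == positive)
  tn <- sum(predicted != positive & truth != positive)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         precision = precision, recall = recall, f1 = f1,
         accuracy = (tp + tn) / length(truth),
         pct_stressed = 100 * mean(predicted == positive),
         pct_unstressed = 100 * mean(predicted != positive)),
    class = "classification_metrics"
  )
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("<classification_metrics> accuracy %.3f, precision %.3f, recall %.3f,",
           " F1 %.3f (TP %d FP %d FN %d TN %d); predicted %s%% stressed\n"),
    x$accuracy, x$precision, x$recall, x$f1, x$tp, x$fp, x$fn, x$tn,
    format(x$pct_stressed)
  ))
  invisible(x)
}

#' Write a cohort feature table to CSV
#'
#' @param features Data frame of features, one row per trace.
#' @param path Output path.
#' @param ids Optional trace identifiers written as the first column.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path, ids = NULL) {
  df <- if (is.null(ids)) features else cbind(data.frame(id = ids), features)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
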