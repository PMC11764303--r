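test_that("features summarize a recording's response morphology", {
  flat <- make_trace(rep(3, 40))
  f <- extract_features(flat, phasic_component(flat), detect_events(flat))
  expect_equal(f$peak_amplitude, 0)
  expect_equal(f$peak_width, 0)
  expect_equal(f$mean_gsr, 3)

  tr <- worked_stress_trace()
  ph <- phasic_component(tr)
  ev <- detect_events(tr)
  f2 <- extract_features(tr, ph, ev)
  expect_equal(f2$peak_amplitude, 2.51, tolerance = 0.02)
  expect_gt(f2$phasic_max, 0)
  expect_equal(f2$amp_minus_mean, max(ev$peak_value) - f2$mean_gsr)

  sh <- scr_shape(stimulus_time = 10, latency = 4, amplitude = 1.5,
                  rise_time = 10, recovery_half_time = 15)
  sim <- simulate_trace(list(sh), tonic_baseline = 3, noise_sd = 0)
  f3 <- extract_features(sim$trace, phasic_component(sim$trace),
                         detect_events(sim$trace))
  expect_equal(f3$peak_amplitude, 1.5, tolerance = 0.08)
})

test_that("feature normalization puts every column on [0,1]", {
  set.seed(4)
  df <- data.frame(peak_amplitude = runif(20, 0, 3), mean_gsr = runif(20, 2, 9))
  nd <- normalize_features(df)
  expect_equal(unname(vapply(nd, min, numeric(1))), c(0, 0))
  expect_equal(unname(vapply(nd, max, numeric(1))), c(1, 1))
  expect_identical(order(nd$peak_amplitude), order(df$peak_amplitude))
})

test_that("k-means pseudo-labels match the brute-force 2-partition optimum", {
  # brute force: minimal within-cluster SSE over all 2-partitions
  pts <- c(0.1, 0.15, 2.0, 2.2)
  best <- NULL; best_sse <- Inf
  for (mask in 1:(2^length(pts) - 2)) {
    grp <- as.logical(bitwAnd(mask, 2^(seq_along(pts) - 1)))
    if (!any(grp) || all(grp)) next
    sse <- sum((pts[grp] - mean(pts[grp]))^2) +
      sum((pts[!grp] - mean(pts[!grp]))^2)
    if (sse < best_sse) { best_sse <- sse; best <- grp }
  }
  want <- if (mean(pts[best]) > mean(pts[!best])) best else !best

  km <- kmeans_stress_clusters(data.frame(peak_amplitude = pts), seed = 1)
  expect_identical(km$labels, ifelse(want, "stressed", "relaxed"))
})

test_that("separated blobs cluster cleanly and label by amplitude", {
  toy <- blob_toy()
  km <- kmeans_stress_clusters(toy$x, seed = 3)
  expect_identical(km$labels, toy$labels)
  # same partition when the rows are permuted (same seed policy)
  perm <- c(11:20, 1:10)
  km2 <- kmeans_stress_clusters(toy$x[perm, ], seed = 3)
  expect_identical(km2$labels, toy$labels[perm])
  expect_error(
    kmeans_stress_clusters(data.frame(peak_amplitude = rep(1, 5)), seed = 1),
    "degenerate"
  )
})

test_that("a linearly separable toy is fit to 100% training accuracy", {
  toy <- blob_toy()
  for (kern in c("linear", "rbf")) {
    clf <- train_classifier(toy$x, toy$labels, kernel = kern, seed = 2)
    expect_identical(predict(clf, toy$x), toy$labels)
    expect_equal(clf$best$cv_accuracy, 1)
  }
  # NuSVM variant at the two conventional nu values
  for (nu in c(0.02, 0.2)) {
    clf <- train_classifier(toy$x, toy$labels, kernel = "rbf", nu = nu,
                            seed = 2)
    expect_identical(predict(clf, toy$x), toy$labels)
  }
})

test_that("the RBF kernel beats the linear kernel on an XOR pattern", {
  toy <- xor_toy()
  lin <- train_classifier(toy$x, toy$labels, kernel = "linear", seed = 7)
  rbf <- train_classifier(toy$x, toy$labels, kernel = "rbf", seed = 7)
  expect_gt(rbf$best$cv_accuracy, lin$best$cv_accuracy)
  expect_gte(rbf$best$cv_accuracy, 0.9)
  expect_lte(lin$best$cv_accuracy, 0.75)
})

test_that("training-set duplication does not move the decision boundary", {
  toy <- blob_toy()
  probe <- expand.grid(peak_amplitude = seq(-1, 4, 0.5),
                       phasic_max = seq(-1, 4, 0.5))
  clf1 <- train_classifier(toy$x, toy$labels, kernel = "linear", seed = 2)
  clf2 <- train_classifier(rbind(toy$x, toy$x), c(toy$labels, toy$labels),
                           kernel = "linear", seed = 2)
  expect_identical(predict(clf1, probe), predict(clf2, probe))
})

test_that("degenerate label sets are rejected", {
  toy <- blob_toy()
  expect_error(train_classifier(toy$x, rep("stressed", nrow(toy$x))),
               "two classes")
})

test_that("classification metrics follow the confusion-count formulas", {
  perfect <- evaluate_classification(c("stressed", "relaxed"),
                                     c("stressed", "relaxed"))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$accuracy, 1)

  # tp = 1, fp = 1, fn = 1 -> P = R = F1 = 0.5
  m <- evaluate_classification(c("stressed", "stressed", "relaxed"),
                               c("stressed", "relaxed", "stressed"))
  expect_equal(c(m$precision, m$recall, m$f1), c(0.5, 0.5, 0.5))

  # nothing predicted positive while positives exist: degenerate convention
  z <- evaluate_classification(rep("relaxed", 3),
                               c("stressed", "relaxed", "relaxed"))
  expect_equal(c(z$precision, z$recall, z$f1), c(0, 0, 0))
  expect_equal(z$pct_stressed, 0)
  expect_equal(z$pct_unstressed, 100)

  expect_error(evaluate_classification("a", c("a", "b")), "same length")
})

test_that("F1 is the harmonic mean and never exceeds max(P, R)", {
  set.seed(12)
  for (i in 1:20) {
    n <- 30
    pred <- sample(c("stressed", "relaxed"), n, replace = TRUE)
    truth <- sample(c("stressed", "relaxed"), n, replace = TRUE)
    m <- evaluate_classification(pred, truth)
    if (m$precision + m$recall > 0) {
      expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
      expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
    }
    expect_gte(m$accuracy, 0)
    expect_lte(m$accuracy, 1)
  }
})
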