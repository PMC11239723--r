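test_that("confusion counts enumerate records per class", {
  pred <- matrix(c(1, 1, 0, 0), 4, 1)
  lab <- matrix(c(1, 0, 0, 1), 4, 1)
  cc <- confusionCounts(pred, lab)
  expect_equal(as.numeric(cc@counts[1, c("TP", "FP", "TN", "FN")]),
               c(1, 1, 1, 1))
  # perfect and inverted predictors
  y <- matrix(rbinom(40, 1, 0.4), 10, 4)
  ccP <- confusionCounts(y, y)
  expect_true(all(ccP@counts[, c("FP", "FN")] == 0))
  ccI <- confusionCounts(1 - y, y)
  expect_true(all(ccI@counts[, c("TP", "TN")] == 0))
  expect_error(confusionCounts(matrix(0.5, 2, 1), matrix(1, 2, 1)), "binary")
  expect_true(all(rowSums(cc@counts) == 4))
})

test_that("thresholded metrics follow their defining ratios", {
  m <- classificationMetrics(c(TP = 90, TN = 5, FP = 3, FN = 2))
  expect_equal(m$accuracy, 0.95)
  m2 <- classificationMetrics(c(TP = 2, TN = 0, FP = 1, FN = 1))
  expect_equal(m2$precision, 2 / 3)
  expect_equal(m2$recall, 2 / 3)
  expect_equal(m2$f1, 2 / 3)
  # degenerate 0/0 convention
  m3 <- classificationMetrics(c(TP = 0, TN = 4, FP = 0, FN = 1))
  expect_equal(m3$precision, 0)
  expect_equal(m3$f1, 0)
})

test_that("rank AUROC matches its examples and tie conventions", {
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(c(0.9, 0.2, 0.8, 0.3), c(1, 1, 0, 0)), 0.5)
  expect_equal(auroc(rep(0.4, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  expect_error(auroc(c(1, 2), c(1, 1)), "both classes")
})

test_that("average-precision AUPRC matches its examples", {
  expect_equal(auprc(c(0.9, 0.8, 0.7), c(1, 1, 0)), 1)
  expect_equal(auprc(c(0.9, 0.8, 0.7), c(0, 1, 0)), 0.5)
  expect_equal(auprc(0.3, 1), 1)
  expect_error(auprc(c(1, 2), c(0, 0)), "positives")
})

test_that("AUROC agrees with an established ROC implementation", {
  set.seed(71)
  for (trial in 1:10) {
    n <- 60
    scores <- rnorm(n)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auroc(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("rank metrics equal brute-force enumeration", {
  set.seed(33)
  for (trial in 1:120) {
    n <- sample(4:50, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), bruteAuroc(scores, labels),
                 tolerance = 1e-12)
    expect_equal(auprc(scores, labels), bruteAuprc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUROC is invariant under strictly increasing transforms", {
  set.seed(9)
  s <- rnorm(40); y <- rbinom(40, 1, 0.5)
  a <- auroc(s, y)
  expect_equal(auroc(exp(s), y), a, tolerance = 1e-12)
  expect_equal(auroc(3 * s + 2, y), a, tolerance = 1e-12)
  # complement under score negation (tie-free scores)
  expect_equal(auroc(-s, y), 1 - a, tolerance = 1e-12)
})

test_that("weighted average interpolates per-class values by support", {
  expect_equal(weightedAverage(c(0.8, 0.4), c(3, 1)), 0.7)
  expect_equal(weightedAverage(c(0.2, 0.6, 0.7), c(2, 2, 2)),
               mean(c(0.2, 0.6, 0.7)))
  expect_equal(weightedAverage(0.42, 5), 0.42)
  expect_error(weightedAverage(c(1, 1), c(0, 0)), "support")
  v <- c(0.3, 0.9); s <- c(4, 1)
  w <- weightedAverage(v, s)
  expect_true(w >= min(v) && w <= max(v))
})

test_that("evaluation on oracle and constant scores behaves as designed", {
  ds <- shortCohort(40, seed = 2)
  cfg <- modelConfig(nLayers = 1, modelDim = 4, stateSize = 4, nClasses = 2,
                     nLeads = 12, classNames = c("AF", "RBBB"))
  model <- buildClassifier(cfg, seed = 1)
  y <- t(cohortArrays(ds$records, c("AF", "RBBB"))$y)
  oracle <- y * 0.98 + 0.01
  colnames(oracle) <- c("AF", "RBBB")
  rep <- evaluateClassifier(model, ds$records, scores = oracle)
  expect_equal(unname(rep@weighted["f1"]), 1)
  expect_equal(unname(rep@weighted["auroc"]), 1)
  expect_equal(unname(rep@weighted["auprc"]), 1)
  const <- matrix(0.5, nrow(y), 2, dimnames = list(NULL, c("AF", "RBBB")))
  repC <- evaluateClassifier(model, ds$records, scores = const)
  expect_equal(unname(repC@weighted["auroc"]), 0.5)
  # class subsetting controls the report rows
  repS <- evaluateClassifier(model, ds$records, scores = oracle,
                             classSubset = "AF")
  expect_equal(nrow(perClassMetrics(repS)), 1L)
  expect_error(evaluateClassifier(model, list()), "empty")
})

test_that("lead masking empties exactly k seeded leads", {
  rec <- synthRecord("AF", syntheticCohortConfig(length = 1024L), 1)
  expect_identical(ecgSignal(maskLeads(rec, 0)), ecgSignal(rec))
  expect_true(all(ecgSignal(maskLeads(rec, 12, seed = 4)) == 0))
  m1 <- maskLeads(rec, 6, seed = 9)
  zeroRows <- which(rowSums(abs(ecgSignal(m1))) == 0)
  expect_length(zeroRows, 6L)
  m2 <- maskLeads(rec, 6, seed = 9)
  expect_identical(ecgSignal(m1), ecgSignal(m2))
  keep <- setdiff(seq_len(12), zeroRows)
  expect_identical(ecgSignal(m1)[keep, ], ecgSignal(rec)[keep, ])
  expect_error(maskLeads(rec, 13), "\\[0, 12\\]")
})

test_that("robustness curve baseline and controls are consistent", {
  ds <- shortCohort(30, seed = 6)
  cfg <- modelConfig(nLayers = 1, modelDim = 4, stateSize = 4, nClasses = 2,
                     nLeads = 12, classNames = c("AF", "RBBB"))
  model <- buildClassifier(cfg, seed = 2)
  rc <- robustnessCurve(model, ds$records, schedule = c(4, 8), repeats = 1,
                        seed = 3)
  expect_equal(rc@metrics$k, c(0, 4, 8))
  base <- evaluateClassifier(model, ds$records)
  expect_equal(rc@metrics$f1[1], unname(base@weighted["f1"]), tolerance = 1e-12)
  rc2 <- robustnessCurve(model, ds$records, schedule = c(4, 8), repeats = 1,
                         seed = 3)
  expect_identical(rc@metrics, rc2@metrics)
  # a model blind to its input (zero lead projection) yields a flat curve
  blind <- model
  blind@params$emb_W[] <- 0
  rcB <- robustnessCurve(blind, ds$records, schedule = c(4, 8), repeats = 1,
                         seed = 5)
  expect_equal(rcB@metrics$f1, rep(rcB@metrics$f1[1], 3), tolerance = 1e-12)
  expect_equal(rcB@metrics$accuracy, rep(rcB@metrics$accuracy[1], 3),
               tolerance = 1e-12)
})
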