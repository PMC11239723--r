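test_that("binary cross-entropy matches closed forms", {
  expect_equal(bceLoss(0.5, 1), log(2), tolerance = 1e-12)
  expect_equal(bceLoss(c(0.5, 0.5), c(0, 1)), log(2), tolerance = 1e-12)
  # loss decreases monotonically as probabilities approach the labels
  y <- c(1, 0, 1, 1)
  ps <- seq(0.5, 0.99, by = 0.07)
  losses <- vapply(ps, function(p)
    bceLoss(ifelse(y == 1, p, 1 - p), y), numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_true(is.finite(bceLoss(c(0, 1), c(1, 0))))  # clamped at the edges
  expect_error(bceLoss(c(0.1, 0.2), 1), "length")
})

test_that("cosine annealing hits its endpoints and midpoint", {
  expect_equal(cosineAnnealedLr(0, 200, 0.001), 0.001)
  expect_equal(cosineAnnealedLr(200, 200, 0.001), 0)
  expect_equal(cosineAnnealedLr(100, 200, 0.001), 0.0005)
  expect_equal(cosineAnnealedLr(50, 200, 0.002, 0.001),
               0.001 + 0.001 * (1 + cos(pi / 4)) / 2)
  expect_error(cosineAnnealedLr(-1, 200, 0.001), "epoch")
  expect_error(cosineAnnealedLr(201, 200, 0.001), "epoch")
})

test_that("train/validation split is disjoint, exhaustive and stratified", {
  ds <- shortCohort(100, seed = 8)
  sp <- splitTrainVal(ds$records, 0.15, seed = 1)
  expect_equal(length(sp$train) + length(sp$val), 100L)
  ids <- function(recs) vapply(recs, recordId, character(1))
  expect_length(intersect(ids(sp$train), ids(sp$val)), 0L)
  expect_equal(length(sp$val), 15L)
  sp2 <- splitTrainVal(ds$records, 0.15, seed = 1)
  expect_identical(ids(sp2$val), ids(sp$val))
  # stratification: prevalent labels appear on both sides
  lab <- function(recs, cl) sum(vapply(recs, function(r)
    recordLabels(r)[[cl]], integer(1)))
  for (cl in c("AF", "RBBB")) {
    expect_gt(lab(sp$train, cl), 0)
    expect_gt(lab(sp$val, cl), 0)
  }
  expect_error(splitTrainVal(list(), 0.15), "nonempty")
  expect_error(splitTrainVal(ds$records, 0), "valFraction")
})

test_that("short training runs reduce the loss and log the schedule", {
  ds <- shortCohort(60, seed = 12)
  cfg <- modelConfig(nLayers = 2, modelDim = 8, stateSize = 8, nClasses = 2,
                     nLeads = 12, dropout = 0.1, classNames = c("AF", "RBBB"))
  model <- buildClassifier(cfg, seed = 1)
  tc <- trainingConfig(epochs = 5, batchSize = 16, seed = 2)
  fit <- trainClassifier(model, ds$records, tc)
  h <- historyTable(fit$history)
  expect_equal(nrow(h), 5L)
  expect_lt(h$train_loss[5], h$train_loss[1])
  expect_equal(h$lr, cosineAnnealedLr(0:4, 5, 0.001, 0), tolerance = 1e-15)
  expect_true(all(is.finite(unlist(h))))
})

test_that("training is reproducible and a frozen model evaluates identically", {
  ds <- shortCohort(30, seed = 5)
  cfg <- modelConfig(nLayers = 1, modelDim = 6, stateSize = 8, nClasses = 2,
                     nLeads = 12, dropout = 0.1, classNames = c("AF", "RBBB"))
  tc <- trainingConfig(epochs = 2, batchSize = 8, seed = 4)
  f1 <- trainClassifier(buildClassifier(cfg, seed = 1), ds$records, tc)
  f2 <- trainClassifier(buildClassifier(cfg, seed = 1), ds$records, tc)
  expect_identical(historyTable(f1$history), historyTable(f2$history))
  expect_identical(f1$model@params, f2$model@params)
  r1 <- evaluateClassifier(f1$model, ds$records)
  r2 <- evaluateClassifier(f1$model, ds$records)
  expect_identical(weightedMetrics(r1), weightedMetrics(r2))
})

test_that("single-batch edge case trains for exactly one step", {
  ds <- shortCohort(6, seed = 3)
  cfg <- modelConfig(nLayers = 1, modelDim = 4, stateSize = 4, nClasses = 2,
                     nLeads = 12, classNames = c("AF", "RBBB"))
  tc <- trainingConfig(epochs = 1, batchSize = 32, valFraction = 0.34,
                       seed = 1)
  fit <- trainClassifier(buildClassifier(cfg, seed = 1), ds$records, tc)
  expect_equal(nrow(historyTable(fit$history)), 1L)
})

test_that("heterogeneous record shapes are rejected with ids", {
  ds <- shortCohort(6, seed = 3)
  odd <- synthRecord("AF", syntheticCohortConfig(length = 300L), 99,
                     recordId = "oddball")
  cfg <- modelConfig(nLayers = 1, modelDim = 4, stateSize = 4, nClasses = 2,
                     nLeads = 12, classNames = c("AF", "RBBB"))
  expect_error(
    trainClassifier(buildClassifier(cfg, seed = 1),
                    c(ds$records, list(odd)),
                    trainingConfig(epochs = 1, batchSize = 4, seed = 1)),
    "oddball")
})

test_that("label-shuffled training cannot beat chance (leakage guard)", {
  ds <- shortCohort(80, seed = 23)
  shuffled <- withr::with_seed(99, {
    perm <- sample(length(ds$records))
    mapply(function(r, j) {
      r@labels <- recordLabels(ds$records[[j]])
      r
    }, ds$records, perm, SIMPLIFY = FALSE)
  })
  cfg <- modelConfig(nLayers = 2, modelDim = 8, stateSize = 8, nClasses = 2,
                     nLeads = 12, dropout = 0.1, classNames = c("AF", "RBBB"))
  tc <- trainingConfig(epochs = 4, batchSize = 16, valFraction = 0.25,
                       seed = 6)
  sp <- splitTrainVal(shuffled, 0.25, seed = 6)
  fit <- trainClassifier(buildClassifier(cfg, seed = 1), sp, tc)
  rep <- evaluateClassifier(fit$model, sp$val)
  # chance-level F1 for a prevalence-p class is at most that of the
  # always-positive predictor, 2p/(1+p)
  y <- cohortArrays(sp$val, c("AF", "RBBB"))$y
  pHat <- rowMeans(y)
  chance <- weightedAverage(2 * pHat / (1 + pHat), rowSums(y))
  f1 <- unname(weightedMetrics(rep)["f1"])
  expect_lt(f1, chance + 0.15)
  au <- unname(weightedMetrics(rep)["auroc"])
  # null-AUROC sd at ~5 positives / 15 negatives is about 0.145; allow a
  # generous band that still flags genuine leakage (AUROC near 0.9+)
  expect_gt(au, 0.15); expect_lt(au, 0.85)
})

test_that("history serializes to CSV", {
  dir <- withr::local_tempdir()
  h <- new("TrainingHistory",
           history = data.frame(epoch = 1:2, train_loss = c(1, 0.5),
                                train_acc = c(0.5, 0.6),
                                val_loss = c(1.1, 0.6),
                                val_acc = c(0.5, 0.55),
                                lr = c(0.001, 0.0005)))
  p <- file.path(dir, "hist.csv")
  writeHistory(h, p)
  back <- read.csv(p)
  expect_equal(back$train_loss, c(1, 0.5))
})
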