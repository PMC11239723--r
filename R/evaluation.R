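#' Per-class confusion counts
#'
#' @param pred binary matrix (records x classes) of predictions.
#' @param labels binary matrix of the same shape.
#' @return a [ConfusionCounts-class] with one row per class.
#' @export
confusionCounts <- function(pred, labels) {
  pred <- as.matrix(pred); labels <- as.matrix(labels)
  assertFlag(all(dim(pred) == dim(labels)),
             "pred and labels must share dimensions")
  assertFlag(all(pred %in% c(0, 1)) && all(labels %in% c(0, 1)),
             "entries must be binary 0/1")
  cls <- colnames(labels)
  if (is.null(cls)) cls <- sprintf("class%d", seq_len(ncol(labels)))
  counts <- t(vapply(seq_len(ncol(labels)), function(j) {
    p <- pred[, j]; y <- labels[, j]
    c(TP = sum(p == 1 & y == 1), TN = sum(p == 0 & y == 0),
      FP = sum(p == 1 & y == 0), FN = sum(p == 0 & y == 1))
  }, numeric(4)))
  rownames(counts) <- cls
  new("ConfusionCounts", counts = counts)
}

#' Thresholded classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, recall `TP/(TP+FN)`, precision
#' `TP/(TP+FP)` and their harmonic mean F1. Degenerate 0/0 ratios are
#' reported as 0.
#'
#' @param counts a [ConfusionCounts-class], or a named numeric vector with
#'   entries TP, TN, FP, FN (single class).
#' @return data.frame with one row per class: accuracy, precision, recall,
#'   f1.
#' @export
classificationMetrics <- function(counts) {
  m <- if (is(counts, "ConfusionCounts")) counts@counts
       else matrix(counts[c("TP", "TN", "FP", "FN")], 1,
                   dimnames = list("class1", c("TP", "TN", "FP", "FN")))
  assertFlag(all(rowSums(m) > 0), "zero total count")
  div0 <- function(num, den) ifelse(den > 0, num / den, 0)
  acc <- (m[, "TP"] + m[, "TN"]) / rowSums(m)
  rec <- div0(m[, "TP"], m[, "TP"] + m[, "FN"])
  prec <- div0(m[, "TP"], m[, "TP"] + m[, "FP"])
  f1 <- div0(2 * prec * rec, prec + rec)
  data.frame(class = rownames(m), accuracy = acc, precision = prec,
             recall = rec, f1 = f1, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a random positive
#' outscores a random negative, with ties credited 1/2.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector; both classes must be present.
#' @return scalar in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  assertFlag(length(scores) == length(labels), "length mismatch")
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  assertFlag(nPos > 0 && nNeg > 0,
             "AUROC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise integral of precision over recall: the mean, over positives,
#' of precision at each positive's rank (ties broken against the positive,
#' i.e. tied negatives count as ranked above).
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector with at least one positive.
#' @return scalar in (0, 1].
#' @export
auprc <- function(scores, labels) {
  labels <- as.numeric(labels)
  assertFlag(length(scores) == length(labels), "length mismatch")
  assertFlag(sum(labels == 1) > 0, "AUPRC undefined without positives")
  ord <- order(scores, labels, decreasing = TRUE)  # ties: negatives first
  y <- labels[ord]
  cumPos <- cumsum(y)
  prec <- cumPos / seq_along(y)
  mean(prec[y == 1])
}

#' Support-weighted average
#'
#' @param values per-class metric values.
#' @param supports per-class positive-label counts (>= 0, sum > 0).
#' @return `sum(values*supports)/sum(supports)`.
#' @export
weightedAverage <- function(values, supports) {
  assertFlag(length(values) == length(supports), "length mismatch")
  assertFlag(all(supports >= 0) && sum(supports) > 0,
             "supports must be nonnegative with positive total")
  sum(values * supports) / sum(supports)
}

#' Evaluate a classifier on labeled records
#'
#' Runs the model on the dataset, binarizes at `threshold`, and reports
#' per-class F1, AUROC, AUPRC and one-vs-rest accuracy together with their
#' support-weighted averages (weights = per-class positive counts).
#' AUROC/AUPRC are `NA` for classes missing a positive (or negative)
#' example and are skipped in the weighted averages.
#'
#' @param model an [S4DClassifier-class].
#' @param records list of labeled [ECGRecord-class] objects.
#' @param threshold binarization threshold.
#' @param classSubset optional subset of class names to evaluate
#'   (e.g. `overlapSubset()`).
#' @param precision forwarded to [modelForward()].
#' @param scores optional precomputed probability matrix (records x
#'   classes, columns named); skips the forward pass.
#' @return a [MetricsReport-class].
#' @export
evaluateClassifier <- function(model, records, threshold = 0.5,
                               classSubset = NULL,
                               precision = "double", scores = NULL) {
  assertFlag(length(records) > 0, "empty dataset")
  classes <- model@config@classNames
  if (!is.null(classSubset)) {
    bad <- setdiff(classSubset, classes)
    assertFlag(length(bad) == 0, "unknown class(es) in subset: %s",
               paste(bad, collapse = ", "))
  }
  if (is.null(scores))
    scores <- probabilities(modelForward(model, records,
                                         precision = precision))
  y <- t(cohortArrays(records, classes)$y)
  colnames(y) <- classes
  use <- if (is.null(classSubset)) classes else classSubset
  scores <- scores[, use, drop = FALSE]
  y <- y[, use, drop = FALSE]
  metricsFromScores(scores, y, threshold)
}

# shared metric assembly from score/label matrices
metricsFromScores <- function(scores, y, threshold = 0.5) {
  pred <- matrix(as.integer(scores >= threshold), nrow(scores), ncol(scores),
                 dimnames = dimnames(scores))
  cc <- confusionCounts(pred, y)
  thr <- classificationMetrics(cc)
  per <- data.frame(class = colnames(y), support = colSums(y),
                    f1 = thr$f1, auroc = NA_real_, auprc = NA_real_,
                    accuracy = thr$accuracy, row.names = NULL,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(y))) {
    if (length(unique(y[, j])) == 2L)
      per$auroc[j] <- auroc(scores[, j], y[, j])
    if (sum(y[, j]) > 0)
      per$auprc[j] <- auprc(scores[, j], y[, j])
  }
  wavg <- function(v) {
    ok <- !is.na(v) & per$support > 0
    if (!any(ok)) return(NA_real_)
    weightedAverage(v[ok], per$support[ok])
  }
  weighted <- c(f1 = wavg(per$f1), auroc = wavg(per$auroc),
                auprc = wavg(per$auprc), accuracy = wavg(per$accuracy))
  new("MetricsReport", perClass = per, weighted = weighted,
      threshold = threshold)
}

#' Mask (empty) leads of a record
#'
#' Sets exactly `k` distinct leads, chosen uniformly under `seed`, to zero;
#' the remaining leads, the lead order and the lead count are unchanged.
#'
#' @param record an [ECGRecord-class].
#' @param k number of leads to empty, `0 <= k <=` lead count.
#' @param seed integer controlling the choice.
#' @return the masked record.
#' @export
maskLeads <- function(record, k, seed = 1L) {
  nl <- nrow(ecgSignal(record))
  assertFlag(k >= 0 && k <= nl, "k must lie in [0, %d], got %s", nl, k)
  if (k == 0) return(record)
  idx <- withSeed(seed, sample(nl, k))
  record@signal[idx, ] <- 0
  record
}

#' Lead-ablation robustness curve
#'
#' For each masking level `k` in the schedule (a `k = 0` baseline is
#' always included), evaluates the model over `repeats` independent
#' maskings (re-drawn per record) and reports the mean weighted metrics.
#'
#' @param model an [S4DClassifier-class].
#' @param records labeled evaluation records.
#' @param schedule masking levels (lead counts to empty).
#' @param repeats independent maskings per level.
#' @param seed integer.
#' @param threshold binarization threshold.
#' @param precision forwarded to [modelForward()].
#' @param classSubset optional class subset.
#' @return a [RobustnessResult-class].
#' @export
robustnessCurve <- function(model, records, schedule = c(2, 4, 6, 8, 10),
                            repeats = 1L, seed = 1L, threshold = 0.5,
                            precision = "double", classSubset = NULL) {
  nl <- nrow(ecgSignal(records[[1]]))
  assertFlag(all(schedule >= 0 & schedule <= nl),
             "schedule values must lie in [0, %d]", nl)
  schedule <- sort(unique(c(0L, as.integer(schedule))))
  maskSeeds <- childSeeds(seed, length(schedule) * repeats * length(records),
                          salt = 77L)
  si <- 0L
  rows <- lapply(schedule, function(k) {
    reps <- vapply(seq_len(repeats), function(r) {
      masked <- lapply(records, function(rec) {
        si <<- si + 1L
        maskLeads(rec, k, seed = maskSeeds[si])
      })
      rep <- evaluateClassifier(model, masked, threshold = threshold,
                                classSubset = classSubset,
                                precision = precision)
      rep@weighted[c("f1", "auroc", "auprc", "accuracy")]
    }, numeric(4))
    data.frame(k = k, f1 = mean(reps["f1", ]), auroc = mean(reps["auroc", ]),
               auprc = mean(reps["auprc", ]),
               accuracy = mean(reps["accuracy", ]))
  })
  new("RobustnessResult", metrics = do.call(rbind, rows),
      repeats = as.integer(repeats), seed = as.integer(seed))
}

#' Write a metrics report as CSV
#'
#' One row per class plus a `weighted_average` row; columns f1, auroc,
#' auprc, accuracy, support.
#'
#' @param report a [MetricsReport-class].
#' @param path output CSV path.
#' @export
writeMetricsReport <- function(report, path) {
  per <- report@perClass
  df <- rbind(
    data.frame(class = per$class, f1 = per$f1, auroc = per$auroc,
               auprc = per$auprc, accuracy = per$accuracy,
               support = per$support, stringsAsFactors = FALSE),
    data.frame(class = "weighted_average", f1 = report@weighted["f1"],
               auroc = report@weighted["auroc"],
               auprc = report@weighted["auprc"],
               accuracy = report@weighted["accuracy"],
               support = sum(per$support), stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname accessors
setMethod("perClassMetrics", "MetricsReport", function(object) object@perClass)
#' @rdname accessors
setMethod("weightedMetrics", "MetricsReport", function(object) object@weighted)

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport (threshold %.2f)\n", object@threshold))
  print(object@perClass, digits = 3)
  w <- object@weighted
  cat(sprintf("  weighted: F1 %.3f  AUROC %.3f  AUPRC %.3f  acc %.3f\n",
              w["f1"], w["auroc"], w["auprc"], w["accuracy"]))
})

setMethod("show", "RobustnessResult", function(object) {
  cat(sprintf("RobustnessResult (%d repeat(s), seed %d)\n",
              object@repeats, object@seed))
  print(object@metrics, digits = 3)
})

setMethod("show", "ConfusionCounts", function(object) {
  cat("ConfusionCounts\n")
  print(object@counts)
})
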