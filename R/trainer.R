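#' Create a training configuration
#'
#' Defaults reproduce the reference optimization recipe: peak learning rate
#' 0.001 annealed to 0 by a cosine schedule, 200 epochs with no early
#' stopping, batch size 32, binary cross-entropy loss and AdamW with
#' decoupled weight decay 0.01.
#'
#' @param learningRate peak learning rate.
#' @param epochs number of epochs (always run in full).
#' @param batchSize mini-batch size.
#' @param weightDecay decoupled weight decay (dense weight matrices and the
#'   SSM output map only).
#' @param lrMin final learning rate of the cosine schedule.
#' @param valFraction validation fraction in (0, 1).
#' @param seed integer, controls the split, shuffling and dropout.
#' @param precision `"single"` (default, fast) or `"double"` compute.
#' @param gradClip global gradient-norm clip; 0 disables clipping.
#' @return a [TrainingConfig-class].
#' @export
trainingConfig <- function(learningRate = 0.001, epochs = 200L,
                           batchSize = 32L, weightDecay = 0.01, lrMin = 0,
                           valFraction = 0.15, seed = 1L,
                           precision = c("single", "double"),
                           gradClip = 0) {
  precision <- match.arg(precision)
  new("TrainingConfig",
      learningRate = learningRate, epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), weightDecay = weightDecay,
      lrMin = lrMin, valFraction = valFraction, seed = as.integer(seed),
      precision = precision, gradClip = gradClip)
}

#' Binary cross-entropy loss
#'
#' Mean over all entries of `-(y*log(p) + (1-y)*log(1-p))`, with
#' probabilities clamped to `[1e-7, 1 - 1e-7]` for finiteness.
#'
#' @param probabilities numeric matrix/vector of probabilities.
#' @param labels 0/1 matrix/vector of the same shape.
#' @return nonnegative scalar.
#' @examples
#' bceLoss(0.5, 1)  # log(2)
#' @export
bceLoss <- function(probabilities, labels) {
  p <- as.numeric(probabilities); y <- as.numeric(labels)
  assertFlag(length(p) == length(y),
             "probabilities and labels differ in length (%d vs %d)",
             length(p), length(y))
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  mean(-(y * log(p) + (1 - y) * log1p(-p)))
}

#' Cosine-annealed learning rate
#'
#' `lr = lrMin + (lrMax - lrMin) * (1 + cos(pi * epoch/totalEpochs)) / 2`.
#'
#' @param epoch current epoch, in `[0, totalEpochs]`.
#' @param totalEpochs schedule horizon.
#' @param lrMax peak learning rate (epoch 0).
#' @param lrMin floor learning rate (epoch `totalEpochs`).
#' @return scalar learning rate.
#' @export
cosineAnnealedLr <- function(epoch, totalEpochs, lrMax, lrMin = 0) {
  assertFlag(all(epoch >= 0 & epoch <= totalEpochs),
             "epoch must lie in [0, totalEpochs]")
  lrMin + (lrMax - lrMin) * (1 + cos(pi * epoch / totalEpochs)) / 2
}

#' Split records into training and validation sets
#'
#' Seeded, disjoint and exhaustive split, stratified by label combination
#' where group sizes permit (singleton label combinations fall back to the
#' global pool).
#'
#' @param records list of [ECGRecord-class] objects.
#' @param valFraction fraction in (0, 1) assigned to validation.
#' @param seed integer.
#' @return list with elements `train` and `val` (lists of records).
#' @export
splitTrainVal <- function(records, valFraction, seed = 1L) {
  assertFlag(length(records) > 0, "dataset must be nonempty")
  assertFlag(is.numeric(valFraction) && valFraction > 0 && valFraction < 1,
             "valFraction must lie strictly inside (0, 1)")
  keys <- vapply(records, function(r) {
    lb <- recordLabels(r)
    paste(names(lb)[lb == 1L], collapse = "+")
  }, character(1))
  n <- length(records)
  valIdx <- withSeed(seed, {
    out <- integer(0)
    leftovers <- integer(0)
    for (k in unique(keys)) {
      idx <- which(keys == k)
      nv <- floor(length(idx) * valFraction)
      if (nv >= 1L) out <- c(out, sample(idx, nv))
      else leftovers <- c(leftovers, idx)
    }
    deficit <- round(n * valFraction) - length(out)
    pool <- setdiff(c(leftovers, setdiff(seq_len(n), out)), out)
    if (deficit > 0 && length(pool))
      out <- c(out, sample(pool, min(deficit, length(pool))))
    sort(out)
  })
  if (length(valIdx) == 0L) valIdx <- withSeed(seed, sample(n, 1L))
  list(train = records[setdiff(seq_len(n), valIdx)],
       val = records[valIdx])
}

# per-entry (micro) accuracy of logits against labels at threshold 0.5
entryAccuracy <- function(logits, labels) {
  mean((logits >= 0) == (labels == 1))
}

adamWUpdate <- function(params, grads, state, lr, weightDecay, decayNames,
                        gradClip = 0) {
  state$t <- state$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  if (gradClip > 0) {
    gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
    if (gn > gradClip) grads <- lapply(grads, function(g) g * gradClip / gn)
  }
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    step <- (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
    if (nm %in% decayNames)
      params[[nm]] <- params[[nm]] - lr * weightDecay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * step
  }
  list(params = params, state = state)
}

#' Train an S4D classifier
#'
#' Full-batch-count training under the configured recipe: AdamW, cosine
#' annealed learning rate (per epoch), binary cross-entropy on the sigmoid
#' outputs, dropout inside blocks. Runs exactly `config@epochs` epochs (no
#' early stopping) and records per-epoch train/validation loss, per-entry
#' accuracy and the learning rate.
#'
#' @param model an [S4DClassifier-class] (fresh or partially trained).
#' @param records list of labeled [ECGRecord-class] objects, or a list with
#'   elements `train` and `val` as produced by [splitTrainVal()] (in which
#'   case the provided split is used as-is).
#' @param config a [TrainingConfig-class].
#' @param classes class names to train on; defaults to the model's
#'   configured classes.
#' @param verbose print one line per epoch.
#' @return list with elements `model` (trained [S4DClassifier-class]) and
#'   `history` ([TrainingHistory-class]).
#' @export
trainClassifier <- function(model, records, config = trainingConfig(),
                            classes = NULL, verbose = FALSE) {
  stopifnot(is(model, "S4DClassifier"), is(config, "TrainingConfig"))
  validObject(config)
  if (is.null(classes)) classes <- model@config@classNames
  if (is.list(records) && !is.null(records$train)) {
    split <- records
  } else {
    split <- splitTrainVal(records, config@valFraction, config@seed)
  }
  checkShapes <- function(recs) {
    shp <- vapply(recs, function(r) paste(dim(ecgSignal(r)), collapse = "x"),
                  character(1))
    if (length(unique(shp)) > 1L) {
      bad <- vapply(recs[shp != shp[1]], recordId, character(1))
      stop("records with mismatching shapes: ", paste(bad, collapse = ", "))
    }
  }
  checkShapes(c(split$train, split$val))

  tr <- cohortArrays(split$train, classes)
  va <- cohortArrays(split$val, classes)
  # start the decoder at the class-prior log-odds so early epochs refine
  # features instead of relearning the base rate
  if (all(model@params$dec_b == 0)) {
    prior <- pmin(pmax(rowMeans(tr$y), 1e-3), 1 - 1e-3)
    model@params$dec_b <- log(prior / (1 - prior))
  }
  P <- dim(tr$x)[1]; L <- dim(tr$x)[2]
  nTr <- dim(tr$x)[3]
  assertFlag(P == model@config@nLeads,
             "records have %d leads; model expects %d", P,
             model@config@nLeads)

  params <- model@params
  state <- list(t = 0L,
                m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  decayNames <- grep("^(emb_W|dec_W|l[0-9]+_(mix_W|gate_W))$",
                     names(params), value = TRUE)
  single <- config@precision == "single"
  cfg <- cppConfig(model@config)

  epochs <- config@epochs
  hist <- data.frame(epoch = seq_len(epochs), train_loss = NA_real_,
                     train_acc = NA_real_, val_loss = NA_real_,
                     val_acc = NA_real_, lr = NA_real_)
  epochSeeds <- childSeeds(config@seed, epochs, salt = 101L)

  evalSet <- function(x, y) {
    B <- dim(x)[3]
    losses <- numeric(0); accs <- numeric(0); ns <- numeric(0)
    for (start in seq(1L, B, by = config@batchSize)) {
      idx <- start:min(start + config@batchSize - 1L, B)
      out <- .cppS4DForward(params, as.numeric(x[, , idx, drop = FALSE]),
                            c(P, L, length(idx)), cfg, single)
      z <- out$logits
      yb <- y[, idx, drop = FALSE]
      l <- mean(pmax(z, 0) - z * yb + log1p(exp(-abs(z))))
      losses <- c(losses, l); ns <- c(ns, length(idx))
      accs <- c(accs, entryAccuracy(z, yb))
    }
    c(loss = sum(losses * ns) / sum(ns), acc = sum(accs * ns) / sum(ns))
  }

  for (e in seq_len(epochs)) {
    lr <- cosineAnnealedLr(e - 1L, epochs, config@learningRate, config@lrMin)
    ord <- withSeed(epochSeeds[e], sample(nTr))
    bl <- 0; ba <- 0; bn <- 0
    batchStarts <- seq(1L, nTr, by = config@batchSize)
    for (bi in seq_along(batchStarts)) {
      idx <- ord[batchStarts[bi]:min(batchStarts[bi] + config@batchSize - 1L,
                                     nTr)]
      xb <- tr$x[, , idx, drop = FALSE]
      yb <- tr$y[, idx, drop = FALSE]
      dropseed <- (epochSeeds[e] + bi * 7919L) %% .Machine$integer.max
      out <- .cppS4DLossGrad(params, as.numeric(xb),
                             c(P, L, length(idx)), cfg, yb,
                             model@config@dropout, as.integer(dropseed),
                             single)
      upd <- adamWUpdate(params, out$grads, state, lr, config@weightDecay,
                         decayNames, config@gradClip)
      params <- upd$params; state <- upd$state
      bl <- bl + out$loss * length(idx)
      ba <- ba + entryAccuracy(out$logits, yb) * length(idx)
      bn <- bn + length(idx)
    }
    ev <- evalSet(va$x, va$y)
    hist$train_loss[e] <- bl / bn
    hist$train_acc[e] <- ba / bn
    hist$val_loss[e] <- ev["loss"]
    hist$val_acc[e] <- ev["acc"]
    hist$lr[e] <- lr
    if (verbose)
      message(sprintf(
        "epoch %3d/%d  lr %.6f  train loss %.4f acc %.4f  val loss %.4f acc %.4f",
        e, epochs, lr, hist$train_loss[e], hist$train_acc[e],
        hist$val_loss[e], hist$val_acc[e]))
  }
  trained <- new("S4DClassifier", config = model@config, params = params,
                 seed = model@seed)
  list(model = trained, history = new("TrainingHistory", history = hist))
}

#' @rdname accessors
setMethod("historyTable", "TrainingHistory", function(object) object@history)

setMethod("show", "TrainingHistory", function(object) {
  h <- object@history
  cat(sprintf("TrainingHistory: %d epoch(s)\n", nrow(h)))
  if (nrow(h)) {
    last <- h[nrow(h), ]
    cat(sprintf("  final: train loss %.4f acc %.4f | val loss %.4f acc %.4f\n",
                last$train_loss, last$train_acc, last$val_loss, last$val_acc))
  }
})

#' Write a training history as CSV
#' @param history a [TrainingHistory-class].
#' @param path output file.
#' @export
writeHistory <- function(history, path) {
  utils::write.csv(history@history, path, row.names = FALSE)
  invisible(path)
}
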