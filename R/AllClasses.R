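#' @import methods
NULL

#' Continuous-time diagonal state-space model
#'
#' Parameters of a bank of per-channel continuous-time single-input
#' single-output state-space models with a purely diagonal state matrix.
#' Each of the \code{nChannels} channels owns \code{stateSize} complex modes,
#' stored as \code{stateSize/2} conjugate-representative modes (the implicit
#' conjugate partner is accounted for by doubling the real part of the
#' output projection), which guarantees real-valued impulse responses.
#'
#' @slot nChannels integer, number of model channels (H).
#' @slot stateSize integer, state dimension N per channel (even; N/2 modes
#'   are stored).
#' @slot a complex matrix (N/2 x H), diagonal of the state matrix A;
#'   \code{Re(a) <= 0} for stability.
#' @slot b complex matrix (N/2 x H), input map B.
#' @slot c complex matrix (N/2 x H), output map C.
#' @slot d numeric length H, feedthrough D.
#' @slot logDelta numeric length H, log of the time step (seconds/sample).
#' @slot conjugatePairs logical; if \code{TRUE} (default) the stored modes
#'   represent conjugate pairs and outputs take \code{2*Re(.)}; if
#'   \code{FALSE} the modes are taken literally (\code{Re(.)} only), which
#'   is useful for real-mode oracles.
#'
#' @seealso [initS4D()], [discretizeZOH()]
#' @export
setClass("ContinuousDiagonalSSM",
  representation(
    nChannels = "integer",
    stateSize = "integer",
    a = "matrix",
    b = "matrix",
    c = "matrix",
    d = "numeric",
    logDelta = "numeric",
    conjugatePairs = "logical"
  )
)

setValidity("ContinuousDiagonalSSM", function(object) {
  msg <- character()
  H <- object@nChannels
  M <- nrow(object@a)
  if (H < 1L) msg <- c(msg, "nChannels must be >= 1")
  if (object@stateSize < 1L) msg <- c(msg, "stateSize must be >= 1")
  if (object@conjugatePairs && object@stateSize %% 2L != 0L)
    msg <- c(msg, "stateSize must be even when modes are conjugate pairs")
  want <- if (object@conjugatePairs) object@stateSize %/% 2L else object@stateSize
  if (M != want)
    msg <- c(msg, sprintf("a has %d mode rows; expected %d", M, want))
  for (nm in c("a", "b", "c")) {
    m <- slot(object, nm)
    if (!is.complex(m)) msg <- c(msg, sprintf("slot '%s' must be complex", nm))
    if (!all(dim(m) == c(M, H)))
      msg <- c(msg, sprintf("slot '%s' must be %d x %d", nm, M, H))
  }
  if (length(object@d) != H) msg <- c(msg, "d must have length nChannels")
  if (length(object@logDelta) != H)
    msg <- c(msg, "logDelta must have length nChannels")
  if (any(Re(object@a) > 1e-12))
    msg <- c(msg, "Re(a) must be <= 0 for all modes (stability)")
  if (any(!is.finite(object@logDelta)))
    msg <- c(msg, "logDelta must be finite (exp(logDelta) > 0)")
  if (length(msg)) msg else TRUE
})

#' Zero-order-hold discretized diagonal state-space model
#'
#' Discrete-time counterpart of [ContinuousDiagonalSSM-class], with
#' \code{aBar = exp(Delta * a)} and \code{bBar = (exp(Delta * a) - 1)/a * b}.
#' The output map \code{c} and feedthrough \code{d} are unchanged by
#' zero-order-hold discretization.
#'
#' @slot nChannels integer, number of channels.
#' @slot stateSize integer, nominal state dimension per channel.
#' @slot aBar complex matrix (modes x channels), discrete diagonal;
#'   \code{|aBar| <= 1}.
#' @slot bBar complex matrix, discrete input map.
#' @slot c complex matrix, output map (equal to the continuous C).
#' @slot d numeric, feedthrough (equal to the continuous D).
#' @slot conjugatePairs logical, see [ContinuousDiagonalSSM-class].
#'
#' @export
setClass("DiscreteDiagonalSSM",
  representation(
    nChannels = "integer",
    stateSize = "integer",
    aBar = "matrix",
    bBar = "matrix",
    c = "matrix",
    d = "numeric",
    conjugatePairs = "logical"
  )
)

setValidity("DiscreteDiagonalSSM", function(object) {
  msg <- character()
  H <- object@nChannels
  M <- nrow(object@aBar)
  for (nm in c("aBar", "bBar", "c")) {
    m <- slot(object, nm)
    if (!is.complex(m)) msg <- c(msg, sprintf("slot '%s' must be complex", nm))
    if (!all(dim(m) == c(M, H)))
      msg <- c(msg, sprintf("slot '%s' must be %d x %d", nm, M, H))
  }
  if (length(object@d) != H) msg <- c(msg, "d must have length nChannels")
  if (any(Mod(object@aBar) > 1 + 1e-9))
    msg <- c(msg, "|aBar| must be <= 1 (discrete stability)")
  if (length(msg)) msg else TRUE
})

#' Materialized state-space convolution kernel
#'
#' The length-L impulse response of a [DiscreteDiagonalSSM-class] (excluding
#' the feedthrough), one row per model channel. Convolving an input with
#' this kernel reproduces the linear recurrence output.
#'
#' @slot values numeric matrix, nChannels x length.
#' @slot length integer, kernel length L.
#'
#' @export
setClass("ConvolutionKernel",
  representation(values = "matrix", length = "integer")
)

setValidity("ConvolutionKernel", function(object) {
  msg <- character()
  if (!is.numeric(object@values)) msg <- c(msg, "values must be numeric")
  if (ncol(object@values) != object@length)
    msg <- c(msg, "ncol(values) must equal length")
  if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (length(msg)) msg else TRUE
})

#' A single multi-lead ECG record
#'
#' Waveform plus metadata for one electrocardiogram recording. Signals are
#' stored leads x samples in millivolts; labels are a multi-hot vector over
#' the abnormality vocabulary (a record may carry several labels, or none).
#'
#' @slot signal numeric matrix, leads x samples (millivolts).
#' @slot samplingRate numeric, Hz.
#' @slot leadNames character, one per signal row (standard 12-lead order is
#'   I, II, III, aVR, aVL, aVF, V1..V6).
#' @slot labels named integer vector of 0/1 over the class vocabulary.
#' @slot recordId character scalar.
#' @slot age numeric scalar (years; NA if unknown).
#' @slot sex character scalar ("M", "F" or NA).
#' @slot excluded logical; TRUE when the record was flagged for exclusion
#'   (e.g. an all-empty signal).
#' @slot padded logical; TRUE when the record was zero-padded to reach the
#'   standard length.
#'
#' @export
setClass("ECGRecord",
  representation(
    signal = "matrix",
    samplingRate = "numeric",
    leadNames = "character",
    labels = "integer",
    recordId = "character",
    age = "numeric",
    sex = "character",
    excluded = "logical",
    padded = "logical"
  ),
  prototype(
    samplingRate = 500,
    recordId = "record",
    age = NA_real_,
    sex = NA_character_,
    excluded = FALSE,
    padded = FALSE
  )
)

setValidity("ECGRecord", function(object) {
  msg <- character()
  if (!is.numeric(object@signal)) msg <- c(msg, "signal must be numeric")
  if (any(!is.finite(object@signal))) msg <- c(msg, "signal must be finite")
  if (nrow(object@signal) != length(object@leadNames))
    msg <- c(msg, "number of signal rows must equal length(leadNames)")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(object@labels) && is.null(names(object@labels)))
    msg <- c(msg, "labels must be named by class acronym")
  if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0/1")
  if (length(msg)) msg else TRUE
})

#' S4D classifier architecture configuration
#'
#' @slot nLayers integer, number of stacked S4D blocks.
#' @slot modelDim integer, model channels H.
#' @slot stateSize integer, state dimension N per channel.
#' @slot nClasses integer, number of output classes.
#' @slot nLeads integer, expected input leads.
#' @slot dropout numeric in [0, 1), dropout rate inside blocks.
#' @slot classNames character of length nClasses.
#'
#' @export
setClass("ModelConfig",
  representation(
    nLayers = "integer", modelDim = "integer", stateSize = "integer",
    nClasses = "integer", nLeads = "integer", dropout = "numeric",
    classNames = "character"
  )
)

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (object@nLayers < 1L) msg <- c(msg, "nLayers must be >= 1")
  if (object@modelDim < 1L) msg <- c(msg, "modelDim must be >= 1")
  if (object@stateSize < 2L || object@stateSize %% 2L != 0L)
    msg <- c(msg, "stateSize must be an even integer >= 2")
  if (object@nClasses < 1L) msg <- c(msg, "nClasses must be >= 1")
  if (object@nLeads < 1L) msg <- c(msg, "nLeads must be >= 1")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must be in [0, 1)")
  if (length(object@classNames) != object@nClasses)
    msg <- c(msg, "classNames must have length nClasses")
  if (length(msg)) msg else TRUE
})

#' A built (possibly trained) S4D classifier
#'
#' Holds the architecture configuration and all trainable parameters.
#' Parameters live in a named list; use [modelForward()] for inference and
#' [trainClassifier()] for optimization.
#'
#' @slot config a [ModelConfig-class].
#' @slot params named list of parameter arrays.
#' @slot seed integer seed the parameters were initialized from.
#'
#' @export
setClass("S4DClassifier",
  representation(config = "ModelConfig", params = "list", seed = "integer")
)

#' Predicted class probabilities for a batch
#'
#' @slot probabilities numeric matrix, batch x classes, entries in (0, 1).
#' @slot logits numeric matrix, batch x classes.
#'
#' @export
setClass("PredictionBatch",
  representation(probabilities = "matrix", logits = "matrix")
)

setValidity("PredictionBatch", function(object) {
  msg <- character()
  if (!all(dim(object@probabilities) == dim(object@logits)))
    msg <- c(msg, "probabilities and logits must share dimensions")
  if (any(!is.finite(object@probabilities)) || any(!is.finite(object@logits)))
    msg <- c(msg, "predictions must be finite")
  if (any(object@probabilities <= 0 | object@probabilities >= 1))
    msg <- c(msg, "probabilities must lie strictly inside (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Training-loop configuration
#'
#' @slot learningRate numeric, peak learning rate.
#' @slot epochs integer, number of epochs (run in full; no early stopping).
#' @slot batchSize integer.
#' @slot weightDecay numeric, decoupled (AdamW) weight decay applied to
#'   dense weight matrices and the SSM output map.
#' @slot lrMin numeric, final learning rate of the cosine schedule.
#' @slot valFraction numeric in (0, 1), validation share of the input data.
#' @slot seed integer, controls shuffling and dropout.
#' @slot precision character, "double" or "single" compute precision.
#' @slot gradClip numeric, global gradient-norm clip (0 disables).
#'
#' @export
setClass("TrainingConfig",
  representation(
    learningRate = "numeric", epochs = "integer", batchSize = "integer",
    weightDecay = "numeric", lrMin = "numeric", valFraction = "numeric",
    seed = "integer", precision = "character", gradClip = "numeric"
  )
)

setValidity("TrainingConfig", function(object) {
  msg <- character()
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@valFraction <= 0 || object@valFraction >= 1)
    msg <- c(msg, "valFraction must be in (0, 1)")
  if (!object@precision %in% c("double", "single"))
    msg <- c(msg, "precision must be 'double' or 'single'")
  if (length(msg)) msg else TRUE
})

#' Per-epoch training history
#'
#' @slot history data.frame with columns epoch, train_loss, train_acc,
#'   val_loss, val_acc, lr.
#'
#' @export
setClass("TrainingHistory", representation(history = "data.frame"))

setValidity("TrainingHistory", function(object) {
  need <- c("epoch", "train_loss", "train_acc", "val_loss", "val_acc", "lr")
  if (!all(need %in% names(object@history)))
    sprintf("history must contain columns %s", paste(need, collapse = ", "))
  else TRUE
})

#' Denoising pipeline configuration
#'
#' Defaults follow the classical ECG cleaning recipe: a 4th-order 0.5-40 Hz
#' Butterworth band-pass, db4 wavelet shrinkage at decomposition level 8,
#' and a 6th-order 0.1 Hz high-pass for residual baseline wander.
#'
#' @slot bandpassLow numeric Hz. @slot bandpassHigh numeric Hz.
#' @slot bandpassOrder integer. @slot waveletName character.
#' @slot waveletLevel integer. @slot highpassCutoff numeric Hz.
#' @slot highpassOrder integer.
#'
#' @export
setClass("DenoiseConfig",
  representation(
    bandpassLow = "numeric", bandpassHigh = "numeric",
    bandpassOrder = "integer", waveletName = "character",
    waveletLevel = "integer", highpassCutoff = "numeric",
    highpassOrder = "integer"
  )
)

setValidity("DenoiseConfig", function(object) {
  msg <- character()
  if (!(object@bandpassLow > 0 && object@bandpassLow < object@bandpassHigh))
    msg <- c(msg, "need 0 < bandpassLow < bandpassHigh")
  if (object@bandpassOrder < 1L || object@highpassOrder < 1L)
    msg <- c(msg, "filter orders must be >= 1")
  if (object@waveletLevel < 1L) msg <- c(msg, "waveletLevel must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Gaussian-bump beat morphology template
#'
#' One cardiac cycle is modelled as a sum of Gaussian bumps for the P, Q,
#' R, S and T waves, plus a plateau between the S and T bumps whose level
#' realises the ST offset. Timing is controlled by the PR interval (P onset
#' to QRS onset) and the QRS duration.
#'
#' @slot amplitudes named numeric (P, Q, R, S, T), millivolts.
#' @slot widths named numeric (P, Q, R, S, T), Gaussian sigmas in seconds.
#' @slot prInterval numeric, seconds (P onset to QRS onset).
#' @slot qrsDuration numeric, seconds.
#' @slot stOffset numeric, millivolts (ST-segment level versus baseline).
#'
#' @export
setClass("BeatTemplate",
  representation(
    amplitudes = "numeric", widths = "numeric", prInterval = "numeric",
    qrsDuration = "numeric", stOffset = "numeric"
  )
)

setValidity("BeatTemplate", function(object) {
  msg <- character()
  waves <- c("P", "Q", "R", "S", "T")
  if (!all(waves %in% names(object@amplitudes)))
    msg <- c(msg, "amplitudes must be named P, Q, R, S, T")
  if (!all(waves %in% names(object@widths)))
    msg <- c(msg, "widths must be named P, Q, R, S, T")
  if (any(object@widths <= 0)) msg <- c(msg, "widths must be > 0")
  if (object@prInterval < 0) msg <- c(msg, "prInterval must be >= 0")
  if (object@qrsDuration <= 0) msg <- c(msg, "qrsDuration must be > 0")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort configuration
#'
#' @slot nRecords integer. @slot classMix named numeric, per-class prevalence
#'   in [0, 1] (labels are drawn independently, so co-occurrence happens).
#' @slot heartRateRange numeric length 2, bpm. @slot noiseSd numeric,
#'   millivolts of additive white noise per lead. @slot samplingRate numeric
#'   Hz. @slot length integer samples. @slot seed integer.
#'
#' @export
setClass("SyntheticCohortConfig",
  representation(
    nRecords = "integer", classMix = "numeric", heartRateRange = "numeric",
    noiseSd = "numeric", samplingRate = "numeric", length = "integer",
    seed = "integer"
  )
)

setValidity("SyntheticCohortConfig", function(object) {
  msg <- character()
  if (object@nRecords < 1L) msg <- c(msg, "nRecords must be >= 1")
  if (is.null(names(object@classMix)))
    msg <- c(msg, "classMix must be named by class acronym")
  if (any(object@classMix < 0 | object@classMix > 1))
    msg <- c(msg, "classMix prevalences must lie in [0, 1]")
  if (length(object@heartRateRange) != 2L ||
      object@heartRateRange[1] > object@heartRateRange[2])
    msg <- c(msg, "heartRateRange must be c(lo, hi) with lo <= hi")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Per-class confusion counts
#'
#' @slot counts integer matrix, classes x c(TP, TN, FP, FN), one row per
#'   class of the evaluated vocabulary.
#'
#' @export
setClass("ConfusionCounts", representation(counts = "matrix"))

setValidity("ConfusionCounts", function(object) {
  msg <- character()
  if (!all(c("TP", "TN", "FP", "FN") %in% colnames(object@counts)))
    msg <- c(msg, "counts must have columns TP, TN, FP, FN")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Multi-label classification metrics report
#'
#' Per-class accuracy/precision/recall/F1/AUROC/AUPRC plus support-weighted
#' averages (weights = per-class positive-label support).
#'
#' @slot perClass data.frame, one row per class.
#' @slot weighted named numeric of weighted averages.
#' @slot threshold numeric, binarization threshold used for the
#'   thresholded metrics.
#'
#' @export
setClass("MetricsReport",
  representation(perClass = "data.frame", weighted = "numeric",
                 threshold = "numeric")
)

#' Lead-ablation robustness summary
#'
#' @slot metrics data.frame with one row per masking level k (mean weighted
#'   metrics over repeats).
#' @slot repeats integer, independent maskings per level.
#' @slot seed integer.
#'
#' @export
setClass("RobustnessResult",
  representation(metrics = "data.frame", repeats = "integer", seed = "integer")
)
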