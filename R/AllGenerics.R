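#' Accessor generics
#'
#' Small accessor generics for the package's S4 classes.
#'
#' @param object an object of the documented classes.
#' @param ... passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("stateSize", function(object) standardGeneric("stateSize"))

#' @rdname accessors
#' @export
setGeneric("ecgSignal", function(object) standardGeneric("ecgSignal"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("leadNames", function(object) standardGeneric("leadNames"))

#' @rdname accessors
#' @export
setGeneric("recordId", function(object) standardGeneric("recordId"))

#' @rdname accessors
#' @export
setGeneric("recordLabels", function(object) standardGeneric("recordLabels"))

#' @rdname accessors
#' @export
setGeneric("kernelValues", function(object) standardGeneric("kernelValues"))

#' @rdname accessors
#' @export
setGeneric("probabilities", function(object) standardGeneric("probabilities"))

#' @rdname accessors
#' @export
setGeneric("historyTable", function(object) standardGeneric("historyTable"))

#' @rdname accessors
#' @export
setGeneric("perClassMetrics", function(object) standardGeneric("perClassMetrics"))

#' @rdname accessors
#' @export
setGeneric("weightedMetrics", function(object) standardGeneric("weightedMetrics"))

#' Zero-order-hold discretization (generic)
#'
#' @param ssm a [ContinuousDiagonalSSM-class].
#' @return a [DiscreteDiagonalSSM-class].
#' @export
setGeneric("discretizeZOH", function(ssm) standardGeneric("discretizeZOH"))

#' Materialize the convolution kernel of a discrete diagonal SSM (generic)
#'
#' @param dssm a [DiscreteDiagonalSSM-class].
#' @param length kernel length L (>= 1).
#' @return a [ConvolutionKernel-class].
#' @export
setGeneric("materializeKernel",
           function(dssm, length) standardGeneric("materializeKernel"))
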