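#' @rdname Epoch
#' @param x,object an object.
#' @param ... passed to methods.
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' @rdname Epoch
#' @export
setGeneric("electrodes", function(x) standardGeneric("electrodes"))

#' @rdname Epoch
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))

#' @rdname Epoch
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname Epoch
#' @export
setGeneric("electrodeData", function(x) standardGeneric("electrodeData"))

#' @rdname Epoch
#' @export
setGeneric("epochMetadata", function(x) standardGeneric("epochMetadata"))

#' @rdname Epoch
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))

#' @rdname Epoch
#' @export
setGeneric("sozElectrodes", function(x) standardGeneric("sozElectrodes"))

#' Crop an epoch to a time interval
#'
#' @param x an [Epoch-class].
#' @param start,end interval bounds in seconds relative to seizure onset.
#'   The half-open interval `[start, end)` is kept.
#' @param ... passed to methods.
#' @return an [Epoch-class] restricted to samples with
#'   `start <= t < end`.
#' @export
setGeneric("crop", function(x, start, end, ...) standardGeneric("crop"))

#' Resample an epoch to a new sampling rate
#'
#' @param x an [Epoch-class].
#' @param newRate target sampling rate in Hz (positive).
#' @param ... passed to methods.
#' @return an [Epoch-class] at `newRate` Hz whose length is
#'   `round(N * newRate / oldRate)` samples. Downsampling applies a
#'   polyphase anti-aliasing low-pass at the new Nyquist frequency;
#'   resampling to the unchanged rate is a bit-exact passthrough.
#' @export
setGeneric("resample", function(x, newRate, ...) standardGeneric("resample"))

#' Estimate the seizure onset zone from fragility
#'
#' @param x a [FragilityResult-class].
#' @param ... passed to methods.
#' @export
setGeneric("estimateSOZ", function(x, ...) standardGeneric("estimateSOZ"))

#' @rdname FragilityResult-class
#' @param x a [FragilityResult-class].
#' @export
setGeneric("fragilityMatrix", function(x) standardGeneric("fragilityMatrix"))

#' @rdname FragilityResult-class
#' @export
setGeneric("rawNorms", function(x) standardGeneric("rawNorms"))

#' @rdname FragilityResult-class
#' @export
setGeneric("windowStarts", function(x) standardGeneric("windowStarts"))

#' @rdname FragilityResult-class
#' @export
setGeneric("windowCenters", function(x) standardGeneric("windowCenters"))

#' @rdname FragilityResult-class
#' @export
setGeneric("windowLambdas", function(x) standardGeneric("windowLambdas"))

#' @rdname FragilityResult-class
#' @export
setGeneric("stableWindows", function(x) standardGeneric("stableWindows"))
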