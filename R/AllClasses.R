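#' @import methods
NULL

#' Epoch: an annotated multichannel iEEG voltage matrix
#'
#' An `Epoch` holds an M-electrode by N-timepoint voltage matrix (microvolts)
#' together with the metadata needed for seizure analysis: electrode names,
#' the time of the first sample relative to seizure onset (onset = 0 s), the
#' sampling rate, a per-electrode annotation table (conventionally with
#' logical columns `soz` and `resected`), and free-form recording metadata.
#' Subsetting, cropping and resampling keep data and metadata consistent.
#'
#' The timestamp of sample `j` (1-based) is `startTime + (j - 1) / samplingRate`.
#'
#' @slot data numeric matrix, electrodes in rows, timepoints in columns.
#' @slot electrodes character vector of unique, non-empty electrode names.
#' @slot startTime numeric scalar, seconds relative to seizure onset.
#' @slot samplingRate positive numeric scalar, Hz.
#' @slot rowData data.frame with one row per electrode.
#' @slot metaData named list of patient/recording attributes.
#'
#' @seealso [Epoch()], [crop()], [resample()], [calcAdjFrag()]
#' @export
setClass("Epoch",
    representation(
        data = "matrix",
        electrodes = "character",
        startTime = "numeric",
        samplingRate = "numeric",
        rowData = "data.frame",
        metaData = "list"
    )
)

setValidity("Epoch", function(object) {
    msg <- character()
    d <- object@data
    if (!is.numeric(d)) {
        msg <- c(msg, "'data' must be a numeric matrix")
    }
    if (ncol(d) < 1L) {
        msg <- c(msg, "'data' must have at least one timepoint (N >= 1)")
    }
    if (nrow(d) != length(object@electrodes)) {
        msg <- c(msg, sprintf(
            "'data' has %d rows but 'electrodes' has %d names",
            nrow(d), length(object@electrodes)
        ))
    }
    if (anyDuplicated(object@electrodes)) {
        msg <- c(msg, "'electrodes' contains duplicated names")
    }
    if (any(!nzchar(object@electrodes))) {
        msg <- c(msg, "'electrodes' contains empty names")
    }
    if (length(object@startTime) != 1L || !is.finite(object@startTime)) {
        msg <- c(msg, "'startTime' must be a single finite number")
    }
    if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
        object@samplingRate <= 0) {
        msg <- c(msg, "'samplingRate' must be a single positive number")
    }
    if (nrow(object@rowData) != nrow(d)) {
        msg <- c(msg, sprintf(
            "'rowData' has %d rows but 'data' has %d electrodes",
            nrow(object@rowData), nrow(d)
        ))
    }
    if (length(msg)) msg else TRUE
})

#' Per-window linear dynamical system fit
#'
#' Result of fitting the one-step linear model `x(t+1) = A x(t)` to a data
#' window by ridge regression. Stability is judged by the spectral radius of
#' the state-transition matrix `A`: discrete-time dynamics are stable when
#' every eigenvalue lies strictly inside the unit circle.
#'
#' @slot A numeric M-by-M state-transition matrix.
#' @slot lambda non-negative ridge penalty used for the fit.
#' @slot spectralRadius largest eigenvalue modulus of `A`.
#' @slot stable logical, `TRUE` when `spectralRadius < 1 + tolerance`.
#' @slot nSamples number of timepoints in the fitted window.
#' @slot lambdaIterations bisection steps taken by the adaptive lambda
#'   search (0 when the initial or a user-supplied lambda was used).
#'
#' @seealso [fitWindowModel()], [selectLambda()]
#' @export
setClass("LinearModelFit",
    representation(
        A = "matrix",
        lambda = "numeric",
        spectralRadius = "numeric",
        stable = "logical",
        nSamples = "integer",
        lambdaIterations = "integer"
    )
)

setValidity("LinearModelFit", function(object) {
    msg <- character()
    if (nrow(object@A) != ncol(object@A)) {
        msg <- c(msg, "'A' must be square")
    }
    if (!all(is.finite(object@A))) {
        msg <- c(msg, "'A' contains non-finite entries")
    }
    if (object@lambda < 0) {
        msg <- c(msg, "'lambda' must be non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' Minimum-norm structured perturbation of a linear system
#'
#' The smallest (two-norm) rank-one perturbation confined to a single row or
#' column of the state-transition matrix `A` that places an eigenvalue of
#' `A + Delta` at a chosen target on the unit circle. For
#' `structure = "column"` the perturbation matrix is
#' `Delta = gamma e_k'`; for `structure = "row"` it is `Delta = e_k gamma'`.
#' The spectral norm of the rank-one `Delta` equals `||gamma||_2`.
#'
#' @slot gamma numeric M-vector, the perturbed row/column.
#' @slot norm two-norm of `gamma` (and of `Delta`).
#' @slot target complex unit-modulus target eigenvalue `sigma + i omega`.
#' @slot electrodeIndex index `k` of the perturbed row/column (1-based).
#' @slot structure `"row"` or `"column"`.
#'
#' @seealso [minNormPerturbation()], [electrodeFragility()]
#' @export
setClass("PerturbationResult",
    representation(
        gamma = "numeric",
        norm = "numeric",
        target = "complex",
        electrodeIndex = "integer",
        structure = "character"
    )
)

#' Spatiotemporal fragility of an iEEG epoch
#'
#' Output of [calcAdjFrag()]: for each sliding window a linear model is
#' fitted and each electrode's minimum destabilizing perturbation norm is
#' computed over a grid of unit-circle target eigenvalues. Raw norms are
#' normalized per window by reverse scaling,
#' `(max - value) / max`, so each column lies in `[0, 1]`, the hardest
#' electrode to destabilize maps to exactly 0, and smaller perturbation
#' norms (more fragile electrodes) map toward 1.
#'
#' @slot fragility M-by-W normalized fragility matrix in `[0, 1]`.
#' @slot rawNorms M-by-W matrix of minimum perturbation two-norms.
#' @slot windowStarts start times (s, relative to onset) of the W windows.
#' @slot windowSize window length in samples.
#' @slot step window hop in samples.
#' @slot samplingRate sampling rate of the analyzed epoch, Hz.
#' @slot lambdas ridge penalty used in each window.
#' @slot stableFlags logical, whether each window's model was stable.
#' @slot lambdaIterations bisection count for each window's lambda search.
#' @slot electrodes electrode names (rows of the matrices).
#' @slot rowData per-electrode annotations carried over from the epoch.
#' @slot omegaGrid the complex unit-circle targets searched.
#' @slot structure `"row"` or `"column"` perturbation structure.
#' @slot normalization `"window"` (per-column) or `"global"`.
#'
#' @seealso [calcAdjFrag()], [estimateSOZ()], [plotFragHeatmap()]
#' @export
setClass("FragilityResult",
    representation(
        fragility = "matrix",
        rawNorms = "matrix",
        windowStarts = "numeric",
        windowSize = "integer",
        step = "integer",
        samplingRate = "numeric",
        lambdas = "numeric",
        stableFlags = "logical",
        lambdaIterations = "integer",
        electrodes = "character",
        rowData = "data.frame",
        omegaGrid = "complex",
        structure = "character",
        normalization = "character"
    )
)

setValidity("FragilityResult", function(object) {
    msg <- character()
    f <- object@fragility
    if (!identical(dim(f), dim(object@rawNorms))) {
        msg <- c(msg, "'fragility' and 'rawNorms' dimensions differ")
    }
    if (nrow(f) != length(object@electrodes)) {
        msg <- c(msg, "row count does not match 'electrodes'")
    }
    w <- ncol(f)
    if (length(object@windowStarts) != w || length(object@lambdas) != w ||
        length(object@stableFlags) != w) {
        msg <- c(msg, "per-window vectors must have one entry per window")
    }
    if (any(f < -1e-12 | f > 1 + 1e-12)) {
        msg <- c(msg, "'fragility' entries must lie in [0, 1]")
    }
    if (any(object@rawNorms < 0)) {
        msg <- c(msg, "'rawNorms' entries must be non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' Seizure onset zone estimate from a fragility matrix
#'
#' Electrodes ranked by fragility aggregated across time windows, with the
#' top fraction selected as the proposed SOZ.
#'
#' @slot rankedElectrodes electrode names in descending score order.
#' @slot scores named per-electrode aggregated fragility (input order).
#' @slot selected the top-N electrode names (a prefix of the ranking).
#' @slot method aggregation method: mean, median, max or min.
#' @slot proportion fraction of electrodes selected.
#'
#' @seealso [estimateSOZ()]
#' @export
setClass("SozEstimate",
    representation(
        rankedElectrodes = "character",
        scores = "numeric",
        selected = "character",
        method = "character",
        proportion = "numeric"
    )
)

#' Specification for the synthetic seizure generator
#'
#' Parameters of a piecewise-stationary linear network simulation: a stable
#' pre-onset system, an ictal system whose near-unstable mode is supported
#' on a chosen set of fragile nodes, and i.i.d. Gaussian process noise.
#' See [generateSynthetic()].
#'
#' @slot nElectrodes number of channels M.
#' @slot samplingRate Hz.
#' @slot preOnsetSeconds,postOnsetSeconds simulated duration on each side
#'   of seizure onset (onset at t = 0).
#' @slot baselineRadius spectral radius of the pre-onset generator.
#' @slot ictalRadius spectral radius of the post-onset generator.
#' @slot fragileNodes 1-based indices of the planted fragile electrodes.
#' @slot couplingBoost gain applied to the fragile nodes' incoming weights
#'   in the residual (non-seizure) dynamics before the ictal mode is
#'   embedded.
#' @slot noiseSd process-noise standard deviation, microvolts.
#' @slot tanhSaturation optional soft saturation amplitude (microvolts);
#'   `Inf` disables the nonlinearity.
#' @slot seed integer RNG seed.
#'
#' @export
setClass("SyntheticSpec",
    representation(
        nElectrodes = "integer",
        samplingRate = "numeric",
        preOnsetSeconds = "numeric",
        postOnsetSeconds = "numeric",
        baselineRadius = "numeric",
        ictalRadius = "numeric",
        fragileNodes = "integer",
        couplingBoost = "numeric",
        noiseSd = "numeric",
        tanhSaturation = "numeric",
        seed = "integer"
    )
)

setValidity("SyntheticSpec", function(object) {
    msg <- character()
    if (object@nElectrodes < 2L) {
        msg <- c(msg, "'nElectrodes' must be at least 2")
    }
    if (!(object@baselineRadius > 0 && object@baselineRadius <
        object@ictalRadius && object@ictalRadius < 1)) {
        msg <- c(msg, "need 0 < baselineRadius < ictalRadius < 1")
    }
    if (length(object@fragileNodes) < 1L ||
        any(object@fragileNodes < 1L | object@fragileNodes > object@nElectrodes)) {
        msg <- c(msg, "'fragileNodes' must be non-empty indices in [1, nElectrodes]")
    }
    if (object@noiseSd < 0) {
        msg <- c(msg, "'noiseSd' must be non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' A generated synthetic dataset with ground truth
#'
#' @slot epoch the simulated [Epoch-class] (with `soz` flags set on the
#'   planted nodes).
#' @slot truth 1-based indices of the planted fragile nodes.
#' @slot spec the [SyntheticSpec-class] used.
#' @slot Apre,Aictal the pre- and post-onset state-transition matrices.
#'
#' @seealso [generateSynthetic()]
#' @export
setClass("SyntheticDataset",
    representation(
        epoch = "Epoch",
        truth = "integer",
        spec = "SyntheticSpec",
        Apre = "matrix",
        Aictal = "matrix"
    )
)
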