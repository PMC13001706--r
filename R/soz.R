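.roundHalfUp <- function(x) floor(x + 0.5)

#' @describeIn estimateSOZ aggregate fragility across time windows per
#'   electrode, rank electrodes by the aggregated score, and select the
#'   top fraction as the proposed seizure onset zone.
#'
#' @param method aggregation across windows: `"mean"` (default),
#'   `"median"`, `"max"` or `"min"`.
#' @param proportion fraction of electrodes to select, in `(0, 1]`
#'   (default 0.1). The selected count is
#'   `max(1, round(proportion * M))`, rounding half away from zero.
#' @param timeRange optional length-2 vector of window indices
#'   `c(first, last)` restricting the aggregation (for example to
#'   post-onset windows); default uses all windows.
#' @return a [SozEstimate-class]. Ties in the ranking are broken by input
#'   electrode order (noted via a message).
#' @examples
#' ds <- generateSynthetic(syntheticSpec(seed = 1))
#' frag <- calcAdjFrag(epochOf(ds))
#' estimateSOZ(frag, method = "mean", proportion = 2 / 12)
#' @export
setMethod("estimateSOZ", "FragilityResult",
    function(x, method = c("mean", "median", "max", "min"),
             proportion = 0.1, timeRange = NULL, ...) {
        method <- match.arg(method)
        if (!(proportion > 0 && proportion <= 1)) {
            stop("'proportion' must lie in (0, 1]", call. = FALSE)
        }
        f <- x@fragility
        if (!is.null(timeRange)) {
            timeRange <- as.integer(timeRange)
            if (length(timeRange) != 2L || timeRange[1L] > timeRange[2L] ||
                timeRange[1L] < 1L || timeRange[2L] > ncol(f)) {
                stop(
                    "'timeRange' must be window indices c(first, last) within [1, ",
                    ncol(f), "]",
                    call. = FALSE
                )
            }
            f <- f[, timeRange[1L]:timeRange[2L], drop = FALSE]
        }
        agg <- switch(method,
            mean = rowMeans(f),
            median = apply(f, 1L, stats::median),
            max = apply(f, 1L, max),
            min = apply(f, 1L, min)
        )
        names(agg) <- x@electrodes
        if (anyDuplicated(agg)) {
            message("tied aggregated scores; ties broken by electrode order")
        }
        ord <- order(-agg) # stable: ties keep input electrode order
        nSel <- max(1L, .roundHalfUp(proportion * length(agg)))
        new("SozEstimate",
            rankedElectrodes = x@electrodes[ord],
            scores = agg,
            selected = x@electrodes[ord][seq_len(nSel)],
            method = method,
            proportion = proportion
        )
    }
)

#' @describeIn SozEstimate-class ranked table of electrodes.
#' @param x a [SozEstimate-class].
#' @return `sozTable` returns a data.frame with columns `electrode`,
#'   `score` and `selected`, in descending score order.
#' @export
sozTable <- function(x) {
    stopifnot(is(x, "SozEstimate"))
    data.frame(
        electrode = x@rankedElectrodes,
        score = unname(x@scores[x@rankedElectrodes]),
        selected = x@rankedElectrodes %in% x@selected
    )
}

setMethod("show", "SozEstimate", function(object) {
    cat(sprintf(
        "SozEstimate (%s aggregation, proportion %.3g): %d of %d electrodes selected\n",
        object@method, object@proportion, length(object@selected),
        length(object@scores)
    ))
    print(utils::head(sozTable(object), 10))
    invisible(NULL)
})
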