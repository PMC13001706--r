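#' Create an Epoch from an iEEG matrix and metadata
#'
#' Builds the validated container used throughout the package. The matrix
#' rows are electrodes and the columns are timepoints; sample `j` (1-based)
#' carries the timestamp `startTime + (j - 1) / samplingRate`, with seizure
#' onset at 0 s by convention.
#'
#' @param data numeric M-by-N matrix of voltages in microvolts.
#' @param electrodes character vector of M unique electrode names. Defaults
#'   to the matrix rownames, or `E1..EM` when those are absent.
#' @param startTime time of the first sample in seconds relative to
#'   seizure onset (default 0).
#' @param samplingRate sampling rate in Hz.
#' @param rowData data.frame with M rows of per-electrode attributes;
#'   conventional logical columns are `soz` and `resected`. Defaults to an
#'   empty table with M rows.
#' @param metaData named list of patient/recording attributes.
#'
#' @return an [Epoch-class] object.
#'
#' @examples
#' x <- matrix(rnorm(300), 3, 100)
#' ep <- Epoch(x, c("A1", "A2", "B1"), startTime = -1, samplingRate = 100)
#' epochTimes(ep)[c(1, 100)] # -1.00 and -0.01 s
#'
#' @export
Epoch <- function(data, electrodes = NULL, startTime = 0, samplingRate,
                  rowData = NULL, metaData = list()) {
    data <- as.matrix(data)
    if (is.null(electrodes)) {
        electrodes <- rownames(data)
        if (is.null(electrodes)) {
            electrodes <- paste0("E", seq_len(nrow(data)))
        }
    }
    electrodes <- as.character(electrodes)
    if (is.null(rowData)) {
        rowData <- data.frame(row.names = seq_len(nrow(data)))
    }
    rowData <- as.data.frame(rowData)
    rownames(data) <- NULL
    new("Epoch",
        data = data, electrodes = electrodes,
        startTime = as.numeric(startTime),
        samplingRate = as.numeric(samplingRate),
        rowData = rowData, metaData = metaData
    )
}

#' @describeIn Epoch the voltage matrix (electrodes by timepoints).
#' @export
setMethod("epochData", "Epoch", function(x) {
    d <- x@data
    dimnames(d) <- list(x@electrodes, NULL)
    d
})

#' @describeIn Epoch electrode names.
#' @export
setMethod("electrodes", "Epoch", function(x) x@electrodes)

#' @describeIn Epoch time of the first sample (s, onset = 0).
#' @export
setMethod("startTime", "Epoch", function(x) x@startTime)

#' @describeIn Epoch sampling rate in Hz.
#' @export
setMethod("samplingRate", "Epoch", function(x) x@samplingRate)

#' @describeIn Epoch per-electrode annotation table.
#' @export
setMethod("electrodeData", "Epoch", function(x) x@rowData)

#' @describeIn Epoch recording/patient metadata list.
#' @export
setMethod("epochMetadata", "Epoch", function(x) x@metaData)

#' @describeIn Epoch timestamps of all samples in seconds.
#' @export
setMethod("epochTimes", "Epoch", function(x) {
    x@startTime + (seq_len(ncol(x@data)) - 1L) / x@samplingRate
})

#' @describeIn Epoch names of electrodes flagged as SOZ in `rowData$soz`;
#'   when the column is absent all electrodes are treated as non-SOZ and a
#'   message is emitted.
#' @export
setMethod("sozElectrodes", "Epoch", function(x) {
    if (is.null(x@rowData$soz)) {
        message("rowData has no 'soz' column; treating all electrodes as non-SOZ")
        return(character())
    }
    x@electrodes[as.logical(x@rowData$soz)]
})

#' @describeIn Epoch dimensions (electrodes, timepoints).
#' @export
setMethod("dim", "Epoch", function(x) dim(x@data))

setMethod("show", "Epoch", function(object) {
    d <- dim(object@data)
    tt <- range(epochTimes(object))
    cat(sprintf(
        "Epoch: %d electrodes x %d timepoints @ %g Hz\n", d[1], d[2],
        object@samplingRate
    ))
    cat(sprintf(
        "  time span: [%.4g, %.4g] s relative to onset\n", tt[1], tt[2]
    ))
    cat(sprintf(
        "  electrodes: %s%s\n",
        paste(utils::head(object@electrodes, 6), collapse = ", "),
        if (d[1] > 6) ", ..." else ""
    ))
    if (ncol(object@rowData)) {
        cat(sprintf(
            "  rowData columns: %s\n",
            paste(colnames(object@rowData), collapse = ", ")
        ))
    }
    if (length(object@metaData)) {
        cat(sprintf(
            "  metaData keys: %s\n",
            paste(names(object@metaData), collapse = ", ")
        ))
    }
    invisible(NULL)
})

## resolve electrode selectors (names, logical, or numeric) to integer indices
.resolveElectrodes <- function(x, i) {
    if (is.character(i)) {
        idx <- match(i, x@electrodes)
        if (anyNA(idx)) {
            stop(
                "unknown electrode name(s): ",
                paste(i[is.na(idx)], collapse = ", "),
                call. = FALSE
            )
        }
        return(idx)
    }
    if (is.logical(i)) {
        if (length(i) != nrow(x@data)) {
            stop("logical electrode index has wrong length", call. = FALSE)
        }
        return(which(i))
    }
    i <- as.integer(i)
    if (any(i < 1L | i > nrow(x@data))) {
        stop(
            "electrode index out of range [1, ", nrow(x@data), "]",
            call. = FALSE
        )
    }
    i
}

.checkTimeIndex <- function(x, j) {
    j <- as.integer(j)
    if (any(j < 1L | j > ncol(x@data))) {
        stop("time index out of range [1, ", ncol(x@data), "]", call. = FALSE)
    }
    if (length(j) > 1L && !all(diff(j) == 1L)) {
        stop(
            "time selection must be a contiguous increasing range; ",
            "scattered timepoints would leave startTime/samplingRate undefined",
            call. = FALSE
        )
    }
    j
}

#' Subset an epoch with consistent metadata
#'
#' `epoch[i, j]` subsets electrodes (`i`, by index, name or logical mask)
#' and time (`j`, a contiguous 1-based sample range). The electrode table
#' is subset row-for-row with the data; `startTime` is recomputed from the
#' first kept sample; `metaData` is carried unchanged. Non-contiguous time
#' selections are rejected because they would make the epoch's uniform
#' time axis meaningless.
#'
#' @param x an [Epoch-class].
#' @param i electrode selector (numeric, character or logical).
#' @param j contiguous time-sample selector (numeric).
#' @param ... ignored.
#' @param drop ignored; the result is always an Epoch.
#' @return an [Epoch-class].
#' @export
setMethod("[", "Epoch", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nrow(x@data))
    if (missing(j)) j <- seq_len(ncol(x@data))
    i <- .resolveElectrodes(x, i)
    j <- .checkTimeIndex(x, j)
    new("Epoch",
        data = x@data[i, j, drop = FALSE],
        electrodes = x@electrodes[i],
        startTime = x@startTime + (j[1L] - 1L) / x@samplingRate,
        samplingRate = x@samplingRate,
        rowData = x@rowData[i, , drop = FALSE],
        metaData = x@metaData
    )
})

#' @describeIn crop keep samples whose timestamps satisfy
#'   `start <= t < end`.
#' @export
setMethod("crop", "Epoch", function(x, start, end, ...) {
    if (!(start < end)) stop("'start' must be < 'end'", call. = FALSE)
    tt <- epochTimes(x)
    keep <- which(tt >= start & tt < end)
    if (!length(keep)) {
        stop(sprintf(
            "crop interval [%g, %g) does not intersect the epoch time span [%g, %g]",
            start, end, tt[1L], tt[length(tt)]
        ), call. = FALSE)
    }
    x[, keep[1L]:keep[length(keep)]]
})

## best rational approximation p/q of a ratio, for the polyphase resampler
.ratApprox <- function(r, tol = 1e-9, maxq = 1e6) {
    p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L
    x <- r
    repeat {
        a <- floor(x)
        p2 <- a * p1 + p0
        q2 <- a * q1 + q0
        if (q2 > maxq || abs(p2 / q2 - r) < tol * r) {
            return(c(p = p2, q = q2))
        }
        p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
        x <- 1 / (x - a)
    }
}

#' @describeIn resample polyphase resampling of every electrode trace.
#' @export
setMethod("resample", "Epoch", function(x, newRate, ...) {
    if (length(newRate) != 1L || !is.finite(newRate) || newRate <= 0) {
        stop("'newRate' must be a single positive number", call. = FALSE)
    }
    oldRate <- x@samplingRate
    if (newRate == oldRate) {
        return(x)
    }
    pq <- .ratApprox(newRate / oldRate)
    n <- ncol(x@data)
    nOut <- round(n * newRate / oldRate)
    res <- t(apply(x@data, 1L, function(tr) {
        y <- signal::resample(tr, pq[["p"]], pq[["q"]])
        if (length(y) >= nOut) {
            y[seq_len(nOut)]
        } else {
            c(y, rep(y[length(y)], nOut - length(y)))
        }
    }))
    new("Epoch",
        data = res, electrodes = x@electrodes, startTime = x@startTime,
        samplingRate = as.numeric(newRate), rowData = x@rowData,
        metaData = x@metaData
    )
})

#' Plot raw voltage traces of an epoch
#'
#' Stacked, vertically offset voltage traces with time (seconds relative
#' to seizure onset) on the x-axis and a vertical marker at onset (t = 0).
#' Highlighted electrodes (for example the clinically annotated SOZ) are
#' drawn in red.
#'
#' @param x an [Epoch-class].
#' @param y unused.
#' @param highlight electrode names or indices to emphasize.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
setMethod("plot", signature(x = "Epoch", y = "missing"),
    function(x, y, highlight = character(), ...) {
        hi <- if (length(highlight)) {
            x@electrodes[.resolveElectrodes(x, highlight)]
        } else {
            character()
        }
        tt <- epochTimes(x)
        m <- nrow(x@data)
        spread <- max(apply(x@data, 1L, function(r) diff(range(r))), 1e-9)
        df <- data.frame(
            time = rep(tt, each = m),
            voltage = as.vector(x@data) + (m - seq_len(m)) * spread,
            electrode = factor(rep(x@electrodes, ncol(x@data)),
                levels = x@electrodes
            ),
            highlighted = rep(x@electrodes %in% hi, ncol(x@data))
        )
        ggplot2::ggplot(df, ggplot2::aes(
            x = time, y = voltage,
            group = electrode, colour = highlighted
        )) +
            ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
            ggplot2::geom_line(linewidth = 0.3) +
            ggplot2::scale_colour_manual(
                values = c(`FALSE` = "grey20", `TRUE` = "red"), guide = "none"
            ) +
            ggplot2::scale_y_continuous(
                breaks = (m - seq_len(m)) * spread, labels = x@electrodes
            ) +
            ggplot2::labs(
                x = "time relative to onset (s)", y = NULL,
                title = "iEEG voltage traces"
            ) +
            ggplot2::theme_minimal()
    }
)
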