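## visualization of FragilityResult objects. Every plot is backed by an
## exported summary-table function so tests (and users) can work with the
## numbers rather than rendered pixels.

.resolveGroup <- function(frag, groupIndex) {
    m <- length(frag@electrodes)
    if (is.character(groupIndex)) {
        idx <- match(groupIndex, frag@electrodes)
        if (anyNA(idx)) {
            stop(
                "unknown electrode name(s) in group: ",
                paste(groupIndex[is.na(idx)], collapse = ", "),
                call. = FALSE
            )
        }
        return(idx)
    }
    idx <- as.integer(groupIndex)
    if (any(idx < 1L | idx > m)) {
        stop("group index out of range [1, ", m, "]", call. = FALSE)
    }
    idx
}

#' Group mean/dispersion summary of fragility over time
#'
#' Per-window mean fragility of a group of electrodes (for example the
#' clinically annotated SOZ) and of its complement, together with a
#' standard-deviation or standard-error dispersion band. This is the
#' table behind [plotFragDistribution()].
#'
#' @param frag a [FragilityResult-class].
#' @param groupIndex electrode names or 1-based indices defining the
#'   group; its complement must be non-empty.
#' @param band `"sd"` (default) or `"se"` half-width of the band.
#' @param labels labels for group and complement (default SOZ / REF).
#' @return a data.frame with columns `time` (window center, s), `group`,
#'   `mean`, `sd`, `se`, `n`, `lower`, `upper`.
#' @export
fragDistributionStats <- function(frag, groupIndex, band = c("sd", "se"),
                                  labels = c("SOZ", "REF")) {
    stopifnot(is(frag, "FragilityResult"))
    band <- match.arg(band)
    idx <- .resolveGroup(frag, groupIndex)
    m <- length(frag@electrodes)
    if (length(unique(idx)) >= m) {
        stop(
            "the group covers all electrodes; the complement must be non-empty",
            call. = FALSE
        )
    }
    if (!length(idx)) stop("the group must be non-empty", call. = FALSE)
    tt <- windowCenters(frag)
    groups <- list(idx, setdiff(seq_len(m), idx))
    out <- do.call(rbind, lapply(1:2, function(g) {
        sub <- frag@fragility[groups[[g]], , drop = FALSE]
        mu <- colMeans(sub)
        sdv <- apply(sub, 2L, stats::sd)
        sdv[is.na(sdv)] <- 0 # single-electrode group
        sev <- sdv / sqrt(nrow(sub))
        half <- if (band == "sd") sdv else sev
        data.frame(
            time = tt, group = labels[g], mean = mu, sd = sdv, se = sev,
            n = nrow(sub), lower = mu - half, upper = mu + half
        )
    }))
    rownames(out) <- NULL
    out
}

#' Group quantile summary of fragility over time
#'
#' Per-window fragility quantiles for a group of electrodes and its
#' complement; the table behind [plotFragQuantile()].
#'
#' @inheritParams fragDistributionStats
#' @param quantiles increasing probabilities in (0, 1)
#'   (default 0.1, ..., 0.9).
#' @return a data.frame with columns `time`, `group`, `quantile`, `value`.
#' @export
fragQuantileStats <- function(frag, groupIndex,
                              quantiles = seq(0.1, 0.9, by = 0.1),
                              labels = c("SOZ", "REF")) {
    stopifnot(is(frag, "FragilityResult"))
    if (any(quantiles <= 0 | quantiles >= 1) || is.unsorted(quantiles)) {
        stop("'quantiles' must be increasing probabilities in (0, 1)", call. = FALSE)
    }
    idx <- .resolveGroup(frag, groupIndex)
    m <- length(frag@electrodes)
    if (length(unique(idx)) >= m) {
        stop(
            "the group covers all electrodes; the complement must be non-empty",
            call. = FALSE
        )
    }
    tt <- windowCenters(frag)
    groups <- list(idx, setdiff(seq_len(m), idx))
    out <- do.call(rbind, lapply(1:2, function(g) {
        sub <- frag@fragility[groups[[g]], , drop = FALSE]
        qm <- apply(sub, 2L, stats::quantile, probs = quantiles, names = FALSE)
        qm <- matrix(qm, nrow = length(quantiles))
        data.frame(
            time = rep(tt, each = length(quantiles)),
            group = labels[g],
            quantile = rep(quantiles, length(tt)),
            value = as.vector(qm)
        )
    }))
    rownames(out) <- NULL
    out
}

#' Spatiotemporal fragility heatmap
#'
#' Electrodes on the y-axis, time windows on the x-axis, color encoding
#' fragility with warmer colors for more fragile electrodes; color limits
#' are scaled to the data range so regional differences stay visible. A
#' dashed vertical line marks seizure onset (t = 0) and the y-axis labels
#' of a highlighted group (for example clinical SOZ electrodes) are drawn
#' in red.
#'
#' @param frag a [FragilityResult-class].
#' @param groupIndex optional electrode names or indices to highlight.
#' @param sortByFragility reorder rows by mean fragility (default keeps
#'   input electrode order).
#' @return a ggplot object.
#' @export
plotFragHeatmap <- function(frag, groupIndex = NULL, sortByFragility = FALSE) {
    stopifnot(is(frag, "FragilityResult"))
    idx <- if (is.null(groupIndex)) integer() else .resolveGroup(frag, groupIndex)
    m <- length(frag@electrodes)
    rowOrder <- if (sortByFragility) {
        order(rowMeans(frag@fragility))
    } else {
        rev(seq_len(m)) # first electrode on top
    }
    lev <- frag@electrodes[rowOrder]
    tt <- windowCenters(frag)
    df <- data.frame(
        time = rep(tt, each = m),
        electrode = factor(rep(frag@electrodes, ncol(frag@fragility)),
            levels = lev
        ),
        fragility = as.vector(frag@fragility)
    )
    labColors <- ifelse(rowOrder %in% idx, "red", "grey20")
    rng <- range(df$fragility)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5) # constant matrix
    ggplot2::ggplot(df, ggplot2::aes(x = time, y = electrode, fill = fragility)) +
        ggplot2::geom_tile() +
        ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "white") +
        ggplot2::scale_fill_viridis_c(
            option = "inferno", limits = rng, name = "fragility"
        ) +
        ggplot2::labs(
            x = "time relative to onset (s)", y = NULL,
            title = "Neural fragility"
        ) +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.y = ggplot2::element_text(colour = labColors))
}

#' @describeIn plotFragHeatmap `plot` on a [FragilityResult-class]
#'   dispatches to the heatmap.
#' @param x a [FragilityResult-class].
#' @param y unused.
#' @param ... passed to `plotFragHeatmap`.
#' @export
setMethod("plot", signature(x = "FragilityResult", y = "missing"),
    function(x, y, ...) plotFragHeatmap(x, ...)
)

#' Group mean fragility over time with dispersion band
#'
#' Line plot of mean fragility per window for a group of electrodes and
#' its complement, with a shaded +-1 sd (or se) band, mirroring the usual
#' SOZ versus non-SOZ comparison.
#'
#' @inheritParams fragDistributionStats
#' @return a ggplot object.
#' @export
plotFragDistribution <- function(frag, groupIndex, band = c("sd", "se"),
                                 labels = c("SOZ", "REF")) {
    stats <- fragDistributionStats(frag, groupIndex, band, labels)
    ggplot2::ggplot(stats, ggplot2::aes(
        x = time, y = mean, colour = group, fill = group
    )) +
        ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
        ggplot2::geom_ribbon(
            ggplot2::aes(ymin = lower, ymax = upper),
            alpha = 0.25, colour = NA
        ) +
        ggplot2::geom_line(linewidth = 0.7) +
        ggplot2::labs(
            x = "time relative to onset (s)", y = "mean fragility",
            title = "Group mean fragility over time"
        ) +
        ggplot2::theme_minimal()
}

#' Group fragility quantiles over time
#'
#' Per-window fragility quantile curves for a group and its complement,
#' juxtaposed in facets.
#'
#' @inheritParams fragQuantileStats
#' @return a ggplot object.
#' @export
plotFragQuantile <- function(frag, groupIndex,
                             quantiles = seq(0.1, 0.9, by = 0.1),
                             labels = c("SOZ", "REF")) {
    stats <- fragQuantileStats(frag, groupIndex, quantiles, labels)
    ggplot2::ggplot(stats, ggplot2::aes(
        x = time, y = value, colour = quantile, group = quantile
    )) +
        ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
        ggplot2::geom_line() +
        ggplot2::facet_wrap(~group) +
        ggplot2::scale_colour_viridis_c(name = "quantile") +
        ggplot2::labs(
            x = "time relative to onset (s)", y = "fragility",
            title = "Fragility quantiles by group"
        ) +
        ggplot2::theme_minimal()
}
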