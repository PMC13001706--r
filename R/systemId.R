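#' Spectral radius of a square matrix
#'
#' The maximum modulus over eigenvalues. Discrete-time linear dynamics
#' `x(t+1) = A x(t)` are stable when the spectral radius is below 1.
#'
#' @param A a square numeric matrix with finite entries.
#' @return a non-negative scalar.
#' @examples
#' spectralRadius(diag(3)) # 1
#' spectralRadius(matrix(c(0, -1, 1, 0), 2)) # 1 (eigenvalues +-i)
#' @export
spectralRadius <- function(A) {
    if (!is.matrix(A) || nrow(A) != ncol(A)) {
        stop("'A' must be a square matrix", call. = FALSE)
    }
    if (!all(is.finite(A))) {
        stop("'A' contains non-finite entries", call. = FALSE)
    }
    max(Mod(eigen(A, only.values = TRUE)$values))
}

.checkWindowData <- function(windowData) {
    windowData <- as.matrix(windowData)
    if (!all(is.finite(windowData))) {
        stop("window data contains NaN/Inf values", call. = FALSE)
    }
    m <- nrow(windowData)
    n <- ncol(windowData)
    if (n < 2L) stop("need at least 2 timepoints to fit transitions", call. = FALSE)
    rng <- apply(windowData, 1L, function(r) diff(range(r)))
    if (any(rng == 0)) {
        stop(
            "degenerate channel(s) with constant signal: row ",
            paste(which(rng == 0), collapse = ", "),
            call. = FALSE
        )
    }
    if (n < m + 1L) {
        warning(sprintf(
            "window has %d samples for %d electrodes; at least M + 1 = %d is recommended",
            n, m, m + 1L
        ), call. = FALSE)
    }
    windowData
}

#' Fit the window's linear state-transition model by ridge regression
#'
#' Estimates `A` minimizing `sum_t ||x(t+1) - A x(t)||^2 + lambda ||A||_F^2`
#' over the window's `n - 1` transition pairs, i.e. the closed form
#' `A = Y X' (X X' + lambda I)^{-1}` with `X` the first `n - 1` columns and
#' `Y` the last `n - 1` columns of the window. The ridge penalty is an
#' absolute additive term (not scaled by window length), so the fixed
#' search bounds of the adaptive lambda selection keep the same meaning for
#' any window size.
#'
#' @param windowData numeric M-by-n voltage matrix (one sliding window).
#' @param lambda ridge penalty, `>= 0`. `lambda = 0` requires `X X'` to be
#'   nonsingular.
#' @param stabilityTol numerical tolerance added to the unit-circle
#'   stability threshold.
#' @return a [LinearModelFit-class].
#' @examples
#' A0 <- matrix(c(0.5, 0.2, -0.1, 0.6), 2)
#' x <- matrix(0, 2, 50)
#' x[, 1] <- c(1, -1)
#' for (t in 2:50) x[, t] <- A0 %*% x[, t - 1] + rnorm(2, 0, 1e-4)
#' fit <- fitWindowModel(x, lambda = 1e-6)
#' fit@spectralRadius
#' @export
fitWindowModel <- function(windowData, lambda = 1e-4, stabilityTol = 1e-12) {
    windowData <- .checkWindowData(windowData)
    if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0) {
        stop("'lambda' must be a single non-negative number", call. = FALSE)
    }
    m <- nrow(windowData)
    n <- ncol(windowData)
    X <- windowData[, -n, drop = FALSE]
    Y <- windowData[, -1L, drop = FALSE]
    G <- tcrossprod(X) + lambda * diag(m)
    A <- tryCatch(
        t(solve(G, tcrossprod(X, Y))),
        error = function(e) {
            stop(
                "normal matrix X X' + lambda I is singular; ",
                "use a positive 'lambda' (", conditionMessage(e), ")",
                call. = FALSE
            )
        }
    )
    sr <- spectralRadius(A)
    new("LinearModelFit",
        A = A, lambda = lambda, spectralRadius = sr,
        stable = sr < 1 + stabilityTol,
        nSamples = as.integer(n), lambdaIterations = 0L
    )
}

#' Adaptive ridge-penalty selection by bisection
#'
#' Fits the window model with the small initial penalty `lambdaMin`
#' (default 1e-4). If that fit is already stable it is returned with zero
#' bisection iterations. Otherwise the penalty is bisected in `log10`
#' space within `[lambdaMin, lambdaMax]` (the bounds span five orders of
#' magnitude) for up to `maxIter` iterations, keeping the smallest penalty
#' whose dynamics are stable; a stable midpoint moves the upper bound
#' down, an unstable one moves the lower bound up. If even `lambdaMax`
#' fails to stabilize the dynamics, the `lambdaMax` fit is returned
#' flagged unstable with a warning: fragility of an unstable model is
#' ill-defined and such windows are flagged downstream.
#'
#' @param windowData numeric M-by-n voltage matrix.
#' @param lambdaMin,lambdaMax search bounds (defaults 1e-4 and 10).
#' @param maxIter maximum bisection iterations (default 20).
#' @param stabilityTol numerical tolerance on the stability threshold.
#' @return a [LinearModelFit-class]; its `lambdaIterations` slot counts
#'   the bisection steps actually taken.
#' @export
selectLambda <- function(windowData, lambdaMin = 1e-4, lambdaMax = 10,
                         maxIter = 20, stabilityTol = 1e-12) {
    if (!(lambdaMin > 0 && lambdaMin < lambdaMax)) {
        stop("need 0 < lambdaMin < lambdaMax", call. = FALSE)
    }
    fit <- fitWindowModel(windowData, lambdaMin, stabilityTol)
    if (fit@stable) {
        return(fit)
    }
    best <- fitWindowModel(windowData, lambdaMax, stabilityTol)
    if (!best@stable) {
        warning(
            "dynamics remain unstable even at lambdaMax = ", lambdaMax,
            "; returning the lambdaMax fit flagged unstable",
            call. = FALSE
        )
        best@lambdaIterations <- 0L
        return(best)
    }
    lo <- log10(lambdaMin)
    hi <- log10(lambdaMax)
    iter <- 0L
    while (iter < maxIter && (hi - lo) > 1e-3) {
        mid <- (lo + hi) / 2
        iter <- iter + 1L
        cand <- fitWindowModel(windowData, 10^mid, stabilityTol)
        if (cand@stable) {
            hi <- mid
            best <- cand
        } else {
            lo <- mid
        }
    }
    best@lambdaIterations <- iter
    best
}
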