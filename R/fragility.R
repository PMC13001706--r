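#' Grid of unit-modulus target eigenvalues
#'
#' Parametrizes the upper half of the unit circle as
#' `exp(i * theta)`, `theta` uniform on `[0, pi]`. For a real
#' state-transition matrix the conjugate targets on the lower half circle
#' give identical perturbation norms, so the upper half (including the real
#' targets +1 and -1 at its endpoints) is a complete search set.
#'
#' @param n number of targets (default 51).
#' @return a complex vector of length `n` with modulus 1.
#' @examples
#' unitCircleTargets(3) # 1, i, -1
#' @export
unitCircleTargets <- function(n = 51) {
    if (n < 1L) stop("'n' must be at least 1", call. = FALSE)
    theta <- seq(0, pi, length.out = n)
    complex(real = cos(theta), imaginary = sin(theta))
}

## minimum two-norm solution of the feasibility system for one electrode.
## r is the relevant row (column structure) or column (row structure) of
## (A - target I)^{-1}; the eigenvalue-placement condition
## 1 + e_k' (A - target I)^{-1} gamma = 0 splits into the two real
## constraints Re(r)' gamma = -1 and Im(r)' gamma = 0.
.gammaFromResolvent <- function(r) {
    a <- Re(r)
    b <- Im(r)
    aa <- sum(a * a)
    bb <- sum(b * b)
    ab <- sum(a * b)
    if (bb <= 1e-14 * max(aa, 1)) {
        ## real target (or numerically real resolvent): single constraint
        return(-a / aa)
    }
    den <- aa * bb - ab * ab
    if (den <= 1e-14 * aa * bb) {
        ## Re(r) and Im(r) numerically collinear: fall back to the
        ## single-constraint minimum-norm solution
        warning(
            "resolvent real and imaginary parts are collinear; ",
            "using the reduced one-constraint solution",
            call. = FALSE
        )
        return(-a / aa)
    }
    w <- c(-bb, ab) / den
    w[1L] * a + w[2L] * b
}

#' Minimum two-norm structured perturbation placing a unit-circle eigenvalue
#'
#' Computes the smallest rank-one perturbation confined to column (or row)
#' `electrode` of `A` such that `A + Delta` has an eigenvalue at the
#' unit-modulus target `sigma + i omega`. For the column structure
#' `Delta = gamma e_k'`, the target is an eigenvalue of `A + Delta` iff
#' `1 + e_k'(A - target I)^{-1} gamma = 0`; writing
#' `r = ((A - target I)^{-1})' e_k`, the real form of this condition is the
#' two-equation linear system `Re(r)' gamma = -1`, `Im(r)' gamma = 0`, and
#' the returned `gamma` is its minimum two-norm solution. For the row
#' structure the same construction uses `r = (A - target I)^{-1} e_k`.
#' If the target is already an eigenvalue of `A` the zero perturbation is
#' returned.
#'
#' @param A square numeric state-transition matrix.
#' @param target complex target eigenvalue with modulus 1 (see
#'   [unitCircleTargets()]).
#' @param electrode 1-based index of the perturbed column/row.
#' @param structure `"column"` (default) or `"row"`.
#' @return a [PerturbationResult-class]; its `norm` slot equals the
#'   spectral norm of the rank-one perturbation matrix.
#' @examples
#' res <- minNormPerturbation(matrix(0, 2, 2), 1 + 0i, 1)
#' res@gamma # (1, 0); A + gamma e_1' then has eigenvalue 1
#' @export
minNormPerturbation <- function(A, target, electrode,
                                structure = c("column", "row")) {
    structure <- match.arg(structure)
    if (!is.matrix(A) || nrow(A) != ncol(A)) {
        stop("'A' must be a square matrix", call. = FALSE)
    }
    if (abs(Mod(target) - 1) > 1e-12) {
        stop("'target' must have modulus 1", call. = FALSE)
    }
    m <- nrow(A)
    electrode <- as.integer(electrode)
    if (electrode < 1L || electrode > m) {
        stop("'electrode' out of range", call. = FALSE)
    }
    shifted <- A - target * diag(m)
    sv <- svd(shifted)$d
    if (min(sv) < 1e-10 * max(sv)) {
        ## target already (numerically) an eigenvalue: zero perturbation
        return(new("PerturbationResult",
            gamma = numeric(m), norm = 0,
            target = as.complex(target),
            electrodeIndex = electrode, structure = structure
        ))
    }
    inv <- tryCatch(solve(shifted), error = function(e) NULL)
    if (is.null(inv)) {
        warning(
            "(A - target I) numerically singular; using least-squares resolvent",
            call. = FALSE
        )
        inv <- .pseudoInverseComplex(shifted)
    }
    r <- if (structure == "column") inv[electrode, ] else inv[, electrode]
    gamma <- .gammaFromResolvent(r)
    new("PerturbationResult",
        gamma = gamma, norm = sqrt(sum(gamma^2)),
        target = as.complex(target),
        electrodeIndex = electrode, structure = structure
    )
}

## Moore-Penrose pseudoinverse of a complex matrix via real embedding
.pseudoInverseComplex <- function(Z) {
    s <- svd(Z)
    tol <- max(dim(Z)) * max(s$d) * .Machine$double.eps
    pos <- s$d > tol
    s$v[, pos, drop = FALSE] %*%
        (Conj(t(s$u[, pos, drop = FALSE])) / s$d[pos])
}

#' Per-electrode fragility: minimum perturbation norm over a target grid
#'
#' The fragility of an electrode is the minimum over all searched targets
#' of the minimum structured perturbation norm that places an eigenvalue
#' at that target.
#'
#' @param A square numeric state-transition matrix.
#' @param electrode 1-based electrode index.
#' @param targets complex vector of unit-modulus target eigenvalues.
#' @param structure `"column"` or `"row"`.
#' @return a list with `norm` (the minimum) and `target` (the achieving
#'   target eigenvalue).
#' @export
electrodeFragility <- function(A, electrode, targets = unitCircleTargets(),
                               structure = c("column", "row")) {
    structure <- match.arg(structure)
    if (!length(targets)) stop("'targets' must be non-empty", call. = FALSE)
    norms <- vapply(targets, function(tg) {
        minNormPerturbation(A, tg, electrode, structure)@norm
    }, numeric(1))
    i <- which.min(norms)
    list(norm = norms[i], target = targets[i])
}

#' Reverse-scale a column of raw perturbation norms to fragility
#'
#' Applies the normalization `(max - value) / max` to a vector of minimum
#' perturbation norms: the electrode that is hardest to destabilize (the
#' maximum norm) maps to exactly 0 and smaller norms (more fragile
#' electrodes) map toward 1, so the output lies in `[0, 1]` and reverses
#' the raw-norm ordering.
#'
#' @param rawNorms non-negative numeric vector of minimum perturbation
#'   norms for one time window.
#' @return numeric vector in `[0, 1]`. An all-zero input (every electrode
#'   trivially destabilizes) returns all zeros with a warning.
#' @examples
#' normalizeFragility(c(2, 1, 4)) # 0.5, 0.75, 0
#' @export
normalizeFragility <- function(rawNorms) {
    if (any(rawNorms < 0)) stop("'rawNorms' must be non-negative", call. = FALSE)
    mx <- max(rawNorms)
    if (mx == 0) {
        warning(
            "all perturbation norms are zero; fragility is degenerate, returning zeros",
            call. = FALSE
        )
        return(rep(0, length(rawNorms)))
    }
    (mx - rawNorms) / mx
}

## all-electrode minimum perturbation norms for one model and target grid:
## one complex inverse per target, then closed-form norms for every
## electrode at once. Equivalent to minNormPerturbation looped over
## electrodes and targets (tested), but O(targets) inversions instead of
## O(targets * electrodes).
.windowRawNorms <- function(A, targets, structure) {
    m <- nrow(A)
    norms <- matrix(Inf, m, length(targets))
    for (j in seq_along(targets)) {
        shifted <- A - targets[j] * diag(m)
        inv <- tryCatch(solve(shifted), error = function(e) NULL)
        if (is.null(inv)) {
            ## target is an exact eigenvalue: zero perturbation everywhere
            norms[, j] <- 0
            next
        }
        R <- if (structure == "column") t(inv) else inv # column k = r_k
        a <- Re(R)
        b <- Im(R)
        aa <- colSums(a * a)
        bb <- colSums(b * b)
        ab <- colSums(a * b)
        den <- aa * bb - ab * ab
        real <- bb <= 1e-14 * pmax(aa, 1) | den <= 1e-14 * aa * bb
        n2 <- ifelse(real, 1 / aa, bb / den)
        norms[, j] <- sqrt(n2)
    }
    apply(norms, 1L, min)
}

#' Sliding-window neural fragility of an iEEG epoch
#'
#' The core analysis. The epoch is divided into `W = floor((N - window) /
#' step) + 1` windows of `window` samples hopped by `step` samples (a
#' trailing partial window is dropped). In each window a linear
#' state-transition model is fitted — with the adaptive penalty search of
#' [selectLambda()] when `lambda` is `NULL`, or with the fixed user
#' penalty otherwise — and each electrode's minimum destabilizing
#' perturbation norm is computed over a grid of unit-circle targets
#' ([unitCircleTargets()]). Raw norms are then reverse-scaled to
#' fragility, by default within each window. Windows whose model is
#' unstable even at the maximum penalty are computed anyway but flagged,
#' since fragility under unstable dynamics is ill-defined.
#'
#' The computation involves no randomness; with `parallel = TRUE` windows
#' are distributed over worker processes and the result is identical to a
#' serial run.
#'
#' @param epoch an [Epoch-class].
#' @param window window length in samples (default 250).
#' @param step window hop in samples (default 125).
#' @param lambda `NULL` (default) for adaptive selection, or a fixed
#'   non-negative ridge penalty.
#' @param omegaGridSize number of unit-circle targets searched (default 51).
#' @param structure `"column"` (default) or `"row"` perturbation structure.
#' @param parallel distribute windows across `nWorkers` forked workers.
#' @param nWorkers worker count for `parallel = TRUE`.
#' @param progress show a progress bar (serial runs only).
#' @param lambdaMin,lambdaMax,maxIter,stabilityTol adaptive-search
#'   controls, see [selectLambda()].
#' @param normalization `"window"` (default) scales each column by its own
#'   maximum raw norm; `"global"` uses the maximum over the whole matrix.
#' @return a [FragilityResult-class].
#' @examples
#' ds <- generateSynthetic(syntheticSpec(seed = 1))
#' frag <- calcAdjFrag(epochOf(ds), window = 250, step = 125)
#' frag
#' @export
calcAdjFrag <- function(epoch, window = 250, step = 125, lambda = NULL,
                        omegaGridSize = 51,
                        structure = c("column", "row"),
                        parallel = FALSE, nWorkers = 2L, progress = FALSE,
                        lambdaMin = 1e-4, lambdaMax = 10, maxIter = 20,
                        stabilityTol = 1e-12,
                        normalization = c("window", "global")) {
    stopifnot(is(epoch, "Epoch"))
    structure <- match.arg(structure)
    normalization <- match.arg(normalization)
    m <- nrow(epoch@data)
    n <- ncol(epoch@data)
    window <- as.integer(window)
    step <- as.integer(step)
    if (window > n) {
        stop(sprintf(
            "'window' (%d samples) exceeds the epoch length (%d samples)",
            window, n
        ), call. = FALSE)
    }
    if (step < 1L) stop("'step' must be at least 1", call. = FALSE)
    if (window < m + 1L) {
        warning(sprintf(
            "'window' (%d) is below the recommended minimum M + 1 = %d",
            window, m + 1L
        ), call. = FALSE)
    }
    targets <- unitCircleTargets(omegaGridSize)
    w <- (n - window) %/% step + 1L
    starts <- (seq_len(w) - 1L) * step + 1L

    oneWindow <- function(wi) {
        cols <- starts[wi]:(starts[wi] + window - 1L)
        wd <- epoch@data[, cols, drop = FALSE]
        fit <- tryCatch(
            if (is.null(lambda)) {
                selectLambda(wd, lambdaMin, lambdaMax, maxIter, stabilityTol)
            } else {
                fitWindowModel(wd, lambda, stabilityTol)
            },
            error = function(e) {
                stop(sprintf(
                    "window %d (starting %.4g s): %s", wi,
                    epoch@startTime + (starts[wi] - 1L) / epoch@samplingRate,
                    conditionMessage(e)
                ), call. = FALSE)
            }
        )
        list(
            raw = .windowRawNorms(fit@A, targets, structure),
            lambda = fit@lambda, stable = fit@stable,
            iters = fit@lambdaIterations
        )
    }

    res <- if (parallel) {
        parallel::mclapply(seq_len(w), oneWindow,
            mc.cores = max(1L, as.integer(nWorkers))
        )
    } else {
        pb <- if (progress) utils::txtProgressBar(0, w, style = 3) else NULL
        out <- vector("list", w)
        for (wi in seq_len(w)) {
            out[[wi]] <- oneWindow(wi)
            if (!is.null(pb)) utils::setTxtProgressBar(pb, wi)
        }
        if (!is.null(pb)) close(pb)
        out
    }
    bad <- vapply(res, inherits, logical(1), "try-error")
    if (any(bad)) stop(res[[which(bad)[1L]]], call. = FALSE)

    raw <- vapply(res, `[[`, numeric(m), "raw")
    raw <- matrix(raw, nrow = m)
    frag <- if (normalization == "window") {
        apply(raw, 2L, normalizeFragility)
    } else {
        gmax <- max(raw)
        if (gmax == 0) {
            warning("all perturbation norms are zero", call. = FALSE)
            raw
        } else {
            (gmax - raw) / gmax
        }
    }
    frag <- matrix(frag, nrow = m)
    dimnames(frag) <- dimnames(raw) <- list(epoch@electrodes, NULL)
    new("FragilityResult",
        fragility = frag, rawNorms = raw,
        windowStarts = epoch@startTime + (starts - 1L) / epoch@samplingRate,
        windowSize = window, step = step,
        samplingRate = epoch@samplingRate,
        lambdas = vapply(res, `[[`, numeric(1), "lambda"),
        stableFlags = vapply(res, `[[`, logical(1), "stable"),
        lambdaIterations = vapply(res, `[[`, integer(1), "iters"),
        electrodes = epoch@electrodes,
        rowData = epoch@rowData,
        omegaGrid = targets,
        structure = structure,
        normalization = normalization
    )
}

#' @describeIn FragilityResult-class the M-by-W normalized fragility matrix.
#' @export
setMethod("fragilityMatrix", "FragilityResult", function(x) x@fragility)

#' @describeIn FragilityResult-class the M-by-W raw minimum perturbation
#'   norms.
#' @export
setMethod("rawNorms", "FragilityResult", function(x) x@rawNorms)

#' @describeIn FragilityResult-class window start times (s).
#' @export
setMethod("windowStarts", "FragilityResult", function(x) x@windowStarts)

#' @describeIn FragilityResult-class window center times (s).
#' @export
setMethod("windowCenters", "FragilityResult", function(x) {
    x@windowStarts + 0.5 * x@windowSize / x@samplingRate
})

#' @describeIn FragilityResult-class ridge penalty used per window.
#' @export
setMethod("windowLambdas", "FragilityResult", function(x) x@lambdas)

#' @describeIn FragilityResult-class logical per-window stability flags.
#' @export
setMethod("stableWindows", "FragilityResult", function(x) x@stableFlags)

#' @describeIn FragilityResult-class electrode names.
#' @export
setMethod("electrodes", "FragilityResult", function(x) x@electrodes)

setMethod("show", "FragilityResult", function(object) {
    d <- dim(object@fragility)
    cat(sprintf(
        "FragilityResult: %d electrodes x %d windows (window %d, step %d samples, %s structure)\n",
        d[1], d[2], object@windowSize, object@step, object@structure
    ))
    cat(sprintf(
        "  window starts: %.4g .. %.4g s; %d/%d windows stable\n",
        object@windowStarts[1], object@windowStarts[d[2]],
        sum(object@stableFlags), d[2]
    ))
    cat(sprintf(
        "  lambda range: [%.3g, %.3g]; normalization: %s\n",
        min(object@lambdas), max(object@lambdas), object@normalization
    ))
    invisible(NULL)
})
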