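#' Random stable linear network dynamics
#'
#' Draws a dense random state-transition matrix and rescales it so its
#' spectral radius equals `targetRadius` exactly. With `normal = TRUE`
#' (the default) the matrix is built as an orthogonal similarity of
#' block-diagonal rotation/scaling blocks, which makes it a normal matrix:
#' its eigenvector basis is orthonormal, so the distance of each mode from
#' the unit circle — the quantity fragility measures — is well conditioned
#' and not confounded by the spurious near-instability that strongly
#' non-normal random matrices exhibit. `normal = FALSE` draws an i.i.d.
#' Gaussian matrix instead.
#'
#' @param m number of nodes (at least 2).
#' @param targetRadius desired spectral radius in `[0, 1)`.
#' @param seed integer RNG seed; the result is a deterministic function of
#'   `(m, targetRadius, seed)`.
#' @param normal build a normal (orthogonally diagonalizable) matrix.
#' @return an `m`-by-`m` numeric matrix with
#'   `spectralRadius(result) == targetRadius` to 1e-10.
#' @examples
#' A <- randomStableSystem(5, 0.8, seed = 1)
#' spectralRadius(A) # 0.8
#' @export
randomStableSystem <- function(m, targetRadius, seed, normal = TRUE) {
    if (m < 2L) stop("'m' must be at least 2", call. = FALSE)
    if (targetRadius < 0 || targetRadius >= 1) {
        stop("'targetRadius' must lie in [0, 1)", call. = FALSE)
    }
    set.seed(seed)
    if (normal) {
        q <- qr.Q(qr(matrix(stats::rnorm(m * m), m, m)))
        nb <- ceiling(m / 2)
        radii <- stats::runif(nb, 0.3, 1)
        radii[1L] <- 1
        d <- matrix(0, m, m)
        i <- 1L
        for (b in seq_len(nb)) {
            if (i < m) {
                th <- stats::runif(1, 0, pi)
                d[i:(i + 1L), i:(i + 1L)] <- radii[b] *
                    matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
                i <- i + 2L
            } else {
                d[i, i] <- radii[b] * sample(c(-1, 1), 1L)
                i <- i + 1L
            }
        }
        a <- q %*% d %*% t(q)
    } else {
        a <- matrix(stats::rnorm(m * m), m, m)
    }
    if (targetRadius == 0) {
        return(matrix(0, m, m))
    }
    a * (targetRadius / spectralRadius(a))
}

#' Plant fragile nodes by embedding a near-unstable network mode
#'
#' Builds the ictal state-transition matrix from a baseline matrix so that
#' the planted nodes carry the system's near-unstable mode and are, by
#' construction, the most fragile: a small perturbation of their
#' column of the dynamics suffices to push the dominant eigenvalue onto
#' the unit circle. Let `v` be the normalized indicator vector of the
#' planted nodes. The baseline dynamics (optionally with the planted
#' nodes' incoming rows scaled by `couplingBoost`) are deflated to the
#' complement of `v` via the projector `P = I - v v'`, rescaled if needed
#' so the residual spectrum stays inside `targetRadius`, and the mode
#' `targetRadius * v v'` is added. The result has spectral radius exactly
#' `targetRadius`, attained by the eigenvector `v` supported on the
#' planted nodes.
#'
#' @param A baseline square state-transition matrix (spectral radius
#'   below 1).
#' @param nodes 1-based indices of the nodes to make fragile.
#' @param couplingBoost gain on the planted nodes' incoming weights in the
#'   deflated residual dynamics (default 1).
#' @param targetRadius spectral radius of the result, in `(0, 1)`;
#'   typically close to 1 so the seizure dynamics are near-unstable.
#' @return a square matrix with spectral radius `targetRadius` whose
#'   dominant mode is supported on `nodes`.
#' @examples
#' A <- randomStableSystem(8, 0.85, seed = 2)
#' Aict <- plantFragileNodes(A, c(2, 5), targetRadius = 0.99)
#' spectralRadius(Aict) # 0.99
#' @export
plantFragileNodes <- function(A, nodes, couplingBoost = 1,
                              targetRadius = 0.99) {
    if (!is.matrix(A) || nrow(A) != ncol(A)) {
        stop("'A' must be square", call. = FALSE)
    }
    m <- nrow(A)
    nodes <- as.integer(nodes)
    if (!length(nodes) || any(nodes < 1L | nodes > m)) {
        stop("'nodes' must be non-empty indices in [1, ", m, "]", call. = FALSE)
    }
    if (!(targetRadius > 0 && targetRadius < 1)) {
        stop("'targetRadius' must lie in (0, 1)", call. = FALSE)
    }
    A[nodes, ] <- A[nodes, ] * couplingBoost
    v <- rep(0, m)
    v[nodes] <- 1 / sqrt(length(nodes))
    p <- diag(m) - tcrossprod(v)
    residual <- p %*% A %*% p
    sr <- spectralRadius(residual)
    if (sr >= targetRadius) {
        residual <- residual * (0.95 * targetRadius / sr)
    }
    residual + targetRadius * tcrossprod(v)
}

#' Specification of a synthetic seizure recording
#'
#' Collects the generator parameters with defaults chosen to resemble a
#' short peri-ictal clinical iEEG clip: 12 electrodes at 500 Hz, 2 s
#' before and after onset, a stable baseline network (spectral radius
#' 0.85), near-unstable ictal dynamics (0.99) whose unstable mode is
#' planted on two electrodes, and 20 microvolt process noise.
#'
#' @param nElectrodes,samplingRate,preOnsetSeconds,postOnsetSeconds,baselineRadius,ictalRadius,fragileNodes,couplingBoost,noiseSd,tanhSaturation,seed
#'   see [SyntheticSpec-class] for the meaning of each field.
#' @return a validated [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nElectrodes = 12, samplingRate = 500,
                          preOnsetSeconds = 2, postOnsetSeconds = 2,
                          baselineRadius = 0.85, ictalRadius = 0.99,
                          fragileNodes = c(3, 8), couplingBoost = 1,
                          noiseSd = 20, tanhSaturation = Inf, seed = 1) {
    new("SyntheticSpec",
        nElectrodes = as.integer(nElectrodes),
        samplingRate = as.numeric(samplingRate),
        preOnsetSeconds = as.numeric(preOnsetSeconds),
        postOnsetSeconds = as.numeric(postOnsetSeconds),
        baselineRadius = as.numeric(baselineRadius),
        ictalRadius = as.numeric(ictalRadius),
        fragileNodes = as.integer(fragileNodes),
        couplingBoost = as.numeric(couplingBoost),
        noiseSd = as.numeric(noiseSd),
        tanhSaturation = as.numeric(tanhSaturation),
        seed = as.integer(seed)
    )
}

#' Generate a synthetic seizure epoch with known fragile nodes
#'
#' Simulates piecewise-stationary linear network dynamics
#' `x(t+1) = A x(t) + e(t)` with i.i.d. Gaussian process noise: the
#' baseline matrix drives the pre-onset segment and the ictal matrix —
#' the baseline with a near-unstable mode planted on the fragile nodes
#' via [plantFragileNodes()] — drives the post-onset segment, with the
#' state carried continuously across the transition. Amplitudes are
#' clipped to +-2000 microvolts (a clipped fraction above 10% aborts with
#' advice to lower `ictalRadius`). The resulting [Epoch-class] has onset
#' at t = 0 and `soz` flags set on the planted nodes. The whole dataset
#' is a deterministic function of the spec (including its seed).
#'
#' @param spec a [SyntheticSpec-class], see [syntheticSpec()].
#' @return a [SyntheticDataset-class].
#' @examples
#' ds <- generateSynthetic(syntheticSpec(seed = 42))
#' epochOf(ds)
#' @export
generateSynthetic <- function(spec = syntheticSpec()) {
    validObject(spec)
    m <- spec@nElectrodes
    nPre <- round(spec@preOnsetSeconds * spec@samplingRate)
    nPost <- round(spec@postOnsetSeconds * spec@samplingRate)
    aPre <- randomStableSystem(m, spec@baselineRadius, spec@seed)
    aIct <- plantFragileNodes(
        aPre, spec@fragileNodes, spec@couplingBoost, spec@ictalRadius
    )
    set.seed(spec@seed + 1L)
    x <- matrix(0, m, nPre + nPost)
    state <- stats::rnorm(m, 0, spec@noiseSd)
    clipBound <- 2000
    for (t in seq_len(nPre + nPost)) {
        a <- if (t <= nPre) aPre else aIct
        state <- drop(a %*% state) + stats::rnorm(m, 0, spec@noiseSd)
        if (is.finite(spec@tanhSaturation)) {
            state <- spec@tanhSaturation * tanh(state / spec@tanhSaturation)
        }
        state <- pmin(pmax(state, -clipBound), clipBound)
        x[, t] <- state
    }
    clippedFrac <- mean(abs(x) >= clipBound)
    if (clippedFrac > 0.1) {
        stop(sprintf(
            "trajectory is explosive (%.1f%% of samples at the clip bound); lower 'ictalRadius'",
            100 * clippedFrac
        ), call. = FALSE)
    }
    electrodes <- paste0("E", seq_len(m))
    rowData <- data.frame(
        soz = seq_len(m) %in% spec@fragileNodes,
        resected = FALSE
    )
    epoch <- Epoch(
        x, electrodes,
        startTime = -nPre / spec@samplingRate,
        samplingRate = spec@samplingRate,
        rowData = rowData,
        metaData = list(source = "synthetic", seed = spec@seed)
    )
    new("SyntheticDataset",
        epoch = epoch, truth = spec@fragileNodes, spec = spec,
        Apre = aPre, Aictal = aIct
    )
}

#' @describeIn SyntheticDataset-class the simulated [Epoch-class].
#' @param x a [SyntheticDataset-class].
#' @export
epochOf <- function(x) {
    stopifnot(is(x, "SyntheticDataset"))
    x@epoch
}

#' @describeIn SyntheticDataset-class 1-based indices of the planted
#'   fragile nodes.
#' @export
groundTruth <- function(x) {
    stopifnot(is(x, "SyntheticDataset"))
    x@truth
}

setMethod("show", "SyntheticDataset", function(object) {
    cat(sprintf(
        "SyntheticDataset: %d electrodes, planted fragile nodes: %s (seed %d)\n",
        object@spec@nElectrodes,
        paste(object@truth, collapse = ", "), object@spec@seed
    ))
    show(object@epoch)
    invisible(NULL)
})
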