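simulateLinear <- function(a, n, noiseSd = 0, seed = 1, x0 = NULL) {
    set.seed(seed)
    m <- nrow(a)
    x <- matrix(0, m, n)
    state <- if (is.null(x0)) rnorm(m) else x0
    for (t in seq_len(n)) {
        state <- drop(a %*% state) +
            (if (noiseSd > 0) rnorm(m, 0, noiseSd) else 0)
        x[, t] <- state
    }
    x
}

test_that("spectralRadius matches closed forms", {
    expect_equal(spectralRadius(diag(3)), 1)
    expect_equal(spectralRadius(matrix(0, 4, 4)), 0)
    expect_equal(spectralRadius(matrix(c(0, -1, 1, 0), 2)), 1)
    expect_error(spectralRadius(matrix(1, 2, 3)), "square")
    expect_error(spectralRadius(matrix(c(1, NA, 0, 1), 2)), "finite")
})

test_that("noiseless dynamics are recovered exactly and ridge shrinks", {
    a0 <- matrix(c(0.6, 0.2, -0.1, 0.1, 0.5, 0.2, 0, -0.2, 0.7), 3, 3)
    x <- simulateLinear(a0, 50, noiseSd = 0, seed = 4)
    fit <- fitWindowModel(x, lambda = 0)
    expect_lt(
        norm(fit@A - a0, "F") / norm(a0, "F"), 1e-8
    )
    expect_equal(fit@spectralRadius, spectralRadius(a0), tolerance = 1e-6)

    big <- fitWindowModel(x, lambda = 1e6)
    expect_lt(norm(big@A, "F"), 1e-3 * norm(fit@A, "F"))
})

test_that("ridge solution matches an augmented least-squares reference", {
    # reference solves the ridge problem as stacked OLS via QR -- an
    # algorithmically different route than the normal equations
    ridgeQR <- function(w, lambda) {
        m <- nrow(w)
        n <- ncol(w)
        X <- w[, -n, drop = FALSE]
        Y <- w[, -1, drop = FALSE]
        Xa <- rbind(t(X), sqrt(lambda) * diag(m))
        Ya <- rbind(t(Y), matrix(0, m, m))
        t(qr.solve(Xa, Ya))
    }
    set.seed(21)
    for (i in 1:20) {
        m <- sample(3:6, 1)
        w <- matrix(rnorm(m * 80), m, 80)
        lam <- 10^runif(1, -4, 1)
        fit <- fitWindowModel(w, lam)
        ref <- ridgeQR(w, lam)
        expect_lt(norm(fit@A - ref, "F") / norm(ref, "F"), 1e-10)
    }
})

test_that("||A||_F is non-increasing in lambda (ridge shrinkage)", {
    set.seed(22)
    for (i in 1:5) {
        w <- matrix(rnorm(5 * 100), 5, 100)
        norms <- vapply(
            10^seq(-4, 2, by = 0.5),
            function(l) norm(fitWindowModel(w, l)@A, "F"), numeric(1)
        )
        expect_true(all(diff(norms) <= 1e-12))
    }
})

test_that("degenerate inputs are rejected with actionable errors", {
    w <- matrix(rnorm(40), 4, 10)
    w[2, ] <- 7
    expect_error(fitWindowModel(w), "degenerate channel")
    w2 <- matrix(rnorm(40), 4, 10)
    w2[1, 5] <- NaN
    expect_error(fitWindowModel(w2), "NaN/Inf")
    # lambda = 0 with rank-deficient Gram matrix
    w3 <- matrix(rnorm(6 * 4), 6, 4)
    expect_warning(
        expect_error(fitWindowModel(w3, lambda = 0), "positive 'lambda'"),
        "recommended"
    )
    expect_warning(
        fitWindowModel(matrix(rnorm(6 * 6), 6, 6), 1e-2),
        "M \\+ 1"
    )
})

test_that("adaptive lambda search short-circuits on stable windows", {
    set.seed(30)
    a <- randomStableSystem(4, 0.8, seed = 31)
    w <- simulateLinear(a, 100, noiseSd = 1, seed = 32)
    fit <- selectLambda(w)
    expect_identical(fit@lambda, 1e-4)
    expect_identical(fit@lambdaIterations, 0L)
    expect_true(fit@stable)
})

test_that("bisection finds a stabilizing lambda within bounds and budget", {
    for (seed in c(1, 7, 13)) {
        w <- expandingWindow(seed)
        low <- fitWindowModel(w, 1e-4)
        expect_false(low@stable) # construction precondition
        fit <- selectLambda(w)
        expect_true(fit@stable)
        expect_gt(fit@lambda, 1e-4)
        expect_lte(fit@lambda, 10)
        expect_lte(fit@lambdaIterations, 20L)
        expect_gt(fit@lambdaIterations, 0L)
    }
})

test_that("the search warns and flags when even lambdaMax is unstable", {
    # strongly expanding system at large amplitude: ridge cannot tame it
    a <- randomStableSystem(4, 0.9, seed = 41) * (1.4 / 0.9)
    w <- simulateLinear(a, 60, noiseSd = 0.01, seed = 42) * 1e4
    expect_warning(fit <- selectLambda(w), "unstable")
    expect_false(fit@stable)
    expect_identical(fit@lambda, 10)
})
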