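test_that("random stable systems hit the target radius deterministically", {
    a <- randomStableSystem(5, 0.8, seed = 1)
    expect_lt(abs(spectralRadius(a) - 0.8), 1e-10)
    expect_identical(a, randomStableSystem(5, 0.8, seed = 1))
    expect_false(identical(a, randomStableSystem(5, 0.8, seed = 2)))
    expect_identical(randomStableSystem(4, 0, seed = 1), matrix(0, 4, 4))
    expect_error(randomStableSystem(4, 1, seed = 1), "targetRadius")
    expect_error(randomStableSystem(1, 0.5, seed = 1), "at least 2")

    dense <- randomStableSystem(5, 0.9, seed = 3, normal = FALSE)
    expect_lt(abs(spectralRadius(dense) - 0.9), 1e-10)
})

test_that("planted nodes carry the dominant mode and are most fragile", {
    targets <- unitCircleTargets(51)
    for (seed in 1:8) {
        a <- randomStableSystem(12, 0.85, seed)
        aict <- plantFragileNodes(a, c(3, 8), targetRadius = 0.99)
        expect_lt(abs(spectralRadius(aict) - 0.99), 1e-8)
        # the dominant eigenvector is supported on the planted nodes
        ev <- eigen(aict)
        dom <- ev$vectors[, which.max(Mod(ev$values))]
        expect_gt(sum(Mod(dom)[c(3, 8)]^2), 0.99)
        # ground-truth fragility: planted nodes have the smallest
        # minimum perturbation norms
        raw <- fragmap:::.windowRawNorms(aict, targets, "column")
        expect_true(all(sort(order(raw)[1:2]) == c(3, 8)))
    }
    expect_error(plantFragileNodes(diag(3) * 0.5, integer()), "non-empty")
    expect_error(plantFragileNodes(diag(3) * 0.5, 1, targetRadius = 1.2),
        "targetRadius"
    )
})

test_that("generated epochs have the right geometry and ground truth", {
    ds <- generateSynthetic(syntheticSpec(
        nElectrodes = 8, samplingRate = 500,
        preOnsetSeconds = 1, postOnsetSeconds = 1, fragileNodes = c(2, 5),
        seed = 9
    ))
    ep <- epochOf(ds)
    expect_identical(dim(ep), c(8L, 1000L))
    expect_equal(epochTimes(ep)[501], 0) # onset sample
    expect_equal(startTime(ep), -1)
    expect_identical(sozElectrodes(ep), c("E2", "E5"))
    expect_identical(groundTruth(ds), c(2L, 5L))

    # bit-reproducibility
    ds2 <- generateSynthetic(syntheticSpec(
        nElectrodes = 8, samplingRate = 500,
        preOnsetSeconds = 1, postOnsetSeconds = 1, fragileNodes = c(2, 5),
        seed = 9
    ))
    expect_identical(epochData(ep), epochData(epochOf(ds2)))
})

test_that("degenerate and explosive trajectories are surfaced", {
    silent <- generateSynthetic(syntheticSpec(noiseSd = 0, seed = 2))
    expect_true(all(epochData(epochOf(silent)) == 0))
    expect_error(
        fitWindowModel(epochData(epochOf(silent))[, 1:100]),
        "degenerate channel"
    )
    expect_error(
        generateSynthetic(syntheticSpec(noiseSd = 5000, seed = 3)),
        "explosive"
    )
})

test_that("the seizure transition is visible to the system identifier", {
    ds <- generateSynthetic(syntheticSpec(seed = 11))
    ep <- epochOf(ds)
    n <- ncol(epochData(ep))
    pre <- fitWindowModel(epochData(ep)[, 1:(n / 2)], 1e-4)
    post <- fitWindowModel(epochData(ep)[, (n / 2 + 1):n], 1e-4)
    expect_gt(post@spectralRadius, pre@spectralRadius)
    # the fitted pre-onset model approximates the true generator
    expect_lt(
        norm(pre@A - ds@Apre, "F") / norm(ds@Apre, "F"), 0.2
    )
})

test_that("tanh saturation bounds the trajectory without exploding", {
    ds <- generateSynthetic(syntheticSpec(tanhSaturation = 100, seed = 12))
    expect_lte(max(abs(epochData(epochOf(ds)))), 100)
})
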