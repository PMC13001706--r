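test_that("Epoch construction validates dimensions and computes timestamps", {
    x <- matrix(rnorm(300), 3, 100)
    ep <- Epoch(x, c("A1", "A2", "B1"), startTime = -1, samplingRate = 100)
    expect_identical(dim(ep), c(3L, 100L))
    tt <- epochTimes(ep)
    expect_equal(tt[1], -1)
    expect_equal(tt[100], -1 + 99 / 100)

    expect_error(
        Epoch(x, c("A1", "A2"), samplingRate = 100),
        "electrodes"
    )
    expect_error(
        Epoch(x, c("A1", "A1", "B1"), samplingRate = 100),
        "duplicated"
    )
    expect_error(
        Epoch(x, c("A1", "A2", "B1"), samplingRate = -5),
        "samplingRate"
    )
    expect_error(
        Epoch(x, c("A1", "A2", "B1"),
            samplingRate = 100,
            rowData = data.frame(soz = c(TRUE, FALSE))
        ),
        "rowData"
    )

    z <- Epoch(matrix(0, 2, 10), c("a", "b"), samplingRate = 10)
    expect_true(all(epochData(z) == 0))
})

test_that("subsetting keeps data and metadata row-for-row consistent", {
    ep <- randomEpoch(3, 100, rate = 100, startTime = 0, seed = 1)
    sub <- ep[c(1, 3), ]
    expect_identical(electrodes(sub), c("CH1", "CH3"))
    expect_identical(electrodeData(sub)$soz, electrodeData(ep)$soz[c(1, 3)])
    expect_identical(unname(epochData(sub)), unname(epochData(ep)[c(1, 3), ]))

    all <- ep[seq_len(3), seq_len(100)]
    expect_equal(epochData(all), epochData(ep))
    expect_equal(startTime(all), startTime(ep))

    tsub <- ep[, 11:20]
    expect_equal(startTime(tsub), 0.1)
    expect_identical(ncol(epochData(tsub)), 10L)

    byName <- ep["CH2", ]
    expect_identical(electrodes(byName), "CH2")

    expect_error(ep["NOPE", ], "NOPE")
    expect_error(ep[5, ], "out of range")
    expect_error(ep[, 150], "out of range")
    expect_error(ep[, c(1, 3, 5)], "contiguous")
    expect_identical(epochMetadata(tsub), epochMetadata(ep))
})

test_that("crop uses half-open interval arithmetic and composes", {
    ep <- Epoch(matrix(rnorm(10000), 1, 10000), "E1",
        startTime = 0, samplingRate = 1000
    )
    cr <- crop(ep, 2, 4)
    expect_identical(ncol(epochData(cr)), 2000L)
    expect_equal(startTime(cr), 2.0)

    whole <- crop(ep, 0, 11)
    expect_equal(epochData(whole), epochData(ep))

    expect_error(crop(ep, 100, 200), "time span")
    expect_error(crop(ep, 4, 2), "start")

    inner <- crop(crop(ep, 1, 8), 2.5, 4.5)
    direct <- crop(ep, 2.5, 4.5)
    expect_equal(epochData(inner), epochData(direct))
    expect_equal(startTime(inner), startTime(direct))
})

test_that("resample preserves duration, length contract, and spectra", {
    ep <- Epoch(matrix(rnorm(5000), 1, 5000), "E1",
        startTime = 0, samplingRate = 1000
    )
    down <- resample(ep, 500)
    expect_identical(ncol(epochData(down)), 2500L)
    expect_equal(samplingRate(down), 500)

    same <- resample(ep, 1000)
    expect_identical(epochData(same), epochData(ep))

    # dominant spectral peak survives anti-aliased downsampling
    t <- (0:4999) / 1000
    sine <- Epoch(matrix(sin(2 * pi * 10 * t), 1), "E1",
        startTime = 0, samplingRate = 1000
    )
    ds <- resample(sine, 250)
    y <- drop(epochData(ds))
    spec <- Mod(stats::fft(y))[2:(length(y) %/% 2)]
    peakHz <- which.max(spec) * 250 / length(y)
    expect_equal(peakHz, 10, tolerance = 0.05)

    # duration preserved within one sample period at the new rate
    up <- resample(ep, 1234)
    oldDur <- 5000 / 1000
    newDur <- ncol(epochData(up)) / 1234
    expect_lt(abs(newDur - oldDur), 1 / 1234)

    expect_error(resample(ep, -1), "positive")
})

test_that("raw voltage plot stacks traces and highlights electrodes", {
    ep <- randomEpoch(3, 50, rate = 50, startTime = -0.5, seed = 2)
    p <- plot(ep)
    expect_s3_class(p, "ggplot")
    expect_identical(nlevels(p$data$electrode), 3L)
    expect_false(any(p$data$highlighted))

    ph <- plot(ep, highlight = "CH2")
    expect_identical(
        unique(as.character(ph$data$electrode[ph$data$highlighted])), "CH2"
    )
    # onset marker layer present
    expect_true(any(vapply(
        ph$layers,
        function(l) inherits(l$geom, "GeomVline"), logical(1)
    )))
    expect_error(plot(ep, highlight = "ZZ"), "ZZ")
})

test_that("soz accessor falls back to all-false when the column is absent", {
    ep <- randomEpoch(3, 20, seed = 3, withSoz = FALSE)
    expect_message(out <- sozElectrodes(ep), "non-SOZ")
    expect_identical(out, character())
    ep2 <- randomEpoch(3, 20, seed = 3, withSoz = TRUE)
    expect_identical(sozElectrodes(ep2), "CH1")
})
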