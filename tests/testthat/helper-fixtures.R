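# Programmatic fixtures shared across the suite.

randomEpoch <- function(m = 4, n = 200, rate = 100, startTime = -1,
                        seed = NULL, withSoz = TRUE) {
    if (!is.null(seed)) set.seed(seed)
    data <- matrix(stats::rnorm(m * n, sd = 50), m, n)
    rowData <- if (withSoz) {
        data.frame(soz = seq_len(m) <= 1, resected = FALSE)
    } else {
        NULL
    }
    Epoch(data, paste0("CH", seq_len(m)),
        startTime = startTime, samplingRate = rate,
        rowData = rowData,
        metaData = list(patient = "synthetic-patient", outcome = "unknown")
    )
}

# window whose lambda = 1e-4 ridge fit is unstable but whose lambda = 10
# fit is stable: a mildly expanding linear system observed at unit
# variance, so the ridge term is comparable to the data Gram matrix at
# the top of the search range.
expandingWindow <- function(seed, m = 6, n = 120, radius = 1.04) {
    a <- randomStableSystem(m, 0.9, seed) * (radius / 0.9)
    set.seed(seed + 1000L)
    x <- matrix(0, m, n)
    state <- stats::rnorm(m)
    for (t in seq_len(n)) {
        state <- drop(a %*% state) + stats::rnorm(m, 0, 0.02)
        x[, t] <- state
    }
    x / stats::sd(x) * 0.5
}

# minimal valid FragilityResult around a given fragility matrix, for
# tests of aggregation/plotting that do not need a full pipeline run
makeFragResult <- function(frag, raw = NULL, rate = 500, windowSize = 250,
                           step = 125, soz = NULL) {
    m <- nrow(frag)
    w <- ncol(frag)
    if (is.null(raw)) raw <- 1 - frag
    electrodes <- paste0("E", seq_len(m))
    dimnames(frag) <- dimnames(raw) <- list(electrodes, NULL)
    rowData <- data.frame(
        soz = if (is.null(soz)) rep(FALSE, m) else seq_len(m) %in% soz
    )
    new("FragilityResult",
        fragility = frag, rawNorms = raw,
        windowStarts = (seq_len(w) - 1) * step / rate,
        windowSize = as.integer(windowSize), step = as.integer(step),
        samplingRate = rate,
        lambdas = rep(1e-4, w), stableFlags = rep(TRUE, w),
        lambdaIterations = rep(0L, w),
        electrodes = electrodes, rowData = rowData,
        omegaGrid = unitCircleTargets(11), structure = "column",
        normalization = "window"
    )
}

# Minimal EDF writer for import tests: fixed-width ASCII headers plus
# 16-bit little-endian sample records.
writeEdfFixture <- function(path, data, rate, labels = NULL,
                            physMin = -1000, physMax = 1000,
                            digMin = -32768L, digMax = 32767L,
                            sampleRates = NULL) {
    m <- nrow(data)
    n <- ncol(data)
    if (is.null(labels)) labels <- paste0("CH", seq_len(m))
    if (is.null(sampleRates)) sampleRates <- rep(rate, m)
    recDur <- 1
    nRecords <- n %/% max(sampleRates)
    stopifnot(n == nRecords * max(sampleRates))
    pad <- function(s, w) {
        s <- as.character(s)
        stopifnot(nchar(s) <= w)
        paste0(s, strrep(" ", w - nchar(s)))
    }
    con <- file(path, "wb")
    on.exit(close(con))
    wr <- function(s, w) writeBin(charToRaw(pad(s, w)), con)
    wr("0", 8)
    wr("test patient", 80)
    wr("test recording", 80)
    wr("01.01.20", 8)
    wr("00.00.00", 8)
    wr(256 + 256 * m, 8)
    wr("", 44)
    wr(nRecords, 8)
    wr(format(recDur), 8)
    wr(m, 4)
    for (s in labels) wr(s, 16)
    for (i in seq_len(m)) wr("unknown", 80)
    for (i in seq_len(m)) wr("uV", 8)
    for (i in seq_len(m)) wr(format(physMin), 8)
    for (i in seq_len(m)) wr(format(physMax), 8)
    for (i in seq_len(m)) wr(format(digMin), 8)
    for (i in seq_len(m)) wr(format(digMax), 8)
    for (i in seq_len(m)) wr("", 80)
    for (i in seq_len(m)) wr(sampleRates[i] * recDur, 8)
    for (i in seq_len(m)) wr("", 32)
    toDig <- function(phys) {
        as.integer(round((phys - physMin) / (physMax - physMin) *
            (digMax - digMin) + digMin))
    }
    for (r in seq_len(nRecords)) {
        for (i in seq_len(m)) {
            nS <- sampleRates[i] * recDur
            cols <- ((r - 1) * nS + 1):(r * nS)
            writeBin(toDig(data[i, cols]), con, size = 2L, endian = "little")
        }
    }
    invisible(path)
}
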