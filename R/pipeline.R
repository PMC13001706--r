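#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its default and
#' validates each against the preconditions of the stage that consumes it.
#'
#' @param bandpassLow,bandpassHigh,bandpassOrder Butterworth bandpass
#'   settings (defaults 0.5 Hz, 150 Hz, order 4); set
#'   `bandpass = FALSE` to skip the stage.
#' @param bandpass logical, apply the bandpass stage.
#' @param notchHz notch center frequency (default 60; use 50 for European
#'   line noise); `notch = FALSE` skips the stage.
#' @param notch logical, apply the notch stage.
#' @param notchQuality notch quality factor.
#' @param window,step sliding-window length and hop in samples.
#' @param lambda `NULL` for adaptive ridge-penalty selection or a fixed
#'   value.
#' @param lambdaMin,lambdaMax,maxIter adaptive-search controls.
#' @param omegaGridSize number of unit-circle targets.
#' @param structure `"column"` or `"row"` perturbation structure.
#' @param sozMethod,sozProportion electrode aggregation and selection
#'   fraction for [estimateSOZ()].
#' @param parallel,nWorkers window-level parallelism.
#' @param seed integer recorded in the run manifest.
#' @return a named list with class `fragilityPipelineConfig`.
#' @export
pipelineConfig <- function(bandpass = TRUE, bandpassLow = 0.5,
                           bandpassHigh = 150, bandpassOrder = 4,
                           notch = TRUE, notchHz = 60, notchQuality = 30,
                           window = 250, step = 125, lambda = NULL,
                           lambdaMin = 1e-4, lambdaMax = 10, maxIter = 20,
                           omegaGridSize = 51,
                           structure = c("column", "row"),
                           sozMethod = c("mean", "median", "max", "min"),
                           sozProportion = 0.1,
                           parallel = FALSE, nWorkers = 2L, seed = 1L) {
    structure <- match.arg(structure)
    sozMethod <- match.arg(sozMethod)
    stopifnot(
        bandpassLow > 0, bandpassLow < bandpassHigh, bandpassOrder >= 1,
        notchHz > 0, notchQuality > 0,
        window >= 2, step >= 1,
        is.null(lambda) || lambda >= 0,
        lambdaMin > 0, lambdaMin < lambdaMax, maxIter >= 1,
        omegaGridSize >= 1,
        sozProportion > 0, sozProportion <= 1
    )
    structure(
        list(
            bandpass = isTRUE(bandpass), bandpassLow = bandpassLow,
            bandpassHigh = bandpassHigh, bandpassOrder = bandpassOrder,
            notch = isTRUE(notch), notchHz = notchHz,
            notchQuality = notchQuality,
            window = as.integer(window), step = as.integer(step),
            lambda = lambda, lambdaMin = lambdaMin, lambdaMax = lambdaMax,
            maxIter = as.integer(maxIter),
            omegaGridSize = as.integer(omegaGridSize),
            structure = structure, sozMethod = sozMethod,
            sozProportion = sozProportion,
            parallel = isTRUE(parallel), nWorkers = as.integer(nWorkers),
            seed = as.integer(seed)
        ),
        class = "fragilityPipelineConfig"
    )
}

.finalizeArtifact <- function(partial, final) {
    file.rename(partial, final)
    final
}

#' Run the full fragility pipeline on an epoch store
#'
#' Reads an epoch, applies the configured preprocessing (bandpass, notch),
#' computes the sliding-window fragility matrix, estimates the SOZ, and
#' writes the artifacts into `outdir`: `frag.h5`, `frag.tsv`, `soz.tsv`,
#' `heatmap.png`, `distribution.png`, `quantile.png`, and `manifest.json`
#' (configuration, package version, seed, input path, and per-window
#' lambda/stability diagnostics — enough to re-run the pipeline exactly
#' via [runPipelineFromManifest()]). Each artifact is written under a
#' `.partial` suffix first and renamed on completion of its stage, so a
#' failed run leaves only `.partial` files behind.
#'
#' @param input path of an HDF5 epoch store ([writeEpoch()]).
#' @param outdir output directory, created if needed.
#' @param config a [pipelineConfig()].
#' @return invisibly, a list with the [FragilityResult-class], the
#'   [SozEstimate-class] and the artifact paths.
#' @export
runPipeline <- function(input, outdir, config = pipelineConfig()) {
    stopifnot(inherits(config, "fragilityPipelineConfig"))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    epoch <- readEpoch(input)
    if (config$bandpass) {
        epoch <- bandpass(
            epoch, config$bandpassLow, config$bandpassHigh,
            config$bandpassOrder
        )
    }
    if (config$notch) {
        epoch <- notch(epoch, config$notchHz, config$notchQuality)
    }
    frag <- calcAdjFrag(
        epoch,
        window = config$window, step = config$step,
        lambda = config$lambda, omegaGridSize = config$omegaGridSize,
        structure = config$structure, parallel = config$parallel,
        nWorkers = config$nWorkers,
        lambdaMin = config$lambdaMin, lambdaMax = config$lambdaMax,
        maxIter = config$maxIter
    )
    soz <- estimateSOZ(frag,
        method = config$sozMethod,
        proportion = config$sozProportion
    )

    paths <- list()
    art <- function(name) file.path(outdir, name)
    part <- function(name) paste0(art(name), ".partial")

    writeFragility(frag, part("frag.h5"), "h5")
    paths$frag_h5 <- .finalizeArtifact(part("frag.h5"), art("frag.h5"))
    writeFragility(frag, part("frag.tsv"), "tsv")
    paths$frag_tsv <- .finalizeArtifact(part("frag.tsv"), art("frag.tsv"))

    utils::write.table(
        sozTable(soz), part("soz.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
    )
    paths$soz_tsv <- .finalizeArtifact(part("soz.tsv"), art("soz.tsv"))

    grp <- which(seq_along(electrodes(frag)) %in%
        which(as.logical(frag@rowData$soz)))
    if (!length(grp) || length(grp) == length(electrodes(frag))) {
        ## no usable SOZ annotation: highlight the estimated SOZ instead
        grp <- match(soz@selected, electrodes(frag))
    }
    figures <- list(
        heatmap.png = plotFragHeatmap(frag, groupIndex = grp),
        distribution.png = plotFragDistribution(frag, groupIndex = grp),
        quantile.png = plotFragQuantile(frag, groupIndex = grp)
    )
    for (name in names(figures)) {
        ggplot2::ggsave(part(name), figures[[name]],
            device = "png", width = 8, height = 5, dpi = 120
        )
        paths[[name]] <- .finalizeArtifact(part(name), art(name))
    }

    manifest <- list(
        package = "fragmap",
        version = as.character(utils::packageVersion("fragmap")),
        input = normalizePath(input),
        config = config[setdiff(names(config), NULL)],
        seed = config$seed,
        windows = list(
            starts = frag@windowStarts,
            lambdas = frag@lambdas,
            stable = frag@stableFlags,
            lambda_iterations = frag@lambdaIterations
        )
    )
    jsonlite::write_json(
        manifest, part("manifest.json"),
        auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
    )
    paths$manifest <- .finalizeArtifact(part("manifest.json"), art("manifest.json"))

    invisible(list(fragility = frag, soz = soz, paths = paths))
}

#' Re-run a pipeline exactly as recorded in a manifest
#'
#' @param manifestPath a `manifest.json` written by [runPipeline()].
#' @param outdir output directory for the reproduced artifacts.
#' @return as [runPipeline()].
#' @export
runPipelineFromManifest <- function(manifestPath, outdir) {
    man <- jsonlite::fromJSON(manifestPath)
    cfg <- man$config
    config <- pipelineConfig(
        bandpass = cfg$bandpass, bandpassLow = cfg$bandpassLow,
        bandpassHigh = cfg$bandpassHigh, bandpassOrder = cfg$bandpassOrder,
        notch = cfg$notch, notchHz = cfg$notchHz,
        notchQuality = cfg$notchQuality,
        window = cfg$window, step = cfg$step,
        lambda = cfg$lambda,
        lambdaMin = cfg$lambdaMin, lambdaMax = cfg$lambdaMax,
        maxIter = cfg$maxIter, omegaGridSize = cfg$omegaGridSize,
        structure = cfg$structure, sozMethod = cfg$sozMethod,
        sozProportion = cfg$sozProportion,
        parallel = cfg$parallel, nWorkers = cfg$nWorkers, seed = man$seed
    )
    runPipeline(man$input, outdir, config)
}
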