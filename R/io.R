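## On-disk stores.
##
## Epoch HDF5 layout:
##   /data           M x N float64 voltage matrix
##   /electrodes     M strings
##   /row_data/<col> one dataset per rowData column (attr r_class keeps type)
##   /meta_data/<k>  scalar/atomic entries as-is; anything else JSON-encoded
##                   (attr encoding = "json")
##   root attributes: start_time, sampling_rate
##
## Writes are atomic: a temporary file in the same directory is renamed
## over the destination once complete.

.h5CloseAll <- function() {
    try(rhdf5::h5closeAll(), silent = TRUE)
}

.atomically <- function(path, writer) {
    tmp <- paste0(path, ".tmp", Sys.getpid())
    on.exit({
        .h5CloseAll()
        if (file.exists(tmp)) unlink(tmp)
    })
    writer(tmp)
    .h5CloseAll()
    if (!file.rename(tmp, path)) {
        ## rename can fail across filesystems; fall back to copy
        if (!file.copy(tmp, path, overwrite = TRUE)) {
            stop("cannot write to '", path, "'", call. = FALSE)
        }
        unlink(tmp)
    }
    invisible(NULL)
}

.writeTyped <- function(file, group, name, value) {
    cls <- class(value)[1L]
    stored <- if (is.logical(value)) as.integer(value) else value
    if (!is.atomic(stored)) {
        stored <- as.character(
            jsonlite::toJSON(value, auto_unbox = TRUE, digits = NA)
        )
        cls <- "json"
    }
    rhdf5::h5write(stored, file, paste0(group, "/", name))
    fid <- rhdf5::H5Fopen(file)
    did <- rhdf5::H5Dopen(fid, paste0(group, "/", name))
    rhdf5::h5writeAttribute(cls, did, "r_class")
    rhdf5::H5Dclose(did)
    rhdf5::H5Fclose(fid)
}

.readTyped <- function(file, name) {
    value <- rhdf5::h5read(file, name, read.attributes = TRUE)
    cls <- attr(value, "r_class")
    attributes(value) <- NULL
    switch(if (is.null(cls)) "" else cls,
        logical = as.logical(value),
        json = jsonlite::fromJSON(as.character(value)),
        integer = as.integer(value),
        value
    )
}

#' Write an epoch to an HDF5 store
#'
#' Serializes an [Epoch-class] to the package's documented HDF5 layout
#' (64-bit float voltage matrix, electrode names, per-electrode table,
#' metadata, and `start_time` / `sampling_rate` root attributes). The
#' write is atomic: a temporary file is renamed over `path` on success.
#'
#' @param epoch an [Epoch-class].
#' @param path destination file path.
#' @return invisibly `NULL`.
#' @seealso [readEpoch()]
#' @export
writeEpoch <- function(epoch, path) {
    stopifnot(is(epoch, "Epoch"))
    .atomically(path, function(tmp) {
        rhdf5::h5createFile(tmp)
        rhdf5::h5write(epoch@data, tmp, "data")
        rhdf5::h5write(epoch@electrodes, tmp, "electrodes")
        rhdf5::h5createGroup(tmp, "row_data")
        for (cn in colnames(epoch@rowData)) {
            .writeTyped(tmp, "row_data", cn, epoch@rowData[[cn]])
        }
        rhdf5::h5createGroup(tmp, "meta_data")
        for (k in names(epoch@metaData)) {
            .writeTyped(tmp, "meta_data", k, epoch@metaData[[k]])
        }
        fid <- rhdf5::H5Fopen(tmp)
        rhdf5::h5writeAttribute(epoch@startTime, fid, "start_time")
        rhdf5::h5writeAttribute(epoch@samplingRate, fid, "sampling_rate")
        if (ncol(epoch@rowData)) {
            rhdf5::h5writeAttribute(
                colnames(epoch@rowData), fid, "row_data_order"
            )
        }
        rhdf5::H5Fclose(fid)
    })
}

.schemaStop <- function(path, member) {
    stop(
        "'", path, "' is not a valid epoch store: missing ", member,
        call. = FALSE
    )
}

#' Read an epoch from an HDF5 store
#'
#' @param path an HDF5 file written by [writeEpoch()].
#' @return a validated [Epoch-class].
#' @export
readEpoch <- function(path) {
    if (!file.exists(path)) {
        stop("file not found: '", path, "'", call. = FALSE)
    }
    on.exit(.h5CloseAll())
    contents <- tryCatch(
        rhdf5::h5ls(path),
        error = function(e) {
            stop(
                "'", path, "' cannot be read as HDF5: ",
                conditionMessage(e),
                call. = FALSE
            )
        }
    )
    members <- paste0(
        sub("^/$", "", contents$group), "/",
        contents$name
    )
    for (need in c("/data", "/electrodes")) {
        if (!need %in% members) .schemaStop(path, paste0("dataset ", need))
    }
    rootAttrs <- rhdf5::h5readAttributes(path, "/")
    for (need in c("start_time", "sampling_rate")) {
        if (is.null(rootAttrs[[need]])) {
            .schemaStop(path, paste0("root attribute ", need))
        }
    }
    data <- rhdf5::h5read(path, "data")
    elec <- as.character(rhdf5::h5read(path, "electrodes"))
    rdCols <- contents$name[contents$group == "/row_data"]
    if (!is.null(rootAttrs$row_data_order)) {
        ord <- as.character(rootAttrs$row_data_order)
        rdCols <- ord[ord %in% rdCols]
    }
    rowData <- data.frame(row.names = seq_along(elec))
    for (cn in rdCols) {
        rowData[[cn]] <- .readTyped(path, paste0("row_data/", cn))
    }
    mdKeys <- contents$name[contents$group == "/meta_data"]
    metaData <- stats::setNames(
        lapply(mdKeys, function(k) .readTyped(path, paste0("meta_data/", k))),
        mdKeys
    )
    Epoch(
        data, elec,
        startTime = as.numeric(rootAttrs$start_time),
        samplingRate = as.numeric(rootAttrs$sampling_rate),
        rowData = rowData, metaData = metaData
    )
}

#' Write a fragility result
#'
#' `format = "h5"` stores every field of the [FragilityResult-class] in an
#' HDF5 file that [readFragility()] restores; `format = "tsv"` writes the
#' normalized fragility matrix as tab-separated text with electrode rows
#' and window-start-time columns at 6 significant digits.
#'
#' @param frag a [FragilityResult-class].
#' @param path destination file path.
#' @param format `"h5"` (default) or `"tsv"`.
#' @return invisibly `NULL`.
#' @export
writeFragility <- function(frag, path, format = c("h5", "tsv")) {
    stopifnot(is(frag, "FragilityResult"))
    format <- match.arg(format)
    if (format == "tsv") {
        df <- data.frame(
            electrode = frag@electrodes,
            signif(frag@fragility, 6),
            check.names = FALSE
        )
        colnames(df) <- c("electrode", sprintf("%.6g", frag@windowStarts))
        tmp <- paste0(path, ".tmp", Sys.getpid())
        utils::write.table(df, tmp,
            sep = "\t", quote = FALSE, row.names = FALSE
        )
        file.rename(tmp, path)
        return(invisible(NULL))
    }
    .atomically(path, function(tmp) {
        rhdf5::h5createFile(tmp)
        rhdf5::h5write(frag@fragility, tmp, "fragility")
        rhdf5::h5write(frag@rawNorms, tmp, "raw_norms")
        rhdf5::h5write(frag@electrodes, tmp, "electrodes")
        rhdf5::h5write(frag@windowStarts, tmp, "window_starts")
        rhdf5::h5write(frag@lambdas, tmp, "lambdas")
        rhdf5::h5write(as.integer(frag@stableFlags), tmp, "stable_flags")
        rhdf5::h5write(frag@lambdaIterations, tmp, "lambda_iterations")
        rhdf5::h5write(Re(frag@omegaGrid), tmp, "omega_grid_re")
        rhdf5::h5write(Im(frag@omegaGrid), tmp, "omega_grid_im")
        rhdf5::h5createGroup(tmp, "row_data")
        for (cn in colnames(frag@rowData)) {
            .writeTyped(tmp, "row_data", cn, frag@rowData[[cn]])
        }
        fid <- rhdf5::H5Fopen(tmp)
        rhdf5::h5writeAttribute(frag@windowSize, fid, "window_size")
        rhdf5::h5writeAttribute(frag@step, fid, "step")
        rhdf5::h5writeAttribute(frag@samplingRate, fid, "sampling_rate")
        rhdf5::h5writeAttribute(frag@structure, fid, "structure")
        rhdf5::h5writeAttribute(frag@normalization, fid, "normalization")
        if (ncol(frag@rowData)) {
            rhdf5::h5writeAttribute(
                colnames(frag@rowData), fid, "row_data_order"
            )
        }
        rhdf5::H5Fclose(fid)
    })
}

#' Read a fragility result written by [writeFragility()]
#'
#' @param path an HDF5 fragility store.
#' @return a [FragilityResult-class].
#' @export
readFragility <- function(path) {
    if (!file.exists(path)) {
        stop("file not found: '", path, "'", call. = FALSE)
    }
    on.exit(.h5CloseAll())
    contents <- rhdf5::h5ls(path)
    members <- paste0(sub("^/$", "", contents$group), "/", contents$name)
    for (need in c("/fragility", "/raw_norms", "/electrodes", "/window_starts")) {
        if (!need %in% members) {
            stop(
                "'", path, "' is not a valid fragility store: missing dataset ",
                need,
                call. = FALSE
            )
        }
    }
    at <- rhdf5::h5readAttributes(path, "/")
    elec <- as.character(rhdf5::h5read(path, "electrodes"))
    rdCols <- contents$name[contents$group == "/row_data"]
    if (!is.null(at$row_data_order)) {
        ord <- as.character(at$row_data_order)
        rdCols <- ord[ord %in% rdCols]
    }
    rowData <- data.frame(row.names = seq_along(elec))
    for (cn in rdCols) {
        rowData[[cn]] <- .readTyped(path, paste0("row_data/", cn))
    }
    frag <- matrix(rhdf5::h5read(path, "fragility"), nrow = length(elec))
    raw <- matrix(rhdf5::h5read(path, "raw_norms"), nrow = length(elec))
    dimnames(frag) <- dimnames(raw) <- list(elec, NULL)
    new("FragilityResult",
        fragility = frag, rawNorms = raw,
        windowStarts = as.numeric(rhdf5::h5read(path, "window_starts")),
        windowSize = as.integer(at$window_size),
        step = as.integer(at$step),
        samplingRate = as.numeric(at$sampling_rate),
        lambdas = as.numeric(rhdf5::h5read(path, "lambdas")),
        stableFlags = as.logical(rhdf5::h5read(path, "stable_flags")),
        lambdaIterations = as.integer(rhdf5::h5read(path, "lambda_iterations")),
        electrodes = elec, rowData = rowData,
        omegaGrid = complex(
            real = as.numeric(rhdf5::h5read(path, "omega_grid_re")),
            imaginary = as.numeric(rhdf5::h5read(path, "omega_grid_im"))
        ),
        structure = as.character(at$structure),
        normalization = as.character(at$normalization)
    )
}

.readFixedAscii <- function(con, n) {
    trimws(rawToChar(readBin(con, "raw", n)))
}

#' Import an EDF/EDF+ recording as an Epoch
#'
#' Reads a European Data Format file: the fixed-width ASCII header, the
#' per-signal headers, and the 16-bit sample records, applying the
#' physical/digital calibration of each channel. Annotation channels are
#' skipped. All retained channels must share one sampling rate.
#'
#' @param path an EDF file.
#' @param channelInclude optional channel names to keep.
#' @param startTime time of the first sample relative to seizure onset
#'   (default 0; EDF itself carries no onset marker).
#' @return an [Epoch-class].
#' @export
readEDF <- function(path, channelInclude = NULL, startTime = 0) {
    if (!file.exists(path)) {
        stop("file not found: '", path, "'", call. = FALSE)
    }
    con <- file(path, "rb")
    on.exit(close(con))
    version <- .readFixedAscii(con, 8L)
    if (!identical(version, "0")) {
        stop("'", path, "' is not an EDF file (bad version field)", call. = FALSE)
    }
    patient <- .readFixedAscii(con, 80L)
    recording <- .readFixedAscii(con, 80L)
    startDate <- .readFixedAscii(con, 8L)
    startClock <- .readFixedAscii(con, 8L)
    invisible(.readFixedAscii(con, 8L)) # header byte count
    invisible(.readFixedAscii(con, 44L)) # reserved
    nRecords <- as.integer(.readFixedAscii(con, 8L))
    recDuration <- as.numeric(.readFixedAscii(con, 8L))
    ns <- as.integer(.readFixedAscii(con, 4L))
    fld <- function(width) {
        vapply(seq_len(ns), function(i) .readFixedAscii(con, width), character(1))
    }
    labels <- fld(16L)
    invisible(fld(80L)) # transducer
    units <- fld(8L)
    physMin <- as.numeric(fld(8L))
    physMax <- as.numeric(fld(8L))
    digMin <- as.numeric(fld(8L))
    digMax <- as.numeric(fld(8L))
    invisible(fld(80L)) # prefiltering
    nSamp <- as.integer(fld(8L))
    invisible(fld(32L)) # reserved

    keepSignal <- !grepl("^EDF Annotations", labels)
    raw <- lapply(seq_len(ns), function(i) vector("list", nRecords))
    for (r in seq_len(nRecords)) {
        for (i in seq_len(ns)) {
            vals <- readBin(con, "integer",
                n = nSamp[i], size = 2L,
                signed = TRUE, endian = "little"
            )
            if (keepSignal[i]) raw[[i]][[r]] <- vals
        }
    }
    keep <- which(keepSignal)
    if (!is.null(channelInclude)) {
        sel <- match(channelInclude, labels[keep])
        if (anyNA(sel)) {
            stop(
                "channel(s) not present in '", path, "': ",
                paste(channelInclude[is.na(sel)], collapse = ", "),
                call. = FALSE
            )
        }
        keep <- keep[sel]
    }
    if (!length(keep)) stop("no channels to import", call. = FALSE)
    rates <- nSamp[keep] / recDuration
    if (length(unique(rates)) > 1L) {
        stop(
            "channels have mixed sampling rates (",
            paste(unique(rates), collapse = ", "),
            " Hz); import subsets of uniform rate and resample() them",
            call. = FALSE
        )
    }
    data <- do.call(rbind, lapply(keep, function(i) {
        dig <- unlist(raw[[i]])
        physMin[i] + (dig - digMin[i]) *
            (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
    }))
    Epoch(
        data, labels[keep],
        startTime = startTime, samplingRate = rates[1L],
        metaData = list(
            edf_patient = patient, edf_recording = recording,
            edf_start = paste(startDate, startClock),
            edf_units = as.list(stats::setNames(units[keep], labels[keep]))
        )
    )
}
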