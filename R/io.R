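## Delimited-text and JSON interchange.
##
## Kinematics CSV: time_s, pos_x, pos_y, vel_x, vel_y (header mandatory).
## Recording CSV: time_s, then one column per channel.
## Event CSV: onset_s, target_label (+ any extra columns preserved).
## Models are persisted as JSON with a provenance block.

#' Read / write kinematics tables
#'
#' @param x a [TrajectorySeries-class].
#' @param path file path.
#' @return `readKinematicsCSV` returns a [TrajectorySeries-class];
#'   the writer returns `path` invisibly.
#' @name kinematics-io
NULL

#' @rdname kinematics-io
#' @export
writeKinematicsCSV <- function(x, path) {
    stopifnot(is(x, "TrajectorySeries"))
    utils::write.csv(data.frame(time_s = x@times,
                                pos_x = x@position[, 1L],
                                pos_y = x@position[, 2L],
                                vel_x = x@velocity[, 1L],
                                vel_y = x@velocity[, 2L]),
                     path, row.names = FALSE)
    invisible(path)
}

#' @rdname kinematics-io
#' @export
readKinematicsCSV <- function(path) {
    df <- utils::read.csv(path)
    need <- c("time_s", "pos_x", "pos_y", "vel_x", "vel_y")
    if (!all(need %in% names(df)))
        stop("kinematics CSV must have columns: ", paste(need, collapse = ", "))
    TrajectorySeries(times = df$time_s,
                     position = cbind(df$pos_x, df$pos_y),
                     velocity = cbind(df$vel_x, df$vel_y))
}

#' Read / write neural recordings as CSV
#'
#' @param x a [NeuralRecording-class].
#' @param path file path.
#' @return `readRecordingCSV` returns a [NeuralRecording-class].
#' @name recording-io
NULL

#' @rdname recording-io
#' @export
writeRecordingCSV <- function(x, path) {
    stopifnot(is(x, "NeuralRecording"))
    df <- data.frame(time_s = (seq_len(ncol(x@data)) - 1L) / x@sampleRate,
                     t(x@data))
    names(df) <- c("time_s", x@channelLabels)
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' @rdname recording-io
#' @export
readRecordingCSV <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE)
    if (names(df)[1L] != "time_s")
        stop("recording CSV must start with a 'time_s' column")
    fs <- 1 / stats::median(diff(df$time_s))
    NeuralRecording(t(as.matrix(df[, -1L, drop = FALSE])), fs,
                    names(df)[-1L])
}

#' Read / write trial event tables
#'
#' @param events data.frame with at least `onset_s` and `target_label`.
#' @param path file path.
#' @return `readEventsCSV` returns the event data.frame.
#' @name events-io
NULL

#' @rdname events-io
#' @export
writeEventsCSV <- function(events, path) {
    if (!all(c("onset_s", "target_label") %in% names(events)))
        stop("events need 'onset_s' and 'target_label' columns")
    utils::write.csv(events, path, row.names = FALSE)
    invisible(path)
}

#' @rdname events-io
#' @export
readEventsCSV <- function(path) {
    df <- utils::read.csv(path)
    if (!all(c("onset_s", "target_label") %in% names(df)))
        stop("events CSV needs 'onset_s' and 'target_label' columns")
    df
}

.provenance <- function() {
    list(package = "reachDecode",
         version = as.character(utils::packageVersion("reachDecode")),
         written = format(Sys.time(), tz = "UTC", usetz = TRUE))
}

#' Persist decoder models as JSON
#'
#' Serializes a [LinearFilterModel-class], [KalmanModel-class] or
#' [HybridModel-class] (with its network) to JSON and back.  Matrices are
#' stored row-major with explicit dimensions, alongside a provenance block.
#'
#' @param model the model object.
#' @param path file path.
#' @return `readModelJSON` returns the reconstructed model.
#' @name model-io
NULL

.mat2json <- function(m) list(dim = dim(m), data = as.numeric(t(m)))
.json2mat <- function(j) matrix(j$data, j$dim[1L], j$dim[2L], byrow = TRUE)

#' @rdname model-io
#' @export
writeModelJSON <- function(model, path) {
    obj <- if (is(model, "LinearFilterModel")) {
        list(type = "LinearFilterModel",
             weights = .mat2json(model@weights),
             lagCount = model@lagCount, channelCount = model@channelCount,
             channelLabels = model@channelLabels)
    } else if (is(model, "KalmanModel")) {
        list(type = "KalmanModel",
             A = .mat2json(model@A), W = .mat2json(model@W),
             H = .mat2json(model@H), Q = .mat2json(model@Q),
             initialState = model@initialState,
             initialCovariance = .mat2json(model@initialCovariance))
    } else if (is(model, "HybridModel")) {
        list(type = "HybridModel",
             kalman = list(A = .mat2json(model@kalman@A),
                           W = .mat2json(model@kalman@W),
                           H = .mat2json(model@kalman@H),
                           Q = .mat2json(model@kalman@Q),
                           initialState = model@kalman@initialState,
                           initialCovariance =
                               .mat2json(model@kalman@initialCovariance)),
             mlp = list(W1 = .mat2json(model@mlp@W1), b1 = model@mlp@b1,
                        w2 = model@mlp@w2, b2 = model@mlp@b2,
                        speedScale = model@mlp@speedScale,
                        seed = model@mlp@seed),
             speedFloor = model@speedFloor, ablation = model@ablation)
    } else stop("unsupported model class: ", class(model))
    obj$provenance <- .provenance()
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname model-io
#' @export
readModelJSON <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    kal <- function(b)
        KalmanModel(.json2mat(b$A), .json2mat(b$W), .json2mat(b$H),
                    .json2mat(b$Q), initialState = b$initialState,
                    initialCovariance = .json2mat(b$initialCovariance))
    switch(j$type,
        LinearFilterModel = new("LinearFilterModel",
            weights = .json2mat(j$weights),
            lagCount = as.integer(j$lagCount),
            channelCount = as.integer(j$channelCount),
            channelLabels = j$channelLabels),
        KalmanModel = kal(j),
        HybridModel = new("HybridModel", kalman = kal(j$kalman),
            mlp = new("MLPSpeedFilter", W1 = .json2mat(j$mlp$W1),
                      b1 = j$mlp$b1, w2 = j$mlp$w2, b2 = j$mlp$b2,
                      speedScale = j$mlp$speedScale,
                      seed = as.integer(j$mlp$seed), lossTrace = numeric(0)),
            speedFloor = j$speedFloor, ablation = j$ablation),
        stop("unknown model type: ", j$type))
}

#' Write a small deterministic fixture dataset
#'
#' Generates a reduced session (5 trials per target by default, fewer
#' channels) and writes its kinematics, events and recording CSVs --
#' useful as a quick, fully reproducible demo dataset.
#'
#' @param dir output directory (created if needed).
#' @param trialsPerTarget trials per target (default 5).
#' @param nChannels channels (default 12).
#' @param seed generator seed (default 1).
#' @return Invisibly, the named vector of written paths.
#' @export
writeFixtureDataset <- function(dir, trialsPerTarget = 5L, nChannels = 12L,
                                seed = 1L) {
    cfg <- syntheticConfig(trialsPerTarget = trialsPerTarget,
                           nChannels = nChannels, seed = seed)
    ses <- genSession(cfg)
    rec <- encodeNeural(ses)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(kinematics = file.path(dir, "kinematics.csv"),
               events = file.path(dir, "events.csv"),
               recording = file.path(dir, "recording.csv"))
    writeKinematicsCSV(ses@kinematics, paths["kinematics"])
    ev <- ses@events
    writeEventsCSV(ev, paths["events"])
    writeRecordingCSV(rec, paths["recording"])
    invisible(paths)
}
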