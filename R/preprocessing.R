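#' Construct a NeuralRecording
#'
#' @param data channels x samples numeric matrix.
#' @param sampleRate sampling rate in Hz.
#' @param channelLabels unique channel labels; defaults to "ch1", "ch2", ...
#' @return A [NeuralRecording-class].
#' @export
NeuralRecording <- function(data, sampleRate, channelLabels = NULL) {
    data <- as.matrix(data)
    storage.mode(data) <- "double"
    if (is.null(channelLabels))
        channelLabels <- paste0("ch", seq_len(nrow(data)))
    new("NeuralRecording", data = data, sampleRate = sampleRate,
        channelLabels = as.character(channelLabels))
}

## Zero-phase 4th-order Butterworth band-pass of the rows of a matrix.
.bandpassMatrix <- function(x, sampleRate, lowHz, highHz, order = 4L) {
    if (!(lowHz > 0 && lowHz < highHz && highHz < sampleRate / 2))
        stop("need 0 < lowHz < highHz < sampleRate/2")
    bf <- signal::butter(order, c(lowHz, highHz) / (sampleRate / 2),
                         type = "pass")
    t(apply(x, 1L, function(row) signal::filtfilt(bf, row)))
}

#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (\code{signal::filtfilt}), giving zero phase distortion -- appropriate
#' for offline decoding where filtering precedes model fitting.  Passband
#' gain at mid-band is within a few percent of unity; out-of-band tones and
#' DC are strongly attenuated.
#'
#' @param x a [NeuralRecording-class], or a channels x samples matrix, or a
#'   numeric vector (a single channel).
#' @param lowHz,highHz band edges in Hz, 0 < lowHz < highHz < Nyquist.
#' @param sampleRate sampling rate in Hz (ignored for recordings, which
#'   carry their own).
#' @param order filter order (default 4).
#' @return An object of the same kind as `x`, filtered along time.
#' @examples
#' fs <- 600
#' tone <- sin(2 * pi * 4 * seq(0, 2, by = 1 / fs))
#' filt <- bandpassFilter(tone, 0.5, 8, sampleRate = fs)
#' @export
setGeneric("bandpassFilter",
    function(x, lowHz, highHz, sampleRate = NULL, order = 4L)
        standardGeneric("bandpassFilter"))

#' @rdname bandpassFilter
#' @export
setMethod("bandpassFilter", "NeuralRecording",
    function(x, lowHz, highHz, sampleRate = NULL, order = 4L) {
        filtered <- .bandpassMatrix(x@data, x@sampleRate, lowHz, highHz,
                                    order)
        new("NeuralRecording", data = filtered, sampleRate = x@sampleRate,
            channelLabels = x@channelLabels)
    })

#' @rdname bandpassFilter
#' @export
setMethod("bandpassFilter", "matrix",
    function(x, lowHz, highHz, sampleRate = NULL, order = 4L) {
        if (is.null(sampleRate)) stop("'sampleRate' is required for matrices")
        .bandpassMatrix(x, sampleRate, lowHz, highHz, order)
    })

#' @rdname bandpassFilter
#' @export
setMethod("bandpassFilter", "numeric",
    function(x, lowHz, highHz, sampleRate = NULL, order = 4L) {
        if (is.null(sampleRate)) stop("'sampleRate' is required for vectors")
        drop(.bandpassMatrix(matrix(x, 1L), sampleRate, lowHz, highHz,
                             order))
    })

#' Downsample a recording
#'
#' Reduces the sampling rate, assuming the signal has already been low-pass
#' filtered below the new Nyquist frequency (as the 0.5--8 Hz band-pass
#' guarantees for a 50 Hz target).  For an integer ratio the samples are
#' sliced directly; otherwise a polyphase resampler
#' (\code{signal::resample}) is used with a rational approximation of the
#' rate ratio.
#'
#' @param recording a [NeuralRecording-class].
#' @param targetRate new sampling rate in Hz; must be below the current one.
#' @return A [NeuralRecording-class] at `targetRate`; the output length is
#'   \code{floor(n * targetRate / sampleRate)} samples (integer ratios keep
#'   the initial sample, so exactly every ratio-th sample is retained).
#' @export
downsampleRecording <- function(recording, targetRate) {
    stopifnot(is(recording, "NeuralRecording"))
    fs <- recording@sampleRate
    if (targetRate >= fs)
        stop("'targetRate' must be below the current sample rate")
    ratio <- fs / targetRate
    n <- ncol(recording@data)
    if (abs(ratio - round(ratio)) < 1e-9) {
        idx <- seq(1L, n, by = round(ratio))
        out <- recording@data[, idx, drop = FALSE]
    } else {
        frac <- .ratApprox(targetRate / fs)
        out <- t(apply(recording@data, 1L, function(row)
            signal::resample(row, frac[1L], frac[2L])))
        keep <- min(ncol(out), floor(n * targetRate / fs))
        out <- out[, seq_len(keep), drop = FALSE]
    }
    new("NeuralRecording", data = out, sampleRate = targetRate,
        channelLabels = recording@channelLabels)
}

## Best rational approximation p/q of x with q <= maxDen (continued
## fractions).
.ratApprox <- function(x, maxDen = 1000L) {
    p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L
    r <- x
    repeat {
        a <- floor(r)
        p2 <- a * p1 + p0; q2 <- a * q1 + q0
        if (q2 > maxDen) break
        p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
        if (abs(p1 / q1 - x) < 1e-12) break
        r <- 1 / (r - a)
    }
    c(as.integer(p1), as.integer(q1))
}

#' Cut a recording into epochs around event onsets
#'
#' Extracts fixed windows \code{[onset + tMin, onset + tMax]} around each
#' onset.  The recording's first sample is taken to be at time 0.  Onsets
#' whose window does not fit inside the recording are dropped with a
#' warning; the count of dropped trials is kept in the result.
#'
#' @param recording a [NeuralRecording-class].
#' @param onsets event (target onset) times in seconds.
#' @param tMin,tMax window edges in seconds relative to onset,
#'   tMin < 0 < tMax (defaults -1 and 2).
#' @param labels optional target identity per onset.
#' @param stateMask optional logical per recording sample (TRUE = reach),
#'   sliced into per-trial masks alongside the data.
#' @return An [EpochSet-class] with
#'   \code{round((tMax - tMin) * sampleRate) + 1} samples per epoch.
#' @export
epochRecording <- function(recording, onsets, tMin = -1, tMax = 2,
                           labels = NULL, stateMask = NULL) {
    stopifnot(is(recording, "NeuralRecording"))
    if (!(tMin < 0 && tMax > 0)) stop("need tMin < 0 < tMax")
    fs <- recording@sampleRate
    n <- ncol(recording@data)
    nSamp <- as.integer(round((tMax - tMin) * fs)) + 1L
    offsets <- as.integer(round(tMin * fs)) + 0:(nSamp - 1L)
    onsetIdx <- as.integer(round(onsets * fs)) + 1L
    keep <- onsetIdx + offsets[1L] >= 1L & onsetIdx + offsets[nSamp] <= n
    if (any(!keep))
        warning(sprintf("dropped %d trial(s) whose window falls outside the recording",
                        sum(!keep)))
    kept <- which(keep)
    nCh <- nrow(recording@data)
    arr <- array(0, dim = c(length(kept), nCh, nSamp))
    maskMat <- matrix(logical(0), 0L, 0L)
    if (!is.null(stateMask))
        maskMat <- matrix(NA, length(kept), nSamp)
    for (k in seq_along(kept)) {
        idx <- onsetIdx[kept[k]] + offsets
        arr[k, , ] <- recording@data[, idx]
        if (!is.null(stateMask)) maskMat[k, ] <- stateMask[idx]
    }
    new("EpochSet", epochs = arr, window = c(tMin, tMax),
        trialLabels = if (is.null(labels)) character(0)
                      else as.character(labels[kept]),
        onsets = as.numeric(onsets[kept]), sampleRate = fs,
        dropped = sum(!keep), stateMask = maskMat)
}

#' Build the lagged design matrix for the linear filter
#'
#' Row \code{t} contains, for every channel \code{i} and lag
#' \code{j = 0..m}, the sample \code{z_i(t - j)} (channel-major column
#' order), followed by an intercept column of ones.  Rows with incomplete
#' history (the first \code{m}) are flagged invalid and zero-filled; they
#' are excluded from fitting rather than zero-padded into it, avoiding edge
#' bias.
#'
#' @param recording a [NeuralRecording-class] (already at the decoding
#'   rate), or a channels x samples matrix.
#' @param lags history length m >= 0; m = 10 at 50 Hz spans 200 ms (the
#'   current sample plus 10 preceding ones).
#' @param sampleRate required when `recording` is a bare matrix.
#' @return A [LaggedDesign-class] with n*(m+1)+1 columns.
#' @export
buildLaggedDesign <- function(recording, lags = 10L, sampleRate = NULL) {
    if (is(recording, "NeuralRecording")) {
        z <- recording@data
        fs <- recording@sampleRate
        labels <- recording@channelLabels
    } else {
        z <- as.matrix(recording)
        fs <- if (is.null(sampleRate)) NA_real_ else sampleRate
        labels <- paste0("ch", seq_len(nrow(z)))
    }
    m <- as.integer(lags)
    if (m < 0L) stop("'lags' must be >= 0")
    nCh <- nrow(z); n <- ncol(z)
    if (n <= m) stop("need more samples than lags")
    X <- matrix(0, n, nCh * (m + 1L) + 1L)
    cn <- character(ncol(X))
    for (i in seq_len(nCh)) {
        for (j in 0:m) {
            col <- (i - 1L) * (m + 1L) + j + 1L
            X[(j + 1L):n, col] <- z[i, 1:(n - j)]
            cn[col] <- sprintf("%s_lag%d", labels[i], j)
        }
    }
    X[, ncol(X)] <- 1
    cn[length(cn)] <- "bias"
    colnames(X) <- cn
    valid <- seq_len(n) > m
    X[!valid, -ncol(X)] <- 0
    new("LaggedDesign", design = X, lagCount = m, channelCount = nCh,
        channelLabels = labels, valid = valid, sampleRate = fs)
}

#' Label reach and rest states from a speed series
#'
#' Splits a session into movement (reach) and stationary (rest) states by
#' thresholding speed: samples below \code{thresholdFrac} of the session
#' peak speed that form a contiguous run of at least \code{minDurationS}
#' are labelled rest; everything else is reach.  The minimum-duration rule
#' acts as hysteresis so brief dips inside a movement do not fragment it.
#' An all-zero speed series is labelled all rest.
#'
#' @param speed nonnegative speed series (units/s).
#' @param sampleRate sampling rate in Hz.
#' @param thresholdFrac rest threshold as a fraction of the session peak
#'   speed (default 0.05).
#' @param minDurationS minimum rest duration in seconds (default 0.1).
#' @return Logical vector, TRUE = reach.
#' @export
labelStates <- function(speed, sampleRate, thresholdFrac = 0.05,
                        minDurationS = 0.1) {
    if (any(speed < 0)) stop("'speed' must be nonnegative")
    n <- length(speed)
    peak <- max(speed)
    if (peak == 0) return(rep(FALSE, n))
    below <- speed < thresholdFrac * peak
    minRun <- max(1L, as.integer(round(minDurationS * sampleRate)))
    reach <- rep(TRUE, n)
    runs <- .trueRuns(below)
    for (k in seq_len(nrow(runs))) {
        if (runs[k, "end"] - runs[k, "start"] + 1L >= minRun)
            reach[runs[k, "start"]:runs[k, "end"]] <- FALSE
    }
    reach
}

#' Label reach and rest states from the event table
#'
#' Timing-based alternative to [labelStates()]: samples inside any
#' \code{[moveStart, moveEnd]} interval are reach, everything else rest.
#'
#' @param n number of session samples.
#' @param sampleRate sampling rate in Hz.
#' @param moveStart,moveEnd per-trial movement start/end times in seconds.
#' @return Logical vector, TRUE = reach.
#' @export
labelStatesFromEvents <- function(n, sampleRate, moveStart, moveEnd) {
    reach <- rep(FALSE, n)
    for (k in seq_along(moveStart)) {
        i0 <- max(1L, as.integer(round(moveStart[k] * sampleRate)) + 1L)
        i1 <- min(n, as.integer(round(moveEnd[k] * sampleRate)) + 1L)
        if (i0 <= i1) reach[i0:i1] <- TRUE
    }
    reach
}

#' Subset a recording by channel labels
#'
#' @param recording a [NeuralRecording-class].
#' @param labels channel labels to keep, in the requested order.
#' @return A [NeuralRecording-class] with the selected channels.
#' @export
selectChannels <- function(recording, labels) {
    stopifnot(is(recording, "NeuralRecording"))
    idx <- match(labels, recording@channelLabels)
    if (any(is.na(idx)))
        stop("unknown channel label(s): ",
             paste(labels[is.na(idx)], collapse = ", "))
    new("NeuralRecording", data = recording@data[idx, , drop = FALSE],
        sampleRate = recording@sampleRate,
        channelLabels = recording@channelLabels[idx])
}
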