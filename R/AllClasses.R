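#' @import methods
NULL

.checkFiniteMatrix <- function(x, what) {
    if (!is.matrix(x) || !is.numeric(x))
        return(sprintf("'%s' must be a numeric matrix", what))
    if (any(!is.finite(x)))
        return(sprintf("'%s' contains non-finite values", what))
    NULL
}

#' Uniformly sampled 2-D hand kinematics
#'
#' \code{TrajectorySeries} stores synchronized 2-D hand position and velocity
#' on a uniform time grid, the common currency of all decoders in this
#' package.  Positions are in arbitrary length units in the x--y plane and
#' velocities in units/s.
#'
#' @slot times numeric vector of sample times in seconds, strictly increasing
#'   with constant step \code{1/sampleRate}.
#' @slot position samples x 2 numeric matrix of x/y coordinates.
#' @slot velocity samples x 2 numeric matrix of x/y velocities.
#' @slot sampleRate sampling rate in Hz.
#'
#' @seealso [minimumJerkReach()], [decomposeVelocity()], [integrateAcceleration()]
#' @export
setClass("TrajectorySeries",
    representation(times = "numeric", position = "matrix",
                   velocity = "matrix", sampleRate = "numeric"))

setValidity("TrajectorySeries", function(object) {
    msgs <- c()
    n <- length(object@times)
    if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
        object@sampleRate <= 0)
        msgs <- c(msgs, "'sampleRate' must be a single positive number")
    if (any(!is.finite(object@times)))
        msgs <- c(msgs, "'times' contains non-finite values")
    if (n > 1L) {
        dt <- diff(object@times)
        if (any(dt <= 0))
            msgs <- c(msgs, "'times' must be strictly increasing")
        if (length(object@sampleRate) == 1L &&
            max(abs(dt - 1 / object@sampleRate)) > 1e-6 / object@sampleRate)
            msgs <- c(msgs, "'times' step must equal 1/sampleRate")
    }
    for (sl in c("position", "velocity")) {
        m <- slot(object, sl)
        bad <- .checkFiniteMatrix(m, sl)
        if (!is.null(bad)) msgs <- c(msgs, bad)
        else {
            if (nrow(m) != n)
                msgs <- c(msgs, sprintf("'%s' must have one row per time", sl))
            if (ncol(m) != 2L)
                msgs <- c(msgs, sprintf("'%s' must have 2 columns", sl))
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' Speed/direction decomposition of a velocity series
#'
#' Holds the polar decomposition of a 2-D velocity series: a nonnegative
#' scalar speed per sample and a 2-D unit direction vector per sample.
#' At samples where the speed is at or below the decomposition floor the
#' direction is carried forward from the last well-defined sample (see
#' [decomposeVelocity()]).
#'
#' @slot speed nonnegative numeric vector (units/s).
#' @slot direction samples x 2 matrix of unit vectors.
#' @slot speedFloor the floor used during decomposition (units/s).
#' @export
setClass("SpeedDirectionSeries",
    representation(speed = "numeric", direction = "matrix",
                   speedFloor = "numeric"))

setValidity("SpeedDirectionSeries", function(object) {
    msgs <- c()
    if (any(!is.finite(object@speed)) || any(object@speed < 0))
        msgs <- c(msgs, "'speed' must be finite and nonnegative")
    bad <- .checkFiniteMatrix(object@direction, "direction")
    if (!is.null(bad)) msgs <- c(msgs, bad)
    else {
        if (nrow(object@direction) != length(object@speed))
            msgs <- c(msgs, "'direction' must have one row per speed sample")
        if (length(object@speed)) {
            nrm <- sqrt(rowSums(object@direction^2))
            if (max(abs(nrm - 1)) > 1e-9)
                msgs <- c(msgs, "'direction' rows must have unit norm (1e-9)")
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' Task-axis coordinates of a point series
#'
#' Coordinates of a 2-D point series relative to the task axis, the straight
#' line from a movement's start point to the target centre.  \code{along} is
#' the signed distance travelled along that axis and \code{perp} the signed
#' perpendicular deviation from it (positive to the left of the axis, i.e.
#' along the +90 degree rotation of the axis unit vector).
#'
#' @slot start,target 2-D points defining the axis.
#' @slot along,perp signed coordinates per sample.
#' @seealso [projectToTaskAxis()], [pointingMetrics()]
#' @export
setClass("TaskAxisFrame",
    representation(start = "numeric", target = "numeric",
                   along = "numeric", perp = "numeric"))

setValidity("TaskAxisFrame", function(object) {
    msgs <- c()
    if (length(object@start) != 2L || length(object@target) != 2L)
        msgs <- c(msgs, "'start' and 'target' must be 2-D points")
    if (sqrt(sum((object@target - object@start)^2)) <= 0)
        msgs <- c(msgs, "'start' and 'target' must be distinct")
    if (length(object@along) != length(object@perp))
        msgs <- c(msgs, "'along' and 'perp' must have equal length")
    if (length(msgs)) msgs else TRUE
})

#' Multichannel neural recording
#'
#' A channels x samples real matrix with a sampling rate and unique channel
#' labels, e.g. band-limited MEG gradiometer signals.
#'
#' @slot data channels x samples numeric matrix.
#' @slot sampleRate sampling rate in Hz.
#' @slot channelLabels character vector, one unique label per channel.
#' @export
setClass("NeuralRecording",
    representation(data = "matrix", sampleRate = "numeric",
                   channelLabels = "character"))

setValidity("NeuralRecording", function(object) {
    msgs <- c()
    bad <- .checkFiniteMatrix(object@data, "data")
    if (!is.null(bad)) msgs <- c(msgs, bad)
    if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
        object@sampleRate <= 0)
        msgs <- c(msgs, "'sampleRate' must be a single positive number")
    if (length(object@channelLabels) != nrow(object@data))
        msgs <- c(msgs, "need one channel label per row of 'data'")
    if (anyDuplicated(object@channelLabels))
        msgs <- c(msgs, "'channelLabels' must be unique")
    if (length(msgs)) msgs else TRUE
})

#' Epoched neural data around trial onsets
#'
#' Fixed-length windows of a [NeuralRecording-class] cut around target-onset
#' events, stored as a trials x channels x samples array.
#'
#' @slot epochs trials x channels x samples numeric array.
#' @slot window numeric length-2, window (t_min, t_max) in seconds relative
#'   to onset, with t_min < 0 < t_max.
#' @slot trialLabels character target identity per retained trial.
#' @slot onsets onset times (s) of retained trials.
#' @slot sampleRate sampling rate in Hz.
#' @slot dropped number of requested onsets that fell outside the recording.
#' @slot stateMask trials x samples logical matrix (TRUE = reach) or a
#'   0 x 0 matrix when no mask was supplied.
#' @export
setClass("EpochSet",
    representation(epochs = "array", window = "numeric",
                   trialLabels = "character", onsets = "numeric",
                   sampleRate = "numeric", dropped = "integer",
                   stateMask = "matrix"))

setValidity("EpochSet", function(object) {
    msgs <- c()
    d <- dim(object@epochs)
    if (length(d) != 3L)
        msgs <- c(msgs, "'epochs' must be a trials x channels x samples array")
    if (length(object@window) != 2L ||
        !(object@window[1] < 0 && object@window[2] > 0))
        msgs <- c(msgs, "'window' must satisfy t_min < 0 < t_max")
    if (length(d) == 3L) {
        if (length(object@trialLabels) &&
            length(object@trialLabels) != d[1])
            msgs <- c(msgs, "one trial label per retained trial required")
        if (length(object@onsets) != d[1])
            msgs <- c(msgs, "one onset per retained trial required")
        if (nrow(object@stateMask) &&
            !identical(dim(object@stateMask), d[c(1L, 3L)]))
            msgs <- c(msgs, "'stateMask' must be trials x samples")
    }
    if (length(msgs)) msgs else TRUE
})

#' Lagged design matrix for the linear filter
#'
#' Row \code{t} stacks, channel by channel, the current and \code{lagCount}
#' preceding samples of every channel, followed by a trailing intercept
#' column of ones.  The first \code{lagCount} rows have incomplete history
#' and are flagged invalid; they are excluded from fitting and withheld from
#' prediction.
#'
#' @slot design samples x (channels * (lagCount + 1) + 1) numeric matrix.
#' @slot lagCount number of preceding samples per channel (m).
#' @slot channelCount number of channels (n).
#' @slot channelLabels channel labels in design order.
#' @slot valid logical per row; FALSE for incomplete-history rows.
#' @slot sampleRate sampling rate in Hz.
#' @export
setClass("LaggedDesign",
    representation(design = "matrix", lagCount = "integer",
                   channelCount = "integer", channelLabels = "character",
                   valid = "logical", sampleRate = "numeric"))

setValidity("LaggedDesign", function(object) {
    msgs <- c()
    expCols <- object@channelCount * (object@lagCount + 1L) + 1L
    if (ncol(object@design) != expCols)
        msgs <- c(msgs, sprintf("design must have n*(m+1)+1 = %d columns",
                                expCols))
    if (length(object@valid) != nrow(object@design))
        msgs <- c(msgs, "'valid' must flag every design row")
    if (object@lagCount < 0L)
        msgs <- c(msgs, "'lagCount' must be >= 0")
    if (length(msgs)) msgs else TRUE
})

#' Lagged linear regression decoder
#'
#' Weights of the linear filter mapping the lagged multichannel history
#' (plus intercept) onto each velocity coordinate, fitted by ordinary least
#' squares.
#'
#' @slot weights (channels * (lagCount + 1) + 1) x 2 matrix; columns are the
#'   x- and y-velocity weight vectors, last row the intercepts.
#' @slot lagCount,channelCount history length m and channel count n.
#' @slot channelLabels channel labels the model was fitted on.
#' @export
setClass("LinearFilterModel",
    representation(weights = "matrix", lagCount = "integer",
                   channelCount = "integer", channelLabels = "character"))

setValidity("LinearFilterModel", function(object) {
    msgs <- c()
    if (any(!is.finite(object@weights)))
        msgs <- c(msgs, "'weights' must be finite")
    if (nrow(object@weights) !=
        object@channelCount * (object@lagCount + 1L) + 1L)
        msgs <- c(msgs, "'weights' rows inconsistent with (n, m)")
    if (ncol(object@weights) != 2L)
        msgs <- c(msgs, "'weights' must have 2 columns (x, y)")
    if (length(msgs)) msgs else TRUE
})

#' Linear-Gaussian state-space decoder
#'
#' Parameters of a time-invariant linear-Gaussian state-space model
#' \eqn{x(t) = A x(t-1) + \nu(t)}, \eqn{z(t) = H x(t) + \epsilon(t)} with
#' \eqn{\nu \sim N(0, W)} and \eqn{\epsilon \sim N(0, Q)}, plus the initial
#' state and covariance used when the decoding recursion (re)starts.
#'
#' @slot A state-transition matrix (d x d).
#' @slot W system noise covariance (d x d, symmetric PSD).
#' @slot H observation matrix (channels x d).
#' @slot Q observation noise covariance (channels x channels, symmetric PSD).
#' @slot stateDim state dimension d.
#' @slot initialState length-d numeric.
#' @slot initialCovariance d x d symmetric PSD matrix.
#' @seealso [fitKalman()], [kalmanDecode()]
#' @export
setClass("KalmanModel",
    representation(A = "matrix", W = "matrix", H = "matrix", Q = "matrix",
                   stateDim = "integer", initialState = "numeric",
                   initialCovariance = "matrix"))

.isSymPSD <- function(m, tol = 1e-8) {
    if (max(abs(m - t(m))) > tol * (1 + max(abs(m)))) return(FALSE)
    ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
    min(ev) > -tol * (1 + max(abs(ev)))
}

setValidity("KalmanModel", function(object) {
    msgs <- c()
    d <- object@stateDim
    if (!identical(dim(object@A), c(d, d)))
        msgs <- c(msgs, "'A' must be stateDim x stateDim")
    if (!identical(dim(object@W), c(d, d)) || !.isSymPSD(object@W))
        msgs <- c(msgs, "'W' must be stateDim x stateDim symmetric PSD")
    if (ncol(object@H) != d)
        msgs <- c(msgs, "'H' must have stateDim columns")
    if (!identical(dim(object@Q), c(nrow(object@H), nrow(object@H))) ||
        !.isSymPSD(object@Q))
        msgs <- c(msgs, "'Q' must be channels x channels symmetric PSD")
    if (length(object@initialState) != d)
        msgs <- c(msgs, "'initialState' must have length stateDim")
    if (!identical(dim(object@initialCovariance), c(d, d)) ||
        !.isSymPSD(object@initialCovariance))
        msgs <- c(msgs, "'initialCovariance' must be symmetric PSD")
    if (length(msgs)) msgs else TRUE
})

#' Decoded state sequence
#'
#' Posterior state means (and optionally covariances) produced by the
#' predict/update recursion of [kalmanDecode()].
#'
#' @slot states samples x stateDim matrix of posterior means.
#' @slot covariances list of per-sample posterior covariances, or an empty
#'   list when covariance retention was off.
#' @slot events number of numerical-conditioning events (jitter applied to a
#'   non-positive-definite innovation covariance) during decoding.
#' @export
setClass("StateSequence",
    representation(states = "matrix", covariances = "list",
                   events = "integer"))

setValidity("StateSequence", function(object) {
    msgs <- c()
    if (any(!is.finite(object@states)))
        msgs <- c(msgs, "'states' must be finite")
    if (length(object@covariances) &&
        length(object@covariances) != nrow(object@states))
        msgs <- c(msgs, "one covariance per decoded sample required")
    if (length(msgs)) msgs else TRUE
})

#' Nonlinear speed read-out network
#'
#' A small multilayer perceptron that maps the three speed state variables
#' (current and two lagged speeds) to the current hand speed: 18 hidden
#' units with tanh activations and one logistic-sigmoid output unit.
#' Inputs and targets are scaled by \code{speedScale} (the maximum training
#' speed) so the sigmoid output, multiplied back by \code{speedScale},
#' always lies strictly inside (0, speedScale).
#'
#' @slot W1 hidden x 3 input weight matrix.
#' @slot b1 hidden bias vector.
#' @slot w2 hidden-to-output weight vector.
#' @slot b2 output bias (length 1).
#' @slot speedScale normalizer in units/s.
#' @slot seed integer seed used for weight initialization.
#' @slot lossTrace mean-squared-error trace over accepted training steps
#'   (scaled units).
#' @seealso [trainSpeedMLP()], [mlpForward()]
#' @export
setClass("MLPSpeedFilter",
    representation(W1 = "matrix", b1 = "numeric", w2 = "numeric",
                   b2 = "numeric", speedScale = "numeric", seed = "integer",
                   lossTrace = "numeric"))

setValidity("MLPSpeedFilter", function(object) {
    msgs <- c()
    h <- nrow(object@W1)
    if (ncol(object@W1) != 3L)
        msgs <- c(msgs, "'W1' must have 3 input columns (speed states only)")
    if (length(object@b1) != h || length(object@w2) != h)
        msgs <- c(msgs, "'b1' and 'w2' must match the hidden layer size")
    if (length(object@b2) != 1L)
        msgs <- c(msgs, "'b2' must be a single output bias")
    if (length(object@speedScale) != 1L || object@speedScale <= 0)
        msgs <- c(msgs, "'speedScale' must be a single positive number")
    if (length(msgs)) msgs else TRUE
})

#' Hybrid speed--direction Kalman decoder
#'
#' The hybrid decoder couples a 5-dimensional Kalman filter over the state
#' \eqn{[r(t), r(t-1), r(t-2), d_x(t), d_y(t)]} with two independent
#' read-outs: hand speed from the three speed states through an
#' [MLPSpeedFilter-class], and direction from the unit-normalized
#' \eqn{(d_x, d_y)} posterior.  Velocity is their product.  With
#' \code{ablation = TRUE} the speed read-out bypasses the network and uses
#' the posterior \eqn{r(t)} directly.
#'
#' @slot kalman [KalmanModel-class] with stateDim 5.
#' @slot mlp [MLPSpeedFilter-class].
#' @slot speedFloor direction-normalization floor (units/s).
#' @slot ablation logical; default speed read-out mode for [hybridDecode()].
#' @export
setClass("HybridModel",
    representation(kalman = "KalmanModel", mlp = "MLPSpeedFilter",
                   speedFloor = "numeric", ablation = "logical"))

setValidity("HybridModel", function(object) {
    msgs <- c()
    if (object@kalman@stateDim != 5L)
        msgs <- c(msgs, "hybrid Kalman state must be 5-dimensional")
    if (length(object@speedFloor) != 1L || object@speedFloor < 0)
        msgs <- c(msgs, "'speedFloor' must be a single nonnegative number")
    if (length(object@ablation) != 1L)
        msgs <- c(msgs, "'ablation' must be a single logical")
    if (length(msgs)) msgs else TRUE
})

#' Simulated center-out session
#'
#' Output of [genSession()]: continuous session kinematics, the trial event
#' table, the ground-truth reach/rest mask and the generating configuration.
#' The reach mask marks samples where the instantaneous speed exceeds 5% of
#' that movement's peak speed, the usual movement onset/offset convention.
#'
#' @slot kinematics [TrajectorySeries-class] covering the whole session.
#' @slot events data.frame with one row per trial: \code{onset_s},
#'   \code{target_label}, \code{target_x}, \code{target_y},
#'   \code{move_start_s}, \code{move_mid_s}, \code{move_end_s},
#'   \code{duration_s}.
#' @slot reachMask logical per session sample (TRUE = reach).
#' @slot config the [syntheticConfig()] list used for generation.
#' @export
setClass("CenterOutSession",
    representation(kinematics = "TrajectorySeries", events = "data.frame",
                   reachMask = "logical", config = "list"))

setValidity("CenterOutSession", function(object) {
    msgs <- c()
    if (length(object@reachMask) != length(object@kinematics@times))
        msgs <- c(msgs, "'reachMask' must flag every kinematic sample")
    need <- c("onset_s", "target_label", "target_x", "target_y",
              "move_start_s", "move_mid_s", "move_end_s", "duration_s")
    if (!all(need %in% names(object@events)))
        msgs <- c(msgs, "'events' is missing required columns")
    if (length(msgs)) msgs else TRUE
})

#' Cross-validated decoder benchmark report
#'
#' Output of [runBenchmark()]: per-decoder, per-regime summaries (mean and
#' SEM over test trials) of position/speed RMSE and the pointing metrics,
#' the underlying per-trial values, paired t-test comparisons between
#' decoders, and everything needed to re-run the benchmark bit-identically
#' (config, seed, fold assignment).
#'
#' @slot summary data.frame: decoder, regime, metric means and SEMs.
#' @slot perTrial data.frame: one row per (decoder, regime, trial).
#' @slot comparisons data.frame of paired t-tests on per-trial RMSE.
#' @slot config generating configuration list.
#' @slot seed integer seed of the benchmark run.
#' @slot folds integer fold assignment per trial.
#' @export
setClass("BenchmarkReport",
    representation(summary = "data.frame", perTrial = "data.frame",
                   comparisons = "data.frame", config = "list",
                   seed = "integer", folds = "integer"))

## ---- accessors ----

#' @rdname accessors
#' @export
setMethod("times", "TrajectorySeries", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("position", "TrajectorySeries", function(x) x@position)
#' @rdname accessors
#' @export
setMethod("velocity", "TrajectorySeries", function(x) x@velocity)
#' @rdname accessors
#' @export
setMethod("sampleRate", "TrajectorySeries", function(x) x@sampleRate)
#' @rdname accessors
#' @export
setMethod("nSamples", "TrajectorySeries", function(x) length(x@times))

#' @rdname accessors
#' @export
setMethod("speed", "SpeedDirectionSeries", function(x) x@speed)
#' @rdname accessors
#' @export
setMethod("direction", "SpeedDirectionSeries", function(x) x@direction)

#' @rdname accessors
#' @export
setMethod("recordingData", "NeuralRecording", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("sampleRate", "NeuralRecording", function(x) x@sampleRate)
#' @rdname accessors
#' @export
setMethod("channelLabels", "NeuralRecording", function(x) x@channelLabels)
#' @rdname accessors
#' @export
setMethod("nChannels", "NeuralRecording", function(x) nrow(x@data))
#' @rdname accessors
#' @export
setMethod("nSamples", "NeuralRecording", function(x) ncol(x@data))

#' @rdname accessors
#' @export
setMethod("epochs", "EpochSet", function(x) x@epochs)
#' @rdname accessors
#' @export
setMethod("trialLabels", "EpochSet", function(x) x@trialLabels)
#' @rdname accessors
#' @export
setMethod("sampleRate", "EpochSet", function(x) x@sampleRate)

#' @rdname accessors
#' @export
setMethod("designMatrix", "LaggedDesign", function(x) x@design)
#' @rdname accessors
#' @export
setMethod("validRows", "LaggedDesign", function(x) x@valid)
#' @rdname accessors
#' @export
setMethod("lagCount", "LaggedDesign", function(x) x@lagCount)
#' @rdname accessors
#' @export
setMethod("nChannels", "LaggedDesign", function(x) x@channelCount)

#' @rdname accessors
#' @export
setMethod("filterWeights", "LinearFilterModel", function(x) x@weights)
#' @rdname accessors
#' @export
setMethod("lagCount", "LinearFilterModel", function(x) x@lagCount)
#' @rdname accessors
#' @export
setMethod("nChannels", "LinearFilterModel", function(x) x@channelCount)
#' @rdname accessors
#' @export
setMethod("channelLabels", "LinearFilterModel", function(x) x@channelLabels)

#' @rdname accessors
#' @export
setMethod("transitionMatrix", "KalmanModel", function(x) x@A)
#' @rdname accessors
#' @export
setMethod("systemNoise", "KalmanModel", function(x) x@W)
#' @rdname accessors
#' @export
setMethod("observationMatrix", "KalmanModel", function(x) x@H)
#' @rdname accessors
#' @export
setMethod("observationNoise", "KalmanModel", function(x) x@Q)
#' @rdname accessors
#' @export
setMethod("stateDim", "KalmanModel", function(x) x@stateDim)

#' @rdname accessors
#' @export
setMethod("states", "StateSequence", function(x) x@states)
#' @rdname accessors
#' @export
setMethod("stateCovariances", "StateSequence", function(x) x@covariances)

#' @rdname accessors
#' @export
setMethod("speedScale", "MLPSpeedFilter", function(x) x@speedScale)

#' @rdname accessors
#' @export
setMethod("times", "CenterOutSession", function(x) x@kinematics@times)
#' @rdname accessors
#' @export
setMethod("sampleRate", "CenterOutSession", function(x) x@kinematics@sampleRate)
#' @rdname accessors
#' @export
setMethod("reachMask", "CenterOutSession", function(x) x@reachMask)
#' @rdname accessors
#' @export
setMethod("trialEvents", "CenterOutSession", function(x) x@events)

#' @rdname accessors
#' @export
setMethod("benchmarkSummary", "BenchmarkReport", function(x) x@summary)
#' @rdname accessors
#' @export
setMethod("perTrialMetrics", "BenchmarkReport", function(x) x@perTrial)
#' @rdname accessors
#' @export
setMethod("decoderComparisons", "BenchmarkReport", function(x) x@comparisons)
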