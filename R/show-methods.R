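#' @describeIn TrajectorySeries-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "TrajectorySeries", function(object) {
    n <- length(object@times)
    cat(sprintf("TrajectorySeries: %d samples at %g Hz (%.2f s)\n",
                n, object@sampleRate,
                if (n) n / object@sampleRate else 0))
})

#' @describeIn NeuralRecording-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "NeuralRecording", function(object) {
    cat(sprintf("NeuralRecording: %d channels x %d samples at %g Hz\n",
                nrow(object@data), ncol(object@data), object@sampleRate))
})

#' @describeIn EpochSet-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "EpochSet", function(object) {
    d <- dim(object@epochs)
    cat(sprintf("EpochSet: %d trials x %d channels x %d samples, window [%g, %g] s (%d dropped)\n",
                d[1L], d[2L], d[3L], object@window[1L], object@window[2L],
                object@dropped))
})

#' @describeIn LaggedDesign-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "LaggedDesign", function(object) {
    cat(sprintf("LaggedDesign: %d rows x %d cols (%d channels, %d lags + bias), %d valid rows\n",
                nrow(object@design), ncol(object@design),
                object@channelCount, object@lagCount, sum(object@valid)))
})

#' @describeIn LinearFilterModel-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "LinearFilterModel", function(object) {
    cat(sprintf("LinearFilterModel: %d channels x %d lags (+ bias) -> 2-D velocity\n",
                object@channelCount, object@lagCount + 1L))
})

#' @describeIn KalmanModel-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "KalmanModel", function(object) {
    cat(sprintf("KalmanModel: state dim %d, %d observation channels\n",
                object@stateDim, nrow(object@H)))
})

#' @describeIn StateSequence-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "StateSequence", function(object) {
    cat(sprintf("StateSequence: %d samples x state dim %d%s\n",
                nrow(object@states), ncol(object@states),
                if (object@events) sprintf(" (%d conditioning events)",
                                           object@events) else ""))
})

#' @describeIn MLPSpeedFilter-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "MLPSpeedFilter", function(object) {
    cat(sprintf("MLPSpeedFilter: 3 -> %d (tanh) -> 1 (sigmoid), speed scale %.3g units/s\n",
                nrow(object@W1), object@speedScale))
})

#' @describeIn HybridModel-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "HybridModel", function(object) {
    cat(sprintf("HybridModel: 5-dim Kalman state + MLP speed read-out (%d channels)%s\n",
                nrow(object@kalman@H),
                if (object@ablation) " [ablation: speed from r(t)]" else ""))
})

#' @describeIn CenterOutSession-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "CenterOutSession", function(object) {
    ev <- object@events
    cat(sprintf("CenterOutSession: %d trials (%s), %.0f s at %g Hz, %.1f%% reach\n",
                nrow(ev),
                paste(sprintf("%s:%d", names(table(ev$target_label)),
                              as.integer(table(ev$target_label))),
                      collapse = " "),
                max(object@kinematics@times) + 1 / object@kinematics@sampleRate,
                object@kinematics@sampleRate,
                100 * mean(object@reachMask)))
})

#' @describeIn BenchmarkReport-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "BenchmarkReport", function(object) {
    cat(sprintf("BenchmarkReport: seed %d, %d folds\n", object@seed,
                max(object@folds)))
    s <- object@summary
    for (regime in unique(s$regime)) {
        cat(sprintf("  regime %s:\n", regime))
        sub <- s[s$regime == regime & s$metric %in%
                 c("rmse_pos", "rmse_speed"), ]
        w <- stats::reshape(sub[c("decoder", "metric", "mean")],
                            direction = "wide", idvar = "decoder",
                            timevar = "metric")
        names(w) <- sub("^mean\\.", "", names(w))
        for (i in seq_len(nrow(w)))
            cat(sprintf("    %-15s rmse_pos %.4f  rmse_speed %.4f\n",
                        w$decoder[i], w$rmse_pos[i], w$rmse_speed[i]))
    }
    invisible(NULL)
})

#' Plot true versus decoded trajectories
#'
#' Base-graphics overlay of true (grey) and decoded (coloured) 2-D paths.
#'
#' @param truePos,decodedPos samples x 2 position matrices (NA rows are
#'   skipped).
#' @param main plot title.
#' @return Invisibly NULL.
#' @export
plotTrajectories <- function(truePos, decodedPos, main = "decoded path") {
    graphics::plot(truePos[, 1L], truePos[, 2L], type = "l", col = "grey60",
                   xlab = "x", ylab = "y", main = main, asp = 1)
    graphics::lines(decodedPos[, 1L], decodedPos[, 2L], col = "firebrick")
    invisible(NULL)
}
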