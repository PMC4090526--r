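#' Fit the lagged linear regression decoder
#'
#' Ordinary least squares per velocity coordinate: each coordinate is
#' regressed on the current and m preceding samples of every channel plus
#' an intercept.  Only design rows with complete history (and, optionally,
#' a caller-supplied subset) enter the fit.  When the design Gram matrix is
#' singular the minimum-norm solution is used with a warning.
#'
#' @param design a [LaggedDesign-class].
#' @param velocity samples x 2 matrix aligned row-for-row with the design.
#' @param rows optional integer/logical subset of rows to fit on (applied
#'   on top of the design's valid-row flags).
#' @return A [LinearFilterModel-class].
#' @export
fitLinearFilter <- function(design, velocity, rows = NULL) {
    stopifnot(is(design, "LaggedDesign"))
    v <- .asMatrix2(velocity, "velocity")
    if (ncol(v) != 2L) stop("'velocity' must have 2 columns")
    if (nrow(v) != nrow(design@design))
        stop("'velocity' must align with the design rows")
    use <- design@valid
    if (!is.null(rows)) {
        sel <- rep(FALSE, nrow(design@design))
        sel[rows] <- TRUE
        use <- use & sel
    }
    X <- design@design[use, , drop = FALSE]
    nonBias <- X[, -ncol(X), drop = FALSE]
    if (ncol(nonBias) && nrow(nonBias)) {
        cm <- colMeans(nonBias)
        cv <- colMeans(nonBias^2) - cm^2
        if (any(cv <= 1e-30 * (1 + cm^2)))
            warning("constant (collinear) design column other than the bias")
    }
    W <- .lsSolve(X, v[use, , drop = FALSE], what = "lagged design")
    dimnames(W) <- list(colnames(design@design), c("vx", "vy"))
    new("LinearFilterModel", weights = W, lagCount = design@lagCount,
        channelCount = design@channelCount,
        channelLabels = design@channelLabels)
}

#' Predict velocity with a fitted linear filter
#'
#' Applies the fitted weights to the lagged history of a recording.  The
#' first m output samples have incomplete history and are returned as NA.
#'
#' @param model a [LinearFilterModel-class].
#' @param recording a [NeuralRecording-class] with the model's channel set,
#'   or a [LaggedDesign-class] built with the model's lag count.
#' @return samples x 2 velocity matrix with NA in the first m rows.
#' @export
predictLinearFilter <- function(model, recording) {
    stopifnot(is(model, "LinearFilterModel"))
    if (is(recording, "LaggedDesign")) {
        design <- recording
        if (design@lagCount != model@lagCount ||
            design@channelCount != model@channelCount ||
            !identical(design@channelLabels, model@channelLabels))
            stop("design does not match the model's channels/lags")
    } else {
        stopifnot(is(recording, "NeuralRecording"))
        if (!identical(recording@channelLabels, model@channelLabels))
            stop("recording channels do not match the model")
        design <- buildLaggedDesign(recording, model@lagCount)
    }
    pred <- design@design %*% model@weights
    pred[!design@valid, ] <- NA_real_
    colnames(pred) <- c("vx", "vy")
    pred
}
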