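## Multilayer perceptron speed read-out and its scaled conjugate gradient
## trainer (Moller's algorithm, full batch).

## Parameter packing: c(W1, b1, w2, b2), W1 stored column-major.
.mlpUnpack <- function(theta, hidden) {
    i <- hidden * 3L
    list(W1 = matrix(theta[1:i], hidden, 3L),
         b1 = theta[(i + 1L):(i + hidden)],
         w2 = theta[(i + hidden + 1L):(i + 2L * hidden)],
         b2 = theta[i + 2L * hidden + 1L])
}

.mlpPack <- function(p) c(p$W1, p$b1, p$w2, p$b2)

## Forward pass on scaled inputs Xs (n x 3); returns hidden activations and
## sigmoid outputs in (0, 1).
.mlpEval <- function(p, Xs) {
    A1 <- tanh(sweep(Xs %*% t(p$W1), 2L, p$b1, "+"))
    y <- plogis(as.numeric(A1 %*% p$w2) + p$b2)
    list(A1 = A1, y = y)
}

## Mean squared error (0.5 factor) and its gradient w.r.t. packed
## parameters, on scaled inputs/targets.
.mlpLossGrad <- function(theta, hidden, Xs, ts, gradient = TRUE) {
    p <- .mlpUnpack(theta, hidden)
    ev <- .mlpEval(p, Xs)
    err <- ev$y - ts
    loss <- 0.5 * mean(err^2)
    if (!gradient) return(list(loss = loss))
    n <- length(ts)
    dz2 <- err * ev$y * (1 - ev$y) / n          # n
    gw2 <- as.numeric(crossprod(ev$A1, dz2))    # hidden
    gb2 <- sum(dz2)
    dH <- (dz2 %o% p$w2) * (1 - ev$A1^2)        # n x hidden
    gW1 <- crossprod(dH, Xs)                    # hidden x 3
    gb1 <- colSums(dH)
    list(loss = loss, grad = c(gW1, gb1, gw2, gb2))
}

## Moller's scaled conjugate gradient minimizer for a loss with gradient.
## fn(theta, gradient=) must return list(loss, grad).  Returns the final
## parameters and the loss trace over accepted steps.
.scgMinimize <- function(theta, fn, maxit = 500L, gradTol = 1e-6,
                         sigma0 = 1e-4, lambda0 = 1e-6) {
    np <- length(theta)
    cur <- fn(theta, gradient = TRUE)
    fw <- cur$loss
    r <- -cur$grad
    p <- r
    lambda <- lambda0
    lambdaBar <- 0
    success <- TRUE
    trace <- fw
    delta <- 0
    for (k in seq_len(maxit)) {
        pNorm2 <- sum(p^2)
        if (sqrt(sum(r^2)) < gradTol || pNorm2 == 0) break
        if (success) {
            sigma <- sigma0 / sqrt(pNorm2)
            gPlus <- fn(theta + sigma * p, gradient = TRUE)$grad
            s <- (gPlus - cur$grad) / sigma   # finite-difference Hessian-vector product
            delta <- sum(p * s)
        }
        delta <- delta + (lambda - lambdaBar) * pNorm2
        if (delta <= 0) {                      # make the Hessian estimate PD
            lambdaBar <- 2 * (lambda - delta / pNorm2)
            delta <- -delta + lambda * pNorm2
            lambda <- lambdaBar
        }
        mu <- sum(p * r)
        alpha <- mu / delta
        thetaNew <- theta + alpha * p
        fNew <- fn(thetaNew, gradient = FALSE)$loss
        Delta <- 2 * delta * (fw - fNew) / mu^2
        if (is.finite(Delta) && Delta >= 0) {  # accept the step
            theta <- thetaNew
            cur <- fn(theta, gradient = TRUE)
            fw <- cur$loss
            trace <- c(trace, fw)
            rNew <- -cur$grad
            lambdaBar <- 0
            success <- TRUE
            if (k %% np == 0) {
                p <- rNew                      # periodic restart
            } else {
                beta <- (sum(rNew^2) - sum(rNew * r)) / mu
                p <- rNew + beta * p
            }
            r <- rNew
            if (Delta >= 0.75) lambda <- lambda / 4
        } else {
            lambdaBar <- lambda
            success <- FALSE
        }
        if (!is.finite(Delta) || Delta < 0.25)
            lambda <- lambda + delta * (1 - Delta) / pNorm2
        if (!is.finite(lambda) || lambda > 1e20) break
    }
    list(theta = theta, trace = trace)
}

#' Train the nonlinear speed read-out
#'
#' Trains the multilayer perceptron that predicts the current hand speed
#' from the three speed state variables \eqn{(r(t), r(t-1), r(t-2))}.
#' Architecture: 18 tanh hidden units and one logistic-sigmoid output.
#' Inputs and targets are divided by `speedScale` (by default the maximum
#' training speed) so that targets lie in \[0, 1\]; the network is trained
#' with the scaled conjugate gradient algorithm on the full-batch mean
#' squared error.  Weight initialization is uniform
#' \eqn{(-0.5, 0.5)/\sqrt{fan~in}} under the recorded seed, so identical
#' calls produce identical networks.
#'
#' Note the network never sees direction components: its input width is
#' fixed at 3, which structurally enforces the independence of speed from
#' direction.
#'
#' @param speedStates samples x 3 matrix of speed states (units/s).
#' @param targetSpeed nonnegative target speed per sample (units/s).
#' @param hidden hidden layer size (default 18).
#' @param seed integer seed for weight initialization (default 1).
#' @param speedScale normalizer in units/s; defaults to
#'   \code{max(targetSpeed)}.  Constant targets are rejected unless an
#'   explicit `speedScale` makes the scaled problem non-degenerate.
#' @param maxit,gradTol scaled-conjugate-gradient stopping rule
#'   (defaults 500 iterations, gradient norm 1e-6).
#' @return An [MLPSpeedFilter-class].
#' @seealso [mlpForward()]
#' @export
trainSpeedMLP <- function(speedStates, targetSpeed, hidden = 18L, seed = 1L,
                          speedScale = NULL, maxit = 500L, gradTol = 1e-6) {
    X <- .asMatrix2(speedStates, "speedStates")
    if (ncol(X) != 3L)
        stop("'speedStates' must have exactly 3 columns (no direction input)")
    ts <- as.numeric(targetSpeed)
    if (length(ts) != nrow(X))
        stop("'targetSpeed' must align with 'speedStates'")
    if (any(ts < 0)) stop("'targetSpeed' must be nonnegative")
    if (is.null(speedScale)) {
        if (stats::sd(ts) == 0)
            stop("zero-variance targets: supply an explicit 'speedScale' or vary the targets")
        speedScale <- max(ts)
    }
    if (speedScale <= 0) stop("'speedScale' must be positive")
    Xs <- X / speedScale
    tsS <- ts / speedScale
    hidden <- as.integer(hidden)
    theta0 <- withSeed(seed, c(
        stats::runif(hidden * 3L, -0.5, 0.5) / sqrt(3),
        stats::runif(hidden, -0.5, 0.5) / sqrt(3),
        stats::runif(hidden, -0.5, 0.5) / sqrt(hidden),
        stats::runif(1L, -0.5, 0.5) / sqrt(hidden)))
    fit <- .scgMinimize(theta0,
                        function(th, gradient = TRUE)
                            .mlpLossGrad(th, hidden, Xs, tsS, gradient),
                        maxit = maxit, gradTol = gradTol)
    p <- .mlpUnpack(fit$theta, hidden)
    new("MLPSpeedFilter", W1 = p$W1, b1 = p$b1, w2 = p$w2, b2 = p$b2,
        speedScale = speedScale, seed = as.integer(seed),
        lossTrace = fit$trace)
}

#' Forward pass of the speed read-out
#'
#' Maps speed states to a speed estimate: the sigmoid output times
#' `speedScale`, hence always strictly inside (0, speedScale).  Inputs
#' above the training maximum simply saturate the sigmoid.
#'
#' @param mlp an [MLPSpeedFilter-class].
#' @param speedStates a 3-vector or samples x 3 matrix (units/s).
#' @return Speed estimate(s) in units/s.
#' @export
mlpForward <- function(mlp, speedStates) {
    stopifnot(is(mlp, "MLPSpeedFilter"))
    X <- if (is.null(dim(speedStates))) matrix(speedStates, ncol = 3L)
         else as.matrix(speedStates)
    if (ncol(X) != 3L) stop("'speedStates' must have 3 columns")
    p <- list(W1 = mlp@W1, b1 = mlp@b1, w2 = mlp@w2, b2 = mlp@b2)
    .mlpEval(p, X / mlp@speedScale)$y * mlp@speedScale
}
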