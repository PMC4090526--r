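#' Construct a KalmanModel
#'
#' Direct constructor for a known state-space model (simulation, testing,
#' deserialization).  [fitKalman()] is the usual entry point.
#'
#' @param A,W,H,Q model matrices (scalars are promoted to 1 x 1 matrices).
#' @param initialState initial state mean; default zero.
#' @param initialCovariance initial state covariance; default W.
#' @return A [KalmanModel-class].
#' @export
KalmanModel <- function(A, W, H, Q, initialState = NULL,
                        initialCovariance = NULL) {
    A <- as.matrix(A); W <- as.matrix(W)
    H <- as.matrix(H); Q <- as.matrix(Q)
    d <- nrow(A)
    if (is.null(initialState)) initialState <- rep(0, d)
    if (is.null(initialCovariance)) initialCovariance <- W
    new("KalmanModel", A = A, W = .symmetrize(W), H = H,
        Q = .symmetrize(Q), stateDim = as.integer(d),
        initialState = as.numeric(initialState),
        initialCovariance = .symmetrize(as.matrix(initialCovariance)))
}

#' Fit a linear-Gaussian state-space model by least squares
#'
#' Estimates the time-invariant system and observation models from aligned
#' training states and neural observations: the transition matrix A
#' minimizes \eqn{\sum_t \|x(t) - A x(t-1)\|^2} over consecutive sample
#' pairs, W is the covariance of its residuals; the observation matrix H
#' minimizes \eqn{\sum_t \|z(t) - H x(t)\|^2}, Q the covariance of its
#' residuals.  Covariances use the 1/(rows - 1) normalization.  The initial
#' state is the mean training state and the initial covariance the
#' covariance of the training states -- the marginal state prior, which is
#' the appropriate statement of ignorance whenever the decoding recursion
#' restarts at an epoch boundary (a prior as tight as the per-step noise W
#' would leave short segments stuck near the initial state).
#'
#' When training samples are a concatenation of disjoint segments (e.g.
#' trials, or reach-only runs), pass `groups`: pairs straddling a group
#' boundary are excluded from the transition fit.
#'
#' @param statesMat samples x d matrix of training states.
#' @param observations samples x channels matrix of aligned neural data.
#' @param groups optional vector marking contiguous segments; only pairs
#'   with equal consecutive group values contribute to A and W.
#' @return A [KalmanModel-class].
#' @export
fitKalman <- function(statesMat, observations, groups = NULL) {
    x <- .asMatrix2(statesMat, "statesMat")
    z <- .asMatrix2(observations, "observations")
    n <- nrow(x)
    if (nrow(z) != n) stop("states and observations must align row-for-row")
    d <- ncol(x)
    if (n < d + 1L) stop("need at least d+1 samples")
    pair <- 2:n
    if (!is.null(groups)) {
        if (length(groups) != n) stop("'groups' must flag every sample")
        pair <- pair[groups[pair] == groups[pair - 1L]]
    }
    if (length(pair) < d)
        stop("too few consecutive sample pairs to estimate the transition")
    X0 <- x[pair - 1L, , drop = FALSE]
    X1 <- x[pair, , drop = FALSE]
    A <- t(.lsSolve(X0, X1, what = "state"))
    resA <- X1 - X0 %*% t(A)
    W <- .symmetrize(crossprod(resA) / (nrow(resA) - 1L))
    H <- t(.lsSolve(x, z, what = "state"))
    resH <- z - x %*% t(H)
    Q <- .symmetrize(crossprod(resH) / (nrow(resH) - 1L))
    P0 <- .symmetrize(stats::cov(x))
    new("KalmanModel", A = A, W = W, H = H, Q = Q, stateDim = as.integer(d),
        initialState = colMeans(x), initialCovariance = P0)
}

#' Decode states from observations by the Kalman recursion
#'
#' Standard predict/update recursion.  At each step the system model
#' predicts the state from the previous posterior
#' (\eqn{x^- = A x, P^- = A P A' + W}); the observation model then corrects
#' the prediction by the innovation
#' (\eqn{x = x^- + K (z - H x^-)}, \eqn{K = P^- H' S^{-1}},
#' \eqn{S = H P^- H' + Q}).  The recursion starts from the model's initial
#' state and covariance; call once per trial for trial-wise re-initialized
#' decoding, or once on a whole session for continuous decoding.
#'
#' The innovation covariance is symmetrized each step; if its Cholesky
#' factorization still fails, a small diagonal jitter is added and the
#' event counted in the result.
#'
#' @param model a [KalmanModel-class].
#' @param observations samples x channels matrix (channels must match H).
#' @param retainCovariances keep the per-sample posterior covariances?
#' @return A [StateSequence-class].
#' @export
kalmanDecode <- function(model, observations, retainCovariances = FALSE) {
    stopifnot(is(model, "KalmanModel"))
    z <- .asMatrix2(observations, "observations")
    if (ncol(z) != nrow(model@H))
        stop("observation channel count does not match H")
    n <- nrow(z)
    d <- model@stateDim
    A <- model@A; W <- model@W; H <- model@H; Q <- model@Q
    x <- model@initialState
    P <- model@initialCovariance
    out <- matrix(NA_real_, n, d)
    covs <- if (retainCovariances) vector("list", n) else list()
    events <- 0L
    tH <- t(H)
    for (t in seq_len(n)) {
        xp <- as.numeric(A %*% x)
        Pp <- .symmetrize(A %*% P %*% t(A) + W)
        S <- .symmetrize(H %*% Pp %*% tH + Q)
        ch <- tryCatch(chol(S), error = function(e) NULL)
        if (is.null(ch)) {
            S <- S + diag(1e-9 * (1 + mean(diag(S))), nrow(S))
            ch <- chol(S)
            events <- events + 1L
        }
        HPp <- H %*% Pp
        K <- t(backsolve(ch, forwardsolve(t(ch), HPp)))
        x <- xp + as.numeric(K %*% (z[t, ] - H %*% xp))
        P <- .symmetrize(Pp - K %*% HPp)
        out[t, ] <- x
        if (retainCovariances) covs[[t]] <- P
    }
    new("StateSequence", states = out, covariances = covs, events = events)
}
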