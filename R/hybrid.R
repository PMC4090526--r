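#' Build the 5-dimensional hybrid state sequence from velocity
#'
#' Decomposes the velocity into speed and direction and assembles, per
#' sample, the state vector \eqn{[r(t), r(t-1), r(t-2), d_x(t), d_y(t)]}:
#' the current speed, its two lagged copies (together carrying the local
#' speed dynamics -- change and curvature of the bell-shaped profile), and
#' the unit direction.  The first two samples lack full lag history; their
#' lagged entries are edge-replicated and the samples flagged invalid.
#'
#' @param velocity samples x 2 velocity matrix (>= 3 samples).
#' @param speedFloor direction carry-forward floor, see
#'   [decomposeVelocity()].
#' @return A list with `states` (samples x 5 matrix, columns `r_t`, `r_t1`,
#'   `r_t2`, `d_x`, `d_y`), `speed` (the target speed sequence, equal to
#'   column `r_t`) and `valid` (logical; FALSE for the two edge-padded
#'   samples).
#' @export
buildHybridStates <- function(velocity, speedFloor = 1e-6) {
    v <- .asMatrix2(velocity, "velocity")
    n <- nrow(v)
    if (n < 3L) stop("need at least 3 samples")
    sd <- decomposeVelocity(v, speedFloor)
    r <- sd@speed
    r1 <- r[pmax(seq_len(n) - 1L, 1L)]
    r2 <- r[pmax(seq_len(n) - 2L, 1L)]
    states <- cbind(r_t = r, r_t1 = r1, r_t2 = r2,
                    d_x = sd@direction[, 1L], d_y = sd@direction[, 2L])
    list(states = states, speed = r,
         valid = seq_len(n) > 2L)
}

#' Fit the hybrid speed--direction decoder
#'
#' Builds the 5-dimensional state sequence from the training velocity,
#' fits its Kalman model against the neural observations with
#' [fitKalman()], and trains the [MLPSpeedFilter-class] speed read-out.
#'
#' By default the network is trained on the Kalman posterior speed states
#' obtained by decoding the training observations (`trainOn =
#' "posterior"`), with the true current speed as target: this matches the
#' input distribution the read-out sees at decode time and lets it correct
#' systematic distortion in the posterior.  `trainOn = "true"` instead
#' teacher-forces the ground-truth speed states as inputs.
#'
#' @param velocity samples x 2 training velocity.
#' @param observations samples x channels matrix or
#'   [NeuralRecording-class], aligned with `velocity`.
#' @param seed integer seed for the network initialization.
#' @param trainOn `"posterior"` (default) or `"true"`; see Details.
#' @param hidden hidden layer size (default 18).
#' @param speedFloor direction floor (units/s).
#' @param maxit scaled-conjugate-gradient iteration cap.
#' @param ablation default speed read-out mode stored in the model: FALSE
#'   (network read-out) or TRUE (posterior r(t) directly).
#' @param groups optional segment marker passed to [fitKalman()].
#' @return A [HybridModel-class].
#' @export
fitHybrid <- function(velocity, observations, seed = 1L,
                      trainOn = c("posterior", "true"), hidden = 18L,
                      speedFloor = 1e-6, maxit = 500L, ablation = FALSE,
                      groups = NULL) {
    trainOn <- match.arg(trainOn)
    if (is(observations, "NeuralRecording"))
        observations <- t(observations@data)
    z <- .asMatrix2(observations, "observations")
    hs <- buildHybridStates(velocity, speedFloor)
    km <- fitKalman(hs$states, z, groups = groups)
    if (trainOn == "posterior") {
        post <- kalmanDecode(km, z)@states[, 1:3, drop = FALSE]
        inputs <- post
    } else {
        inputs <- hs$states[, 1:3, drop = FALSE]
    }
    mlp <- trainSpeedMLP(inputs, hs$speed, hidden = hidden, seed = seed,
                         speedScale = max(hs$speed), maxit = maxit)
    new("HybridModel", kalman = km, mlp = mlp, speedFloor = speedFloor,
        ablation = ablation)
}

#' Decode velocity with the hybrid decoder
#'
#' Runs the Kalman predict/update recursion on the 5-dimensional state and
#' reads speed and direction out independently at every step: direction is
#' the posterior \eqn{(d_x, d_y)} normalized to unit length (carrying the
#' previous direction forward when its norm is at or below the model's
#' speed floor), speed is the network output on the posterior speed states
#' -- or the raw posterior \eqn{r(t)} in the ablation variant -- and the
#' emitted velocity is their product.  The speed read-out never feeds back
#' into the recursion, which therefore stays linear-Gaussian; the full and
#' ablation variants share identical Kalman posteriors.
#'
#' @param model a [HybridModel-class].
#' @param observations samples x channels matrix or
#'   [NeuralRecording-class].
#' @param ablation override of the model's stored read-out mode.
#' @return A list with `velocity` (samples x 2), `speed`, `direction`
#'   (samples x 2 unit vectors), and `states` (the
#'   [StateSequence-class] of Kalman posteriors).
#' @export
hybridDecode <- function(model, observations, ablation = model@ablation) {
    stopifnot(is(model, "HybridModel"))
    if (is(observations, "NeuralRecording"))
        observations <- t(observations@data)
    seq <- kalmanDecode(model@kalman, observations)
    S <- seq@states
    n <- nrow(S)
    dirRaw <- S[, 4:5, drop = FALSE]
    nrm <- sqrt(rowSums(dirRaw^2))
    dir <- matrix(0, n, 2L)
    ok <- nrm > model@speedFloor
    dir[ok, ] <- dirRaw[ok, , drop = FALSE] / nrm[ok]
    lastOk <- cummax(ifelse(ok, seq_len(n), 0L))
    fallback <- lastOk == 0L
    carried <- !ok & !fallback
    if (any(carried)) dir[carried, ] <- dir[lastOk[carried], , drop = FALSE]
    if (any(fallback))
        dir[fallback, ] <- matrix(c(1, 0), sum(fallback), 2L, byrow = TRUE)
    spd <- if (ablation) S[, 1L] else
        as.numeric(mlpForward(model@mlp, S[, 1:3, drop = FALSE]))
    list(velocity = dir * spd, speed = spd, direction = dir, states = seq)
}
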