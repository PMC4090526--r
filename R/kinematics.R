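#' Construct a TrajectorySeries
#'
#' Convenience constructor validating the uniform-grid invariants.
#'
#' @param times sample times in seconds (uniform grid).
#' @param position samples x 2 matrix of x/y positions.
#' @param velocity samples x 2 matrix of x/y velocities.
#' @param sampleRate sampling rate in Hz; inferred from `times` if missing.
#' @return A [TrajectorySeries-class].
#' @examples
#' tr <- TrajectorySeries(times = seq(0, 1, by = 0.02),
#'                        position = cbind(seq(0, 1, by = 0.02), 0),
#'                        velocity = cbind(rep(1, 51), 0))
#' sampleRate(tr)
#' @export
TrajectorySeries <- function(times, position, velocity,
                             sampleRate = NULL) {
    if (is.null(sampleRate)) {
        if (length(times) < 2L)
            stop("'sampleRate' is required for series shorter than 2 samples")
        sampleRate <- 1 / median(diff(times))
    }
    new("TrajectorySeries", times = as.numeric(times),
        position = .asMatrix2(position, "position"),
        velocity = .asMatrix2(velocity, "velocity"),
        sampleRate = sampleRate)
}

#' Integrate acceleration into velocity
#'
#' Cumulative trapezoidal integration of a uniformly sampled acceleration
#' series with zero initial velocity, as used to recover finger velocity
#' from a band-passed accelerometer signal (drift is assumed pre-removed by
#' the band-pass).  Only the x--y plane is modelled: a third (z) column is
#' accepted and dropped with a warning.
#'
#' @param accel samples x 2 (or x 3) acceleration matrix, or a numeric
#'   vector for a single axis.
#' @param sampleRate sampling rate in Hz.
#' @return Velocity matrix of the same length (columns as retained axes).
#' @examples
#' v <- integrateAcceleration(cbind(rep(1, 51), 0), sampleRate = 50)
#' v[51, 1]  # ~ a * t = 1
#' @export
integrateAcceleration <- function(accel, sampleRate) {
    a <- .asMatrix2(accel, "accel")
    if (ncol(a) == 3L) {
        warning("third (z) axis dropped; only the x-y plane is modelled")
        a <- a[, 1:2, drop = FALSE]
    }
    if (ncol(a) > 3L)
        stop("'accel' must have at most 3 columns")
    dt <- 1 / sampleRate
    apply(a, 2L, function(col) pracma::cumtrapz(col)[, 1L] * dt)
}

#' Decompose velocity into speed and direction
#'
#' Polar decomposition of a 2-D velocity series: speed is the Euclidean
#' norm, direction the unit vector `velocity / speed`.  Where speed does not
#' exceed `speedFloor` the direction is undefined (0/0); it is carried
#' forward from the last sample with a well-defined direction, with (1, 0)
#' as the fallback before the first such sample.  This keeps
#' [composeVelocity()] an exact inverse wherever speed exceeds the floor.
#'
#' @param velocity samples x 2 velocity matrix.
#' @param speedFloor floor (units/s) below which direction is carried
#'   forward; default 1e-6.
#' @return A [SpeedDirectionSeries-class].
#' @examples
#' sd <- decomposeVelocity(rbind(c(3, 4), c(0, 0)))
#' speed(sd)       # 5, 0
#' direction(sd)   # (0.6, 0.8) carried forward
#' @export
decomposeVelocity <- function(velocity, speedFloor = 1e-6) {
    v <- .asMatrix2(velocity, "velocity")
    if (ncol(v) != 2L) stop("'velocity' must have 2 columns")
    spd <- sqrt(rowSums(v^2))
    n <- length(spd)
    dir <- matrix(0, n, 2L)
    ok <- spd > speedFloor
    dir[ok, ] <- v[ok, , drop = FALSE] / spd[ok]
    ## carry forward the last well-defined direction
    lastOk <- cummax(ifelse(ok, seq_len(n), 0L))
    fallback <- lastOk == 0L
    carried <- !ok & !fallback
    if (any(carried))
        dir[carried, ] <- dir[lastOk[carried], , drop = FALSE]
    if (any(fallback))
        dir[fallback, ] <- matrix(c(1, 0), sum(fallback), 2L, byrow = TRUE)
    new("SpeedDirectionSeries", speed = spd, direction = dir,
        speedFloor = speedFloor)
}

#' Compose velocity from speed and direction
#'
#' Elementwise product `speed * direction`, the inverse of
#' [decomposeVelocity()] wherever speed exceeds the decomposition floor.
#'
#' @param speed nonnegative numeric vector (units/s), or a
#'   [SpeedDirectionSeries-class] (in which case `direction` is ignored).
#' @param direction samples x 2 matrix of unit vectors (within 1e-6).
#' @return samples x 2 velocity matrix.
#' @export
composeVelocity <- function(speed, direction = NULL) {
    if (is(speed, "SpeedDirectionSeries")) {
        direction <- speed@direction
        speed <- speed@speed
    }
    d <- .asMatrix2(direction, "direction")
    if (ncol(d) != 2L) stop("'direction' must have 2 columns")
    if (length(speed) != nrow(d))
        stop("'speed' and 'direction' lengths differ")
    if (any(speed < 0)) stop("'speed' must be nonnegative")
    if (length(speed)) {
        nrm <- sqrt(rowSums(d^2))
        if (max(abs(nrm - 1)) > 1e-6)
            stop("'direction' rows must have unit norm (tolerance 1e-6)")
    }
    d * speed
}

#' Project a point series onto the task axis
#'
#' The task axis is the straight line from `start` to `target` (the optimal
#' path of a point-to-point reach).  Each point is expressed as a signed
#' distance travelled along the axis (`along`) and a signed perpendicular
#' deviation (`perp`), with the perpendicular direction the +90 degree
#' (counter-clockwise) rotation of the axis unit vector.  The map is an
#' isometry of the plane, so pointing metrics computed from it are
#' invariant under rigid motions of the whole scene.
#'
#' @param points samples x 2 matrix of positions.
#' @param start,target 2-D points; must be distinct.
#' @return A [TaskAxisFrame-class].
#' @examples
#' fr <- projectToTaskAxis(rbind(c(4, 1)), c(0, 0), c(10, 0))
#' fr@along  # 4
#' fr@perp   # 1
#' @export
projectToTaskAxis <- function(points, start, target) {
    p <- .asMatrix2(points, "points")
    if (ncol(p) != 2L) stop("'points' must have 2 columns")
    start <- as.numeric(start); target <- as.numeric(target)
    L <- sqrt(sum((target - start)^2))
    if (!(L > 0)) stop("'start' and 'target' must be distinct")
    u <- (target - start) / L
    uPerp <- c(-u[2L], u[1L])
    centered <- sweep(p, 2L, start)
    new("TaskAxisFrame", start = start, target = target,
        along = as.numeric(centered %*% u),
        perp = as.numeric(centered %*% uPerp))
}
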