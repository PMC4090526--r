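#' Configuration of the synthetic center-out session generator
#'
#' Returns the generator configuration as a validated list.  The defaults
#' emulate a single recording session of the center-out paradigm the
#' decoders are designed for: 120 trials (30 per corner target) at 4 s
#' spacing, bell-shaped point-to-point movements of about 0.93 s, 50 Hz
#' kinematics, and 68 surrogate neural channels carrying a lagged linear
#' velocity code plus, on half the channels, a sigmoidal speed tuning, all
#' embedded in band-limited (0.5--8 Hz) Gaussian noise.
#'
#' @param nTargets number of targets (4; corner layout at (+-1, +-1)).
#' @param trialsPerTarget trials per target (default 30).
#' @param movementDuration nominal one-way movement duration in s
#'   (default 0.93).
#' @param durationJitterSD,durationJitterMax per-trial Gaussian jitter of
#'   the duration (s), truncated at +-`durationJitterMax` (defaults 0.1 and
#'   0.3).
#' @param interTrial trial spacing in s (default 4; movements must fit
#'   inside it).
#' @param sampleRate kinematic/neural sampling rate in Hz (default 50).
#' @param onsetOffset target onset time of trial k is
#'   (k-1)*interTrial + onsetOffset (default 1 s, so a (-1, 2) s epoch
#'   always fits).
#' @param reactionTime delay from target onset to movement start (default
#'   0.25 s).
#' @param nChannels number of surrogate neural channels (default 68).
#' @param noiseSD per-channel noise standard deviation (default 5).  The
#'   default puts the lagged linear decoder's cross-validated velocity
#'   correlation near 0.65, the upper-middle of the range reported for
#'   noninvasive kinematic decoding; per-channel SNR is low, as for real
#'   gradiometers, and accuracy comes from pooling channels.
#' @param linearGainSD SD of the per-channel linear velocity gains
#'   (default 0.5).  Deliberately weaker than the speed tuning: direction
#'   information in noninvasive recordings is scarcer than speed
#'   information.
#' @param nonlinearFraction fraction of channels carrying the sigmoidal
#'   speed term (default 0.5).
#' @param nonlinearGainSD SD of the nonlinear gains (default 2.5).
#' @param sigmoidThreshold,sigmoidWidth speed-tuning sigmoid location and
#'   width in units/s (defaults 1.5 and 0.4).
#' @param lagRange integer range of per-channel encoding lags in samples
#'   (default 0..5).
#' @param noiseBand band limits of the noise in Hz (default c(0.5, 8)).
#' @param noiseSpectrum shape of the noise spectrum inside the band:
#'   `"pink"` (1/f power, the empirical low-frequency spectrum of MEG
#'   sensor and brain noise; the default) or `"white"` (flat).
#' @param outboundOnly generate only outbound movements (position resets to
#'   the centre at each onset; default FALSE, i.e. out-and-back).
#' @param seed integer RNG seed; every random draw of the generator flows
#'   from it.
#' @return A named list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(nTargets = 4L, trialsPerTarget = 30L,
                            movementDuration = 0.93,
                            durationJitterSD = 0.1,
                            durationJitterMax = 0.3,
                            interTrial = 4, sampleRate = 50,
                            onsetOffset = 1, reactionTime = 0.25,
                            nChannels = 68L, noiseSD = 5,
                            linearGainSD = 0.5, nonlinearFraction = 0.5,
                            nonlinearGainSD = 2.5,
                            sigmoidThreshold = 1.5, sigmoidWidth = 0.4,
                            lagRange = c(0L, 5L), noiseBand = c(0.5, 8),
                            noiseSpectrum = c("pink", "white"),
                            outboundOnly = FALSE, seed = 1L) {
    noiseSpectrum <- match.arg(noiseSpectrum)
    cfg <- list(nTargets = as.integer(nTargets),
                trialsPerTarget = as.integer(trialsPerTarget),
                movementDuration = movementDuration,
                durationJitterSD = durationJitterSD,
                durationJitterMax = durationJitterMax,
                interTrial = interTrial, sampleRate = sampleRate,
                onsetOffset = onsetOffset, reactionTime = reactionTime,
                nChannels = as.integer(nChannels), noiseSD = noiseSD,
                linearGainSD = linearGainSD,
                nonlinearFraction = nonlinearFraction,
                nonlinearGainSD = nonlinearGainSD,
                sigmoidThreshold = sigmoidThreshold,
                sigmoidWidth = sigmoidWidth,
                lagRange = as.integer(lagRange),
                noiseBand = noiseBand,
                noiseSpectrum = noiseSpectrum,
                outboundOnly = isTRUE(outboundOnly),
                seed = as.integer(seed))
    .validateSyntheticConfig(cfg)
    class(cfg) <- "syntheticConfig"
    cfg
}

.validateSyntheticConfig <- function(cfg) {
    stopifnot(cfg$nTargets == 4L,
              cfg$trialsPerTarget > 0L,
              cfg$movementDuration > 0,
              cfg$noiseSD >= 0,
              cfg$sampleRate > 0,
              cfg$nChannels > 0L,
              cfg$nonlinearFraction >= 0, cfg$nonlinearFraction <= 1,
              cfg$durationJitterMax >= 0)
    maxDur <- cfg$movementDuration + cfg$durationJitterMax
    need <- cfg$reactionTime + 2 * maxDur
    if (need >= cfg$interTrial)
        stop("movement (reaction + out-and-back) must fit inside 'interTrial'")
    invisible(cfg)
}

## Corner target layout: unit half-width square around the centre (0, 0).
.cornerTargets <- function() {
    rbind(UL = c(-1, 1), UR = c(1, 1), LL = c(-1, -1), LR = c(1, -1))
}

#' Minimum-jerk point-to-point reach
#'
#' The minimum-jerk quintic is the canonical parametric model of the
#' bell-shaped speed profile of point-to-point reaches:
#' \eqn{p(\tau) = start + (target - start)(10\tau^3 - 15\tau^4 + 6\tau^5)}
#' with \eqn{\tau = t / duration}, giving a unimodal symmetric speed that
#' is zero (with zero acceleration) at both ends and peaks at
#' \eqn{1.875 \, \|target - start\| / duration} at midpoint.  The duration
#' is snapped to the sample grid
#' (\code{round(duration * sampleRate) / sampleRate}) so the series ends
#' exactly on the target.
#'
#' @param start,target 2-D endpoints.
#' @param duration movement duration in s.
#' @param sampleRate sampling rate in Hz.
#' @return A [TrajectorySeries-class] from `start` (at time 0, speed 0) to
#'   `target`.
#' @export
minimumJerkReach <- function(start, target, duration, sampleRate) {
    if (duration <= 0) stop("'duration' must be positive")
    nStep <- max(2L, as.integer(round(duration * sampleRate)))
    dur <- nStep / sampleRate
    tt <- (0:nStep) / sampleRate
    tau <- tt / dur
    shape <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
    dshape <- (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / dur
    delta <- as.numeric(target) - as.numeric(start)
    TrajectorySeries(times = tt,
                     position = cbind(start[1L] + delta[1L] * shape,
                                      start[2L] + delta[2L] * shape),
                     velocity = cbind(delta[1L] * dshape,
                                      delta[2L] * dshape),
                     sampleRate = sampleRate)
}

## Quintic shape and derivative on clamped tau.
.mjShape <- function(tau) {
    tau <- pmin(pmax(tau, 0), 1)
    list(s = 10 * tau^3 - 15 * tau^4 + 6 * tau^5,
         ds = 30 * tau^2 - 60 * tau^3 + 30 * tau^4)
}

#' Generate a synthetic center-out session
#'
#' Simulates a full recording session under the given configuration: a
#' pseudorandom, exactly balanced target order; per trial an outbound
#' minimum-jerk reach from the centre to the corner target followed by a
#' return reach (unless `outboundOnly`), both with the trial's jittered
#' duration; rest at the centre otherwise.  All randomness flows from
#' `config$seed`, so equal configurations reproduce the session
#' bit-identically.
#'
#' The ground-truth reach mask marks samples whose analytic speed exceeds
#' 5% of the trial's peak speed -- the standard movement onset/offset
#' convention -- and is what [labelStates()] estimates from speed alone.
#'
#' @param config a [syntheticConfig()] list.
#' @return A [CenterOutSession-class].
#' @export
genSession <- function(config = syntheticConfig()) {
    .validateSyntheticConfig(config)
    fs <- config$sampleRate
    nTrials <- config$nTargets * config$trialsPerTarget
    targets <- .cornerTargets()
    drawn <- withSeed(config$seed, {
        order <- sample(rep(seq_len(config$nTargets),
                            each = config$trialsPerTarget))
        jit <- stats::rnorm(nTrials, 0, config$durationJitterSD)
        jit <- pmin(pmax(jit, -config$durationJitterMax),
                    config$durationJitterMax)
        list(order = order, durations = config$movementDuration + jit)
    })
    n <- as.integer(round(nTrials * config$interTrial * fs))
    tt <- (0:(n - 1L)) / fs
    pos <- matrix(0, n, 2L)
    vel <- matrix(0, n, 2L)
    reach <- rep(FALSE, n)
    onsets <- (seq_len(nTrials) - 1L) * config$interTrial +
        config$onsetOffset
    ev <- data.frame(onset_s = onsets,
                     target_label = rownames(targets)[drawn$order],
                     target_x = targets[drawn$order, 1L],
                     target_y = targets[drawn$order, 2L],
                     move_start_s = onsets + config$reactionTime,
                     move_mid_s = NA_real_, move_end_s = NA_real_,
                     duration_s = drawn$durations,
                     row.names = NULL)
    L <- sqrt(sum(targets[1L, ]^2))
    for (k in seq_len(nTrials)) {
        tgt <- targets[drawn$order[k], ]
        d <- drawn$durations[k]
        t0 <- ev$move_start_s[k]
        ev$move_mid_s[k] <- t0 + d
        ev$move_end_s[k] <- if (config$outboundOnly) t0 + d else t0 + 2 * d
        peak <- 1.875 * L / d
        ## outbound
        idx <- which(tt >= t0 & tt <= t0 + d)
        sh <- .mjShape((tt[idx] - t0) / d)
        pos[idx, ] <- outer(sh$s, tgt)
        vel[idx, ] <- outer(sh$ds / d, tgt)
        if (config$outboundOnly) {
            hold <- which(tt > t0 + d)
            hold <- hold[tt[hold] < onsets[k] + config$interTrial]
            pos[hold, 1L] <- tgt[1L]; pos[hold, 2L] <- tgt[2L]
        } else {
            idx2 <- which(tt > t0 + d & tt <= t0 + 2 * d)
            sh2 <- .mjShape((tt[idx2] - t0 - d) / d)
            pos[idx2, ] <- outer(1 - sh2$s, tgt)
            vel[idx2, ] <- outer(-sh2$ds / d, tgt)
        }
        win <- which(tt >= t0 & tt <= ev$move_end_s[k])
        spdWin <- sqrt(rowSums(vel[win, , drop = FALSE]^2))
        reach[win] <- spdWin > 0.05 * peak
    }
    kin <- TrajectorySeries(times = tt, position = pos, velocity = vel,
                            sampleRate = fs)
    new("CenterOutSession", kinematics = kin, events = ev,
        reachMask = reach, config = unclass(config))
}

#' Encode kinematics into a surrogate multichannel neural recording
#'
#' Produces the surrogate neural signals the decoders are benchmarked on.
#' Channel i carries a lagged linear velocity code plus, on a random subset
#' of channels, a sigmoidal speed tuning:
#' \deqn{z_i(t) = g_i \cdot v(t - l_i) +
#'   h_i \, \sigma((s(t - l_i) - \theta) / \kappa) + n_i(t),}
#' with \eqn{g_i} the 2-D linear gain, \eqn{l_i} the channel's encoding lag
#' (samples), \eqn{h_i} the nonlinear gain (zero outside the tuned subset)
#' and \eqn{n_i} Gaussian noise band-limited to the configured band.  The
#' sigmoidal term is what gives the nonlinear speed read-out something a
#' purely linear decoder cannot capture.
#'
#' The encoding draws (gains, lags, tuned subset, noise) are seeded at
#' \code{seed = config$seed + 1} by default, a stream distinct from the
#' kinematic draws of [genSession()].
#'
#' @param session a [CenterOutSession-class], or a
#'   [TrajectorySeries-class] at the configured rate.
#' @param config a [syntheticConfig()] list; defaults to the session's own.
#' @param seed RNG seed for the encoding draws.
#' @return A [NeuralRecording-class] with `config$nChannels` channels at
#'   the kinematic sampling rate.
#' @export
encodeNeural <- function(session, config = NULL, seed = NULL) {
    if (is(session, "CenterOutSession")) {
        if (is.null(config)) config <- session@config
        kin <- session@kinematics
    } else {
        stopifnot(is(session, "TrajectorySeries"))
        if (is.null(config)) stop("'config' is required for bare kinematics")
        kin <- session
    }
    if (is.null(seed)) seed <- config$seed + 1L
    fs <- kin@sampleRate
    v <- kin@velocity
    n <- nrow(v)
    spd <- sqrt(rowSums(v^2))
    nCh <- config$nChannels
    lagMax <- max(config$lagRange)
    if (lagMax >= n) stop("encoding lag exceeds the series length")
    pars <- withSeed(seed, {
        list(G = matrix(stats::rnorm(nCh * 2L, 0, config$linearGainSD),
                        nCh, 2L),
             lags = sample(seq(config$lagRange[1L], config$lagRange[2L]),
                           nCh, replace = TRUE),
             tuned = sample(nCh, ceiling(config$nonlinearFraction * nCh)),
             noise = matrix(stats::rnorm(nCh * n), nCh, n))
    })
    h <- numeric(nCh)
    h[pars$tuned] <- withSeed(seed + 1L,
        stats::rnorm(length(pars$tuned), 0, config$nonlinearGainSD))
    sig <- stats::plogis((spd - config$sigmoidThreshold) /
                         config$sigmoidWidth)
    z <- matrix(0, nCh, n)
    idxAll <- seq_len(n)
    for (i in seq_len(nCh)) {
        src <- pmax(idxAll - pars$lags[i], 1L)
        z[i, ] <- v[src, 1L] * pars$G[i, 1L] + v[src, 2L] * pars$G[i, 2L] +
            h[i] * sig[src]
    }
    if (config$noiseSD > 0) {
        noise <- pars$noise
        if (identical(config$noiseSpectrum, "pink")) {
            ## impose 1/f power inside the band (amplitude 1/sqrt(f)),
            ## flattening below the band edge to avoid the DC pole
            freq <- fs * (0:(n - 1)) / n
            freq <- pmin(freq, fs - freq)
            amp <- 1 / sqrt(pmax(freq, config$noiseBand[1L]))
            noise <- t(apply(noise, 1L, function(row)
                Re(stats::fft(stats::fft(row) * amp, inverse = TRUE)) / n))
        }
        noise <- .bandpassMatrix(noise, fs, config$noiseBand[1L],
                                 config$noiseBand[2L])
        sds <- apply(noise, 1L, stats::sd)
        noise <- noise / sds * config$noiseSD
        z <- z + noise
    }
    NeuralRecording(z, fs, sprintf("MEG%03d", seq_len(nCh)))
}
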