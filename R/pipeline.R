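#' Integrate decoded velocity into position
#'
#' Cumulative trapezoidal integration of a 2-D velocity series with a given
#' initial position, the step needed to score position error from decoded
#' velocity.
#'
#' @param velocity samples x 2 velocity matrix.
#' @param sampleRate sampling rate in Hz.
#' @param start initial 2-D position (default the origin).
#' @return samples x 2 position matrix.
#' @export
integratePositions <- function(velocity, sampleRate, start = c(0, 0)) {
    v <- .asMatrix2(velocity, "velocity")
    dt <- 1 / sampleRate
    p <- apply(v, 2L, function(col) pracma::cumtrapz(col)[, 1L] * dt)
    p <- matrix(p, nrow = nrow(v))
    sweep(p, 2L, as.numeric(start), "+")
}

## Split a sorted index vector into contiguous runs (list of integer
## vectors).
.contigRuns <- function(idx) {
    if (!length(idx)) return(list())
    unname(split(idx, cumsum(c(1L, diff(idx) != 1L))))
}

## Stratified trial-wise fold assignment: within each target the trials are
## shuffled and dealt into k folds.
.assignFolds <- function(labels, k, seed) {
    folds <- integer(length(labels))
    withSeed(seed, {
        for (lab in unique(labels)) {
            ids <- sample(which(labels == lab))
            folds[ids] <- rep(seq_len(k), length.out = length(ids))
        }
    })
    folds
}

#' Cross-validated decoder benchmark on a center-out session
#'
#' End-to-end comparison of the three decoders (lagged linear filter,
#' velocity-state Kalman filter, hybrid speed--direction Kalman filter,
#' plus the hybrid's no-network ablation read-out) under two movement-state
#' regimes:
#' \describe{
#'   \item{reach_rest}{models are fitted and scored on all samples;}
#'   \item{reach_only}{rest samples are excluded from fitting and from
#'     scoring, and decoding restarts at every contiguous reach run.}
#' }
#' Trials are split into k stratified folds (by target); each trial is
#' decoded exactly once, as part of the test fold it belongs to, with the
#' Kalman recursions re-initialized per decoded segment.  Decoded velocity
#' is integrated into position per contiguous decoded run, starting from
#' the true position at the run start.  Per test trial the report records
#' position and speed RMSE over the regime's evaluated samples and the
#' pointing metrics of the decoded outbound path against the trial's task
#' axis.  Decoders are compared by paired t-tests on per-trial RMSE (raw P
#' values, no multiplicity correction).
#'
#' @param config a [syntheticConfig()] list describing the session.
#' @param k number of folds (default 5); every target must keep at least 2
#'   trials per fold.
#' @param lags linear-filter history length m (default 10, i.e. 200 ms at
#'   50 Hz).
#' @param seed benchmark seed (fold shuffling, network initialization);
#'   defaults to `config$seed`.
#' @param regimes subset of `c("reach_rest", "reach_only")`.
#' @param trainOn MLP training-input mode, see [fitHybrid()].
#' @param mlpMaxit scaled-conjugate-gradient iteration cap (default 500).
#' @param session,recording optionally, a pre-generated
#'   [CenterOutSession-class] and matching [NeuralRecording-class] (e.g.
#'   user data); by default both are generated from `config`.
#' @return A [BenchmarkReport-class].
#' @export
runBenchmark <- function(config = syntheticConfig(), k = 5L, lags = 10L,
                         seed = NULL,
                         regimes = c("reach_rest", "reach_only"),
                         trainOn = "posterior", mlpMaxit = 500L,
                         session = NULL, recording = NULL) {
    regimes <- match.arg(regimes, several.ok = TRUE)
    if (is.null(session)) session <- genSession(config)
    if (is.null(recording)) recording <- encodeNeural(session)
    if (is.null(seed)) seed <- session@config$seed
    seed <- as.integer(seed)
    cfg <- session@config
    fs <- sampleRate(session)
    n <- length(times(session))
    ev <- session@events
    nTrials <- nrow(ev)
    perTrialTarget <- table(ev$target_label)
    if (any(perTrialTarget / k < 2))
        stop("fewer than 2 trials per target per fold; reduce k or add trials")
    segLen <- as.integer(round(cfg$interTrial * fs))
    if (nTrials * segLen != n)
        stop("session length inconsistent with the trial grid")
    trialOf <- rep(seq_len(nTrials), each = segLen)
    v <- session@kinematics@velocity
    posTrue <- session@kinematics@position
    spdTrue <- sqrt(rowSums(v^2))
    reach <- session@reachMask
    obs <- t(recording@data)
    design <- buildLaggedDesign(recording, lags)
    folds <- .assignFolds(ev$target_label, k, seed)
    tt <- times(session)

    perTrial <- list()
    for (regime in regimes) {
        evalMask <- if (regime == "reach_only") reach else rep(TRUE, n)
        ## per-decoder session-length containers
        dec <- c("linear", "kalman", "hybrid", "hybridAblation")
        vhat <- lapply(dec, function(d) matrix(NA_real_, n, 2L))
        names(vhat) <- dec
        shat <- lapply(dec, function(d) rep(NA_real_, n))
        names(shat) <- dec
        phat <- lapply(dec, function(d) matrix(NA_real_, n, 2L))
        names(phat) <- dec
        for (f in seq_len(k)) {
            trainRows <- which(trialOf %in% which(folds != f) & evalMask)
            grp <- cumsum(c(1L, diff(trainRows) != 1L))
            lf <- fitLinearFilter(design, v, rows = trainRows)
            km <- fitKalman(v[trainRows, , drop = FALSE],
                            obs[trainRows, , drop = FALSE], groups = grp)
            hm <- fitHybrid(v[trainRows, , drop = FALSE],
                            obs[trainRows, , drop = FALSE],
                            seed = seed + f, trainOn = trainOn,
                            maxit = mlpMaxit, groups = grp)
            lfPred <- predictLinearFilter(lf, design)
            testRows <- which(trialOf %in% which(folds == f) & evalMask)
            for (seg in .contigRuns(testRows)) {
                vhat$linear[seg, ] <- lfPred[seg, ]
                kfSeq <- kalmanDecode(km, obs[seg, , drop = FALSE])
                vhat$kalman[seg, ] <- kfSeq@states
                hd <- hybridDecode(hm, obs[seg, , drop = FALSE])
                vhat$hybrid[seg, ] <- hd$velocity
                shat$hybrid[seg] <- hd$speed
                abSpd <- hd$states@states[, 1L]
                shat$hybridAblation[seg] <- abSpd
                vhat$hybridAblation[seg, ] <- hd$direction * abSpd
            }
        }
        for (d in dec) {
            if (d %in% c("linear", "kalman"))
                shat[[d]] <- sqrt(rowSums(vhat[[d]]^2))
            ## integrate decoded velocity into position trial-wise, one
            ## contiguous decoded run at a time, starting each run from
            ## the true position at its first sample
            for (trial in seq_len(nTrials)) {
                rows <- which(trialOf == trial)
                good <- rows[stats::complete.cases(vhat[[d]][rows, ,
                                                             drop = FALSE])]
                for (run in .contigRuns(good))
                    phat[[d]][run, ] <- integratePositions(
                        vhat[[d]][run, , drop = FALSE], fs,
                        start = posTrue[run[1L], ])
            }
        }
        for (trial in seq_len(nTrials)) {
            rows <- which(trialOf == trial & evalMask)
            outb <- which(tt >= ev$move_start_s[trial] &
                          tt <= ev$move_mid_s[trial])
            tgt <- c(ev$target_x[trial], ev$target_y[trial])
            for (d in dec) {
                ok <- rows[stats::complete.cases(vhat[[d]][rows, ,
                                                           drop = FALSE])]
                if (length(ok) < 3L) next
                pm <- {
                    ob <- outb[stats::complete.cases(phat[[d]][outb, ,
                                                               drop = FALSE])]
                    if (length(ob) >= 3L)
                        pointingMetrics(phat[[d]][ob, , drop = FALSE],
                                        c(0, 0), tgt)
                    else data.frame(odc = NA, mdc = NA, me = NA, mv = NA)
                }
                perTrial[[length(perTrial) + 1L]] <- data.frame(
                    decoder = d, regime = regime, trial = trial,
                    target = ev$target_label[trial],
                    fold = folds[trial],
                    rmse_pos = rmse(posTrue[ok, ], phat[[d]][ok, ]),
                    rmse_speed = rmse(spdTrue[ok], shat[[d]][ok]),
                    pm)
            }
        }
    }
    perTrial <- do.call(rbind, perTrial)

    metricCols <- c("rmse_pos", "rmse_speed", "odc", "mdc", "me", "mv")
    summary <- do.call(rbind, lapply(split(
        perTrial, list(perTrial$decoder, perTrial$regime), drop = TRUE),
        function(g) {
            s <- summarizeTrials(g[metricCols])
            data.frame(decoder = g$decoder[1L], regime = g$regime[1L],
                       metric = s$metric, mean = s$mean, sem = s$sem,
                       n = s$n)
        }))
    rownames(summary) <- NULL

    pairs <- list(c("hybrid", "kalman"), c("hybrid", "linear"),
                  c("kalman", "linear"), c("hybrid", "hybridAblation"))
    comparisons <- list()
    for (regime in regimes) {
        for (pr in pairs) {
            for (mc in c("rmse_pos", "rmse_speed")) {
                a <- perTrial[perTrial$decoder == pr[1L] &
                              perTrial$regime == regime, ]
                b <- perTrial[perTrial$decoder == pr[2L] &
                              perTrial$regime == regime, ]
                shared <- intersect(a$trial, b$trial)
                if (length(shared) < 3L) next
                x <- a[[mc]][match(shared, a$trial)]
                y <- b[[mc]][match(shared, b$trial)]
                tst <- stats::t.test(x, y, paired = TRUE)
                comparisons[[length(comparisons) + 1L]] <- data.frame(
                    regime = regime, metric = mc,
                    decoderA = pr[1L], decoderB = pr[2L],
                    meanDiff = mean(x - y), t = unname(tst$statistic),
                    p = tst$p.value, n = length(shared))
            }
        }
    }
    comparisons <- do.call(rbind, comparisons)

    new("BenchmarkReport", summary = summary, perTrial = perTrial,
        comparisons = comparisons, config = unclass(cfg), seed = seed,
        folds = folds)
}
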