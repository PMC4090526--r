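test_that("minimum-jerk reaches have the quintic's closed-form properties", {
    fs <- 50
    mj <- minimumJerkReach(c(0, 0), c(2, 1), 1.0, fs)  # grid hits midpoint
    pos <- position(mj)
    expect_equal(pos[1, ], c(0, 0))
    expect_equal(pos[nrow(pos), ], c(2, 1))
    spd <- sqrt(rowSums(velocity(mj)^2))
    L <- sqrt(5)
    ## calculus oracle: peak speed 1.875 L / T at tau = 1/2
    expect_equal(max(spd), 1.875 * L / 1.0, tolerance = 1e-9)
    expect_equal(which.max(spd), 26L)
    ## symmetric speed profile, zero at both ends
    expect_lt(max(abs(spd - rev(spd))), 1e-9)
    expect_equal(spd[1], 0)
    ## velocity is the derivative of position (central differences)
    v <- velocity(mj)
    num <- (pos[3:51, ] - pos[1:49, ]) * fs / 2
    expect_lt(max(abs(num - v[2:50, ])), 2e-2)
})

test_that("sessions have the configured trial structure", {
    ses <- genSession(syntheticConfig(seed = 1))
    ev <- trialEvents(ses)
    expect_equal(nrow(ev), 120L)
    expect_true(all(table(ev$target_label) == 30))
    ## total session length within one sample of trials x spacing
    expect_equal(length(times(ses)), 120L * 4L * 50L)
    ## determinism and seed sensitivity
    ses2 <- genSession(syntheticConfig(seed = 1))
    expect_identical(position(ses@kinematics), position(ses2@kinematics))
    expect_identical(trialEvents(ses), trialEvents(ses2))
    ses3 <- genSession(syntheticConfig(seed = 2))
    expect_false(identical(ev$target_label,
                           trialEvents(ses3)$target_label))
    ## movements fit between onsets
    expect_true(all(ev$move_end_s < ev$onset_s + 4))
})

test_that("ground-truth masks agree with speed-threshold labeling", {
    ses <- genSession(syntheticConfig(seed = 3))
    spd <- sqrt(rowSums(velocity(ses@kinematics)^2))
    lab <- labelStates(spd, sampleRate(ses))
    expect_gte(mean(lab == reachMask(ses)), 0.95)
    ## speed is nonnegative and zero at rest
    expect_true(all(spd >= 0))
    expect_true(all(spd[!reachMask(ses)] < 0.2 * max(spd)))
})

test_that("encoded recordings are band-limited and deterministic", {
    cfg <- smallConfig(seed = 6)
    ses <- genSession(cfg)
    rec <- encodeNeural(ses)
    expect_equal(nChannels(rec), 12L)
    expect_equal(nSamples(rec), length(times(ses)))
    ## spectral power above 8 Hz below 5% of the total
    for (ch in 1:3) {
        x <- recordingData(rec)[ch, ]
        pw <- Mod(fft(x - mean(x)))^2
        freq <- (seq_along(pw) - 1) * sampleRate(ses) / length(pw)
        half <- freq <= sampleRate(ses) / 2
        hi <- sum(pw[half & freq > 8]) / sum(pw[half])
        expect_lt(hi, 0.05)
    }
    expect_identical(recordingData(rec),
                     recordingData(encodeNeural(ses)))
})

test_that("noiseless linear encoding is exactly invertible by the linear filter", {
    cfg <- smallConfig(seed = 7, noiseSD = 0, nonlinearFraction = 0,
                       nChannels = 10, lagRange = c(0L, 2L))
    ses <- genSession(cfg)
    rec <- encodeNeural(ses)
    v <- velocity(ses@kinematics)
    d <- buildLaggedDesign(rec, 10)
    fit <- suppressWarnings(fitLinearFilter(d, v))  # collinear by design
    pred <- predictLinearFilter(fit, d)
    ok <- validRows(d)
    expect_lt(rmse(v[ok, ], pred[ok, ]), 1e-6)
})

test_that("pure-noise channels carry no decodable information", {
    cfg <- smallConfig(seed = 8, linearGainSD = 0, nonlinearFraction = 0,
                       noiseSD = 1, nChannels = 8)
    ses <- genSession(cfg)
    rec <- encodeNeural(ses)
    v <- velocity(ses@kinematics)
    n <- nrow(v)
    half <- seq_len(n %/% 2)
    d <- buildLaggedDesign(rec, 10)
    fit <- fitLinearFilter(d, v, rows = half)
    pred <- predictLinearFilter(fit, d)
    test <- (n %/% 2 + 1):n
    base <- matrix(colMeans(v[half, ]), length(test), 2, byrow = TRUE)
    expect_lt(abs(rmse(v[test, ], pred[test, ]) /
                  rmse(v[test, ], base) - 1), 0.1)
})

test_that("outbound-only sessions rest at the target between trials", {
    cfg <- smallConfig(seed = 9, outboundOnly = TRUE)
    ses <- genSession(cfg)
    ev <- trialEvents(ses)
    i <- as.integer(round((ev$move_end_s[1] + 0.5) * 50)) + 1L
    expect_equal(position(ses@kinematics)[i, ],
                 c(ev$target_x[1], ev$target_y[1]), ignore_attr = TRUE)
    expect_equal(ev$move_end_s, ev$move_mid_s)
})

test_that("invalid configurations are rejected", {
    expect_error(syntheticConfig(movementDuration = 2.5), "fit inside")
    expect_error(syntheticConfig(trialsPerTarget = 0))
})
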