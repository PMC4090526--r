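test_that("band-pass keeps in-band tones and rejects DC and out-of-band", {
    fs <- 600
    tt <- seq(0, 10, by = 1 / fs)
    mid <- 2000:4000                      # away from filter edges
    inband <- bandpassFilter(sin(2 * pi * 4 * tt), 0.5, 8, sampleRate = fs)
    expect_lt(abs(max(abs(inband[mid])) - 1), 0.05)
    out <- bandpassFilter(sin(2 * pi * 30 * tt), 0.5, 8, sampleRate = fs)
    expect_lt(max(abs(out[mid])), 0.1)    # > 90% attenuation
    dc <- bandpassFilter(rep(10, length(tt)), 0.5, 8, sampleRate = fs)
    expect_lt(mean(abs(dc[mid])), 0.1)
    expect_error(bandpassFilter(rep(0, 100), 8, 0.5, sampleRate = fs))
    expect_error(bandpassFilter(rep(0, 100), 0.5, 400, sampleRate = fs))
})

test_that("downsampling slices integer ratios and matches closed forms", {
    fs <- 600
    rec <- NeuralRecording(matrix(sin(2 * pi * 2 * (0:599) / fs), 1), fs)
    down <- downsampleRecording(rec, 50)
    expect_equal(sampleRate(down), 50)
    expect_equal(nSamples(down), 50)
    ## coarse-grid closed form
    expect_lt(max(abs(recordingData(down)[1, ] -
                      sin(2 * pi * 2 * (0:49) / 50))), 1e-2)
    ## constant stays constant
    recC <- NeuralRecording(matrix(5, 2, 120), 600)
    expect_true(all(recordingData(downsampleRecording(recC, 50)) == 5))
    expect_error(downsampleRecording(rec, 600), "below")
})

test_that("filtering then downsampling agrees with downsampling a band-limited signal", {
    ## commutation holds up to the Butterworth passband ripple (~1%)
    fs <- 600
    tt <- seq(0, 10, by = 1 / fs)
    x <- sin(2 * pi * 2 * tt) + 0.5 * sin(2 * pi * 3 * tt)
    rec <- NeuralRecording(matrix(x, 1), fs)
    a <- recordingData(downsampleRecording(
        bandpassFilter(rec, 0.5, 8), 50))[1, ]
    b <- recordingData(downsampleRecording(rec, 50))[1, ]
    interior <- 100:400
    expect_lt(max(abs(a[interior] - b[interior])), 0.02 * max(abs(x)))
})

test_that("epoching cuts exact windows and drops out-of-range onsets", {
    fs <- 50
    z <- matrix(rnorm(2 * 500), 2, 500)   # 10 s recording
    rec <- NeuralRecording(z, fs)
    es <- epochRecording(rec, onsets = 5, tMin = -1, tMax = 2)
    expect_equal(dim(epochs(es)), c(1L, 2L, 151L))
    ## values are bit-identical slices of the source
    expect_identical(epochs(es)[1, , ], z[, 201:351])
    ## empty onset list
    expect_equal(dim(epochs(epochRecording(rec, numeric(0))))[1], 0L)
    ## boundary onset dropped with warning and counted
    expect_warning(es2 <- epochRecording(rec, c(0.5, 5)), "dropped 1")
    expect_equal(es2@dropped, 1L)
    expect_equal(dim(epochs(es2))[1], 1L)
})

test_that("lagged design matches a brute-force constructor", {
    fs <- 50
    ## column count: n * (m + 1) + 1
    rec2 <- NeuralRecording(matrix(rnorm(2 * 40), 2, 40), fs)
    expect_equal(ncol(designMatrix(buildLaggedDesign(rec2, 10))), 23L)
    ## m = 0: channels plus bias
    d0 <- buildLaggedDesign(rec2, 0)
    expect_equal(designMatrix(d0)[, 1:2], t(recordingData(rec2)),
                 ignore_attr = TRUE)
    expect_true(all(designMatrix(d0)[, 3] == 1))
    ## brute-force double loop on random 5 x 30 input
    z <- matrix(rnorm(150), 5, 30)
    m <- 3L
    d <- buildLaggedDesign(NeuralRecording(z, fs), m)
    X <- designMatrix(d)
    for (t in (m + 1):30) {
        for (i in 1:5) {
            for (j in 0:m) {
                expect_identical(unname(X[t, (i - 1) * (m + 1) + j + 1]),
                                 z[i, t - j])
            }
        }
        expect_identical(unname(X[t, ncol(X)]), 1)
    }
    expect_equal(validRows(d), seq_len(30) > m)
    ## full-rank random input gives a full-rank valid design
    expect_equal(qr(X[validRows(d), ])$rank, min(30 - m, ncol(X)))
})

test_that("speed thresholding labels reach and rest states", {
    fs <- 50
    expect_false(any(labelStates(rep(0, 100), fs)))
    expect_true(all(labelStates(rep(2, 100), fs)))
    ## single bell-shaped reach padded by rest: labeled reach covers the
    ## ground-truth movement interval (speed above 5% of peak)
    mj <- minimumJerkReach(c(0, 0), c(1, 1), 0.9, fs)
    spd <- sqrt(rowSums(velocity(mj)^2))
    session <- c(rep(0, 100), spd, rep(0, 100))
    truth <- c(rep(FALSE, 100), spd > 0.05 * max(spd), rep(FALSE, 100))
    lab <- labelStates(session, fs, thresholdFrac = 0.05,
                       minDurationS = 0.1)
    expect_gte(sum(lab & truth) / sum(truth), 0.9)
    ## brief dips below threshold do not fragment a movement
    dip <- c(rep(0, 50), rep(1, 30), rep(0.001, 2), rep(1, 30), rep(0, 50))
    labDip <- labelStates(dip, fs)
    expect_true(all(labDip[51:112]))
})

test_that("event-based labeling marks the configured movement windows", {
    lab <- labelStatesFromEvents(100, 50, moveStart = 0.5, moveEnd = 1.0)
    expect_equal(which(lab), 26:51)
})

test_that("channel subsetting reorders by label", {
    rec <- NeuralRecording(rbind(1:5, 6:10, 11:15), 50,
                           c("a", "b", "c"))
    sub <- selectChannels(rec, c("c", "a"))
    expect_equal(channelLabels(sub), c("c", "a"))
    expect_equal(recordingData(sub)[1, ], 11:15, ignore_attr = TRUE)
    expect_error(selectChannels(rec, "z"), "unknown")
})
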