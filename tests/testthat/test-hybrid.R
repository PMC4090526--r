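test_that("hybrid state sequence stacks speed lags and direction", {
    ## constant velocity (1, 0)
    hs <- buildHybridStates(matrix(rep(c(1, 0), each = 5), 5, 2))
    expect_true(all(apply(hs$states, 1, function(r)
        all(r == c(1, 1, 1, 1, 0)))))
    ## lag bookkeeping on a speed ramp 0, 1, 2, 3
    v <- cbind(c(0, 1, 2, 3), 0)
    hs2 <- buildHybridStates(v)
    expect_equal(as.numeric(hs2$states[4, 1:3]), c(3, 2, 1))
    expect_equal(hs2$valid, c(FALSE, FALSE, TRUE, TRUE))
    ## shift oracle on a random series
    set.seed(31)
    vr <- matrix(rnorm(100), 50, 2)
    hsr <- buildHybridStates(vr)
    expect_identical(hsr$states[2:50, "r_t1"], hsr$states[1:49, "r_t"],
                     ignore_attr = TRUE)
    expect_identical(hsr$states[3:50, "r_t2"], hsr$states[1:48, "r_t"],
                     ignore_attr = TRUE)
    ## direction rows are unit norm
    expect_lt(max(abs(sqrt(rowSums(hsr$states[, 4:5]^2)) - 1)), 1e-9)
})

test_that("the network can represent a constant and is deterministic", {
    set.seed(32)
    X <- matrix(runif(300), 100, 3)
    ## constant target at half the (explicit) scale
    mlp <- trainSpeedMLP(X, rep(0.5, 100), speedScale = 1, seed = 2)
    expect_lt(max(abs(mlpForward(mlp, X) - 0.5)), 0.01)
    ## zero-variance targets need the explicit scale
    expect_error(trainSpeedMLP(X, rep(0.5, 100)), "zero-variance")
    ## determinism: same seed and data give identical weights
    a <- trainSpeedMLP(X, X[, 1], seed = 7)
    b <- trainSpeedMLP(X, X[, 1], seed = 7)
    expect_identical(a@W1, b@W1)
    expect_identical(a@b2, b@b2)
    ## structural contract: no direction inputs
    expect_error(trainSpeedMLP(cbind(X, 1), rep(1, 100)), "3 columns")
    ## training loss is non-increasing over accepted steps
    expect_true(all(diff(a@lossTrace) <= 1e-12))
})

test_that("forward pass is bounded and matches explicit arithmetic", {
    set.seed(33)
    mlp <- new("MLPSpeedFilter", W1 = matrix(rnorm(54), 18, 3),
               b1 = rnorm(18), w2 = rnorm(18), b2 = rnorm(1),
               speedScale = 2.5, seed = 1L, lossTrace = numeric(0))
    X <- matrix(rnorm(30), 10, 3)
    out <- mlpForward(mlp, X)
    expect_true(all(out > 0 & out < 2.5))
    ## independent per-unit arithmetic oracle
    for (r in 1:10) {
        h <- numeric(18)
        for (u in 1:18)
            h[u] <- tanh(sum(mlp@W1[u, ] * X[r, ] / 2.5) + mlp@b1[u])
        y <- 1 / (1 + exp(-(sum(h * mlp@w2) + mlp@b2)))
        expect_equal(out[r], y * 2.5, tolerance = 1e-12)
    }
    ## all-zero weights give the sigmoid midpoint
    mlp0 <- new("MLPSpeedFilter", W1 = matrix(0, 18, 3), b1 = rep(0, 18),
                w2 = rep(0, 18), b2 = 0, speedScale = 2, seed = 1L,
                lossTrace = numeric(0))
    expect_equal(as.numeric(mlpForward(mlp0, c(1, 1, 1))), 1)
})

test_that("the network fits posterior speed states better than a linear map", {
    cfg <- smallConfig(seed = 4)
    ses <- genSession(cfg)
    rec <- encodeNeural(ses)
    v <- velocity(ses@kinematics)
    obs <- t(recordingData(rec))
    hs <- buildHybridStates(v)
    km <- fitKalman(hs$states, obs)
    post <- states(kalmanDecode(km, obs))[, 1:3]
    mlp <- trainSpeedMLP(post, hs$speed, seed = 1,
                         speedScale = max(hs$speed))
    mseMLP <- mean((mlpForward(mlp, post) - hs$speed)^2)
    lin <- lm.fit(cbind(1, post), hs$speed)
    mseLin <- mean(lin$residuals^2)
    expect_lt(mseMLP, mseLin)
})

test_that("hybrid fitting recovers a noiseless observation map", {
    ## varied directions and speeds so the 5-dim state has full rank
    fs <- 50
    r1 <- minimumJerkReach(c(0, 0), c(1, 1), 0.9, fs)
    r2 <- minimumJerkReach(c(0, 0), c(1, -0.5), 0.7, fs)
    r3 <- minimumJerkReach(c(0, 0), c(-1, 0.3), 0.8, fs)
    v <- rbind(velocity(r1), velocity(r2), velocity(r3))
    hs <- buildHybridStates(v)
    set.seed(34)
    H <- matrix(rnorm(8 * 5), 8, 5)
    z <- hs$states %*% t(H)
    hm <- fitHybrid(v, z, seed = 1, maxit = 50)
    expect_lt(max(abs(observationMatrix(hm@kalman) - H)), 1e-6)
    expect_equal(stateDim(hm@kalman), 5L)
    ## refitting with the same seed gives identical artifacts
    hm2 <- fitHybrid(v, z, seed = 1, maxit = 50)
    expect_identical(hm@mlp@W1, hm2@mlp@W1)
    expect_identical(hm@kalman@A, hm2@kalman@A)
})

test_that("hybrid decoding honors the speed and direction contracts", {
    cfg <- smallConfig(seed = 5)
    ses <- genSession(cfg)
    rec <- encodeNeural(ses)
    v <- velocity(ses@kinematics)
    obs <- t(recordingData(rec))
    hm <- fitHybrid(v, obs, seed = 1, maxit = 150)
    hd <- hybridDecode(hm, obs)
    ## direction unit norm at every emitted sample
    expect_lt(max(abs(sqrt(rowSums(hd$direction^2)) - 1)), 1e-9)
    ## speed strictly inside (0, speedScale)
    expect_true(all(hd$speed > 0))
    expect_true(all(hd$speed <= speedScale(hm@mlp)))
    ## velocity is the product of the two read-outs
    expect_equal(hd$velocity, hd$direction * hd$speed)
    ## ablation shares the identical Kalman posterior
    ha <- hybridDecode(hm, obs, ablation = TRUE)
    expect_identical(states(hd$states), states(ha$states))
    expect_equal(ha$speed, states(ha$states)[, 1], ignore_attr = TRUE)
    ## decoding is deterministic
    hd2 <- hybridDecode(hm, obs)
    expect_identical(hd$velocity, hd2$velocity)
})

test_that("without nonlinearity the raw posterior read-out is competitive", {
    ## speed following exact linear (AR) dynamics: a sinusoid plus offset;
    ## trained by teacher forcing, the network's only possible edge is
    ## nonlinearity, so the ablation must come within 10%
    set.seed(42)
    fs <- 50
    tt <- seq(0, 120, by = 1 / fs)
    n <- length(tt)
    spd <- 1.2 + sin(2 * pi * 0.8 * tt)
    ang <- 2 * pi * 0.05 * tt
    v <- cbind(spd * cos(ang), spd * sin(ang))
    hs <- buildHybridStates(v)
    H <- matrix(rnorm(20 * 5), 20, 5)
    z <- hs$states %*% t(H) + matrix(rnorm(n * 20, 0, 0.5), n, 20)
    hm <- fitHybrid(v, z, seed = 1, trainOn = "true")
    hd <- hybridDecode(hm, z)
    rFull <- rmse(spd, hd$speed)
    rAbl <- rmse(spd, states(hd$states)[, 1])
    expect_lt(rAbl, 1.10 * rFull)
})
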