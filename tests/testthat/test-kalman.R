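test_that("least squares recovers noiseless system and observation models", {
    set.seed(21)
    d <- 3
    A <- matrix(rnorm(d * d, 0, 0.4), d, d)
    x <- matrix(0, 200, d)
    x[1, ] <- rnorm(d)
    for (t in 2:200) x[t, ] <- A %*% x[t - 1, ]
    H <- matrix(rnorm(6 * d), 6, d)
    z <- x %*% t(H)
    fit <- fitKalman(x, z)
    expect_lt(max(abs(transitionMatrix(fit) - A)), 1e-8)
    expect_lt(max(abs(systemNoise(fit))), 1e-10)
    expect_lt(max(abs(observationMatrix(fit) - H)), 1e-8)
    expect_lt(max(abs(observationNoise(fit))), 1e-10)
    expect_equal(fit@initialState, colMeans(x))
})

test_that("white-noise states have a near-zero transition estimate", {
    set.seed(22)
    n <- 2000
    x <- matrix(rnorm(n), n, 1)
    fit <- fitKalman(x, x + rnorm(n))
    expect_lt(abs(transitionMatrix(fit)[1, 1]), 3 / sqrt(n))
})

test_that("group boundaries are excluded from the transition fit", {
    ## two segments with opposite deterministic dynamics at the boundary
    x1 <- matrix(2^(0:10), ncol = 1)          # x(t) = 2 x(t-1)
    x <- rbind(x1, x1)
    g <- rep(1:2, each = 11)
    fit <- fitKalman(x, cbind(x), groups = g)
    expect_equal(transitionMatrix(fit)[1, 1], 2, tolerance = 1e-10)
})

test_that("noiseless identity model reproduces constant observations", {
    m <- KalmanModel(A = 1, W = 0, H = 1, Q = 0, initialState = 0,
                     initialCovariance = 1)
    z <- matrix(3.5, 10, 1)
    out <- states(kalmanDecode(m, z))
    expect_equal(as.numeric(out), rep(3.5, 10), tolerance = 1e-9)
})

test_that("two-step recursion matches the hand-computed oracle", {
    ## scalar A=1, W=0.01, H=1, Q=1, x0=0, P0=1, z=(1, 1): the oracle is
    ## the closed-form gain/update arithmetic written out explicitly
    P <- 1; x <- 0
    oracle <- numeric(2)
    for (t in 1:2) {
        Pp <- P + 0.01
        K <- Pp / (Pp + 1)
        x <- x + K * (1 - x)
        P <- (1 - K) * Pp
        oracle[t] <- x
    }
    m <- KalmanModel(A = 1, W = 0.01, H = 1, Q = 1, initialState = 0,
                     initialCovariance = 1)
    out <- states(kalmanDecode(m, matrix(1, 2, 1)))
    expect_equal(as.numeric(out), oracle, tolerance = 1e-12)
})

test_that("one-step decode equals the closed-form Kalman gain formula", {
    set.seed(23)
    for (i in 1:5) {
        d <- 2; c <- 4
        A <- matrix(rnorm(d * d, 0, 0.3), d, d)
        W <- crossprod(matrix(rnorm(d * d), d, d)) / d
        H <- matrix(rnorm(c * d), c, d)
        Q <- crossprod(matrix(rnorm(c * c), c, c)) / c
        x0 <- rnorm(d); P0 <- crossprod(matrix(rnorm(d * d), d, d))
        z <- rnorm(c)
        m <- KalmanModel(A, W, H, Q, x0, P0)
        out <- states(kalmanDecode(m, matrix(z, 1)))
        xp <- A %*% x0
        Pp <- A %*% P0 %*% t(A) + W
        K <- Pp %*% t(H) %*% solve(H %*% Pp %*% t(H) + Q)
        expect_equal(as.numeric(out),
                     as.numeric(xp + K %*% (z - H %*% xp)),
                     tolerance = 1e-9)
    }
})

test_that("decoding beats per-sample pseudo-inverse inversion", {
    set.seed(24)
    d <- 2; c <- 6; n <- 500
    A <- diag(0.95, d)
    W <- diag(0.01, d)
    H <- matrix(rnorm(c * d), c, d)
    Q <- diag(0.25, c)
    x <- matrix(0, n, d)
    x[1, ] <- rnorm(d)
    for (t in 2:n) x[t, ] <- A %*% x[t - 1, ] + rnorm(d, 0, 0.1)
    z <- x %*% t(H) + matrix(rnorm(n * c, 0, 0.5), n, c)
    m <- KalmanModel(A, W, H, Q, initialState = c(0, 0),
                     initialCovariance = W)
    dec <- states(kalmanDecode(m, z))
    pinv <- z %*% H %*% solve(crossprod(H))   # (H'H)^-1 H' z per sample
    expect_lt(rmse(x, dec), rmse(x, pinv))
})

test_that("noise-scale limits recover prior-only and inversion extremes", {
    set.seed(25)
    d <- 2
    A <- matrix(c(0.9, 0.1, -0.1, 0.8), d, d)
    W <- diag(0.05, d)
    H <- matrix(c(1, 0.3, -0.2, 1.1), d, d)   # invertible
    Q <- diag(0.2, d)
    x0 <- c(1, -1); P0 <- diag(1, d)
    z <- matrix(rnorm(40), 20, d)
    ## Q -> infinity: posterior tends to the prior prediction
    big <- states(kalmanDecode(KalmanModel(A, W, H, Q * 1e6, x0, P0), z))
    prior <- matrix(0, 20, d)
    xx <- x0
    for (t in 1:20) { xx <- A %*% xx; prior[t, ] <- xx }
    expect_lt(max(abs(big - prior)), 1e-3)
    ## Q -> 0: posterior tends to H^-1 z
    small <- states(kalmanDecode(KalmanModel(A, W, H, Q * 1e-6, x0, P0), z))
    inv <- t(solve(H) %*% t(z))
    expect_lt(max(abs(small - inv)), 1e-3)
})

test_that("posterior covariance is PSD and shrinks with added channels", {
    set.seed(26)
    for (i in 1:20) {
        d <- 3; c <- 4
        A <- matrix(rnorm(d * d, 0, 0.3), d, d)
        W <- crossprod(matrix(rnorm(d * d), d, d)) / d
        H <- matrix(rnorm(c * d), c, d)
        Q <- diag(runif(c, 0.1, 1))
        x0 <- rnorm(d); P0 <- crossprod(matrix(rnorm(d * d), d, d))
        z <- matrix(rnorm(3 * c), 3, c)
        m <- kalmanDecode(KalmanModel(A, W, H, Q, x0, P0), z,
                          retainCovariances = TRUE)
        P <- stateCovariances(m)[[3]]
        expect_lt(max(abs(P - t(P))), 1e-10)
        expect_gte(min(eigen(P, only.values = TRUE)$values), -1e-10)
        ## augment with one extra channel: trace never increases
        H2 <- rbind(H, rnorm(d))
        Q2 <- diag(c(diag(Q), 0.5))
        z2 <- cbind(z, rnorm(3))
        m2 <- kalmanDecode(KalmanModel(A, W, H2, Q2, x0, P0), z2,
                           retainCovariances = TRUE)
        expect_lte(sum(diag(stateCovariances(m2)[[3]])),
                   sum(diag(P)) + 1e-10)
    }
})
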