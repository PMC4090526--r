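test_that("acceleration integrates to velocity with a trapezoidal rule", {
    fs <- 50
    ## constant acceleration: v = a * t
    v <- integrateAcceleration(cbind(rep(1, fs + 1), 0), fs)
    expect_equal(v[fs + 1, 1], 1, tolerance = 1 / fs)
    expect_equal(v[1, ], c(0, 0))
    ## zero in, zero out
    expect_equal(integrateAcceleration(matrix(0, 20, 2), fs),
                 matrix(0, 20, 2))
    ## closed-form oracle: d/dt sin(2*pi*t)/(2*pi) = cos(2*pi*t)
    tt <- seq(0, 1, by = 1 / fs)
    v <- integrateAcceleration(cbind(cos(2 * pi * tt), 0), fs)
    expect_lt(max(abs(v[, 1] - sin(2 * pi * tt) / (2 * pi))), 1e-3)
})

test_that("integration is linear and rejects bad input", {
    set.seed(7)
    a <- matrix(rnorm(60), 30, 2)
    b <- matrix(rnorm(60), 30, 2)
    expect_lt(max(abs(integrateAcceleration(a + b, 50) -
                      integrateAcceleration(a, 50) -
                      integrateAcceleration(b, 50))), 1e-12)
    expect_error(integrateAcceleration(matrix(c(1, NA), 1), 50),
                 "non-finite")
    ## 3-axis input: z dropped with a warning
    expect_warning(v <- integrateAcceleration(matrix(1, 10, 3), 50),
                   "z")
    expect_equal(ncol(v), 2L)
})

test_that("velocity decomposes into speed and carried-forward direction", {
    sd <- decomposeVelocity(rbind(c(3, 4), c(1, 0), c(0, 0)))
    expect_equal(speed(sd), c(5, 1, 0))
    expect_equal(direction(sd)[1, ], c(0.6, 0.8))
    expect_equal(direction(sd)[3, ], c(1, 0))  # carried forward
    ## first-sample fallback
    sd0 <- decomposeVelocity(rbind(c(0, 0), c(0, 2)))
    expect_equal(direction(sd0)[1, ], c(1, 0))
})

test_that("compose inverts decompose above the speed floor", {
    set.seed(11)
    v <- matrix(rnorm(200), 100, 2)
    v[sample(100, 10), ] <- 0                 # some rest samples
    sd <- decomposeVelocity(v)
    back <- composeVelocity(sd)
    moving <- speed(sd) > 1e-6
    expect_lt(max(abs(back[moving, ] - v[moving, ])), 1e-9)
    ## direct composition
    expect_equal(composeVelocity(2, rbind(c(0, 1))), rbind(c(0, 2)))
    expect_equal(composeVelocity(0, rbind(c(0.6, 0.8))), rbind(c(0, 0)))
    expect_error(composeVelocity(1, rbind(c(1, 1))), "unit norm")
})

test_that("task-axis projection gives signed along/perp coordinates", {
    fr <- projectToTaskAxis(rbind(c(4, 1), c(10, 0)), c(0, 0), c(10, 0))
    expect_equal(fr@along, c(4, 10))
    expect_equal(fr@perp, c(1, 0))
    ## oblique axis against the rotation-matrix oracle
    pts <- rbind(c(3, 4) / 2, c(1, 1), c(-2, 0.5))
    fr2 <- projectToTaskAxis(pts, c(0, 0), c(3, 4))
    or <- oracleProject(pts, c(0, 0), c(3, 4))
    expect_equal(fr2@along, or$along, tolerance = 1e-12)
    expect_equal(fr2@perp, or$perp, tolerance = 1e-12)
    expect_equal(fr2@along[1], 2.5)
    expect_equal(fr2@perp[1], 0)
    expect_error(projectToTaskAxis(pts, c(1, 1), c(1, 1)), "distinct")
})

test_that("task-axis projection is an isometry", {
    set.seed(3)
    for (i in 1:10) {
        pts <- matrix(rnorm(40), 20, 2)
        start <- rnorm(2); target <- start + rnorm(2)
        fr <- projectToTaskAxis(pts, start, target)
        expect_lt(max(abs(sqrt(fr@along^2 + fr@perp^2) -
                          sqrt(rowSums(sweep(pts, 2, start)^2)))), 1e-9)
    }
})

test_that("trajectory series enforce the uniform-grid invariants", {
    expect_error(TrajectorySeries(c(0, 0.02, 0.05), matrix(0, 3, 2),
                                  matrix(0, 3, 2), sampleRate = 50),
                 "step")
    expect_error(TrajectorySeries(c(0, 0.02), matrix(0, 3, 2),
                                  matrix(0, 3, 2), sampleRate = 50))
    tr <- TrajectorySeries(seq(0, 1, 0.02), matrix(1, 51, 2),
                           matrix(0, 51, 2))
    expect_equal(sampleRate(tr), 50)
})
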