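## Reduced-size generator configuration used across the unit tests: same
## task structure as the defaults, fewer trials and channels.
smallConfig <- function(seed = 1L, trialsPerTarget = 5L, nChannels = 12L,
                        ...) {
    syntheticConfig(trialsPerTarget = trialsPerTarget,
                    nChannels = nChannels, seed = seed, ...)
}

## Independent task-axis projection via an explicit rotation matrix
## (oracle for projectToTaskAxis and the pointing metrics).
oracleProject <- function(points, start, target) {
    u <- (target - start) / sqrt(sum((target - start)^2))
    R <- rbind(c(u[1], u[2]), c(-u[2], u[1]))   # rows: along, perp
    out <- t(R %*% t(sweep(points, 2, start)))
    list(along = out[, 1], perp = out[, 2])
}

## Independent sign-change scanner: explicit loop with carried last sign.
oracleSignChanges <- function(d) {
    last <- 0
    changes <- 0L
    for (x in d) {
        s <- sign(x)
        if (s == 0) next
        if (last != 0 && s != last) changes <- changes + 1L
        last <- s
    }
    changes
}
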