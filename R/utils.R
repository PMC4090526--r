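## Internal helpers shared across modules.

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG state afterwards so library code never perturbs user
## simulations.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

.symmetrize <- function(m) (m + t(m)) / 2

## Least-squares solve of X B = Y through the normal equations, falling back
## to the Moore-Penrose minimum-norm solution when the Gram matrix is
## singular (X+ = (X'X)+ X').
.lsSolve <- function(X, Y, warnSingular = TRUE, what = "design") {
    XtX <- crossprod(X)
    XtY <- crossprod(X, Y)
    B <- tryCatch(solve(XtX, XtY), error = function(e) NULL)
    if (is.null(B)) {
        if (warnSingular)
            warning(sprintf("singular %s Gram matrix; using minimum-norm solution",
                            what))
        e <- eigen(.symmetrize(XtX), symmetric = TRUE)
        tol <- max(e$values, 0) * length(e$values) * .Machine$double.eps
        inv <- ifelse(e$values > tol, 1 / e$values, 0)
        B <- e$vectors %*% (inv * crossprod(e$vectors, XtY))
    }
    B
}

.asMatrix2 <- function(x, what = "series") {
    if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    if (any(!is.finite(x)))
        stop(sprintf("'%s' contains non-finite values", what))
    x
}

## Contiguous runs of TRUE in a logical vector, as a 2-column matrix of
## (start, end) indices.
.trueRuns <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(start = starts[r$values], end = ends[r$values])
}
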