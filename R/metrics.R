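#' Root-mean-squared error between two series
#'
#' \eqn{\sqrt{\mathrm{mean}_t \|a_t - b_t\|^2}}: for 2-D series the
#' per-sample error is the Euclidean distance, for scalar series (e.g.
#' speed) the absolute difference.  Rows where either series is NA (e.g.
#' invalid-history samples of the linear filter) are excluded; an empty
#' intersection is an error.
#'
#' @param trueSeries,decodedSeries equal-length numeric vectors or
#'   samples x k matrices.
#' @return A single nonnegative number.
#' @export
rmse <- function(trueSeries, decodedSeries) {
    a <- if (is.null(dim(trueSeries))) matrix(trueSeries, ncol = 1L)
         else as.matrix(trueSeries)
    b <- if (is.null(dim(decodedSeries))) matrix(decodedSeries, ncol = 1L)
         else as.matrix(decodedSeries)
    if (!all(dim(a) == dim(b))) stop("series dimensions differ")
    ok <- stats::complete.cases(a) & stats::complete.cases(b)
    if (!any(ok)) stop("no valid samples in common")
    d2 <- rowSums((a[ok, , drop = FALSE] - b[ok, , drop = FALSE])^2)
    sqrt(mean(d2))
}

## Count sign changes of an increment series.  Zero increments inherit the
## previous nonzero sign (so flat segments never create spurious counts);
## leading zeros are skipped.
.signChanges <- function(d) {
    s <- sign(d)
    s <- s[s != 0]
    if (length(s) < 2L) return(0L)
    sum(diff(s) != 0)
}

#' Pointing-device metrics of a decoded trial path
#'
#' Evaluates a trajectory against the task axis (the straight line from
#' `start` to `target`) with the four pointing-device accuracy measures:
#' \describe{
#'   \item{ODC (orthogonal direction change)}{number of reversals of
#'     progress along the task axis, i.e. sign changes of the increments of
#'     the along-axis coordinate -- the consistency of movement toward the
#'     target.}
#'   \item{MDC (movement direction change)}{number of reversals of the
#'     perpendicular drift, i.e. sign changes of the increments of the
#'     perpendicular coordinate -- the smoothness of the path about the
#'     axis.}
#'   \item{ME (movement error)}{mean absolute perpendicular deviation from
#'     the axis.}
#'   \item{MV (movement variability)}{sample standard deviation (n - 1
#'     denominator) of the signed perpendicular deviation.}
#' }
#' All four are invariant under rigid motions (rotation + translation) of
#' the whole scene.  Note the direction-change mapping: ODC counts
#' along-axis reversals and MDC perpendicular reversals; comparisons
#' against other implementations must use the same convention.
#'
#' @param path >= 3 trajectory points (samples x 2).
#' @param start,target distinct 2-D points defining the task axis.
#' @return A one-row data.frame with columns `odc`, `mdc`, `me`, `mv`.
#' @examples
#' p <- rbind(c(0, 0), c(2, 1), c(4, -1), c(6, 1), c(8, 0), c(10, 0))
#' pointingMetrics(p, c(0, 0), c(10, 0))  # odc 0, mdc 3, me 0.5
#' @export
pointingMetrics <- function(path, start, target) {
    p <- .asMatrix2(path, "path")
    if (nrow(p) < 3L) stop("need at least 3 path points")
    fr <- projectToTaskAxis(p, start, target)
    data.frame(odc = .signChanges(diff(fr@along)),
               mdc = .signChanges(diff(fr@perp)),
               me = mean(abs(fr@perp)),
               mv = stats::sd(fr@perp))
}

#' Summarize per-trial metrics as mean and standard error
#'
#' @param perTrial data.frame of per-trial metric values (numeric columns
#'   are summarized, others ignored); >= 2 trials required.
#' @return data.frame with columns `metric`, `mean`, `sem`
#'   (\eqn{sd/\sqrt{n}}) and `n`.
#' @export
summarizeTrials <- function(perTrial) {
    perTrial <- as.data.frame(perTrial)
    num <- vapply(perTrial, is.numeric, logical(1))
    if (nrow(perTrial) < 2L) stop("need at least 2 trials")
    cols <- names(perTrial)[num]
    do.call(rbind, lapply(cols, function(cn) {
        v <- perTrial[[cn]]
        v <- v[is.finite(v)]
        data.frame(metric = cn, mean = mean(v),
                   sem = stats::sd(v) / sqrt(length(v)), n = length(v))
    }))
}
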