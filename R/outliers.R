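#' Grubbs test statistic (maximum normalized residual)
#'
#' `G = max_i |x_i - mean(x)| / sd(x)`, two-sided: the candidate outlier is
#' the observation farthest from the mean in units of the sample SD. Ties at
#' the maximum deviation resolve to the lowest index, for deterministic
#' behaviour.
#'
#' @param values Numeric vector, `n >= 3`, with positive sample SD.
#' @return A list of class `grubbs_result` with `G`, `candidate_index`, `n`.
#' @export
grubbs_statistic <- function(values) {
  n <- length(values)
  if (n < 3) stop("Grubbs's test needs at least 3 observations")
  if (anyNA(values) || any(!is.finite(values))) stop("values must be finite")
  s <- stats::sd(values)
  if (s == 0) stop("Grubbs's test undefined for constant data (zero SD)")
  dev <- abs(values - mean(values))
  i <- which.max(dev)  # lowest index on ties
  structure(list(G = dev[i] / s, candidate_index = i, n = n),
            class = "grubbs_result")
}

#' Two-sided Grubbs critical value
#'
#' `((n-1)/sqrt(n)) * sqrt(t^2 / (n-2+t^2))` with `t` the upper `alpha/(2n)`
#' quantile of Student's t with `n-2` degrees of freedom — the standard
#' two-sided critical value of the maximum normalized residual test.
#'
#' @param n Sample size, `n >= 3`.
#' @param alpha Significance level in (0, 1).
#' @return Scalar critical value.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  if (n < 3 || alpha <= 0 || alpha >= 1)
    stop("need n >= 3 and 0 < alpha < 1")
  t <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

outlier_report <- function(method, flagged_ids, n_total, parameters,
                           status = "ok") {
  structure(
    list(method = method, flagged_ids = flagged_ids,
         n_flagged = length(flagged_ids), n_total = n_total,
         parameters = parameters, status = status),
    class = "outlier_report"
  )
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> %s: %d/%d flagged%s\n", x$method,
              x$n_flagged, x$n_total,
              if (x$status != "ok") paste0(" [", x$status, "]") else ""))
  invisible(x)
}

#' Iterative Grubbs outlier detection
#'
#' Applies the two-sided Grubbs test repeatedly: while the statistic exceeds
#' its critical value, the candidate observation is removed and recorded, and
#' the test reruns on the remainder. Iteration stops when no outlier is
#' detected or fewer than 3 observations remain.
#'
#' @param values Numeric vector.
#' @param alpha Significance level (default 0.05, two-sided).
#' @param ids Optional identifiers parallel to `values`; defaults to indices.
#' @return An `outlier_report` (method `"grubbs"`) with `flagged_ids` in
#'   removal order. With fewer than 3 initial observations an empty report
#'   with status `"insufficient_n"` is returned, with a warning.
#' @export
iterative_grubbs <- function(values, alpha = 0.05, ids = NULL) {
  if (is.null(ids)) ids <- seq_along(values)
  stopifnot(length(ids) == length(values))
  if (length(values) < 3) {
    warning("fewer than 3 observations: Grubbs's test not applicable")
    return(outlier_report("grubbs", ids[0], length(values),
                          list(alpha = alpha), status = "insufficient_n"))
  }
  n_total <- length(values)
  flagged <- ids[0]
  x <- values; xid <- ids
  repeat {
    if (length(x) < 3) break
    if (stats::sd(x) == 0) break  # constant data: no outlier detectable
    g <- grubbs_statistic(x)
    if (g$G <= grubbs_critical(g$n, alpha)) break
    flagged <- c(flagged, xid[g$candidate_index])
    x <- x[-g$candidate_index]
    xid <- xid[-g$candidate_index]
  }
  outlier_report("grubbs", flagged, n_total, list(alpha = alpha))
}

#' Benchmark-percentile outlier criterion
#'
#' Flags RMSE values strictly greater than the p-th percentile of the
#' benchmark (test-retest) RMSE distribution. The percentile uses linear
#' interpolation between order statistics; the strict comparison means a
#' value exactly at the threshold is not flagged.
#'
#' @param records `data.frame` of [impact_record()] rows (only `"ok"` rows
#'   are assessed) or a bare numeric vector of RMSE values.
#' @param benchmark Numeric vector of benchmark RMSE values (non-empty).
#' @param percentile Percentile in (0, 100), default 75.
#' @return An `outlier_report` (method `"benchmark_percentile"`) whose
#'   `parameters` record the percentile and the threshold value.
#' @export
benchmark_outliers <- function(records, benchmark, percentile = 75) {
  if (length(benchmark) < 1) stop("empty benchmark")
  stopifnot(percentile > 0, percentile < 100)
  if (is.data.frame(records)) {
    ok <- records$status == "ok"
    v <- records$rmse[ok]
    ids <- records$subject_id[ok]
  } else {
    v <- as.numeric(records)
    ids <- seq_along(v)
  }
  thr <- unname(stats::quantile(benchmark, percentile / 100, type = 7))
  flagged <- ids[v > thr]
  outlier_report("benchmark_percentile", flagged, length(v),
                 list(percentile = percentile, threshold = thr))
}
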