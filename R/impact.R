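#' Per-subject impact record
#'
#' One row of the impact bookkeeping: which two processing conditions of a
#' subject were compared, the z-score RMSE between them, and whether the
#' comparison completed (`"ok"`) or failed at some stage
#' (`"failed:<stage>"`), in which case the RMSE is absent.
#'
#' @param subject_id,condition_a,condition_b Identifiers.
#' @param rmse Non-negative RMSE (omit for failures).
#' @param status `"ok"` or `"failed:<stage>"`.
#' @return A one-row `data.frame`.
#' @export
impact_record <- function(subject_id, condition_a, condition_b,
                          rmse = NA_real_, status = "ok") {
  if (status == "ok") {
    if (!is.finite(rmse) || rmse < 0) stop("ok records need a finite rmse >= 0")
  } else {
    if (!startsWith(status, "failed:")) stop("status must be ok or failed:<stage>")
    rmse <- NA_real_
  }
  data.frame(subject_id = subject_id, condition_a = condition_a,
             condition_b = condition_b, rmse = rmse, status = status,
             stringsAsFactors = FALSE)
}

#' Root-mean-square error between two z-score maps
#'
#' `sqrt(mean((z_a - z_b)^2))` over the voxels of the analysis mask — the
#' scalar impact statistic comparing two processing conditions of the same
#' subject.
#'
#' @param zmap_a,zmap_b [zscore_map()] objects on the same grid, both defined
#'   exactly on the mask voxels.
#' @param mask The shared [derive_gm_mask()] result.
#' @return Non-negative scalar.
#' @export
zmap_rmse <- function(zmap_a, zmap_b, mask) {
  stopifnot(inherits(zmap_a, "zscore_map"), inherits(zmap_b, "zscore_map"),
            inherits(mask, "analysis_mask"))
  if (!identical(zmap_a$grid$shape, mask$grid$shape) ||
      !identical(zmap_b$grid$shape, mask$grid$shape))
    stop("grid mismatch between z-maps and mask")
  if (mask$n_voxels < 1) stop("empty analysis mask")
  za <- zmap_a$z[mask$mask]
  zb <- zmap_b$z[mask$mask]
  if (anyNA(za) || anyNA(zb))
    stop("z-maps are not defined on every mask voxel (mask mismatch)")
  sqrt(mean((za - zb)^2))
}

#' Aggregate spatial deviation map across subjects
#'
#' For each voxel, the absolute value of the mean (over subjects) of the
#' z-score difference `z_a - z_b` — the volume behind the deviation heat
#' maps. `method = "mean_abs"` instead averages `|z_a - z_b|`, the
#' alternative reading in which sign cancellation across subjects is not
#' allowed.
#'
#' @param pairs List of two-element lists `(zmap_a, zmap_b)`, all on the same
#'   mask.
#' @param mask The shared [derive_gm_mask()] result.
#' @param method `"signed_mean"` (default, `|mean(dz)|`) or `"mean_abs"`
#'   (`mean(|dz|)`).
#' @return An object of class `deviation_map` with `map` (3D array, `NA`
#'   off-mask), `n_subjects` and `method`.
#' @export
deviation_map <- function(pairs, mask, method = c("signed_mean", "mean_abs")) {
  method <- match.arg(method)
  stopifnot(inherits(mask, "analysis_mask"))
  if (length(pairs) < 1) stop("need at least one pair of z-maps")
  acc <- numeric(mask$n_voxels)
  for (p in pairs) {
    dz <- p[[1]]$z[mask$mask] - p[[2]]$z[mask$mask]
    if (anyNA(dz)) stop("z-maps are not defined on every mask voxel")
    acc <- acc + if (method == "mean_abs") abs(dz) else dz
  }
  vals <- acc / length(pairs)
  if (method == "signed_mean") vals <- abs(vals)
  m <- array(NA_real_, dim = mask$grid$shape)
  m[mask$mask] <- vals
  structure(list(map = m, n_subjects = length(pairs), method = method),
            class = "deviation_map")
}

#' Summarize RMSE impact records
#'
#' Mean, SD, range and interquartile bounds of the RMSE values over records
#' with status `"ok"`; failed records are counted separately and excluded
#' from the statistics. Percentiles use linear interpolation between order
#' statistics (the p-th quantile at rank `1 + (n-1) p`). With a single ok
#' record the SD is undefined and reported as 0 with `sd_defined = FALSE`.
#'
#' @param records `data.frame` of [impact_record()] rows.
#' @return A list with `n_ok`, `n_failed`, `mean`, `sd`, `sd_defined`,
#'   `min`, `q25`, `q75`, `max`, and `values` (the ok RMSEs).
#' @export
summarize_rmse <- function(records) {
  stopifnot(is.data.frame(records), all(c("rmse", "status") %in% names(records)))
  ok <- records$status == "ok"
  if (!any(ok)) stop("no ok records to summarize")
  v <- records$rmse[ok]
  q <- unname(stats::quantile(v, c(0.25, 0.75), type = 7))
  list(n_ok = sum(ok), n_failed = sum(!ok),
       mean = mean(v),
       sd = if (length(v) > 1) stats::sd(v) else 0,
       sd_defined = length(v) > 1,
       min = min(v), q25 = q[1], q75 = q[2], max = max(v),
       values = v)
}
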