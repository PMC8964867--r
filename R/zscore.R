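#' Compute a voxel-wise atrophy z-score map
#'
#' For every voxel in the analysis mask,
#' `z = (scan - template mean) / template SD`; negative values indicate
#' gray-matter density below the reference population for that sex and age.
#' Off-mask voxels carry `NA`, never 0, so downstream statistics cannot be
#' silently diluted.
#'
#' @param scan A [subject_scan()].
#' @param template A `normative_template` built at the scan's sex and age
#'   (the scan age must fall inside the template's age window).
#' @param mask An [derive_gm_mask()] result on the same grid.
#' @param allow_stratum_mismatch Set `TRUE` to z-score against a template
#'   from a different stratum (off-label use, e.g. sensitivity analyses).
#' @return An object of class `zscore_map` with `z` (3D array, `NA`
#'   off-mask), `subject_id`, `condition`, `stratum` and `grid`.
#' @export
zscore_map <- function(scan, template, mask, allow_stratum_mismatch = FALSE) {
  stopifnot(inherits(scan, "subject_scan"),
            inherits(template, "normative_template"),
            inherits(mask, "analysis_mask"))
  if (!identical(scan$grid$shape, template$grid$shape) ||
      !identical(scan$grid$shape, mask$grid$shape))
    stop("grid mismatch between scan, template and mask")
  stratum_ok <- scan$sex == template$sex &&
    scan$age >= template$target_age - template$window &&
    scan$age <= template$target_age + template$window
  if (!stratum_ok && !allow_stratum_mismatch)
    stop(sprintf(
      "stratum mismatch: scan (%s, %.1f y) vs template (%s, %s +/- %s y)",
      scan$sex, scan$age, template$sex, format(template$target_age),
      format(template$window)))
  sdm <- template$sd_map[mask$mask]
  if (any(sdm <= 0))
    stop("template SD is zero inside the analysis mask; rebuild the mask")
  z <- array(NA_real_, dim = scan$grid$shape)
  z[mask$mask] <- (scan$volume[mask$mask] - template$mean_map[mask$mask]) / sdm
  structure(
    list(z = z, subject_id = scan$subject_id, condition = scan$condition,
         stratum = list(sex = template$sex, target_age = template$target_age,
                        window = template$window, n_ref = template$n_ref),
         grid = scan$grid),
    class = "zscore_map"
  )
}

#' @export
print.zscore_map <- function(x, ...) {
  zz <- x$z[!is.na(x$z)]
  cat(sprintf("<zscore_map> %s (%s): %d mask voxels, z in [%.2f, %.2f]\n",
              x$subject_id, x$condition, length(zz), min(zz), max(zz)))
  invisible(x)
}

#' Classify voxels as within the expected z-score range
#'
#' By convention, z-scores between -2.5 and 2.5 denote volume changes within
#' expected limits; voxels outside that closed interval are flagged as
#' abnormal.
#'
#' @param zmap A [zscore_map()].
#' @param lo,hi Range bounds (defaults -2.5 and 2.5), `lo < hi`.
#' @return Logical 3D array: `TRUE` where `lo <= z <= hi`, `FALSE` outside,
#'   `NA` off-mask.
#' @export
classify_normal_range <- function(zmap, lo = -2.5, hi = 2.5) {
  stopifnot(inherits(zmap, "zscore_map"), lo < hi)
  zmap$z >= lo & zmap$z <= hi
}
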