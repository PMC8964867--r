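#' Select reference subjects for a sex/age stratum
#'
#' Templates are stratified by sex and by an age window containing the target
#' age +/- `window` years; the window is a closed interval and ages are
#' compared as floating point values.
#'
#' @param cohort List of [subject_scan()] objects.
#' @param sex `"F"` or `"M"`.
#' @param target_age Target age in years.
#' @param window Half-width of the age window in years (default 2).
#' @return The matching subset of `cohort` (possibly empty).
#' @export
#' @examples
#' # ages 60..65, target 63, window 2 selects ages 61..65
select_reference_subjects <- function(cohort, sex, target_age, window = 2) {
  sex <- match.arg(sex, c("F", "M"))
  stopifnot(window >= 0)
  keep <- vapply(cohort, function(s) {
    s$sex == sex && s$age >= target_age - window && s$age <= target_age + window
  }, logical(1))
  cohort[keep]
}

#' Build a voxel-wise normative mean/SD template
#'
#' Computes the voxel-wise mean and sample standard deviation (n-1
#' denominator) across the selected reference subjects. Both maps are
#' computed by an explicit two-pass algorithm (mean first, then centred sum
#' of squares) for numerical stability.
#'
#' @param selected List of [subject_scan()] objects, typically from
#'   [select_reference_subjects()].
#' @param sex,target_age,window Stratum metadata recorded in the template.
#' @param min_n Minimum acceptable number of reference subjects; below this
#'   the stratum is rejected with an error.
#' @return An object of class `normative_template` with `mean_map`, `sd_map`,
#'   `sex`, `target_age`, `window`, `n_ref` and `grid`.
#' @export
build_template <- function(selected, sex, target_age, window = 2, min_n = 10) {
  n <- length(selected)
  stratum <- sprintf("sex=%s, age=%s +/- %s y", sex, format(target_age),
                     format(window))
  if (n < 2)
    stop(sprintf("stratum %s: sample SD undefined with n=%d (< 2)", stratum, n))
  if (n < min_n)
    stop(sprintf("stratum %s: only %d reference subjects (min_n=%d)",
                 stratum, n, min_n))
  grid <- selected[[1]]$grid
  nv <- prod(grid$shape)
  X <- vapply(selected, function(s) as.vector(s$volume), numeric(nv))
  mu <- rowMeans(X)
  sdv <- sqrt(rowSums((X - mu)^2) / (n - 1))
  structure(
    list(mean_map = array(mu, dim = grid$shape),
         sd_map = array(sdv, dim = grid$shape),
         sex = sex, target_age = target_age, window = window,
         n_ref = n, grid = grid),
    class = "normative_template"
  )
}

#' @export
print.normative_template <- function(x, ...) {
  cat(sprintf("<normative_template> %s, age %s +/- %s y, n_ref=%d, grid %s\n",
              x$sex, format(x$target_age), format(x$window), x$n_ref,
              paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

#' Construct a normative template from explicit maps
#'
#' Used for synthetic benchmarks where a template with known properties
#' (e.g. a spatially constant SD) is required, bypassing cohort estimation.
#'
#' @param mean_map,sd_map 3D numeric arrays; `sd_map` must be non-negative.
#' @param grid The [grid_spec()].
#' @param sex,target_age,window,n_ref Stratum metadata.
#' @return A `normative_template`.
#' @export
normative_template <- function(mean_map, sd_map, grid, sex = "F",
                               target_age = 60, window = 2, n_ref = 2L) {
  stopifnot(is_grid_spec(grid),
            identical(dim(mean_map), as.integer(grid$shape)),
            identical(dim(sd_map), as.integer(grid$shape)))
  if (min(sd_map) < 0) stop("sd_map must be non-negative")
  structure(
    list(mean_map = mean_map, sd_map = sd_map, sex = sex,
         target_age = target_age, window = window, n_ref = as.integer(n_ref),
         grid = grid),
    class = "normative_template"
  )
}

#' Derive the gray-matter analysis mask from a template
#'
#' The mask is the set of voxels with template mean above `mean_threshold`
#' and SD above `sd_floor`. The SD floor excludes voxels whose z-scores would
#' be numerically unstable; such voxels are dropped from the analysis rather
#' than zero-filled.
#'
#' @param template A `normative_template`.
#' @param mean_threshold Minimum mean gray-matter density (default 0.1).
#' @param sd_floor Minimum SD (default 1e-6 density units).
#' @return An object of class `analysis_mask` with `mask` (logical 3D array),
#'   `n_voxels` and `provenance`.
#' @export
derive_gm_mask <- function(template, mean_threshold = 0.1, sd_floor = 1e-6) {
  stopifnot(inherits(template, "normative_template"),
            mean_threshold >= 0, sd_floor >= 0)
  m <- template$mean_map > mean_threshold & template$sd_map > sd_floor
  if (!any(m))
    stop("empty analysis mask: thresholds exclude every voxel")
  structure(
    list(mask = m, n_voxels = sum(m),
         provenance = list(mean_threshold = mean_threshold,
                           sd_floor = sd_floor,
                           template_stratum = list(sex = template$sex,
                                                   target_age = template$target_age,
                                                   window = template$window,
                                                   n_ref = template$n_ref)),
         grid = template$grid),
    class = "analysis_mask"
  )
}

#' @export
print.analysis_mask <- function(x, ...) {
  cat(sprintf("<analysis_mask> %d voxels (mean > %g, SD > %g)\n",
              x$n_voxels, x$provenance$mean_threshold,
              x$provenance$sd_floor))
  invisible(x)
}
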