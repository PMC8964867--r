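# Persistence: volumes as single-file NIfTI-1 (.nii.gz) with an
# identity-scaled affine, tables as TSV, metadata as JSON sidecars.

nifti_image <- function(vol, voxel_size) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- voxel_size
  img
}

#' Write / read a volume as NIfTI-1
#'
#' @param vol 3D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Voxel size in mm (scalar or length 3).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   list with `volume` and `voxel_size`.
#' @export
write_volume <- function(vol, path, voxel_size = 1) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  RNifti::writeNifti(nifti_image(vol, voxel_size), path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(volume = array(as.numeric(img), dim = dim(img)),
       voxel_size = RNifti::pixdim(img)[seq_len(3)])
}

#' Write / read a cohort of scans
#'
#' Volumes are written one NIfTI per subject next to a `metadata.tsv` with
#' columns `subject_id`, `age`, `sex`, `condition`, `path`.
#'
#' @param cohort List of [subject_scan()] objects.
#' @param dir Output directory (created if needed).
#' @return `write_cohort` returns the metadata `data.frame` invisibly;
#'   `read_cohort` returns a list of [subject_scan()] objects.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- do.call(rbind, lapply(cohort, function(s) {
    fn <- sprintf("%s_%s.nii.gz", s$subject_id, gsub("[^A-Za-z0-9]", "_", s$condition))
    write_volume(s$volume, file.path(dir, fn), s$grid$voxel_size)
    data.frame(subject_id = s$subject_id, age = s$age, sex = s$sex,
               condition = s$condition, path = fn, stringsAsFactors = FALSE)
  }))
  utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(meta)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta <- utils::read.table(
    file.path(dir, "metadata.tsv"), sep = "\t", header = TRUE,
    colClasses = c(subject_id = "character", age = "numeric",
                   sex = "character", condition = "character",
                   path = "character"))
  lapply(seq_len(nrow(meta)), function(i) {
    v <- read_volume(file.path(dir, meta$path[i]))
    grid <- grid_spec(dim(v$volume), v$voxel_size)
    subject_scan(v$volume, meta$age[i], meta$sex[i], meta$subject_id[i],
                 meta$condition[i], grid)
  })
}

#' Write / read a normative template
#'
#' Persisted as paired NIfTI files `<prefix>_mean.nii.gz` and
#' `<prefix>_sd.nii.gz` plus a JSON sidecar `<prefix>.json` recording the
#' stratum (sex, target age, window, n_ref).
#'
#' @param template A `normative_template`.
#' @param prefix Path prefix.
#' @return `write_template` returns `prefix` invisibly; `read_template`
#'   returns the `normative_template`.
#' @export
write_template <- function(template, prefix) {
  stopifnot(inherits(template, "normative_template"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  write_volume(template$mean_map, paste0(prefix, "_mean.nii.gz"),
               template$grid$voxel_size)
  write_volume(template$sd_map, paste0(prefix, "_sd.nii.gz"),
               template$grid$voxel_size)
  jsonlite::write_json(
    list(sex = template$sex, target_age = template$target_age,
         window = template$window, n_ref = template$n_ref),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_template
#' @export
read_template <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  mu <- read_volume(paste0(prefix, "_mean.nii.gz"))
  sdv <- read_volume(paste0(prefix, "_sd.nii.gz"))
  grid <- grid_spec(dim(mu$volume), mu$voxel_size)
  normative_template(mu$volume, sdv$volume, grid, sex = meta$sex,
                     target_age = meta$target_age, window = meta$window,
                     n_ref = meta$n_ref)
}

#' Write a z-score map as NIfTI
#'
#' Off-mask voxels are stored as NaN (the missing-value convention, recorded
#' in the JSON sidecar), never as 0.
#'
#' @param zmap A [zscore_map()].
#' @param path Output path (`.nii.gz`); a sidecar `.json` is written next to
#'   it.
#' @param voxel_size Voxel size in mm (defaults to the z-map's grid).
#' @return `path`, invisibly.
#' @export
write_zmap <- function(zmap, path, voxel_size = zmap$grid$voxel_size) {
  write_volume(zmap$z, path, voxel_size)
  jsonlite::write_json(
    list(subject_id = zmap$subject_id, condition = zmap$condition,
         stratum = zmap$stratum, missing_value = "NaN (off-mask voxels)"),
    sub("\\.nii(\\.gz)?$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read impact records as TSV
#'
#' @param records `data.frame` of [impact_record()] rows.
#' @param path Output TSV path.
#' @return `write_impact_records` returns `path` invisibly;
#'   `read_impact_records` the `data.frame`.
#' @export
write_impact_records <- function(records, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  out <- records
  out$rmse <- ifelse(is.na(out$rmse), "NA", sprintf("%.12g", out$rmse))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_impact_records
#' @export
read_impact_records <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$rmse <- suppressWarnings(as.numeric(df$rmse))
  df
}

#' Write an outlier report as JSON
#'
#' @param report An `outlier_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_outlier_report <- function(report, path) {
  stopifnot(inherits(report, "outlier_report"))
  jsonlite::write_json(
    list(method = report$method, parameters = report$parameters,
         n_flagged = report$n_flagged, n_total = report$n_total,
         status = report$status,
         flagged_ids = as.character(report$flagged_ids)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
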