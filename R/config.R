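#' Read / write an experiment configuration file
#'
#' Configurations are stored as YAML (or JSON, by extension) mirroring the
#' arguments of [experiment_config()], [cohort_spec()] and
#' [perturbation_spec()]. A config file plus the master seed fully determines
#' an experiment run.
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return `read_experiment_config` returns an [experiment_config()];
#'   `write_experiment_config` returns `path` invisibly.
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  grid <- if (is.null(raw$grid)) grid_spec() else
    grid_spec(unlist(raw$grid$shape), unlist(raw$grid$voxel_size) %||% 4)
  reference <- if (is.null(raw$reference)) NULL else
    do.call(cohort_spec, raw$reference)
  perts <- if (is.null(raw$perturbations)) default_perturbations() else
    lapply(raw$perturbations, function(p) do.call(perturbation_spec, p))
  args <- raw[setdiff(names(raw), c("grid", "reference", "perturbations"))]
  args$patient_age_range <- unlist(args$patient_age_range) %||% c(45, 65)
  args$patient_atrophy <- as.list(args$patient_atrophy %||%
                                    list(temporal = 2.5))
  do.call(experiment_config,
          c(list(grid = grid, reference = reference, perturbations = perts),
            args))
}

#' @rdname read_experiment_config
#' @param config An [experiment_config()].
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  out <- list(
    grid = list(shape = config$grid$shape,
                voxel_size = config$grid$voxel_size),
    reference = unclass(config$reference),
    n_patients = config$n_patients,
    patient_age_range = config$patient_age_range,
    patient_sex_ratio = config$patient_sex_ratio,
    patient_atrophy = config$patient_atrophy,
    patient_subject_sd = config$patient_subject_sd,
    patient_noise_sd = config$patient_noise_sd,
    n_benchmark = config$n_benchmark,
    repeat_sd = config$repeat_sd, repeat_fwhm = config$repeat_fwhm,
    perturbations = lapply(config$perturbations, function(p) {
      p <- unclass(p)
      p[!vapply(p, is.null, logical(1))]
    }),
    window = config$window, min_n = config$min_n,
    mean_threshold = config$mean_threshold, sd_floor = config$sd_floor,
    alpha = config$alpha, percentile = config$percentile,
    seed = config$seed
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
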