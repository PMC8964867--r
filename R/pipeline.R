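#' Configure a full perturbation-impact experiment
#'
#' Bundles every parameter of the evaluation: the grid, the reference cohort,
#' the patient and benchmark samples, the repeat-noise model, the set of
#' emulated perturbation methods, template and mask parameters, and the
#' outlier criteria. Patients, benchmark subjects and the reference cohort
#' are three disjoint synthetic samples drawn from the same generator.
#'
#' The default reference cohort samples ages uniformly over an interval
#' bracketing the patient age range, so every sex/age template stratum is
#' evenly covered at desk-scale n; the demographic-moment defaults of
#' [cohort_spec()] remain available via `reference`.
#'
#' @param grid A [grid_spec()].
#' @param reference A [cohort_spec()] for the normative cohort.
#' @param n_patients,patient_age_range,patient_sex_ratio Patient sample.
#' @param patient_atrophy Named list region -> planted z-effect applied to
#'   every patient.
#' @param patient_subject_sd,patient_noise_sd Patient scan variability
#'   (default: the reference cohort values).
#' @param n_benchmark Number of test-retest benchmark subjects.
#' @param repeat_sd Point SD of within-session repeat acquisition noise
#'   (density units). The default 0.0107 puts the expected benchmark RMSE
#'   near 0.28 given the default reference variability.
#' @param repeat_fwhm FWHM (mm) of the repeat-noise smoothing.
#' @param perturbations Named list of [perturbation_spec()] objects.
#' @param window,min_n Template age window (years) and minimum stratum size.
#' @param mean_threshold,sd_floor Analysis-mask parameters.
#' @param alpha Grubbs significance level (two-sided).
#' @param percentile Benchmark outlier percentile.
#' @param seed Master integer seed; all sampling derives from it.
#' @param out_dir Optional output directory for artifacts.
#' @param write_volumes Write deviation maps as NIfTI when `out_dir` is set.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(grid = grid_spec(c(32L, 32L, 32L), 4),
                              reference = NULL,
                              n_patients = 30, patient_age_range = c(45, 65),
                              patient_sex_ratio = 0.5,
                              patient_atrophy = list(temporal = 2.5),
                              patient_subject_sd = NULL,
                              patient_noise_sd = NULL,
                              n_benchmark = 30,
                              repeat_sd = 0.0107, repeat_fwhm = 8,
                              perturbations = default_perturbations(),
                              window = 2, min_n = 10,
                              mean_threshold = 0.1, sd_floor = 1e-6,
                              alpha = 0.05, percentile = 75,
                              seed = 1L, out_dir = NULL,
                              write_volumes = TRUE) {
  stopifnot(is_grid_spec(grid), n_patients >= 1, n_benchmark >= 1,
            repeat_sd >= 0, length(perturbations) >= 1)
  if (is.null(reference))
    reference <- cohort_spec(n_subjects = 600,
                             age_range = patient_age_range + c(-2, 2),
                             age_dist = "uniform",
                             seed = derive_seed(seed, 1))
  if (is.null(names(perturbations)) || any(names(perturbations) == ""))
    names(perturbations) <- vapply(perturbations, `[[`, "", "name")
  for (p in perturbations) stopifnot(inherits(p, "perturbation_spec"))
  structure(
    list(grid = grid, reference = reference,
         n_patients = as.integer(n_patients),
         patient_age_range = as.numeric(patient_age_range),
         patient_sex_ratio = patient_sex_ratio,
         patient_atrophy = patient_atrophy,
         patient_subject_sd = patient_subject_sd %||% reference$subject_sd,
         patient_noise_sd = patient_noise_sd %||% reference$noise_sd,
         n_benchmark = as.integer(n_benchmark),
         repeat_sd = repeat_sd, repeat_fwhm = repeat_fwhm,
         perturbations = perturbations,
         window = window, min_n = min_n,
         mean_threshold = mean_threshold, sd_floor = sd_floor,
         alpha = alpha, percentile = percentile,
         seed = as.integer(seed), out_dir = out_dir,
         write_volumes = isTRUE(write_volumes)),
    class = "experiment_config"
  )
}

# pooled voxel-wise mean/SD over the whole reference cohort; used only to
# derive the single common analysis mask shared by all subjects
pooled_template <- function(cohort) {
  n <- length(cohort)
  grid <- cohort[[1]]$grid
  X <- vapply(cohort, function(s) as.vector(s$volume), numeric(prod(grid$shape)))
  mu <- rowMeans(X)
  sdv <- sqrt(rowSums((X - mu)^2) / (n - 1))
  normative_template(array(mu, dim = grid$shape), array(sdv, dim = grid$shape),
                     grid, sex = "F", target_age = NA_real_, window = Inf,
                     n_ref = n)
}

# per-stratum template cache keyed by (sex, rounded age)
template_store <- function(cohort, window, min_n) {
  cache <- new.env(parent = emptyenv())
  list(
    get = function(sex, age) {
      target <- round(age)
      key <- paste(sex, target, sep = ":")
      if (!is.null(cache[[key]])) return(cache[[key]])
      sel <- select_reference_subjects(cohort, sex, target, window)
      tpl <- build_template(sel, sex, target, window, min_n)
      cache[[key]] <- tpl
      tpl
    },
    count = function(sex, age) {
      length(select_reference_subjects(cohort, sex, round(age), window))
    }
  )
}

draw_demographics <- function(n, age_range, sex_ratio, seed, prefix) {
  withr::with_seed(seed, {
    data.frame(
      subject_id = sprintf("%s%04d", prefix, seq_len(n)),
      age = stats::runif(n, age_range[1], age_range[2]),
      sex = ifelse(stats::runif(n) < sex_ratio, "F", "M"),
      seed = vapply(seq_len(n), function(i) derive_seed(seed, 100 + i),
                    integer(1)),
      stringsAsFactors = FALSE
    )
  })
}

#' Run the test-retest benchmark
#'
#' For each benchmark subject, two same-session acquisitions of the same
#' underlying anatomy are simulated (each with independent smoothed noise of
#' SD `repeat_sd`), z-scored against the subject's sex/age template, and the
#' RMSE between the two z-maps is computed. The 75th percentile of these
#' RMSEs is the outlier threshold later applied to perturbed scans.
#'
#' @param config An [experiment_config()].
#' @param state Optional precomputed pipeline state (internal reuse).
#' @return A list with `values` (RMSE vector), `records`, `summary`
#'   (see [summarize_rmse()]) and `p75`.
#' @export
run_benchmark <- function(config, state = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(state)) state <- pipeline_state(config)

  demo <- draw_demographics(config$n_benchmark, config$patient_age_range,
                            config$patient_sex_ratio,
                            derive_seed(config$seed, 2), "bench")
  precheck_strata(state$templates, demo, config$min_n)

  records <- do.call(rbind, lapply(seq_len(nrow(demo)), function(i) {
    tpl <- state$templates$get(demo$sex[i], demo$age[i])
    anatomy <- generate_patient_scan(
      demo$age[i], demo$sex[i], atrophy_regions = config$patient_atrophy,
      grid = config$grid, atlas = state$atlas, cohort = config$reference,
      template = tpl, noise_sd = 0,
      subject_sd = config$patient_subject_sd,
      seed = demo$seed[i], subject_id = demo$subject_id[i])
    acq1 <- simulate_repeat(anatomy, config$repeat_sd, config$repeat_fwhm,
                            seed = derive_seed(demo$seed[i], 1))
    acq2 <- simulate_repeat(anatomy, config$repeat_sd, config$repeat_fwhm,
                            seed = derive_seed(demo$seed[i], 2))
    z1 <- zscore_map(acq1, tpl, state$mask)
    z2 <- zscore_map(acq2, tpl, state$mask)
    impact_record(demo$subject_id[i], "fullface", "repeat",
                  rmse = zmap_rmse(z1, z2, state$mask))
  }))
  s <- summarize_rmse(records)
  list(values = s$values, records = records, summary = s, p75 = s$q75)
}

# shared pipeline state: atlas, reference cohort, common mask, template cache
pipeline_state <- function(config) {
  atlas <- region_atlas(config$grid)
  cohort <- generate_reference_cohort(config$reference, config$grid, atlas)
  mask <- derive_gm_mask(pooled_template(cohort), config$mean_threshold,
                         config$sd_floor)
  templates <- template_store(cohort, config$window, config$min_n)
  list(atlas = atlas, cohort = cohort, mask = mask, templates = templates)
}

precheck_strata <- function(templates, demo, min_n) {
  key <- unique(data.frame(sex = demo$sex, age = round(demo$age)))
  short <- vapply(seq_len(nrow(key)), function(i) {
    templates$count(key$sex[i], key$age[i]) < min_n
  }, logical(1))
  if (any(short)) {
    bad <- key[short, , drop = FALSE]
    stop(sprintf(
      "insufficient reference subjects in strata: %s (min_n=%d); enlarge the reference cohort or narrow the age range",
      paste(sprintf("%s/%d", bad$sex, bad$age), collapse = ", "), min_n))
  }
  invisible(TRUE)
}

#' Run the full perturbation-impact experiment
#'
#' Generates the reference cohort, derives the common gray-matter analysis
#' mask, runs the test-retest benchmark, then for every perturbation method
#' perturbs each patient's full-face scan, z-scores both versions against the
#' patient's sex/age template, computes per-subject RMSEs (recording
#' perturbation failures separately), summarizes them, applies the iterative
#' Grubbs and benchmark-percentile outlier criteria, and aggregates a spatial
#' deviation map. The whole run is a pure function of the configuration.
#'
#' @param config An [experiment_config()].
#' @return An object of class `experiment_report`; see
#'   [format_report_table()] for a rendered summary. When `config$out_dir`
#'   is set, per-subject TSVs, the report JSON and deviation-map NIfTI
#'   volumes are written there.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  state <- pipeline_state(config)

  demo <- draw_demographics(config$n_patients, config$patient_age_range,
                            config$patient_sex_ratio,
                            derive_seed(config$seed, 3), "pat")
  precheck_strata(state$templates, demo, config$min_n)

  bench <- run_benchmark(config, state)

  patients <- lapply(seq_len(nrow(demo)), function(i) {
    tpl <- state$templates$get(demo$sex[i], demo$age[i])
    scan <- generate_patient_scan(
      demo$age[i], demo$sex[i], atrophy_regions = config$patient_atrophy,
      grid = config$grid, atlas = state$atlas, cohort = config$reference,
      template = tpl,
      subject_sd = config$patient_subject_sd,
      noise_sd = config$patient_noise_sd,
      seed = demo$seed[i], subject_id = demo$subject_id[i])
    list(scan = scan, template = tpl,
         zmap = zscore_map(scan, tpl, state$mask))
  })

  methods <- lapply(names(config$perturbations), function(mname) {
    pert <- config$perturbations[[mname]]
    recs <- list(); pairs <- list()
    for (p in patients) {
      out <- apply_perturbation(p$scan, pert, state$atlas)
      if (is_perturbation_failure(out)) {
        recs[[length(recs) + 1L]] <- impact_record(
          p$scan$subject_id, "fullface", paste0("perturbed:", mname),
          status = paste0("failed:", out$stage))
      } else {
        zp <- zscore_map(out, p$template, state$mask)
        recs[[length(recs) + 1L]] <- impact_record(
          p$scan$subject_id, "fullface", paste0("perturbed:", mname),
          rmse = zmap_rmse(zp, p$zmap, state$mask))
        pairs[[length(pairs) + 1L]] <- list(zp, p$zmap)
      }
    }
    records <- do.call(rbind, recs)
    ok <- records$status == "ok"
    summary <- if (any(ok)) summarize_rmse(records) else NULL
    grubbs <- if (any(ok)) {
      iterative_grubbs(records$rmse[ok], config$alpha,
                       ids = records$subject_id[ok])
    } else {
      outlier_report("grubbs", character(0), 0L,
                     list(alpha = config$alpha), status = "no_ok_records")
    }
    benchmark_rep <- if (any(ok)) {
      benchmark_outliers(records, bench$values, config$percentile)
    } else {
      outlier_report("benchmark_percentile", character(0), 0L,
                     list(percentile = config$percentile,
                          threshold = bench$p75), status = "no_ok_records")
    }
    dev <- if (length(pairs) > 0) deviation_map(pairs, state$mask) else NULL
    list(name = mname, records = records, summary = summary,
         grubbs = grubbs, benchmark = benchmark_rep, deviation = dev)
  })
  names(methods) <- names(config$perturbations)

  report <- structure(
    list(benchmark = bench, methods = methods, patients = demo,
         mask_n_voxels = state$mask$n_voxels, config = config),
    class = "experiment_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

method_row <- function(m) {
  n_failed <- sum(m$records$status != "ok")
  n_total <- nrow(m$records)
  n_ok <- n_total - n_failed
  s <- m$summary
  data.frame(
    method = m$name,
    n_failed = n_failed, n_total = n_total,
    mean_rmse = if (is.null(s)) NA_real_ else s$mean,
    sd_rmse = if (is.null(s)) NA_real_ else s$sd,
    min_rmse = if (is.null(s)) NA_real_ else s$min,
    q25_rmse = if (is.null(s)) NA_real_ else s$q25,
    q75_rmse = if (is.null(s)) NA_real_ else s$q75,
    max_rmse = if (is.null(s)) NA_real_ else s$max,
    grubbs_outliers = m$grubbs$n_flagged,
    grubbs_pct = if (n_ok > 0) 100 * m$grubbs$n_flagged / n_ok else NA_real_,
    benchmark_outliers = m$benchmark$n_flagged,
    benchmark_pct = if (n_ok > 0) 100 * m$benchmark$n_flagged / n_ok else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Summary table of an experiment report
#'
#' One row per perturbation method: failure counts, mean RMSE +/- SD, range
#' and IQR bounds, and both outlier counts with percentages of processed
#' subjects.
#'
#' @param report An `experiment_report` from [run_experiment()].
#' @return A `data.frame`.
#' @export
report_summary_table <- function(report) {
  stopifnot(inherits(report, "experiment_report"))
  do.call(rbind, lapply(report$methods, method_row))
}

#' Render an experiment report as text
#'
#' @param report An `experiment_report`.
#' @return Character vector of lines, invisibly; also printed.
#' @export
format_report_table <- function(report) {
  b <- report$benchmark$summary
  tab <- report_summary_table(report)
  lines <- c(
    sprintf("Benchmark (test-retest) RMSE: %.2f +/- %.2f (min %.2f, 75th pct %.2f, max %.2f), n=%d",
            b$mean, b$sd, b$min, b$q75, b$max, b$n_ok),
    sprintf("%-24s %8s %16s %22s %14s %14s", "method", "failed",
            "mean RMSE +/- SD", "range (IQR)", "Grubbs", "benchmark"))
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    lines <- c(lines, if (is.na(r$mean_rmse)) {
      sprintf("%-24s %3d/%-4d %16s %22s %14s %14s", r$method, r$n_failed,
              r$n_total, "-", "-", "-", "-")
    } else {
      sprintf("%-24s %3d/%-4d %7.2f +/- %.2f %9s (%s) %6d (%4.1f%%) %6d (%4.1f%%)",
              r$method, r$n_failed, r$n_total, r$mean_rmse, r$sd_rmse,
              sprintf("%.2f-%.2f", r$min_rmse, r$max_rmse),
              sprintf("%.2f-%.2f", r$q25_rmse, r$q75_rmse),
              r$grubbs_outliers, r$grubbs_pct,
              r$benchmark_outliers, r$benchmark_pct)
    })
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}

#' @export
print.experiment_report <- function(x, ...) {
  format_report_table(x)
  invisible(x)
}

# serialize the report (tables + JSON + deviation volumes) to a directory
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_impact_records(report$benchmark$records,
                       file.path(out_dir, "benchmark_records.tsv"))
  all_records <- do.call(rbind, lapply(report$methods, `[[`, "records"))
  write_impact_records(all_records, file.path(out_dir, "impact_records.tsv"))

  tab <- report_summary_table(report)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) sprintf("%.12g", v))
  utils::write.table(tab, file.path(out_dir, "summary_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  b <- report$benchmark$summary
  jsonlite::write_json(
    list(
      benchmark = list(n = b$n_ok, mean = b$mean, sd = b$sd, min = b$min,
                       q75 = b$q75, max = b$max),
      mask_n_voxels = report$mask_n_voxels,
      methods = lapply(report$methods, function(m) {
        row <- method_row(m)
        list(n_failed = row$n_failed, n_total = row$n_total,
             mean_rmse = row$mean_rmse, sd_rmse = row$sd_rmse,
             min_rmse = row$min_rmse, q25_rmse = row$q25_rmse,
             q75_rmse = row$q75_rmse, max_rmse = row$max_rmse,
             grubbs = list(n_flagged = m$grubbs$n_flagged,
                           flagged_ids = as.character(m$grubbs$flagged_ids),
                           alpha = m$grubbs$parameters$alpha),
             benchmark = list(n_flagged = m$benchmark$n_flagged,
                              flagged_ids = as.character(m$benchmark$flagged_ids),
                              threshold = m$benchmark$parameters$threshold))
      })
    ),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  if (report$config$write_volumes) {
    for (m in report$methods) {
      if (!is.null(m$deviation))
        write_volume(m$deviation$map,
                     file.path(out_dir, sprintf("deviation_%s.nii.gz", m$name)),
                     report$config$grid$voxel_size)
    }
  }
  invisible(out_dir)
}
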