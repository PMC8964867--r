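#' Construct a subject scan
#'
#' A `subject_scan` holds one subject's gray-matter density volume in common
#' space, already segmented, normalized, modulated and smoothed (the phantom
#' generator emits maps directly at this stage; there is no preprocessing
#' emulation).
#'
#' @param volume 3D numeric array of gray-matter density (unitless, >= 0).
#' @param age Age in years.
#' @param sex `"F"` or `"M"`.
#' @param subject_id Identifier string.
#' @param condition Acquisition/processing label: `"fullface"`, `"repeat"`,
#'   or `"perturbed:<name>"`.
#' @param grid The [grid_spec()] the volume lives on.
#' @return An object of class `subject_scan`.
#' @export
subject_scan <- function(volume, age, sex, subject_id,
                         condition = "fullface", grid) {
  stopifnot(is_grid_spec(grid))
  if (!identical(dim(volume), as.integer(grid$shape)))
    stop("volume shape does not match the grid")
  if (!all(is.finite(volume)))
    stop("volume contains non-finite values")
  if (min(volume) < 0)
    stop("gray-matter density must be non-negative")
  sex <- match.arg(sex, c("F", "M"))
  if (!is.finite(age) || age < 0) stop("invalid age")
  ok_cond <- condition %in% c("fullface", "repeat") ||
    startsWith(condition, "perturbed:")
  if (!ok_cond) stop("condition must be fullface, repeat or perturbed:<name>")
  structure(
    list(volume = volume, age = as.numeric(age), sex = sex,
         subject_id = as.character(subject_id), condition = condition,
         grid = grid),
    class = "subject_scan"
  )
}

#' @export
print.subject_scan <- function(x, ...) {
  cat(sprintf("<subject_scan> %s (%s, %.1f y, %s) on %s grid\n",
              x$subject_id, x$sex, x$age, x$condition,
              paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

#' Specify a synthetic reference cohort
#'
#' Defaults emulate, at reduced sample size, the demographic moments of a
#' large community normative cohort: about two-thirds female, ages 18-77 with
#' mean 46.3 and SD 17.1 years. Age can alternatively be sampled uniformly
#' over `age_range`, which gives even per-stratum coverage when the cohort is
#' used to build many age-windowed templates.
#'
#' @param n_subjects Number of reference subjects.
#' @param age_range Closed age interval in years.
#' @param age_mean,age_sd Moments of the truncated-normal age distribution
#'   (used when `age_dist = "truncnorm"`).
#' @param age_dist `"truncnorm"` or `"uniform"`.
#' @param sex_ratio Fraction of female subjects.
#' @param age_slope_amplitude Gray-matter density loss per year at the
#'   density peak.
#' @param subject_sd Point SD of the smooth between-subject random field
#'   (density units).
#' @param noise_sd Point SD of white within-scan noise (density units).
#' @param smoothness_fwhm FWHM (mm) of the between-subject field smoothing.
#' @param seed Integer seed; generation is a pure function of it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 120, age_range = c(18, 77),
                        age_mean = 46.3, age_sd = 17.1,
                        age_dist = c("truncnorm", "uniform"),
                        sex_ratio = 0.65, age_slope_amplitude = 0.003,
                        subject_sd = 0.05, noise_sd = 0.02,
                        smoothness_fwhm = 8, seed = 1L) {
  age_dist <- match.arg(age_dist)
  stopifnot(n_subjects >= 1, length(age_range) == 2L,
            age_range[1] <= age_range[2],
            sex_ratio >= 0, sex_ratio <= 1,
            subject_sd >= 0, noise_sd >= 0, smoothness_fwhm >= 0)
  structure(
    list(n_subjects = as.integer(n_subjects), age_range = as.numeric(age_range),
         age_mean = age_mean, age_sd = age_sd, age_dist = age_dist,
         sex_ratio = sex_ratio, age_slope_amplitude = age_slope_amplitude,
         subject_sd = subject_sd, noise_sd = noise_sd,
         smoothness_fwhm = smoothness_fwhm, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

draw_ages <- function(spec, n) {
  lo <- spec$age_range[1]; hi <- spec$age_range[2]
  if (spec$age_dist == "uniform" || spec$age_sd == 0) {
    stats::runif(n, lo, hi)
  } else {
    plo <- stats::pnorm(lo, spec$age_mean, spec$age_sd)
    phi <- stats::pnorm(hi, spec$age_mean, spec$age_sd)
    stats::qnorm(stats::runif(n, plo, phi), spec$age_mean, spec$age_sd)
  }
}

# one subject volume: mean model + smooth subject field + white noise, clipped
synth_volume <- function(age, sex, spec, atlas, subject_sd = spec$subject_sd,
                         noise_sd = spec$noise_sd) {
  grid <- atlas$grid
  v <- mean_gm_model(age, sex, atlas, spec$age_slope_amplitude)
  if (subject_sd > 0)
    v <- v + smooth_noise_field(grid, subject_sd, spec$smoothness_fwhm)
  if (noise_sd > 0)
    v <- v + array(stats::rnorm(prod(grid$shape), sd = noise_sd),
                   dim = grid$shape)
  clip0(v)
}

#' Generate a synthetic reference cohort
#'
#' Each scan is the age/sex mean density model plus a smooth subject-specific
#' random field and white scan noise, clipped at zero. Generation is
#' deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param grid A [grid_spec()].
#' @param atlas Optional pre-computed [region_atlas()] for `grid`.
#' @return A list of [subject_scan()] objects.
#' @export
generate_reference_cohort <- function(spec, grid, atlas = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), is_grid_spec(grid))
  if (is.null(atlas)) atlas <- region_atlas(grid)
  withr::with_seed(spec$seed, {
    ages <- draw_ages(spec, spec$n_subjects)
    sexes <- ifelse(stats::runif(spec$n_subjects) < spec$sex_ratio, "F", "M")
    lapply(seq_len(spec$n_subjects), function(i) {
      subject_scan(synth_volume(ages[i], sexes[i], spec, atlas),
                   age = ages[i], sex = sexes[i],
                   subject_id = sprintf("ref%04d", i),
                   condition = "fullface", grid = grid)
    })
  })
}

#' Simulate a within-session repeat acquisition
#'
#' Adds an independent, spatially smoothed, zero-mean noise field to the
#' volume, emulating the acquisition noise that differs between two
#' back-to-back scans of the same subject.
#'
#' @param scan A [subject_scan()].
#' @param repeat_sd Point SD of the added noise (density units).
#' @param smoothness_fwhm FWHM (mm) of the noise smoothing.
#' @param seed Integer seed.
#' @return A [subject_scan()] with condition `"repeat"`.
#' @export
simulate_repeat <- function(scan, repeat_sd, smoothness_fwhm = 8, seed = 1L) {
  stopifnot(inherits(scan, "subject_scan"), repeat_sd >= 0)
  vol <- scan$volume
  if (repeat_sd > 0)
    vol <- clip0(vol + smooth_noise_field(scan$grid, repeat_sd,
                                          smoothness_fwhm, seed = seed))
  subject_scan(vol, scan$age, scan$sex, scan$subject_id,
               condition = "repeat", grid = scan$grid)
}

#' Generate a patient scan with planted regional atrophy
#'
#' The patient volume starts from the population mean model for the given age
#' and sex (plus optional subject field and noise), then gray-matter density
#' is reduced inside each named atlas region by `effect x local reference SD`,
#' so the planted voxel-level z-effect is known by construction. When a
#' [build_template()] result is supplied as `template`, its `sd_map` is the
#' local reference SD and recovery through [zscore_map()] is exact up to
#' template sampling error; otherwise the theoretical point SD of the
#' generator, `sqrt(subject_sd^2 + noise_sd^2)` of `cohort`, is used.
#'
#' @param age,sex Patient demographics.
#' @param atrophy_regions Named numeric vector/list: region label ->
#'   planted z-effect (positive = atrophy, i.e. density reduction).
#' @param grid A [grid_spec()].
#' @param atlas Optional pre-computed [region_atlas()].
#' @param cohort A [cohort_spec()] giving the generator parameters the
#'   patient shares with the reference population.
#' @param template Optional `normative_template` whose `sd_map` scales the
#'   planted effect.
#' @param subject_sd,noise_sd Variability of the patient scan itself;
#'   default to the cohort values, set to 0 for a noise-free patient.
#' @param seed Integer seed.
#' @param subject_id Identifier.
#' @return A [subject_scan()] with condition `"fullface"`.
#' @export
generate_patient_scan <- function(age, sex, atrophy_regions = list(),
                                  grid, atlas = NULL,
                                  cohort = cohort_spec(),
                                  template = NULL,
                                  subject_sd = cohort$subject_sd,
                                  noise_sd = cohort$noise_sd,
                                  seed = 1L, subject_id = "patient") {
  stopifnot(is_grid_spec(grid))
  if (is.null(atlas)) atlas <- region_atlas(grid)
  for (r in names(atrophy_regions)) region_mask(atlas, r)  # validate labels

  sd_ref <- if (!is.null(template)) {
    stopifnot(inherits(template, "normative_template"))
    template$sd_map
  } else {
    array(sqrt(cohort$subject_sd^2 + cohort$noise_sd^2), dim = grid$shape)
  }

  vol <- withr::with_seed(derive_seed(seed, 0), {
    synth_volume(age, sex, cohort, atlas,
                 subject_sd = subject_sd, noise_sd = noise_sd)
  })
  for (r in names(atrophy_regions)) {
    eff <- as.numeric(atrophy_regions[[r]])
    if (eff != 0) {
      m <- region_mask(atlas, r)
      vol[m] <- vol[m] - eff * sd_ref[m]
    }
  }
  subject_scan(clip0(vol), age, sex, subject_id,
               condition = "fullface", grid = grid)
}
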