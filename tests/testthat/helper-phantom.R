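# shared fixture builders (all generated in code; nothing on disk)

tiny_grid <- function(n = 16L, vox = 8) grid_spec(rep(n, 3L), vox)

# a template with hand-chosen mean/SD supported on `n_active` voxels of an
# 8^3 grid: mean 10, SD 1 on the active voxels, 0 elsewhere, so the derived
# analysis mask is exactly the active set and z values equal (scan - 10)
toy_template <- function(n_active = 3L, grid = grid_spec(rep(8L, 3L), 1)) {
  mu <- array(0, dim = grid$shape)
  sdv <- array(0, dim = grid$shape)
  mu[seq_len(n_active)] <- 10
  sdv[seq_len(n_active)] <- 1
  normative_template(mu, sdv, grid, sex = "F", target_age = 60)
}

# scan whose z-scores against toy_template are exactly `z` on the active set
toy_scan <- function(z, template, age = 60, sex = "F", id = "s1") {
  vol <- template$mean_map
  vol[seq_along(z)] <- 10 + z
  subject_scan(vol, age, sex, id, grid = template$grid)
}

# single-stratum reference cohort (all female, ages 63-67 uniform)
stratum_cohort <- function(n = 40L, grid = grid_spec(c(32L, 32L, 32L), 4),
                           seed = 7L, subject_sd = 0.05, noise_sd = 0.02) {
  spec <- cohort_spec(n_subjects = n, age_range = c(63, 67),
                      age_dist = "uniform", sex_ratio = 1,
                      subject_sd = subject_sd, noise_sd = noise_sd,
                      seed = seed)
  list(spec = spec, grid = grid, atlas = region_atlas(grid),
       cohort = generate_reference_cohort(spec, grid))
}

# small but fully populated experiment configuration for pipeline tests
small_config <- function(seed = 1L, perturbations = NULL, ...) {
  grid <- grid_spec(c(16L, 16L, 16L), 8)
  reference <- cohort_spec(n_subjects = 160, age_range = c(58, 72),
                           age_dist = "uniform", seed = derive_tiny_seed(seed))
  if (is.null(perturbations))
    perturbations <- list(
      frontobasal_bias = perturbation_spec("frontobasal_bias",
                                           bias_amplitude = 0.02,
                                           bias_center = "frontobasal",
                                           bias_decay = 20),
      identity = perturbation_spec("identity")
    )
  experiment_config(grid = grid, reference = reference,
                    n_patients = 5, patient_age_range = c(60, 70),
                    n_benchmark = 5, min_n = 5,
                    perturbations = perturbations,
                    seed = seed, write_volumes = FALSE, ...)
}

derive_tiny_seed <- function(seed) as.integer(seed * 131 + 17)
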