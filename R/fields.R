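# Smooth scalar fields on the phantom grid.
#
# Smoothness is stated as FWHM in mm, the neuroimaging convention; the
# Gaussian kernel sigma is FWHM / (2*sqrt(2*log(2))).

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  x <- seq.int(-r, r)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# banded convolution matrix for a symmetric kernel, zero boundary
kernel_matrix <- function(k, n) {
  r <- (length(k) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (o in seq.int(-r, r)) {
    idx <- seq_len(n)
    src <- idx + o
    ok <- src >= 1L & src <= n
    K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + k[o + r + 1L]
  }
  K
}

conv_axis <- function(vol, K, axis) {
  n <- dim(vol)
  if (axis == 1L) {
    array(K %*% matrix(vol, n[1], n[2] * n[3]), dim = n)
  } else {
    perm <- switch(axis - 1L, c(2L, 1L, 3L), c(3L, 2L, 1L))
    v <- aperm(vol, perm)
    dv <- dim(v)
    v <- array(K %*% matrix(v, dv[1], dv[2] * dv[3]), dim = dv)
    aperm(v, perm)
  }
}

#' Smooth a volume with a separable Gaussian kernel
#'
#' Zero boundary condition (values outside the grid are treated as 0), the
#' natural choice for fields that vanish at the edge of the field of view.
#'
#' @param vol 3D numeric array.
#' @param fwhm_mm Kernel full width at half maximum in mm; 0 disables
#'   smoothing.
#' @param voxel_size Voxel size in mm per axis (length 3 or scalar).
#' @return Smoothed array of the same dimensions.
#' @export
smooth_volume <- function(vol, fwhm_mm, voxel_size) {
  stopifnot(length(dim(vol)) == 3L, fwhm_mm >= 0)
  if (fwhm_mm == 0) return(vol)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  for (a in 1:3) {
    k <- gaussian_kernel_1d(fwhm_to_sigma(fwhm_mm) / voxel_size[a])
    if (length(k) > 1L) vol <- conv_axis(vol, kernel_matrix(k, dim(vol)[a]), a)
  }
  vol
}

# point-SD attenuation factor of unit white noise under separable smoothing
# (interior voxels; exact for the zero-boundary kernel away from edges)
smooth_sd_factor <- function(fwhm_mm, voxel_size) {
  if (fwhm_mm == 0) return(1)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  f <- 1
  for (a in 1:3) {
    k <- gaussian_kernel_1d(fwhm_to_sigma(fwhm_mm) / voxel_size[a])
    f <- f * sum(k^2)
  }
  sqrt(f)
}

#' Generate a smooth zero-mean Gaussian random field
#'
#' White Gaussian noise is filtered with a Gaussian kernel of the stated FWHM
#' and rescaled so that the interior point standard deviation equals `sd`,
#' emulating the spatial correlation of smoothed voxel-based-morphometry maps.
#'
#' @param grid A [grid_spec()].
#' @param sd Target point standard deviation (gray-matter density units).
#' @param fwhm_mm Smoothing kernel FWHM in mm; 0 gives white noise.
#' @param seed Optional integer; when given, the field is a pure function of
#'   it and the global RNG state is left untouched.
#' @return 3D numeric array.
#' @export
smooth_noise_field <- function(grid, sd, fwhm_mm = 0, seed = NULL) {
  stopifnot(is_grid_spec(grid), sd >= 0)
  if (sd == 0) return(array(0, dim = grid$shape))
  draw <- function() {
    w <- array(stats::rnorm(prod(grid$shape)), dim = grid$shape)
    if (fwhm_mm > 0)
      w <- smooth_volume(w, fwhm_mm, grid$voxel_size) /
        smooth_sd_factor(fwhm_mm, grid$voxel_size)
    w * sd
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Baseline gray-matter density field: a smooth paraboloid profile on the
# ellipsoidal brain support, peak density at the centre.
base_gm_field <- function(atlas, peak = 0.85) {
  peak * pmax(1 - atlas$r2, 0)  # array first so dim attributes survive
}

#' Expected (noise-free) gray-matter density map for a given age and sex
#'
#' The population mean model is a smooth ellipsoidal density profile with a
#' linear age-related decline (proportional to local density, so loss is
#' strongest where gray matter is densest) and a small multiplicative sex
#' offset. Age is centred at a fixed reference age of 40 years.
#'
#' @param age Age in years.
#' @param sex `"F"` or `"M"`.
#' @param atlas A [region_atlas()].
#' @param age_slope_amplitude Density loss per year at the density peak.
#' @param peak Peak density of the baseline field.
#' @param sex_offset Fractional density offset: `+sex_offset` for F,
#'   `-sex_offset` for M.
#' @param reference_age Centering constant for the age term (years).
#' @return 3D numeric array (not yet clipped at 0).
#' @export
mean_gm_model <- function(age, sex, atlas, age_slope_amplitude = 0.003,
                          peak = 0.85, sex_offset = 0.02, reference_age = 40) {
  sex <- match.arg(sex, c("F", "M"))
  base <- base_gm_field(atlas, peak)
  s <- if (sex == "F") sex_offset else -sex_offset
  base * (1 + s) - age_slope_amplitude * (age - reference_age) * (base / peak)
}
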