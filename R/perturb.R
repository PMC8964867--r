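#' Specify a defacing-emulating perturbation
#'
#' Perturbations act directly on the gray-matter density map and are
#' parameterized to reproduce the kinds of deviation patterns defacing tools
#' induce downstream: a global multiplicative intensity change, a localized
#' Gaussian additive bias field (e.g. near the face or frontobasal brain), a
#' sub-voxel translation (registration jitter) and a density reduction
#' (erosion) inside a named region. A perturbation can also "crash" with a
#' given probability, emulating tools that fail to produce usable volumes.
#'
#' @param name Label for the emulated method.
#' @param bias_amplitude Peak of the additive Gaussian bias field (density
#'   units; may be negative).
#' @param bias_center Region label (bias centred at the region centroid) or a
#'   numeric length-3 voxel coordinate.
#' @param bias_decay Gaussian decay length sigma of the bias field, in mm.
#' @param global_scale Multiplicative factor applied to the whole volume
#'   (must be > 0).
#' @param jitter_mm Magnitude of a sub-voxel translation along the fixed
#'   diagonal direction (1,1,1)/sqrt(3), in mm, applied by trilinear
#'   interpolation.
#' @param erosion_region Optional region label in which density is reduced.
#' @param erosion_frac Fractional density reduction inside `erosion_region`.
#' @param failure_prob Probability that the perturbation fails and returns a
#'   [perturbation_failure] signal instead of a scan.
#' @param seed Integer seed (drives the failure draw; the geometric operators
#'   are deterministic).
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(name, bias_amplitude = 0,
                              bias_center = "face_exterior", bias_decay = 15,
                              global_scale = 1, jitter_mm = 0,
                              erosion_region = NULL, erosion_frac = 0,
                              failure_prob = 0, seed = 1L) {
  stopifnot(is.character(name), nchar(name) > 0,
            global_scale > 0, bias_decay > 0, jitter_mm >= 0,
            erosion_frac >= 0, erosion_frac <= 1,
            failure_prob >= 0, failure_prob <= 1)
  structure(
    list(name = name, bias_amplitude = bias_amplitude,
         bias_center = bias_center, bias_decay = bias_decay,
         global_scale = global_scale, jitter_mm = jitter_mm,
         erosion_region = erosion_region, erosion_frac = erosion_frac,
         failure_prob = failure_prob, seed = as.integer(seed)),
    class = "perturbation_spec"
  )
}

#' @rdname perturbation_spec
#' @param x Object to test.
#' @export
is_perturbation_failure <- function(x) inherits(x, "perturbation_failure")

perturbation_failure <- function(name, subject_id, stage = "perturbation") {
  structure(list(name = name, subject_id = subject_id, stage = stage),
            class = "perturbation_failure")
}

#' @export
print.perturbation_failure <- function(x, ...) {
  cat(sprintf("<perturbation_failure> %s on %s (stage %s)\n",
              x$name, x$subject_id, x$stage))
  invisible(x)
}

# shift a volume by an integer voxel offset, zero-filling
shift_integer <- function(vol, off) {
  n <- dim(vol)
  out <- array(0, dim = n)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    o <- off[a]
    if (abs(o) >= n[a]) return(out)
    if (o >= 0) { dst[[a]] <- seq.int(1L + o, n[a]); src[[a]] <- seq.int(1L, n[a] - o) }
    else        { dst[[a]] <- seq.int(1L, n[a] + o); src[[a]] <- seq.int(1L - o, n[a]) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
  out
}

# translate by a fractional voxel offset via trilinear interpolation
translate_trilinear <- function(vol, off_vox) {
  fl <- floor(off_vox)
  fr <- off_vox - fl
  out <- array(0, dim = dim(vol))
  for (c1 in 0:1) for (c2 in 0:1) for (c3 in 0:1) {
    w <- prod(ifelse(c(c1, c2, c3) == 1, fr, 1 - fr))
    if (w > 0) out <- out + w * shift_integer(vol, fl + c(c1, c2, c3))
  }
  out
}

#' Apply a perturbation to a scan
#'
#' Operators are applied in a fixed order: global scaling, additive bias
#' field `A * exp(-d^2 / (2 * sigma^2))`, sub-voxel translation, erosion,
#' then clipping at zero density. With probability `failure_prob` (drawn
#' deterministically from `pert$seed`) a typed failure signal is returned
#' instead; failures are bookkeeping outcomes, not errors.
#'
#' @param scan A [subject_scan()].
#' @param pert A [perturbation_spec()].
#' @param atlas Optional pre-computed [region_atlas()].
#' @return A [subject_scan()] with condition `"perturbed:<name>"`, or a
#'   `perturbation_failure` object.
#' @export
apply_perturbation <- function(scan, pert, atlas = NULL) {
  stopifnot(inherits(scan, "subject_scan"), inherits(pert, "perturbation_spec"))
  if (is.null(atlas)) atlas <- region_atlas(scan$grid)

  if (pert$failure_prob > 0) {
    scan_key <- sprintf("%s:%.6f:%s", scan$subject_id, scan$age, scan$sex)
    u <- withr::with_seed(
      derive_seed(pert$seed, label_offset(scan_key)),
      stats::runif(1))
    if (u < pert$failure_prob)
      return(perturbation_failure(pert$name, scan$subject_id))
  }

  vol <- scan$volume
  if (pert$global_scale != 1) vol <- vol * pert$global_scale
  if (pert$bias_amplitude != 0) {
    centre <- if (is.character(pert$bias_center)) {
      region_centroid(atlas, pert$bias_center)
    } else {
      (as.numeric(pert$bias_center) - 0.5) * scan$grid$voxel_size
    }
    d2 <- squared_distance_field(scan$grid, centre)
    vol <- vol + pert$bias_amplitude * exp(-d2 / (2 * pert$bias_decay^2))
  }
  if (pert$jitter_mm > 0) {
    off_vox <- pert$jitter_mm / sqrt(3) / scan$grid$voxel_size
    vol <- translate_trilinear(vol, off_vox)
  }
  if (!is.null(pert$erosion_region) && pert$erosion_frac > 0) {
    m <- region_mask(atlas, pert$erosion_region)
    vol[m] <- vol[m] * (1 - pert$erosion_frac)
  }
  subject_scan(clip0(vol), scan$age, scan$sex, scan$subject_id,
               condition = paste0("perturbed:", pert$name), grid = scan$grid)
}

#' Illustrative perturbation presets
#'
#' Six parameterizations spanning the qualitative behaviours observed when
#' defacing precedes voxel-based atrophy estimation: strong localized bias
#' with occasional failures, frontal/frontobasal bias, crash-prone moderate
#' bias, a small global intensity shift, and near-negligible perturbations
#' confined to the face region. The presets are illustrative operating points,
#' not calibrated models of any particular defacing tool.
#'
#' @return Named list of [perturbation_spec()] objects.
#' @export
default_perturbations <- function() {
  list(
    face_replace_average = perturbation_spec(
      "face_replace_average", bias_amplitude = 0.060,
      bias_center = "frontobasal", bias_decay = 18, jitter_mm = 0.3,
      failure_prob = 0.013, seed = 11L),
    face_crop = perturbation_spec(
      "face_crop", bias_amplitude = 0.010, bias_center = "frontobasal",
      bias_decay = 12, seed = 12L),
    crash_prone_strip = perturbation_spec(
      "crash_prone_strip", bias_amplitude = 0.015, bias_center = "temporal",
      bias_decay = 15, failure_prob = 0.21, seed = 13L),
    global_intensity_shift = perturbation_spec(
      "global_intensity_shift", global_scale = 1.01, seed = 14L),
    minimal_mask = perturbation_spec(
      "minimal_mask", bias_amplitude = 0.004, bias_center = "face_exterior",
      bias_decay = 20, seed = 15L),
    exterior_only = perturbation_spec(
      "exterior_only", bias_amplitude = 0.05, bias_center = "face_exterior",
      bias_decay = 3, seed = 16L)
  )
}
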