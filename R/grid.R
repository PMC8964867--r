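#' Define the sampling grid for synthetic volumes
#'
#' All synthetic scans live on a common regular grid, the stand-in for the
#' common template space that spatially normalized gray-matter maps share.
#'
#' @param shape Integer vector of length 3, voxels per axis. Each dimension
#'   must be at least 8.
#' @param voxel_size Numeric vector of length 3 (or a scalar, recycled), voxel
#'   edge length in mm per axis. Must be positive.
#'
#' @return An object of class `grid_spec` with elements `shape`, `voxel_size`
#'   and `extent` (field of view in mm per axis).
#' @export
#' @examples
#' grid_spec(c(32, 32, 32), 4)
grid_spec <- function(shape = c(32L, 32L, 32L), voxel_size = 4) {
  if (length(shape) != 3L || any(!is.finite(shape)))
    stop("`shape` must be three finite integers")
  shape <- as.integer(shape)
  if (any(shape < 8L))
    stop("degenerate grid: every dimension must be >= 8 voxels")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive values (mm)")
  structure(
    list(shape = shape, voxel_size = as.numeric(voxel_size),
         extent = shape * as.numeric(voxel_size)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %s voxels at %s mm (extent %s mm)\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size), collapse = "x"),
              paste(format(x$extent), collapse = "x")))
  invisible(x)
}

is_grid_spec <- function(x) inherits(x, "grid_spec")

# mm coordinate of each voxel centre along one axis (0-based corners)
axis_coords <- function(grid, axis) {
  (seq_len(grid$shape[axis]) - 0.5) * grid$voxel_size[axis]
}

# full 3D array whose value at (i,j,k) is the mm coordinate along `axis`
coord_array <- function(grid, axis) {
  n <- grid$shape
  co <- axis_coords(grid, axis)
  switch(axis,
         array(rep(co, times = n[2] * n[3]), dim = n),
         array(rep(rep(co, each = n[1]), times = n[3]), dim = n),
         array(rep(co, each = n[1] * n[2]), dim = n))
}

# squared mm distance of every voxel centre from a point `centre` (mm, length 3)
squared_distance_field <- function(grid, centre) {
  d1 <- (axis_coords(grid, 1L) - centre[1])^2
  d2 <- (axis_coords(grid, 2L) - centre[2])^2
  d3 <- (axis_coords(grid, 3L) - centre[3])^2
  outer(outer(d1, d2, "+"), d3, "+")
}

#' Geometric region atlas for the phantom brain
#'
#' The phantom brain is an axis-aligned ellipsoid occupying roughly 60% of
#' each grid dimension. Named regions are geometric sectors of it: four
#' octant-like sectors (`frontal`, `frontobasal`, `occipital`, `cerebellum`),
#' bilateral inferior-lateral `temporal` sectors, and a central `deep` ball.
#' A `face_exterior` slab sits anterior-inferior to the ellipsoid, outside
#' the brain support, as the stand-in for facial soft tissue removed or
#' replaced by defacing. Axis convention: axis 1 left-right, axis 2
#' posterior-anterior, axis 3 inferior-superior.
#'
#' @param grid A [grid_spec()].
#'
#' @return An object of class `region_atlas` with elements `labels` (named
#'   list of logical 3D masks), `brain` (logical mask of the whole ellipsoid),
#'   `centre`, `semiaxes` (mm) and `r2` (normalized squared ellipsoidal
#'   radius, used by the density model).
#' @export
region_atlas <- function(grid) {
  stopifnot(is_grid_spec(grid))
  centre <- grid$extent * c(0.5, 0.45, 0.55)
  semi <- 0.3 * grid$extent

  u1 <- (axis_coords(grid, 1L) - centre[1]) / semi[1]
  u2 <- (axis_coords(grid, 2L) - centre[2]) / semi[2]
  u3 <- (axis_coords(grid, 3L) - centre[3]) / semi[3]
  r2 <- outer(outer(u1^2, u2^2, "+"), u3^2, "+")
  brain <- r2 <= 1

  ux <- coord_array(grid, 1L); uy <- coord_array(grid, 2L); uz <- coord_array(grid, 3L)
  ux <- (ux - centre[1]) / semi[1]
  uy <- (uy - centre[2]) / semi[2]
  uz <- (uz - centre[3]) / semi[3]

  deep <- brain & (squared_distance_field(grid, centre) <= (0.35 * min(semi))^2)
  shell <- brain & !deep

  labels <- list(
    frontal     = shell & uy >  0.25 & uz >= 0,
    frontobasal = shell & uy >  0.25 & uz <  0,
    temporal    = shell & abs(uy) <= 0.25 & uz < 0 & abs(ux) > 0.3,
    occipital   = shell & uy < -0.25 & uz >= 0,
    cerebellum  = shell & uy < -0.25 & uz <  0,
    deep        = deep,
    face_exterior = (coord_array(grid, 2L) > centre[2] + semi[2]) &
                    (coord_array(grid, 3L) < centre[3]) & !brain
  )

  structure(
    list(labels = labels, brain = brain, centre = centre, semiaxes = semi,
         r2 = r2, grid = grid),
    class = "region_atlas"
  )
}

#' @export
print.region_atlas <- function(x, ...) {
  counts <- vapply(x$labels, sum, integer(1))
  cat("<region_atlas>\n")
  cat(sprintf("  brain support: %d voxels\n", sum(x$brain)))
  for (nm in names(counts)) cat(sprintf("  %-14s %d voxels\n", nm, counts[nm]))
  invisible(x)
}

region_mask <- function(atlas, name) {
  if (!name %in% names(atlas$labels))
    stop(sprintf("unknown region label '%s' (known: %s)", name,
                 paste(names(atlas$labels), collapse = ", ")))
  atlas$labels[[name]]
}

# mm centroid of a region
region_centroid <- function(atlas, name) {
  m <- region_mask(atlas, name)
  if (!any(m)) stop(sprintf("region '%s' is empty on this grid", name))
  c(mean(coord_array(atlas$grid, 1L)[m]),
    mean(coord_array(atlas$grid, 2L)[m]),
    mean(coord_array(atlas$grid, 3L)[m]))
}
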