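#' 3D image grid with physical geometry
#'
#' A `volume_grid` bundles a 3D scalar array with the physical geometry
#' needed to map voxel indices to millimetre coordinates: per-axis voxel
#' spacing, the physical position of voxel (0,0,0), and a 3x3 orthonormal
#' direction-cosine matrix. The internal physical frame is LPS
#' (+x = patient Left, +y = Posterior, +z = Superior) throughout the
#' package. Voxel indices are 0-based and voxel *centers* map to physical
#' points:
#'
#'   world(i,j,k) = origin + direction %*% (spacing * c(i,j,k))
#'
#' This mapping is the single source of truth for all coordinate math.
#'
#' @param voxels 3D numeric array of intensities (HU-like for CT images,
#'   0/1 integers for label maps).
#' @param spacing numeric length-3 (or scalar, recycled), voxel size in mm
#'   along each index axis; all components must be positive.
#' @param origin numeric length-3, physical LPS position (mm) of the center
#'   of voxel (0,0,0).
#' @param direction 3x3 direction-cosine matrix; columns are the physical
#'   directions of the three index axes. Must be orthonormal to 1e-6.
#' @param type `"image"` or `"label"`; label grids are restricted to
#'   values in {0,1} and are always resampled with nearest-neighbour
#'   interpolation.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(voxels, spacing, origin = c(0, 0, 0),
                        direction = diag(3), type = c("image", "label")) {
  type <- match.arg(type)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite values", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite values", call. = FALSE)
  direction <- matrix(as.numeric(direction), 3L, 3L)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("`direction` must be orthonormal (|D'D - I| <= 1e-6)", call. = FALSE)
  if (type == "label") {
    v <- as.vector(voxels)
    if (!all(v %in% c(0, 1)))
      stop("label volumes must contain only 0/1 values", call. = FALSE)
  }
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin,
         direction = direction, type = type),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume_grid [%s]> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              x$type, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (LPS mm): %.3f %.3f %.3f\n",
              x$origin[1], x$origin[2], x$origin[3]))
  rng <- range(x$voxels)
  cat(sprintf("  intensity range: [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Map 0-based voxel indices to physical LPS coordinates
#'
#' @param volume a [volume_grid].
#' @param idx numeric matrix (n x 3) of 0-based voxel indices (may be
#'   fractional), or a length-3 vector.
#' @return n x 3 matrix of LPS mm coordinates.
#' @export
voxel_to_world <- function(volume, idx) {
  idx <- rbind3(idx)
  scaled <- sweep(idx, 2L, volume$spacing, `*`)
  out <- scaled %*% t(volume$direction)
  sweep(out, 2L, volume$origin, `+`)
}

#' Map physical LPS coordinates to 0-based (fractional) voxel indices
#'
#' Inverse of [voxel_to_world()].
#'
#' @inheritParams voxel_to_world
#' @param points numeric matrix (n x 3) of LPS mm coordinates, or a
#'   length-3 vector.
#' @return n x 3 matrix of continuous 0-based voxel indices.
#' @export
world_to_voxel <- function(volume, points) {
  points <- rbind3(points)
  centered <- sweep(points, 2L, volume$origin, `-`)
  # direction is orthonormal: inverse = transpose
  idx <- centered %*% volume$direction
  sweep(idx, 2L, volume$spacing, `/`)
}

# coerce a length-3 vector or n x 3 matrix to an n x 3 matrix
rbind3 <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop("expected a length-3 point or n x 3 matrix", call. = FALSE)
    matrix(x, 1L, 3L)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != 3L) stop("expected an n x 3 coordinate matrix", call. = FALSE)
    x
  }
}

# physical centers of the 8 corner voxels (0-based index corners)
grid_corner_points <- function(volume) {
  d <- dim(volume$voxels) - 1L
  corners <- as.matrix(expand.grid(c(0, d[1]), c(0, d[2]), c(0, d[3])))
  voxel_to_world(volume, corners)
}

# physical extent corners (outer voxel *edges*, i.e. index -0.5 .. d-0.5)
grid_extent_corners <- function(volume) {
  d <- dim(volume$voxels)
  corners <- as.matrix(expand.grid(c(-0.5, d[1] - 0.5),
                                   c(-0.5, d[2] - 0.5),
                                   c(-0.5, d[3] - 0.5)))
  voxel_to_world(volume, corners)
}

# is a physical point strictly inside the voxel-edge extent of the grid?
point_in_extent <- function(volume, point) {
  idx <- world_to_voxel(volume, point)
  d <- dim(volume$voxels)
  all(idx > -0.5) && all(idx < d - 0.5)
}
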