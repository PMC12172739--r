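#' Read a CT volume from a NIfTI file
#'
#' Reads a NIfTI-1 file (`.nii` or `.nii.gz`) into a [volume_grid] in the
#' package's canonical LPS frame. NIfTI stores its voxel-to-world affine in
#' RAS; the first two rows are negated on read so that +x = Left and
#' +y = Posterior.
#'
#' @param path path to a NIfTI file.
#' @param type `"image"` or `"label"`.
#' @return A [volume_grid].
#' @seealso [write_volume()], [reorient_to_lps()]
#' @export
read_volume <- function(path, type = c("image", "label")) {
  type <- match.arg(type)
  if (dir.exists(path))
    stop("'", path, "' is a directory; only NIfTI files are supported ",
         "(convert DICOM series to NIfTI first)", call. = FALSE)
  if (!file.exists(path))
    stop("volume file not found: '", path, "'", call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to read '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  aff <- RNifti::xform(img)
  arr <- as.array(img)
  if (length(dim(arr)) > 3L) {
    if (prod(dim(arr)[-(1:3)]) != 1L)
      stop("'", path, "' has more than 3 non-singleton dimensions", call. = FALSE)
    arr <- array(arr, dim = dim(arr)[1:3])
  }
  attributes(arr) <- list(dim = dim(arr))
  geo <- affine_ras_to_geometry(aff)
  if (type == "label") arr[] <- as.numeric(arr != 0)
  volume_grid(arr, spacing = geo$spacing, origin = geo$origin,
              direction = geo$direction, type = type)
}

#' Write a volume to a NIfTI file
#'
#' Writes the voxel array and LPS geometry as a NIfTI-1 file with both
#' sform and qform set (RAS affine, per the NIfTI standard). Images are
#' stored as float64 so a write/read round trip preserves voxels exactly.
#'
#' @param volume a [volume_grid].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  aff <- geometry_to_affine_ras(volume)
  arr <- volume$voxels
  attr(arr, "pixdim") <- volume$spacing
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  datatype <- if (volume$type == "label") "uint8" else "double"
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

# NIfTI RAS affine (0-based voxel index -> RAS mm) to LPS geometry
affine_ras_to_geometry <- function(aff) {
  lps <- diag(c(-1, -1, 1)) %*% aff[1:3, , drop = FALSE]
  m <- lps[, 1:3, drop = FALSE]
  spacing <- sqrt(colSums(m^2))
  if (any(spacing <= 0)) stop("degenerate NIfTI affine", call. = FALSE)
  direction <- sweep(m, 2L, spacing, `/`)
  list(spacing = spacing, origin = lps[, 4], direction = direction)
}

geometry_to_affine_ras <- function(volume) {
  m <- sweep(volume$direction, 2L, volume$spacing, `*`)
  lps <- cbind(m, volume$origin)
  rbind(diag(c(-1, -1, 1)) %*% lps, c(0, 0, 0, 1))
}

#' Reorient a volume to axis-aligned LPS
#'
#' Permutes and flips the voxel array so that index axis 1 runs towards
#' patient Left, axis 2 towards Posterior and axis 3 towards Superior.
#' This is a pure index shuffle: the physical location of every voxel's
#' content is unchanged and no interpolation occurs.
#'
#' @param volume a [volume_grid].
#' @param tolerance maximum permitted off-axis component of the direction
#'   matrix (default 1e-3). Oblique volumes beyond this must be resampled
#'   instead.
#' @return A [volume_grid] whose direction matrix is the identity.
#' @export
reorient_to_lps <- function(volume, tolerance = 1e-3) {
  D <- volume$direction
  perm <- integer(3)
  sign <- numeric(3)
  for (ax in 1:3) {
    j <- which.max(abs(D[ax, ]))
    perm[ax] <- j
    sign[ax] <- base::sign(D[ax, j])
    if (abs(abs(D[ax, j]) - 1) > tolerance)
      stop("volume is oblique (off-axis direction cosines exceed tolerance ",
           tolerance, "); resample it to an axis-aligned grid first",
           call. = FALSE)
  }
  if (length(unique(perm)) != 3L)
    stop("degenerate direction matrix: axes are not separable", call. = FALSE)
  if (identical(perm, 1:3) && all(sign == 1))
    return(volume)

  arr <- aperm(volume$voxels, perm)
  d <- dim(arr)
  first_idx <- integer(3)  # old 0-based index (on permuted axes) of new voxel 0
  for (ax in 1:3) {
    if (sign[ax] < 0) {
      arr <- flip_axis(arr, ax)
      first_idx[ax] <- d[ax] - 1L
    }
  }
  # new origin = physical position of the voxel now at index (0,0,0)
  old_idx <- numeric(3)
  old_idx[perm] <- first_idx  # map back to original axis order
  new_origin <- as.numeric(voxel_to_world(volume, old_idx))
  new_spacing <- volume$spacing[perm]
  volume_grid(arr, spacing = new_spacing, origin = new_origin,
              direction = diag(3), type = volume$type)
}

flip_axis <- function(arr, axis) {
  d <- dim(arr)
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- d[axis]:1
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

#' Resample a volume to a new voxel spacing
#'
#' Resamples onto a new axis-aligned grid covering the input's physical
#' extent, with trilinear interpolation for images and nearest-neighbour
#' for label maps (labels are never linearly interpolated, so their values
#' stay in {0,1}). Voxels outside the input extent receive `fill`
#' (default -1024 for images — air in Hounsfield units — and 0 for labels).
#'
#' @param volume a [volume_grid] with an axis-aligned direction matrix
#'   (run [reorient_to_lps()] first if needed).
#' @param target_spacing numeric length-3 (or scalar, recycled), mm.
#' @param interpolation `"linear"` or `"nearest"`; defaults to linear for
#'   images and nearest for labels.
#' @param fill value assigned outside the input extent.
#' @return A [volume_grid] at the requested spacing.
#' @export
resample <- function(volume, target_spacing,
                     interpolation = if (volume$type == "label") "nearest" else "linear",
                     fill = default_fill(volume)) {
  target_spacing <- rep_len(as.numeric(target_spacing), 3L)
  if (any(!is.finite(target_spacing)) || any(target_spacing <= 0))
    stop("`target_spacing` must be positive", call. = FALSE)
  interpolation <- match.arg(interpolation, c("linear", "nearest"))
  if (volume$type == "label" && interpolation != "nearest")
    stop("label maps must be resampled with nearest-neighbour interpolation",
         call. = FALSE)

  d <- dim(volume$voxels)
  extent <- volume$spacing * d  # voxel-edge physical extent along each axis
  n_out <- pmax(1L, as.integer(ceiling(extent / target_spacing - 1e-9)))
  # corner (outer edge) of the input grid, then back in by half an output voxel
  corner <- volume$origin - as.numeric(volume$direction %*% (volume$spacing / 2))
  origin_out <- corner + as.numeric(volume$direction %*% (target_spacing / 2))

  out <- volume_grid(array(0, dim = n_out), spacing = target_spacing,
                     origin = origin_out, direction = volume$direction,
                     type = volume$type)
  pts <- all_voxel_centers(out)
  vals <- sample_at_points(volume, pts, interpolation = interpolation, fill = fill)
  out$voxels <- array(vals, dim = n_out)
  out
}

#' Rescale intensities to the unit interval
#'
#' Maps intensities linearly so the minimum becomes 0 and the maximum 1:
#' `(v - min) / (max - min)`.
#'
#' @param volume a [volume_grid] of type `"image"` with finite min < max.
#' @return A [volume_grid] with voxels in `[0, 1]`.
#' @export
normalize_intensity <- function(volume) {
  rng <- range(volume$voxels)
  if (any(!is.finite(rng)))
    stop("volume contains non-finite intensities", call. = FALSE)
  if (rng[1] >= rng[2])
    stop("constant volume: intensity normalization is undefined", call. = FALSE)
  volume$voxels <- (volume$voxels - rng[1]) / (rng[2] - rng[1])
  volume
}
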