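#' Specification of a synthetic skull phantom
#'
#' Describes a schematic head-like CT phantom: an ellipsoidal head with a
#' bony shell, soft-tissue interior, an anterior bony wedge at the nasal
#' bridge, and three small high-density spheres marking the alignment
#' landmarks (right cochlea, left cochlea, nasal bridge). Geometry is
#' schematic by design — only the landmark geometry matters to the
#' alignment algorithm under test — but proportions are anatomically
#' plausible: cochleas ~60 mm apart left-right near the skull base, nasal
#' bridge anterior and close to the cochlear plane.
#'
#' The default grid (128 x 128 x 80 voxels at 1.5 mm isotropic) matches
#' the working resolution of the alignment pipeline.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing_mm numeric length-3 (or scalar), voxel size in mm.
#' @param cochlea_separation_mm left-right distance between the cochlear
#'   landmark centers (mm); must exceed one landmark diameter.
#' @param nasal_bridge_offset_mm length-2: anterior offset and craniocaudal
#'   (superior) offset of the nasal bridge from the inter-cochlear
#'   midpoint, in mm. The default craniocaudal offset of 0 puts the
#'   canonical phantom exactly in its aligned pose, so a recovered
#'   alignment can be compared directly against the applied misalignment.
#' @param cochlea_center_mm LPS position of the inter-cochlear midpoint.
#' @param head_semiaxes_mm semi-axes of the head ellipsoid (mm).
#' @param skull_intensity,tissue_intensity,air_intensity Hounsfield-unit
#'   like intensities for bone, soft tissue and background air.
#' @param landmark_intensity intensity of the landmark spheres; kept above
#'   `skull_intensity` so a simple threshold detector can find them.
#' @param landmark_radius_mm radius of the landmark spheres (mm); default
#'   5 (a 1 cm diameter sphere, matching the annotation ROI size).
#' @param seed integer recorded for provenance; generation itself is
#'   deterministic.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(128L, 128L, 80L),
                         spacing_mm = 1.5,
                         cochlea_separation_mm = 60,
                         nasal_bridge_offset_mm = c(70, 0),
                         cochlea_center_mm = c(0, 10, -15),
                         head_semiaxes_mm = c(70, 85, 55),
                         skull_intensity = 700,
                         tissue_intensity = 40,
                         air_intensity = -1024,
                         landmark_intensity = 2000,
                         landmark_radius_mm = 5,
                         seed = 1L) {
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  if (any(spacing_mm <= 0)) stop("all spacings must be positive", call. = FALSE)
  if (any(grid_shape < 8L)) stop("grid_shape must be at least 8 voxels per axis", call. = FALSE)
  if (landmark_radius_mm <= 0) stop("landmark_radius_mm must be positive", call. = FALSE)
  if (cochlea_separation_mm <= 2 * landmark_radius_mm)
    stop("cochlea_separation_mm must exceed one landmark diameter (",
         2 * landmark_radius_mm, " mm)", call. = FALSE)
  if (length(nasal_bridge_offset_mm) != 2L)
    stop("nasal_bridge_offset_mm must be c(anterior, craniocaudal)", call. = FALSE)
  if (landmark_intensity <= skull_intensity)
    stop("landmark_intensity must exceed skull_intensity so landmarks are ",
         "separable by threshold", call. = FALSE)
  spec <- structure(
    list(grid_shape = grid_shape, spacing_mm = spacing_mm,
         cochlea_separation_mm = cochlea_separation_mm,
         nasal_bridge_offset_mm = as.numeric(nasal_bridge_offset_mm),
         cochlea_center_mm = as.numeric(cochlea_center_mm),
         head_semiaxes_mm = as.numeric(head_semiaxes_mm),
         skull_intensity = skull_intensity,
         tissue_intensity = tissue_intensity,
         air_intensity = air_intensity,
         landmark_intensity = landmark_intensity,
         landmark_radius_mm = landmark_radius_mm,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
  # landmark points must lie strictly inside the grid's physical extent
  geo <- phantom_geometry(spec)
  lm <- phantom_landmarks(spec)
  for (nm in c("right_cochlea", "left_cochlea", "nasal_bridge")) {
    if (!point_in_extent(geo, lm[[nm]]))
      stop("configuration error: landmark '", nm,
           "' lies outside the phantom grid extent", call. = FALSE)
  }
  spec
}

# empty grid centered on the LPS origin
phantom_geometry <- function(spec) {
  extent <- spec$grid_shape * spec$spacing_mm
  origin <- -extent / 2 + spec$spacing_mm / 2
  volume_grid(array(0, dim = spec$grid_shape), spacing = spec$spacing_mm,
              origin = origin, direction = diag(3), type = "image")
}

#' Exact landmark positions implied by a phantom spec
#'
#' The analytic sphere centers, without voxelizing anything. These are the
#' ground truth every detection and alignment result is judged against.
#'
#' @param spec a [phantom_spec].
#' @return A [landmark_set] with `source = "manual"`.
#' @export
phantom_landmarks <- function(spec) {
  mid <- spec$cochlea_center_mm
  half <- spec$cochlea_separation_mm / 2
  rc <- mid + c(-half, 0, 0)
  lc <- mid + c(half, 0, 0)
  nb <- mid + c(0, -spec$nasal_bridge_offset_mm[1], spec$nasal_bridge_offset_mm[2])
  landmark_set(rc, lc, nb, source = "manual")
}

#' Generate a synthetic skull phantom
#'
#' Builds the phantom volume described by `spec` together with the exact
#' landmark positions and one voxelized spherical label map per landmark.
#' Generation is fully deterministic: the same spec always yields
#' bit-identical arrays.
#'
#' @param spec a [phantom_spec].
#' @return A list with elements `volume` ([volume_grid]), `landmarks`
#'   (exact [landmark_set]), `labels` (named list of label [volume_grid]s)
#'   and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_geometry(spec)
  lm <- phantom_landmarks(spec)
  pts <- all_voxel_centers(geo)

  ax <- spec$head_semiaxes_mm
  # normalized ellipsoid radius about the head center
  rr <- (pts[, 1] / ax[1])^2 + (pts[, 2] / ax[2])^2 + (pts[, 3] / ax[3])^2
  vox <- rep(spec$air_intensity, nrow(pts))
  vox[rr <= 1] <- spec$skull_intensity          # bony shell (outer ellipsoid)
  vox[rr <= 0.88^2] <- spec$tissue_intensity    # soft-tissue interior

  # anterior bony wedge suggesting the nasal ridge (cosmetic; the landmark
  # sphere itself defines the nasal bridge point)
  nb <- lm$nasal_bridge
  wedge <- pts[, 2] < nb[2] + 6 & pts[, 2] > nb[2] - 14 &
           abs(pts[, 3] - nb[3]) < 16 &
           abs(pts[, 1]) < 6 * (pts[, 2] - (nb[2] - 14)) / 20 &
           rr <= 1
  vox[wedge] <- spec$skull_intensity

  # landmark spheres, written last so they dominate locally
  r2 <- spec$landmark_radius_mm^2
  for (nm in c("right_cochlea", "left_cochlea", "nasal_bridge")) {
    p <- lm[[nm]]
    d2 <- (pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 + (pts[, 3] - p[3])^2
    vox[d2 <= r2] <- spec$landmark_intensity
  }

  geo$voxels <- array(vox, dim = spec$grid_shape)
  labels <- list(
    right_cochlea = sphere_label(lm$right_cochlea, geo, 2 * spec$landmark_radius_mm),
    left_cochlea = sphere_label(lm$left_cochlea, geo, 2 * spec$landmark_radius_mm),
    nasal_bridge = sphere_label(lm$nasal_bridge, geo, 2 * spec$landmark_radius_mm)
  )
  list(volume = geo, landmarks = lm, labels = labels, spec = spec)
}

#' Specification of a rigid misalignment
#'
#' Signed rotation angles (degrees) about the z (yaw), x (pitch) and y
#' (roll) axes, applied in yaw -> pitch -> roll order about `center`.
#' Angles are capped at `max_deg` per plane, mirroring the rotation
#' envelope the detection model is trained for (45 degrees per plane).
#'
#' @param yaw_deg,pitch_deg,roll_deg rotation angles in degrees.
#' @param center rotation center (LPS mm); `NULL` means the inter-cochlear
#'   midpoint of whatever landmark set it is applied to.
#' @param max_deg per-plane cap on |angle| (default 45).
#' @param seed optional integer recorded for provenance.
#' @return An object of class `misalignment_spec`.
#' @export
misalignment_spec <- function(yaw_deg = 0, pitch_deg = 0, roll_deg = 0,
                              center = NULL, max_deg = 45, seed = NULL) {
  ang <- c(yaw_deg, pitch_deg, roll_deg)
  if (any(!is.finite(ang))) stop("angles must be finite", call. = FALSE)
  if (any(abs(ang) > max_deg))
    stop("misalignment angles must satisfy |angle| <= ", max_deg,
         " degrees per plane", call. = FALSE)
  structure(
    list(yaw_deg = yaw_deg, pitch_deg = pitch_deg, roll_deg = roll_deg,
         center = if (is.null(center)) NULL else as.numeric(center),
         max_deg = max_deg, seed = seed),
    class = "misalignment_spec"
  )
}

misalignment_transform <- function(mis, landmarks = NULL) {
  center <- mis$center
  if (is.null(center)) {
    if (is.null(landmarks))
      stop("misalignment has no center and no landmarks were supplied", call. = FALSE)
    center <- cochlear_midpoint(landmarks)
  }
  rigid_transform(euler_to_matrix(mis$yaw_deg, mis$pitch_deg, mis$roll_deg),
                  center = center,
                  angles = c(yaw_deg = mis$yaw_deg, pitch_deg = mis$pitch_deg,
                             roll_deg = mis$roll_deg))
}

#' Apply a known rigid misalignment to a phantom
#'
#' Rotates the volume in a single interpolation pass (extending the grid
#' in z so no slice data is lost) and propagates the landmark points
#' *analytically* through the same transform — image discretization never
#' contaminates the ground truth.
#'
#' @param volume a [volume_grid].
#' @param landmarks the exact [landmark_set] in the volume's frame.
#' @param mis a [misalignment_spec].
#' @param expand_z grow the output grid in z to cover the rotated extent
#'   (default `TRUE`).
#' @return A list with `volume` (rotated), `landmarks` (exactly
#'   transformed), and `transform` (the applied [rigid_transform],
#'   determinant +1).
#' @export
apply_misalignment <- function(volume, landmarks, mis, expand_z = TRUE) {
  stopifnot(inherits(mis, "misalignment_spec"))
  tr <- misalignment_transform(mis, landmarks)
  rotated <- apply_transform(volume, tr, expand_z = expand_z)
  lm2 <- transform_landmarks(landmarks, tr, validate = FALSE)
  list(volume = rotated, landmarks = lm2, transform = tr)
}

#' Draw random misalignment specifications
#'
#' Each angle is drawn independently and uniformly on
#' `[-max_deg, +max_deg]`. Reproducible under `seed`; the caller's RNG
#' state is left untouched.
#'
#' @param n number of specs (>= 1).
#' @param max_deg per-plane angle bound in degrees (>= 0, default 45).
#' @param seed integer seed.
#' @return A list of `n` [misalignment_spec] objects.
#' @export
sample_misalignments <- function(n, max_deg = 45, seed = 1L) {
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  if (max_deg < 0) stop("`max_deg` must be non-negative", call. = FALSE)
  ang <- with_preserved_seed(seed, {
    matrix(stats::runif(3 * n, -max_deg, max_deg), ncol = 3)
  })
  lapply(seq_len(n), function(i)
    misalignment_spec(ang[i, 1], ang[i, 2], ang[i, 3],
                      max_deg = max(max_deg, 45), seed = seed))
}

# run code under a fixed seed, restoring the caller's RNG state afterwards
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
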