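#' Axial (yaw) alignment angle
#'
#' Rotation about the z axis that brings the two cochleas to equal y
#' (anterior-posterior symmetry in the axial plane). The solution with
#' |yaw| <= 90 degrees is chosen, which keeps the left cochlea on the
#' patient's left.
#'
#' @param landmarks a [landmark_set].
#' @return Yaw angle in degrees.
#' @export
compute_yaw <- function(landmarks) {
  d <- landmarks$left_cochlea - landmarks$right_cochlea
  if (sqrt(d[1]^2 + d[2]^2) < 1e-9)
    stop("degenerate geometry: cochleas coincide in the x-y plane; ",
         "yaw is undefined", call. = FALSE)
  yaw <- -atan2(d[2], d[1]) * 180 / pi
  if (abs(yaw) > 90 + 1e-9)
    stop("degenerate geometry: no yaw within 90 degrees keeps the left ",
         "cochlea on the left", call. = FALSE)
  yaw
}

#' Sagittal (pitch) alignment angle
#'
#' Rotation about the x axis that brings the nasal bridge and the right
#' cochlea to equal z, on the branch that keeps the nasal bridge anterior
#' (|pitch| <= 90 degrees).
#'
#' @param landmarks a [landmark_set].
#' @return Pitch angle in degrees.
#' @export
compute_pitch <- function(landmarks) {
  d <- landmarks$nasal_bridge - landmarks$right_cochlea
  if (sqrt(d[2]^2 + d[3]^2) < 1e-9)
    stop("degenerate geometry: nasal bridge and right cochlea coincide in ",
         "the y-z plane; pitch is undefined", call. = FALSE)
  # rotate the in-plane angle of (dy, dz) onto 180 degrees (pure -y)
  alpha <- atan2(d[3], d[2])
  pitch <- (pi - alpha) * 180 / pi
  if (pitch > 180) pitch <- pitch - 360
  if (abs(pitch) > 90 + 1e-9)
    stop("degenerate geometry: no pitch within 90 degrees keeps the nasal ",
         "bridge anterior to the right cochlea", call. = FALSE)
  pitch
}

#' Coronal (roll) alignment angle
#'
#' Rotation about the y axis that brings the two cochleas to equal z
#' (craniocaudal symmetry), on the branch keeping the left cochlea left.
#'
#' @param landmarks a [landmark_set].
#' @return Roll angle in degrees.
#' @export
compute_roll <- function(landmarks) {
  d <- landmarks$left_cochlea - landmarks$right_cochlea
  if (sqrt(d[1]^2 + d[3]^2) < 1e-9)
    stop("degenerate geometry: cochleas coincide in the x-z plane; ",
         "roll is undefined", call. = FALSE)
  roll <- atan2(d[3], d[1]) * 180 / pi
  if (abs(roll) > 90 + 1e-9)
    stop("degenerate geometry: no roll within 90 degrees keeps the left ",
         "cochlea on the left", call. = FALSE)
  roll
}

#' Sequential three-rotation alignment
#'
#' The plane-by-plane alignment procedure: yaw is computed on the input
#' landmarks, the landmarks are rotated; pitch is computed on the rotated
#' set, rotated again; roll is computed last. The three rotations are
#' composed into a single rigid transform
#' `R = R_roll %*% R_pitch %*% R_yaw` about one center, so applying it to
#' an image incurs exactly one interpolation.
#'
#' After the composite, the cochlear z deviation is exactly zero (roll is
#' last and exact) while a small residual y deviation of
#' `|dz after yaw| * |sin(pitch)|` remains — the pitch rotation re-tilts
#' the cochlear axis out of the y plane that yaw had fixed.
#'
#' @param landmarks a [landmark_set].
#' @param center rotation center; default the inter-cochlear midpoint.
#' @return A list with `angles` (named: `yaw_deg`, `pitch_deg`,
#'   `roll_deg`) and `transform` (a [rigid_transform] with
#'   `mode = "sequential"`).
#' @export
compute_alignment_sequential <- function(landmarks, center = NULL) {
  if (is.null(center)) center <- cochlear_midpoint(landmarks)
  yaw <- compute_yaw(landmarks)
  l1 <- transform_landmarks(landmarks,
                            rigid_transform(rot_z(yaw), center),
                            validate = FALSE)
  pitch <- compute_pitch(l1)
  l2 <- transform_landmarks(l1,
                            rigid_transform(rot_x(pitch), center),
                            validate = FALSE)
  roll <- compute_roll(l2)
  angles <- c(yaw_deg = yaw, pitch_deg = pitch, roll_deg = roll)
  tr <- rigid_transform(euler_to_matrix(yaw, pitch, roll), center,
                        angles = angles, mode = "sequential")
  list(angles = angles, transform = tr)
}

#' Exact closed-form alignment
#'
#' One-shot rotation that satisfies all three alignment constraints
#' simultaneously: cochleas at equal y and equal z, nasal bridge and right
#' cochlea at equal z. It maps the orthonormal anatomical frame
#' `e1 = unit(left - right cochlea)`,
#' `e2 = unit component of (nasal bridge - right cochlea) orthogonal to e1`,
#' `e3 = e1 x e2` onto `(1,0,0)`, `(0,-1,0)`, `(0,0,-1)` respectively.
#' Used as the analytic oracle for the sequential method and as an
#' optional "perfect" alignment variant.
#'
#' @param landmarks a [landmark_set].
#' @param center rotation center; default the inter-cochlear midpoint.
#' @return A [rigid_transform] with `mode = "exact"`.
#' @export
compute_alignment_exact <- function(landmarks, center = NULL) {
  if (is.null(center)) center <- cochlear_midpoint(landmarks)
  e1 <- landmarks$left_cochlea - landmarks$right_cochlea
  n1 <- sqrt(sum(e1^2))
  if (n1 < 1e-9) stop("degenerate geometry: cochleas coincide", call. = FALSE)
  e1 <- e1 / n1
  v <- landmarks$nasal_bridge - landmarks$right_cochlea
  e2 <- v - sum(v * e1) * e1
  n2 <- sqrt(sum(e2^2))
  if (n2 < 1e-9)
    stop("degenerate geometry: landmarks are collinear", call. = FALSE)
  e2 <- e2 / n2
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  E <- cbind(e1, e2, e3)
  R <- diag(c(1, -1, -1)) %*% t(E)
  angles <- tryCatch(matrix_to_euler(R), error = function(e) NULL)
  rigid_transform(R, center, angles = angles, mode = "exact")
}

#' Resample a volume through a rigid transform in one pass
#'
#' Applies `transform` to the volume with exactly one interpolation
#' (trilinear for images, nearest-neighbour for labels). With
#' `expand_z = TRUE` the output grid is extended along z until every
#' transformed corner of the input extent is covered, so no craniocaudal
#' data is lost to rotation; the x-y extent is unchanged and new voxels
#' receive `fill`.
#'
#' @param volume a [volume_grid].
#' @param transform a [rigid_transform].
#' @param expand_z grow the z extent to cover the rotated volume
#'   (default `FALSE`).
#' @param fill value for voxels mapping outside the input (default -1024
#'   for images, 0 for labels).
#' @param interpolation override (`"linear"`/`"nearest"`); defaults by
#'   volume type.
#' @return A resampled [volume_grid].
#' @export
apply_transform <- function(volume, transform, expand_z = FALSE,
                            fill = default_fill(volume),
                            interpolation = if (volume$type == "label") "nearest" else "linear") {
  interpolation <- match.arg(interpolation, c("linear", "nearest"))
  if (volume$type == "label" && interpolation != "nearest")
    stop("label maps must be resampled with nearest-neighbour interpolation",
         call. = FALSE)
  out <- volume
  if (expand_z) {
    corners <- transform_points(grid_extent_corners(volume), transform)
    # continuous index of each corner along the third index axis
    rel <- sweep(corners, 2L, volume$origin, `-`) %*% volume$direction
    t3 <- rel[, 3] / volume$spacing[3]
    n3 <- dim(volume$voxels)[3]
    k_lo <- max(0L, as.integer(ceiling(-min(t3) - 0.5 - 1e-9)))
    k_hi <- max(0L, as.integer(ceiling(max(t3) - (n3 - 0.5) + 1e-9)))
    if (k_lo > 0L || k_hi > 0L) {
      d <- dim(volume$voxels)
      new_d <- c(d[1], d[2], d[3] + k_lo + k_hi)
      out <- volume_grid(array(as.numeric(fill), dim = new_d),
                         spacing = volume$spacing,
                         origin = volume$origin -
                           as.numeric(volume$direction %*% c(0, 0, k_lo * volume$spacing[3])),
                         direction = volume$direction, type = volume$type)
    }
  }
  inv <- invert_transform(transform)
  pts <- transform_points(all_voxel_centers(out), inv)
  vals <- sample_at_points(volume, pts, interpolation = interpolation, fill = fill)
  out$voxels <- array(vals, dim = dim(out$voxels))
  out
}

#' Align a head CT volume from its three landmarks
#'
#' One-stop pipeline: computes the alignment rotation from the landmarks
#' (sequential plane-by-plane method by default, or the exact closed
#' form), applies it to the volume in a single interpolation pass, and
#' propagates the landmark points analytically. An optional constant
#' sagittal offset can be added to bias the result towards true AC-PC
#' orientation (the cochlea-nasal bridge plane sits about 5 degrees off
#' AC-PC on average).
#'
#' @param volume a [volume_grid].
#' @param landmarks a [landmark_set] in the volume's frame.
#' @param mode `"sequential"` (plane-by-plane, the default) or `"exact"`.
#' @param expand_z preserve craniocaudal data by adding slices
#'   (default `TRUE`).
#' @param fill fill value for created voxels (default -1024).
#' @param sagittal_offset_deg extra pitch applied after alignment,
#'   in (-15, 15) degrees; default 0.
#' @return A list with `volume` (aligned), `landmarks` (analytically
#'   aligned), `angles`, `transform` and `residuals` (the post-alignment
#'   cochlear y/z deviations in mm).
#' @export
align_volume <- function(volume, landmarks, mode = c("sequential", "exact"),
                         expand_z = TRUE, fill = default_fill(volume),
                         sagittal_offset_deg = 0) {
  mode <- match.arg(mode)
  if (abs(sagittal_offset_deg) >= 15)
    stop("`sagittal_offset_deg` must lie within (-15, 15)", call. = FALSE)
  if (mode == "sequential") {
    fit <- compute_alignment_sequential(landmarks)
    tr <- fit$transform
  } else {
    tr <- compute_alignment_exact(landmarks)
  }
  if (sagittal_offset_deg != 0) {
    R <- rot_x(sagittal_offset_deg) %*% tr$rotation
    tr <- rigid_transform(R, tr$center,
                          angles = tryCatch(matrix_to_euler(R), error = function(e) NULL),
                          mode = mode)
  }
  aligned_lm <- transform_landmarks(landmarks, tr, validate = FALSE)
  aligned <- apply_transform(volume, tr, expand_z = expand_z, fill = fill)
  res <- cochlear_deviation(aligned_lm)
  list(volume = aligned, landmarks = aligned_lm,
       angles = tr$angles, transform = tr,
       residuals = c(y_dev_mm = res$y_dev_mm, z_dev_mm = res$z_dev_mm))
}
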