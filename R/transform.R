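#' Rigid (proper rotation) transform about a center point
#'
#' Represents the mapping `p -> R (p - c) + c` where `R` is a proper
#' rotation matrix (`R'R = I`, `det(R) = +1`) and `c` a fixed center in
#' LPS mm. No translation or scaling component: the alignment method is
#' purely rotational.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param center length-3 LPS mm point the rotation pivots about.
#' @param angles optional named numeric of the yaw/pitch/roll decomposition
#'   (degrees), carried for reporting.
#' @param mode optional label (`"sequential"` or `"exact"`).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation, center = c(0, 0, 0),
                            angles = NULL, mode = NULL) {
  rotation <- matrix(as.numeric(rotation), 3L, 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("`rotation` is not orthonormal to 1e-9", call. = FALSE)
  if (abs(det(rotation) - 1) > 1e-9)
    stop("`rotation` is not a proper rotation (det != +1)", call. = FALSE)
  structure(
    list(rotation = rotation, center = as.numeric(center),
         angles = angles, mode = mode),
    class = "rigid_transform"
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>")
  if (!is.null(x$mode)) cat(" mode =", x$mode)
  cat("\n  center (LPS mm):", sprintf("%.3f", x$center), "\n")
  if (!is.null(x$angles))
    cat("  angles (deg):",
        paste(names(x$angles), sprintf("%.4f", x$angles), collapse = ", "), "\n")
  print(round(x$rotation, 6))
  invisible(x)
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform].
#' @return The inverse [rigid_transform] (same center, transposed rotation).
#' @export
invert_transform <- function(transform) {
  rigid_transform(t(transform$rotation), transform$center, mode = transform$mode)
}

#' Compose two rigid transforms about a shared center
#'
#' Returns the transform equivalent to applying `first`, then `second`.
#' Both must share the same center point.
#'
#' @param first,second [rigid_transform] objects with equal centers.
#' @return A [rigid_transform].
#' @export
compose_transforms <- function(second, first) {
  if (max(abs(second$center - first$center)) > 1e-9)
    stop("transforms must share a rotation center to compose", call. = FALSE)
  rigid_transform(second$rotation %*% first$rotation, first$center)
}

#' Apply a rigid transform to physical points
#'
#' Exact analytic mapping `p -> R (p - c) + c`; no image grid or
#' discretization involved.
#'
#' @param points n x 3 matrix of LPS mm coordinates (or a length-3 vector).
#' @param transform a [rigid_transform].
#' @return n x 3 matrix of transformed coordinates.
#' @export
transform_points <- function(points, transform) {
  p <- rbind3(points)
  centered <- sweep(p, 2L, transform$center, `-`)
  out <- centered %*% t(transform$rotation)
  sweep(out, 2L, transform$center, `+`)
}

# --- Elemental rotations (right-handed, angles in degrees) ---------------
# Axes follow the LPS frame: yaw rotates about z (axial plane), pitch
# about x (sagittal plane), roll about y (coronal plane).

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' Compose yaw, pitch and roll into one rotation matrix
#'
#' Order is fixed as axial -> sagittal -> coronal: the composite is
#' `R_y(roll) %*% R_x(pitch) %*% R_z(yaw)`, i.e. yaw is applied first.
#'
#' @param yaw_deg,pitch_deg,roll_deg rotation angles in degrees about the
#'   z, x and y axes respectively.
#' @return 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(yaw_deg, pitch_deg, roll_deg) {
  rot_y(roll_deg) %*% rot_x(pitch_deg) %*% rot_z(yaw_deg)
}

#' Decompose a rotation matrix into yaw, pitch and roll
#'
#' Inverse of [euler_to_matrix()] under the same z -> x -> y order.
#' Valid away from the gimbal singularity at |pitch| = 90 degrees.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param max_pitch_deg decompositions with |pitch| beyond this raise an
#'   error (default 89.9; the construction degenerates at 90).
#' @return Named numeric: `yaw_deg`, `pitch_deg`, `roll_deg`.
#' @export
matrix_to_euler <- function(rotation, max_pitch_deg = 89.9) {
  R <- rotation
  # with M = Ry(c) Rx(b) Rz(a):  M[2,3] = -sin b, M[2,1] = cos b sin a,
  # M[2,2] = cos b cos a, M[1,3] = sin c cos b, M[3,3] = cos c cos b
  sb <- -R[2, 3]
  sb <- min(1, max(-1, sb))
  pitch <- asin(sb) * 180 / pi
  if (abs(pitch) > max_pitch_deg)
    stop("pitch of ", round(pitch, 2),
         " degrees is outside the supported decomposition range (gimbal lock)",
         call. = FALSE)
  yaw <- atan2(R[2, 1], R[2, 2]) * 180 / pi
  roll <- atan2(R[1, 3], R[3, 3]) * 180 / pi
  c(yaw_deg = yaw, pitch_deg = pitch, roll_deg = roll)
}

#' Serialize a rigid transform to JSON
#'
#' Writes the rotation matrix (row-major), center, decomposed angles and
#' mode so a stored alignment can be re-applied later (e.g. to register a
#' follow-up study to the initially aligned one).
#'
#' @param transform a [rigid_transform].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(transform, path) {
  obj <- list(
    rotation_row_major = as.numeric(t(transform$rotation)),
    center_lps_mm = transform$center,
    angles_deg = as.list(transform$angles),
    mode = transform$mode
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a rigid transform from JSON
#'
#' @param path JSON file written by [write_transform()].
#' @return A [rigid_transform].
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stop("transform file not found: '", path, "'", call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  angles <- if (length(obj$angles_deg)) unlist(obj$angles_deg) else NULL
  rigid_transform(matrix(obj$rotation_row_major, 3, 3, byrow = TRUE),
                  center = obj$center_lps_mm, angles = angles,
                  mode = obj$mode)
}
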