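#' The three alignment landmarks as physical points
#'
#' Holds the right cochlea, left cochlea and nasal bridge as LPS mm
#' points. Validity requires the anatomy the alignment relies on: the
#' points are pairwise distinct (> 1 mm), non-collinear (the nasal bridge
#' sits > 1 mm off the inter-cochlear line), the left cochlea is on the
#' patient's left (larger x in LPS) and the nasal bridge is anterior to
#' the inter-cochlear midpoint (smaller y in LPS).
#'
#' @param right_cochlea,left_cochlea,nasal_bridge length-3 LPS mm points.
#' @param source provenance of the points: `"manual"`, `"oracle"` (the
#'   phantom intensity-threshold detector) or `"network"`.
#' @param validate set `FALSE` to skip anatomical checks (used internally
#'   when points are mid-rotation).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(right_cochlea, left_cochlea, nasal_bridge,
                         source = c("manual", "oracle", "network"),
                         validate = TRUE) {
  source <- match.arg(source)
  pts <- rbind(as.numeric(right_cochlea), as.numeric(left_cochlea),
               as.numeric(nasal_bridge))
  if (ncol(pts) != 3L || any(!is.finite(pts)))
    stop("landmarks must be finite length-3 points", call. = FALSE)
  ls <- structure(
    list(right_cochlea = pts[1, ], left_cochlea = pts[2, ],
         nasal_bridge = pts[3, ], source = source),
    class = "landmark_set"
  )
  if (validate) validate_landmarks(ls)
  ls
}

validate_landmarks <- function(ls) {
  d_rl <- sqrt(sum((ls$left_cochlea - ls$right_cochlea)^2))
  d_rn <- sqrt(sum((ls$nasal_bridge - ls$right_cochlea)^2))
  d_ln <- sqrt(sum((ls$nasal_bridge - ls$left_cochlea)^2))
  if (min(d_rl, d_rn, d_ln) <= 1)
    stop("degenerate landmark set: points are less than 1 mm apart", call. = FALSE)
  # perpendicular distance of nasal bridge from the inter-cochlear line
  u <- (ls$left_cochlea - ls$right_cochlea) / d_rl
  v <- ls$nasal_bridge - ls$right_cochlea
  perp <- v - sum(v * u) * u
  if (sqrt(sum(perp^2)) <= 1)
    stop("degenerate landmark set: landmarks are collinear ",
         "(nasal bridge within 1 mm of the inter-cochlear line)", call. = FALSE)
  if (ls$left_cochlea[1] <= ls$right_cochlea[1])
    stop("invalid landmark set: left cochlea must have larger x than the ",
         "right cochlea in LPS", call. = FALSE)
  mid <- (ls$left_cochlea + ls$right_cochlea) / 2
  if (ls$nasal_bridge[2] >= mid[2])
    stop("invalid landmark set: nasal bridge must be anterior ",
         "(smaller y in LPS) to the inter-cochlear midpoint", call. = FALSE)
  invisible(ls)
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> source = %s\n", x$source))
  for (nm in c("right_cochlea", "left_cochlea", "nasal_bridge"))
    cat(sprintf("  %-13s %9.3f %9.3f %9.3f\n", nm,
                x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  invisible(x)
}

landmark_matrix <- function(ls) {
  rbind(right_cochlea = ls$right_cochlea,
        left_cochlea = ls$left_cochlea,
        nasal_bridge = ls$nasal_bridge)
}

#' Apply a rigid transform to a landmark set
#'
#' Exact analytic propagation of the three points through
#' [transform_points()]; no image involved.
#'
#' @param landmarks a [landmark_set].
#' @param transform a [rigid_transform].
#' @param validate validate the result anatomically (default `TRUE`).
#' @return A transformed [landmark_set] with the same `source`.
#' @export
transform_landmarks <- function(landmarks, transform, validate = TRUE) {
  m <- transform_points(landmark_matrix(landmarks), transform)
  landmark_set(m[1, ], m[2, ], m[3, ], source = landmarks$source,
               validate = validate)
}

#' Inter-cochlear midpoint
#'
#' The default rotation center for all alignment transforms.
#'
#' @param landmarks a [landmark_set].
#' @return Length-3 LPS mm point.
#' @export
cochlear_midpoint <- function(landmarks) {
  (landmarks$right_cochlea + landmarks$left_cochlea) / 2
}

#' Voxelize a spherical label around a physical point
#'
#' Builds a binary label map on the given grid geometry with voxel = 1
#' iff the voxel center lies within `diameter_mm / 2` of `center`. The
#' default 10 mm diameter matches the 1 cm spherical ROI used to annotate
#' the cochlear modiolus and nasal bridge.
#'
#' @param center LPS mm point; must lie inside the grid's extent.
#' @param grid a [volume_grid] supplying the geometry (voxel values unused).
#' @param diameter_mm sphere diameter in mm (default 10).
#' @return A [volume_grid] of type `"label"`.
#' @export
sphere_label <- function(center, grid, diameter_mm = 10) {
  if (diameter_mm <= 0) stop("`diameter_mm` must be positive", call. = FALSE)
  center <- as.numeric(center)
  if (!point_in_extent(grid, center))
    stop("sphere center [", paste(signif(center, 6), collapse = ", "),
         "] lies outside the grid extent", call. = FALSE)
  d <- dim(grid$voxels)
  r <- diameter_mm / 2
  # restrict the scan to a bounding box around the center
  cidx <- as.numeric(world_to_voxel(grid, center))
  half <- r / grid$spacing + 1
  lo <- pmax(0L, as.integer(floor(cidx - half)))
  hi <- pmin(d - 1L, as.integer(ceiling(cidx + half)))
  arr <- array(0, dim = d)
  if (all(lo <= hi)) {
    idx <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    pts <- voxel_to_world(grid, idx)
    dist2 <- (pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2 +
             (pts[, 3] - center[3])^2
    inside <- idx[dist2 <= r^2, , drop = FALSE]
    if (nrow(inside))
      arr[1 + inside[, 1] + d[1] * (inside[, 2] + d[2] * inside[, 3])] <- 1
  }
  volume_grid(arr, spacing = grid$spacing, origin = grid$origin,
              direction = grid$direction, type = "label")
}

#' Center of mass of a binary label map
#'
#' Returns the unweighted mean of the physical centers of the foreground
#' voxels of the *largest* 26-connected component, in LPS mm. Restricting
#' to the largest component guards against speckle in predicted labels.
#'
#' @param label a [volume_grid] of type `"label"` with at least one
#'   foreground voxel.
#' @return Length-3 LPS mm point.
#' @export
label_center_of_mass <- function(label) {
  fg <- which(label$voxels > 0)
  if (!length(fg))
    stop("landmark not found: label map has no foreground voxels", call. = FALSE)
  comp <- largest_component(fg, dim(label$voxels))
  d <- dim(label$voxels)
  lin0 <- comp - 1L
  i <- lin0 %% d[1]
  j <- (lin0 %/% d[1]) %% d[2]
  k <- lin0 %/% (d[1] * d[2])
  colMeans(voxel_to_world(label, cbind(i, j, k)))
}

# linear indices (1-based) of the largest 26-connected component among
# the given foreground linear indices
largest_component <- function(fg, d) {
  lin0 <- fg - 1L
  coords <- cbind(lin0 %% d[1], (lin0 %/% d[1]) %% d[2], lin0 %/% (d[1] * d[2]))
  # 26-neighbourhood offsets in index space
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  key <- function(m) m[, 1] + d[1] * (m[, 2] + d[2] * m[, 3])
  fg_key <- key(coords)
  pos <- seq_along(fg_key)
  names(pos) <- fg_key
  comp_id <- integer(length(fg_key))
  cur <- 0L
  for (s in seq_along(fg_key)) {
    if (comp_id[s]) next
    cur <- cur + 1L
    frontier <- s
    comp_id[s] <- cur
    while (length(frontier)) {
      cm <- coords[frontier, , drop = FALSE]
      nb <- do.call(rbind, lapply(seq_len(nrow(off)), function(o)
        sweep(cm, 2L, off[o, ], `+`)))
      ok <- nb[, 1] >= 0 & nb[, 1] < d[1] & nb[, 2] >= 0 & nb[, 2] < d[2] &
            nb[, 3] >= 0 & nb[, 3] < d[3]
      nb <- nb[ok, , drop = FALSE]
      hit <- pos[as.character(key(nb))]
      hit <- unique(hit[!is.na(hit)])
      hit <- hit[comp_id[hit] == 0L]
      comp_id[hit] <- cur
      frontier <- hit
    }
  }
  sizes <- tabulate(comp_id, nbins = cur)
  fg[comp_id == which.max(sizes)]
}

# number of 26-connected components among foreground voxels, with their
# member linear indices
label_components <- function(voxels_logical) {
  d <- dim(voxels_logical)
  fg <- which(voxels_logical)
  if (!length(fg)) return(list())
  comps <- list()
  remaining <- fg
  while (length(remaining)) {
    comp <- largest_component(remaining, d)
    comps[[length(comps) + 1L]] <- comp
    remaining <- setdiff(remaining, comp)
  }
  comps[order(vapply(comps, length, 1L), decreasing = TRUE)]
}

#' Detect phantom landmarks by intensity thresholding
#'
#' Network-free detector for synthetic phantoms: thresholds the volume
#' midway between the skull and landmark-sphere intensities, splits the
#' result into 26-connected components, and assigns the component
#' centroids to landmarks — the most anterior (smallest y) component is
#' the nasal bridge and the remaining two are the cochleas ordered by x
#' (left cochlea = larger x in LPS).
#'
#' @param volume a [volume_grid] produced by [generate_phantom()] (possibly
#'   rotated).
#' @param spec the [phantom_spec()] that generated it (supplies the
#'   intensities).
#' @param threshold override the detection threshold (HU); defaults to the
#'   midpoint of `skull_intensity` and `landmark_intensity`.
#' @return A [landmark_set] with `source = "oracle"`.
#' @export
detect_landmarks_oracle <- function(volume, spec, threshold = NULL) {
  if (is.null(threshold))
    threshold <- (spec$skull_intensity + spec$landmark_intensity) / 2
  comps <- label_components(volume$voxels > threshold)
  if (length(comps) != 3L)
    stop("landmark not found: expected 3 landmark components above ",
         "threshold, found ", length(comps), call. = FALSE)
  cent <- t(vapply(comps, function(lin) {
    lin0 <- lin - 1L
    d <- dim(volume$voxels)
    colMeans(voxel_to_world(volume, cbind(lin0 %% d[1],
                                          (lin0 %/% d[1]) %% d[2],
                                          lin0 %/% (d[1] * d[2]))))
  }, numeric(3)))
  nb <- which.min(cent[, 2])
  coch <- setdiff(1:3, nb)
  coch <- coch[order(cent[coch, 1])]  # smaller x first = right cochlea
  landmark_set(right_cochlea = cent[coch[1], ],
               left_cochlea = cent[coch[2], ],
               nasal_bridge = cent[nb, ],
               source = "oracle")
}

#' Write landmarks (and optional metadata) as a JSON sidecar
#'
#' Schema: each landmark name maps to its `[x, y, z]` LPS mm coordinates;
#' `source` records provenance; entries of `extra` (e.g. applied
#' misalignment angles in degrees) are stored alongside.
#'
#' @param landmarks a [landmark_set].
#' @param path output JSON path.
#' @param extra optional named list of additional fields.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path, extra = NULL) {
  obj <- list(
    right_cochlea = landmarks$right_cochlea,
    left_cochlea = landmarks$left_cochlea,
    nasal_bridge = landmarks$nasal_bridge,
    source = landmarks$source
  )
  if (!is.null(extra)) obj <- c(obj, extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a landmark JSON sidecar
#'
#' @param path JSON file written by [write_landmarks()].
#' @param validate validate anatomically (default `TRUE`).
#' @return A [landmark_set]; extra fields are attached as the
#'   `"extra"` attribute.
#' @export
read_landmarks <- function(path, validate = TRUE) {
  if (!file.exists(path))
    stop("landmark sidecar not found: '", path, "'", call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ls <- landmark_set(obj$right_cochlea, obj$left_cochlea, obj$nasal_bridge,
                     source = if (is.null(obj$source)) "manual" else obj$source,
                     validate = validate)
  extra <- obj[setdiff(names(obj),
                       c("right_cochlea", "left_cochlea", "nasal_bridge", "source"))]
  if (length(extra)) attr(ls, "extra") <- extra
  ls
}
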