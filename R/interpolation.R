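# Shared interpolation kernel: sample a volume at arbitrary physical points.
# Trilinear for images, nearest-neighbour for labels; points outside the
# grid get the fill value. All resampling in the package funnels through
# this so every pathway has exactly one interpolation model.

sample_at_points <- function(volume, points,
                             interpolation = c("linear", "nearest"),
                             fill = default_fill(volume)) {
  interpolation <- match.arg(interpolation)
  idx <- world_to_voxel(volume, points)
  d <- dim(volume$voxels)
  vox <- volume$voxels
  n <- nrow(idx)
  out <- rep(as.numeric(fill), n)

  if (interpolation == "nearest") {
    ri <- round(idx)
    ok <- ri[, 1] >= 0 & ri[, 1] <= d[1] - 1 &
          ri[, 2] >= 0 & ri[, 2] <= d[2] - 1 &
          ri[, 3] >= 0 & ri[, 3] <= d[3] - 1
    if (any(ok)) {
      lin <- 1 + ri[ok, 1] + d[1] * (ri[ok, 2] + d[2] * ri[ok, 3])
      out[ok] <- vox[lin]
    }
    return(out)
  }

  # trilinear; valid interpolation domain is the hull of voxel centers,
  # with a small tolerance so on-grid points never fall out
  tol <- 1e-9
  ok <- idx[, 1] >= -tol & idx[, 1] <= d[1] - 1 + tol &
        idx[, 2] >= -tol & idx[, 2] <= d[2] - 1 + tol &
        idx[, 3] >= -tol & idx[, 3] <= d[3] - 1 + tol
  if (!any(ok)) return(out)

  p <- idx[ok, , drop = FALSE]
  p[, 1] <- pmin(pmax(p[, 1], 0), d[1] - 1)
  p[, 2] <- pmin(pmax(p[, 2], 0), d[2] - 1)
  p[, 3] <- pmin(pmax(p[, 3], 0), d[3] - 1)
  i0 <- floor(p)
  # keep the 8-neighbour stencil inside the array at the upper faces
  i0[, 1] <- pmin(i0[, 1], d[1] - 2); i0[, 1] <- pmax(i0[, 1], 0)
  i0[, 2] <- pmin(i0[, 2], d[2] - 2); i0[, 2] <- pmax(i0[, 2], 0)
  i0[, 3] <- pmin(i0[, 3], d[3] - 2); i0[, 3] <- pmax(i0[, 3], 0)
  if (d[1] < 2 || d[2] < 2 || d[3] < 2)
    stop("trilinear interpolation needs at least 2 voxels per axis", call. = FALSE)
  f <- p - i0

  base <- 1 + i0[, 1] + d[1] * (i0[, 2] + d[2] * i0[, 3])
  sx <- 1; sy <- d[1]; sz <- d[1] * d[2]
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  gx <- 1 - fx; gy <- 1 - fy; gz <- 1 - fz

  acc <- vox[base]                    * (gx * gy * gz)
  acc <- acc + vox[base + sx]         * (fx * gy * gz)
  acc <- acc + vox[base + sy]         * (gx * fy * gz)
  acc <- acc + vox[base + sx + sy]    * (fx * fy * gz)
  acc <- acc + vox[base + sz]         * (gx * gy * fz)
  acc <- acc + vox[base + sx + sz]    * (fx * gy * fz)
  acc <- acc + vox[base + sy + sz]    * (gx * fy * fz)
  acc <- acc + vox[base + sx + sy + sz] * (fx * fy * fz)

  out[ok] <- acc
  out
}

default_fill <- function(volume) {
  if (volume$type == "label") 0 else -1024
}

# physical centers of every voxel of a grid, as an N x 3 matrix in the
# array's native storage order (first index fastest)
all_voxel_centers <- function(volume) {
  d <- dim(volume$voxels)
  idx <- cbind(
    rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  )
  voxel_to_world(volume, idx)
}
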