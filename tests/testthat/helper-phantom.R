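# Shared fixtures, built in code.

# Coarse phantom for unit tests: same 192 x 192 x 120 mm physical extent
# as the default spec, at 3 mm voxels so volumetric tests stay fast.
coarse_spec <- function(...) {
  phantom_spec(grid_shape = c(64L, 64L, 40L), spacing_mm = 3, ...)
}

# A plausible random landmark geometry: jittered canonical anatomy put
# through a random rigid rotation of up to `max_deg` per plane.
random_landmarks <- function(seed, max_deg = 45) {
  set.seed(seed)
  sep <- runif(1, 50, 70)
  ant <- runif(1, 60, 85)
  cc <- runif(1, -10, 10)
  mid <- runif(3, -10, 10)
  base <- landmark_set(
    right_cochlea = mid + c(-sep / 2, 0, 0),
    left_cochlea = mid + c(sep / 2, 0, 0),
    nasal_bridge = mid + c(0, -ant, cc)
  )
  ang <- runif(3, -max_deg, max_deg)
  tr <- rigid_transform(euler_to_matrix(ang[1], ang[2], ang[3]),
                        center = cochlear_midpoint(base))
  transform_landmarks(base, tr, validate = FALSE)
}

expect_points_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(rbind(a) - rbind(b))), tol)
}

# physical positions of the 8 corner voxels, via the public mapping
grid_corner_points_pub <- function(vol) {
  d <- dim(vol$voxels) - 1L
  idx <- as.matrix(expand.grid(c(0, d[1]), c(0, d[2]), c(0, d[3])))
  voxel_to_world(vol, idx)
}

landmark_dist_matrix <- function(lm) {
  m <- rbind(lm$right_cochlea, lm$left_cochlea, lm$nasal_bridge)
  as.matrix(stats::dist(m))
}
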