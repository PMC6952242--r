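# Independent geometric oracles for the scene-graph tests. These build
# 4x4 homogeneous matrices directly (Rodrigues rotations, explicit TRS
# products) without going through the package's quaternion/compose code.

rot_rodrigues <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

trs_oracle_matrix <- function(translation, axis, angle, scale) {
  if (length(scale) == 1L) scale <- rep(scale, 3L)
  M <- diag(4)
  M[1:3, 1:3] <- rot_rodrigues(axis, angle) %*% diag(scale, 3L)
  M[1:3, 4] <- translation
  M
}

apply_mat <- function(M, p) as.numeric(M[1:3, 1:3] %*% p + M[1:3, 4])

random_axis <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# random transform3d plus its oracle matrix, matched by construction
random_pose <- function(iso = TRUE) {
  axis <- random_axis()
  angle <- stats::runif(1, -pi, pi)
  s <- if (iso) rep(stats::runif(1, 0.3, 3), 3) else stats::runif(3, 0.3, 3)
  tr <- stats::rnorm(3)
  list(
    transform = transform3d(tr, quat_axis_angle(axis, angle), s),
    matrix = trs_oracle_matrix(tr, axis, angle, s)
  )
}

# random chain of scene nodes under a fresh root; isotropic scales so
# every pose stays decomposable
random_chain <- function(depth, iso = TRUE) {
  root_pose <- random_pose(iso = TRUE)
  nodes <- list(scene_node("n1", root_pose$transform))
  mats <- list(root_pose$matrix)
  for (i in seq_len(depth - 1L)) {
    p <- random_pose(iso = iso && TRUE)
    nodes[[i + 1L]] <- scene_node(paste0("n", i + 1L), p$transform,
                                  parent = nodes[[i]])
    mats[[i + 1L]] <- mats[[i]] %*% p$matrix
  }
  list(nodes = nodes, mats = mats)
}

# small scene with a volume and one measurement at given mm endpoints
measurement_fixture <- function(p1_mm, p2_mm, mm_per_world_unit = 1000) {
  root <- scene_node("root")
  img <- volume_image(array(0, c(4, 4, 4)))
  vol <- attach_volume(root, img, mm_per_world_unit = mm_per_world_unit)
  m <- create_measurement(vol, volume_to_world(vol, p1_mm),
                          volume_to_world(vol, p2_mm), "m1")
  list(root = root, vol = vol, m = m)
}

# brute-force mean/SD with explicit summation (oracle for the summaries)
brute_mean <- function(x) sum(x) / length(x)
brute_sd <- function(x) {
  m <- brute_mean(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}
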