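#' Rigid-plus-scale transforms
#'
#' A `transform3d` is a local pose in a scene graph: a translation (world
#' units; by convention 1 world unit = 1 m), a rotation stored as a unit
#' quaternion `(w, x, y, z)`, and a per-axis positive scale. Points map
#' through a transform in scale, then rotation, then translation (TRS)
#' order, the dominant scene-graph convention. World coordinates are
#' right-handed.
#'
#' @param translation Numeric length-3 translation, world units.
#' @param rotation Unit quaternion as `c(w, x, y, z)`; normalised on
#'   construction. Must have non-negligible norm.
#' @param scale Numeric length-3 (or scalar, recycled) positive per-axis
#'   scale.
#' @return An object of class `transform3d`.
#' @examples
#' t1 <- transform3d(translation = c(1, 0, 0))
#' t2 <- transform3d(rotation = quat_axis_angle(c(0, 0, 1), pi / 2))
#' compose_transforms(t1, t2)
#' @export
transform3d <- function(translation = c(0, 0, 0),
                        rotation = c(1, 0, 0, 0),
                        scale = c(1, 1, 1)) {
  translation <- as.numeric(translation)
  rotation <- as.numeric(rotation)
  scale <- as.numeric(scale)
  if (length(scale) == 1L) scale <- rep(scale, 3L)
  stopifnot(length(translation) == 3L, length(rotation) == 4L,
            length(scale) == 3L)
  if (any(!is.finite(c(translation, rotation, scale)))) {
    rlang::abort("transform components must be finite", class = "caliper3d_invalid_transform")
  }
  nq <- sqrt(sum(rotation^2))
  if (nq < 1e-12) {
    rlang::abort("rotation quaternion has zero norm", class = "caliper3d_invalid_transform")
  }
  if (any(scale <= 0)) {
    rlang::abort("scale components must be > 0", class = "caliper3d_invalid_transform")
  }
  structure(
    list(translation = translation, rotation = rotation / nq, scale = scale),
    class = "transform3d"
  )
}

#' @export
print.transform3d <- function(x, ...) {
  cat("<transform3d>\n")
  cat("  translation:", format(x$translation, digits = 6), "\n")
  cat("  rotation (wxyz):", format(x$rotation, digits = 6), "\n")
  cat("  scale:", format(x$scale, digits = 6), "\n")
  invisible(x)
}

is_transform3d <- function(x) inherits(x, "transform3d")

#' Quaternion from axis and angle
#'
#' @param axis Numeric length-3 rotation axis (need not be unit length).
#' @param angle Rotation angle in radians, right-handed about `axis`.
#' @return Unit quaternion `c(w, x, y, z)`.
#' @export
quat_axis_angle <- function(axis, angle) {
  axis <- as.numeric(axis)
  stopifnot(length(axis) == 3L)
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) rlang::abort("rotation axis has zero norm")
  axis <- axis / n
  c(cos(angle / 2), sin(angle / 2) * axis)
}

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

# Shepperd's method; robust to all rotation-matrix traces.
quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s,
           0.25 * s,
           (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s,
           (R[1, 2] + R[2, 1]) / s,
           0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s,
           (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s,
           0.25 * s)
  }
  q / sqrt(sum(q^2))
}

#' Homogeneous matrix of a transform
#'
#' Returns the 4x4 homogeneous matrix mapping points in the transform's
#' local frame to its parent frame (scale, then rotation, then translation).
#'
#' @param t A [transform3d()].
#' @return A 4x4 numeric matrix.
#' @export
transform_matrix <- function(t) {
  stopifnot(is_transform3d(t))
  M <- diag(4)
  M[1:3, 1:3] <- quat_to_matrix(t$rotation) %*% diag(t$scale, 3L)
  M[1:3, 4] <- t$translation
  M
}

#' Transform from a homogeneous matrix
#'
#' Decomposes a 4x4 homogeneous matrix into translation, rotation and
#' per-axis scale. The linear part must factor as rotation x positive
#' diagonal scale: a matrix with shear (which arises when an anisotropic
#' scale sits above a rotation in a hierarchy) or a reflection is rejected,
#' because such a pose is not representable in TRS form.
#'
#' @param M 4x4 numeric homogeneous matrix.
#' @param tol Relative tolerance for the shear / orthogonality check.
#' @return A [transform3d()].
#' @export
transform_from_matrix <- function(M, tol = 1e-8) {
  stopifnot(is.matrix(M), all(dim(M) == c(4L, 4L)))
  L <- M[1:3, 1:3]
  G <- crossprod(L) # t(L) %*% L = S R'R S = S^2 when shear-free
  s <- sqrt(diag(G))
  off <- max(abs(G[upper.tri(G)]))
  if (off > tol * max(s)^2) {
    rlang::abort(
      "matrix linear part contains shear; not representable as scale-rotate-translate",
      class = "caliper3d_shear_error"
    )
  }
  if (any(s <= 0) || det(L) <= 0) {
    rlang::abort("matrix linear part is singular or reflecting",
                 class = "caliper3d_invalid_transform")
  }
  R <- L %*% diag(1 / s, 3L)
  transform3d(translation = M[1:3, 4], rotation = quat_from_matrix(R), scale = s)
}

#' Compose two transforms
#'
#' Returns the transform mapping the child's local coordinates to the
#' parent's parent frame: `compose_transforms(parent, local)` applies
#' `local` first, then `parent`. Equivalent to the product of the 4x4
#' homogeneous matrices; associative.
#'
#' @param parent,local [transform3d()] objects.
#' @return A [transform3d()].
#' @export
compose_transforms <- function(parent, local) {
  transform_from_matrix(transform_matrix(parent) %*% transform_matrix(local))
}

#' Apply a transform to points
#'
#' @param t A [transform3d()].
#' @param p A length-3 point or a 3-row matrix of points (one column each).
#' @param inverse Apply the inverse mapping instead.
#' @return Points in the same shape as `p`.
#' @export
apply_transform <- function(t, p, inverse = FALSE) {
  M <- transform_matrix(t)
  if (inverse) M <- solve(M)
  apply_homogeneous(M, p)
}

apply_homogeneous <- function(M, p) {
  vec <- !is.matrix(p)
  if (vec) p <- matrix(as.numeric(p), nrow = 3L)
  stopifnot(nrow(p) == 3L)
  out <- M[1:3, 1:3] %*% p + M[1:3, 4]
  if (vec) as.numeric(out) else out
}
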