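#' Rigid-body transform
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1).
#' @param translation Length-3 numeric translation (\eqn{\mathrm{\AA}}).
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-9 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation must be a proper rotation matrix (orthonormal, det = +1)")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param xyz Coordinate matrix (one point per row).
#' @param tf A `rigid_transform`.
#' @return Transformed coordinate matrix.
#' @export
apply_transform <- function(xyz, tf) {
  xyz <- as.matrix(xyz)
  sweep(xyz %*% t(tf$rotation), 2, tf$translation, `+`)
}

#' Invert a rigid transform
#' @param tf A `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  rt <- t(tf$rotation)
  rigid_transform(rt, -as.numeric(rt %*% tf$translation))
}

#' Compose two rigid transforms (apply `b` first, then `a`)
#' @param a,b `rigid_transform` objects.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Rotation matrix about an axis
#' @param axis Length-3 axis (normalised internally).
#' @param angle Angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) * c_ + s_ * ux + (1 - c_) * tcrossprod(u)
}

# rotation mapping unit vector a onto unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth > 1 - 1e-12) return(diag(3))
  if (cth < -1 + 1e-12) {
    # pick any perpendicular axis for a half-turn
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- c(a[2] * p[3] - a[3] * p[2], a[3] * p[1] - a[1] * p[3], a[1] * p[2] - a[2] * p[1])
    return(rotation_about_axis(ax, pi))
  }
  rotation_about_axis(v, acos(max(-1, min(1, cth))))
}

#' Uniformly distributed random rotation matrix
#' @param n Number of rotations.
#' @return A list of 3x3 rotation matrices (uses the current RNG stream).
#' @export
random_rotations <- function(n = 1) {
  lapply(seq_len(n), function(i) {
    # Shoemake quaternion method
    u <- stats::runif(3)
    q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]), sqrt(1 - u[1]) * cos(2 * pi * u[2]),
           sqrt(u[1]) * sin(2 * pi * u[3]), sqrt(u[1]) * cos(2 * pi * u[3]))
    quat_to_rot(q)
  })
}

quat_to_rot <- function(q) {
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}
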