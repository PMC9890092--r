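# Small rigid-geometry utilities shared across the kinematics and wrapping code.
# All lengths are metres, all user-facing angles degrees (radians internally).

DEG2RAD <- pi / 180

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

norm3 <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- norm3(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

#' Rotation matrix about an arbitrary axis (Rodrigues)
#'
#' @param axis unit 3-vector.
#' @param angle_rad rotation angle in radians (right-hand rule).
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_axis_angle <- function(axis, angle_rad) {
  u <- unit3(axis)
  c_ <- cos(angle_rad); s_ <- sin(angle_rad)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3L, 3L, byrow = TRUE)
  diag(3L) * c_ + s_ * K + (1 - c_) * (u %o% u)
}

# 4x4 homogeneous rigid transform from rotation + translation
rigid_tf <- function(R = diag(3L), t = c(0, 0, 0)) {
  T_ <- diag(4L)
  T_[1:3, 1:3] <- R
  T_[1:3, 4L] <- t
  T_
}

tf_rotation <- function(T_) T_[1:3, 1:3, drop = FALSE]
tf_translation <- function(T_) T_[1:3, 4L]

# Apply homogeneous transform to one 3-point or an n x 3 matrix of points
tf_point <- function(T_, p) {
  if (is.matrix(p)) {
    t(T_[1:3, 1:3] %*% t(p) + T_[1:3, 4L])
  } else {
    as.numeric(T_[1:3, 1:3] %*% p + T_[1:3, 4L])
  }
}

tf_vector <- function(T_, v) as.numeric(T_[1:3, 1:3] %*% v)

tf_inverse <- function(T_) {
  R <- tf_rotation(T_)
  rigid_tf(t(R), -t(R) %*% tf_translation(T_))
}

# Rotation about an axis through a fixed point, as a homogeneous transform
rot_about_line <- function(point, axis, angle_rad) {
  R <- rot_axis_angle(axis, angle_rad)
  rigid_tf(R, point - R %*% point)
}

is_rotation_matrix <- function(R, tol = 1e-9) {
  all(abs(crossprod(R) - diag(3L)) < tol) && abs(det(R) - 1) < tol
}

# Deterministic uniform random rotation (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}
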