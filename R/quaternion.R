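#' Quaternion utilities
#'
#' Head orientation is stored as unit quaternions in scalar-first order
#' (w, x, y, z). The coordinate frame is right-handed with z vertical (up):
#' yaw rotates about +z (0 = facing +x, counterclockwise positive), pitch is
#' positive upward, roll about the forward (visual) axis.
#'
#' @name quaternions
NULL

quat_norm <- function(q) sqrt(rowSums(q^2))

quat_normalize <- function(q) q / quat_norm(q)

# Hamilton product of two quaternion matrices (n x 4, scalar first).
quat_multiply <- function(a, b) {
  w <- a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4]
  x <- a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3]
  y <- a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2]
  z <- a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  cbind(w, x, y, z, deparse.level = 0)
}

# Quaternion from yaw/pitch/roll (degrees), intrinsic z-y'-x'' with pitch
# positive up; applied to the body-frame forward axis +x.
quat_from_euler <- function(yaw_deg, pitch_deg, roll_deg = 0) {
  half <- pi / 360
  cy <- cos(yaw_deg * half);  sy <- sin(yaw_deg * half)
  cp <- cos(-pitch_deg * half); sp <- sin(-pitch_deg * half)
  cr <- cos(roll_deg * half); sr <- sin(roll_deg * half)
  qz <- cbind(cy, 0, 0, sy, deparse.level = 0)
  qy <- cbind(cp, 0, sp, 0, deparse.level = 0)
  qx <- cbind(cr, sr, 0, 0, deparse.level = 0)
  quat_multiply(quat_multiply(qz, qy), qx)
}

# Rotate the body-frame vector v (length 3) by each quaternion row.
quat_rotate <- function(q, v) {
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  # R %*% v expanded for a fixed v
  r11 <- 1 - 2 * (y^2 + z^2); r12 <- 2 * (x * y - w * z); r13 <- 2 * (x * z + w * y)
  r21 <- 2 * (x * y + w * z); r22 <- 1 - 2 * (x^2 + z^2); r23 <- 2 * (y * z - w * x)
  r31 <- 2 * (x * z - w * y); r32 <- 2 * (y * z + w * x); r33 <- 1 - 2 * (x^2 + y^2)
  cbind(r11 * v[1] + r12 * v[2] + r13 * v[3],
        r21 * v[1] + r22 * v[2] + r23 * v[3],
        r31 * v[1] + r32 * v[2] + r33 * v[3])
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Geodesic angular distance between unit quaternions
#'
#' Rotation angle theta = 2*acos(|<q1, q2>|) in degrees; insensitive to the
#' q/-q double cover.
#'
#' @param q1,q2 quaternion matrices (n x 4, scalar-first) or length-4 vectors.
#' @return angular distance(s) in degrees.
#' @export
angular_distance <- function(q1, q2) {
  if (is.null(dim(q1))) q1 <- matrix(q1, 1)
  if (is.null(dim(q2))) q2 <- matrix(q2, 1)
  n1 <- quat_norm(q1); n2 <- quat_norm(q2)
  if (any(n1 < 1e-8) || any(n2 < 1e-8)) stop("zero-norm quaternion")
  d <- abs(rowSums(q1 * q2) / (n1 * n2))
  unname(2 * acos(pmin(d, 1)) * 180 / pi)
}
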