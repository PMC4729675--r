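#' Rigid-body transforms
#'
#' A rigid transform is a proper rotation (stored as a unit quaternion)
#' followed by a translation in Angstrom. Applied to coordinates as
#' \code{x' = R x + t}.
#'
#' @param q numeric(4) quaternion (w, x, y, z); normalized on construction.
#' @param t numeric(3) translation, Angstrom.
#' @return An object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(q = c(1, 0, 0, 0), t = c(0, 0, 0)) {
  q <- as.numeric(q)
  t <- as.numeric(t)
  stopifnot(length(q) == 4L, length(t) == 3L, all(is.finite(q)), all(is.finite(t)))
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("degenerate quaternion")
  structure(list(q = q / n, t = t), class = "rigid_transform")
}

#' Rotation matrix of a unit quaternion
#'
#' @param q numeric(4) unit quaternion (w, x, y, z).
#' @return 3x3 proper rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Quaternion of a rotation matrix
#'
#' Shepperd's method; returns the hemisphere with non-negative w.
#'
#' @param R 3x3 proper rotation matrix.
#' @return numeric(4) unit quaternion (w, x, y, z).
#' @export
matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Compose two rigid transforms
#'
#' \code{compose_transform(a, b)} is the transform equivalent to applying
#' \code{b} first, then \code{a}.
#'
#' @param a,b \code{rigid_transform} objects.
#' @return A \code{rigid_transform}.
#' @export
compose_transform <- function(a, b) {
  Ra <- quat_to_matrix(a$q)
  rigid_transform(quat_multiply(a$q, b$q), as.numeric(Ra %*% b$t + a$t))
}

#' Invert a rigid transform
#'
#' @param tr a \code{rigid_transform}.
#' @return The inverse \code{rigid_transform}.
#' @export
invert_transform <- function(tr) {
  qi <- c(tr$q[1], -tr$q[2:4])
  Ri <- quat_to_matrix(qi)
  rigid_transform(qi, as.numeric(-Ri %*% tr$t))
}

#' Apply a rigid transform to a coordinate matrix
#'
#' @param coords n x 3 matrix of positions.
#' @param tr a \code{rigid_transform}.
#' @return n x 3 matrix of transformed positions.
#' @export
transform_coords <- function(coords, tr) {
  R <- quat_to_matrix(tr$q)
  sweep(coords %*% t(R), 2, -tr$t)
}

#' Uniform random unit quaternions
#'
#' Draws orientations uniformly from SO(3) (Shoemake's subgroup algorithm),
#' using the current RNG state.
#'
#' @param n number of quaternions.
#' @return n x 4 matrix of unit quaternions (w, x, y, z).
#' @export
random_quaternions <- function(n) {
  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  a <- sqrt(1 - u1); b <- sqrt(u1)
  cbind(b * cos(2 * pi * u3),
        a * sin(2 * pi * u2),
        a * cos(2 * pi * u2),
        b * sin(2 * pi * u3))
}

#' Deterministic near-equidistant points on a sphere
#'
#' Fibonacci (golden-spiral) lattice scaled to the requested radius and
#' centered on \code{center}.
#'
#' @param n number of points (>= 1).
#' @param radius sphere radius, Angstrom.
#' @param center numeric(3) sphere center.
#' @return n x 3 matrix of points.
#' @export
fibonacci_sphere <- function(n, radius = 1, center = c(0, 0, 0)) {
  stopifnot(n >= 1, radius > 0)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  pts <- cbind(r * cos(phi), r * sin(phi), z) * radius
  sweep(pts, 2, -as.numeric(center))
}
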