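## Low-level vector geometry.  All angles in degrees; coordinates in angstrom.
## Points are length-3 numeric vectors; point sets are n x 3 matrices.

.DEG <- 180 / pi

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

.cross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

#' Planar angle at a vertex
#'
#' @param a,b,c coordinate triples; the angle is measured at `b`.
#' @return angle in degrees, in (0, 180].
#' @export
vecAngle <- function(a, b, c) {
  u <- .unit(a - b); v <- .unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * .DEG
}

#' Signed four-atom torsion angle
#'
#' Standard IUPAC convention: looking from `b` to `c`, the angle from the
#' projection of `a` to the projection of `d`, positive clockwise.
#'
#' @param a,b,c,d coordinate triples.
#' @return torsion in degrees, in (-180, 180].
#' @export
torsionAngle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  m1 <- .cross(n1, .unit(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- -atan2(y, x) * .DEG
  if (ang <= -180) ang + 360 else ang
}

#' Rotate points about an arbitrary axis
#'
#' Rodrigues rotation by `angle` degrees about the axis through `origin`
#' with direction `axis`, right-hand rule (positive angle = counter-
#' clockwise looking down the axis vector toward the origin).
#'
#' @param pts n x 3 matrix (or length-3 vector) of points.
#' @param origin point on the axis.
#' @param axis axis direction (need not be unit length).
#' @param angle rotation angle in degrees.
#' @return rotated points, same shape as `pts`.
#' @export
rotateAboutAxis <- function(pts, origin, axis, angle) {
  vec <- is.null(dim(pts))
  if (vec) pts <- matrix(pts, nrow = 1L)
  k <- .unit(axis)
  th <- angle / .DEG
  ct <- cos(th); st <- sin(th)
  p <- sweep(pts, 2L, origin)
  kd <- drop(p %*% k)                       # k . p
  kx <- cbind(k[2] * p[, 3] - k[3] * p[, 2],
              k[3] * p[, 1] - k[1] * p[, 3],
              k[1] * p[, 2] - k[2] * p[, 1])
  out <- p * ct + kx * st + outer(kd * (1 - ct), k)
  out <- sweep(out, 2L, origin, "+")
  if (vec) drop(out) else out
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rotation + translation taking `mobile` onto `target`
#' (row-matched point sets), via SVD of the covariance with determinant
#' correction so the result is a proper rotation.
#'
#' @param mobile,target n x 3 matrices, n >= 3.
#' @return list with `R` (3 x 3 rotation), `t` (translation), and `rmsd`
#'   over the input points; apply as `p %*% t(R) + t`.
#' @export
kabsch <- function(mobile, target) {
  if (nrow(mobile) < 3L) stop("need at least 3 points for superposition")
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2L, cm); B <- sweep(target, 2L, ct)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  tvec <- ct - drop(R %*% cm)
  moved <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  list(R = R, t = tvec, rmsd = rmsd)
}

#' Apply a rigid transform from [kabsch()]
#'
#' @param pts n x 3 matrix of points.
#' @param tr list with `R` and `t`.
#' @return transformed points.
#' @export
applyTransform <- function(pts, tr) {
  vec <- is.null(dim(pts))
  if (vec) pts <- matrix(pts, nrow = 1L)
  out <- pts %*% t(tr$R) + matrix(tr$t, nrow(pts), 3L, byrow = TRUE)
  if (vec) drop(out) else out
}

#' Coordinate RMSD between matched point sets
#'
#' @param a,b n x 3 matrices.
#' @return root-mean-square deviation in angstrom.
#' @export
coordRmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

## distance from point p to the plane through q1,q2,q3
.planeDistance <- function(p, q1, q2, q3) {
  n <- .unit(.cross(q2 - q1, q3 - q1))
  abs(sum((p - q1) * n))
}
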