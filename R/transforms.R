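#' Rigid transform in 3-D patient space
#'
#' A proper rigid transform (rotation + translation, millimetres). The
#' rotation must be orthonormal with determinant +1; this is checked at
#' construction to 1e-9.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation numeric length-3 translation (mm).
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal (R'R != I beyond 1e-9)")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation is not proper (det != +1)")
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform: rotation angle", format(rotation_angle_deg(x), digits = 4),
      "deg, translation", paste(format(x$t, digits = 4), collapse = " "), "mm\n")
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `compose_transform(a, b)` returns the transform applying `b` first,
#' then `a` (i.e. `x -> a(b(x))`).
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param x A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(x) {
  rigid_transform(t(x$R), as.numeric(-t(x$R) %*% x$t))
}

#' Apply a rigid transform to points
#' @param x A `rigid_transform`.
#' @param points Nx3 matrix of points (mm).
#' @return Transformed Nx3 matrix.
#' @export
apply_transform <- function(x, points) {
  points <- as_points(points)
  sweep(points %*% t(x$R), 2, x$t, "+")
}

#' Rotation angle of a rigid transform
#' @param x A `rigid_transform`.
#' @return Rotation angle in degrees.
#' @export
rotation_angle_deg <- function(x) {
  ct <- (sum(diag(x$R)) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Rigid transform as a 4x4 homogeneous matrix
#' @param x A `rigid_transform`.
#' @return 4x4 matrix.
#' @export
transform_matrix <- function(x) {
  m <- diag(4)
  m[1:3, 1:3] <- x$R
  m[1:3, 4] <- x$t
  m
}

#' Rigid transform from a 4x4 homogeneous matrix
#' @param m 4x4 matrix with rigid upper-left block.
#' @return A `rigid_transform`.
#' @export
transform_from_matrix <- function(m) {
  m <- as.matrix(m)
  stopifnot(identical(dim(m), c(4L, 4L)))
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

# Rodrigues: rotation matrix from axis-angle vector (radians)
rotation_from_omega <- function(omega) {
  th <- sqrt(sum(omega^2))
  if (th < 1e-300) return(diag(3))
  k <- omega / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation about an axis
#' @param axis rotation axis (length-3, need not be unit).
#' @param angle_deg rotation angle in degrees.
#' @param center point the axis passes through (default origin).
#' @return A `rigid_transform`.
#' @export
rotation_about <- function(axis, angle_deg, center = c(0, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  R <- rotation_from_omega(axis * angle_deg * pi / 180)
  rigid_transform(R, as.numeric(center - R %*% center))
}

#' An oriented plane in 3-D
#'
#' @param normal plane normal (normalised internally; must be non-zero).
#' @param point any point on the plane (mm).
#' @return An object of class `plane3` with unit `normal` and `point`.
#' @export
plane3 <- function(normal, point) {
  normal <- as.numeric(normal)
  point <- as.numeric(point)
  stopifnot(length(normal) == 3L, length(point) == 3L)
  n <- sqrt(sum(normal^2))
  if (n < 1e-12) stop("plane normal is (near) zero")
  structure(list(normal = normal / n, point = point), class = "plane3")
}

#' @export
print.plane3 <- function(x, ...) {
  cat("plane3: normal", paste(format(x$normal, digits = 4), collapse = " "),
      "through", paste(format(x$point, digits = 4), collapse = " "), "\n")
  invisible(x)
}

#' Signed distance of points from a plane
#'
#' Positive on the side the normal points to.
#' @param plane A `plane3`.
#' @param points Nx3 matrix (or length-3 vector) of points.
#' @return Numeric vector of signed distances (mm).
#' @export
plane_signed_distance <- function(plane, points) {
  points <- as_points(points)
  as.numeric(sweep(points, 2, plane$point, "-") %*% plane$normal)
}

#' Reflect points across a plane
#' @param plane A `plane3`.
#' @param points Nx3 matrix of points.
#' @return Reflected Nx3 matrix.
#' @export
reflect_points <- function(plane, points) {
  points <- as_points(points)
  d <- plane_signed_distance(plane, points)
  points - 2 * outer(d, plane$normal)
}

# coerce to an Nx3 double matrix
as_points <- function(x) {
  if (is.null(dim(x))) {
    stopifnot(length(x) == 3L)
    x <- matrix(as.numeric(x), 1, 3)
  }
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3L)
  storage.mode(x) <- "double"
  unname(x)
}

#' Least-squares rigid alignment of paired point sets (Kabsch)
#'
#' Finds the rigid transform minimising the RMS distance between
#' `transform(src)` and `dst`.
#'
#' @param src,dst Nx3 matrices of corresponding points (N >= 3).
#' @return A `rigid_transform`.
#' @export
align_points <- function(src, dst) {
  src <- as_points(src); dst <- as_points(dst)
  stopifnot(nrow(src) == nrow(dst), nrow(src) >= 3L)
  cs <- colMeans(src); cd <- colMeans(dst)
  H <- crossprod(sweep(src, 2, cs), sweep(dst, 2, cd))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, as.numeric(cd - R %*% cs))
}
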