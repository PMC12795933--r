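#' Rigid (SE(3)) transforms in millimetres
#'
#' A rigid transform maps model coordinates to scene coordinates as
#' `R %*% p + t`. The rotation must be orthonormal with determinant +1
#' (checked to 1e-9); this is the pose estimated by surface registration.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation vector (mm).
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L,
            all(is.finite(rotation)), all(is.finite(translation)))
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-9)
    stop("rotation is not orthonormal (max deviation ", format(err), ")")
  if (det(rotation) < 0)
    stop("rotation has determinant -1 (reflection, not a rotation)")
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param x object to test.
#' @export
is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' @rdname rigid_transform
#' @export
rt_identity <- function() rigid_transform()

#' Compose and invert rigid transforms
#'
#' `rt_compose(a, b)` returns the transform acting as `a` after `b`
#' (i.e. `x -> a(b(x))`); `rt_invert(a)` is the group inverse.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  stopifnot(is_rigid_transform(a), is_rigid_transform(b))
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' @rdname rt_compose
#' @export
rt_invert <- function(a) {
  stopifnot(is_rigid_transform(a))
  rigid_transform(t(a$R), as.numeric(-t(a$R) %*% a$t))
}

#' Convert between rigid transforms and 4x4 homogeneous matrices
#'
#' @param m 4x4 homogeneous matrix with last row (0,0,0,1).
#' @return `rt_from_matrix` returns a `rigid_transform`; `rt_to_matrix`
#'   returns a 4x4 matrix.
#' @export
rt_from_matrix <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == c(4L, 4L)))
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("last row of a rigid homogeneous matrix must be (0,0,0,1)")
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' @rdname rt_from_matrix
#' @param a a `rigid_transform`.
#' @export
rt_to_matrix <- function(a) {
  stopifnot(is_rigid_transform(a))
  rbind(cbind(a$R, a$t), c(0, 0, 0, 1))
}

#' Build a rigid transform from a unit quaternion
#'
#' Quaternions are accepted at I/O boundaries in `(w, x, y, z)` order and
#' normalised on ingest.
#'
#' @param q length-4 quaternion `(w, x, y, z)`.
#' @param translation length-3 translation (mm).
#' @return A `rigid_transform`.
#' @export
rt_from_quaternion <- function(q, translation = c(0, 0, 0)) {
  q <- as.numeric(q)
  stopifnot(length(q) == 4L, all(is.finite(q)))
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("zero quaternion")
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rot <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  # re-orthonormalise against rounding
  s <- svd(rot)
  rigid_transform(s$u %*% t(s$v), translation)
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis length-3 axis (normalised internally).
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix (Rodrigues formula).
#' @export
rot_axis_angle <- function(axis, angle) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  stopifnot(n > 1e-12, is.finite(angle))
  a <- axis / n
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Rotation angle of a rotation matrix, in degrees
#' @param rot 3x3 rotation matrix.
#' @return Angle in `[0, 180]` degrees.
#' @export
rotation_angle_deg <- function(rot) {
  # atan2 of the sine (from the skew part) and cosine (from the trace):
  # numerically accurate near 0, where acos alone loses half the digits
  ct <- (sum(diag(rot)) - 1) / 2
  st <- 0.5 * sqrt((rot[3, 2] - rot[2, 3])^2 + (rot[1, 3] - rot[3, 1])^2 +
                     (rot[2, 1] - rot[1, 2])^2)
  atan2(st, ct) * 180 / pi
}

#' Pose error between two rigid transforms
#'
#' Rotation error is the geodesic angle of `a$R %*% t(b$R)`; translation
#' error is the Euclidean distance between the two translations.
#'
#' @param a,b `rigid_transform` objects.
#' @return Error in degrees / millimetres.
#' @export
rt_rotation_error_deg <- function(a, b) rotation_angle_deg(a$R %*% t(b$R))

#' @rdname rt_rotation_error_deg
#' @export
rt_translation_error_mm <- function(a, b) sqrt(sum((a$t - b$t)^2))

#' Draw a random rigid transform
#'
#' Axis uniform on the sphere, angle uniform on `[0, max_angle_deg]`,
#' translation uniform in the ball of radius `max_translation_mm`.
#'
#' @param max_angle_deg maximum rotation angle (degrees).
#' @param max_translation_mm maximum translation norm (mm).
#' @param seed optional integer seed.
#' @return A `rigid_transform`.
#' @export
random_rigid_transform <- function(max_angle_deg, max_translation_mm, seed = NULL) {
  with_seed(seed, {
    ax <- rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, 0, max_angle_deg) * pi / 180
    td <- rnorm(3)
    td <- td / sqrt(sum(td^2))
    r <- max_translation_mm * runif(1)^(1 / 3)
    rigid_transform(rot_axis_angle(ax, ang), r * td)
  })
}

#' Apply a rigid transform to points, clouds or meshes
#'
#' Points map as `R p + t`; normals rotate only. Pairwise distances are
#' preserved exactly (up to floating point).
#'
#' @param transform a `rigid_transform`.
#' @param x a length-3 point, an `n x 3` matrix of points, a `point_cloud`
#'   or a `triangle_mesh`.
#' @return An object of the same kind as `x`.
#' @export
apply_transform <- function(transform, x) {
  stopifnot(is_rigid_transform(transform))
  map <- function(p) sweep(p %*% t(transform$R), 2, -transform$t)
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 3L)
    return(as.numeric(transform$R %*% x + transform$t))
  if (is.matrix(x) && ncol(x) == 3L) return(map(x))
  if (inherits(x, "point_cloud")) {
    x$points <- map(x$points)
    if (!is.null(x$normals)) x$normals <- x$normals %*% t(transform$R)
    return(x)
  }
  if (inherits(x, "triangle_mesh")) {
    x$vertices <- map(x$vertices)
    if (!is.null(x$normals)) x$normals <- x$normals %*% t(transform$R)
    return(x)
  }
  stop("unsupported type for apply_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>  angle", sprintf("%.3f deg,", rotation_angle_deg(x$R)),
      "translation", sprintf("%.3f mm", sqrt(sum(x$t^2))), "\n")
  invisible(x)
}
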