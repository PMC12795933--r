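#' Planned biopsy trajectory
#'
#' A trajectory runs from an entry point on the skin to a deep target point
#' (for the phantom, the apex of a conical fiducial). Entry and target must
#' be separated by more than 1e-6 mm.
#'
#' @param entry length-3 entry point on the skin (mm).
#' @param target length-3 deep target point (mm).
#' @param label identifier.
#' @return A `trajectory`.
#' @export
trajectory <- function(entry, target, label = "traj") {
  entry <- as.numeric(entry); target <- as.numeric(target)
  stopifnot(length(entry) == 3L, length(target) == 3L,
            all(is.finite(entry)), all(is.finite(target)))
  if (sqrt(sum((entry - target)^2)) <= 1e-6)
    stop("degenerate trajectory: entry and target coincide")
  structure(list(entry = entry, target = target, label = as.character(label)),
            class = "trajectory")
}

#' @rdname trajectory
#' @param x object to test.
#' @export
is_trajectory <- function(x) inherits(x, "trajectory")

#' Off-plan distance of a probe tip
#'
#' The shortest Euclidean distance from the measured probe tip to the
#' planned trajectory. By default this is the distance to the infinite line
#' through the entry and target points (the navigated trajectory extends
#' beyond both); `segment = TRUE` restricts to the entry-target segment.
#'
#' @param tip length-3 probe-tip position (mm).
#' @param traj a `trajectory`.
#' @param segment clamp to the segment instead of the infinite line.
#' @return Nonnegative distance in mm.
#' @export
off_plan_distance <- function(tip, traj, segment = FALSE) {
  stopifnot(is_trajectory(traj))
  tip <- as.numeric(tip)
  stopifnot(length(tip) == 3L, all(is.finite(tip)))
  d <- traj$target - traj$entry
  len2 <- sum(d^2)
  s <- sum((tip - traj$entry) * d) / len2
  if (segment) s <- min(1, max(0, s))
  sqrt(sum((tip - (traj$entry + s * d))^2))
}

#' Entry-point offset between two navigation systems
#'
#' Euclidean distance between an overlaid entry point and a reference entry
#' point; invariant under a common rigid transform of both.
#'
#' @param overlaid_entry,reference_entry length-3 points (mm).
#' @return Distance in mm.
#' @export
entry_point_offset <- function(overlaid_entry, reference_entry) {
  a <- as.numeric(overlaid_entry); b <- as.numeric(reference_entry)
  stopifnot(length(a) == 3L, length(b) == 3L)
  sqrt(sum((a - b)^2))
}

#' Closest point on a triangle mesh
#'
#' Exact nearest point over all triangles (exhaustive per query).
#'
#' @param p length-3 query point.
#' @param mesh a nonempty `triangle_mesh`.
#' @return List with `point` (length-3) and `distance` (mm).
#' @export
closest_point_on_mesh <- function(p, mesh) {
  stopifnot(is_triangle_mesh(mesh))
  if (nrow(mesh$faces) == 0) stop("empty mesh")
  r <- cpp_closest_point_mesh(mesh$vertices, mesh$faces, matrix(as.numeric(p), 1))
  list(point = as.numeric(r$point[1, ]), distance = r$distance[1])
}

#' @rdname closest_point_on_mesh
#' @param points `n x 3` matrix of query points.
#' @export
closest_points_on_mesh <- function(points, mesh) {
  stopifnot(is_triangle_mesh(mesh))
  if (nrow(mesh$faces) == 0) stop("empty mesh")
  cpp_closest_point_mesh(mesh$vertices, mesh$faces, as.matrix(points))
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", x$label, " length",
      sprintf("%.2f mm", sqrt(sum((x$target - x$entry)^2))), "\n")
  invisible(x)
}
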