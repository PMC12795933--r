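# Preoperative processing chain: threshold segmentation, median smoothing,
# solidification, iso-surfacing, decimation and reference-model cropping.

#' Threshold segmentation with largest-component filtering
#'
#' The mask is true exactly where intensity is at least `tau`; of the
#' resulting foreground only the largest 26-connected component is kept
#' (the automated counterpart of manual threshold segmentation of the skin).
#'
#' @param vol a [volume()].
#' @param tau intensity threshold.
#' @return A [binary_mask()].
#' @export
threshold_segment <- function(vol, tau) {
  stopifnot(is_volume(vol))
  raw <- vol$data >= tau
  if (!any(raw)) stop("threshold ", tau, " leaves an empty mask")
  keep <- cpp_largest_component26(raw, dim(vol$data))
  binary_mask(array(keep, dim(vol$data)), vol$spacing, vol$origin)
}

# Clamped box sum along one axis via a running cumulative sum.
axis_boxsum <- function(arr, half, axis) {
  d <- dim(arr)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  inv <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(2, 3, 1))
  a <- if (axis == 1) arr else aperm(arr, perm)
  da <- dim(a)
  cs <- apply(a, c(2, 3), cumsum)
  dim(cs) <- da
  n1 <- da[1]
  hi <- pmin(seq_len(n1) + half, n1)
  lo <- seq_len(n1) - half - 1L
  out <- cs[hi, , , drop = FALSE]
  pos <- lo >= 1L
  if (any(pos))
    out[pos, , ] <- out[pos, , , drop = FALSE] - cs[lo[pos], , , drop = FALSE]
  if (axis != 1) out <- aperm(out, inv)
  out
}

# Windowed box sums (window clamped at the borders), separably per axis.
# Returns list(sum, count) with count the in-bounds window volume.
box_counts3d <- function(arr, half) {
  d <- dim(arr)
  s <- arr
  for (ax in 1:3) s <- axis_boxsum(s, half[ax], ax)
  len <- lapply(1:3, function(a)
    pmin(seq_len(d[a]) + half[a], d[a]) - pmax(seq_len(d[a]) - half[a], 1L) + 1L)
  cnt <- outer(len[[1]], outer(len[[2]], len[[3]]))
  list(sum = s, count = cnt)
}

#' Median (majority) smoothing of a binary mask
#'
#' Per-voxel majority vote in a cubic window whose edge length is
#' `window_mm` converted to voxels per axis and rounded to the nearest odd
#' integer (minimum 3). For a binary mask the windowed median is the
#' majority vote; the window is clamped at the volume borders.
#'
#' @param mask a [binary_mask()].
#' @param window_mm window edge length in mm (default 3).
#' @return The smoothed [binary_mask()].
#' @export
median_smooth <- function(mask, window_mm = 3) {
  stopifnot(is_binary_mask(mask), window_mm > 0)
  w <- as.integer(round(window_mm / mask$spacing))
  w <- ifelse(w %% 2L == 0L, w + 1L, w)  # nearest odd, per axis
  w <- pmax(3L, w)
  half <- (w - 1L) %/% 2L
  bc <- box_counts3d(mask$mask * 1, half)
  binary_mask(array(2 * bc$sum > bc$count, dim(mask$mask)),
              mask$spacing, mask$origin)
}

#' Extract a solid surface mesh from a binary mask
#'
#' Internal cavities are filled first (flood fill of the background from
#' the volume border, then inversion) so the result is solid; the filled
#' mask is box-smoothed `smooth_passes` times and the 0.5 iso-surface is
#' extracted by marching tetrahedra, in world mm through the grid affine.
#'
#' @param mask a [binary_mask()] with both foreground and background.
#' @param smooth_passes number of 3x3x3 box-smoothing passes applied to the
#'   indicator before iso-surfacing (reduces voxel staircase bias).
#' @return A watertight `triangle_mesh`.
#' @export
extract_surface <- function(mask, smooth_passes = 2) {
  stopifnot(is_binary_mask(mask))
  m <- mask$mask
  if (!any(m) || all(m)) stop("mask must contain both classes")
  solid <- array(cpp_fill_holes(m, dim(m)), dim(m))
  field <- solid * 1
  for (i in seq_len(smooth_passes)) {
    bc <- box_counts3d(field, c(1L, 1L, 1L))
    field <- bc$sum / bc$count
  }
  res <- cpp_isosurface(as.numeric(field), dim(field), 0.5,
                        mask$origin, mask$spacing)
  if (nrow(res$vertices) == 0) stop("empty iso-surface")
  triangle_mesh(res$vertices, res$faces)
}

#' Decimate a mesh by quadric-error-metric edge collapse
#'
#' Reduces the face count to at most `target_faces` (default the 100,000
#' triangles used for the reference skin models). Meshes already at or
#' below the target are returned unchanged.
#'
#' @param mesh a `triangle_mesh`.
#' @param target_faces maximum face count (at least 4).
#' @return The simplified `triangle_mesh`.
#' @export
decimate <- function(mesh, target_faces = 100000) {
  stopifnot(is_triangle_mesh(mesh), target_faces >= 4)
  if (nrow(mesh$faces) <= target_faces) return(mesh)
  r <- cpp_decimate_qem(mesh$vertices, mesh$faces, as.integer(target_faces))
  triangle_mesh(r$vertices, r$faces)
}

#' Estimate facial landmarks on a head-like mesh
#'
#' Heuristics in the phantom frame (+y anterior, +z superior): the nose tip
#' is the most anterior vertex near the midline; eye centres are the surface
#' points in the eye-socket directions; the ear plane is the coronal plane
#' through the centroid.
#'
#' @param mesh a `triangle_mesh`.
#' @return List with `nose_tip`, `eye_left`, `eye_right`, `ear_plane_y`.
#' @export
estimate_landmarks <- function(mesh) {
  v <- mesh$vertices
  ctr <- colMeans(v)
  rel <- sweep(v, 2, ctr)
  rel_u <- rel / sqrt(rowSums(rel^2))
  nose <- v[which.max(rel[, 2] - 0.5 * abs(rel[, 1])), ]
  eye_dir <- function(sgn) {
    d <- c(sgn * 0.33, 0.90, 0.22)
    d <- d / sqrt(sum(d^2))
    v[which.max(rel_u %*% d), ]
  }
  list(nose_tip = nose, eye_left = eye_dir(-1), eye_right = eye_dir(1),
       ear_plane_y = ctr[2])
}

#' Crop a skin surface into a registration reference model
#'
#' `face_only` keeps the surface anterior to the coronal (ear) plane;
#' both modes remove vertices inside the two eye-exclusion spheres (the
#' eye region is unreliable for depth-based registration).
#'
#' @param mesh a `triangle_mesh`.
#' @param mode `"face_only"` or `"full_head"`.
#' @param landmarks as returned by [estimate_landmarks()]; auto-estimated
#'   when `NULL`.
#' @param eye_radius_mm radius of the eye-exclusion spheres (mm).
#' @return The cropped `triangle_mesh` (open surface).
#' @export
crop_reference <- function(mesh, mode = c("face_only", "full_head"),
                           landmarks = NULL, eye_radius_mm = 15) {
  mode <- match.arg(mode)
  stopifnot(is_triangle_mesh(mesh))
  if (is.null(landmarks)) landmarks <- estimate_landmarks(mesh)
  v <- mesh$vertices
  keep <- rep(TRUE, nrow(v))
  if (mode == "face_only") keep <- v[, 2] > landmarks$ear_plane_y
  for (eye in list(landmarks$eye_left, landmarks$eye_right))
    keep <- keep & sqrt(rowSums(sweep(v, 2, eye)^2)) > eye_radius_mm
  if (!any(keep)) stop("crop removed all vertices")
  idx <- which(keep)
  remap <- integer(nrow(v))
  remap[idx] <- seq_along(idx)
  f <- mesh$faces
  fk <- keep[f[, 1]] & keep[f[, 2]] & keep[f[, 3]]
  f <- f[fk, , drop = FALSE]
  if (nrow(f) == 0) stop("crop removed all faces")
  triangle_mesh(v[idx, , drop = FALSE],
                matrix(remap[f], ncol = 3))
}
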