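# Simulation of the head-mounted depth sensor: pinhole depth rendering
# with z-buffer semantics, inverse projection to a world point cloud, and
# a time-of-flight style noise model.

#' Pinhole depth camera
#'
#' Defaults approximate a head-mounted time-of-flight sensor: 320x288
#' pixels with a 75 degree horizontal field of view. The camera frame is
#' x right, y down, z forward; `pose` maps camera to world coordinates.
#' Pixel (u, v) (0-based) casts the ray `((u - cx)/fx, (v - cy)/fy, 1)`.
#'
#' @param width,height image size in pixels.
#' @param fov_deg horizontal field of view (used when `fx` is `NULL`).
#' @param fx,fy focal lengths in pixels; `fy` defaults to `fx`.
#' @param cx,cy principal point (defaults to the image centre).
#' @param pose camera-to-world [rigid_transform()].
#' @param max_range_mm maximum measurable depth.
#' @return A `depth_camera`.
#' @export
depth_camera <- function(width = 320, height = 288, fov_deg = 75,
                         fx = NULL, fy = NULL, cx = NULL, cy = NULL,
                         pose = rt_identity(), max_range_mm = 1500) {
  if (is.null(fx)) fx <- (width / 2) / tan(fov_deg * pi / 360)
  if (is.null(fy)) fy <- fx
  if (is.null(cx)) cx <- (width - 1) / 2
  if (is.null(cy)) cy <- (height - 1) / 2
  stopifnot(fx > 0, fy > 0, cx >= 0, cx < width, cy >= 0, cy < height,
            is_rigid_transform(pose), max_range_mm > 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 fx = fx, fy = fy, cx = cx, cy = cy, pose = pose,
                 max_range_mm = max_range_mm), class = "depth_camera")
}

#' Aim a camera at a target point
#'
#' @param eye camera position (mm).
#' @param target point the optical axis passes through (mm).
#' @param up world up direction (default +z).
#' @param ... passed to [depth_camera()].
#' @return A `depth_camera` positioned at `eye` looking at `target`.
#' @export
camera_look_at <- function(eye, target, up = c(0, 0, 1), ...) {
  f <- as.numeric(target) - as.numeric(eye)
  f <- f / sqrt(sum(f^2))
  r <- c(f[2] * up[3] - f[3] * up[2], f[3] * up[1] - f[1] * up[3],
         f[1] * up[2] - f[2] * up[1])
  if (sqrt(sum(r^2)) < 1e-9) stop("view direction parallel to up vector")
  r <- r / sqrt(sum(r^2))
  d <- c(f[2] * r[3] - f[3] * r[2], f[3] * r[1] - f[1] * r[3],
         f[1] * r[2] - f[2] * r[1])  # camera y (down) = f x r
  depth_camera(pose = rigid_transform(cbind(r, d, f), as.numeric(eye)), ...)
}

#' Render a depth image of a mesh
#'
#' Each pixel holds the depth (mm along the camera z axis) of the first
#' ray-mesh intersection, or 0 where the ray misses or exceeds the range.
#'
#' @param mesh a nonempty `triangle_mesh`.
#' @param cam a [depth_camera()].
#' @return A `depth_image`: `height x width` matrix with the camera attached.
#' @export
render_depth <- function(mesh, cam) {
  stopifnot(is_triangle_mesh(mesh), inherits(cam, "depth_camera"))
  if (nrow(mesh$faces) == 0) stop("empty mesh")
  img <- cpp_render_depth(mesh$vertices, mesh$faces, cam$width, cam$height,
                          cam$fx, cam$fy, cam$cx, cam$cy,
                          cam$pose$R, cam$pose$t, cam$max_range_mm)
  structure(list(depth = img, camera = cam), class = "depth_image")
}

#' Convert a depth image to a world-frame point cloud
#'
#' One point per valid pixel by inverse pinhole projection through the
#' camera pose; normals are not attached.
#'
#' @param img a `depth_image`.
#' @param cam the camera that produced it (defaults to the one attached).
#' @return A `point_cloud` in world mm.
#' @export
depth_to_pointcloud <- function(img, cam = img$camera) {
  stopifnot(inherits(img, "depth_image"))
  d <- img$depth
  valid <- which(d > 0, arr.ind = TRUE)
  if (nrow(valid) == 0) return(point_cloud(matrix(numeric(0), 0, 3)))
  v <- valid[, 1] - 1
  u <- valid[, 2] - 1
  z <- d[valid]
  pc <- cbind((u - cam$cx) / cam$fx * z, (v - cam$cy) / cam$fy * z, z)
  point_cloud(sweep(pc %*% t(cam$pose$R), 2, -cam$pose$t))
}

#' Depth-sensor noise model
#'
#' Time-of-flight style corruption: axial Gaussian noise along the viewing
#' ray, range quantization, then Bernoulli dropout. Deterministic for a
#' fixed seed.
#'
#' @param axial_sd_mm standard deviation of axial noise (mm).
#' @param dropout_rate probability a point is dropped.
#' @param quantization_mm range quantization step (0 = none).
#' @param seed integer seed.
#' @return A `noise_model`.
#' @export
noise_model <- function(axial_sd_mm = 1.0, dropout_rate = 0.05,
                        quantization_mm = 0.25, seed = 1L) {
  stopifnot(axial_sd_mm >= 0, dropout_rate >= 0, dropout_rate <= 1,
            quantization_mm >= 0)
  structure(list(axial_sd_mm = axial_sd_mm, dropout_rate = dropout_rate,
                 quantization_mm = quantization_mm, seed = as.integer(seed)),
            class = "noise_model")
}

#' Corrupt a point cloud with sensor noise
#'
#' Points are perturbed along the ray from the sensor origin (axial noise),
#' the range is quantized, and points are dropped independently.
#'
#' @param cloud a `point_cloud`.
#' @param model a [noise_model()].
#' @param eye sensor origin in world mm (e.g. `cam$pose$t`).
#' @return The corrupted `point_cloud`.
#' @export
corrupt <- function(cloud, model, eye = c(0, 0, 0)) {
  stopifnot(is_point_cloud(cloud), inherits(model, "noise_model"))
  p <- cloud$points
  n <- nrow(p)
  if (n == 0) return(cloud)
  with_seed(model$seed, {
    rel <- sweep(p, 2, as.numeric(eye))
    rng <- sqrt(rowSums(rel^2))
    u <- rel / pmax(rng, 1e-12)
    if (model$axial_sd_mm > 0) rng <- rng + rnorm(n, 0, model$axial_sd_mm)
    if (model$quantization_mm > 0)
      rng <- round(rng / model$quantization_mm) * model$quantization_mm
    q <- sweep(u * rng, 2, -as.numeric(eye))
    keep <- if (model$dropout_rate > 0) runif(n) >= model$dropout_rate
            else rep(TRUE, n)
    point_cloud(q[keep, , drop = FALSE],
                if (!is.null(cloud$normals)) cloud$normals[keep, , drop = FALSE])
  })
}

#' Fraction of a mesh's area visible from a camera
#'
#' Area-weighted surface samples are tested for frustum containment and
#' occlusion; used to label partial-view scenarios.
#'
#' @param mesh a `triangle_mesh` (e.g. the reference model).
#' @param cam a [depth_camera()].
#' @param occluder mesh blocking the view (default `mesh` itself); pass the
#'   full scene mesh when `mesh` is an open reference shell, which cannot
#'   occlude itself.
#' @param n_samples number of surface samples.
#' @param seed optional seed.
#' @return Visible area fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(mesh, cam, occluder = mesh, n_samples = 2000,
                              seed = 1L) {
  s <- sample_surface(mesh, n_samples, seed = seed)
  rel <- sweep(s$points, 2, cam$pose$t) %*% cam$pose$R  # world -> camera
  z <- rel[, 3]
  u <- rel[, 1] / z * cam$fx + cam$cx
  v <- rel[, 2] / z * cam$fy + cam$cy
  in_frustum <- z > 0 & z <= cam$max_range_mm &
    u >= 0 & u <= cam$width - 1 & v >= 0 & v <= cam$height - 1
  vis <- cpp_points_visible(occluder$vertices, occluder$faces, s$points,
                            cam$pose$t, 1e-4)
  mean(in_frustum & vis)
}

#' @export
print.depth_image <- function(x, ...) {
  cat("<depth_image> ", nrow(x$depth), "x", ncol(x$depth), "pixels,",
      sum(x$depth > 0), "valid\n")
  invisible(x)
}
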