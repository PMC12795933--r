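#' Triangle meshes and point clouds (millimetre units)
#'
#' `triangle_mesh()` stores vertices as an `n x 3` matrix and faces as an
#' `m x 3` integer matrix of 1-based vertex indices. Zero-area faces are
#' dropped at construction; out-of-range indices are an error.
#'
#' @param vertices `n x 3` numeric matrix (mm).
#' @param faces `m x 3` integer matrix of vertex indices.
#' @param normals optional `n x 3` per-vertex normals.
#' @return A `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- unname(as.matrix(vertices))
  storage.mode(vertices) <- "double"
  faces <- unname(as.matrix(faces))
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L,
            all(is.finite(vertices)))
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (nrow(faces) > 0) {
    a <- face_areas_(vertices, faces)
    if (any(a <= 1e-12)) faces <- faces[a > 1e-12, , drop = FALSE]
  }
  if (!is.null(normals)) {
    normals <- unname(as.matrix(normals))
    stopifnot(all(dim(normals) == dim(vertices)))
  }
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "triangle_mesh")
}

#' @rdname triangle_mesh
#' @param x object to test.
#' @export
is_triangle_mesh <- function(x) inherits(x, "triangle_mesh")

#' @param points `n x 3` numeric matrix (mm).
#' @rdname triangle_mesh
#' @export
point_cloud <- function(points, normals = NULL) {
  points <- unname(as.matrix(points))
  storage.mode(points) <- "double"
  stopifnot(ncol(points) == 3L, all(is.finite(points)))
  if (!is.null(normals)) {
    normals <- unname(as.matrix(normals))
    stopifnot(all(dim(normals) == dim(points)))
  }
  structure(list(points = points, normals = normals), class = "point_cloud")
}

#' @rdname triangle_mesh
#' @export
is_point_cloud <- function(x) inherits(x, "point_cloud")

face_areas_ <- function(v, f) {
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Mesh measurements
#'
#' @param mesh a `triangle_mesh`.
#' @return `mesh_area`: total surface area (mm^2); `mesh_bounds`: 2x3 matrix
#'   of min/max; `face_areas`: per-face areas.
#' @export
mesh_area <- function(mesh) sum(face_areas_(mesh$vertices, mesh$faces))

#' @rdname mesh_area
#' @export
face_areas <- function(mesh) face_areas_(mesh$vertices, mesh$faces)

#' @rdname mesh_area
#' @export
mesh_bounds <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2, min), max = apply(mesh$vertices, 2, max))
}

#' Area-weighted per-vertex normals
#'
#' Face normals (consistent with the stored winding) accumulated on vertices
#' and normalised.
#'
#' @param mesh a `triangle_mesh`.
#' @return `n x 3` matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- matrix(0, nrow(v), 3)
  for (j in 1:3) {
    acc <- rowsum(fn, f[, j])
    at <- as.integer(rownames(acc))
    n[at, ] <- n[at, ] + acc
  }
  len <- sqrt(rowSums(n^2))
  len[len < 1e-300] <- 1
  n / len
}

#' Watertightness test
#'
#' A mesh is considered watertight when every undirected edge is shared by
#' exactly two faces with opposite orientation.
#'
#' @param mesh a `triangle_mesh`.
#' @return `TRUE`/`FALSE`.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(FALSE)
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  tab <- table(key)
  if (any(tab != 2)) return(FALSE)
  dir_key <- paste(he[, 1], he[, 2])
  all(table(dir_key) == 1)  # each directed edge once => opposite windings
}

#' Uniform area-weighted surface sampling
#'
#' @param mesh a `triangle_mesh`.
#' @param n number of samples.
#' @param seed optional seed.
#' @param with_normals attach the sampled face normals.
#' @return A `point_cloud`.
#' @export
sample_surface <- function(mesh, n, seed = NULL, with_normals = FALSE) {
  a <- face_areas_(mesh$vertices, mesh$faces)
  with_seed(seed, {
    fi <- sample.int(length(a), n, replace = TRUE, prob = a)
    r1 <- sqrt(runif(n)); r2 <- runif(n)
    w1 <- 1 - r1; w2 <- r1 * (1 - r2); w3 <- r1 * r2
    v <- mesh$vertices; f <- mesh$faces
    p <- v[f[fi, 1], , drop = FALSE] * w1 + v[f[fi, 2], , drop = FALSE] * w2 +
      v[f[fi, 3], , drop = FALSE] * w3
    if (!with_normals) return(point_cloud(p))
    e1 <- v[f[fi, 2], , drop = FALSE] - v[f[fi, 1], , drop = FALSE]
    e2 <- v[f[fi, 3], , drop = FALSE] - v[f[fi, 1], , drop = FALSE]
    nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                 e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                 e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    nrm <- nrm / sqrt(rowSums(nrm^2))
    point_cloud(p, nrm)
  })
}

#' Point-in-mesh test (watertight meshes)
#'
#' Ray-parity test along +x with duplicate-hit collapsing.
#'
#' @param points length-3 point or `n x 3` matrix.
#' @param mesh a watertight `triangle_mesh`.
#' @return Logical vector.
#' @export
points_in_mesh <- function(points, mesh) {
  p <- if (is.null(dim(points))) matrix(points, 1) else as.matrix(points)
  cpp_points_in_mesh(mesh$vertices, mesh$faces, p)
}

#' Symmetric sampled Hausdorff-style surface distance
#'
#' Samples each surface and reports the maximum over both directions of the
#' sample-to-other-surface distances (an upper-bound estimate of geometric
#' deviation, as used to validate decimation).
#'
#' @param mesh_a,mesh_b `triangle_mesh` objects.
#' @param n_samples samples per surface.
#' @param seed optional seed.
#' @return Maximum sampled distance (mm).
#' @export
hausdorff_sampled <- function(mesh_a, mesh_b, n_samples = 1000, seed = NULL) {
  sa <- sample_surface(mesh_a, n_samples, seed = seed)
  sb <- sample_surface(mesh_b, n_samples,
                       seed = if (is.null(seed)) NULL else subseed(seed, 1))
  d_ab <- cpp_closest_point_mesh(mesh_b$vertices, mesh_b$faces, sa$points)$distance
  d_ba <- cpp_closest_point_mesh(mesh_a$vertices, mesh_a$faces, sb$points)$distance
  max(max(d_ab), max(d_ba))
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("<triangle_mesh> ", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  invisible(x)
}

#' @export
print.point_cloud <- function(x, ...) {
  cat("<point_cloud> ", nrow(x$points), "points",
      if (!is.null(x$normals)) "(with normals)" else "", "\n")
  invisible(x)
}
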