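#' Specification of a synthetic head phantom
#'
#' The digital stand-in for the physical measurement phantom: a watertight
#' head-like surface carrying conical measurement fiducials whose apexes sit
#' `fiducial_depth_mm` below the skin (default 20 mm, with a 0.2 mm radial
#' cone margin), 51 fiducials by default. Axes: +x right, +y anterior
#' (facial direction), +z superior.
#'
#' @param seed integer seed controlling all procedural randomness.
#' @param head_dims_mm full extents (x, y, z) of the head in mm.
#' @param feature_amplitude_mm scale of the facial relief (nose, brow, chin);
#'   the face's asymmetric relief is what makes markerless surface
#'   registration well-posed.
#' @param n_fiducials number of conical fiducials.
#' @param fiducial_depth_mm apex depth below the skin surface (mm).
#' @param cone_margin_mm radial margin of the cone opening (metadata; mm).
#' @param mesh_resolution target vertex count of the generated surface.
#' @param min_spacing_mm minimum Euclidean spacing between fiducial centres.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L,
                         head_dims_mm = c(160, 195, 225),
                         feature_amplitude_mm = 12,
                         n_fiducials = 51L,
                         fiducial_depth_mm = 20,
                         cone_margin_mm = 0.2,
                         mesh_resolution = 10242L,
                         min_spacing_mm = 15) {
  stopifnot(n_fiducials >= 1L, fiducial_depth_mm > 0,
            all(head_dims_mm > 0), length(head_dims_mm) == 3L,
            feature_amplitude_mm >= 0, mesh_resolution >= 12)
  structure(list(seed = as.integer(seed), head_dims_mm = as.numeric(head_dims_mm),
                 feature_amplitude_mm = feature_amplitude_mm,
                 n_fiducials = as.integer(n_fiducials),
                 fiducial_depth_mm = fiducial_depth_mm,
                 cone_margin_mm = cone_margin_mm,
                 mesh_resolution = as.integer(mesh_resolution),
                 min_spacing_mm = min_spacing_mm),
            class = "phantom_spec")
}

# Unit icosphere by midpoint subdivision; deterministic, watertight,
# outward-wound. Levels give 12, 42, 162, 642, 2562, 10242, 40962 vertices.
icosphere <- function(subdiv) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    edge_id <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- edge_id[[key]]
      if (!is.null(id)) return(id)
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1L]] <<- m
      id <- nv + length(newv)
      edge_id[[key]] <- id
      id
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[4 * i - 3, ] <- c(a, ab, ca)
      nf[4 * i - 2, ] <- c(b, bc, ab)
      nf[4 * i - 1, ] <- c(c, ca, bc)
      nf[4 * i, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  list(vertices = v, faces = f)
}

# smooth angular bump: exp(-angle(dir, center)^2 / (2 sigma^2))
angular_bump <- function(dirs, center, sigma) {
  center <- center / sqrt(sum(center^2))
  ct <- pmin(1, pmax(-1, dirs %*% center))
  ang <- acos(ct)
  exp(-ang^2 / (2 * sigma^2))
}

#' Generate a procedural head phantom surface
#'
#' A watertight, genus-0 head: an ellipsoid cranium with procedural facial
#' relief (nose, brow, chin, cheekbones, eye sockets) plus small seeded
#' asymmetries, rescaled so the bounding box equals `head_dims_mm` exactly.
#' Deterministic for a fixed spec.
#'
#' @param spec a [phantom_spec()].
#' @return A `triangle_mesh` in mm, centred near the origin.
#' @export
generate_head_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sizes <- c(12, 42, 162, 642, 2562, 10242, 40962)
  lvl <- match(TRUE, sizes >= spec$mesh_resolution)
  if (is.na(lvl)) stop("mesh_resolution beyond the supported subdivision range")
  ico <- icosphere(lvl - 1L)
  dirs <- ico$vertices
  amp <- spec$feature_amplitude_mm
  # relief pattern deliberately asymmetric top-to-bottom along the face
  # (protrusive nose ridge below the eye line, broad forehead dome, narrow
  # chin, recessed sockets and mouth): the asymmetry is what makes
  # markerless surface registration well-posed
  relief <-
    amp * 1.60 * angular_bump(dirs, c(0, 1, -0.15), 0.13) +       # nose tip
    amp * 0.80 * angular_bump(dirs, c(0, 0.98, -0.32), 0.10) +    # nose ridge
    amp * 0.35 * angular_bump(dirs, c(0, 0.92, 0.45), 0.30) +     # brow
    amp * 0.25 * angular_bump(dirs, c(0, 0.80, 0.55), 0.50) +     # forehead dome
    amp * 0.55 * angular_bump(dirs, c(0, 0.80, -0.80), 0.16) +    # chin
    amp * 0.30 * angular_bump(dirs, c(0.60, 0.70, -0.20), 0.25) + # cheekbones
    amp * 0.30 * angular_bump(dirs, c(-0.60, 0.70, -0.20), 0.25) -
    amp * 0.50 * angular_bump(dirs, c(0.30, 0.88, 0.18), 0.13) -  # eye sockets
    amp * 0.50 * angular_bump(dirs, c(-0.30, 0.88, 0.18), 0.13) -
    amp * 0.20 * angular_bump(dirs, c(0, 0.95, -0.52), 0.12)      # mouth
  relief <- relief + with_seed(spec$seed, {
    r <- numeric(nrow(dirs))
    for (i in 1:4) {
      ctr <- rnorm(3); ctr[2] <- abs(ctr[2])  # bias bumps toward the face
      r <- r + amp * runif(1, 0.08, 0.2) * sign(runif(1) - 0.35) *
        angular_bump(dirs, ctr, runif(1, 0.2, 0.45))
    }
    r
  })
  semi <- spec$head_dims_mm / 2
  e <- sweep(dirs, 2, semi, `*`)
  u <- e / sqrt(rowSums(e^2))
  v <- e + relief * u
  # rescale each axis so the bounding box matches the requested extents
  for (ax in 1:3) {
    ext <- max(v[, ax]) - min(v[, ax])
    ctr <- (max(v[, ax]) + min(v[, ax])) / 2
    v[, ax] <- (v[, ax] - ctr) * (spec$head_dims_mm[ax] / ext)
  }
  triangle_mesh(v, ico$faces)
}

#' Place conical fiducials on a phantom surface
#'
#' Farthest-point sampling over the upper (face/scalp) surface vertices with
#' a minimum Euclidean spacing; each fiducial's cone apex lies
#' `fiducial_depth_mm` below its skin opening along the inward surface
#' normal, strictly inside the mesh.
#'
#' @param mesh a watertight `triangle_mesh`.
#' @param spec a [phantom_spec()].
#' @return A `fiducial_set`: list with `id`, `surface_center` (n x 3),
#'   `tip` (n x 3), `axis` (n x 3, inward unit vectors).
#' @export
place_fiducials <- function(mesh, spec) {
  stopifnot(is_triangle_mesh(mesh), inherits(spec, "phantom_spec"))
  nrm <- vertex_normals(mesh)
  ctr <- colMeans(mesh$vertices)
  # ensure outward orientation
  outward <- rowSums(nrm * sweep(mesh$vertices, 2, ctr)) > 0
  if (mean(outward) < 0.5) nrm <- -nrm
  z <- mesh$vertices[, 3]
  cand <- which(z > min(z) + 0.22 * (max(z) - min(z)))  # exclude neck/base cap
  # candidate tips must land strictly inside
  tips <- mesh$vertices[cand, , drop = FALSE] - spec$fiducial_depth_mm * nrm[cand, , drop = FALSE]
  ok <- points_in_mesh(tips, mesh)
  # keep sites whose apex clears the whole surface by ~the nominal depth
  # (rules out high-curvature sites such as the nose ridge)
  margin <- closest_points_on_mesh(tips[ok, , drop = FALSE], mesh)$distance
  cand <- cand[ok][margin >= 0.95 * spec$fiducial_depth_mm]
  if (length(cand) < spec$n_fiducials)
    stop("cannot place ", spec$n_fiducials, " fiducials; only ",
         length(cand), " admissible sites")
  P <- mesh$vertices[cand, , drop = FALSE]
  start <- with_seed(subseed(spec$seed, 17), sample.int(length(cand), 1))
  sel <- integer(0)
  d2 <- rep(Inf, length(cand))
  cur <- start
  for (k in seq_len(spec$n_fiducials)) {
    sel <- c(sel, cur)
    d2 <- pmin(d2, rowSums(sweep(P, 2, P[cur, ])^2))
    cur <- which.max(d2)
    if (k < spec$n_fiducials && sqrt(d2[cur]) < spec$min_spacing_mm)
      stop("cannot place ", spec$n_fiducials, " fiducials at ",
           spec$min_spacing_mm, " mm spacing; achieved ", k)
  }
  idx <- cand[sel]
  sc <- mesh$vertices[idx, , drop = FALSE]
  ax <- -nrm[idx, , drop = FALSE]
  structure(list(id = seq_len(spec$n_fiducials),
                 surface_center = sc,
                 tip = sc + spec$fiducial_depth_mm * ax,
                 axis = ax,
                 depth_mm = spec$fiducial_depth_mm,
                 cone_margin_mm = spec$cone_margin_mm),
            class = "fiducial_set")
}

#' Plan biopsy trajectories through the fiducials
#'
#' One trajectory per fiducial, from the middle of the cone's surface
#' opening (entry) to the inverted cone tip (target).
#'
#' @param fiducials a `fiducial_set`.
#' @return List of [trajectory()] objects.
#' @export
plan_trajectories <- function(fiducials) {
  stopifnot(inherits(fiducials, "fiducial_set"))
  lapply(seq_along(fiducials$id), function(i)
    trajectory(fiducials$surface_center[i, ], fiducials$tip[i, ],
               label = sprintf("point_%02d", fiducials$id[i])))
}

#' Voxelize a watertight mesh into a scalar volume
#'
#' Voxels whose centres fall inside the mesh receive `inside_value` (plus
#' optional Gaussian noise), all others `outside_value`. The default pitch
#' is the 0.5 mm isotropic grid of the preoperative scans; anisotropic
#' pitches (e.g. `c(1.0, 0.5, 0.5)`) are supported.
#'
#' @param mesh a watertight `triangle_mesh`.
#' @param voxel_mm voxel spacing per axis (mm).
#' @param inside_value,outside_value intensities of the two classes.
#' @param noise_sd Gaussian intensity noise (0 = none).
#' @param seed optional seed for the noise.
#' @param padding_mm empty margin around the mesh bounding box.
#' @return A [volume()].
#' @export
voxelize <- function(mesh, voxel_mm = c(0.5, 0.5, 0.5), inside_value = 100,
                     outside_value = 0, noise_sd = 0, seed = NULL,
                     padding_mm = 3) {
  stopifnot(is_triangle_mesh(mesh))
  if (!is_watertight(mesh)) stop("voxelize requires a watertight mesh")
  voxel_mm <- rep(as.numeric(voxel_mm), length.out = 3)
  stopifnot(all(voxel_mm > 0))
  b <- mesh_bounds(mesh)
  origin <- b["min", ] - padding_mm
  dims <- as.integer(ceiling((b["max", ] + padding_mm - origin) / voxel_mm)) + 1L
  mask <- cpp_voxelize_parity(mesh$vertices, mesh$faces, origin, voxel_mm, dims)
  arr <- array(ifelse(mask, inside_value, outside_value), dim = dims)
  if (noise_sd > 0)
    arr <- arr + with_seed(seed, array(rnorm(length(arr), 0, noise_sd), dim = dims))
  volume(arr, spacing = voxel_mm, origin = origin)
}

#' Smooth skin-shift deformation field
#'
#' Models the soft-tissue distortion caused by patient positioning as a sum
#' of up to five Gaussian radial-basis displacement bumps with seeded
#' centres. With `region_weighting = "posterior"` the magnitude is
#' multiplied by a smooth ramp that grows toward the dorsal (-y) side,
#' mirroring the posteriorly-worse surface shift reported for skin-based
#' registration. The summed amplitude never exceeds `max_magnitude_mm`.
#'
#' @param bounds 2x3 matrix (min/max rows) over which bump centres are drawn,
#'   typically [mesh_bounds()] of the phantom.
#' @param max_magnitude_mm upper bound on the displacement norm (mm).
#' @param n_bumps number of Gaussian bumps (at most 5).
#' @param sigma_mm spatial width of each bump (mm).
#' @param region_weighting `"posterior"`, `"anterior"` or `"none"`.
#' @param seed integer seed.
#' @return A `deformation_field`: callable via [eval_deformation()].
#' @export
deformation_field <- function(bounds, max_magnitude_mm, n_bumps = 5,
                              sigma_mm = 60,
                              region_weighting = c("posterior", "none", "anterior"),
                              seed = 1L) {
  region_weighting <- match.arg(region_weighting)
  stopifnot(n_bumps >= 1, n_bumps <= 5, max_magnitude_mm >= 0)
  prm <- with_seed(seed, {
    centers <- sapply(1:3, function(a) runif(n_bumps, bounds[1, a], bounds[2, a]))
    centers <- matrix(centers, n_bumps, 3)
    dirs <- matrix(rnorm(3 * n_bumps), n_bumps, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    w <- runif(n_bumps, 0.5, 1)
    list(centers = centers, dirs = dirs, amp = max_magnitude_mm * w / sum(w))
  })
  # normalise so the peak displacement over the domain equals the nominal
  # magnitude (the Gaussians overlap only partially, so the raw sum of
  # amplitudes is reached nowhere); the regional ramp (<= 1) keeps the
  # bound intact
  if (max_magnitude_mm > 0) {
    gr <- as.matrix(expand.grid(seq(bounds[1, 1], bounds[2, 1], length.out = 12),
                                seq(bounds[1, 2], bounds[2, 2], length.out = 12),
                                seq(bounds[1, 3], bounds[2, 3], length.out = 12)))
    raw <- matrix(0, nrow(gr), 3)
    for (i in seq_len(n_bumps)) {
      d2 <- rowSums(sweep(gr, 2, prm$centers[i, ])^2)
      raw <- raw + outer(prm$amp[i] * exp(-d2 / (2 * sigma_mm^2)), prm$dirs[i, ])
    }
    peak <- max(sqrt(rowSums(raw^2)))
    if (peak > 1e-12) prm$amp <- prm$amp * (max_magnitude_mm / peak)
  }
  structure(list(centers = prm$centers, dirs = prm$dirs, amp = prm$amp,
                 sigma_mm = sigma_mm, max_magnitude_mm = max_magnitude_mm,
                 region_weighting = region_weighting,
                 y_range = c(bounds[1, 2], bounds[2, 2])),
            class = "deformation_field")
}

#' Evaluate a deformation field
#'
#' @param field a [deformation_field()].
#' @param points `n x 3` matrix (mm).
#' @return `n x 3` matrix of displacement vectors (mm).
#' @export
eval_deformation <- function(field, points) {
  stopifnot(inherits(field, "deformation_field"))
  P <- as.matrix(points)
  disp <- matrix(0, nrow(P), 3)
  for (i in seq_along(field$amp)) {
    d2 <- rowSums(sweep(P, 2, field$centers[i, ])^2)
    g <- field$amp[i] * exp(-d2 / (2 * field$sigma_mm^2))
    disp <- disp + outer(g, field$dirs[i, ])
  }
  # hard bound (the grid-based normalisation is accurate to ~1%)
  nrm <- sqrt(rowSums(disp^2))
  over <- nrm > field$max_magnitude_mm
  if (any(over))
    disp[over, ] <- disp[over, , drop = FALSE] *
      (field$max_magnitude_mm / nrm[over])
  if (field$region_weighting != "none") {
    yr <- field$y_range
    frac <- (P[, 2] - yr[1]) / max(yr[2] - yr[1], 1e-9)
    frac <- pmin(1, pmax(0, frac))
    ramp <- if (field$region_weighting == "posterior") 1 - frac else frac
    # quadratic ramp with a small floor: the weighted end retains nearly
    # the full magnitude while the opposite end is strongly suppressed,
    # so the regional gradient dominates the bump-placement variation
    disp <- disp * (0.05 + 0.95 * ramp^2)
  }
  disp
}

#' Apply a skin-shift field to a mesh
#'
#' Displaces vertices by the field; connectivity is unchanged.
#'
#' @param mesh a `triangle_mesh`.
#' @param field a [deformation_field()].
#' @return The deformed `triangle_mesh`.
#' @export
apply_skin_shift <- function(mesh, field) {
  stopifnot(is_triangle_mesh(mesh))
  v <- mesh$vertices + eval_deformation(field, mesh$vertices)
  triangle_mesh(v, mesh$faces)
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat("<fiducial_set> ", length(x$id), "fiducials at depth",
      x$depth_mm, "mm\n")
  invisible(x)
}
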