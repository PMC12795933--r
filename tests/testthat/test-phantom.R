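test_that("phantom generation is deterministic, watertight and to size", {
  spec <- fx_spec_small()
  m1 <- generate_head_phantom(spec)
  m2 <- generate_head_phantom(spec)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$faces, m2$faces)
  expect_true(is_watertight(m1))
  expect_true(points_in_mesh(colMeans(m1$vertices), m1))
  ext <- mesh_bounds(m1)[2, ] - mesh_bounds(m1)[1, ]
  expect_lt(max(abs(ext - spec$head_dims_mm) / spec$head_dims_mm), 0.01)
  # different seed changes the asymmetry bumps
  m3 <- generate_head_phantom(phantom_spec(seed = 4, mesh_resolution = 2562L))
  expect_false(identical(m1$vertices, m3$vertices))
  expect_error(generate_head_phantom(phantom_spec(mesh_resolution = 1e6)),
               "resolution")
})

test_that("fiducials sit 20 mm deep, inside, inward-pointing, well spaced", {
  spec <- fx_spec_small()
  mesh <- fx_phantom_small()
  fid <- place_fiducials(mesh, spec)
  expect_length(fid$id, 51L)
  depth <- sqrt(rowSums((fid$surface_center - fid$tip)^2))
  expect_true(all(abs(depth - 20) <= 0.1))
  expect_true(all(points_in_mesh(fid$tip, mesh)))
  expect_true(all(closest_points_on_mesh(fid$tip, mesh)$distance >= 19))
  # axes inward: against the outward surface normal
  nrm <- vertex_normals(mesh)
  ctr <- colMeans(mesh$vertices)
  out <- sign(rowSums(nrm * sweep(mesh$vertices, 2, ctr)))
  idx <- vapply(seq_len(51), function(i)
    which.min(colSums((t(mesh$vertices) - fid$surface_center[i, ])^2)), 0L)
  expect_true(all(rowSums(fid$axis * (nrm[idx, ] * out[idx])) < 0))
  # minimum spacing between skin openings
  expect_gte(min(dist(fid$surface_center)), spec$min_spacing_mm)
  # unmeetable spacing errors out with the achieved count
  expect_error(place_fiducials(mesh, phantom_spec(seed = 3,
                                                  mesh_resolution = 2562L,
                                                  min_spacing_mm = 80)),
               "achieved")
})

test_that("planned trajectories run from the skin opening to the cone tip", {
  fidu <- place_fiducials(fx_phantom_small(), fx_spec_small())
  trajs <- plan_trajectories(fidu)
  expect_length(trajs, length(fidu$id))
  lens <- vapply(trajs, function(t) sqrt(sum((t$entry - t$target)^2)), 0)
  expect_true(all(abs(lens - 20) <= 0.1))
  for (i in c(1, 25, 51))
    expect_equal(off_plan_distance(trajs[[i]]$target, trajs[[i]]), 0,
                 tolerance = 1e-12)
})

test_that("voxelization matches analytic volume and is two-valued", {
  sph <- fx_sphere(4)
  vol <- voxelize(sph, c(0.5, 0.5, 0.5))
  inside <- sum(vol$data == 100)
  expect_lt(abs(inside * 0.125 - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.05)
  expect_identical(sort(unique(as.numeric(vol$data))), c(0, 100))
  # known inside / outside points
  ijk_of <- function(p) round((p - vol$origin) / vol$spacing) + 1
  ctr <- ijk_of(c(0, 0, 0))
  expect_equal(vol$data[ctr[1], ctr[2], ctr[3]], 100)
  corner <- vol$data[1, 1, 1]
  expect_equal(corner, 0)
  # noise makes it non-binary but seeded-reproducible
  v1 <- voxelize(sph, c(1, 1, 1), noise_sd = 5, seed = 9)
  v2 <- voxelize(sph, c(1, 1, 1), noise_sd = 5, seed = 9)
  expect_identical(v1$data, v2$data)
  expect_gt(length(unique(as.numeric(v1$data))), 2)
  open_mesh <- crop_reference(sph, "full_head",
                              landmarks = list(nose_tip = c(0, 10, 0),
                                               eye_left = c(-3, 9, 2),
                                               eye_right = c(3, 9, 2),
                                               ear_plane_y = 0),
                              eye_radius_mm = 2)
  expect_error(voxelize(open_mesh), "watertight")
})

test_that("skin-shift fields are bounded, seeded and posterior-weighted", {
  mesh <- fx_phantom_small()
  b <- mesh_bounds(mesh)
  f0 <- deformation_field(b, max_magnitude_mm = 0, seed = 2)
  m0 <- apply_skin_shift(mesh, f0)
  expect_equal(m0$vertices, mesh$vertices)
  f3 <- deformation_field(b, max_magnitude_mm = 3, seed = 2)
  d <- eval_deformation(f3, mesh$vertices)
  expect_true(all(sqrt(rowSums(d^2)) <= 3 + 1e-9))
  expect_identical(d, eval_deformation(deformation_field(b, 3, seed = 2),
                                       mesh$vertices))
  # posterior third moves more than the anterior third on average
  y <- mesh$vertices[, 2]
  qs <- quantile(y, c(1 / 3, 2 / 3))
  mean_disp <- function(sel) mean(sqrt(rowSums(d[sel, , drop = FALSE]^2)))
  expect_gt(mean_disp(y <= qs[1]), mean_disp(y >= qs[2]))
  # deformation changes geometry but not connectivity
  m3 <- apply_skin_shift(mesh, f3)
  expect_identical(m3$faces, mesh$faces)
  expect_false(identical(m3$vertices, mesh$vertices))
  # field smoothness: bounded finite-difference gradient
  p0 <- mesh$vertices[1:200, ]
  g <- (eval_deformation(f3, p0 + matrix(c(0.5, 0, 0), 200, 3, byrow = TRUE)) -
          eval_deformation(f3, p0)) / 0.5
  expect_lt(max(abs(g)), 1)
})
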