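test_that("depth rendering matches the exhaustive intersection oracle", {
  sph <- fx_sphere(2)
  cam <- camera_look_at(c(25, 18, 30), c(0, 0, 0), width = 64, height = 64,
                        fov_deg = 60, max_range_mm = 500)
  img <- render_depth(sph, cam)
  oracle <- oracle_render_depth(sph, cam)
  expect_lt(max(abs(img$depth - oracle)), 1e-6)
  # rays that miss are marked invalid (0)
  expect_true(any(img$depth == 0))
  expect_identical(img$depth == 0, oracle == 0)
})

test_that("principal ray of a sphere returns d - r", {
  sph <- fx_sphere(4)
  # odd-sized image puts a pixel exactly on the optical axis; the icosphere
  # subdivision has a vertex on the axis, so the analytic value is exact
  cam <- camera_look_at(c(0, 0, 100), c(0, 0, 0), up = c(0, 1, 0),
                        width = 65, height = 65)
  img <- render_depth(sph, cam)
  expect_lt(abs(img$depth[33, 33] - 90), 1e-6)
})

test_that("depth images invert to world clouds on the surface", {
  mesh <- fx_phantom_small()
  cam <- fx_frontal_camera(mesh)
  img <- render_depth(mesh, cam)
  pc <- depth_to_pointcloud(img)
  expect_equal(nrow(pc$points), sum(img$depth > 0))
  # reprojection round trip
  rel <- sweep(pc$points, 2, cam$pose$t) %*% cam$pose$R
  u <- rel[, 1] / rel[, 3] * cam$fx + cam$cx
  v <- rel[, 2] / rel[, 3] * cam$fy + cam$cy
  valid <- which(img$depth > 0, arr.ind = TRUE)
  expect_lt(max(abs(u - (valid[, 2] - 1))), 1e-6)
  expect_lt(max(abs(v - (valid[, 1] - 1))), 1e-6)
  expect_lt(max(abs(rel[, 3] - img$depth[valid])), 1e-6)
  # noiseless points lie on the source mesh
  d <- closest_points_on_mesh(pc$points[seq(1, nrow(pc$points), by = 7), ],
                              mesh)$distance
  expect_lt(max(d), 1e-3)
})

test_that("rendering is equivariant under a joint rigid motion", {
  mesh <- fx_phantom_small()
  cam <- fx_frontal_camera(mesh)
  Tr <- random_rigid_transform(40, 80, seed = 31)
  cam2 <- depth_camera(width = cam$width, height = cam$height, fx = cam$fx,
                       fy = cam$fy, cx = cam$cx, cy = cam$cy,
                       pose = rt_compose(Tr, cam$pose),
                       max_range_mm = cam$max_range_mm)
  pc1 <- depth_to_pointcloud(render_depth(mesh, cam))
  pc2 <- depth_to_pointcloud(render_depth(apply_transform(Tr, mesh), cam2))
  expect_equal(nrow(pc1$points), nrow(pc2$points))
  expect_lt(max(abs(apply_transform(Tr, pc1$points) - pc2$points)), 1e-6)
})

test_that("sensor noise model: determinism, dropout rate, degenerate case", {
  mesh <- fx_phantom_small()
  cam <- fx_frontal_camera(mesh)
  pc <- depth_to_pointcloud(render_depth(mesh, cam))
  clean <- corrupt(pc, noise_model(0, 0, 0, seed = 1), eye = cam$pose$t)
  expect_equal(clean$points, pc$points)
  n1 <- corrupt(pc, noise_model(seed = 5), eye = cam$pose$t)
  n2 <- corrupt(pc, noise_model(seed = 5), eye = cam$pose$t)
  expect_identical(n1$points, n2$points)
  # Monte-Carlo dropout expectation on 1e5 points
  big <- point_cloud(matrix(rnorm(3e5), 1e5, 3) * 100)
  kept <- nrow(corrupt(big, noise_model(0, 0.05, 0, seed = 8))$points) / 1e5
  expect_lt(abs(kept - 0.95), 0.01)
  # axial-only noise: perturbation parallel to the viewing ray
  ax <- corrupt(pc, noise_model(1, 0, 0, seed = 2), eye = cam$pose$t)
  delta <- ax$points - pc$points
  ray <- sweep(pc$points, 2, cam$pose$t)
  ray <- ray / sqrt(rowSums(ray^2))
  cross_norm <- sqrt(rowSums((delta - rowSums(delta * ray) * ray)^2))
  expect_lt(max(cross_norm), 1e-9)
})

test_that("coverage labels partial views", {
  mesh <- fx_phantom_small()
  face <- crop_reference(mesh, "face_only")
  front <- fx_frontal_camera(mesh)
  ctr <- colMeans(mesh$vertices)
  back <- camera_look_at(eye = ctr + c(0, -450, 40), target = ctr)
  cov_front <- coverage_fraction(face, front, occluder = mesh)
  cov_back <- coverage_fraction(face, back, occluder = mesh)
  expect_gt(cov_front, 0.5)
  expect_lt(cov_back, 0.1)
})
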