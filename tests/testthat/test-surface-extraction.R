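test_that("threshold segmentation counts and edge cases", {
  sph <- fx_sphere(3)
  vol <- voxelize(sph, c(1, 1, 1))
  mask <- threshold_segment(vol, 50)
  expect_equal(sum(mask$mask), sum(vol$data >= 50))
  expect_error(threshold_segment(vol, 200), "empty")
  all_true <- threshold_segment(vol, -1)
  expect_true(all(all_true$mask))
  # largest-component rule: add a detached speck
  v2 <- vol
  v2$data[1, 1, 1] <- 100
  m2 <- threshold_segment(v2, 50)
  expect_false(m2$mask[1, 1, 1])
  expect_equal(sum(m2$mask), sum(mask$mask))
})

test_that("median smoothing equals the naive sliding-window oracle", {
  set.seed(21)
  arr <- array(runif(20^3) < 0.45, c(20, 20, 20))
  mask <- binary_mask(arr, spacing = c(1, 1, 1))
  sm <- median_smooth(mask, 3)
  expect_identical(sm$mask, oracle_median_smooth(arr, c(1L, 1L, 1L)))
  # anisotropic spacing: window 3 mm -> 7 voxels on the fine axes
  mask2 <- binary_mask(arr, spacing = c(1, 0.5, 0.5))
  sm2 <- median_smooth(mask2, 3)
  expect_identical(sm2$mask, oracle_median_smooth(arr, c(1L, 3L, 3L)))
  # speckle removal and solid-interior stability
  sp <- array(FALSE, c(11, 11, 11)); sp[6, 6, 6] <- TRUE
  expect_false(any(median_smooth(binary_mask(sp), 3)$mask))
  solid <- array(FALSE, c(12, 12, 12)); solid[3:10, 3:10, 3:10] <- TRUE
  smd <- median_smooth(binary_mask(solid), 3)
  expect_true(all(smd$mask[5:8, 5:8, 5:8]))
})

test_that("iso-surface of a ball reproduces the analytic sphere", {
  sph <- fx_sphere(4)
  vol <- voxelize(sph, c(0.5, 0.5, 0.5))
  mask <- threshold_segment(vol, 50)
  surf <- extract_surface(mask)
  expect_true(is_watertight(surf))
  expect_lt(abs(mesh_area(surf) - 4 * pi * 100) / (4 * pi * 100), 0.05)
  # vertices stay within one voxel diagonal of a boundary voxel centre
  m <- mask$mask
  d <- dim(m)
  inner <- array(FALSE, d)
  inner[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <-
    m[1:(d[1] - 2), 2:(d[2] - 1), 2:(d[3] - 1)] &
    m[3:d[1], 2:(d[2] - 1), 2:(d[3] - 1)] &
    m[2:(d[1] - 1), 1:(d[2] - 2), 2:(d[3] - 1)] &
    m[2:(d[1] - 1), 3:d[2], 2:(d[3] - 1)] &
    m[2:(d[1] - 1), 2:(d[2] - 1), 1:(d[3] - 2)] &
    m[2:(d[1] - 1), 2:(d[2] - 1), 3:d[3]]
  bnd <- which(m & !inner, arr.ind = TRUE)
  bnd_pts <- sweep(sweep(bnd - 1, 2, mask$spacing, `*`), 2, mask$origin, `+`)
  nn <- surgnav:::cpp_nn1(bnd_pts, surf$vertices)
  expect_lt(max(nn$dist), sqrt(3) * 0.5 + 1e-9)
  expect_error(extract_surface(binary_mask(array(TRUE, c(4, 4, 4)))), "classes")
})

test_that("solidification fills internal cavities before meshing", {
  # hollow shell: ball with an empty core
  sph <- fx_sphere(3)
  vol <- voxelize(sph, c(1, 1, 1))
  m <- vol$data >= 50
  ctr <- round((c(0, 0, 0) - vol$origin) / vol$spacing) + 1
  rng <- function(c0) (c0 - 3):(c0 + 3)
  m[rng(ctr[1]), rng(ctr[2]), rng(ctr[3])] <- FALSE
  hollow <- binary_mask(m, vol$spacing, vol$origin)
  surf <- extract_surface(hollow)
  # one closed outer surface only: no vertices near the cavity wall
  expect_true(is_watertight(surf))
  expect_gt(min(sqrt(rowSums(surf$vertices^2))), 5)
})

test_that("quadric decimation respects the target and the geometry", {
  sph <- fx_sphere(4)
  small <- decimate(sph, 10^5)
  expect_identical(small, sph)  # already below target
  vol <- voxelize(sph, c(0.5, 0.5, 0.5))
  surf <- extract_surface(threshold_segment(vol, 50))
  dec <- decimate(surf, 5000)
  expect_lte(nrow(dec$faces), 5000)
  expect_true(is_watertight(dec))
  expect_lt(hausdorff_sampled(surf, dec, 800, seed = 1), 0.5)
})

test_that("reference cropping removes the eyes and the posterior head", {
  mesh <- fx_phantom_small()
  lm <- estimate_landmarks(mesh)
  face <- crop_reference(mesh, "face_only", lm)
  full <- crop_reference(mesh, "full_head", lm)
  expect_lt(nrow(face$vertices), nrow(full$vertices))
  for (cropped in list(face, full)) {
    d_l <- sqrt(rowSums(sweep(cropped$vertices, 2, lm$eye_left)^2))
    d_r <- sqrt(rowSums(sweep(cropped$vertices, 2, lm$eye_right)^2))
    expect_true(all(d_l > 15 & d_r > 15))
  }
  expect_true(all(face$vertices[, 2] > lm$ear_plane_y))
  expect_gt(mesh_area(full) / mesh_area(mesh), 0.9)
  expect_error(crop_reference(mesh, "full_head", lm, eye_radius_mm = 1e4),
               "removed all")
})

test_that("voxelize/extract round trip stays within two voxel diagonals", {
  mesh <- fx_phantom_small()
  vol <- voxelize(mesh, c(1, 1, 1))
  surf <- extract_surface(threshold_segment(vol, 50))
  s <- sample_surface(surf, 800, seed = 5)
  d <- closest_points_on_mesh(s$points, mesh)$distance
  expect_lt(quantile(d, 0.95), 2 * sqrt(3))
})
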