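test_that("voxel downsampling matches the grid-bucket oracle", {
  p <- rbind(c(0.1, 0.1, 0.1), c(0.9, 0.4, 0.2))
  one <- downsample_voxel(point_cloud(p), 2)
  expect_equal(nrow(one$points), 1L)
  expect_equal(one$points[1, ], colMeans(p))
  set.seed(17)
  pts <- matrix(runif(3000, -50, 50), 1000, 3)
  ds <- downsample_voxel(point_cloud(pts), 5)
  expect_equal(ds$points, oracle_downsample(pts, 5), tolerance = 1e-12)
  # every input point near some output point
  nn <- surgnav:::cpp_nn1(ds$points, pts)
  expect_lt(max(nn$dist), 5 * sqrt(3) + 1e-9)
  expect_error(downsample_voxel(point_cloud(matrix(numeric(0), 0, 3)), 1),
               "empty")
})

test_that("covariance normals are unit, oriented and plane-accurate", {
  set.seed(23)
  # tilted plane
  uv <- matrix(runif(600, -20, 20), 300, 2)
  nrm_true <- c(1, 2, 2) / 3
  b1 <- c(2, -1, 0) / sqrt(5); b2 <- c(nrm_true[2] * b1[3] - nrm_true[3] * b1[2],
                                       nrm_true[3] * b1[1] - nrm_true[1] * b1[3],
                                       nrm_true[1] * b1[2] - nrm_true[2] * b1[1])
  pl <- uv %*% rbind(b1, b2)
  cl <- estimate_normals(point_cloud(pl), 15, viewpoint = 100 * nrm_true)
  expect_lt(max(abs(sqrt(rowSums(cl$normals^2)) - 1)), 1e-9)
  ang <- acos(pmin(1, abs(cl$normals %*% nrm_true))) * 180 / pi
  expect_lt(max(ang), 1)
  expect_true(all(cl$normals %*% nrm_true > 0))  # toward the viewpoint
  # sphere cloud oriented from an exterior viewpoint: radial agreement
  sph <- sample_surface(fx_sphere(4), 2000, seed = 3)
  sn <- estimate_normals(sph, 20, viewpoint = c(0, 0, 0))
  radial <- -sph$points / sqrt(rowSums(sph$points^2))  # toward centre
  expect_gt(mean(rowSums(sn$normals * radial) > 0.95), 0.99)
  # the consistent-propagation path agrees up to sign with the radial truth
  sn2 <- estimate_normals(sph, 20)
  expect_gt(mean(abs(rowSums(sn2$normals * radial)) > 0.95), 0.99)
  expect_gt(mean(rowSums(sn2$normals * (-radial)) > 0), 0.99)  # outward
})

test_that("FPFH histograms match the literal-formula oracle", {
  set.seed(29)
  cl <- sample_surface(fx_phantom_small(), 400, seed = 7)
  cl <- estimate_normals(cl, 12)
  sub <- point_cloud(cl$points[1:20, ], cl$normals[1:20, ])
  f <- compute_fpfh(sub, 40)
  expect_equal(dim(f$descriptors), c(20L, 33L))
  expect_true(all(f$descriptors >= 0))
  expect_equal(unname(f$descriptors),
               oracle_fpfh(sub$points, sub$normals, 40), tolerance = 1e-9)
  # rotation invariance
  Tr <- random_rigid_transform(120, 60, seed = 41)
  f2 <- compute_fpfh(apply_transform(Tr, sub), 40)
  expect_lt(max(rowSums(abs(f$descriptors - f2$descriptors))), 1e-6)
  # isolated point: zero histogram
  iso <- point_cloud(rbind(sub$points, c(500, 500, 500)),
                     rbind(sub$normals, c(0, 0, 1)))
  fi <- compute_fpfh(iso, 40)
  expect_equal(sum(fi$descriptors[21, ]), 0)
})

test_that("correspondence matching is mutual-NN with oracle agreement", {
  cl <- estimate_normals(sample_surface(fx_phantom_small(), 600, seed = 9), 15)
  f <- compute_fpfh(cl, 20)
  self <- match_correspondences(f, f)
  expect_true(all(self$pairs[, 1] == self$pairs[, 2]))
  expect_lte(nrow(self$pairs), nrow(cl$points))
  # against an independent all-pairs search on a random subset
  A <- f$descriptors[1:80, ]; B <- f$descriptors[101:220, ]
  fa <- structure(list(keypoints = point_cloud(cl$points[1:80, ]),
                       descriptors = A), class = "feature_set")
  fb <- structure(list(keypoints = point_cloud(cl$points[101:220, ]),
                       descriptors = B), class = "feature_set")
  got <- match_correspondences(fa, fb)
  D <- as.matrix(dist(rbind(A, B)))[1:80, 81:200]
  fw <- apply(D, 1, which.min); bw <- apply(D, 2, which.min)
  mutual <- which(bw[fw] == seq_len(80))
  want <- cbind(mutual, fw[mutual])
  expect_setequal(paste(got$pairs[, 1], got$pairs[, 2]),
                  paste(want[, 1], want[, 2]))
})

test_that("robust global registration survives 70% outliers", {
  errs <- t(vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 100
    S <- matrix(runif(3 * n, -100, 100), n, 3)
    Tt <- random_rigid_transform(180, 200, seed = seed + 1000)
    D <- apply_transform(Tt, S) + matrix(rnorm(3 * n, 0, 0.5), n, 3)
    D[sample(n, 70), ] <- matrix(runif(210, -150, 150), 70, 3)
    corr <- structure(list(pairs = cbind(1:n, 1:n), src = point_cloud(S),
                           dst = point_cloud(D)), class = "correspondence_set")
    r <- global_register(corr, 1.5)
    c(rt_rotation_error_deg(r$transform, Tt),
      rt_translation_error_mm(r$transform, Tt))
  }, numeric(2)))
  expect_gte(sum(errs[, 1] < 1 & errs[, 2] < 1), 19)
})

test_that("global registration: exact case equals the closed form", {
  set.seed(9)
  S <- matrix(runif(30, -100, 100), 10, 3)
  Tt <- random_rigid_transform(50, 50, seed = 11)
  D <- apply_transform(Tt, S)
  corr <- structure(list(pairs = cbind(1:10, 1:10), src = point_cloud(S),
                         dst = point_cloud(D)), class = "correspondence_set")
  r <- global_register(corr, 1.5)
  expect_lt(max(abs(r$transform$R - Tt$R)), 1e-9)
  expect_lt(max(abs(r$transform$t - Tt$t)), 1e-9)
  expect_equal(r$inlier_count, 10L)
  too_few <- structure(list(pairs = cbind(1:2, 1:2), src = point_cloud(S[1:2, ]),
                            dst = point_cloud(D[1:2, ])),
                       class = "correspondence_set")
  expect_error(global_register(too_few, 1.5), "3")
})

test_that("global registration is invariant to correspondence order", {
  set.seed(15)
  n <- 60
  S <- matrix(runif(3 * n, -80, 80), n, 3)
  Tt <- random_rigid_transform(90, 100, seed = 51)
  D <- apply_transform(Tt, S) + matrix(rnorm(3 * n, 0, 0.3), n, 3)
  D[sample(n, 18), ] <- matrix(runif(54, -120, 120), 18, 3)
  mk <- function(ord) structure(list(pairs = cbind(ord, ord),
                                     src = point_cloud(S), dst = point_cloud(D)),
                                class = "correspondence_set")
  r1 <- global_register(mk(1:n), 1.5)
  r2 <- global_register(mk(sample(n)), 1.5)
  expect_lt(rt_rotation_error_deg(r1$transform, r2$transform), 1e-6)
  expect_lt(rt_translation_error_mm(r1$transform, r2$transform), 1e-6)
})

test_that("ICP: convergence, recovery and point-to-point monotonicity", {
  cl <- sample_surface(fx_phantom_small(), 2500, seed = 19)
  scene <- estimate_normals(point_cloud(cl$points), 30)
  # identical clouds from the identity: immediate convergence
  r0 <- refine_icp(cl, scene, rt_identity())
  expect_lte(length(r0$rmse_history), 2)
  expect_lt(r0$inlier_rmse_mm, 1e-9)
  # 2 deg / 2 mm perturbation recovered within 0.05 deg / 0.05 mm
  Tp <- random_rigid_transform(2, 2, seed = 61)
  Tp$t <- Tp$t / max(1, sqrt(sum(Tp$t^2)) / 2)
  scene2 <- estimate_normals(point_cloud(apply_transform(Tp, cl$points)), 30)
  for (method in c("point_to_plane", "point_to_point")) {
    r <- refine_icp(cl, scene2, rt_identity(), method = method)
    expect_lt(rt_rotation_error_deg(r$transform, Tp), 0.05)
    expect_lt(rt_translation_error_mm(r$transform, Tp), 0.05)
  }
  # monotone RMSE on 50 random full-overlap trials
  for (s in 1:50) {
    set.seed(s + 700)
    pts <- matrix(runif(450, -40, 40), 150, 3)
    Tr <- random_rigid_transform(8, 6, seed = s + 900)
    tgt <- point_cloud(apply_transform(Tr, pts))
    r <- refine_icp(point_cloud(pts), tgt, rt_identity(),
                    method = "point_to_point", d_max_mm = 1e6, max_iter = 30)
    expect_true(all(diff(r$rmse_history) <= 1e-9))
  }
  # unreachable scene: failure result, not an exception
  far <- point_cloud(matrix(rnorm(90) + 1e4, 30, 3))
  rf <- refine_icp(cl, far, rt_identity(), method = "point_to_point",
                   d_max_mm = 10)
  expect_false(rf$success)
  expect_equal(rf$reason, "no_correspondences")
})

test_that("the full cascade recovers poses and is equivariant", {
  face <- fx_face()
  scene <- fx_scene(noise_seed = 301)
  Ti <- random_rigid_transform(30, 100, seed = 71)
  res <- register_pipeline(apply_transform(Ti, face), scene,
                           list(sampling_seed = 72))
  Tt <- rt_invert(Ti)
  expect_true(res$success)
  expect_lt(rt_rotation_error_deg(res$transform, Tt), 1)
  expect_lt(rt_translation_error_mm(res$transform, Tt), 2)
  # equivariance: a different model-frame offset gives a consistent map
  Ti2 <- random_rigid_transform(30, 100, seed = 73)
  res2 <- register_pipeline(apply_transform(Ti2, face), scene,
                            list(sampling_seed = 72))
  map1 <- rt_compose(res$transform, Ti)    # model -> world
  map2 <- rt_compose(res2$transform, Ti2)
  expect_lt(rt_rotation_error_deg(map1, map2), 0.5)
  expect_lt(rt_translation_error_mm(map1, map2), 1)
})

test_that("identical model and scene registration is the identity", {
  face <- fx_face()
  cfg <- list(sampling_seed = 99)
  ref_cloud <- sample_surface(face, validate_config()$registration$model_samples,
                              seed = 99)
  res <- register_pipeline(face, ref_cloud, cfg)
  expect_true(res$success)
  expect_lt(rt_rotation_error_deg(res$transform, rt_identity()), 1e-6)
  expect_lt(sqrt(sum(res$transform$t^2)), 1e-6)
})

test_that("face-only and full-head references both register frontal views", {
  scene <- fx_scene(noise_seed = 311)
  for (ref in list(fx_face(), fx_full_head())) {
    r <- register_pipeline(ref, scene, list(sampling_seed = 13))
    expect_true(r$success)
    expect_lt(rt_rotation_error_deg(r$transform, rt_identity()), 1)
  }
})
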