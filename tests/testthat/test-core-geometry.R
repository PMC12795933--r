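test_that("rigid transforms form a group and preserve distances", {
  for (s in 1:20) {
    T1 <- random_rigid_transform(170, 150, seed = s)
    T2 <- random_rigid_transform(170, 150, seed = s + 500)
    p <- matrix(rnorm(60), 20, 3) * 50
    # identity and inverse
    expect_equal(apply_transform(rt_identity(), p), p)
    expect_lt(max(abs(apply_transform(rt_compose(rt_invert(T1), T1), p) - p)),
              1e-9)
    expect_lt(rt_rotation_error_deg(rt_compose(rt_invert(T1), T1),
                                    rt_identity()), 1e-9)
    # compose acts as T1 after T2
    expect_equal(apply_transform(rt_compose(T1, T2), p),
                 apply_transform(T1, apply_transform(T2, p)), tolerance = 1e-12)
    # pairwise distances preserved
    q <- apply_transform(T1, p)
    expect_lt(max(abs(dist(q) - dist(p))), 1e-9)
  }
  expect_equal(rt_compose(rt_identity(), T1)$R, T1$R)
  expect_equal(rt_invert(rt_identity())$t, c(0, 0, 0))
})

test_that("rotation validation, quaternions and 4x4 round trips", {
  expect_error(rigid_transform(matrix(1:9, 3, 3)), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl), "determinant")
  # quaternion (w,x,y,z) for 90 deg about z, unnormalised on purpose
  q <- 3 * c(cos(pi / 4), 0, 0, sin(pi / 4))
  Tq <- rt_from_quaternion(q, c(1, 2, 3))
  expect_equal(apply_transform(Tq, c(1, 0, 0)), c(0, 1, 0) + c(1, 2, 3),
               tolerance = 1e-12)
  Tm <- rt_from_matrix(rt_to_matrix(Tq))
  expect_equal(Tm$R, Tq$R, tolerance = 1e-12)
  expect_equal(Tm$t, Tq$t)
  # 90 deg about z maps x to y
  R90 <- rot_axis_angle(c(0, 0, 1), pi / 2)
  expect_equal(as.numeric(R90 %*% c(1, 0, 0)), c(0, 1, 0), tolerance = 1e-12)
})

test_that("off-plan distance matches its definition and the sampling oracle", {
  tr <- trajectory(c(0, 0, 0), c(0, 0, 10))
  expect_equal(off_plan_distance(tr$entry, tr), 0)
  expect_equal(off_plan_distance(c(3, 4, 5), tr), 5)
  # beyond the segment: the infinite line is the default
  expect_equal(off_plan_distance(c(3, 4, 25), tr), 5)
  expect_gt(off_plan_distance(c(3, 4, 25), tr, segment = TRUE), 5)
  expect_error(trajectory(c(1, 1, 1), c(1, 1, 1)), "degenerate")

  set.seed(41)
  for (i in 1:1000) {
    entry <- runif(3, -100, 100)
    target <- entry + runif(3, -50, 50)
    if (sqrt(sum((entry - target)^2)) < 1e-3) next
    tip <- runif(3, -120, 120)
    tr <- trajectory(entry, target)
    d <- off_plan_distance(tip, tr)
    expect_lt(abs(d - oracle_off_plan(tip, entry, target)), 1e-6)
    # never exceeds the distances to the defining points
    expect_lte(d, sqrt(sum((tip - entry)^2)) + 1e-12)
    expect_lte(d, sqrt(sum((tip - target)^2)) + 1e-12)
  }
})

test_that("off-plan distance is invariant under a common rigid motion", {
  set.seed(7)
  for (i in 1:50) {
    Tr <- random_rigid_transform(170, 100, seed = i)
    entry <- runif(3, -50, 50); target <- runif(3, -50, 50)
    tip <- runif(3, -80, 80)
    tr <- trajectory(entry, target)
    tr2 <- trajectory(apply_transform(Tr, entry), apply_transform(Tr, target))
    expect_equal(off_plan_distance(apply_transform(Tr, tip), tr2),
                 off_plan_distance(tip, tr), tolerance = 1e-9)
  }
})

test_that("entry-point offset is the rigidly invariant Euclidean distance", {
  expect_equal(entry_point_offset(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(entry_point_offset(c(0, 0, 0), c(2, 0, 0)), 2)
  set.seed(11)
  for (i in 1:100) {
    Tr <- random_rigid_transform(180, 200, seed = i + 300)
    a <- runif(3, -100, 100); b <- runif(3, -100, 100)
    expect_lt(abs(entry_point_offset(apply_transform(Tr, a), apply_transform(Tr, b)) -
                    entry_point_offset(a, b)), 1e-9)
  }
})

test_that("closest point on mesh agrees with the all-triangles oracle", {
  # a mesh vertex is its own closest point
  sph <- fx_sphere(2)
  r <- closest_point_on_mesh(sph$vertices[5, ], sph)
  expect_equal(r$distance, 0, tolerance = 1e-12)
  expect_equal(r$point, sph$vertices[5, ], tolerance = 1e-12)
  # unit triangle in z = 0, query 1 above the centroid
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       matrix(1:3, 1))
  expect_equal(closest_point_on_mesh(c(1 / 3, 1 / 3, 1), tri)$distance, 1)
  expect_error(closest_point_on_mesh(c(0, 0, 0),
                                     triangle_mesh(matrix(0, 0, 3),
                                                   matrix(0L, 0, 3))), "empty")
  # random queries vs brute force (mesh has 320 faces)
  set.seed(13)
  Q <- matrix(runif(3 * 60, -15, 15), 60, 3)
  d <- closest_points_on_mesh(Q, sph)$distance
  for (i in seq_len(nrow(Q)))
    expect_lt(abs(d[i] - oracle_closest_mesh_dist(Q[i, ], sph)), 1e-9)
})
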