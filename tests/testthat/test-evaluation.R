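test_that("perturb_to_accuracy hits the requested surface displacement", {
  surf <- sample_surface(fx_phantom_small(), 1500, seed = 2)
  T_true <- random_rigid_transform(20, 50, seed = 3)
  expect_identical(perturb_to_accuracy(T_true, surf, 0, seed = 4), T_true)
  achieved <- vapply(c(0.5, 1, 1.5, 2, 2.5), function(tgt) {
    Tp <- perturb_to_accuracy(T_true, surf, tgt, seed = 4)
    P <- apply_transform(T_true, surf$points)
    mean(sqrt(rowSums((apply_transform(Tp, surf$points) - P)^2)))
  }, 0)
  expect_true(all(abs(achieved - c(0.5, 1, 1.5, 2, 2.5)) /
                    c(0.5, 1, 1.5, 2, 2.5) <= 0.02))
  expect_true(all(diff(achieved) > 0))
})

test_that("phantom study has the paper's factorial shape", {
  mesh <- fx_phantom()
  fid <- fx_fiducials()
  rec <- run_phantom_study(mesh, fid, seed = 1)
  expect_equal(nrow(rec), 5 * 51 * 3)
  expect_equal(length(unique(rec$requested_accuracy_mm)), 5)
  expect_equal(max(rec$repeat_index), 3)
  expect_true(all(rec$off_plan_mm >= 0))
  # zero perturbation and zero jitter: all off-plan exactly zero
  rec0 <- run_phantom_study(mesh, fid, accuracy_levels = 0, jitter_sd_mm = 0,
                            seed = 1)
  expect_true(all(rec0$off_plan_mm == 0))
  # jitter 0: repeats of a point at a level are identical (deterministic)
  recd <- run_phantom_study(mesh, fid, jitter_sd_mm = 0, seed = 2)
  v <- tapply(recd$off_plan_mm,
              interaction(recd$point_id, recd$requested_accuracy_mm), var)
  expect_lt(max(v), 1e-24)
  # reproducibility under the master seed
  expect_identical(run_phantom_study(mesh, fid, seed = 5),
                   run_phantom_study(mesh, fid, seed = 5))
})

test_that("accuracy sweep induces a positive off-plan trend", {
  rec <- run_phantom_study(fx_phantom(), fx_fiducials(), seed = 1)
  s <- summarize_study(rec)
  expect_gt(s$spearman$rho, 0)
  expect_lt(s$spearman$p_value, 0.01)
  expect_true(all(diff(s$per_level$mean_off_plan_mm) >= 0))
})

test_that("study summaries match their definitions and the rank oracle", {
  rec <- data.frame(point_id = 1:3, requested_accuracy_mm = 1,
                    achieved_accuracy_mm = 1, repeat_index = 1,
                    off_plan_mm = c(1, 2, 3), entry_offset_mm = c(1, 2, 3),
                    region = "frontal", reference_mode = "full_head",
                    success = TRUE)
  s <- summarize_study(rec)
  expect_equal(s$per_level$mean_off_plan_mm, 2)
  expect_equal(s$per_level$sd_off_plan_mm, 1)
  # perfectly monotone set: rho = 1
  mono <- data.frame(point_id = 1:10,
                     requested_accuracy_mm = seq(0.5, 5, by = 0.5),
                     achieved_accuracy_mm = NA, repeat_index = 1,
                     off_plan_mm = seq(0.1, 1, by = 0.1),
                     entry_offset_mm = 0, region = "frontal",
                     reference_mode = "full_head", success = TRUE)
  expect_equal(unname(summarize_study(mono)$spearman$rho), 1)
  # random records vs rank-then-Pearson oracle
  set.seed(37)
  rnd <- data.frame(point_id = 1:200,
                    requested_accuracy_mm = sample(seq(0.5, 2.5, 0.5), 200, TRUE),
                    achieved_accuracy_mm = NA, repeat_index = 1,
                    off_plan_mm = rexp(200), entry_offset_mm = 0,
                    region = sample(c("frontal", "temporal", "posterior"),
                                    200, TRUE),
                    reference_mode = "full_head", success = TRUE)
  s2 <- summarize_study(rnd)
  expect_lt(abs(s2$spearman$rho -
                  oracle_spearman(rnd$requested_accuracy_mm, rnd$off_plan_mm)),
            1e-9)
  # all-failure input: NaN statistics, counted failures
  fails <- rnd
  fails$success <- FALSE
  sf <- summarize_study(fails)
  expect_equal(sf$n_failures, 200L)
  expect_true(is.nan(sf$mean_off_plan_mm))
})

test_that("patient-style study records offsets and supports the fallback", {
  rec <- run_patient_style_study(3, seed = 5, use_volume_chain = FALSE)
  expect_equal(nrow(rec), 3)
  expect_setequal(rec$region, c("frontal", "temporal", "posterior"))
  expect_true(all(rec$off_plan_mm[rec$success] >= 0))
  expect_true(all(rec$attempts %in% c(1L, 2L)))
  # near-ideal baseline: sub-half-millimetre entry overlay
  rec0 <- run_patient_style_study(3, seed = 2, skin_shift_mm = 0,
                                  use_volume_chain = FALSE,
                                  noise = noise_model(0, 0, 0),
                                  jitter_sd_mm = 0)
  expect_lt(mean(rec0$entry_offset_mm[rec0$success]), 0.5)
  # reproducible under the master seed
  expect_identical(rec, run_patient_style_study(3, seed = 5,
                                                use_volume_chain = FALSE))
})

test_that("a failed face-only registration triggers exactly one retry", {
  mesh <- fx_phantom()
  ctr <- colMeans(mesh$vertices)
  cam_back <- camera_look_at(eye = ctr + c(0, -450, 40), target = ctr)
  scene <- corrupt(depth_to_pointcloud(render_depth(mesh, cam_back)),
                   noise_model(seed = 1), eye = cam_back$pose$t)
  fb <- register_with_fallback(fx_face(), fx_full_head(), scene,
                               list(sampling_seed = 1))
  expect_equal(fb$attempts, 2L)
  expect_equal(fb$reference_mode, "full_head")
  # a frontal scene succeeds on the first (face-only) attempt
  fb2 <- register_with_fallback(fx_face(), fx_full_head(),
                                fx_scene(noise_seed = 321),
                                list(sampling_seed = 2))
  expect_equal(fb2$attempts, 1L)
  expect_equal(fb2$reference_mode, "face_only")
})

test_that("regions partition the head by azimuth", {
  expect_equal(assign_region(c(0, 100, 0)), "frontal")
  expect_equal(assign_region(c(100, 0, 0)), "temporal")
  expect_equal(assign_region(c(0, -100, 0)), "posterior")
  expect_equal(assign_region(rbind(c(10, 90, 5), c(-80, -80, 0))),
               c("frontal", "posterior"))
})
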