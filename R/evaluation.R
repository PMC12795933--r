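# In-silico counterparts of the two study designs: the 51-point phantom
# sweep over controlled registration accuracies, and the patient-style
# entry-point-offset study with skin shift and head-region analysis.

#' Assign head regions by azimuth
#'
#' Points are binned by the polar angle of their horizontal direction from
#' the head centre relative to anterior (+y): frontal within 60 degrees,
#' temporal between 60 and 120, posterior beyond.
#'
#' @param points length-3 point or `n x 3` matrix (mm).
#' @param center head centre (mm).
#' @return Character vector of `"frontal"`, `"temporal"`, `"posterior"`.
#' @export
assign_region <- function(points, center = c(0, 0, 0)) {
  p <- if (is.null(dim(points))) matrix(points, 1) else as.matrix(points)
  rel <- sweep(p[, 1:2, drop = FALSE], 2, as.numeric(center)[1:2])
  ang <- atan2(abs(rel[, 1]), rel[, 2]) * 180 / pi
  ifelse(ang < 60, "frontal", ifelse(ang <= 120, "temporal", "posterior"))
}

#' Perturb a registration to a requested surface accuracy
#'
#' Composes `T_true` with a small random rotation (about the sample
#' centroid) and translation, jointly scaled so that the mean displacement
#' of the surface sample equals `target_mm` (within 2%, matching the way a
#' navigation system's surface trace is repeated until a target
#' within-system accuracy is reached).
#'
#' @param T_true the true registration ([rigid_transform()]).
#' @param surface_sample a `point_cloud` of skin-surface points.
#' @param target_mm requested mean surface displacement (mm); 0 returns
#'   `T_true` unchanged.
#' @param seed integer seed.
#' @return A `rigid_transform`.
#' @export
perturb_to_accuracy <- function(T_true, surface_sample, target_mm, seed = 1L) {
  stopifnot(is_rigid_transform(T_true), target_mm >= 0)
  if (target_mm == 0) return(T_true)
  P <- apply_transform(T_true, surface_sample$points)
  ctr <- colMeans(P)
  prm <- with_seed(seed, {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    td <- rnorm(3); td <- td / sqrt(sum(td^2))
    list(ax = ax, td = td, mix = runif(1, 0.3, 0.7))
  })
  span <- max(sqrt(rowSums(sweep(P, 2, ctr)^2)))
  delta <- function(s) {
    ang <- s * prm$mix * target_mm / span        # radians; ~target at the rim
    tr <- s * (1 - prm$mix) * target_mm
    R <- rot_axis_angle(prm$ax, ang)
    rigid_transform(R, ctr - as.numeric(R %*% ctr) + tr * prm$td)
  }
  mean_disp <- function(s) {
    Q <- apply_transform(delta(s), P)
    mean(sqrt(rowSums((Q - P)^2)))
  }
  s_hi <- 1
  while (mean_disp(s_hi) < target_mm && s_hi < 1e4) s_hi <- s_hi * 2
  s <- stats::uniroot(function(s) mean_disp(s) - target_mm, c(0, s_hi),
                      tol = 1e-10)$root
  rt_compose(delta(s), T_true)
}

#' Run the in-silico 51-point phantom study
#'
#' For each registration-accuracy level a registration perturbed to that
#' accuracy is applied; each planned entry point is then mapped through it
#' and measured `repeats` times with seeded freehand probe jitter, and the
#' off-plan distance to the planned trajectory is recorded.
#'
#' @param mesh the phantom `triangle_mesh`.
#' @param fiducials a `fiducial_set` (see [place_fiducials()]).
#' @param accuracy_levels requested accuracies in mm (default 0.5..2.5).
#' @param repeats off-plan measurements per point and level (default 3).
#' @param jitter_sd_mm isotropic sd of the freehand probe placement (mm).
#' @param entry_jitter_sd_mm optional extra planning jitter (default 0 = off).
#' @param n_surface_samples surface points used to measure the achieved
#'   accuracy.
#' @param seed master seed.
#' @return A data frame of study records (one row per measurement).
#' @export
run_phantom_study <- function(mesh, fiducials,
                              accuracy_levels = seq(0.5, 2.5, by = 0.5),
                              repeats = 3, jitter_sd_mm = 0.5,
                              entry_jitter_sd_mm = 0,
                              n_surface_samples = 2000, seed = 1L) {
  stopifnot(is_triangle_mesh(mesh), inherits(fiducials, "fiducial_set"))
  trajs <- plan_trajectories(fiducials)
  surf <- sample_surface(mesh, n_surface_samples, seed = subseed(seed, 0))
  ctr <- colMeans(mesh$vertices)
  region <- assign_region(fiducials$surface_center, ctr)
  recs <- vector("list", length(accuracy_levels))
  for (li in seq_along(accuracy_levels)) {
    lvl <- accuracy_levels[li]
    T_p <- perturb_to_accuracy(rt_identity(), surf, lvl,
                               seed = subseed(seed, 100 + li))
    disp <- apply_transform(T_p, surf$points) - surf$points
    achieved <- mean(sqrt(rowSums(disp^2)))
    n <- length(trajs) * repeats
    jit <- with_seed(subseed(seed, 200 + li), {
      j <- matrix(rnorm(3 * n, 0, jitter_sd_mm), n, 3)
      if (entry_jitter_sd_mm > 0)
        j <- j + matrix(rnorm(3 * n, 0, entry_jitter_sd_mm), n, 3)
      j
    })
    rows <- vector("list", n)
    r <- 1L
    for (pi in seq_along(trajs)) {
      mapped <- apply_transform(T_p, trajs[[pi]]$entry)
      for (rep_i in seq_len(repeats)) {
        tip <- mapped + jit[r, ]
        rows[[r]] <- data.frame(
          point_id = pi, requested_accuracy_mm = lvl,
          achieved_accuracy_mm = achieved, repeat_index = rep_i,
          off_plan_mm = off_plan_distance(tip, trajs[[pi]]),
          entry_offset_mm = entry_point_offset(tip, trajs[[pi]]$entry),
          region = region[pi], reference_mode = "full_head",
          success = TRUE, stringsAsFactors = FALSE)
        r <- r + 1L
      }
    }
    recs[[li]] <- do.call(rbind, rows)
  }
  do.call(rbind, recs)
}

#' Run the patient-style entry-point-offset study
#'
#' Per subject: a fresh seeded phantom; one trajectory in the assigned head
#' region; a skin-shift deformation applied to the live surface; a frontal
#' depth render corrupted by sensor noise; the full registration cascade
#' run against a reference model built through the volumetric chain
#' (voxelize, threshold, median smooth, solidify, iso-surface, decimate,
#' crop), starting from a random unknown initial pose. A failed face-only
#' registration triggers exactly one full-head retry. The probe tip is the
#' point on the (deformed) skin nearest the overlaid entry point, plus
#' freehand jitter.
#'
#' @param n_subjects number of simulated subjects.
#' @param skin_shift_mm maximum skin-shift magnitude (mm).
#' @param regions head regions cycled across subjects.
#' @param seed master seed.
#' @param jitter_sd_mm freehand probe jitter sd (mm).
#' @param config optional registration parameter overrides.
#' @param noise depth-sensor [noise_model()] (seed is re-derived per subject).
#' @param mesh_resolution phantom resolution per subject.
#' @param voxel_mm voxel pitch of the subject's volumetric chain (mm).
#' @param reference_faces decimation target of the reference model.
#' @param use_volume_chain build the reference through the volumetric chain
#'   (`FALSE` crops the phantom mesh directly; faster, used for smoke tests).
#' @param max_init_angle_deg,max_init_trans_mm bounds of the random unknown
#'   initial pose of the reference model.
#' @return A data frame of study records (one row per subject).
#' @export
run_patient_style_study <- function(n_subjects, skin_shift_mm = 3,
                                    regions = c("frontal", "temporal", "posterior"),
                                    seed = 1L, jitter_sd_mm = 0.5,
                                    config = list(),
                                    noise = noise_model(),
                                    mesh_resolution = 2562L,
                                    voxel_mm = 1.0,
                                    reference_faces = 100000L,
                                    use_volume_chain = TRUE,
                                    max_init_angle_deg = 30,
                                    max_init_trans_mm = 100) {
  stopifnot(n_subjects >= 1)
  rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sseed <- subseed(seed, i)
    region <- regions[(i - 1L) %% length(regions) + 1L]
    spec <- phantom_spec(seed = sseed, mesh_resolution = mesh_resolution)
    mesh <- generate_head_phantom(spec)
    ctr <- colMeans(mesh$vertices)
    traj <- region_trajectory(mesh, region, spec, seed = subseed(sseed, 1))

    # live (deformed) surface and its depth scan
    field <- deformation_field(mesh_bounds(mesh), skin_shift_mm,
                               region_weighting = "posterior",
                               seed = subseed(sseed, 2))
    live <- apply_skin_shift(mesh, field)
    face_ctr <- ctr + c(0, 0.5 * (mesh_bounds(mesh)[2, 2] - ctr[2]), 0)
    cam <- camera_look_at(eye = ctr + c(0, 450, 40), target = face_ctr)
    nm <- noise_model(noise$axial_sd_mm, noise$dropout_rate,
                      noise$quantization_mm, seed = subseed(sseed, 3))
    scene <- corrupt(depth_to_pointcloud(render_depth(live, cam)), nm,
                     eye = cam$pose$t)

    # reference models through the preoperative chain, in an unknown pose
    if (use_volume_chain) {
      vol <- voxelize(mesh, voxel_mm = rep(voxel_mm, 3), noise_sd = 5,
                      seed = subseed(sseed, 4))
      mask <- median_smooth(threshold_segment(vol, 50), 3)
      surf <- decimate(extract_surface(mask), reference_faces)
    } else {
      surf <- mesh
    }
    lm <- estimate_landmarks(surf)
    face_ref <- crop_reference(surf, "face_only", lm)
    full_ref <- crop_reference(surf, "full_head", lm)
    T_init <- random_rigid_transform(max_init_angle_deg, max_init_trans_mm,
                                     seed = subseed(sseed, 5))
    cfg <- utils::modifyList(list(sampling_seed = subseed(sseed, 6)), config)
    reg <- register_with_fallback(apply_transform(T_init, face_ref),
                                  apply_transform(T_init, full_ref),
                                  scene, cfg)
    res <- reg$result
    # the tissue (and with it the true trajectory) has shifted between the
    # scan and positioning; the overlay presents the undeformed plan
    disp_e <- eval_deformation(field, matrix(traj$entry, 1))[1, ]
    disp_t <- eval_deformation(field, matrix(traj$target, 1))[1, ]
    traj_true <- trajectory(traj$entry + disp_e, traj$target + disp_t,
                            label = traj$label)
    T_total <- rt_compose(res$transform, T_init)  # model -> world estimate
    overlaid <- apply_transform(T_total, traj$entry)
    # the probe is placed on the actual (deformed) skin at the overlay
    skin_tip <- closest_point_on_mesh(overlaid, live)$point
    tip <- skin_tip + with_seed(subseed(sseed, 7), rnorm(3, 0, jitter_sd_mm))
    rows[[i]] <- data.frame(
      point_id = i, requested_accuracy_mm = NA_real_,
      achieved_accuracy_mm = NA_real_, repeat_index = 1L,
      off_plan_mm = if (res$success) off_plan_distance(tip, traj_true) else NA_real_,
      entry_offset_mm = if (res$success)
        entry_point_offset(overlaid, traj_true$entry) else NA_real_,
      region = region, reference_mode = reg$reference_mode,
      success = res$success, attempts = reg$attempts,
      inlier_rmse_mm = res$inlier_rmse_mm,
      overlap_fraction = res$overlap_fraction, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# One planned trajectory with its entry in the requested head region:
# seeded choice among surface vertices in the region band (upper head,
# inward-pointing normal with enough depth clearance).
region_trajectory <- function(mesh, region, spec, seed = 1L) {
  nrm <- vertex_normals(mesh)
  ctr <- colMeans(mesh$vertices)
  outward <- rowSums(nrm * sweep(mesh$vertices, 2, ctr)) > 0
  if (mean(outward) < 0.5) nrm <- -nrm
  z <- mesh$vertices[, 3]
  cand <- which(assign_region(mesh$vertices, ctr) == region &
                  z > min(z) + 0.3 * (max(z) - min(z)))
  tips <- mesh$vertices[cand, , drop = FALSE] -
    spec$fiducial_depth_mm * nrm[cand, , drop = FALSE]
  ok <- points_in_mesh(tips, mesh)
  ok[ok] <- closest_points_on_mesh(tips[ok, , drop = FALSE],
                                   mesh)$distance >= 0.8 * spec$fiducial_depth_mm
  cand <- cand[ok]
  if (length(cand) == 0) stop("no admissible trajectory site in region ", region)
  pick <- with_seed(seed, sample(length(cand), 1))
  i <- cand[pick]
  entry <- mesh$vertices[i, ]
  trajectory(entry, entry - spec$fiducial_depth_mm * nrm[i, ],
             label = paste0("subject_", region))
}

#' Summarize study records
#'
#' Per-accuracy-level mean and sample SD of the off-plan distance, Spearman
#' rank correlation between requested accuracy and off-plan distance
#' (average-rank ties, large-sample p approximation), per-region means, and
#' the failure count.
#'
#' @param records data frame from [run_phantom_study()] or
#'   [run_patient_style_study()].
#' @return A `study_summary` list.
#' @export
summarize_study <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  ok <- records[records$success & !is.na(records$off_plan_mm), , drop = FALSE]
  per_level <- NULL
  spearman <- list(rho = NA_real_, p_value = NA_real_)
  if (nrow(ok) > 0 && any(!is.na(ok$requested_accuracy_mm))) {
    lv <- ok[!is.na(ok$requested_accuracy_mm), ]
    agg_m <- tapply(lv$off_plan_mm, lv$requested_accuracy_mm, mean)
    agg_s <- tapply(lv$off_plan_mm, lv$requested_accuracy_mm, sd)
    per_level <- data.frame(requested_accuracy_mm = as.numeric(names(agg_m)),
                            mean_off_plan_mm = as.numeric(agg_m),
                            sd_off_plan_mm = as.numeric(agg_s))
    if (length(unique(lv$requested_accuracy_mm)) > 1) {
      ct <- suppressWarnings(cor.test(lv$requested_accuracy_mm, lv$off_plan_mm,
                                      method = "spearman", exact = FALSE))
      spearman <- list(rho = unname(ct$estimate), p_value = ct$p.value)
    }
  }
  per_region <- if (nrow(ok) > 0)
    data.frame(region = names(tapply(ok$off_plan_mm, ok$region, mean)),
               mean_off_plan_mm = as.numeric(tapply(ok$off_plan_mm, ok$region, mean)),
               n = as.integer(table(ok$region)[names(tapply(ok$off_plan_mm, ok$region, mean))]))
    else NULL
  structure(list(
    n_records = nrow(records),
    n_failures = sum(!records$success),
    mean_off_plan_mm = if (nrow(ok)) mean(ok$off_plan_mm) else NaN,
    sd_off_plan_mm = if (nrow(ok) > 1) sd(ok$off_plan_mm) else NaN,
    mean_entry_offset_mm = if (nrow(ok) && "entry_offset_mm" %in% names(ok))
      mean(ok$entry_offset_mm) else NaN,
    per_level = per_level, spearman = spearman, per_region = per_region),
    class = "study_summary")
}

#' Write a study report (JSON summary + CSV records)
#'
#' @param records study records data frame.
#' @param summary a `study_summary` (recomputed when `NULL`).
#' @param path_json,path_csv output paths (`NULL` = skip).
#' @param seed,config provenance embedded into the JSON report.
#' @return The summary, invisibly.
#' @export
write_study_report <- function(records, summary = NULL, path_json = NULL,
                               path_csv = NULL, seed = NULL, config = NULL) {
  if (is.null(summary)) summary <- summarize_study(records)
  if (!is.null(path_csv)) utils::write.csv(records, path_csv, row.names = FALSE)
  if (!is.null(path_json)) {
    payload <- unclass(summary)
    payload$seed <- seed
    if (!is.null(config)) payload$config_hash <- config_hash(config)
    jsonlite::write_json(payload, path_json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(summary)
}

#' @export
print.study_summary <- function(x, ...) {
  cat("<study_summary>", x$n_records, "records,", x$n_failures, "failures\n")
  cat(sprintf("  off-plan: %.2f +/- %.2f mm\n", x$mean_off_plan_mm, x$sd_off_plan_mm))
  if (!is.null(x$per_level)) {
    cat("  per accuracy level:\n")
    for (i in seq_len(nrow(x$per_level)))
      cat(sprintf("    %.1f mm -> %.2f +/- %.2f mm\n",
                  x$per_level$requested_accuracy_mm[i],
                  x$per_level$mean_off_plan_mm[i], x$per_level$sd_off_plan_mm[i]))
    cat(sprintf("  Spearman rho %.3f (p %.3g)\n", x$spearman$rho, x$spearman$p_value))
  }
  invisible(x)
}
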