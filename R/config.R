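#' Default run configuration
#'
#' A single nested document of every tunable parameter, grouped by stage.
#' [validate_config()] rejects unknown keys and merges user overrides onto
#' these defaults; [config_hash()] fingerprints the fully resolved
#' configuration for provenance.
#'
#' @return Named nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    phantom = list(seed = 1L, head_dims_mm = c(160, 195, 225),
                   feature_amplitude_mm = 12, n_fiducials = 51L,
                   fiducial_depth_mm = 20, cone_margin_mm = 0.2,
                   mesh_resolution = 10242L, min_spacing_mm = 15),
    volume = list(voxel_mm = c(0.5, 0.5, 0.5), inside_value = 100,
                  outside_value = 0, noise_sd = 5, threshold = 50,
                  smooth_window_mm = 3),
    extraction = list(target_faces = 100000L, eye_radius_mm = 15),
    camera = list(width = 320L, height = 288L, fov_deg = 75,
                  max_range_mm = 1500),
    noise = list(axial_sd_mm = 1.0, dropout_rate = 0.05,
                 quantization_mm = 0.25),
    registration = list(model_samples = 20000L, sampling_seed = 1L,
                        voxel_mm = 4, normal_k = 30L, fpfh_radius_mm = 15,
                        max_correspondences = 500L, noise_bound_mm = 6,
                        max_hypotheses = 4L, saliency_frac = 0.4,
                        icp_method = "point_to_plane", icp_d_max_mm = 10,
                        icp_tol = 1e-6, icp_max_iter = 50L,
                        rmse_max_mm = 3, overlap_min = 0.3, overlap_d_mm = 5),
    evaluation = list(accuracy_levels = seq(0.5, 2.5, by = 0.5),
                      repeats = 3L, jitter_sd_mm = 0.5,
                      entry_jitter_sd_mm = 0, skin_shift_mm = 3)
  )
}

#' @rdname default_config
#' @param config partial configuration (nested named list).
#' @return `validate_config`: the fully resolved configuration.
#' @export
validate_config <- function(config = list()) {
  defaults <- default_config()
  check <- function(user, ref, path) {
    if (!is.list(user)) return(invisible())
    unknown <- setdiff(names(user), names(ref))
    if (length(unknown))
      stop("unknown config key(s): ",
           paste0(path, unknown, collapse = ", "), call. = FALSE)
    for (nm in names(user))
      if (is.list(ref[[nm]])) check(user[[nm]], ref[[nm]], paste0(path, nm, "."))
  }
  check(config, defaults, "")
  utils::modifyList(defaults, config)
}

#' @rdname default_config
#' @return `config_hash`: md5 fingerprint of the resolved configuration.
#' @export
config_hash <- function(config = list()) {
  cfg <- validate_config(config)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Read a configuration file (JSON or YAML)
#'
#' @param path file path; keys are validated against [default_config()].
#' @return The resolved configuration list.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_config(cfg)
}
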