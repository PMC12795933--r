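# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# r = 10 mm sphere meshes at two resolutions
fx_sphere <- function(subdiv = 4, r = 10) {
  fx_get(paste0("sphere", subdiv, "_", r), function() {
    s <- surgnav:::icosphere(subdiv)
    triangle_mesh(s$vertices * r, s$faces)
  })
}

# small phantom (unit-test scale) and its derivatives
fx_phantom_small <- function() fx_get("ph_small", function()
  generate_head_phantom(fx_spec_small()))
fx_spec_small <- function() phantom_spec(seed = 3, mesh_resolution = 2562L)

# full-resolution study phantom and derivatives
fx_phantom <- function() fx_get("ph_full", function()
  generate_head_phantom(fx_spec()))
fx_spec <- function() phantom_spec(seed = 3)
fx_fiducials <- function() fx_get("fid_full", function()
  place_fiducials(fx_phantom(), fx_spec()))
fx_face <- function() fx_get("face_full", function()
  crop_reference(fx_phantom(), "face_only"))
fx_full_head <- function() fx_get("fullhead_full", function()
  crop_reference(fx_phantom(), "full_head"))

# frontal study camera for a given mesh
fx_frontal_camera <- function(mesh = fx_phantom()) {
  ctr <- colMeans(mesh$vertices)
  b <- mesh_bounds(mesh)
  camera_look_at(eye = ctr + c(0, 450, 40),
                 target = ctr + c(0, 0.5 * (b[2, 2] - ctr[2]), 0))
}

# frontal depth scene of the full phantom under the default noise model
fx_scene <- function(noise_seed) {
  img <- fx_get("frontal_render", function()
    render_depth(fx_phantom(), fx_frontal_camera()))
  cam <- fx_frontal_camera()
  corrupt(depth_to_pointcloud(img), noise_model(seed = noise_seed),
          eye = cam$pose$t)
}
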