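# Lazily generated, cached phantoms and derived objects shared across test
# files. Everything is deterministic (fixed seeds inside the specs).

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, fun) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- fun()
  .fixtures[[key]]
}

# default study conditions: 0.5 mm voxels, 26.6 ml cavity, 3.4 ml
# enlargement, 1.5 mm residual, CT/CBCT noise
phantom_default <- function() cached("default", function()
  generate_phantom(phantom_spec(seed = 7L)))

# same conditions without imaging noise (exact-recovery oracles)
phantom_noiseless <- function() cached("noiseless", function()
  generate_phantom(phantom_spec(noise_sigma = c(CT = 0, CBCT = 0), seed = 7L)))

# intact symmetric phantom (no fracture, no reconstruction residual)
phantom_intact <- function() cached("intact", function()
  generate_phantom(phantom_spec(fracture = NULL, reconstruction = NULL,
                                noise_sigma = c(CT = 0, CBCT = 0), seed = 7L)))

# 1 mm voxels for fast pipeline-level tests
phantom_coarse <- function() cached("coarse", function()
  generate_phantom(phantom_spec(spacing_mm = 1.0, seed = 7L)))

# mirrored unaffected-side template of the noiseless phantom (truth masks)
template_noiseless <- function() cached("template_noiseless", function() {
  ph <- phantom_noiseless()
  m <- extract_surface(ph$truth$cavity_masks$unaffected, ph$truth$spacing,
                       ph$truth$origin)
  reflect_mesh(m, ph$truth$mirror_plane)
})

# reconstructed-side surface of the noiseless phantom (truth masks)
target_noiseless <- function() cached("target_noiseless", function() {
  ph <- phantom_noiseless()
  extract_surface(ph$truth$cavity_masks$reconstructed, ph$truth$spacing,
                  ph$truth$origin)
})

# one full pipeline run on the coarse phantom, reused by pipeline tests
coarse_case <- function() cached("coarse_case", function() {
  ph <- phantom_coarse()
  root <- file.path(tempdir(), "orbitqc-coarse-case")
  unlink(root, recursive = TRUE)
  write_phantom(ph, file.path(root, "input"))
  cfg <- coarse_config(root)
  res <- run_case(cfg)
  list(phantom = ph, config = cfg, result = res, root = root)
})

coarse_config <- function(root, out = "out") {
  pipeline_config(
    preop_volume = file.path(root, "input", "preop.nii.gz"),
    postop_volume = file.path(root, "input", "postop.nii.gz"),
    landmarks = file.path(root, "input", "landmarks.json"),
    out_dir = file.path(root, out),
    affected_side = "right", affected_wall = "floor",
    segmentation_pre = segmentation_params(300, closing_radius_mm = 2.0),
    segmentation_post = segmentation_params(240, closing_radius_mm = 2.0),
    case_id = "coarse")
}
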