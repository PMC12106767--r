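# Shared fixtures, memoised so expensive phantoms and segmentations are
# computed once per test run.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(key, fun) {
  if (!exists(key, envir = .fx_cache)) assign(key, fun(), envir = .fx_cache)
  get(key, envir = .fx_cache)
}

# straight tube mask along an arbitrary segment, voxel units
tube_mask <- function(dims, p0_um, p1_um, r_um, h = 1) {
  mk <- array(FALSE, dims)
  mk[hepavasc:::rasterize_segment(p0_um, p1_um, r_um, dims, h)] <- TRUE
  mk
}

# small control-like phantom for unit tests (full presets live in the
# acceptance suite)
small_control <- function() fx("small_control", function() {
  generate_phantom("control", seed = 11, shape = c(128L, 128L, 128L))
})

small_control_metrics <- function() fx("small_control_metrics", function() {
  ph <- small_control()
  run_specimen(phantom_config(ph), volume = ph$volume)
})

small_metastatic <- function() fx("small_metastatic", function() {
  generate_phantom("metastatic", seed = 11, shape = c(192L, 192L, 96L))
})

small_metastatic_metrics <- function() fx("small_metastatic_metrics", function() {
  ph <- small_metastatic()
  run_specimen(phantom_config(ph), volume = ph$volume)
})

# low-resolution phantoms for the RMS/classification stage
lowres_phantom <- function(name, seed = 1) {
  fx(paste0("lowres_", name, "_", seed), function() {
    generate_phantom(name, seed = seed, shape = c(192L, 192L, 40L),
                     voxel_size = 3.1)
  })
}
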