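test_that("presets carry the reference condition values and reject unknowns", {
  expect_equal(liver_preset("control")$spec$target_vvf, 0.0165)
  expect_equal(liver_preset("metastatic")$spec$target_vvf, 0.0045)
  expect_error(liver_preset("liver"), "valid presets")
  # low-resolution (RMS-modality) phantoms carry the reported class
  # amplitudes; high-resolution ones the quiet control-level texture
  expect_equal(liver_preset("metastatic", voxel_size = 3.1)$spec$texture_rms, 0.010)
  expect_equal(liver_preset("metastatic")$spec$texture_rms, 0.004)
  expect_equal(liver_preset("control")$spec$texture_rms, 0.004)
})

test_that("phantom_spec enforces its invariants", {
  expect_error(phantom_spec(target_vvf = 0.6), "0.5")
  expect_error(phantom_spec(sinusoid_diameter_mean = -1), "> 0")
  expect_error(phantom_spec(min_centerline_spacing = 1), "at least the sinusoid")
  expect_error(nodule_spec(c(1, 1, 1), c(10, -1, 10)), "positive")
  expect_error(nodule_spec(c(1, 1, 1), c(10, 10, 10), rim_peak_vvf = 0.001,
                           farfield_vvf = 0.005), "at least")
})

test_that("identical spec and seed reproduce the phantom bit-exactly", {
  spec <- phantom_spec(volume_shape = c(48, 48, 48), voxel_size = 1,
                       target_vvf = 0.012, min_centerline_spacing = 10,
                       central_vein_diameter = 0, seed = 5)
  p1 <- rasterize_and_texture(generate_vessel_tree(spec), spec)
  p2 <- rasterize_and_texture(generate_vessel_tree(spec), spec)
  expect_identical(p1$volume$data, p2$volume$data)
  expect_identical(p1$vessel_mask_truth$data, p2$vessel_mask_truth$data)
})

test_that("zero-vessel limit gives an empty truth mask", {
  spec <- phantom_spec(volume_shape = c(32, 32, 32), voxel_size = 1,
                       target_vvf = 0, central_vein_diameter = 0,
                       texture_rms = 0, seed = 1)
  ph <- rasterize_and_texture(generate_vessel_tree(spec), spec)
  expect_equal(sum(ph$vessel_mask_truth$data), 0)
  expect_true(all(ph$volume$data == spec$background_grey)) # constant volume
})

test_that("a forced straight tube rasterizes to the analytic cylinder volume", {
  h <- 0.7
  dims <- c(48L, 48L, 160L)
  r <- 1.5
  len <- 100
  curve <- list(points = rbind(c(16.8, 16.8, 5), c(16.8, 16.8, 5 + len)),
                radius = r, kind = "sinusoid")
  vox <- hepavasc:::rasterize_curve(curve, dims, h)
  analytic <- pi * r^2 * len / h^3
  expect_lt(abs(length(vox) - analytic) / analytic, 0.15) # discretization
})

test_that("a spherical nodule rasterizes to the analytic sphere volume", {
  h <- 1.4
  dims <- c(96L, 96L, 96L)
  spec <- phantom_spec(volume_shape = dims, voxel_size = h, target_vvf = 0,
                       central_vein_diameter = 0, texture_rms = 0, seed = 1)
  nod <- nodule_spec(center = c(48.5, 48.5, 48.5), semi_axes = c(50, 50, 50))
  ph <- rasterize_and_texture(generate_vessel_tree(spec, list(nod)), spec,
                              list(nod))
  analytic <- 4 / 3 * pi * 50^3 / h^3
  expect_lt(abs(sum(ph$nodule_mask_truth$data) - analytic) / analytic, 0.02)
})

test_that("band-limited texture recovers the requested window RMS", {
  spec <- phantom_spec(volume_shape = c(96L, 96L, 32L), voxel_size = 3.1,
                       target_vvf = 0, central_vein_diameter = 0,
                       texture_rms = 0.006, seed = 3)
  ph <- rasterize_and_texture(generate_vessel_tree(spec), spec)
  rm <- rms_map(ph$volume, window_side = 30)
  expect_lt(abs(mean(rms_values(rm)) - 0.006) / 0.006, 0.05)
})

test_that("truth VVF calibration and mask disjointness hold on generation", {
  ph <- small_control()
  expect_lt(abs(100 * phantom_truth_vvf(ph) - 1.65), 0.1) # percentage points
  expect_equal(sum(ph$vessel_mask_truth$data & ph$nodule_mask_truth$data), 0)
  expect_identical(dim(ph$vessel_mask_truth$data), dim(ph$volume$data))
  # small/large truth partition the full truth mask
  expect_identical(ph$vessel_mask_truth$data,
                   ph$small_vessel_mask_truth$data | ph$large_vessel_mask_truth$data)
})

test_that("raising target_vvf never decreases the truth voxel count", {
  counts <- vapply(c(0.004, 0.008, 0.012), function(v) {
    spec <- phantom_spec(volume_shape = c(64, 64, 64), voxel_size = 1,
                         target_vvf = v, central_vein_diameter = 0,
                         min_centerline_spacing = 12, texture_rms = 0,
                         seed = 7)
    length(attr(generate_vessel_tree(spec), "truth_voxels"))
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("an unreachable density/spacing pair fails naming both parameters", {
  spec <- phantom_spec(volume_shape = c(32, 32, 32), voxel_size = 1,
                       target_vvf = 0.3, min_centerline_spacing = 25,
                       central_vein_diameter = 0, texture_rms = 0, seed = 1)
  expect_error(generate_vessel_tree(spec),
               "target_vvf.*min_centerline_spacing")
})

test_that("phantoms round-trip to disk as TIFF stacks with metadata", {
  ph <- fx("tiny_phantom", function()
    generate_phantom(phantom_spec(volume_shape = c(32, 32, 16), voxel_size = 1,
                                  target_vvf = 0.01, central_vein_diameter = 0,
                                  min_centerline_spacing = 8, seed = 2)))
  dir <- file.path(tempdir(), "ph_out")
  write_phantom(ph, dir)
  v <- read_volume(file.path(dir, "volume.tif"))
  expect_equal(v$voxel_size, 1)
  expect_equal(dim(v$data), dim(ph$volume$data))
  meta <- hepavasc:::read_metadata(file.path(dir, "phantom_meta.txt"))
  expect_equal(as.numeric(meta$target_vvf), 0.01)
})
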