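#' Configuration of a full specimen run
#'
#' Collects every stage parameter with its reference default: Frangi scales
#' 1-10, alpha = beta = 0.5, c = 0.013, vesselness threshold 0.16; 15 um
#' small/large diameter split with a separate 10 um exclusion for VVF
#' reporting; 30-pixel RMS window with mean +/- 1.5 SD classification bands;
#' five ROIs of 5e-3 mm^3; 50-voxel VVF cube; 10 um radial shells.
#'
#' @param input path to the input volume (TIFF stack or NIfTI), or `NULL`
#'   when a volume object is passed to [run_specimen()] directly.
#' @param voxel_size voxel size in um (required for TIFF input).
#' @param output_dir where stage outputs and the manifest are written;
#'   `NULL` disables writing.
#' @param frangi a [frangi_params()].
#' @param large_vessel_threshold grey threshold for large vessels (`NULL`
#'   for Otsu).
#' @param diameter_split_um small/large vessel split diameter (um).
#' @param vvf_exclusion_um diameter above which vessels are excluded from
#'   VVF reporting (um).
#' @param roi_volume_mm3,n_rois ROI sampling for the VVF summary.
#' @param cube_side sliding-cube side in voxels for the VVF map.
#' @param shell_width_um,n_shells radial VVF shells.
#' @param rms_window RMS window side in pixels.
#' @param rms_stride `"tile"` or `"slide"`.
#' @param band_k classification band half-width in SD units.
#' @param large_vessel_margin_um margin (um) around the large-vessel mask
#'   removed from the sinusoid masks (the vesselness filter rings the rim of
#'   thick vessels).
#' @param prune_spurs_um terminal skeleton branches shorter than this (um)
#'   are pruned as voxelization spurs; see [skeletonize()].
#' @param min_component_voxels connected components of the merged mask
#'   smaller than this are removed as segmentation noise (sub-resolution
#'   despeckle).
#' @param length_bin_um,diameter_bin_um histogram bin widths.
#' @param seed integer seed driving every random choice (ROI sampling).
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(input = NULL, voxel_size = NULL, output_dir = NULL,
                       frangi = frangi_params(),
                       large_vessel_threshold = NULL,
                       diameter_split_um = 15, vvf_exclusion_um = 10,
                       large_vessel_margin_um = 4, prune_spurs_um = 3,
                       min_component_voxels = 27L,
                       roi_volume_mm3 = 5e-3, n_rois = 5L, cube_side = 50L,
                       shell_width_um = 10, n_shells = 15L, rms_window = 30L,
                       rms_stride = "tile", band_k = 1.5, length_bin_um = 1,
                       diameter_bin_um = 0.5, seed = 1L) {
  structure(list(input = input, voxel_size = voxel_size,
                 output_dir = output_dir, frangi = frangi,
                 large_vessel_threshold = large_vessel_threshold,
                 diameter_split_um = diameter_split_um,
                 vvf_exclusion_um = vvf_exclusion_um,
                 large_vessel_margin_um = large_vessel_margin_um,
                 prune_spurs_um = prune_spurs_um,
                 min_component_voxels = as.integer(min_component_voxels),
                 roi_volume_mm3 = roi_volume_mm3, n_rois = as.integer(n_rois),
                 cube_side = as.integer(cube_side),
                 shell_width_um = shell_width_um,
                 n_shells = as.integer(n_shells),
                 rms_window = as.integer(rms_window), rms_stride = rms_stride,
                 band_k = band_k, length_bin_um = length_bin_um,
                 diameter_bin_um = diameter_bin_um, seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration as a flat key-value text file
#'
#' The round trip is lossless: `read_config(write_config(cfg, f))` rebuilds
#' an identical configuration.
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  flat <- unclass(config)
  flat$frangi <- NULL
  flat <- c(flat, setNames(unclass(config$frangi),
                           paste0("frangi_", names(config$frangi))))
  yaml::write_yaml(flat, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  flat <- yaml::yaml.load_file(path)
  fr_keys <- grep("^frangi_", names(flat), value = TRUE)
  fr <- setNames(flat[fr_keys], sub("^frangi_", "", fr_keys))
  flat[fr_keys] <- NULL
  flat$frangi <- do.call(frangi_params, fr)
  null_keys <- setdiff(names(formals(run_config)), names(flat))
  cfg <- do.call(run_config, flat)
  for (k in null_keys) cfg[k] <- list(NULL)
  cfg
}

#' Run the full quantification pipeline on one specimen
#'
#' Segments small (vesselness) and large (intensity) vessels, merges them,
#' splits by diameter, skeletonizes the sinusoid network, and computes the
#' metric bundle: per-ROI VVF (with the configured diameter exclusion), the
#' sliding-cube VVF map, branch lengths and diameters, nearest-neighbour
#' distances, the RMS map, and (when a nodule mask is given) the radial VVF
#' profile. When `output_dir` is set, metric tables are written as CSV with
#' a manifest recording the configuration hash and seed, so a rerun with the
#' same config and input is reproducible.
#'
#' @param config a [run_config()].
#' @param volume optional [volume3d()] (otherwise read from `config$input`).
#' @param nodule_mask optional logical array of nodule voxels; these are
#'   removed from the vessel mask (metastatic nodules are excluded from the
#'   analyses) and drive the radial profile.
#' @param rms_exclusion optional extra exclusion mask for the RMS map
#'   (defaults to the segmented vessels plus the nodule mask).
#' @param class_stats optional [class_stats()] table; when given, the RMS
#'   map is classified and class fractions are reported.
#' @return A list (class `specimen_metrics`) with elements `vvf_rois`,
#'   `vvf_mean`, `vvf_map_summary`, `branch_lengths`, `diameters`, `nnd`,
#'   `rms`, `class_fractions`, `radial`, `masks`, `skeleton`, `config`.
#' @export
run_specimen <- function(config, volume = NULL, nodule_mask = NULL,
                         rms_exclusion = NULL, class_stats = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(volume)) {
    if (is.null(config$input)) stop("no input volume (config$input is NULL)")
    volume <- read_volume(config$input, config$voxel_size)
  }
  set.seed(config$seed)
  h <- volume$voxel_size

  vness <- frangi_vesselness(volume, config$frangi)
  small <- segment_small_vessels(volume, config$frangi, vesselness = vness)
  rm(vness) # large volumes: free the response field before the next stage
  large <- segment_large_vessels(volume, config$large_vessel_threshold,
                                 min_diameter = config$diameter_split_um,
                                 dark_vessels = config$frangi$dark_vessels)
  merged <- merge_masks(small, large)
  rm(small, large)
  gc(FALSE)
  if (!is.null(nodule_mask))
    merged <- vessel_mask(merged$data & !nodule_mask, h, "merged")
  if (config$min_component_voxels > 1L && any(merged$data)) {
    # despeckle: connected components smaller than a minimal sinusoid
    # fragment are segmentation noise
    sz <- component_sizes_cpp(as.integer(merged$data), dim(merged$data))
    merged <- vessel_mask(merged$data & sz >= config$min_component_voxels,
                          h, "merged")
  }

  parts <- split_by_diameter(merged, config$diameter_split_um)
  sinusoids <- parts$small
  vvf_mask <- split_by_diameter(merged, config$vvf_exclusion_um)$small
  # vesselness rings the rim of thick vessels; drop a small margin around
  # the large-vessel mask from the sinusoid masks
  if (config$large_vessel_margin_um > 0 && any(parts$large$data)) {
    near_large <- edt_voxels(!parts$large$data) * h <=
      config$large_vessel_margin_um
    sinusoids <- vessel_mask(sinusoids$data & !near_large, h, "small")
    vvf_mask <- vessel_mask(vvf_mask$data & !near_large, h, "small")
    rm(near_large)
  }
  rm(parts)
  gc(FALSE)

  rois <- sample_rois(dim(volume$data), h, config$roi_volume_mm3,
                      config$n_rois)
  vvf_rois <- vapply(rois, function(r)
    vvf(vvf_mask, roi_region(r, dim(volume$data))), numeric(1))

  vmap <- vvf_map(vvf_mask, config$cube_side)

  graph <- skeletonize(sinusoids, prune_um = config$prune_spurs_um)
  lengths <- if (length(graph$branches) > 0)
    branch_lengths(graph, config$length_bin_um) else NULL
  diams <- diameter_distribution(graph, config$diameter_bin_um)
  nnd <- if (length(graph$branches) >= 2)
    nearest_neighbour_distances(graph) else NULL

  excl <- if (is.null(rms_exclusion)) {
    e <- merged$data
    if (!is.null(nodule_mask)) e <- e | nodule_mask
    e
  } else rms_exclusion
  rms <- rms_map(volume, exclusion = excl, window_side = config$rms_window,
                 stride = config$rms_stride)
  fractions <- if (!is.null(class_stats))
    class_fractions(classify_tissue(rms, class_stats)) else NULL

  radial <- if (!is.null(nodule_mask))
    radial_vvf(vvf_mask, nodule_mask, config$shell_width_um,
               config$n_shells) else NULL

  metrics <- structure(list(
    vvf_rois = vvf_rois, vvf_mean = mean(vvf_rois),
    vvf_map_summary = c(min = vmap$min, mean = vmap$mean, max = vmap$max),
    vvf_map = vmap,
    branch_lengths = lengths, diameters = diams, nnd = nnd, rms = rms,
    class_fractions = fractions, radial = radial,
    masks = list(merged = merged, sinusoids = sinusoids, vvf = vvf_mask),
    skeleton = graph, config = config), class = "specimen_metrics")
  if (!is.null(config$output_dir)) write_metrics(metrics, config$output_dir)
  metrics
}

#' @export
print.specimen_metrics <- function(x, ...) {
  cat(sprintf("<specimen_metrics> mean ROI VVF %.3g%%; %d branches\n",
              100 * x$vvf_mean, length(x$skeleton$branches)))
  if (!is.null(x$nnd))
    cat(sprintf("  NND weighted mean %.3g um; length mode %.3g um; diameter mode %.3g um\n",
                x$nnd$weighted_mean, x$branch_lengths$mode_um, x$diameters$mode_um))
  invisible(x)
}

write_metrics <- function(metrics, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- metrics$config
  write.csv(data.frame(roi = seq_along(metrics$vvf_rois),
                       vvf_fraction = metrics$vvf_rois),
            file.path(dir, "vvf_rois.csv"), row.names = FALSE)
  if (!is.null(metrics$branch_lengths))
    write.csv(data.frame(length_um = metrics$branch_lengths$lengths,
                         diameter_um = metrics$diameters$diameters,
                         nnd_um = if (is.null(metrics$nnd)) NA
                                  else metrics$nnd$nnd),
              file.path(dir, "branches.csv"), row.names = FALSE)
  if (!is.null(metrics$radial))
    write.csv(metrics$radial, file.path(dir, "radial_vvf.csv"),
              row.names = FALSE)
  cfg_file <- file.path(dir, "config.yaml")
  write_config(cfg, cfg_file)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = cfg$seed,
    vvf_mean = metrics$vvf_mean,
    n_branches = length(metrics$skeleton$branches))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Parameter-recovery validation on phantom presets
#'
#' For each seed, generates the preset phantom, runs the full segmentation
#' and quantification, and tabulates recovered statistics against the
#' generator truth.
#'
#' @param seeds integer vector of at least 3 seeds.
#' @param preset preset name (see [liver_preset()]).
#' @param shape,voxel_size optional phantom size overrides (smaller phantoms
#'   for quick checks).
#' @param config optional [run_config()] template.
#' @return A data.frame with one row per seed: truth and recovered VVF,
#'   NND weighted mean, branch-length mode, diameter mode, RMS mean.
#' @export
run_validation <- function(seeds, preset = "control", shape = NULL,
                           voxel_size = NULL, config = NULL) {
  if (length(seeds) < 3L) stop("need at least 3 seeds for a recovery report")
  rows <- lapply(seeds, function(s) {
    ph <- generate_phantom(preset, seed = s, shape = shape,
                           voxel_size = voxel_size)
    cfg <- if (is.null(config)) phantom_config(ph, seed = s) else config
    met <- run_specimen(cfg, volume = ph$volume,
                        nodule_mask = if (any(ph$nodule_mask_truth$data))
                          ph$nodule_mask_truth$data else NULL)
    data.frame(preset = preset, seed = s,
               truth_vvf = phantom_truth_vvf(ph),
               vvf = met$vvf_mean,
               truth_texture_rms = ph$spec$texture_rms,
               rms_mean = mean(met$rms$values, na.rm = TRUE),
               nnd_um = if (is.null(met$nnd)) NA else met$nnd$weighted_mean,
               length_mode_um = if (is.null(met$branch_lengths)) NA
                                else met$branch_lengths$mode_um,
               diameter_mode_um = met$diameters$mode_um)
  })
  do.call(rbind, rows)
}

#' Default run configuration for a phantom
#'
#' Uses the phantom's grey levels for the large-vessel threshold (midpoint
#' between vessel and background grey), instead of Otsu, which is unreliable
#' when a bright nodule dominates the histogram.
#'
#' @param phantom a `liver_phantom`.
#' @param seed seed for ROI sampling.
#' @return A [run_config()].
#' @export
phantom_config <- function(phantom, seed = phantom$spec$seed) {
  spec <- phantom$spec
  d <- dim(phantom$volume$data)
  h <- spec$voxel_size
  rw <- min(30L, d[1] %/% 2L, d[2] %/% 2L)
  # shrink the ROI and cube to the volume when the phantom is small
  roi_v <- min(5e-3, (0.9 * min(d) * h * 1e-3)^3)
  run_config(voxel_size = h,
             large_vessel_threshold =
               (spec$vessel_grey + spec$background_grey) / 2,
             roi_volume_mm3 = roi_v,
             cube_side = min(50L, min(d) %/% 2L),
             rms_window = rw, seed = seed)
}
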