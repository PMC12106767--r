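#' Parameters of the multiscale Hessian (Frangi) vesselness filter
#'
#' Defaults follow the reference tomography pipeline for hepatic sinusoids:
#' integer scales 1 to 10 voxels, `alpha = beta = 0.5`, `c = 0.013`, and a
#' vesselness ("probability") threshold of 0.16. `c` is calibrated for
#' volumes with grey values normalized to \[0, 1\].
#'
#' @param scales strictly increasing positive scales, in voxels, of the
#'   Gaussian scale space at which the Hessian is evaluated.
#' @param alpha sensitivity of the plate-vs-line ratio term.
#' @param beta sensitivity of the blob deviation term.
#' @param c sensitivity of the structureness (second-order energy) term.
#' @param probability_threshold vesselness cut used by
#'   [segment_small_vessels()]; strict inequality, in (0, 1).
#' @param dark_vessels logical; `TRUE` when vessels are darker than the
#'   parenchyma (the phase-contrast case), `FALSE` for bright vessels.
#' @return An object of class `frangi_params`.
#' @export
frangi_params <- function(scales = 1:10, alpha = 0.5, beta = 0.5, c = 0.013,
                          probability_threshold = 0.16, dark_vessels = TRUE) {
  scales <- as.numeric(scales)
  if (length(scales) < 1L || any(scales <= 0) || is.unsorted(scales, strictly = TRUE))
    stop("`scales` must be strictly increasing and positive")
  for (nm in c("alpha", "beta", "c")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stop("`", nm, "` must be a single positive number")
  }
  if (probability_threshold <= 0 || probability_threshold >= 1)
    stop("`probability_threshold` must lie in (0, 1)")
  structure(list(scales = scales, alpha = alpha, beta = beta, c = c,
                 probability_threshold = probability_threshold,
                 dark_vessels = isTRUE(dark_vessels)),
            class = "frangi_params")
}

#' Multiscale Frangi vesselness of a volume
#'
#' Computes, at every voxel, the maximum over scales of the Frangi vesselness
#' built from the eigenvalues of the gamma-normalized Gaussian-scale-space
#' Hessian. Values lie in \[0, 1\]; a constant volume maps to 0 everywhere,
#' and the response is invariant under adding a constant to the volume.
#' Boundaries are handled by mirror reflection.
#'
#' @param vol a [volume3d()] (isotropic; anisotropic input is rejected at
#'   construction).
#' @param params a [frangi_params()].
#' @return A [volume3d()] whose `data` is the vesselness field in \[0, 1\].
#' @export
frangi_vesselness <- function(vol, params = frangi_params()) {
  stopifnot(inherits(vol, "volume3d"), inherits(params, "frangi_params"))
  d <- dim(vol$data)
  if (any(d <= 2 * max(params$scales)))
    stop("volume must be larger than twice the maximum scale (",
         max(params$scales), " voxels) along every axis")
  v <- frangi_cpp(as.numeric(vol$data), d, params$scales, params$alpha,
                  params$beta, params$c, params$dark_vessels)
  volume3d(v, vol$voxel_size)
}

#' Segment small vessels by thresholding the vesselness field
#'
#' Voxels with vesselness strictly above `params$probability_threshold` are
#' flagged as vessel.
#'
#' @inheritParams frangi_vesselness
#' @param vesselness optionally, a precomputed [frangi_vesselness()] field for
#'   `vol` (avoids recomputation in pipelines).
#' @return A [vessel_mask()] with provenance `"frangi"`.
#' @export
segment_small_vessels <- function(vol, params = frangi_params(),
                                  vesselness = NULL) {
  if (is.null(vesselness)) vesselness <- frangi_vesselness(vol, params)
  mask <- vesselness$data > params$probability_threshold
  vessel_mask(mask, vol$voxel_size, "frangi")
}

#' Segment large vessels by intensity thresholding
#'
#' Voxels on the vessel side of a grey threshold (below it for dark vessels)
#' are flagged, then structures thinner than `min_diameter` are removed via
#' the local-thickness split of [split_by_diameter()], leaving only the large
#' vessels (central veins and similar).
#'
#' @inheritParams frangi_vesselness
#' @param grey_threshold grey threshold; `NULL` uses Otsu's method on the
#'   volume histogram.
#' @param min_diameter minimum local diameter (um) a structure must reach to
#'   be kept; default 15 um, the empirical sinusoid/large-vessel split.
#' @param dark_vessels vessels darker than background?
#' @return A [vessel_mask()] with provenance `"threshold"`.
#' @export
segment_large_vessels <- function(vol, grey_threshold = NULL,
                                  min_diameter = 15, dark_vessels = TRUE) {
  stopifnot(inherits(vol, "volume3d"))
  rng <- range(vol$data)
  if (is.null(grey_threshold)) grey_threshold <- otsu_threshold(vol$data)
  if (grey_threshold < rng[1] || grey_threshold > rng[2])
    warning("grey threshold ", signif(grey_threshold, 4),
            " lies outside the volume grey range [", signif(rng[1], 4), ", ",
            signif(rng[2], 4), "]; mask is empty or full by definition")
  mask <- if (dark_vessels) vol$data < grey_threshold else vol$data > grey_threshold
  m <- vessel_mask(mask, vol$voxel_size, "threshold")
  if (min_diameter > 0 && any(mask)) {
    m <- split_by_diameter(m, min_diameter)$large
    m$provenance <- "threshold"
  }
  m
}

#' Merge two binary vessel masks (voxelwise OR)
#'
#' @param small,large [vessel_mask()] objects on the same grid.
#' @return A [vessel_mask()] with provenance `"merged"`.
#' @export
merge_masks <- function(small, large) {
  stopifnot(inherits(small, "vessel_mask"), inherits(large, "vessel_mask"))
  check_same_grid(small, large)
  vessel_mask(small$data | large$data, small$voxel_size, "merged")
}

#' Split a vessel mask into small and large vessels by local diameter
#'
#' The local diameter at a vessel voxel follows the local-thickness
#' convention: twice the distance-transform value at the nearest centerline
#' (skeleton) voxel. Voxels belonging to structures with local diameter
#' strictly above `cutoff_diameter` go to the large mask, the rest to the
#' small mask; the two parts partition the input exactly.
#'
#' @param mask a [vessel_mask()].
#' @param cutoff_diameter diameter cut in micrometres (15 um separates
#'   sinusoids from large vessels; 10 um is the cut used for vascular volume
#'   fraction reporting).
#' @return A list with [vessel_mask()] elements `small` and `large`.
#' @export
split_by_diameter <- function(mask, cutoff_diameter) {
  stopifnot(inherits(mask, "vessel_mask"))
  h <- mask$voxel_size
  d <- dim(mask$data)
  empty <- vessel_mask(array(FALSE, d), h, "small")
  if (!any(mask$data))
    return(list(small = empty,
                large = vessel_mask(array(FALSE, d), h, "large")))
  if (cutoff_diameter <= 0) { # everything has positive diameter -> all large
    return(list(small = empty,
                large = vessel_mask(mask$data, h, "large")))
  }
  skel <- thin3d_cpp(as.integer(mask$data), d)
  edt <- edt_voxels(mask$data)
  # inscribed-sphere local thickness: paint each centerline voxel's sphere,
  # keeping the largest covering radius; voxels no sphere reaches fall back
  # to their nearest centerline voxel's radius
  sk_lin <- which(skel == 1L)
  sk_rad <- edt[sk_lin]
  rm(edt)
  painted <- paint_spheres_cpp(d, sk_lin, sk_rad)
  uncovered <- which(mask$data & painted == 0)
  if (length(uncovered) > 0L) {
    ns_idx <- nearest_site_cpp(skel, d)
    painted[uncovered] <- sk_rad[match(ns_idx[uncovered], sk_lin)]
    rm(ns_idx)
  }
  rm(skel)
  large <- mask$data & (2 * radius_from_edt(painted, h) > cutoff_diameter)
  small <- mask$data & !large
  list(small = vessel_mask(small, h, "small"),
       large = vessel_mask(large, h, "large"))
}
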