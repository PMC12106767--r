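#' Rasterize a vessel tree into a textured phantom volume
#'
#' Builds the grey volume: parenchyma at `background_grey` carrying a
#' zero-mean band-limited Gaussian texture (white noise smoothed with a
#' 1-voxel Gaussian, correlation length about 2 voxels, rescaled to a
#' standard deviation of `texture_rms`), vessel voxels at `vessel_grey`
#' (darker), nodule interiors and rim shells at their own grey levels.
#' Ground-truth masks are returned alongside; vessel and nodule truth masks
#' are disjoint by construction (tube voxels falling inside a nodule are
#' clipped).
#'
#' @param curves result of [generate_vessel_tree()].
#' @param spec the [phantom_spec()] used to generate them.
#' @param nodules list of [nodule_spec()]; nodules exceeding the volume are
#'   clipped with a warning.
#' @return An object of class `liver_phantom`: list with `volume`
#'   ([volume3d()]), `vessel_mask_truth` (all vessels, provenance
#'   `"truth"`), `small_vessel_mask_truth`, `large_vessel_mask_truth`
#'   (central vein), `nodule_mask_truth`, `exclusion` (vessels + nodules,
#'   for RMS maps), `spec`, `nodules`.
#' @export
rasterize_and_texture <- function(curves, spec, nodules = list()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed + 7919L)
  dims <- spec$volume_shape
  h <- spec$voxel_size
  ntot <- prod(dims)

  small <- array(FALSE, dims)
  large <- array(FALSE, dims)
  tv <- attr(curves, "truth_voxels")
  vv <- attr(curves, "vein_voxels")
  if (!is.null(tv)) { # fast path: the generator already rasterized
    small[tv] <- TRUE
    large[vv] <- TRUE
  } else {
    for (cv in curves) {
      vox <- rasterize_curve(cv, dims, h)
      if (identical(cv$kind, "vein")) large[vox] <- TRUE else small[vox] <- TRUE
    }
    small <- small & !large
  }

  nodule_mask <- array(FALSE, dims)
  rim_mask <- array(FALSE, dims)
  interior_grey <- rim_grey <- NULL
  if (length(nodules) > 0L) {
    xs <- ((1:dims[1]) - 0.5) * h
    ys <- ((1:dims[2]) - 0.5) * h
    for (nd in nodules) {
      ctr_um <- (nd$center - 0.5) * h
      if (any(ctr_um - nd$semi_axes < 0) || any(ctr_um + nd$semi_axes > dims * h))
        warning("nodule exceeds the volume bounds; clipping at the edges")
      # slice-wise to keep the working set small on large grids
      qx <- (xs - ctr_um[1])^2
      qy <- (ys - ctr_um[2])^2
      for (k in seq_len(dims[3])) {
        z_um <- (k - 0.5) * h
        m2 <- outer(qx / nd$semi_axes[1]^2, qy / nd$semi_axes[2]^2, "+") +
          (z_um - ctr_um[3])^2 / nd$semi_axes[3]^2
        inside <- m2 <= 1
        if (!any(inside)) next
        nodule_mask[, , k] <- nodule_mask[, , k] | inside
        r <- sqrt(outer(qx, qy, "+") + (z_um - ctr_um[3])^2)
        depth <- r * (1 / pmax(sqrt(m2), 1e-9) - 1) # depth below the surface
        rim_mask[, , k] <- rim_mask[, , k] |
          (inside & depth <= nd$rim_thickness)
      }
      interior_grey <- nd$interior_grey
      rim_grey <- nd$rim_grey
    }
    small <- small & !nodule_mask
    large <- large & !nodule_mask
  }

  base <- array(spec$background_grey, dims)
  if (length(nodules) > 0L) {
    base[nodule_mask] <- interior_grey
    base[rim_mask] <- rim_grey
  }
  base[small | large] <- spec$vessel_grey

  if (spec$texture_rms > 0 || !is.na(spec$texture_rms2)) {
    noise <- array(rnorm(ntot), dims)
    noise <- gauss_smooth(noise, 1.0)
    noise <- noise / sd(noise)
    on.exit(rm(noise), add = TRUE)
    if (!is.na(spec$texture_rms2)) {
      amp <- array(spec$texture_rms, dims)
      amp[, seq_len(dims[2] %/% 2) + dims[2] - dims[2] %/% 2, ] <- spec$texture_rms2
      base <- base + noise * amp
    } else {
      base <- base + noise * spec$texture_rms
    }
  }

  vessel_all <- small | large
  structure(list(
    volume = volume3d(base, h),
    vessel_mask_truth = vessel_mask(vessel_all, h, "truth"),
    small_vessel_mask_truth = vessel_mask(small, h, "truth"),
    large_vessel_mask_truth = vessel_mask(large, h, "truth"),
    nodule_mask_truth = vessel_mask(nodule_mask, h, "truth"),
    exclusion = vessel_mask(vessel_all | nodule_mask, h, "truth"),
    spec = spec, nodules = nodules), class = "liver_phantom")
}

#' Generate a complete phantom from a spec or preset name
#'
#' @param x a preset name (see [liver_preset()]), a [phantom_spec()], or a
#'   `list(spec=, nodules=)` pair.
#' @param nodules list of [nodule_spec()] (ignored when `x` carries its own).
#' @param seed optional seed override.
#' @param shape,voxel_size optional overrides when `x` is a preset name.
#' @return A `liver_phantom` (see [rasterize_and_texture()]).
#' @export
generate_phantom <- function(x, nodules = list(), seed = NULL, shape = NULL,
                             voxel_size = NULL) {
  if (is.character(x)) {
    x <- liver_preset(x, shape = shape, voxel_size = voxel_size,
                      seed = if (is.null(seed)) 1L else seed)
  }
  if (inherits(x, "phantom_spec")) x <- list(spec = x, nodules = nodules)
  spec <- x$spec
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  curves <- generate_vessel_tree(spec, x$nodules)
  rasterize_and_texture(curves, spec, x$nodules)
}

#' @export
print.liver_phantom <- function(x, ...) {
  d <- dim(x$volume$data)
  cat(sprintf("<liver_phantom> %d x %d x %d voxels at %.3g um\n",
              d[1], d[2], d[3], x$volume$voxel_size))
  cat(sprintf("  truth VVF %.3g%% (small vessels), %d nodule voxels, seed %d\n",
              100 * phantom_truth_vvf(x), sum(x$nodule_mask_truth$data),
              x$spec$seed))
  invisible(x)
}

#' Ground-truth small-vessel VVF of a phantom
#'
#' Voxel-counted: sinusoid truth voxels over all remaining (tissue) voxels;
#' the central vein and nodules count as tissue, matching the VVF convention
#' in which vessels above the diameter cut are excluded from the mask.
#'
#' @param phantom a `liver_phantom`.
#' @return Fraction.
#' @export
phantom_truth_vvf <- function(phantom) {
  n <- sum(phantom$small_vessel_mask_truth$data)
  n / (prod(dim(phantom$volume$data)) - n)
}

#' Write a phantom to disk (TIFF volume + mask stacks + metadata sidecar)
#'
#' @param phantom a `liver_phantom`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(phantom$volume, file.path(dir, "volume.tif"),
               extra = list(seed = phantom$spec$seed,
                            target_vvf = phantom$spec$target_vvf))
  write_volume(phantom$vessel_mask_truth, file.path(dir, "vessel_mask.tif"))
  write_volume(phantom$nodule_mask_truth, file.path(dir, "nodule_mask.tif"))
  meta <- phantom$spec
  meta$volume_shape <- paste(meta$volume_shape, collapse = "x")
  meta$length_long_range <- paste(meta$length_long_range, collapse = " ")
  write_metadata(unclass(meta), file.path(dir, "phantom_meta.txt"))
  invisible(dir)
}
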