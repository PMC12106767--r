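#' Vascular volume fraction (VVF) in a region
#'
#' VVF is the ratio between the number of vessel voxels and the number of
#' tissue voxels in a region, where tissue means region voxels not flagged as
#' vessel. When `exclusion_diameter` is given, vessels with local diameter
#' above it are removed from the mask first (their voxels then count as
#' tissue), mirroring the reporting convention in which vessels larger than
#' 10 um are excluded from VVF.
#'
#' @param mask a [vessel_mask()].
#' @param region logical array (same shape) delimiting the region of
#'   interest; `NULL` means the whole volume.
#' @param exclusion_diameter diameter (um) above which vessels are excluded
#'   via [split_by_diameter()]; `NULL` to use the mask as is.
#' @return VVF as a fraction (multiply by 100 for percent).
#' @export
vvf <- function(mask, region = NULL, exclusion_diameter = NULL) {
  stopifnot(inherits(mask, "vessel_mask"))
  if (!is.null(exclusion_diameter))
    mask <- split_by_diameter(mask, exclusion_diameter)$small
  m <- mask$data
  if (is.null(region)) region <- array(TRUE, dim(m))
  if (!identical(dim(region), dim(m))) stop("region shape mismatch")
  if (!any(region)) stop("region is empty")
  n_vessel <- sum(m & region)
  n_tissue <- sum(region & !m)
  if (n_tissue == 0L) stop("region contains no tissue voxels")
  n_vessel / n_tissue
}

#' Cubic region-of-interest specification
#'
#' @param origin 1-based voxel coordinates of the ROI corner (3 integers).
#' @param shape ROI extent in voxels (3 integers).
#' @param voxel_size voxel size in um (to derive the ROI volume in mm^3).
#' @return A list with `origin`, `shape` and `volume_mm3`.
#' @export
roi_spec <- function(origin, shape, voxel_size) {
  origin <- as.integer(origin); shape <- as.integer(shape)
  stopifnot(length(origin) == 3L, length(shape) == 3L, all(shape >= 1L))
  list(origin = origin, shape = shape,
       volume_mm3 = prod(shape) * (voxel_size * 1e-3)^3)
}

#' Sample random cubic ROIs of a given physical volume
#'
#' @param dims volume shape in voxels.
#' @param voxel_size voxel size in um.
#' @param volume_mm3 target ROI volume (default 5e-3 mm^3, the reporting
#'   standard).
#' @param n number of ROIs.
#' @return List of [roi_spec()] objects. ROIs are sampled uniformly at
#'   random (use `set.seed()` upstream for reproducibility) and must fit in
#'   the volume.
#' @export
sample_rois <- function(dims, voxel_size, volume_mm3 = 5e-3, n = 5L) {
  side <- round((volume_mm3 * 1e9)^(1 / 3) / voxel_size)
  if (any(side > dims))
    stop("an ROI of ", volume_mm3, " mm^3 (side ", side,
         " voxels) does not fit in the volume")
  lapply(seq_len(n), function(i) {
    origin <- vapply(dims, function(d) sample.int(d - side + 1L, 1L), integer(1))
    roi_spec(origin, rep(side, 3L), voxel_size)
  })
}

roi_region <- function(roi, dims) {
  region <- array(FALSE, dims)
  region[roi$origin[1]:(roi$origin[1] + roi$shape[1] - 1L),
         roi$origin[2]:(roi$origin[2] + roi$shape[2] - 1L),
         roi$origin[3]:(roi$origin[3] + roi$shape[3] - 1L)] <- TRUE
  region
}

#' Local VVF on a sliding cubic window
#'
#' Computes the VVF restricted to every cubic window of `cube_side` voxels
#' (stride 1, via box sums), following the [vvf()] definition.
#'
#' @param mask a [vessel_mask()] (already exclusion-filtered if desired).
#' @param cube_side window side in voxels (default 50).
#' @return An object of class `vvf_map`: list with `map` (3D array indexed by
#'   window start position), `cube_side`, `voxel_size` and summary
#'   `min`/`mean`/`max`.
#' @export
vvf_map <- function(mask, cube_side = 50L) {
  stopifnot(inherits(mask, "vessel_mask"))
  d <- dim(mask$data)
  if (any(cube_side > d)) stop("cube does not fit in the volume")
  s <- box_sum3d_cpp(as.numeric(mask$data), d, rep(as.integer(cube_side), 3L))
  map <- s / (cube_side^3 - s)
  structure(list(map = map, cube_side = as.integer(cube_side),
                 voxel_size = mask$voxel_size,
                 min = min(map), mean = mean(map), max = max(map)),
            class = "vvf_map")
}

#' @export
print.vvf_map <- function(x, ...) {
  cat(sprintf("<vvf_map> cube %d voxels: VVF min %.3g%%, mean %.3g%%, max %.3g%%\n",
              x$cube_side, 100 * x$min, 100 * x$mean, 100 * x$max))
  invisible(x)
}

#' Radial VVF profile around a nodule
#'
#' Shell `k` collects voxels whose Euclidean distance from the nodule
#' boundary lies in `(k*w, (k+1)*w]` micrometres (distance transform of the
#' nodule complement, so shells follow the nodule shape). Per shell, the VVF
#' is computed as in [vvf()], and the shell's size is summarized by the major
#' semi-axis of a second-moment (inertia-tensor) ellipsoid fit to the
#' shell-outer-surface voxels. Shells reaching the volume edge are flagged
#' incomplete; trailing empty shells truncate the profile with a warning.
#'
#' @param mask a [vessel_mask()].
#' @param nodule logical array (same grid) flagging nodule voxels, non-empty
#'   and strictly inside the volume.
#' @param shell_width shell width in micrometres (default 10).
#' @param n_shells number of shells.
#' @return A data.frame with columns `shell`, `inner_um`, `outer_um`, `vvf`,
#'   `axis_length_um`, `complete`, `n_voxels`.
#' @export
radial_vvf <- function(mask, nodule, shell_width = 10, n_shells = 15L) {
  stopifnot(inherits(mask, "vessel_mask"))
  d <- dim(mask$data)
  if (!identical(dim(nodule), d)) stop("nodule mask shape mismatch")
  if (!any(nodule)) stop("nodule mask is empty")
  h <- mask$voxel_size
  # distance (um) to the nodule for voxels outside it
  dist_um <- edt_voxels(!nodule) * h
  # minimum boundary distance reached on the volume faces: shells beyond it
  # may be clipped
  face <- array(FALSE, d)
  face[1, , ] <- TRUE; face[d[1], , ] <- TRUE
  face[, 1, ] <- TRUE; face[, d[2], ] <- TRUE
  face[, , 1] <- TRUE; face[, , d[3]] <- TRUE
  face_min <- min(dist_um[face])
  if (face_min == 0) stop("nodule touches the volume boundary")
  vm <- mask$data
  rows <- vector("list", n_shells)
  for (k in seq_len(n_shells) - 1L) {
    inner <- k * shell_width
    outer <- (k + 1) * shell_width
    shell <- dist_um > inner & dist_um <= outer
    nvox <- sum(shell)
    if (nvox == 0L) {
      warning("radial profile truncated at shell ", k,
              ": no voxels left inside the volume")
      rows <- rows[seq_len(k)]
      break
    }
    n_ves <- sum(vm & shell)
    n_tis <- nvox - n_ves
    # outer-surface voxels of the shell: within one voxel of the outer bound
    surf <- shell & dist_um > outer - h
    if (sum(surf) < 10L) surf <- shell
    idx <- which(surf)
    cosu <- lin_to_vox(idx, d)
    ctr <- colMeans(cosu)
    cc <- sweep(cosu, 2, ctr)
    ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE, only.values = TRUE)
    axis_um <- sqrt(3 * max(ev$values)) * h
    rows[[k + 1L]] <- data.frame(shell = k, inner_um = inner, outer_um = outer,
                                 vvf = n_ves / n_tis, axis_length_um = axis_um,
                                 complete = outer <= face_min, n_voxels = nvox)
  }
  do.call(rbind, rows)
}

#' Curved branch lengths of a skeleton graph
#'
#' Each branch's ordered voxel path is interpolated with a natural cubic
#' spline through the voxel centres (chord-length parameterization, in um);
#' the branch length is the arc length of the spline, evaluated by dense
#' resampling. Single-voxel branches have length 0. The histogram is
#' normalized to the total number of branches.
#'
#' @param graph a [skeletonize()] result.
#' @param bin_width histogram bin width in micrometres (default 1).
#' @return A list with `lengths` (um per branch), `histogram` (data.frame:
#'   `bin_center_um`, `count`, `frequency` summing to 1) and `mode_um`.
#' @export
branch_lengths <- function(graph, bin_width = 1) {
  stopifnot(inherits(graph, "skeleton_graph"))
  if (length(graph$branches) == 0L) stop("empty skeleton graph")
  h <- graph$voxel_size
  len <- vapply(graph$branches, function(b) branch_arc_length(b, h), numeric(1))
  hist_with_mode(len, bin_width, value_name = "lengths")
}

# arc length (um) of the spline through a branch voxel path; spline knots
# are thinned to every 3rd voxel (endpoints kept) so the interpolant tracks
# the underlying curve instead of the half-voxel digitization zigzag, which
# would otherwise inflate curved lengths by tens of percent
branch_arc_length <- function(path_vox, voxel_size, n_sub = 10L, knot_step = 3L) {
  p <- (path_vox - 0.5) * voxel_size # voxel centres in um
  n <- nrow(p)
  if (n < 2L) return(0)
  if (n > 3L && knot_step > 1L) {
    keep <- unique(c(seq(1L, n, by = knot_step), n))
    p <- p[keep, , drop = FALSE]
    n <- nrow(p)
  }
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-n, , drop = FALSE])^2))
  if (n == 2L) return(sum(seg))
  t <- c(0, cumsum(seg))
  tt <- seq(0, t[n], length.out = (n - 1L) * n_sub + 1L)
  xyz <- vapply(1:3, function(a)
    spline(t, p[, a], xout = tt, method = "natural")$y,
    numeric(length(tt)))
  sum(sqrt(rowSums((xyz[-1, , drop = FALSE] -
                      xyz[-nrow(xyz), , drop = FALSE])^2)))
}

#' Nearest-neighbour distances between vessels
#'
#' Each branch is represented by its curve-constrained centre: the skeleton
#' voxel sitting at half the branch's arc length (guaranteed to lie inside
#' the vessel). The nearest-neighbour distance (NND) of a branch is the
#' minimum Euclidean distance from its representative point to any other
#' branch's representative point; the weighted average is the mean over the
#' branch distribution (each vessel counted once, as in a histogram
#' normalized to the total number of vessels).
#'
#' @param graph a [skeletonize()] result with at least 2 branches.
#' @return A list with `nnd` (um per branch), `weighted_mean` (um) and
#'   `points` (matrix of representative points, um).
#' @export
nearest_neighbour_distances <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  nb <- length(graph$branches)
  if (nb < 2L) stop("need at least 2 branches to compute NND")
  h <- graph$voxel_size
  pts <- t(vapply(graph$branches, function(b) branch_midpoint(b, h), numeric(3)))
  dm <- as.matrix(stats::dist(pts))
  diag(dm) <- Inf
  nnd <- apply(dm, 1, min)
  list(nnd = nnd, weighted_mean = mean(nnd), points = pts)
}

# representative point: voxel centre at half the cumulative path length
branch_midpoint <- function(path_vox, voxel_size) {
  p <- (path_vox - 0.5) * voxel_size
  n <- nrow(p)
  if (n == 1L) return(p[1, ])
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-n, , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  p[which.min(abs(cum - cum[n] / 2)), ]
}
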