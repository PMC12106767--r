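#' 3D grey-value volume with isotropic voxel size
#'
#' A `volume3d` is the basic container of the pipeline: a 3D numeric array of
#' (dimensionless, typically \[0, 1\]-normalized) grey values together with the
#' isotropic voxel size in micrometres. Phase-contrast CT reconstructions are
#' assumed isotropic; anisotropic data must be resampled upstream.
#'
#' @param data 3D numeric array of finite grey values.
#' @param voxel_size isotropic voxel size in micrometres (single positive
#'   number).
#' @return An object of class `volume3d` with fields `data` and `voxel_size`.
#' @export
volume3d <- function(data, voxel_size) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L ||
      !is.finite(voxel_size) || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (micrometres); ",
         "anisotropic voxel sizes are not supported")
  if (anyNA(data) || !all(is.finite(range(data))))
    stop("`data` must be finite everywhere")
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels at %.3g um (%.3g x %.3g x %.3g um)\n",
              d[1], d[2], d[3], x$voxel_size,
              d[1] * x$voxel_size, d[2] * x$voxel_size, d[3] * x$voxel_size))
  cat(sprintf("  grey range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Binary vessel (or nodule) mask aligned to a volume
#'
#' @param data 3D logical (or 0/1) array.
#' @param voxel_size isotropic voxel size in micrometres.
#' @param provenance one of `"frangi"`, `"threshold"`, `"merged"`, `"small"`,
#'   `"large"`, `"truth"`.
#' @return An object of class `vessel_mask`.
#' @export
vessel_mask <- function(data, voxel_size,
                        provenance = c("frangi", "threshold", "merged",
                                       "small", "large", "truth")) {
  provenance <- match.arg(provenance)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!is.logical(data)) {
    storage.mode(data) <- "logical"
  }
  if (anyNA(data)) stop("mask must not contain NA")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 provenance = provenance),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vessel_mask/%s> %d x %d x %d voxels at %.3g um, %d set (%.3g%%)\n",
              x$provenance, d[1], d[2], d[3], x$voxel_size, sum(x$data),
              100 * mean(x$data)))
  invisible(x)
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("volumes/masks have different shapes: ",
         paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"))
  if (abs(a$voxel_size - b$voxel_size) > 1e-9)
    stop("volumes/masks have different voxel sizes")
  invisible(TRUE)
}

#' Read a volume from a multi-page TIFF stack or a NIfTI file
#'
#' The voxel size is never guessed: for TIFF it must be given explicitly or
#' through a metadata sidecar (`<file>_meta.txt`, a `key: value` file with a
#' `voxel_size_um` entry, as written by [write_volume()]); for NIfTI it is
#' taken from the header (mm converted to um) unless overridden.
#'
#' @param path path to a `.tif`/`.tiff` stack or `.nii`/`.nii.gz` file.
#' @param voxel_size voxel size in micrometres; mandatory for TIFF without
#'   sidecar.
#' @return A [volume3d()].
#' @export
read_volume <- function(path, voxel_size = NULL) {
  if (!file.exists(path)) stop("input volume not found: ", path)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)
    if (is.null(voxel_size)) {
      if (max(pd) - min(pd) > 1e-6 * max(pd))
        stop("anisotropic NIfTI voxels (", paste(signif(pd, 4), collapse = ", "),
             " mm); resample before analysis")
      voxel_size <- pd[1] * 1000 # mm -> um
    }
    return(volume3d(array(as.numeric(img), dim = dim(img)), voxel_size))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  data <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  if (is.null(voxel_size)) {
    sidecar <- paste0(sub("\\.[^.]+$", "", path), "_meta.txt")
    if (!file.exists(sidecar))
      stop("voxel size must be supplied for TIFF volumes (argument or sidecar ",
           sidecar, ")")
    meta <- read_metadata(sidecar)
    if (is.null(meta$voxel_size_um))
      stop("sidecar ", sidecar, " lacks a voxel_size_um entry")
    voxel_size <- as.numeric(meta$voxel_size_um)
  }
  volume3d(data, voxel_size)
}

#' Write a volume (or mask) as a multi-page 32-bit float TIFF plus sidecar
#'
#' @param vol a [volume3d()] or [vessel_mask()].
#' @param path output `.tif` path; a `<file>_meta.txt` sidecar with the voxel
#'   size is written next to it.
#' @param extra named list of extra key-value entries for the sidecar.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, extra = list()) {
  data <- vol$data
  if (is.logical(data)) storage.mode(data) <- "double"
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > 1) { # writeTIFF stores [0,1]; record the scale
    extra$grey_offset <- rng[1]
    extra$grey_scale <- max(rng[2] - rng[1], .Machine$double.eps)
    data <- (data - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  }
  pages <- lapply(seq_len(dim(data)[3]), function(k) data[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- c(list(voxel_size_um = vol$voxel_size), extra)
  write_metadata(meta, paste0(sub("\\.[^.]+$", "", path), "_meta.txt"))
  invisible(path)
}

write_metadata <- function(meta, path) {
  lines <- vapply(names(meta), function(k)
    paste0(k, ": ", paste(format(meta[[k]], digits = 15), collapse = " ")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

read_metadata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  keys <- sub(":.*$", "", lines)
  vals <- trimws(sub("^[^:]*:", "", lines))
  setNames(as.list(vals), trimws(keys))
}
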