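#' In-plane RMS roughness map
#'
#' For every slice and every square window position, computes the root mean
#' square of the mean-subtracted grey values over the non-excluded pixels in
#' the window (the population standard deviation of the valid window pixels).
#' Windows where fewer than `min_valid_frac` of the pixels are valid are
#' undefined (`NA`). By default windows tile the slice (stride equal to the
#' window side), which preserves the classification statistics at a fraction
#' of the cost of a stride-1 sliding window; set `stride = "slide"` for the
#' dense map.
#'
#' @param vol a [volume3d()].
#' @param exclusion a [vessel_mask()] (vessels, nodules, damaged regions) or
#'   logical array of pixels to exclude; `NULL` for none.
#' @param window_side window side in pixels (default 30).
#' @param stride `"tile"` (default) or `"slide"`.
#' @param min_valid_frac minimum fraction of valid pixels for a window to be
#'   defined (default 0.1).
#' @return An object of class `rms_map`: list with `values` (3D array:
#'   window-x, window-y, slice), `window_side`, `stride`, `voxel_size`.
#' @export
rms_map <- function(vol, exclusion = NULL, window_side = 30L,
                    stride = c("tile", "slide"), min_valid_frac = 0.1) {
  stopifnot(inherits(vol, "volume3d"))
  stride <- match.arg(stride)
  w <- as.integer(window_side)
  if (w < 2L) stop("`window_side` must be at least 2")
  d <- dim(vol$data)
  if (w > d[1] || w > d[2])
    stop("window (", w, " px) is larger than the slice (", d[1], " x ", d[2], ")")
  excl <- if (is.null(exclusion)) array(FALSE, d)
          else if (inherits(exclusion, "vessel_mask")) exclusion$data
          else exclusion
  if (!identical(dim(excl), d)) stop("exclusion mask shape mismatch")
  valid <- !excl
  g <- vol$data * valid

  if (stride == "tile") {
    nx <- d[1] %/% w
    ny <- d[2] %/% w
    vals <- array(NA_real_, c(nx, ny, d[3]))
    # reshape-trick tile sums per slice
    for (k in seq_len(d[3])) {
      gs <- g[seq_len(nx * w), seq_len(ny * w), k]
      vs <- valid[seq_len(nx * w), seq_len(ny * w), k]
      tile_sum <- function(m) {
        dim(m) <- c(w, nx, w, ny)
        apply(m, c(2, 4), sum)
      }
      n <- tile_sum(vs + 0)
      s1 <- tile_sum(gs)
      s2 <- tile_sum(gs^2)
      mvar <- s2 / n - (s1 / n)^2
      mvar[n < min_valid_frac * w^2] <- NA_real_
      vals[, , k] <- sqrt(pmax(mvar, 0))
    }
  } else {
    m1 <- d[1] - w + 1L
    m2 <- d[2] - w + 1L
    vals <- array(NA_real_, c(m1, m2, d[3]))
    for (k in seq_len(d[3])) {
      dd <- c(d[1], d[2], 1L)
      ww <- c(w, w, 1L)
      n <- box_sum3d_cpp(as.numeric(valid[, , k]), dd, ww)
      s1 <- box_sum3d_cpp(as.numeric(g[, , k]), dd, ww)
      s2 <- box_sum3d_cpp(as.numeric(g[, , k]^2), dd, ww)
      mvar <- s2 / n - (s1 / n)^2
      mvar[n < min_valid_frac * w^2] <- NA_real_
      vals[, , k] <- sqrt(pmax(mvar, 0))
    }
  }
  structure(list(values = vals, window_side = w, stride = stride,
                 voxel_size = vol$voxel_size),
            class = "rms_map")
}

#' @export
print.rms_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<rms_map> window %d px (%s): %d windows, RMS mean %.3g (range %.3g-%.3g)\n",
              x$window_side, x$stride, length(v), mean(v), min(v), max(v)))
  invisible(x)
}

#' Per-class RMS statistics and classification bands
#'
#' Pools the training RMS values of each class and derives the
#' mean +/- `k` standard deviation band used for tissue classification.
#'
#' @param samples named list of numeric vectors of RMS values, one per class
#'   (typically `healthy` and `metastatic`), each with at least `min_n`
#'   values.
#' @param k half-width of the band in standard deviations (default 1.5).
#' @param min_n minimum training samples per class (default 30).
#' @return A data.frame of class `class_stats` with columns `class`, `n`,
#'   `mean`, `sd`, `lower`, `upper`.
#' @export
class_stats <- function(samples, k = 1.5, min_n = 30L) {
  stopifnot(is.list(samples), !is.null(names(samples)))
  rows <- lapply(names(samples), function(cl) {
    v <- samples[[cl]]
    v <- v[!is.na(v)]
    if (length(v) < min_n)
      stop("class '", cl, "' has only ", length(v),
           " valid RMS samples (minimum ", min_n, ")")
    m <- mean(v)
    s <- stats::sd(v)
    data.frame(class = cl, n = length(v), mean = m, sd = s,
               lower = m - k * s, upper = m + k * s)
  })
  out <- do.call(rbind, rows)
  attr(out, "k") <- k
  class(out) <- c("class_stats", class(out))
  out
}

#' Extract RMS values from training regions of a map
#'
#' @param map an [rms_map()].
#' @param regions optional list of rectangles, each
#'   `c(x0, x1, y0, y1, z0, z1)` in window-grid coordinates; `NULL` uses all
#'   defined windows.
#' @return Numeric vector of RMS values.
#' @export
rms_values <- function(map, regions = NULL) {
  stopifnot(inherits(map, "rms_map"))
  if (is.null(regions)) {
    v <- as.vector(map$values)
    return(v[!is.na(v)])
  }
  out <- unlist(lapply(regions, function(r) {
    as.vector(map$values[r[1]:r[2], r[3]:r[4], r[5]:r[6]])
  }))
  out[!is.na(out)]
}

#' Classify tissue windows as healthy or metastatic
#'
#' A window is assigned to a class when its RMS value falls within that
#' class's mean +/- k*SD band (inclusive). Values inside both bands go to
#' the class whose mean is nearest in SD units (an exact tie is
#' unclassified); values in neither band are unclassified; undefined
#' (excluded) windows stay excluded.
#'
#' @param rms an [rms_map()].
#' @param stats a two-class [class_stats()] table.
#' @return An object of class `tissue_class_map`: integer array with levels
#'   attribute `c("healthy-like", "metastatic-like", "unclassified",
#'   "excluded")` using the class names from `stats`.
#' @export
classify_tissue <- function(rms, stats) {
  stopifnot(inherits(rms, "rms_map"), inherits(stats, "class_stats"))
  if (nrow(stats) != 2L) stop("classification needs stats for exactly 2 classes")
  v <- rms$values
  lab <- array(NA_integer_, dim(v))
  in1 <- v >= stats$lower[1] & v <= stats$upper[1]
  in2 <- v >= stats$lower[2] & v <= stats$upper[2]
  in1[is.na(in1)] <- FALSE
  in2[is.na(in2)] <- FALSE
  z1 <- abs(v - stats$mean[1]) / ifelse(stats$sd[1] > 0, stats$sd[1], Inf)
  z2 <- abs(v - stats$mean[2]) / ifelse(stats$sd[2] > 0, stats$sd[2], Inf)
  z1[v == stats$mean[1]] <- 0 # zero-SD class: exact match only
  z2[v == stats$mean[2]] <- 0
  lab[in1 & !in2] <- 1L
  lab[in2 & !in1] <- 2L
  both <- which(in1 & in2)
  lab[both[z1[both] < z2[both]]] <- 1L
  lab[both[z2[both] < z1[both]]] <- 2L
  lab[both[z1[both] == z2[both]]] <- 3L
  lab[!is.na(v) & is.na(lab)] <- 3L # in neither band
  lab[is.na(v)] <- 4L # excluded / undefined window
  structure(lab, levels = c(stats$class, "unclassified", "excluded"),
            class = "tissue_class_map")
}

#' Healthy/metastatic fractions of a classified map
#'
#' Percentages are relative to classified windows only (the two class labels)
#' and sum to 100 exactly.
#'
#' @param map a [classify_tissue()] result.
#' @return Named numeric vector of two percentages.
#' @export
class_fractions <- function(map) {
  stopifnot(inherits(map, "tissue_class_map"))
  lev <- attr(map, "levels")
  n1 <- sum(map == 1L, na.rm = TRUE)
  n2 <- sum(map == 2L, na.rm = TRUE)
  if (n1 + n2 == 0L) stop("no classified windows")
  setNames(c(100 * n1 / (n1 + n2), 100 * n2 / (n1 + n2)), lev[1:2])
}
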