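#' Colour range of an immunohistochemical stain
#'
#' Per-channel inclusive bounds in a colour space; the default is an HSV
#' range for DAB brown (CD31-positive endothelium) against an
#' eosin/hematoxylin pink background.
#'
#' @param space colour-space label, `"hsv"` or `"rgb"`.
#' @param lower,upper per-channel lower/upper bounds (length 3, each
#'   `lower <= upper`).
#' @return An object of class `stain_range`.
#' @export
stain_range <- function(space = c("hsv", "rgb"),
                        lower = c(0.02, 0.25, 0.10),
                        upper = c(0.18, 1.00, 0.80)) {
  space <- match.arg(space)
  if (length(lower) != 3L || length(upper) != 3L || any(lower > upper))
    stop("`lower` and `upper` must be length-3 with lower <= upper per channel")
  structure(list(space = space, lower = lower, upper = upper),
            class = "stain_range")
}

#' 2D vascular fraction on a CD31-stained RGB image
#'
#' For each region of interest, the percentage of pixels whose colour falls
#' inclusively within the stain range: the 2D analogue of the vascular
#' volume fraction, as used for histological validation.
#'
#' @param image H x W x 3 numeric array, values in \[0, 1\].
#' @param range a [stain_range()].
#' @param rois list of ROI rectangles `c(row0, row1, col0, col1)` (1-based,
#'   inclusive); `NULL` uses the whole image as a single ROI.
#' @return A data.frame with columns `roi`, `stained_pixels`,
#'   `total_pixels`, `fraction_pct`.
#' @export
cd31_fraction <- function(image, range = stain_range(), rois = NULL) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L,
            inherits(range, "stain_range"))
  d <- dim(image)
  if (is.null(rois)) rois <- list(c(1L, d[1], 1L, d[2]))
  ch <- if (range$space == "hsv") {
    m <- rgb2hsv(r = as.vector(image[, , 1]), g = as.vector(image[, , 2]),
                 b = as.vector(image[, , 3]), maxColorValue = 1)
    array(t(m), dim = c(d[1], d[2], 3))
  } else image
  inr <- (ch[, , 1] >= range$lower[1] & ch[, , 1] <= range$upper[1] &
            ch[, , 2] >= range$lower[2] & ch[, , 2] <= range$upper[2] &
            ch[, , 3] >= range$lower[3] & ch[, , 3] <= range$upper[3])
  rows <- lapply(seq_along(rois), function(i) {
    r <- as.integer(rois[[i]])
    if (r[1] > r[2] || r[3] > r[4] || r[1] < 1 || r[3] < 1 ||
        r[2] > d[1] || r[4] > d[2])
      stop("ROI ", i, " is empty or outside the image")
    sub <- inr[r[1]:r[2], r[3]:r[4]]
    data.frame(roi = i, stained_pixels = sum(sub), total_pixels = length(sub),
               fraction_pct = 100 * mean(sub))
  })
  do.call(rbind, rows)
}

#' Generate a synthetic CD31-like IHC image with known stained fraction
#'
#' Brown (DAB-range) structures on a pink background, either as endothelial
#' dot profiles or curvilinear sinusoid profiles. Structures are added until
#' the truth-mask pixel fraction is within 0.1 percentage points of the
#' request. This is a synthetic stand-in for scanned histology, intended for
#' validating [cd31_fraction()] by pixel-count recovery.
#'
#' @param fraction requested stained fraction in percent, within \[0, 50\].
#' @param vessel_texture `"dots"` or `"curvilinear"`.
#' @param seed integer seed (bit-identical rerun for a fixed seed).
#' @param width,height image size in pixels.
#' @return List with `image` (H x W x 3), `mask` (logical truth),
#'   `fraction_pct` (achieved truth fraction).
#' @export
make_synthetic_ihc <- function(fraction, vessel_texture = c("dots", "curvilinear"),
                               seed = 1L, width = 512L, height = 512L) {
  vessel_texture <- match.arg(vessel_texture)
  if (fraction < 0 || fraction > 50)
    stop("`fraction` must lie in [0, 50] percent")
  set.seed(as.integer(seed))
  npix <- width * height
  target <- fraction / 100 * npix
  mask <- matrix(FALSE, height, width)
  count <- 0
  rowg <- matrix(seq_len(height), height, width)
  colg <- matrix(seq_len(width), height, width, byrow = TRUE)
  stalls <- 0L
  while (count < target - 0.0005 * npix) {
    if (stalls > 50L) { # near the target: top up with single pixels
      free <- which(!mask)
      need <- min(length(free), max(0L, round(target - count)))
      if (need > 0L) mask[sample(free, need)] <- TRUE
      count <- count + need
      break
    }
    if (vessel_texture == "dots") {
      r <- runif(1, 2.5, 6)
      cy <- runif(1, 1, height)
      cx <- runif(1, 1, width)
      add <- (rowg - cy)^2 + (colg - cx)^2 <= r^2
    } else {
      # short random-walk stroke of ~2 px half-thickness
      len <- sample(20:60, 1)
      cy <- runif(1, 1, height); cx <- runif(1, 1, width)
      ang <- runif(1, 0, 2 * pi)
      pts <- matrix(NA_real_, len, 2)
      for (t in seq_len(len)) {
        pts[t, ] <- c(cy, cx)
        ang <- ang + rnorm(1, 0, 0.25)
        cy <- min(max(cy + sin(ang), 1), height)
        cx <- min(max(cx + cos(ang), 1), width)
      }
      add <- matrix(FALSE, height, width)
      for (t in seq_len(len)) {
        rr <- max(1, round(pts[t, 1] - 2)):min(height, round(pts[t, 1] + 2))
        cc <- max(1, round(pts[t, 2] - 2)):min(width, round(pts[t, 2] + 2))
        add[rr, cc] <- add[rr, cc] |
          (outer((rr - pts[t, 1])^2, (cc - pts[t, 2])^2, "+") <= 4)
      }
    }
    new <- add & !mask
    if (count + sum(new) > target + 0.001 * npix) { # would overshoot
      stalls <- stalls + 1L
      next
    }
    stalls <- 0L
    mask <- mask | new
    count <- count + sum(new)
  }
  # colours: pink background, brown stain, light per-pixel jitter
  img <- array(0, c(height, width, 3))
  bg <- c(0.91, 0.73, 0.80)
  st <- c(0.38, 0.24, 0.12)
  for (c3 in 1:3) {
    layer <- matrix(bg[c3], height, width)
    layer[mask] <- st[c3]
    img[, , c3] <- pmin(1, pmax(0, layer + rnorm(npix, 0, 0.015)))
  }
  list(image = img, mask = mask, fraction_pct = 100 * count / npix)
}
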