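# CD31-style colour-range segmentation on synthetic IHC images.

test_that("synthetic IHC images honour the requested stained fraction", {
  ihc0 <- make_synthetic_ihc(0, "dots", seed = 1, width = 128, height = 128)
  expect_equal(sum(ihc0$mask), 0) # background only
  for (f in c(3, 10)) {
    ihc <- make_synthetic_ihc(f, "dots", seed = 2)
    expect_lt(abs(ihc$fraction_pct - f), 0.1)
  }
  ihc_c <- make_synthetic_ihc(10, "curvilinear", seed = 3)
  expect_lt(abs(ihc_c$fraction_pct - 10), 0.1)
  expect_error(make_synthetic_ihc(60), "\\[0, 50\\]")
})

test_that("fixed seeds reproduce IHC images bit-exactly", {
  a <- make_synthetic_ihc(5, "dots", seed = 7, width = 128, height = 128)
  b <- make_synthetic_ihc(5, "dots", seed = 7, width = 128, height = 128)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
})

test_that("colour-range fractions recover the generated stained fraction", {
  for (tex in c("dots", "curvilinear")) {
    ihc <- make_synthetic_ihc(3, tex, seed = 5)
    fr <- cd31_fraction(ihc$image)
    expect_lt(abs(fr$fraction_pct - 3), 0.2)
  }
  # an image with no in-range pixels scores 0%
  blank <- array(0, c(32, 32, 3)); blank[, , 1] <- 0.9; blank[, , 3] <- 0.9
  expect_equal(cd31_fraction(blank)$fraction_pct, 0)
})

test_that("half-stained ROIs score exactly 50% on clean colours", {
  img <- array(0, c(40, 40, 3))
  bg <- c(0.91, 0.73, 0.80); st <- c(0.38, 0.24, 0.12)
  for (c3 in 1:3) {
    img[, , c3] <- bg[c3]
    img[1:20, , c3] <- st[c3]
  }
  fr <- cd31_fraction(img, rois = list(c(1, 40, 1, 40)))
  expect_equal(fr$fraction_pct, 50)
  expect_equal(fr$stained_pixels, 800)
})

test_that("fractions are invariant to ROI order and row permutation", {
  ihc <- make_synthetic_ihc(8, "dots", seed = 11, width = 256, height = 256)
  rois <- list(c(1, 128, 1, 256), c(129, 256, 1, 256))
  f12 <- cd31_fraction(ihc$image, rois = rois)
  f21 <- cd31_fraction(ihc$image, rois = rev(rois))
  expect_equal(f12$fraction_pct, rev(f21$fraction_pct))
  perm <- sample(256)
  f_perm <- cd31_fraction(ihc$image[perm, , ])
  expect_equal(f_perm$fraction_pct, cd31_fraction(ihc$image)$fraction_pct)
  expect_error(cd31_fraction(ihc$image, rois = list(c(10, 5, 1, 20))), "empty or outside")
})

test_that("stain ranges validate their bounds", {
  expect_error(stain_range(lower = c(0.5, 0, 0), upper = c(0.1, 1, 1)),
               "lower <= upper")
  sr <- stain_range("rgb", lower = c(0.3, 0.1, 0), upper = c(0.5, 0.35, 0.3))
  img <- array(0.4, c(8, 8, 3)); img[, , 2] <- 0.2; img[, , 3] <- 0.1
  expect_equal(cd31_fraction(img, sr)$fraction_pct, 100)
})
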