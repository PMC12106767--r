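# RMS roughness maps and mean +/- k*SD tissue classification.

test_that("RMS of a constant slice is zero and exclusions give NA windows", {
  v <- volume3d(array(0.5, c(60, 60, 2)), 3.1)
  rm <- rms_map(v, window_side = 30)
  expect_true(all(rm$values == 0))
  # fully excluded window is undefined
  excl <- array(FALSE, c(60, 60, 2)); excl[1:30, 1:30, 1] <- TRUE
  rm2 <- rms_map(v, exclusion = excl, window_side = 30)
  expect_true(is.na(rm2$values[1, 1, 1]))
  expect_false(anyNA(rm2$values[, , 2]))
  expect_error(rms_map(v, window_side = 100), "larger than the slice")
  expect_error(rms_map(v, window_side = 1), "at least 2")
})

test_that("window RMS matches the sampling statistics of i.i.d. noise", {
  set.seed(42)
  sigma <- 0.01
  v <- volume3d(array(rnorm(120 * 120 * 4, 0.5, sigma), c(120, 120, 4)), 3.1)
  rm <- rms_map(v, window_side = 30)
  vals <- rms_values(rm)
  expect_equal(length(vals), 16 * 4)
  expect_lt(abs(mean(vals) - sigma) / sigma, 0.03)
  # spread of the window SD ~ sigma / sqrt(2 (n - 1)) for n = 900
  expect_lt(abs(sd(vals) - sigma / sqrt(2 * 899)) / (sigma / sqrt(2 * 899)), 0.35)
})

test_that("RMS is offset-invariant and scales with grey rescaling", {
  set.seed(1)
  base <- array(rnorm(60 * 60 * 2, 0.5, 0.01), c(60, 60, 2))
  r1 <- rms_map(volume3d(base, 1), window_side = 30)
  r2 <- rms_map(volume3d(base + 0.2, 1), window_side = 30)
  r3 <- rms_map(volume3d(base * 3, 1), window_side = 30)
  expect_equal(r1$values, r2$values, tolerance = 1e-12)
  expect_equal(3 * r1$values, r3$values, tolerance = 1e-12)
})

test_that("sliding-stride maps agree with tiling at tile positions", {
  set.seed(2)
  v <- volume3d(array(rnorm(64 * 64 * 2, 0.5, 0.01), c(64, 64, 2)), 1)
  tl <- rms_map(v, window_side = 32, stride = "tile")
  sl <- rms_map(v, window_side = 32, stride = "slide")
  expect_equal(tl$values[1, 1, 1], sl$values[1, 1, 1], tolerance = 1e-10)
  expect_equal(tl$values[2, 2, 2], sl$values[33, 33, 2], tolerance = 1e-10)
})

test_that("class statistics pool training values and enforce sample minima", {
  st <- class_stats(list(healthy = rep(0.004, 40), metastatic = rep(0.01, 40)))
  expect_equal(st$mean, c(0.004, 0.01))
  expect_equal(st$sd, c(0, 0))
  expect_equal(st$lower, st$mean) # zero-SD band collapses to the mean
  expect_error(class_stats(list(healthy = rep(1, 40), metastatic = rep(1, 5))),
               "'metastatic' has only 5")
})

test_that("band classification matches the brute-force band rule", {
  mk_map <- function(vals) {
    structure(list(values = array(vals, c(length(vals), 1, 1)),
                   window_side = 30L, stride = "tile", voxel_size = 1),
              class = "rms_map")
  }
  st <- class_stats(list(healthy = rnorm(100, 0.004, 0.0004),
                         metastatic = rnorm(100, 0.010, 0.002)))
  vals <- c(st$mean[1], st$mean[2], 0.02, NA,
            seq(0.002, 0.015, length.out = 60))
  cls <- classify_tissue(mk_map(vals), st)
  # brute-force reference
  ref <- vapply(vals, function(x) {
    if (is.na(x)) return(4L)
    in1 <- x >= st$lower[1] && x <= st$upper[1]
    in2 <- x >= st$lower[2] && x <= st$upper[2]
    if (in1 && in2) {
      z1 <- abs(x - st$mean[1]) / st$sd[1]
      z2 <- abs(x - st$mean[2]) / st$sd[2]
      if (z1 < z2) 1L else if (z2 < z1) 2L else 3L
    } else if (in1) 1L else if (in2) 2L else 3L
  }, integer(1))
  expect_identical(as.integer(cls), ref)
  # value at the healthy mean is healthy; far outside both is unclassified
  expect_equal(as.integer(cls)[1], 1L)
  expect_equal(as.integer(cls)[3], 3L)
})

test_that("class fractions cover classified windows only and sum to 100", {
  lab <- structure(array(c(rep(1L, 30), rep(2L, 10), rep(3L, 60)), c(100, 1, 1)),
                   levels = c("healthy", "metastatic", "unclassified", "excluded"),
                   class = "tissue_class_map")
  f <- class_fractions(lab)
  expect_equal(unname(f), c(75, 25))
  expect_equal(sum(f), 100)
  all_h <- structure(array(1L, c(5, 1, 1)),
                     levels = c("healthy", "metastatic", "unclassified", "excluded"),
                     class = "tissue_class_map")
  expect_equal(unname(class_fractions(all_h)), c(100, 0))
  none <- structure(array(3L, c(5, 1, 1)),
                    levels = c("healthy", "metastatic", "unclassified", "excluded"),
                    class = "tissue_class_map")
  expect_error(class_fractions(none), "no classified")
})

test_that("the two condition textures are separable by their bands", {
  ctl <- lowres_phantom("control")
  met <- lowres_phantom("metastatic")
  rm_ctl <- rms_map(ctl$volume, exclusion = ctl$exclusion)
  rm_met <- rms_map(met$volume, exclusion = met$exclusion)
  st <- class_stats(list(healthy = rms_values(rm_ctl),
                         metastatic = rms_values(rm_met)))
  # healthy band upper edge below metastatic band lower edge
  expect_lt(st$upper[1], st$lower[2])
  # >= 80% correct self-classification among classified windows
  f_ctl <- class_fractions(classify_tissue(rm_ctl, st))
  f_met <- class_fractions(classify_tissue(rm_met, st))
  expect_gte(f_ctl["healthy"], 80)
  expect_gte(f_met["metastatic"], 80)
})
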