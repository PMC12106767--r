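# Frangi vesselness, small/large segmentation, diameter split, skeleton.

gaussian_tube <- function(dims = c(41, 41, 41), sd = 2, contrast = 0.2) {
  vol <- array(0.5, dims)
  c1 <- (dims[1] + 1) / 2
  c2 <- (dims[2] + 1) / 2
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    vol[i, j, ] <- 0.5 - contrast * exp(-((i - c1)^2 + (j - c2)^2) / (2 * sd^2))
  vol
}

test_that("vesselness is zero on constant volumes and rejects bad input", {
  v <- frangi_vesselness(volume3d(array(0.3, c(25, 25, 25)), 1),
                         frangi_params(scales = 1:3))
  expect_equal(max(v$data), 0)
  expect_error(frangi_vesselness(volume3d(array(0, c(10, 10, 10)), 1),
                                 frangi_params(scales = 1:10)), "twice the maximum scale")
  expect_error(frangi_params(scales = c(3, 2, 1)), "strictly increasing")
  expect_error(frangi_params(probability_threshold = 1.5), "\\(0, 1\\)")
})

test_that("the scale of maximum tube response matches the tube width", {
  vol <- gaussian_tube(sd = 2)
  ctr <- c(21, 21, 21)
  per_scale <- vapply(1:6, function(s)
    frangi_vesselness(volume3d(vol, 1), frangi_params(scales = s))$data[21, 21, 21],
    numeric(1))
  expect_equal(which.max(per_scale), 2) # argmax at the scale nearest the SD
  # centerline response dominates every off-tube voxel
  v <- frangi_vesselness(volume3d(vol, 1), frangi_params(scales = 1:6))
  expect_true(v$data[21, 21, 21] > max(v$data[1:8, 1:8, ]))
})

test_that("a tube outscores a ball of the same peak contrast (blob penalty)", {
  tube <- gaussian_tube(sd = 2)
  ball <- array(0.5, c(41, 41, 41))
  for (i in 1:41) for (j in 1:41) for (k in 1:41)
    ball[i, j, k] <- 0.5 - 0.2 * exp(-((i - 21)^2 + (j - 21)^2 + (k - 21)^2) / 8)
  vt <- frangi_vesselness(volume3d(tube, 1), frangi_params(scales = 1:6))
  vb <- frangi_vesselness(volume3d(ball, 1), frangi_params(scales = 1:6))
  expect_gt(vt$data[21, 21, 21], vb$data[21, 21, 21])
})

test_that("vesselness is invariant to grey offsets and 90-degree rotations", {
  vol <- gaussian_tube()
  p <- frangi_params(scales = 1:4)
  v1 <- frangi_vesselness(volume3d(vol, 1), p)
  v2 <- frangi_vesselness(volume3d(vol + 0.17, 1), p)
  expect_lt(max(abs(v1$data - v2$data)), 1e-3) # single-precision internals
  # tilted tube rotated about each axis: thresholded response agrees
  dims <- c(40L, 40L, 40L)
  mk <- tube_mask(dims, c(6, 7, 5) * 0.7, c(34, 31, 35) * 0.7, 1.5, 0.7)
  vol2 <- array(0.5, dims); vol2[mk] <- 0.435
  ref <- frangi_vesselness(volume3d(vol2, 0.7), frangi_params(scales = 1:5))
  n_ref <- sum(ref$data > 0.16)
  for (perm in list(c(2, 3, 1), c(3, 1, 2), c(2, 1, 3))) {
    rot <- frangi_vesselness(volume3d(aperm(vol2, perm), 0.7),
                             frangi_params(scales = 1:5))
    expect_lt(abs(sum(rot$data > 0.16) - n_ref) / n_ref, 0.05)
  }
})

test_that("small-vessel segmentation is a strict threshold of the response", {
  vol <- gaussian_tube()
  p <- frangi_params(scales = 1:4)
  v <- frangi_vesselness(volume3d(vol, 1), p)
  m <- segment_small_vessels(volume3d(vol, 1), p)
  expect_identical(m$data, v$data > p$probability_threshold)
  expect_equal(m$provenance, "frangi")
  # constant volume -> empty mask
  empty <- segment_small_vessels(volume3d(array(0.4, c(25, 25, 25)), 1),
                                 frangi_params(scales = 1:3))
  expect_equal(sum(empty$data), 0)
})

test_that("large-vessel thresholding honours polarity, range and filtering", {
  dims <- c(48L, 48L, 48L)
  vein <- tube_mask(dims, c(24.3, 24.2, 0), c(24.8, 24.6, 48), 20, 1)
  vol <- array(0.5, dims); vol[vein] <- 0.435
  m <- segment_large_vessels(volume3d(vol, 1), 0.47, min_diameter = 15)
  expect_gt(sum(m$data & vein) / sum(vein), 0.95) # vein recovered
  expect_equal(sum(m$data & !vein), 0)
  # all-background volume -> empty mask (threshold at the grey minimum)
  flat <- volume3d(array(seq(0.6, 0.7, length.out = 8000), c(20, 20, 20)), 1)
  expect_equal(sum(segment_large_vessels(flat, 0.6)$data), 0)
  # threshold below the global minimum -> warning + full mask by definition
  expect_warning(mfull <- segment_large_vessels(volume3d(array(0.5, c(20, 20, 20)), 1),
                                                0.6, min_diameter = 0),
                 "outside the volume grey range")
  expect_true(all(mfull$data))
})

test_that("merging masks is identity on empty, idempotent and additive", {
  d <- c(20L, 20L, 20L)
  x <- vessel_mask(tube_mask(d, c(5, 5, 2), c(5, 5, 18), 1.5, 1), 1, "frangi")
  e <- vessel_mask(array(FALSE, d), 1, "threshold")
  expect_identical(merge_masks(x, e)$data, x$data)
  expect_identical(merge_masks(x, x)$data, x$data)
  y <- vessel_mask(tube_mask(d, c(14, 14, 2), c(14, 14, 18), 1.5, 1), 1, "threshold")
  expect_equal(sum(merge_masks(x, y)$data), sum(x$data) + sum(y$data))
  expect_equal(merge_masks(x, y)$provenance, "merged")
})

test_that("the diameter split partitions exactly and matches per-tube truth", {
  d <- c(64L, 64L, 64L)
  thin <- tube_mask(d, c(10.2, 10.4, 1), c(10.8, 11.1, 64), 1.5, 1)
  thick <- tube_mask(d, c(40.3, 40.2, 1), c(40.9, 40.7, 64), 20, 1)
  m <- vessel_mask(thin | thick, 1, "merged")
  sp <- split_by_diameter(m, 15)
  # exact partition
  expect_identical(sp$small$data | sp$large$data, m$data)
  expect_equal(sum(sp$small$data & sp$large$data), 0)
  # >= 95% voxel agreement with the per-tube truth labels
  agree <- sum((sp$small$data & thin) | (sp$large$data & thick)) / sum(m$data)
  expect_gte(agree, 0.95)
  # all-thin mask with a 15 um cutoff stays entirely small
  sp2 <- split_by_diameter(vessel_mask(thin, 1, "merged"), 15)
  expect_equal(sum(sp2$large$data), 0)
  # cutoff 0: everything is "large" (positive diameter), small empty
  sp3 <- split_by_diameter(m, 0)
  expect_equal(sum(sp3$small$data), 0)
  expect_identical(sp3$large$data, m$data)
})

test_that("skeletons follow the branch/junction/endpoint classification", {
  # one straight tube: one branch, two end nodes
  d <- c(21L, 21L, 41L)
  tube <- tube_mask(d, c(10.2, 10.4, 1), c(10.6, 10.8, 41), 3, 1)
  g <- skeletonize(vessel_mask(tube, 1, "merged"))
  expect_equal(length(g$branches), 1)
  expect_equal(sum(g$nodes$degree == 1), 2)
  expect_lt(abs(g$branch_radius - 3), 0.8)
  # a T of two tubes: three branches, one junction cluster, three ends
  dT <- c(41L, 41L, 11L)
  bar <- tube_mask(dT, c(2, 20.4, 5.6), c(40, 20.6, 5.4), 2, 1)
  stem <- tube_mask(dT, c(20.4, 21, 5.5), c(20.6, 40, 5.5), 2, 1)
  gT <- skeletonize(vessel_mask(bar | stem, 1, "merged"))
  expect_equal(length(gT$branches), 3)
  expect_equal(sum(gT$nodes$degree == 1), 3)
  expect_gte(sum(gT$nodes$degree >= 3), 1)
  # single voxel: one degenerate branch of length 0
  one <- array(FALSE, c(9L, 9L, 9L)); one[5, 5, 5] <- TRUE
  g1 <- skeletonize(vessel_mask(one, 1, "merged"))
  expect_equal(length(g1$branches), 1)
  expect_equal(branch_lengths(g1)$lengths, 0)
  # empty mask: empty graph, not an error
  g0 <- skeletonize(vessel_mask(array(FALSE, c(5, 5, 5)), 1, "merged"))
  expect_equal(length(g0$branches), 0)
})

test_that("skeleton length matches the generating centerline within 10%", {
  d <- c(40L, 40L, 60L)
  p0 <- c(8, 9, 4); p1 <- c(30, 26, 55)
  tube <- tube_mask(d, p0, p1, 1.5, 1)
  g <- skeletonize(vessel_mask(tube, 1, "merged"))
  expect_equal(length(g$branches), 1)
  true_len <- sqrt(sum((p1 - p0)^2))
  # thinning erodes about one radius from each open end
  expect_lt(abs(branch_lengths(g)$lengths - true_len) / true_len, 0.10)
})

test_that("diameter distributions recover tube radii and bimodality", {
  d <- c(64L, 64L, 64L)
  thin <- tube_mask(d, c(10.2, 10.4, 1), c(10.8, 11.1, 64), 1.5, 1)
  g <- skeletonize(vessel_mask(thin, 1, "merged"))
  dd <- diameter_distribution(g)
  expect_equal(length(dd$diameters), 1)
  expect_lt(abs(dd$mode_um - 3), 0.8) # single tube: single bin near 2r
  thick <- tube_mask(d, c(40.3, 40.2, 1), c(40.9, 40.7, 64), 20, 1)
  g2 <- skeletonize(vessel_mask(thin | thick, 1, "merged"))
  dd2 <- diameter_distribution(g2)
  expect_equal(length(dd2$diameters), 2)
  expect_true(any(abs(dd2$diameters - 3) < 1) && any(abs(dd2$diameters - 40) < 4))
})

test_that("spur pruning removes sub-diameter spurs and re-merges the chain", {
  d <- c(41L, 41L, 11L)
  main <- tube_mask(d, c(2, 20.4, 5.6), c(40, 20.6, 5.4), 2, 1)
  spur <- tube_mask(d, c(20.4, 21, 5.5), c(20.6, 24, 5.5), 1.2, 1)
  g_raw <- skeletonize(vessel_mask(main | spur, 1, "merged"))
  g_pruned <- skeletonize(vessel_mask(main | spur, 1, "merged"), prune_um = 6)
  expect_gt(length(g_raw$branches), 1)
  expect_equal(length(g_pruned$branches), 1) # chain re-merged
})
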