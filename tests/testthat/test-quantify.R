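# VVF (regions, sliding cubes, radial shells), branch lengths, NND.

test_that("VVF follows its counting definition and degenerate cases error", {
  d <- c(10L, 10L, 10L)
  m <- array(FALSE, d); m[1:10] <- TRUE
  vmask <- vessel_mask(m, 1, "merged")
  expect_equal(vvf(vmask), 10 / 990)
  empty <- vessel_mask(array(FALSE, d), 1, "merged")
  expect_equal(vvf(empty), 0)
  expect_error(vvf(vmask, region = array(FALSE, d)), "empty")
  full <- vessel_mask(array(TRUE, d), 1, "merged")
  expect_error(vvf(full), "no tissue")
})

test_that("region VVF equals the tissue-weighted mean over any partition", {
  set.seed(9)
  d <- c(24L, 24L, 24L)
  m <- vessel_mask(array(runif(prod(d)) < 0.05, d), 1, "merged")
  whole <- vvf(m)
  for (rep in 1:5) {
    labels <- array(sample.int(3, prod(d), replace = TRUE), d)
    parts <- lapply(1:3, function(l) labels == l)
    vvfs <- vapply(parts, function(p) vvf(m, region = p), numeric(1))
    tiss <- vapply(parts, function(p) sum(p & !m$data), numeric(1))
    expect_equal(sum(vvfs * tiss) / sum(tiss), whole, tolerance = 1e-12)
  }
})

test_that("ROI sampling respects the requested physical volume", {
  rois <- sample_rois(c(256L, 256L, 256L), 0.7, 5e-3, 5L)
  expect_length(rois, 5)
  for (r in rois) {
    expect_lt(abs(r$volume_mm3 - 5e-3) / 5e-3, 0.02)
    expect_true(all(r$origin >= 1 & r$origin + r$shape - 1 <= 256))
  }
  expect_error(sample_rois(c(64L, 64L, 64L), 0.7, 5e-3), "does not fit")
})

test_that("cube-VVF maps concentrate at p/(1-p) for uniform random masks", {
  set.seed(4)
  d <- c(60L, 60L, 60L)
  p <- 0.02
  m <- vessel_mask(array(runif(prod(d)) < p, d), 1, "merged")
  vm <- vvf_map(m, 20)
  expect_lt(abs(vm$mean - p / (1 - p)), 0.002)
  expect_lt(max(abs(vm$map - p / (1 - p))), 0.012) # binomial concentration
  # empty mask -> all-zero map; cube must fit
  expect_equal(max(vvf_map(vessel_mask(array(FALSE, d), 1, "merged"), 20)$map), 0)
  expect_error(vvf_map(m, 100), "does not fit")
})

test_that("radial profiles are flat under uniform density with growing axes", {
  set.seed(8)
  d <- c(80L, 80L, 80L)
  co <- as.matrix(expand.grid(1:80, 1:80, 1:80))
  nod <- array(rowSums(sweep(co, 2, c(40.5, 40.5, 40.5))^2) <= 100, d)
  p <- 0.03
  m <- vessel_mask(array(runif(prod(d)) < p, d) & !nod, 1, "merged")
  rp <- radial_vvf(m, nod, shell_width = 5, n_shells = 5)
  expect_true(all(abs(rp$vvf - p / (1 - p)) < 0.005))
  expect_true(all(diff(rp$axis_length_um) > 0)) # strictly increasing
  # sphere of radius r: shell-0 outer axis near r + w
  expect_lt(abs(rp$axis_length_um[1] - 15) / 15, 0.07)
  # empty vessel mask -> all-zero profile
  rp0 <- radial_vvf(vessel_mask(array(FALSE, d), 1, "merged"), nod, 5, 3)
  expect_true(all(rp0$vvf == 0))
  expect_error(radial_vvf(m, array(FALSE, d), 5, 3), "empty")
})

test_that("branch lengths: collinear paths are exact, arcs within 5%", {
  h <- 0.7
  line <- cbind(5:44, 7L, 7L) # 40 collinear voxels
  expect_equal(hepavasc:::branch_arc_length(line, h), 39 * h, tolerance = 1e-9)
  # digital quarter circle of radius 20 um
  r <- 20 / h
  th <- seq(0, pi / 2, length.out = 2000)
  arc <- unique(round(cbind(30 + r * cos(th), 30 + r * sin(th), 10)))
  len <- hepavasc:::branch_arc_length(arc, h)
  expect_lt(abs(len - 10 * pi) / (10 * pi), 0.05)
})

test_that("branch-length histograms are normalized and rotation-stable", {
  # tubes long enough that direction-dependent skeleton end erosion (a few
  # voxels per end) stays well under the 2% bound
  d <- c(100L, 100L, 100L)
  tubes <- tube_mask(d, c(8, 10, 5), c(60, 50, 95), 1.5, 1) |
    tube_mask(d, c(70, 15, 10), c(30, 80, 90), 1.5, 1) |
    tube_mask(d, c(15, 75, 12), c(85, 35, 88), 1.5, 1)
  g <- skeletonize(vessel_mask(tubes, 1, "truth"), prune_um = 3)
  bl <- branch_lengths(g)
  expect_equal(sum(bl$histogram$frequency), 1, tolerance = 1e-12)
  # rotate the volume by 90 degrees about each axis: total length within 2%
  for (perm in list(c(3, 1, 2), c(2, 3, 1))) {
    rot <- vessel_mask(aperm(tubes, perm), 1, "truth")
    bl_rot <- branch_lengths(skeletonize(rot, prune_um = 3))
    expect_lt(abs(sum(bl_rot$lengths) - sum(bl$lengths)) / sum(bl$lengths),
              0.02)
  }
})

test_that("NND: parallel tubes give the axis separation, collinear give d", {
  d <- c(40L, 40L, 40L)
  two <- tube_mask(d, c(10, 10, 5), c(10, 10, 35), 1.5, 1) |
    tube_mask(d, c(22, 10, 5), c(22, 10, 35), 1.5, 1)
  g <- skeletonize(vessel_mask(two, 1, "merged"))
  nn <- nearest_neighbour_distances(g)
  expect_equal(unname(nn$nnd), c(12, 12), tolerance = 0.1)
  expect_equal(nn$weighted_mean, 12, tolerance = 0.1)
  # three collinear equal tubes with equal midpoint spacing d
  d2 <- c(20L, 20L, 100L)
  three <- tube_mask(d2, c(10, 10, 5), c(10, 10, 25), 1.5, 1) |
    tube_mask(d2, c(10, 10, 35), c(10, 10, 55), 1.5, 1) |
    tube_mask(d2, c(10, 10, 65), c(10, 10, 85), 1.5, 1)
  g3 <- skeletonize(vessel_mask(three, 1, "merged"))
  nn3 <- nearest_neighbour_distances(g3)
  expect_equal(length(nn3$nnd), 3)
  expect_true(all(abs(nn3$nnd - 30) < 1.5))
  expect_error(nearest_neighbour_distances(skeletonize(
    vessel_mask(tube_mask(d, c(10, 10, 5), c(10, 10, 35), 1.5, 1), 1, "merged"))),
    "at least 2")
})

test_that("NND is invariant under global translation of the mask", {
  d <- c(48L, 48L, 48L)
  base <- tube_mask(d, c(10, 10, 5), c(10, 12, 35), 1.5, 1) |
    tube_mask(d, c(25, 11, 6), c(24, 9, 36), 1.5, 1) |
    tube_mask(d, c(10, 30, 8), c(13, 28, 38), 1.5, 1)
  shift <- array(FALSE, d)
  shift[7:48, 5:48, 9:48] <- base[1:42, 1:44, 1:40]
  n1 <- nearest_neighbour_distances(skeletonize(vessel_mask(base, 1, "merged")))
  n2 <- nearest_neighbour_distances(skeletonize(vessel_mask(shift, 1, "merged")))
  expect_equal(sort(n1$nnd), sort(n2$nnd), tolerance = 1e-9)
})
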