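test_that("distance examples: 3-4-5 triangle and containment zero", {
  m <- matrix(FALSE, 10, 10); m[1, 1] <- TRUE
  cs <- as_cell_set(4, 5, c(10, 10))  # offset (3, 4) from the positive pixel
  d <- nearest_structure_distances(cs, region_mask(m), pixel_scale = 1)
  expect_equal(d$per_cell_um, 5)
  expect_equal(d$mean_um, 5)
  # centroid whose containing pixel is positive: exactly zero
  m2 <- matrix(FALSE, 10, 10); m2[4:6, 4:6] <- TRUE
  cs2 <- as_cell_set(5.2, 4.8, c(10, 10))
  d2 <- nearest_structure_distances(cs2, region_mask(m2), pixel_scale = 1)
  expect_identical(d2$per_cell_um, 0)
})

test_that("distances match the exhaustive brute-force oracle", {
  set.seed(21)
  for (i in 1:20) {
    H <- sample(16:128, 1); W <- sample(16:128, 1)
    m <- random_mask(H, W, p = runif(1, 0.005, 0.2))
    n <- sample(1:30, 1)
    rows <- runif(n, 0.5, H + 0.5); cols <- runif(n, 0.5, W + 0.5)
    cs <- as_cell_set(rows, cols, c(H, W))
    got <- nearest_structure_distances(cs, region_mask(m), pixel_scale = 1.98)
    want <- oracle_nearest_distance(rows, cols, m) / 1.98
    expect_equal(got$per_cell_um, want, tolerance = 1e-12)
  }
})

test_that("empty mask errors; empty cell set is flagged, not an error", {
  cs <- as_cell_set(2, 2, c(8, 8))
  expect_error(
    nearest_structure_distances(cs, region_mask(matrix(FALSE, 8, 8)), 1),
    "no positive")
  empty <- as_cell_set(numeric(), numeric(), c(8, 8))
  m <- matrix(FALSE, 8, 8); m[1, 1] <- TRUE
  d <- nearest_structure_distances(empty, region_mask(m), 1)
  expect_true(d$empty)
  expect_true(is.na(d$mean_um))
})

test_that("distance binning matches direct counts and flags bad edges", {
  expect_equal(bin_distances(c(5, 15, 25, 40), c(0, 20)), c(0.5, 0.5))
  expect_equal(bin_distances(rep(0, 4), c(0, 20)), c(1, 0))
  set.seed(3)
  d <- rexp(1000, 1 / 25)
  edges <- c(0, 10, 20, 50)
  got <- bin_distances(d, edges)
  want <- c(mean(d < 10), mean(d >= 10 & d < 20), mean(d >= 20 & d < 50),
            mean(d >= 50))
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(sum(got), 1, tolerance = 1e-12)
  expect_error(bin_distances(d, c(10, 20)), "start at 0")
  expect_error(bin_distances(d, c(0, 20, 20)), "strictly increasing")
  expect_error(bin_distances(numeric(), c(0, 20)), "empty")
})

test_that("grid occupancy matches the double-loop oracle in all modes", {
  set.seed(31)
  for (i in 1:15) {
    H <- sample(60:300, 1); W <- sample(60:300, 1)
    side <- sample(c(25, 50, 100), 1)
    n <- sample(0:60, 1)
    rows <- runif(n, 0.5, H + 0.5); cols <- runif(n, 0.5, W + 0.5)
    m <- matrix(runif(H * W) < runif(1, 0.2, 0.7), H, W)
    cs <- as_cell_set(rows, cols, c(H, W))
    rmask <- region_mask(m)
    for (mode in c("centroid", "pixel_fraction", "either")) {
      got <- grid_occupancy(cs, mask = rmask, field_shape = c(H, W),
                            grid_side_px = side, mode = mode)
      want <- oracle_grid_occupancy(rows, cols, m, H, W, side, mode)
      expect_equal(got$n_grids, want$n_grids)
      expect_equal(got$n_positive, want$n_positive,
                   label = sprintf("mode %s, instance %d", mode, i))
    }
  }
})

test_that("grid occupancy honors mode contracts and edge cases", {
  # one centroid per grid cell -> full occupancy
  ctr <- expand.grid(row = c(50, 150), col = c(50, 150))
  cs <- as_cell_set(ctr$row, ctr$col, c(200, 200))
  g <- grid_occupancy(cs, grid_side_px = 100)
  expect_equal(g$n_positive, 4L)
  expect_equal(g$occupancy_fraction, 1)
  # no cells
  g0 <- grid_occupancy(as_cell_set(numeric(), numeric(), c(200, 200)),
                       grid_side_px = 100)
  expect_equal(g0$n_positive, 0L)
  # partial grids included
  g2 <- grid_occupancy(as_cell_set(1, 1, c(250, 130)), grid_side_px = 100)
  expect_equal(g2$n_grids, 3L * 2L)
  # mask required when mode uses pixels
  expect_error(grid_occupancy(cs, grid_side_px = 100, mode = "pixel_fraction"),
               "mask")
})

test_that("grid occupancy is order-invariant and monotone in cell count", {
  set.seed(12)
  rows <- runif(40, 0.5, 200.5); cols <- runif(40, 0.5, 200.5)
  a <- grid_occupancy(as_cell_set(rows, cols, c(200, 200)), grid_side_px = 50)
  perm <- sample(40)
  b <- grid_occupancy(as_cell_set(rows[perm], cols[perm], c(200, 200)),
                      grid_side_px = 50)
  expect_equal(a$n_positive, b$n_positive)
  occ <- vapply(c(5, 10, 20, 40), function(k) {
    grid_occupancy(as_cell_set(rows[1:k], cols[1:k], c(200, 200)),
                   grid_side_px = 50)$n_positive
  }, numeric(1))
  expect_true(all(diff(occ) >= 0))
})

test_that("distances are translation invariant and monotone under dilation", {
  set.seed(55)
  H <- 80; W <- 80
  m <- matrix(FALSE, H, W); m[30:40, 20:25] <- TRUE
  rows <- runif(10, 5, 70); cols <- runif(10, 5, 70)
  base <- nearest_structure_distances(as_cell_set(rows, cols, c(H, W)),
                                      region_mask(m), 1)$per_cell_um
  # shift everything by (7, 9)
  m2 <- matrix(FALSE, H + 10, W + 10)
  m2[30:40 + 7, 20:25 + 9] <- TRUE
  shifted <- nearest_structure_distances(
    as_cell_set(rows + 7, cols + 9, c(H + 10, W + 10)),
    region_mask(m2), 1)$per_cell_um
  expect_equal(shifted, base, tolerance = 1e-10)
  # dilation: distances can only shrink
  md <- m
  md[29:41, 19:26] <- TRUE
  dil <- nearest_structure_distances(as_cell_set(rows, cols, c(H, W)),
                                     region_mask(md), 1)$per_cell_um
  expect_true(all(dil <= base + 1e-12))
})

test_that("cell density uses physical field area", {
  side <- 1.98e3  # 1 mm at 1.98 px/um
  cs <- as_cell_set(100, 100, c(side, side))
  expect_equal(cell_density(cs, pixel_scale = 1.98), 1)
  cs0 <- as_cell_set(numeric(), numeric(), c(side, side))
  expect_equal(cell_density(cs0, pixel_scale = 1.98), 0)
})

test_that("generator density estimate is within the Poisson sampling bound", {
  n <- 400
  shape <- c(1024, 1024)
  g <- generate_field(field_spec(shape = shape, n_cells = n, seed = 17))
  thr <- 100 + 3 * 20
  cs <- segment_cells(g$field, "CD3", segmentation_params(thr))
  area_mm2 <- prod(shape) / 1.98^2 / 1e6
  lambda <- n / area_mm2
  est <- cell_density(cs, pixel_scale = 1.98)
  expect_lt(abs(est - lambda), 3 * sqrt(lambda * area_mm2) / area_mm2)
})

test_that("rich/poor split uses the mean cutoff with ties to poor", {
  sp <- split_rich_poor(c(0.1, 0.3), ids = c("a", "b"))
  expect_equal(sp$cutoff, 0.2)
  expect_equal(sp$rich, "b")
  expect_equal(sp$poor, "a")
  tie <- split_rich_poor(c(0.2, 0.2, 0.2))
  expect_length(tie$rich, 0)
  expect_length(tie$poor, 3)
  set.seed(9)
  fr <- runif(20)
  sp2 <- split_rich_poor(fr)
  expect_setequal(sp2$rich, which(fr > mean(fr)))
  expect_setequal(sp2$poor, which(fr <= mean(fr)))
  expect_error(split_rich_poor(0.5), ">= 2")
})
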