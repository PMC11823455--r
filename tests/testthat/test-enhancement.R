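# Percentile backgrounds, enhancements, and the decile-selection procedure.

test_that("background matches the sort-and-interpolate order-statistic oracle", {
  g <- manual_grid(matrix(1:100, 10, 10))
  expect_equal(compute_background(g, 10)$value, 10.9)
  set.seed(31)
  for (rep in 1:5) {
    vals <- matrix(rlnorm(15 * 13, log(5e15), 0.6), 15, 13)
    g <- manual_grid(vals)
    for (p in c(10, 25, 50, 90))
      expect_equal(compute_background(g, p)$value,
                   sort_interp_pctl(as.vector(vals), p))
  }
})

test_that("background of a constant grid is that constant, all cells flagged", {
  B <- 3.8e15
  g <- manual_grid(matrix(B, 8, 8))
  bg <- compute_background(g, 10)
  expect_equal(bg$value, B)
  enh <- compute_enhancement(g, bg)
  expect_false(any(enh$enhanced))
  expect_true(all(is.na(enh$delta)))
})

test_that("enhanced-cell fraction complements the background percentile", {
  g <- manual_grid(matrix(1:100, 10, 10))
  bg <- compute_background(g, 10)
  enh <- compute_enhancement(g, bg)
  expect_equal(sum(enh$enhanced), 90L)
  expect_equal(enhanced_fraction(enh, g), 0.90)
  # continuous values: fraction within one cell's mass of 1 - p/100
  set.seed(7)
  g2 <- manual_grid(matrix(rnorm(400, 5e15, 1e15), 20, 20))
  for (p in c(10, 30, 70)) {
    f <- enhanced_fraction(compute_enhancement(g2, compute_background(g2, p)), g2)
    expect_lt(abs(f - (1 - p / 100)), 1 / 400 + 1e-12)
  }
})

test_that("deltas are invariant to constant column shifts, equivariant to scale", {
  set.seed(8)
  vals <- matrix(rlnorm(144, log(4e15), 0.5), 12, 12)
  g <- manual_grid(vals)
  enh <- compute_enhancement(g, compute_background(g, 10))

  c_shift <- 2.2e15
  g2 <- manual_grid(vals + c_shift)
  bg2 <- compute_background(g2, 10)
  expect_equal(bg2$value, compute_background(g, 10)$value + c_shift)
  enh2 <- compute_enhancement(g2, bg2)
  expect_identical(enh$enhanced, enh2$enhanced)
  expect_equal(enh$delta, enh2$delta)

  s <- 3.7
  g3 <- manual_grid(vals * s)
  bg3 <- compute_background(g3, 10)
  expect_equal(bg3$value, s * compute_background(g, 10)$value)
  enh3 <- compute_enhancement(g3, bg3)
  expect_equal(enh3$delta, enh$delta * s)
})

test_that("background demands enough valid cells and a finite value", {
  g <- manual_grid(matrix(1:9, 3, 3))
  expect_error(compute_background(g, 10), "fewer than 10")
  g2 <- manual_grid(matrix(1:100, 10, 10))
  expect_error(compute_enhancement(g2, NaN), "finite")
})

test_that("decile selection accepts low deciles on a proximity-structured scene", {
  scene <- generate_scene(tiny_scene_config())
  met <- generate_meteorology(8, seed = 5)
  px <- simulate_columns(scene, met, pixels_per_day = 120, noise_cv = 0.05,
                         seed = 6)
  px <- filter_pixels(px, max_cloud = 0.3)
  gs <- grid_spec_for_bounds(scene$config$region_bounds, 0.01)
  grid <- oversample(px, gs, k = 2)
  sel <- select_background_decile(grid, scene$blockgroups,
                                  scene$demographics,
                                  reference = "white")
  expect_true(sel$percentile %in% seq(10, 90, 10))
  # the chosen decile is equivalent for every group; 10 always examined
  tab <- sel$table
  chosen <- tab[tab$decile == sel$percentile, ]
  expect_true(all(chosen$equivalent))
  expect_true(all(seq(10, 90, 10) %in% tab$decile))
})

test_that("population mass concentrated in low-column block groups forces decile 10", {
  # 8 west-east column strips over a 40x40 grid. Strip 1 holds the lowest
  # 12.5% of columns (so the 10th percentile falls inside it); strip 2 -- the
  # reference group's home -- is constant at 1e15, i.e. entirely between the
  # 10th and 20th percentiles; strips 5-8 hold the minority group at high
  # columns. At decile 10 the background sits below every populated cell and
  # subtraction is a pure shift (equivalent); at decile 20+ the reference
  # strip drops below background entirely, changing the underlying population
  # distribution and breaking equivalence.
  n <- 40
  vals <- matrix(NA_real_, n, n)
  vals[, 1:5] <- rep(seq(1e14, 9e14, length.out = 5), each = n)
  vals[, 6:10] <- 1e15
  vals[, 11:20] <- rep(seq(2e15, 4e15, length.out = 10), each = n)
  vals[, 21:40] <- rep(seq(5e15, 2e16, length.out = 20), each = n)
  g <- manual_grid(vals, lat0 = 35, lon0 = -78, spacing = 0.01)
  sp <- 0.01
  lon_edges <- -78 - sp / 2 + sp * seq(0, n, by = 5)
  polys <- lapply(seq_len(8), function(j)
    cbind(lon = c(lon_edges[j], lon_edges[j + 1], lon_edges[j + 1], lon_edges[j]),
          lat = 35 - sp / 2 + c(0, 0, n * sp, n * sp)))
  bgs <- blockgroup_set(sprintf("bg_%d", 1:8), polys)
  dem <- rbind(
    data.frame(blockgroup_id = bgs$id, group = "minority",
               population = ifelse(1:8 >= 5, 1000, 0)),
    data.frame(blockgroup_id = bgs$id, group = "reference",
               population = ifelse(1:8 == 2, 1000, 0)),
    data.frame(blockgroup_id = bgs$id, group = "other", population = 100))
  sel <- suppressWarnings(
    select_background_decile(g, bgs, dem, groups = "minority",
                             reference = "reference"))
  expect_equal(sel$percentile, 10)
  high <- sel$table[sel$table$decile > 10, ]
  expect_false(any(high$equivalent))
  expect_true(all(sel$table$equivalent[sel$table$decile == 10]))
})
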