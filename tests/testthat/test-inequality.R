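# Area-weighted block-group aggregation and population-weighted inequality.

test_that("area-weighted mean reproduces exact geometric cases", {
  sp <- 0.01
  enh <- manual_enhancement(matrix(7, 5, 5), spacing = sp)
  g <- enh$grid
  # polygon strictly inside one cell
  ring <- rect_poly(g$lon[3] - sp / 4, g$lon[3] + sp / 4,
                    g$lat[3] - sp / 4, g$lat[3] + sp / 4)
  r <- area_weighted_mean(enh, ring)
  expect_equal(r$value, 7)
  expect_equal(r$coverage, 1, tolerance = 1e-10)

  # uniform field: any polygon returns the constant
  ring2 <- cbind(lon = c(g$lon[2], g$lon[4], g$lon[3]),
                 lat = c(g$lat[2], g$lat[2], g$lat[4]))  # a triangle
  expect_equal(area_weighted_mean(enh, ring2)$value, 7)

  # polygon split 50/50 by area across deltas 1 and 3 -> 2
  vals <- matrix(3, 3, 4)
  vals[, 1:2] <- 1
  enh3 <- manual_enhancement(vals, spacing = sp)
  g3 <- enh3$grid
  # rectangle spanning equal areas either side of the cell-2|cell-3 boundary
  ring3 <- rect_poly(g3$lon[2], g3$lon[3], g3$lat[2] - sp / 4, g3$lat[2] + sp / 4)
  r3 <- area_weighted_mean(enh3, ring3)
  expect_equal(r3$value, 2, tolerance = 1e-9)
})

test_that("zero coverage yields an undefined value", {
  delta <- matrix(NA_real_, 4, 4)   # nothing enhanced
  enh <- manual_enhancement(delta)
  ring <- rect_poly(enh$grid$lon[1], enh$grid$lon[3],
                    enh$grid$lat[1], enh$grid$lat[3])
  r <- area_weighted_mean(enh, ring)
  expect_true(is.na(r$value))
  expect_equal(r$coverage, 0)
})

test_that("intersection and cell-centre aggregation agree on coarse polygons", {
  set.seed(12)
  vals <- matrix(rlnorm(900, log(2e15), 0.4), 30, 30)
  enh <- manual_enhancement(vals)
  g <- enh$grid
  ring <- rect_poly(g$lon[3] - 0.005, g$lon[20] + 0.005,
                    g$lat[5] - 0.005, g$lat[25] + 0.005)
  exact <- area_weighted_mean(enh, ring, method = "intersection")
  fast <- area_weighted_mean(enh, ring, method = "centers")
  expect_equal(fast$value, exact$value, tolerance = 1e-6)
})

test_that("population-weighted mean follows the weighted formulas", {
  tab <- data.frame(blockgroup_id = c("a", "b", "c"),
                    delta = c(1e15, 2e15, 3e15),
                    coverage = 1, has_enhancement = TRUE)
  class(tab) <- c("nh3_bgtable", "data.frame")
  dem <- data.frame(blockgroup_id = c("a", "b", "c"), group = "g",
                    population = c(100, 200, 700))
  r <- population_weighted_mean(tab, dem, "g", subset = c("a", "b", "c"))
  expect_equal(r$mean, 2.6e15)
  # independent weighted-sem evaluation
  w <- c(0.1, 0.2, 0.7)
  expect_equal(r$sem, sqrt(sum(w^2 * (c(1e15, 2e15, 3e15) - 2.6e15)^2)))

  # uniform populations reduce to the arithmetic mean
  dem$population <- 50
  expect_equal(population_weighted_mean(tab, dem, "g", subset = dem$blockgroup_id)$mean,
               2e15)
  # a single block group has its own value and zero sem
  r1 <- population_weighted_mean(tab, dem, "g", subset = "b")
  expect_equal(r1$mean, 2e15)
  expect_equal(r1$sem, 0)
  # population weights are invariant to uniform population scaling
  dem2 <- dem; dem2$population <- dem2$population * 13
  ra <- population_weighted_mean(tab, dem2, "g", subset = dem$blockgroup_id)
  rb <- population_weighted_mean(tab, dem, "g", subset = dem$blockgroup_id)
  expect_equal(ra$mean, rb$mean)
  expect_equal(ra$sem, rb$sem)
})

test_that("eligibility keeps block groups at or above the mean share", {
  dem <- rbind(
    data.frame(blockgroup_id = paste0("bg", 1:4), group = "g",
               population = c(10, 20, 30, 40)),
    data.frame(blockgroup_id = paste0("bg", 1:4), group = "ref",
               population = c(90, 80, 70, 60)))
  el <- eligible_subset(dem, "g")
  expect_setequal(el, c("bg3", "bg4"))      # shares 30%, 40% vs mean 25%
  expect_equal(attr(el, "threshold"), 0.25)
  # all-equal shares: everything eligible
  dem$population <- rep(c(50, 50), each = 4)
  expect_setequal(eligible_subset(dem, "g"), paste0("bg", 1:4))
  # count basis
  dem2 <- rbind(
    data.frame(blockgroup_id = paste0("bg", 1:4), group = "g",
               population = c(10, 20, 30, 40)))
  expect_setequal(eligible_subset(dem2, "g", basis = "count"), c("bg3", "bg4"))
  expect_error(eligible_subset(dem2, "nope"), "unknown group")
})

test_that("inequality arithmetic and symmetry behave as defined", {
  tab <- data.frame(blockgroup_id = paste0("bg", 1:4),
                    delta = c(2e15, 3e15, 2e15, 3e15),
                    coverage = 1, has_enhancement = TRUE)
  class(tab) <- c("nh3_bgtable", "data.frame")
  # identical distributions -> zero inequality
  dem <- rbind(
    data.frame(blockgroup_id = paste0("bg", 1:4), group = "g",
               population = c(1, 2, 1, 2) * 100),
    data.frame(blockgroup_id = paste0("bg", 1:4), group = "ref",
               population = c(1, 2, 1, 2) * 300))
  r <- compute_inequality(tab, dem, "g", "ref")
  expect_equal(r$absolute, 0)
  expect_equal(r$relative, 0)

  # hand-computed gap: pw_g 2.6e15 vs pw_ref 2.0e15 -> +6e14, +30%
  tab2 <- data.frame(blockgroup_id = c("a", "b", "c", "d"),
                     delta = c(1e15, 2e15, 3e15, 2e15),
                     coverage = 1, has_enhancement = TRUE)
  class(tab2) <- c("nh3_bgtable", "data.frame")
  dem2 <- rbind(
    data.frame(blockgroup_id = c("a", "b", "c"), group = "g",
               population = c(100, 200, 700)),
    data.frame(blockgroup_id = "d", group = "ref", population = 500))
  r2 <- compute_inequality(tab2, dem2, "g", "ref",
                           subset_group = c("a", "b", "c"), subset_ref = "d")
  expect_equal(r2$absolute, 6e14)
  expect_equal(r2$relative, 30)
  expect_equal(r2$sem_abs, sqrt(r2$sem_abs^2))   # non-negative by construction

  # absolute inequality is invariant to adding a constant to all values;
  # relative inequality is not
  tab3 <- tab2; tab3$delta <- tab3$delta + 5e14
  r3 <- compute_inequality(tab3, dem2, "g", "ref",
                           subset_group = c("a", "b", "c"), subset_ref = "d")
  expect_equal(r3$absolute, r2$absolute)
  expect_false(isTRUE(all.equal(r3$relative, r2$relative)))
})

test_that("trend decomposition separates column and composition effects", {
  tabs <- lapply(c(1, 2), function(s) {
    t <- data.frame(blockgroup_id = paste0("bg", 1:4),
                    delta = s * c(1e15, 2e15, 3e15, 4e15),
                    coverage = 1, has_enhancement = TRUE)
    class(t) <- c("nh3_bgtable", "data.frame")
    t
  })
  names(tabs) <- c("p1", "p2")
  dem_a <- rbind(
    data.frame(blockgroup_id = paste0("bg", 1:4), group = "g",
               population = c(10, 10, 40, 40)),
    data.frame(blockgroup_id = paste0("bg", 1:4), group = "ref",
               population = c(40, 40, 10, 10)))
  # identical vintages -> coinciding series
  r_same <- decompose_trend(tabs, dem_a, dem_a, reference = "ref")
  a <- r_same[r_same$vintage == "a", ]
  b <- r_same[r_same$vintage == "b", ]
  expect_equal(a$absolute, b$absolute)
  expect_equal(a$relative, b$relative)

  # uniformly doubled counts leave inequalities unchanged
  dem_b <- dem_a; dem_b$population <- dem_b$population * 2
  r_dbl <- decompose_trend(tabs, dem_a, dem_b, reference = "ref")
  expect_equal(r_dbl$absolute[r_dbl$vintage == "a"],
               r_dbl$absolute[r_dbl$vintage == "b"])

  # spatially shifted composition changes the sign as a two-run oracle says
  dem_c <- dem_a
  dem_c$population[dem_c$group == "g"] <- c(40, 40, 10, 10)
  dem_c$population[dem_c$group == "ref"] <- c(10, 10, 40, 40)
  r_shift <- decompose_trend(tabs, dem_a, dem_c, reference = "ref")
  direct_a <- inequality_table(tabs$p1, dem_a, reference = "ref")
  direct_c <- inequality_table(tabs$p1, dem_c, reference = "ref")
  got <- r_shift[r_shift$period == "p1", ]
  expect_equal(got$absolute[got$vintage == "a"], direct_a$absolute)
  expect_equal(got$absolute[got$vintage == "b"], direct_c$absolute)
  expect_equal(sign(got$absolute[got$vintage == "a"]),
               -sign(got$absolute[got$vintage == "b"]))

  expect_error(decompose_trend(tabs[1], dem_a, dem_a, reference = "ref"))
  dem_bad <- dem_a; dem_bad$blockgroup_id[1] <- "zz"
  expect_error(decompose_trend(tabs, dem_a, dem_bad, reference = "ref"),
               "different block-group ids")
})
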