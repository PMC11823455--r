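# Median-split stratification, facility distances, decay profiles and the
# SNR-based spatial extent.

test_that("median split partitions days with the at-median tie rule", {
  met <- data.frame(date = as.Date("2016-04-01") + 0:3,
                    morning_wind = c(1, 2, 3, 4), morning_temp = c(20, 22, 26, 28))
  s <- median_split(met, "wind")
  expect_setequal(s$date[s$stratum == "calm"], met$date[1:2])
  expect_setequal(s$date[s$stratum == "windy"], met$date[3:4])
  expect_equal(attr(s, "median"), 2.5)

  # repeated values: at-or-below-median days all go to the lower stratum
  met2 <- data.frame(date = met$date, morning_wind = c(1, 1, 5, 5),
                     morning_temp = 20 + c(1, 1, 5, 5))
  s2 <- median_split(met2, "wind")
  expect_equal(sum(s2$stratum == "calm"), 2)
  expect_equal(sum(s2$stratum == "windy"), 2)
  s2t <- median_split(met2, "temp")
  expect_setequal(unique(s2t$stratum), c("cool", "hot"))

  expect_error(median_split(met[1, ], "wind"), "at least 2")
  met3 <- met; met3$morning_wind <- 3
  expect_error(median_split(met3, "wind"), "identical")
})

test_that("nearest-facility distances agree with an independent great-circle oracle", {
  fac <- data.frame(id = c("f1", "f2", "f3"),
                    lat = c(35.0, 35.3, 34.9), lon = c(-77.9, -78.2, -78.4),
                    type = c("swine", "swine", "other"))
  pts <- data.frame(id = c("p1", "p2"), lat = c(35.0, 35.25),
                    lon = c(-78.0, -78.2))
  d <- nearest_facility_distance(pts, fac)
  # p1 vs f1: 0.1 degrees of longitude at 35 N is about 9.1 km
  expect_equal(unname(d["p1"]), 9.1, tolerance = 0.01)
  oracle <- sapply(seq_len(nrow(pts)), function(i)
    min(slc_distance_km(pts$lon[i], pts$lat[i], fac$lon[1:2], fac$lat[1:2])))
  expect_equal(unname(d), oracle, tolerance = 1e-6)

  # a coincident facility gives distance zero
  pts0 <- data.frame(id = "x", lat = 35.3, lon = -78.2)
  expect_equal(unname(nearest_facility_distance(pts0, fac)), 0)

  # adding a facility never increases any distance
  fac2 <- rbind(fac, data.frame(id = "f4", lat = 34.0, lon = -79.0,
                                type = "swine"))
  expect_true(all(nearest_facility_distance(pts, fac2) <= d))

  # the type filter can empty the set
  expect_error(nearest_facility_distance(pts, fac[3, ], "swine"),
               "no facilities")
})

make_bg_table <- function(deltas) {
  t <- data.frame(blockgroup_id = sprintf("bg%02d", seq_along(deltas)),
                  delta = deltas, coverage = 1,
                  has_enhancement = !is.na(deltas))
  class(t) <- c("nh3_bgtable", "data.frame")
  t
}

test_that("distance profile bins means and sems correctly", {
  # deltas decay exponentially with 5 km e-folding; far-field noise known
  set.seed(21)
  dist <- runif(120, 0, 20)
  delta <- 1e16 * exp(-dist / 5)
  tab <- make_bg_table(delta)
  d <- setNames(dist, tab$blockgroup_id)
  prof <- distance_profile(tab, d, bin_width_km = 1)
  for (b in c(1, 5, 12)) {
    sel <- dist >= prof$bin_lo[b] & dist < prof$bin_hi[b]
    if (!any(sel)) next
    expect_equal(prof$mean[b], mean(delta[sel]))
    if (sum(sel) > 1)
      expect_equal(prof$sem[b], sd(delta[sel]) / sqrt(sum(sel)))
  }
  band <- dist >= 15 & dist < 20
  expect_equal(attr(prof, "noise_2sigma"), 2 * sd(delta[band]))

  # block-group order is irrelevant
  ord <- sample(nrow(tab))
  prof2 <- distance_profile(tab[ord, ], d, bin_width_km = 1)
  expect_equal(as.data.frame(prof2), as.data.frame(prof))

  # empty noise band is an error unless a noise level is supplied
  near <- dist < 12
  expect_error(distance_profile(tab[near, ], d[near], 1), "noise band")
  prof3 <- distance_profile(tab[near, ], d[near], 1, noise_2sigma = 1e14)
  expect_equal(attr(prof3, "noise_2sigma"), 1e14)
})

test_that("spatial extent scans contiguously from the source", {
  prof <- data.frame(bin_lo = 0:3, bin_hi = 1:4,
                     mean = c(10, 6, 3, 1) * 1e14, n = 5)
  # threshold 2 x noise: bins 10,6,3 pass at noise 1e14, bin 1 fails
  expect_equal(spatial_extent(prof, noise_2sigma = 1e14), 3)
  # doubling signal and noise together leaves the extent unchanged
  prof2 <- prof; prof2$mean <- prof2$mean * 2
  expect_equal(spatial_extent(prof2, noise_2sigma = 2e14), 3)
  # all bins below threshold -> 0
  expect_equal(spatial_extent(prof, noise_2sigma = 1e15), 0)
  # non-contiguous exceedances beyond a failing bin do not count
  prof3 <- prof; prof3$mean <- c(10, 1, 6, 6) * 1e14
  expect_equal(spatial_extent(prof3, noise_2sigma = 1e14), 1)
  # NA bins stop the scan
  prof4 <- prof; prof4$mean[2] <- NA
  expect_equal(spatial_extent(prof4, noise_2sigma = 1e14), 1)
  expect_error(spatial_extent(prof, noise_2sigma = 0), "positive")
})

test_that("population-weighted distance averages over eligible block groups", {
  d <- c(bg1 = 4, bg2 = 8)
  dem <- data.frame(blockgroup_id = c("bg1", "bg2"), group = "g",
                    population = c(1, 3))
  expect_equal(population_weighted_distance(d, dem, "g",
                                            subset = c("bg1", "bg2")), 7)
  dem$population <- c(5, 5)
  expect_equal(population_weighted_distance(d, dem, "g",
                                            subset = c("bg1", "bg2")), 6)
})
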