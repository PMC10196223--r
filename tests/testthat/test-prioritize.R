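test_that("greedy reserve selection covers everything it can", {
  # one population holding every allele: single-step selection
  inc <- rbind(all = rep(TRUE, 6),
               some = c(TRUE, TRUE, rep(FALSE, 4)))
  colnames(inc) <- paste0("a", 1:6)
  sel <- reserve_selection(inc)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$pop, "all")
  expect_equal(sel$coverage, 1)
  # disjoint sets: everyone gets picked, gains equal the set sizes
  inc2 <- matrix(FALSE, 3, 6,
                 dimnames = list(c("x", "y", "z"), paste0("a", 1:6)))
  inc2["x", 1:3] <- TRUE; inc2["y", 4:5] <- TRUE; inc2["z", 6] <- TRUE
  sel2 <- reserve_selection(inc2)
  expect_equal(sel2$pop, c("x", "y", "z"))
  expect_equal(sel2$gain, c(3, 2, 1))
  expect_equal(utils::tail(sel2$coverage, 1), 1)
  # coverage is non-decreasing step by step
  expect_true(all(diff(sel2$coverage) >= 0))
})

test_that("greedy selection is near-optimal against exhaustive set cover", {
  set.seed(80)
  sizes <- gaps <- integer(40)
  for (i in 1:40) {
    inc <- random_incidence(sample(5:8, 1), sample(10:18, 1))
    sel <- reserve_selection(inc)
    expect_equal(utils::tail(sel$coverage, 1), 1)
    opt <- min_cover_oracle(inc)
    sizes[i] <- nrow(sel); gaps[i] <- nrow(sel) - opt
  }
  expect_true(all(gaps <= 1))
  expect_gte(mean(gaps == 0), 0.9)
})

test_that("forest fraction integrates the raster over a geodesic circle", {
  ones <- raster_grid(matrix(1, 30, 30), 41, 41, 0.02)
  expect_equal(forest_fraction(ones, 41.3, 41.3, 20), 1)
  zeros <- raster_grid(matrix(0, 30, 30), 41, 41, 0.02)
  expect_equal(forest_fraction(zeros, 41.3, 41.3, 20), 0)
  # half-plane raster, circle centred on the boundary: close to 1/2
  half <- raster_grid(cbind(matrix(1, 60, 30), matrix(0, 60, 30)),
                      41, 41, 0.01)
  boundary_lon <- 41 + 30 * 0.01
  got <- forest_fraction(half, boundary_lon, 41.3, 15)
  expect_lt(abs(got - 0.5), 0.03)
  expect_error(forest_fraction(ones, 50, 41.3, 20), "outside")
})

test_that("the climate-shift factor follows its closed form", {
  expect_equal(climate_shift_factor(c(bio18 = 400, bio19 = 900),
                                    c(bio18 = 400, bio19 = 900)), 1)
  # bio18 halves, bio19 unchanged: sqrt(1.5)
  expect_equal(climate_shift_factor(c(bio18 = 400, bio19 = 900),
                                    c(bio18 = 200, bio19 = 900)),
               sqrt(1.5))
  # both variables shifted by the same relative amount rho: 1 + rho
  expect_equal(climate_shift_factor(c(bio18 = 100, bio19 = 200),
                                    c(bio18 = 130, bio19 = 260)), 1.3)
  # direction of change does not matter, magnitude does
  expect_equal(climate_shift_factor(c(a = 100), c(a = 80)),
               climate_shift_factor(c(a = 100), c(a = 120)))
  expect_error(climate_shift_factor(c(a = 0), c(a = 10)), "positive")
})

test_that("the conservation index is C_i = A_r * F_c / C_l with monotone
           behaviour", {
  expect_equal(conservation_index(2.0, 0.5, 1.0), 1.0)
  expect_equal(conservation_index(4.0, 0.75, 1.5), 2.0)
  base <- conservation_index(3, 0.6, 1.2)
  expect_gt(conservation_index(3.5, 0.6, 1.2), base)
  expect_gt(conservation_index(3, 0.7, 1.2), base)
  expect_lt(conservation_index(3, 0.6, 1.4), base)
  expect_equal(conservation_index(6, 0.6, 1.2), 2 * base)  # scale-consistent
  expect_error(conservation_index(3, 0.6, 0), "positive")
})

test_that("interval binning assigns unit-width categories", {
  rec <- tibble::tibble(pop = paste0("p", 1:6),
                        C_i = c(4.5, 4.01, 3.2, 2.0, 1.01, 0.4))
  out <- rank_categories(rec, k = 5, method = "interval")
  expect_equal(out$category, c(1L, 1L, 2L, 4L, 4L, 5L))
  # values above the top break still land in category 1
  high <- rank_categories(tibble::tibble(pop = "x", C_i = 9.7), k = 5)
  expect_equal(high$category, 1L)
})

test_that("equal-rank binning splits as evenly as possible", {
  rec <- tibble::tibble(pop = sprintf("p%02d", 1:21), C_i = 21:1)
  out <- rank_categories(rec, k = 5, method = "equal_rank")
  expect_equal(unname(table(out$category)), c(5L, 4L, 4L, 4L, 4L),
               ignore_attr = TRUE)
  expect_equal(out$category[1], 1L)   # highest C_i in category 1
  # all-tied indices fall back to the label order with ceiling sizes
  tied <- tibble::tibble(pop = sprintf("p%02d", 1:7), C_i = 2)
  out2 <- rank_categories(tied, k = 5, method = "equal_rank")
  expect_equal(out2$category[order(tied$pop)][1:2], c(1L, 1L))
  # five records into five categories: one each, in C_i order
  five <- tibble::tibble(pop = letters[1:5], C_i = c(5, 3, 4, 1, 2))
  out3 <- rank_categories(five, k = 5, method = "equal_rank")
  expect_equal(out3$category, c(1L, 3L, 2L, 5L, 4L))
  # appending a record with the lowest C_i keeps the top group intact and
  # sends the newcomer to the bottom category
  rec2 <- dplyr::bind_rows(rec, tibble::tibble(pop = "zz", C_i = 0.1))
  out5 <- rank_categories(rec2, k = 5, method = "equal_rank")
  expect_equal(out5$pop[out5$category == 1][1:5],
               out$pop[out$category == 1])
  expect_equal(out5$category[out5$pop == "zz"], 5L)
})

test_that("the full prioritization table assembles and ranks populations", {
  world <- small_world()
  pri <- prioritize_populations(world$genotypes, world$sites, world$forest,
                                world$climate_current, world$climate_future)
  expect_setequal(pri$pop, world$sites$pop)
  expect_true(all(pri$C_l >= 1))
  expect_true(all(pri$F_c >= 0 & pri$F_c <= 1))
  expect_equal(pri$C_i, pri$A_r * pri$F_c / pri$C_l)
  expect_true(all(pri$category %in% 1:5))
  # categories never increase with C_i
  ord <- order(-pri$C_i)
  expect_true(all(diff(pri$category[ord]) >= 0))
})

test_that("GeoJSON export carries coordinates and properties", {
  world <- small_world()
  pri <- prioritize_populations(world$genotypes, world$sites, world$forest,
                                world$climate_current, world$climate_future)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_priority_geojson(pri, world$sites, path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), nrow(pri))
  f1 <- gj$features[[1]]
  expect_equal(f1$properties$pop, pri$pop[1])
  expect_equal(f1$properties$C_i, pri$C_i[1])
  expect_equal(f1$geometry$coordinates[[1]], world$sites$lon[1])
})
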