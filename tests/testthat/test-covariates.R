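test_that("standardize uses the population SD and supports no-centering", {
  z <- standardize(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(mean(z^2), 1, tolerance = 1e-12)
  # idempotence
  expect_equal(standardize(z), z, tolerance = 1e-12)
  # wind-direction convention: scale only
  w <- standardize(c(1, 2, 3), center = FALSE)
  expect_equal(w, c(1, 2, 3) / kdbym:::pop_sd(c(1, 2, 3)), tolerance = 1e-12)
  expect_gt(mean(w), 0)
  expect_error(standardize(rep(2, 5), name = "windspeed"), "windspeed")
})

test_that("pollutants are summed before standardization and order matters", {
  expect_equal(combine_pollutants(c(1, 2), c(3, 4)), c(4, 6))
  no2 <- c(5, 1, 3)
  expect_equal(combine_pollutants(no2, c(0, 0, 0)), no2)
  expect_error(combine_pollutants(1:3, 1:4), "misaligned")
  # sum-then-standardize differs from standardize-then-sum
  set.seed(1)
  a <- rnorm(20); b <- 3 * rnorm(20)
  expect_false(isTRUE(all.equal(standardize(combine_pollutants(a, b)),
                                standardize(a) + standardize(b))))
})

test_that("nearest-station assignment matches brute force, ties to lower id", {
  set.seed(2)
  stations <- cbind(runif(10, -100, -60), runif(10, 40, 60))
  series <- matrix(rnorm(10 * 6), 10, 6)
  regions <- cbind(runif(100, -100, -60), runif(100, 40, 60))
  got <- assign_nearest_station(regions, stations, series, lonlat = TRUE)
  brute <- vapply(seq_len(100), function(i) {
    d <- kdbym:::haversine(regions[i, ], stations)
    which.min(d)
  }, integer(1))
  expect_identical(got$station, brute)
  expect_equal(got$values, series[brute, ])

  # single station: everyone gets it
  one <- assign_nearest_station(regions[1:5, ], stations[1, , drop = FALSE],
                                series[1, , drop = FALSE])
  expect_true(all(one$station == 1L))

  # exact midpoint: lower-indexed station wins
  st <- rbind(c(0, 0), c(2, 0))
  mid <- assign_nearest_station(matrix(c(1, 0), 1), st,
                                matrix(1:2, 2, 1))
  expect_identical(mid$station, 1L)
  expect_error(assign_nearest_station(regions, stations[0, , drop = FALSE],
                                      series[0, , drop = FALSE]), "no stations")
})

test_that("grid-to-region aggregation equals point-in-polygon brute force", {
  map <- simulate_map(5, seed = 9)   # unit squares in a row-major lattice
  set.seed(3)
  gx <- seq(0.1, 2.9, length.out = 20)
  gy <- seq(0.1, 1.9, length.out = 20)
  grid <- as.matrix(expand.grid(gx, gy))
  vals <- rnorm(nrow(grid))
  got <- aggregate_grid_to_region(grid, vals, map)
  for (i in seq_along(map$ids)) {
    ring <- map$polygons[[map$ids[i]]]
    inside <- vapply(seq_len(nrow(grid)), function(k) {
      kdbym:::point_in_polygon(grid[k, ], ring)
    }, logical(1))
    if (any(inside)) expect_equal(unname(got[i, 1]), mean(vals[inside]))
  }
  # one cell centre inside a 1x1 region: that value
  m1 <- region_map("A", 10, list(), polygons = list(A = square_ring(0, 0)))
  expect_equal(unname(aggregate_grid_to_region(rbind(c(0.5, 0.5)), 7, m1)[1, 1]), 7)
  # two centres, values 2 and 4 -> mean 3
  expect_equal(aggregate_grid_to_region(rbind(c(0.2, 0.5), c(0.8, 0.5)),
                                        c(2, 4), m1)[1, 1] |> unname(), 3)
  # empty region inherits the nearest cell's value
  m2 <- region_map(c("A", "B"), c(1, 1), data.frame(id_a = "A", id_b = "B"),
                   polygons = list(A = square_ring(0, 0),
                                   B = square_ring(5, 0)))
  out <- aggregate_grid_to_region(rbind(c(0.5, 0.5), c(1.5, 0.5)),
                                  c(1, 9), m2)
  expect_equal(unname(out["B", 1]), 9)
})

test_that("out-of-season zeroing honours inclusive, wrapping windows", {
  months <- 1:12
  x <- rep(7, 12)
  z <- zero_out_of_season(x, months, c(4, 10))
  expect_equal(z, ifelse(months >= 4 & months <= 10, 7, 0))
  expect_equal(z[3], 0)
  # full-year window is the identity
  expect_equal(zero_out_of_season(x, months, c(1, 12)), x)
  # wrapping window Nov-Feb zeroes June
  zw <- zero_out_of_season(x, months, c(11, 2))
  expect_equal(zw[6], 0)
  expect_equal(zw[c(11, 12, 1, 2)], rep(7, 4))
  # month-membership oracle for the wrap
  expect_equal(which(zw != 0), which(months >= 11 | months <= 2))
  expect_error(zero_out_of_season(x, months, c(0, 5)), "invalid season")
})

test_that("rural fraction is the population-weighted share of '0' codes", {
  expect_equal(rural_fraction("R0B", 50), 1)
  expect_equal(rural_fraction("M5V", 50), 0)
  expect_equal(rural_fraction(c("R0B", "M5V"), c(100, 300)), 0.25)
  # weighted-mean oracle
  set.seed(4)
  codes <- sample(c("R0B", "M5V", "K0A", "T2N"), 20, replace = TRUE)
  pops <- runif(20, 10, 100)
  want <- weighted.mean(substr(codes, 2, 2) == "0", pops)
  expect_equal(rural_fraction(codes, pops), want)
  expect_error(rural_fraction("X", 1), "malformed")
})

test_that("census vintages map to the documented study years", {
  expect_equal(census_vintage(6, 11, 16, 2007), 6)
  expect_equal(census_vintage(6, 11, 16, 2014), 11)
  expect_equal(census_vintage(6, 11, 16, 2015), 16)
  expect_equal(census_vintage(6, 11, 16, c(2004, 2008, 2009, 2017)),
               c(6, 6, 11, 16))
  expect_error(census_vintage(6, 11, 16, 2003), "out of range")
  expect_error(census_vintage(6, 11, 16, 2018), "out of range")
})
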