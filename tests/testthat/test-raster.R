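test_that("aggregation averages source-cell centres, NA-ignoring", {
  r <- make_raster(matrix(7, 20, 20), cell = 0.01)
  agg <- aggregate_raster(r, 0.05)
  expect_equal(dim(agg$values), c(4, 4))
  expect_true(all(agg$values == 7))

  # checkerboard averages to one half
  cb <- make_raster(outer(1:40, 1:40, function(i, j) (i + j) %% 2),
                    cell = 0.005)
  agg2 <- aggregate_raster(cb, 0.05)
  expect_true(all(abs(agg2$values - 0.5) < 1e-12))

  # a sub-target-cell cloud hole is filled by neighbouring source cells
  v <- matrix(3, 10, 10)
  v[4, 5] <- NA
  agg3 <- aggregate_raster(make_raster(v, cell = 0.01), 0.05)
  expect_false(any(is.na(agg3$values)))
  expect_true(all(agg3$values == 3))

  # exact mean oracle on random data with missingness
  set.seed(41)
  v4 <- matrix(runif(400), 20, 20)
  v4[sample(400, 60)] <- NA
  agg4 <- aggregate_raster(make_raster(v4, cell = 0.01), 0.05)
  for (ri in 1:4) for (ci in 1:4) {
    block <- v4[(ri - 1) * 5 + 1:5, (ci - 1) * 5 + 1:5]
    expect_equal(agg4$values[ri, ci], mean(block, na.rm = TRUE))
  }

  expect_error(aggregate_raster(r, 0.05,
                                window = list(lon_min = 5, lon_max = 6,
                                              lat_min = 5, lat_max = 6)),
               "overlap")
  # aggregating at the already-aggregated resolution is the identity
  expect_equal(aggregate_raster(agg4, 0.05)$values, agg4$values)
})

test_that("two-day averaging is a cellwise NA-ignoring mean", {
  a <- make_raster(matrix(10, 3, 3))
  b <- make_raster(matrix(20, 3, 3))
  b$values[2, 2] <- NA
  a2 <- a; a2$values[1, 1] <- NA; a2$values[2, 2] <- 7
  st <- make_stack(list(b, a2))  # day-before = b, day = a2
  avg <- two_day_average(st, "sst", st$date[2])
  expect_equal(avg$values[3, 3], 15)
  expect_equal(avg$values[1, 1], 20)  # missing today, value from yesterday
  expect_equal(avg$values[2, 2], 7)   # missing yesterday
  # identical days: mean is the identity
  st2 <- make_stack(list(a, a))
  expect_equal(two_day_average(st2, "sst", st2$date[2])$values, a$values)
  expect_warning(two_day_average(st2, "sst", st2$date[1]), "one day")
  expect_error(two_day_average(st2, "sst", st2$date[1] + 30), "no raster")
})

test_that("rank standardisation maps onto [0, 20] with average ranks for ties", {
  r <- make_raster(matrix(c(1, 2, 3), 1, 3))
  expect_equal(as.vector(rank_standardise(r)$values), c(0, 10, 20))
  r2 <- make_raster(matrix(c(5, 5, 9), 1, 3))
  expect_equal(as.vector(rank_standardise(r2)$values), c(5, 5, 20))
  # invariance under strictly monotone transforms
  set.seed(42)
  v <- matrix(rlnorm(100), 10, 10)
  v[c(3, 50)] <- NA
  a <- rank_standardise(make_raster(v))$values
  b <- rank_standardise(make_raster(log(v)))$values
  expect_equal(a, b)
  expect_true(all(a >= 0 & a <= 20, na.rm = TRUE))
  expect_true(all(is.na(a) == is.na(v)))
  expect_equal(mean(a, na.rm = TRUE), 10)  # tie-free input
  expect_warning(out <- rank_standardise(make_raster(matrix(4, 2, 2))),
                 "degenerate")
  expect_true(all(out$values == 10))
})

test_that("point sampling uses containing cells with half-open edges", {
  v <- matrix(seq_len(12), 3, 4)
  r <- make_raster(v, cell = 0.5)
  expect_equal(sample_raster(r, 0.25, 0.25), v[1, 1])   # cell centre
  expect_equal(sample_raster(r, 0.5, 0.5), v[2, 2])     # shared edge -> east/north
  set.seed(43)
  lon <- runif(100, 0, 2 - 1e-9)
  lat <- runif(100, 0, 1.5 - 1e-9)
  expect_equal(sample_raster(r, lon, lat),
               v[cbind(floor(lat / 0.5) + 1, floor(lon / 0.5) + 1)])
  expect_error(sample_raster(r, 5, 0.2), "outside")
})

test_that("rank order of sampled values is preserved by standardisation", {
  set.seed(44)
  v <- matrix(runif(64), 8, 8)
  r <- make_raster(v, cell = 0.1)
  rr <- rank_standardise(r)
  lon <- runif(30, 0, 0.8 - 1e-9); lat <- runif(30, 0, 0.8 - 1e-9)
  expect_equal(order(sample_raster(r, lon, lat)),
               order(sample_raster(rr, lon, lat)))
})

test_that("temporal predictability estimates between-image correlation", {
  a <- make_raster(matrix(rnorm(100), 10, 10))
  st <- make_stack(list(a, a, a))
  expect_equal(temporal_predictability(st, "sst"), 1)

  set.seed(45)
  sims <- replicate(20, {
    imgs <- lapply(1:3, function(i) make_raster(matrix(rnorm(400), 20, 20)))
    temporal_predictability(make_stack(imgs), "sst")
  })
  expect_lt(abs(mean(sims)), 0.05)

  # AR(1) fields with day-to-day correlation 0.8, few dates so the mean
  # pairwise correlation stays near the one-step value
  sims2 <- replicate(20, {
    z1 <- matrix(rnorm(900), 30, 30)
    z2 <- 0.8 * z1 + sqrt(1 - 0.8^2) * matrix(rnorm(900), 30, 30)
    temporal_predictability(make_stack(list(make_raster(z1),
                                            make_raster(z2))), "sst")
  })
  expect_lt(abs(mean(sims2) - 0.8), 0.1)
})

test_that("covariate correlations recover construction and flag degeneracy", {
  fx <- tibble::tibble(sst_rank = c(1, 2, 3, 4), turbidity_rank = c(2, 4, 6, 8),
                       chla_rank = c(1, 1, 1, 1))
  expect_warning(cc <- covariate_correlations(fx), "constant")
  expect_equal(cc$r[cc$var1 == "sst_rank" & cc$var2 == "turbidity_rank"], 1)

  set.seed(46)
  ind <- tibble::tibble(sst_rank = runif(1000), turbidity_rank = runif(1000),
                        chla_rank = runif(1000))
  expect_true(all(abs(covariate_correlations(ind)$r) < 0.1))

  # known cross-correlation 0.5 between two columns
  z <- rnorm(2000)
  cr <- tibble::tibble(sst_rank = sqrt(0.5) * z + sqrt(0.5) * rnorm(2000),
                       turbidity_rank = sqrt(0.5) * z + sqrt(0.5) * rnorm(2000),
                       chla_rank = rnorm(2000))
  got <- covariate_correlations(cr)
  expect_lt(abs(got$r[got$var1 == "sst_rank" &
                      got$var2 == "turbidity_rank"] - 0.5), 0.15)
})

test_that("ASCII grid rasters round-trip through disk", {
  set.seed(47)
  v <- matrix(runif(48), 6, 8)
  v[sample(48, 5)] <- NA
  r <- make_raster(v, cell = 0.05, xmin = -33.5, ymin = -5.1,
                   variable = "chla", date = as.Date("2015-09-03"))
  dir <- withr::local_tempdir()
  path <- write_ascii_raster(r, dir)
  expect_match(basename(path), "chla_20150903.asc")
  back <- read_ascii_raster(path)
  expect_equal(back$values, r$values, tolerance = 1e-7)
  expect_equal(back$xmin, r$xmin)
  expect_equal(back$cell, r$cell)
  expect_equal(back$variable, "chla")
  expect_equal(back$date, as.Date("2015-09-03"))
})

test_that("fix annotation averages, ranks and samples per fix date", {
  # two days with known values: today constant 4, yesterday constant 2 in
  # one half, gradient elsewhere -> check the sampled ranks directly
  set.seed(48)
  v1 <- matrix(runif(100), 10, 10)
  v2 <- matrix(runif(100), 10, 10)
  d2 <- as.Date("2015-09-02")
  st <- dplyr::bind_rows(
    make_stack(list(make_raster(v1, cell = 0.1), make_raster(v2, cell = 0.1)),
               variable = "sst"),
    make_stack(list(make_raster(v1 * 3, cell = 0.1),
                    make_raster(v2 * 3, cell = 0.1)), variable = "turbidity"),
    make_stack(list(make_raster(sqrt(v1), cell = 0.1),
                    make_raster(sqrt(v2), cell = 0.1)), variable = "chla"))
  fx <- tibble::tibble(individual_id = "b", trip_id = "1",
                       timestamp = as.POSIXct("2015-09-02 10:00", tz = "UTC") +
                         0:9 * 60,
                       lon = runif(10, 0, 1 - 1e-9),
                       lat = runif(10, 0, 1 - 1e-9))
  ann <- annotate_fixes(fx, st)
  avg <- (v1 + v2) / 2
  rk <- 20 * (rank(avg) - 1) / (length(avg) - 1)
  expected <- matrix(rk, 10, 10)[cbind(floor(fx$lat / 0.1) + 1,
                                       floor(fx$lon / 0.1) + 1)]
  expect_equal(ann$sst_rank, expected)
  expect_true(all(ann$sst_rank >= 0 & ann$sst_rank <= 20))
})
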