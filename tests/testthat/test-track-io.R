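test_that("read_tracks parses a minimal CSV into sorted fixes", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_track_csv(tibble::tibble(
    individual_id = "b1", trip_id = "1",
    timestamp = c("2015-09-01T06:00:00Z", "2015-09-01T06:01:00Z",
                  "2015-09-01T06:02:00Z"),
    lon = c(-32.4, -32.41, -32.42), lat = c(-3.9, -3.91, -3.92)), path)
  fx <- read_tracks(path)
  expect_s3_class(fx, "tbl_df")
  expect_equal(nrow(fx), 3)
  expect_equal(fx$individual_id, rep("b1", 3))
  expect_true(!is.unsorted(fx$timestamp))
})

test_that("read_tracks re-sorts out-of-order rows with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_track_csv(tibble::tibble(
    individual_id = "b1",
    timestamp = c("2015-09-01T06:02:00Z", "2015-09-01T06:00:00Z",
                  "2015-09-01T06:01:00Z"),
    lon = c(3, 1, 2), lat = 0), path)
  expect_warning(fx <- read_tracks(path), "re-sorted")
  expect_equal(fx$lon, c(1, 2, 3))
})

test_that("read_tracks reports offending line numbers for bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_track_csv(tibble::tibble(
    individual_id = "b1",
    timestamp = c("2015-09-01T06:00:00Z", "2015-09-01T06:01:00Z"),
    lon = c(0, 0), lat = c(10, 95)), path)
  expect_error(read_tracks(path), "line\\(s\\): 3")
})

test_that("read_tracks handles empty files, missing columns, duplicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("individual_id,timestamp,lon,lat", path)
  expect_equal(nrow(read_tracks(path)), 0)

  path2 <- withr::local_tempfile(fileext = ".csv")
  write_track_csv(tibble::tibble(id = "x", t = "2015-09-01T06:00:00Z"), path2)
  expect_error(read_tracks(path2), "required column")

  path3 <- withr::local_tempfile(fileext = ".csv")
  write_track_csv(tibble::tibble(
    individual_id = "b1",
    timestamp = c("2015-09-01T06:00:00Z", "2015-09-01T06:00:00Z",
                  "2015-09-01T06:01:00Z"),
    lon = c(1, 99, 2), lat = 0), path3)
  expect_warning(fx <- read_tracks(path3), "duplicate")
  expect_equal(fx$lon, c(1, 2))
})

test_that("haversine distance is exact on the meridian, symmetric, metric", {
  expect_equal(haversine_m(10, -5, 10, -5), 0)
  # 0.01 degree of latitude = 0.01 * pi/180 * R
  expect_equal(haversine_m(0, 0, 0, 0.01), 0.01 * pi / 180 * 6371000,
               tolerance = 1e-9)
  set.seed(11)
  a <- cbind(runif(100, -180, 180), runif(100, -60, 60))
  b <- cbind(runif(100, -180, 180), runif(100, -60, 60))
  c_ <- cbind(runif(100, -180, 180), runif(100, -60, 60))
  expect_equal(haversine_m(a[, 1], a[, 2], b[, 1], b[, 2]),
               haversine_m(b[, 1], b[, 2], a[, 1], a[, 2]))
  dab <- haversine_m(a[, 1], a[, 2], b[, 1], b[, 2])
  dbc <- haversine_m(b[, 1], b[, 2], c_[, 1], c_[, 2])
  dac <- haversine_m(a[, 1], a[, 2], c_[, 1], c_[, 2])
  expect_true(all(dac <= dab + dbc + 1e-6))
})

test_that("regularise keeps every 6th fix of a 6-per-minute track", {
  n <- 121
  fx <- tibble::tibble(
    individual_id = "b1", trip_id = "1",
    timestamp = t_origin + (seq_len(n) - 1) * 10,
    lon = (seq_len(n) - 1) * 1e-4, lat = 0)
  out <- regularise(fx, interval = 60)
  expect_equal(nrow(out), 21)
  expect_true(all(diff(as.numeric(out$timestamp)) == 60))
  expect_equal(out$lon, fx$lon[seq(1, n, by = 6)])
})

test_that("regularise is idempotent and preserves gaps without interpolation", {
  fx <- make_straight_track(n = 30)[, 1:5]
  once <- regularise(fx, 60)
  twice <- regularise(once[, 1:5], 60)
  expect_equal(twice$timestamp, once$timestamp)
  expect_equal(twice$lon, once$lon)

  # 5-minute hole: no fabricated fixes, later fixes on a new segment
  gap <- fx[-(11:15), ]
  out <- regularise(gap, 60)
  expect_equal(nrow(out), nrow(gap))
  expect_equal(max(out$dt_s, na.rm = TRUE), 360)
  expect_equal(dplyr::n_distinct(out$segment_id), 2)
  expect_true(all(out$timestamp %in% gap$timestamp))
})

test_that("regularise flags trips shorter than one interval", {
  fx <- tibble::tibble(individual_id = "b1", trip_id = "1",
                       timestamp = t_origin + c(0, 10),
                       lon = c(0, 1e-4), lat = 0)
  expect_warning(out <- regularise(fx, 60), "unusable")
  expect_equal(nrow(out), 1)
})

test_that("sitting flag follows the incoming-segment speed rule", {
  fx <- make_straight_track(n = 20, v = 40 / 3.6)  # constant 40 km/h
  expect_false(any(flag_sitting(fx)$sitting))

  # three consecutive fixes 50 m apart at 60 s spacing = 3 km/h
  m_per_deg <- 6371000 * pi / 180
  slow <- tibble::tibble(
    individual_id = "b1", trip_id = "1",
    timestamp = t_origin + (0:4) * 60,
    lon = c(0, 600, 650, 700, 1300) / m_per_deg, lat = 0)
  out <- flag_sitting(regularise(slow, 60))
  expect_equal(out$sitting, c(FALSE, FALSE, TRUE, TRUE, FALSE))

  # all retained fixes have incoming speed at or above the threshold
  kept <- out[!out$sitting & !is.na(out$speed_ms), ]
  expect_true(all(kept$speed_ms >= 10 / 3.6))
})

test_that("sitting flags agree with generator truth at 95%+", {
  cfg <- sim_config(n_individuals = 2, trips_min = 2, trips_max = 2,
                    trip_duration_h = 5, seed = 301)
  sim <- suppressWarnings(simulate_tracks(cfg))
  flagged <- flag_sitting(regularise(sim$fixes, 60))
  agree <- mean(flagged$sitting == flagged$true_sitting)
  expect_gt(agree, 0.95)
})

test_that("retained_fixes recomputes kinematics and breaks segments at bouts", {
  cfg <- sim_config(n_individuals = 1, trips_min = 1, trips_max = 1,
                    trip_duration_h = 4, sitting_rate_per_h = 3, seed = 302)
  sim <- suppressWarnings(simulate_tracks(cfg))
  ret <- retained_fixes(flag_sitting(regularise(sim$fixes, 60)), 60)
  expect_false(any(ret$sitting))
  # a removed multi-fix bout must open a new segment
  expect_gt(dplyr::n_distinct(ret$segment_id), 1)
  d <- haversine_m(ret$lon[-nrow(ret)], ret$lat[-nrow(ret)],
                   ret$lon[-1], ret$lat[-1])
  expect_equal(ret$speed_ms[-1], d / ret$dt_s[-1])
})
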