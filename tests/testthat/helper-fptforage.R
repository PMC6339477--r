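# Fixtures and independent oracles shared across the suite.

t_origin <- as.POSIXct("2015-09-01 06:00:00", tz = "UTC")

# Straight eastbound track along the equator at constant speed (m/s).
# Distance along the equator is exactly linear in longitude, so chord
# interpolation of the crossing point is exact and FPT(r) = 2r/v.
make_straight_track <- function(n = 100, v = 10, dt = 60,
                                individual_id = "a", trip_id = "1") {
  m_per_deg <- 6371000 * pi / 180
  fx <- tibble::tibble(
    individual_id = individual_id, trip_id = trip_id,
    timestamp = t_origin + (seq_len(n) - 1) * dt,
    lon = (seq_len(n) - 1) * v * dt / m_per_deg,
    lat = 0
  )
  fx$dt_s <- c(NA, diff(as.numeric(fx$timestamp)))
  fx$speed_ms <- c(NA, rep(v, n - 1))
  fx$segment_id <- 1L
  fx$sitting <- FALSE
  fx
}

# Two-mode correlated random walk in local planar metres, mapped to
# lon/lat near the equator. Independent of the package's simulator.
make_crw_track <- function(n = 200, dt = 60, individual_id = "c",
                           trip_id = "1") {
  m_per_deg <- 6371000 * pi / 180
  x <- y <- numeric(n)
  heading <- stats::runif(1, 0, 2 * pi)
  mode_search <- FALSE
  for (i in 2:n) {
    if (stats::runif(1) < 0.08) mode_search <- !mode_search
    if (mode_search) {
      heading <- heading + stats::runif(1, -2.5, 2.5)
      step <- stats::rgamma(1, 8, scale = 250 / 8)
    } else {
      heading <- heading + stats::rnorm(1, 0, 0.15)
      step <- stats::rgamma(1, 8, scale = 650 / 8)
    }
    x[i] <- x[i - 1] + step * cos(heading)
    y[i] <- y[i - 1] + step * sin(heading)
  }
  fx <- tibble::tibble(
    individual_id = individual_id, trip_id = trip_id,
    timestamp = t_origin + (seq_len(n) - 1) * dt,
    lon = x / m_per_deg, lat = y / m_per_deg
  )
  fx$dt_s <- c(NA, diff(as.numeric(fx$timestamp)))
  d <- haversine_ref(fx$lon[-n], fx$lat[-n], fx$lon[-1], fx$lat[-1])
  fx$speed_ms <- c(NA, d / dt)
  fx$segment_id <- 1L
  fx$sitting <- FALSE
  fx
}

# Reference haversine written out in R (independent of both geosphere and
# the compiled kernel).
haversine_ref <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  p1 <- lat1 * rad; p2 <- lat2 * rad
  dp <- (lat2 - lat1) * rad; dl <- (lon2 - lon1) * rad
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * 6371000 * atan2(sqrt(a), sqrt(pmax(0, 1 - a)))
}

# Brute-force first-passage time: walk fix by fix away from the focal fix
# accumulating time until the distance to the centre first exceeds the
# radius, interpolating the crossing instant linearly on distance along
# the final chord. Mirrors the definition, not the implementation.
brute_force_fpt <- function(fixes, i, radius) {
  tt <- as.numeric(fixes$timestamp)
  one_dir <- function(dir) {
    prev_d <- 0
    prev_t <- tt[i]
    j <- i + dir
    while (j >= 1 && j <= nrow(fixes)) {
      if (fixes$segment_id[j] != fixes$segment_id[i]) return(NA_real_)
      d <- haversine_ref(fixes$lon[i], fixes$lat[i], fixes$lon[j], fixes$lat[j])
      if (d > radius) {
        f <- (radius - prev_d) / (d - prev_d)
        return(abs(prev_t + f * (tt[j] - prev_t) - tt[i]))
      }
      prev_d <- d
      prev_t <- tt[j]
      j <- j + dir
    }
    NA_real_
  }
  fwd <- one_dir(1L)
  bwd <- one_dir(-1L)
  if (is.na(fwd) || is.na(bwd)) NA_real_ else fwd + bwd
}

# Small raster constructors.
make_raster <- function(values, cell = 0.01, xmin = 0, ymin = 0,
                        variable = "sst", date = as.Date("2015-09-01")) {
  ocean_raster(values, xmin = xmin, ymin = ymin, cell = cell,
               variable = variable, date = date)
}

make_stack <- function(rasters, variable = "sst", dates = NULL) {
  if (is.null(dates))
    dates <- as.Date("2015-09-01") + seq_along(rasters) - 1
  tibble::tibble(
    variable = variable,
    date = dates,
    raster = purrr::map2(rasters, dates, function(r, d) {
      r$variable <- variable
      r$date <- d
      r
    })
  )
}

write_track_csv <- function(df, path) {
  readr::write_csv(df, path, progress = FALSE)
  path
}
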