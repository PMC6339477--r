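#' Simulation configuration
#'
#' Defaults emulate the study system the package targets: a fleet of 15
#' central-place foraging tropicbirds making looping trips of ~8.7 h at one
#' fix per minute from an oceanic-island colony, with two latent movement
#' modes (fast, directed transit vs. slow, tortuous area-restricted
#' search), sitting-on-water bouts, and daily ocean covariate fields with
#' near-zero day-to-day correlation. The habitat effect enters the
#' transit-to-search switching hazard on ranked covariates, which is the
#' structure the downstream GLMM assumes; its default coefficients are the
#' study-scale effect sizes for the intercept, SST and turbidity, with a
#' null chlorophyll-a effect.
#'
#' @param n_individuals Number of birds (default 15).
#' @param trips_min,trips_max Trips per bird, drawn uniformly (1-4).
#' @param trip_duration_h Trip duration in hours (default 8.7).
#' @param fix_interval_s Fix interval in seconds (default 60).
#' @param colony_lon,colony_lat Colony location (decimal degrees).
#' @param transit_speed_ms,transit_turn_rho Transit mode: mean step speed
#'   (m/s) and wrapped-Cauchy turning concentration.
#' @param search_speed_ms,search_turn_rho Search mode likewise (the
#'   wrapped-Cauchy noise concentration around the rotational offset).
#' @param search_turn_mean_deg Mean absolute turning angle per step in
#'   search mode (degrees). Search turning is drawn as a per-bout rotation
#'   direction times this angle plus wrapped-Cauchy noise, producing the
#'   loitering, circling flight with which a plunge-diver stays over a prey
#'   patch while keeping flight speed above the sitting threshold.
#' @param step_shape Gamma shape of step-length draws.
#' @param patch_radius_m Confinement radius of a search patch in metres
#'   (sets the area-restricted-search scale; default 400).
#' @param search_dwell_min Mean dwell in a search patch, minutes.
#' @param search_refractory_min Minutes after leaving a patch during which a
#'   new search bout cannot start (patch depletion / giving-up time); keeps
#'   successive patches spatially separated.
#' @param sitting_rate_per_h Poisson rate of sitting-bout initiation.
#' @param sitting_duration_min Mean sitting-bout duration, minutes.
#' @param sitting_speed_ms Drift speed while sitting (below the 10 km/h
#'   speed-filter threshold).
#' @param beta Named vector of switching-hazard coefficients on the logit
#'   scale: `intercept`, then per-variable slopes on 0-20 ranked
#'   covariates.
#' @param sigma_alpha SD of the per-bird random intercept.
#' @param homing_strength Strength of the return-to-colony heading bias in
#'   the second half of a trip (0-1).
#' @param window Analysis window (list lon_min/lon_max/lat_min/lat_max);
#'   default spans the ~2.5 x 2.5 degree study box around the colony.
#' @param raster_cell Generator raster cell size in degrees (default
#'   0.025, finer than the 0.05 analysis grid so aggregation is exercised).
#' @param smoothing_cells Gaussian smoothing SD of the fields, in cells.
#' @param day_rho Day-to-day correlation of the latent fields (default
#'   0.05, a highly unpredictable environment).
#' @param cross_rho Cross-variable correlation of the latent fields.
#' @param cloud_fraction Fraction of cells masked as missing per day.
#' @param start_date First raster/trip date.
#' @param seed Integer seed; the full run is reproducible given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals = 15,
                       trips_min = 1, trips_max = 4,
                       trip_duration_h = 8.7,
                       fix_interval_s = 60,
                       colony_lon = -32.42, colony_lat = -3.86,
                       transit_speed_ms = 11, transit_turn_rho = 0.97,
                       search_speed_ms = 5, search_turn_rho = 0.8,
                       search_turn_mean_deg = 100,
                       step_shape = 10,
                       patch_radius_m = 400,
                       search_dwell_min = 8,
                       search_refractory_min = 10,
                       sitting_rate_per_h = 0.7,
                       sitting_duration_min = 6,
                       sitting_speed_ms = 0.3,
                       beta = c(intercept = -2.247, sst = 0.065,
                                turbidity = -0.050, chla = 0),
                       sigma_alpha = 1.0,
                       homing_strength = 0.35,
                       window = list(lon_min = -33.6806, lon_max = -31.1726,
                                     lat_min = -5.1134, lat_max = -2.6054),
                       raster_cell = 0.025,
                       smoothing_cells = 3,
                       day_rho = 0.05,
                       cross_rho = 0.2,
                       cloud_fraction = 0.05,
                       start_date = as.Date("2015-08-28"),
                       seed = NULL) {
  cfg <- as.list(environment())
  stopifnot(cfg$trip_duration_h > 0, cfg$fix_interval_s > 0,
            cfg$patch_radius_m > 0, cfg$search_dwell_min > 0,
            cfg$sigma_alpha >= 0, cfg$day_rho >= 0, cfg$day_rho <= 1)
  structure(cfg, class = "sim_config")
}

# physical scales of the synthetic covariates: mean, sd, floor
.sim_scales <- list(
  sst = c(mean = 24.4, sd = 3.2, floor = -Inf),
  turbidity = c(mean = 0.03, sd = 0.005, floor = 0.001),
  chla = c(mean = 0.12, sd = 0.03, floor = 0.005)
)

#' Simulate daily oceanographic raster fields
#'
#' Each day's field per variable is spatially smoothed Gaussian noise
#' (smoothing length sets the autocorrelation range), evolved over days as
#' an AR(1) mixture `rho * previous + sqrt(1 - rho^2) * new` on the latent
#' scale, with optional cross-variable correlation via a shared latent
#' field, and rescaled to plausible physical ranges (SST in deg C,
#' turbidity Kd(490) in 1/m, chlorophyll-a in mg/m^3).
#'
#' @param config A [sim_config()].
#' @param dates Vector of `Date`s to generate.
#' @return Raster stack tibble (`variable`, `date`, `raster`).
#' @export
simulate_rasters <- function(config, dates) {
  if (!is.null(config$seed)) set.seed(config$seed)
  w <- config$window
  nc <- max(2L, floor((w$lon_max - w$lon_min) / config$raster_cell))
  nr <- max(2L, floor((w$lat_max - w$lat_min) / config$raster_cell))
  vars <- names(config$beta)[-1]

  smooth_field <- function(z) {
    s <- config$smoothing_cells
    if (s <= 0) return(z)
    half <- ceiling(3 * s)
    k <- stats::dnorm(-half:half, sd = s)
    Kr <- kernel_matrix(nrow(z), k)
    Kc <- kernel_matrix(ncol(z), k)
    f <- Kr %*% z %*% t(Kc)
    (f - mean(f)) / stats::sd(f)
  }
  new_latent <- function() smooth_field(matrix(stats::rnorm(nr * nc), nr, nc))

  rho_d <- config$day_rho
  rho_x <- config$cross_rho
  common <- new_latent()
  specific <- lapply(vars, function(v) new_latent())
  names(specific) <- vars

  out <- list()
  for (d in seq_along(dates)) {
    if (d > 1) {
      common <- rho_d * common + sqrt(1 - rho_d^2) * new_latent()
      specific <- lapply(specific, function(z)
        rho_d * z + sqrt(1 - rho_d^2) * new_latent())
    }
    for (v in vars) {
      z <- sqrt(rho_x) * common + sqrt(1 - rho_x) * specific[[v]]
      sc <- .sim_scales[[v]]
      vals <- pmax(sc[["mean"]] + sc[["sd"]] * z, sc[["floor"]])
      if (config$cloud_fraction > 0)
        vals[stats::runif(length(vals)) < config$cloud_fraction] <- NA
      out[[length(out) + 1]] <- tibble::tibble(
        variable = v, date = dates[d],
        raster = list(ocean_raster(vals, xmin = w$lon_min, ymin = w$lat_min,
                                   cell = config$raster_cell, variable = v,
                                   date = dates[d])))
    }
  }
  dplyr::bind_rows(out)
}

# row-normalised band matrix applying a 1-D smoothing kernel
kernel_matrix <- function(n, k) {
  half <- (length(k) - 1) / 2
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - half):(i + half)
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- k[ok]
    K[i, ] <- K[i, ] / sum(K[i, ])
  }
  K
}

wrapped_cauchy <- function(n, rho) {
  # circular turning-angle draw; rho = 0 uniform, rho -> 1 degenerate at 0
  if (rho >= 1) return(rep(0, n))
  2 * atan(((1 - rho) / (1 + rho)) * tan(pi * (stats::runif(n) - 0.5)))
}

wrap_angle <- function(a) atan2(sin(a), cos(a))

#' Simulate a fleet of central-place foraging trips
#'
#' Two-mode correlated random walk per trip: transit (long gamma steps,
#' tightly concentrated wrapped-Cauchy turning) and search (short steps,
#' dispersed turning, confined within `patch_radius_m` of the patch entry
#' point for a gamma-distributed dwell). The per-minute probability of
#' switching from transit into search is
#' `invlogit(beta[1] + alpha_i + beta[-1] . x(cell))` where `x(cell)` are
#' the ranked two-day-averaged covariates of the bird's current cell and
#' `alpha_i ~ N(0, sigma_alpha^2)` is the bird's random intercept. Sitting
#' bouts are inserted as near-zero-speed runs; a soft homing bias bends
#' transit headings back toward the colony in the trip's second half,
#' producing looping rather than commuting trips.
#'
#' @param config A [sim_config()].
#' @param rasters Optional raster stack from [simulate_rasters()]; when
#'   `NULL` one is generated covering all trip dates plus the day before.
#' @return A `sim_output` list: `fixes` (tibble with true per-fix labels
#'   `true_mode` among transit/search/sitting), `rasters`, `truth` (beta,
#'   sigma_alpha, per-bird intercepts, patch scale), `config`.
#' @export
simulate_tracks <- function(config, rasters = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  vars <- names(config$beta)[-1]

  # trip plan: each bird gets consecutive trip days, birds staggered 3 days
  n_trips <- sample(config$trips_min:config$trips_max, config$n_individuals,
                    replace = TRUE)
  plan <- purrr::map_dfr(seq_len(config$n_individuals), function(i) {
    tibble::tibble(individual_id = sprintf("bird%02d", i),
                   trip_id = as.character(seq_len(n_trips[i])),
                   date = config$start_date + (i - 1) * 3 +
                     seq_len(n_trips[i]) - 1)
  })

  if (is.null(rasters)) {
    dates <- seq(min(plan$date) - 1, max(plan$date), by = "day")
    rasters <- simulate_rasters_noseed(config, dates)
  }

  alpha <- stats::rnorm(config$n_individuals, 0, config$sigma_alpha)
  names(alpha) <- sprintf("bird%02d", seq_len(config$n_individuals))

  # per-date hazard covariates: ranked two-day average at generator grid
  hazard_cache <- new.env(parent = emptyenv())
  hazard_rasters <- function(date) {
    key <- format(date)
    if (!is.null(hazard_cache[[key]])) return(hazard_cache[[key]])
    rl <- lapply(vars, function(v)
      suppressWarnings(rank_standardise(two_day_average(rasters, v, date))))
    names(rl) <- vars
    hazard_cache[[key]] <- rl
    rl
  }

  trips <- purrr::map(seq_len(nrow(plan)), function(k) {
    simulate_one_trip(config, plan$individual_id[k], plan$trip_id[k],
                      plan$date[k], alpha[[plan$individual_id[k]]],
                      hazard_rasters(plan$date[k]))
  })
  fixes <- dplyr::bind_rows(trips)

  structure(list(
    fixes = fixes, rasters = rasters,
    truth = list(beta = config$beta, sigma_alpha = config$sigma_alpha,
                 alpha = tibble::tibble(individual_id = names(alpha),
                                        alpha = unname(alpha)),
                 patch_radius_m = config$patch_radius_m),
    config = config
  ), class = "sim_output")
}

# simulate_rasters without re-seeding (used inside simulate_tracks so the
# whole run consumes one RNG stream)
simulate_rasters_noseed <- function(config, dates) {
  cfg <- config
  cfg$seed <- NULL
  simulate_rasters(cfg, dates)
}

simulate_one_trip <- function(config, individual_id, trip_id, date, alpha_i,
                              hazard) {
  n_steps <- max(2L, round(config$trip_duration_h * 3600 / config$fix_interval_s))
  dt <- config$fix_interval_s
  w <- config$window
  vars <- names(config$beta)[-1]
  b0 <- config$beta[[1]]
  bslope <- config$beta[-1]

  lon <- lat <- numeric(n_steps)
  mode <- character(n_steps)
  lon[1] <- config$colony_lon
  lat[1] <- config$colony_lat
  mode[1] <- "transit"
  heading <- stats::runif(1, -pi, pi)

  state <- "transit"
  dwell_left <- 0L
  sit_left <- 0L
  refractory <- 0L
  rot_sign <- 1
  patch_lon <- patch_lat <- NA_real_
  p_sit <- config$sitting_rate_per_h * dt / 3600

  cell_rank <- function(lo, la) {
    vapply(vars, function(v) {
      r <- hazard[[v]]
      ci <- floor((lo - r$xmin) / r$cell) + 1
      ri <- floor((la - r$ymin) / r$cell) + 1
      if (ci < 1 || ci > ncol(r$values) || ri < 1 || ri > nrow(r$values))
        return(10)
      val <- r$values[ri, ci]
      if (is.na(val)) 10 else val
    }, numeric(1))
  }

  for (t in 2:n_steps) {
    if (state == "sitting") {
      sit_left <- sit_left - 1L
      step_m <- config$sitting_speed_ms * dt * stats::runif(1, 0.5, 1.5)
      heading <- stats::runif(1, -pi, pi)
      if (sit_left <= 0L) state <- "transit"
    } else if (state == "transit") {
      if (stats::runif(1) < p_sit) {
        state <- "sitting"
        sit_left <- max(1L, round(stats::rexp(1, 1 / config$sitting_duration_min) *
                                    60 / dt))
        step_m <- config$sitting_speed_ms * dt
      } else {
        if (refractory > 0L) refractory <- refractory - 1L
        x <- cell_rank(lon[t - 1], lat[t - 1])
        p_search <- stats::plogis(b0 + alpha_i + sum(bslope * x))
        if (refractory <= 0L && stats::runif(1) < p_search) {
          state <- "search"
          patch_lon <- lon[t - 1]
          patch_lat <- lat[t - 1]
          rot_sign <- sample(c(-1, 1), 1)
          dwell_left <- max(1L, round(stats::rgamma(1, shape = 2,
                                                    scale = config$search_dwell_min / 2) *
                                        60 / dt))
        }
      }
      if (state == "transit") {
        heading <- heading + wrapped_cauchy(1, config$transit_turn_rho)
        frac <- t / n_steps
        near_edge <- lon[t - 1] < w$lon_min + 0.15 | lon[t - 1] > w$lon_max - 0.15 |
          lat[t - 1] < w$lat_min + 0.15 | lat[t - 1] > w$lat_max - 0.15
        if (frac > 0.5 || near_edge) {
          to_col <- geosphere::bearingRhumb(c(lon[t - 1], lat[t - 1]),
                                            c(config$colony_lon, config$colony_lat)) *
            pi / 180
          wgt <- if (near_edge) 0.8 else
            config$homing_strength * 2 * (frac - 0.5)
          heading <- heading + wgt * wrap_angle(to_col - heading)
        }
        step_m <- stats::rgamma(1, shape = config$step_shape,
                                scale = config$transit_speed_ms * dt /
                                  config$step_shape)
      }
    }
    if (state == "search") {
      d_patch <- haversine_m(lon[t - 1], lat[t - 1], patch_lon, patch_lat)
      if (d_patch > 0.5 * config$patch_radius_m) {
        to_patch <- geosphere::bearingRhumb(c(lon[t - 1], lat[t - 1]),
                                            c(patch_lon, patch_lat)) * pi / 180
        heading <- to_patch + wrapped_cauchy(1, 0.5)
      } else {
        heading <- heading + rot_sign * config$search_turn_mean_deg * pi / 180 +
          wrapped_cauchy(1, config$search_turn_rho)
      }
      step_m <- stats::rgamma(1, shape = config$step_shape,
                              scale = config$search_speed_ms * dt /
                                config$step_shape)
      dwell_left <- dwell_left - 1L
      if (dwell_left <= 0L) {
        state <- "transit"
        heading <- stats::runif(1, -pi, pi)
        refractory <- max(1L, round(config$search_refractory_min * 60 / dt))
      }
    }

    nxt <- geosphere::destPoint(c(lon[t - 1], lat[t - 1]),
                                b = (heading * 180 / pi) %% 360,
                                d = step_m, r = 6371000)
    lon[t] <- nxt[1]
    lat[t] <- nxt[2]
    mode[t] <- if (state == "sitting") "sitting" else state

    if (lon[t] < w$lon_min || lon[t] > w$lon_max ||
        lat[t] < w$lat_min || lat[t] > w$lat_max) {
      warning("trip ", individual_id, "/", trip_id,
              " left the raster window; truncated", call. = FALSE)
      lon <- lon[1:(t - 1)]
      lat <- lat[1:(t - 1)]
      mode <- mode[1:(t - 1)]
      break
    }
  }

  t0 <- as.POSIXct(paste(date, "05:30:00"), tz = "UTC")
  tibble::tibble(
    individual_id = individual_id, trip_id = trip_id,
    timestamp = t0 + (seq_along(lon) - 1) * dt,
    lon = lon, lat = lat,
    true_mode = mode,
    true_sitting = mode == "sitting"
  )
}

#' @export
print.sim_output <- function(x, ...) {
  cat("<sim_output>", nrow(x$fixes), "fixes,",
      dplyr::n_distinct(x$fixes$individual_id), "individuals,",
      nrow(dplyr::distinct(x$fixes, .data$individual_id, .data$trip_id)),
      "trips;", nrow(x$rasters), "daily rasters\n")
  invisible(x)
}

#' Write a simulation as a self-contained fixture bundle
#'
#' Writes `tracks.csv`, `rasters/<variable>_<YYYYMMDD>.asc`, `truth.json`
#' and `config.yaml` so a run can be reloaded losslessly and re-analysed
#' end to end.
#'
#' @param sim A [simulate_tracks()] output.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- dplyr::mutate(sim$fixes,
                      timestamp = format(.data$timestamp,
                                         "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  readr::write_csv(fx, file.path(dir, "tracks.csv"), progress = FALSE)
  write_raster_stack(sim$rasters, file.path(dir, "rasters"))
  jsonlite::write_json(list(
    beta = as.list(sim$truth$beta), sigma_alpha = sim$truth$sigma_alpha,
    alpha = sim$truth$alpha, patch_radius_m = sim$truth$patch_radius_m
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  cfg <- unclass(sim$config)
  cfg$start_date <- format(cfg$start_date)
  cfg$beta <- as.list(cfg$beta)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Reload a fixture bundle written by [write_fixture_bundle()]
#'
#' @param dir Bundle directory.
#' @return A `sim_output` list (config restored from YAML).
#' @export
read_fixture_bundle <- function(dir) {
  fx <- readr::read_csv(file.path(dir, "tracks.csv"),
                        col_types = readr::cols(
                          individual_id = "c", trip_id = "c",
                          timestamp = readr::col_datetime(), lon = "d",
                          lat = "d", true_mode = "c", true_sitting = "l"),
                        progress = FALSE)
  rasters <- read_raster_stack(file.path(dir, "rasters"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  truth$beta <- unlist(truth$beta)
  truth$alpha <- tibble::as_tibble(truth$alpha)
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg$start_date <- as.Date(cfg$start_date)
  cfg$beta <- unlist(cfg$beta)
  cfg <- structure(cfg, class = "sim_config")
  structure(list(fixes = fx, rasters = rasters, truth = truth, config = cfg),
            class = "sim_output")
}
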