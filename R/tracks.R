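#' Read GPS tracks from delimited text
#'
#' Reads per-fix GPS records (individual id, trip id, timestamp, longitude,
#' latitude) from a CSV/TSV file into a single tidy fix table, one row per
#' fix, sorted by time within each (individual, trip). Duplicate timestamps
#' within a trip are collapsed to the first occurrence with a warning, and
#' out-of-order rows are re-sorted with a warning.
#'
#' @param path Path to a delimited text file. Timestamps must parse as
#'   ISO-8601 and are interpreted as UTC.
#' @param schema Named character vector mapping the canonical column names
#'   (`individual_id`, `timestamp`, `lon`, `lat`, and optionally `trip_id`)
#'   to the column names used in the file. When `trip_id` is not mapped each
#'   individual is treated as a single trip.
#' @param delim Field delimiter, default `","`.
#'
#' @return A tibble with columns `individual_id`, `trip_id`, `timestamp`
#'   (POSIXct, UTC), `lon`, `lat`. An empty file yields a zero-row tibble.
#' @export
read_tracks <- function(path,
                        schema = c(individual_id = "individual_id",
                                   trip_id = "trip_id",
                                   timestamp = "timestamp",
                                   lon = "lon", lat = "lat"),
                        delim = ",") {
  if (!file.exists(path)) stop("track file not found: ", path)
  required <- c("individual_id", "timestamp", "lon", "lat")
  missing_map <- setdiff(required, names(schema))
  if (length(missing_map) > 0)
    stop("schema must map columns: ", paste(missing_map, collapse = ", "))

  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (nrow(raw) == 0) return(empty_fix_table())

  missing_cols <- setdiff(unname(schema[required]), names(raw))
  if (length(missing_cols) > 0)
    stop("input file lacks required column(s): ", paste(missing_cols, collapse = ", "))

  fixes <- tibble::tibble(
    .line = seq_len(nrow(raw)) + 1L,  # header occupies line 1
    individual_id = as.character(raw[[schema[["individual_id"]]]]),
    trip_id = if ("trip_id" %in% names(schema) && schema[["trip_id"]] %in% names(raw))
      as.character(raw[[schema[["trip_id"]]]]) else "1",
    timestamp = suppressWarnings(
      as.POSIXct(raw[[schema[["timestamp"]]]], tz = "UTC",
                 tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                "%Y/%m/%d %H:%M:%OS"))),
    lon = suppressWarnings(as.numeric(raw[[schema[["lon"]]]])),
    lat = suppressWarnings(as.numeric(raw[[schema[["lat"]]]]))
  )

  bad <- is.na(fixes$timestamp) | is.na(fixes$lon) | is.na(fixes$lat) |
    fixes$lat < -90 | fixes$lat > 90 | fixes$lon < -180 | fixes$lon > 180
  if (any(bad))
    stop("unparseable or out-of-range rows at line(s): ",
         paste(fixes$.line[bad], collapse = ", "))

  out <- fixes |>
    dplyr::group_by(.data$individual_id, .data$trip_id) |>
    dplyr::group_modify(function(df, key) {
      if (is.unsorted(df$timestamp)) {
        warning("fixes out of time order for ", key$individual_id, "/",
                key$trip_id, "; re-sorted", call. = FALSE)
        df <- dplyr::arrange(df, .data$timestamp)
      }
      dup <- duplicated(df$timestamp)
      if (any(dup)) {
        warning(sum(dup), " duplicate timestamp(s) dropped for ",
                key$individual_id, "/", key$trip_id, call. = FALSE)
        df <- df[!dup, , drop = FALSE]
      }
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::select("individual_id", "trip_id", "timestamp", "lon", "lat")
  out
}

empty_fix_table <- function() {
  tibble::tibble(individual_id = character(), trip_id = character(),
                 timestamp = as.POSIXct(character(), tz = "UTC"),
                 lon = numeric(), lat = numeric())
}

#' Great-circle distance in metres
#'
#' Haversine distance on a sphere of radius 6,371,000 m, vectorised over
#' coordinate pairs. This is the distance kernel used throughout the package
#' (speed filtering and first-passage-time geometry); ellipsoidal precision
#' is unnecessary at the 1-minute fix scale of seabird tracks.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84).
#' @return Distance(s) in metres.
#' @export
haversine_m <- function(lon1, lat1, lon2, lat2) {
  stopifnot(all(abs(lat1) <= 90, na.rm = TRUE), all(abs(lat2) <= 90, na.rm = TRUE),
            all(abs(lon1) <= 180, na.rm = TRUE), all(abs(lon2) <= 180, na.rm = TRUE))
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371000)
}

#' Regularise tracks to a nominal fix interval
#'
#' Reduces each trip to a near-regular time series by greedy forward
#' subsampling: the first fix is kept, then each subsequent kept fix is the
#' one closest in time to (last kept + `interval`) within half an interval.
#' No positions are interpolated; gaps in the recording are preserved and
#' surface as segment boundaries (a new `segment_id` starts wherever the
#' interval between kept fixes exceeds `2 * interval`).
#'
#' @param fixes A fix table as returned by [read_tracks()].
#' @param interval Nominal inter-fix interval in seconds (default 60, i.e.
#'   1 fix per minute).
#' @return The retained fixes with added columns `dt_s` (seconds since the
#'   previous retained fix of the trip), `speed_ms` (incoming-segment speed),
#'   and `segment_id` (gap-delimited run within the trip).
#' @export
regularise <- function(fixes, interval = 60) {
  stopifnot(interval > 0)
  fixes |>
    dplyr::group_by(.data$individual_id, .data$trip_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$timestamp)
      keep <- greedy_grid_select(as.numeric(df$timestamp), interval)
      if (length(keep) < 2)
        warning("trip ", key$individual_id, "/", key$trip_id,
                " shorter than one interval; unusable downstream", call. = FALSE)
      df <- df[keep, , drop = FALSE]
      add_kinematics(df, interval)
    }) |>
    dplyr::ungroup()
}

# Greedy nearest-to-grid subsampling. Returns indices of kept fixes.
greedy_grid_select <- function(t, interval) {
  n <- length(t)
  keep <- integer(n)
  keep[1] <- 1L
  nk <- 1L
  i <- 1L
  last <- t[1]
  while (i < n) {
    target <- last + interval
    lo <- target - interval / 2
    hi <- target + interval / 2
    # candidates strictly after the last kept fix and inside the window
    j <- i + 1L
    while (j <= n && t[j] < lo) j <- j + 1L
    if (j > n) break
    if (t[j] <= hi) {
      best <- j
      while (j <= n && t[j] <= hi) {
        if (abs(t[j] - target) < abs(t[best] - target)) best <- j
        j <- j + 1L
      }
    } else {
      best <- j  # gap: resume at the first fix beyond the window
    }
    nk <- nk + 1L
    keep[nk] <- best
    i <- best
    last <- t[best]
  }
  keep[seq_len(nk)]
}

# dt, incoming speed and gap-delimited segment ids for one trip's fixes.
add_kinematics <- function(df, interval) {
  n <- nrow(df)
  dt <- c(NA_real_, diff(as.numeric(df$timestamp)))
  dist <- c(NA_real_,
            if (n > 1) haversine_m(df$lon[-n], df$lat[-n], df$lon[-1], df$lat[-1]))
  df$dt_s <- dt
  df$speed_ms <- dist / dt
  gap <- !is.na(dt) & dt > 2 * interval
  df$segment_id <- cumsum(dplyr::coalesce(gap, FALSE)) + 1L
  df
}

#' Flag fixes where the bird is sitting on the water
#'
#' A fix is flagged as sitting when the speed of the track segment arriving
#' at it is below `speed_threshold_kmh` (slow fixes on a flying seabird
#' track indicate resting on the water). Flagged fixes stay in the returned
#' table (column `sitting`) but are meant to be dropped from behavioural
#' analysis; use [retained_fixes()] to extract the non-sitting sequence with
#' speeds and segment ids recomputed once over it.
#'
#' @param fixes A regularised fix table from [regularise()].
#' @param speed_threshold_kmh Speed threshold in km/h (default 10).
#' @return `fixes` with a logical `sitting` column. The first fix of a trip
#'   (undefined incoming speed) is never flagged.
#' @export
flag_sitting <- function(fixes, speed_threshold_kmh = 10) {
  thr_ms <- speed_threshold_kmh / 3.6
  dplyr::mutate(fixes,
                sitting = !is.na(.data$speed_ms) & .data$speed_ms < thr_ms)
}

#' Non-sitting fixes with kinematics recomputed
#'
#' Drops sitting-flagged fixes and recomputes `dt_s`, `speed_ms` and
#' `segment_id` over the retained sequence in a single pass (removed sitting
#' bouts longer than two nominal intervals therefore become segment
#' boundaries, which breaks first-passage-time accumulation across them).
#'
#' @param fixes Output of [flag_sitting()].
#' @param interval Nominal interval in seconds used for gap detection.
#' @return The retained fixes, same columns, `sitting` all `FALSE`.
#' @export
retained_fixes <- function(fixes, interval = 60) {
  fixes |>
    dplyr::filter(!.data$sitting) |>
    dplyr::group_by(.data$individual_id, .data$trip_id) |>
    dplyr::group_modify(~ add_kinematics(.x, interval)) |>
    dplyr::ungroup()
}
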