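#' Log-spaced radius sweep for first-passage-time analysis
#'
#' @param n Number of radii (default 40).
#' @param min,max Smallest and largest radius in metres (defaults 5 and
#'   1000, the range over which area-restricted search scales of a
#'   plunge-diving seabird are expected to fall).
#' @return Strictly increasing numeric vector of radii in metres.
#' @export
fpt_radii <- function(n = 40, min = 5, max = 1000) {
  stopifnot(n >= 2, min > 0, max > min)
  exp(seq(log(min), log(max), length.out = n))
}

#' First-passage time of one fix through one circle
#'
#' Time for the track to cross a circle of radius `radius` centred on the
#' focal fix, summing the forward passage (focal fix until the path first
#' leaves the circle moving forward) and the backward passage (likewise
#' moving backward). Exit instants are located by linear interpolation of
#' the great-circle distance to the centre along the chord between the last
#' inside fix and the first outside fix. The result is `NA` when the track
#' ends, or a recording gap (segment boundary) occurs, before the circle is
#' exited in either direction.
#'
#' @param fixes Retained fixes of a single trip ([retained_fixes()]), with
#'   `segment_id`.
#' @param fix_index Row index of the focal fix.
#' @param radius Circle radius in metres.
#' @return First-passage time in seconds, or `NA`.
#' @export
first_passage_time <- function(fixes, fix_index, radius) {
  stopifnot(radius > 0)
  n <- nrow(fixes)
  if (fix_index < 1 || fix_index > n) stop("fix_index out of range")
  m <- fpt_matrix_cpp(fixes$lon, fixes$lat, as.numeric(fixes$timestamp),
                      as.integer(fixes$segment_id), radius)
  m[fix_index, 1]
}

#' First-passage-time profile of one trip
#'
#' Computes the full fix-by-radius FPT matrix for one trip and the
#' per-radius dispersion of log-FPT. The radius maximising that dispersion
#' is the trip's candidate area-restricted-search scale: at radii near the
#' size of search patches, passage times split most strongly between fast
#' transit crossings and long patch residencies.
#'
#' @param fixes Retained fixes of a single trip ([retained_fixes()]).
#' @param radii Ascending radius sweep in metres, default [fpt_radii()].
#' @param var_stat Dispersion statistic: `"var_log_fpt"` (default; variance
#'   of log FPT) or `"log_var_fpt"` (log of the variance of raw FPT, the
#'   wording-literal alternative, exposed for sensitivity checks).
#' @param min_defined Minimum number of fixes with a defined FPT for a
#'   radius to enter the variance profile (default 5).
#' @return An object of class `fpt_profile`: list with `fpt` (fix x radius
#'   matrix, seconds), `radii`, `variance_profile` (tibble of radius,
#'   variance, n_defined), `peak_radius` (metres, `NA` when undetectable),
#'   `individual_id`, `trip_id` and the fix table.
#' @export
fpt_profile <- function(fixes, radii = fpt_radii(),
                        var_stat = c("var_log_fpt", "log_var_fpt"),
                        min_defined = 5) {
  var_stat <- match.arg(var_stat)
  stopifnot(all(diff(radii) > 0), all(radii > 0))
  if (nrow(fixes) < 3) stop("fpt_profile needs at least 3 non-sitting fixes")
  if (length(unique(fixes$individual_id)) > 1 ||
      length(unique(fixes$trip_id)) > 1)
    stop("fpt_profile operates on a single trip; got several")

  m <- fpt_matrix_cpp(fixes$lon, fixes$lat, as.numeric(fixes$timestamp),
                      as.integer(fixes$segment_id), radii)
  n_def <- colSums(!is.na(m))
  vp <- vapply(seq_along(radii), function(k) {
    v <- m[, k]
    v <- v[!is.na(v)]
    if (length(v) < min_defined) return(NA_real_)
    if (var_stat == "var_log_fpt") stats::var(log(v)) else log(stats::var(v))
  }, numeric(1))

  if (all(is.na(vp)))
    stop("scale undetectable: no radius has >= ", min_defined,
         " defined FPT values for trip ", fixes$individual_id[1], "/",
         fixes$trip_id[1])

  peak <- NA_real_
  finite_vp <- vp[is.finite(vp)]
  if (length(finite_vp) > 0 && diff(range(finite_vp)) > 1e-12) {
    peak <- radii[which.max(vp)]
  } else {
    warning("flat variance profile; ARS scale undetectable for trip ",
            fixes$individual_id[1], "/", fixes$trip_id[1], call. = FALSE)
  }

  structure(list(
    fpt = m, radii = radii,
    variance_profile = tibble::tibble(radius_m = radii, variance = vp,
                                      n_defined = n_def),
    peak_radius = peak, var_stat = var_stat,
    individual_id = fixes$individual_id[1], trip_id = fixes$trip_id[1],
    fixes = fixes
  ), class = "fpt_profile")
}

#' @export
print.fpt_profile <- function(x, ...) {
  cat("<fpt_profile> trip", x$individual_id, "/", x$trip_id, "\n",
      nrow(x$fpt), "fixes x", length(x$radii), "radii;",
      "peak radius:", ifelse(is.na(x$peak_radius), "undetectable",
                             paste0(round(x$peak_radius, 1), " m")), "\n")
  invisible(x)
}

#' FPT values of each fix at one working radius
#'
#' @param profile An [fpt_profile()] object.
#' @param radius Working radius in metres; the nearest radius of the sweep
#'   is used (exact match not required).
#' @return The profile's fix table with an `fpt_s` column.
#' @export
fpt_at_scale <- function(profile, radius) {
  k <- which.min(abs(profile$radii - radius))
  dplyr::mutate(profile$fixes, fpt_s = profile$fpt[, k])
}

#' Area-restricted-search scale across trips
#'
#' Collects the per-trip variance-peak radii and takes their median as the
#' working ARS scale of the data set (with an even number of trips, the
#' mean of the central pair). Trips whose profile has no detectable peak
#' are omitted with a warning.
#'
#' @param profiles List of [fpt_profile()] objects.
#' @return Object of class `ars_scale`: list with `per_track_peaks`
#'   (tibble: individual_id, trip_id, peak_radius_m) and `global_scale_m`.
#' @export
ars_scale <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  peaks <- purrr::map_dfr(profiles, function(p) {
    tibble::tibble(individual_id = p$individual_id, trip_id = p$trip_id,
                   peak_radius_m = p$peak_radius)
  })
  undet <- is.na(peaks$peak_radius_m)
  if (any(undet))
    warning(sum(undet), " trip(s) with undetectable ARS scale omitted",
            call. = FALSE)
  peaks_use <- peaks[!undet, , drop = FALSE]
  if (nrow(peaks_use) == 0) stop("no trip with a detectable ARS scale")
  structure(list(per_track_peaks = peaks,
                 global_scale_m = stats::median(peaks_use$peak_radius_m)),
            class = "ars_scale")
}

#' @export
print.ars_scale <- function(x, ...) {
  cat("<ars_scale> global scale:", round(x$global_scale_m, 1), "m (median of",
      sum(!is.na(x$per_track_peaks$peak_radius_m)), "trip peaks)\n")
  invisible(x)
}

#' Serialise an FPT profile to a long table
#'
#' @param x An `fpt_profile`.
#' @param ... Unused.
#' @return Tibble with one row per (fix, radius): `fix`, `radius_m`, `fpt_s`.
#' @method tidy fpt_profile
#' @export
tidy.fpt_profile <- function(x, ...) {
  tibble::tibble(
    fix = rep(seq_len(nrow(x$fpt)), times = length(x$radii)),
    radius_m = rep(x$radii, each = nrow(x$fpt)),
    fpt_s = as.vector(x$fpt)
  )
}
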