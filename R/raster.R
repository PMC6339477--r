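#' Daily oceanographic raster
#'
#' A minimal single-band georeferenced grid: a numeric matrix in geographic
#' (WGS84) coordinates with square cells, south-up storage (row 1 is the
#' southernmost row, column 1 the westernmost column). Cells are half-open,
#' `[west, east) x [south, north)`.
#'
#' @param values Numeric matrix (rows = latitude bands, cols = longitude
#'   bands); `NA` marks missing cells (cloud cover).
#' @param xmin,ymin Western and southern edge of the grid, decimal degrees.
#' @param cell Cell size in decimal degrees (> 0).
#' @param variable Variable name, e.g. `"sst"`, `"turbidity"`, `"chla"`.
#' @param date Acquisition date (`Date`).
#' @param units Physical units string.
#' @return An `ocean_raster` object.
#' @export
ocean_raster <- function(values, xmin, ymin, cell,
                         variable = NA_character_, date = NA, units = NA_character_) {
  stopifnot(is.matrix(values), cell > 0)
  structure(list(values = values, xmin = xmin, ymin = ymin, cell = cell,
                 variable = variable, date = date, units = units),
            class = "ocean_raster")
}

#' @export
print.ocean_raster <- function(x, ...) {
  cat("<ocean_raster>", x$variable, format(x$date), ":",
      nrow(x$values), "x", ncol(x$values), "cells of", x$cell, "deg;",
      sum(is.na(x$values)), "missing\n")
  invisible(x)
}

#' @method as_tibble ocean_raster
#' @export
as_tibble.ocean_raster <- function(x, ...) {
  tibble::tibble(
    lon = rep(x$xmin + (seq_len(ncol(x$values)) - 0.5) * x$cell,
              each = nrow(x$values)),
    lat = rep(x$ymin + (seq_len(nrow(x$values)) - 0.5) * x$cell,
              times = ncol(x$values)),
    value = as.vector(x$values)
  )
}

raster_lon_centres <- function(r) r$xmin + (seq_len(ncol(r$values)) - 0.5) * r$cell
raster_lat_centres <- function(r) r$ymin + (seq_len(nrow(r$values)) - 0.5) * r$cell

#' Aggregate a raster to a coarser cell size
#'
#' Each target cell takes the mean of the source cells whose centres fall
#' inside it, ignoring missing values; a target cell is missing only when
#' it contains no valid source cell. Coarsening daily ocean-colour imagery
#' this way fills small cloud holes from neighbouring clear pixels. The
#' target grid is anchored at the analysis-window origin.
#'
#' @param r An [ocean_raster()].
#' @param target_cell Target cell size in decimal degrees (default 0.05,
#'   about 5.57 km at the equator); must be >= the source cell size.
#' @param window Optional list with `lon_min`, `lon_max`, `lat_min`,
#'   `lat_max` anchoring (and cropping to) the analysis extent; default is
#'   the raster's own extent.
#' @return An aggregated `ocean_raster`.
#' @export
aggregate_raster <- function(r, target_cell = 0.05, window = NULL) {
  stopifnot(target_cell >= r$cell - 1e-12)
  if (is.null(window))
    window <- list(lon_min = r$xmin, lon_max = r$xmin + ncol(r$values) * r$cell,
                   lat_min = r$ymin, lat_max = r$ymin + nrow(r$values) * r$cell)
  ncol_t <- ceiling((window$lon_max - window$lon_min) / target_cell - 1e-9)
  nrow_t <- ceiling((window$lat_max - window$lat_min) / target_cell - 1e-9)
  if (ncol_t < 1 || nrow_t < 1) stop("empty analysis window")

  lonc <- raster_lon_centres(r)
  latc <- raster_lat_centres(r)
  ci <- floor((lonc - window$lon_min) / target_cell)
  ri <- floor((latc - window$lat_min) / target_cell)
  keep_c <- ci >= 0 & ci < ncol_t
  keep_r <- ri >= 0 & ri < nrow_t
  if (!any(keep_c) || !any(keep_r))
    stop("raster does not overlap the analysis window")

  v <- r$values[keep_r, keep_c, drop = FALSE]
  idx <- as.vector(outer(ri[keep_r], ci[keep_c] * nrow_t, "+")) + 1L
  vals <- as.vector(v)
  ok <- !is.na(vals)
  sums <- rowsum(vals[ok], idx[ok])
  cnts <- rowsum(rep(1, sum(ok)), idx[ok])
  out <- rep(NA_real_, nrow_t * ncol_t)
  out[as.integer(rownames(sums))] <- sums / cnts
  ocean_raster(matrix(out, nrow = nrow_t, ncol = ncol_t),
               xmin = window$lon_min, ymin = window$lat_min,
               cell = target_cell, variable = r$variable, date = r$date,
               units = r$units)
}

#' Average a day's raster with the previous day's
#'
#' Cellwise NA-ignoring mean of the rasters for `date` and `date - 1` of a
#' variable, reflecting that a foraging bird's route choice uses recent
#' (previous-day) experience of the ocean surface. With only one of the two
#' days available that day is returned with a warning.
#'
#' @param stack Raster stack: tibble with columns `variable`, `date`
#'   (`Date`) and `raster` (list of [ocean_raster()]).
#' @param variable Variable name.
#' @param date Target `Date`.
#' @return An `ocean_raster` of the two-day mean.
#' @export
two_day_average <- function(stack, variable, date) {
  r_today <- stack_get(stack, variable, date)
  r_prev <- stack_get(stack, variable, date - 1)
  if (is.null(r_today) && is.null(r_prev))
    stop("no raster for ", variable, " on ", date, " or the day before")
  if (is.null(r_today) || is.null(r_prev)) {
    warning("only one day available for ", variable, " on ", format(date),
            "; using it alone", call. = FALSE)
    r <- if (is.null(r_today)) r_prev else r_today
    r$date <- date
    return(r)
  }
  stopifnot(identical(dim(r_today$values), dim(r_prev$values)))
  a <- r_today$values
  b <- r_prev$values
  m <- ifelse(is.na(a), b, ifelse(is.na(b), a, (a + b) / 2))
  out <- r_today
  out$values <- m
  out$date <- date
  out
}

stack_get <- function(stack, variable, date) {
  i <- which(stack$variable == variable & stack$date == date)
  if (length(i) == 0) return(NULL)
  stack$raster[[i[1]]]
}

#' Rank-standardise a raster onto a 0-20 scale
#'
#' Replaces each valid cell by its within-image rank (average ranks for
#' ties) mapped linearly onto `[0, 20]`. This makes covariate images
#' comparable across days whose absolute ranges differ strongly, as in an
#' oligotrophic ocean with low day-to-day predictability. Missing cells
#' stay missing; ranks are continuous, not binned.
#'
#' @param r An [ocean_raster()] with at least 2 valid cells.
#' @return The ranked `ocean_raster` (values in `[0, 20]`).
#' @export
rank_standardise <- function(r) {
  v <- as.vector(r$values)
  ok <- !is.na(v)
  if (sum(ok) < 2) stop("rank standardisation needs >= 2 valid cells")
  out <- rep(NA_real_, length(v))
  vv <- v[ok]
  if (diff(range(vv)) == 0) {
    warning("all cells equal; degenerate ranking to mid-scale", call. = FALSE)
    out[ok] <- 10
  } else {
    rk <- rank(vv, ties.method = "average")
    out[ok] <- 20 * (rk - 1) / (length(vv) - 1)
  }
  r$values <- matrix(out, nrow = nrow(r$values))
  r
}

#' Sample a raster at point locations
#'
#' Returns the value of the cell containing each point (half-open cells:
#' a point on a shared edge belongs to the cell to its east/north). No
#' interpolation: behaviour is related to the habitat pixel.
#'
#' @param r An [ocean_raster()].
#' @param lon,lat Point coordinates in decimal degrees (vectorised).
#' @return Numeric vector of cell values (`NA` for missing cells).
#' @export
sample_raster <- function(r, lon, lat) {
  ci <- floor((lon - r$xmin) / r$cell) + 1
  ri <- floor((lat - r$ymin) / r$cell) + 1
  outside <- ci < 1 | ci > ncol(r$values) | ri < 1 | ri > nrow(r$values)
  if (any(outside))
    stop(sum(outside), " point(s) outside the raster window")
  r$values[cbind(ri, ci)]
}

#' Temporal predictability of a covariate field
#'
#' Mean Pearson correlation over all pairs of daily images of a variable,
#' computed on jointly valid cells. Values near zero characterise a highly
#' unpredictable environment in which foraging site fidelity pays little.
#'
#' @param stack Raster stack (see [two_day_average()]).
#' @param variable Variable name.
#' @param min_cells Minimum jointly valid cells for a pair (default 3);
#'   sparser pairs are skipped with a warning.
#' @return Mean pairwise correlation (scalar).
#' @export
temporal_predictability <- function(stack, variable, min_cells = 3) {
  sub <- stack[stack$variable == variable, , drop = FALSE]
  if (nrow(sub) < 2) stop("need >= 2 dates for ", variable)
  sub <- sub[order(sub$date), , drop = FALSE]
  vals <- lapply(sub$raster, function(r) as.vector(r$values))
  rs <- c()
  for (i in seq_len(length(vals) - 1)) {
    for (j in seq(i + 1, length(vals))) {
      ok <- !is.na(vals[[i]]) & !is.na(vals[[j]])
      if (sum(ok) < min_cells) {
        warning("pair ", format(sub$date[i]), "/", format(sub$date[j]),
                " skipped: too few jointly valid cells", call. = FALSE)
        next
      }
      rs <- c(rs, stats::cor(vals[[i]][ok], vals[[j]][ok]))
    }
  }
  mean(rs)
}

#' Pairwise correlations between annotated covariates
#'
#' Pearson correlations between the ranked covariate columns of the fixes
#' entering the habitat model, a collinearity diagnostic for the fixed
#' effects.
#'
#' @param fixes Annotated fix table.
#' @param cols Covariate column names (default the three ranked variables).
#' @return Tibble with columns `var1`, `var2`, `r`.
#' @export
covariate_correlations <- function(fixes,
                                   cols = c("sst_rank", "turbidity_rank",
                                            "chla_rank")) {
  x <- fixes[, cols, drop = FALSE]
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3) stop("need >= 3 fixes with all covariates defined")
  constant <- vapply(x, function(v) stats::sd(v) == 0, logical(1))
  if (any(constant))
    warning("constant covariate column(s): ",
            paste(cols[constant], collapse = ", "),
            "; correlation undefined", call. = FALSE)
  pairs <- utils::combn(cols, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]
    b <- pairs[2, k]
    r <- if (constant[[a]] || constant[[b]]) NA_real_ else
      stats::cor(x[[a]], x[[b]])
    tibble::tibble(var1 = a, var2 = b, r = r)
  })
}

#' Annotate fixes with ranked two-day-averaged covariates
#'
#' For each fix, takes the raster of its own UTC calendar date and the day
#' before, averages them cellwise, rank-standardises the averaged image
#' over the analysis window, and samples the result at the fix location.
#' The alternative order (rank each day, then average the ranked images) is
#' available via `order`.
#'
#' @param fixes Fix table with `timestamp`, `lon`, `lat`.
#' @param stack Raster stack of aggregated daily rasters.
#' @param variables Variable names to annotate (columns `<variable>_rank`).
#' @param order `"average_then_rank"` (default) or `"rank_then_average"`.
#' @return `fixes` with one ranked covariate column per variable.
#' @export
annotate_fixes <- function(fixes, stack,
                           variables = c("sst", "turbidity", "chla"),
                           order = c("average_then_rank", "rank_then_average")) {
  order <- match.arg(order)
  dates <- as.Date(fixes$timestamp, tz = "UTC")
  out <- fixes
  for (v in variables) {
    col <- rep(NA_real_, nrow(fixes))
    for (d in unique(dates)) {
      d <- as.Date(d, origin = "1970-01-01")
      idx <- which(dates == d)
      r <- if (order == "average_then_rank") {
        rank_standardise(two_day_average(stack, v, d))
      } else {
        rank_pair_average(stack, v, d)
      }
      col[idx] <- sample_raster(r, fixes$lon[idx], fixes$lat[idx])
    }
    out[[paste0(v, "_rank")]] <- col
  }
  out
}

# rank each day's image first, then average the ranked pair
rank_pair_average <- function(stack, variable, date) {
  r_today <- stack_get(stack, variable, date)
  r_prev <- stack_get(stack, variable, date - 1)
  ranked <- lapply(Filter(Negate(is.null), list(r_today, r_prev)),
                   rank_standardise)
  if (length(ranked) == 0)
    stop("no raster for ", variable, " on ", date, " or the day before")
  if (length(ranked) == 1) {
    warning("only one day available for ", variable, " on ", format(date),
            "; using it alone", call. = FALSE)
    out <- ranked[[1]]
    out$date <- date
    return(out)
  }
  a <- ranked[[1]]$values
  b <- ranked[[2]]$values
  out <- ranked[[1]]
  out$values <- ifelse(is.na(a), b, ifelse(is.na(b), a, (a + b) / 2))
  out$date <- date
  out
}
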