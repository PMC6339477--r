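#' Read a single-band raster from an ESRI ASCII grid file
#'
#' ASCII grid (`.asc`) is the plain-text sibling of single-band GeoTIFF:
#' a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by rows of cell values ordered
#' north to south. Variable and date are taken from the file name, which
#' follows `<variable>_<YYYYMMDD>.asc`.
#'
#' @param path Path to an `.asc` file.
#' @return An [ocean_raster()].
#' @export
read_ascii_raster <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # file is north-up; store south-up

  base <- sub("\\.asc$", "", basename(path))
  parts <- strsplit(base, "_")[[1]]
  variable <- paste(parts[-length(parts)], collapse = "_")
  date <- tryCatch(as.Date(parts[length(parts)], format = "%Y%m%d"),
                   error = function(e) NA)
  ocean_raster(m, xmin = hdr$xllcorner, ymin = hdr$yllcorner,
               cell = hdr$cellsize, variable = variable, date = date)
}

#' Write a raster as an ESRI ASCII grid file
#'
#' @param r An [ocean_raster()].
#' @param path Output path; with `path` a directory, the file is named
#'   `<variable>_<YYYYMMDD>.asc`.
#' @param nodata Sentinel written for missing cells (default -9999).
#' @return The file path, invisibly.
#' @export
write_ascii_raster <- function(r, path, nodata = -9999) {
  if (dir.exists(path))
    path <- file.path(path, sprintf("%s_%s.asc", r$variable,
                                    format(r$date, "%Y%m%d")))
  m <- r$values[rev(seq_len(nrow(r$values))), , drop = FALSE]  # north-up on disk
  m[is.na(m)] <- nodata
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           paste("xllcorner", format(r$xmin, digits = 12)),
           paste("yllcorner", format(r$ymin, digits = 12)),
           paste("cellsize", format(r$cell, digits = 12)),
           paste("NODATA_value", nodata))
  body <- apply(m, 1, function(row) paste(format(row, digits = 9, trim = TRUE),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a directory of daily rasters into a stack
#'
#' @param dir Directory containing `<variable>_<YYYYMMDD>.asc` files.
#' @return Raster stack tibble (`variable`, `date`, `raster` list-column).
#' @export
read_raster_stack <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (length(files) == 0) stop("no .asc rasters in ", dir)
  rasters <- lapply(files, read_ascii_raster)
  tibble::tibble(
    variable = vapply(rasters, function(r) r$variable, character(1)),
    date = as.Date(vapply(rasters, function(r) as.character(r$date),
                          character(1))),
    raster = rasters
  )
}

#' Write a raster stack to a directory of ASCII grid files
#'
#' @param stack Raster stack tibble.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_raster_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(stack))) write_ascii_raster(stack$raster[[i]], dir)
  invisible(dir)
}

#' Write labelled fixes as GeoJSON points
#'
#' @param fixes Behaviour table with `lon`, `lat` and any further columns,
#'   written as feature properties.
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_geojson_points <- function(fixes, path) {
  props <- fixes[, setdiff(names(fixes), c("lon", "lat")), drop = FALSE]
  features <- lapply(seq_len(nrow(fixes)), function(i) {
    p <- lapply(props[i, , drop = FALSE], function(v) {
      if (inherits(v, "POSIXct")) format(v, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
      else if (is.factor(v)) as.character(v) else v
    })
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(fixes$lon[i], fixes$lat[i])),
         properties = p)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
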