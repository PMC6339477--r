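#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. `tracks` and `rasters`
#' may be in-memory objects (fix tibble / raster stack) or paths (CSV file
#' / directory of `.asc` rasters), so a written fixture bundle and a live
#' simulation run identically.
#'
#' @param tracks Fix table or path to a tracks CSV.
#' @param rasters Raster stack tibble or path to a raster directory.
#' @param window Analysis window list (`lon_min`, `lon_max`, `lat_min`,
#'   `lat_max`); `NULL` uses the extent of the first raster.
#' @param interval Nominal fix interval, seconds (default 60).
#' @param speed_threshold_kmh Sitting speed threshold (default 10 km/h).
#' @param radii FPT radius sweep in metres (default [fpt_radii()], 40
#'   log-spaced radii over 5-1000 m).
#' @param t_high Travel/search FPT threshold, seconds (default 300).
#' @param var_stat Dispersion statistic for the ARS-scale profile (see
#'   [fpt_profile()]).
#' @param rank_order Covariate processing order (see [annotate_fixes()]).
#' @param target_cell Aggregation cell size in degrees (default 0.05).
#' @param variables Covariate names (default sst, turbidity, chla).
#' @param quadrature_nodes Gauss-Hermite nodes for the GLMM (default 25).
#' @param output_dir Optional directory for CSV/JSON outputs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tracks, rasters, window = NULL,
                            interval = 60, speed_threshold_kmh = 10,
                            radii = fpt_radii(), t_high = 300,
                            var_stat = "var_log_fpt",
                            rank_order = "average_then_rank",
                            target_cell = 0.05,
                            variables = c("sst", "turbidity", "chla"),
                            quadrature_nodes = 25,
                            output_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full foraging-habitat analysis
#'
#' Executes the chain: read tracks, regularise to the nominal interval,
#' flag and drop sitting fixes, compute per-trip FPT profiles and the
#' global ARS scale, classify travel/search at that scale, aggregate and
#' rank-standardise the two-day-averaged covariate rasters, annotate each
#' fix by its own UTC date, and fit the binomial random-intercept GLMM of
#' search probability on the ranked covariates. Stage failures for single
#' trips (e.g. an undetectable ARS scale) are downgraded to warnings and
#' the trip dropped; failures of whole stages propagate with the stage
#' name.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report`: list with `behaviour` (labelled fix table
#'   with covariates), `ars` ([ars_scale()]), `fit` ([fit_binomial_glmm()]),
#'   `stage_counts` tibble, and `diagnostics` (per-trip peaks, covariate
#'   correlations, temporal predictability per variable, label counts).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  fixes <- if (is.character(cfg$tracks)) read_tracks(cfg$tracks) else cfg$tracks
  stack <- if (is.character(cfg$rasters)) read_raster_stack(cfg$rasters) else cfg$rasters
  if (is.null(cfg$window)) {
    r1 <- stack$raster[[1]]
    cfg$window <- list(lon_min = r1$xmin,
                       lon_max = r1$xmin + ncol(r1$values) * r1$cell,
                       lat_min = r1$ymin,
                       lat_max = r1$ymin + nrow(r1$values) * r1$cell)
  }
  n_raw <- nrow(fixes)
  if (n_raw == 0) stop("stage read: no fixes")

  reg <- regularise(fixes, interval = cfg$interval)
  n_reg <- nrow(reg)

  flagged <- flag_sitting(reg, speed_threshold_kmh = cfg$speed_threshold_kmh)
  active <- retained_fixes(flagged, interval = cfg$interval)
  n_active <- nrow(active)
  if (n_active == 0) stop("stage flag_sitting: no non-sitting fixes")

  trips <- dplyr::group_split(dplyr::group_by(active, .data$individual_id,
                                              .data$trip_id))
  profiles <- list()
  failed <- character()
  for (tr in trips) {
    p <- tryCatch(fpt_profile(tr, radii = cfg$radii, var_stat = cfg$var_stat),
                  error = function(e) e)
    if (inherits(p, "error")) {
      failed <- c(failed, paste0(tr$individual_id[1], "/", tr$trip_id[1],
                                 " (", conditionMessage(p), ")"))
    } else {
      profiles[[length(profiles) + 1]] <- p
    }
  }
  if (length(profiles) == 0)
    stop("stage fpt: no usable trip; failures: ",
         paste(failed, collapse = "; "))
  if (length(failed) > 0)
    warning("stage fpt: dropped trip(s) ", paste(failed, collapse = "; "),
            call. = FALSE)

  ars <- ars_scale(profiles)
  at_scale <- dplyr::bind_rows(lapply(profiles, fpt_at_scale,
                                      radius = ars$global_scale_m))
  n_fpt <- sum(!is.na(at_scale$fpt_s))

  behaviour <- classify_behaviour(at_scale, t_high = cfg$t_high)
  n_classified <- sum(behaviour$label %in% c("travel", "search"))

  agg_stack <- stack
  agg_stack$raster <- lapply(stack$raster, aggregate_raster,
                             target_cell = cfg$target_cell,
                             window = cfg$window)
  behaviour <- annotate_fixes(behaviour, agg_stack,
                              variables = cfg$variables,
                              order = cfg$rank_order)

  model_data <- behaviour |>
    dplyr::filter(.data$label %in% c("travel", "search")) |>
    dplyr::mutate(y = as.integer(.data$label == "search"))
  rank_cols <- paste0(cfg$variables, "_rank")
  fit <- fit_binomial_glmm(model_data, response = "y",
                           covariates = rank_cols,
                           group = "individual_id",
                           quadrature_nodes = cfg$quadrature_nodes)
  n_model <- fit$nobs

  counts <- tibble::tibble(
    stage = c("raw", "regularised", "non_sitting", "fpt_defined",
              "classified", "modelled"),
    n = c(n_raw, n_reg, n_active, n_fpt, n_classified, n_model))

  diagnostics <- list(
    per_track_peaks = ars$per_track_peaks,
    covariate_correlations = covariate_correlations(model_data,
                                                    cols = rank_cols),
    temporal_predictability = stats::setNames(
      vapply(cfg$variables, function(v)
        temporal_predictability(stack, v), numeric(1)), cfg$variables),
    label_counts = dplyr::count(behaviour, .data$label, .drop = FALSE)
  )

  report <- structure(list(behaviour = behaviour, ars = ars, fit = fit,
                           stage_counts = counts, diagnostics = diagnostics,
                           config = cfg),
                      class = "pipeline_report")
  if (!is.null(cfg$output_dir)) write_report(report, cfg$output_dir)
  report
}

#' Fix counts surviving each pipeline stage
#'
#' Ordered counts of fixes at each filtering stage: raw, regularised,
#' non-sitting, FPT-defined, classified (travel + search) and modelled.
#' Counts are non-increasing along the chain.
#'
#' @param report A [run_pipeline()] report.
#' @return Tibble with `stage` and `n`.
#' @export
stage_counts <- function(report) {
  stopifnot(inherits(report, "pipeline_report"))
  report$stage_counts
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat("ARS scale:", round(x$ars$global_scale_m, 1), "m\n")
  print(as.data.frame(x$stage_counts), row.names = FALSE)
  cat("\n")
  print(x$fit)
  invisible(x)
}

# CSV/JSON outputs of a completed run
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$behaviour, file.path(dir, "behaviour.csv"),
                   progress = FALSE)
  write_fit_json(report$fit, file.path(dir, "fit.json"))
  readr::write_csv(report$stage_counts, file.path(dir, "stage_counts.csv"),
                   progress = FALSE)
  readr::write_csv(report$diagnostics$per_track_peaks,
                   file.path(dir, "ars_peaks.csv"), progress = FALSE)
  summary_txt <- utils::capture.output(print(report$fit))
  writeLines(summary_txt, file.path(dir, "model_summary.txt"))
  invisible(dir)
}
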