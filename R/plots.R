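#' Variance profile of an FPT sweep
#'
#' Plots the dispersion of log first-passage time against circle radius
#' (log axis) with the detected area-restricted-search scale marked.
#'
#' @param object An [fpt_profile()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fpt_profile
#' @export
autoplot.fpt_profile <- function(object, ...) {
  df <- object$variance_profile
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$radius_m, y = .data$variance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Radius (m)",
                  y = if (object$var_stat == "var_log_fpt")
                    "var(log FPT)" else "log var(FPT)",
                  title = paste("FPT variance profile,",
                                object$individual_id, "/", object$trip_id)) +
    ggplot2::theme_minimal()
  if (!is.na(object$peak_radius))
    p <- p + ggplot2::geom_vline(xintercept = object$peak_radius,
                                 linetype = "dashed", colour = "red")
  p
}

#' Partial-effect curves of a habitat-preference GLMM
#'
#' One panel per covariate: population-level predicted probability of
#' search behaviour over the 0-20 rank range, other covariates held at
#' mid-rank, with 95% Wald bands.
#'
#' @param object A [fit_binomial_glmm()] object.
#' @param at Reference rank for the covariates held fixed (default 10).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot glmm_fit
#' @export
autoplot.glmm_fit <- function(object, at = 10, ...) {
  curves <- purrr::map_dfr(object$covariates, function(v)
    dplyr::mutate(partial_effect(object, v, at = at), covariate = v))
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$value, y = .data$prob)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~covariate) +
    ggplot2::labs(x = "Covariate rank (0-20)",
                  y = "P(search behaviour)") +
    ggplot2::theme_minimal()
}

#' Map of a labelled track
#'
#' Longitude-latitude scatter of fixes coloured by behavioural label.
#'
#' @param behaviour A [classify_behaviour()] table.
#' @param colony Optional `c(lon, lat)` of the colony, drawn as a cross.
#' @return A ggplot.
#' @export
plot_track_behaviour <- function(behaviour, colony = NULL) {
  p <- ggplot2::ggplot(behaviour,
                       ggplot2::aes(x = .data$lon, y = .data$lat,
                                    colour = .data$label)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude", y = "Latitude", colour = "Behaviour") +
    ggplot2::theme_minimal()
  if (!is.null(colony))
    p <- p + ggplot2::annotate("point", x = colony[1], y = colony[2],
                               shape = 4, size = 3, colour = "black")
  p
}
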