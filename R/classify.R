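#' Classify travel and search behaviour from FPT at the working scale
#'
#' Implements the histogram-based rule used for plunge-diving seabird
#' tracks: fixes whose first-passage time at the area-restricted-search
#' scale exceeds `t_high` are labelled `search` (high residency indicates
#' foraging effort); among the remaining low-FPT fixes, the half with the
#' lowest values (at or below the low-band median) are labelled `travel`;
#' the intermediate remainder is `excluded` from modelling because the two
#' behaviours cannot be separated cleanly there. Fixes with undefined FPT
#' are `undefined`; sitting-flagged fixes keep the label `sitting`.
#'
#' The travel/excluded split is made on the pooled low band of the whole
#' table (all trips together), mirroring a single pooled FPT histogram.
#'
#' @param fixes Fix table with an `fpt_s` column (seconds; `NA` allowed) and
#'   optionally a logical `sitting` column.
#' @param t_high Upper FPT threshold in seconds separating the low-FPT band
#'   from unambiguous search (default 300).
#' @return The input with a `label` factor column with levels
#'   `travel`, `search`, `excluded`, `sitting`, `undefined`.
#' @export
classify_behaviour <- function(fixes, t_high = 300) {
  stopifnot(t_high > 0, "fpt_s" %in% names(fixes))
  sitting <- if ("sitting" %in% names(fixes)) fixes$sitting else
    rep(FALSE, nrow(fixes))
  fpt <- fixes$fpt_s
  active <- !sitting
  if (sum(active & !is.na(fpt)) < 2)
    stop("classification needs at least 2 fixes with defined FPT")

  label <- rep(NA_character_, nrow(fixes))
  label[sitting] <- "sitting"
  label[active & is.na(fpt)] <- "undefined"
  label[active & !is.na(fpt) & fpt > t_high] <- "search"

  low <- active & !is.na(fpt) & fpt <= t_high
  if (!any(low)) {
    warning("degenerate split: no fixes at or below t_high; all search",
            call. = FALSE)
  } else {
    med <- stats::median(fpt[low])
    label[low & fpt <= med] <- "travel"
    label[low & fpt > med] <- "excluded"
    if (!any(label == "search", na.rm = TRUE))
      warning("degenerate split: no fixes above t_high; no search labels",
              call. = FALSE)
  }
  dplyr::mutate(fixes, label = factor(label, levels = c(
    "travel", "search", "excluded", "sitting", "undefined")))
}

#' Concordance of predicted behaviour with generator truth
#'
#' Compares travel/search labels with the latent modes of a simulated
#' track. Only fixes labelled `travel` or `search` enter; truth values
#' `transit` are treated as travel, `search` as search.
#'
#' @param fixes Output of [classify_behaviour()].
#' @param truth Character vector of true modes aligned 1:1 with `fixes`
#'   rows (values among `transit`/`travel`, `search`, `sitting`).
#' @return List with `confusion` (tibble truth x predicted counts) and
#'   `balanced_accuracy` (mean of per-class recall over travel and search).
#' @export
label_concordance <- function(fixes, truth) {
  if (length(truth) != nrow(fixes))
    stop("truth must align 1:1 with fixes (", nrow(fixes), " rows, got ",
         length(truth), ")")
  truth <- ifelse(truth %in% c("transit", "travel"), "travel",
                  ifelse(truth == "search", "search", NA_character_))
  keep <- fixes$label %in% c("travel", "search") & !is.na(truth)
  pred <- as.character(fixes$label[keep])
  tru <- truth[keep]
  confusion <- dplyr::count(tibble::tibble(truth = tru, predicted = pred),
                            .data$truth, .data$predicted)
  recalls <- vapply(c("travel", "search"), function(cl) {
    n_cl <- sum(tru == cl)
    if (n_cl == 0) return(NA_real_)
    sum(tru == cl & pred == cl) / n_cl
  }, numeric(1))
  list(confusion = confusion, balanced_accuracy = mean(recalls, na.rm = TRUE))
}
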