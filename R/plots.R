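#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_vline geom_point
#'   geom_tile geom_text labs theme_minimal facet_wrap geom_boxplot
#'   scale_fill_gradient2 after_stat
#' @export
ggplot2::autoplot

#' Histogram of per-split prediction strengths
#'
#' @param object A `prediction_strength`.
#' @param threshold Reference replication threshold line. Default 0.8.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.prediction_strength <- function(object, threshold = 0.8, ...) {
  ggplot(tidy(object), aes(x = .data$ps)) +
    geom_histogram(bins = 30, fill = "grey35") +
    geom_vline(xintercept = object$mean_ps, colour = "firebrick") +
    geom_vline(xintercept = threshold, linetype = 2) +
    labs(x = "prediction strength (per split)", y = "splits",
         title = sprintf("Mean prediction strength %.3f over %d splits",
                         object$mean_ps, object$n_splits)) +
    theme_minimal()
}

#' Observed prediction strength against its permutation null
#'
#' @param object A `ps_null`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ps_null <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$ps_null)) +
    geom_histogram(bins = 30, fill = "grey65") +
    geom_vline(xintercept = object$ps_obs, colour = "firebrick") +
    labs(x = "null mean prediction strength", y = "permutations",
         title = sprintf("Observed %.3f, p = %.3g", object$ps_obs,
                         object$p_value)) +
    theme_minimal()
}

#' Scatter of typed lesions on two features
#'
#' @param object A `lesion_cluster_model`.
#' @param data Lesion tibble with a `type` column (e.g. from
#'   [assign_types()]).
#' @param features Two feature names; default the model's first two.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lesion_cluster_model <- function(object, data,
                                          features = object$features[1:2],
                                          ...) {
  stopifnot(length(features) == 2)
  if (!"type" %in% names(data)) data <- assign_types(data, object)
  ggplot(data, aes(x = .data[[features[1]]], y = .data[[features[2]]],
                   colour = .data$type)) +
    geom_point(alpha = 0.6, size = 1) +
    labs(colour = "lesion type") +
    theme_minimal()
}

#' Per-type feature distributions
#'
#' @param lesions Typed lesion tibble.
#' @param features Feature columns to show.
#' @return A faceted boxplot ggplot.
#' @export
plot_type_profiles <- function(lesions, features = c("fa", "rd", "ufa", "f_in")) {
  long <- tidyr::pivot_longer(lesions[, c("type", features)],
                              dplyr::all_of(features),
                              names_to = "feature", values_to = "value")
  ggplot(long, aes(x = .data$type, y = .data$value, fill = .data$type)) +
    geom_boxplot(outlier.size = 0.4) +
    facet_wrap(~ feature, scales = "free_y") +
    labs(x = "lesion type", y = NULL) +
    theme_minimal()
}

#' Outcome-by-stratum association grid
#'
#' Tile grid of signed -log10 permutation p-values, starred where the
#' Bonferroni flag holds.
#'
#' @param results Tidied association tibble (rows from
#'   [tidy.perm_association()], optionally with a `stratum` column).
#' @return A ggplot.
#' @export
plot_association_grid <- function(results) {
  if (!"stratum" %in% names(results)) results$stratum <- results$predictor
  results <- dplyr::mutate(results,
    signed = ifelse(.data$direction == "Negative", 1, -1) *
      log10(.data$p_perm),
    label = paste0(sprintf("%.3g", .data$p_perm),
                   ifelse(isTRUE(results$bonferroni_significant) |
                            .data$bonferroni_significant %in% TRUE, "*", "")))
  ggplot(results, aes(x = .data$stratum, y = .data$outcome,
                      fill = .data$signed)) +
    geom_tile() +
    geom_text(aes(label = .data$label), size = 2.8) +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick",
                         midpoint = 0, name = "signed -log10 p") +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}
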