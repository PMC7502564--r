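#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted lesion typing model
#'
#' @param x A `lesion_cluster_model`.
#' @param ... Unused.
#' @return Long tibble of centroids: `type`, `feature`, `value`
#'   (standardized) and `value_raw` (original units).
#' @export
tidy.lesion_cluster_model <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x$centroids)), function(j) {
    tibble(type = unname(x$label_map[j]), feature = x$features,
           value = as.numeric(x$centroids[j, ]),
           value_raw = as.numeric(x$centroids[j, ]) * x$center_sd +
             x$center_mean)
  })
}

#' @rdname tidy.lesion_cluster_model
#' @export
glance.lesion_cluster_model <- function(x, ...) {
  tibble(k = x$k, n = x$n, features = paste(x$features, collapse = "+"),
         tot_withinss = x$tot_withinss, betweenss = x$betweenss)
}

#' Tidy prediction-strength replication results
#'
#' @param x A `prediction_strength`.
#' @param ... Unused.
#' @return `tidy()`: one row per random split; `glance()`: one summary row
#'   (mean prediction strength plus per-stratum means).
#' @export
tidy.prediction_strength <- function(x, ...) {
  tibble(split = seq_len(x$n_splits), ps = x$ps)
}

#' @rdname tidy.prediction_strength
#' @export
glance.prediction_strength <- function(x, ...) {
  out <- tibble(mean_ps = x$mean_ps, n_splits = x$n_splits, k = x$k, n = x$n)
  if (!is.null(x$strata_ps)) {
    for (nm in names(x$strata_ps)) out[[paste0("ps_", nm)]] <- x$strata_ps[[nm]]
  }
  out
}

#' Tidy a permutation-null prediction-strength result
#'
#' @param x A `ps_null`.
#' @param ... Unused.
#' @return `tidy()`: one row per permutation; `glance()`: observed value,
#'   p-value, permutation count.
#' @export
tidy.ps_null <- function(x, ...) {
  tibble(perm = seq_len(x$n_perms), ps_null = x$null)
}

#' @rdname tidy.ps_null
#' @export
glance.ps_null <- function(x, ...) {
  tibble(ps_obs = x$ps_obs, p_value = x$p_value, n_perms = x$n_perms)
}

#' Tidy a permutation association result
#'
#' @param x A `perm_association`.
#' @param ... Unused.
#' @return One-row tibble with outcome, predictor, family, coefficient,
#'   direction, permutation p-value and multiplicity flags.
#' @export
tidy.perm_association <- function(x, ...) {
  tibble(outcome = x$outcome, predictor = x$predictor, family = x$family,
         coefficient = x$coefficient, direction = x$direction,
         statistic = x$statistic, p_perm = x$p_perm, n_perms = x$n_perms,
         n = x$n, n_dropped = x$n_dropped, separation = x$separation,
         bonferroni_significant = x$bonferroni_significant,
         m = x$m)
}
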