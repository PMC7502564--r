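numeric_features <- function(data, features = NULL) {
  if (is.null(features)) {
    features <- names(data)[vapply(data, is.numeric, logical(1))]
    features <- setdiff(features, c("volume_mm3", "lesion_id"))
  }
  missing <- setdiff(features, names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing feature column(s): ", paste(missing, collapse = ", ")))
  }
  X <- as.matrix(data[, features, drop = FALSE])
  if (anyNA(X)) abort("Feature matrix contains missing values.")
  X
}

zscore_fit <- function(X) {
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  zero <- sdev <= 0
  if (any(zero)) {
    abort(paste0("Constant feature(s) cannot be standardized: ",
                 paste(colnames(X)[zero], collapse = ", ")))
  }
  list(mean = mu, sd = sdev, z = sweep(sweep(X, 2, mu), 2, sdev, "/"))
}

# stats::kmeans wrapped for determinism and degenerate inputs (duplicated
# rows can make its random initial centers coincide)
safe_kmeans <- function(Xz, k, seed, nstart = 10) {
  with_seed(seed, {
    ux <- unique(Xz)
    if (nrow(ux) < k) abort("Fewer distinct points than clusters.")
    if (nrow(ux) == k) {
      return(kmeans(Xz, centers = ux, iter.max = 100))
    }
    tryCatch(kmeans(Xz, centers = k, nstart = nstart, iter.max = 100),
             error = function(e) {
               # fall back to explicit distinct starting centers
               best <- NULL
               for (i in seq_len(nstart)) {
                 ctr <- ux[sample(nrow(ux), k), , drop = FALSE]
                 km <- kmeans(Xz, centers = ctr, iter.max = 100)
                 if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
               }
               best
             })
  })
}

# A/B convention: B is the centroid with lower f_in; tie-break lower FA;
# otherwise lower first feature. Centroids are in standardized space but the
# ordering is unaffected by the (positive-scale) standardization.
ab_labels <- function(centroids, features) {
  key <- if ("f_in" %in% features) "f_in" else if ("fa" %in% features) "fa"
         else features[1]
  v <- centroids[, key]
  if (v[1] == v[2] && "fa" %in% features) v <- centroids[, "fa"]
  out <- if (v[1] <= v[2]) c("B", "A") else c("A", "B")
  setNames(out, rownames(centroids))
}

#' Two-cluster k-means lesion typing
#'
#' Z-scores the selected features, runs k-means with `k = 2` and multiple
#' random restarts, and labels the clusters A/B by convention: B is the
#' cluster whose centroid has the lower intra-neurite volume fraction
#' (`f_in`; tie-break lower `fa`) — the putatively more damaged class.
#' Standardization parameters and centroids are stored for out-of-sample
#' assignment.
#'
#' @param data Lesion feature tibble (>= 4 rows, no missing values).
#' @param features Feature columns to cluster on; default all numeric columns
#'   except `volume_mm3`.
#' @param k Number of clusters (fixed at 2 for the A/B scheme; other values
#'   are accepted but the A/B labelling only applies to k = 2).
#' @param seed Seed (restarts are deterministic given it).
#' @param nstart k-means restarts. Default 10.
#' @return A `lesion_cluster_model`: features, standardization means/SDs,
#'   standardized centroids, cluster->label map, per-row `type`, and the
#'   within/between sums of squares.
#' @export
kmeans2 <- function(data, features = NULL, k = 2, seed = 1L, nstart = 10) {
  X <- numeric_features(data, features)
  features <- colnames(X)
  if (nrow(X) < 4) abort("Need at least 4 rows to cluster.")
  zs <- zscore_fit(X)
  km <- safe_kmeans(zs$z, k, derive_seed(seed, 1), nstart)
  labmap <- if (k == 2) ab_labels(km$centers, features)
            else setNames(LETTERS[seq_len(k)], seq_len(k))
  structure(list(features = features, center_mean = zs$mean,
                 center_sd = zs$sd, centroids = km$centers,
                 label_map = setNames(unname(labmap), seq_len(k)),
                 type = unname(labmap[km$cluster]),
                 k = k, n = nrow(X),
                 tot_withinss = km$tot.withinss, betweenss = km$betweenss,
                 seed = seed),
            class = "lesion_cluster_model")
}

#' @export
print.lesion_cluster_model <- function(x, ...) {
  cat(sprintf("k-means lesion typing (k = %d, n = %d) on: %s\n", x$k, x$n,
              paste(x$features, collapse = ", ")))
  cat("Cluster labels:", paste(x$label_map, collapse = ", "), "\n")
  invisible(x)
}

#' Nearest-centroid type assignment
#'
#' `predict()` standardizes new rows with the model's stored means/SDs and
#' returns the label of the nearest centroid (Euclidean; exact ties go to the
#' lower-index centroid). `assign_types()` is the pipe-friendly wrapper that
#' appends a `type` column.
#'
#' @param object A `lesion_cluster_model`.
#' @param newdata Tibble containing the model's feature columns.
#' @param ... Unused.
#' @return `predict()`: character vector of labels; `assign_types()`: the
#'   input tibble with a `type` column.
#' @export
predict.lesion_cluster_model <- function(object, newdata, ...) {
  X <- numeric_features(newdata, object$features)
  Z <- sweep(sweep(X, 2, object$center_mean), 2, object$center_sd, "/")
  d2 <- sapply(seq_len(nrow(object$centroids)), function(j) {
    rowSums(sweep(Z, 2, object$centroids[j, ])^2)
  })
  if (is.vector(d2)) d2 <- matrix(d2, nrow = 1)
  idx <- apply(d2, 1, which.min) # which.min takes the lower index on ties
  unname(object$label_map[idx])
}

#' @rdname predict.lesion_cluster_model
#' @param data Lesion tibble.
#' @param model A `lesion_cluster_model`.
#' @export
assign_types <- function(data, model) {
  dplyr::mutate(data, type = predict(model, data))
}

#' Pair-counting prediction-strength score of one train/test direction
#'
#' Worst-case (over test clusters) fraction of within-cluster ordered pairs
#' that the training-side classifier keeps together:
#' `min_j sum_l n_jl (n_jl - 1) / (n_j (n_j - 1))` where `n_jl` counts test
#' points of test-cluster `j` assigned to training cluster `l`. Test clusters
#' of size <= 1 contribute 1 (no pair to violate).
#'
#' @param test_clusters Integer/character cluster ids from clustering the
#'   test half.
#' @param train_assign Training-centroid assignments of the same points.
#' @return Scalar in \[0, 1\].
#' @export
ps_pair_score <- function(test_clusters, train_assign) {
  stopifnot(length(test_clusters) == length(train_assign))
  sc <- vapply(split(train_assign, test_clusters), function(a) {
    nj <- length(a)
    if (nj < 2) return(1)
    nl <- table(a)
    sum(nl * (nl - 1)) / (nj * (nj - 1))
  }, numeric(1))
  min(sc)
}

ps_one_direction <- function(Z, train_idx, test_idx, k, seed, nstart,
                             strata = NULL) {
  km_tr <- safe_kmeans(Z[train_idx, , drop = FALSE], k, derive_seed(seed, 1),
                       nstart)
  km_te <- safe_kmeans(Z[test_idx, , drop = FALSE], k, derive_seed(seed, 2),
                       nstart)
  Zt <- Z[test_idx, , drop = FALSE]
  d2 <- sapply(seq_len(k), function(j) {
    rowSums(sweep(Zt, 2, km_tr$centers[j, ])^2)
  })
  if (is.vector(d2)) d2 <- matrix(d2, nrow = 1)
  assign <- apply(d2, 1, which.min)
  overall <- ps_pair_score(km_te$cluster, assign)
  strat <- NULL
  if (!is.null(strata)) {
    st <- strata[test_idx]
    lev <- sort(unique(strata[!is.na(strata)]))
    strat <- vapply(lev, function(s) {
      sel <- !is.na(st) & st == s
      if (sum(sel) < 2) return(NA_real_)
      ps_pair_score(km_te$cluster[sel], assign[sel])
    }, numeric(1))
    names(strat) <- lev
  }
  list(overall = overall, strata = strat)
}

#' Averaged prediction strength over repeated random half-splits
#'
#' Replication evidence for a clustering: for each of `n_splits` random
#' half-partitions, both halves are clustered with k-means; the test half is
#' then classified by the training half's centroids and the worst-case
#' within-cluster pair agreement ([ps_pair_score()]) is recorded. Each
#' split's value is symmetrized by averaging the two train/test role
#' assignments, and the `n_splits` values are averaged. When `strata` (e.g.
#' lesion locations) are given, a per-stratum score is computed from the same
#' pooled splits by restricting the pair counting to each stratum's test
#' points.
#'
#' @param data Lesion feature tibble (n >= 8).
#' @param features Feature columns (default all numeric).
#' @param n_splits Number of random half-splits. Default 500.
#' @param k Clusters. Default 2.
#' @param seed Master seed; split- and restart-level seeds are derived from
#'   it by counter, so results are reproducible and independent of row order
#'   given fixed split membership.
#' @param strata Optional per-row stratum labels.
#' @param nstart k-means restarts per half.
#' @return A `prediction_strength` object: per-split values `ps`, their mean
#'   `mean_ps`, optional per-stratum means `strata_ps`, and the call
#'   parameters.
#' @export
prediction_strength <- function(data, features = NULL, n_splits = 500, k = 2,
                                seed = 1L, strata = NULL, nstart = 10) {
  X <- numeric_features(data, features)
  n <- nrow(X)
  if (n < 8) abort("Need at least 8 rows to split and cluster.")
  zs <- zscore_fit(X)
  Z <- zs$z
  if (!is.null(strata)) stopifnot(length(strata) == n)
  ps <- numeric(n_splits)
  strat_acc <- NULL
  for (s in seq_len(n_splits)) {
    idx <- with_seed(derive_seed(seed, 1000 + s), sample(n))
    half1 <- idx[seq_len(floor(n / 2))]
    half2 <- idx[(floor(n / 2) + 1):n]
    d1 <- ps_one_direction(Z, half1, half2, k, derive_seed(seed, 2000 + s),
                           nstart, strata)
    d2 <- ps_one_direction(Z, half2, half1, k, derive_seed(seed, 3000 + s),
                           nstart, strata)
    ps[s] <- (d1$overall + d2$overall) / 2
    if (!is.null(strata)) {
      sm <- rbind(d1$strata, d2$strata)
      m <- colMeans(sm, na.rm = TRUE)
      strat_acc <- if (is.null(strat_acc)) rbind(m) else rbind(strat_acc, m)
    }
  }
  strata_ps <- if (!is.null(strat_acc)) colMeans(strat_acc, na.rm = TRUE)
  structure(list(ps = ps, mean_ps = mean(ps), n_splits = n_splits, k = k,
                 n = n, strata_ps = strata_ps, seed = seed,
                 features = colnames(X)),
            class = "prediction_strength")
}

#' @export
print.prediction_strength <- function(x, ...) {
  cat(sprintf("Mean prediction strength %.3f over %d random half-splits (k = %d, n = %d)\n",
              x$mean_ps, x$n_splits, x$k, x$n))
  if (!is.null(x$strata_ps)) {
    cat("Per-stratum:", paste(sprintf("%s %.3f", names(x$strata_ps),
                                      x$strata_ps), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Permutation null for the averaged prediction strength
#'
#' Destroys the multivariate cluster structure while preserving marginals by
#' shuffling each feature column independently across lesions (permuting
#' whole rows would be a no-op for a row-order-invariant clustering), then
#' recomputes the averaged prediction strength. Add-one estimator:
#' `p = (1 + #\{ps_null >= ps_obs\}) / (1 + n_perms)`.
#'
#' @inheritParams prediction_strength
#' @param n_perms Number of column-shuffled replicates (>= 1).
#' @param n_splits_obs Splits used for the observed statistic.
#' @param n_splits_null Splits per null replicate (fewer than the observed
#'   run is customary; the null mean is what matters).
#' @return A `ps_null` object: `p_value`, `ps_obs`, `null` (vector),
#'   `n_perms`.
#' @export
ps_null_pvalue <- function(data, features = NULL, n_perms = 100,
                           n_splits_obs = 100, n_splits_null = 20, k = 2,
                           seed = 1L, nstart = 10) {
  if (n_perms < 1) abort("`n_perms` must be >= 1.")
  X <- numeric_features(data, features)
  dat <- as_tibble(as.data.frame(X))
  obs <- prediction_strength(dat, n_splits = n_splits_obs, k = k,
                             seed = derive_seed(seed, 1), nstart = nstart)
  null <- vapply(seq_len(n_perms), function(p) {
    Xp <- with_seed(derive_seed(seed, 5000 + p), {
      apply(X, 2, sample)
    })
    prediction_strength(as_tibble(as.data.frame(Xp)),
                        n_splits = n_splits_null, k = k,
                        seed = derive_seed(seed, 9000 + p),
                        nstart = nstart)$mean_ps
  }, numeric(1))
  pval <- (1 + sum(null >= obs$mean_ps)) / (1 + n_perms)
  structure(list(p_value = pval, ps_obs = obs$mean_ps, null = null,
                 n_perms = n_perms, n_splits_obs = n_splits_obs,
                 n_splits_null = n_splits_null, seed = seed),
            class = "ps_null")
}

#' @export
print.ps_null <- function(x, ...) {
  cat(sprintf("Prediction strength %.3f vs column-shuffled null (n_perms = %d): p = %.4g\n",
              x$ps_obs, x$n_perms, x$p_value))
  invisible(x)
}

#' Screen metrics for degenerate variation before clustering
#'
#' Discards features whose share of values at their fit ceiling exceeds
#' `ceiling_frac` (a bounded estimator piling up at its upper bound carries
#' little contrast — e.g. a microscopic axial diffusivity saturating at the
#' free-water ceiling) or whose coefficient of variation falls below
#' `cv_floor` (constant features included). Also reports the pairwise feature
#' correlation matrix.
#'
#' @param data Lesion feature tibble.
#' @param features Candidate feature columns.
#' @param bounds Named numeric vector of upper bounds for bounded metrics
#'   (default: 3.0 for `uad` and `ad`, in 1e-3 mm^2/s table units).
#' @param ceiling_frac Discard threshold on the at-bound share. Default 0.30.
#' @param cv_floor Discard threshold on |CV|. Default 0.01.
#' @return A `metric_screen` tibble: `feature`, `ceiling_frac`, `cv`,
#'   `retained`, `reason`; attribute `correlation` (matrix over retained
#'   features).
#' @export
screen_metrics <- function(data, features = NULL,
                           bounds = c(uad = 3.0, ad = 3.0),
                           ceiling_frac = 0.30, cv_floor = 0.01) {
  X <- numeric_features(data, features)
  res <- purrr::map_dfr(colnames(X), function(f) {
    x <- X[, f]
    bd <- unname(bounds[f])
    cf <- if (!is.na(bd) && !is.null(bd)) mean(x >= bd * (1 - 1e-6)) else 0
    mu <- mean(x)
    cv <- if (mu == 0) ifelse(sd(x) == 0, 0, Inf) else sd(x) / abs(mu)
    reason <- if (cf > ceiling_frac) "at_ceiling"
      else if (cv < cv_floor) "low_variation" else NA_character_
    tibble(feature = f, ceiling_frac = cf, cv = cv,
           retained = is.na(reason), reason = reason)
  })
  keep <- res$feature[res$retained]
  attr(res, "correlation") <- if (length(keep) >= 2) {
    cor(X[, keep, drop = FALSE])
  }
  class(res) <- c("metric_screen", class(res))
  res
}

#' Rank candidate feature sets by replicated clustering quality
#'
#' For each candidate set, computes the averaged prediction strength overall
#' and within each location stratum (pooled splits, stratum-restricted pair
#' counting). A set passes when the overall value and every evaluable stratum
#' exceed `ps_threshold`; passing sets are ranked by overall mean prediction
#' strength with ties broken by smaller set size. For the passing sets, the
#' pairwise agreement of their lesion labelings (best of direct and
#' label-flipped match) is reported.
#'
#' @param data Lesion feature tibble.
#' @param candidate_sets List of character vectors; default all subsets of
#'   `sizes` of `features`.
#' @param features Pool of (screened) feature names for the default
#'   enumeration.
#' @param strata Per-row location labels (optional).
#' @param sizes Subset sizes enumerated when `candidate_sets` is NULL.
#' @param ps_threshold Replication threshold. Default 0.8.
#' @param n_splits Splits per evaluation.
#' @param min_stratum Strata with fewer rows are skipped with a warning.
#' @param k,seed,nstart Passed to [prediction_strength()].
#' @return Tibble: `features` (list-column), `set` (collapsed name),
#'   `n_features`, `mean_ps`, `min_stratum_ps`, `pass`, ranked; attribute
#'   `agreement` (matrix over passing sets).
#' @export
select_feature_sets <- function(data, candidate_sets = NULL, features = NULL,
                                strata = NULL, sizes = 3:5,
                                ps_threshold = 0.8, n_splits = 100,
                                min_stratum = 16, k = 2, seed = 1L,
                                nstart = 10) {
  if (is.null(candidate_sets)) {
    pool <- colnames(numeric_features(data, features))
    candidate_sets <- unlist(lapply(sizes[sizes <= length(pool)], function(sz) {
      utils::combn(pool, sz, simplify = FALSE)
    }), recursive = FALSE)
  }
  if (length(candidate_sets) == 0) abort("No candidate feature sets.")
  use_strata <- strata
  if (!is.null(strata)) {
    small <- names(which(table(strata) < min_stratum))
    if (length(small) > 0) {
      warn(paste0("Stratum/strata skipped (too few lesions): ",
                  paste(small, collapse = ", ")))
      use_strata <- ifelse(strata %in% small, NA, strata)
    }
  }
  rows <- purrr::imap_dfr(candidate_sets, function(fs, i) {
    psr <- prediction_strength(data, features = fs, n_splits = n_splits,
                               k = k, seed = derive_seed(seed, i),
                               strata = if (!is.null(use_strata)) use_strata,
                               nstart = nstart)
    sp <- psr$strata_ps
    sp <- sp[!is.na(names(sp)) & names(sp) != "NA"]
    minsp <- if (length(sp) > 0) min(sp, na.rm = TRUE) else NA_real_
    tibble(features = list(fs), set = paste(fs, collapse = "+"),
           n_features = length(fs), mean_ps = psr$mean_ps,
           min_stratum_ps = minsp,
           pass = psr$mean_ps > ps_threshold &
             (is.na(minsp) | minsp > ps_threshold))
  })
  rows <- rows |>
    dplyr::arrange(dplyr::desc(.data$pass), dplyr::desc(.data$mean_ps),
                   .data$n_features)
  passing <- which(rows$pass)
  if (length(passing) >= 2) {
    models <- lapply(rows$features[passing], function(fs) {
      kmeans2(data, features = fs, k = k, seed = seed)$type
    })
    agg <- outer(seq_along(models), seq_along(models),
                 Vectorize(function(i, j) {
                   a <- models[[i]] == models[[j]]
                   max(mean(a), 1 - mean(a))
                 }))
    dimnames(agg) <- list(rows$set[passing], rows$set[passing])
    attr(rows, "agreement") <- agg
  }
  rows
}

#' Per-patient lesion-type burden
#'
#' Counts and volumes of A- and B-type lesions per patient, per location and
#' whole-brain, with B-type percentages by count and by volume. Percentages
#' are undefined (NA) where a patient has no lesions in a cell — never
#' reported as zero.
#'
#' @param lesions Lesion tibble with `patient_id`, `location`, `volume_mm3`,
#'   `type`.
#' @param patients Optional patient tibble; patients without lesions then
#'   appear with zero counts.
#' @return Tibble: `patient_id`, `location` (including `"whole_brain"`),
#'   `n_a`, `n_b`, `vol_a`, `vol_b`, `pct_b_count`, `pct_b_volume`.
#' @export
patient_burden <- function(lesions, patients = NULL) {
  if (!"type" %in% names(lesions)) abort("Assign lesion types first.")
  summarize_cell <- function(d) {
    tibble(n_a = sum(d$type == "A"), n_b = sum(d$type == "B"),
           vol_a = sum(d$volume_mm3[d$type == "A"]),
           vol_b = sum(d$volume_mm3[d$type == "B"]))
  }
  per_loc <- lesions |>
    dplyr::group_by(.data$patient_id, .data$location) |>
    dplyr::group_modify(~ summarize_cell(.x)) |>
    dplyr::ungroup()
  whole <- lesions |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(~ summarize_cell(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(location = "whole_brain", .after = "patient_id")
  out <- dplyr::bind_rows(whole, per_loc)
  if (!is.null(patients)) {
    missing <- setdiff(patients$patient_id, out$patient_id)
    if (length(missing) > 0) {
      out <- dplyr::bind_rows(out, tibble(patient_id = missing,
                                          location = "whole_brain",
                                          n_a = 0L, n_b = 0L,
                                          vol_a = 0, vol_b = 0))
    }
  }
  out |>
    dplyr::mutate(
      pct_b_count = dplyr::if_else(.data$n_a + .data$n_b > 0,
                                   100 * .data$n_b / (.data$n_a + .data$n_b),
                                   NA_real_),
      pct_b_volume = dplyr::if_else(.data$vol_a + .data$vol_b > 0,
                                    100 * .data$vol_b /
                                      (.data$vol_a + .data$vol_b),
                                    NA_real_)) |>
    dplyr::arrange(.data$patient_id, .data$location)
}
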