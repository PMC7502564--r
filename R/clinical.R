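design_matrices <- function(data, outcome, predictor, covariates) {
  cols <- c(outcome, predictor, covariates)
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing column(s): ", paste(missing, collapse = ", ")))
  }
  d <- data[, cols]
  # sex-like character/factor covariates become 0/1 indicators
  for (nm in c(predictor, covariates)) {
    if (!is.numeric(d[[nm]])) {
      lev <- sort(unique(as.character(d[[nm]])))
      if (length(lev) != 2) abort(sprintf("`%s` must be numeric or binary.", nm))
      d[[nm]] <- as.numeric(as.character(d[[nm]]) == lev[2])
    }
  }
  cc <- stats::complete.cases(d)
  n_dropped <- sum(!cc)
  if (n_dropped > 0) {
    inform(sprintf("Dropped %d row(s) with missing values.", n_dropped))
  }
  d <- d[cc, ]
  y <- d[[outcome]]
  x <- d[[predictor]]
  Z <- cbind(intercept = 1,
             as.matrix(d[, covariates, drop = FALSE]))
  list(y = y, x = x, Z = Z, n = nrow(d), n_dropped = n_dropped)
}

new_association <- function(outcome, predictor, family, coefficient, p_perm,
                            n_perms, n, n_dropped, statistic,
                            separation = FALSE) {
  structure(list(outcome = outcome, predictor = predictor, family = family,
                 coefficient = coefficient,
                 direction = if (is.na(coefficient)) NA_character_
                   else if (coefficient >= 0) "Positive" else "Negative",
                 p_perm = p_perm, n_perms = n_perms, n = n,
                 n_dropped = n_dropped, statistic = statistic,
                 separation = separation,
                 bonferroni_significant = NA, m = NA_real_),
            class = "perm_association")
}

#' @export
print.perm_association <- function(x, ...) {
  cat(sprintf("%s ~ %s (%s): coef %.4g, %s, p_perm = %.4g (n = %d, %d perms)\n",
              x$outcome, x$predictor, x$family, x$coefficient, x$direction,
              x$p_perm, x$n, x$n_perms))
  invisible(x)
}

#' Freedman-Lane permutation test for a linear-model coefficient
#'
#' Fits the reduced model `y ~ Z` (nuisance only), keeps its fitted values
#' and residuals, and for each permutation rebuilds
#' `y* = fitted_reduced + permuted(residuals_reduced)`, refits the full model
#' `y* ~ x + Z` and records the t-statistic of `x`. Two-sided add-one
#' p-value: `(1 + #\{|t*| >= |t_obs|\}) / (1 + n_perms)`. The reported
#' coefficient and direction come from the unpermuted full fit. Robust to
#' non-normal residuals, hence standard in neuroimaging association testing.
#'
#' @param data Tibble of patient records.
#' @param outcome,predictor Column names (outcome continuous).
#' @param covariates Nuisance columns (default age and sex; binary
#'   character/factor covariates are converted to 0/1). Rows with missing
#'   values are dropped with a message.
#' @param n_perms Number of permutations. Default 5000.
#' @param seed Seed.
#' @return A `perm_association` object.
#' @export
freedman_lane_lm <- function(data, outcome, predictor,
                             covariates = c("age", "sex"), n_perms = 5000,
                             seed = 1L) {
  dm <- design_matrices(data, outcome, predictor, covariates)
  y <- dm$y; x <- dm$x; Z <- dm$Z
  p_full <- ncol(Z) + 1
  if (dm$n < p_full + 1) abort("Too few complete rows for the model.")
  X <- cbind(x = x, Z)
  if (qr(X)$rank < ncol(X)) {
    abort("Predictor is collinear with the nuisance covariates.")
  }
  if (var(y) == 0) {
    return(new_association(outcome, predictor, "linear", 0, 1, n_perms,
                           dm$n, dm$n_dropped, statistic = 0))
  }
  XtXi <- solve(crossprod(X))
  A <- XtXi %*% t(X) # coefficient operator
  df <- dm$n - ncol(X)
  t_of <- function(ymat) {
    B <- A %*% ymat
    fitted <- X %*% B
    rss <- colSums((ymat - fitted)^2)
    se <- sqrt(pmax(XtXi[1, 1] * rss / df, 1e-300))
    B[1, ] / se
  }
  t_obs <- t_of(matrix(y))[1]
  beta_obs <- (A %*% y)[1]
  # reduced-model decomposition
  ZtZi <- solve(crossprod(Z))
  yhat_r <- Z %*% (ZtZi %*% (t(Z) %*% y))
  e_r <- as.vector(y - yhat_r)
  perms <- with_seed(derive_seed(seed, 1), {
    vapply(seq_len(n_perms), function(i) sample(dm$n), integer(dm$n))
  })
  Ystar <- matrix(e_r[perms], dm$n, n_perms) + as.vector(yhat_r)
  t_star <- t_of(Ystar)
  p <- (1 + sum(abs(t_star) >= abs(t_obs))) / (1 + n_perms)
  new_association(outcome, predictor, "linear", beta_obs, p, n_perms,
                  dm$n, dm$n_dropped, statistic = t_obs)
}

#' Permutation test for a logistic-model coefficient
#'
#' Likelihood-ratio statistic for the predictor in
#' `glm(y ~ x + Z, binomial)`, with a null distribution built by
#' predictor-residual permutation: `x` is residualized on the nuisance
#' matrix, the residuals are permuted and added back to the nuisance-fitted
#' part, and the model is refit. This is the Freedman-Lane analogue for a
#' non-Gaussian outcome, permuting the only exchangeable quantity available.
#' Complete separation is flagged (`separation = TRUE`) and inference then
#' rests on the permutation p-value alone.
#'
#' @inheritParams freedman_lane_lm
#' @param outcome Binary 0/1 column; both classes must be present.
#' @return A `perm_association` object.
#' @export
perm_logistic <- function(data, outcome, predictor,
                          covariates = c("age", "sex"), n_perms = 5000,
                          seed = 1L) {
  dm <- design_matrices(data, outcome, predictor, covariates)
  y <- dm$y; x <- dm$x; Z <- dm$Z
  if (length(unique(y)) < 2) abort("Outcome has a single class.")
  if (!all(y %in% c(0, 1))) abort("Outcome must be binary 0/1.")
  fit_dev <- function(M) {
    f <- suppressWarnings(stats::glm.fit(M, y, family = stats::binomial()))
    list(dev = f$deviance, coef = f$coefficients, mu = f$fitted.values)
  }
  red <- fit_dev(Z)
  full <- fit_dev(cbind(x = x, Z))
  lrt_obs <- red$dev - full$dev
  separation <- any(full$mu < 1e-8 | full$mu > 1 - 1e-8) ||
    abs(full$coef[1]) > 20
  # residualize the predictor on the nuisance space
  ZtZi <- solve(crossprod(Z))
  xhat <- Z %*% (ZtZi %*% (t(Z) %*% x))
  ex <- as.vector(x - xhat)
  lrt_star <- with_seed(derive_seed(seed, 1), {
    vapply(seq_len(n_perms), function(i) {
      xs <- as.vector(xhat) + ex[sample(dm$n)]
      red$dev - fit_dev(cbind(x = xs, Z))$dev
    }, numeric(1))
  })
  p <- (1 + sum(lrt_star >= lrt_obs)) / (1 + n_perms)
  new_association(outcome, predictor, "logistic", unname(full$coef[1]), p,
                  n_perms, dm$n, dm$n_dropped, statistic = lrt_obs,
                  separation = separation)
}

#' Permutation test and bootstrap CI for a two-group mean difference
#'
#' Difference of group means (second factor level minus first), two-sided
#' label-permutation p-value and a percentile bootstrap confidence interval.
#'
#' @param values Numeric vector.
#' @param group Two-level grouping vector, each level with n >= 2.
#' @param n_perms Permutations. Default 5000.
#' @param n_boot Bootstrap resamples for the CI. Default 2000.
#' @param conf Confidence level. Default 0.95.
#' @param seed Seed.
#' @return List: `difference`, `ci` (length 2), `p_value`, group means and
#'   sizes.
#' @export
perm_group_diff <- function(values, group, n_perms = 5000, n_boot = 2000,
                            conf = 0.95, seed = 1L) {
  g <- as.factor(group)
  if (nlevels(g) != 2) abort("`group` must have exactly two levels.")
  n1 <- sum(g == levels(g)[1]); n2 <- sum(g == levels(g)[2])
  if (min(n1, n2) < 2) abort("Each group needs at least 2 observations.")
  v1 <- values[g == levels(g)[1]]; v2 <- values[g == levels(g)[2]]
  d_obs <- mean(v2) - mean(v1)
  d_star <- with_seed(derive_seed(seed, 1), {
    vapply(seq_len(n_perms), function(i) {
      gp <- sample(as.integer(g))
      mean(values[gp == 2]) - mean(values[gp == 1])
    }, numeric(1))
  })
  p <- (1 + sum(abs(d_star) >= abs(d_obs))) / (1 + n_perms)
  boot <- with_seed(derive_seed(seed, 2), {
    vapply(seq_len(n_boot), function(i) {
      mean(sample(v2, n2, replace = TRUE)) - mean(sample(v1, n1, replace = TRUE))
    }, numeric(1))
  })
  a <- (1 - conf) / 2
  list(difference = d_obs, ci = unname(quantile(boot, c(a, 1 - a))),
       p_value = p, mean_1 = mean(v1), mean_2 = mean(v2), n_1 = n1, n_2 = n2,
       n_perms = n_perms, levels = levels(g))
}

#' Bonferroni multiplicity flags for a family of association results
#'
#' Marks each result significant iff `p_perm < alpha / m`; the family size
#' `m` is an explicit input (it is study design, never inferred from the
#' number of rows supplied). Correction can only shrink the significant set.
#'
#' @param results A `perm_association`, a list of them, or a tidied tibble
#'   with a `p_perm` column.
#' @param m Family size (>= 1).
#' @param alpha Family-wise level. Default 0.05.
#' @return Same shape as the input with `bonferroni_significant` and `m`
#'   filled in (tibbles also gain `p_threshold`).
#' @export
adjust_bonferroni <- function(results, m, alpha = 0.05) {
  assert_scalar_num(m, "m", lower = 1)
  thr <- alpha / m
  if (inherits(results, "perm_association")) {
    results$bonferroni_significant <- results$p_perm < thr
    results$m <- m
    return(results)
  }
  if (is.data.frame(results)) {
    return(dplyr::mutate(results, m = m, p_threshold = thr,
                         bonferroni_significant = .data$p_perm < thr))
  }
  lapply(results, adjust_bonferroni, m = m, alpha = alpha)
}
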