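#' Per-shell spherical mean of a multi-shell signal
#'
#' Averages `S_i / S0` over the directions of each non-zero shell, where `S0`
#' is the mean of the unweighted measurements (or supplied). The b = 0 "shell"
#' has mean 1 by construction. All shells are used: orientation-averaged
#' signals carry the microscopic (per-axon-segment) diffusion information that
#' the fits in [fit_smt()] and [fit_mcsmt()] recover.
#'
#' @param signals Signal vector, one value per scheme row.
#' @param scheme A [gradient_scheme()].
#' @param s0 Optional unweighted signal; estimated from the b = 0 rows when
#'   missing.
#' @param min_dirs Warn when a shell has fewer directions than this (a sparse
#'   shell makes the powder average a poor rotational invariant). Set 0 to
#'   silence. Default 30.
#' @param rician_sigma Optional known Rician noise SD (signal units). When
#'   given, each measurement is bias-corrected by the moment relation
#'   `E[S_noisy^2] = S^2 + 2 sigma^2`, i.e. `S_hat = sqrt(max(S_noisy^2 -
#'   2 sigma^2, 0))`, before averaging; without it the Rician floor inflates
#'   the high-b shell means.
#' @return Tibble with one row per non-zero shell: `b`, `mean_signal`
#'   (normalized), `n_dirs`; attribute `s0`.
#' @export
spherical_mean <- function(signals, scheme, s0 = NULL, min_dirs = 30,
                           rician_sigma = NULL) {
  signals <- as.numeric(signals)
  if (length(signals) != nrow(scheme)) abort("signals/scheme length mismatch.")
  if (!is.null(rician_sigma)) {
    if (rician_sigma < 0) abort("`rician_sigma` must be >= 0.")
    signals <- sqrt(pmax(signals^2 - 2 * rician_sigma^2, 0))
  }
  if (is.null(s0)) {
    if (!any(scheme$shell == 0)) abort("No b = 0 measurements to estimate S0.")
    s0 <- mean(signals[scheme$shell == 0])
  }
  if (s0 <= 0) abort("S0 estimate must be positive.")
  sh <- sort(unique(scheme$shell[scheme$shell > 0]))
  if (length(sh) == 0) abort("Scheme has no non-zero shell.")
  out <- purrr::map_dfr(sh, function(s) {
    idx <- scheme$shell == s
    if (sum(idx) == 0) abort("Empty shell.")
    if (sum(idx) < min_dirs) {
      warn(sprintf("Shell b = %g has only %d directions; spherical mean may be noisy.",
                   stats::median(scheme$b[idx]), sum(idx)))
    }
    tibble(b = mean(scheme$b[idx]), mean_signal = mean(signals[idx]) / s0,
           n_dirs = sum(idx))
  })
  attr(out, "s0") <- s0
  out
}

#' Microscopic metrics of the single micro-tensor from its diffusivities
#'
#' `umd = (uad + 2 urd) / 3`; `ufa` is the FA of the eigenvalue triple
#' `(uad, urd, urd)`.
#'
#' @param uad,urd Microscopic axial and radial diffusivities (same units).
#' @return One-row tibble with `ufa`, `umd`, `urd`, `uad`.
#' @export
#' @examples
#' smt_metrics(2.66e-3, 0.23e-3)$umd * 1e3 # 1.04
smt_metrics <- function(uad, urd) {
  m <- dti_metrics(c(uad, urd, urd))
  tibble(ufa = m$fa, umd = m$md, urd = urd, uad = uad)
}

#' Derived two-compartment metrics
#'
#' The extra-neurite transverse microscopic diffusivity follows the tortuosity
#' constraint `v_ad = (1 - f_in) * lambda_diff` (computed when `v_ad` is not
#' supplied) and the extra-neurite microscopic mean diffusivity is the linear
#' combination `v_md = (lambda_diff + 2 v_ad) / 3`.
#'
#' @param lambda_diff Intrinsic diffusivity.
#' @param f_in Intra-neurite volume fraction (needed when `v_ad` missing).
#' @param v_ad Extra-neurite transverse microscopic diffusivity.
#' @return One-row tibble with `f_in` (NA if not given), `lambda_diff`,
#'   `v_ad`, `v_md`.
#' @export
#' @examples
#' mcsmt_metrics(lambda_diff = 2.02e-3, v_ad = 0.91e-3)$v_md * 1e3 # 1.28
mcsmt_metrics <- function(lambda_diff, f_in = NULL, v_ad = NULL) {
  if (is.null(v_ad)) {
    if (is.null(f_in)) abort("Supply `f_in` or `v_ad`.")
    v_ad <- (1 - f_in) * lambda_diff
  }
  tibble(f_in = f_in %||% NA_real_, lambda_diff = lambda_diff,
         v_ad = v_ad, v_md = (lambda_diff + 2 * v_ad) / 3)
}

# Levenberg-Marquardt with box bounds over a small start grid; residual_fn maps
# the parameter vector to the residual vector. Ties (within 1e-12 of the best
# objective) broken by tie_value (lower wins), then first found.
multistart_lm <- function(residual_fn, starts, lower, upper,
                          tie_value = function(p) 0) {
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = residual_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-15, ptol = 1e-15, gtol = 0,
                           maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    obj <- sum(fit$fvec^2)
    if (is.null(best) || obj < best$obj - 1e-12 ||
        (abs(obj - best$obj) <= 1e-12 && tie_value(fit$par) < best$tie)) {
      best <- list(par = fit$par, obj = obj, tie = tie_value(fit$par),
                   converged = fit$info %in% 1:4)
    }
  }
  if (is.null(best)) abort("Optimizer failed from every start point.")
  if (!best$converged) warn("Least-squares fit did not report convergence.")
  best
}

#' Fit the single micro-tensor to per-shell spherical means
#'
#' Bounded least squares of the axially symmetric micro-tensor powder average
#' [zeppelin_mean()] over `(l_par, l_perp)` with
#' `0 <= l_perp <= l_par <= lambda_free`, via a Levenberg-Marquardt multistart
#' (parametrized as `l_par` and the ratio `l_perp / l_par` so the ordering
#' constraint is a box).
#'
#' @param shell_means Tibble from [spherical_mean()], or a numeric vector of
#'   normalized shell means (then supply `b`).
#' @param b Shell b-values (s/mm^2) when `shell_means` is a bare vector.
#' @param lambda_free Upper diffusivity bound, mm^2/s. Default 3.0e-3 (the
#'   free-water ceiling used throughout).
#' @return Object of class `smt_fit`: `uad`, `urd`, `umd`, `ufa` (mm^2/s /
#'   unitless), `residual` (RSS), `converged`.
#' @export
fit_smt <- function(shell_means, b = NULL, lambda_free = 3e-3) {
  if (is.data.frame(shell_means)) {
    b <- shell_means$b
    eps <- shell_means$mean_signal
  } else {
    eps <- as.numeric(shell_means)
  }
  if (length(eps) < 2) abort("Need at least 2 non-zero shells.")
  if (length(b) != length(eps)) abort("b/shell-mean length mismatch.")
  if (any(eps <= 0) || any(eps > 1 + 1e-9)) {
    abort("Shell means must lie in (0, 1].")
  }
  sc <- 1e3 # optimize diffusivities in 1e-3 mm^2/s so parameters are O(1)
  resid <- function(p) zeppelin_mean(b, p[1] / sc, p[1] * p[2] / sc) - eps
  starts <- as.matrix(expand.grid(l_par = c(0.8, 2.4), r = c(0.1, 0.7)))
  best <- multistart_lm(resid, starts, lower = c(1e-9, 0),
                        upper = c(lambda_free * sc, 1))
  uad <- unname(best$par[1]) / sc
  urd <- unname(best$par[1] * best$par[2]) / sc
  m <- smt_metrics(uad, urd)
  structure(list(uad = uad, urd = urd, umd = m$umd, ufa = m$ufa,
                 residual = best$obj, converged = best$converged,
                 lambda_free = lambda_free),
            class = "smt_fit")
}

#' Fit the two-compartment spherical-mean model
#'
#' Bounded least squares of [forward_mcsmt_mean()] over
#' `(f_in, lambda_diff)` in `[0, 1] x (0, lambda_free]` from a 4-point start
#' grid; `v_ad` and `v_md` follow from [mcsmt_metrics()]. Ties are broken by
#' lower residual then lower `f_in`.
#'
#' @inheritParams fit_smt
#' @return Object of class `mcsmt_fit`: `f_in`, `lambda_diff`, `v_ad`, `v_md`,
#'   `residual`, `converged`.
#' @export
fit_mcsmt <- function(shell_means, b = NULL, lambda_free = 3e-3) {
  if (is.data.frame(shell_means)) {
    b <- shell_means$b
    eps <- shell_means$mean_signal
  } else {
    eps <- as.numeric(shell_means)
  }
  if (length(eps) < 2) abort("Need at least 2 non-zero shells.")
  if (length(b) != length(eps)) abort("b/shell-mean length mismatch.")
  if (any(eps <= 0) || any(eps > 1 + 1e-9)) {
    abort("Shell means must lie in (0, 1].")
  }
  if (all(eps > 0.999)) {
    abort("No measurable attenuation across shells: (f_in, lambda_diff) unidentifiable.")
  }
  sc <- 1e3
  resid <- function(p) forward_mcsmt_mean(p[1], p[2] / sc, b) - eps
  starts <- as.matrix(expand.grid(f_in = c(0.2, 0.8), l = c(1.0, 2.5)))
  best <- multistart_lm(resid, starts, lower = c(0, 1e-6),
                        upper = c(1, lambda_free * sc),
                        tie_value = function(p) p[1])
  f_in <- unname(best$par[1])
  lam <- unname(best$par[2]) / sc
  m <- mcsmt_metrics(lambda_diff = lam, f_in = f_in)
  structure(list(f_in = f_in, lambda_diff = lam, v_ad = m$v_ad, v_md = m$v_md,
                 residual = best$obj, converged = best$converged,
                 lambda_free = lambda_free),
            class = "mcsmt_fit")
}

#' @export
print.smt_fit <- function(x, ...) {
  cat(sprintf("SMT micro-tensor fit: uFA %.3f  uMD %.3f  uRD %.3f  uAD %.3f (x1e-3)\n",
              x$ufa, x$umd * 1e3, x$urd * 1e3, x$uad * 1e3))
  invisible(x)
}

#' @export
print.mcsmt_fit <- function(x, ...) {
  cat(sprintf("MC-SMT fit: f_in %.3f  lambda_diff %.3f  v_AD %.3f  v_MD %.3f (x1e-3)\n",
              x$f_in, x$lambda_diff * 1e3, x$v_ad * 1e3, x$v_md * 1e3))
  invisible(x)
}

#' Fit all diffusion models to a voxel x measurement signal matrix
#'
#' Applies [fit_dti()] (lowest shell only), [fit_smt()] and [fit_mcsmt()]
#' (all shells, through [spherical_mean()]) voxel-wise. Voxels are independent,
#' so results do not depend on row order.
#'
#' @param signals Matrix (voxels x measurements) or vector for one voxel.
#' @param scheme A [gradient_scheme()].
#' @param models Subset of `c("dti", "smt", "mcsmt")`.
#' @param lambda_free Diffusivity ceiling for the microscopic fits (mm^2/s).
#' @param report_units If TRUE (default) diffusivity columns are reported in
#'   1e-3 mm^2/s, the convention used in lesion feature tables; otherwise in
#'   mm^2/s.
#' @param rician_sigma Optional known noise SD passed to [spherical_mean()]
#'   for Rician bias correction of the microscopic fits.
#' @return Tibble with one row per voxel and one column per metric
#'   (see [diffusion_metric_names()]), plus `voxel` index.
#' @export
fit_dwi_metrics <- function(signals, scheme, models = c("dti", "smt", "mcsmt"),
                            lambda_free = 3e-3, report_units = TRUE,
                            rician_sigma = NULL) {
  models <- match.arg(models, several.ok = TRUE)
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1)
  u <- if (report_units) 1e3 else 1
  rows <- purrr::map_dfr(seq_len(nrow(signals)), function(v) {
    s <- signals[v, ]
    out <- tibble(voxel = v)
    if ("dti" %in% models) {
      f <- fit_dti(s, scheme)
      out <- dplyr::bind_cols(out, tibble(fa = f$fa, md = f$md * u,
                                          rd = f$rd * u, ad = f$ad * u))
    }
    if (any(c("smt", "mcsmt") %in% models)) {
      sm <- spherical_mean(s, scheme, min_dirs = 0,
                           rician_sigma = rician_sigma)
      # noise can push a shell mean marginally above the S0 estimate
      sm$mean_signal <- pmin(sm$mean_signal, 1)
      if ("smt" %in% models) {
        f <- fit_smt(sm, lambda_free = lambda_free)
        out <- dplyr::bind_cols(out, tibble(ufa = f$ufa, umd = f$umd * u,
                                            urd = f$urd * u, uad = f$uad * u))
      }
      if ("mcsmt" %in% models) {
        f <- fit_mcsmt(sm, lambda_free = lambda_free)
        out <- dplyr::bind_cols(out, tibble(f_in = f$f_in,
                                            lambda_diff = f$lambda_diff * u,
                                            v_ad = f$v_ad * u,
                                            v_md = f$v_md * u))
      }
    }
    out
  })
  rows
}
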