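#' Scalar DTI metrics from an eigenvalue triple
#'
#' `md = (l1 + l2 + l3) / 3`, `ad = l1`, `rd = (l2 + l3) / 2` (so
#' `md = (ad + 2 rd) / 3` exactly) and
#' `fa = sqrt(3/2) * ||l - md|| / ||l||` (0 for an all-zero triple).
#'
#' @param lambdas Length-3 non-negative eigenvalues, descending.
#' @return One-row tibble with `fa`, `md`, `rd`, `ad` (same units as input).
#' @export
#' @examples
#' dti_metrics(c(0.64, 0.37, 0.37) * 1e-3)$md * 1e3 # 0.46
dti_metrics <- function(lambdas) {
  stopifnot(length(lambdas) == 3)
  l <- sort(as.numeric(lambdas), decreasing = TRUE)
  md <- mean(l)
  ss <- sum(l^2)
  fa <- if (ss <= 0) 0 else sqrt(1.5 * sum((l - md)^2) / ss)
  tibble(fa = fa, md = md, rd = (l[2] + l[3]) / 2, ad = l[1])
}

#' Log-linear least-squares diffusion tensor fit
#'
#' Fits `ln S = ln S0 - b g' D g` by ordinary least squares using only the
#' measurements with `b <= b_max` (plus the unweighted images); by default the
#' lowest shell (b <= 1000 s/mm^2), the conventional choice because the
#' monoexponential tensor model breaks down at strong diffusion weighting.
#' Negative eigenvalues are clamped to zero and flagged.
#'
#' @param signals Positive signal vector, one value per scheme row.
#' @param scheme A [gradient_scheme()].
#' @param b_max Largest b-value entering the fit (s/mm^2). Default 1000.
#' @return An object of class `dti_fit`: a list with `tensor` (3 x 3),
#'   `eigenvalues` (descending), `s0`, the metrics `fa`, `md`, `rd`, `ad`
#'   (mm^2/s) and `clamped` (TRUE if an eigenvalue was negative before
#'   clamping).
#' @export
fit_dti <- function(signals, scheme, b_max = 1000) {
  signals <- as.numeric(signals)
  if (length(signals) != nrow(scheme)) abort("signals/scheme length mismatch.")
  if (any(!is.finite(signals)) || any(signals <= 0)) {
    abort("Signals must be positive and finite for the log-linear fit.")
  }
  keep <- scheme$b <= b_max + 1e-9
  sch <- scheme[keep, ]
  if (sum(sch$shell == 0) < 1) abort("Need at least one b = 0 measurement.")
  if (sum(sch$shell > 0) < 6) {
    abort("Need at least 6 diffusion-weighted measurements with b <= b_max.")
  }
  y <- log(signals[keep])
  X <- cbind(1,
             -sch$b * sch$gx^2, -sch$b * sch$gy^2, -sch$b * sch$gz^2,
             -2 * sch$b * sch$gx * sch$gy,
             -2 * sch$b * sch$gx * sch$gz,
             -2 * sch$b * sch$gy * sch$gz)
  if (qr(X)$rank < 7) abort("Singular design: gradient directions are collinear.")
  beta <- qr.solve(X, y)
  D <- matrix(c(beta[2], beta[5], beta[6],
                beta[5], beta[3], beta[7],
                beta[6], beta[7], beta[4]), 3, 3)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(ev, decreasing = TRUE)
  clamped <- any(ev < 0)
  if (clamped) {
    warn("Negative tensor eigenvalue(s) clamped to zero.")
    ev <- pmax(ev, 0)
  }
  m <- dti_metrics(ev)
  structure(list(tensor = D, eigenvalues = ev, s0 = exp(beta[1]),
                 fa = m$fa, md = m$md, rd = m$rd, ad = m$ad,
                 clamped = clamped, b_max = b_max),
            class = "dti_fit")
}

#' @export
print.dti_fit <- function(x, ...) {
  cat("DTI fit (b <=", x$b_max, "s/mm^2)\n")
  cat(sprintf("  FA %.3f  MD %.3f  RD %.3f  AD %.3f (x1e-3 mm^2/s)\n",
              x$fa, x$md * 1e3, x$rd * 1e3, x$ad * 1e3))
  invisible(x)
}
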