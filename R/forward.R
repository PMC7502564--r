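#' Spherical-mean signal of a stick (zero-radius cylinder) compartment
#'
#' Powder average over uniformly distributed orientations of
#' `exp(-b * lambda * cos^2(theta))`:
#' `sqrt(pi) * erf(sqrt(b * lambda)) / (2 * sqrt(b * lambda))`,
#' with the continuous limit 1 as `b * lambda -> 0` (series expansion used for
#' small arguments for numerical stability).
#'
#' @param b b-value(s), s/mm^2.
#' @param lambda Diffusivity along the stick, mm^2/s (>= 0).
#' @return Spherical-mean attenuation in (0, 1].
#' @export
#' @examples
#' stick_mean(1000, 2e-3) # about 0.598
stick_mean <- function(b, lambda) {
  x <- b * lambda
  if (any(x < -1e-12)) abort("b * lambda must be non-negative.")
  x <- pmax(x, 0)
  out <- numeric(length(x))
  small <- x < 1e-5
  # Taylor series of sqrt(pi) erf(sqrt(x)) / (2 sqrt(x)) about 0
  out[small] <- 1 - x[small] / 3 + x[small]^2 / 10 - x[small]^3 / 42
  xs <- x[!small]
  out[!small] <- sqrt(pi) * erf(sqrt(xs)) / (2 * sqrt(xs))
  out
}

#' Spherical-mean signal of an axially symmetric micro-tensor (zeppelin)
#'
#' `epsilon(b) = exp(-b * l_perp) * sqrt(pi) * erf(sqrt(b (l_par - l_perp))) /
#' (2 sqrt(b (l_par - l_perp)))`, reducing to `exp(-b * l)` when
#' `l_par = l_perp = l` (isotropic limit).
#'
#' @param b b-value(s), s/mm^2.
#' @param l_par,l_perp Parallel and perpendicular micro-diffusivities, mm^2/s,
#'   with `0 <= l_perp <= l_par`.
#' @return Spherical-mean attenuation in (0, 1].
#' @export
zeppelin_mean <- function(b, l_par, l_perp) {
  if (any(l_perp < -1e-15) || any(l_par - l_perp < -1e-12)) {
    abort("Require 0 <= l_perp <= l_par.")
  }
  exp(-b * pmax(l_perp, 0)) * stick_mean(b, pmax(l_par - l_perp, 0))
}

#' Two-compartment (stick + tortuosity zeppelin) spherical-mean forward model
#'
#' Intra-neurite water is a stick with diffusivity `lambda_diff`; extra-neurite
#' water is a zeppelin with the same parallel diffusivity and perpendicular
#' diffusivity set by the tortuosity constraint
#' `l_perp = (1 - f_in) * lambda_diff`:
#' `epsilon(b) = f_in * e_stick(b; lambda_diff) +
#'  (1 - f_in) * e_zeppelin(b; lambda_diff, (1 - f_in) lambda_diff)`.
#'
#' @param f_in Intra-neurite volume fraction in \[0, 1\].
#' @param lambda_diff Intrinsic diffusivity, mm^2/s (> 0).
#' @param b b-value(s), s/mm^2.
#' @return Spherical-mean attenuation in (0, 1], monotone non-increasing in b.
#' @export
#' @examples
#' forward_mcsmt_mean(0.5, 2e-3, 1000) # about 0.436
forward_mcsmt_mean <- function(f_in, lambda_diff, b) {
  assert_scalar_num(f_in, "f_in", 0, 1)
  if (!is.numeric(lambda_diff) || lambda_diff <= 0) {
    abort("`lambda_diff` must be > 0.")
  }
  f_in * stick_mean(b, lambda_diff) +
    (1 - f_in) * zeppelin_mean(b, lambda_diff, (1 - f_in) * lambda_diff)
}

#' Monoexponential tensor forward signal
#'
#' `S_i = S0 * exp(-b_i * g_i' D g_i)` for every measurement of the scheme.
#'
#' @param tensor Symmetric positive semi-definite 3 x 3 diffusion tensor,
#'   mm^2/s.
#' @param s0 Non-diffusion-weighted signal.
#' @param scheme A [gradient_scheme()].
#' @return Numeric signal vector, one value per scheme row.
#' @export
forward_dti_signal <- function(tensor, s0, scheme) {
  tensor <- as.matrix(tensor)
  if (!isTRUE(all.equal(tensor, t(tensor), tolerance = 1e-8))) {
    abort("`tensor` must be symmetric.")
  }
  ev <- eigen(tensor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12 * max(abs(ev), 1e-30)) {
    abort("`tensor` must be positive semi-definite.")
  }
  g <- cbind(scheme$gx, scheme$gy, scheme$gz)
  quad <- rowSums((g %*% tensor) * g)
  s0 * exp(-scheme$b * quad)
}

#' Build a diffusion tensor from eigenvalues and an orientation
#'
#' @param lambdas Length-3 eigenvalues (mm^2/s), principal first.
#' @param mu Unit principal direction (default x axis).
#' @return 3 x 3 symmetric tensor with axial symmetry about `mu` when
#'   `lambdas[2] == lambdas[3]` (general orthonormal completion otherwise).
#' @export
tensor_from_eigen <- function(lambdas, mu = c(1, 0, 0)) {
  stopifnot(length(lambdas) == 3)
  mu <- mu / sqrt(sum(mu^2))
  # orthonormal completion
  a <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- a - sum(a * mu) * mu
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(mu[2] * e2[3] - mu[3] * e2[2],
          mu[3] * e2[1] - mu[1] * e2[3],
          mu[1] * e2[2] - mu[2] * e2[1])
  v <- cbind(mu, e2, e3)
  v %*% diag(lambdas) %*% t(v)
}

#' Per-direction two-compartment signal
#'
#' Directional (not powder-averaged) signal of the stick + tortuosity-zeppelin
#' model for a voxel with a single fibre orientation `mu`; its spherical mean
#' over uniform directions is [forward_mcsmt_mean()].
#'
#' @inheritParams forward_mcsmt_mean
#' @param mu Unit fibre orientation.
#' @param s0 Unweighted signal.
#' @param scheme A [gradient_scheme()].
#' @return Signal vector, one value per scheme row.
#' @export
forward_mcsmt_signal <- function(f_in, lambda_diff, mu, s0, scheme) {
  assert_scalar_num(f_in, "f_in", 0, 1)
  mu <- mu / sqrt(sum(mu^2))
  g <- cbind(scheme$gx, scheme$gy, scheme$gz)
  c2 <- as.vector(g %*% mu)^2
  l_perp <- (1 - f_in) * lambda_diff
  stick <- exp(-scheme$b * lambda_diff * c2)
  zepp <- exp(-scheme$b * (l_perp + (lambda_diff - l_perp) * c2))
  s0 * (f_in * stick + (1 - f_in) * zepp)
}
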