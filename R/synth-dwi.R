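#' Simulate multi-shell diffusion signals from known tissue parameters
#'
#' Forward-generates per-measurement signals for a set of voxels whose ground
#' truth is given either as two-compartment parameters (`model = "mcsmt"`:
#' columns `f_in`, `lambda_diff`, optional orientation `mu_x/mu_y/mu_z`,
#' optional `s0`) or as tensor eigenvalues (`model = "tensor"`: columns `l1`,
#' `l2`, `l3`, optional orientation, optional `s0`). Optional Rician
#' corruption adds two independent Gaussian channels:
#' `S_noisy = sqrt((S + e1)^2 + e2^2)`, `e ~ N(0, sigma^2)`.
#'
#' @param params Tibble of per-voxel true parameters.
#' @param scheme A [gradient_scheme()].
#' @param model `"mcsmt"` or `"tensor"`.
#' @param noise_sigma Rician channel SD in signal units (>= 0; 0 = noise
#'   free, in which case the output is independent of `seed`).
#' @param seed Seed for noise and random orientations.
#' @return List: `signals` (voxels x measurements matrix) and `truth` (the
#'   input parameters plus the orientation actually used, one row per voxel).
#' @export
gen_dwi_voxels <- function(params, scheme, model = c("mcsmt", "tensor"),
                           noise_sigma = 0, seed = 1L) {
  model <- match.arg(model)
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  if (any(scheme$b < 0)) abort("Negative b-value in scheme.")
  n <- nrow(params)
  s0 <- if ("s0" %in% names(params)) params$s0 else rep(1, n)
  if (length(s0) == 1) s0 <- rep(s0, n)

  orient <- with_seed(derive_seed(seed, 7), {
    if (all(c("mu_x", "mu_y", "mu_z") %in% names(params))) {
      as.matrix(params[, c("mu_x", "mu_y", "mu_z")])
    } else {
      m <- matrix(rnorm(3 * n), n, 3)
      m / sqrt(rowSums(m^2))
    }
  })

  signals <- t(sapply(seq_len(n), function(v) {
    if (model == "mcsmt") {
      forward_mcsmt_signal(params$f_in[v], params$lambda_diff[v],
                           orient[v, ], s0[v], scheme)
    } else {
      tensor <- tensor_from_eigen(c(params$l1[v], params$l2[v], params$l3[v]),
                                  orient[v, ])
      forward_dti_signal(tensor, s0[v], scheme)
    }
  }))
  if (n == 1) signals <- matrix(signals, nrow = 1)

  if (noise_sigma > 0) {
    signals <- with_seed(derive_seed(seed, 11), {
      e1 <- matrix(rnorm(length(signals), 0, noise_sigma), nrow(signals))
      e2 <- matrix(rnorm(length(signals), 0, noise_sigma), nrow(signals))
      sqrt((signals + e1)^2 + e2^2)
    })
  }
  base <- as_tibble(params)
  base <- base[, setdiff(names(base), c("mu_x", "mu_y", "mu_z", "s0")),
               drop = FALSE]
  truth <- dplyr::bind_cols(base,
                            tibble(mu_x = orient[, 1], mu_y = orient[, 2],
                                   mu_z = orient[, 3], s0 = s0))
  list(signals = signals, truth = truth)
}
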