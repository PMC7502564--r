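test_that("gradient schemes validate inputs and round-trip through bval/bvec", {
  expect_error(gradient_scheme(c(-1, 0), matrix(0, 2, 3)), "non-negative")
  expect_error(gradient_scheme(1000, matrix(c(2, 0, 0), 1, 3)), "unit norm")

  sch <- default_scheme()
  expect_equal(nrow(sch), 185) # 3 x 60 + 5 b0
  expect_equal(shell_bvalues(sch), c(1000, 2000, 3000))
  nrm <- sqrt(sch$gx^2 + sch$gy^2 + sch$gz^2)
  expect_true(all(abs(nrm[sch$b > 0] - 1) < 1e-6))

  d <- withr::local_tempdir()
  write_gradients(sch, file.path(d, "b.bval"), file.path(d, "b.bvec"))
  sch2 <- read_gradients(file.path(d, "b.bval"), file.path(d, "b.bvec"))
  expect_equal(sch2$b, sch$b, tolerance = 1e-6)
  expect_equal(sch2$gx, sch$gx, tolerance = 1e-6)
  expect_equal(sch2$shell, sch$shell)
})

test_that("tensor forward signal matches scalar evaluation and is rotation invariant", {
  sch <- gradient_scheme(c(0, rep(1000, 3)),
                         rbind(c(0, 0, 0), diag(3)))
  D <- diag(c(1.7, 0.3, 0.3)) * 1e-3
  s <- forward_dti_signal(D, 100, sch)
  expect_equal(s[1], 100) # b = 0 returns S0
  expect_equal(s[2] / 100, exp(-1.7), tolerance = 1e-12)

  # isotropic tensor: same attenuation in every direction
  iso <- forward_dti_signal(diag(3) * 0.8e-3, 1, test_scheme())
  sh1 <- iso[test_scheme()$shell == 1]
  expect_equal(max(sh1) - min(sh1), 0, tolerance = 1e-15)
  expect_equal(unique(round(sh1, 12)), round(exp(-1000 * 0.8e-3), 12))

  expect_error(forward_dti_signal(diag(c(1, 1, -1)) * 1e-3, 1, sch),
               "positive semi-definite")
})

test_that("stick and two-compartment powder averages agree with spherical quadrature", {
  # stick with b*lambda = 2
  quad <- sphere_quadrature(function(c2) exp(-2 * c2))
  expect_equal(stick_mean(1000, 2e-3), quad, tolerance = 1e-9)
  expect_equal(stick_mean(1000, 2e-3), 0.598, tolerance = 1e-3)

  # two-compartment mean vs quadrature of the per-direction signal
  f <- 0.5; lam <- 2e-3; b <- 1000
  lp <- (1 - f) * lam
  quad2 <- sphere_quadrature(function(c2) {
    f * exp(-b * lam * c2) + (1 - f) * exp(-b * (lp + (lam - lp) * c2))
  })
  expect_equal(forward_mcsmt_mean(f, lam, b), quad2, tolerance = 1e-9)
  expect_lt(abs(forward_mcsmt_mean(f, lam, b) - 0.436), 1e-3)

  # degenerate compartments
  expect_equal(forward_mcsmt_mean(0, 2e-3, c(1000, 3000)),
               exp(-c(1000, 3000) * 2e-3), tolerance = 1e-12)
  expect_equal(forward_mcsmt_mean(1, 2e-3, 2000), stick_mean(2000, 2e-3))

  # strictly decreasing in b
  eps <- forward_mcsmt_mean(0.4, 1.5e-3, seq(0, 3000, by = 250))
  expect_true(all(diff(eps) < 0))
})

test_that("powder average of per-direction signals matches the closed form on a dense lattice", {
  sch <- gradient_scheme(c(0, rep(2000, 500)),
                         rbind(c(0, 0, 0), fibonacci_directions(500)))
  s <- forward_mcsmt_signal(0.6, 2.2e-3, mu = c(0, 0, 1), s0 = 1, sch)
  sm <- spherical_mean(s, sch)
  expect_equal(sm$mean_signal, forward_mcsmt_mean(0.6, 2.2e-3, 2000),
               tolerance = 1e-4)
})

test_that("DTI fit recovers noise-free tensors and uses only the low shell", {
  sch <- test_scheme()
  set.seed(11)
  for (i in 1:5) {
    ev <- sort(runif(3, 0.2, 2.5), decreasing = TRUE) * 1e-3
    mu <- rnorm(3); mu <- mu / sqrt(sum(mu^2))
    D <- tensor_from_eigen(ev, mu)
    s <- forward_dti_signal(D, 50, sch)
    f <- fit_dti(s, sch)
    expect_lt(max(abs(f$tensor - D)) / max(abs(D)), 1e-10)
    expect_equal(f$eigenvalues, ev, tolerance = 1e-8)
    expect_equal(f$s0, 50, tolerance = 1e-8)
  }
  # only b <= 1000 informs the fit: corrupting high shells changes nothing
  D <- tensor_from_eigen(c(1.7, 0.4, 0.3) * 1e-3)
  s <- forward_dti_signal(D, 10, sch)
  s2 <- s
  s2[sch$b > 1500] <- s2[sch$b > 1500] * 5
  expect_identical(fit_dti(s, sch)$tensor, fit_dti(s2, sch)$tensor)
})

test_that("DTI metric identities hold and degenerate inputs are handled", {
  # isotropic signal gives FA exactly 0
  sch <- test_scheme()
  s <- forward_dti_signal(diag(3) * 0.7e-3, 1, sch)
  expect_equal(fit_dti(s, sch)$fa, 0, tolerance = 1e-10)

  # MD = (AD + 2 RD) / 3: the reference NAWM eigenvalues give MD 0.46
  m <- dti_metrics(c(0.64, 0.37, 0.37) * 1e-3)
  expect_equal(m$md * 1e3, 0.46, tolerance = 1e-12)
  expect_equal(m$ad * 1e3, 0.64)
  expect_equal(m$rd * 1e3, 0.37)

  expect_error(fit_dti(rep(-1, nrow(sch)), sch), "positive")

  # signal increasing with b in one direction implies a negative eigenvalue
  s_bad <- exp(0.2e-3 * sch$b * sch$gx^2) * exp(-1e-3 * sch$b * (sch$gy^2 + sch$gz^2))
  expect_warning(f <- fit_dti(s_bad, sch), "clamped")
  expect_true(all(f$eigenvalues >= 0))
})

test_that("spherical mean normalizes by S0 and flags sparse or empty shells", {
  sch <- test_scheme()
  s <- rep(0.42, nrow(sch)); s[sch$shell == 0] <- 1
  sm <- spherical_mean(s, sch)
  expect_equal(sm$mean_signal, rep(0.42, 3))
  expect_equal(attr(sm, "s0"), 1)

  sparse <- gradient_scheme(c(0, rep(1000, 5)),
                            rbind(c(0, 0, 0), fibonacci_directions(5)))
  expect_warning(spherical_mean(rep(1, 6), sparse), "directions")
  no_b0 <- gradient_scheme(rep(1000, 6), fibonacci_directions(6))
  expect_error(spherical_mean(rep(1, 6), no_b0), "S0")
})

test_that("SMT micro-tensor fit round-trips noise-free shell means", {
  b <- c(1000, 2000, 3000)
  for (pars in list(c(2.0e-3, 0.5e-3), c(1.2e-3, 0.9e-3), c(2.8e-3, 0.1e-3))) {
    eps <- zeppelin_mean(b, pars[1], pars[2])
    f <- fit_smt(eps, b = b)
    expect_lt(abs(f$uad - pars[1]) / pars[1], 1e-6)
    expect_lt(abs(f$urd - pars[2]) / pars[2], 1e-6)
    # derived identities exact at the fit
    expect_equal(f$umd, (f$uad + 2 * f$urd) / 3, tolerance = 1e-15)
    expect_gte(f$ufa, 0); expect_lte(f$ufa, 1)
    expect_true(f$urd <= f$uad)
  }
  # isotropic means give (near) zero microscopic anisotropy
  f_iso <- fit_smt(exp(-b * 0.9e-3), b = b)
  expect_lt(f_iso$ufa, 1e-3)
  # reference NAWM identity: uMD from (uAD, uRD)
  expect_equal(smt_metrics(2.66, 0.23)$umd, 1.04, tolerance = 1e-12)
})

test_that("MC-SMT fit round-trips and rejects unidentifiable input", {
  b <- c(1000, 2000, 3000)
  for (pars in list(c(0.5, 2.0e-3), c(0.2, 1.2e-3), c(0.8, 2.7e-3))) {
    eps <- forward_mcsmt_mean(pars[1], pars[2], b)
    f <- fit_mcsmt(eps, b = b)
    expect_lt(abs(f$f_in - pars[1]) / pars[1], 1e-6)
    expect_lt(abs(f$lambda_diff - pars[2]) / pars[2], 1e-6)
    expect_equal(f$v_ad, (1 - f$f_in) * f$lambda_diff, tolerance = 1e-15)
    expect_equal(f$v_md, (f$lambda_diff + 2 * f$v_ad) / 3, tolerance = 1e-15)
  }
  expect_error(fit_mcsmt(c(1, 1, 1), b = b), "unidentifiable")
  # reference NAWM identity: v_MD from printed (lambda_diff, v_AD)
  expect_equal(mcsmt_metrics(lambda_diff = 2.02, v_ad = 0.91)$v_md, 1.28,
               tolerance = 1e-12)
})

test_that("map-level fitting is row-order independent and reports table units", {
  sch <- test_scheme()
  pars <- tibble::tibble(f_in = c(0.3, 0.6, 0.45), lambda_diff = c(2, 1.6, 2.4) * 1e-3)
  sig <- gen_dwi_voxels(pars, sch, noise_sigma = 0, seed = 1)$signals
  tab <- fit_dwi_metrics(sig, sch)
  expect_setequal(setdiff(names(tab), "voxel"), diffusion_metric_names())
  tab_rev <- fit_dwi_metrics(sig[3:1, ], sch)
  expect_equal(tab$f_in, rev(tab_rev$f_in), tolerance = 1e-9)
  expect_true(all(tab$lambda_diff > 1 & tab$lambda_diff < 3)) # 1e-3 units
})

test_that("microscopic fits tolerate Rician noise at SNR 20", {
  sch <- default_scheme() # full 180-direction protocol
  set.seed(42)
  n <- 500
  pars <- tibble::tibble(f_in = runif(n, 0.3, 0.8),
                         lambda_diff = runif(n, 1.5e-3, 2.6e-3))
  gd <- gen_dwi_voxels(pars, sch, noise_sigma = 1 / 20, seed = 99)
  fits <- fit_dwi_metrics(gd$signals, sch, models = "mcsmt",
                          report_units = FALSE, rician_sigma = 1 / 20)
  mae <- stats::median(abs(fits$f_in - pars$f_in))
  expect_lte(mae, 0.05)
})
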