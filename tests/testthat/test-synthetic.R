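test_that("cohort generation is a pure function of its seed", {
  cfg <- cohort_config(n_patients = 20, seed = 123)
  a <- gen_cohort(cfg)
  b <- gen_cohort(cfg)
  expect_identical(a$lesions, b$lesions)
  expect_identical(a$patients, b$patients)
  expect_identical(a$truth, b$truth)
  c <- gen_cohort(cohort_config(n_patients = 20, seed = 124))
  expect_false(identical(a$lesions, c$lesions))
})

test_that("default cohort size and ground-truth closure match the design", {
  co <- gen_cohort(cohort_config(seed = 5))
  # 59 patients at the per-location reference rates: ~1236 lesions expected,
  # Poisson SD ~ sqrt(1236) ~ 35
  expect_equal(nrow(co$patients), 59)
  expect_gt(nrow(co$lesions), 1236 - 4 * 36)
  expect_lt(nrow(co$lesions), 1236 + 4 * 36)
  # exactly one truth row per lesion, truth ids = lesion ids
  expect_setequal(co$truth$lesion_id, co$lesions$lesion_id)
  expect_equal(nrow(co$truth), nrow(co$lesions))
  expect_true(all(co$truth$true_type %in% c("A", "B")))
})

test_that("latent B fraction honours the configured probability", {
  les <- simulate_lesion_features(10000, p_b = 0.52, seed = 8)
  k <- sum(les$true_type == "B")
  ci <- stats::qbinom(c(0.005, 0.995), 10000, 0.52)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("pooled feature moments match the reference whole-brain row", {
  les <- simulate_lesion_features(10000, seed = 21)
  for (met in c("fa", "rd", "ufa", "f_in")) {
    row <- whole_brain_row(met)
    expect_lt(abs(mean(les[[met]]) - row$mean), 0.01)
    expect_lt(abs(sd(les[[met]]) - row$sd), 0.005)
    # and the B-minus-A separation matches the reference delta
    dlt <- default_type_deltas()
    dref <- dlt$delta[dlt$location == "whole_brain" & dlt$metric == met]
    dobs <- mean(les[[met]][les$true_type == "B"]) -
      mean(les[[met]][les$true_type == "A"])
    expect_lt(abs(dobs - dref), 0.01)
  }
})

test_that("variance decomposition rejects impossible type separations", {
  expect_error(type_mixture_params(
    tibble::tibble(metric = "f_in", mean = 0.5, sd = 0.02),
    tibble::tibble(metric = "f_in", delta = -0.27), p_b = 0.5),
    "decomposition")
})

test_that("clinical generator links outcomes to burden as configured", {
  set.seed(3)
  pts <- tibble::tibble(patient_id = sprintf("P%02d", 1:200),
                        age = rnorm(200, 45, 9),
                        sex = sample(c("female", "male"), 200, TRUE))
  burden <- stats::setNames(rpois(200, 10), pts$patient_id)

  # zero effect: correlation inside the null band
  co0 <- list(y = c(intercept = 1, burden = 0, age = 0, sex = 0, sd = 1))
  out0 <- gen_clinical(pts, burden, co0, seed = 4)
  expect_lt(abs(cor(out0$y, burden[out0$patient_id])), 3 / sqrt(200))

  # noiseless positive effect: perfect rank correlation net of covariates
  co1 <- list(y = c(intercept = 1, burden = 0.5, age = 0, sex = 0, sd = 0))
  out1 <- gen_clinical(pts, burden, co1, seed = 4)
  expect_equal(cor(out1$y, burden[out1$patient_id], method = "spearman"), 1)

  # logistic outcome at zero coefficient: prevalence set by the intercept
  co2 <- list(th = c(intercept = qlogis(0.23), burden = 0, age = 0, sex = 0, sd = 0))
  attr(co2, "family") <- c(th = "logistic")
  big <- tibble::tibble(patient_id = sprintf("Q%04d", 1:5000),
                        age = rnorm(5000, 45, 9),
                        sex = sample(c("female", "male"), 5000, TRUE))
  out2 <- gen_clinical(big, stats::setNames(rpois(5000, 10), big$patient_id),
                       co2, seed = 9)
  ci <- stats::qbinom(c(0.005, 0.995), 5000, 0.23) / 5000
  expect_gte(mean(out2$th), ci[1])
  expect_lte(mean(out2$th), ci[2])

  expect_error(gen_clinical(pts, stats::setNames(1:3, c("a", "b", "c")), co0),
               "Mismatched")
})

test_that("signal generator matches the forward model and noise conventions", {
  sch <- test_scheme()
  pars <- tibble::tibble(f_in = 1, lambda_diff = 2e-3,
                         mu_x = 0, mu_y = 0, mu_z = 1)
  gd <- gen_dwi_voxels(pars, sch, noise_sigma = 0, seed = 1)
  expect_equal(as.numeric(gd$signals),
               forward_mcsmt_signal(1, 2e-3, c(0, 0, 1), 1, sch),
               tolerance = 1e-12)
  # noise-free output is seed independent
  gd2 <- gen_dwi_voxels(pars, sch, noise_sigma = 0, seed = 999)
  expect_identical(gd$signals, gd2$signals)
  expect_error(gen_dwi_voxels(pars, sch, noise_sigma = -1), ">= 0")

  # Rician floor: at SNR 50 the b = 0 mean is within 1% of S0
  many <- tibble::tibble(f_in = rep(0.5, 400), lambda_diff = 2e-3)
  gn <- gen_dwi_voxels(many, sch, noise_sigma = 1 / 50, seed = 2)
  b0 <- gn$signals[, sch$shell == 0]
  expect_lt(abs(mean(b0) - 1), 0.01)
  expect_gt(mean(b0), 1) # Rician bias is upward
})

test_that("phantom generator realizes requested overlaps with honest truth", {
  ph <- gen_phantom_masks()
  expect_equal(max(ph$lesion_volume), nrow(default_phantom_lesions()))
  # a 6%-contact lesion is periventricular ground truth
  expect_equal(ph$truth$true_location[1], "periventricular")
  expect_equal(ph$truth$frac_ventricle[1], 1 / 16)
  # the 26-voxel lesion is flagged sub-threshold, the 27-voxel one is not
  expect_true(ph$truth$sub_threshold[ph$truth$volume_mm3 == 26])
  expect_false(ph$truth$sub_threshold[ph$truth$volume_mm3 == 27])

  # empty spec: all-zero volume and empty truth
  e <- gen_phantom_masks(default_phantom_lesions()[0, ])
  expect_true(all(e$lesion_volume == 0))
  expect_equal(nrow(e$truth), 0)

  # an oversized lesion cannot be placed
  big <- default_phantom_lesions()[1, ]
  big$lx <- 100
  expect_error(gen_phantom_masks(big), "does not fit")
})

test_that("phantom volumes survive a NIfTI round trip", {
  ph <- gen_phantom_masks()
  d <- withr::local_tempdir()
  write_phantom_nifti(ph, d)
  back <- read_volume(file.path(d, "lesions.nii"))
  expect_equal(array(back, dim(back)), ph$lesion_volume + 0,
               ignore_attr = TRUE)
  expect_equal(attr(back, "voxel_size"), rep(1, 3), ignore_attr = TRUE)
})
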