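sim_patients <- function(n = 50, beta = 0, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    d <- tibble::tibble(age = rnorm(n, 45, 9),
                        sex = sample(c("female", "male"), n, TRUE),
                        burden = rpois(n, 8))
    d$y <- 1 + beta * d$burden + 0.01 * d$age + rnorm(n, 0, sd)
    d
  })
}

test_that("Freedman-Lane handles degenerate and separated cases", {
  d <- sim_patients(40, beta = 0, seed = 2)
  d$y <- 5 # zero-variance outcome
  r <- freedman_lane_lm(d, "y", "burden", n_perms = 99, seed = 1)
  expect_equal(r$coefficient, 0)
  expect_equal(r$p_perm, 1)

  # strong effect, vanishing noise: minimum attainable p, Positive direction
  d2 <- sim_patients(40, beta = 1, sd = 1e-9, seed = 3)
  r2 <- freedman_lane_lm(d2, "y", "burden", n_perms = 199, seed = 1)
  expect_equal(r2$p_perm, 1 / 200)
  expect_equal(r2$direction, "Positive")

  # collinearity with the nuisance block is an explicit error
  d3 <- sim_patients(40, seed = 4)
  d3$xcol <- 2 * d3$age - 1
  expect_error(freedman_lane_lm(d3, "y", "xcol", n_perms = 9), "collinear")
})

test_that("Freedman-Lane p-values are affine invariant and match the t-test asymptotically", {
  d <- sim_patients(50, beta = 0.1, sd = 1.5, seed = 8)
  r <- freedman_lane_lm(d, "y", "burden", n_perms = 499, seed = 5)
  d2 <- dplyr::mutate(d, y = 3 * .data$y - 7, burden = 0.1 * .data$burden + 2)
  r2 <- freedman_lane_lm(d2, "y", "burden", n_perms = 499, seed = 5)
  expect_equal(r$p_perm, r2$p_perm)

  # convergence to the classical t-test for Gaussian data
  r10k <- freedman_lane_lm(d, "y", "burden", n_perms = 10000, seed = 5)
  ct <- summary(stats::lm(y ~ burden + age + I(sex == "female"), data = d))
  p_classic <- ct$coefficients["burden", "Pr(>|t|)"]
  expect_equal(r10k$p_perm, p_classic, tolerance = 0.01)
})

test_that("logistic permutation test rejects degenerate outcomes and finds real effects", {
  d <- sim_patients(80, seed = 11)
  d$th <- 1
  expect_error(perm_logistic(d, "th", "burden", n_perms = 9), "single class")

  withr::with_seed(12, {
    d$th <- rbinom(80, 1, plogis(-8 + 1.0 * d$burden))
  })
  r <- perm_logistic(d, "th", "burden", n_perms = 199, seed = 3)
  expect_lt(r$p_perm, 0.05)
  expect_equal(r$direction, "Positive")
})

test_that("logistic permutation test is calibrated under the null", {
  n_sims <- 200
  rejections <- 0
  for (i in seq_len(n_sims)) {
    d <- withr::with_seed(3000 + i, {
      dd <- tibble::tibble(age = rnorm(60, 45, 9),
                           sex = sample(c("female", "male"), 60, TRUE),
                           burden = rpois(60, 8))
      dd$th <- rbinom(60, 1, plogis(-1 + 0.02 * dd$age))
      dd
    })
    if (length(unique(d$th)) < 2) next
    r <- perm_logistic(d, "th", "burden", n_perms = 49, seed = i)
    if (r$p_perm <= 0.05) rejections <- rejections + 1
  }
  # with 49 perms, P(p <= .05) = 2/50 = .04 under the null; 99% binomial band
  ci <- stats::qbinom(c(0.005, 0.995), n_sims, 0.04)
  expect_gte(rejections, ci[1])
  expect_lte(rejections, ci[2])
})

test_that("two-group permutation difference behaves on degenerate and shifted groups", {
  same <- rep(1.7, 20)
  g <- rep(c("a", "b"), 10)
  r <- perm_group_diff(same, g, n_perms = 99, n_boot = 99, seed = 1)
  expect_equal(r$difference, 0)
  expect_equal(r$p_value, 1)
  expect_true(r$ci[1] <= 0 && r$ci[2] >= 0)

  shifted <- c(rep(0, 10), rep(0.29, 10))
  g2 <- rep(c("a", "b"), each = 10)
  r2 <- perm_group_diff(shifted, g2, n_perms = 99, n_boot = 99, seed = 1)
  expect_equal(r2$difference, 0.29)

  expect_error(perm_group_diff(1:5, c("a", "a", "a", "a", "b")), "at least 2")
})

test_that("the RR/SP volume-share contrast is detectable at the study group sizes", {
  # 6 vs 53 patients, mean shares 0.90 vs 0.61, between-patient SD 0.22
  hits <- 0
  for (i in 1:20) {
    v <- withr::with_seed(500 + i, {
      c(pmin(rnorm(6, 0.90, 0.22), 1), pmin(rnorm(53, 0.61, 0.22), 1))
    })
    g <- rep(c("SP", "RR"), c(6, 53))
    r <- perm_group_diff(v, g, n_perms = 499, seed = i)
    if (r$p_value < 0.05) hits <- hits + 1
  }
  expect_gt(hits, 12) # powered well above chance
})

test_that("Bonferroni control uses the explicit family size and only shrinks", {
  res <- tibble::tibble(p_perm = c(0.0049, 0.0051, 0.04, 0.5))
  adj10 <- adjust_bonferroni(res, m = 10)
  expect_equal(adj10$p_threshold[1], 0.005)
  expect_equal(adj10$bonferroni_significant, c(TRUE, FALSE, FALSE, FALSE))
  adj1 <- adjust_bonferroni(res, m = 1)
  expect_equal(adj1$bonferroni_significant, c(TRUE, TRUE, TRUE, FALSE))
  # monotone: correcting never adds discoveries
  expect_true(all(adj10$bonferroni_significant <= adj1$bonferroni_significant))
  # m = 12 gives the threshold that rounds to 0.004
  expect_equal(round(0.05 / 12, 3), 0.004)
})
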