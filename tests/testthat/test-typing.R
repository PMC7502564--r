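two_blob_data <- function(n_per = 30, sep = 8, seed = 1, p = 2) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per * p), n_per, p),
               matrix(rnorm(n_per * p, mean = sep), n_per, p))
    colnames(X) <- paste0("v", seq_len(p))
    tibble::as_tibble(as.data.frame(X))
  })
}

test_that("k-means typing is deterministic and enforces the A/B convention", {
  les <- simulate_lesion_features(600, seed = 14)
  m1 <- kmeans2(les, features = c("fa", "rd", "ufa", "f_in"), seed = 3)
  m2 <- kmeans2(les, features = c("fa", "rd", "ufa", "f_in"), seed = 3)
  expect_identical(m1$centroids, m2$centroids)
  expect_identical(m1$type, m2$type)

  # B centroid: lower FA, uFA, f_in; higher RD (raw units)
  td <- tidy(m1)
  raw <- function(ty, f) td$value_raw[td$type == ty & td$feature == f]
  expect_lt(raw("B", "fa"), raw("A", "fa"))
  expect_lt(raw("B", "ufa"), raw("A", "ufa"))
  expect_lt(raw("B", "f_in"), raw("A", "f_in"))
  expect_gt(raw("B", "rd"), raw("A", "rd"))

  les$flat <- 1
  expect_error(kmeans2(les, features = c("fa", "flat")), "flat")
})

test_that("duplicated point-masses split perfectly with zero dispersion", {
  d <- tibble::tibble(a = rep(c(0, 5), each = 20), b = rep(c(0, 5), each = 20))
  m <- kmeans2(d, seed = 1)
  expect_equal(m$tot_withinss, 0)
  expect_equal(sort(table(m$type)), sort(c(A = 20, B = 20)), ignore_attr = TRUE)
})

test_that("pair-counting score equals brute-force enumeration for n <= 12", {
  set.seed(99)
  for (i in 1:60) {
    n <- sample(2:12, 1)
    te <- sample(1:2, n, replace = TRUE)
    tr <- sample(1:2, n, replace = TRUE)
    expect_equal(ps_pair_score(te, tr), bf_pair_score(te, tr))
  }
  # singleton test clusters contribute 1, not NaN
  expect_equal(ps_pair_score(c(1, 2, 2), c(1, 1, 2)), min(1, 0))
  expect_equal(ps_pair_score(c(1, 2), c(1, 2)), 1)
})

test_that("prediction strength is 1 for well-separated duplicated clusters and bounded", {
  d <- two_blob_data(20, sep = 10)
  ps <- prediction_strength(d, n_splits = 25, seed = 2)
  expect_equal(ps$mean_ps, 1)
  expect_true(all(ps$ps >= 0 & ps$ps <= 1))

  # weak data still yields values in [0, 1]
  noise <- tibble::as_tibble(as.data.frame(matrix(rnorm(120), 60, 2)))
  psn <- prediction_strength(noise, n_splits = 25, seed = 2)
  expect_true(all(psn$ps >= 0 & psn$ps <= 1))
  expect_lt(psn$mean_ps, 1)
  expect_error(prediction_strength(noise[1:5, ], n_splits = 5), "at least 8")
})

test_that("prediction strength is stable under row shuffling and duplication", {
  d <- two_blob_data(40, sep = 5, seed = 7)
  base <- prediction_strength(d, n_splits = 40, seed = 11)$mean_ps
  shuf <- withr::with_seed(1, d[sample(nrow(d)), ])
  ps_shuf <- prediction_strength(shuf, n_splits = 40, seed = 11)$mean_ps
  expect_equal(ps_shuf, base, tolerance = 0.05)
  dup <- dplyr::bind_rows(d, d)
  ps_dup <- prediction_strength(dup, n_splits = 40, seed = 11)$mean_ps
  expect_equal(ps_dup, base, tolerance = 0.05)
})

test_that("permutation null p-values respect add-one bounds and detect structure", {
  d <- two_blob_data(30, sep = 8, seed = 5)
  pn <- ps_null_pvalue(d, n_perms = 19, n_splits_obs = 15, n_splits_null = 8,
                       seed = 4)
  expect_equal(pn$p_value, 1 / 20) # minimum attainable with 19 perms
  expect_true(all(pn$null >= 0 & pn$null <= 1))

  noise <- tibble::as_tibble(as.data.frame(matrix(rnorm(160), 80, 2)))
  pn2 <- ps_null_pvalue(noise, n_perms = 19, n_splits_obs = 8,
                        n_splits_null = 8, seed = 4)
  expect_gte(pn2$p_value, 1 / 20)
  expect_lte(pn2$p_value, 1)
})

test_that("metric screening discards ceilinged and constant features", {
  set.seed(6)
  n <- 500
  d <- tibble::tibble(
    uad = ifelse(runif(n) < 0.38, 3.0, runif(n, 2.7, 2.999)), # 38% at ceiling
    fa = rnorm(n, 0.32, 0.11),
    rd = rnorm(n, 0.47, 0.10),
    flat = rep(1.5, n))
  sc <- screen_metrics(d)
  expect_false(sc$retained[sc$feature == "uad"])
  expect_equal(sc$reason[sc$feature == "uad"], "at_ceiling")
  expect_gt(sc$ceiling_frac[sc$feature == "uad"], 0.30)
  expect_false(sc$retained[sc$feature == "flat"])
  expect_true(all(sc$retained[sc$feature %in% c("fa", "rd")]))
  expect_equal(dim(attr(sc, "correlation")), c(2, 2))
})

test_that("feature-set selection ranks separating sets above noise sets", {
  les <- simulate_lesion_features(400, seed = 31,
                                  noise_metrics = c("n1", "n2", "n3"))
  les$location <- rep(c("periventricular", "deep_wm"), 200)
  sel <- select_feature_sets(
    les,
    candidate_sets = list(c("fa", "rd", "ufa", "f_in"), c("n1", "n2", "n3")),
    strata = les$location, n_splits = 15, seed = 2)
  expect_equal(sel$set[1], "fa+rd+ufa+f_in")
  expect_true(sel$pass[sel$set == "fa+rd+ufa+f_in"])
  expect_false(sel$pass[sel$set == "n1+n2+n3"])
  # a stratum below the size floor is skipped with a warning
  les$location[1:5] <- "brainstem"
  les$location[6:400] <- rep(c("periventricular", "deep_wm"), length.out = 395)
  expect_warning(
    select_feature_sets(les, candidate_sets = list(c("fa", "rd")),
                        strata = les$location, n_splits = 5, seed = 2),
    "brainstem")
})

test_that("nearly identical passing sets are reported with high label agreement", {
  les <- simulate_lesion_features(300, seed = 77)
  les$fa2 <- les$fa + rnorm(300, 0, 0.005) # near-duplicate feature
  sel <- select_feature_sets(
    les, candidate_sets = list(c("fa", "rd", "ufa", "f_in"),
                               c("fa2", "rd", "ufa", "f_in")),
    n_splits = 10, seed = 3)
  agg <- attr(sel, "agreement")
  expect_false(is.null(agg))
  expect_gt(min(agg), 0.97)
})

test_that("nearest-centroid assignment reproduces training labels and tie rules", {
  les <- simulate_lesion_features(300, seed = 9)
  m <- kmeans2(les, features = c("fa", "rd", "ufa", "f_in"), seed = 1)
  typed <- assign_types(les, m)
  expect_identical(typed$type, m$type)
  # a point exactly at the B centroid maps to B
  td <- tidy(m)
  bpt <- tidyr::pivot_wider(td[td$type == "B", c("feature", "value_raw")],
                            names_from = "feature", values_from = "value_raw")
  expect_equal(predict(m, bpt), "B")
  expect_error(predict(m, bpt[, 1:2]), "Missing feature")
  # exactly equidistant point: lower-index centroid wins (documented tie rule)
  sym <- tibble::tibble(v = c(-1, -1, -1, 1, 1, 1))
  ms <- kmeans2(sym, features = "v", seed = 1)
  expect_equal(predict(ms, tibble::tibble(v = 0)), unname(ms$label_map[1]))
})

test_that("patient burden summarises counts, volumes and percentages", {
  les <- tibble::tibble(
    patient_id = c("P1", "P1", "P1", "P2"),
    location = c("deep_wm", "deep_wm", "periventricular", "deep_wm"),
    volume_mm3 = c(100, 100, 100, 50),
    type = c("B", "B", "A", "A"))
  pb <- patient_burden(les, patients = tibble::tibble(patient_id = c("P1", "P2", "P3")))
  p1 <- pb[pb$patient_id == "P1" & pb$location == "whole_brain", ]
  expect_equal(p1$pct_b_volume, 200 / 300 * 100, tolerance = 1e-10)
  expect_equal(p1$n_b, 2)
  p3 <- pb[pb$patient_id == "P3", ]
  expect_equal(p3$n_a + p3$n_b, 0)
  expect_true(is.na(p3$pct_b_count)) # undefined, not zero
})

test_that("cohort-level assigned B share sits near the generating mixture", {
  co <- gen_cohort(cohort_config(seed = 17))
  typed <- assign_types(co$lesions, kmeans2(co$lesions,
                                            features = c("fa", "rd", "ufa", "f_in"),
                                            seed = 1))
  pct_b <- 100 * mean(typed$type == "B")
  expect_gt(pct_b, 52 - 6)
  expect_lt(pct_b, 52 + 6)
  # and assigned types agree closely with the latent truth
  agree <- mean(typed$type == co$truth$true_type[match(typed$lesion_id,
                                                       co$truth$lesion_id)])
  expect_gt(max(agree, 1 - agree), 0.9)
})

test_that("typing models serialize to text and back without changing predictions", {
  les <- simulate_lesion_features(200, seed = 2)
  m <- kmeans2(les, features = c("fa", "rd", "ufa", "f_in"), seed = 1)
  p <- withr::local_tempfile(fileext = ".yaml")
  write_cluster_model(m, p)
  m2 <- read_cluster_model(p)
  expect_equal(predict(m2, les), predict(m, les))
})
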