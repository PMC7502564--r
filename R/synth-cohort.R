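#' Published summary moments used as simulation defaults
#'
#' `default_lesion_moments()` returns the per-location mean (SD) of each
#' diffusion metric across MS lesions, and the NAWM reference column, from the
#' published cohort this package's defaults emulate (59 patients, 1236
#' lesions; diffusivities in 1e-3 mm^2/s). `default_type_deltas()` returns the
#' reported B-minus-A differences for the four type-separating metrics and the
#' per-location percentage of B-type lesions. These tables parameterize
#' [cohort_config()]; they are not estimated at run time.
#'
#' @return Tibbles in long format (`location`, `metric`, `mean`, `sd`;
#'   or `location`, `metric`, `delta` / `pct_b`).
#' @export
default_lesion_moments <- function() {
  loc <- c("whole_brain", "periventricular", "juxtacortical", "brainstem",
           "cerebellum", "deep_wm", "nawm")
  m <- list(
    fa          = c(0.32, 0.31, 0.27, 0.36, 0.36, 0.36, 0.36),
    md          = c(0.57, 0.60, 0.62, 0.43, 0.48, 0.54, 0.46),
    rd          = c(0.47, 0.49, 0.53, 0.34, 0.38, 0.43, 0.37),
    ad          = c(0.77, 0.80, 0.79, 0.61, 0.67, 0.76, 0.64),
    ufa         = c(0.83, 0.78, 0.82, 0.93, 0.91, 0.87, 0.90),
    umd         = c(1.30, 1.40, 1.30, 1.09, 1.13, 1.23, 1.04),
    urd         = c(0.44, 0.60, 0.47, 0.18, 0.23, 0.35, 0.23),
    uad         = c(2.99, 3.02, 2.97, 2.92, 2.92, 3.01, 2.66),
    f_in        = c(0.34, 0.29, 0.28, 0.56, 0.47, 0.38, 0.50),
    lambda_diff = c(2.09, 2.19, 1.93, 2.25, 2.10, 2.11, 2.02),
    v_ad        = c(1.35, 1.54, 1.40, 0.92, 1.10, 1.27, 0.91),
    v_md        = c(1.60, 1.75, 1.60, 1.36, 1.40, 1.55, 1.28))
  s <- list(
    fa          = c(0.11, 0.12, 0.10, 0.08, 0.12, 0.11, 0.04),
    md          = c(0.09, 0.08, 0.08, 0.07, 0.08, 0.08, 0.03),
    rd          = c(0.10, 0.09, 0.09, 0.07, 0.09, 0.09, 0.04),
    ad          = c(0.11, 0.10, 0.11, 0.10, 0.09, 0.11, 0.03),
    ufa         = c(0.09, 0.12, 0.06, 0.04, 0.03, 0.07, 0.03),
    umd         = c(0.19, 0.23, 0.13, 0.08, 0.08, 0.14, 0.06),
    urd         = c(0.26, 0.33, 0.16, 0.09, 0.09, 0.18, 0.07),
    uad         = c(0.11, 0.07, 0.14, 0.12, 0.12, 0.09, 0.07),
    f_in        = c(0.13, 0.10, 0.09, 0.02, 0.15, 0.13, 0.06),
    lambda_diff = c(0.35, 0.32, 0.31, 0.40, 0.48, 0.34, 0.16),
    v_ad        = c(0.32, 0.33, 0.23, 0.30, 0.21, 0.28, 0.13),
    v_md        = c(0.28, 0.30, 0.23, 0.18, 0.20, 0.24, 0.10))
  purrr::map_dfr(names(m), function(met) {
    tibble(location = loc, metric = met, mean = m[[met]], sd = s[[met]])
  })
}

#' @rdname default_lesion_moments
#' @export
default_type_deltas <- function() {
  loc <- c("whole_brain", "periventricular", "juxtacortical", "brainstem",
           "cerebellum", "deep_wm")
  d <- list(fa = c(-0.15, -0.16, -0.13, -0.10, -0.18, -0.14),
            rd = c(0.17, 0.15, 0.15, 0.12, 0.15, 0.15),
            ufa = c(-0.12, -0.14, -0.14, -0.05, -0.05, -0.09),
            f_in = c(-0.20, -0.16, -0.14, -0.27, -0.22, -0.19))
  deltas <- purrr::map_dfr(names(d), function(met) {
    tibble(location = loc, metric = met, delta = d[[met]])
  })
  attr(deltas, "pct_b") <-
    tibble(location = loc, pct_b = c(0.52, 0.54, 0.60, 0.50, 0.53, 0.46))
  deltas
}

#' Per-location lesion counts of the reference cohort
#'
#' @return Named numeric vector of total lesion counts by location (reference
#'   cohort of 59 patients; total 1236).
#' @export
default_lesion_counts <- function() {
  c(periventricular = 357, juxtacortical = 343, brainstem = 44,
    cerebellum = 60, deep_wm = 432)
}

# within-type SD by variance decomposition:
# pooled_var = within_var + p (1 - p) delta^2  (two-point mixture)
within_type_sd <- function(pooled_sd, delta, p_b) {
  w <- pooled_sd^2 - p_b * (1 - p_b) * delta^2
  if (any(w < 0)) {
    abort("Variance decomposition failed: pooled SD too small for the requested type separation.")
  }
  sqrt(w)
}

#' Per-type feature means and SDs implied by mixture moments
#'
#' Given the pooled (mixture) mean and SD of a metric, the B-minus-A mean
#' difference and the B fraction `p_b`, returns the per-type Gaussian
#' parameters that reproduce those pooled moments:
#' `mean_A = mean - p_b * delta`, `mean_B = mean + (1 - p_b) * delta`, and
#' within-type variance `pooled_var - p_b (1 - p_b) delta^2` (error if
#' negative).
#'
#' @param moments Tibble with `metric`, `mean`, `sd` (one location).
#' @param deltas Tibble with `metric`, `delta`; metrics absent from `deltas`
#'   get delta 0 (no type separation).
#' @param p_b Probability of the B type.
#' @return Tibble `metric`, `delta`, `mean_a`, `mean_b`, `sd_within`.
#' @export
type_mixture_params <- function(moments, deltas, p_b = 0.52) {
  assert_scalar_num(p_b, "p_b", 0, 1)
  dd <- setNames(deltas$delta, deltas$metric)
  purrr::map_dfr(seq_len(nrow(moments)), function(i) {
    met <- moments$metric[i]
    delta <- unname(dd[met])
    if (is.na(delta) || is.null(delta)) delta <- 0
    tibble(metric = met, delta = delta,
           mean_a = moments$mean[i] - p_b * delta,
           mean_b = moments$mean[i] + (1 - p_b) * delta,
           sd_within = within_type_sd(moments$sd[i], delta, p_b))
  })
}

#' Configuration of the synthetic lesion cohort generator
#'
#' Defaults reproduce the reference cohort: 59 patients; per-location Poisson
#' lesion rates equal to the published per-location counts divided by 59;
#' per-location latent B-type probabilities from the published percentages;
#' per-type feature means and within-type SDs derived from the whole-brain
#' pooled moments and the B-minus-A deltas by variance decomposition (see
#' [type_mixture_params()]). Features are drawn as independent Gaussians per
#' type unless `feature_correlation` (a correlation matrix over the metrics)
#' is supplied; `uad` is additionally truncated at the fit ceiling
#' `lambda_free` (3.0), emulating the ceiling a bounded estimator produces.
#'
#' @param n_patients Number of patients.
#' @param lesion_rate Named vector: mean lesions per patient per location.
#' @param p_b Either a single probability or a named per-location vector of
#'   latent B-type probabilities.
#' @param metrics Metrics to simulate. Default all 12.
#' @param moments Pooled moments tibble (whole-brain rows used).
#' @param deltas Type-delta tibble.
#' @param feature_correlation Optional correlation matrix (metrics x metrics)
#'   applied within type.
#' @param patient_sd Optional SD of a patient-level random intercept added to
#'   every metric (standardized scale: multiples of the within-type SD).
#'   Default 0 (the reference publication gives no within-patient clustering
#'   magnitude).
#' @param volume_sdlog Log-scale SD of per-lesion volumes.
#' @param b_volume_ratio Mean volume ratio of B- to A-type lesions (B lesions
#'   are reported to carry a disproportionate volume share: 64% of volume at
#'   52% of count implies about 1.64).
#' @param age_mean,age_sd,p_female,p_sp Patient demographics (means from the
#'   reference cohort: age 44.7 (9.3), 63% female, 6/59 secondary
#'   progressive).
#' @param clinical_coeffs See [default_clinical_coeffs()].
#' @param seed Master seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 59,
                          lesion_rate = default_lesion_counts() / 59,
                          p_b = NULL,
                          metrics = diffusion_metric_names(),
                          moments = default_lesion_moments(),
                          deltas = default_type_deltas(),
                          feature_correlation = NULL,
                          patient_sd = 0,
                          volume_sdlog = 1,
                          b_volume_ratio = 1.64,
                          age_mean = 44.7, age_sd = 9.3,
                          p_female = 0.63, p_sp = 6 / 59,
                          clinical_coeffs = default_clinical_coeffs(),
                          seed = 1L) {
  if (n_patients < 1) abort("`n_patients` must be positive.")
  if (any(lesion_rate < 0)) abort("Lesion rates must be >= 0.")
  locs <- names(lesion_rate)
  if (is.null(p_b)) {
    pb_tab <- attr(default_type_deltas(), "pct_b")
    p_b <- setNames(pb_tab$pct_b[match(locs, pb_tab$location)], locs)
    p_b[is.na(p_b)] <- 0.52
  } else if (length(p_b) == 1) {
    p_b <- setNames(rep(p_b, length(locs)), locs)
  }
  if (any(p_b < 0 | p_b > 1)) abort("B-type probabilities must lie in [0, 1].")
  unknown <- setdiff(metrics, unique(moments$metric))
  if (length(unknown) > 0) {
    abort(paste0("Unknown metric name(s) in moments: ",
                 paste(unknown, collapse = ", ")))
  }
  if (!is.null(feature_correlation)) {
    feature_correlation <- as.matrix(feature_correlation)
    stopifnot(nrow(feature_correlation) == length(metrics))
  }
  structure(list(n_patients = as.integer(n_patients),
                 lesion_rate = lesion_rate, p_b = p_b, metrics = metrics,
                 moments = moments, deltas = deltas,
                 feature_correlation = feature_correlation,
                 patient_sd = patient_sd, volume_sdlog = volume_sdlog,
                 b_volume_ratio = b_volume_ratio,
                 age_mean = age_mean, age_sd = age_sd,
                 p_female = p_female, p_sp = p_sp,
                 clinical_coeffs = clinical_coeffs,
                 lambda_free = 3.0, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default linear/logistic coefficients linking outcomes to B-type burden
#'
#' Each element is `c(intercept, burden, age, sex, sd)` where `burden` is the
#' per-patient count of B-type lesions, `age` is in years, `sex` is 1 for
#' female and `sd` is the Gaussian noise SD (ignored for the logistic
#' `therapy_high`). Signs follow the reported associations (disability up,
#' cognition down with B burden); magnitudes are set so that outcome means and
#' SDs sit near the published cohort descriptives and burden-outcome
#' correlations land in the reported 0.4-0.67 band.
#'
#' @return Named list of coefficient vectors; `family` attribute marks
#'   `therapy_high` as logistic.
#' @export
default_clinical_coeffs <- function() {
  co <- list(
    msss             = c(intercept = 0.50, burden = 0.20, age = 0.005, sex = 0.10, sd = 1.20),
    edss             = c(intercept = 0.60, burden = 0.12, age = 0.005, sex = 0.00, sd = 1.20),
    cerebellar_fs    = c(intercept = -0.30, burden = 0.08, age = 0.000, sex = 0.00, sd = 0.80),
    global_cognition = c(intercept = 0.40, burden = -0.10, age = -0.002, sex = 0.00, sd = 0.80),
    attention        = c(intercept = 0.60, burden = -0.10, age = 0.000, sex = 0.00, sd = 1.00),
    fluency          = c(intercept = 0.30, burden = -0.10, age = 0.000, sex = 0.00, sd = 1.00),
    verbal_memory    = c(intercept = 0.00, burden = -0.10, age = 0.000, sex = 0.00, sd = 1.30),
    visual_memory    = c(intercept = 0.60, burden = -0.09, age = 0.000, sex = 0.00, sd = 0.90),
    therapy_high     = c(intercept = -2.85, burden = 0.15, age = 0.000, sex = 0.00, sd = 0))
  attr(co, "family") <- c(therapy_high = "logistic")
  co
}

# draw per-type features for n lesions (rows aligned with `type`)
draw_features <- function(n, type, params, corr = NULL, lambda_free = 3.0,
                          patient_effect = NULL) {
  p <- nrow(params)
  Z <- matrix(rnorm(n * p), n, p)
  if (!is.null(corr)) {
    Z <- Z %*% chol(corr)
  }
  if (!is.null(patient_effect)) Z <- Z + patient_effect
  X <- sapply(seq_len(p), function(j) {
    m <- ifelse(type == "B", params$mean_b[j], params$mean_a[j])
    m + Z[, j] * params$sd_within[j]
  })
  X <- matrix(X, n, p, dimnames = list(NULL, params$metric))
  # bounded metrics: fractions clipped to [0,1]; uad truncated at the ceiling
  for (met in intersect(c("fa", "ufa", "f_in"), params$metric)) {
    X[, met] <- pmin(pmax(X[, met], 0), 1)
  }
  if ("uad" %in% params$metric) X[, "uad"] <- pmin(X[, "uad"], lambda_free)
  for (met in setdiff(params$metric, c("fa", "ufa", "f_in"))) {
    X[, met] <- pmax(X[, met], 1e-4)
  }
  X
}

#' Generate a synthetic lesion cohort with known latent types
#'
#' Draws per-patient lesion counts per location (Poisson), a latent A/B type
#' per lesion, per-type Gaussian features, lognormal volumes (B lesions larger
#' on average), and clinical outcomes via [gen_clinical()] using the true
#' per-patient B-lesion count as burden. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return List with tibbles `patients` (demographics + outcomes), `lesions`
#'   (patient_id, lesion_id, location, volume_mm3, one column per metric) and
#'   `truth` (lesion_id, true_type, true_volume_mm3) — one truth row per
#'   generated lesion, never mutated downstream.
#' @export
gen_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(derive_seed(config$seed, 101), {
    np <- config$n_patients
    patients <- tibble(
      patient_id = sprintf("P%03d", seq_len(np)),
      age = rnorm(np, config$age_mean, config$age_sd),
      sex = ifelse(rbinom(np, 1, config$p_female) == 1, "female", "male"),
      ms_type = ifelse(rbinom(np, 1, config$p_sp) == 1, "SP", "RR"))

    locs <- names(config$lesion_rate)
    wb <- config$moments[config$moments$location == "whole_brain", ]
    wb_delta <- config$deltas[config$deltas$location == "whole_brain", ]

    lesion_rows <- list()
    truth_rows <- list()
    lesion_counter <- 0
    # per-patient random intercept (standardized units)
    pat_fx <- if (config$patient_sd > 0) {
      matrix(rnorm(np * length(config$metrics), 0, config$patient_sd),
             np, length(config$metrics))
    } else NULL

    for (loc in locs) {
      n_by_pat <- rpois(np, config$lesion_rate[[loc]])
      n_loc <- sum(n_by_pat)
      if (n_loc == 0) next
      pat_idx <- rep(seq_len(np), n_by_pat)
      type <- ifelse(rbinom(n_loc, 1, config$p_b[[loc]]) == 1, "B", "A")
      params <- type_mixture_params(
        wb[match(config$metrics, wb$metric), ],
        wb_delta, p_b = config$p_b[[loc]])
      pe <- if (is.null(pat_fx)) NULL else pat_fx[pat_idx, , drop = FALSE]
      X <- draw_features(n_loc, type, params, config$feature_correlation,
                         config$lambda_free, pe)
      # volumes: lognormal, mean tied to the per-location reference mean
      loc_mom <- config$moments[config$moments$location == loc, ]
      count_ref <- default_lesion_counts()
      vol_mean_cm3 <- c(periventricular = 9.75, juxtacortical = 0.82,
                        brainstem = 0.20, cerebellum = 0.47, deep_wm = 1.54)
      per_lesion_mm3 <- unname(vol_mean_cm3[loc] * 1000 /
                                 (count_ref[loc] / 59))
      if (is.na(per_lesion_mm3)) per_lesion_mm3 <- 300
      base_meanlog <- log(per_lesion_mm3) - config$volume_sdlog^2 / 2
      tshift <- log(sqrt(config$b_volume_ratio))
      meanlog <- ifelse(type == "B", base_meanlog + tshift,
                        base_meanlog - tshift)
      vol <- rlnorm(n_loc, meanlog, config$volume_sdlog)
      ids <- sprintf("L%05d", lesion_counter + seq_len(n_loc))
      lesion_counter <- lesion_counter + n_loc
      lesion_rows[[loc]] <- dplyr::bind_cols(
        tibble(patient_id = patients$patient_id[pat_idx], lesion_id = ids,
               location = loc, volume_mm3 = vol),
        as_tibble(X))
      truth_rows[[loc]] <- tibble(lesion_id = ids, patient_id =
                                    patients$patient_id[pat_idx],
                                  location = loc, true_type = type,
                                  true_volume_mm3 = vol)
    }
    lesions <- dplyr::bind_rows(lesion_rows)
    truth <- dplyr::bind_rows(truth_rows)

    burden <- truth |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(b_count = sum(.data$true_type == "B"), .groups = "drop")
    burden_vec <- setNames(rep(0, np), patients$patient_id)
    burden_vec[burden$patient_id] <- burden$b_count

    patients <- gen_clinical(patients, burden_vec, config$clinical_coeffs,
                             seed = derive_seed(config$seed, 202))
    list(patients = patients, lesions = lesions, truth = truth)
  })
}

#' Attach simulated clinical outcomes to a patient table
#'
#' Continuous outcomes follow
#' `y = intercept + b_burden * burden + b_age * age + b_sex * sex + N(0, sd)`;
#' outcomes marked logistic in the coefficient list's `family` attribute are
#' drawn as Bernoulli with `logit(p)` equal to the same linear predictor.
#'
#' @param patients Tibble with `patient_id`, `age`, `sex`.
#' @param burden Named numeric vector (names = patient ids) of per-patient
#'   B-type burden (count or volume).
#' @param coeffs Named list of `c(intercept, burden, age, sex, sd)` vectors.
#' @param seed Seed.
#' @return `patients` with one new column per outcome.
#' @export
gen_clinical <- function(patients, burden, coeffs = default_clinical_coeffs(),
                         seed = 1L) {
  if (is.null(names(burden))) {
    if (length(burden) != nrow(patients)) abort("Burden/patient mismatch.")
    names(burden) <- patients$patient_id
  }
  if (!all(patients$patient_id %in% names(burden))) {
    abort("Mismatched patient ids between `patients` and `burden`.")
  }
  b <- unname(burden[patients$patient_id])
  sexn <- as.numeric(patients$sex == "female")
  fam <- attr(coeffs, "family") %||% character(0)
  with_seed(seed, {
    for (nm in names(coeffs)) {
      co <- coeffs[[nm]]
      if (co[["sd"]] < 0) abort("Noise SD must be >= 0.")
      eta <- co[["intercept"]] + co[["burden"]] * b +
        co[["age"]] * patients$age + co[["sex"]] * sexn
      if (identical(unname(fam[nm]), "logistic")) {
        patients[[nm]] <- rbinom(nrow(patients), 1, plogis(eta))
      } else {
        patients[[nm]] <- eta + rnorm(nrow(patients), 0, co[["sd"]])
      }
    }
    patients
  })
}

#' Simulate a two-type lesion feature table directly
#'
#' Convenience generator for typing experiments: draws `n` lesions with latent
#' B probability `p_b` and per-type Gaussian features for the selected metrics
#' whose pooled moments match the whole-brain reference row and whose
#' B-minus-A separations match the reference deltas.
#'
#' @param n Number of lesions.
#' @param p_b Latent B-type probability (default 0.52).
#' @param metrics Metrics to draw (default the four type-separating ones).
#' @param seed Seed.
#' @param noise_metrics Optional extra metric names appended as pure
#'   standard-normal noise columns (no type separation).
#' @return Tibble with `lesion_id`, `true_type` and one column per metric.
#' @export
simulate_lesion_features <- function(n, p_b = 0.52,
                                     metrics = c("fa", "rd", "ufa", "f_in"),
                                     seed = 1L, noise_metrics = NULL) {
  moments <- default_lesion_moments()
  wb <- moments[moments$location == "whole_brain", ]
  wb <- wb[match(metrics, wb$metric), ]
  deltas <- default_type_deltas()
  wbd <- deltas[deltas$location == "whole_brain", ]
  params <- type_mixture_params(wb, wbd, p_b = p_b)
  with_seed(seed, {
    type <- ifelse(rbinom(n, 1, p_b) == 1, "B", "A")
    X <- draw_features(n, type, params)
    out <- dplyr::bind_cols(
      tibble(lesion_id = sprintf("L%05d", seq_len(n)), true_type = type),
      as_tibble(X))
    for (nm in noise_metrics) out[[nm]] <- rnorm(n)
    out
  })
}
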