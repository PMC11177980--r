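# One moderately large default cohort shared by the calibration checks.
big_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(generator_config(n = 20000L, seed = 42L))
    }
    cache
  }
})

test_that("generation is deterministic given the seed", {
  cfg <- generator_config(n = 300L, seed = 9L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$labels, b$labels)
  c <- generate_cohort(generator_config(n = 300L, seed = 10L))
  expect_false(identical(a$labels, c$labels))
})

test_that("outcome prevalences are calibrated to the configured targets", {
  co <- big_cohort()
  n <- cohort_size(co)
  sd3 <- function(p) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(co$labels$acs) - 0.20), sd3(0.20))
  # subtype proportions among ACS cases follow the configured split
  sub <- co$labels$subtype[co$labels$acs == 1]
  split <- generator_config()$subtype_split
  for (i in seq_along(split)) {
    nm <- toupper(names(split)[i])
    expect_lt(abs(mean(sub == nm) - split[[i]]),
              3 * sqrt(split[[i]] * (1 - split[[i]]) / length(sub)))
  }
})

test_that("binary covariate marginals match the configured rates", {
  co <- big_cohort()
  n <- cohort_size(co)
  marg <- default_marginals("internal")
  base <- setdiff(names(marg), c("ecg_st_elevation", "ecg_st_depression",
                                 "ecg_t_wave_inversion"))
  for (nm in base) {
    emp <- mean(co$covariates[[nm]], na.rm = TRUE)
    expect_lt(abs(emp - marg[[nm]]), 4 * sqrt(marg[[nm]] * (1 - marg[[nm]]) / n),
              label = sprintf("marginal of %s (%.3f vs %.2f)", nm, emp, marg[[nm]]))
  }
  # ECG rates are any-lead positivity
  for (nm in c("ecg_st_elevation", "ecg_st_depression", "ecg_t_wave_inversion")) {
    leads <- co$covariates[, sprintf("%s_L%02d", nm, 1:11)]
    emp <- mean(rowSums(leads, na.rm = TRUE) > 0)
    expect_lt(abs(emp - marg[[nm]]), 4 * sqrt(marg[[nm]] * (1 - marg[[nm]]) / n))
  }
  # age: truncated normal around the configured centre
  expect_lt(abs(mean(co$covariates$age, na.rm = TRUE) - 61), 1.5)
  expect_gte(min(co$covariates$age, na.rm = TRUE), 21)
})

test_that("patient-level missingness stays near its configured rate", {
  co <- big_cohort()
  n <- cohort_size(co)
  rate <- generator_config()$missingness_rate
  frac <- mean(rowSums(missing_mask(co)) > 0)
  expect_lte(frac, rate + 3 * sqrt(rate * (1 - rate) / n))
  expect_gt(frac, 0)
})

test_that("zero effects give an outcome independent of the covariates", {
  cfg <- generator_config(n = 4000L, seed = 5L,
                          effects = default_effects() * 0,
                          missingness_rate = 0)
  co <- generate_cohort(cfg)
  expect_lt(abs(mean(co$labels$acs) - 0.20), 3 * sqrt(0.2 * 0.8 / 4000))
  # any covariate-based score is uninformative; use the latent design itself
  s <- rowSums(select_covariates(co, "full"))
  a <- auroc(co$labels$acs, s)
  expect_lt(abs(a - 0.5), 0.04)
})

test_that("a logistic refit on generated data recovers the planted effects", {
  co <- big_cohort()
  keep <- rowSums(missing_mask(co)) == 0
  cov <- co$covariates[keep, ]
  eff <- default_effects()
  # design on the generator's own scale: ECG enters as positive-lead counts
  X <- cbind(age = cov$age)
  for (nm in setdiff(names(eff), c("age", "ecg_st_elevation",
                                   "ecg_st_depression", "ecg_t_wave_inversion"))) {
    X <- cbind(X, stats::setNames(data.frame(cov[[nm]]), nm))
  }
  for (nm in c("ecg_st_elevation", "ecg_st_depression", "ecg_t_wave_inversion")) {
    X <- cbind(X, stats::setNames(
      data.frame(rowSums(cov[, sprintf("%s_L%02d", nm, 1:11)])), nm))
  }
  fit <- stats::glm(co$labels$acs[keep] ~ ., data = as.data.frame(X),
                    family = stats::binomial())
  est <- summary(fit)$coefficients
  z <- (est[names(eff), "Estimate"] - eff) / est[names(eff), "Std. Error"]
  # planted coefficients are jointly recovered (no systematic bias)
  expect_lt(mean(abs(z) > 2), 0.15)
  expect_true(all(abs(z) < 4))
})

test_that("the temporal split pair reflects the documented shift", {
  pair <- temporal_split_pair()
  expect_equal(cohort_size(pair$internal), 1756)
  expect_equal(cohort_size(pair$external), 1127)
  expect_equal(pair$internal$tag, "internal")
  expect_equal(pair$external$tag, "external")
  # hypertension shifts upwards in the external preset (0.53 -> 0.71)
  h_int <- mean(pair$internal$covariates$hypertension, na.rm = TRUE)
  h_ext <- mean(pair$external$covariates$hypertension, na.rm = TRUE)
  expect_lt(abs(h_int - 0.53), 0.05)
  expect_lt(abs(h_ext - 0.71), 0.05)
  # same mechanism is required
  cfg_bad <- generator_config(n = 100L, seed = 3L, preset = "external",
                              effects = default_effects() * 0.5)
  expect_error(temporal_split_pair(generator_config(n = 100L, seed = 2L),
                                   cfg_bad),
               "share effect coefficients")
})

test_that("troponin bands follow their conditional distributions", {
  cfg <- generator_config(n = 20000L, seed = 77L)
  co <- generate_troponin(big_cohort(), cfg)
  expect_true(all(co$troponin_band %in% 0:2))
  for (cls in 0:1) {
    p_cfg <- if (cls == 1) cfg$troponin_cond$given_acs else cfg$troponin_cond$given_no_acs
    band <- co$troponin_band[co$labels$acs == cls]
    for (b in 0:2) {
      tol <- 3 * sqrt(p_cfg[b + 1] * (1 - p_cfg[b + 1]) / length(band))
      expect_lt(abs(mean(band == b) - p_cfg[b + 1]), tol)
    }
  }
  # perfect-marker limit separates the classes outright
  cfg2 <- generator_config(n = 200L, seed = 8L,
                           troponin_cond = list(given_acs = c(0, 0, 1),
                                                given_no_acs = c(1, 0, 0)))
  co2 <- generate_troponin(generate_cohort(cfg2), cfg2)
  expect_equal(auroc(co2$labels$acs, co2$troponin_band), 1.0)
})
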