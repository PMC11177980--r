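#' Default binary-covariate marginals (internal / external presets)
#'
#' Bernoulli rates for the binary covariates and any-lead ECG positivity,
#' matching the published cohort summary tables for the development
#' (internal, n = 1756) and temporally held-out (external, n = 1127)
#' populations.
#'
#' @param preset "internal" or "external".
#' @return Named numeric vector of rates over the 21 binary covariates
#'   (ECG entries are any-lead positivity rates).
#' @export
default_marginals <- function(preset = c("internal", "external")) {
  preset <- match.arg(preset)
  internal <- c(
    gender_male = 0.53,
    hypercholesterolemia = 0.39, hypertension = 0.53, current_smoker = 0.20,
    diabetes = 0.28, prior_mi = 0.17, angina = 0.02, prior_cabg = 0.09,
    prior_pci = 0.07, cad = 0.19, family_history_cv = 0.11,
    sym_other = 0.99, sym_chestpain = 0.56, sym_syncope = 0.05,
    sym_shortness_breath = 0.23, sym_diaphoresis = 0.06,
    sym_nausea_vomiting = 0.09, sym_palpitations = 0.12,
    sym_other_symptoms = 0.49,
    ecg_st_elevation = 0.18, ecg_st_depression = 0.28,
    ecg_t_wave_inversion = 0.14
  )
  external <- c(
    gender_male = 0.55,
    hypercholesterolemia = 0.43, hypertension = 0.71, current_smoker = 0.25,
    diabetes = 0.31, prior_mi = 0.21, angina = 0.07, prior_cabg = 0.15,
    prior_pci = 0.005, cad = 0.24, family_history_cv = 0.07,
    sym_other = 0.99, sym_chestpain = 0.57, sym_syncope = 0.06,
    sym_shortness_breath = 0.25, sym_diaphoresis = 0.07,
    sym_nausea_vomiting = 0.10, sym_palpitations = 0.14,
    sym_other_symptoms = 0.54,
    ecg_st_elevation = 0.15, ecg_st_depression = 0.19,
    ecg_t_wave_inversion = 0.15
  )
  if (preset == "internal") internal else external
}

#' Default per-covariate log-odds effects on the latent ACS risk score
#'
#' Log-odds contribution per unit of each covariate; for the ECG
#' interpretations the contribution is per positive lead. ST elevation
#' carries the strongest weight, ST depression, chest pain and the history
#' covariates moderate weight, and the non-specific "Other" symptom none,
#' so that a boosted-tree classifier trained on default cohorts reaches an
#' AUROC in the high 0.8s. This is a modelling choice of the generator, not
#' an estimate from real data.
#'
#' @return Named numeric vector (23 base covariates; age per year).
#' @export
default_effects <- function() {
  c(
    age = 0.055, gender_male = 0.55,
    hypercholesterolemia = 0.45, hypertension = 0.65, current_smoker = 0.75,
    diabetes = 0.65, prior_mi = 1.00, angina = 0.65, prior_cabg = 0.55,
    prior_pci = 0.55, cad = 0.90, family_history_cv = 0.45,
    sym_other = 0.00, sym_chestpain = 1.55, sym_syncope = 0.20,
    sym_shortness_breath = 0.45, sym_diaphoresis = 1.10,
    sym_nausea_vomiting = 0.65, sym_palpitations = -0.55,
    sym_other_symptoms = 0.00,
    ecg_st_elevation = 1.75, ecg_st_depression = 0.65,
    ecg_t_wave_inversion = 0.25
  )
}

#' Synthetic cohort generator configuration
#'
#' Covariates are drawn from the preset marginals; a latent linear risk
#' score (sum of per-covariate log-odds effects) determines P(ACS) through
#' a logistic link whose intercept is calibrated by bisection so the
#' marginal ACS prevalence matches `acs_prevalence`. ACS subtypes are drawn
#' from `subtype_split`; missingness is injected completely at random at
#' patient level.
#'
#' @param n Number of patients.
#' @param seed RNG seed; all draws are deterministic given it.
#' @param preset Covariate-marginal preset ("internal"/"external").
#' @param acs_prevalence Target marginal P(ACS); default 0.20.
#' @param subtype_split Probabilities of (STEMI, NSTEMI, UA) given ACS;
#'   must sum to 1. Default (0.65, 0.20, 0.15), i.e. marginal rates of
#'   13%, 4% and 3% at 20% ACS prevalence.
#' @param marginals Named Bernoulli rates; defaults to the preset's.
#' @param effects Named log-odds effects; defaults to [default_effects()].
#' @param age_mean,age_sd,age_min Age distribution: normal truncated below
#'   at `age_min` (21 years, the enrolment threshold). Default mean 61
#'   (internal) / 60 (external), SD 15.5 years.
#' @param ecg_lead_geom_p Success parameter of the truncated geometric
#'   distribution of the number of positive leads given any-lead
#'   positivity (support 1..11).
#' @param missingness_rate Probability a patient has at least one missing
#'   covariate (default 0.015; the study reports under 2%).
#' @param troponin_cond List with `given_acs` and `given_no_acs`: length-3
#'   probability vectors over the ordinal troponin bands {0,1,2}.
#' @param tag Tag for generated cohorts.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n = 1756L, seed = 1L,
                             preset = c("internal", "external"),
                             acs_prevalence = 0.20,
                             subtype_split = c(stemi = 0.65, nstemi = 0.20,
                                               ua = 0.15),
                             marginals = NULL,
                             effects = default_effects(),
                             age_mean = NULL, age_sd = 15.5, age_min = 21,
                             ecg_lead_geom_p = 0.45,
                             missingness_rate = 0.015,
                             troponin_cond = list(
                               given_acs = c(0.05, 0.25, 0.70),
                               given_no_acs = c(0.85, 0.12, 0.03)),
                             tag = "synthetic") {
  preset <- match.arg(preset)
  if (is.null(marginals)) marginals <- default_marginals(preset)
  if (is.null(age_mean)) age_mean <- if (preset == "internal") 61 else 60
  stopifnot(acs_prevalence > 0, acs_prevalence < 1,
            all(subtype_split >= 0), all(marginals >= 0 & marginals <= 1),
            missingness_rate >= 0, missingness_rate <= 1)
  if (abs(sum(subtype_split) - 1) > 1e-9) {
    stop("subtype_split must sum to 1")
  }
  if (abs(sum(troponin_cond$given_acs) - 1) > 1e-9 ||
      abs(sum(troponin_cond$given_no_acs) - 1) > 1e-9) {
    stop("troponin band conditionals must sum to 1")
  }
  structure(list(
    n = as.integer(n), seed = as.integer(seed), preset = preset,
    acs_prevalence = acs_prevalence, subtype_split = subtype_split,
    marginals = marginals, effects = effects,
    age_mean = age_mean, age_sd = age_sd, age_min = age_min,
    ecg_lead_geom_p = ecg_lead_geom_p,
    missingness_rate = missingness_rate,
    troponin_cond = troponin_cond, tag = tag
  ), class = "generator_config")
}

# Draw the expanded 53-column covariate frame (no missingness yet).
draw_covariates <- function(n, config) {
  cols <- schema_columns()
  out <- vector("list", length(cols))
  names(out) <- cols
  age <- config$age_mean + config$age_sd * stats::rnorm(n)
  while (any(bad <- age < config$age_min)) {
    age[bad] <- config$age_mean + config$age_sd * stats::rnorm(sum(bad))
  }
  out[["age"]] <- round(age, 1)
  binary_names <- names(config$marginals)
  base_binaries <- setdiff(binary_names,
                           c("ecg_st_elevation", "ecg_st_depression",
                             "ecg_t_wave_inversion"))
  for (nm in base_binaries) {
    out[[nm]] <- stats::rbinom(n, 1L, config$marginals[[nm]])
  }
  # ECG vectors: any-lead positivity at the marginal rate; positive-lead
  # count truncated-geometric on 1..11; positions uniform without replacement.
  for (nm in c("ecg_st_elevation", "ecg_st_depression",
               "ecg_t_wave_inversion")) {
    mat <- matrix(0L, n, ECG_LEADS)
    pos <- stats::rbinom(n, 1L, config$marginals[[nm]]) == 1L
    k_pmf <- stats::dgeom(0:(ECG_LEADS - 1), config$ecg_lead_geom_p)
    k_pmf <- k_pmf / sum(k_pmf)
    if (any(pos)) {
      n_pos <- sum(pos)
      ks <- sample.int(ECG_LEADS, n_pos, replace = TRUE, prob = k_pmf)
      # vectorised uniform placement: mark the k smallest of 11 uniforms
      u <- matrix(stats::runif(n_pos * ECG_LEADS), n_pos, ECG_LEADS)
      rk <- matrix(0L, n_pos, ECG_LEADS)
      for (l in seq_len(ECG_LEADS)) rk[, l] <- rowSums(u <= u[, l])
      mat[pos, ] <- (rk <= ks) * 1L
    }
    for (l in seq_len(ECG_LEADS)) {
      out[[sprintf("%s_L%02d", nm, l)]] <- mat[, l]
    }
  }
  as.data.frame(out[cols], check.names = FALSE)
}

# Latent linear risk score (without intercept) for an expanded frame.
latent_score <- function(covariates, effects) {
  s <- numeric(nrow(covariates))
  for (nm in names(effects)) {
    if (nm %in% names(covariates)) {
      s <- s + effects[[nm]] * covariates[[nm]]
    } else {
      lead_cols <- sprintf("%s_L%02d", nm, seq_len(ECG_LEADS))
      s <- s + effects[[nm]] * rowSums(covariates[, lead_cols])
    }
  }
  s
}

# Calibrate the logistic intercept by bisection on a pilot score sample so
# that mean(plogis(b0 + s)) hits the target prevalence.
calibrate_intercept <- function(scores, target, lo = -60, hi = 60,
                                tol = 1e-8, max_iter = 200) {
  f <- function(b0) mean(stats::plogis(b0 + scores)) - target
  if (f(lo) > 0 || f(hi) < 0) {
    stop("prevalence unreachable with the given effect coefficients")
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Generate a synthetic chest-pain cohort
#'
#' Deterministic given `config$seed`. Covariates are drawn from the
#' configured marginals; the intercept of the logistic outcome model is
#' calibrated on a pilot sample of 200,000 latent scores so the marginal
#' ACS prevalence matches `config$acs_prevalence`; subtypes are drawn from
#' `subtype_split` for ACS cases; patient-level missingness is injected at
#' `missingness_rate` and left unimputed (cells set to NA).
#'
#' @param config A [generator_config()].
#' @return An `acs_cohort` (unimputed).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  pilot <- draw_covariates(200000L, config)
  b0 <- calibrate_intercept(latent_score(pilot, config$effects),
                            config$acs_prevalence)
  n <- config$n
  cov <- draw_covariates(n, config)
  p_acs <- stats::plogis(b0 + latent_score(cov, config$effects))
  acs <- stats::rbinom(n, 1L, p_acs)
  subtype <- rep("NONE", n)
  n_pos <- sum(acs)
  if (n_pos > 0) {
    subtype[acs == 1L] <- sample(c("STEMI", "NSTEMI", "UA"), n_pos,
                                 replace = TRUE, prob = config$subtype_split)
  }
  # missingness: completely at random at patient level; a hit blanks one or
  # two base covariates (a hit on an ECG interpretation blanks its 11 cells)
  if (config$missingness_rate > 0) {
    hit <- which(stats::rbinom(n, 1L, config$missingness_rate) == 1L)
    base_names <- acs_schema()$name
    for (i in hit) {
      k <- sample(1:2, 1L)
      for (nm in sample(base_names, k)) {
        cells <- if (acs_schema()$kind[match(nm, base_names)] == "binary_vector_11") {
          sprintf("%s_L%02d", nm, seq_len(ECG_LEADS))
        } else nm
        cov[i, cells] <- NA
      }
    }
  }
  cohort <- new_cohort(cov,
                       data.frame(acs = acs, subtype = subtype,
                                  stringsAsFactors = FALSE),
                       tag = config$tag)
  attr(cohort, "latent_intercept") <- b0
  attr(cohort, "p_acs") <- p_acs
  cohort
}

#' Generate an internal/external cohort pair under distribution shift
#'
#' Emulates the study's temporal split: a development cohort (default
#' n = 1756) and a later external cohort (default n = 1127) sharing the
#' same disease mechanism (`effects`) but drawn from different covariate
#' marginals.
#'
#' @param config_internal,config_external [generator_config()] objects;
#'   they must share `effects` (same covariate-outcome mechanism).
#' @return List with elements `internal` and `external` (`acs_cohort`s).
#' @export
temporal_split_pair <- function(config_internal = generator_config(
                                  n = 1756L, seed = 1L, preset = "internal",
                                  tag = "internal"),
                                config_external = generator_config(
                                  n = 1127L, seed = 2L, preset = "external",
                                  tag = "external")) {
  if (!isTRUE(all.equal(config_internal$effects, config_external$effects))) {
    stop("internal and external configs must share effect coefficients")
  }
  config_internal$tag <- "internal"
  config_external$tag <- "external"
  list(internal = generate_cohort(config_internal),
       external = generate_cohort(config_external))
}

#' Attach an ordinal troponin band to a labelled cohort
#'
#' Draws `troponin_band` in {0,1,2} from conditionals on ACS status
#' (`config$troponin_cond`), enabling the HEART comparator. Troponin is
#' generally unavailable in the prehospital setting, so the band is not a
#' model covariate.
#'
#' @param cohort A labelled `acs_cohort`.
#' @param config A [generator_config()] (uses `troponin_cond` and `seed`).
#' @return The cohort with `troponin_band` filled.
#' @export
generate_troponin <- function(cohort, config = generator_config()) {
  set.seed(config$seed + 777L)
  acs <- cohort$labels$acs
  n <- length(acs)
  band <- integer(n)
  pos <- acs == 1L
  if (any(pos)) {
    band[pos] <- sample(0:2, sum(pos), replace = TRUE,
                        prob = config$troponin_cond$given_acs)
  }
  if (any(!pos)) {
    band[!pos] <- sample(0:2, sum(!pos), replace = TRUE,
                         prob = config$troponin_cond$given_no_acs)
  }
  cohort$troponin_band <- band
  cohort
}
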