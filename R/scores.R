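#' Default HEAR/HEART component mapping
#'
#' The component definitions are read from the editable YAML asset
#' `heart_component_map.yaml` under `extdata`, so institutions can align
#' the mapping with their own HEART conventions. The default mapping:
#' \describe{
#'   \item{age_pts}{0 / 1 / 2 for age < 45 / 45-64 / >= 65.}
#'   \item{risk_pts}{0 / 1 / 2 for 0 / 1-2 / >= 3 of the risk factors
#'     (hypercholesterolemia, hypertension, current smoker, diabetes,
#'     family history); any of prior MI / PCI / CABG / known CAD forces 2.}
#'   \item{ecg_pts}{2 if any ST-elevation or ST-depression lead is
#'     positive, 1 if only T-wave inversion, else 0.}
#'   \item{history_pts}{proxied from the symptom pattern: 2 for chest pain
#'     plus at least one autonomic symptom (diaphoresis, nausea/vomiting,
#'     syncope), 1 for chest pain alone, else 0.}
#' }
#'
#' @return Named list describing the component mapping.
#' @export
default_component_map <- function() {
  path <- system.file("extdata", "heart_component_map.yaml",
                      package = "acsselect")
  yaml::read_yaml(path)
}

ecg_any <- function(cov, nm) {
  rowSums(cov[, sprintf("%s_L%02d", nm, seq_len(ECG_LEADS)), drop = FALSE]) > 0
}

#' HEAR/HEART score components for every record
#'
#' @param cohort An imputed `acs_cohort`.
#' @param map Component mapping (see [default_component_map()]).
#' @return Data frame with columns history_pts, ecg_pts, age_pts, risk_pts,
#'   each in {0, 1, 2}.
#' @export
score_components <- function(cohort, map = default_component_map()) {
  cov <- cohort$covariates
  if (any(is.na(as.matrix(cov)))) stop("cohort must be imputed before scoring")

  age_pts <- findInterval(cov$age, map$age_breaks)           # 0/1/2
  n_risk <- rowSums(cov[, map$risk_factors, drop = FALSE])
  risk_pts <- findInterval(n_risk, map$risk_breaks)
  forcing <- rowSums(cov[, map$risk_forcing, drop = FALSE]) > 0
  risk_pts[forcing] <- 2L

  st_change <- ecg_any(cov, "ecg_st_elevation") | ecg_any(cov, "ecg_st_depression")
  twi <- ecg_any(cov, "ecg_t_wave_inversion")
  ecg_pts <- ifelse(st_change, 2L, ifelse(twi, 1L, 0L))

  autonomic <- rowSums(cov[, map$autonomic_symptoms, drop = FALSE]) > 0
  chest <- cov$sym_chestpain == 1
  history_pts <- ifelse(chest & autonomic, 2L, ifelse(chest, 1L, 0L))

  data.frame(history_pts = as.integer(history_pts),
             ecg_pts = as.integer(ecg_pts),
             age_pts = as.integer(age_pts),
             risk_pts = as.integer(risk_pts))
}

#' HEAR score (0-8)
#'
#' Rule-based chest-pain risk score summing the History, ECG, Age and
#' Risk-factor components (0-2 points each); the troponin-free variant of
#' HEART, usable in the prehospital setting.
#'
#' @inheritParams score_components
#' @return Integer vector in [0, 8].
#' @export
hear_score <- function(cohort, map = default_component_map()) {
  comp <- score_components(cohort, map)
  as.integer(rowSums(comp))
}

#' HEART score (0-10)
#'
#' HEAR components plus the ordinal troponin band (0-2 points), so
#' `heart_score - troponin_band = hear_score` record-for-record.
#'
#' @inheritParams score_components
#' @return Integer vector in [0, 10].
#' @export
heart_score <- function(cohort, map = default_component_map()) {
  if (is.null(cohort$troponin_band) || anyNA(cohort$troponin_band)) {
    stop("heart_score requires a complete troponin_band (see generate_troponin)")
  }
  hear_score(cohort, map) + as.integer(cohort$troponin_band)
}

#' Use integer scores as AUROC ranking statistics
#'
#' The raw score is the ranking statistic (higher = more ACS-like); ties
#' are handled by the midrank (ties count one half) convention of
#' [auroc()], so no threshold is needed.
#'
#' @param scores Integer (or numeric) score vector.
#' @return Numeric ranking scores.
#' @export
score_as_classifier <- function(scores) as.numeric(scores)
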