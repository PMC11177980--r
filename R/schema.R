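#' Prehospital ACS covariate schema
#'
#' The 23 covariates available in the prehospital setting: two baseline
#' covariates (age in years, male gender), ten medical-history binaries,
#' eight symptom binaries, and three per-lead ECG interpretations, each a
#' length-11 binary vector (one entry per ECG lead, labelled L01..L11).
#'
#' @return A data frame with columns `name`, `group`
#'   (baseline/history/symptom/ecg) and `kind`
#'   (numeric/binary/binary_vector_11), one row per covariate.
#' @export
#' @examples
#' s <- acs_schema()
#' table(s$group)
acs_schema <- function() {
  data.frame(
    name = c(
      "age", "gender_male",
      "hypercholesterolemia", "hypertension", "current_smoker", "diabetes",
      "prior_mi", "angina", "prior_cabg", "prior_pci", "cad",
      "family_history_cv",
      "sym_other", "sym_chestpain", "sym_syncope", "sym_shortness_breath",
      "sym_diaphoresis", "sym_nausea_vomiting", "sym_palpitations",
      "sym_other_symptoms",
      "ecg_st_elevation", "ecg_st_depression", "ecg_t_wave_inversion"
    ),
    group = c(
      "baseline", "baseline",
      rep("history", 10),
      rep("symptom", 8),
      rep("ecg", 3)
    ),
    kind = c(
      "numeric", "binary",
      rep("binary", 10),
      rep("binary", 8),
      rep("binary_vector_11", 3)
    ),
    stringsAsFactors = FALSE
  )
}

#' Number of ECG leads per interpretation vector
#' @keywords internal
ECG_LEADS <- 11L

#' Expanded feature-column names for a schema
#'
#' ECG interpretation vectors are stored one column per lead
#' (`<name>_L01` .. `<name>_L11`), so the 23 covariates expand to 53 columns.
#'
#' @param schema A schema data frame, as from [acs_schema()].
#' @param groups Optional subset of covariate groups to expand.
#' @return Character vector of column names in deterministic schema order.
#' @export
schema_columns <- function(schema = acs_schema(), groups = NULL) {
  if (!is.null(groups)) schema <- schema[schema$group %in% groups, , drop = FALSE]
  unlist(lapply(seq_len(nrow(schema)), function(i) {
    if (schema$kind[i] == "binary_vector_11") {
      sprintf("%s_L%02d", schema$name[i], seq_len(ECG_LEADS))
    } else {
      schema$name[i]
    }
  }), use.names = FALSE)
}

#' Map each expanded column back to its base covariate name
#' @keywords internal
column_base <- function(cols) sub("_L\\d\\d$", "", cols)

#' Read the schema shipped as a package data asset
#'
#' The machine-readable schema (`covariate_schema.csv` under `extdata`)
#' mirrors [acs_schema()] and is provided so external tools can consume it.
#'
#' @return Schema data frame.
#' @export
read_schema_asset <- function() {
  path <- system.file("extdata", "covariate_schema.csv", package = "acsselect")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
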