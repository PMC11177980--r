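#' Construct a cohort object
#'
#' A cohort bundles covariates (in expanded 53-column form, `NA` marking
#' missing cells), outcome labels, and an optional troponin band used only
#' by the HEART comparator.
#'
#' @param covariates Data frame with exactly the columns of
#'   [schema_columns()]; binary columns contain 0/1/NA.
#' @param labels Data frame with columns `acs` (0/1) and `subtype`
#'   (one of STEMI, NSTEMI, UA, NONE).
#' @param tag Cohort provenance: "internal", "external" or "synthetic".
#' @param troponin_band Optional integer vector in {0,1,2} (NA allowed),
#'   the ordinal initial-troponin band consumed by [heart_score()].
#' @return An object of class `acs_cohort`.
#' @export
new_cohort <- function(covariates, labels, tag = "synthetic",
                       troponin_band = NULL) {
  cols <- schema_columns()
  if (!identical(names(covariates), cols)) {
    stop("covariates must have exactly the 53 schema columns in schema order")
  }
  if (nrow(covariates) == 0L) stop("a cohort must contain at least one record")
  if (!identical(nrow(covariates), nrow(labels))) {
    stop("covariates and labels must have the same number of rows")
  }
  if (!all(c("acs", "subtype") %in% names(labels))) {
    stop("labels must contain columns 'acs' and 'subtype'")
  }
  tag <- match.arg(tag, c("internal", "external", "synthetic"))
  obj <- structure(
    list(covariates = covariates,
         labels = labels[, c("acs", "subtype")],
         troponin_band = troponin_band,
         tag = tag),
    class = "acs_cohort"
  )
  validate_cohort(obj)
  obj
}

#' Validate an `acs_cohort`
#'
#' Checks binary columns for 0/1/NA values, label consistency
#' (subtype is NONE iff acs is 0) and troponin-band range.
#'
#' @param cohort An `acs_cohort`.
#' @return The cohort, invisibly; errors describe the first offending row.
#' @export
validate_cohort <- function(cohort) {
  sch <- acs_schema()
  binary_cols <- setdiff(schema_columns(), "age")
  for (cn in binary_cols) {
    v <- cohort$covariates[[cn]]
    bad <- which(!is.na(v) & !(v %in% c(0, 1)))
    if (length(bad)) {
      stop(sprintf("non-{0,1} value in binary column '%s' at row %d", cn, bad[1]))
    }
  }
  age <- cohort$covariates$age
  if (any(!is.na(age) & age < 0 & age != -1)) {
    # -1 is the default imputation constant; genuine ages are nonnegative
    stop("negative age that is not the imputation constant")
  }
  lab <- cohort$labels
  if (!all(lab$acs %in% c(0, 1))) stop("acs labels must be 0/1")
  if (!all(lab$subtype %in% c("STEMI", "NSTEMI", "UA", "NONE"))) {
    stop("subtype must be one of STEMI, NSTEMI, UA, NONE")
  }
  bad <- which((lab$acs == 0) != (lab$subtype == "NONE"))
  if (length(bad)) {
    stop(sprintf("subtype/acs inconsistency at row %d (subtype NONE iff acs 0)",
                 bad[1]))
  }
  tb <- cohort$troponin_band
  if (!is.null(tb) && !all(is.na(tb) | tb %in% 0:2)) {
    stop("troponin_band must be in {0,1,2} or NA")
  }
  invisible(cohort)
}

#' @export
print.acs_cohort <- function(x, ...) {
  cat(sprintf("<acs_cohort> %d records (%s), ACS prevalence %.1f%%, %d cells missing\n",
              nrow(x$covariates), x$tag, 100 * mean(x$labels$acs),
              sum(is.na(x$covariates))))
  invisible(x)
}

#' Number of records in a cohort
#' @param cohort An `acs_cohort`.
#' @export
cohort_size <- function(cohort) nrow(cohort$covariates)

#' Missingness mask of a cohort
#'
#' @param cohort An `acs_cohort`.
#' @return Logical matrix (records x 53 expanded columns), TRUE where the
#'   cell is missing.
#' @export
missing_mask <- function(cohort) {
  as.matrix(is.na(cohort$covariates))
}

#' Derived NSTE-ACS indicator
#'
#' NSTE-ACS is ACS without ST elevation: NSTEMI or unstable angina.
#'
#' @param cohort An `acs_cohort`.
#' @return Integer 0/1 vector.
#' @export
nste_acs_label <- function(cohort) {
  as.integer(cohort$labels$subtype %in% c("NSTEMI", "UA"))
}

# ---- CSV I/O ---------------------------------------------------------------

#' Read a cohort from CSV
#'
#' Expects one row per patient with the 53 expanded covariate columns
#' (ECG vectors as `<name>_L01..L11`), label columns `acs` and `subtype`,
#' and optionally `troponin_band`. Empty cells are missing values.
#'
#' @param path CSV file path.
#' @param schema Covariate schema (defaults to [acs_schema()]).
#' @param tag Cohort tag for the returned object.
#' @return An `acs_cohort` with missing cells recorded as NA.
#' @export
read_cohort_csv <- function(path, schema = acs_schema(), tag = "synthetic") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = "", check.names = FALSE)
  cols <- schema_columns(schema)
  need <- c(cols, "acs", "subtype")
  if (!all(need %in% names(df))) {
    stop("malformed header: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  cov <- df[, cols, drop = FALSE]
  for (cn in cols) cov[[cn]] <- as.numeric(cov[[cn]])
  tb <- if ("troponin_band" %in% names(df)) as.integer(df$troponin_band) else NULL
  labels <- data.frame(acs = as.integer(df$acs),
                       subtype = as.character(df$subtype),
                       stringsAsFactors = FALSE)
  new_cohort(cov, labels, tag = tag, troponin_band = tb)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort_csv()]: `read_cohort_csv(write_cohort_csv(c))`
#' reproduces the cohort field-for-field, with missing cells written as
#' empty strings.
#'
#' @param cohort An `acs_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  df <- cohort$covariates
  if (!is.null(cohort$troponin_band)) df$troponin_band <- cohort$troponin_band
  df$acs <- cohort$labels$acs
  df$subtype <- cohort$labels$subtype
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

# ---- Imputation ------------------------------------------------------------

#' Constant imputation of missing covariates
#'
#' Fills missing numeric cells with `numeric_fill` and missing binary cells
#' with `binary_fill`, leaving observed values untouched. Idempotent.
#'
#' @param cohort An `acs_cohort`.
#' @param numeric_fill Fill constant for numeric covariates (default -1).
#' @param binary_fill Fill constant for binary covariates (0 or 1, default 0).
#' @return The imputed cohort (no missing cells remain).
#' @export
impute_constant <- function(cohort, numeric_fill = -1, binary_fill = 0) {
  stopifnot(binary_fill %in% c(0, 1))
  cov <- cohort$covariates
  num_cols <- "age"
  for (cn in names(cov)) {
    fill <- if (cn %in% num_cols) numeric_fill else binary_fill
    cov[[cn]][is.na(cov[[cn]])] <- fill
  }
  cohort$covariates <- cov
  cohort
}

# ---- Covariate subsets -----------------------------------------------------

#' Feature matrix for a named covariate subset
#'
#' Subsets used in the ablation study and the clinical-score comparison:
#' \describe{
#'   \item{baseline}{age, sex, and the 33 per-lead ECG columns (p = 35).}
#'   \item{baseline_symptoms}{baseline plus the 8 symptom binaries (p = 43).}
#'   \item{baseline_symptoms_history}{plus the 10 history binaries (p = 53).}
#'   \item{full}{alias for baseline_symptoms_history (the schema is exhausted).}
#'   \item{hear_matched}{the covariates the HEAR score consumes: age, sex,
#'     chest pain, any-lead summaries of the three ECG interpretations, and
#'     the nine risk-factor history binaries (angina excluded) (p = 15).}
#' }
#' Column order is deterministic (schema order within each block).
#'
#' @param cohort An imputed `acs_cohort`.
#' @param subset Subset name.
#' @return Numeric matrix (records x p) with column names.
#' @export
select_covariates <- function(cohort,
                              subset = c("full", "baseline",
                                         "baseline_symptoms",
                                         "baseline_symptoms_history",
                                         "hear_matched")) {
  subset <- match.arg(subset)
  if (any(is.na(as.matrix(cohort$covariates)))) {
    stop("cohort must be imputed before feature extraction")
  }
  cov <- cohort$covariates
  cols <- switch(subset,
    baseline = schema_columns(groups = c("baseline", "ecg")),
    baseline_symptoms = schema_columns(groups = c("baseline", "ecg", "symptom")),
    baseline_symptoms_history = schema_columns(),
    full = schema_columns(),
    hear_matched = NULL
  )
  if (subset == "hear_matched") {
    interp <- c("ecg_st_elevation", "ecg_st_depression", "ecg_t_wave_inversion")
    ecg_any <- vapply(interp, function(nm) {
      as.numeric(rowSums(cov[, sprintf("%s_L%02d", nm, 1:ECG_LEADS),
                             drop = FALSE]) > 0)
    }, numeric(nrow(cov)))
    if (!is.matrix(ecg_any)) ecg_any <- matrix(ecg_any, nrow = 1,
                                               dimnames = list(NULL, interp))
    colnames(ecg_any) <- paste0(interp, "_any")
    risk_cols <- c("hypercholesterolemia", "hypertension", "current_smoker",
                   "diabetes", "family_history_cv", "prior_mi", "prior_pci",
                   "prior_cabg", "cad")
    m <- cbind(as.matrix(cov[, c("age", "gender_male", "sym_chestpain")]),
               ecg_any,
               as.matrix(cov[, risk_cols]))
    return(m)
  }
  m <- as.matrix(cov[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  m
}
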