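#' Confusion-matrix metrics
#'
#' Standard ratios from hard predictions. Ratios with a zero denominator
#' (e.g. PPV when nothing is called positive) are reported as NA, never 0.
#'
#' @param y_true,y_pred Equal-length 0/1 vectors.
#' @return Named vector: sensitivity, specificity, ppv, npv, accuracy,
#'   prevalence.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!length(y_true)) stop("empty input")
  tp <- sum(y_true == 1 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  rat <- function(a, b) if (b == 0) NA_real_ else a / b
  c(sensitivity = rat(tp, tp + fn),
    specificity = rat(tn, tn + fp),
    ppv = rat(tp, tp + fp),
    npv = rat(tn, tn + fn),
    accuracy = (tp + tn) / length(y_true),
    prevalence = mean(y_true))
}

#' Area under the ROC curve (rank-sum, ties count one half)
#'
#' Probability that a random positive outranks a random negative, computed
#' from midranks (equivalent to the Mann-Whitney statistic), so tied
#' scores contribute one half.
#'
#' @param y_true 0/1 labels.
#' @param scores Real-valued ranking scores.
#' @return AUROC in [0, 1]; NA if only one class is present.
#' @export
auroc <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores))
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified k-fold assignment
#'
#' Assigns each case to one of `k` folds, stratified on the binary label so
#' each fold's class ratio matches the cohort's within one case per class.
#'
#' @param labels 0/1 label vector.
#' @param k Number of folds (default 5).
#' @param seed RNG seed for the shuffle.
#' @return Integer fold id per case (1..k).
#' @export
make_cv_folds <- function(labels, k = 5L, seed = 1L) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Assert the cross-validation plan leaks nothing
#'
#' Verifies folds partition the internal cohort, that the training portion
#' (D plus D_val) is disjoint from the fold's internal test set, and that
#' no external-cohort index occurs anywhere in the plan.
#'
#' @param split List with `train`, `val`, `test` internal index vectors.
#' @param n_internal Internal cohort size.
#' @param external_ids Identifiers of external cases (must not appear).
#' @return TRUE invisibly; errors on any leak.
#' @export
assert_no_leakage <- function(split, n_internal, external_ids = integer(0)) {
  all_idx <- c(split$train, split$val, split$test)
  if (any(duplicated(all_idx))) stop("leakage: overlapping fold index sets")
  if (length(intersect(all_idx, external_ids))) {
    stop("leakage: external-cohort case inside the internal plan")
  }
  if (!setequal(all_idx, seq_len(n_internal))) {
    stop("leakage: fold sets do not partition the internal cohort")
  }
  invisible(TRUE)
}

task_labels <- function(cohort, task = c("acs", "nste_acs")) {
  task <- match.arg(task)
  if (task == "acs") as.integer(cohort$labels$acs) else nste_acs_label(cohort)
}

metrics_row <- function(y, probs_acs, u_total, cutoff, selective, threshold = 0.5) {
  if (selective) {
    keep <- apply_filter(u_total, cutoff) == 1L
    cov_val <- mean(keep)
  } else {
    keep <- rep(TRUE, length(y))
    cov_val <- 1
  }
  yk <- y[keep]
  pk <- probs_acs[keep]
  pred <- as.integer(pk >= threshold)
  cm <- confusion_metrics(yk, pred)
  a <- auroc(yk, pk)
  data.frame(selective = selective, coverage = cov_val,
             prevalence = unname(cm["prevalence"]),
             sensitivity = unname(cm["sensitivity"]),
             specificity = unname(cm["specificity"]),
             ppv = unname(cm["ppv"]), npv = unname(cm["npv"]),
             auroc = a, accuracy = unname(cm["accuracy"]))
}

#' Run the full cross-validation evaluation protocol
#'
#' Five-fold stratified cross-validation on the internal cohort. Per fold:
#' the fold's 20% is held out as the internal test set; 10% of the
#' remaining training portion is split off as validation (D_val) for the
#' hyperparameter search and the abstention cutoff; the model is fit on
#' the rest (D). Selective and non-selective metrics are computed on the
#' internal fold-test set and on the entire external cohort, giving five
#' performance samples per metric. The external cohort never influences
#' fitting or cutoff estimation (asserted every fold).
#'
#' @param internal,external Imputed `acs_cohort`s.
#' @param task "acs" or "nste_acs" (NSTEMI or UA vs the rest; STEMI cases
#'   become negatives and a fresh model is fit on the relabelled outcome).
#' @param subset Covariate subset (see [select_covariates()]).
#' @param config An [ensemble_config()]; if its `grid` is non-NULL a grid
#'   search runs per fold, otherwise the point configuration is used.
#' @param coverage_target Validation quantile for the cutoff (default 0.8).
#' @param val_fraction Fraction of the training portion used as D_val.
#' @param n_folds Number of folds (default 5).
#' @param seed Seed controlling fold assignment and validation splits.
#' @param grid_members Members per candidate during grid search.
#' @param threshold Decision threshold on P(positive).
#' @return List of class `cv_result`: `internal` and `external` per-fold
#'   metric tables (selective and non-selective rows), `cutoffs`,
#'   `grid_traces`, and the `folds` assignment.
#' @export
run_cv_protocol <- function(internal, external, task = "acs",
                            subset = "full", config = ensemble_config(),
                            coverage_target = 0.8, val_fraction = 0.10,
                            n_folds = 5L, seed = 1L, grid_members = 1L,
                            threshold = 0.5) {
  y_int <- task_labels(internal, task)
  y_ext <- task_labels(external, task)
  if (length(unique(y_int)) < 2L) stop("task label absent from internal cohort")
  X_int <- select_covariates(internal, subset)
  X_ext <- select_covariates(external, subset)
  n_int <- nrow(X_int)
  folds <- make_cv_folds(y_int, k = n_folds, seed = seed)

  rows_int <- list(); rows_ext <- list()
  cutoffs <- numeric(0); traces <- list()
  for (f in seq_len(n_folds)) {
    idx_test <- which(folds == f)
    idx_pool <- which(folds != f)
    # stratified validation split inside the training portion
    set.seed(seed + 1000L * f)
    idx_val <- unlist(lapply(c(0L, 1L), function(cls) {
      cls_idx <- idx_pool[y_int[idx_pool] == cls]
      cls_idx <- sample(cls_idx)
      cls_idx[seq_len(max(1L, round(val_fraction * length(cls_idx))))]
    }))
    idx_train <- setdiff(idx_pool, idx_val)
    assert_no_leakage(list(train = idx_train, val = idx_val, test = idx_test),
                      n_internal = n_int,
                      external_ids = n_int + seq_len(nrow(X_ext)))

    cfg <- config
    cfg$base_seed <- config$base_seed + 101L * f
    if (!is.null(cfg$grid)) {
      fit <- grid_search_fit(X_int[idx_train, , drop = FALSE], y_int[idx_train],
                             cfg,
                             validation = list(
                               features = X_int[idx_val, , drop = FALSE],
                               labels = y_int[idx_val]),
                             grid_members = grid_members)
      traces[[f]] <- attr(fit, "trace")
    } else {
      fit <- fit_ensemble(X_int[idx_train, , drop = FALSE], y_int[idx_train], cfg)
    }

    u_val <- uncertainty_table(
      predict_members(fit, X_int[idx_val, , drop = FALSE]))$total
    cut <- estimate_cutoff(u_val, min(coverage_target, 1))
    cutoffs[f] <- cut$cutoff
    # a coverage target of 1 means no abstention at all, even for test
    # cases more uncertain than anything seen in validation
    cut_eff <- if (coverage_target >= 1) Inf else cut

    for (side in c("internal", "external")) {
      X <- if (side == "internal") X_int[idx_test, , drop = FALSE] else X_ext
      y <- if (side == "internal") y_int[idx_test] else y_ext
      mp <- predict_members(fit, X)
      probs <- mean_probs(mp)[, "acs"]
      u <- uncertainty_table(mp)$total
      rws <- rbind(
        metrics_row(y, probs, u, cut_eff, selective = FALSE, threshold),
        metrics_row(y, probs, u, cut_eff, selective = TRUE, threshold))
      rws <- cbind(fold = f, rws)
      if (side == "internal") rows_int[[f]] <- rws else rows_ext[[f]] <- rws
    }
  }
  structure(list(internal = do.call(rbind, rows_int),
                 external = do.call(rbind, rows_ext),
                 cutoffs = cutoffs, grid_traces = traces, folds = folds,
                 task = task, subset = subset,
                 coverage_target = coverage_target, seed = seed),
            class = "cv_result")
}

#' Aggregate per-fold metrics as mean and 2 x standard error
#'
#' One performance sample per fold; the dispersion reported is twice the
#' standard error of the fold values (sd / sqrt(n_folds)), with twice the
#' standard deviation available via `dispersion = "sd"`. Folds with a
#' missing value for a metric are excluded from that metric's aggregate
#' with a warning.
#'
#' @param rows Per-fold metric table (one selective or non-selective slice).
#' @param dispersion "se" (default) or "sd".
#' @return Data frame: metric, mean, two_sigma, n_folds.
#' @export
aggregate_report <- function(rows, dispersion = c("se", "sd")) {
  dispersion <- match.arg(dispersion)
  if (nrow(rows) < 2L) stop("need at least 2 fold rows to aggregate")
  metrics <- c("coverage", "prevalence", "sensitivity", "specificity",
               "ppv", "npv", "auroc", "accuracy")
  out <- lapply(metrics, function(m) {
    v <- rows[[m]]
    if (anyNA(v)) {
      warning(sprintf("metric '%s': %d fold value(s) missing, excluded",
                      m, sum(is.na(v))))
      v <- v[!is.na(v)]
    }
    disp <- if (length(v) > 1) {
      if (dispersion == "se") 2 * stats::sd(v) / sqrt(length(v)) else 2 * stats::sd(v)
    } else NA_real_
    data.frame(metric = m, mean = mean(v), two_sigma = disp,
               n_folds = length(v))
  })
  do.call(rbind, out)
}

#' Format an aggregate report like the study tables
#'
#' @param agg Output of [aggregate_report()].
#' @return Named character vector of "mean±2sigma" percentages.
#' @export
format_report <- function(agg) {
  stats::setNames(sprintf("%.0f±%.0f", 100 * agg$mean, 100 * agg$two_sigma),
                  agg$metric)
}

#' Covariate-subset ablation
#'
#' Runs the full protocol for the three nested covariate subsets (baseline;
#' baseline + symptoms; baseline + symptoms + medical history) and returns
#' per-subset results plus a summary table of external-cohort aggregates.
#'
#' @inheritParams run_cv_protocol
#' @param subsets Covariate subsets to compare (nested by default).
#' @param selective Aggregate the selective (TRUE) or plain rows.
#' @return List: `results` (per-subset `cv_result`s) and `summary`
#'   (long data frame of external aggregates by subset).
#' @export
run_ablation <- function(internal, external, task = "acs",
                         config = ensemble_config(),
                         subsets = c("baseline", "baseline_symptoms",
                                     "baseline_symptoms_history"),
                         coverage_target = 0.8, seed = 1L,
                         grid_members = 1L, selective = FALSE) {
  results <- lapply(subsets, function(s) {
    run_cv_protocol(internal, external, task = task, subset = s,
                    config = config, coverage_target = coverage_target,
                    seed = seed, grid_members = grid_members)
  })
  names(results) <- subsets
  summary <- do.call(rbind, lapply(subsets, function(s) {
    rows <- results[[s]]$external
    agg <- aggregate_report(rows[rows$selective == selective, ])
    cbind(subset = s, agg)
  }))
  list(results = results, summary = summary)
}
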