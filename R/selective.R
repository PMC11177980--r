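#' Estimate the abstention cutoff on a validation split
#'
#' The cutoff is the empirical `coverage_target` quantile of the validation
#' total uncertainties under the inverse-ECDF (lower) convention: the
#' smallest observed value v such that the fraction of validation values
#' <= v is at least the target. With the default 0.8 target, 80% of the
#' validation cases sit at or below the cutoff.
#'
#' @param val_uncertainties Nonempty numeric vector of validation total
#'   uncertainties (nats).
#' @param coverage_target Targeted retained fraction in (0, 1]; default 0.8.
#' @return An `sc_cutoff` list: `cutoff`, `coverage_target`, `source_size`.
#' @export
estimate_cutoff <- function(val_uncertainties, coverage_target = 0.8) {
  if (!length(val_uncertainties)) stop("empty validation uncertainty list")
  stopifnot(coverage_target > 0, coverage_target <= 1,
            all(is.finite(val_uncertainties)))
  cutoff <- unname(stats::quantile(val_uncertainties, coverage_target,
                                   type = 1, names = FALSE))
  structure(list(cutoff = cutoff, coverage_target = coverage_target,
                 source_size = length(val_uncertainties)),
            class = "sc_cutoff")
}

#' Apply the selective-classification filter
#'
#' The filter rule excludes cases whose total uncertainty is strictly
#' greater than the cutoff; equality retains the case.
#'
#' @param test_uncertainties Numeric vector of test total uncertainties.
#' @param cutoff An `sc_cutoff` (or a bare numeric cutoff).
#' @return Integer retain mask (1 = retained/filtered-in, 0 = abstained).
#' @export
apply_filter <- function(test_uncertainties, cutoff) {
  cut <- if (inherits(cutoff, "sc_cutoff")) cutoff$cutoff else cutoff
  as.integer(test_uncertainties <= cut)
}

#' Coverage of a retain mask
#'
#' @param mask Nonempty 0/1 retain mask.
#' @return Fraction of cases retained.
#' @export
coverage <- function(mask) {
  if (!length(mask)) stop("empty mask")
  mean(mask)
}

#' Risk-coverage sweep
#'
#' For each exclusion fraction f, drops the f-most-uncertain cases (ties
#' broken by original case order for determinism) and records the AUROC of
#' the supplied scores on the remainder. Points where the remainder
#' contains a single outcome class get an NA AUROC rather than an error.
#'
#' @param test_uncertainties Total uncertainties (nats), one per case.
#' @param labels 0/1 outcome labels.
#' @param scores Ranking scores (e.g. mean P(ACS) or a clinical score).
#' @param exclusion_fractions Grid of fractions in [0, 1).
#' @return Data frame (exclusion_fraction, auroc, n_retained).
#' @export
risk_coverage_sweep <- function(test_uncertainties, labels, scores,
                                exclusion_fractions = seq(0, 0.5, by = 0.05)) {
  n <- length(test_uncertainties)
  stopifnot(length(labels) == n, length(scores) == n,
            all(exclusion_fractions >= 0), all(exclusion_fractions < 1))
  # most-uncertain-first order; ties by original index (stable)
  drop_order <- order(-test_uncertainties, seq_len(n))
  res <- lapply(exclusion_fractions, function(f) {
    k <- floor(f * n)
    keep <- if (k > 0) setdiff(seq_len(n), drop_order[seq_len(k)]) else seq_len(n)
    a <- if (length(unique(labels[keep])) < 2L) NA_real_ else {
      auroc(labels[keep], scores[keep])
    }
    data.frame(exclusion_fraction = f, auroc = a, n_retained = length(keep))
  })
  do.call(rbind, res)
}
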