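#' Ensemble configuration
#'
#' Hyperparameters for an ensemble of M gradient-boosted tree classifiers.
#' The default search grid spans learning_rate {0.01, 0.1, 1.0}, depth
#' {1, 3, 6, 10} and subsample {0.25, 0.5, 0.75} (36 points) at 1000
#' boosting iterations with M = 10 members.
#'
#' @param learning_rate Shrinkage (eta) used when fitting without a grid.
#' @param depth Maximum tree depth.
#' @param subsample Row-subsampling rate in (0, 1]; also the source of
#'   member diversity together with independent member seeds.
#' @param iterations Number of boosting rounds.
#' @param n_members Ensemble size M.
#' @param base_seed Seed; member m uses `base_seed + m`.
#' @param class_weight_mode "inverse_frequency" (default) or "none".
#' @param grid Named list of candidate values for learning_rate, depth and
#'   subsample used by [grid_search_fit()]; NULL disables the search.
#' @return An `ensemble_config` list.
#' @export
ensemble_config <- function(learning_rate = 0.1, depth = 6, subsample = 0.75,
                            iterations = 1000L, n_members = 10L,
                            base_seed = 1419528L,
                            class_weight_mode = c("inverse_frequency", "none"),
                            grid = list(learning_rate = c(0.01, 0.1, 1.0),
                                        depth = c(1L, 3L, 6L, 10L),
                                        subsample = c(0.25, 0.5, 0.75))) {
  class_weight_mode <- match.arg(class_weight_mode)
  stopifnot(learning_rate > 0, depth >= 1, subsample > 0, subsample <= 1,
            iterations >= 1, n_members >= 1)
  structure(list(learning_rate = learning_rate, depth = as.integer(depth),
                 subsample = subsample, iterations = as.integer(iterations),
                 n_members = as.integer(n_members),
                 base_seed = as.integer(base_seed),
                 class_weight_mode = class_weight_mode, grid = grid),
            class = "ensemble_config")
}

#' Inverse-frequency class weights
#'
#' Per-class weights proportional to the inverse class frequency,
#' normalised so the two weights average to 1; estimated from the labels
#' available for training (per fold in cross-validation).
#'
#' @param labels 0/1 vector with both classes present.
#' @return Named vector `c(neg = w0, pos = w1)`.
#' @export
#' @examples
#' compute_class_weights(c(rep(1, 20), rep(0, 80)))  # pos/neg ratio 4
compute_class_weights <- function(labels) {
  stopifnot(all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2L) {
    stop("degenerate labels: both classes must be present")
  }
  f1 <- mean(labels)
  w <- c(neg = 1 / (1 - f1), pos = 1 / f1)
  w / mean(w)
}

fit_member <- function(features, labels, config, member_seed, weights) {
  dtrain <- xgboost::xgb.DMatrix(features, label = labels, weight = weights,
                                 nthread = 1)
  params <- list(objective = "binary:logistic",
                 eta = config$learning_rate,
                 max_depth = config$depth,
                 subsample = config$subsample,
                 seed = member_seed,
                 nthread = 1)
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = config$iterations, verbose = 0)
}

#' Fit an ensemble of gradient-boosted tree classifiers
#'
#' Trains M members with identical hyperparameters but independent
#' stochasticity (member seed `base_seed + m` plus row subsampling), so the
#' members act as exchangeable samples from an approximate posterior over
#' model parameters. Inverse-frequency class weights are applied during
#' fitting when configured. Deterministic given `base_seed`.
#'
#' @param features Numeric matrix (n x p) with column names.
#' @param labels 0/1 outcome vector, both classes present, n >= 20.
#' @param config An [ensemble_config()].
#' @return A `fitted_ensemble` (members, config, feature_names).
#' @export
fit_ensemble <- function(features, labels, config = ensemble_config()) {
  stopifnot(is.matrix(features), nrow(features) >= 20, ncol(features) >= 1,
            nrow(features) == length(labels))
  if (is.null(colnames(features))) stop("features must have column names")
  weights <- if (config$class_weight_mode == "inverse_frequency") {
    compute_class_weights(labels)[labels + 1L]
  } else {
    if (length(unique(labels)) < 2L) stop("degenerate labels")
    rep(1, length(labels))
  }
  members <- lapply(seq_len(config$n_members), function(m) {
    fit_member(features, labels, config, config$base_seed + m, weights)
  })
  structure(list(members = members, config = config,
                 feature_names = colnames(features)),
            class = "fitted_ensemble")
}

#' @export
print.fitted_ensemble <- function(x, ...) {
  cat(sprintf("<fitted_ensemble> M=%d members, %d features, depth=%d, eta=%g\n",
              length(x$members), length(x$feature_names),
              x$config$depth, x$config$learning_rate))
  invisible(x)
}

#' Per-member class probabilities
#'
#' Returns the full member-by-case probability tensor (not just the
#' ensemble mean) so predictive uncertainty can be decomposed downstream.
#'
#' @param ensemble A `fitted_ensemble`.
#' @param features Numeric matrix whose columns match the training features.
#' @return Array M x n x 2; `[, , 1]` is P(no ACS), `[, , 2]` is P(ACS);
#'   each (m, i) row sums to 1.
#' @export
predict_members <- function(ensemble, features) {
  stopifnot(inherits(ensemble, "fitted_ensemble"))
  if (!identical(colnames(features), ensemble$feature_names)) {
    stop("feature columns do not match the fitted ensemble")
  }
  M <- length(ensemble$members)
  n <- nrow(features)
  dmat <- xgboost::xgb.DMatrix(features, nthread = 1)
  probs <- array(NA_real_, dim = c(M, n, 2L),
                 dimnames = list(NULL, NULL, c("no_acs", "acs")))
  for (m in seq_len(M)) {
    p1 <- predict(ensemble$members[[m]], dmat)
    probs[m, , 1L] <- 1 - p1
    probs[m, , 2L] <- p1
  }
  probs
}

#' Ensemble-mean class probabilities
#'
#' @param member_probs Array M x n x 2 from [predict_members()].
#' @return Matrix n x 2 (columns no_acs, acs), the Monte-Carlo estimate of
#'   the posterior predictive distribution.
#' @export
mean_probs <- function(member_probs) {
  apply(member_probs, c(2, 3), mean)
}

#' Grid search over ensemble hyperparameters
#'
#' Exhaustively evaluates every point of `config$grid` by the AUROC of the
#' candidate's mean probability on a held-out validation set, breaks ties
#' toward simpler models (smaller depth, then smaller learning rate, then
#' smaller subsample), and refits the full M-member ensemble at the winner.
#' Candidates are scored with `grid_members` members (default 1) to keep
#' the search affordable; the winning point is always refit at full size.
#' The search trace is attached as attribute `"trace"`.
#'
#' @param features,labels Training data.
#' @param config An [ensemble_config()] with a non-empty `grid`.
#' @param validation List with `features` and `labels`, disjoint from the
#'   training set.
#' @param grid_members Members per candidate during the search.
#' @return A `fitted_ensemble` fitted at the selected grid point.
#' @export
grid_search_fit <- function(features, labels, config, validation,
                            grid_members = 1L) {
  if (is.null(config$grid) || !length(config$grid)) {
    stop("configuration error: empty hyperparameter grid")
  }
  cand <- expand.grid(learning_rate = config$grid$learning_rate,
                      depth = config$grid$depth,
                      subsample = config$grid$subsample,
                      KEEP.OUT.ATTRS = FALSE)
  scores <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    cfg_i <- config
    cfg_i$learning_rate <- cand$learning_rate[i]
    cfg_i$depth <- as.integer(cand$depth[i])
    cfg_i$subsample <- cand$subsample[i]
    cfg_i$n_members <- as.integer(grid_members)
    fit_i <- fit_ensemble(features, labels, cfg_i)
    mp <- mean_probs(predict_members(fit_i, validation$features))
    scores[i] <- auroc(validation$labels, mp[, "acs"])
  }
  ord <- order(-scores, cand$depth, cand$learning_rate, cand$subsample)
  best <- ord[1]
  winner <- config
  winner$learning_rate <- cand$learning_rate[best]
  winner$depth <- as.integer(cand$depth[best])
  winner$subsample <- cand$subsample[best]
  fit <- fit_ensemble(features, labels, winner)
  trace <- cbind(cand, val_auroc = scores)
  trace$selected <- seq_len(nrow(cand)) == best
  attr(fit, "trace") <- trace
  fit
}

#' Hard labels from mean probabilities
#'
#' @param probs n x 2 matrix of mean class probabilities (rows sum to 1).
#' @param threshold Decision threshold on P(ACS); a case is called positive
#'   when P(ACS) >= threshold. Default 0.5.
#' @return Integer 0/1 vector.
#' @export
predict_label <- function(probs, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) {
    stop("configuration error: threshold must be in (0, 1)")
  }
  as.integer(probs[, "acs"] >= threshold)
}
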