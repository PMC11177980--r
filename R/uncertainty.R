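#' Shannon entropy of a probability row (nats)
#'
#' Natural-log entropy with the convention 0 * log 0 = 0.
#'
#' @param p Probability vector or matrix (rows are distributions).
#' @return Entropy in nats (vector if `p` is a matrix).
#' @keywords internal
shannon_entropy <- function(p) {
  if (is.matrix(p)) {
    terms <- ifelse(p > 0, -p * log(p), 0)
    rowSums(terms)
  } else {
    sum(ifelse(p > 0, -p * log(p), 0))
  }
}

check_prob_rows <- function(member_probs, tol = 1e-6) {
  if (is.null(dim(member_probs))) member_probs <- matrix(member_probs, 1)
  if (any(member_probs < -tol | member_probs > 1 + tol)) {
    stop("probabilities outside [0, 1]")
  }
  s <- rowSums(member_probs)
  if (any(abs(s - 1) > tol)) {
    stop("member probability rows must sum to 1")
  }
  member_probs
}

#' Total predictive uncertainty of one case (nats)
#'
#' Entropy of the posterior predictive distribution, estimated as the
#' entropy of the ensemble-mean class probabilities (Monte-Carlo average
#' over the M members).
#'
#' @param member_probs M x K matrix of per-member class probabilities for
#'   one case; every row sums to 1.
#' @return Total uncertainty in nats, in [0, log K].
#' @export
total_uncertainty <- function(member_probs) {
  member_probs <- check_prob_rows(member_probs)
  shannon_entropy(colMeans(member_probs))
}

#' Data (aleatoric) uncertainty of one case (nats)
#'
#' Expected per-member predictive entropy: high when the outcome is
#' inherently random given the covariates.
#'
#' @inheritParams total_uncertainty
#' @return Data uncertainty in nats.
#' @export
data_uncertainty <- function(member_probs) {
  member_probs <- check_prob_rows(member_probs)
  mean(shannon_entropy(member_probs))
}

#' Model (epistemic) uncertainty of one case (nats)
#'
#' Mutual information between the prediction and the model parameters:
#' total minus data uncertainty. High when members disagree, i.e. when the
#' input is unlike the training data. Negative values within 1e-9 are
#' floating-point noise and clipped to 0; anything more negative signals a
#' bug and raises an error.
#'
#' @inheritParams total_uncertainty
#' @return Model uncertainty in nats (0 when all members agree; 0 for M=1).
#' @export
model_uncertainty <- function(member_probs) {
  mi <- total_uncertainty(member_probs) - data_uncertainty(member_probs)
  if (mi < -1e-9) {
    stop("internal error: uncertainty decomposition violated (total < data)")
  }
  max(mi, 0)
}

#' Per-case uncertainty decomposition for a prediction tensor
#'
#' Vectorised total/data/model uncertainty over an M x n x K member
#' probability tensor; row order matches case order, and
#' total = data + model holds per case (up to clipping at 1e-9).
#'
#' @param member_probs Array M x n x K from [predict_members()].
#' @return Data frame with columns `total`, `data`, `model` (n rows, nats).
#' @export
uncertainty_table <- function(member_probs) {
  stopifnot(length(dim(member_probs)) == 3L)
  M <- dim(member_probs)[1]
  n <- dim(member_probs)[2]
  K <- dim(member_probs)[3]
  flat <- matrix(aperm(member_probs, c(2, 1, 3)), nrow = M * n, ncol = K)
  check_prob_rows(flat)
  per_member_ent <- matrix(shannon_entropy(flat), nrow = n, ncol = M)
  data_u <- rowMeans(per_member_ent)
  mean_p <- apply(member_probs, c(2, 3), mean)
  total_u <- shannon_entropy(mean_p)
  model_u <- total_u - data_u
  if (any(model_u < -1e-9)) {
    stop("internal error: uncertainty decomposition violated (total < data)")
  }
  model_u <- pmax(model_u, 0)
  data.frame(total = total_u, data = data_u, model = model_u)
}
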