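# Small hand-built cohorts for unit tests (no generator involved).

empty_record <- function() {
  cols <- schema_columns()
  rec <- as.data.frame(as.list(stats::setNames(rep(0, length(cols)), cols)),
                       check.names = FALSE)
  rec$age <- 50
  rec
}

# Build a cohort from a list of per-record overrides, e.g.
# tiny_cohort(list(age = 70, sym_chestpain = 1), list(), acs = c(1, 0))
tiny_cohort <- function(..., acs = NULL, subtype = NULL, tag = "synthetic",
                        troponin_band = NULL) {
  overrides <- list(...)
  if (!length(overrides)) {
    return(new_cohort(empty_record()[0, , drop = FALSE],
                      data.frame(acs = integer(0), subtype = character(0)),
                      tag = tag))
  }
  recs <- lapply(overrides, function(ov) {
    rec <- empty_record()
    for (nm in names(ov)) rec[[nm]] <- ov[[nm]]
    rec
  })
  cov <- do.call(rbind, recs)
  n <- nrow(cov)
  if (is.null(acs)) acs <- rep(0L, n)
  if (is.null(subtype)) subtype <- ifelse(acs == 1, "STEMI", "NONE")
  new_cohort(cov, data.frame(acs = acs, subtype = subtype,
                             stringsAsFactors = FALSE),
             tag = tag, troponin_band = troponin_band)
}

# A small generated cohort pair shared across tests that need fitted models.
small_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- temporal_split_pair(
        generator_config(n = 600L, seed = 101L, preset = "internal",
                         tag = "internal"),
        generator_config(n = 400L, seed = 102L, preset = "external",
                         tag = "external"))
      cache$internal <<- impute_constant(cache$internal)
      cache$external <<- impute_constant(cache$external)
    }
    cache
  }
})

# Random valid member-probability tensor (M x n x 2).
random_member_tensor <- function(M, n, seed = 1) {
  set.seed(seed)
  p <- matrix(stats::runif(M * n), M, n)
  array(c(1 - p, p), dim = c(M, n, 2),
        dimnames = list(NULL, NULL, c("no_acs", "acs")))
}

# Brute-force AUROC over all positive-negative pairs (independent oracle).
auroc_bruteforce <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Direct-formula entropy (independent of the package implementation).
entropy_direct <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}
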