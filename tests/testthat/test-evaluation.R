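test_that("confusion metrics match direct ratio arithmetic", {
  y_true <- c(rep(1, 10), rep(0, 10))
  y_pred <- c(rep(1, 9), 0, rep(0, 8), 1, 1)
  m <- confusion_metrics(y_true, y_pred)
  expect_equal(unname(m["sensitivity"]), 0.9)
  expect_equal(unname(m["specificity"]), 0.8)
  expect_equal(unname(m["ppv"]), 9 / 11, tolerance = 1e-12)
  expect_equal(unname(m["npv"]), 8 / 9, tolerance = 1e-12)
  expect_equal(unname(m["accuracy"]), 0.85)
  expect_equal(unname(m["prevalence"]), 0.5)
  # perfect prediction
  mp <- confusion_metrics(y_true, y_true)
  expect_true(all(mp[c("sensitivity", "specificity", "ppv", "npv",
                       "accuracy")] == 1))
  # all-negative predictions: PPV undefined, NPV = 1 - prevalence
  mn <- confusion_metrics(y_true, rep(0, 20))
  expect_true(is.na(mn["ppv"]))
  expect_equal(unname(mn["npv"]), 0.5)
  expect_error(confusion_metrics(c(0, 1), c(0)), "length")
})

test_that("rank-based AUROC equals the pairwise oracle", {
  # 3 pairwise wins, no ties, out of 4 positive-negative pairs
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2)), 3 / 4)
  expect_true(is.na(auroc(c(1, 1), c(0.2, 0.3))))
  set.seed(17)
  for (i in 1:60) {
    n <- sample(4:30, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    expect_equal(auroc(y, s), auroc_bruteforce(y, s), tolerance = 1e-12)
  }
})

test_that("fold assignment stratifies the class ratio within one case", {
  set.seed(1)
  y <- rbinom(437, 1, 0.2)
  folds <- make_cv_folds(y, k = 5, seed = 3)
  expect_equal(sort(unique(folds)), 1:5)
  pos_per_fold <- tapply(y, folds, sum)
  n_per_fold <- tapply(y, folds, length)
  expect_lte(diff(range(pos_per_fold)), 1)
  expect_lte(diff(range(n_per_fold - pos_per_fold)), 1)
})

test_that("the leakage guard catches overlap, gaps and external intrusion", {
  ok <- list(train = 1:60, val = 61:80, test = 81:100)
  expect_true(assert_no_leakage(ok, 100))
  expect_error(assert_no_leakage(list(train = 1:60, val = 60:80,
                                      test = 81:100), 100), "overlap")
  expect_error(assert_no_leakage(list(train = 1:50, val = 61:80,
                                      test = 81:100), 100), "partition")
  expect_error(assert_no_leakage(list(train = c(1:60, 105), val = 61:80,
                                      test = 81:100), 100,
                                 external_ids = 101:120), "external")
})

test_that("fold aggregation reports mean and twice the standard error", {
  rows <- data.frame(coverage = 1, prevalence = 0.2,
                     sensitivity = c(0.8, 0.9), specificity = 0.9,
                     ppv = 0.5, npv = 0.9, auroc = c(0.8, 0.9),
                     accuracy = 0.9)
  agg <- aggregate_report(rows)
  a <- agg[agg$metric == "auroc", ]
  expect_equal(a$mean, 0.85)
  expect_equal(a$two_sigma, 2 * stats::sd(c(0.8, 0.9)) / sqrt(2))
  # constant folds have zero dispersion
  expect_equal(agg$two_sigma[agg$metric == "coverage"], 0)
  # SD interpretation available on request
  expect_equal(aggregate_report(rows, "sd")$two_sigma[3],
               2 * stats::sd(c(0.8, 0.9)))
  # permuting folds changes nothing
  expect_equal(aggregate_report(rows[2:1, ]), agg)
  # missing fold values are excluded with a warning
  rows$ppv <- c(NA, 0.5)
  expect_warning(agg2 <- aggregate_report(rows), "missing")
  expect_equal(agg2$n_folds[agg2$metric == "ppv"], 1)
  expect_error(aggregate_report(rows[1, , drop = FALSE]), "at least 2")
})

test_that("the CV protocol is deterministic and leak-free end to end", {
  pair <- small_pair()
  cfg <- ensemble_config(iterations = 30L, n_members = 3L, grid = NULL)
  r1 <- run_cv_protocol(pair$internal, pair$external, config = cfg, seed = 5)
  r2 <- run_cv_protocol(pair$internal, pair$external, config = cfg, seed = 5)
  expect_identical(r1$internal, r2$internal)
  expect_identical(r1$external, r2$external)
  expect_equal(nrow(r1$external), 10)           # 5 folds x {plain, selective}
  expect_length(r1$cutoffs, 5)
  # non-selective rows always have full coverage; prevalence is empirical
  plain <- r1$external[!r1$external$selective, ]
  expect_true(all(plain$coverage == 1))
  expect_equal(unique(plain$prevalence), mean(pair$external$labels$acs))
})

test_that("a coverage target of 1 makes selective rows identical to plain", {
  pair <- small_pair()
  cfg <- ensemble_config(iterations = 25L, n_members = 3L, grid = NULL)
  res <- run_cv_protocol(pair$internal, pair$external, config = cfg,
                         coverage_target = 1.0, seed = 7)
  for (side in c("internal", "external")) {
    rows <- res[[side]]
    plain <- rows[!rows$selective, setdiff(names(rows), "selective")]
    sel <- rows[rows$selective, setdiff(names(rows), "selective")]
    expect_equal(sel, plain, ignore_attr = TRUE)
  }
})

test_that("the NSTE-ACS task relabels STEMI as negative", {
  pair <- small_pair()
  y <- nste_acs_label(pair$internal)
  lab <- pair$internal$labels
  expect_true(all(y[lab$subtype == "STEMI"] == 0))
  expect_true(all(y[lab$subtype %in% c("NSTEMI", "UA")] == 1))
  expect_true(all(y[lab$acs == 0] == 0))
  cfg <- ensemble_config(iterations = 25L, n_members = 3L, grid = NULL)
  res <- run_cv_protocol(pair$internal, pair$external, task = "nste_acs",
                         config = cfg, seed = 9)
  plain <- res$external[!res$external$selective, ]
  expect_equal(unique(plain$prevalence), mean(nste_acs_label(pair$external)))
  expect_equal(res$task, "nste_acs")
})

test_that("ablation returns nested subsets in a Table-style summary", {
  pair <- small_pair()
  cfg <- ensemble_config(iterations = 25L, n_members = 3L, grid = NULL)
  ab <- run_ablation(pair$internal, pair$external, config = cfg, seed = 11)
  expect_named(ab$results, c("baseline", "baseline_symptoms",
                             "baseline_symptoms_history"))
  expect_equal(nrow(ab$summary), 3 * 8)  # 3 subsets x 8 metrics
  expect_true(all(ab$summary$mean[ab$summary$metric == "coverage"] == 1))
})
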