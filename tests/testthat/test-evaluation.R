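test_that("S1 folds partition pairs with stratification; S2/S3 respect the drug holdout", {
  ds <- tiny_dataset(m = 30L, seed = 17L)
  ia <- match(ds$ddis$pairs$drug_a, ds$catalog$drug_ids)
  ib <- match(ds$ddis$pairs$drug_b, ds$catalog$drug_ids)

  plan1 <- split_cv(ds$ddis, ds$catalog, "S1", 5L, seed = 1L)
  test_sets <- lapply(plan1$folds, `[[`, "test")
  expect_equal(sort(unlist(test_sets)), seq_len(nrow(ds$ddis$pairs)))
  for (f in plan1$folds) {
    expect_length(intersect(f$train, f$test), 0L)
    expect_equal(sort(c(f$train, f$test)), seq_len(nrow(ds$ddis$pairs)))
  }

  for (scene in c("S2", "S3")) {
    plan <- split_cv(ds$ddis, ds$catalog, scene, 5L, seed = 1L)
    for (f in plan$folds) {
      held <- ds$catalog$drug_ids[match(f$held_drugs, ds$catalog$drug_ids)]
      n_held_test <- (ds$ddis$pairs$drug_a[f$test] %in% held) +
        (ds$ddis$pairs$drug_b[f$test] %in% held)
      expect_true(all(n_held_test == (if (scene == "S2") 1L else 2L)))
      # leakage check: training pairs never touch a held-out drug
      expect_false(any(ds$ddis$pairs$drug_a[f$train] %in% held |
                         ds$ddis$pairs$drug_b[f$train] %in% held))
    }
  }

  # determinism of the plan
  expect_identical(split_cv(ds$ddis, ds$catalog, "S2", 5L, seed = 3L),
                   split_cv(ds$ddis, ds$catalog, "S2", 5L, seed = 3L))
})

test_that("metrics reproduce the hand-worked four-sample case and the degenerate ones", {
  # truth (0,0,1,1), argmax (0,1,1,1)
  probs <- rbind(c(0.9, 0.1), c(0.4, 0.6), c(0.2, 0.8), c(0.3, 0.7))
  mr <- compute_metrics(c(0L, 0L, 1L, 1L), probs, 2L)
  expect_equal(mr$acc, 0.75)
  expect_equal(mr$precision_macro, (1 + 2 / 3) / 2, tolerance = 1e-12)
  expect_equal(mr$recall_macro, 0.75)
  expect_equal(mr$f1_macro, 2 * (5 / 6) * 0.75 / (5 / 6 + 0.75),
               tolerance = 1e-12)

  # perfect prediction saturates every metric
  y <- c(0L, 1L, 2L, 0L, 2L)
  perfect <- matrix(0.01, 5, 3); perfect[cbind(1:5, y + 1L)] <- 0.98
  mp <- compute_metrics(y, perfect, 3L)
  expect_equal(mp$acc, 1); expect_equal(mp$f1_macro, 1)
  expect_equal(mp$aupr_micro, 1); expect_equal(mp$auc_micro, 1)

  # a constant scorer on balanced binary labels has micro AUC 1/2
  const <- matrix(0.5, 10, 2)
  mc <- compute_metrics(rep(c(0L, 1L), 5), const, 2L)
  expect_equal(mc$auc_micro, 0.5)

  expect_error(compute_metrics(c(0L, 1L), rbind(c(0.9, 0.2), c(0.5, 0.5)), 2L),
               "sum to 1")
})

test_that("metrics match the independent brute-force oracle on random predictions", {
  set.seed(55)
  for (rep in 1:20) {
    ps <- random_prediction_set(n = 80L, l = 4L)
    mr <- compute_metrics(ps$y, ps$probs, 4L)
    or <- metrics_oracle(ps$y, ps$probs, 4L)
    for (nm in names(or)) expect_equal(mr[[nm]], or[[nm]], tolerance = 1e-9)
  }
})

test_that("micro ROC area agrees with an external ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  ps <- random_prediction_set(n = 120L, l = 3L)
  ybin <- matrix(0, 120, 3); ybin[cbind(1:120, ps$y + 1L)] <- 1
  ours <- compute_metrics(ps$y, ps$probs, 3L)$auc_micro
  ref <- pROC::auc(pROC::roc(as.vector(ybin), as.vector(ps$probs),
                             quiet = TRUE, direction = "<"))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-9)
})

test_that("chance macro-F1 equals the reciprocal class count", {
  expect_equal(chance_macro_f1(c(0, 0, 0, 1, 2, 2), 3L), 1 / 3)
  expect_equal(chance_macro_f1(rep(0:4, times = c(50, 5, 5, 5, 5)), 5L), 1 / 5)
})

test_that("cross-validated runs are reproducible and beat chance on planted data", {
  ds <- tiny_dataset(m = 30L, seed = 19L)
  cfg <- tiny_config(cv = list(folds = 3L, seed = 19L))
  r1 <- run_cv(ds, cfg)
  r2 <- run_cv(ds, cfg)
  expect_identical(r1$aggregate, r2$aggregate)
  expect_gt(r1$aggregate[["f1_macro"]], 3 * r1$chance_f1_macro)
  expect_equal(length(r1$per_fold), 3L)
  for (mr in r1$per_fold) {
    vals <- unlist(mr[c("acc", "f1_macro", "aupr_micro", "auc_micro")])
    expect_true(all(vals >= 0 & vals <= 1))
    # per-class one-vs-rest counts always total the fold's test size
    totals <- with(mr$counts, TP + FP + FN + TN)
    expect_true(all(totals == totals[1]))
  }
})
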