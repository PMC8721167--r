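test_that("pair aggregation operators compute the documented combinations", {
  catalog <- drug_catalog(c("a", "b"))
  emb <- structure(list(values = rbind(a = c(1, 2), b = c(3, 4)), d_u = 2L),
                   class = "unified_embedding")
  pairs <- data.frame(drug_a = "a", drug_b = "b")
  expect_equal(unname(aggregate_pairs(emb, pairs, "inner", catalog)$values),
               matrix(c(3, 8), 1))
  expect_equal(unname(aggregate_pairs(emb, pairs, "sum", catalog)$values),
               matrix(c(4, 6), 1))
  expect_equal(unname(aggregate_pairs(emb, pairs, "concat", catalog)$values),
               matrix(c(1, 2, 3, 4), 1))
  expect_error(aggregate_pairs(emb, pairs, "hadamard", catalog))
  expect_error(aggregate_pairs(emb, data.frame(drug_a = "a", drug_b = "z"),
                               "sum", catalog), "unknown drug")
})

test_that("the classifier learns planted structure and is deterministic", {
  ds <- tiny_dataset(m = 30L, seed = 12L)
  cfg <- tiny_config(cv = list(seed = 12L))
  emb <- build_embedding(ds, cfg, "full")
  pairs <- ds$ddis$pairs
  l <- length(ds$ddis$type_names)
  samp <- ddinet:::training_samples(emb, pairs, pairs$type, "concat", ds$catalog)
  model <- train_dnn(samp$values, samp$labels, cfg$dnn, l = l, seed = 5L)
  pred <- predict_pair_types(model, emb, pairs, "concat", ds$catalog)
  expect_gt(mean(pred$predicted == pairs$type), 1 / l)

  model2 <- train_dnn(samp$values, samp$labels, cfg$dnn, l = l, seed = 5L)
  expect_identical(model$params, model2$params)

  expect_error(train_dnn(samp$values, rep(0L, length(samp$labels)), cfg$dnn),
               "single class")
})

test_that("shuffled labels give no better than majority-class accuracy", {
  ds <- tiny_dataset(m = 30L, seed = 13L)
  cfg <- tiny_config(cv = list(seed = 13L))
  emb <- build_embedding(ds, cfg, "full")
  pairs <- ds$ddis$pairs
  l <- length(ds$ddis$type_names)
  set.seed(99)
  y_shuf <- sample(pairs$type)
  n <- nrow(pairs)
  holdout <- sample(n, round(0.3 * n))
  train <- setdiff(seq_len(n), holdout)
  samp <- ddinet:::training_samples(emb, pairs[train, ], y_shuf[train],
                                    "concat", ds$catalog)
  model <- train_dnn(samp$values, samp$labels, cfg$dnn, l = l, seed = 5L)
  pred <- predict_pair_types(model, emb, pairs[holdout, ], "concat", ds$catalog)
  acc <- mean(pred$predicted == y_shuf[holdout])
  p0 <- max(tabulate(y_shuf[holdout] + 1L, l)) / length(holdout)
  se <- sqrt(p0 * (1 - p0) / length(holdout))
  expect_lt(acc, p0 + 3 * se)
})

test_that("probabilities are normalized, pure at inference, and orientation invariant", {
  ds <- tiny_dataset(m = 20L, seed = 14L)
  cfg <- tiny_config(cv = list(seed = 14L))
  emb <- build_embedding(ds, cfg, "full")
  pairs <- ds$ddis$pairs
  l <- length(ds$ddis$type_names)
  samp <- ddinet:::training_samples(emb, pairs, pairs$type, "concat", ds$catalog)
  model <- train_dnn(samp$values, samp$labels, cfg$dnn, l = l, seed = 2L)

  X <- aggregate_pairs(emb, pairs, "concat", ds$catalog)
  pr <- predict_proba(model, X)
  expect_equal(unname(rowSums(pr$probs)), rep(1, nrow(pairs)), tolerance = 1e-6)
  # duplicated rows give identical outputs (inference is a pure function)
  Xdup <- rbind(X$values[1, , drop = FALSE], X$values[1, , drop = FALSE])
  prdup <- predict_proba(model, Xdup)
  expect_identical(prdup$probs[1, ], prdup$probs[2, ])
  expect_error(predict_proba(model, X$values[, -1]), "width")

  # symmetric averaging makes the reported score orientation invariant
  fwd <- predict_pair_types(model, emb, pairs[1:10, ], "concat", ds$catalog)
  rev <- predict_pair_types(model, emb,
                            data.frame(drug_a = pairs$drug_b[1:10],
                                       drug_b = pairs$drug_a[1:10]),
                            "concat", ds$catalog)
  expect_equal(fwd$probs, rev$probs)
})

test_that("novel-pair ranking excludes known pairs and enriches the withheld group pair", {
  # noiseless planted data; the target type maps to exactly one group pair,
  # part of which is withheld from the labeled table
  rule <- outer(1:4, 1:4, function(a, b) (a + b - 2L) %% 5L)
  rule[4, 4] <- 4L                      # leave type 1 unique to groups (1,2)
  cfg <- synth_config(m = 40L, n_groups = 4L,
                      dims = c(struct = 60L, target = 40L, pathway = 30L,
                               enzyme = 20L),
                      l = 5L, type_rule = rule, label_noise = 0,
                      pair_density = 0.6, seed = 21L)
  ds <- generate_dataset(cfg)
  pairs <- ds$ddis$pairs
  ia <- match(pairs$drug_a, ds$catalog$drug_ids)
  ib <- match(pairs$drug_b, ds$catalog$drug_ids)
  gpair <- paste(pmin(ds$groups[ia], ds$groups[ib]),
                 pmax(ds$groups[ia], ds$groups[ib]))
  target_gpair <- "1 2"                 # maps to type 1 under the default rule
  type_id <- pairs$type[gpair == target_gpair][1]
  set.seed(31)
  withheld <- sample(which(gpair == target_gpair), 25)
  known <- ddi_table(pairs[-withheld, ], ds$ddis$type_names, ds$catalog)

  pcfg <- tiny_config(cv = list(seed = 21L))
  emb <- build_embedding(ds, pcfg, "full")
  samp <- ddinet:::training_samples(emb, known$pairs, known$pairs$type,
                                    "concat", ds$catalog)
  model <- train_dnn(samp$values, samp$labels, pcfg$dnn,
                     l = length(ds$ddis$type_names), seed = 3L)

  top <- rank_novel_pairs(model, emb, known, type_id, k = 20L, "concat",
                          ds$catalog)
  expect_lte(nrow(top), 20L)
  # no labeled pair may appear
  expect_false(any(ddinet:::pair_key(top$drug_a, top$drug_b) %in%
                     ddinet:::pair_key(known$pairs$drug_a, known$pairs$drug_b)))
  # withheld pairs of the target group pair are enriched in the top list
  wh_keys <- ddinet:::pair_key(pairs$drug_a[withheld], pairs$drug_b[withheld])
  n_cand <- choose(40, 2) - nrow(known$pairs)
  top40 <- rank_novel_pairs(model, emb, known, type_id, k = 40L, "concat",
                            ds$catalog)
  hits <- sum(ddinet:::pair_key(top40$drug_a, top40$drug_b) %in% wh_keys)
  p_enrich <- stats::phyper(hits - 1, length(withheld),
                            n_cand - length(withheld), nrow(top40),
                            lower.tail = FALSE)
  expect_lt(p_enrich, 1e-3)
  expect_error(rank_novel_pairs(model, emb, known, 99L, 5L, "concat",
                                ds$catalog), "type_id")
})
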