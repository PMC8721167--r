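test_that("Jaccard similarity reproduces hand-counted and degenerate cases", {
  catalog <- drug_catalog(paste0("d", 1:4))
  V <- rbind(c(1, 1, 0, 1),
             c(1, 0, 1, 1),
             c(1, 1, 0, 0),
             c(0, 0, 1, 1))
  fm <- feature_matrix(V, "struct", catalog)
  S <- jaccard_similarity(fm)$values
  expect_equal(S[1, 2], 2 / 4)         # shared bits {1,4}, union {1,2,3,4}
  expect_equal(S[3, 4], 0)             # disjoint supports
  expect_equal(unname(diag(S)), rep(1, 4))
  expect_equal(S, t(S))

  # identical nonzero rows are maximally similar
  fm2 <- feature_matrix(rbind(c(1, 0, 1), c(1, 0, 1)), "target",
                        drug_catalog(c("a", "b")))
  expect_equal(jaccard_similarity(fm2)$values["a", "b"], 1)

  # all-zero rows: self-similarity 1, cross-similarity 0
  fm3 <- suppressMessages(feature_matrix(rbind(c(0, 0), c(1, 0)), "enzyme",
                                         drug_catalog(c("a", "b"))))
  S3 <- jaccard_similarity(fm3)$values
  expect_equal(S3["a", "a"], 1)
  expect_equal(S3["a", "b"], 0)
})

test_that("Jaccard agrees exactly with a brute-force set oracle", {
  set.seed(101)
  for (rep in 1:25) {
    m <- sample(3:30, 1); w <- sample(4:40, 1)
    V <- matrix(rbinom(m * w, 1, runif(1, 0.1, 0.6)), m, w)
    fm <- suppressMessages(feature_matrix(V, "struct",
                                          drug_catalog(paste0("d", 1:m))))
    expect_equal(unname(jaccard_similarity(fm)$values), jaccard_oracle(V))
  }
})

test_that("ATC similarity counts common hierarchy levels top-down", {
  catalog <- drug_catalog(c("a", "b", "c", "d", "e"))
  atc <- atc_table(list(a = "B01AC06", b = "B01AC04", c = "B01AC06",
                        d = "C09AA01"))
  S <- atc_similarity(atc, catalog)$values
  expect_equal(S["a", "b"], 0.8)       # B|01|A|C shared, substance differs
  expect_equal(S["a", "c"], 1.0)       # identical codes
  expect_equal(S["a", "d"], 0.0)       # anatomical group differs
  expect_equal(S["a", "e"], 0.0)       # e has no code
  expect_equal(S["e", "e"], 1.0)       # diagonal forced even without codes
  expect_error(atc_table(list(a = "B1AC06")), "malformed")
})

test_that("ATC similarities take only the six hierarchy values; multi-code drugs use the max", {
  catalog <- drug_catalog(c("x", "y"))
  atc <- atc_table(list(x = c("A01AA01", "B02BB02"), y = c("B02BB05")))
  S <- atc_similarity(atc, catalog)$values
  expect_equal(S["x", "y"], 0.8)       # best code pair wins
  ds <- tiny_dataset(m = 20L, seed = 9L)
  vals <- atc_similarity(ds$atc, ds$catalog)$values
  expect_true(all(vals %in% c(0, 0.2, 0.4, 0.6, 0.8, 1)))
})

test_that("the similarity set is complete, ordered, and permutation-equivariant", {
  ds <- tiny_dataset(m = 15L, seed = 4L)
  sims <- build_all_similarities(ds$features, ds$atc, ds$catalog)
  expect_named(sims, c("struct", "target", "pathway", "enzyme", "atc"))
  for (s in sims) {
    expect_equal(dim(s$values), c(15L, 15L))
    expect_equal(s$values, t(s$values))
    expect_equal(unname(diag(s$values)), rep(1, 15))
  }
  # dropping the ATC table yields the four-network variant
  sims4 <- build_all_similarities(ds$features, NULL, ds$catalog)
  expect_named(sims4, c("struct", "target", "pathway", "enzyme"))

  # permuting the drugs permutes every output identically
  perm <- sample(15)
  cat2 <- drug_catalog(ds$catalog$drug_ids[perm])
  feats2 <- lapply(ds$features, function(f) {
    suppressMessages(feature_matrix(f$values[perm, , drop = FALSE],
                                    f$source_name, cat2, f$descriptor_ids))
  })
  sims2 <- build_all_similarities(feats2, ds$atc, cat2)
  for (nm in names(sims)) {
    expect_equal(unname(sims2[[nm]]$values), unname(sims[[nm]]$values[perm, perm]))
  }
})
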