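test_that("leave-one-out folds partition the samples", {
  ids <- paste0("s", 1:16)
  folds <- loo_folds(ids)
  expect_length(folds, 16)
  expect_setequal(vapply(folds, `[[`, character(1), "test"), ids)
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), ids)
  }
  f2 <- loo_folds(c("a", "b"))
  expect_identical(f2[[1]], list(train = "b", test = "a"))
  expect_error(loo_folds(c("a", "a")), "duplicate")
  expect_error(loo_folds("a"), "at least 2")
})

test_that("micro metrics hit their closed-form values on degenerate cases", {
  t <- matrix(c(1, 0, 0, 1), 2)
  expect_equal(multilabel_metrics(t, t, scores = t)$f1, 1)
  expect_equal(multilabel_metrics(t, t, scores = t)$mcc, 1)
  expect_equal(multilabel_metrics(t, t, scores = t)$rocauc, 1)
  comp <- 1 - t
  m <- multilabel_metrics(t, comp)
  expect_equal(m$f1, 0)
  expect_equal(m$mcc, -1)
  # single-class truth: ROC undefined, reported as NA
  ones <- matrix(1, 2, 2)
  expect_true(is.na(multilabel_metrics(ones, ones, scores = ones)$rocauc))
  expect_error(multilabel_metrics(t, t[1, , drop = FALSE]), "shape")
})

test_that("micro metrics equal brute-force confusion counting", {
  withr::with_seed(99, {
    for (rep in 1:30) {
      truth <- matrix(rbinom(16 * 16, 1, 0.3), 16)
      pred <- matrix(rbinom(16 * 16, 1, 0.3), 16)
      scores <- matrix(rnorm(16 * 16), 16)
      got <- multilabel_metrics(truth, pred, scores)
      want <- oracle_micro_metrics(truth, pred)
      for (k in c("tp", "fp", "fn", "tn"))
        expect_equal(got[[k]], want[[k]])
      expect_equal(got$f1, want$f1, tolerance = 1e-12)
      expect_equal(got$mcc, want$mcc, tolerance = 1e-12)
      expect_equal(got$rocauc, oracle_auc(truth, scores), tolerance = 1e-12)
    }
  })
})

test_that("metric pooling is order-free", {
  withr::with_seed(13, {
    truth <- matrix(rbinom(60, 1, 0.4), 10)
    pred <- matrix(rbinom(60, 1, 0.4), 10)
    perm <- sample(10)
    a <- multilabel_metrics(truth, pred)
    b <- multilabel_metrics(truth[perm, ], pred[perm, ])
    expect_equal(a$f1, b$f1)
    expect_equal(a$mcc, b$mcc)
  })
})

test_that("Pearson correlation matches the covariance oracle", {
  expect_equal(pearson_correlation(1:5, 1:5), 1)
  expect_equal(pearson_correlation(-(1:5), 1:5), -1)
  withr::with_seed(4, {
    p <- matrix(rnorm(50), 10)
    t <- matrix(rnorm(50), 10)
    want <- sum((p - mean(p)) * (t - mean(t))) /
      sqrt(sum((p - mean(p))^2) * sum((t - mean(t))^2))
    expect_equal(pearson_correlation(p, t), want, tolerance = 1e-12)
  })
  expect_warning(r <- pearson_correlation(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
  expect_error(pearson_correlation(1, 1), "at least 2")
})

test_that("experiments are reproducible and leak no test data into folds", {
  cfg <- synth_config(n_samples = 8, pool_size = 60,
                      molecules_per_sample = c(20, 30), n_descriptors = 8,
                      n_panelists = 4, seed = 5)
  ds <- generate_dataset(cfg)
  r1 <- run_experiment(ds, "owsum", task = "descriptor", seed = 2)
  r2 <- run_experiment(ds, "owsum", task = "descriptor", seed = 2)
  expect_identical(r1$aggregate, r2$aggregate)
  expect_identical(r1$scores, r2$scores)

  # corrupt the held-out sample's molecules: every fold artifact fitted on
  # the training split must be unchanged for the fold that holds it out
  held <- ds$sample_ids[1]
  ds2 <- ds
  drop_rows <- ds2$composition$sample_id == held &
    !(ds2$composition$molecule_id %in% unlist(ds2$truth$exclusive))
  keep <- which(drop_rows)
  ds2$composition <- ds2$composition[-keep[seq_len(min(10, length(keep)))], ]
  r3 <- run_experiment(ds2, "owsum", task = "descriptor", seed = 2)
  expect_equal(r1$fold_artifacts[[held]]$influence,
               r3$fold_artifacts[[held]]$influence)
  expect_equal(r1$fold_artifacts[[held]]$scaler$mean,
               r3$fold_artifacts[[held]]$scaler$mean)
})

test_that("re-creation never trails leave-one-out for OWSum on planted data", {
  cfg <- synth_config(n_samples = 10, pool_size = 60,
                      molecules_per_sample = c(20, 30), n_descriptors = 8,
                      n_panelists = 4, seed = 9)
  ds <- generate_dataset(cfg)
  loo <- run_experiment(ds, "owsum", task = "type", weighting = "tfidf",
                        variant = "cp1")
  rec <- run_experiment(ds, "owsum", task = "type", mode = "recreation",
                        weighting = "tfidf", variant = "cp1")
  expect_gte(rec$aggregate["accuracy"], loo$aggregate["accuracy"])
})

test_that("the guess report carries frequencies, not trained state", {
  cfg <- synth_config(n_samples = 8, pool_size = 60,
                      molecules_per_sample = c(20, 30), n_descriptors = 8,
                      n_panelists = 4, seed = 5)
  ds <- generate_dataset(cfg)
  r <- run_experiment(ds, "guess", task = "descriptor")
  expect_null(r$fold_artifacts[[1]]$influence)
  expect_true(all(c("frequencies") %in% names(r$fold_artifacts[[1]])))
  # the guess never uses the held-out labels: frequencies differ from the
  # full-data occurrence by at most one per class
  labs <- top5_labels(sum_rata(ds$rata), seed = 1)
  occ_all <- label_occurrence(labs, names(r$fold_artifacts[[1]]$frequencies))
  for (f in names(r$fold_artifacts)) {
    diffs <- occ_all - r$fold_artifacts[[f]]$frequencies[names(occ_all)]
    expect_true(all(diffs %in% 0:1))
  }
})
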