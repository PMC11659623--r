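# toy corpus used throughout: two classes, four samples
toy_features <- list(s1 = c("a", "b"), s2 = c("b", "c"), s3 = "a",
                     s4 = c("c", "d"))
toy_labels <- c("A", "A", "B", "B")

test_that("fit_counts tallies per-class binary occurrences", {
  cts <- fit_counts(list(c("a", "b"), "b"), c("A", "B"))
  expect_equal(cts$occ["A", "a"], 1L)
  expect_equal(cts$occ["A", "b"], 1L)
  expect_equal(cts$occ["B", "b"], 1L)
  expect_equal(unname(cts$class_totals), c(2, 1))
  # multi-label samples count towards every label
  cts2 <- fit_counts(list("a"), list(c("A", "B")))
  expect_equal(unname(cts2$occ[, "a"]), c(1L, 1L))
  # duplicated feature within one sample still counts once
  cts3 <- fit_counts(list(c("a", "a", "b")), "A")
  expect_equal(cts3$occ["A", "a"], 1L)
  expect_error(fit_counts(list(), character(0)), "empty")
})

test_that("conditional probabilities follow their definitions", {
  cts <- fit_counts(toy_features, toy_labels)
  # feature b exclusive to class A
  expect_equal(conditional_probability(cts, "cp1", "A", "b"), 1)
  expect_equal(conditional_probability(cts, "cp1", "B", "b"), 0)
  # direct ratio: occ(A,a)=1, occ(B,a)=1
  expect_equal(conditional_probability(cts, "cp1", "A", "a"), 0.5)
  # cp2: occ(A,b)=2, len(A)=4
  expect_equal(conditional_probability(cts, "cp2", "A", "b"), 0.5)
  # unknown feature contributes nothing
  expect_equal(conditional_probability(cts, "cp1", "A", "zzz"), 0)
  # occ(A,f)=1 against occ(B,f)=3 gives CP1 = 1/4
  cts4 <- fit_counts(list("f", "f", "f", "f"), c("A", "B", "B", "B"))
  expect_equal(conditional_probability(cts4, "cp1", "A", "f"), 0.25)
  # occ(A,f)=2 with len(A)=8 gives CP2 = 1/4
  cts5 <- fit_counts(list(c("f", "p", "q", "r"), c("f", "x", "y", "z")),
                     c("A", "A"))
  expect_equal(conditional_probability(cts5, "cp2", "A", "f"), 0.25)
})

test_that("tf-idf weights match the direct formula and vanish when shared", {
  cts <- fit_counts(toy_features, toy_labels)
  # a occurs in both classes: idf = log10(2/2) = 0
  expect_equal(tfidf_weight(cts, "A", "a"), 0)
  # b exclusive to A: tf = 2/4, idf = log10(2)
  expect_equal(tfidf_weight(cts, "A", "b"), 0.5 * log10(2), tolerance = 1e-12)
  expect_equal(tfidf_weight(cts, "A", "zzz"), 0)
  # linearity in the term frequency: doubling occ at fixed len doubles tf-idf
  c1 <- fit_counts(list(c("f", "g"), c("h", "g"), "h", "h"),
                   c("A", "A", "B", "B"))
  c2 <- fit_counts(list(c("f", "g"), c("f", "h"), "h", "h"),
                   c("A", "A", "B", "B"))
  expect_equal(tfidf_weight(c2, "A", "f"), 2 * tfidf_weight(c1, "A", "f"),
               tolerance = 1e-12)
})

test_that("influence tables equal hand-computed products on the toy corpus", {
  # hand-derived: occ(A,.) = a1 b2 c1, len 4; occ(B,.) = a1 c1 d1, len 3
  fit <- owsum(toy_features, toy_labels, variant = "cp1", weighting = "tfidf")
  infl <- coef(fit)
  expect_equal(infl["A", "b"], 0.5 * log10(2) * 1, tolerance = 1e-12)
  expect_equal(infl["B", "d"], (1 / 3) * log10(2) * 1, tolerance = 1e-12)
  expect_equal(infl["A", "a"], 0)  # idf(a) = 0
  fit2 <- owsum(toy_features, toy_labels, variant = "cp2", weighting = "tfidf")
  expect_equal(coef(fit2)["A", "b"], 0.5 * log10(2) * 0.5, tolerance = 1e-12)
  expect_equal(coef(fit2)["B", "d"], (1 / 3) * log10(2) * (1 / 3),
               tolerance = 1e-12)
})

test_that("same-weighted CP1 columns and CP2 rows normalize to one", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      n <- 12
      feats <- lapply(seq_len(n), function(i)
        sample(letters[1:8], sample(2:5, 1)))
      labs <- sample(c("X", "Y", "Z"), n, replace = TRUE)
      if (length(unique(labs)) < 3) next
      f1 <- owsum(feats, labs, variant = "cp1")
      expect_equal(unname(colSums(coef(f1))), rep(1, ncol(coef(f1))),
                   tolerance = 1e-12)
      f2 <- owsum(feats, labs, variant = "cp2")
      expect_equal(unname(rowSums(coef(f2))), rep(1, nrow(coef(f2))),
                   tolerance = 1e-12)
    }
  })
})

test_that("scores sum influence values and predictions break ties stably", {
  fit <- owsum(toy_features, toy_labels)
  # empty feature set: all scores zero, lexicographic fallback with warning
  expect_warning(p <- predict(fit, list(character(0))), "vocabulary")
  expect_equal(as.vector(p), "A")
  expect_true(attr(p, "zero_score")[1])
  # an exclusive class-A feature under same-weighted CP1 scores 1 vs 0
  sc <- predict(fit, list("b"), type = "score")
  expect_equal(unname(sc[1, ]), c(1, 0))
  # three features sum like hand addition
  sc3 <- predict(fit, list(c("a", "b", "d")), type = "score")
  infl <- coef(fit)
  expect_equal(unname(sc3[1, "A"]), sum(infl["A", c("a", "b", "d")]))
  # k > classes rejected; unknown features ignored
  expect_error(predict(fit, list("a"), k = 5), "exceeds")
  expect_equal(unname(predict(fit, list(c("b", "never-seen")),
                              type = "score")[1, "A"]), 1)
})

test_that("top-k prediction is deterministic under exact ties", {
  scores <- c(z = 0.3, b = 0.5, a = 0.5, m = 0.1)
  expect_identical(mixodor:::top_k(scores, 2), c("a", "b"))
  expect_identical(mixodor:::top_k(scores, 3), c("a", "b", "z"))
})

test_that("influence differences are antisymmetric and dissimilarity symmetric", {
  fit <- owsum(toy_features, toy_labels, weighting = "tfidf")
  d1 <- influence_difference(fit, "b", "A", "B")
  expect_gt(d1, 0)
  expect_equal(influence_difference(fit, "b", "B", "A"), -d1)
  expect_equal(unname(influence_difference(fit, "nope", "A", "B")), 0)
  dd <- descriptor_dissimilarity(fit, "A", "B")
  expect_equal(dd$dissimilarity,
               sum(abs(coef(fit)["A", ] - coef(fit)["B", ])))
  expect_equal(descriptor_dissimilarity(fit, "B", "A")$dissimilarity,
               dd$dissimilarity)
  expect_equal(dd$arc_width, 1.1 ^ (dd$dissimilarity * 1000))
  same <- descriptor_dissimilarity(fit, "A", "A")
  expect_equal(same$dissimilarity, 0)
  expect_equal(same$arc_width, 1)
})

test_that("prediction is invariant to positive rescaling of influences", {
  fit <- owsum(toy_features, toy_labels, weighting = "tfidf")
  newdata <- list(c("a", "b"), c("c", "d"), "c")
  p1 <- predict(fit, newdata, k = 1)
  fit2 <- fit
  fit2$influence <- fit$influence * 37.5
  p2 <- predict(fit2, newdata, k = 1)
  expect_identical(unname(p1), unname(p2))
})

test_that("the scaled presence rule standardizes on training rows only", {
  m <- matrix(0, 10, 3, dimnames = list(NULL, c("f1", "f2", "f3")))
  m[1:2, "f1"] <- 1   # rare feature
  m[, "f2"] <- 1      # constant feature: zero variance
  m[1:6, "f3"] <- 1   # common feature
  sc <- presence_scaler(m)
  # present rare feature -> strongly positive z -> present
  expect_true("f1" %in% scaled_presence(sc, c(1, 1, 0)))
  # constant feature never present
  expect_false("f2" %in% scaled_presence(sc, c(1, 1, 1)))
  # absent common feature -> negative z -> non-present
  expect_false("f3" %in% scaled_presence(sc, c(0, 1, 0)))
  # present common feature -> (1 - 0.6)/sd > 0 -> present
  expect_true("f3" %in% scaled_presence(sc, c(0, 1, 1)))
  expect_error(scaled_presence(sc, c(1, 0)), "dimension")
})

test_that("OWSum survives a JSON round trip intact", {
  fit <- owsum(toy_features, toy_labels, variant = "cp2", weighting = "tfidf")
  tmp <- tempfile(fileext = ".json")
  write_owsum(fit, tmp)
  back <- read_owsum(tmp)
  expect_equal(coef(back), coef(fit))
  expect_identical(back$variant, fit$variant)
  newdata <- list(c("a", "d"), "b")
  expect_identical(unname(predict(back, newdata, k = 1)),
                   unname(predict(fit, newdata, k = 1)))
})
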