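# small deterministic planted problem: class A samples contain pattern-rich
# rows, class B samples do not
planted_stacks <- function(n_per_class = 4, rows = 8, width = 10, seed = 1) {
  withr::with_seed(seed, {
    mk <- function(strong) {
      m <- matrix(rexp(rows * width, 5), rows, width)
      if (strong) m[2:4, 1:3] <- m[2:4, 1:3] + 3
      m
    }
    stacks <- c(lapply(seq_len(n_per_class), function(i) mk(TRUE)),
                lapply(seq_len(n_per_class), function(i) mk(FALSE)))
    names(stacks) <- paste0("s", seq_along(stacks))
    y <- matrix(0, 2 * n_per_class, 2, dimnames = list(names(stacks),
                                                       c("hit", "miss")))
    y[seq_len(n_per_class), "hit"] <- 1
    y[n_per_class + seq_len(n_per_class), "miss"] <- 1
    list(stacks = stacks, y = y)
  })
}

test_that("peak-area scaling multiplies rows and guards its inputs", {
  m <- matrix(1:6, 2, 3)
  expect_equal(scale_features_by_peak_area(m, c(1, 1)), m)
  s <- scale_features_by_peak_area(m, c(2, 1))
  expect_equal(s[1, ], m[1, ] * 2)
  expect_equal(s[2, ], m[2, ])
  withr::with_seed(2, {
    mm <- matrix(rnorm(12), 4)
    aa <- rexp(4) + 0.1
    expect_equal(scale_features_by_peak_area(mm, aa), mm * aa)
  })
  expect_error(scale_features_by_peak_area(m, 1), "one peak area")
  expect_error(scale_features_by_peak_area(m, c(1, -1)), "positive")
  expect_error(scale_features_by_peak_area(m, NULL), "required")
})

test_that("stack_and_pad pads to the batch maximum with an honest mask", {
  b <- list(a = matrix(1, 195, 4), b = matrix(1, 180, 4))
  out <- stack_and_pad(b)
  expect_equal(dim(out$tensor), c(2, 195, 4))
  expect_equal(out$n_rows, c(a = 195L, b = 180L))
  expect_true(all(out$tensor[2, 181:195, ] == 0))
  expect_equal(rowSums(out$mask), c(a = 195, b = 180))
  # single-sample batch needs no padding
  one <- stack_and_pad(b["a"])
  expect_equal(dim(one$tensor)[2], 195)
  # permuting the batch keeps the padded width
  expect_equal(dim(stack_and_pad(rev(b))$tensor)[2], 195)
  expect_error(stack_and_pad(list(matrix(1, 2, 3), matrix(1, 2, 4))),
               "width")
})

test_that("backpropagation matches numerical gradients", {
  withr::with_seed(42, {
    x <- matrix(rnorm(9 * 7), 9, 7)
    p <- mixodor:::init_params(7, 3, 5, 4, 10, 4, seed = 3)
    dout <- rnorm(4)
    g <- mixodor:::cnn_backward_cpp(x, p, dout)
    f <- function(params) sum(mixodor:::cnn_forward_cpp(x, params) * dout)
    eps <- 1e-6
    for (nm in setdiff(names(p), "pool")) {
      for (i in sample(length(p[[nm]]), min(4, length(p[[nm]])))) {
        pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- p; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (f(pp) - f(pm)) / (2 * eps)
        expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                     info = paste("param", nm, "index", i))
      }
    }
  })
})

test_that("appending zero padding rows never changes predictions", {
  pl <- planted_stacks()
  fit <- odor_cnn(pl$stacks, pl$y,
                  cnn_config("classify", epochs = 3, seed = 11))
  s <- pl$stacks[[1]]
  padded <- rbind(s, matrix(0, 10, ncol(s)))
  a <- predict(fit, s, type = "score")
  b <- predict(fit, padded, type = "score")
  expect_identical(a, b)
})

test_that("training is bitwise reproducible for a fixed seed", {
  pl <- planted_stacks()
  cfg <- cnn_config("classify", epochs = 4, seed = 5)
  f1 <- odor_cnn(pl$stacks, pl$y, cfg)
  f2 <- odor_cnn(pl$stacks, pl$y, cfg)
  expect_identical(f1$loss_curve, f2$loss_curve)
  expect_identical(f1$params, f2$params)
  f3 <- odor_cnn(pl$stacks, pl$y, cnn_config("classify", epochs = 4,
                                             seed = 6))
  expect_false(identical(f1$loss_curve, f3$loss_curve))
})

test_that("a zero fold weight removes the class from the loss", {
  pl <- planted_stacks()
  logits <- matrix(rnorm(16), 8, 2)
  l1 <- mixodor:::weighted_bce(logits, pl$y, c(1, 0), 8)
  l2 <- mixodor:::weighted_bce(logits[, 1, drop = FALSE],
                               pl$y[, 1, drop = FALSE], 1, 8)
  # only the surviving class contributes (up to the mean-over-classes factor)
  expect_equal(l1$loss * 2, l2$loss, tolerance = 1e-12)
  expect_true(all(l1$grad[, 2] == 0))
  # doubling a class weight doubles its contribution
  la <- mixodor:::weighted_bce(logits, pl$y, c(2, 1), 8)
  lb <- mixodor:::weighted_bce(logits, pl$y, c(1, 1), 8)
  contrib_a <- la$loss - lb$loss
  lc <- mixodor:::weighted_bce(logits, pl$y, c(3, 1), 8)
  expect_equal(lc$loss - la$loss, contrib_a, tolerance = 1e-12)
})

test_that("the network can overfit a small separable training set", {
  pl <- planted_stacks()
  fit <- odor_cnn(pl$stacks, pl$y,
                  cnn_config("classify", epochs = 120, seed = 3))
  pred <- predict(fit, pl$stacks, k = 1)
  predm <- mixodor:::label_matrix(pred, colnames(pl$y))
  m <- multilabel_metrics(pl$y, predm)
  expect_gte(m$f1, 0.95)
})

test_that("regression mode returns one raw score per descriptor", {
  pl <- planted_stacks()
  targets <- matrix(rexp(8 * 3), 8, 3,
                    dimnames = list(names(pl$stacks), paste0("d", 1:3)))
  fit <- odor_cnn(pl$stacks, targets,
                  cnn_config("regress", epochs = 3, seed = 2))
  out <- predict(fit, pl$stacks[[1]])
  expect_equal(dim(out), c(1, 3))
  expect_identical(colnames(out), paste0("d", 1:3))
  # MSE variant trains too and differs from L1
  fit2 <- odor_cnn(pl$stacks, targets,
                   cnn_config("regress", epochs = 3, loss = "mse", seed = 2))
  expect_false(identical(fit$loss_curve, fit2$loss_curve))
})

test_that("prediction rejects stacks of the wrong width", {
  pl <- planted_stacks()
  fit <- odor_cnn(pl$stacks, pl$y, cnn_config("classify", epochs = 2))
  expect_error(predict(fit, matrix(0, 4, 99)), "width")
  expect_error(odor_cnn(pl$stacks, pl$y[1:3, ]), "one target row")
  expect_error(odor_cnn(pl$stacks, pl$y, class_weights = c(1, 2, 3)),
               "length")
})
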