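#' Configuration of the stack-and-pad CNN
#'
#' Architecture and training defaults for [odor_cnn()]: two 3x3 convolution
#' stages (1 -> 8 -> 16 channels, ReLU), adaptive max pooling to 4x4 over the
#' real (non-padding) molecule rows, then fully connected 256 -> 64 -> output.
#' Classification trains 11 epochs with a class-weighted binary cross-entropy
#' loss; regression trains 21 epochs with L1 (or MSE) loss on raw consensus
#' RATA scores.
#'
#' @param task `"classify"` (top-5 descriptors) or `"regress"` (RATA scores).
#' @param epochs Training epochs; defaults 11 (classification) / 21
#'   (regression).
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size (samples are taken in a seeded order).
#' @param weight_decay Decoupled weight decay coefficient (AdamW-style;
#'   0 disables it).
#' @param conv_channels Output channels of the two convolution stages.
#' @param pool_size Side of the adaptive max-pooling output grid.
#' @param hidden Width of the first fully connected stage.
#' @param feature_scaling Scale each molecule row by its relative peak area
#'   (concentration proxy). Off by default: classification and regression
#'   both work best without it.
#' @param loss `"weighted_bce"` (classification), `"l1"` or `"mse"`
#'   (regression).
#' @param seed Integer seed fixing initialization and data order.
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(task = c("classify", "regress"), epochs = NULL,
                       learning_rate = 1e-3, batch_size = 4,
                       weight_decay = 0, conv_channels = c(8, 16),
                       pool_size = 4, hidden = 64,
                       feature_scaling = FALSE, loss = NULL, seed = 1) {
  task <- match.arg(task)
  if (is.null(epochs)) epochs <- if (task == "classify") 11 else 21
  if (is.null(loss)) loss <- if (task == "classify") "weighted_bce" else "l1"
  loss <- match.arg(loss, c("weighted_bce", "l1", "mse"))
  if (task == "classify" && loss != "weighted_bce")
    stop("classification uses the weighted BCE loss", call. = FALSE)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  structure(list(task = task, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay,
                 conv_channels = conv_channels, pool_size = pool_size,
                 hidden = hidden, feature_scaling = feature_scaling,
                 loss = loss, seed = as.integer(seed)),
            class = "cnn_config")
}

#' Scale a feature stack by relative peak areas
#'
#' Multiplies each molecule row of a sample's applicability stack by the
#' molecule's relative peak area, a proxy for its concentration. Padding
#' rows (all zero) are unaffected by construction.
#'
#' @param stack Numeric molecules-by-patterns matrix (one sample).
#' @param peak_areas Positive numeric vector, one value per molecule row.
#' @return The scaled stack.
#' @export
scale_features_by_peak_area <- function(stack, peak_areas) {
  if (is.null(peak_areas))
    stop("peak areas are required when feature scaling is on", call. = FALSE)
  if (length(peak_areas) != nrow(stack))
    stop("need one peak area per molecule row", call. = FALSE)
  if (any(!is.finite(peak_areas)) || any(peak_areas <= 0))
    stop("peak areas must be positive", call. = FALSE)
  stack * peak_areas
}

#' Stack-and-pad a batch of per-sample feature stacks
#'
#' Each sample's stack has one row per detected molecule (its applicability
#' profile over the pattern vocabulary); samples differ in molecule count, so
#' the batch is zero-padded to the largest row count. A logical mask records
#' which rows are real.
#'
#' @param batch List of molecules-by-patterns matrices sharing a common
#'   pattern-count width.
#' @return A list with `tensor` (samples x max rows x patterns array),
#'   `mask` (samples x max rows logical matrix) and `n_rows` (real row
#'   counts).
#' @export
stack_and_pad <- function(batch) {
  if (!length(batch)) stop("empty batch", call. = FALSE)
  widths <- vapply(batch, ncol, integer(1))
  if (length(unique(widths)) != 1)
    stop("all stacks in a batch must share the pattern-count width",
         call. = FALSE)
  rows <- vapply(batch, nrow, integer(1))
  H <- max(unname(rows))
  W <- unname(widths[1])
  tensor <- array(0, dim = c(length(batch), H, W))
  mask <- matrix(FALSE, length(batch), H)
  for (i in seq_along(batch)) {
    if (rows[i] > 0) {
      tensor[i, seq_len(rows[i]), ] <- batch[[i]]
      mask[i, seq_len(rows[i])] <- TRUE
    }
  }
  if (!is.null(names(batch))) {
    dimnames(tensor) <- list(names(batch), NULL, colnames(batch[[1]]))
    rownames(mask) <- names(batch)
  }
  list(tensor = tensor, mask = mask, n_rows = rows)
}

# drop trailing all-zero rows; the network is defined on this trimmed stack,
# which makes outputs exactly invariant to extra zero-row padding
trim_stack <- function(stack) {
  nz <- which(rowSums(abs(stack)) > 0)
  h <- if (length(nz)) max(nz) else 1L
  stack[seq_len(h), , drop = FALSE]
}

# parameter initialization (He for conv/ReLU stages); P = pooling grid
# c(rows, cols)
init_params <- function(W, C1, C2, P, hidden, n_out, seed) {
  P <- rep(as.integer(P), length.out = 2)
  nflat <- C2 * P[1] * P[2]
  withr::with_seed(seed, {
    p <- list(
      W1 = array(rnorm(3 * 3 * 1 * C1, sd = sqrt(2 / 9)), c(3, 3, 1, C1)),
      b1 = numeric(C1),
      W2 = array(rnorm(3 * 3 * C1 * C2, sd = sqrt(2 / (9 * C1))), c(3, 3, C1, C2)),
      b2 = numeric(C2),
      Wf1 = matrix(rnorm(hidden * nflat, sd = sqrt(2 / nflat)),
                   hidden, nflat),
      bf1 = numeric(hidden),
      Wf2 = matrix(rnorm(n_out * hidden, sd = sqrt(1 / hidden)), n_out, hidden),
      bf2 = numeric(n_out)
    )
    p$pool <- P
    p
  })
}

# class-weighted binary cross-entropy: mean over classes of w_c * BCE_c.
# returns loss and d(loss)/d(logits) for a batch (samples x classes)
weighted_bce <- function(logits, y, w, n_total) {
  p <- 1 / (1 + exp(-logits))
  eps <- 1e-12
  per <- -(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  loss <- sum(sweep(per, 2, w, "*")) / (n_total * length(w))
  grad <- sweep(p - y, 2, w, "*") / (n_total * length(w))
  list(loss = loss, grad = grad)
}

regression_loss <- function(out, y, kind, n_total) {
  d <- out - y
  if (kind == "l1") {
    list(loss = sum(abs(d)) / (n_total * ncol(y)),
         grad = sign(d) / (n_total * ncol(y)))
  } else {
    list(loss = sum(d^2) / (n_total * ncol(y)),
         grad = 2 * d / (n_total * ncol(y)))
  }
}

#' Fit the stack-and-pad CNN
#'
#' Trains a small 2D convolutional network on per-molecule substructure
#' applicability stacks, for multi-label top-5 descriptor classification
#' (class-weighted binary cross-entropy, with weights from
#' [fold_class_weights()]) or RATA-score regression (L1/MSE on consensus
#' scores). Training is deterministic given the config seed: fixed
#' initialization and seeded minibatch order, optimized with Adam.
#'
#' @param train_stacks List of molecules-by-patterns matrices, one per
#'   training sample.
#' @param targets Numeric samples-by-classes matrix: 0/1 indicators
#'   (classification) or non-negative scores (regression). Column names are
#'   the class vocabulary.
#' @param config A [cnn_config()].
#' @param class_weights Per-class weights (classification; default all 1).
#' @param peak_areas Optional list of per-row peak areas, required when
#'   `config$feature_scaling` is on.
#' @return An object of class `odor_cnn` with a [predict.odor_cnn()] method.
#' @export
odor_cnn <- function(train_stacks, targets, config = cnn_config(),
                     class_weights = NULL, peak_areas = NULL) {
  if (!length(train_stacks)) stop("empty training set", call. = FALSE)
  if (length(train_stacks) != nrow(targets))
    stop("one target row per training sample required", call. = FALSE)
  n_out <- ncol(targets)
  if (is.null(class_weights)) class_weights <- rep(1, n_out)
  if (length(class_weights) != n_out)
    stop("class weight vector length must equal the number of classes",
         call. = FALSE)
  if (config$feature_scaling) {
    if (is.null(peak_areas))
      stop("feature scaling requires peak areas", call. = FALSE)
    train_stacks <- Map(scale_features_by_peak_area, train_stacks, peak_areas)
  }
  stacks <- lapply(train_stacks, trim_stack)
  W <- ncol(stacks[[1]])
  C1 <- config$conv_channels[1]; C2 <- config$conv_channels[2]
  P <- config$pool_size
  params <- init_params(W, C1, C2, P, config$hidden, n_out, config$seed)

  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0
  n <- length(stacks)
  bs <- max(1L, min(config$batch_size, n))
  loss_curve <- numeric(config$epochs)

  order_seq <- withr::with_seed(config$seed + 1L, {
    lapply(seq_len(config$epochs), function(e) sample.int(n))
  })

  for (epoch in seq_len(config$epochs)) {
    idx <- order_seq[[epoch]]
    epoch_loss <- 0
    for (start in seq(1, n, by = bs)) {
      batch <- idx[start:min(start + bs - 1, n)]
      outs <- cnn_forward_batch_cpp(stacks[batch], params)
      if (config$loss == "weighted_bce") {
        lg <- weighted_bce(outs, targets[batch, , drop = FALSE],
                           class_weights, length(batch))
      } else {
        lg <- regression_loss(outs, targets[batch, , drop = FALSE],
                              config$loss, length(batch))
      }
      epoch_loss <- epoch_loss + lg$loss * length(batch) / n
      grads <- cnn_backward_batch_cpp(stacks[batch], params,
                                      matrix(lg$grad, nrow = length(batch)))
      grads[["out"]] <- NULL
      step <- step + 1
      for (nmp in setdiff(names(params), "pool")) {
        adam_m[[nmp]] <- b1 * adam_m[[nmp]] + (1 - b1) * grads[[nmp]]
        adam_v[[nmp]] <- b2 * adam_v[[nmp]] + (1 - b2) * grads[[nmp]]^2
        mhat <- adam_m[[nmp]] / (1 - b1^step)
        vhat <- adam_v[[nmp]] / (1 - b2^step)
        params[[nmp]] <- params[[nmp]] -
          config$learning_rate * (mhat / (sqrt(vhat) + eps) +
                                    config$weight_decay * params[[nmp]])
      }
    }
    loss_curve[epoch] <- epoch_loss
  }
  structure(list(params = params, config = config,
                 classes = colnames(targets), width = W,
                 class_weights = class_weights, loss_curve = loss_curve),
            class = "odor_cnn")
}

#' @export
print.odor_cnn <- function(x, ...) {
  cat("<odor CNN> task: ", x$config$task, ", ", length(x$classes),
      " outputs, pattern width ", x$width, "\n", sep = "")
  cat("trained ", x$config$epochs, " epochs; final loss ",
      signif(x$loss_curve[length(x$loss_curve)], 4), "\n", sep = "")
  invisible(x)
}

#' @describeIn odor_cnn Training loss curve.
#' @param x An `odor_cnn` fit.
#' @param ... Passed to `plot`.
#' @export
plot.odor_cnn <- function(x, ...) {
  graphics::plot(seq_along(x$loss_curve), x$loss_curve, type = "b",
                 xlab = "epoch", ylab = "training loss", ...)
  invisible(x)
}

#' Predict descriptors or scores for new feature stacks
#'
#' For classification returns the five classes with the highest output
#' activations per sample (ties broken by descending activation then
#' ascending class name); for regression returns the raw per-descriptor
#' output scores. Trailing all-zero padding rows in a stack never change the
#' output.
#'
#' @param object An [odor_cnn()] fit.
#' @param stacks A single molecules-by-patterns matrix or a list of them.
#' @param k Number of classes returned per sample (classification).
#' @param type `"label"` (classification default), `"score"` for raw
#'   activations.
#' @param peak_areas Optional per-row peak areas (needed when the model was
#'   trained with feature scaling).
#' @param ... Unused.
#' @return A list of top-k label vectors, or a samples-by-classes score
#'   matrix.
#' @export
predict.odor_cnn <- function(object, stacks, k = 5,
                             type = c("label", "score"), peak_areas = NULL,
                             ...) {
  type <- match.arg(type)
  if (is.matrix(stacks)) {
    stacks <- list(stacks)
    if (!is.null(peak_areas) && !is.list(peak_areas))
      peak_areas <- list(peak_areas)
  }
  if (object$config$feature_scaling) {
    if (is.null(peak_areas))
      stop("model was trained with feature scaling; peak areas required",
           call. = FALSE)
    stacks <- Map(scale_features_by_peak_area, stacks, peak_areas)
  }
  bad <- vapply(stacks, function(s) ncol(s) != object$width, logical(1))
  if (any(bad))
    stop("stack width does not match the training pattern vocabulary",
         call. = FALSE)
  scores <- t(vapply(stacks, function(s)
    cnn_forward_cpp(trim_stack(s), object$params),
    numeric(length(object$classes))))
  colnames(scores) <- object$classes
  if (type == "score" || object$config$task == "regress") return(scores)
  lapply(seq_len(nrow(scores)), function(i) top_k(scores[i, ], k))
}
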