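#' Educated top-5 guessing
#'
#' Predicts, for any held-out sample, the five descriptors that occur most
#' frequently across the training label sets; the occurrence frequencies
#' double as ranking scores. Ties at the fifth place are broken
#' lexicographically.
#'
#' @param train_label_sets List of top-5 label sets (training split only).
#' @param descriptors Class vocabulary; defaults to all labels seen in
#'   training.
#' @return A list with `predicted` (ordered 5-descriptor guess) and
#'   `score_vector` (named frequency vector over the vocabulary).
#' @export
educated_guess <- function(train_label_sets, descriptors = NULL) {
  if (is.null(descriptors))
    descriptors <- sort(unique(unlist(train_label_sets)))
  if (length(descriptors) < 5)
    stop("need at least 5 descriptors", call. = FALSE)
  freq <- vapply(descriptors, function(d)
    sum(vapply(train_label_sets, function(l) d %in% l, logical(1))),
    numeric(1))
  list(predicted = top_k(freq, 5), score_vector = freq)
}

#' Inter-subject (Subject-X) performance
#'
#' Treats each panelist in turn as "Subject X": the prediction for a sample
#' is the top-5 of X's own ratings, the ground truth is the top-5 of the
#' summed ratings of all other panelists. Micro metrics are computed per
#' panelist over all samples and then averaged, giving an inter-panelist
#' agreement baseline.
#'
#' @param rata A [rata_table()] with at least 2 panelists.
#' @param seed Seed for tie draws in the top-5 selections.
#' @return A list with `per_panelist` (data.frame of micro F1 / MCC /
#'   precision / ROCAUC per panelist) and `aggregate` (their means).
#' @export
subject_x_metrics <- function(rata, seed = 1) {
  arr <- unclass(rata)
  np <- dim(arr)[1]
  if (np < 2) stop("need at least 2 panelists", call. = FALSE)
  panelists <- dimnames(arr)[[1]]
  samples <- dimnames(arr)[[2]]
  descriptors <- dimnames(arr)[[3]]
  rows <- vector("list", np)
  for (p in seq_len(np)) {
    own <- matrix(arr[p, , ], length(samples), length(descriptors),
                  dimnames = list(samples, descriptors))
    if (any(rowSums(own) == 0))
      warning("panelist ", panelists[p],
              " has all-zero ratings for some sample; tie draw over zeros")
    others <- apply(arr[-p, , , drop = FALSE], c(2, 3), sum)
    dimnames(others) <- list(samples, descriptors)
    pred_sets <- top5_labels(own, seed = seed)
    true_sets <- top5_labels(others, seed = seed + 7919L)
    pred <- label_matrix(pred_sets, descriptors)
    truth <- label_matrix(true_sets, descriptors)
    m <- multilabel_metrics(truth, pred, scores = own)
    rows[[p]] <- data.frame(panelist = panelists[p], f1 = m$f1, mcc = m$mcc,
                            precision = m$precision, rocauc = m$rocauc,
                            stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  list(per_panelist = per,
       aggregate = c(f1 = mean(per$f1), mcc = mean(per$mcc),
                     precision = mean(per$precision),
                     rocauc = mean(per$rocauc, na.rm = TRUE)))
}

# label sets -> binary samples x descriptors matrix
label_matrix <- function(label_sets, descriptors) {
  m <- matrix(0L, length(label_sets), length(descriptors),
              dimnames = list(names(label_sets), descriptors))
  for (i in seq_along(label_sets)) m[i, match(label_sets[[i]], descriptors)] <- 1L
  m
}

#' One-vs-rest SVM / random-forest top-5 baselines
#'
#' Fits, per cross-validation fold and per descriptor, a binary one-vs-rest
#' classifier on molecule-presence features and predicts the top-5
#' descriptors of each test sample by decision score (linear SVM) or
#' positive-class probability (random forest, 100 trees). SVM features are
#' standardized with statistics fitted on the fold's training rows only. A
#' descriptor whose fold training labels are single-class yields a constant
#' score with a warning instead of failing.
#'
#' @param kind `"svm"` or `"rf"`.
#' @param folds List of folds from [loo_folds()] (elements `train`, `test`).
#' @param presence_matrix Binary samples-by-features matrix with row names.
#' @param label_matrix Binary samples-by-descriptors matrix.
#' @param seed Seed for the random forest.
#' @return A list per fold with `sample_id`, `predicted` (top-5) and
#'   `score_vector`.
#' @export
ovr_baseline <- function(kind = c("svm", "rf"), folds, presence_matrix,
                         label_matrix, seed = 1) {
  kind <- match.arg(kind)
  descriptors <- colnames(label_matrix)
  lapply(folds, function(fold) {
    Xtr <- presence_matrix[fold$train, , drop = FALSE]
    Xte <- presence_matrix[fold$test, , drop = FALSE]
    if (kind == "svm") {
      mu <- colMeans(Xtr)
      sg <- apply(Xtr, 2, stats::sd)
      sg[sg == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
      Xte <- sweep(sweep(Xte, 2, mu), 2, sg, "/")
    }
    scores <- vapply(descriptors, function(d) {
      ytr <- factor(label_matrix[fold$train, d], levels = c(0, 1))
      if (length(unique(ytr)) < 2) {
        warning("descriptor '", d, "' is single-class in a fold; ",
                "constant score used")
        return(rep(as.numeric(as.character(ytr[1])), nrow(Xte)))
      }
      tryCatch({
        if (kind == "svm") {
          fit <- e1071::svm(Xtr, ytr, kernel = "linear", scale = FALSE)
          dv <- attr(predict(fit, Xte, decision.values = TRUE),
                     "decision.values")
          # orient decision values so larger means class "1"
          if (colnames(dv)[1] == "0/1") -dv[, 1] else dv[, 1]
        } else {
          fit <- withr::with_seed(seed,
            randomForest::randomForest(Xtr, ytr, ntree = 100))
          predict(fit, Xte, type = "prob")[, "1"]
        }
      }, error = function(e) {
        # degenerate features (e.g. all-constant matrix): constant score
        warning("descriptor '", d, "': classifier degenerate (",
                conditionMessage(e), "); constant score used")
        rep(0, nrow(Xte))
      })
    }, numeric(nrow(Xte)))
    scores <- matrix(scores, nrow = nrow(Xte),
                     dimnames = list(fold$test, descriptors))
    list(sample_id = fold$test,
         predicted = lapply(seq_len(nrow(scores)), function(i)
           top_k(scores[i, ], 5)),
         score_vector = scores)
  })
}
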