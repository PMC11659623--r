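#' Fit an OWSum linear classifier
#'
#' OWSum scores a class for a sample by summing per-feature influence values
#' over the features present in the sample. Influence values are conditional
#' probabilities estimated from training counts, optionally multiplied by
#' tf-idf weights:
#' \deqn{CP1(C_i, F_j) = \#(F_j, C_i) / \sum_n \#(F_j, C_n)}{CP1 = occ(C,F) / sum_n occ(Cn,F)}
#' \deqn{CP2(F_j, C_i) = \#(F_j, C_i) / len(C_i)}{CP2 = occ(C,F) / len(C)}
#' where \eqn{\#(F_j, C_i)} counts training samples of class \eqn{C_i} whose
#' feature set contains \eqn{F_j} and \eqn{len(C_i)} is the total number of
#' feature occurrences in class \eqn{C_i}. The tf-idf weight of a feature in
#' a class is
#' \deqn{tfidf_{i,j} = \frac{\#(F_j,C_i)}{len(C_i)} \cdot
#'   \log\Big(\frac{|C|}{\sum_{C_n : F_j \in C_n} 1}\Big)}
#' so features present in every class get weight exactly 0.
#'
#' @param features A list with one feature set (character vector) per sample,
#'   or a binary sample-by-feature matrix with column names.
#' @param labels Class labels: a character/factor vector (one label per
#'   sample) or a list of character vectors (multi-label, e.g. top-5
#'   descriptor sets).
#' @param variant `"cp1"` (class given feature) or `"cp2"` (feature given
#'   class).
#' @param weighting `"same"` (unweighted) or `"tfidf"`.
#' @param log_base Base of the idf logarithm (default 10; the base rescales
#'   all weights by a constant and cannot change any ranking).
#' @return An object of class `owsum` with methods [predict.owsum()],
#'   [coef.owsum()], [summary.owsum()] and [plot.owsum()].
#' @examples
#' fit <- owsum(list(c("a", "b"), "b", c("a", "c")), c("A", "B", "A"))
#' predict(fit, list(c("a", "c")))
#' @export
owsum <- function(features, labels, variant = c("cp1", "cp2"),
                  weighting = c("same", "tfidf"), log_base = 10) {
  variant <- match.arg(variant)
  weighting <- match.arg(weighting)
  counts <- fit_counts(features, labels)
  infl <- influence_matrix(counts, variant, weighting, log_base)
  structure(list(counts = counts, variant = variant, weighting = weighting,
                 log_base = log_base, influence = infl,
                 call = match.call()),
            class = "owsum")
}

#' Tally feature-class occurrence counts
#'
#' Counts, for every (class, feature) pair, the number of training samples
#' labelled with the class whose feature set contains the feature (binary per
#' sample). Multi-label samples contribute to every one of their classes.
#'
#' @inheritParams owsum
#' @return A list of class `owsum_counts`: `occ` (class-by-feature integer
#'   matrix), `class_totals`, `n_classes`, `feature_class_presence`.
#' @export
fit_counts <- function(features, labels) {
  sets <- .as_feature_sets(features)
  labs <- .as_label_sets(labels)
  if (length(sets) != length(labs))
    stop("features and labels differ in length", call. = FALSE)
  if (!length(sets)) stop("empty training set", call. = FALSE)
  classes <- sort(unique(unlist(labs)))
  if (!length(classes)) stop("no class labels supplied", call. = FALSE)
  feats <- sort(unique(unlist(sets)))
  occ <- matrix(0L, length(classes), length(feats),
                dimnames = list(classes, feats))
  for (s in seq_along(sets)) {
    f <- unique(sets[[s]])
    f <- f[f %in% feats]
    for (cl in labs[[s]]) occ[cl, f] <- occ[cl, f] + 1L
  }
  structure(list(
    occ = occ,
    class_totals = rowSums(occ),
    n_classes = length(classes),
    feature_class_presence = colSums(occ > 0)
  ), class = "owsum_counts")
}

.as_feature_sets <- function(features) {
  if (is.matrix(features)) {
    if (is.null(colnames(features)))
      stop("feature matrix needs column names", call. = FALSE)
    lapply(seq_len(nrow(features)), function(i)
      colnames(features)[features[i, ] > 0])
  } else if (is.list(features)) {
    lapply(features, as.character)
  } else stop("features must be a list of sets or a binary matrix", call. = FALSE)
}

.as_label_sets <- function(labels) {
  if (is.list(labels)) lapply(labels, as.character)
  else lapply(as.character(labels), identity)
}

#' Conditional probability of a class-feature pair
#'
#' @param counts An `owsum_counts` object from [fit_counts()].
#' @param variant `"cp1"` (class given feature) or `"cp2"` (feature given
#'   class).
#' @param class,feature Identifiers. An unknown feature returns 0 under both
#'   variants.
#' @return A probability in \[0, 1\].
#' @export
conditional_probability <- function(counts, variant = c("cp1", "cp2"),
                                    class, feature) {
  variant <- match.arg(variant)
  if (!feature %in% colnames(counts$occ)) return(0)
  if (!class %in% rownames(counts$occ))
    stop("unknown class '", class, "'", call. = FALSE)
  o <- counts$occ[class, feature]
  if (variant == "cp1") {
    tot <- sum(counts$occ[, feature])
    if (tot == 0) 0 else o / tot
  } else {
    o / counts$class_totals[[class]]
  }
}

#' tf-idf weight of a feature in a class
#'
#' Term frequency (feature occurrences in the class over total feature
#' occurrences in the class) times the log-scaled inverse class frequency.
#' Features present in every class get weight exactly 0; a feature absent
#' from the training vocabulary returns 0.
#'
#' @inheritParams conditional_probability
#' @param log_base Logarithm base (default 10).
#' @return A non-negative weight.
#' @export
tfidf_weight <- function(counts, class, feature, log_base = 10) {
  if (!feature %in% colnames(counts$occ)) return(0)
  pres <- counts$feature_class_presence[[feature]]
  if (pres == 0) return(0)
  tf <- counts$occ[class, feature] / counts$class_totals[[class]]
  tf * log(counts$n_classes / pres, base = log_base)
}

# full influence matrix (classes x features)
influence_matrix <- function(counts, variant, weighting, log_base = 10) {
  occ <- counts$occ
  cp <- if (variant == "cp1") {
    tot <- colSums(occ)
    sweep(occ, 2, ifelse(tot == 0, 1, tot), "/")
  } else {
    sweep(occ, 1, counts$class_totals, "/")
  }
  if (weighting == "same") return(cp)
  idf <- log(counts$n_classes / counts$feature_class_presence, base = log_base)
  tf <- sweep(occ, 1, counts$class_totals, "/")
  w <- sweep(tf, 2, idf, "*")
  w * cp
}

#' @describeIn owsum Influence values as a classes-by-features matrix.
#' @param object,x An `owsum` fit.
#' @param ... Unused.
#' @export
coef.owsum <- function(object, ...) object$influence

#' @export
print.owsum <- function(x, ...) {
  cat("OWSum classifier (", toupper(x$variant), ", ", x$weighting,
      "-weighted)\n", sep = "")
  cat("  classes:  ", paste(rownames(x$influence), collapse = ", "), "\n")
  cat("  features: ", ncol(x$influence), "\n")
  invisible(x)
}

#' @export
summary.owsum <- function(object, n_top = 5, ...) {
  infl <- object$influence
  cat("OWSum classifier (", toupper(object$variant), ", ", object$weighting,
      "-weighted), ", nrow(infl), " classes, ", ncol(infl), " features\n",
      sep = "")
  for (cl in rownames(infl)) {
    v <- sort(infl[cl, ], decreasing = TRUE)
    v <- v[v > 0]
    top <- utils::head(v, n_top)
    cat("  ", cl, ": ", paste0(names(top), " (", signif(top, 3), ")",
                               collapse = ", "), "\n", sep = "")
  }
  invisible(object)
}

#' Score and predict classes for new samples
#'
#' A sample's score for a class is the sum of the class's influence values
#' over the features present in the sample; features unseen in training
#' contribute 0. `type = "label"` returns the `k` highest-scoring classes per
#' sample (ties broken by descending score then ascending class name). When
#' all scores are zero the `k` lexicographically first classes are returned
#' and the sample is flagged in the `"zero_score"` attribute.
#'
#' @param object An `owsum` fit.
#' @param newdata List of feature sets or binary matrix (as in [owsum()]).
#' @param k Number of classes to return per sample (`k = 1`: origin-type
#'   prediction; `k = 5`: top-5 descriptor prediction).
#' @param type `"label"` for top-k classes, `"score"` for the full score
#'   matrix.
#' @param ... Unused.
#' @return For `"label"`: a list of ordered character vectors (length `k`),
#'   with attribute `"zero_score"`; simplified to a vector when `k = 1`.
#'   For `"score"`: a samples-by-classes numeric matrix.
#' @export
predict.owsum <- function(object, newdata, k = 1,
                          type = c("label", "score"), ...) {
  type <- match.arg(type)
  sets <- .as_feature_sets(newdata)
  infl <- object$influence
  scores <- t(vapply(sets, function(f) score_features(object, f),
                     numeric(nrow(infl))))
  colnames(scores) <- rownames(infl)
  if (type == "score") return(scores)
  if (k > ncol(scores)) stop("k exceeds the number of classes", call. = FALSE)
  zero <- apply(scores, 1, function(s) all(s == 0))
  if (any(zero))
    warning(sum(zero), " sample(s) share no feature with the training ",
            "vocabulary; returning lexicographically first classes")
  labs <- lapply(seq_len(nrow(scores)), function(i) top_k(scores[i, ], k))
  if (k == 1) {
    out <- vapply(labs, `[`, character(1), 1)
  } else out <- labs
  attr(out, "zero_score") <- zero
  out
}

# sum of influence values of present features for every class
score_features <- function(object, features) {
  infl <- object$influence
  f <- unique(as.character(features))
  f <- f[f %in% colnames(infl)]
  if (!length(f)) return(setNames(numeric(nrow(infl)), rownames(infl)))
  rowSums(infl[, f, drop = FALSE])
}

# deterministic top-k: score descending, then name ascending
top_k <- function(scores, k) {
  nm <- names(scores)
  ord <- order(-scores, nm, method = "radix")
  nm[ord][seq_len(k)]
}

#' Influence difference of a feature between two classes
#'
#' The signed difference `influence(class_a, feature) - influence(class_b,
#' feature)`; positive values push the classification towards `class_a`.
#' Antisymmetric under swapping the classes; unknown features give 0.
#'
#' @param object An `owsum` fit.
#' @param feature Feature identifier (vectorized).
#' @param class_a,class_b Class identifiers.
#' @return Signed numeric vector.
#' @export
influence_difference <- function(object, feature, class_a, class_b) {
  infl <- object$influence
  if (!all(c(class_a, class_b) %in% rownames(infl)))
    stop("unknown class", call. = FALSE)
  vapply(feature, function(f) {
    if (!f %in% colnames(infl)) return(0)
    infl[class_a, f] - infl[class_b, f]
  }, numeric(1))
}

#' Molecular dissimilarity between two classes
#'
#' Sums the absolute influence-value differences over all features, giving a
#' symmetric dissimilarity between two classes' molecular importance
#' profiles, plus the arc-width transform used to draw it
#' (`1.1 ^ (dissimilarity * 1000)`).
#'
#' @inheritParams influence_difference
#' @return A list with `dissimilarity` and `arc_width`.
#' @export
descriptor_dissimilarity <- function(object, class_a, class_b) {
  infl <- object$influence
  if (!all(c(class_a, class_b) %in% rownames(infl)))
    stop("unknown class", call. = FALSE)
  d <- sum(abs(infl[class_a, ] - infl[class_b, ]))
  list(dissimilarity = d, arc_width = 1.1 ^ (d * 1000))
}

#' @describeIn owsum Dot chart of the strongest influence differences between
#'   two classes (positive bars pull towards `class_a`).
#' @param class_a,class_b Classes to contrast (defaults: first two).
#' @param n_top Number of features shown.
#' @export
plot.owsum <- function(x, class_a = rownames(x$influence)[1],
                       class_b = rownames(x$influence)[2], n_top = 15, ...) {
  d <- x$influence[class_a, ] - x$influence[class_b, ]
  d <- d[order(abs(d), decreasing = TRUE)]
  d <- rev(utils::head(d[d != 0], n_top))
  graphics::dotchart(unname(d), labels = names(d),
                     xlab = sprintf("influence difference (%s - %s)",
                                    class_a, class_b), ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

# --- fold-wise presence scaling --------------------------------------------

#' Standard-scaling presence rule
#'
#' Fits per-feature means and standard deviations on a training presence
#' matrix (rows = samples). [scaled_presence()] then declares a feature
#' present for a sample exactly when its standardized value `(x - mean) / sd`
#' is positive; zero-variance features are treated as non-present. Fitting on
#' the training rows of the active fold only keeps test information out of
#' the scaler.
#'
#' @param train_matrix Numeric samples-by-features matrix with column names.
#' @return An object of class `presence_scaler`.
#' @export
presence_scaler <- function(train_matrix) {
  if (is.null(colnames(train_matrix)))
    stop("presence matrix needs column names", call. = FALSE)
  structure(list(
    mean = colMeans(train_matrix),
    sd = apply(train_matrix, 2, stats::sd),
    features = colnames(train_matrix)
  ), class = "presence_scaler")
}

#' @rdname presence_scaler
#' @param scaler A fitted `presence_scaler`.
#' @param x A numeric vector (one sample) or samples-by-features matrix with
#'   the scaler's feature columns.
#' @return For a vector, the character set of present features; for a matrix,
#'   a list of such sets.
#' @export
scaled_presence <- function(scaler, x) {
  if (is.matrix(x)) {
    if (!identical(colnames(x), scaler$features))
      stop("feature columns do not match the scaler", call. = FALSE)
    return(lapply(seq_len(nrow(x)), function(i) scaled_presence(scaler, x[i, ])))
  }
  if (length(x) != length(scaler$features))
    stop("feature dimension mismatch", call. = FALSE)
  ok <- scaler$sd > 0
  z <- (x - scaler$mean) / ifelse(ok, scaler$sd, 1)
  scaler$features[ok & z > 0]
}
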