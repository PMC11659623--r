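#' Leave-one-out folds
#'
#' @param sample_ids Unique sample identifiers (n >= 2).
#' @return A list of `n` folds, each `list(train = ids[-i], test = ids[i])`;
#'   every sample appears in the test position exactly once.
#' @export
loo_folds <- function(sample_ids) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  if (length(sample_ids) < 2) stop("need at least 2 samples", call. = FALSE)
  lapply(seq_along(sample_ids), function(i)
    list(train = sample_ids[-i], test = sample_ids[i]))
}

# micro ROCAUC over flattened (truth, score) pairs; NA when truth is
# single-class (undefined, not 0)
micro_roc_auc <- function(truth, scores) {
  t <- as.vector(truth); s <- as.vector(scores)
  n1 <- sum(t == 1); n0 <- sum(t == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(s, ties.method = "average")
  (sum(r[t == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Micro-pooled multi-label metrics
#'
#' Pools the binary confusion counts over every (sample, class) cell and
#' computes micro precision, recall, F1 and MCC in closed form; when a score
#' matrix is supplied, a micro ROCAUC over the flattened (truth, score)
#' pairs is added (NA when the flattened truth is single-class, where the
#' ROC is undefined).
#'
#' @param true_matrix,pred_matrix Binary samples-by-classes matrices of the
#'   same shape.
#' @param scores Optional numeric score matrix of the same shape.
#' @return A list with `tp`, `fp`, `fn`, `tn`, `precision`, `recall`, `f1`,
#'   `mcc`, `accuracy` and `rocauc`.
#' @export
multilabel_metrics <- function(true_matrix, pred_matrix, scores = NULL) {
  if (!all(dim(true_matrix) == dim(pred_matrix)))
    stop("shape mismatch between truth and prediction", call. = FALSE)
  t <- as.vector(true_matrix) > 0
  p <- as.vector(pred_matrix) > 0
  # double precision: the MCC denominator overflows integer range easily
  tp <- as.numeric(sum(t & p)); fp <- as.numeric(sum(!t & p))
  fn <- as.numeric(sum(t & !p)); tn <- as.numeric(sum(!t & !p))
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else
    (tp * tn - fp * fn) / sqrt(den)
  rocauc <- if (is.null(scores)) NA_real_ else {
    if (!all(dim(scores) == dim(true_matrix)))
      stop("shape mismatch between truth and scores", call. = FALSE)
    micro_roc_auc(true_matrix, scores)
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn, precision = precision,
       recall = recall, f1 = f1, mcc = mcc,
       accuracy = (tp + tn) / length(t), rocauc = rocauc)
}

#' Pearson correlation between prediction and truth matrices
#'
#' Flattens both matrices over all (sample, descriptor) cells and returns
#' the product-moment correlation; constant input makes the correlation
#' undefined and returns NA with a warning.
#'
#' @param pred,truth Numeric matrices (or vectors) of equal shape.
#' @return A correlation in \[-1, 1\], or NA when undefined.
#' @export
pearson_correlation <- function(pred, truth) {
  p <- as.vector(pred); t <- as.vector(truth)
  if (length(p) != length(t)) stop("shape mismatch", call. = FALSE)
  if (length(p) < 2) stop("need at least 2 values", call. = FALSE)
  if (stats::sd(p) == 0 || stats::sd(t) == 0) {
    warning("constant input; Pearson correlation undefined")
    return(NA_real_)
  }
  stats::cor(p, t)
}

# molecule presence: samples x molecules binary matrix from a composition
# table (columns sample_id, molecule_id)
presence_matrix <- function(composition, sample_ids = NULL,
                            molecule_ids = NULL) {
  s <- if (is.null(sample_ids)) sort(unique(composition$sample_id)) else sample_ids
  m <- if (is.null(molecule_ids)) sort(unique(composition$molecule_id)) else molecule_ids
  out <- matrix(0L, length(s), length(m), dimnames = list(s, m))
  out[cbind(match(composition$sample_id, s),
            match(composition$molecule_id, m))] <- 1L
  out
}

#' Per-sample applicability feature stacks
#'
#' Extracts, for each sample, the applicability rows of its detected
#' molecules from the global applicability matrix (rows ordered by the
#' matrix's molecule order, so a molecule keeps a stable position across
#' samples), together with the matching relative peak areas.
#'
#' @param composition Composition table (`sample_id`, `molecule_id`,
#'   optional `peak_area`).
#' @param applicability An [build_applicability_matrix()] result whose rows
#'   cover the detected molecules.
#' @return A list with `stacks` (named list of per-sample matrices) and
#'   `peak_areas` (named list of per-row area vectors, NULL-free only if the
#'   composition has areas).
#' @export
build_sample_stacks <- function(composition, applicability) {
  samples <- sort(unique(composition$sample_id))
  has_area <- "peak_area" %in% names(composition) &&
    !all(is.na(composition$peak_area))
  stacks <- list(); areas <- list()
  for (s in samples) {
    rows <- composition[composition$sample_id == s, , drop = FALSE]
    ix <- match(rows$molecule_id, rownames(applicability))
    if (anyNA(ix))
      stop("molecule(s) of sample ", s, " missing from applicability matrix",
           call. = FALSE)
    ord <- order(ix)
    stacks[[s]] <- unclass(applicability)[ix[ord], , drop = FALSE]
    areas[[s]] <- if (has_area) rows$peak_area[ord] else NULL
  }
  list(stacks = stacks, peak_areas = if (has_area) areas else NULL)
}

#' Run a full evaluation experiment
#'
#' Orchestrates the evaluation protocol for one method on one dataset:
#' builds the task's features and labels, iterates the folds (leave-one-out
#' by default, or re-creation with train = test), fits every fold-specific
#' artifact (tf-idf influence tables, presence scalers, class weights, CNN
#' states) on the fold's training split only, and pools the per-fold test
#' predictions into aggregate micro metrics.
#'
#' @param dataset A dataset as produced by [generate_dataset()] (or an
#'   equivalent list with `composition`, `rata`, `type`, `sample_ids`,
#'   `descriptors`).
#' @param method One of `"owsum"`, `"cnn"`, `"svm"`, `"rf"`, `"guess"`,
#'   `"subjectx"`.
#' @param task `"type"` (binary origin classification, OWSum),
#'   `"descriptor"` (top-5 multi-label classification) or `"regression"`
#'   (RATA consensus scores, CNN).
#' @param mode `"loo"` or `"recreation"` (same data for train and test).
#' @param variant,weighting,scaled_presence OWSum options; the presence
#'   scaling rule defaults to on for the descriptor task only.
#' @param cnn A [cnn_config()] for the CNN method.
#' @param features Precomputed output of [build_sample_stacks()] (CNN); when
#'   NULL the stacks are built from `dataset$applicability` or a reference
#'   pool drawn from the dataset.
#' @param label_seed Seed of the fixed top-5 label selection.
#' @param seed Seed for fold-level randomness (forest, tie draws).
#' @return A list of class `metrics_report`: `method`, `task`, `mode`,
#'   `per_fold`, `aggregate`, `pcc` (regression), `fold_artifacts`, `seeds`.
#' @export
run_experiment <- function(dataset, method = c("owsum", "cnn", "svm", "rf",
                                               "guess", "subjectx"),
                           task = c("descriptor", "type", "regression"),
                           mode = c("loo", "recreation"),
                           variant = "cp2", weighting = "tfidf",
                           scaled_presence = NULL, cnn = cnn_config(),
                           features = NULL, label_seed = 1, seed = 1) {
  method <- match.arg(method)
  task <- match.arg(task)
  mode <- match.arg(mode)
  if (task == "type" && method != "owsum")
    stop("the origin-type task is evaluated with OWSum", call. = FALSE)
  if (task == "regression" && method != "cnn")
    stop("the regression task is evaluated with the CNN", call. = FALSE)
  if (is.null(scaled_presence)) scaled_presence <- task == "descriptor"

  ids <- dataset$sample_ids
  folds <- if (mode == "loo") loo_folds(ids)
           else lapply(ids, function(i) list(train = ids, test = i))

  consensus <- sum_rata(dataset$rata)
  label_sets <- top5_labels(consensus, seed = label_seed)
  occ <- label_occurrence(label_sets, dataset$descriptors)
  vocab <- dataset$descriptors
  for (d in names(occ)[occ == 0])
    vocab <- remove_class(label_sets, vocab, d)$descriptors
  Y <- label_matrix(label_sets, vocab)[ids, , drop = FALSE]
  pres <- presence_matrix(dataset$composition, sample_ids = ids)

  report <- list(method = method, task = task, mode = mode,
                 seeds = c(label_seed = label_seed, seed = seed),
                 fold_artifacts = list())

  if (method == "subjectx") {
    sx <- subject_x_metrics(dataset$rata, seed = seed)
    report$per_fold <- sx$per_panelist
    report$aggregate <- sx$aggregate
    class(report) <- "metrics_report"
    return(report)
  }

  if (task == "type") {
    sets <- .as_feature_sets(pres)
    names(sets) <- ids
    truth <- dataset$type[ids]
    preds <- character(length(ids)); names(preds) <- ids
    for (f in folds) {
      fit <- owsum(sets[f$train], truth[f$train], variant = variant,
                   weighting = weighting)
      preds[f$test] <- predict(fit, sets[f$test], k = 1)
      report$fold_artifacts[[f$test]] <- list(influence = coef(fit))
    }
    report$per_fold <- data.frame(sample_id = ids, true = unname(truth),
                                  predicted = unname(preds),
                                  correct = unname(preds == truth))
    report$aggregate <- c(accuracy = mean(preds == truth))
    class(report) <- "metrics_report"
    return(report)
  }

  if (task == "regression") {
    targets <- consensus[ids, , drop = FALSE]
    stacks <- default_feature_stacks(dataset, features)
    pred <- matrix(NA_real_, length(ids), ncol(targets),
                   dimnames = dimnames(targets))
    for (f in folds) {
      fit <- odor_cnn(stacks$stacks[f$train], targets[f$train, , drop = FALSE],
                      config = cnn, peak_areas = stacks$peak_areas[f$train])
      pred[f$test, ] <- predict(fit, stacks$stacks[[f$test]], type = "score",
                                peak_areas = stacks$peak_areas[[f$test]])
    }
    report$pcc <- pearson_correlation(pred, targets)
    report$per_fold <- data.frame(
      sample_id = ids,
      pcc = vapply(ids, function(s) suppressWarnings(
        pearson_correlation(pred[s, ], targets[s, ])), numeric(1)))
    report$aggregate <- c(pcc = report$pcc)
    class(report) <- "metrics_report"
    return(report)
  }

  # descriptor classification
  pred <- matrix(0L, length(ids), ncol(Y), dimnames = dimnames(Y))
  scores <- matrix(NA_real_, length(ids), ncol(Y), dimnames = dimnames(Y))
  per_fold <- list()
  if (method %in% c("svm", "rf")) {
    fp <- ovr_baseline(method, folds, pres, Y, seed = seed)
    for (k in seq_along(folds)) {
      s <- folds[[k]]$test
      pred[s, match(fp[[k]]$predicted[[1]], colnames(Y))] <- 1L
      scores[s, ] <- fp[[k]]$score_vector[1, colnames(Y)]
    }
  } else if (method == "guess") {
    for (f in folds) {
      g <- educated_guess(label_sets[f$train], vocab)
      pred[f$test, match(g$predicted, colnames(Y))] <- 1L
      scores[f$test, ] <- g$score_vector[colnames(Y)]
      report$fold_artifacts[[f$test]] <- list(frequencies = g$score_vector)
    }
  } else if (method == "owsum") {
    for (f in folds) {
      if (scaled_presence) {
        scaler <- presence_scaler(pres[f$train, , drop = FALSE])
        train_sets <- scaled_presence(scaler, pres[f$train, , drop = FALSE])
        test_sets <- list(scaled_presence(scaler, pres[f$test, ]))
      } else {
        scaler <- NULL
        train_sets <- .as_feature_sets(pres[f$train, , drop = FALSE])
        test_sets <- .as_feature_sets(pres[f$test, , drop = FALSE])
      }
      fit <- owsum(train_sets, label_sets[f$train], variant = variant,
                   weighting = weighting)
      sc <- predict(fit, test_sets, type = "score")
      full <- setNames(numeric(ncol(Y)), colnames(Y))
      full[intersect(colnames(sc), names(full))] <-
        sc[1, intersect(colnames(sc), names(full))]
      scores[f$test, ] <- full
      pred[f$test, match(top_k(full, 5), colnames(Y))] <- 1L
      report$fold_artifacts[[f$test]] <-
        list(influence = coef(fit), scaler = scaler)
    }
  } else {  # cnn
    stacks <- default_feature_stacks(dataset, features)
    for (f in folds) {
      w <- fold_class_weights(label_sets[f$train], label_sets, colnames(Y))
      cfg <- cnn
      fit <- odor_cnn(stacks$stacks[f$train], Y[f$train, , drop = FALSE],
                      config = cfg, class_weights = w,
                      peak_areas = stacks$peak_areas[f$train])
      sc <- predict(fit, stacks$stacks[[f$test]], type = "score",
                    peak_areas = stacks$peak_areas[[f$test]])
      scores[f$test, ] <- sc[1, colnames(Y)]
      pred[f$test, match(top_k(sc[1, ], 5), colnames(Y))] <- 1L
      report$fold_artifacts[[f$test]] <- list(class_weights = w)
    }
  }
  report$aggregate <- multilabel_metrics(Y, pred, scores)
  report$per_fold <- do.call(rbind, lapply(seq_along(ids), function(i) {
    m <- multilabel_metrics(Y[i, , drop = FALSE], pred[i, , drop = FALSE],
                            scores[i, , drop = FALSE])
    data.frame(sample_id = ids[i], f1 = m$f1, mcc = m$mcc,
               rocauc = m$rocauc)
  }))
  report$truth <- Y
  report$predicted <- pred
  report$scores <- scores
  class(report) <- "metrics_report"
  report
}

#' Default CNN feature stacks for a dataset
#'
#' Builds the stack features [run_experiment()] uses for the CNN when none
#' are supplied: MCS patterns from a seeded 24-molecule reference subset of
#' the dataset's pool, applicability rows for every pool molecule, stack
#' rows ordered chemically (family, size, structure) so related molecules
#' sit on adjacent rows.
#'
#' @param dataset A dataset as produced by [generate_dataset()].
#' @param features Optional precomputed [build_sample_stacks()] output,
#'   returned unchanged.
#' @return A [build_sample_stacks()] result.
#' @export
default_feature_stacks <- function(dataset, features = NULL) {
  if (!is.null(features)) return(features)
  if (!is.null(dataset$feature_stacks)) return(dataset$feature_stacks)
  app <- dataset$applicability
  if (is.null(app)) {
    p <- dataset$pool
    ref_n <- min(24L, nrow(p))
    ref <- withr::with_seed(dataset$config$seed %||% 1L,
                            sample(p$molecule_id, ref_n))
    pats <- pairwise_mcs(setNames(p$smiles[match(ref, p$molecule_id)], ref))
    # order molecules chemically (family, size, structure) so that related
    # molecules occupy adjacent stack rows
    if (!is.null(p$family)) {
      n_heavy <- vapply(p$smiles, function(sm)
        nchar(gsub("[^A-Z]", "", sm)), numeric(1))
      p <- p[order(p$family, n_heavy, p$smiles), , drop = FALSE]
    }
    mols <- setNames(p$smiles, p$molecule_id)
    app <- build_applicability_matrix(mols, pats)
  }
  build_sample_stacks(dataset$composition, app)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics report> method: ", x$method, ", task: ", x$task,
      ", mode: ", x$mode, "\n", sep = "")
  agg <- x$aggregate
  if (is.list(agg))
    agg <- unlist(agg[c("f1", "mcc", "rocauc", "precision", "recall")])
  cat(paste(sprintf("%s = %.4g", names(agg), agg), collapse = ", "), "\n")
  invisible(x)
}
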