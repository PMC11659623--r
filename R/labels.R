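#' RATA rating table
#'
#' A rate-all-that-apply (RATA) table holds integer intensity ratings per
#' (panelist, sample, descriptor); a rating of 0 means the panelist did not
#' select the descriptor. Each panelist may rate at most 5 descriptors with
#' nonzero intensity per sample.
#'
#' @param ratings Either a 3-d array `[panelist, sample, descriptor]` with
#'   dimnames, or a long data.frame with columns `panelist_id`, `sample_id`,
#'   `descriptor`, `rating` (absent triples are 0).
#' @param panelists,samples,descriptors Optional identifier vectors fixing
#'   the table dimensions (useful when the long form does not mention every
#'   level).
#' @return A 3-d integer array of class `rata_table`.
#' @export
rata_table <- function(ratings, panelists = NULL, samples = NULL,
                       descriptors = NULL) {
  if (is.data.frame(ratings)) {
    need <- c("panelist_id", "sample_id", "descriptor", "rating")
    if (!all(need %in% names(ratings)))
      stop("long RATA input needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    p <- if (is.null(panelists)) sort(unique(as.character(ratings$panelist_id))) else panelists
    s <- if (is.null(samples)) sort(unique(as.character(ratings$sample_id))) else samples
    d <- if (is.null(descriptors)) sort(unique(as.character(ratings$descriptor))) else descriptors
    arr <- array(0L, dim = c(length(p), length(s), length(d)),
                 dimnames = list(p, s, d))
    idx <- cbind(match(as.character(ratings$panelist_id), p),
                 match(as.character(ratings$sample_id), s),
                 match(as.character(ratings$descriptor), d))
    if (anyNA(idx)) stop("ratings mention unknown identifiers", call. = FALSE)
    arr[idx] <- as.integer(ratings$rating)
  } else if (is.array(ratings) && length(dim(ratings)) == 3) {
    arr <- ratings
    storage.mode(arr) <- "integer"
    if (is.null(dimnames(arr)))
      dimnames(arr) <- list(paste0("panelist", seq_len(dim(arr)[1])),
                            paste0("sample", seq_len(dim(arr)[2])),
                            paste0("descriptor", seq_len(dim(arr)[3])))
  } else stop("ratings must be a long data.frame or a 3-d array", call. = FALSE)
  if (any(arr < 0)) stop("negative RATA ratings", call. = FALSE)
  nz <- apply(arr > 0, c(1, 2), sum)
  if (any(nz > 5))
    stop("a panelist rated more than 5 descriptors for one sample",
         call. = FALSE)
  structure(arr, class = "rata_table")
}

#' @export
print.rata_table <- function(x, ...) {
  d <- dim(x)
  cat("<RATA table> ", d[1], " panelists x ", d[2], " samples x ", d[3],
      " descriptors; ", sum(x > 0), " nonzero ratings\n", sep = "")
  invisible(x)
}

#' Sum RATA ratings across panelists
#'
#' The consensus score of a descriptor for a sample is the exact integer sum
#' of all panelists' ratings; descriptors never rated get 0.
#'
#' @param table A [rata_table()].
#' @return An integer samples-by-descriptors matrix.
#' @export
sum_rata <- function(table) {
  if (!inherits(table, "rata_table")) table <- rata_table(table)
  apply(unclass(table), c(2, 3), sum)
}

#' Top-5 descriptor labels for a sample
#'
#' Picks the five descriptors with the highest consensus score. Descriptors
#' strictly above the fifth-place score are always included; ties across the
#' fifth-place boundary are resolved by a seeded uniform draw among exactly
#' the tied candidates, so the same seed reproduces the same label sets.
#'
#' @param scores Consensus score matrix from [sum_rata()] (or any
#'   samples-by-descriptors numeric matrix).
#' @param sample Sample id (row name) or row index; omit to label every
#'   sample.
#' @param seed Integer seed for the tie draw.
#' @return For one sample, a character vector of 5 descriptors; otherwise a
#'   named list of such vectors.
#' @export
top5_labels <- function(scores, sample = NULL, seed = 1) {
  if (ncol(scores) < 5)
    stop("need at least 5 descriptors in the vocabulary", call. = FALSE)
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("descriptor", seq_len(ncol(scores)))
  if (is.null(rownames(scores)))
    rownames(scores) <- paste0("sample", seq_len(nrow(scores)))
  if (is.null(sample)) {
    out <- lapply(rownames(scores), function(s) top5_labels(scores, s, seed))
    names(out) <- rownames(scores)
    return(out)
  }
  v <- scores[sample, ]
  nm <- colnames(scores)
  ord <- order(-v, nm, method = "radix")
  cut_val <- v[ord[5]]
  sure <- nm[v > cut_val]
  tied <- nm[v == cut_val]
  need <- 5 - length(sure)
  picked <- if (length(tied) == need) tied else {
    # per-sample deterministic tie draw: seed offset by the sample's position
    srow <- if (is.character(sample)) match(sample, rownames(scores)) else sample
    withr::with_seed(as.integer(seed) + srow * 131L,
                     sample(tied, need))
  }
  labs <- c(sure, picked)
  labs[order(match(labs, nm))]
}

#' Drop a descriptor class from the classification vocabulary
#'
#' Removes a descriptor from the label vocabulary used for classification
#' (the regression task keeps all descriptors). To prevent silent label
#' corruption the descriptor must not occur in any computed label set; drop
#' a descriptor that was never selected into a top-5 set (e.g. one tied out
#' by the seeded draw).
#'
#' @param label_sets Named list of top-5 label sets from [top5_labels()].
#' @param descriptors Character vector, the current vocabulary.
#' @param descriptor The descriptor to remove.
#' @return A list with the (unchanged) `label_sets` and the reduced
#'   `descriptors` vocabulary.
#' @export
remove_class <- function(label_sets, descriptors, descriptor) {
  if (!descriptor %in% descriptors) {
    warning("descriptor '", descriptor, "' not in vocabulary; nothing to drop")
    return(list(label_sets = label_sets, descriptors = descriptors))
  }
  hit <- vapply(label_sets, function(l) descriptor %in% l, logical(1))
  if (any(hit))
    stop("descriptor '", descriptor, "' occurs in ", sum(hit),
         " label set(s); refusing to drop it", call. = FALSE)
  list(label_sets = label_sets,
       descriptors = setdiff(descriptors, descriptor))
}

#' Inverse-frequency class weights for one cross-validation fold
#'
#' For each descriptor, with `x` its frequency among the fold's training
#' label sets and `y` its frequency in the full dataset, the loss weight is
#' 0 when `x = 0` and `log(1 + y/x)` otherwise, so rare classes get larger
#' weights. Weights are computed for each fold independently.
#'
#' @param train_label_sets List of label sets in the fold's training split.
#' @param all_label_sets List of label sets for the full dataset.
#' @param descriptors Class vocabulary; defaults to all labels seen overall.
#' @param log_base Logarithm base (default natural log).
#' @return Named non-negative weight vector over `descriptors`.
#' @export
fold_class_weights <- function(train_label_sets, all_label_sets,
                               descriptors = NULL, log_base = exp(1)) {
  if (is.null(descriptors))
    descriptors <- sort(unique(unlist(all_label_sets)))
  cnt <- function(sets) vapply(descriptors, function(d)
    sum(vapply(sets, function(l) d %in% l, logical(1))), numeric(1))
  x <- cnt(train_label_sets)
  y <- cnt(all_label_sets)
  ifelse(x == 0, 0, log(1 + y / x, base = log_base))
}

#' Occurrence of each descriptor across top-5 label sets
#'
#' @param label_sets List of top-5 label sets.
#' @param descriptors Vocabulary (defaults to all labels seen).
#' @return Named integer vector; its values always sum to
#'   `5 * length(label_sets)`.
#' @export
label_occurrence <- function(label_sets, descriptors = NULL) {
  if (is.null(descriptors))
    descriptors <- sort(unique(unlist(label_sets)))
  vapply(descriptors, function(d)
    sum(vapply(label_sets, function(l) d %in% l, logical(1))), integer(1))
}
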