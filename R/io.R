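#' Read and write mixture composition tables
#'
#' The composition CSV has one row per (sample, molecule) with columns
#' `sample_id`, `molecule_id`, `smiles` and optionally `peak_area`. On
#' reading, SMILES are canonicalized and duplicate (sample, canonical
#' molecule) rows are collapsed with a warning; unparsable SMILES are
#' reported with their line number.
#'
#' @param path File path.
#' @return A data.frame with canonicalized `smiles`.
#' @export
read_composition <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "molecule_id", "smiles")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("composition file misses column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  can <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    can[i] <- tryCatch(canonicalize_smiles(df$smiles[i]), error = function(e)
      stop("line ", i + 1, ": ", conditionMessage(e), call. = FALSE))
  }
  df$smiles <- can
  key <- paste(df$sample_id, df$smiles)
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate (sample, molecule) row(s) collapsed")
    df <- df[!duplicated(key), , drop = FALSE]
  }
  if ("peak_area" %in% names(df)) {
    if (any(!is.na(df$peak_area) & df$peak_area <= 0))
      stop("peak_area must be positive where present", call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_composition
#' @param composition Composition data.frame.
#' @export
write_composition <- function(composition, path) {
  utils::write.csv(composition, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write RATA tables
#'
#' Long CSV with columns `panelist_id`, `sample_id`, `descriptor`, `rating`;
#' absent triples are zero. Ratings must be non-negative integers and no
#' panelist may have more than 5 nonzero descriptors for one sample.
#'
#' @param path File path.
#' @param panelists,samples,descriptors Optional dimension identifiers (see
#'   [rata_table()]).
#' @return A [rata_table()].
#' @export
read_rata <- function(path, panelists = NULL, samples = NULL,
                      descriptors = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("panelist_id", "sample_id", "descriptor", "rating")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("RATA file misses column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) > 0) {
    if (any(df$rating < 0)) stop("negative ratings", call. = FALSE)
    if (any(df$rating != round(df$rating)))
      stop("ratings must be integers", call. = FALSE)
  }
  rata_table(df, panelists = panelists, samples = samples,
             descriptors = descriptors)
}

#' @rdname read_rata
#' @param rata A [rata_table()].
#' @export
write_rata <- function(rata, path) {
  arr <- unclass(rata)
  ix <- which(arr > 0, arr.ind = TRUE)
  df <- data.frame(panelist_id = dimnames(arr)[[1]][ix[, 1]],
                   sample_id = dimnames(arr)[[2]][ix[, 2]],
                   descriptor = dimnames(arr)[[3]][ix[, 3]],
                   rating = arr[ix], stringsAsFactors = FALSE)
  df <- df[order(df$panelist_id, df$sample_id, df$descriptor), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write SMILES pool files
#'
#' One molecule per line: `smiles<TAB>id`; lines starting with `#` are
#' comments.
#'
#' @param path File path.
#' @return A data.frame with `smiles` and `molecule_id`.
#' @export
read_pool <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t")
  data.frame(
    smiles = vapply(parts, `[`, character(1), 1),
    molecule_id = vapply(parts, function(p)
      if (length(p) > 1) p[2] else p[1], character(1)),
    stringsAsFactors = FALSE)
}

#' @rdname read_pool
#' @param pool Data.frame with `smiles` and `molecule_id`.
#' @export
write_pool <- function(pool, path) {
  writeLines(paste(pool$smiles, pool$molecule_id, sep = "\t"), path)
  invisible(path)
}

#' Read and write substructure pattern files
#'
#' One pattern per line: `smarts<TAB>pattern_id<TAB>atom_count`.
#'
#' @param path File path.
#' @return A `substructure_patterns` data.frame (graphs re-parsed from the
#'   SMARTS).
#' @export
read_patterns <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t")
  out <- data.frame(
    pattern_id = vapply(parts, `[`, character(1), 2),
    smarts = vapply(parts, `[`, character(1), 1),
    atom_count = as.integer(vapply(parts, `[`, character(1), 3)),
    stringsAsFactors = FALSE)
  graphs <- lapply(out$smarts, parse_smarts)
  names(graphs) <- out$pattern_id
  attr(out, "graphs") <- graphs
  class(out) <- c("substructure_patterns", "data.frame")
  out
}

#' @rdname read_patterns
#' @param patterns A `substructure_patterns` table.
#' @export
write_patterns <- function(patterns, path) {
  writeLines(paste(patterns$smarts, patterns$pattern_id,
                   patterns$atom_count, sep = "\t"), path)
  invisible(path)
}

#' Write and read top-5 label sets
#'
#' CSV with columns `sample_id`, `label1` .. `label5`.
#'
#' @param label_sets Named list of 5-descriptor sets.
#' @param path File path.
#' @export
write_labels <- function(label_sets, path) {
  m <- do.call(rbind, label_sets)
  df <- data.frame(sample_id = names(label_sets), m, stringsAsFactors = FALSE)
  names(df) <- c("sample_id", paste0("label", 1:5))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    as.character(df[i, paste0("label", 1:5)]))
  names(out) <- df$sample_id
  out
}

#' Persist an OWSum model as JSON
#'
#' Versioned JSON document holding the training counts, variant, weighting
#' and influence values; [read_owsum()] restores a fully functional fit.
#'
#' @param object An [owsum()] fit.
#' @param path File path.
#' @export
write_owsum <- function(object, path) {
  doc <- list(
    schema = "mixodor-owsum-1",
    variant = object$variant,
    weighting = object$weighting,
    log_base = object$log_base,
    classes = rownames(object$counts$occ),
    features = colnames(object$counts$occ),
    occ = unname(as.matrix(object$counts$occ)),
    influence = unname(as.matrix(object$influence))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_owsum
#' @export
read_owsum <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "mixodor-owsum-1"))
    stop("not a mixodor OWSum document", call. = FALSE)
  occ <- matrix(as.integer(doc$occ), length(doc$classes),
                length(doc$features),
                dimnames = list(doc$classes, doc$features))
  counts <- structure(list(
    occ = occ, class_totals = rowSums(occ), n_classes = length(doc$classes),
    feature_class_presence = colSums(occ > 0)), class = "owsum_counts")
  infl <- matrix(doc$influence, length(doc$classes), length(doc$features),
                 dimnames = list(doc$classes, doc$features))
  structure(list(counts = counts, variant = doc$variant,
                 weighting = doc$weighting, log_base = doc$log_base,
                 influence = infl, call = NULL), class = "owsum")
}

#' Influence-difference and dissimilarity reports
#'
#' Writes the ranked per-feature influence differences for a class pair and
#' the pairwise class dissimilarity table (with the arc-width transform used
#' for drawing) as CSV files.
#'
#' @param object An [owsum()] fit.
#' @param class_a,class_b Class pair for the difference report.
#' @param path Output CSV path.
#' @export
write_influence_report <- function(object, class_a, class_b, path) {
  feats <- colnames(object$influence)
  d <- influence_difference(object, feats, class_a, class_b)
  df <- data.frame(feature = feats, difference = unname(d),
                   stringsAsFactors = FALSE)
  df <- df[order(-abs(df$difference), df$feature), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_influence_report
#' @export
write_dissimilarity_report <- function(object, path) {
  cls <- rownames(object$influence)
  rows <- list()
  for (i in seq_along(cls)) for (j in seq_along(cls)) {
    if (j <= i) next
    dd <- descriptor_dissimilarity(object, cls[i], cls[j])
    rows[[length(rows) + 1]] <- data.frame(
      class_a = cls[i], class_b = cls[j],
      dissimilarity = dd$dissimilarity, arc_width = dd$arc_width,
      stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records the configuration, seeds and content hashes of the files a run
#' read and wrote, sufficient to re-run it bit-identically.
#'
#' @param config Named list of configuration values.
#' @param files Character vector of file paths to hash.
#' @param path Output JSON path.
#' @export
write_manifest <- function(config, files, path) {
  hash_file <- function(f) {
    con <- file(f, "rb")
    on.exit(close(con))
    raw <- as.integer(readBin(con, "raw", file.size(f)))
    # rolling polynomial content hash; no external digest dependency needed
    h <- 0
    for (byte in raw) h <- (h * 31 + byte) %% 2147483647
    sprintf("%08x", h)
  }
  doc <- list(schema = "mixodor-manifest-1",
              timestamp = format(Sys.time(), tz = "UTC"),
              config = config,
              files = lapply(setNames(files, files), hash_file))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
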