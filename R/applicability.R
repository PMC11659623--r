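#' Applicability of a substructure pattern to a molecule
#'
#' The applicability weight is 0 exactly when the pattern has no substructure
#' match in the molecule. For a matching pattern it is either the number of
#' distinct matches (`mode = "match_count"`, distinct matched atom sets: the
#' frequency-of-occurrence reading) or the pattern's atom count
#' (`mode = "overlap_length"`: the length-of-overlap reading).
#'
#' @param molecule SMILES string, [molecule_record()] or [mol_graph()].
#' @param pattern A pattern graph (one element of the `"graphs"` attribute of
#'   [pairwise_mcs()]) or a SMARTS string.
#' @param mode `"match_count"` (default) or `"overlap_length"`.
#' @return A single non-negative number.
#' @export
applicability_value <- function(molecule, pattern,
                                mode = c("match_count", "overlap_length")) {
  mode <- match.arg(mode)
  mg <- .as_graph(molecule)
  pgr <- if (is.character(pattern)) parse_smarts(pattern) else pattern
  if (mode == "match_count") {
    match_count_cpp(unclass(pgr), unclass(mg))
  } else {
    if (has_match_cpp(unclass(pgr), unclass(mg))) length(pgr$elem) else 0
  }
}

.as_graph <- function(molecule) {
  if (inherits(molecule, "mol_graph")) return(molecule)
  if (inherits(molecule, "molecule_record")) return(mol_graph(molecule$canonical_smiles))
  if (is.character(molecule)) return(mol_graph(molecule))
  stop("unsupported molecule input", call. = FALSE)
}

#' Build the molecules-by-patterns applicability matrix
#'
#' Computes [applicability_value()] for every (molecule, pattern) combination.
#' Row `i`, column `j` holds the applicability of pattern `j` to molecule `i`;
#' a value of 0 means the pattern does not occur in the molecule.
#'
#' @param molecules Character vector of SMILES (optionally named by molecule
#'   id) or list of [molecule_record()]s; must be unique by canonical SMILES.
#' @param patterns A `substructure_patterns` table from [pairwise_mcs()], or a
#'   character vector of SMARTS.
#' @param mode `"match_count"` or `"overlap_length"`; see
#'   [applicability_value()].
#' @return A numeric matrix of class `applicability_matrix` with molecule ids
#'   as row names, pattern ids as column names and the mode stored in
#'   attribute `"mode"`.
#' @export
build_applicability_matrix <- function(molecules, patterns,
                                       mode = c("match_count", "overlap_length")) {
  mode <- match.arg(mode)
  pool <- .as_pool(molecules)
  if (anyDuplicated(pool$ids))
    stop("duplicate molecule ids in training set", call. = FALSE)
  cans <- vapply(pool$graphs, function(g) g$smiles, character(1))
  if (anyDuplicated(cans))
    stop("duplicate molecules (identical canonical SMILES) in training set",
         call. = FALSE)
  pg <- .as_patterns(patterns)
  m <- applicability_cpp(lapply(pool$graphs, unclass),
                         lapply(pg$graphs, unclass),
                         mode == "match_count")
  dimnames(m) <- list(pool$ids, pg$ids)
  attr(m, "mode") <- mode
  class(m) <- c("applicability_matrix", class(m))
  m
}

.as_patterns <- function(patterns) {
  if (inherits(patterns, "substructure_patterns")) {
    list(ids = patterns$pattern_id, graphs = attr(patterns, "graphs"))
  } else if (is.character(patterns)) {
    ids <- if (!is.null(names(patterns))) names(patterns) else patterns
    list(ids = ids, graphs = lapply(patterns, parse_smarts))
  } else if (is.list(patterns)) {
    list(ids = vapply(seq_along(patterns), function(i)
      if (!is.null(names(patterns))) names(patterns)[i] else as.character(i),
      character(1)), graphs = patterns)
  } else stop("unsupported patterns input", call. = FALSE)
}

#' @export
print.applicability_matrix <- function(x, ...) {
  cat("<applicability matrix> ", nrow(x), " molecules x ", ncol(x),
      " patterns, mode '", attr(x, "mode"), "'\n", sep = "")
  cat("nonzero entries: ", sum(x > 0), " (",
      round(100 * mean(x > 0), 1), "%)\n", sep = "")
  invisible(x)
}
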