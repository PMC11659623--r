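#' Canonicalize a SMILES string
#'
#' Converts a SMILES string to its OpenBabel canonical form, so that two
#' spellings of the same molecule map to identical text. Canonicalization is
#' idempotent: the canonical form of a canonical SMILES is itself.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES.
#' @examples
#' canonicalize_smiles(c("OCC", "CCO"))  # identical output
#' @export
canonicalize_smiles <- function(smiles) {
  if (!is.character(smiles) || any(!nzchar(smiles)))
    stop("smiles must be non-empty character strings", call. = FALSE)
  vapply(smiles, function(s) {
    out <- suppressWarnings(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\tx"))
    )
    can <- sub("\t.*$", "", sub("\\s+$", "", out))
    if (!nzchar(can))
      stop("unparsable SMILES: '", s, "'", call. = FALSE)
    can
  }, character(1), USE.NAMES = FALSE)
}

#' Create a molecule record
#'
#' Standardizes one detected volatile: identifier, canonical structure and an
#' optional relative peak area (GC-MS abundance relative to an internal
#' standard).
#'
#' @param smiles SMILES string.
#' @param molecule_id Identifier; defaults to the canonical SMILES.
#' @param peak_area Optional positive relative peak area.
#' @return A list of class `molecule_record` with fields `molecule_id`,
#'   `smiles`, `canonical_smiles`, `peak_area`.
#' @export
molecule_record <- function(smiles, molecule_id = NULL, peak_area = NULL) {
  can <- canonicalize_smiles(smiles)
  if (!is.null(peak_area)) {
    peak_area <- as.numeric(peak_area)
    if (!is.finite(peak_area) || peak_area <= 0)
      stop("peak_area must be a positive number", call. = FALSE)
  }
  structure(list(
    molecule_id = if (is.null(molecule_id)) can else as.character(molecule_id),
    smiles = smiles,
    canonical_smiles = can,
    peak_area = peak_area
  ), class = "molecule_record")
}

#' @export
print.molecule_record <- function(x, ...) {
  cat("<molecule> ", x$molecule_id, ": ", x$canonical_smiles, sep = "")
  if (!is.null(x$peak_area)) cat("  (peak area ", signif(x$peak_area, 4), ")", sep = "")
  cat("\n")
  invisible(x)
}

# symbol -> atomic number for the elements seen in volatile pools
.ELEMENTS <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
               S = 16, Cl = 17, Br = 35, I = 53)

#' Parse a molecule into a labelled graph
#'
#' Returns the heavy-atom molecular graph used by the MCS and substructure
#' matching kernels: atomic numbers plus a bond list with integer bond orders
#' (kekulized; aromatic rings appear as alternating single/double bonds).
#'
#' @param smiles SMILES string.
#' @return A list of class `mol_graph` with `elem` (atomic numbers), `bonds`
#'   (n x 3 integer matrix: atom i, atom j, order) and `smiles` (canonical).
#' @export
mol_graph <- function(smiles) {
  can <- canonicalize_smiles(smiles)
  sdf <- ChemmineR::smiles2sdf(can)[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  syms <- sub("_.*$", "", rownames(ab))
  elem <- unname(.ELEMENTS[syms])
  if (anyNA(elem))
    stop("unsupported element in '", smiles, "'", call. = FALSE)
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    matrix(integer(0), 0, 3)
  } else {
    matrix(as.integer(bb[, 1:3]), ncol = 3)
  }
  # drop explicit hydrogens (heavy-atom graph)
  heavy <- which(elem != 1L)
  if (length(heavy) < length(elem)) {
    remap <- match(seq_along(elem), heavy)
    keep <- bonds[, 1] %in% heavy & bonds[, 2] %in% heavy
    bonds <- bonds[keep, , drop = FALSE]
    bonds[, 1] <- remap[bonds[, 1]]
    bonds[, 2] <- remap[bonds[, 2]]
    elem <- elem[heavy]
  }
  structure(list(elem = as.integer(elem), bonds = bonds, smiles = can),
            class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$smiles, ": ", length(x$elem), " atoms, ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

# parse many SMILES into graphs, caching by canonical form
mol_graph_list <- function(smiles) {
  can <- canonicalize_smiles(smiles)
  uniq <- unique(can)
  gs <- lapply(uniq, mol_graph)
  gs[match(can, uniq)]
}
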