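#' Chemical family of a molecule
#'
#' Classifies a molecule into a coarse functional-group family by priority:
#' aromatic > ester (incl. lactones) > carboxylic acid > ketone > aldehyde >
#' alcohol/ether > alkene > alkane. Used by the synthetic generator to give
#' odor descriptors chemically coherent molecular families (fruity esters,
#' smoky phenols, ...), which is what makes substructure-based featurization
#' informative.
#'
#' @param molecule SMILES string, [molecule_record()] or [mol_graph()];
#'   vectorized over character input.
#' @return Character family label(s).
#' @export
molecule_family <- function(molecule) {
  if (is.character(molecule) && length(molecule) > 1)
    return(vapply(molecule, molecule_family, character(1), USE.NAMES = FALSE))
  g <- .as_graph(molecule)
  pats <- .family_patterns()
  for (fam in names(pats)) {
    if (has_match_cpp(unclass(pats[[fam]]), unclass(g))) return(fam)
  }
  "alkane"
}

.family_patterns <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- list(
        aromatic = parse_smarts("C1=CC=CC=C1"),
        ester = parse_smarts("CC(=O)OC"),
        acid = parse_smarts("CC(=O)O"),
        ketone = parse_smarts("CC(=O)C"),
        aldehyde = parse_smarts("CC=O"),
        alcohol = parse_smarts("CO"),
        alkene = parse_smarts("C=C")
      )
    }
    cache
  }
})
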