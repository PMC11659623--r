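#' Pairwise maximum-common-substructure feature extraction
#'
#' Compares every unordered pair of molecules in a reference pool and extracts
#' the maximum common substructure (MCS) of each pair: the largest connected
#' subgraph present in both molecules, with atoms compared by element and
#' bonds by bond order. The resulting substructure patterns, deduplicated by
#' canonical SMARTS, form the feature space of the applicability matrix.
#'
#' The search is an exact branch-and-bound over atom mappings, capped by a
#' deterministic node-expansion budget per pair; if a pair exhausts its budget
#' the best substructure found so far is kept, so results are reproducible
#' byte-for-byte across runs on any machine.
#'
#' @param reference_pool Character vector of SMILES, or a list of
#'   [molecule_record()] objects, with at least two valid molecules.
#' @param min_atoms Minimum number of atoms for a pattern to be kept
#'   (default 2: single atoms carry no substructural signal).
#' @param budget Search-node budget per molecule pair.
#' @return A data.frame of class `substructure_patterns` with columns
#'   `pattern_id`, `smarts`, `atom_count`, `source_a`, `source_b` (ids of the
#'   molecule pair that produced the pattern), ordered by decreasing
#'   `atom_count` then lexicographic `smarts`. The parsed pattern graphs are
#'   attached as attribute `"graphs"`.
#' @examples
#' pairwise_mcs(c("CCO", "CCCO"), min_atoms = 1)
#' @export
pairwise_mcs <- function(reference_pool, min_atoms = 2, budget = 2e5) {
  pool <- .as_pool(reference_pool)
  if (length(pool$ids) < 2)
    stop("reference pool must contain at least 2 molecules", call. = FALSE)
  if (min_atoms < 1) stop("min_atoms must be >= 1", call. = FALSE)
  gs <- pool$graphs
  n <- length(gs)

  seen <- new.env(parent = emptyenv())
  rows <- list()
  graphs <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      res <- mcs_cpp(unclass(gs[[i]]), unclass(gs[[j]]), budget)
      if (res$n_atoms < min_atoms || res$n_atoms == 0) next
      pg <- list(elem = gs[[i]]$elem[res$atoms_a],
                 bonds = matrix(as.integer(res$bonds), ncol = 3))
      pg <- canonical_pattern(pg)
      key <- pg$smarts
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      rows[[length(rows) + 1]] <- data.frame(
        smarts = key, atom_count = length(pg$elem),
        source_a = pool$ids[i], source_b = pool$ids[j],
        stringsAsFactors = FALSE)
      graphs[[length(graphs) + 1]] <- pg
    }
  }
  if (!length(rows)) {
    out <- data.frame(pattern_id = character(0), smarts = character(0),
                      atom_count = integer(0), source_a = character(0),
                      source_b = character(0), stringsAsFactors = FALSE)
    attr(out, "graphs") <- list()
    class(out) <- c("substructure_patterns", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$atom_count, out$smarts, method = "radix")
  out <- out[ord, , drop = FALSE]
  graphs <- graphs[ord]
  out <- cbind(pattern_id = sprintf("P%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  names(graphs) <- out$pattern_id
  attr(out, "graphs") <- graphs
  class(out) <- c("substructure_patterns", "data.frame")
  out
}

#' @export
print.substructure_patterns <- function(x, ...) {
  cat("<substructure patterns> ", nrow(x), " unique patterns\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

# normalize pool input to list(ids, graphs)
.as_pool <- function(pool) {
  if (inherits(pool, "molecule_record")) pool <- list(pool)
  if (is.character(pool)) {
    ids <- if (!is.null(names(pool)) && all(nzchar(names(pool)))) names(pool)
           else canonicalize_smiles(pool)
    graphs <- mol_graph_list(pool)
  } else if (is.list(pool)) {
    ids <- vapply(pool, function(m) m$molecule_id, character(1))
    graphs <- mol_graph_list(vapply(pool, function(m) m$canonical_smiles,
                                    character(1)))
  } else stop("unsupported pool input", call. = FALSE)
  list(ids = ids, graphs = graphs)
}

# --- canonical pattern form -------------------------------------------------

# Relabel a pattern graph into its canonical atom order (igraph BLISS on the
# bond-subdivided, vertex-colored graph) and attach its canonical SMARTS.
# Isomorphic patterns yield byte-identical SMARTS, which is the dedup key.
canonical_pattern <- function(pg) {
  n <- length(pg$elem)
  nb <- nrow(pg$bonds)
  if (n == 1) {
    pg$smarts <- smarts_for(pg)
    return(pg)
  }
  g <- igraph::make_empty_graph(n + nb, directed = FALSE)
  if (nb > 0) {
    ev <- integer(0)
    for (k in seq_len(nb))
      ev <- c(ev, pg$bonds[k, 1], n + k, n + k, pg$bonds[k, 2])
    g <- igraph::add_edges(g, ev)
  }
  colors <- c(pg$elem, 1000L + pg$bonds[, 3])
  lab <- igraph::canonical_permutation(g, colors = as.integer(colors))$labeling
  # canonical rank of the atom vertices only
  perm <- order(lab[seq_len(n)])          # perm[k] = old index of k-th canonical atom
  inv <- match(seq_len(n), perm)          # old -> new
  bonds <- pg$bonds
  bonds[, 1] <- inv[bonds[, 1]]
  bonds[, 2] <- inv[bonds[, 2]]
  swap <- bonds[, 1] > bonds[, 2]
  tmp <- bonds[swap, 1]; bonds[swap, 1] <- bonds[swap, 2]; bonds[swap, 2] <- tmp
  bonds <- bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
  out <- list(elem = pg$elem[perm], bonds = bonds)
  out$smarts <- smarts_for(out)
  out
}

.BOND_SYM <- c("-", "=", "#")

# deterministic SMARTS writer: DFS from atom 1, neighbors in ascending index
smarts_for <- function(pg) {
  n <- length(pg$elem)
  adj <- rep(list(integer(0)), n)
  ord <- rep(list(integer(0)), n)
  if (nrow(pg$bonds) > 0) {
    for (k in seq_len(nrow(pg$bonds))) {
      i <- pg$bonds[k, 1]; j <- pg$bonds[k, 2]; o <- pg$bonds[k, 3]
      adj[[i]] <- c(adj[[i]], j); ord[[i]] <- c(ord[[i]], o)
      adj[[j]] <- c(adj[[j]], i); ord[[j]] <- c(ord[[j]], o)
    }
    for (i in seq_len(n)) {
      ix <- order(adj[[i]])
      adj[[i]] <- adj[[i]][ix]; ord[[i]] <- ord[[i]][ix]
    }
  }
  visited <- rep(FALSE, n)
  ring_ct <- 0L
  ring <- rep(list(character(0)), n)  # closure tokens per atom
  closed <- new.env(parent = emptyenv())

  # first DFS: assign ring-closure digits to back edges
  assign_rings <- function(u, parent) {
    visited[u] <<- TRUE
    for (k in seq_along(adj[[u]])) {
      v <- adj[[u]][k]
      if (v == parent) next  # the single tree edge back to the parent
      if (visited[v]) {
        ekey <- paste(min(u, v), max(u, v))
        if (is.null(closed[[ekey]])) {
          closed[[ekey]] <- TRUE
          ring_ct <<- ring_ct + 1L
          d <- if (ring_ct < 10) as.character(ring_ct) else sprintf("%%%02d", ring_ct)
          tok <- paste0(.BOND_SYM[ord[[u]][k]], d)
          ring[[u]] <<- c(ring[[u]], tok)
          ring[[v]] <<- c(ring[[v]], tok)
        }
      } else {
        assign_rings(v, u)
      }
    }
  }
  assign_rings(1L, -1L)

  visited <- rep(FALSE, n)
  emit <- function(u, bond_sym) {
    visited[u] <<- TRUE
    s <- paste0(bond_sym, "[#", pg$elem[u], "]",
                paste0(ring[[u]], collapse = ""))
    parts <- character(0)
    for (k in seq_along(adj[[u]])) {
      v <- adj[[u]][k]
      if (visited[v]) next
      parts <- c(parts, emit(v, .BOND_SYM[ord[[u]][k]]))
    }
    if (length(parts)) {
      np <- length(parts)
      wrapped <- c(if (np > 1) paste0("(", parts[-np], ")"), parts[np])
      s <- paste0(s, paste0(wrapped, collapse = ""))
    }
    s
  }
  emit(1L, "")
}

#' Parse a SMARTS substructure query into a pattern graph
#'
#' Supports the dialect the package writes (`[#6]`-style atoms, explicit
#' `-`/`=`/`#` bonds, ring closures, branches) plus bare organic-subset
#' element symbols with implicit single bonds (e.g. `"C-O"` or `"CCO"`).
#'
#' @param smarts SMARTS string.
#' @return A pattern graph (list with `elem`, `bonds`, `smarts`).
#' @export
parse_smarts <- function(smarts) {
  s <- smarts
  elem <- integer(0)
  bonds <- matrix(integer(0), 0, 3)
  stack <- integer(0)
  prev <- 0L
  pending <- 1L
  rings <- new.env(parent = emptyenv())
  i <- 1L
  nc <- nchar(s)
  two <- c("Cl", "Br", "Si")
  while (i <= nc) {
    ch <- substr(s, i, i)
    if (ch == "(") { stack <- c(stack, prev); i <- i + 1L; next }
    if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMARTS", call. = FALSE)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (ch %in% c("-", "=", "#")) { pending <- match(ch, .BOND_SYM); i <- i + 1L; next }
    if (ch %in% as.character(0:9) || ch == "%") {
      if (ch == "%") { d <- substr(s, i + 1L, i + 2L); i <- i + 3L } else { d <- ch; i <- i + 1L }
      open <- rings[[d]]
      if (is.null(open)) {
        rings[[d]] <- c(prev, pending)
      } else {
        bonds <- rbind(bonds, c(open[1], prev, pending))
        rm(list = d, envir = rings)
      }
      pending <- 1L
      next
    }
    z <- NA_integer_
    if (ch == "[") {
      close <- regexpr("]", substr(s, i, nc), fixed = TRUE)
      if (close < 0) stop("unclosed '[' in SMARTS", call. = FALSE)
      tok <- substr(s, i + 1L, i + close - 2L)
      i <- i + close
      if (grepl("^#[0-9]+$", tok)) {
        z <- as.integer(sub("#", "", tok))
      } else {
        sym <- sub("^([A-Za-z][a-z]?).*$", "\\1", tok)
        cap <- paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
        z <- unname(.ELEMENTS[cap])
      }
    } else {
      sym <- ch
      if (i < nc && substr(s, i, i + 1L) %in% two) { sym <- substr(s, i, i + 1L); i <- i + 1L }
      i <- i + 1L
      cap <- paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
      z <- unname(.ELEMENTS[cap])
    }
    if (is.na(z)) stop("cannot parse SMARTS atom in '", smarts, "'", call. = FALSE)
    elem <- c(elem, z)
    cur <- length(elem)
    if (prev > 0L) bonds <- rbind(bonds, c(prev, cur, pending))
    prev <- cur
    pending <- 1L
  }
  if (!length(elem)) stop("empty SMARTS", call. = FALSE)
  storage.mode(bonds) <- "integer"
  list(elem = elem, bonds = bonds, smarts = smarts)
}
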