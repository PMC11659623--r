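# Independent brute-force oracles used to validate the optimized
# implementations, plus small shared fixtures.

# adjacency list with bond orders from a mol_graph / pattern graph
.adj_list <- function(g) {
  n <- length(g$elem)
  adj <- rep(list(integer(0)), n)
  ord <- rep(list(integer(0)), n)
  if (nrow(g$bonds) > 0) for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds[k, 1]; j <- g$bonds[k, 2]; o <- g$bonds[k, 3]
    adj[[i]] <- c(adj[[i]], j); ord[[i]] <- c(ord[[i]], o)
    adj[[j]] <- c(adj[[j]], i); ord[[j]] <- c(ord[[j]], i * 0 + o)
  }
  list(adj = adj, ord = ord)
}

# exhaustive enumeration of common connected subgraphs (atoms matched by
# element, bonds by order); returns the maximum atom count. Plain recursive
# enumeration without bounds, budgets or tie-breaking.
oracle_mcs_atoms <- function(ga, gb) {
  A <- .adj_list(ga); B <- .adj_list(gb)
  nA <- length(ga$elem); nB <- length(gb$elem)
  best <- 0L
  grow <- function(mapA, mapB, forbidden) {
    best <<- max(best, sum(mapA > 0))
    frontier <- integer(0)
    for (a in seq_len(nA)) {
      if (mapA[a] > 0 || forbidden[a]) next
      for (k in seq_along(A$adj[[a]])) {
        ap <- A$adj[[a]][k]
        if (mapA[ap] > 0) { frontier <- c(frontier, a); break }
      }
    }
    if (!length(frontier)) return()
    a <- min(frontier)
    for (k in seq_along(A$adj[[a]])) {
      ap <- A$adj[[a]][k]; o <- A$ord[[a]][k]
      if (mapA[ap] == 0) next
      bp <- mapA[ap]
      for (m in seq_along(B$adj[[bp]])) {
        b <- B$adj[[bp]][m]
        if (mapB[b] > 0 || B$ord[[bp]][m] != o || gb$elem[b] != ga$elem[a]) next
        mapA[a] <- b; mapB[b] <- a
        grow(mapA, mapB, forbidden)
        mapA[a] <- 0L; mapB[b] <- 0L
      }
    }
    forbidden[a] <- TRUE
    grow(mapA, mapB, forbidden)
  }
  for (a0 in seq_len(nA)) {
    for (b0 in seq_len(nB)) {
      if (gb$elem[b0] != ga$elem[a0]) next
      mapA <- integer(nA); mapB <- integer(nB)
      mapA[a0] <- b0; mapB[b0] <- a0
      forbidden <- rep(FALSE, nA)
      if (a0 > 1) forbidden[seq_len(a0 - 1)] <- TRUE
      grow(mapA, mapB, forbidden)
    }
  }
  best
}

# brute-force subgraph isomorphism enumeration: number of distinct matched
# atom sets of pattern p in molecule m
oracle_match_count <- function(p, m) {
  P <- .adj_list(p); M <- .adj_list(m)
  np <- length(p$elem); nm <- length(m$elem)
  if (np > nm) return(0L)
  found <- character(0)
  assign_next <- function(mapP) {
    d <- sum(mapP > 0) + 1L
    if (d > np) {
      found <<- c(found, paste(sort(mapP), collapse = ","))
      return()
    }
    for (cand in seq_len(nm)) {
      if (cand %in% mapP || m$elem[cand] != p$elem[d]) next
      ok <- TRUE
      for (k in seq_along(P$adj[[d]])) {
        pp <- P$adj[[d]][k]
        if (pp >= d || mapP[pp] == 0) next
        hit <- which(M$adj[[cand]] == mapP[pp])
        if (!length(hit) || M$ord[[cand]][hit[1]] != P$ord[[d]][k]) ok <- FALSE
      }
      # also check pattern bonds from d to earlier atoms exist (covered above)
      if (ok) {
        mapP[d] <- cand
        assign_next(mapP)
        mapP[d] <- 0L
      }
    }
  }
  assign_next(integer(np))
  length(unique(found))
}

# confusion-count metrics by explicit loops (independent of the vectorized
# implementation)
oracle_micro_metrics <- function(truth, pred) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(nrow(truth))) for (j in seq_len(ncol(truth))) {
    t <- truth[i, j] > 0; p <- pred[i, j] > 0
    if (t && p) tp <- tp + 1
    if (!t && p) fp <- fp + 1
    if (t && !p) fn <- fn + 1
    if (!t && !p) tn <- tn + 1
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
  list(tp = tp, fp = fp, fn = fn, tn = tn, precision = prec, recall = rec,
       f1 = f1, mcc = mcc)
}

# ROC AUC by exhaustive positive-negative pair comparison
oracle_auc <- function(truth, scores) {
  t <- as.vector(truth); s <- as.vector(scores)
  pos <- s[t == 1]; neg <- s[t == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# small molecules (<= 8 heavy atoms) for MCS oracle comparisons
small_molecule_smiles <- function() {
  c("CCO", "CCCO", "CCCC", "CC(C)O", "CC(C)C", "CCOC", "CC=O", "CCC=O",
    "CC(=O)C", "CC(=O)O", "CCC(=O)O", "CCOC(C)=O", "C1CCCCC1", "C1CCCC1",
    "C1CC1", "c1ccccc1", "Cc1ccccc1", "Oc1ccccc1", "CC=C", "CC=CC",
    "C=CC=C", "OCCO", "OCCCO", "CC(O)CO", "CNC", "CCN", "CC(C)N", "CCS",
    "CSC", "CC(C)=O", "CC(C)CO", "CCCCO", "OC=O", "COC=O", "CC#N", "CC#C",
    "ClCCCl", "CCCl", "CC(Cl)C", "OCC=C")
}

# a tiny deterministic RATA fixture: 3 panelists x 2 samples x 6 descriptors
toy_rata <- function() {
  arr <- array(0L, dim = c(3, 2, 6),
               dimnames = list(paste0("p", 1:3), paste0("s", 1:2),
                               paste0("d", 1:6)))
  arr["p1", "s1", c("d1", "d2", "d3")] <- c(5L, 3L, 1L)
  arr["p2", "s1", c("d1", "d4")] <- c(2L, 4L)
  arr["p3", "s1", c("d2", "d5", "d6")] <- c(1L, 2L, 2L)
  arr["p1", "s2", c("d4", "d5")] <- c(3L, 3L)
  arr["p2", "s2", c("d4", "d6")] <- c(5L, 1L)
  arr["p3", "s2", "d1"] <- 4L
  rata_table(arr)
}
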