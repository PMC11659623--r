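test_that("canonicalization unifies spellings, is idempotent, rejects junk", {
  expect_identical(canonicalize_smiles("OCC"), canonicalize_smiles("CCO"))
  once <- canonicalize_smiles("CCO")
  expect_identical(canonicalize_smiles(once), once)
  expect_error(canonicalize_smiles("C1CC"), "unparsable SMILES.*C1CC")
  expect_error(canonicalize_smiles(""), "non-empty")
})

test_that("molecule records carry canonical structure and guard peak areas", {
  m <- molecule_record("OCC", "ethanol", peak_area = 0.5)
  expect_identical(m$canonical_smiles, canonicalize_smiles("CCO"))
  expect_identical(m$molecule_id, "ethanol")
  expect_error(molecule_record("CCO", peak_area = 0), "positive")
  expect_error(molecule_record("CCO", peak_area = -1), "positive")
})

test_that("molecular graphs are heavy-atom graphs with kekulized bond orders", {
  g <- mol_graph("CCOC(=O)C")  # ethyl acetate: 6 heavy atoms, one C=O
  expect_length(g$elem, 6)
  expect_equal(sum(g$bonds[, 3] == 2), 1)
  ring <- mol_graph("c1ccccc1")
  expect_length(ring$elem, 6)
  expect_setequal(ring$bonds[, 3], c(1, 2))  # alternating kekulized orders
})

test_that("pairwise MCS finds the shared substructure of simple pairs", {
  p <- pairwise_mcs(c("CCO", "CCCO"), min_atoms = 1)
  expect_equal(nrow(p), 1)
  expect_equal(p$atom_count, 3)  # the whole of ethanol
  # a molecule against itself: the full molecule
  p2 <- pairwise_mcs(c("CCOC(=O)C", "CCOC(=O)C"))
  expect_equal(p2$atom_count[1], 6)
  # ring MCS keeps the ring closure bond
  p3 <- pairwise_mcs(c("Cc1ccccc1", "Oc1ccccc1"))
  expect_equal(p3$atom_count[1], 6)
  g3 <- attr(p3, "graphs")[[1]]
  expect_equal(nrow(g3$bonds), 6)  # 6 atoms, 6 bonds: a cycle
})

test_that("pairwise MCS validates inputs and orders output deterministically", {
  expect_error(pairwise_mcs("CCO"), "at least 2")
  expect_error(pairwise_mcs(c("CCO", "CCCO"), min_atoms = 0), "min_atoms")
  pool <- c("CCO", "CCCO", "CCCCO", "CC(C)O", "OCC=C")
  a <- pairwise_mcs(pool)
  b <- pairwise_mcs(pool)
  expect_identical(a, b)  # byte-identical reruns
  expect_false(is.unsorted(rev(a$atom_count)))  # atom_count descending
  expect_false(anyDuplicated(a$smarts) > 0)
})

test_that("isomorphic substructures from different pairs dedup to one pattern", {
  # both pairs share the C-C-O fragment, spelled differently
  a <- pairwise_mcs(c("CCO", "CCCO"), min_atoms = 1)$smarts
  b <- pairwise_mcs(c("OCC", "OCCCC"), min_atoms = 1)$smarts
  expect_identical(a, b)
})

test_that("growing the reference pool never loses existing patterns", {
  small <- pairwise_mcs(c("CCO", "CCCO", "CCCC"))
  grown <- pairwise_mcs(c("CCO", "CCCO", "CCCC", "CC(C)CO"))
  expect_true(all(small$smarts %in% grown$smarts))
})

test_that("MCS atom counts match exhaustive enumeration on random small pairs", {
  smis <- small_molecule_smiles()
  graphs <- lapply(smis, mol_graph)
  withr::with_seed(421, {
    for (rep in 1:20) {
      ij <- sample(length(graphs), 2)
      got <- mixodor:::mcs_cpp(unclass(graphs[[ij[1]]]),
                               unclass(graphs[[ij[2]]]), 2e5)$n_atoms
      want <- oracle_mcs_atoms(graphs[[ij[1]]], graphs[[ij[2]]])
      expect_equal(got, want,
                   info = paste(smis[ij[1]], "vs", smis[ij[2]]))
    }
  })
})

test_that("applicability values count matches and respect the zero rule", {
  # ethyl acetate has exactly two C-O single bonds
  expect_equal(applicability_value("CCOC(=O)C", "C-O", "match_count"), 2)
  expect_equal(oracle_match_count(parse_smarts("C-O"), mol_graph("CCOC(=O)C")), 2)
  # no nitrogen anywhere: zero in both modes
  expect_equal(applicability_value("CCO", "N", "match_count"), 0)
  expect_equal(applicability_value("CCO", "N", "overlap_length"), 0)
  # self-match in overlap mode returns the heavy-atom count
  expect_equal(applicability_value("CCO", "CCO", "overlap_length"), 3)
})

test_that("match counts equal brute-force enumeration on random cases", {
  smis <- small_molecule_smiles()
  pats <- c("C-C", "C-O", "C=O", "C-C-O", "C-C-C", "C-C=O")
  withr::with_seed(77, {
    for (rep in 1:25) {
      m <- mol_graph(sample(smis, 1))
      p <- parse_smarts(sample(pats, 1))
      expect_equal(mixodor:::match_count_cpp(unclass(p), unclass(m)),
                   oracle_match_count(p, m),
                   info = paste(p$smarts, "in", m$smiles))
    }
  })
})

test_that("the applicability matrix honors its shape and zero contracts", {
  pool <- c(eth = "CCO", prop = "CCCO", benz = "c1ccccc1")
  pats <- pairwise_mcs(c("CCO", "CCCO", "CCCCO"), min_atoms = 1)
  m <- build_applicability_matrix(pool, pats)
  expect_equal(dim(m), c(3, nrow(pats)))
  expect_identical(rownames(m), names(pool))
  # zero-consistency between the two modes
  m2 <- build_applicability_matrix(pool, pats, mode = "overlap_length")
  expect_identical(unname(m == 0), unname(m2 == 0))
  # benzene shares no single-bond C-C/C-O chain with the alcohols
  expect_true(all(m["benz", ] == 0))
  # patterns came from ethanol/propanol pairs: both parents match
  expect_true(all(m[c("eth", "prop"), pats$atom_count <= 3] >= 0))
  expect_error(build_applicability_matrix(c(a = "CCO", b = "OCC"), pats),
               "duplicate")
})

test_that("SMARTS round-trip through write and parse preserves matching", {
  pats <- pairwise_mcs(c("CCOC(=O)C", "CCCC(=O)OC", "Cc1ccccc1O"))
  tmp <- tempfile(fileext = ".smarts")
  write_patterns(pats, tmp)
  back <- read_patterns(tmp)
  expect_identical(back$smarts, pats$smarts)
  mols <- c(x = "CCOC(=O)CCC", y = "COc1ccccc1")
  m1 <- build_applicability_matrix(mols, pats)
  m2 <- build_applicability_matrix(mols, back)
  expect_equal(unname(unclass(m1)), unname(unclass(m2)))
})
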