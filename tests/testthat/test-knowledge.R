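# Knowledge base construction, substructure matching, graph augmentation.

test_that("quantile binning splits weight at the median for two elements", {
  pt <- crossmol:::.periodic_table()
  kb <- build_knowledge_base(pt[pt$symbol %in% c("H", "O"), ], n_bins = 2)
  # oracle: sort by atomic weight, split at the median
  expect_equal(unname(kb$element_properties$H[["weight"]]), "Weight1")
  expect_equal(unname(kb$element_properties$O[["weight"]]), "Weight2")
  expect_equal(unname(kb$element_properties$H[["radius"]]), "Radius1")
  expect_equal(unname(kb$element_properties$O[["radius"]]), "Radius2")
})

test_that("degenerate single-bin kb gives every element one shared label", {
  kb <- build_knowledge_base(n_bins = 1)
  ws <- vapply(kb$element_properties, `[[`, character(1), "weight")
  expect_true(all(ws == "Weight1"))
})

test_that("every covered element maps to exactly 5 labels, one per category", {
  kb <- test_kb()
  for (el in names(kb$element_properties)) {
    p <- kb$element_properties[[el]]
    expect_named(p, c("periodicity", "metallicity", "group", "radius",
                      "weight"), info = el)
    expect_true(all(nzchar(p)))
  }
  tr <- kb_triples(kb)
  expect_equal(nrow(tr), 5L * length(kb$element_properties))
  expect_setequal(unique(tr$relation),
                  c("isPeriodOf", "isMetallicityOf", "isGroupOf",
                    "isRadiusOf", "isWeightOf"))
})

test_that("kb construction rejects incomplete attribute tables", {
  pt <- crossmol:::.periodic_table()
  pt$weight[pt$symbol == "O"] <- NA
  expect_error(build_knowledge_base(pt), "O")
})

test_that("functional-group matching finds the documented examples", {
  kb <- test_kb()
  # methanol with explicit H: one hydroxyl {O, H} and one methyl
  g <- parse_smiles("CO", add_hydrogens = TRUE)
  m <- match_functional_groups(g, kb)
  hyd <- Filter(function(x) x$group == "hydroxyl", m)
  expect_length(hyd, 1L)
  expect_setequal(g$nodes$element[hyd[[1]]$atoms], c("O", "H"))
  # ethane: no hydroxyl
  g2 <- parse_smiles("CC", add_hydrogens = TRUE)
  m2 <- match_functional_groups(g2, kb)
  expect_length(Filter(function(x) x$group == "hydroxyl", m2), 0L)
  # ethylene glycol: two hydroxyls (hand-checked substructure search)
  g3 <- parse_smiles("OCCO", add_hydrogens = TRUE)
  m3 <- match_functional_groups(g3, kb)
  expect_length(Filter(function(x) x$group == "hydroxyl", m3), 2L)
})

test_that("matches are deterministic, deduplicated and ordered", {
  kb <- test_kb()
  g <- parse_smiles("OCCO", add_hydrogens = TRUE)
  m1 <- match_functional_groups(g, kb)
  expect_identical(m1, match_functional_groups(g, kb))
  sets <- lapply(m1, function(x) paste(x$group, paste(x$atoms, collapse = ",")))
  expect_equal(anyDuplicated(unlist(sets)), 0L)
  mins <- vapply(m1, function(x) min(x$atoms), numeric(1))
  expect_true(all(diff(mins) >= 0))
})

test_that("augmentation attaches 5 property edges per atom and shares labels", {
  kb <- test_kb()
  # single heavy-atom methane graph: no matches, exactly 5 property edges
  aug1 <- augment_graph(parse_smiles("C"), kb)
  expect_equal(nrow(aug1$virtual_edges), 5L)
  expect_equal(nrow(aug1$virtual_nodes), 5L)
  # ethanol heavy-atom graph: 3 atoms x 5 categories = 15 property edges
  aug <- augment_graph(parse_smiles("CCO"), kb)
  pe <- aug$virtual_edges[aug$virtual_edges$category != "functional-group", ]
  expect_equal(nrow(pe), 15L)
  per_atom <- table(pe$dst)
  expect_true(all(per_atom == 5L))
  # shared-label compression: far fewer virtual nodes than 5 x atoms
  ep <- aug$virtual_nodes[aug$virtual_nodes$kind == "element-property", ]
  labels <- unlist(lapply(c("C", "O"), function(el)
    unname(kb$element_properties[[el]])))
  expect_equal(sort(ep$label), sort(unique(labels)))
})

test_that("hydroxyl match yields one virtual node with edges to O and to H", {
  kb <- test_kb()
  g <- parse_smiles("CO", add_hydrogens = TRUE)
  aug <- augment_graph(g, kb)
  vn <- aug$virtual_nodes
  hid <- vn$id[vn$label == "hydroxyl"]
  expect_length(hid, 1L)
  ve <- aug$virtual_edges[aug$virtual_edges$src == hid, ]
  expect_equal(nrow(ve), 2L)
  expect_setequal(g$nodes$element[ve$dst], c("O", "H"))
  expect_true(all(ve$relation == "hasFunctionalGroup"))
})

test_that("a weight-group triple materialises as a directed edge to oxygen", {
  pt <- crossmol:::.periodic_table()
  kb2 <- build_knowledge_base(pt[pt$symbol %in% c("H", "O"), ], n_bins = 2,
                              fg_patterns = data.frame(name = character(0),
                                                       pattern = character(0)))
  g <- parse_smiles("O")        # water, heavy atom only
  aug <- augment_graph(g, kb2)
  ve <- aug$virtual_edges
  w <- ve[ve$relation == "isWeightOf", ]
  expect_equal(nrow(w), 1L)
  expect_equal(aug$virtual_nodes$label[w$src], "Weight2")
  expect_equal(g$nodes$element[w$dst], "O")
})

test_that("augmentation invariants hold: direction, base recovery, one-shot", {
  kb <- test_kb()
  g <- parse_smiles("OCCO", add_hydrogens = TRUE)
  aug <- augment_graph(g, kb)
  # no edge leaves an atom toward a property node: sources are virtual ids
  expect_true(all(aug$virtual_edges$src %in% aug$virtual_nodes$id))
  expect_true(all(aug$virtual_edges$dst %in% seq_len(g$n_nodes)))
  # removing virtual structure recovers the base graph exactly
  expect_identical(aug$base, g)
  # augmenting an augmented graph is a type error
  expect_error(augment_graph(aug, kb), "already augmented")
})

test_that("uncovered elements are reported by name", {
  pt <- crossmol:::.periodic_table()
  kb2 <- build_knowledge_base(pt[pt$symbol == "C", , drop = FALSE])
  expect_error(augment_graph(parse_smiles("CCO"), kb2), "O")
})

test_that("malformed patterns fail at kb load, not at match time", {
  expect_error(build_knowledge_base(
    fg_patterns = data.frame(name = "bad", pattern = "C((O")),
    "malformed pattern")
})
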