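# Molecular parsing and featurization.

test_that("parse_molecule handles simple molecules and malformed input", {
  m <- parse_molecule("CCO", "ethanol")
  expect_s3_class(m, "dta_molecule")
  expect_equal(n_atoms(m), 3L)
  expect_equal(n_bonds(m), 2L)

  b <- parse_molecule("c1ccccc1", "benzene")
  expect_equal(n_atoms(b), 6L)
  expect_equal(n_bonds(b), 6L)
  expect_true(all(b$atoms$aromatic))
  expect_true(all(b$bonds$aromatic))

  g <- parse_molecule("C", "methane")
  expect_equal(n_atoms(g), 1L)
  expect_equal(n_bonds(g), 0L)
  expect_equal(g$atoms$n_h, 4L)

  err <- tryCatch(parse_molecule("C(", "badmol"), error = identity)
  expect_s3_class(err, "dta_parse_error")
  expect_equal(err$source_id, "badmol")
  expect_error(parse_molecule("", "empty"))
})

test_that("atom feature vectors follow the nine-code contract", {
  b <- parse_molecule("c1ccccc1")
  fa <- featurize_atom(b, 1L)
  expect_length(fa, 9L)
  expect_true(all(fa >= 0))
  # benzene carbon: aromatic, in ring, two heavy neighbours, one hydrogen
  expect_equal(unname(fa[["a8"]]), 1L)
  expect_equal(unname(fa[["a9"]]), 1L)
  expect_equal(unname(fa[["a3"]]), 2L)
  expect_equal(unname(fa[["a5"]]), 1L)
  expect_equal(unname(fa[["a1"]]), 6L)

  e <- parse_molecule("CCO")
  fo <- featurize_atom(e, 3L)  # the oxygen
  expect_equal(unname(fo[["a5"]]), 1L)  # one attached hydrogen
  expect_equal(unname(fo[["a8"]]), 0L)
  expect_equal(unname(fo[["a4"]]), 3L)  # neutral: charge 0 -> code 3

  expect_error(featurize_atom(e, 4L), "out of range")
  expect_error(featurize_atom(e, 0L), "out of range")
})

test_that("bond feature vectors are symmetric and classed correctly", {
  b <- parse_molecule("c1ccccc1")
  fb <- featurize_bond(b, 1L, 2L)
  expect_length(fb, 3L)
  expect_equal(unname(fb[["b1"]]), 3L)  # aromatic class
  expect_equal(unname(fb[["b3"]]), 1L)  # conjugated
  expect_equal(featurize_bond(b, 2L, 1L), fb)

  e <- parse_molecule("CCO")
  fe <- featurize_bond(e, 2L, 3L)  # C-O
  expect_equal(unname(fe[["b1"]]), 0L)  # single
  expect_equal(unname(fe[["b3"]]), 0L)  # not conjugated
  expect_error(featurize_bond(e, 1L, 3L), "no bond")
})

test_that("drug graphs satisfy the adjacency/degree invariants", {
  for (m in test_mol_pool()) {
    g <- build_drug_graph(m)
    a <- g$adjacency
    expect_equal(a, t(a))
    expect_true(all(diag(a) == 0))
    expect_equal(sum(a[upper.tri(a)]), nrow(g$edges))
    expect_equal(unname(g$degrees), unname(rowSums(a)))
    expect_equal(nrow(g$node_features), n_atoms(m))
    expect_equal(ncol(g$node_features), 9L)
  }
  # methane: one node, no edges
  g1 <- build_drug_graph(parse_molecule("C"))
  expect_equal(nrow(g1$adjacency), 1L)
  expect_equal(nrow(g1$edges), 0L)
  # ethanol: exactly 4 nonzero adjacency entries
  ge <- build_drug_graph(parse_molecule("CCO"))
  expect_equal(sum(ge$adjacency), 4L)
})

test_that("featurization is permutation-equivariant", {
  withr::with_seed(7, {
    for (m in test_mol_pool()[c(2, 3, 4, 7)]) {
      n <- n_atoms(m)
      perm <- sample(n)
      mp <- permute_molecule(m, perm)
      g <- build_drug_graph(m)
      gp <- build_drug_graph(mp)
      expect_equal(gp$node_features, g$node_features[perm, , drop = FALSE])
      expect_equal(gp$adjacency, g$adjacency[perm, perm])
      expect_equal(unname(gp$degrees), unname(g$degrees[perm]))
    }
  })
})

test_that("SDF records round-trip with matching bond counts", {
  smis <- c("CCO", "CC(=O)Oc1ccccc1C(=O)O", "C1CCNCC1")
  for (smi in smis) {
    sdf_txt <- ChemmineOB::convertFormat("SMI", "SDF", paste0(smi, "\tx"))
    m <- parse_molecule(sdf_txt, source_id = "roundtrip", format = "sdf")
    # count the declared bond-block size on the counts line
    counts <- strsplit(sdf_txt, "\n")[[1L]][4L]
    declared <- as.integer(substr(counts, 4L, 6L))
    expect_equal(n_bonds(m), declared)
    expect_equal(n_atoms(m), n_atoms(parse_molecule(smi)))
  }
})

test_that("smiles files and graph dumps round-trip", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "drugs.csv")
  writeLines(c("drug_id,smiles", "d1,CCO", "d2,c1ccccc1"), csv)
  smi <- read_smiles_file(csv)
  expect_equal(unname(smi), c("CCO", "c1ccccc1"))
  expect_equal(names(smi), c("d1", "d2"))

  plain <- file.path(dir, "drugs.smi")
  writeLines(c("CCO d1", "c1ccccc1 d2"), plain)
  expect_equal(read_smiles_file(plain), smi)

  graphs <- lapply(names(smi), function(id)
    build_drug_graph(parse_molecule(smi[[id]], source_id = id)))
  out <- file.path(dir, "graphs.jsonl")
  write_drug_graphs_jsonl(graphs, out)
  lines <- readLines(out)
  expect_length(lines, 2L)
  parsed <- jsonlite::fromJSON(lines[1L])
  expect_equal(parsed$source_id, "d1")
  expect_equal(nrow(parsed$node_features), 3L)
})
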