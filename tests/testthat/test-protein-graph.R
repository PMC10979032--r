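# Protein records, contact-map edges, and residue graphs.

make_record <- function(m = 3L, dist = NULL, kind = "distance",
                        ss8 = NULL, asa = NULL,
                        seq = paste(rep("A", m), collapse = "")) {
  if (is.null(dist)) {
    dist <- matrix(20, m, m); diag(dist) <- 0
    for (i in seq_len(m - 1)) dist[i, i + 1] <- dist[i + 1, i] <- 3.8
  }
  if (is.null(ss8)) ss8 <- paste(rep("C", m), collapse = "")
  if (is.null(asa)) asa <- rep(0.5, m)
  protein_record("p1", seq, ss8, asa, dist, kind = kind)
}

test_that("record validation names the offending field", {
  expect_error(make_record(ss8 = "CC"), "ss8")
  expect_error(make_record(asa = rep(0.5, 4)), "asa")
  expect_error(make_record(dist = matrix(0, 4, 4)), "distmap")
  expect_error(make_record(ss8 = "CXC"), "8-state")
  asym <- matrix(20, 3, 3); diag(asym) <- 0; asym[1, 3] <- 5
  expect_error(make_record(dist = asym), "asymmetric")
})

test_that("absolute ASA is normalized to relative accessibility", {
  rec <- make_record(asa = c(64.5, 129, 12.9))  # alanine max ASA = 129
  expect_equal(rec$asa, c(0.5, 1, 0.1))
  rec2 <- make_record(asa = c(0.2, 0.4, 1.0))
  expect_equal(rec2$asa, c(0.2, 0.4, 1.0))
})

test_that("contact edges use the strict 8-Angstrom rule on non-adjacent pairs", {
  d <- matrix(20, 4, 4); diag(d) <- 0
  for (i in 1:3) d[i, i + 1] <- d[i + 1, i] <- 3.8
  d[1, 3] <- d[3, 1] <- 7.9   # contact
  d[1, 4] <- d[4, 1] <- 8.0   # not a contact (strictly less than 8)
  d[2, 4] <- d[4, 2] <- 8.1   # not a contact
  rec <- make_record(4, dist = d)
  ed <- build_contact_edges(rec)
  ct <- ed[ed$kind == "contact", ]
  expect_equal(nrow(ct), 1L)
  expect_equal(c(ct$i, ct$j), c(1L, 3L))
  # backbone edges always present: a 3-residue chain with long distances
  # has exactly its 2 backbone edges
  rec3 <- make_record(3)
  ed3 <- build_contact_edges(rec3)
  expect_equal(nrow(ed3), 2L)
  expect_true(all(ed3$kind == "backbone"))
  expect_equal(ed3$j - ed3$i, c(1L, 1L))
})

test_that("probability maps threshold at 0.5", {
  p <- diag(4)
  p[1, 3] <- p[3, 1] <- 0.9
  p[1, 4] <- p[4, 1] <- 0.5   # not > 0.5
  rec <- make_record(4, dist = p, kind = "probability")
  ct <- build_contact_edges(rec)
  ct <- ct[ct$kind == "contact", ]
  expect_equal(nrow(ct), 1L)
  expect_equal(c(ct$i, ct$j), c(1L, 3L))
})

test_that("protein graphs concatenate embedding, SS8 one-hot and ASA", {
  prov <- synthetic_embedding_provider(16)
  spec <- dta_fixture_spec(protein_length = c(10, 10), seed = 3)
  rec <- gen_protein_record(spec, "p10", seed = 3)
  pg <- build_protein_graph(rec, prov)
  expect_equal(nrow(pg$node_features), 10L)
  expect_equal(ncol(pg$node_features), 16L + 8L + 1L)
  # embedding block is the provider output; determinism across builds
  expect_equal(pg$node_features[, 1:16], prov$embed(rec$sequence))
  pg2 <- build_protein_graph(rec, prov)
  expect_identical(pg$node_features, pg2$node_features)
  # one-hot block has exactly one 1 per row; ASA column matches the record
  expect_equal(rowSums(pg$node_features[, 17:24]), rep(1, 10))
  expect_equal(unname(pg$node_features[, 25]), rec$asa)
  # constant provider + uniform ss8/asa: identical node features
  cprov <- list(embed = function(s) matrix(1, nchar(s), 4), width = 4L,
                version = "const")
  recu <- make_record(5)
  pgu <- build_protein_graph(recu, cprov)
  expect_equal(pgu$node_features,
               pgu$node_features[rep(1, 5), , drop = FALSE],
               ignore_attr = TRUE)
})

test_that("synthetic records have plausible contact density", {
  spec <- dta_fixture_spec(protein_length = c(25, 45), seed = 1)
  dens <- vapply(1:20, function(k) {
    rec <- gen_protein_record(spec, sprintf("p%02d", k), seed = 100 + k)
    m <- nchar(rec$sequence)
    ed <- build_contact_edges(rec)
    nc <- sum(ed$kind == "contact")
    nonadj <- m * (m - 1) / 2 - (m - 1)
    nc / nonadj
  }, numeric(1))
  expect_true(all(dens > 0.01 & dens < 0.4))
  expect_true(mean(dens) > 0 && mean(dens) < 0.5)
})

test_that("protein records round-trip through the on-disk format", {
  dir <- withr::local_tempdir()
  spec <- dta_fixture_spec(protein_length = c(12, 12), seed = 9)
  rec <- gen_protein_record(spec, "PRT01", seed = 9)
  write_protein_record(rec, dir)
  back <- read_protein_record(dir, "PRT01")
  expect_equal(back$sequence, rec$sequence)
  expect_equal(back$ss8, rec$ss8)
  expect_equal(back$asa, rec$asa, tolerance = 1e-6)
  expect_equal(back$distmap, rec$distmap, tolerance = 1e-4)
  expect_equal(back$kind, rec$kind)
  expect_error(read_protein_record(dir, "NOPE"), "no protein record")
})
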