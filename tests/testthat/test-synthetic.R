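# Synthetic fixtures: generators, label function, and loader round trips.

test_that("generated drug sets are valid, bounded, and reproducible", {
  spec <- dta_fixture_spec(n_drugs = 10, n_proteins = 2, n_pairs = 20,
                           seed = 1)
  smi <- gen_drug_set(spec)
  expect_length(smi, 10L)
  sizes <- vapply(names(smi), function(id) {
    m <- parse_molecule(smi[[id]], source_id = id)  # must not error
    n_atoms(m)
  }, integer(1))
  expect_true(all(sizes <= 64L))
  expect_identical(gen_drug_set(spec), smi)
  spec2 <- dta_fixture_spec(n_drugs = 10, n_proteins = 2, n_pairs = 20,
                            seed = 2)
  expect_false(identical(gen_drug_set(spec2), smi))
})

test_that("generated protein records are consistent and reproducible", {
  spec <- dta_fixture_spec(protein_length = c(30, 30), seed = 4)
  rec <- gen_protein_record(spec, "P001", seed = 4)
  m <- nchar(rec$sequence)
  expect_equal(m, 30L)
  expect_equal(nchar(rec$ss8), m)
  expect_length(rec$asa, m)
  expect_equal(dim(rec$distmap), c(m, m))
  expect_equal(rec$kind, "distance")
  expect_identical(gen_protein_record(spec, "P001", seed = 4), rec)
  # consecutive residues sit at the fixed walk step length
  steps <- vapply(seq_len(m - 1), function(i) rec$distmap[i, i + 1],
                  numeric(1))
  expect_equal(steps, rep(3.8, m - 1), tolerance = 1e-6)
})

test_that("noiseless labels reproduce the printed descriptor formula", {
  spec <- dta_fixture_spec(n_drugs = 6, n_proteins = 4, n_pairs = 20,
                           noise_sd = 0, seed = 8)
  ds <- gen_dataset(spec)
  for (k in seq_len(nrow(ds$pairs))) {
    did <- ds$pairs$drug_id[k]; pid <- ds$pairs$protein_id[k]
    mol <- parse_molecule(ds$drugs[[did]], source_id = did)
    rec <- ds$proteins[[pid]]
    # independent evaluation with the printed weights (2, 1.5, 1, 1.5, 2)
    helix <- mean(strsplit(rec$ss8, "")[[1]] %in% c("H", "G", "I"))
    expected <- 2.0 * n_atoms(mol) / 64 +
      1.5 * mol$n_aromatic_rings / 6 +
      1.0 * mean(rec$asa) +
      1.5 * helix +
      2.0 * (mol$n_aromatic_rings / 6) * helix
    expect_equal(ds$pairs$affinity[k], expected, tolerance = 1e-12)
  }
  expect_identical(gen_dataset(spec)$pairs, ds$pairs)
})

test_that("label noise adds the configured variance", {
  base <- dta_fixture_spec(n_drugs = 20, n_proteins = 20, n_pairs = 400,
                           noise_sd = 0, seed = 12)
  noisy <- dta_fixture_spec(n_drugs = 20, n_proteins = 20, n_pairs = 400,
                            noise_sd = 0.1, seed = 12)
  y0 <- gen_dataset(base)$pairs$affinity
  y1 <- gen_dataset(noisy)$pairs$affinity
  resid <- y1 - y0
  expect_equal(mean(resid), 0, tolerance = 0.02)
  expect_equal(stats::sd(resid), 0.1, tolerance = 0.02)
  expect_lt(abs(stats::var(y1) - stats::var(y0) - 0.01), 0.02)
})

test_that("datasets round-trip through the on-disk pipeline formats", {
  spec <- dta_fixture_spec(n_drugs = 4, n_proteins = 3, n_pairs = 12,
                           protein_length = c(12, 18), seed = 3)
  ds <- gen_dataset(spec)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "drugs.csv")))
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  back <- load_dataset(file.path(dir, "manifest.tsv"),
                       file.path(dir, "drugs.csv"),
                       file.path(dir, "proteins"))
  expect_equal(back$pairs$affinity, ds$pairs$affinity, tolerance = 1e-6)
  expect_equal(back$pairs$drug_id, ds$pairs$drug_id)
  expect_equal(sort(names(back$proteins)), sort(names(ds$proteins)))
  p1 <- names(ds$proteins)[1]
  expect_equal(back$proteins[[p1]]$sequence, ds$proteins[[p1]]$sequence)
  # loader validation: all generated artifacts pass without warnings
  expect_silent(build_protein_graph(back$proteins[[p1]],
                                    synthetic_embedding_provider(16)))
})

test_that("the loader skips missing affinities and rejects dangling ids", {
  spec <- dta_fixture_spec(n_drugs = 3, n_proteins = 2, n_pairs = 6,
                           protein_length = c(10, 12), seed = 5)
  ds <- gen_dataset(spec)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  man <- file.path(dir, "manifest.tsv")
  rows <- readLines(man)
  # blank out one affinity
  parts <- strsplit(rows[2], "\t")[[1]]
  rows[2] <- paste(parts[1], parts[2], "NA", sep = "\t")
  writeLines(rows, man)
  expect_message(back <- load_dataset(man, file.path(dir, "drugs.csv"),
                                      file.path(dir, "proteins")),
                 "skipping 1")
  expect_equal(nrow(back$pairs), nrow(ds$pairs) - 1L)
  # dangling drug id errors with the offending id
  rows[3] <- sub("^D[0-9]+", "D999", rows[3])
  writeLines(rows, man)
  expect_error(load_dataset(man, file.path(dir, "drugs.csv"),
                            file.path(dir, "proteins")), "D999")
})

test_that("kd_nM affinities are transformed to pKd at load", {
  dir <- withr::local_tempdir()
  spec <- dta_fixture_spec(n_drugs = 2, n_proteins = 1, n_pairs = 2,
                           protein_length = c(10, 10), seed = 6)
  ds <- gen_dataset(spec)
  ds$pairs$affinity <- c(1e9, 1)  # 1 M and 1 nM
  write_dataset(ds, dir)
  back <- load_dataset(file.path(dir, "manifest.tsv"),
                       file.path(dir, "drugs.csv"),
                       file.path(dir, "proteins"), affinity_kind = "kd_nM")
  expect_equal(sort(back$pairs$affinity), c(0, 9))
  expect_equal(back$affinity_kind, "pkd")
})
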