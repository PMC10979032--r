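# Structural encodings: shortest-path distances, degree augmentation,
# spatial and edge-path attention biases.

test_that("compute_spd matches hand cases and marks unreachable pairs", {
  # path graph 0-1-2 (1-based here)
  a <- matrix(0L, 3, 3); a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- 1L
  spd <- compute_spd(a)
  expect_equal(spd[1, 3], 2L)
  expect_equal(diag(spd), rep(0L, 3))
  # two disconnected components
  b <- matrix(0L, 4, 4); b[1, 2] <- b[2, 1] <- b[3, 4] <- b[4, 3] <- 1L
  spdb <- compute_spd(b)
  expect_equal(spdb[1, 3], -1L)
  expect_equal(spdb[2, 4], -1L)
  expect_equal(spdb[1, 2], 1L)
  # single node
  expect_equal(compute_spd(matrix(0L, 1, 1)), matrix(0L, 1, 1))
})

test_that("compute_spd equals the Floyd-Warshall oracle on random graphs", {
  withr::with_seed(42, {
    for (rep in 1:200) {
      n <- sample(2:12, 1)
      a <- random_adjacency(n, p = stats::runif(1, 0.15, 0.6))
      expect_identical(compute_spd(a), fw_oracle(a))
    }
  })
})

test_that("degree_encode adds bucketed embeddings with clipping", {
  d <- 4L
  tab <- list(in_table = matrix(0, 17, d), out_table = matrix(0, 17, d),
              max_degree_bucket = 16L)
  x <- matrix(rnorm(3 * d), 3, d)
  # all-zero tables: identity
  expect_equal(degree_encode(x, c(0, 2, 5), tab), x)
  # nonzero tables: in and out lookups keyed by the same undirected degree
  withr::with_seed(1, {
    tab$in_table <- matrix(rnorm(17 * d), 17, d)
    tab$out_table <- matrix(rnorm(17 * d), 17, d)
  })
  h <- degree_encode(x, c(0, 2, 5), tab)
  expect_equal(h[2, ], x[2, ] + tab$in_table[3, ] + tab$out_table[3, ])
  # clipping: degree 40 uses the bucket for 16
  h2 <- degree_encode(x[1, , drop = FALSE], 40, tab)
  expect_equal(h2[1, ], x[1, ] + tab$in_table[17, ] + tab$out_table[17, ])
  expect_error(degree_encode(x, c(-1, 0, 1), tab))
})

test_that("spatial_bias looks up per-bucket scalars with unreachable bucket", {
  a <- matrix(0L, 3, 3); a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- 1L
  spd <- compute_spd(a)
  w <- rep(0, 22)
  expect_equal(spatial_bias(spd, w), matrix(0, 3, 3))
  # one-hot on bucket for distance 1: bias is 1 exactly at adjacent pairs
  w1 <- rep(0, 22); w1[2] <- 1
  expect_equal(spatial_bias(spd, w1), matrix(as.numeric(a), 3, 3))
  # unreachable pairs take the dedicated last bucket
  b <- matrix(0L, 4, 4); b[1, 2] <- b[2, 1] <- b[3, 4] <- b[4, 3] <- 1L
  wu <- rep(0, 22); wu[22] <- 5
  sb <- spatial_bias(compute_spd(b), wu)
  expect_equal(sb[1, 3], 5)
  expect_equal(sb[1, 2], 0)
  # symmetric input gives symmetric bias on random graphs
  withr::with_seed(3, {
    for (rep in 1:20) {
      g <- random_adjacency(sample(3:10, 1), 0.4)
      wr <- rnorm(22)
      bias <- spatial_bias(compute_spd(g), wr)
      expect_equal(bias, t(bias))
    }
  })
})

test_that("edge_path_bias averages bond projections along one shortest path", {
  mol <- parse_molecule("CCO")
  g <- build_drug_graph(mol)
  spd <- compute_spd(g)
  tab <- list(w_edge = c(1, 0, 0), max_path_len = 20L)
  bias <- edge_path_bias(g, spd, tab)
  # adjacent pair: the single bond's projection (b1 code of a single bond = 0)
  expect_equal(bias[1, 2], g$edges$b1[1] * 1)
  # two-hop path with equal bond features: mean equals the single-bond value
  tab2 <- list(w_edge = c(0, 0, 1), max_path_len = 20L)
  b2 <- edge_path_bias(g, spd, tab2)
  expect_equal(b2[1, 3], mean(g$edges$b3))
  expect_equal(diag(bias), rep(0, 3))
})

test_that("edge_path_bias matches the exhaustive path-enumeration oracle", {
  withr::with_seed(11, {
    for (m in test_mol_pool()) {
      g <- build_drug_graph(m)
      n <- nrow(g$adjacency)
      if (n > 10) next
      spd <- compute_spd(g)
      w <- rnorm(3)
      tab <- list(w_edge = w, max_path_len = 20L)
      bias <- edge_path_bias(g, spd, tab)
      bf <- as.matrix(g$edges[, c("b1", "b2", "b3")])
      key <- paste(g$edges$i, g$edges$j)
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        p <- lex_shortest_path_oracle(g$adjacency, i, j)
        if (is.null(p)) { expect_equal(bias[i, j], 0); next }
        a <- p[-length(p)]; b <- p[-1L]
        rows <- match(paste(pmin(a, b), pmax(a, b)), key)
        expect_equal(bias[i, j],
                     mean(bf[rows, , drop = FALSE] %*% w),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("encodings are invariant to isomorphic relabelling", {
  withr::with_seed(13, {
    for (m in test_mol_pool()[c(1, 3, 5)]) {
      n <- n_atoms(m)
      perm <- sample(n)
      mp <- permute_molecule(m, perm)
      g <- build_drug_graph(m); gp <- build_drug_graph(mp)
      spd <- compute_spd(g); spdp <- compute_spd(gp)
      expect_equal(spdp, spd[perm, perm])
      w <- rnorm(22); tab <- list(w_edge = rnorm(3), max_path_len = 20L)
      expect_equal(spatial_bias(spdp, w), spatial_bias(spd, w)[perm, perm])
      expect_equal(edge_path_bias(gp, spdp, tab),
                   edge_path_bias(g, spd, tab)[perm, perm])
    }
  })
})

test_that("zero weights give the zero bias set (ablation baseline)", {
  g <- build_drug_graph(parse_molecule("CC(=O)Oc1ccccc1C(=O)O"))
  bs <- attention_bias_set(g, w_phi = rep(0, 22),
                           edge_table = list(w_edge = c(0, 0, 0),
                                             max_path_len = 20L))
  expect_true(all(bs$spatial_bias == 0))
  expect_true(all(bs$edge_bias == 0))
  expect_equal(dim(bs$spatial_bias), dim(g$adjacency))
})
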