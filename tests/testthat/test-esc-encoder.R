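# Sparse-attention drug encoder: sparsity scores, top-S attention,
# convolutional distillation, and the full sandwich.

test_that("query sparsity scores rank informative queries higher", {
  # identical queries score equally
  q <- matrix(1, 4, 3)
  k <- matrix(rnorm(12), 4, 3)
  sc <- query_sparsity_scores(q, k)
  expect_equal(sc, rep(sc[1], 4))
  # a query aligned to one key scores higher than one orthogonal to all
  k2 <- rbind(c(10, 0, 0, 0), c(0, 10, 0, 0), c(0, 0, 10, 0), c(0, 0, 0, 0))
  q2 <- rbind(c(10, 0, 0, 0),   # strongly aligned to key 1
              c(0, 0, 0, 10))   # orthogonal to every key
  sc2 <- query_sparsity_scores(q2, k2)
  expect_gt(sc2[1], sc2[2])
  # element-wise agreement with a direct evaluation on random input
  withr::with_seed(8, {
    qq <- matrix(rnorm(80), 10, 8); kk <- matrix(rnorm(80), 10, 8)
    u <- qq %*% t(kk) / sqrt(8)
    expect_equal(query_sparsity_scores(qq, kk),
                 apply(u, 1, max) - rowMeans(u), tolerance = 1e-12)
  })
})

test_that("sparse attention reduces to dense attention when S >= L", {
  withr::with_seed(21, {
    for (rep in 1:25) {
      L <- sample(2:12, 1); d <- sample(c(4, 8), 1)
      h <- matrix(rnorm(L * d), L, d)
      p <- list(w_q = matrix(rnorm(d * d) / 2, d, d),
                w_k = matrix(rnorm(d * d) / 2, d, d),
                w_v = matrix(rnorm(d * d) / 2, d, d),
                top_s = L)
      out <- sparsepro_attention(h, bias = NULL, params = p)
      expect_lt(max(abs(out - dense_attention_oracle(h, p$w_q, p$w_k,
                                                     p$w_v))), 1e-6)
    }
  })
})

test_that("non-selected queries emit the mean value vector", {
  withr::with_seed(22, {
    L <- 8L; d <- 4L
    h <- matrix(rnorm(L * d), L, d)
    p <- list(w_q = matrix(rnorm(d * d), d, d),
              w_k = matrix(rnorm(d * d), d, d),
              w_v = matrix(rnorm(d * d), d, d), top_s = 3L)
    out <- sparsepro_attention(h, NULL, p)
    sel <- order(-query_sparsity_scores(h %*% p$w_q, h %*% p$w_k),
                 seq_len(L))[1:3]
    v <- h %*% p$w_v
    meanv <- colMeans(v)
    for (i in setdiff(seq_len(L), sel))
      expect_equal(out[i, ], meanv, tolerance = 1e-12)
    # selected rows equal the dense-attention rows
    dense <- dense_attention_oracle(h, p$w_q, p$w_k, p$w_v)
    for (i in sel) expect_equal(out[i, ], dense[i, ], tolerance = 1e-12)
  })
})

test_that("identical keys with zero bias yield the mean value vector", {
  withr::with_seed(23, {
    d <- 4L
    h <- matrix(rnorm(d), 1, d)[rep(1, 6), ]  # six identical nodes
    p <- list(w_q = matrix(rnorm(d * d), d, d),
              w_k = matrix(rnorm(d * d), d, d),
              w_v = matrix(rnorm(d * d), d, d), top_s = 10L)
    out <- sparsepro_attention(h, NULL, p)
    v <- h %*% p$w_v
    for (i in 1:6) expect_equal(out[i, ], colMeans(v), tolerance = 1e-12)
  })
})

test_that("attention is invariant to constant logit shifts", {
  withr::with_seed(24, {
    L <- 7L; d <- 4L
    h <- matrix(rnorm(L * d), L, d)
    p <- list(w_q = matrix(rnorm(d * d), d, d),
              w_k = matrix(rnorm(d * d), d, d),
              w_v = matrix(rnorm(d * d), d, d), top_s = 4L)
    b0 <- list(spatial_bias = matrix(rnorm(L * L), L, L))
    bc <- list(spatial_bias = b0$spatial_bias + 3.7)
    expect_equal(sparsepro_attention(h, b0, p),
                 sparsepro_attention(h, bc, p), tolerance = 1e-10)
  })
})

test_that("distillation convolves, rectifies and halves the node axis", {
  d <- 3L
  zero_block <- list(w_prev = matrix(0, d, d), w_center = matrix(0, d, d),
                     w_next = matrix(0, d, d), b = matrix(0, 1, d))
  x0 <- matrix(0, 6, d)
  expect_equal(gcn_distill(x0, zero_block), matrix(0, 3, d))
  # shape contract
  id_block <- list(w_prev = matrix(0, d, d), w_center = diag(d),
                   w_next = matrix(0, d, d), b = matrix(0, 1, d))
  x8 <- matrix(abs(rnorm(8 * d)) + 0.1, 8, d)
  expect_equal(nrow(gcn_distill(x8, id_block)), 4L)
  # identity kernel on strictly positive input: strided max of rows
  x5 <- matrix(c(1, 5, 2, 4, 3,
                 2, 1, 6, 2, 1) + 0.5, 5, 2)
  out <- gcn_distill(x5, list(w_prev = matrix(0, 2, 2), w_center = diag(2),
                              w_next = matrix(0, 2, 2), b = matrix(0, 1, 2)))
  man <- rbind(apply(x5[1:2, ], 2, max), apply(x5[2:4, ], 2, max),
               apply(x5[4:5, ], 2, max))
  expect_equal(out, man)
})

test_that("the full encoder is deterministic with the right shape", {
  model <- dta_init_model(dta_config(), 16, seed = 4)
  for (m in test_mol_pool()[c(1, 3, 4)]) {
    g <- build_drug_graph(m)
    x1 <- esc_forward(g, model)
    x2 <- esc_forward(g, model)
    expect_identical(x1, x2)
    expect_equal(dim(x1), c(1L, model$config$d))
    expect_true(all(is.finite(x1)))
  }
  # single atom degenerates gracefully
  g1 <- build_drug_graph(parse_molecule("C"))
  x <- esc_forward(g1, model)
  expect_equal(dim(x), c(1L, model$config$d))
  expect_true(all(is.finite(x)))
  # zero-weight stack collapses to zero output
  mz <- model
  for (nm in names(mz$params)) mz$params[[nm]][] <- 0
  expect_true(all(esc_forward(build_drug_graph(test_mol_pool()[[3]]),
                              mz) == 0))
})
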