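# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: direct summation formulas, Floyd-Warshall,
# exhaustive path enumeration, dense attention written out longhand.

# all-pairs shortest paths by Floyd-Warshall on a 0/1 adjacency
fw_oracle <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d[is.infinite(d)] <- -1
  storage.mode(d) <- "integer"
  d
}

# random symmetric 0/1 adjacency with zero diagonal
random_adjacency <- function(n, p = 0.3) {
  a <- matrix(0L, n, n)
  if (n >= 2) {
    up <- which(upper.tri(a))
    on <- up[stats::runif(length(up)) < p]
    a[on] <- 1L
    a[lower.tri(a)] <- t(a)[lower.tri(a)]
  }
  a
}

# dense softmax attention written out longhand
dense_attention_oracle <- function(h, wq, wk, wv, bias = NULL) {
  q <- h %*% wq; k <- h %*% wk; v <- h %*% wv
  logits <- q %*% t(k) / sqrt(ncol(h))
  if (!is.null(bias)) logits <- logits + bias
  a <- exp(logits - apply(logits, 1, max))
  a <- a / rowSums(a)
  a %*% v
}

# direct-summation regression metrics (textbook formulas)
metrics_oracle <- function(y, yhat) {
  n <- length(y)
  mse <- sum((y - yhat)^2) / n
  mx <- sum(yhat) / n; my <- sum(y) / n
  pearson <- sum((yhat - mx) * (y - my)) /
    (sqrt(sum((yhat - mx)^2)) * sqrt(sum((y - my)^2)))
  ry <- rank(y); rx <- rank(yhat)
  a <- ry - mean(ry); b <- rx - mean(rx)
  spearman <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  r2 <- 1 - sum((yhat - y)^2) / sum((my - y)^2)
  list(mse = mse, rmse = sqrt(mse), pearson = pearson, spearman = spearman,
       r2 = r2)
}

# O(n^2) concordance index by explicit pair enumeration (vectorized)
ci_oracle <- function(y, yhat) {
  dy <- outer(y, y, "-")
  dx <- outer(yhat, yhat, "-")
  sel <- dy > 0
  z <- sum(sel)
  if (z == 0) return(NA_real_)
  h <- ifelse(dx[sel] > 0, 1, ifelse(dx[sel] == 0, 0.5, 0))
  sum(h) / z
}

# all shortest paths between i and j (node sequences) by BFS layering;
# returns the lexicographically smallest
lex_shortest_path_oracle <- function(adj, i, j) {
  n <- nrow(adj)
  d <- fw_oracle(adj)
  if (d[i, j] < 0) return(NULL)
  if (i == j) return(i)
  paths <- list(i)
  for (step in seq_len(d[i, j])) {
    nxt <- list()
    for (p in paths) {
      last <- p[length(p)]
      for (v in which(adj[last, ] == 1L))
        if (d[v, j] == d[last, j] - 1) nxt[[length(nxt) + 1L]] <- c(p, v)
    }
    paths <- nxt
  }
  keys <- vapply(paths, function(p) paste(sprintf("%04d", p), collapse = ""),
                 "")
  paths[[order(keys)[1L]]]
}

# a small pool of parsed molecules shared by tests (parsing is the slow bit)
test_mol_pool <- local({
  pool <- NULL
  function() {
    if (is.null(pool)) {
      smis <- c("CCO", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O",
                "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "C1CCNCC1", "N#Cc1ccccc1",
                "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "c1ccc2[nH]ccc2c1",
                "O=S(=O)(N)c1ccccc1", "NCCO")
      pool <<- lapply(seq_along(smis), function(k)
        parse_molecule(smis[k], source_id = sprintf("T%02d", k)))
    }
    pool
  }
})

# tiny deterministic protein record for reuse
test_protein_record <- function(m = 10L, seed = 1L, kind = "distance") {
  spec <- dta_fixture_spec(n_drugs = 1L, n_proteins = 1L, n_pairs = 1L,
                           protein_length = c(m, m), seed = seed)
  gen_protein_record(spec, protein_id = sprintf("TP%02d", seed), seed = seed)
}
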