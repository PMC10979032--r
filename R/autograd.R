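# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Nodes are environments linked in creation order (a reverse-linked list);
# backward() walks the chain from the newest node down, so every node is
# visited after all of its consumers.  Node fields: v (value, numeric
# matrix), g (accumulated gradient or NULL), bw (backward closure), prev.
# Constant nodes skip gradient accumulation.  The engine is deliberately
# small: it supports exactly the operations the affinity model needs, all
# shapes are (rows x features) matrices, and scalars are 1 x 1.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$last <- NULL
  tp
}

.ad_new <- function(tape, value, bw = NULL, const = FALSE) {
  # force the value before linking: argument promises may create parent
  # nodes, which must precede this node in the chain
  force(value)
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  nd$bw <- bw
  nd$const <- const
  nd$prev <- tape$last
  tape$last <- nd
  nd
}

.ad_acc <- function(nd, g) {
  if (nd$const) return(invisible(NULL))
  nd$g <- if (is.null(nd$g)) g else nd$g + g
  invisible(NULL)
}

ad_const <- function(tape, x) .ad_new(tape, as.matrix(x), const = TRUE)

ad_leaf <- function(tape, x) .ad_new(tape, as.matrix(x))

ad_value <- function(nd) nd$v

#' @keywords internal
ad_backward <- function(tape, loss) {
  loss$g <- matrix(1, 1L, 1L)
  nd <- tape$last
  while (!is.null(nd)) {
    if (!is.null(nd$g) && !is.null(nd$bw)) nd$bw(nd)
    nd <- nd$prev
  }
  invisible(NULL)
}

# ---- arithmetic ----------------------------------------------------------

ad_mm <- function(tape, a, b) {
  .ad_new(tape, a$v %*% b$v, bw = function(nd) {
    .ad_acc(a, tcrossprod(nd$g, b$v))
    .ad_acc(b, crossprod(a$v, nd$g))
  })
}

# constant %*% node
ad_cmm <- function(tape, C, b) {
  .ad_new(tape, C %*% b$v, bw = function(nd) .ad_acc(b, crossprod(C, nd$g)))
}

ad_t <- function(tape, a) {
  .ad_new(tape, t(a$v), bw = function(nd) .ad_acc(a, t(nd$g)))
}

ad_add <- function(tape, a, b) {
  .ad_new(tape, a$v + b$v, bw = function(nd) {
    .ad_acc(a, nd$g); .ad_acc(b, nd$g)
  })
}

ad_addc <- function(tape, a, C) {
  .ad_new(tape, a$v + C, bw = function(nd) .ad_acc(a, nd$g))
}

ad_scale <- function(tape, a, s) {
  .ad_new(tape, a$v * s, bw = function(nd) .ad_acc(a, nd$g * s))
}

# a %*% W + bias row, fused: the workhorse affine map
ad_affine <- function(tape, a, W, B) {
  v <- a$v %*% W$v
  .ad_new(tape, v + rep(B$v, each = nrow(v)), bw = function(nd) {
    .ad_acc(a, tcrossprod(nd$g, W$v))
    .ad_acc(W, crossprod(a$v, nd$g))
    .ad_acc(B, matrix(colSums(nd$g), 1L))
  })
}

# add a 1 x d bias row to every row of a
ad_addbias <- function(tape, a, b) {
  .ad_new(tape, a$v + rep(b$v, each = nrow(a$v)), bw = function(nd) {
    .ad_acc(a, nd$g)
    .ad_acc(b, matrix(colSums(nd$g), 1L))
  })
}

# ---- nonlinearities ------------------------------------------------------

ad_relu <- function(tape, a) {
  v <- a$v; v[v < 0] <- 0
  .ad_new(tape, v, bw = function(nd) .ad_acc(a, nd$g * (a$v > 0)))
}

ad_elu <- function(tape, a) {
  v <- a$v
  neg <- v <= 0
  v[neg] <- exp(v[neg]) - 1
  .ad_new(tape, v, bw = function(nd) {
    d <- nd$g
    d[neg] <- d[neg] * (v[neg] + 1)
    .ad_acc(a, d)
  })
}

# row-wise softmax
ad_softmax_rows <- function(tape, a) {
  x <- a$v
  mx <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - mx)
  v <- e / rowSums(e)
  .ad_new(tape, v, bw = function(nd) {
    .ad_acc(a, v * (nd$g - rowSums(nd$g * v)))
  })
}

# ---- indexing and lookups ------------------------------------------------

# select rows by (possibly repeated) index; gradient scatter-adds
ad_rows <- function(tape, a, idx) {
  .ad_new(tape, a$v[idx, , drop = FALSE], bw = function(nd) {
    if (a$const) return(invisible(NULL))
    g <- matrix(0, nrow(a$v), ncol(a$v))
    part <- rowsum(nd$g, group = idx)
    g[as.integer(rownames(part)), ] <- part
    .ad_acc(a, g)
  })
}

# sum of embedding-table row lookups: value = sum_k tables[[k]][idxs[[k]], ];
# gradients accumulate in place on the touched rows only
ad_embed_sum <- function(tape, tables, idxs) {
  v <- tables[[1L]]$v[idxs[[1L]], , drop = FALSE]
  for (k in seq_along(tables)[-1L])
    v <- v + tables[[k]]$v[idxs[[k]], , drop = FALSE]
  .ad_new(tape, v, bw = function(nd) {
    for (k in seq_along(tables)) {
      tb <- tables[[k]]
      if (tb$const) next
      if (is.null(tb$g)) tb$g <- matrix(0, nrow(tb$v), ncol(tb$v))
      part <- rowsum(nd$g, group = idxs[[k]])
      r <- as.integer(rownames(part))
      tb$g[r, ] <- tb$g[r, , drop = FALSE] + part
    }
  })
}

# principal submatrix (rows and columns at idx)
ad_submat <- function(tape, a, idx) {
  .ad_new(tape, a$v[idx, idx, drop = FALSE], bw = function(nd) {
    if (a$const) return(invisible(NULL))
    g <- matrix(0, nrow(a$v), ncol(a$v))
    g[idx, idx] <- nd$g
    .ad_acc(a, g)
  })
}

# matrix-shaped lookup into a parameter vector (n x 1): value[r, c] =
# vec[idxm[r, c]]; gradient scatter-adds over buckets
ad_lookup <- function(tape, a, idxm) {
  .ad_new(tape, matrix(a$v[as.vector(idxm)], nrow(idxm), ncol(idxm)),
          bw = function(nd) {
    if (a$const) return(invisible(NULL))
    g <- matrix(0, nrow(a$v), 1L)
    part <- rowsum(as.vector(nd$g), group = as.vector(idxm))
    g[as.integer(rownames(part)), 1L] <- part
    .ad_acc(a, g)
  })
}

# mean bond-feature array (n x n x 3) projected through a 3 x 1 parameter:
# the edge-path bias as one differentiable op
ad_edge_bias <- function(tape, w, arr) {
  v <- arr[, , 1L] * w$v[1L] + arr[, , 2L] * w$v[2L] + arr[, , 3L] * w$v[3L]
  .ad_new(tape, v, bw = function(nd) {
    .ad_acc(w, matrix(c(sum(nd$g * arr[, , 1L]),
                        sum(nd$g * arr[, , 2L]),
                        sum(nd$g * arr[, , 3L])), 3L, 1L))
  })
}

# ---- pooling and reshaping -----------------------------------------------

# column-wise max over rows -> 1 x d (global max pooling)
ad_colmax <- function(tape, a) {
  w <- max.col(t(a$v), ties.method = "first")
  v <- matrix(a$v[cbind(w, seq_along(w))], 1L)
  .ad_new(tape, v, bw = function(nd) {
    if (a$const) return(invisible(NULL))
    g <- matrix(0, nrow(a$v), ncol(a$v))
    g[cbind(w, seq_along(w))] <- as.numeric(nd$g)
    .ad_acc(a, g)
  })
}

# centers of the width-3, stride-2, same-padded pooling windows over L rows
dta_pool_centers <- function(L) seq(1L, L, by = 2L)

# max pooling over the row axis: window 3, stride 2, same-padded; output
# row t covers input rows {2t-2, 2t-1, 2t} intersected with 1..L; ties
# resolve to the smallest input row
ad_maxpool_rows <- function(tape, a) {
  v <- a$v
  L <- nrow(v); d <- ncol(v)
  centers <- dta_pool_centers(L)
  nc <- length(centers)
  up <- centers - 1L; dn <- centers + 1L
  m0 <- v[centers, , drop = FALSE]
  m_up <- matrix(-Inf, nc, d); m_dn <- matrix(-Inf, nc, d)
  oku <- up >= 1L; okd <- dn <= L
  m_up[oku, ] <- v[up[oku], , drop = FALSE]
  m_dn[okd, ] <- v[dn[okd], , drop = FALSE]
  out <- pmax(m0, m_up, m_dn)
  arg <- matrix(rep(dn, d), nc, d)
  arg[m0 == out] <- centers[row(arg)[m0 == out]]
  arg[m_up == out] <- up[row(arg)[m_up == out]]
  .ad_new(tape, out, bw = function(nd) {
    g <- matrix(0, L, d)
    lin <- as.vector(arg) + (rep(seq_len(d), each = nc) - 1L) * L
    part <- rowsum(as.vector(nd$g), group = lin)
    g[as.integer(rownames(part))] <- part
    .ad_acc(a, g)
  })
}

ad_rbind <- function(tape, a, b) {
  na <- nrow(a$v)
  .ad_new(tape, rbind(a$v, b$v), bw = function(nd) {
    .ad_acc(a, nd$g[seq_len(na), , drop = FALSE])
    .ad_acc(b, nd$g[-seq_len(na), , drop = FALSE])
  })
}

ad_cbind <- function(tape, a, b) {
  na <- ncol(a$v)
  .ad_new(tape, cbind(a$v, b$v), bw = function(nd) {
    .ad_acc(a, nd$g[, seq_len(na), drop = FALSE])
    .ad_acc(b, nd$g[, -seq_len(na), drop = FALSE])
  })
}

# row-wise rescale by a constant vector (premultiplication by diag(s))
ad_diagscale <- function(tape, a, s) {
  .ad_new(tape, a$v * s, bw = function(nd) .ad_acc(a, nd$g * s))
}

# elementwise multiply by a constant mask (dropout: mask already rescaled)
ad_mask <- function(tape, a, mask) {
  .ad_new(tape, a$v * mask, bw = function(nd) .ad_acc(a, nd$g * mask))
}

# sum of squared differences against a constant target -> 1 x 1
ad_sqerr <- function(tape, a, target) {
  diff <- a$v - target
  .ad_new(tape, matrix(sum(diff * diff), 1L, 1L), bw = function(nd) {
    .ad_acc(a, 2 * diff * as.numeric(nd$g))
  })
}
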