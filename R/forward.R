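# Model forward passes.  Every exported operation below is a thin wrapper
# around the same autodiff forward pieces the training loop uses, evaluated
# on a throwaway tape, so the tested math and the trained math are one
# implementation.

# ---- building blocks (node-level) ----------------------------------------

.fwd_gcn <- function(tp, H, ahat, W) {
  ad_relu(tp, ad_mm(tp, ad_cmm(tp, ahat, H), W))
}

.fwd_res <- function(tp, H, W1, B1, W2) {
  inner <- ad_mm(tp, ad_relu(tp, ad_affine(tp, H, W1, B1)), W2)
  ad_relu(tp, ad_add(tp, inner, H))
}

# sparse self-attention with additive pair bias; bias may be NULL, a numeric
# matrix, or a tape node
.fwd_attention <- function(tp, X, Wq, Wk, Wv, bias, top_s) {
  d <- ncol(X$v)
  L <- nrow(X$v)
  Q <- ad_mm(tp, X, Wq)
  K <- ad_mm(tp, X, Wk)
  V <- ad_mm(tp, X, Wv)
  logits <- ad_scale(tp, ad_mm(tp, Q, ad_t(tp, K)), 1 / sqrt(d))
  if (!is.null(bias)) {
    logits <- if (is.matrix(bias)) ad_addc(tp, logits, bias)
              else ad_add(tp, logits, bias)
  }
  A <- ad_softmax_rows(tp, logits)
  s_eff <- min(top_s, L)
  sc <- query_sparsity_scores(Q$v, K$v)
  sel <- order(-sc, seq_along(sc))[seq_len(s_eff)]
  selvec <- numeric(L); selvec[sel] <- 1
  W <- ad_diagscale(tp, A, selvec)
  if (s_eff < L)
    W <- ad_addc(tp, W, outer(1 - selvec, rep(1 / L, L)))
  ad_mm(tp, W, V)
}

.fwd_distill <- function(tp, X, Wm, W0, Wp, B) {
  L <- nrow(X$v)
  Sm <- matrix(0, L, L); Sp <- matrix(0, L, L)
  if (L >= 2L) {
    Sm[cbind(2:L, 1:(L - 1L))] <- 1
    Sp[cbind(1:(L - 1L), 2:L)] <- 1
  }
  conv <- ad_addbias(tp, ad_add(tp, ad_add(tp,
    ad_mm(tp, ad_cmm(tp, Sm, X), Wm),
    ad_mm(tp, X, W0)),
    ad_mm(tp, ad_cmm(tp, Sp, X), Wp)), B)
  ad_maxpool_rows(tp, ad_elu(tp, conv))
}

# ESC drug encoder: embeddings (+ degree augmentation), spatial/edge-path
# attention biases, three sparse-attention layers with residual skips
# interleaved with two distillation layers, final global max pool
.fwd_esc <- function(tp, P, dc, config) {
  tables <- lapply(1:9, function(k) P[[sprintf("esc_emb_a%d", k)]])
  idxs <- dc$idx9
  if (config$use_degree) {
    tables <- c(tables, list(P$esc_deg_in, P$esc_deg_out))
    idxs <- c(idxs, list(dc$deg_idx, dc$deg_idx))
  }
  X <- ad_embed_sum(tp, tables, idxs)
  bias <- NULL
  if (config$use_spatial)
    bias <- ad_lookup(tp, P$esc_wphi, dc$spd_idx)
  if (config$use_edge) {
    eb <- ad_edge_bias(tp, P$esc_wedge, dc$path_arr)
    bias <- if (is.null(bias)) eb else ad_add(tp, bias, eb)
  }
  surv <- seq_len(dc$n)
  for (l in 1:3) {
    bl <- if (is.null(bias)) NULL
          else if (length(surv) == dc$n) bias
          else ad_submat(tp, bias, surv)
    attn <- .fwd_attention(tp, X,
                           P[[sprintf("esc_attn%d_wq", l)]],
                           P[[sprintf("esc_attn%d_wk", l)]],
                           P[[sprintf("esc_attn%d_wv", l)]],
                           bl, config$top_s)
    X <- ad_add(tp, X, attn)
    if (l < 3L) {
      X <- .fwd_distill(tp, X,
                        P[[sprintf("esc_conv%d_wm", l)]],
                        P[[sprintf("esc_conv%d_w0", l)]],
                        P[[sprintf("esc_conv%d_wp", l)]],
                        P[[sprintf("esc_conv%d_b", l)]])
      surv <- surv[dta_pool_centers(length(surv))]
    }
  }
  ad_colmax(tp, X)
}

# molecular-graph encoder: attribute embeddings, GCN blocks, residual
# blocks, global max pool, two linear layers
.fwd_mol <- function(tp, P, dc, config) {
  mi <- dc$mol_idx
  Y <- ad_embed_sum(tp, list(P$mol_emb_elem, P$mol_emb_deg, P$mol_emb_idx,
                             P$mol_emb_val, P$mol_emb_chg, P$mol_emb_hyb),
                    list(mi$elem, mi$deg, mi$pos, mi$val, mi$chg, mi$hyb))
  for (b in seq_len(config$gcn_blocks))
    Y <- .fwd_gcn(tp, Y, dc$ahat, P[[sprintf("mol_gcn%d_w", b)]])
  for (r in seq_len(config$res_blocks))
    Y <- .fwd_res(tp, Y, P[[sprintf("mol_res%d_w1", r)]],
                  P[[sprintf("mol_res%d_b1", r)]],
                  P[[sprintf("mol_res%d_w2", r)]])
  vmax <- ad_colmax(tp, Y)
  ad_affine(tp, ad_affine(tp, vmax, P$mol_lin0_w, P$mol_lin0_b),
            P$mol_lin1_w, P$mol_lin1_b)
}

# early fusion + heterograph refinement; returns refined drug row and
# protein rows (masked separation)
.fwd_fusion <- function(tp, P, pc, xd, config) {
  drugrow <- ad_affine(tp, xd, P$fus_proj_w, P$fus_proj_b)
  prot <- ad_affine(tp, ad_const(tp, pc$features), P$prot_proj_w,
                    P$prot_proj_b)
  H <- ad_rbind(tp, drugrow, prot)
  H <- .fwd_gcn(tp, H, pc$ahat_fused, P$dtg_gcn1_w)
  for (r in seq_len(config$res_blocks))
    H <- .fwd_res(tp, H, P[[sprintf("dtg_res%d_w1", r)]],
                  P[[sprintf("dtg_res%d_b1", r)]],
                  P[[sprintf("dtg_res%d_w2", r)]])
  list(drug = ad_rows(tp, H, 1L),
       protein = ad_rows(tp, H, 2:(pc$m + 1L)))
}

# regression head: drug path (pre-fusion global feature + refined super
# node), protein path (GCN -> pool -> ReLU -> linear), fully connected block
.fwd_head <- function(tp, P, x_esc, drug_row, prot_rows, ahat_p, config,
                      training = FALSE) {
  dg <- ad_relu(tp, ad_mm(tp, drug_row, P$head_dgcn_w))
  xd_final <- ad_cbind(tp, x_esc, dg)
  pg <- .fwd_gcn(tp, prot_rows, ahat_p, P$head_pgcn_w)
  pp <- ad_relu(tp, ad_colmax(tp, pg))
  xp_final <- ad_affine(tp, pp, P$head_plin_w, P$head_plin_b)
  Z <- ad_cbind(tp, xd_final, xp_final)
  if (training && config$dropout > 0) {
    keep <- 1 - config$dropout
    Z <- ad_mask(tp, Z, matrix(stats::rbinom(length(Z$v), 1L, keep) / keep,
                               1L))
  }
  h1 <- ad_relu(tp, ad_affine(tp, Z, P$head_fc1_w, P$head_fc1_b))
  if (training && config$dropout > 0) {
    keep <- 1 - config$dropout
    h1 <- ad_mask(tp, h1, matrix(stats::rbinom(length(h1$v), 1L, keep) / keep,
                                 1L))
  }
  ad_affine(tp, h1, P$head_fc2_w, P$head_fc2_b)
}

# full forward for one (drug, protein) pair -> 1 x 1 prediction node
.fwd_pair <- function(tp, P, dc, pc, config, training = FALSE) {
  x_esc <- .fwd_esc(tp, P, dc, config)
  xd <- .fwd_mol(tp, P, dc, config)
  fused <- .fwd_fusion(tp, P, pc, xd, config)
  .fwd_head(tp, P, x_esc, fused$drug, fused$protein, pc$ahat_p, config,
            training)
}

.dta_pnodes <- function(tp, params) lapply(params, function(x) ad_leaf(tp, x))
.dta_cnodes <- function(tp, params) lapply(params, function(x) ad_const(tp, x))

# ---- exported operation surface ------------------------------------------

#' Query sparsity scores for top-S attention
#'
#' Scores each query by `max_j(q_i . k_j / sqrt(d)) - mean_j(q_i . k_j /
#' sqrt(d))`, computed exactly (molecular graphs are small enough that the
#' sampled approximation of long-sequence attention is unnecessary).  Higher
#' scores mark queries whose attention distribution is far from uniform.
#'
#' @param q_proj,k_proj L x d matrices of projected queries and keys.
#' @return Numeric vector of L per-query scores.
#' @export
query_sparsity_scores <- function(q_proj, k_proj) {
  u <- tcrossprod(q_proj, k_proj) / sqrt(ncol(q_proj))
  u[cbind(seq_len(nrow(u)), max.col(u, ties.method = "first"))] - rowMeans(u)
}

#' Top-S sparse self-attention
#'
#' Computes attention logits `(h W_Q)(h W_K)^T / sqrt(d)` plus the additive
#' spatial and edge-path biases, softmax-normalizes rows, and emits the
#' attention-weighted value vectors for the `top_s` queries with the highest
#' sparsity scores (ties broken by lower index); non-selected queries output
#' the mean value vector.  With `top_s >= L` this is exactly dense
#' softmax attention.
#'
#' @param h L x d node feature matrix.
#' @param bias `NULL`, or a list with L x L matrices `spatial_bias` and/or
#'   `edge_bias` (missing entries count as zero).
#' @param params List with square projection matrices `w_q`, `w_k`, `w_v`
#'   and the integer budget `top_s`.
#' @return L x d output matrix.
#' @export
sparsepro_attention <- function(h, bias = NULL, params) {
  if (!all(is.finite(h))) stop("non-finite input to sparse attention")
  bmat <- NULL
  if (!is.null(bias)) {
    bmat <- matrix(0, nrow(h), nrow(h))
    if (!is.null(bias$spatial_bias)) bmat <- bmat + bias$spatial_bias
    if (!is.null(bias$edge_bias)) bmat <- bmat + bias$edge_bias
    if (!all(is.finite(bmat))) stop("non-finite attention bias")
  }
  tp <- ad_tape()
  out <- .fwd_attention(tp, ad_const(tp, h), ad_const(tp, params$w_q),
                        ad_const(tp, params$w_k), ad_const(tp, params$w_v),
                        bmat, params$top_s)
  ad_value(out)
}

#' Convolutional distillation layer
#'
#' Width-3 same-padded one-dimensional convolution along the node axis,
#' exponential-linear-unit activation, then max pooling (window 3, stride 2,
#' same-padded).  Halves the node count (`ceil(L / 2)`), preserving the
#' feature dimension.
#'
#' @param x L x d input matrix.
#' @param block List with d x d kernels `w_prev`, `w_center`, `w_next` and a
#'   `1 x d` bias `b`.
#' @return `ceiling(L / 2)` x d matrix.
#' @export
gcn_distill <- function(x, block) {
  tp <- ad_tape()
  out <- .fwd_distill(tp, ad_const(tp, x), ad_const(tp, block$w_prev),
                      ad_const(tp, block$w_center),
                      ad_const(tp, block$w_next), ad_const(tp, block$b))
  ad_value(out)
}

#' Graph-convolution layer
#'
#' `ReLU(Ahat h W)` with `Ahat` the symmetrically normalized adjacency with
#' self-loops (see [normalize_adjacency()]).
#'
#' @param h N x d_in node features.
#' @param adj N x N symmetric 0/1 adjacency with zero diagonal.
#' @param weight d_in x d_out weight matrix.
#' @return N x d_out matrix.
#' @export
gcn_layer <- function(h, adj, weight) {
  tp <- ad_tape()
  ad_value(.fwd_gcn(tp, ad_const(tp, h), normalize_adjacency(adj),
                    ad_const(tp, weight)))
}

#' Residual block
#'
#' `ReLU(F(h) + h)` with the inner transform `F(h) = ReLU(h W1 + b1) W2`;
#' input and output shapes are equal.
#'
#' @param h N x d input.
#' @param w1,w2 d x d weight matrices.
#' @param b1 `1 x d` bias.
#' @return N x d matrix.
#' @export
residual_block <- function(h, w1, b1, w2) {
  tp <- ad_tape()
  ad_value(.fwd_res(tp, ad_const(tp, h), ad_const(tp, w1), ad_const(tp, b1),
                    ad_const(tp, w2)))
}

#' Global drug feature from the sparse-attention encoder
#'
#' Runs the full sandwich (attention / distill / attention / distill /
#' attention with residual skips around each attention layer, pair biases
#' subsampled to surviving nodes after each distillation) and reduces the
#' node axis by max pooling to one length-d vector.
#'
#' @param g A `dta_drug_graph`.
#' @param model A [dta_init_model()] model.
#' @return `1 x d` matrix (the global drug feature).
#' @export
esc_forward <- function(g, model) {
  dc <- .dta_esc_cache(g, model$config)
  tp <- ad_tape()
  P <- .dta_cnodes(tp, model$params)
  ad_value(.fwd_esc(tp, P, dc, model$config))
}

# encoding caches for a bare drug graph (ESC path only)
.dta_esc_cache <- function(g, config) {
  nf <- g$node_features
  spd <- compute_spd(g)
  list(idx9 = lapply(1:9, function(k) as.integer(nf[, k]) + 1L),
       deg_idx = pmin(as.integer(g$degrees), config$deg_clip) + 1L,
       spd_idx = .dta_spd_bucket(spd, config$spd_clip) + 1L,
       path_arr = .dta_path_feature_means(g, spd, config$max_path_len),
       n = nrow(nf))
}

#' Molecular-graph drug encoder
#'
#' Embeds the six-attribute atom features (element, degree, position,
#' implicit valence, formal charge, hybridization), applies the GCN and
#' residual blocks, pools column-wise over nodes, and maps through two
#' linear layers to the drug vector.
#'
#' @param mol A `dta_molecule`.
#' @param model A [dta_init_model()] model.
#' @return `1 x d` drug vector.
#' @export
encode_drug <- function(mol, model) {
  dc <- dta_drug_cache_from_mol(mol, model$config)
  tp <- ad_tape()
  P <- .dta_cnodes(tp, model$params)
  ad_value(.fwd_mol(tp, P, dc, model$config))
}

# full drug cache from an already-parsed molecule
dta_drug_cache_from_mol <- function(mol, config = dta_config()) {
  g <- build_drug_graph(mol)
  dct <- dta_dictionaries()
  esc <- .dta_esc_cache(g, config)
  elem_idx <- match(mol$atoms$element, dct$elements)
  elem_idx[is.na(elem_idx)] <- length(dct$elements) + 1L
  c(esc, list(
    drug_id = mol$source_id, mol = mol, graph = g,
    ahat = normalize_adjacency(g$adjacency),
    mol_idx = list(elem = elem_idx, deg = esc$idx9[[3L]],
                   pos = pmin(seq_len(esc$n), dct$atom_index_max),
                   val = esc$idx9[[5L]], chg = esc$idx9[[4L]],
                   hyb = esc$idx9[[7L]])))
}

#' Fuse a drug vector and a protein graph into a heterograph
#'
#' Row 1 is the drug super node (the drug vector projected to the shared
#' width), rows `2..(M + 1)` are the protein's residue nodes (projected to
#' the shared width); cross edges connect the super node to every residue,
#' protein internal edges are preserved with indices shifted by one.
#'
#' @param x_d `1 x d` drug vector (from [encode_drug()]).
#' @param pg A `dta_protein_graph`.
#' @param model A [dta_init_model()] model (supplies the projections).
#' @return Object of class `dta_dtg_graph`: list with `node_features`
#'   (`(1 + M) x d`), `edges` (data frame `i`, `j`, `kind`), `node_mask`
#'   (logical, `TRUE` at protein rows), `adjacency`.
#' @export
fuse <- function(x_d, pg, model) {
  m <- nrow(pg$node_features)
  if (m < 1L) stop("empty protein graph")
  p <- model$params
  drugrow <- x_d %*% p$fus_proj_w +
    matrix(p$fus_proj_b, 1L, ncol(p$fus_proj_w))
  feats <- pg$node_features
  if (!model$config$use_ss_asa)
    feats[, (ncol(feats) - 8L):ncol(feats)] <- 0
  prot <- feats %*% p$prot_proj_w +
    matrix(p$prot_proj_b, m, ncol(p$prot_proj_w), byrow = TRUE)
  pe <- pg$edges
  edges <- rbind(
    data.frame(i = rep(1L, m), j = seq_len(m) + 1L, kind = "cross"),
    if (nrow(pe)) data.frame(i = pe$i + 1L, j = pe$j + 1L, kind = pe$kind)
    else NULL)
  adj <- matrix(0L, m + 1L, m + 1L)
  adj[cbind(edges$i, edges$j)] <- 1L
  adj[cbind(edges$j, edges$i)] <- 1L
  structure(list(node_features = rbind(drugrow, prot), edges = edges,
                 node_mask = c(FALSE, rep(TRUE, m)), adjacency = adj),
            class = "dta_dtg_graph")
}

#' Refine the fused heterograph
#'
#' One graph-convolution layer (same normalized-adjacency construction as
#' the molecular encoder) followed by the configured number of residual
#' blocks; shape preserved.
#'
#' @param g A `dta_dtg_graph` from [fuse()].
#' @param model A [dta_init_model()] model.
#' @return `(1 + M) x d` matrix of refined node features.
#' @export
dtg_refine <- function(g, model) {
  tp <- ad_tape()
  P <- .dta_cnodes(tp, model$params)
  ahat <- normalize_adjacency(g$adjacency)
  H <- .fwd_gcn(tp, ad_const(tp, g$node_features), ahat, P$dtg_gcn1_w)
  for (r in seq_len(model$config$res_blocks))
    H <- .fwd_res(tp, H, P[[sprintf("dtg_res%d_w1", r)]],
                  P[[sprintf("dtg_res%d_b1", r)]],
                  P[[sprintf("dtg_res%d_w2", r)]])
  ad_value(H)
}

#' Separate refined heterograph nodes by the node-type mask
#'
#' Protein rows are `refined[mask]`, drug rows are `refined[!mask]`;
#' together they partition the node set.  Edge lists are the induced
#' subgraphs (protein edges shifted back to residue indexing; the one-node
#' drug subgraph has no edges).
#'
#' @param g A `dta_dtg_graph`.
#' @param refined `(1 + M) x d` matrix from [dtg_refine()].
#' @return List with `drug` (1 x d), `protein` (M x d), `drug_edges`,
#'   `protein_edges`.
#' @export
masked_split <- function(g, refined) {
  mask <- g$node_mask
  pe <- g$edges[g$edges$kind != "cross", , drop = FALSE]
  pe$i <- pe$i - 1L; pe$j <- pe$j - 1L
  rownames(pe) <- NULL
  list(drug = refined[!mask, , drop = FALSE],
       protein = refined[mask, , drop = FALSE],
       drug_edges = data.frame(i = integer(0), j = integer(0)),
       protein_edges = pe)
}

#' Affinity score from the separated representations
#'
#' Drug path: the pre-fusion global drug feature is concatenated with a
#' graph convolution of the refined one-node drug subgraph (max pooling over
#' the node axis is the identity for a single row).  Protein path: graph
#' convolution over the masked protein subgraph, global max pooling, a
#' rectifier and a linear layer.  The two vectors are concatenated and
#' mapped through the fully connected block to one real number.
#'
#' @param x_esc `1 x d` global drug feature (from [esc_forward()]).
#' @param drug_masked `1 x d` refined drug row (from [masked_split()]).
#' @param prot_masked M x d refined protein rows.
#' @param prot_adjacency M x M adjacency of the masked protein subgraph.
#' @param model A [dta_init_model()] model.
#' @return Scalar affinity prediction.
#' @export
predict_affinity <- function(x_esc, drug_masked, prot_masked,
                             prot_adjacency, model) {
  stopifnot(all(is.finite(x_esc)), all(is.finite(drug_masked)),
            all(is.finite(prot_masked)))
  tp <- ad_tape()
  P <- .dta_cnodes(tp, model$params)
  out <- .fwd_head(tp, P, ad_const(tp, x_esc), ad_const(tp, drug_masked),
                   ad_const(tp, prot_masked),
                   normalize_adjacency(prot_adjacency), model$config,
                   training = FALSE)
  as.numeric(ad_value(out))
}

#' Predict affinity for one drug-protein pair
#'
#' Composes the full pipeline: both drug encoders, early fusion, heterograph
#' refinement, masked separation, and the regression head.
#'
#' @param model A `dta_model`.
#' @param mol A `dta_molecule` (or SMILES string).
#' @param rec A `dta_protein_record`.
#' @param provider Embedding provider; defaults to the synthetic provider at
#'   the model's embedding width.
#' @return Scalar predicted affinity.
#' @export
dta_predict_pair <- function(model, mol, rec,
                             provider = synthetic_embedding_provider(
                               model$embed_width)) {
  if (is.character(mol)) mol <- parse_molecule(mol)
  dc <- dta_drug_cache_from_mol(mol, model$config)
  pc <- dta_protein_cache(rec, provider, model$config)
  tp <- ad_tape()
  P <- .dta_cnodes(tp, model$params)
  as.numeric(ad_value(.fwd_pair(tp, P, dc, pc, model$config)))
}
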