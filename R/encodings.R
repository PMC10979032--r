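# Structural encodings of the molecular graph: degree centrality (node
# augmentation), shortest-path spatial distance and bond-path edge features
# (per-pair attention biases).

#' All-pairs shortest-path hop counts
#'
#' Computes the unweighted shortest-path distance (in hops) between every
#' atom pair of a drug graph; `-1` marks unreachable pairs, the diagonal is 0.
#'
#' @param g A `dta_drug_graph` (or a bare symmetric 0/1 adjacency matrix).
#' @return N x N integer matrix of hop counts with `-1` for unreachable.
#' @export
compute_spd <- function(g) {
  adj <- if (inherits(g, "dta_drug_graph")) g$adjacency else g
  n <- nrow(adj)
  if (n == 1L) return(matrix(0L, 1L, 1L))
  ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  d <- igraph::distances(ig)
  d[is.infinite(d)] <- -1
  storage.mode(d) <- "integer"
  dimnames(d) <- NULL
  d
}

# bucket a raw SPD value: 0..clip, plus one dedicated unreachable bucket
# (returned as clip + 1); 1-based table row = bucket + 1
.dta_spd_bucket <- function(spd, clip) {
  b <- pmin(spd, clip)
  b[spd < 0L] <- clip + 1L
  b
}

#' Degree-centrality node augmentation
#'
#' Adds learnable in-/out-degree embeddings to embedded node features:
#' `h[j] = x[j] + in_table[bucket(deg_j)] + out_table[bucket(deg_j)]`.  For
#' undirected molecular graphs both lookups use the same (undirected) degree.
#' Degrees are clipped to `table$max_degree_bucket`.
#'
#' @param x N x d matrix of embedded node features.
#' @param degrees Length-N non-negative integer degrees.
#' @param table List with `in_table`, `out_table` (each
#'   `(max_degree_bucket + 1) x d`, row `k` = degree `k - 1`) and
#'   `max_degree_bucket`.
#' @return N x d matrix of augmented features.
#' @export
degree_encode <- function(x, degrees, table) {
  stopifnot(length(degrees) == nrow(x), all(degrees >= 0))
  b <- pmin(as.integer(degrees), table$max_degree_bucket) + 1L
  x + table$in_table[b, , drop = FALSE] + table$out_table[b, , drop = FALSE]
}

#' Spatial (shortest-path) attention bias
#'
#' Looks up one learnable scalar per shortest-path-distance bucket:
#' `bias[i, j] = weights[bucket(spd[i, j])]`.  Distances are clipped at
#' `length(weights) - 2`; unreachable pairs (`-1`) use the dedicated last
#' bucket.
#'
#' @param spd N x N matrix from [compute_spd()].
#' @param weights Numeric vector of per-bucket scalars: entries `1..(B+1)`
#'   cover distances `0..B`, entry `B + 2` is the unreachable bucket.
#' @return N x N numeric bias matrix.
#' @export
spatial_bias <- function(spd, weights) {
  clip <- length(weights) - 2L
  stopifnot(clip >= 0L)
  b <- .dta_spd_bucket(spd, clip)
  matrix(weights[b + 1L], nrow(spd), ncol(spd))
}

# lexicographically smallest shortest path between i and j (node sequence),
# given BFS distances from j; NULL if unreachable
.dta_lex_path <- function(neighbors, dist_from_j, i, j) {
  if (dist_from_j[i] < 0L) return(NULL)
  path <- i
  cur <- i
  while (cur != j) {
    nb <- neighbors[[cur]]
    nb <- nb[dist_from_j[nb] == dist_from_j[cur] - 1L]
    cur <- min(nb)
    path <- c(path, cur)
  }
  path
}

# per-pair mean bond-feature vector along the (deterministic) shortest path:
# returns an N x N x 3 array; zero rows for the diagonal and unreachable
# pairs; paths longer than max_path_len are truncated to their first
# max_path_len edges before averaging
.dta_path_feature_means <- function(g, spd, max_path_len = 20L) {
  n <- nrow(g$adjacency)
  arr <- array(0, dim = c(n, n, 3L))
  if (n == 1L || nrow(g$edges) == 0L) return(arr)
  neighbors <- lapply(seq_len(n), function(v) which(g$adjacency[v, ] == 1L))
  bf <- as.matrix(g$edges[, c("b1", "b2", "b3")])
  bkey <- paste(g$edges$i, g$edges$j)
  for (j in seq_len(n)) {
    dj <- spd[j, ]
    for (i in seq_len(n)) {
      if (i == j || dj[i] < 0L) next
      p <- .dta_lex_path(neighbors, dj, i, j)
      a <- p[-length(p)]; b <- p[-1L]
      rows <- match(paste(pmin(a, b), pmax(a, b)), bkey)
      if (length(rows) > max_path_len) rows <- rows[seq_len(max_path_len)]
      arr[i, j, ] <- colMeans(bf[rows, , drop = FALSE])
    }
  }
  arr
}

#' Edge-path attention bias
#'
#' For every reachable atom pair, selects one shortest path deterministically
#' (the lexicographically smallest node sequence among shortest paths),
#' projects each bond's feature vector through `table$w_edge` and averages
#' over the path's edges.  Unreachable pairs and the diagonal are 0.  Paths
#' longer than `table$max_path_len` are truncated to their first
#' `max_path_len` edges before averaging.
#'
#' @param g A `dta_drug_graph`.
#' @param spd Matrix from [compute_spd()] for `g`.
#' @param table List with `w_edge` (length-3 numeric projection) and
#'   `max_path_len` (default 20).
#' @return N x N numeric bias matrix.
#' @export
edge_path_bias <- function(g, spd, table) {
  mpl <- if (is.null(table$max_path_len)) 20L else table$max_path_len
  arr <- .dta_path_feature_means(g, spd, mpl)
  w <- as.numeric(table$w_edge)
  arr[, , 1L] * w[1L] + arr[, , 2L] * w[2L] + arr[, , 3L] * w[3L]
}

#' Assemble the attention-bias set for a drug graph
#'
#' Convenience constructor combining [spatial_bias()] and [edge_path_bias()];
#' the degree term enters through node features via [degree_encode()].
#'
#' @param g A `dta_drug_graph`.
#' @param w_phi Per-bucket spatial weights (see [spatial_bias()]).
#' @param edge_table Edge projection table (see [edge_path_bias()]).
#' @param spd Optional precomputed SPD matrix.
#' @return List with `spatial_bias` and `edge_bias` (both N x N).
#' @export
attention_bias_set <- function(g, w_phi, edge_table, spd = compute_spd(g)) {
  list(spatial_bias = spatial_bias(spd, w_phi),
       edge_bias = edge_path_bias(g, spd, edge_table))
}
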