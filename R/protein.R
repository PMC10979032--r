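# Residue-level protein graphs: sequence embeddings + 8-state secondary
# structure + solvent accessibility as node features, contact-map edges.

#' Construct a protein record
#'
#' Validates and assembles the four per-protein inputs.  Absolute accessible
#' surface areas (values above 1) are normalized to relative accessibility by
#' the per-residue maximum-ASA constants at load time.
#'
#' @param protein_id Text identifier.
#' @param sequence Amino-acid string of length M.
#' @param ss8 Length-M string over the 8-letter secondary-structure alphabet
#'   (H, G, I, E, B, T, S, C).
#' @param asa Numeric vector of M accessibilities; relative (in `[0, 1]`) or
#'   absolute in square Angstroms.
#' @param distmap M x M symmetric matrix of residue-residue distances in
#'   Angstroms (`kind = "distance"`) or contact probabilities in `[0, 1]`
#'   (`kind = "probability"`).
#' @param kind Interpretation of `distmap`.
#' @return An object of class `dta_protein_record`.
#' @export
protein_record <- function(protein_id, sequence, ss8, asa, distmap,
                           kind = c("distance", "probability")) {
  kind <- match.arg(kind)
  m <- nchar(sequence)
  if (nchar(ss8) != m)
    stop("field ss8: length ", nchar(ss8), " does not match sequence length ",
         m, " for ", protein_id)
  if (length(asa) != m)
    stop("field asa: length ", length(asa), " does not match sequence length ",
         m, " for ", protein_id)
  if (!all(dim(distmap) == c(m, m)))
    stop("field distmap: dimensions do not match sequence length for ",
         protein_id)
  ss_chars <- strsplit(ss8, "")[[1L]]
  if (!all(ss_chars %in% .dta_ss8_alphabet))
    stop("field ss8: letters outside the 8-state alphabet for ", protein_id,
         ": ", paste(unique(setdiff(ss_chars, .dta_ss8_alphabet)),
                     collapse = ""))
  if (max(abs(distmap - t(distmap))) > 1e-6)
    stop("field distmap: asymmetric beyond tolerance for ", protein_id)
  asa <- as.numeric(asa)
  if (any(asa < 0)) stop("field asa: negative values for ", protein_id)
  if (any(asa > 1)) {
    mx <- .dta_max_asa[strsplit(sequence, "")[[1L]]]
    mx[is.na(mx)] <- mean(.dta_max_asa)
    asa <- unname(pmin(asa / mx, 1))
  }
  structure(list(protein_id = protein_id, sequence = sequence, ss8 = ss8,
                 asa = asa, distmap = unname(as.matrix(distmap)),
                 kind = kind),
            class = "dta_protein_record")
}

#' Contact and backbone edges of a protein record
#'
#' Distance maps yield a contact edge between residues `i` and `j` whenever
#' `|i - j| >= 2` and the distance is strictly below 8 Angstroms; probability
#' maps use `prob > 0.5`.  Backbone edges `(i, i + 1)` are always added so
#' the residue graph is chain-connected.
#'
#' @param rec A [protein_record()].
#' @return Data frame with columns `i`, `j` (1-based, `i < j`) and `kind`
#'   (`"backbone"` or `"contact"`).
#' @export
build_contact_edges <- function(rec) {
  stopifnot(inherits(rec, "dta_protein_record"))
  m <- nchar(rec$sequence)
  bb <- if (m >= 2L)
    data.frame(i = seq_len(m - 1L), j = 2:m, kind = "backbone")
  else data.frame(i = integer(0), j = integer(0), kind = character(0))
  ut <- which(upper.tri(rec$distmap), arr.ind = TRUE)
  sep <- ut[, 2L] - ut[, 1L] >= 2L
  hit <- if (rec$kind == "distance") rec$distmap[ut] < 8.0
         else rec$distmap[ut] > 0.5
  keep <- sep & hit
  ct <- data.frame(i = ut[keep, 1L], j = ut[keep, 2L],
                   kind = if (any(keep)) "contact" else character(0))
  out <- rbind(bb, ct)
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Synthetic sequence-embedding provider
#'
#' A deterministic stand-in for a pretrained protein language model: each
#' sequence maps to an M x h Gaussian matrix seeded by a rolling hash of the
#' sequence, so embeddings are reproducible and sequence-specific but carry
#' no learned biology.  Satisfies the embedding-provider contract
#' (`$embed(sequence)`, `$width`, `$version`).
#'
#' @param width Embedding width h.
#' @return Provider list with fields `embed`, `width`, `version`.
#' @export
synthetic_embedding_provider <- function(width = 16L) {
  width <- as.integer(width)
  list(
    embed = function(sequence) {
      m <- nchar(sequence)
      seed <- .dta_string_seed(sequence)
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                          globalenv())
             else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      matrix(stats::rnorm(m * width), m, width)
    },
    width = width,
    version = "synthetic-1"
  )
}

# deterministic 31-bit rolling hash of a string (seed derivation)
.dta_string_seed <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% 2147483647
  as.integer(h)
}

#' Build the residue-level protein graph
#'
#' Node `i`'s feature is the provider's embedding row concatenated with the
#' one-hot 8-state secondary-structure class and the scalar relative
#' accessibility (width `h + 9`); edges come from [build_contact_edges()].
#'
#' @param rec A [protein_record()].
#' @param provider An embedding provider such as
#'   [synthetic_embedding_provider()].
#' @return Object of class `dta_protein_graph`: list with `node_features`
#'   (M x (h+9)), `edges`, `protein_id`, `provider_version`.
#' @export
build_protein_graph <- function(rec, provider) {
  stopifnot(inherits(rec, "dta_protein_record"))
  m <- nchar(rec$sequence)
  emb <- provider$embed(rec$sequence)
  if (nrow(emb) != m)
    stop("embedding provider returned ", nrow(emb), " rows for ", m,
         " residues")
  ss_chars <- strsplit(rec$ss8, "")[[1L]]
  onehot <- matrix(0, m, 8L)
  onehot[cbind(seq_len(m), match(ss_chars, .dta_ss8_alphabet))] <- 1
  structure(list(
    node_features = unname(cbind(emb, onehot, rec$asa)),
    edges = build_contact_edges(rec),
    protein_id = rec$protein_id,
    provider_version = provider$version
  ), class = "dta_protein_graph")
}

#' @export
print.dta_protein_record <- function(x, ...) {
  cat(sprintf("<dta_protein_record %s: %d residues, %s map>\n",
              x$protein_id, nchar(x$sequence), x$kind))
  invisible(x)
}

#' @export
print.dta_protein_graph <- function(x, ...) {
  cat(sprintf("<dta_protein_graph %s: %d nodes (width %d), %d edges>\n",
              x$protein_id, nrow(x$node_features), ncol(x$node_features),
              nrow(x$edges)))
  invisible(x)
}

# ---- on-disk formats ------------------------------------------------------

#' Write / read a protein record directory entry
#'
#' On-disk layout per protein id under `dir`: `<id>.fasta` (sequence),
#' `<id>.ss8` (one line), `<id>.asa.tsv` (index, value), `<id>.dm.txt`
#' (header line `distance` or `probability`, then the whitespace-delimited
#' square matrix).
#'
#' @param rec A [protein_record()].
#' @param dir Directory (created if missing).
#' @return Invisibly, the protein id.
#' @export
write_protein_record <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- rec$protein_id
  writeLines(c(paste0(">", id), rec$sequence),
             file.path(dir, paste0(id, ".fasta")))
  writeLines(rec$ss8, file.path(dir, paste0(id, ".ss8")))
  utils::write.table(
    data.frame(index = seq_along(rec$asa), value = rec$asa),
    file.path(dir, paste0(id, ".asa.tsv")),
    sep = "\t", row.names = FALSE, quote = FALSE)
  con <- file(file.path(dir, paste0(id, ".dm.txt")), "w")
  writeLines(rec$kind, con)
  utils::write.table(format(rec$distmap, digits = 6, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  close(con)
  invisible(id)
}

#' @rdname write_protein_record
#' @param id Protein id to read.
#' @export
read_protein_record <- function(dir, id) {
  fa <- file.path(dir, paste0(id, ".fasta"))
  if (!file.exists(fa)) stop("no protein record for id ", id, " in ", dir)
  sequence <- if (requireNamespace("Biostrings", quietly = TRUE)) {
    as.character(Biostrings::readAAStringSet(fa))[[1L]]
  } else {
    paste(readLines(fa, warn = FALSE)[-1L], collapse = "")
  }
  ss8 <- readLines(file.path(dir, paste0(id, ".ss8")), warn = FALSE)[1L]
  asa_df <- utils::read.table(file.path(dir, paste0(id, ".asa.tsv")),
                              header = TRUE, sep = "\t")
  asa <- asa_df$value[order(asa_df$index)]
  dm_lines <- readLines(file.path(dir, paste0(id, ".dm.txt")), warn = FALSE)
  kind <- trimws(dm_lines[1L])
  dm <- as.matrix(utils::read.table(text = dm_lines[-1L]))
  protein_record(id, sequence, ss8, asa, dm, kind = kind)
}
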