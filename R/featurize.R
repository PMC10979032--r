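# Molecular parsing and featurization.
#
# Parsing goes through ChemmineR (openbabel backend for SMILES); chemical
# perception that ChemmineR does not expose -- aromaticity flags per atom/bond,
# hybridization, implicit hydrogen counts, conjugation -- is derived here from
# kekule bond orders and ring perception.

#' Parse a drug structure into a molecule object
#'
#' Accepts a SMILES string or the text of a single SDF (V2000) record and
#' returns the heavy-atom molecular graph: hydrogens are implicit (recorded as
#' per-atom attached-H counts), atom order is the parser's input order and
#' defines the node order of every downstream graph.
#'
#' @param source SMILES string, SDF record text (with newlines), or a path to
#'   an SDF file containing one record.
#' @param source_id Identifier attached to the molecule (and to parse errors).
#' @param format `"auto"` (default; SMILES unless the text contains the V2000
#'   tag or is an existing file), `"smiles"`, or `"sdf"`.
#' @return An object of class `dta_molecule`: a list with `atoms` (data frame:
#'   `element`, `charge`, `n_h`, `radical`, `degree`, `hybridization`,
#'   `aromatic`, `in_ring`, `chirality`), `bonds` (data frame: `i`, `j`,
#'   `order`, `aromatic`, `stereo`, `conjugated`; 1-based atom indices with
#'   `i < j`), and `source_id`.
#' @export
parse_molecule <- function(source, source_id = "mol", format = "auto") {
  format <- match.arg(format, c("auto", "smiles", "sdf"))
  if (!is.character(source) || length(source) != 1L || !nzchar(source))
    stop(dta_parse_error(source_id, "empty or non-character source"))
  if (format == "auto") {
    format <- if (grepl("V2000", source, fixed = TRUE) ||
                  (nchar(source) < 300 && file.exists(source))) "sdf"
              else "smiles"
  }
  lines <- if (format == "smiles") {
    # openbabel silently repairs some malformed strings; reject obvious
    # syntax errors (unbalanced branches/brackets, unpaired ring bonds,
    # stray characters) up front
    if (!.dta_smiles_syntax_ok(source))
      stop(dta_parse_error(source_id, paste("malformed SMILES:", source)))
    txt <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat(
        "SMI", "SDF", paste0(source, "\t", source_id))),
      error = function(e) "")
    if (!nzchar(txt) || !grepl("V2000", txt, fixed = TRUE))
      stop(dta_parse_error(source_id, paste("unparsable SMILES:", source)))
    strsplit(txt, "\n", fixed = TRUE)[[1L]]
  } else {
    if (file.exists(source)) readLines(source, warn = FALSE)
    else strsplit(source, "\n", fixed = TRUE)[[1L]]
  }
  .dta_mol_from_sdf_lines(lines, source_id)
}

# dispatch on the V2000 counts line: ChemmineR handles records with bonds;
# zero-bond records (single heavy atom) are parsed directly
.dta_mol_from_sdf_lines <- function(lines, source_id) {
  if (length(lines) < 4L)
    stop(dta_parse_error(source_id, "truncated SDF record"))
  counts <- lines[4L]
  natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 1L)
    stop(dta_parse_error(source_id, "malformed SDF counts line"))
  if (nbonds >= 1L) {
    res <- tryCatch(
      suppressWarnings(ChemmineR::read.SDFset(lines)),
      error = function(e) NULL)
    if (is.null(res) || length(res) == 0L ||
        !isTRUE(ChemmineR::validSDF(res)[1L]))
      stop(dta_parse_error(source_id, "unparsable SDF record"))
    return(.dta_mol_from_sdf(res[[1L]], source_id))
  }
  # single atoms / zero bonds: minimal direct parse of the atom block
  toks <- strsplit(trimws(lines[5:(4L + natoms)]), "[[:space:]]+")
  element <- vapply(toks, `[[`, "", 4L)
  ccode <- vapply(toks, function(t)
    if (length(t) >= 6L) suppressWarnings(as.integer(t[[6L]])) else 0L,
    integer(1))
  ccode[is.na(ccode)] <- 0L
  charge <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L,
              `6` = -2L, `7` = -3L)[as.character(ccode)]
  charge[is.na(charge)] <- 0L
  structure(list(
    atoms = data.frame(
      element = element, charge = charge,
      n_h = .dta_implicit_h(element, charge, integer(0), integer(0),
                            integer(0), natoms),
      radical = as.integer(ccode == 4L), degree = 0L,
      hybridization = ifelse(element %in% names(.dta_default_valence),
                             "sp3", "other"),
      aromatic = FALSE, in_ring = FALSE, chirality = "none",
      stringsAsFactors = FALSE),
    bonds = data.frame(i = integer(0), j = integer(0), order = integer(0),
                       aromatic = logical(0), stereo = integer(0),
                       conjugated = logical(0)),
    n_aromatic_rings = 0L,
    source_id = source_id
  ), class = "dta_molecule")
}

# lightweight SMILES syntax screen (not a full grammar): branch and bracket
# balance, ring-closure pairing, character set
.dta_smiles_syntax_ok <- function(s) {
  chars <- strsplit(s, "")[[1L]]
  allowed <- strsplit(paste0("ABCDEFGHIJKLMNOPQRSTUVWXYZ",
                             "abcdefghijklmnopqrstuvwxyz",
                             "0123456789%()[]@+-=#$:/.\\*"), "")[[1L]]
  if (!all(chars %in% allowed)) return(FALSE)
  depth <- 0L; brk <- FALSE
  digits <- character(0)
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") { depth <- depth - 1L; if (depth < 0L) return(FALSE) }
    else if (ch == "[") { if (brk) return(FALSE); brk <- TRUE }
    else if (ch == "]") { if (!brk) return(FALSE); brk <- FALSE }
    else if (!brk && ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$",
                               paste0(chars[i + 1L], chars[i + 2L])))
        return(FALSE)
      digits <- c(digits, paste0("%", chars[i + 1L], chars[i + 2L]))
      i <- i + 2L
    } else if (!brk && grepl("[0-9]", ch)) digits <- c(digits, ch)
    i <- i + 1L
  }
  if (depth != 0L || brk) return(FALSE)
  if (length(digits) && any(table(digits) %% 2L != 0L)) return(FALSE)
  # a branch must follow an atom and the string must not end mid-branch
  if (grepl("^\\(|\\($", s)) return(FALSE)
  TRUE
}

dta_parse_error <- function(source_id, msg) {
  structure(
    class = c("dta_parse_error", "error", "condition"),
    list(message = sprintf("[%s] %s", source_id, msg), call = NULL,
         source_id = source_id))
}

# build a dta_molecule from a ChemmineR SDF object (perception happens here)
.dta_mol_from_sdf <- function(sdf, source_id) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  if (is.null(n) || n < 1L)
    stop(dta_parse_error(source_id, "molecule has no atoms"))
  element <- sub("_[0-9]+$", "", rownames(ab))
  # V2000 atom line fields after x,y,z: mass-diff, charge code, ..., parity
  charge_code <- if (ncol(ab) >= 5L) as.integer(ab[, 5L]) else integer(n)
  charge <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L,
              `6` = -2L, `7` = -3L)[as.character(charge_code)]
  charge[is.na(charge)] <- 0L
  radical <- as.integer(charge_code == 4L)

  nb <- if (is.null(bb) || length(bb) == 0L) 0L else nrow(bb)
  if (nb > 0L) {
    bi <- as.integer(bb[, 1L]); bj <- as.integer(bb[, 2L])
    border <- as.integer(bb[, 3L])
    bstereo <- if (ncol(bb) >= 4L) as.integer(bb[, 4L]) else integer(nb)
    if (any(bi < 1L | bi > n | bj < 1L | bj > n | bi == bj))
      stop(dta_parse_error(source_id, "bond references invalid atom index"))
    swap <- bi > bj
    tmp <- bi[swap]; bi[swap] <- bj[swap]; bj[swap] <- tmp
    if (anyDuplicated(paste(bi, bj)))
      stop(dta_parse_error(source_id, "duplicate undirected bond"))
  } else {
    bi <- bj <- border <- bstereo <- integer(0)
  }

  # ring perception + aromaticity (ChemmineR flags rings with alternating /
  # aromatic bond orders); atoms and bonds inherit flags from aromatic rings
  in_ring <- logical(n); arom_atom <- logical(n)
  arom_bond <- logical(nb)
  n_arom_rings <- 0L
  if (nb > 0L) {
    # smallest set of smallest rings; fall back to bounded enumeration if
    # the inner-ring search fails on an unusual topology
    rl <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf, upper = Inf, type = "all",
                                        arom = TRUE, inner = TRUE)),
      error = function(e) tryCatch(
        suppressWarnings(ChemmineR::rings(sdf, upper = 12L, type = "all",
                                          arom = TRUE)),
        error = function(e2) NULL))
    if (!is.null(rl) && length(rl$RINGS)) {
      bond_key <- paste(bi, bj)
      for (k in seq_along(rl$RINGS)) {
        ridx <- as.integer(sub("^[^_]+_", "", rl$RINGS[[k]]))
        in_ring[ridx] <- TRUE
        if (isTRUE(rl$AROMATIC[[k]])) {
          n_arom_rings <- n_arom_rings + 1L
          arom_atom[ridx] <- TRUE
          r2 <- c(ridx, ridx[1L])
          for (t in seq_along(ridx)) {
            a <- min(r2[t], r2[t + 1L]); b <- max(r2[t], r2[t + 1L])
            arom_bond[bond_key == paste(a, b)] <- TRUE
          }
        }
      }
    }
  }

  degree <- tabulate(c(bi, bj), nbins = n)
  n_h <- .dta_implicit_h(element, charge, border, bi, bj, n)
  hybrid <- .dta_hybridization(element, border, arom_bond, bi, bj, n)

  # chirality: SDF atom parity when present (proxy classes), else "none"
  chir <- rep("none", n)
  if (ncol(ab) >= 6L) {
    parity <- as.integer(ab[, 6L])
    chir[!is.na(parity) & parity == 1L] <- "R"
    chir[!is.na(parity) & parity == 2L] <- "S"
  }

  # conjugation: aromatic bonds, or bonds linking two pi-bearing atoms
  pi_atom <- logical(n)
  if (nb > 0L) {
    multi <- border >= 2L | arom_bond
    pi_atom[unique(c(bi[multi], bj[multi]))] <- TRUE
  }
  conj <- if (nb > 0L) arom_bond | (pi_atom[bi] & pi_atom[bj]) else logical(0)

  structure(list(
    atoms = data.frame(
      element = element, charge = charge, n_h = n_h, radical = radical,
      degree = degree, hybridization = hybrid, aromatic = arom_atom,
      in_ring = in_ring, chirality = chir, stringsAsFactors = FALSE),
    bonds = data.frame(
      i = bi, j = bj, order = border, aromatic = arom_bond,
      stereo = bstereo, conjugated = conj),
    n_aromatic_rings = n_arom_rings,
    source_id = source_id
  ), class = "dta_molecule")
}

# implicit hydrogens from default valence, formal charge and kekule orders
.dta_implicit_h <- function(element, charge, border, bi, bj, n) {
  val <- .dta_default_valence[element]
  val[is.na(val)] <- 0
  adj <- val
  # charge shifts the bonding capacity of the common organic elements
  is_cn <- element %in% c("N", "P")
  is_os <- element %in% c("O", "S", "Se")
  is_c <- element == "C"
  adj[is_cn] <- adj[is_cn] + charge[is_cn]
  adj[is_os] <- adj[is_os] + charge[is_os]
  adj[is_c] <- adj[is_c] - abs(charge[is_c])
  ord <- ifelse(border == 4L, 1.5, border)  # order 4 = aromatic SDF bond
  bosum <- numeric(n)
  for (t in seq_along(bi)) {
    bosum[bi[t]] <- bosum[bi[t]] + ord[t]
    bosum[bj[t]] <- bosum[bj[t]] + ord[t]
  }
  pmax(0L, as.integer(round(adj - bosum)))
}

.dta_hybridization <- function(element, border, arom_bond, bi, bj, n) {
  ndouble <- ntriple <- integer(n)
  naromb <- integer(n)
  for (t in seq_along(bi)) {
    if (arom_bond[t]) {
      naromb[bi[t]] <- naromb[bi[t]] + 1L
      naromb[bj[t]] <- naromb[bj[t]] + 1L
    } else if (border[t] == 2L) {
      ndouble[bi[t]] <- ndouble[bi[t]] + 1L
      ndouble[bj[t]] <- ndouble[bj[t]] + 1L
    } else if (border[t] == 3L) {
      ntriple[bi[t]] <- ntriple[bi[t]] + 1L
      ntriple[bj[t]] <- ntriple[bj[t]] + 1L
    }
  }
  out <- rep("sp3", n)
  out[ndouble >= 1L | naromb >= 1L] <- "sp2"
  out[ntriple >= 1L | ndouble >= 2L] <- "sp"
  out[!element %in% names(.dta_default_valence)] <- "other"
  out
}

#' Number of atoms/bonds in a molecule
#' @param mol A `dta_molecule`.
#' @return Integer count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' @rdname n_atoms
#' @export
n_bonds <- function(mol) nrow(mol$bonds)

#' Atom feature vector (nine integer codes)
#'
#' Encodes atom `idx` of `mol` as the nine-attribute integer vector: molecule
#' heavy-atom count, chirality class, degree, formal charge, attached
#' hydrogens, radical electrons, hybridization class, aromatic flag, ring
#' flag.  Codes index the frozen dictionaries of [dta_dictionaries()];
#' out-of-dictionary values map to the reserved unknown code.
#'
#' @param mol A `dta_molecule`.
#' @param idx 1-based atom index.
#' @return Named integer vector of length 9 (`a1` .. `a9`).
#' @export
featurize_atom <- function(mol, idx) {
  if (!is.numeric(idx) || length(idx) != 1L || idx < 1L || idx > n_atoms(mol))
    stop("atom index out of range: ", idx)
  idx <- as.integer(idx)
  d <- dta_dictionaries()
  a <- mol$atoms[idx, ]
  deg <- a$degree
  chg <- a$charge
  nh <- a$n_h
  rad <- a$radical
  c(
    a1 = min(n_atoms(mol), d$a1_atom_count$max),
    a2 = unname(d$a2_chirality$codes[[
      if (a$chirality %in% names(d$a2_chirality$codes)) a$chirality
      else "none"]]),
    a3 = if (deg <= d$a3_degree$max) deg else d$a3_degree$unknown,
    a4 = if (chg >= d$a4_charge$min && chg <= d$a4_charge$max) chg + 3L
         else d$a4_charge$unknown,
    a5 = if (nh <= d$a5_num_h$max) nh else d$a5_num_h$unknown,
    a6 = if (rad <= d$a6_radical$max) rad else d$a6_radical$unknown,
    a7 = unname(d$a7_hybridization$codes[[
      if (a$hybridization %in% names(d$a7_hybridization$codes))
        a$hybridization else "other"]]),
    a8 = as.integer(a$aromatic),
    a9 = as.integer(a$in_ring)
  )
}

#' Bond feature vector (three integer codes)
#'
#' Encodes a bond as (bond-type class, stereo class, conjugation flag).
#' Symmetric in the two endpoints.
#'
#' @param mol A `dta_molecule`.
#' @param i,j 1-based atom indices of the bond's endpoints (either order).
#' @return Named integer vector of length 3 (`b1`, `b2`, `b3`).
#' @export
featurize_bond <- function(mol, i, j) {
  a <- min(i, j); b <- max(i, j)
  row <- which(mol$bonds$i == a & mol$bonds$j == b)
  if (length(row) != 1L)
    stop("no bond between atoms ", i, " and ", j)
  bd <- mol$bonds[row, ]
  d <- dta_dictionaries()
  b1 <- if (bd$aromatic) d$b1_bond_type$codes[["aromatic"]]
        else if (bd$order == 1L) d$b1_bond_type$codes[["single"]]
        else if (bd$order == 2L) d$b1_bond_type$codes[["double"]]
        else if (bd$order == 3L) d$b1_bond_type$codes[["triple"]]
        else d$b1_bond_type$unknown
  b2 <- if (bd$stereo == 0L) d$b2_stereo$codes[["none"]]
        else if (bd$stereo == 1L) d$b2_stereo$codes[["up"]]
        else if (bd$stereo == 6L) d$b2_stereo$codes[["down"]]
        else d$b2_stereo$codes[["other"]]
  c(b1 = unname(b1), b2 = unname(b2), b3 = as.integer(bd$conjugated))
}

#' Build the attributed drug graph
#'
#' Stacks the per-atom nine-code feature vectors, the symmetric 0/1 adjacency
#' matrix, the bond list with bond feature vectors, and per-node degrees.
#'
#' @param mol A `dta_molecule` with at least one atom.
#' @return An object of class `dta_drug_graph`: list with `node_features`
#'   (N x 9 integer matrix), `adjacency` (N x N), `edges` (data frame `i`,
#'   `j`, `b1`, `b2`, `b3`), `degrees`, and `source_id`.
#' @export
build_drug_graph <- function(mol) {
  stopifnot(inherits(mol, "dta_molecule"), n_atoms(mol) >= 1L)
  n <- n_atoms(mol)
  nf <- t(vapply(seq_len(n), function(k) featurize_atom(mol, k),
                 integer(9)))
  rownames(nf) <- NULL
  adj <- matrix(0L, n, n)
  ed <- mol$bonds
  if (nrow(ed)) {
    adj[cbind(ed$i, ed$j)] <- 1L
    adj[cbind(ed$j, ed$i)] <- 1L
    bf <- t(mapply(function(i, j) featurize_bond(mol, i, j), ed$i, ed$j))
    edges <- data.frame(i = ed$i, j = ed$j, b1 = bf[, 1L], b2 = bf[, 2L],
                        b3 = bf[, 3L])
  } else {
    edges <- data.frame(i = integer(0), j = integer(0), b1 = integer(0),
                        b2 = integer(0), b3 = integer(0))
  }
  structure(list(
    node_features = nf, adjacency = adj, edges = edges,
    degrees = rowSums(adj), source_id = mol$source_id
  ), class = "dta_drug_graph")
}

#' Relabel a molecule's atoms
#'
#' Applies a permutation to atom indices (atom `k` of the output is atom
#' `perm[k]` of the input).  Useful for permutation-equivariance checks.
#'
#' @param mol A `dta_molecule`.
#' @param perm Integer permutation of `1:n_atoms(mol)`.
#' @return A `dta_molecule` with relabelled atoms.
#' @export
permute_molecule <- function(mol, perm) {
  stopifnot(sort(perm) == seq_len(n_atoms(mol)))
  inv <- order(perm)  # inv[old] = new index
  atoms <- mol$atoms[perm, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mol$bonds
  if (nrow(bonds)) {
    ni <- inv[bonds$i]; nj <- inv[bonds$j]
    bonds$i <- pmin(ni, nj); bonds$j <- pmax(ni, nj)
    bonds <- bonds[order(bonds$i, bonds$j), , drop = FALSE]
    rownames(bonds) <- NULL
  }
  structure(list(atoms = atoms, bonds = bonds, source_id = mol$source_id),
            class = "dta_molecule")
}

#' @export
print.dta_molecule <- function(x, ...) {
  cat(sprintf("<dta_molecule %s: %d atoms, %d bonds>\n",
              x$source_id, n_atoms(x), n_bonds(x)))
  invisible(x)
}

#' @export
print.dta_drug_graph <- function(x, ...) {
  cat(sprintf("<dta_drug_graph %s: %d nodes, %d edges>\n",
              x$source_id, nrow(x$node_features), nrow(x$edges)))
  invisible(x)
}

#' Read drug structures from a file
#'
#' Accepts either a plain text file with one SMILES per line (optionally
#' `id<whitespace>smiles` or `smiles<whitespace>id`) or a CSV with columns
#' `drug_id,smiles`.
#'
#' @param path File path.
#' @return Named character vector of SMILES (names are drug ids).
#' @export
read_smiles_file <- function(path) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl(",", first, fixed = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("drug_id", "smiles") %in% names(df)))
      stop("CSV drug file must have columns drug_id,smiles: ", path)
    return(stats::setNames(df$smiles, df$drug_id))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  smi <- vapply(parts, `[[`, "", 1L)
  ids <- vapply(seq_along(parts), function(k) {
    if (length(parts[[k]]) >= 2L) parts[[k]][[2L]]
    else sprintf("drug%03d", k)
  }, "")
  stats::setNames(smi, ids)
}

#' Dump drug graphs as JSON lines
#'
#' One molecule per line: node features, edge list with bond features,
#' degrees.  Intended for debugging and interchange.
#'
#' @param graphs List of `dta_drug_graph` objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_drug_graphs_jsonl <- function(graphs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in graphs) {
    writeLines(jsonlite::toJSON(list(
      source_id = g$source_id,
      node_features = unname(g$node_features),
      edges = g$edges,
      degrees = unname(g$degrees)
    ), auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
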