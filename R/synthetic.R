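# Synthetic fixtures: drug-like molecules, protein records with plausible
# secondary-structure / accessibility / contact statistics, and affinity
# labels drawn from a known descriptor function plus Gaussian noise.  The
# generator emulates the *formats and statistics* of affinity benchmarks,
# not binding physics: labels are a printed deterministic function of drug
# and protein descriptors so that recovery is checkable.

# curated template list of valid drug-like SMILES (all parse, <= 64 heavy
# atoms); decorations substitute a phenyl ring or append a methyl chain
.dta_smiles_templates <- c(
  "CC(=O)Oc1ccccc1C(=O)O",          # aspirin
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O",     # ibuprofen
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C",     # caffeine
  "CC(=O)Nc1ccc(O)cc1",             # paracetamol
  "c1ccc2ncccc2c1",                 # quinoline
  "c1ccc2[nH]ccc2c1",               # indole
  "c1ccncc1",                       # pyridine
  "c1ccsc1",                        # thiophene
  "c1ccoc1",                        # furan
  "c1cc[nH]c1",                     # pyrrole
  "C1CCCCC1",                       # cyclohexane
  "C1CCNCC1",                       # piperidine
  "C1CCOC1",                        # tetrahydrofuran
  "O=C(O)c1ccccc1",                 # benzoic acid
  "Nc1ccccc1",                      # aniline
  "Oc1ccccc1",                      # phenol
  "COc1ccccc1",                     # anisole
  "CCN(CC)CC",                      # triethylamine
  "CC(=O)NCCc1ccccc1",              # phenethylacetamide
  "O=S(=O)(N)c1ccccc1",             # benzenesulfonamide
  "CC(N)C(=O)O",                    # alanine
  "NCCc1ccc(O)c(O)c1",              # dopamine
  "CN1CCCC1c1cccnc1",               # nicotine (achiral form)
  "O=C1CCCCC1",                     # cyclohexanone
  "c1ccc(-c2ccccc2)cc1",            # biphenyl
  "c1ccc2ccccc2c1",                 # naphthalene
  "CC(C)(C)c1ccc(O)cc1",            # tert-butylphenol
  "CCOC(=O)c1ccccc1",               # ethyl benzoate
  "N#Cc1ccccc1",                    # benzonitrile
  "FC(F)(F)c1ccccc1",               # benzotrifluoride
  "O=C(Nc1ccccc1)c1ccccc1",         # benzanilide
  "OCC1OC(O)C(O)C(O)C1O",           # pyranose scaffold
  "CCCCCCCC(=O)O",                  # octanoic acid
  "CNC(=O)c1ccccc1",                # N-methylbenzamide
  "COC(=O)C1CCCCC1",                # methyl cyclohexanecarboxylate
  "O=C(O)CCc1ccccc1",               # hydrocinnamic acid
  "Cc1ccc(S(N)(=O)=O)cc1",          # toluenesulfonamide
  "c1ccc(Oc2ccccc2)cc1",            # diphenyl ether
  "NCCO",                           # ethanolamine
  "CC(C)NCC(O)COc1ccccc1",          # aryloxypropanolamine scaffold
  "Cc1ccccc1C",                     # o-xylene
  "CC(C)=CCCC(C)=CC=O",             # citral
  "Nc1ncnc2[nH]cnc12",              # adenine
  "CC(=O)c1ccccc1",                 # acetophenone
  "Oc1ccc(Cl)cc1",                  # chlorophenol
  "CN1CCN(CC1)c1ccccc1",            # phenylpiperazine
  "O=C(O)c1ccc(N)cc1",              # aminobenzoic acid
  "CCOc1ccc(CC(N)C(=O)O)cc1",       # tyrosine-ether scaffold
  "Clc1ccc(C(=O)Nc2ccccc2)cc1",     # chlorobenzanilide
  "CC1=CC(=O)CC(C)(C)C1"            # isophorone
)

.dta_decorations <- c("c1ccc(F)cc1", "c1ccc(Cl)cc1", "c1ccc(C)cc1",
                      "c1ccc(Br)cc1", "c1ccc(OC)cc1")

# fixed, printed affinity weights: both drug and protein descriptors enter,
# plus an interaction term, so neither branch alone can fit the labels
.dta_affinity_weights <- c(w_size = 2.0, w_rings = 1.5, w_asa = 1.0,
                           w_helix = 1.5, w_interact = 2.0)

#' Synthetic fixture specification
#'
#' @param n_drugs,n_proteins Entity counts.
#' @param n_pairs Number of (drug, protein) pairs sampled without
#'   replacement from the full grid (default: the whole grid).
#' @param protein_length Length-2 range of residue counts.
#' @param embed_width Width of the synthetic sequence-embedding provider.
#' @param noise_sd Gaussian label noise standard deviation (0 = noiseless
#'   oracle labels).
#' @param seed Generator seed.
#' @return List of class `dta_fixture_spec`.
#' @export
dta_fixture_spec <- function(n_drugs = 10L, n_proteins = 10L,
                             n_pairs = n_drugs * n_proteins,
                             protein_length = c(25L, 45L),
                             embed_width = 16L, noise_sd = 0.1, seed = 1L) {
  stopifnot(n_drugs >= 1L, n_proteins >= 1L, noise_sd >= 0,
            n_pairs <= n_drugs * n_proteins)
  structure(list(n_drugs = as.integer(n_drugs),
                 n_proteins = as.integer(n_proteins),
                 n_pairs = as.integer(n_pairs),
                 protein_length = as.integer(protein_length),
                 embed_width = as.integer(embed_width),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "dta_fixture_spec")
}

#' Generate a set of drug-like SMILES
#'
#' Samples from the curated template list with seeded decoration (halogen /
#' methyl / methoxy phenyl substitutions or a short alkyl extension); every
#' decorated string is validated by re-parsing and rejected back to its
#' template on failure, so all outputs parse.
#'
#' @param spec A [dta_fixture_spec()].
#' @return Named character vector of `n_drugs` SMILES (names `D001`, ...).
#' @export
gen_drug_set <- function(spec) {
  set.seed(spec$seed)
  out <- character(spec$n_drugs)
  for (k in seq_len(spec$n_drugs)) {
    smi <- sample(.dta_smiles_templates, 1L)
    if (stats::runif(1) < 0.5) {
      cand <- if (grepl("c1ccccc1", smi, fixed = TRUE)) {
        sub("c1ccccc1", sample(.dta_decorations, 1L), smi, fixed = TRUE)
      } else {
        paste0(sample(c("C", "CC"), 1L), smi)
      }
      ok <- tryCatch({
        parse_molecule(cand, source_id = "cand")
        TRUE
      }, error = function(e) FALSE)
      if (ok) smi <- cand
    }
    out[k] <- smi
  }
  stats::setNames(out, sprintf("D%03d", seq_len(spec$n_drugs)))
}

#' Generate a synthetic protein record
#'
#' Sequence uniform over the 20 canonical residues; 8-state secondary
#' structure from a persistent Markov chain (self-transition 0.8); relative
#' accessibility from Beta(2, 2); pseudo-C-beta coordinates from a seeded
#' 3.8-Angstrom-step random walk with excluded-volume rejection, from which
#' the pairwise distance map is computed.
#'
#' @param spec A [dta_fixture_spec()].
#' @param protein_id Identifier.
#' @param seed Seed for this record (defaults to the spec seed).
#' @return A [protein_record()] with a distance-kind map.
#' @export
gen_protein_record <- function(spec, protein_id = "P001",
                               seed = spec$seed) {
  set.seed(seed)
  m <- spec$protein_length[1L] +
    sample.int(spec$protein_length[2L] - spec$protein_length[1L] + 1L,
               1L) - 1L
  sequence <- paste(sample(.dta_amino_acids, m, replace = TRUE),
                    collapse = "")
  ss <- character(m)
  ss[1L] <- sample(.dta_ss8_alphabet, 1L)
  for (i in 2:m) {
    ss[i] <- if (stats::runif(1) < 0.8) ss[i - 1L]
             else sample(setdiff(.dta_ss8_alphabet, ss[i - 1L]), 1L)
  }
  asa <- stats::rbeta(m, 2, 2)
  coords <- matrix(0, m, 3L)
  if (m >= 2L) for (i in 2:m) {
    for (try in 1:50) {
      dir <- stats::rnorm(3L)
      step <- coords[i - 1L, ] + 3.8 * dir / sqrt(sum(dir^2))
      if (i <= 2L) break
      dmin <- min(sqrt(rowSums(sweep(coords[1:(i - 2L), , drop = FALSE], 2L,
                                     step)^2)))
      if (dmin >= 3.0) break
    }
    coords[i, ] <- step
  }
  dm <- as.matrix(stats::dist(coords))
  protein_record(protein_id, sequence, paste(ss, collapse = ""), asa, dm,
                 kind = "distance")
}

# descriptor extraction used by the label function
.dta_drug_descriptors <- function(mol) {
  c(heavy_atoms = n_atoms(mol), aromatic_rings = mol$n_aromatic_rings)
}

.dta_protein_descriptors <- function(rec) {
  c(mean_asa = mean(rec$asa),
    helix_frac = mean(strsplit(rec$ss8, "")[[1L]] %in% c("H", "G", "I")))
}

#' Synthetic affinity label function
#'
#' The noiseless label is
#' `w_size * heavy_atoms / 64 + w_rings * aromatic_rings / 6 + w_asa *
#' mean_asa + w_helix * helix_frac + w_interact * (aromatic_rings / 6) *
#' helix_frac` with the fixed weights `(2.0, 1.5, 1.0, 1.5, 2.0)`.  Both
#' drug and protein descriptors and their interaction enter, so fitting the
#' labels requires information from both branches.
#'
#' @param drug_desc Named vector with `heavy_atoms`, `aromatic_rings`.
#' @param prot_desc Named vector with `mean_asa`, `helix_frac`.
#' @return Noiseless affinity value.
#' @export
dta_affinity_formula <- function(drug_desc, prot_desc) {
  w <- .dta_affinity_weights
  unname(w["w_size"] * drug_desc[["heavy_atoms"]] / 64 +
         w["w_rings"] * drug_desc[["aromatic_rings"]] / 6 +
         w["w_asa"] * prot_desc[["mean_asa"]] +
         w["w_helix"] * prot_desc[["helix_frac"]] +
         w["w_interact"] * (drug_desc[["aromatic_rings"]] / 6) *
           prot_desc[["helix_frac"]])
}

#' Generate a complete synthetic affinity dataset
#'
#' Drugs, protein records, and (drug, protein, affinity) pairs with labels
#' from [dta_affinity_formula()] plus Gaussian noise of standard deviation
#' `spec$noise_sd`.
#'
#' @param spec A [dta_fixture_spec()].
#' @return Object of class `dta_dataset`: list with `drugs` (named SMILES),
#'   `proteins` (named list of records), `pairs` (data frame `drug_id`,
#'   `protein_id`, `affinity`), `affinity_kind = "pkd"`, `spec`, and the
#'   descriptor tables used by the label function.
#' @export
gen_dataset <- function(spec) {
  drugs <- gen_drug_set(spec)
  proteins <- lapply(seq_len(spec$n_proteins), function(k)
    gen_protein_record(spec, sprintf("P%03d", k), seed = spec$seed + 1000L + k))
  names(proteins) <- vapply(proteins, `[[`, "", "protein_id")
  mols <- lapply(names(drugs), function(id)
    parse_molecule(drugs[[id]], source_id = id))
  names(mols) <- names(drugs)
  ddesc <- t(vapply(mols, .dta_drug_descriptors, numeric(2)))
  pdesc <- t(vapply(proteins, .dta_protein_descriptors, numeric(2)))
  set.seed(spec$seed + 500L)
  grid <- expand.grid(drug_id = names(drugs), protein_id = names(proteins),
                      stringsAsFactors = FALSE)
  grid <- grid[sample(nrow(grid), spec$n_pairs), , drop = FALSE]
  base <- mapply(function(d, p) dta_affinity_formula(ddesc[d, ], pdesc[p, ]),
                 grid$drug_id, grid$protein_id)
  noise <- if (spec$noise_sd > 0) stats::rnorm(nrow(grid), 0, spec$noise_sd)
           else 0
  pairs <- data.frame(drug_id = grid$drug_id, protein_id = grid$protein_id,
                      affinity = as.numeric(base + noise))
  rownames(pairs) <- NULL
  structure(list(drugs = drugs, proteins = proteins, pairs = pairs,
                 affinity_kind = "pkd", spec = spec,
                 drug_descriptors = ddesc, protein_descriptors = pdesc),
            class = "dta_dataset")
}

#' Write a synthetic dataset in the pipeline's input formats
#'
#' Produces `drugs.csv` (`drug_id,smiles`), one protein record per id under
#' `proteins/` (see [write_protein_record()]), and `manifest.tsv`
#' (`drug_id`, `protein_id`, `affinity`).
#'
#' @param ds A `dta_dataset`.
#' @param dir Output directory (created).
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(
    data.frame(drug_id = names(ds$drugs), smiles = unname(ds$drugs)),
    file.path(dir, "drugs.csv"), row.names = FALSE, quote = FALSE)
  pdir <- file.path(dir, "proteins")
  for (rec in ds$proteins) write_protein_record(rec, pdir)
  utils::write.table(ds$pairs, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @export
print.dta_dataset <- function(x, ...) {
  cat(sprintf("<dta_dataset: %d drugs, %d proteins, %d pairs (%s)>\n",
              length(x$drugs), length(x$proteins), nrow(x$pairs),
              x$affinity_kind))
  invisible(x)
}
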