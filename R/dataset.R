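# Dataset loading and the 6-part split protocol with 5-fold cross-validation.

#' Load an affinity dataset from disk
#'
#' Reads the pair manifest (TSV with header `drug_id`, `protein_id`,
#' `affinity`), the drug file (SMILES CSV or one-per-line, see
#' [read_smiles_file()]), and one protein record per referenced id from
#' `protein_dir` (see [read_protein_record()]).  Rows with missing or
#' non-finite affinity are skipped with a message; `kd_nM` affinities are
#' transformed to pKd at load.
#'
#' @param manifest_path Path to the manifest TSV.
#' @param drug_file Path to the drug file.
#' @param protein_dir Directory of protein records.
#' @param affinity_kind `"pkd"` (used as-is), `"kd_nM"` (transformed via
#'   [kd_to_pkd()]), or `"kiba"` (used as-is).
#' @return A `dta_dataset`.
#' @export
load_dataset <- function(manifest_path, drug_file, protein_dir,
                         affinity_kind = c("pkd", "kd_nM", "kiba")) {
  affinity_kind <- match.arg(affinity_kind)
  man <- utils::read.table(manifest_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("drug_id", "protein_id", "affinity") %in% names(man)))
    stop("manifest must have columns drug_id, protein_id, affinity: ",
         manifest_path)
  drugs <- read_smiles_file(drug_file)
  bad_drug <- !man$drug_id %in% names(drugs)
  if (any(bad_drug))
    stop("manifest line ", which(bad_drug)[1L] + 1L,
         ": unknown drug id '", man$drug_id[bad_drug][1L], "'")
  keep <- is.finite(man$affinity)
  if (any(!keep))
    message("skipping ", sum(!keep), " pair(s) with missing affinity")
  man <- man[keep, , drop = FALSE]
  prot_ids <- unique(man$protein_id)
  proteins <- lapply(prot_ids, function(id)
    tryCatch(read_protein_record(protein_dir, id),
             error = function(e)
               stop("protein id '", id, "' referenced by manifest: ",
                    conditionMessage(e), call. = FALSE)))
  names(proteins) <- prot_ids
  aff <- if (affinity_kind == "kd_nM") kd_to_pkd(man$affinity)
         else man$affinity
  structure(list(
    drugs = drugs[unique(man$drug_id)],
    proteins = proteins,
    pairs = data.frame(drug_id = man$drug_id, protein_id = man$protein_id,
                       affinity = aff),
    affinity_kind = if (affinity_kind == "kd_nM") "pkd" else affinity_kind,
    spec = NULL), class = "dta_dataset")
}

#' Split a dataset into six parts with 5-fold cross-validation
#'
#' Seeded shuffle of the pairs into 6 equal parts (sizes differing by at
#' most one); the last part is the independent test set and the remaining
#' five parts form the cross-validation folds (fold `k` validates on part
#' `k`).  The split unit is the (drug, protein) pair (warm-start protocol).
#' With `quadrants = TRUE` the pairs are first partitioned into four seeded
#' subsets, each independently split six ways.
#'
#' @param ds A `dta_dataset` (or an integer pair count).
#' @param seed Shuffle seed.
#' @param quadrants Return four independent subset plans.
#' @return A `dta_split_plan`: list with `part` (1..6 per pair),
#'   `test_part = 6`, `cv_folds` (list of 5 integer vectors of validation
#'   pair indices), `seed`; or a list of four such plans (each with a
#'   `subset` index vector) when `quadrants = TRUE`.
#' @export
make_splits <- function(ds, seed = 1L, quadrants = FALSE) {
  n <- if (is.numeric(ds)) as.integer(ds) else nrow(ds$pairs)
  if (n < 12L) stop("too few pairs to split six ways: ", n)
  set.seed(seed)
  if (quadrants) {
    quad <- sample(rep_len(1:4, n))
    return(lapply(1:4, function(q) {
      idx <- which(quad == q)
      plan <- make_splits(length(idx), seed = seed + q)
      plan$subset <- idx
      plan
    }))
  }
  part <- sample(rep_len(1:6, n))
  folds <- lapply(1:5, function(k) which(part == k))
  structure(list(part = part, test_part = 6L, cv_folds = folds,
                 seed = as.integer(seed)),
            class = "dta_split_plan")
}

#' @export
print.dta_split_plan <- function(x, ...) {
  cat(sprintf("<dta_split_plan: %d pairs, parts %s, test part %d>\n",
              length(x$part),
              paste(tabulate(x$part, 6L), collapse = "/"), x$test_part))
  invisible(x)
}
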