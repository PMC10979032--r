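# Frozen featurization dictionaries.  Codes are stable across releases; raw
# values outside a dictionary map to its reserved "unknown" code.  Embedding
# tables are sized from `n_codes`, so changing any entry is a breaking change.

.dta_dict_version <- "1"

#' Featurization dictionaries
#'
#' Returns the frozen integer-code dictionaries used by [featurize_atom()] and
#' [featurize_bond()].  Every attribute maps to a dense non-negative code;
#' out-of-dictionary raw values map to the attribute's `unknown` code.
#'
#' @return A named list; each element has `n_codes` and (where relevant) the
#'   code table and `unknown` code.
#' @export
dta_dictionaries <- function() {
  list(
    version = .dta_dict_version,
    # a1: heavy-atom count of the parent molecule, clipped to [1, 128]
    a1_atom_count = list(max = 128L, n_codes = 129L),
    # a2: chirality class
    a2_chirality = list(
      codes = c(none = 0L, R = 1L, S = 2L, axial = 3L, planar = 4L,
                helical = 5L),
      n_codes = 6L
    ),
    # a3: heavy-atom degree
    a3_degree = list(max = 6L, unknown = 7L, n_codes = 8L),
    # a4: formal charge, code = charge + 3 for charge in [-3, 3]
    a4_charge = list(min = -3L, max = 3L, unknown = 7L, n_codes = 8L),
    # a5: attached (implicit) hydrogen count
    a5_num_h = list(max = 4L, unknown = 5L, n_codes = 6L),
    # a6: radical electron count
    a6_radical = list(max = 2L, unknown = 3L, n_codes = 4L),
    # a7: hybridization class
    a7_hybridization = list(
      codes = c(other = 0L, s = 1L, sp = 2L, sp2 = 3L, sp3 = 4L,
                sp3d = 5L, sp3d2 = 6L),
      n_codes = 7L
    ),
    a8_aromatic = list(n_codes = 2L),
    a9_in_ring = list(n_codes = 2L),
    # bond dictionaries
    b1_bond_type = list(
      codes = c(single = 0L, double = 1L, triple = 2L, aromatic = 3L),
      unknown = 4L, n_codes = 5L
    ),
    b2_stereo = list(
      codes = c(none = 0L, up = 1L, down = 2L, other = 3L),
      n_codes = 4L
    ),
    b3_conjugated = list(n_codes = 2L),
    # mol-encoder path: element vocabulary (index into this vector + unknown)
    elements = c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "B", "Si",
                 "Se"),
    # atom index feature (position in molecule), clipped
    atom_index_max = 128L
  )
}

# default valences used to infer implicit hydrogen counts from kekule bond
# orders; effective valence is adjusted by formal charge (see .dta_implicit_h)
.dta_default_valence <- c(
  B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2, Cl = 1,
  Br = 1, I = 1, Se = 2
)

# Wilke (tripeptide) maximum accessible surface areas in Angstrom^2, used to
# normalize absolute ASA inputs to relative accessibility in [0, 1]
.dta_max_asa <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225, G = 104,
  H = 224, I = 197, L = 201, K = 236, M = 224, F = 240, P = 159, S = 155,
  T = 172, W = 285, Y = 263, V = 174
)

# 8-state secondary-structure alphabet (DSSP order)
.dta_ss8_alphabet <- c("H", "G", "I", "E", "B", "T", "S", "C")

# 20 canonical amino acids
.dta_amino_acids <- names(.dta_max_asa)
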