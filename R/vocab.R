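# Feature vocabularies for molecular graph tensors.
#
# Node features: (atom-type index, chirality index). The atom-type index is
# the atomic number (1..118); one extra reserved index is the mask token,
# used only when a graph is corrupted for pretraining. Edge features:
# (bond-type index, bond-direction index).

#' Feature vocabulary sizes
#'
#' Returns the sizes of the integer feature vocabularies used by
#' [featurize()] and the encoder: atom types (118 elements plus one reserved
#' mask token), chirality tags, bond types and bond directions.
#'
#' @return Named list with elements `atom` (119), `mask_token` (119, the
#'   reserved atom-type index), `chirality` (4), `bond_type` (4),
#'   `bond_dir` (3).
#' @export
#' @examples
#' feature_vocab()$mask_token
feature_vocab <- function() {
  list(
    atom = 119L, mask_token = 119L,
    chirality = 4L,   # unspecified, CW, CCW, other
    bond_type = 4L,   # single, double, triple, aromatic
    bond_dir = 3L     # none, end-up, end-down
  )
}

CHIRALITY_TAGS <- c("unspecified", "CW", "CCW", "other")
BOND_TYPES <- c("single", "double", "triple", "aromatic")
BOND_DIRS <- c("none", "end-up", "end-down")

# IUPAC element symbols indexed by atomic number 1..118.
ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm",
  "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og"
)

#' @keywords internal
atomic_number <- function(symbol) {
  z <- match(symbol, ELEMENT_SYMBOLS)
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(z)]), collapse = ", "))
  }
  z
}

# Maximum number of single-bond neighbours a heavy atom may take in the
# synthetic generator (standard organic valences, halogens monovalent).
ORGANIC_VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L,
                     F = 1L, Cl = 1L, Br = 1L, I = 1L, B = 3L)
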