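# Fixed alphabets and lookup tables.

# Amino-acid column ordering used everywhere in this package (alphabetical).
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Non-standard residue codes: rejected in strict mode, encoded as all-zero
# rows in lenient mode.
AA_NONSTANDARD <- c("B", "J", "O", "U", "X", "Z")

# Column order of PSI-BLAST ASCII PSSM files.
PSSM_AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# The 15 therapeutic peptide function classes, in canonical order.
DEFAULT_FUNCTIONS <- c("AMP", "TXP", "ABP", "AIP", "AVP", "ACP", "AFP", "DDV",
                       "CPP", "CCC", "APP", "AAP", "AHTP", "PBP", "QSP")

# BLOSUM62 substitution scores, rows/columns in AA_ALPHABET order; used as an
# optional per-residue profile substitute when no PSSM is available.
BLOSUM62_AA <- matrix(c(
   4,  0, -2, -1, -2,  0, -2, -1, -1, -1, -1, -2, -1, -1, -1,  1,  0,  0, -3, -2,
   0,  9, -3, -4, -2, -3, -3, -1, -3, -1, -1, -3, -3, -3, -3, -1, -1, -1, -2, -2,
  -2, -3,  6,  2, -3, -1, -1, -3, -1, -4, -3,  1, -1,  0, -2,  0, -1, -3, -4, -3,
  -1, -4,  2,  5, -3, -2,  0, -3,  1, -3, -2,  0, -1,  2,  0,  0, -1, -2, -3, -2,
  -2, -2, -3, -3,  6, -3, -1,  0, -3,  0,  0, -3, -4, -3, -3, -2, -2, -1,  1,  3,
   0, -3, -1, -2, -3,  6, -2, -4, -2, -4, -3,  0, -2, -2, -2,  0, -2, -3, -2, -3,
  -2, -3, -1,  0, -1, -2,  8, -3, -1, -3, -2,  1, -2,  0,  0, -1, -2, -3, -2,  2,
  -1, -1, -3, -3,  0, -4, -3,  4, -3,  2,  1, -3, -3, -3, -3, -2, -1,  3, -3, -1,
  -1, -3, -1,  1, -3, -2, -1, -3,  5, -2, -1,  0, -1,  1,  2,  0, -1, -2, -3, -2,
  -1, -1, -4, -3,  0, -4, -3,  2, -2,  4,  2, -3, -3, -2, -2, -2, -1,  1, -2, -1,
  -1, -1, -3, -2,  0, -3, -2,  1, -1,  2,  5, -2, -2,  0, -1, -1, -1,  1, -1, -1,
  -2, -3,  1,  0, -3,  0,  1, -3,  0, -3, -2,  6, -2,  0,  0,  1,  0, -3, -4, -2,
  -1, -3, -1, -1, -4, -2, -2, -3, -1, -3, -2, -2,  7, -1, -2, -1, -1, -2, -4, -3,
  -1, -3,  0,  2, -3, -2,  0, -3,  1, -2,  0,  0, -1,  5,  1,  0, -1, -2, -2, -1,
  -1, -3, -2,  0, -3, -2,  0, -3,  2, -2, -1,  0, -2,  1,  5, -1, -1, -3, -3, -2,
   1, -1,  0,  0, -2,  0, -1, -2,  0, -2, -1,  1, -1,  0, -1,  4,  1, -2, -3, -2,
   0, -1, -1, -1, -2, -2, -2, -1, -1, -1, -1,  0, -1, -1, -1,  1,  5,  0, -2, -2,
   0, -1, -3, -2, -1, -3, -3,  3, -2,  1,  1, -3, -2, -2, -3, -2,  0,  4, -3, -1,
  -3, -2, -4, -3,  1, -2, -2, -3, -3, -2, -1, -4, -4, -2, -3, -3, -2, -3, 11,  2,
  -2, -2, -3, -2,  3, -3,  2, -1, -2, -1, -1, -2, -3, -1, -2, -2, -2, -1,  2,  7),
  nrow = 20, byrow = TRUE, dimnames = list(AA_ALPHABET, AA_ALPHABET))

#' Function vocabulary
#'
#' The ordered set of therapeutic peptide function classes the model predicts.
#' The default is the canonical 15-class vocabulary (AMP, TXP, ABP, AIP, AVP,
#' ACP, AFP, DDV, CPP, CCC, APP, AAP, AHTP, PBP, QSP); any vocabulary with at
#' least two unique names is accepted, e.g. a subset for smaller synthetic
#' benchmarks.
#'
#' @param names Character vector of function names, or `NULL` for the default
#'   15-class vocabulary. Optionally, a single integer to take the first
#'   `names` classes of the default vocabulary.
#' @return Character vector of class names (the vocabulary, in order).
#' @examples
#' function_vocabulary()        # all 15 classes
#' function_vocabulary(8)       # first 8 classes
#' @export
function_vocabulary <- function(names = NULL) {
  if (is.null(names)) return(DEFAULT_FUNCTIONS)
  if (is.numeric(names) && length(names) == 1) {
    stopifnot(names >= 2, names <= length(DEFAULT_FUNCTIONS))
    return(DEFAULT_FUNCTIONS[seq_len(names)])
  }
  names <- as.character(names)
  if (anyDuplicated(names)) stop("function names must be unique")
  if (length(names) < 2) stop("a function vocabulary needs at least 2 classes")
  names
}
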