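# Conversion of raw peptides into the fixed-shape numeric inputs the network
# consumes: an L x 40 residue feature matrix (one-hot composition in columns
# 1-20, PSSM scores or a documented fallback in columns 21-40) plus the C x C
# identity pattern of function tokens.

#' Pad or truncate a sequence to the model length
#'
#' Sequences shorter than `L` are padded at the end (padding positions are
#' written as `-` and flagged in the mask); sequences longer than `L` are
#' spliced as the first `L/2` N-terminal residues concatenated with the last
#' `L/2` C-terminal residues, so both termini are preserved. A sequence of
#' exactly length `L` is returned unchanged. Idempotent on its own output.
#'
#' @param sequence A single peptide sequence (non-empty string). `-`
#'   characters are interpreted as existing padding.
#' @param L Model length (default 50); must be even so the splice rule can
#'   take `L/2` residues from each terminus.
#' @return A list with `sequence` (string of length `L`) and `mask` (logical
#'   vector of length `L`; `TRUE` marks real residues).
#' @export
pad_or_truncate <- function(sequence, L = 50) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) < 1) stop("sequence must be non-empty")
  if (L %% 2 != 0)
    stop("L must be even: the truncation rule takes L/2 residues from each terminus")
  n <- nchar(sequence)
  if (n < L) {
    out <- paste0(sequence, strrep("-", L - n))
  } else if (n > L) {
    out <- paste0(substr(sequence, 1, L / 2), substr(sequence, n - L / 2 + 1, n))
  } else {
    out <- sequence
  }
  mask <- strsplit(out, "")[[1]] != "-"
  list(sequence = out, mask = mask)
}

#' One-hot encode a length-L sequence
#'
#' Maps each residue to a 20-dimensional indicator vector using the fixed
#' alphabetical column order `ACDEFGHIKLMNPQRSTVWY`. Padding positions (mask
#' `FALSE` or `-`) become all-zero rows. Non-standard residues (B, J, O, U,
#' X, Z) are an error in strict mode and all-zero rows otherwise; any other
#' character is always an error.
#'
#' @param sequence50 String as produced by [pad_or_truncate()].
#' @param mask Logical vector marking real residues; defaults to `!= "-"`.
#' @param strict Reject non-standard residues.
#' @return An L x 20 numeric matrix with column names `AA_ALPHABET`.
#' @export
one_hot_encode <- function(sequence50, mask = NULL, strict = FALSE) {
  chars <- strsplit(sequence50, "")[[1]]
  L <- length(chars)
  if (is.null(mask)) mask <- chars != "-"
  stopifnot(length(mask) == L)
  X <- matrix(0, nrow = L, ncol = 20, dimnames = list(NULL, AA_ALPHABET))
  for (i in seq_len(L)) {
    if (!mask[i]) next
    ch <- chars[i]
    j <- match(ch, AA_ALPHABET)
    if (!is.na(j)) {
      X[i, j] <- 1
    } else if (ch %in% AA_NONSTANDARD) {
      if (strict)
        stop("non-standard residue '", ch, "' at position ", i,
             " (strict mode rejects non-standard residues)")
      # lenient: all-zero composition row
    } else {
      stop("unknown character '", ch, "' at position ", i)
    }
  }
  X
}

# Apply the same pad/truncate splice rule to the rows of a per-residue
# profile matrix (n_raw x 20).
splice_profile_rows <- function(profile, n_raw, L) {
  out <- matrix(0, nrow = L, ncol = 20)
  if (n_raw <= L) {
    out[seq_len(n_raw), ] <- profile
  } else {
    out[] <- rbind(profile[seq_len(L / 2), , drop = FALSE],
                   profile[(n_raw - L / 2 + 1):n_raw, , drop = FALSE])
  }
  out
}

#' Encode one peptide as network input
#'
#' Builds the residue feature matrix `Xs` (L x 40: one-hot composition in
#' columns 1-20, per-residue profile scores in columns 21-40) and the function
#' token matrix `Xt` (the C x C identity pattern). The profile block uses the
#' supplied PSSM, spliced by the same pad/truncate rule as the sequence; when
#' no PSSM is available the fallback fills it with zeros (default) or with the
#' BLOSUM62 row of each residue.
#'
#' @param peptide A sequence string, or a one-row peptide table with a
#'   `sequence` column.
#' @param pssm Optional matrix from [parse_pssm()]; row count must equal the
#'   raw sequence length.
#' @param vocab Function vocabulary.
#' @param L Model length.
#' @param pssm_fallback `"zero"` or `"blosum62"`.
#' @param strict Passed to [one_hot_encode()].
#' @return A list of class `mp_encoded`: `Xs` (L x 40), `Xt` (C x C identity),
#'   `mask` (logical L).
#' @export
encode_sample <- function(peptide, pssm = NULL, vocab = function_vocabulary(),
                          L = 50, pssm_fallback = c("zero", "blosum62"),
                          strict = FALSE) {
  pssm_fallback <- match.arg(pssm_fallback)
  seqc <- if (is.character(peptide)) peptide else peptide$sequence[[1]]
  n_raw <- nchar(seqc)
  pt <- pad_or_truncate(seqc, L)
  onehot <- one_hot_encode(pt$sequence, pt$mask, strict = strict)
  if (!is.null(pssm)) {
    if (nrow(pssm) != n_raw)
      stop("PSSM has ", nrow(pssm), " rows but sequence has ", n_raw, " residues")
    prof <- splice_profile_rows(unclass(pssm)[, , drop = FALSE], n_raw, L)
  } else if (pssm_fallback == "blosum62") {
    chars <- strsplit(pt$sequence, "")[[1]]
    prof <- matrix(0, nrow = L, ncol = 20)
    hit <- match(chars, AA_ALPHABET)
    ok <- which(!is.na(hit) & pt$mask)
    prof[ok, ] <- BLOSUM62_AA[hit[ok], , drop = FALSE]
  } else {
    prof <- matrix(0, nrow = L, ncol = 20)
  }
  Xs <- cbind(onehot, prof)
  C <- length(vocab)
  structure(list(Xs = Xs, Xt = diag(C), mask = pt$mask),
            class = "mp_encoded")
}

#' Encode a peptide table into stacked arrays
#'
#' Vectorised version of [encode_sample()] producing the stacked inputs used
#' by training and batched prediction.
#'
#' @param peps Peptide table (`id`, `sequence`).
#' @param vocab Function vocabulary.
#' @param pssms Optional named list of PSSM matrices keyed by peptide id.
#' @param L Model length.
#' @param pssm_fallback See [encode_sample()].
#' @return A list: `X` (L x 40 x N array), `mask` (L x N matrix), `ids`.
#' @export
encode_peptides <- function(peps, vocab = function_vocabulary(), pssms = NULL,
                            L = 50, pssm_fallback = c("zero", "blosum62")) {
  pssm_fallback <- match.arg(pssm_fallback)
  n <- nrow(peps)
  X <- array(0, dim = c(L, 40, n))
  mask <- matrix(FALSE, nrow = L, ncol = n)
  for (i in seq_len(n)) {
    ps <- if (!is.null(pssms)) pssms[[peps$id[[i]]]] else NULL
    enc <- encode_sample(peps$sequence[[i]], pssm = ps, vocab = vocab, L = L,
                         pssm_fallback = pssm_fallback)
    X[, , i] <- enc$Xs
    mask[, i] <- enc$mask
  }
  list(X = X, mask = mask * 1, ids = peps$id)
}
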