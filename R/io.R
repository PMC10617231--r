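# Readers/writers for the standard interchange formats: FASTA peptides,
# binary label tables (CSV/TSV) and PSI-BLAST ASCII PSSM profiles.

#' Read peptides from a FASTA file
#'
#' Parses a (possibly multi-line) FASTA file of amino-acid sequences into a
#' peptide table. Record ids are the first whitespace-delimited token of each
#' header; duplicated ids are disambiguated deterministically by appending
#' `.2`, `.3`, ... in file order. Sequences are upper-cased.
#'
#' Residue policy: the 20 standard one-letter codes are always accepted.
#' Non-standard codes (B, J, O, U, X, Z) are rejected with the offending
#' record and position when `strict = TRUE`, and kept (they encode to all-zero
#' feature rows) otherwise. Any other character is a parse error. Sequences
#' shorter than `min_length` produce a warning (`strict = FALSE`) or an error
#' (`strict = TRUE`); predictions on very short peptides are unreliable.
#'
#' @param path Path to a FASTA file.
#' @param min_length Minimum recommended sequence length (default 10).
#' @param strict If `TRUE`, reject non-standard residues and short sequences
#'   instead of warning.
#' @return A `data.frame` with columns `id`, `sequence`, and a `labels`
#'   list-column (empty sets; labels come from [read_label_table()]).
#' @export
read_fasta <- function(path, min_length = 10, strict = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) return(empty_peptides())
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  if (length(set) == 0) return(empty_peptides())
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1)
  if (any(is.na(ids) | ids == ""))
    ids[is.na(ids) | ids == ""] <- sprintf("record%d", which(is.na(ids) | ids == ""))
  ids <- make.unique(ids, sep = ".")
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    if (nchar(s) < 1)
      stop("malformed FASTA: record '", ids[[i]], "' has an empty sequence")
    chars <- strsplit(s, "")[[1]]
    bad <- !(chars %in% c(AA_ALPHABET, AA_NONSTANDARD))
    if (any(bad))
      stop("malformed FASTA: record '", ids[[i]], "' contains invalid character '",
           chars[which(bad)[1]], "' at position ", which(bad)[1])
    ns <- chars %in% AA_NONSTANDARD
    if (any(ns) && strict)
      stop("record '", ids[[i]], "' contains non-standard residue '",
           chars[which(ns)[1]], "' at position ", which(ns)[1],
           " (strict mode rejects non-standard residues)")
  }
  short <- nchar(seqs) < min_length
  if (any(short)) {
    msg <- paste0(sum(short), " sequence(s) shorter than ", min_length,
                  " residues: ", paste(head(ids[short], 5), collapse = ", "))
    if (strict) stop(msg) else warning(msg, call. = FALSE)
  }
  peptides(ids, unname(seqs))
}

empty_peptides <- function() {
  data.frame(id = character(0), sequence = character(0))
}

peptides <- function(ids, seqs, labels = NULL) {
  df <- data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
  df$labels <- if (is.null(labels)) replicate(nrow(df), character(0), simplify = FALSE)
               else labels
  df
}

#' Write peptides to a FASTA file
#'
#' @param peps Peptide table (`id`, `sequence` columns).
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(peps, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(peps))) {
    writeLines(paste0(">", peps$id[[i]]), con)
    s <- peps$sequence[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a binary label table
#'
#' Reads a delimited (CSV or TSV, auto-detected) table whose header is
#' `id,<func1>,...,<funcC>` and whose cells are 0/1, and returns the label
#' matrix with columns reordered to the vocabulary order.
#'
#' @param path Path to the label table.
#' @param vocab Function vocabulary (see [function_vocabulary()]).
#' @param ids Optional character vector of expected sample ids (e.g. from a
#'   FASTA); an error lists ids missing from the table.
#' @return A list with `ids` (character) and `Y` (N x C binary integer matrix,
#'   rownames = ids, colnames = vocab).
#' @export
read_label_table <- function(path, vocab = function_vocabulary(), ids = NULL) {
  if (!file.exists(path)) stop("label table not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("label table must have an id column and function columns")
  tab_ids <- as.character(tab[[1]])
  cols <- colnames(tab)[-1]
  missing_fn <- setdiff(vocab, cols)
  if (length(missing_fn) > 0)
    stop("label table is missing function column(s): ", paste(missing_fn, collapse = ", "))
  unknown <- setdiff(cols, vocab)
  if (length(unknown) > 0)
    stop("label table has unknown function column(s): ", paste(unknown, collapse = ", "))
  Y <- as.matrix(tab[, vocab, drop = FALSE])
  bad <- which(!(Y %in% c(0, 1)))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(Y))
    stop("non-binary label value '", Y[bad[1]], "' at row ", rc[1],
         " (id '", tab_ids[rc[1]], "'), column '", vocab[rc[2]], "'")
  }
  storage.mode(Y) <- "integer"
  rownames(Y) <- tab_ids
  if (!is.null(ids)) {
    miss <- setdiff(ids, tab_ids)
    if (length(miss) > 0)
      stop("label table is missing id(s): ", paste(head(miss, 10), collapse = ", "))
    Y <- Y[ids, , drop = FALSE]
    tab_ids <- ids
  }
  list(ids = tab_ids, Y = Y)
}

#' Write a binary label table
#'
#' Inverse of [read_label_table()]; round-trips bit-exactly.
#'
#' @param ids Sample ids (row order of `Y`).
#' @param Y N x C binary matrix with colnames = function names.
#' @param path Output path; `.tsv` extension writes tab-separated, else CSV.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(ids, Y, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(id = ids, Y, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the position-specific scoring matrix written by PSI-BLAST's
#' `-out_ascii_pssm` option (running PSI-BLAST itself is outside this
#' package's scope) and returns the 20 log-odds score columns per residue,
#' reordered from PSI-BLAST's column order to this package's alphabetical
#' amino-acid order (`ACDEFGHIKLMNPQRSTVWY`). Scores are kept as raw log-odds.
#'
#' @param path Path to the ASCII PSSM file.
#' @param sequence Optional raw peptide sequence to cross-check residue
#'   letters against (error names the first mismatching position).
#' @return An n x 20 numeric matrix (one row per residue of the raw,
#'   untruncated sequence), with the residue letters as a `residues`
#'   attribute.
#' @export
parse_pssm <- function(path, sequence = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("PSSM parse error: file is empty: ", path)
  data_re <- "^\\s*([0-9]+)\\s+([A-Za-z])\\s+(-?[0-9].*)$"
  hits <- grep(data_re, lines)
  if (length(hits) == 0)
    stop("PSSM parse error: no matrix rows found in ", path)
  pos <- integer(0); res <- character(0)
  scores <- matrix(numeric(0), ncol = 20)
  for (i in hits) {
    m <- regmatches(lines[i], regexec(data_re, lines[i]))[[1]]
    vals <- suppressWarnings(as.numeric(strsplit(trimws(m[4]), "\\s+")[[1]]))
    if (length(vals) < 20 || anyNA(vals[1:20]))
      stop("PSSM parse error at line ", i, ": expected at least 20 numeric scores, got ",
           sum(!is.na(vals)))
    pos <- c(pos, as.integer(m[2]))
    res <- c(res, toupper(m[3]))
    scores <- rbind(scores, vals[1:20])
  }
  if (!all(pos == seq_along(pos)))
    stop("PSSM parse error: residue positions are not consecutive from 1 (file truncated?)")
  colnames(scores) <- PSSM_AA_ORDER
  scores <- scores[, AA_ALPHABET, drop = FALSE]
  rownames(scores) <- NULL
  if (!is.null(sequence)) {
    sq <- strsplit(toupper(sequence), "")[[1]]
    if (length(sq) != nrow(scores))
      stop("PSSM has ", nrow(scores), " rows but sequence has ", length(sq), " residues")
    mism <- which(sq != res)
    if (length(mism) > 0)
      stop("PSSM residue mismatch at position ", mism[1], ": PSSM has '",
           res[mism[1]], "', sequence has '", sq[mism[1]], "'")
  }
  attr(scores, "residues") <- res
  scores
}
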