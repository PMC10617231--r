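# Reading standard formats and producing the fixed-shape network inputs.

test_that("read_fasta parses records, tracks ids and enforces the residue policy", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "GVAKFGKAAAHFGKGWIKEMLNS"), f)
  peps <- read_fasta(f)
  expect_equal(nrow(peps), 1)
  expect_equal(peps$id, "p1")
  expect_equal(nchar(peps$sequence), 23)
  expect_equal(peps$labels[[1]], character(0))

  # multi-line sequences are concatenated
  writeLines(c(">p1", "GVAKFGKAAAHF", "GKGWIKEMLNS"), f)
  expect_equal(read_fasta(f)$sequence, "GVAKFGKAAAHFGKGWIKEMLNS")

  # empty file -> empty table
  writeLines(character(0), f)
  expect_equal(nrow(read_fasta(f)), 0)

  # duplicate ids are suffixed deterministically
  writeLines(c(">a", "ACDEFGHIKLMN", ">a", "ACDEFGHIKLMV"), f)
  expect_equal(read_fasta(f)$id, c("a", "a.1"))

  # non-standard residue: lenient keeps, strict rejects naming the position
  writeLines(c(">b1", "ACDEFGHIKBMN"), f)
  expect_equal(nrow(read_fasta(f)), 1)
  expect_error(read_fasta(f, strict = TRUE), "position 10")

  # invalid characters are always rejected
  writeLines(c(">b2", "ACDEFGHIK1MN"), f)
  expect_error(read_fasta(f), "invalid character")

  # short-sequence policy
  writeLines(c(">s", "ACDEF"), f)
  expect_warning(read_fasta(f), "shorter than 10")
  expect_error(read_fasta(f, strict = TRUE), "shorter than 10")
})

test_that("label tables round-trip, reorder columns, and reject bad schemas", {
  vocab <- function_vocabulary()
  n <- 3
  Y <- matrix(0L, n, 15, dimnames = list(NULL, vocab))
  Y[2, "ACP"] <- 1L
  ids <- c("s1", "s2", "s3")
  f <- withr::local_tempfile(fileext = ".csv")
  write_label_table(ids, Y, f)
  back <- read_label_table(f, vocab)
  expect_identical(back$ids, ids)
  expect_identical(unname(back$Y), unname(Y))
  expect_equal(sum(back$Y), 1)

  # shuffled column order reads back to the identical matrix
  perm <- sample(15)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_label_table(ids, Y[, perm], f2)
  expect_identical(unname(read_label_table(f2, vocab)$Y), unname(Y))

  # missing function column is a schema error
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_label_table(ids, Y[, 1:14], f3)
  expect_error(read_label_table(f3, vocab), "missing function column")

  # unknown columns, non-binary cells, missing ids
  Yx <- Y; colnames(Yx)[3] <- "XXX"
  write_label_table(ids, Yx, f3)
  expect_error(read_label_table(f3, vocab), "unknown function|missing function")
  Yb <- Y; Yb[1, 1] <- 2L
  write_label_table(ids, Yb, f3)
  expect_error(read_label_table(f3, vocab), "non-binary.*row 1", )
  write_label_table(ids, Y, f3)
  expect_error(read_label_table(f3, vocab, ids = c(ids, "s9")), "missing id")
})

test_that("pad_or_truncate pads short, splices long, and is idempotent", {
  # 23-residue example pads to 27 trailing padding positions
  s <- "GVAKFGKAAAHFGKGWIKEMLNS"
  pt <- pad_or_truncate(s, 50)
  expect_equal(nchar(pt$sequence), 50)
  expect_equal(sum(pt$mask), 23)
  expect_equal(substr(pt$sequence, 1, 23), s)
  expect_true(all(!pt$mask[24:50]))

  # exact length unchanged, mask all-real
  s50 <- strrep("AC", 25)
  expect_equal(pad_or_truncate(s50, 50)$sequence, s50)
  expect_true(all(pad_or_truncate(s50, 50)$mask))

  # 60-residue: first 25 + last 25 by direct slicing oracle
  set.seed(3)
  s60 <- paste(sample(c("A", "C", "D", "W"), 60, replace = TRUE), collapse = "")
  pt60 <- pad_or_truncate(s60, 50)
  expect_equal(pt60$sequence,
               paste0(substr(s60, 1, 25), substr(s60, 36, 60)))
  expect_true(all(pt60$mask))

  # idempotent on its own output
  again <- pad_or_truncate(pt$sequence, 50)
  expect_identical(again$sequence, pt$sequence)
  expect_identical(again$mask, pt$mask)

  expect_error(pad_or_truncate("ACD", 7), "even")
  expect_error(pad_or_truncate("", 50), "non-empty")

  # truncation never invents characters
  expect_true(all(strsplit(pt60$sequence, "")[[1]] %in% strsplit(s60, "")[[1]]))
})

test_that("one_hot_encode maps residues to the documented columns", {
  pt <- pad_or_truncate(strrep("A", 50), 50)
  X <- one_hot_encode(pt$sequence, pt$mask)
  expect_equal(dim(X), c(50, 20))
  expect_true(all(X[, "A"] == 1))
  expect_equal(rowSums(X), rep(1, 50))

  # padded input has exactly as many nonzero rows as real residues
  pt23 <- pad_or_truncate("GVAKFGKAAAHFGKGWIKEMLNS", 50)
  X23 <- one_hot_encode(pt23$sequence, pt23$mask)
  expect_equal(sum(rowSums(X23) > 0), 23)
  expect_equal(rowSums(X23), pt23$mask * 1)

  # the alphabet itself is a permutation matrix over the first 20 rows
  ptaa <- pad_or_truncate("ACDEFGHIKLMNPQRSTVWY", 50)
  Xaa <- one_hot_encode(ptaa$sequence, ptaa$mask)
  expect_equal(colSums(Xaa[1:20, ]), rep(1, 20), ignore_attr = TRUE)
  expect_equal(diag(Xaa[1:20, ]), rep(1, 20), ignore_attr = TRUE)

  expect_error(one_hot_encode(pad_or_truncate("AB", 4)$sequence, strict = TRUE),
               "non-standard")
  expect_error(one_hot_encode("A1"), "unknown character")
})

test_that("parse_pssm reads the ASCII dialect and reorders columns", {
  f <- system.file("extdata", "synthetic_GVAKF.pssm", package = "multipep")
  prof <- parse_pssm(f, sequence = "GVAKF")
  expect_equal(dim(prof), c(5, 20))
  expect_equal(attr(prof, "residues"), c("G", "V", "A", "K", "F"))
  # self-residue scores read back verbatim
  expect_equal(unname(prof[1, "G"]), 6)
  expect_equal(unname(prof[2, "V"]), 4)
  expect_equal(unname(prof[3, "A"]), 5)
  expect_equal(unname(prof[4, "K"]), 5)
  expect_equal(unname(prof[5, "F"]), 7)
  # full row in alphabetical order (hand-mapped from the file's PSI order)
  expect_equal(unname(prof[3, ]),
               c(5, -1, -2, -1, -3, 0, -2, -2, -1, -2, -1, -2, -1, -1, -2, 1, 0, 0, -3, -2))

  expect_error(parse_pssm(f, sequence = "GVAKW"), "position 5")
  expect_error(parse_pssm(f, sequence = "GVAK"), "4 residues")

  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  expect_error(parse_pssm(empty), "empty|no matrix rows")
  trunc <- withr::local_tempfile()
  writeLines(c("header", "    1 G   -1 -3 -2"), trunc)
  expect_error(parse_pssm(trunc), "line 2")
})

test_that("encode_sample concatenates one-hot and profile blocks correctly", {
  vocab <- function_vocabulary()
  s <- "GVAKFGKAAAHFGKGWIKEMLNS"
  enc <- encode_sample(s, vocab = vocab)
  expect_s3_class(enc, "mp_encoded")
  expect_equal(dim(enc$Xs), c(50, 40))
  # no PSSM, zero fallback: profile block all zero
  expect_true(all(enc$Xs[, 21:40] == 0))
  # Xt is the 15 x 15 identity pattern
  expect_equal(enc$Xt, diag(15))
  expect_equal(sum(enc$Xt), 15)
  # one-hot row sums equal the mask exactly
  expect_equal(rowSums(enc$Xs[, 1:20]), enc$mask * 1)

  # with a PSSM the profile rows appear in columns 21-40
  f <- system.file("extdata", "synthetic_GVAKF.pssm", package = "multipep")
  prof <- parse_pssm(f)
  enc2 <- encode_sample("GVAKF", pssm = prof, vocab = vocab)
  expect_equal(unname(enc2$Xs[1:5, 21:40]), unname(unclass(prof)[, ]))
  expect_true(all(enc2$Xs[6:50, 21:40] == 0))
  expect_error(encode_sample("GVAKFA", pssm = prof, vocab = vocab), "rows")

  # PSSM rows follow the same splice rule as the sequence
  set.seed(9)
  long <- paste(sample(multipep:::AA_ALPHABET, 60, replace = TRUE), collapse = "")
  fake <- matrix(rnorm(60 * 20), 60, 20)
  enc3 <- encode_sample(long, pssm = fake, vocab = vocab)
  expect_equal(unname(enc3$Xs[, 21:40]),
               unname(rbind(fake[1:25, ], fake[36:60, ])))

  # BLOSUM62 fallback fills rows by residue
  enc4 <- encode_sample("GVAKF", vocab = vocab, pssm_fallback = "blosum62")
  expect_equal(unname(enc4$Xs[1, 21:40]),
               unname(multipep:::BLOSUM62_AA["G", ]))
  expect_true(all(enc4$Xs[6:50, 21:40] == 0))
})

test_that("encode_peptides stacks samples and matches encode_sample", {
  peps <- multipep:::peptides(c("a", "b"), c("GVAKF", "ACDEFGHIKLMNPQRSTVWY"))
  enc <- encode_peptides(peps, vocab = function_vocabulary(8))
  expect_equal(dim(enc$X), c(50, 40, 2))
  single <- encode_sample("GVAKF", vocab = function_vocabulary(8))
  expect_equal(enc$X[, , 1], single$Xs, ignore_attr = TRUE)
  expect_equal(enc$mask[, 1], single$mask * 1)
})
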