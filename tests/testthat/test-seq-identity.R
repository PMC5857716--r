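test_that("percent identity follows the comparable-column convention", {
  expect_equal(percent_identity("MKT", "MKT"), 100)
  expect_equal(percent_identity("MKT", "MAT"), 100 * 2 / 3)
  # gap columns drop out of the denominator
  expect_equal(percent_identity("M-KT", "MAKT"), 100)
  # X never matches, not even X vs X, but stays in the denominator
  expect_equal(percent_identity("MXT", "MXT"), 100 * 2 / 3)
  # case-insensitive, '.' is a gap
  expect_equal(percent_identity("mkt", "MKT"), 100)
  expect_equal(percent_identity("M.KT", "MAKT"), 100)
})

test_that("percent identity is symmetric, bounded, and gap-invariant", {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  withr::with_seed(42, {
    for (i in 1:20) {
      n <- sample(5:40, 1)
      a <- paste(sample(c(aa, "-"), n, replace = TRUE), collapse = "")
      b <- paste(sample(c(aa, "-"), n, replace = TRUE), collapse = "")
      ok <- tryCatch({
        p <- percent_identity(a, b)
        TRUE
      }, error = function(e) FALSE)
      if (!ok) next  # no comparable columns
      expect_equal(percent_identity(b, a), p)
      expect_gte(p, 0)
      expect_lte(p, 100)
      # appending a both-gap column changes nothing
      expect_equal(percent_identity(paste0(a, "-"), paste0(b, "-")), p)
    }
  })
})

test_that("percent identity rejects degenerate input", {
  expect_error(percent_identity("M-", "-A"), "no comparable")
  expect_error(percent_identity("MK", "MKT"), "equal length")
})

test_that("aligned FASTA reading preserves order and normalises case", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s2 some description", "mk.t", ">s1", "MKTA"), fa)
  aln <- read_aligned_fasta(fa)
  expect_equal(aln$label, c("s2 some description", "s1"))
  expect_equal(aln$sequence, c("MK-T", "MKTA"))

  # Windows line endings give the identical result
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  writeBin(charToRaw(">s2 some description\r\nmk.t\r\n>s1\r\nMKTA\r\n"), fa2)
  expect_equal(read_aligned_fasta(fa2), aln)
})

test_that("aligned FASTA reading rejects ragged and empty input", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MKT", ">b", "MK"), fa)
  expect_error(read_aligned_fasta(fa), "not aligned")
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), fa2)
  expect_error(read_aligned_fasta(fa2))
})

test_that("identity tables carry annotations and preserve order", {
  aln <- tibble::tibble(
    label = c("x", "y", "z"),
    sequence = c("MKTA", "MKTV", "MATV")
  )
  expect_equal(nrow(identity_table(aln, tibble::tibble(id_a = character(),
                                                       id_b = character()))),
               0)
  pairs <- tibble::tibble(
    id_a = c("x", "x", "x"), id_b = c("y", "z", "y"),
    subunit = "A-vs-A",
    age_min_ma = c(82, NA, 82), age_max_ma = c(127, NA, 127)
  )
  tbl <- identity_table(aln, pairs)
  expect_equal(nrow(tbl), 3)            # duplicates are kept
  expect_equal(tbl$identity_pct, c(75, 50, 75))
  expect_equal(tbl$age_min_ma[1], 82)
  expect_equal(tbl$age_max_ma[1], 127)
  expect_equal(tbl$pair_label[1], "x vs y")

  # TSV round trip
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_identity_table(tbl, tsv)
  back <- read_identity_table(tsv)
  expect_equal(back$identity_pct, tbl$identity_pct)
  expect_equal(back$age_min_ma, tbl$age_min_ma)
})

test_that("identity tables validate labels and age ordering", {
  aln <- tibble::tibble(label = c("x", "y"), sequence = c("MK", "MK"))
  expect_error(identity_table(aln, tibble::tibble(id_a = "x", id_b = "q")),
               "not in alignment")
  expect_error(
    identity_table(aln, tibble::tibble(id_a = "x", id_b = "y",
                                       age_min_ma = 10, age_max_ma = 5)),
    "age_min_ma"
  )
})

test_that("the bundled identity table matches its printed source", {
  tbl <- psa_identity_table()
  expect_equal(nrow(tbl), 2 * 15 + 4)
  arab <- tbl[tbl$pair_label == "Arabidopsis thaliana vs Populus trichocarpa", ]
  expect_equal(sort(arab$identity_pct), c(98.2, 98.6))
  ab <- tbl$identity_pct[tbl$subunit == "A-vs-B"]
  expect_equal(mean(ab), 42.575)
})
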