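#' Read an aligned amino-acid FASTA file
#'
#' Reads a protein alignment in FASTA format and returns one row per
#' sequence, in file order, with the full header text as the label.
#' Sequences are normalised to uppercase and `'.'` gap characters are
#' converted to `'-'`. All sequences must have the same length: this is the
#' alignment contract, and ragged input is an error, not a warning.
#'
#' @param path Path to an aligned FASTA file.
#' @return A tibble with columns `label` and `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "MKT-", ">s2", "MKTA"), fa)
#' read_aligned_fasta(fa)
#' @export
read_aligned_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    abort("empty FASTA file: no sequences found")
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1) {
    abort(paste0(
      "sequences are not aligned: lengths range from ",
      min(widths), " to ", max(widths)
    ))
  }
  tibble::tibble(label = names(set), sequence = unname(seqs))
}

#' Write an alignment to FASTA
#'
#' @param alignment A tibble with columns `label` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(alignment, path) {
  alignment <- as_alignment(alignment)
  lines <- as.vector(rbind(paste0(">", alignment$label), alignment$sequence))
  writeLines(lines, path)
  invisible(path)
}

# Coerce a named character vector or data frame to the canonical alignment
# tibble, validating the aligned-length contract.
as_alignment <- function(x) {
  if (is.character(x)) {
    if (is.null(names(x))) abort("alignment vector must be named")
    x <- tibble::tibble(label = names(x), sequence = unname(x))
  }
  if (!all(c("label", "sequence") %in% names(x))) {
    abort("alignment must have columns 'label' and 'sequence'")
  }
  x <- tibble::as_tibble(x)
  x$sequence <- gsub(".", "-", toupper(x$sequence), fixed = TRUE)
  if (nrow(x) > 0 && length(unique(nchar(x$sequence))) != 1) {
    abort("sequences are not aligned (unequal lengths)")
  }
  x
}

#' Pairwise percent identity between two aligned sequences
#'
#' Identity is computed over comparable columns only: columns where both
#' sequences carry a non-gap character. A column counts as a match when both
#' residues are the same amino-acid letter; `'X'` (unknown residue) never
#' matches anything, including another `'X'`, but still counts in the
#' denominator. The measure is symmetric and is returned at full precision
#' (rounding is a presentation concern only).
#'
#' @param seq_a,seq_b Aligned sequences of equal length (character scalars).
#' @return Percent identity in `[0, 100]`.
#' @examples
#' percent_identity("MKT", "MAT")   # 66.67
#' percent_identity("M-KT", "MAKT") # 100: 3 comparable columns, 3 matches
#' @export
percent_identity <- function(seq_a, seq_b) {
  a <- strsplit(gsub(".", "-", toupper(seq_a), fixed = TRUE), "")[[1]]
  b <- strsplit(gsub(".", "-", toupper(seq_b), fixed = TRUE), "")[[1]]
  if (length(a) != length(b)) {
    abort("sequences must be aligned to equal length")
  }
  comparable <- a != "-" & b != "-"
  if (!any(comparable)) {
    abort("no comparable columns: every position is a gap in one sequence")
  }
  matches <- comparable & a == b & a != "X"
  100 * sum(matches) / sum(comparable)
}

#' Assemble an identity table from aligned sequence pairs
#'
#' Computes percent identity for each requested pair of sequences and joins
#' optional age annotations, producing one record per pair in input order.
#'
#' @param alignment A tibble from [read_aligned_fasta()] (or a named
#'   character vector of aligned sequences).
#' @param pairs A data frame with columns `id_a` and `id_b` (sequence
#'   labels) and, optionally, `pair_label`, `subunit`,
#'   `divergence_age_ma`, `age_min_ma` and `age_max_ma`.
#' @return A tibble with columns `pair_label`, `subunit`, `identity_pct`,
#'   `divergence_age_ma`, `age_min_ma`, `age_max_ma`.
#' @export
identity_table <- function(alignment, pairs) {
  alignment <- as_alignment(alignment)
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) == 0) {
    return(tibble::tibble(
      pair_label = character(), subunit = character(),
      identity_pct = double(), divergence_age_ma = double(),
      age_min_ma = double(), age_max_ma = double()
    ))
  }
  seqs <- setNames(alignment$sequence, alignment$label)
  missing <- setdiff(c(pairs$id_a, pairs$id_b), names(seqs))
  if (length(missing) > 0) {
    abort(paste0("labels not in alignment: ",
                 paste(missing, collapse = ", ")))
  }
  col <- function(nm, default) {
    if (nm %in% names(pairs)) pairs[[nm]] else default
  }
  lo <- col("age_min_ma", NA)
  hi <- col("age_max_ma", NA)
  if (any(!is.na(lo) & !is.na(hi) & lo > hi)) {
    abort("age_min_ma must not exceed age_max_ma")
  }
  tibble::tibble(
    pair_label = col("pair_label", paste(pairs$id_a, "vs", pairs$id_b)),
    subunit = col("subunit", NA_character_),
    identity_pct = purrr::map2_dbl(pairs$id_a, pairs$id_b,
                                   ~ percent_identity(seqs[[.x]], seqs[[.y]])),
    divergence_age_ma = as.numeric(col("divergence_age_ma", NA)),
    age_min_ma = as.numeric(lo),
    age_max_ma = as.numeric(hi)
  )
}

#' Read and write identity tables as TSV
#'
#' The on-disk schema is the tab-separated table written by
#' [identity_table()]: `pair_label`, `subunit`, `identity_pct`,
#' `divergence_age_ma`, `age_min_ma`, `age_max_ma`.
#'
#' @param records An identity tibble.
#' @param path File path.
#' @return `write_identity_table()` returns `path` invisibly;
#'   `read_identity_table()` returns a tibble.
#' @export
write_identity_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_identity_table
#' @export
read_identity_table <- function(path) {
  tbl <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
  tibble::as_tibble(tbl)
}
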