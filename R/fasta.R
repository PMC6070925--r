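#' Read a FASTA file into a tibble
#'
#' Reads nucleotide or protein FASTA. Record order is preserved, sequences are
#' uppercased, and record ids (the first whitespace-delimited token of each
#' header) must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `desc` (remainder of the header line,
#'   `NA` if absent) and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) mm_format_error("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) mm_format_error("malformed FASTA in ", path, ": ", conditionMessage(e))
  )
  if (length(set) == 0) mm_format_error("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), NA_character_)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    mm_format_error("duplicate FASTA id: ", dup)
  }
  tibble(id = ids, desc = desc, sequence = unname(toupper(as.character(set))))
}

#' Write a tibble of sequences as FASTA
#'
#' @param seqs A tibble with columns `id` and `sequence` (and optionally
#'   `desc`), or a named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  seqs_tbl <- as_seq_tbl(seqs, "seqs")
  desc <- if (is.data.frame(seqs) && "desc" %in% names(seqs)) seqs$desc else rep(NA_character_, nrow(seqs_tbl))
  lines <- unlist(purrr::pmap(list(seqs_tbl$id, desc, seqs_tbl$sequence), function(id, d, s) {
    header <- if (is.na(d)) paste0(">", id) else paste0(">", id, " ", d)
    starts <- seq(1, nchar(s), by = width)
    c(header, substring(s, starts, pmin(starts + width - 1, nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Represent FASTA records as contigs
#'
#' @param genome A tibble as returned by [read_fasta()].
#' @return A tibble with columns `id`, `length` and `sequence`.
#' @export
as_contigs <- function(genome) {
  genome <- as_seq_tbl(genome, "genome")
  tibble(id = genome$id, length = nchar(genome$sequence), sequence = genome$sequence)
}
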