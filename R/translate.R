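#' Genetic code tables
#'
#' `"standard"` is the standard nuclear code. `"ctg_clade"` is the CTG-clade
#' yeast code, which differs from the standard code only at codon CTG
#' (serine instead of leucine) — the reassignment found in *Candida*/
#' *Scheffersomyces* and relatives.
#'
#' @param id `"standard"` or `"ctg_clade"`.
#' @return A named character vector of 64 codons to one-letter amino acids
#'   (`*` for stops).
#' @export
genetic_code <- function(id = c("standard", "ctg_clade")) {
  id <- match.arg(id)
  code <- Biostrings::GENETIC_CODE
  code <- setNames(as.character(code), gsub("U", "T", names(code)))
  if (id == "ctg_clade") code[["CTG"]] <- "S"
  code
}

#' Translate a coding sequence
#'
#' @param dna A nucleotide string (A/C/G/T/N), length divisible by 3, with no
#'   internal stop codon. A terminal stop codon is allowed and stripped.
#' @param code Genetic code id or table from [genetic_code()].
#' @return The protein string. Codons containing N translate to `X`.
#' @export
translate_cds <- function(dna, code = "standard") {
  if (is.character(code) && length(code) == 1) code <- genetic_code(code)
  dna <- toupper(dna)
  n <- nchar(dna)
  if (n == 0 || n %% 3 != 0) {
    mm_format_error("CDS length ", n, " is not a positive multiple of 3")
  }
  if (grepl("[^ACGTN]", dna)) {
    mm_format_error("CDS contains characters outside A/C/G/T/N")
  }
  codons <- substring(dna, seq(1, n, by = 3), seq(3, n, by = 3))
  aa <- ifelse(grepl("N", codons), "X", unname(code[codons]))
  stops <- which(aa == "*")
  if (length(stops)) {
    internal <- stops[stops < length(codons)]
    if (length(internal)) {
      mm_format_error("internal stop codon at codon ", internal[1])
    }
    aa <- aa[-length(aa)]
  }
  paste(aa, collapse = "")
}

#' Reverse-complement a nucleotide string
#' @param dna A nucleotide string (A/C/G/T/N).
#' @return The reverse complement.
#' @export
reverse_complement <- function(dna) {
  paste(rev(chars(chartr("ACGTN", "TGCAN", toupper(dna)))), collapse = "")
}

#' Assemble the coding sequence of a gene from its contig
#'
#' Concatenates exon sequence in transcription order; minus-strand genes are
#' reverse-complemented.
#'
#' @param gene One row of a gene tibble ([read_gff3()]).
#' @param contigs Contig tibble with sequences ([as_contigs()]).
#' @return The CDS as a nucleotide string.
#' @export
extract_cds <- function(gene, contigs) {
  seqs <- setNames(contigs$sequence, contigs$id)
  cs <- seqs[[gene$contig_id]]
  if (is.null(cs) || is.na(cs)) mm_stop("contig sequence missing for ", gene$contig_id)
  ex <- gene$exons[[1]]
  pieces <- substring(cs, ex$start, ex$end)
  cds <- paste(pieces, collapse = "")
  if (gene$strand == "-") cds <- reverse_complement(cds)
  cds
}

#' Count introns per gene
#'
#' An intron count is simply the exon count minus one.
#'
#' @param genes A gene tibble ([read_gff3()]).
#' @return A tibble with columns `gene_id` and `n_introns`.
#' @export
count_introns <- function(genes) {
  tibble(
    gene_id = genes$gene_id,
    n_introns = vapply(genes$exons, nrow, integer(1)) - 1L
  )
}

#' Translate every gene of an annotated genome
#'
#' @param genes Gene tibble ([read_gff3()]).
#' @param contigs Contig tibble with sequences.
#' @param code Genetic code id (see [genetic_code()]).
#' @return A tibble with columns `id` (gene id) and `sequence` (protein).
#' @export
translate_genome <- function(genes, contigs, code = "standard") {
  code_tbl <- genetic_code(code)
  prot <- vapply(seq_len(nrow(genes)), function(k) {
    tryCatch(
      translate_cds(extract_cds(genes[k, ], contigs), code_tbl),
      error = function(e) {
        mm_format_error("translation failed for gene ", genes$gene_id[k], ": ",
                        conditionMessage(e))
      }
    )
  }, character(1))
  tibble(id = genes$gene_id, sequence = prot)
}
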