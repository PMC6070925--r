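#' Alignment scoring parameters
#'
#' Defaults are BLOSUM62 with gap open 10 and gap extension 0.5 (a gap run of
#' length L costs `open + (L - 1) * ext`). The matrix is taken from
#' Biostrings' bundled substitution matrices.
#'
#' @param matrix Substitution matrix name (`"BLOSUM62"`, `"BLOSUM45"`,
#'   `"BLOSUM80"`, `"PAM250"`, ...) or a numeric matrix with residue
#'   dimnames.
#' @param gap_open Gap opening penalty (positive).
#' @param gap_ext Gap extension penalty (positive).
#' @return A list with elements `matrix`, `gap_open`, `gap_ext`.
#' @export
alignment_scoring <- function(matrix = "BLOSUM62", gap_open = 10, gap_ext = 0.5) {
  if (is.character(matrix)) {
    key <- paste0("submat_", matrix)
    if (is.null(.malminer_cache[[key]])) {
      env <- new.env()
      utils::data(list = matrix, package = "Biostrings", envir = env)
      .malminer_cache[[key]] <- get(matrix, envir = env)
    }
    matrix <- .malminer_cache[[key]]
  }
  stopifnot(is.matrix(matrix), gap_open >= 0, gap_ext >= 0)
  list(matrix = matrix, gap_open = gap_open, gap_ext = gap_ext)
}

check_protein <- function(x, alphabet, arg = "sequence") {
  if (!is.character(x) || length(x) != 1 || is.na(x) || nchar(x) == 0) {
    mm_stop("`", arg, "` must be a non-empty string")
  }
  bad <- setdiff(unique(chars(x)), alphabet)
  if (length(bad)) {
    mm_stop("illegal character in `", arg, "`: ", bad[1])
  }
  invisible(x)
}

#' Optimal global pairwise alignment
#'
#' End-to-end (Needleman–Wunsch) alignment with affine gap penalties, computed
#' by a Gotoh three-state dynamic program. Traceback is deterministic: on
#' score ties the diagonal (match) state is preferred, then a gap in `b`, then
#' a gap in `a`, so co-optimal alignments always resolve identically — a
#' requirement for reproducible reference-anchored residue mapping.
#'
#' @param a,b Protein strings.
#' @param scoring Scoring parameters from [alignment_scoring()].
#' @return An object of class `pairwise_alignment`: a list with `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `score` and `identity`
#'   (percent identical columns, terminal-gap columns excluded).
#' @export
global_align <- function(a, b, scoring = alignment_scoring()) {
  alphabet <- rownames(scoring$matrix)
  check_protein(a, alphabet, "a")
  check_protein(b, alphabet, "b")
  ai <- match(chars(a), alphabet)
  bi <- match(chars(b), alphabet)
  res <- align_seqs_cpp(ai, bi, scoring$matrix, scoring$gap_open, scoring$gap_ext)
  ca <- chars(a); cb <- chars(b)
  aligned_a <- ifelse(res$pos_a == 0L, "-", ca[pmax(res$pos_a, 1L)])
  aligned_b <- ifelse(res$pos_b == 0L, "-", cb[pmax(res$pos_b, 1L)])
  out <- structure(
    list(aligned_a = paste(aligned_a, collapse = ""),
         aligned_b = paste(aligned_b, collapse = ""),
         score = res$score,
         identity = NA_real_),
    class = "pairwise_alignment"
  )
  out$identity <- alignment_identity(out)
  out
}

# which columns are part of leading/trailing gap runs of either row
terminal_gap_columns <- function(ga, gb) {
  ncol_aln <- length(ga)
  term <- rep(FALSE, ncol_aln)
  for (g in list(ga, gb)) {
    is_gap <- g == "-"
    if (all(is_gap)) { term[] <- TRUE; next }
    if (is_gap[1]) term[seq_len(which.min(is_gap) - 1)] <- TRUE
    if (is_gap[ncol_aln]) {
      last_res <- ncol_aln + 1 - which.min(rev(is_gap))
      term[seq(last_res + 1, ncol_aln)] <- TRUE
    }
  }
  term
}

#' Percent identity of an alignment
#'
#' Identities divided by alignment columns, with columns belonging to terminal
#' gap runs excluded from the denominator.
#'
#' @param alignment A `pairwise_alignment`.
#' @return Percent identity (0–100).
#' @export
alignment_identity <- function(alignment) {
  ga <- chars(alignment$aligned_a)
  gb <- chars(alignment$aligned_b)
  keep <- !terminal_gap_columns(ga, gb)
  if (!any(keep)) return(0)
  100 * sum(ga[keep] == gb[keep] & ga[keep] != "-") / sum(keep)
}

#' Pairwise percent identity of two proteins
#'
#' @inheritParams global_align
#' @return Percent identity under the optimal global alignment, with
#'   terminal-gap columns excluded from the denominator.
#' @export
pairwise_identity <- function(a, b, scoring = alignment_scoring()) {
  global_align(a, b, scoring)$identity
}

# fraction of reference (row b) residues aligned to a residue of row a
alignment_coverage <- function(alignment) {
  ga <- chars(alignment$aligned_a)
  gb <- chars(alignment$aligned_b)
  ref_res <- gb != "-"
  if (!any(ref_res)) return(0)
  100 * sum(ref_res & ga != "-") / sum(ref_res)
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("Global alignment: score %.1f, identity %.1f%%, %d columns\n",
              x$score, x$identity, nchar(x$aligned_a)))
  cat(substr(x$aligned_a, 1, 60), "\n")
  cat(substr(x$aligned_b, 1, 60), "\n")
  invisible(x)
}
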