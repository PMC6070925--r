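# Independent oracles and small fixture builders used across the suite.

# Exhaustive global-alignment score by enumeration of every alignment path,
# with affine gap cost open + (L - 1) * ext. Deliberately recursion-based and
# memo-free so it shares nothing with the package's dynamic program.
brute_force_score <- function(a, b, S, open, ext) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B)) {
      best <- max(best, S[A[i], B[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= length(A)) {
      best <- max(best, -(if (prev == "X") ext else open) + rec(i + 1, j, "X"))
    }
    if (j <= length(B)) {
      best <- max(best, -(if (prev == "Y") ext else open) + rec(i, j + 1, "Y"))
    }
    best
  }
  rec(1, 1, "")
}

random_protein <- function(n) {
  paste(sample(aa_alphabet(), n, replace = TRUE), collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a small annotated-genome fixture built in code: genes placed on one contig
# at given (start, end, strand), single-exon, with optional products
toy_genes <- function(coords, contig = "ctg1", products = NULL) {
  n <- nrow(coords)
  if (is.null(products)) products <- rep(NA_character_, n)
  tibble::tibble(
    gene_id = sprintf("g%02d", seq_len(n)),
    contig_id = contig,
    start = as.integer(coords[, 1]),
    end = as.integer(coords[, 2]),
    strand = coords[, 3],
    product = products,
    exons = lapply(seq_len(n), function(i) {
      tibble::tibble(start = as.integer(coords[i, 1]), end = as.integer(coords[i, 2]))
    })
  )
}

# candidate rows shaped like find_candidates() output, for geometry tests
toy_candidates <- function(genes, roles, ambiguous = rep(FALSE, nrow(genes))) {
  tibble::tibble(
    gene_id = genes$gene_id, contig_id = genes$contig_id,
    start = genes$start, end = genes$end, strand = genes$strand,
    role = roles, ambiguous = ambiguous, via = "homology",
    best_reference = "ref", score = 100, identity = 90, coverage = 100,
    n_introns = 0L
  )
}

expect_same_topology <- function(t1, t2) {
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
}
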