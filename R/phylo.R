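#' Progressive multiple alignment
#'
#' Guide-tree progressive alignment built from the package's own pairwise
#' global aligner: pairwise p-distances (computed on optimal pairwise
#' alignments) feed a neighbor-joining guide tree, and profiles are merged in
#' guide-tree order by profile-profile global alignment (expected BLOSUM
#' score between column residue frequencies, affine gaps). Deterministic for
#' a fixed input order.
#'
#' @param seqs A tibble (`id`, `sequence`) or named character vector of at
#'   least two protein sequences with unique ids.
#' @param scoring Scoring parameters ([alignment_scoring()]).
#' @return An object of class `mal_msa`: a tibble with columns `id` and
#'   `aligned` (equal-length gapped strings).
#' @export
progressive_align <- function(seqs, scoring = alignment_scoring()) {
  tbl <- as_seq_tbl(seqs, "seqs")
  n <- nrow(tbl)
  if (n < 2) mm_stop("need at least 2 sequences")
  if (anyDuplicated(tbl$id)) mm_stop("sequence ids must be unique")
  alphabet <- rownames(scoring$matrix)
  for (s in tbl$sequence) check_protein(s, alphabet)
  if (n == 2) {
    aln <- global_align(tbl$sequence[1], tbl$sequence[2], scoring)
    return(new_msa(tbl$id, c(aln$aligned_a, aln$aligned_b)))
  }

  # guide tree from pairwise p-distances
  D <- matrix(0, n, n, dimnames = list(tbl$id, tbl$id))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      aln <- global_align(tbl$sequence[i], tbl$sequence[j], scoring)
      D[i, j] <- D[j, i] <- p_distance(aln$aligned_a, aln$aligned_b)
    }
  }
  guide <- neighbor_joining(stats::as.dist(D))

  # merge profiles following the guide tree, deepest clades first
  merges <- guide_merge_order(guide)
  profiles <- lapply(seq_len(n), function(i) {
    matrix(chars(tbl$sequence[i]), nrow = 1, dimnames = list(tbl$id[i], NULL))
  })
  names(profiles) <- as.character(seq_len(n))
  for (m in merges) {
    a <- profiles[[as.character(m[1])]]
    b <- profiles[[as.character(m[2])]]
    profiles[[as.character(m[1])]] <- NULL
    profiles[[as.character(m[2])]] <- NULL
    profiles[[as.character(m[3])]] <- align_profiles(a, b, scoring)
  }
  stopifnot(length(profiles) == 1)
  prof <- profiles[[1]]
  prof <- prof[tbl$id, , drop = FALSE]
  new_msa(rownames(prof), apply(prof, 1, paste, collapse = ""))
}

new_msa <- function(ids, rows) {
  stopifnot(length(unique(nchar(rows))) == 1)
  out <- tibble(id = ids, aligned = unname(rows))
  class(out) <- c("mal_msa", class(out))
  out
}

# postorder list of merges (child_node_a, child_node_b, parent_node) covering
# all internal nodes of an (unrooted) guide tree, rooted at the NJ join node
guide_merge_order <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  children <- split(tree$edge[, 2], tree$edge[, 1])
  merges <- list()
  walk <- function(node) {
    if (node <= n) return(node)
    kids <- children[[as.character(node)]]
    ids <- vapply(kids, walk, numeric(1))
    acc <- ids[1]
    for (k in seq(2, length(ids))) {
      merges[[length(merges) + 1]] <<- c(acc, ids[k], node)
      acc <- node
    }
    node
  }
  walk(root)
  merges
}

# profile-profile global alignment; profiles are character matrices
# (rows = sequences, cols = alignment columns, "-" = gap)
align_profiles <- function(a, b, scoring) {
  alphabet <- rownames(scoring$matrix)
  freq <- function(p) {
    f <- apply(p, 2, function(col) {
      tabulate(match(col, alphabet), nbins = length(alphabet))
    })
    f / nrow(p) # gaps contribute zero weight
  }
  fa <- freq(a); fb <- freq(b)
  cells <- t(fa) %*% scoring$matrix %*% fb
  res <- align_cells_cpp(cells, scoring$gap_open, scoring$gap_ext)
  expand <- function(p, pos) {
    out <- matrix("-", nrow = nrow(p), ncol = length(pos),
                  dimnames = list(rownames(p), NULL))
    out[, pos != 0L] <- p[, pos[pos != 0L], drop = FALSE]
    out
  }
  rbind(expand(a, res$pos_a), expand(b, res$pos_b))
}

#' Uncorrected p-distance between two aligned rows
#'
#' Mismatches divided by compared columns; columns with a gap in either row
#' are skipped (pairwise deletion).
#'
#' @param row_a,row_b Equal-length gapped strings.
#' @return Proportion of differing sites.
#' @export
p_distance <- function(row_a, row_b) {
  a <- chars(row_a); b <- chars(row_b)
  if (length(a) != length(b)) mm_stop("rows differ in length")
  keep <- a != "-" & b != "-"
  if (!any(keep)) mm_stop("no comparable columns (all gapped)")
  sum(a[keep] != b[keep]) / sum(keep)
}

# Dayhoff machinery: rate matrix from phangorn's model constants, scaled to
# one expected substitution per site per unit time; cached eigendecomposition
dayhoff_model <- function() {
  if (!is.null(.malminer_cache$dayhoff)) return(.malminer_cache$dayhoff)
  raw <- utils::getFromNamespace(".Dayhoff", "phangorn")
  bf <- unname(raw$bf)
  k <- length(bf)
  S <- matrix(0, k, k)
  S[lower.tri(S)] <- raw$Q
  S <- S + t(S)
  Q <- S * rep(bf, each = k)
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(bf * -diag(Q)) # unit: expected substitutions/site
  eig <- eigen(Q)
  model <- list(bf = bf, Q = Q, V = eig$vectors, Vi = solve(eig$vectors),
                lambda = eig$values,
                # maximum observable proportion of differing sites
                p_max = 1 - sum(bf^2))
  .malminer_cache$dayhoff <- model
  model
}

# expected proportion of differing sites after t substitutions/site
dayhoff_expected_diff <- function(t, model = dayhoff_model()) {
  P <- Re(model$V %*% (exp(model$lambda * t) * model$Vi))
  1 - sum(model$bf * diag(P))
}

#' Dayhoff-model distance between two aligned rows
#'
#' Evolutionary distance in substitutions per site under the Dayhoff (PAM)
#' empirical substitution model: the branch length `t` at which the model's
#' expected proportion of differing sites equals the observed p-distance
#' (pairwise deletion of gapped columns). This matrix-based correction is
#' zero for identical rows, strictly increasing in p, and always at least p.
#' Observed p beyond the model's saturation range yields `Inf` with a
#' warning.
#'
#' @inheritParams p_distance
#' @param max_t Upper search bound in substitutions/site (default 10).
#' @return Distance in substitutions/site (possibly `Inf`).
#' @export
dayhoff_distance <- function(row_a, row_b, max_t = 10) {
  p <- p_distance(row_a, row_b)
  dayhoff_from_p(p, max_t)
}

dayhoff_from_p <- function(p, max_t = 10) {
  if (p == 0) return(0)
  model <- dayhoff_model()
  if (p >= dayhoff_expected_diff(max_t, model)) {
    warning("saturated pair (p = ", signif(p, 3), "): distance flagged infinite")
    return(Inf)
  }
  uniroot(function(t) dayhoff_expected_diff(t, model) - p,
          lower = 1e-6, upper = max_t, tol = 1e-8)$root
}

#' Jukes–Cantor nucleotide distance
#'
#' Provided for nucleotide (e.g. rRNA D1/D2) species trees as a simple
#' substitute for composite-likelihood distances.
#'
#' @inheritParams p_distance
#' @return Distance in substitutions/site (`Inf` when p >= 3/4).
#' @export
jukes_cantor_distance <- function(row_a, row_b) {
  p <- p_distance(row_a, row_b)
  if (p >= 0.75) {
    warning("saturated pair (p = ", signif(p, 3), "): distance flagged infinite")
    return(Inf)
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Distance matrix from a multiple alignment
#'
#' @param msa A `mal_msa` ([progressive_align()]) or tibble (`id`, `aligned`).
#' @param method `"dayhoff"` (default), `"p"` or `"jc"` (Jukes–Cantor,
#'   nucleotide rows).
#' @param gap_handling `"pairwise"` deletion (default) or `"complete"`
#'   (columns containing any gap are removed first).
#' @param saturation_cap In a matrix context a saturated pair cannot be
#'   excluded, so infinite distances are capped at this value (the
#'   optimizer's upper bound) with a warning.
#' @return A `dist` object labeled with the taxa.
#' @export
msa_distances <- function(msa, method = c("dayhoff", "p", "jc"),
                          gap_handling = c("pairwise", "complete"),
                          saturation_cap = 10) {
  method <- match.arg(method)
  gap_handling <- match.arg(gap_handling)
  rows <- msa$aligned
  ids <- msa$id
  if (gap_handling == "complete") {
    m <- do.call(rbind, lapply(rows, chars))
    keep <- colSums(m == "-") == 0
    if (!any(keep)) mm_stop("complete deletion removed every column")
    rows <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  }
  n <- length(rows)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  fn <- switch(method, dayhoff = dayhoff_distance, p = p_distance,
               jc = jukes_cantor_distance)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- fn(rows[i], rows[j])
      if (is.infinite(d)) {
        warning("capping saturated distance ", ids[i], " - ", ids[j],
                " at ", saturation_cap)
        d <- saturation_cap
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  stats::as.dist(D)
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration on the Q-criterion. Ties on the Q-matrix are
#' broken by the smallest (row, column) index pair in taxon-sorted order, so
#' the result is deterministic and invariant under permutation of the input.
#' Negative branch lengths are clamped to zero; the number of clamped edges
#' is recorded in the `clamped` attribute. Consistent on additive matrices:
#' recovers the generating topology and branch lengths exactly.
#'
#' @param D A `dist` object or symmetric matrix with taxon labels (>= 2 taxa).
#' @return An unrooted `phylo` tree (ape). For 2 taxa, a single edge split
#'   evenly between the two tips.
#' @export
neighbor_joining <- function(D) {
  M <- as.matrix(D)
  labels <- rownames(M)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(M)))
  if (!isTRUE(all.equal(M, t(M))) || any(!is.finite(M)) || any(M < 0)) {
    mm_stop("distance matrix must be symmetric, finite and non-negative")
  }
  n <- nrow(M)
  if (n < 2) mm_stop("need at least 2 taxa")
  ord <- order(labels)
  M <- M[ord, ord, drop = FALSE]
  labels <- labels[ord]
  clamped <- 0L
  cl <- function(x) {
    if (x < 0) { clamped <<- clamped + 1L; 0 } else x
  }
  fmt <- function(x) sprintf("%.15g", x)
  nodes <- labels # current newick fragment per active node
  if (n == 2) {
    v <- M[1, 2] / 2
    tr <- ape::read.tree(text = sprintf("(%s:%s,%s:%s);",
                                        nodes[1], fmt(v), nodes[2], fmt(v)))
    attr(tr, "clamped") <- clamped
    return(tr)
  }
  while (nrow(M) > 3) {
    m <- nrow(M)
    r <- rowSums(M)
    Q <- (m - 2) * M - outer(r, r, `+`)
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    vi <- cl(M[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    vj <- cl(M[i, j] - (M[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    newick <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt(vi), nodes[j], fmt(vj))
    dnew <- (M[i, -c(i, j)] + M[j, -c(i, j)] - M[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    M2 <- rbind(cbind(M[keep, keep, drop = FALSE], dnew), c(dnew, 0))
    nodes <- c(nodes[keep], newick)
    rownames(M2) <- colnames(M2) <- NULL
    M <- M2
  }
  # final three-way join
  v1 <- cl((M[1, 2] + M[1, 3] - M[2, 3]) / 2)
  v2 <- cl((M[1, 2] + M[2, 3] - M[1, 3]) / 2)
  v3 <- cl((M[1, 3] + M[2, 3] - M[1, 2]) / 2)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 nodes[1], fmt(v1), nodes[2], fmt(v2), nodes[3], fmt(v3))
  tr <- ape::read.tree(text = txt)
  attr(tr, "clamped") <- clamped
  tr
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and labels each internal edge of the reference tree with
#' the percentage of replicates containing the same bipartition. Identical
#' seeds give identical supports.
#'
#' @param msa A `mal_msa` (or tibble with `id`, `aligned`).
#' @param n_reps Number of bootstrap replicates (>= 1; 1000 is the
#'   conventional choice, smaller values are fine for exploratory trees).
#' @param seed Integer seed for the resampling.
#' @param method,gap_handling Passed to [msa_distances()].
#' @return The reference `phylo` tree with `node.label` holding supports in
#'   percent (root label empty) and an attribute `n_reps`.
#' @export
bootstrap_support <- function(msa, n_reps = 1000, seed = 1,
                              method = "dayhoff", gap_handling = "pairwise") {
  if (n_reps < 1) mm_stop("n_reps must be >= 1")
  ref <- neighbor_joining(msa_distances(msa, method, gap_handling))
  m <- do.call(rbind, lapply(msa$aligned, chars))
  rownames(m) <- msa$id
  L <- ncol(m)
  trees <- withr::with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_msa <- new_msa(msa$id, apply(m[, cols, drop = FALSE], 1, paste, collapse = ""))
      suppressWarnings(neighbor_joining(msa_distances(rep_msa, method, gap_handling)))
    })
  })
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(ref, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_reps, 1)
  ref$node.label <- as.character(support)
  ref$node.label[1] <- "" # root of the representation carries no bipartition
  attr(ref, "n_reps") <- n_reps
  ref
}

#' Write a tree as Newick
#'
#' Branch lengths are always written; bootstrap supports (node labels) are
#' written when present. [ape::read.tree()] round-trips the output.
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Path to a Newick file.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
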