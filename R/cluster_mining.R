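#' Bundled role reference proteins
#'
#' Synthetic reference proteins for the three MAL-cluster gene roles:
#' `AG` (alpha-glucosidase; identical to the signature scaffold), `AGT`
#' (alpha-glucoside transporter) and `ACT` (Zn(2)-Cys(6) MAL-activator).
#' These stand in for the *Op* MAL1/MAL2-style query proteins a practitioner
#' would use; any real reference set with a `role` column can be supplied to
#' [find_candidates()] instead.
#'
#' @return A tibble with columns `id`, `role`, `sequence`.
#' @export
reference_proteins <- function() {
  if (is.null(.malminer_cache$reference_proteins)) {
    path <- system.file("extdata", "reference_proteins_synthetic.fasta", package = "malminer")
    tbl <- read_fasta(path)
    role <- sub("^.*role=(\\w+).*$", "\\1", tbl$desc)
    .malminer_cache$reference_proteins <- tibble(id = tbl$id, role = role,
                                                 sequence = tbl$sequence)
  }
  .malminer_cache$reference_proteins
}

#' Default annotation keywords per role
#'
#' Genes whose `product` annotation matches one of these (case-insensitive,
#' fixed-string) keywords are kept as candidates even below the homology
#' thresholds — most importantly the Zn(2)-Cys(6) DNA-binding domain keyword
#' that identifies MAL-activators, whose sequences diverge too fast for
#' reliable homology calls.
#'
#' @return A named list of character vectors (names: AG, AGT, ACT).
#' @export
role_keywords <- function() {
  list(
    AG  = c("alpha-glucosidase", "maltase", "isomaltase"),
    AGT = c("alpha-glucoside permease", "alpha-glucoside transporter", "maltose permease"),
    ACT = c("Zn(2)-Cys(6)", "MAL-activator", "zinc cluster transcription factor")
  )
}

keyword_role <- function(product, keywords) {
  if (is.na(product)) return(NA_character_)
  for (role in names(keywords)) {
    for (kw in keywords[[role]]) {
      if (grepl(tolower(kw), tolower(product), fixed = TRUE)) return(role)
    }
  }
  NA_character_
}

#' Find candidate MAL genes by homology and annotation
#'
#' Aligns every gene's protein against each role reference and keeps genes
#' passing the identity and coverage thresholds, assigning the role of the
#' best-scoring passing reference. Score ties across roles are broken by
#' higher identity; genes still tied are kept but flagged `ambiguous` (they
#' count as cluster members but not towards the AG-presence requirement).
#' Genes whose `product` text matches a role keyword are candidates even
#' below the homology thresholds.
#'
#' @param genes Gene tibble ([read_gff3()]).
#' @param proteome Tibble (`id`, `sequence`) or named character vector mapping
#'   every gene id to its protein.
#' @param references Reference tibble (`id`, `role`, `sequence`);
#'   default [reference_proteins()].
#' @param keywords Named list of product keywords per role ([role_keywords()]).
#' @param identity_min,coverage_min Homology thresholds in percent
#'   (defaults 30 and 50; coverage is the fraction of the reference aligned).
#' @param scoring Scoring parameters ([alignment_scoring()]).
#' @return A tibble with one row per candidate: gene coordinates, `role`,
#'   `ambiguous`, `via` (`"homology"` or `"keyword"`), `best_reference`,
#'   `score`, `identity`, `coverage`, and `n_introns`.
#' @export
find_candidates <- function(genes, proteome, references = reference_proteins(),
                            keywords = role_keywords(),
                            identity_min = 30, coverage_min = 50,
                            scoring = alignment_scoring()) {
  prot_tbl <- as_seq_tbl(proteome, "proteome")
  prot <- setNames(prot_tbl$sequence, prot_tbl$id)
  missing <- setdiff(genes$gene_id, names(prot))
  if (length(missing)) mm_stop("missing protein for gene ", missing[1])
  introns <- setNames(count_introns(genes)$n_introns, genes$gene_id)

  rows <- purrr::map(seq_len(nrow(genes)), function(k) {
    g <- genes[k, ]
    p <- prot[[g$gene_id]]
    hits <- purrr::map(seq_len(nrow(references)), function(r) {
      aln <- global_align(p, references$sequence[r], scoring)
      tibble(reference = references$id[r], role = references$role[r],
             score = aln$score, identity = aln$identity,
             coverage = alignment_coverage(aln))
    })
    hits <- bind_rows(hits)
    pass <- hits[hits$identity >= identity_min & hits$coverage >= coverage_min, ]
    kw <- keyword_role(g$product, keywords)

    if (nrow(pass) > 0) {
      best_score <- max(pass$score)
      top <- pass[pass$score == best_score, ]
      top <- top[top$identity == max(top$identity), ]
      ambiguous <- length(unique(top$role)) > 1
      top <- top[order(top$reference), ][1, ]
      tibble(gene_id = g$gene_id, contig_id = g$contig_id, start = g$start,
             end = g$end, strand = g$strand,
             role = if (ambiguous) NA_character_ else top$role,
             ambiguous = ambiguous, via = "homology",
             best_reference = top$reference, score = top$score,
             identity = top$identity, coverage = top$coverage,
             n_introns = unname(introns[g$gene_id]))
    } else if (!is.na(kw)) {
      best <- hits[hits$role == kw, ]
      best <- best[order(-best$score), ][1, ]
      tibble(gene_id = g$gene_id, contig_id = g$contig_id, start = g$start,
             end = g$end, strand = g$strand,
             role = kw, ambiguous = FALSE, via = "keyword",
             best_reference = best$reference, score = best$score,
             identity = best$identity, coverage = best$coverage,
             n_introns = unname(introns[g$gene_id]))
    } else {
      NULL
    }
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(gene_id = character(), contig_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  role = character(), ambiguous = logical(), via = character(),
                  best_reference = character(), score = double(),
                  identity = double(), coverage = double(), n_introns = integer())
  }
  arrange(out, .data$contig_id, .data$start)
}

#' Call MAL clusters from candidate genes
#'
#' A cluster is a maximal run of candidate genes on one contig whose
#' consecutive inter-candidate gaps do not exceed `max_gap`, containing at
#' least two members of which at least one is an unambiguous AG. Genes that
#' are not candidates may lie between members without breaking the run.
#'
#' @param candidates Candidate tibble ([find_candidates()]).
#' @param max_gap Maximum gap in bp between consecutive candidate genes
#'   (default 10000).
#' @return A tibble with one row per cluster: `cluster_id`, `contig_id`,
#'   `start`, `end`, `n_members` and a list-column `members` holding the
#'   member candidate rows ordered by start coordinate.
#' @export
find_clusters <- function(candidates, max_gap = 10000) {
  empty <- tibble(cluster_id = character(), contig_id = character(),
                  start = integer(), end = integer(), n_members = integer(),
                  members = list())
  if (nrow(candidates) == 0) return(empty)
  candidates <- arrange(candidates, .data$contig_id, .data$start, .data$gene_id)
  out <- list()
  for (ctg in unique(candidates$contig_id)) {
    cc <- candidates[candidates$contig_id == ctg, ]
    gap_before <- c(Inf, cc$start[-1] - cc$end[-nrow(cc)] - 1L)
    run_id <- cumsum(gap_before > max_gap)
    for (r in unique(run_id)) {
      mem <- cc[run_id == r, ]
      has_ag <- any(mem$role == "AG" & !mem$ambiguous, na.rm = TRUE)
      if (nrow(mem) >= 2 && has_ag) {
        out[[length(out) + 1]] <- tibble(
          contig_id = ctg,
          start = min(mem$start), end = max(mem$end),
          n_members = nrow(mem), members = list(mem)
        )
      }
    }
  }
  if (!length(out)) return(empty)
  res <- bind_rows(out)
  res <- arrange(res, .data$contig_id, .data$start)
  res$cluster_id <- sprintf("cluster_%02d", seq_len(nrow(res)))
  res[, c("cluster_id", "contig_id", "start", "end", "n_members", "members")]
}

#' Detect divergent gene pairs sharing a putative bidirectional promoter
#'
#' Returns ordered pairs of cluster members that are genomically adjacent in
#' the full annotation (no annotated gene between them), with the left gene
#' on the minus strand and the right gene on the plus strand — i.e. their 5'
#' ends face a shared intergenic region — and with an intergenic distance of
#' at most `max_promoter_span`.
#'
#' @param members Member tibble of a single cluster (rows of
#'   [find_candidates()] output).
#' @param genes Full gene annotation of the genome ([read_gff3()]).
#' @param max_promoter_span Maximum intergenic distance in bp (default 2000,
#'   a typical yeast bidirectional promoter scale).
#' @return A tibble with columns `gene_minus`, `gene_plus`, `intergenic_bp`.
#' @export
find_divergent_pairs <- function(members, genes, max_promoter_span = 2000) {
  empty <- tibble(gene_minus = character(), gene_plus = character(),
                  intergenic_bp = integer())
  if (nrow(members) < 2) return(empty)
  members <- arrange(members, .data$start)
  ctg_genes <- arrange(genes[genes$contig_id == members$contig_id[1], ], .data$start)
  out <- list()
  for (i in seq_len(nrow(members) - 1)) {
    g1 <- members[i, ]; g2 <- members[i + 1, ]
    if (!(g1$strand == "-" && g2$strand == "+")) next
    gap <- g2$start - g1$end - 1L
    if (gap < 0 || gap > max_promoter_span) next
    between <- ctg_genes$gene_id[ctg_genes$start > g1$end & ctg_genes$end < g2$start]
    if (length(between)) next
    out[[length(out) + 1]] <- tibble(gene_minus = g1$gene_id,
                                     gene_plus = g2$gene_id,
                                     intergenic_bp = gap)
  }
  if (!length(out)) empty else bind_rows(out)
}

#' Distance of a cluster span from the nearest contig end
#'
#' @param start,end Cluster span (1-based inclusive).
#' @param contig_length Contig length in bp.
#' @return `min(start - 1, contig_length - end)` in bp.
#' @export
telomere_distance <- function(start, end, contig_length) {
  if (any(start < 1 | end > contig_length | start > end)) {
    mm_stop("cluster span outside contig")
  }
  pmin(start - 1L, contig_length - end)
}

#' Annotate cluster geometry
#'
#' Enriches clusters with the distance to the nearest contig end, a
#' subtelomeric flag, divergent gene pairs and per-member intron counts.
#'
#' @param clusters Cluster tibble ([find_clusters()]).
#' @param genes Full gene annotation.
#' @param contigs Contig tibble ([as_contigs()]).
#' @param subtelomeric_threshold Maximum distance in bp from a contig end for
#'   a cluster to be called subtelomeric (default 50000; distances of the
#'   order of 400 kb are firmly non-subtelomeric).
#' @param max_promoter_span Passed to [find_divergent_pairs()].
#' @return The cluster tibble with added columns `telomere_distance`,
#'   `subtelomeric`, `divergent_pairs` (list) and `intron_counts` (list).
#' @export
annotate_clusters <- function(clusters, genes, contigs,
                              subtelomeric_threshold = 50000,
                              max_promoter_span = 2000) {
  if (nrow(clusters) == 0) {
    clusters$telomere_distance <- integer()
    clusters$subtelomeric <- logical()
    clusters$divergent_pairs <- list()
    clusters$intron_counts <- list()
    return(clusters)
  }
  clen <- setNames(contigs$length, contigs$id)
  clusters$telomere_distance <- purrr::map2_int(
    seq_len(nrow(clusters)), clusters$contig_id,
    function(k, ctg) as.integer(telomere_distance(clusters$start[k], clusters$end[k], clen[[ctg]]))
  )
  clusters$subtelomeric <- clusters$telomere_distance <= subtelomeric_threshold
  clusters$divergent_pairs <- purrr::map(clusters$members, find_divergent_pairs,
                                         genes = genes,
                                         max_promoter_span = max_promoter_span)
  clusters$intron_counts <- purrr::map(clusters$members, function(mem) {
    setNames(mem$n_introns, mem$gene_id)
  })
  clusters
}
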