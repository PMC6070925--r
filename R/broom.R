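#' Tidy a MAL cluster scan
#'
#' One row per cluster member, with cluster geometry columns repeated.
#'
#' @param x A `mal_scan` from [run_scan()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mal_scan <- function(x, ...) {
  cl <- x$clusters
  if (nrow(cl) == 0) {
    return(tibble(cluster_id = character(), gene_id = character(),
                  role = character(), strand = character(),
                  identity = double(), n_introns = integer(),
                  contig_id = character(), telomere_distance = integer(),
                  subtelomeric = logical()))
  }
  out <- purrr::map(seq_len(nrow(cl)), function(k) {
    mem <- cl$members[[k]]
    tibble(cluster_id = cl$cluster_id[k], gene_id = mem$gene_id,
           role = mem$role, strand = mem$strand, identity = mem$identity,
           n_introns = mem$n_introns, contig_id = cl$contig_id[k],
           telomere_distance = cl$telomere_distance[k],
           subtelomeric = cl$subtelomeric[k])
  })
  bind_rows(out)
}

#' Glance at a MAL cluster scan
#'
#' @param x A `mal_scan`.
#' @param ... Unused.
#' @return A one-row tibble with scan-level summary counts.
#' @export
glance.mal_scan <- function(x, ...) {
  cl <- x$clusters
  tibble(
    n_contigs = nrow(x$contigs),
    n_genes = nrow(x$genes),
    n_candidates = nrow(x$candidates),
    n_clusters = nrow(cl),
    n_subtelomeric = sum(cl$subtelomeric),
    n_divergent_pairs = sum(purrr::map_int(cl$divergent_pairs, nrow)),
    n_intron_genes = sum(purrr::map_int(cl$intron_counts, ~ sum(.x > 0)))
  )
}

#' Tidy a signature classification
#'
#' Flattens the nearest-reference evidence into `nearest_reference` /
#' `nearest_matches` columns.
#'
#' @param x A `mal_classification` from [classify_signature()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mal_classification <- function(x, ...) {
  tibble(
    id = x$id, signature = x$signature, label = x$label, rule = x$rule,
    nearest_reference = purrr::map_chr(x$evidence, function(e) {
      if (nrow(e) == 0) NA_character_ else e$name[1]
    }),
    nearest_matches = purrr::map_int(x$evidence, function(e) {
      if (nrow(e) == 0) NA_integer_ else as.integer(e$matches[1])
    })
  )
}

#' Glance at a signature classification
#'
#' @param x A `mal_classification`.
#' @param ... Unused.
#' @return A one-row tibble with per-label counts.
#' @export
glance.mal_classification <- function(x, ...) {
  tibble(
    n = nrow(x),
    n_maltase = sum(x$label == "maltase"),
    n_isomaltase = sum(x$label == "isomaltase"),
    n_maltase_isomaltase = sum(x$label == "maltase-isomaltase"),
    n_ambiguous = sum(x$label == "ambiguous")
  )
}
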