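report_header <- function(config, seed = NULL) {
  ver <- as.character(utils::packageVersion("malminer"))
  cfg <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, null = "null")
  c(sprintf("# malminer %s", ver),
    sprintf("# config: %s", cfg),
    if (!is.null(seed)) sprintf("# seed: %d", seed))
}

write_report_tsv <- function(tbl, path, config, seed = NULL) {
  writeLines(report_header(config, seed), path)
  suppressWarnings(readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE))
  invisible(path)
}

scan_config <- function(identity_min = 30, coverage_min = 50, max_gap = 10000,
                        max_promoter_span = 2000, subtelomeric_threshold = 50000,
                        code = "standard") {
  list(identity_min = identity_min, coverage_min = coverage_min,
       max_gap = max_gap, max_promoter_span = max_promoter_span,
       subtelomeric_threshold = subtelomeric_threshold, code = code)
}

#' Scan an annotated genome for MAL clusters
#'
#' Runs the full mining pipeline — read genome and annotation, translate
#' genes, find candidate MAL genes, call clusters, annotate their geometry —
#' and optionally writes a TSV cluster report plus a JSON evidence document
#' (all candidates with scores, identities and the thresholds used; every
#' report embeds the package version, configuration and parameters).
#'
#' @param genome_fasta Path to the genome FASTA.
#' @param gff3 Path to the GFF3 annotation.
#' @param out_dir Output directory for `clusters.tsv` and `evidence.json`,
#'   or `NULL` to skip writing.
#' @param identity_min,coverage_min Homology thresholds
#'   ([find_candidates()]).
#' @param max_gap Cluster chaining distance ([find_clusters()]).
#' @param max_promoter_span Divergent-pair distance
#'   ([find_divergent_pairs()]).
#' @param subtelomeric_threshold Subtelomeric call distance
#'   ([annotate_clusters()]).
#' @param code Genetic code for translation ([genetic_code()]).
#' @param references,keywords Passed to [find_candidates()].
#' @param quiet Suppress progress messages.
#' @return An object of class `mal_scan`: a list with `clusters`,
#'   `candidates`, `genes`, `contigs` and `config`.
#' @export
run_scan <- function(genome_fasta, gff3, out_dir = NULL,
                     identity_min = 30, coverage_min = 50, max_gap = 10000,
                     max_promoter_span = 2000, subtelomeric_threshold = 50000,
                     code = "standard", references = reference_proteins(),
                     keywords = role_keywords(), quiet = FALSE) {
  cfg <- scan_config(identity_min, coverage_min, max_gap, max_promoter_span,
                     subtelomeric_threshold, code)
  say <- function(...) if (!quiet) message(...)
  contigs <- as_contigs(read_fasta(genome_fasta))
  genes <- read_gff3(gff3, contigs)
  say("read ", nrow(contigs), " contigs, ", nrow(genes), " genes")
  proteome <- translate_genome(genes, contigs, code)
  candidates <- find_candidates(genes, proteome, references, keywords,
                                identity_min, coverage_min)
  clusters <- find_clusters(candidates, max_gap)
  clusters <- annotate_clusters(clusters, genes, contigs,
                                subtelomeric_threshold, max_promoter_span)
  say("found ", nrow(candidates), " candidates in ", nrow(clusters), " clusters")

  out <- structure(list(clusters = clusters, candidates = candidates,
                        genes = genes, contigs = contigs, config = cfg),
                   class = "mal_scan")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_tsv(cluster_report(clusters), file.path(out_dir, "clusters.tsv"), cfg)
    evidence <- list(config = cfg,
                     version = as.character(utils::packageVersion("malminer")),
                     candidates = candidates,
                     clusters = cluster_report(clusters))
    jsonlite::write_json(evidence, file.path(out_dir, "evidence.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

# flat one-row-per-cluster table for TSV reports
cluster_report <- function(clusters) {
  if (nrow(clusters) == 0) {
    return(tibble(cluster_id = character(), contig_id = character(),
                  start = integer(), end = integer(), n_members = integer(),
                  members = character(), roles = character(),
                  strands = character(), divergent_pairs = character(),
                  telomere_distance = integer(), subtelomeric = logical(),
                  intron_counts = character()))
  }
  tibble(
    cluster_id = clusters$cluster_id,
    contig_id = clusters$contig_id,
    start = clusters$start,
    end = clusters$end,
    n_members = clusters$n_members,
    members = purrr::map_chr(clusters$members, ~ paste(.x$gene_id, collapse = ",")),
    roles = purrr::map_chr(clusters$members,
                           ~ paste(ifelse(is.na(.x$role), "ambiguous", .x$role), collapse = ",")),
    strands = purrr::map_chr(clusters$members, ~ paste(.x$strand, collapse = ",")),
    divergent_pairs = purrr::map_chr(clusters$divergent_pairs, function(dp) {
      if (nrow(dp) == 0) "" else paste(dp$gene_minus, dp$gene_plus, sep = "|", collapse = ",")
    }),
    telomere_distance = clusters$telomere_distance,
    subtelomeric = clusters$subtelomeric,
    intron_counts = purrr::map_chr(clusters$intron_counts, ~ paste(.x, collapse = ","))
  )
}

#' Classify proteins from a FASTA file
#'
#' Reads proteins (or coding DNA, translated under the chosen genetic code),
#' extracts the nine-residue signature of each and predicts substrate
#' specificity. Optionally writes a TSV report (one row per protein:
#' signature, label, rule, top nearest references).
#'
#' @param fasta Path to a protein FASTA (or CDS FASTA with `input = "dna"`).
#' @param out_dir Output directory for `signatures.tsv`, or `NULL`.
#' @param input `"protein"` or `"dna"`.
#' @param code Genetic code for `input = "dna"`.
#' @param profile,refs,scoring See [classify_proteins()].
#' @param quiet Suppress progress messages.
#' @return A `mal_classification` tibble.
#' @export
run_classify <- function(fasta, out_dir = NULL, input = c("protein", "dna"),
                         code = "standard", profile = signature_profile(),
                         refs = reference_signatures(),
                         scoring = alignment_scoring(), quiet = FALSE) {
  input <- match.arg(input)
  # a recordless FASTA is a legitimate (if vacuous) classification input:
  # it yields a header-only report rather than a format error
  if (file.exists(fasta) && !any(grepl("^>", readLines(fasta, warn = FALSE)))) {
    seqs <- tibble(id = character(), desc = character(), sequence = character())
  } else {
    seqs <- read_fasta(fasta)
  }
  if (input == "dna") {
    seqs$sequence <- vapply(seqs$sequence, translate_cds, character(1),
                            code = code, USE.NAMES = FALSE)
  }
  res <- classify_proteins(seqs, profile, refs, scoring)
  if (!quiet) message("classified ", nrow(res), " proteins")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    flat <- mutate(res, evidence = purrr::map_chr(.data$evidence, function(e) {
      if (nrow(e) == 0) "" else paste0(e$name, ":", e$matches, collapse = ",")
    }))
    write_report_tsv(flat, file.path(out_dir, "signatures.tsv"),
                     list(input = input, code = code))
  }
  res
}

#' Align proteins and build a bootstrapped NJ phylogram
#'
#' Progressive alignment, Dayhoff (or p / Jukes–Cantor) distances,
#' neighbor-joining, bootstrap supports, Newick output.
#'
#' @param fasta Path to a protein FASTA (>= 2 sequences).
#' @param out_dir Output directory for `tree.nwk` and `distances.tsv`, or
#'   `NULL`.
#' @param method,gap_handling Distance options ([msa_distances()]).
#' @param n_reps Bootstrap replicates (0 to skip bootstrapping).
#' @param seed Bootstrap seed.
#' @param scoring Alignment scoring.
#' @param quiet Suppress progress messages.
#' @return A list with `tree` (`phylo`), `msa` and `distances`.
#' @export
run_tree <- function(fasta, out_dir = NULL, method = "dayhoff",
                     gap_handling = "pairwise", n_reps = 1000, seed = 1,
                     scoring = alignment_scoring(), quiet = FALSE) {
  seqs <- read_fasta(fasta)
  msa <- progressive_align(seqs, scoring)
  D <- msa_distances(msa, method, gap_handling)
  tree <- if (n_reps >= 1 && nrow(msa) >= 4) {
    bootstrap_support(msa, n_reps, seed, method, gap_handling)
  } else {
    neighbor_joining(D)
  }
  if (!quiet) message("tree over ", nrow(msa), " taxa")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_newick(tree, file.path(out_dir, "tree.nwk"))
    Dm <- as.matrix(D)
    dist_tbl <- as_tibble(Dm, rownames = "taxon")
    write_report_tsv(dist_tbl, file.path(out_dir, "distances.tsv"),
                     list(method = method, gap_handling = gap_handling,
                          n_reps = n_reps), seed)
  }
  list(tree = tree, msa = msa, distances = D)
}

#' Generate and write a synthetic genome
#'
#' Runs [make_synthetic_genome()] and writes `genome.fasta`, `annotation.gff3`,
#' `proteome.fasta` and `truth.json` to `out_dir`. With a fixed seed the
#' files are byte-identical across runs.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory.
#' @param quiet Suppress progress messages.
#' @return The simulation result (list), invisibly.
#' @export
run_simulate <- function(config, out_dir, quiet = FALSE) {
  sim <- make_synthetic_genome(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$contigs[, c("id", "sequence")], file.path(out_dir, "genome.fasta"))
  write_gff3(sim$genes, sim$contigs, file.path(out_dir, "annotation.gff3"))
  write_fasta(sim$proteome, file.path(out_dir, "proteome.fasta"))
  truth <- sim$truth
  truth$clusters <- as.list(truth$clusters)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  if (!quiet) {
    message("wrote synthetic genome (", nrow(sim$genes), " genes, ",
            nrow(sim$truth$clusters), " clusters) to ", out_dir)
  }
  invisible(sim)
}

#' Compare a scan against a simulation truth
#'
#' A detected cluster counts as a true positive when contig and member gene
#' set match a planted cluster exactly.
#'
#' @param scan A `mal_scan` ([run_scan()]) or cluster tibble.
#' @param truth A simulation truth (from [make_synthetic_genome()]).
#' @return A one-row tibble: `n_truth`, `n_detected`, `tp`, `precision`,
#'   `recall`.
#' @export
score_scan <- function(scan, truth) {
  clusters <- if (inherits(scan, "mal_scan")) scan$clusters else scan
  det <- purrr::map_chr(clusters$members,
                        ~ paste(sort(.x$gene_id), collapse = ","))
  tru <- purrr::map_chr(truth$clusters$member_ids,
                        ~ paste(sort(.x), collapse = ","))
  tp <- length(intersect(det, tru))
  tibble(
    n_truth = length(tru), n_detected = length(det), tp = tp,
    precision = if (length(det)) tp / length(det) else NA_real_,
    recall = if (length(tru)) tp / length(tru) else NA_real_
  )
}

#' @export
print.mal_scan <- function(x, ...) {
  cat("MAL cluster scan\n")
  cat(sprintf("  contigs: %d, genes: %d, candidates: %d\n",
              nrow(x$contigs), nrow(x$genes), nrow(x$candidates)))
  cat(sprintf("  clusters: %d (%d subtelomeric)\n", nrow(x$clusters),
              sum(x$clusters$subtelomeric)))
  invisible(x)
}
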