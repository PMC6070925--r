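# fixed codon choice per amino acid for reverse translation (never emits CTG,
# so the standard and CTG-clade codes agree unless Ser is deliberately coded
# as CTG under the ctg_clade configuration)
codon_choice <- function(code = "standard") {
  tab <- c(A = "GCT", R = "AGA", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
           E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "TTG", K = "AAA",
           M = "ATG", F = "TTT", P = "CCA", S = "TCT", T = "ACT", W = "TGG",
           Y = "TAT", V = "GTT")
  if (code == "ctg_clade") tab[["S"]] <- "CTG"
  tab
}

reverse_translate <- function(protein, code = "standard") {
  tab <- codon_choice(code)
  paste0(paste(tab[chars(protein)], collapse = ""), "TAA")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_protein <- function(protein, rate, protected = integer()) {
  if (rate <= 0) return(protein)
  res <- chars(protein)
  eligible <- setdiff(seq_along(res), protected)
  hit <- eligible[stats::runif(length(eligible)) < rate]
  for (i in hit) {
    res[i] <- sample(setdiff(aa_alphabet(), res[i]), 1)
  }
  paste(res, collapse = "")
}

#' Build a protein carrying a planted signature
#'
#' Plants an arbitrary 9-symbol signature into a scaffold protein at the
#' anchor positions (the inverse of [extract_signature()]): non-gap symbols
#' replace the scaffold residues at the anchors, a `"-"` symbol deletes a
#' short window around the anchor, and non-anchor residues are mutated at
#' `mutation_rate`. The result is verified by re-extraction and re-drawn (up
#' to `max_tries` times) if the planted signature is not recovered exactly.
#'
#' @param signature A 9-symbol string over the amino-acid alphabet plus `-`.
#' @param scaffold Scaffold protein string (default: the bundled synthetic
#'   IMA1-like scaffold).
#' @param mutation_rate Per-residue substitution probability outside anchors.
#' @param seed Integer seed, or `NULL` to draw from the current RNG state.
#' @param profile The [signature_profile()] used for verification.
#' @param max_tries Redraw bound before giving up.
#' @return The protein string, with the verified signature as attribute
#'   `signature`.
#' @export
make_protein_with_signature <- function(signature, scaffold = NULL,
                                        mutation_rate = 0, seed = NULL,
                                        profile = signature_profile(),
                                        max_tries = 10) {
  if (nchar(signature) != 9) mm_stop("signature must have 9 symbols")
  scaffold <- scaffold %||% ima1_scaffold()$sequence
  anchors <- profile$anchors
  build <- function() {
    res <- chars(scaffold)
    sym <- chars(signature)
    res[anchors[sym != "-"]] <- sym[sym != "-"]
    drop <- integer()
    for (a in anchors[sym == "-"]) {
      w <- setdiff(seq(max(a - 3, 1), min(a + 3, length(res))),
                   setdiff(anchors, a))
      # keep only the contiguous run containing the anchor itself
      runs <- split(w, cumsum(c(1L, diff(w) != 1L)))
      drop <- c(drop, runs[[which(vapply(runs, function(r) a %in% r, logical(1)))]])
    }
    protected <- unique(c(anchors, drop))
    p <- mutate_protein(paste(res, collapse = ""), mutation_rate, protected)
    res <- chars(p)
    if (length(drop)) res <- res[-unique(drop)]
    paste(res, collapse = "")
  }
  attempt <- function() {
    for (k in seq_len(max_tries)) {
      p <- build()
      got <- extract_signature(p, profile)$signature
      if (got == signature) return(structure(p, signature = signature))
    }
    mm_stop("could not plant signature ", signature,
            " (mutation_rate too high?)")
  }
  if (is.null(seed)) attempt() else withr::with_seed(seed, attempt())
}

#' Draw a labeled synthetic signature dataset
#'
#' Samples reference signatures per specificity class and plants each into
#' the scaffold, yielding a labeled protein set for classifier validation.
#'
#' @param refs Reference signature set ([reference_signatures()]).
#' @param per_label Number of proteins per class (>= 1).
#' @param mutation_rate Non-anchor substitution rate.
#' @param seed Integer seed.
#' @return A tibble with columns `id`, `sequence`, `signature`, `label`.
#' @export
make_signature_dataset <- function(refs = reference_signatures(), per_label = 1,
                                   mutation_rate = 0, seed = 1) {
  if (per_label < 1) mm_stop("per_label must be >= 1")
  labels <- c("maltase", "isomaltase", "maltase-isomaltase")
  withr::with_seed(seed, {
    rows <- purrr::map(labels, function(lab) {
      pool <- refs$signature[refs$label == lab]
      sig <- sample(pool, per_label, replace = TRUE)
      tibble(
        id = sprintf("%s_%02d", gsub("-", "_", lab), seq_len(per_label)),
        sequence = vapply(sig, function(s) {
          as.character(make_protein_with_signature(s, mutation_rate = mutation_rate))
        }, character(1), USE.NAMES = FALSE),
        signature = sig,
        label = lab
      )
    })
    bind_rows(rows)
  })
}

#' Plan one synthetic MAL cluster
#'
#' @param roles Member roles in genomic order (`AG`, `AGT`, `ACT`); at least
#'   two members, at least one AG.
#' @param strands Member strands (`+`/`-`), same length as `roles`.
#' @param gaps Intergenic gaps in bp between consecutive members
#'   (length `length(roles) - 1`).
#' @param introns Intron count per member gene.
#' @param contig Index of the target contig.
#' @param offset_from_end Distance in bp between cluster end and contig end,
#'   or `NA` for automatic placement.
#' @return A cluster plan (list).
#' @export
cluster_plan <- function(roles = c("ACT", "AGT", "AG", "ACT"),
                         strands = c("+", "-", "+", "+"),
                         gaps = c(800, 499, 900),
                         introns = rep(0L, length(roles)),
                         contig = 1L, offset_from_end = NA) {
  stopifnot(length(strands) == length(roles),
            length(gaps) == length(roles) - 1,
            length(introns) == length(roles))
  if (length(roles) < 2 || !any(roles == "AG")) {
    mm_stop("a planted cluster needs >= 2 members including an AG")
  }
  if (!all(roles %in% c("AG", "AGT", "ACT"))) mm_stop("unknown role in plan")
  if (!all(strands %in% c("+", "-"))) mm_stop("unknown strand in plan")
  if (any(gaps < 0) || any(introns < 0)) mm_stop("gaps and introns must be >= 0")
  list(roles = roles, strands = strands, gaps = as.integer(gaps),
       introns = as.integer(introns), contig = as.integer(contig),
       offset_from_end = offset_from_end)
}

#' Synthetic genome simulation configuration
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig in bp (recycled).
#' @param clusters List of [cluster_plan()]s.
#' @param n_decoys Number of decoy genes (composition-preserving shuffles of
#'   the references, kept only when below the identity ceiling against every
#'   reference).
#' @param decoy_identity_ceiling Maximum percent identity of a decoy protein
#'   to any reference (default 20).
#' @param mutation_rate Per-residue substitution rate applied to the role
#'   references when deriving member proteins (default 0.05, i.e. planted
#'   genes sit at roughly 95 percent identity to their reference).
#' @param code Genetic code used for reverse translation and later
#'   re-translation (`"standard"` or `"ctg_clade"`).
#' @param seed Integer seed; the same seed gives byte-identical output files.
#' @return A `simulation_config` (list).
#' @export
simulation_config <- function(n_contigs = 2, contig_length = 200000,
                              clusters = list(cluster_plan()),
                              n_decoys = 50, decoy_identity_ceiling = 20,
                              mutation_rate = 0.05,
                              code = c("standard", "ctg_clade"), seed = 1) {
  code <- match.arg(code)
  stopifnot(n_contigs >= 1, all(contig_length >= 1000), n_decoys >= 0,
            mutation_rate >= 0, mutation_rate <= 1)
  lens <- rep_len(as.integer(contig_length), n_contigs)
  for (pl in clusters) {
    if (pl$contig > n_contigs) mm_stop("cluster plan references contig ", pl$contig,
                                       " but only ", n_contigs, " contigs exist")
  }
  structure(list(n_contigs = n_contigs, contig_length = lens,
                 clusters = clusters, n_decoys = n_decoys,
                 decoy_identity_ceiling = decoy_identity_ceiling,
                 mutation_rate = mutation_rate, code = code,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# build genic DNA (transcript orientation) with introns; returns list with
# genic sequence and exon intervals in genic coordinates (transcript order)
intronate <- function(cds, n_introns) {
  L <- nchar(cds)
  if (n_introns == 0) {
    return(list(genic = cds, exons = tibble(start = 1L, end = L)))
  }
  cuts <- sort(sample(seq(30, L - 30), n_introns))
  seg_start <- c(1L, cuts + 1L)
  seg_end <- c(cuts, L)
  intron_seqs <- vapply(seq_len(n_introns), function(i) {
    paste0("GT", random_dna(sample(30:60, 1)), "AG")
  }, character(1))
  genic <- character(0)
  exons <- tibble(start = integer(), end = integer())
  pos <- 0L
  for (i in seq_along(seg_start)) {
    piece <- substr(cds, seg_start[i], seg_end[i])
    exons <- bind_rows(exons, tibble(start = pos + 1L,
                                     end = pos + nchar(piece)))
    genic <- c(genic, piece)
    pos <- pos + nchar(piece)
    if (i <= n_introns) {
      genic <- c(genic, intron_seqs[i])
      pos <- pos + nchar(intron_seqs[i])
    }
  }
  list(genic = paste(genic, collapse = ""), exons = exons)
}

# map genic-coordinate exons to genomic coordinates for a gene placed at
# `at` (1-based genomic start) on `strand`
place_exons <- function(exons, genic_len, at, strand) {
  if (strand == "+") {
    tibble(start = at + exons$start - 1L, end = at + exons$end - 1L)
  } else {
    ex <- tibble(start = at + (genic_len - exons$end + 1L) - 1L,
                 end = at + (genic_len - exons$start + 1L) - 1L)
    ex[order(ex$start), ]
  }
}

shuffle_protein <- function(protein) {
  paste(sample(chars(protein)), collapse = "")
}

#' Generate a seeded synthetic genome with planted MAL clusters
#'
#' Emulates an annotated yeast genome assembly: contigs of random sequence
#' carrying planted MAL clusters (divergent AG/AGT pairs, optional
#' activators, introns, configurable distance from the contig end) plus decoy
#' genes, together with a machine-readable truth record. Member proteins are
#' derived from the bundled role references; AG members carry a signature
#' drawn from the reference signature set, recorded in the truth. The same
#' seed yields identical output.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `contigs` (tibble: id, length, sequence),
#'   `genes` (gene tibble as from [read_gff3()]), `proteome` (tibble: id,
#'   sequence) and `truth` (list: `clusters` tibble, `proteins` tibble,
#'   `config`, `seed`).
#' @export
make_synthetic_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  refs <- reference_proteins()
  ref_by_role <- setNames(refs$sequence, refs$role)
  sig_refs <- reference_signatures()
  products <- c(AG = "alpha-glucosidase (GH13)",
                AGT = "alpha-glucoside transporter",
                ACT = "Zn(2)-Cys(6) transcription factor (MAL-activator)")

  withr::with_seed(config$seed, {
    contig_ids <- sprintf("contig_%d", seq_len(config$n_contigs))
    contig_seq <- lapply(config$contig_length, function(L) chars(random_dna(L)))
    names(contig_seq) <- contig_ids

    genes <- list()
    truth_clusters <- list()
    truth_proteins <- list()
    proteome <- list()
    cursor <- setNames(rep(5000L, config$n_contigs), contig_ids) # left margin
    gene_no <- 0L

    # ---- planted clusters ----
    for (ci in seq_along(config$clusters)) {
      pl <- config$clusters[[ci]]
      ctg <- contig_ids[pl$contig]
      L <- config$contig_length[pl$contig]

      # member proteins and genic sequences first, so the span is known
      members <- purrr::map(seq_along(pl$roles), function(k) {
        role <- pl$roles[k]
        if (role == "AG") {
          ridx <- sample.int(nrow(sig_refs), 1)
          prot <- make_protein_with_signature(sig_refs$signature[ridx],
                                              scaffold = ref_by_role[["AG"]],
                                              mutation_rate = config$mutation_rate)
          sig <- sig_refs$signature[ridx]
          lab <- sig_refs$label[ridx]
        } else {
          prot <- mutate_protein(ref_by_role[[role]], config$mutation_rate)
          sig <- NA_character_
          lab <- NA_character_
        }
        cds <- reverse_translate(as.character(prot), config$code)
        gi <- intronate(cds, pl$introns[k])
        list(role = role, protein = as.character(prot), signature = sig,
             label = lab, genic = gi$genic, exons = gi$exons)
      })
      glens <- vapply(members, function(m) nchar(m$genic), integer(1))
      span_len <- sum(glens) + sum(pl$gaps)

      if (is.na(pl$offset_from_end)) {
        at <- cursor[[ctg]] + sample(12000:20000, 1)
      } else {
        at <- L - pl$offset_from_end - span_len + 1L
      }
      if (at <= cursor[[ctg]] || at + span_len - 1L > L - 1000L) {
        mm_stop("infeasible layout: cluster ", ci, " does not fit on ", ctg)
      }
      cursor[[ctg]] <- at + span_len + 1L

      pos <- at
      ids <- character(length(members))
      for (k in seq_along(members)) {
        m <- members[[k]]
        gene_no <- gene_no + 1L
        gid <- sprintf("gene_%03d", gene_no)
        ids[k] <- gid
        glen <- nchar(m$genic)
        seq_genomic <- if (pl$strands[k] == "+") m$genic else reverse_complement(m$genic)
        contig_seq[[ctg]][pos:(pos + glen - 1L)] <- chars(seq_genomic)
        genes[[gid]] <- tibble(
          gene_id = gid, contig_id = ctg, start = pos, end = pos + glen - 1L,
          strand = pl$strands[k], product = unname(products[m$role]),
          exons = list(place_exons(m$exons, glen, pos, pl$strands[k]))
        )
        proteome[[gid]] <- m$protein
        if (!is.na(m$signature)) {
          truth_proteins[[gid]] <- tibble(gene_id = gid, signature = m$signature,
                                          label = m$label)
        }
        pos <- pos + glen + (if (k < length(members)) pl$gaps[k] else 0L)
      }

      cl_start <- at
      cl_end <- at + span_len - 1L
      div <- which(pl$strands[-length(pl$strands)] == "-" &
                     pl$strands[-1] == "+" & pl$gaps <= 2000)
      truth_clusters[[ci]] <- tibble(
        contig_id = ctg, start = cl_start, end = cl_end,
        member_ids = list(ids), roles = list(pl$roles),
        strands = list(pl$strands),
        divergent_pairs = list(tibble(gene_minus = ids[div],
                                      gene_plus = ids[div + 1L],
                                      intergenic_bp = pl$gaps[div])),
        telomere_distance = min(cl_start - 1L, L - cl_end),
        intron_counts = list(setNames(pl$introns, ids))
      )
    }

    # ---- decoy genes ----
    # decoys must not land inside a planted cluster span (an intervening gene
    # would alter the cluster's divergent-pair truth), nor overlap any gene
    spans <- if (length(truth_clusters)) bind_rows(truth_clusters) else NULL
    occupied <- lapply(contig_ids, function(ctg) {
      occ <- matrix(numeric(0), ncol = 2)
      if (length(genes)) {
        g <- bind_rows(genes)
        g <- g[g$contig_id == ctg, ]
        if (nrow(g)) occ <- rbind(occ, cbind(g$start, g$end))
      }
      if (!is.null(spans)) {
        s <- spans[spans$contig_id == ctg, ]
        if (nrow(s)) occ <- rbind(occ, cbind(s$start, s$end))
      }
      occ
    })
    names(occupied) <- contig_ids

    for (d in seq_len(config$n_decoys)) {
      src <- refs$sequence[(d - 1L) %% nrow(refs) + 1L]
      prot <- NULL
      for (try in 1:20) {
        cand <- shuffle_protein(substr(src, 1, sample(250:420, 1)))
        idents <- vapply(refs$sequence, function(r) pairwise_identity(cand, r),
                         numeric(1), USE.NAMES = FALSE)
        if (all(idents < config$decoy_identity_ceiling)) { prot <- cand; break }
      }
      if (is.null(prot)) mm_stop("could not generate decoy below identity ceiling")
      cds <- reverse_translate(prot, config$code)
      glen <- nchar(cds)
      placed <- FALSE
      for (try in 1:200) {
        ctg_i <- sample.int(config$n_contigs, 1)
        ctg <- contig_ids[ctg_i]
        L <- config$contig_length[ctg_i]
        at <- sample.int(L - glen - 2000L, 1) + 1000L
        occ <- occupied[[ctg]]
        clash <- nrow(occ) > 0 &&
          any(at <= occ[, 2] + 200 & at + glen - 1L >= occ[, 1] - 200)
        if (!clash) {
          strand <- sample(c("+", "-"), 1)
          gene_no <- gene_no + 1L
          gid <- sprintf("decoy_%03d", gene_no)
          seq_genomic <- if (strand == "+") cds else reverse_complement(cds)
          contig_seq[[ctg]][at:(at + glen - 1L)] <- chars(seq_genomic)
          genes[[gid]] <- tibble(
            gene_id = gid, contig_id = ctg, start = at, end = at + glen - 1L,
            strand = strand, product = "hypothetical protein",
            exons = list(tibble(start = at, end = at + glen - 1L))
          )
          proteome[[gid]] <- prot
          occupied[[ctg]] <- rbind(occ, c(at, at + glen - 1L))
          placed <- TRUE
          break
        }
      }
      if (!placed) mm_stop("infeasible layout: no room for decoy genes")
    }

    contigs <- tibble(
      id = contig_ids,
      length = config$contig_length,
      sequence = vapply(contig_seq, paste, character(1), collapse = "")
    )
    genes_tbl <- arrange(bind_rows(genes), .data$contig_id, .data$start)
    proteome_tbl <- tibble(id = names(proteome),
                           sequence = unlist(proteome, use.names = FALSE))
    truth <- list(
      clusters = if (length(truth_clusters)) bind_rows(truth_clusters) else
        tibble(contig_id = character(), start = integer(), end = integer()),
      proteins = if (length(truth_proteins)) bind_rows(truth_proteins) else
        tibble(gene_id = character(), signature = character(), label = character()),
      config = unclass(config),
      seed = config$seed
    )
    list(contigs = contigs, genes = genes_tbl, proteome = proteome_tbl,
         truth = truth)
  })
}

#' Sample random cluster plans
#'
#' Draws `n` cluster layouts from the shapes seen in real MAL loci: a
#' divergent AGT/AG pair, the same pair with one or two activators, and a
#' four-gene activator-flanked arrangement. All layouts contain an AG and a
#' divergently oriented AGT/AG pair candidate. Uses the current RNG state.
#'
#' @param n Number of plans.
#' @param n_contigs Number of contigs to spread the clusters over.
#' @return A list of [cluster_plan()]s.
#' @export
sample_cluster_plans <- function(n, n_contigs = 2) {
  shapes <- list(
    list(roles = c("AGT", "AG"), strands = c("-", "+")),
    list(roles = c("ACT", "AGT", "AG"), strands = c("+", "-", "+")),
    list(roles = c("AGT", "AG", "ACT"), strands = c("-", "+", "-")),
    list(roles = c("ACT", "AGT", "AG", "ACT"), strands = c("+", "-", "+", "+"))
  )
  purrr::map(seq_len(n), function(i) {
    sh <- shapes[[sample.int(length(shapes), 1)]]
    k <- length(sh$roles)
    cluster_plan(
      roles = sh$roles, strands = sh$strands,
      gaps = sample(300:1800, k - 1, replace = TRUE),
      introns = sample(0:2, k, replace = TRUE),
      # round-robin over contigs so any feasible count of clusters fits
      contig = ((i - 1L) %% n_contigs) + 1L,
      offset_from_end = NA
    )
  })
}
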