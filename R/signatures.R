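#' The nine signature anchor positions
#'
#' Residue positions, in *S. cerevisiae* IMA1 numbering, of the nine amino
#' acids bordering the GH13 alpha-glucosidase substrate-binding pocket. These
#' positions carry the substrate-specificity signal exploited by
#' [classify_signature()].
#' @return An integer vector of length 9.
#' @export
signature_anchors <- function() {
  c(158L, 216L, 217L, 218L, 219L, 278L, 279L, 307L, 411L)
}

#' Build a signature extraction profile
#'
#' A profile bundles the reference protein that carries the anchor numbering
#' with the anchor positions themselves. The default reference is a bundled
#' synthetic stand-in for Sc IMA1: a 589-residue scaffold with the isomaltase
#' signature YVGSLMQDE planted at the canonical anchor positions (the true
#' IMA1 sequence is not redistributed with the package; any real reference
#' can be supplied instead).
#'
#' @param reference_id Name of the reference.
#' @param reference_sequence Protein string carrying the anchor numbering.
#' @param anchors Strictly increasing 1-based residue positions.
#' @return An object of class `signature_profile`.
#' @export
signature_profile <- function(reference_id = NULL, reference_sequence = NULL,
                              anchors = signature_anchors()) {
  if (is.null(reference_sequence)) {
    scaffold <- ima1_scaffold()
    reference_id <- reference_id %||% scaffold$id
    reference_sequence <- scaffold$sequence
  }
  stopifnot(is.character(reference_sequence), length(reference_sequence) == 1)
  anchors <- as.integer(anchors)
  if (is.unsorted(anchors, strictly = TRUE)) mm_stop("anchors must be strictly increasing")
  if (max(anchors) > nchar(reference_sequence)) {
    mm_stop("anchor position ", max(anchors), " beyond reference length ",
            nchar(reference_sequence))
  }
  structure(
    list(reference_id = reference_id %||% "reference",
         reference_sequence = toupper(reference_sequence),
         anchors = anchors),
    class = "signature_profile"
  )
}

#' The bundled synthetic IMA1-like scaffold
#'
#' @return A one-row tibble (`id`, `desc`, `sequence`) with the synthetic
#'   589-residue scaffold used as default signature reference and as default
#'   backbone by the synthetic-data generator.
#' @export
ima1_scaffold <- function() {
  if (is.null(.malminer_cache$ima1_scaffold)) {
    path <- system.file("extdata", "ima1_scaffold_synthetic.fasta", package = "malminer")
    .malminer_cache$ima1_scaffold <- read_fasta(path)
  }
  .malminer_cache$ima1_scaffold[1, ]
}

#' Reference signature set
#'
#' The bundled table of alpha-glucosidase signatures with their substrate
#' specificity labels (maltase, isomaltase or maltase-isomaltase) and a flag
#' for enzymes with experimentally established specificity. This set drives
#' the nearest-reference step of [classify_signature()].
#'
#' @return A tibble with columns `name`, `signature`, `label`, `studied`.
#' @export
reference_signatures <- function() {
  path <- system.file("extdata", "table2_signatures.tsv", package = "malminer")
  tbl <- readr::read_tsv(path, col_types = "cccl", progress = FALSE)
  stopifnot(!anyDuplicated(tbl$name),
            all(tbl$label %in% c("maltase", "isomaltase", "maltase-isomaltase")),
            all(nchar(tbl$signature) == 9))
  tbl
}

extract_signature_one <- function(protein, profile, scoring) {
  aln <- global_align(protein, profile$reference_sequence, scoring)
  gq <- chars(aln$aligned_a)
  gr <- chars(aln$aligned_b)
  refpos <- cumsum(gr != "-")
  cols <- match(profile$anchors, refpos)
  sym <- gq[cols]
  sym[gr[cols] == "-"] <- "-" # defensive; anchors always map to reference residues
  paste(sym, collapse = "")
}

#' Extract the nine-residue signature of alpha-glucosidases
#'
#' Globally aligns each protein to the profile reference and reads off the
#' residues aligned to the anchor positions; a deletion at an anchor yields
#' `"-"`. With the default profile this is the signature in Sc IMA1
#' numbering (158, 216, 217, 218, 219, 278, 279, 307, 411).
#'
#' @param proteins A tibble with columns `id`, `sequence`, a (possibly named)
#'   character vector, or a single protein string.
#' @param profile A [signature_profile()].
#' @param scoring Scoring parameters ([alignment_scoring()]).
#' @return A tibble with columns `id` and `signature` (9-symbol strings over
#'   the amino-acid alphabet plus `-`).
#' @export
extract_signature <- function(proteins, profile = signature_profile(),
                              scoring = alignment_scoring()) {
  tbl <- as_seq_tbl(proteins, "proteins")
  sig <- vapply(tbl$sequence, extract_signature_one, character(1),
                profile = profile, scoring = scoring, USE.NAMES = FALSE)
  tibble(id = tbl$id, signature = sig)
}

#' Count matching signature positions
#'
#' Number of positions at which two 9-symbol signatures carry the same
#' non-gap residue. Symmetric; 9 iff the signatures are gap-free identical.
#'
#' @param s1,s2 Signature strings of length 9 (vectorized, recycled).
#' @return Integer count(s) in 0–9.
#' @export
match_count <- function(s1, s2) {
  n <- max(length(s1), length(s2))
  s1 <- rep_len(s1, n); s2 <- rep_len(s2, n)
  if (any(nchar(c(s1, s2)) != 9)) mm_stop("signatures must have length 9")
  vapply(seq_len(n), function(i) {
    a <- chars(s1[i]); b <- chars(s2[i])
    sum(a == b & a != "-")
  }, integer(1))
}

classify_one <- function(sig, refs) {
  sym <- chars(sig)
  p216 <- sym[2]; p217 <- sym[3]
  ev <- tibble(name = character(), label = character(), matches = integer())
  if (p216 == "-") {
    return(list(label = "ambiguous", rule = "gap216", evidence = ev))
  }
  if (p216 == "V") {
    return(list(label = "isomaltase", rule = "V216", evidence = ev))
  }
  motif <- paste0(p216, p217)
  if (motif == "TV") return(list(label = "maltase", rule = "motif_TV", evidence = ev))
  if (motif == "AI") return(list(label = "maltase", rule = "motif_AI", evidence = ev))
  if (motif == "VI") return(list(label = "isomaltase", rule = "motif_VI", evidence = ev))
  # maltose-capable signature: nearest-reference vote among experimentally
  # studied maltases and maltase-isomaltases
  pool <- refs[refs$studied & refs$label %in% c("maltase", "maltase-isomaltase"), ]
  if (nrow(pool) == 0) return(list(label = "ambiguous", rule = "nearest_reference", evidence = ev))
  m <- match_count(rep(sig, nrow(pool)), pool$signature)
  ev <- tibble(name = pool$name, label = pool$label, matches = m)
  ev <- ev[order(-ev$matches, ev$name), ]
  top <- ev$label[ev$matches == max(ev$matches)]
  label <- if (length(unique(top)) > 1) "ambiguous" else top[1]
  list(label = label, rule = "nearest_reference", evidence = head(ev, 3))
}

#' Predict substrate specificity from a signature
#'
#' Applies a fixed-order decision procedure to each 9-residue signature:
#' \enumerate{
#'   \item Val at position 216 → isomaltase (`V216`; Val216 is the key
#'     isomaltase determinant).
#'   \item Positions 216–217 TV or AI → maltase (`motif_TV` / `motif_AI`).
#'   \item Positions 216–217 VI → isomaltase (`motif_VI`; unreachable after
#'     step 1, retained for reporting).
#'   \item Otherwise (maltose-capable signatures, e.g. TAG at 216–218) the
#'     label of the experimentally studied maltase / maltase-isomaltase
#'     reference with the highest [match_count()] wins; a tie across
#'     different labels is reported as `ambiguous`.
#' }
#' A gap at position 216 yields `ambiguous` with rule `gap216`.
#'
#' @param signatures A tibble with columns `id`, `signature` (as returned by
#'   [extract_signature()]), or a character vector of signatures.
#' @param refs Reference signature set ([reference_signatures()]).
#' @return A tibble of class `mal_classification`: `id`, `signature`,
#'   `label`, `rule` and a list-column `evidence` holding the top nearest
#'   references with their match counts.
#' @export
classify_signature <- function(signatures, refs = reference_signatures()) {
  if (is.character(signatures)) {
    ids <- names(signatures) %||% paste0("sig", seq_along(signatures))
    signatures <- tibble(id = ids, signature = unname(signatures))
  }
  stopifnot(all(c("id", "signature") %in% names(signatures)))
  res <- purrr::map(signatures$signature, classify_one, refs = refs)
  out <- tibble(
    id = signatures$id,
    signature = signatures$signature,
    label = purrr::map_chr(res, "label"),
    rule = purrr::map_chr(res, "rule"),
    evidence = purrr::map(res, "evidence")
  )
  class(out) <- c("mal_classification", class(out))
  out
}

#' Extract signatures and classify proteins in one step
#'
#' @inheritParams extract_signature
#' @inheritParams classify_signature
#' @return A `mal_classification` tibble (see [classify_signature()]).
#' @export
classify_proteins <- function(proteins, profile = signature_profile(),
                              refs = reference_signatures(),
                              scoring = alignment_scoring()) {
  classify_signature(extract_signature(proteins, profile, scoring), refs = refs)
}
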