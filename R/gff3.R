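#' Read gene features from a GFF3 annotation
#'
#' Parses a GFF3 file (via rtracklayer) and assembles one gene feature per
#' `gene` row, with exon structure taken from `exon` children (or `CDS`
#' children when no exons are annotated) linked through `mRNA` rows by their
#' `Parent` attributes. Coordinates are 1-based inclusive throughout.
#'
#' @param path Path to a GFF3 file.
#' @param contigs A contig tibble from [as_contigs()] (columns `id`, `length`),
#'   used to reject features on unknown contigs and beyond contig bounds.
#' @return A tibble with one row per gene: `gene_id`, `contig_id`, `start`,
#'   `end`, `strand`, `product` and a list-column `exons` of tibbles with
#'   columns `start`, `end` sorted ascending.
#' @export
read_gff3 <- function(path, contigs) {
  if (!file.exists(path)) mm_format_error("GFF3 file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) mm_format_error("malformed GFF3 in ", path, ": ", conditionMessage(e))
  )
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (nrow(df) == 0) mm_format_error("GFF3 file has no features: ", path)
  df$ID <- as.character(df$ID)
  df$Parent <- vapply(
    if (is.null(df$Parent)) rep(list(character()), nrow(df)) else df$Parent,
    function(p) if (length(p)) as.character(p)[1] else NA_character_, character(1)
  )
  df$product <- if ("product" %in% names(df)) as.character(df$product) else NA_character_
  if ("Note" %in% names(df)) {
    note <- vapply(df$Note, function(x) if (length(x)) paste(as.character(x), collapse = "; ") else NA_character_, character(1))
    df$product <- ifelse(is.na(df$product), note, df$product)
  }
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)

  unknown <- setdiff(unique(df$seqnames), contigs$id)
  if (length(unknown)) {
    mm_format_error("feature references unknown contig: ", unknown[1])
  }

  genes <- df[df$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) {
    return(tibble(gene_id = character(), contig_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  product = character(), exons = list()))
  }
  if (any(is.na(genes$ID))) mm_format_error("gene feature without ID attribute")
  if (anyDuplicated(genes$ID)) {
    mm_format_error("duplicate gene ID: ", genes$ID[duplicated(genes$ID)][1])
  }
  bad_strand <- !(genes$strand %in% c("+", "-"))
  if (any(bad_strand)) {
    mm_format_error("unknown strand for gene ", genes$ID[bad_strand][1])
  }

  # map every feature to its owning gene through Parent chains (depth <= 2)
  id2gene <- setNames(genes$ID, genes$ID)
  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  if (nrow(mrna)) {
    dangling <- !(mrna$Parent %in% genes$ID)
    if (any(dangling)) {
      mm_format_error("dangling Parent for feature ",
                      ifelse(is.na(mrna$ID[dangling][1]), "<no ID>", mrna$ID[dangling][1]))
    }
    id2gene <- c(id2gene, setNames(mrna$Parent, mrna$ID))
  }

  parts <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (nrow(parts)) {
    if (any(is.na(parts$Parent))) mm_format_error("exon/CDS feature without Parent")
    dangling <- !(parts$Parent %in% names(id2gene))
    if (any(dangling)) {
      mm_format_error("dangling Parent for feature ",
                      ifelse(is.na(parts$ID[dangling][1]), parts$Parent[dangling][1], parts$ID[dangling][1]))
    }
    parts$gene_id <- unname(id2gene[parts$Parent])
  }

  clen <- setNames(contigs$length, contigs$id)
  exons_of <- function(gid, gstart, gend) {
    own <- parts[parts$gene_id == gid, , drop = FALSE]
    sel <- if (any(own$type == "exon")) own[own$type == "exon", ] else own[own$type == "CDS", ]
    if (nrow(sel) == 0) {
      return(tibble(start = as.integer(gstart), end = as.integer(gend)))
    }
    ex <- tibble(start = as.integer(sel$start), end = as.integer(sel$end))
    ex <- ex[order(ex$start), ]
    if (any(ex$start < gstart | ex$end > gend)) {
      mm_format_error("exon outside gene bounds for gene ", gid)
    }
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      mm_format_error("overlapping exons for gene ", gid)
    }
    ex
  }

  out <- tibble(
    gene_id = genes$ID,
    contig_id = genes$seqnames,
    start = as.integer(genes$start),
    end = as.integer(genes$end),
    strand = genes$strand,
    product = genes$product
  )
  if (any(out$end > clen[out$contig_id])) {
    bad <- out$gene_id[out$end > clen[out$contig_id]][1]
    mm_format_error("gene beyond contig end: ", bad)
  }
  out$exons <- purrr::pmap(list(out$gene_id, out$start, out$end), exons_of)
  arrange(out, .data$contig_id, .data$start)
}

#' Write gene features as GFF3
#'
#' Emits `gene`, `mRNA`, `exon` and `CDS` rows with deterministic field and
#' attribute order, so identical inputs yield byte-identical files.
#'
#' @param genes A gene tibble as returned by [read_gff3()].
#' @param contigs A contig tibble ([as_contigs()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, contigs, path) {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", contigs$id, contigs$length))
  genes <- arrange(genes, .data$contig_id, .data$start)
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    prod <- if (is.na(g$product)) "" else paste0(";product=", g$product)
    mid <- paste0(g$gene_id, ".t1")
    lines <- c(
      lines,
      sprintf("%s\tmalminer\tgene\t%d\t%d\t.\t%s\t.\tID=%s%s",
              g$contig_id, g$start, g$end, g$strand, g$gene_id, prod),
      sprintf("%s\tmalminer\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$contig_id, g$start, g$end, g$strand, mid, g$gene_id)
    )
    ex <- g$exons[[1]]
    for (i in seq_len(nrow(ex))) {
      lines <- c(
        lines,
        sprintf("%s\tmalminer\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
                g$contig_id, ex$start[i], ex$end[i], g$strand, mid, i, mid),
        sprintf("%s\tmalminer\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
                g$contig_id, ex$start[i], ex$end[i], g$strand, mid, i, mid)
      )
    }
  }
  writeLines(lines, path)
  invisible(path)
}
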