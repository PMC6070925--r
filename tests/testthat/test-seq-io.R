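test_that("read_fasta parses records, preserves order, uppercases and wraps", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT"), f)
  tbl <- read_fasta(f)
  expect_equal(tbl$id, "a")
  expect_equal(tbl$sequence, "ACGT")

  writeLines(c(">b first", "acg", "tac", "gt", ">a", "TTT"), f)
  tbl <- read_fasta(f)
  expect_equal(tbl$id, c("b", "a"))
  expect_equal(tbl$sequence[1], "ACGTACGT")
  expect_equal(tbl$desc[1], "first")
})

test_that("read_fasta rejects duplicates, empty and malformed files", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate", class = "malminer_format_error")
  writeLines(character(0), f)
  expect_error(read_fasta(f), class = "malminer_format_error")
  expect_error(read_fasta(file.path(tempdir(), "nope.fasta")),
               class = "malminer_format_error")
})

test_that("GFF3 write/read round-trip preserves genes exactly", {
  withr::local_seed(11)
  for (rep in 1:5) {
    n_genes <- sample(2:6, 1)
    contigs <- tibble::tibble(id = "ctgA", length = 50000L,
                              sequence = random_dna_str(50000))
    pos <- sort(sample(seq(100, 45000, by = 50), n_genes * 2))
    genes <- tibble::tibble(
      gene_id = sprintf("gene%02d", seq_len(n_genes)),
      contig_id = "ctgA",
      start = as.integer(pos[seq(1, by = 2, length.out = n_genes)]),
      end = as.integer(pos[seq(2, by = 2, length.out = n_genes)]),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      product = sample(c(NA, "hypothetical protein"), n_genes, replace = TRUE)
    )
    genes$exons <- lapply(seq_len(n_genes), function(i) {
      k <- sample(1:3, 1)
      span <- genes$end[i] - genes$start[i]
      if (k == 1 || span < 40) {
        return(tibble::tibble(start = genes$start[i], end = genes$end[i]))
      }
      cuts <- sort(sample(seq(genes$start[i] + 5, genes$end[i] - 5), 2 * (k - 1)))
      tibble::tibble(
        start = as.integer(c(genes$start[i], cuts[seq(2, length(cuts), 2)] + 1L)),
        end = as.integer(c(cuts[seq(1, length(cuts), 2)], genes$end[i]))
      )
    })
    f <- withr::local_tempfile(fileext = ".gff3")
    write_gff3(genes, contigs, f)
    back <- read_gff3(f, contigs)
    back <- back[match(genes$gene_id, back$gene_id), ]
    expect_equal(back$start, genes$start)
    expect_equal(back$end, genes$end)
    expect_equal(back$strand, genes$strand)
    expect_equal(lapply(back$exons, as.data.frame),
                 lapply(genes$exons, as.data.frame))
  }
})

test_that("read_gff3 enforces the gene-feature contract", {
  contigs <- tibble::tibble(id = "ctgA", length = 10000L, sequence = NA)
  f <- withr::local_tempfile(fileext = ".gff3")
  # exon outside gene bounds
  writeLines(c("##gff-version 3",
               "ctgA\tx\tgene\t100\t200\t.\t+\t.\tID=g1",
               "ctgA\tx\tmRNA\t100\t200\t.\t+\t.\tID=m1;Parent=g1",
               "ctgA\tx\texon\t100\t300\t.\t+\t.\tID=e1;Parent=m1"), f)
  expect_error(read_gff3(f, contigs), "outside gene bounds",
               class = "malminer_format_error")
  # unknown contig
  writeLines(c("##gff-version 3",
               "ctgB\tx\tgene\t100\t200\t.\t+\t.\tID=g1"), f)
  expect_error(read_gff3(f, contigs), "unknown contig",
               class = "malminer_format_error")
  # dangling Parent
  writeLines(c("##gff-version 3",
               "ctgA\tx\tgene\t100\t200\t.\t+\t.\tID=g1",
               "ctgA\tx\texon\t100\t200\t.\t+\t.\tID=e1;Parent=nosuch"), f)
  expect_error(read_gff3(f, contigs), "dangling Parent",
               class = "malminer_format_error")
  # unknown strand
  writeLines(c("##gff-version 3",
               "ctgA\tx\tgene\t100\t200\t.\t.\t.\tID=g1"), f)
  expect_error(read_gff3(f, contigs), "strand",
               class = "malminer_format_error")
})

test_that("multi-exon genes come back with exons sorted ascending", {
  contigs <- tibble::tibble(id = "ctgA", length = 10000L, sequence = NA)
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "ctgA\tx\tgene\t100\t900\t.\t+\t.\tID=g1",
               "ctgA\tx\tmRNA\t100\t900\t.\t+\t.\tID=m1;Parent=g1",
               "ctgA\tx\texon\t700\t900\t.\t+\t.\tID=e3;Parent=m1",
               "ctgA\tx\texon\t100\t300\t.\t+\t.\tID=e1;Parent=m1",
               "ctgA\tx\texon\t400\t600\t.\t+\t.\tID=e2;Parent=m1"), f)
  g <- read_gff3(f, contigs)
  expect_equal(g$exons[[1]]$start, c(100L, 400L, 700L))
  expect_equal(count_introns(g)$n_introns, 2L)
})

test_that("translation honors the genetic code and its error contract", {
  expect_equal(translate_cds("ATGAAA"), "MK")
  expect_equal(translate_cds("ATGCTGGGT", "standard"), "MLG")
  expect_equal(translate_cds("ATGCTGGGT", "ctg_clade"), "MSG")
  expect_equal(translate_cds("ATGAAATAA"), "MK") # terminal stop stripped
  expect_equal(translate_cds("ATGANA"), "MX")    # N degrades to X
  expect_error(translate_cds("ATGA"), "multiple of 3",
               class = "malminer_format_error")
  expect_error(translate_cds("ATGTAAAAA"), "codon 2",
               class = "malminer_format_error")
  expect_error(translate_cds("ATGRAA"), class = "malminer_format_error")
})

test_that("ctg_clade translation equals standard when no CTG codon occurs", {
  withr::local_seed(4)
  for (i in 1:20) {
    aa <- paste(sample(setdiff(aa_alphabet(), "L"), 30, replace = TRUE), collapse = "")
    cds <- malminer:::reverse_translate(aa, "standard")
    expect_false(grepl("CTG", substring(cds, seq(1, nchar(cds), 3),
                                        seq(3, nchar(cds), 3))[1]))
    expect_equal(translate_cds(cds, "standard"), translate_cds(cds, "ctg_clade"))
  }
})

test_that("intron counts equal exon count minus one and are never negative", {
  g <- toy_genes(cbind(c(100, 500), c(300, 900), c("+", "-")))
  g$exons[[2]] <- tibble::tibble(start = c(500L, 600L, 700L, 800L),
                                 end = c(550L, 650L, 750L, 900L))
  ic <- count_introns(g)
  expect_equal(ic$n_introns, c(0L, 3L))
  expect_true(all(ic$n_introns >= 0))
})

test_that("minus-strand CDS assembly reverse-complements in exon order", {
  contigs <- tibble::tibble(id = "c", length = 30L,
                            sequence = "AAACATTCCGGGTTTAAACCCGGGTTTAAA")
  g <- toy_genes(cbind(4, 9, "-"), contig = "c")
  # genomic CATTCC -> revcomp GGAATG
  expect_equal(extract_cds(g[1, ], contigs), "GGAATG")
})
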