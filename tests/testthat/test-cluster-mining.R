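test_that("a protein identical to a reference is a full-score candidate", {
  refs <- reference_proteins()
  g <- toy_genes(cbind(1000, 1000 + nchar(refs$sequence[refs$role == "AG"]) * 3, "+"))
  prot <- stats::setNames(refs$sequence[refs$role == "AG"], g$gene_id)
  cand <- find_candidates(g, prot)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$role, "AG")
  expect_equal(cand$identity, 100)
  expect_equal(cand$coverage, 100)
  expect_equal(cand$via, "homology")
})

test_that("unrelated proteins without keywords are not candidates", {
  withr::local_seed(8)
  g <- toy_genes(cbind(1000, 2000, "+"))
  prot <- stats::setNames(random_protein(300), g$gene_id)
  cand <- find_candidates(g, prot)
  expect_equal(nrow(cand), 0)
})

test_that("a Zn(2)-Cys(6) product keyword rescues a weak homolog as activator", {
  withr::local_seed(9)
  g <- toy_genes(cbind(1000, 2000, "+"),
                 products = "Zn(2)-Cys(6) transcription factor")
  prot <- stats::setNames(random_protein(400), g$gene_id)
  cand <- find_candidates(g, prot)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$role, "ACT")
  expect_equal(cand$via, "keyword")
})

test_that("missing proteins are reported by gene id", {
  g <- toy_genes(cbind(1000, 2000, "+"))
  expect_error(find_candidates(g, c(other = "MKV")), "missing protein for gene g01")
})

test_that("cluster calling follows the two-member one-AG definition", {
  g <- toy_genes(cbind(c(1000, 4000, 8000, 30000),
                       c(3000, 6000, 10000, 32000),
                       c("+", "-", "+", "+")))
  # single AG alone (others too far / absent): no cluster
  cand <- toy_candidates(g[1, ], "AG")
  expect_equal(nrow(find_clusters(cand)), 0)
  # adjacent AG + AGT: one two-gene cluster
  cand <- toy_candidates(g[1:2, ], c("AG", "AGT"))
  cl <- find_clusters(cand)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_members, 2)
  expect_equal(cl$start, 1000L)
  expect_equal(cl$end, 6000L)
  # ACT + AGT + AG + ACT within gaps: one four-gene cluster
  g4 <- toy_genes(cbind(c(1000, 4000, 8000, 12000),
                        c(3000, 6000, 10000, 14000),
                        c("+", "-", "+", "+")))
  cand <- toy_candidates(g4, c("ACT", "AGT", "AG", "ACT"))
  cl <- find_clusters(cand)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_members, 4)
  # AGT + ACT with no AG: no cluster
  cand <- toy_candidates(g[1:2, ], c("AGT", "ACT"))
  expect_equal(nrow(find_clusters(cand)), 0)
  # an ambiguous-role AG does not satisfy the AG requirement
  cand <- toy_candidates(g[1:2, ], c("AG", "AGT"), ambiguous = c(TRUE, FALSE))
  expect_equal(nrow(find_clusters(cand)), 0)
})

test_that("a gap beyond max_gap splits candidate runs", {
  g <- toy_genes(cbind(c(1000, 4000, 40000, 43000),
                       c(3000, 6000, 42000, 45000),
                       c("+", "-", "-", "+")))
  cand <- toy_candidates(g, c("AG", "AGT", "AGT", "AG"))
  cl <- find_clusters(cand, max_gap = 10000)
  expect_equal(nrow(cl), 2)
  cl_wide <- find_clusters(cand, max_gap = 50000)
  expect_equal(nrow(cl_wide), 1)
  expect_equal(cl_wide$n_members, 4)
})

test_that("cluster output is invariant under candidate permutation", {
  withr::local_seed(10)
  g <- toy_genes(cbind(c(1000, 4000, 8000, 12000),
                       c(3000, 6000, 10000, 14000),
                       c("+", "-", "+", "+")))
  cand <- toy_candidates(g, c("ACT", "AGT", "AG", "ACT"))
  ref <- find_clusters(cand)
  for (k in 1:5) {
    perm <- cand[sample(nrow(cand)), ]
    expect_equal(find_clusters(perm), ref)
  }
})

test_that("divergent pairs require facing 5' ends, adjacency, and proximity", {
  # minus then plus, 499 bp apart: one pair
  g <- toy_genes(cbind(c(1000, 2500), c(2000, 3500), c("-", "+")))
  cand <- toy_candidates(g, c("AGT", "AG"))
  dp <- find_divergent_pairs(cand, g)
  expect_equal(nrow(dp), 1)
  expect_equal(dp$intergenic_bp, 499L)
  # both plus: no pair
  g2 <- toy_genes(cbind(c(1000, 2500), c(2000, 3500), c("+", "+")))
  expect_equal(nrow(find_divergent_pairs(toy_candidates(g2, c("AGT", "AG")), g2)), 0)
  # convergent (plus then minus): no pair
  g3 <- toy_genes(cbind(c(1000, 2500), c(2000, 3500), c("+", "-")))
  expect_equal(nrow(find_divergent_pairs(toy_candidates(g3, c("AGT", "AG")), g3)), 0)
  # too far apart: no pair
  g4 <- toy_genes(cbind(c(1000, 9000), c(2000, 9900), c("-", "+")))
  expect_equal(nrow(find_divergent_pairs(toy_candidates(g4, c("AGT", "AG")), g4)), 0)
  # an intervening annotated gene annuls the shared promoter
  g5 <- toy_genes(cbind(c(1000, 2100, 2500), c(2000, 2400, 3500),
                        c("-", "+", "+")))
  cand5 <- toy_candidates(g5[c(1, 3), ], c("AGT", "AG"))
  expect_equal(nrow(find_divergent_pairs(cand5, g5)), 0)
})

test_that("divergent pairs are preserved under contig mirroring", {
  withr::local_seed(12)
  L <- 100000L
  for (k in 1:10) {
    starts <- sort(sample(seq(5000, 90000, by = 100), 3))
    ends <- starts + sample(500:1500, 3)
    strands <- sample(c("+", "-"), 3, replace = TRUE)
    g <- toy_genes(cbind(starts, ends, strands))
    cand <- toy_candidates(g, c("AGT", "AG", "ACT"))
    dp <- find_divergent_pairs(cand, g)
    # mirror: reverse-complement coordinates and flip strands
    gm <- g
    gm$start <- L - g$end + 1L
    gm$end <- L - g$start + 1L
    gm$strand <- ifelse(g$strand == "+", "-", "+")
    gm$exons <- lapply(seq_len(nrow(g)), function(i) {
      tibble::tibble(start = gm$start[i], end = gm$end[i])
    })
    candm <- toy_candidates(gm, c("AGT", "AG", "ACT"))
    dpm <- find_divergent_pairs(candm, gm)
    expect_equal(nrow(dpm), nrow(dp))
    if (nrow(dp)) {
      expect_setequal(paste(dpm$gene_minus, dpm$gene_plus),
                      paste(dp$gene_plus, dp$gene_minus))
      expect_setequal(dpm$intergenic_bp, dp$intergenic_bp)
    }
  }
})

test_that("telomere distance takes the nearer contig end", {
  expect_equal(telomere_distance(1, 500, 10000), 0L)
  expect_equal(telomere_distance(100, 500, 10000), 99L)
  expect_equal(telomere_distance(9000, 9900, 10000), 100L)
  expect_error(telomere_distance(100, 10500, 10000), "outside contig")
})

test_that("cluster annotation sets geometry fields coherently", {
  contigs <- tibble::tibble(id = "ctg1", length = 500000L, sequence = NA)
  g <- toy_genes(cbind(c(100, 2500), c(2000, 3500), c("-", "+")))
  cand <- toy_candidates(g, c("AGT", "AG"))
  cl <- annotate_clusters(find_clusters(cand), g, contigs)
  expect_equal(cl$telomere_distance, 99L)
  expect_true(cl$subtelomeric)
  expect_equal(nrow(cl$divergent_pairs[[1]]), 1)
  expect_equal(unname(cl$intron_counts[[1]]), c(0L, 0L))

  # a cluster ~410 kb from either end is not subtelomeric
  g2 <- toy_genes(cbind(c(410001, 412500), c(412000, 413500), c("-", "+")))
  contigs2 <- tibble::tibble(id = "ctg1", length = 900000L, sequence = NA)
  cl2 <- annotate_clusters(find_clusters(toy_candidates(g2, c("AGT", "AG"))),
                           g2, contigs2)
  expect_equal(cl2$telomere_distance, 410000L)
  expect_false(cl2$subtelomeric)
})
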