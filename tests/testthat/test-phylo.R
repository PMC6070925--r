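test_that("progressive alignment handles identical and near-identical inputs", {
  msa <- progressive_align(c(a = "MKVLLT", b = "MKVLLT"))
  expect_equal(msa$aligned[1], "MKVLLT")
  expect_equal(msa$aligned[2], "MKVLLT")

  msa <- progressive_align(c(a = "MKV", b = "MKAV"))
  expect_equal(nchar(msa$aligned[1]), 4)
  expect_equal(sum(strsplit(msa$aligned[1], "")[[1]] == "-"), 1)

  msa <- progressive_align(c(a = "MKVWWT", b = "MKVWWT", c = "MKVWT"))
  expect_identical(msa$aligned[msa$id == "a"], msa$aligned[msa$id == "b"])
})

test_that("alignment rows preserve every input residue", {
  withr::local_seed(21)
  seqs <- stats::setNames(vapply(1:6, function(i) random_protein(sample(30:60, 1)),
                                 character(1)), letters[1:6])
  msa <- progressive_align(seqs)
  expect_equal(length(unique(nchar(msa$aligned))), 1)
  for (id in names(seqs)) {
    expect_equal(gsub("-", "", msa$aligned[msa$id == id]), unname(seqs[id]))
  }
})

test_that("p-distance uses pairwise deletion", {
  expect_equal(p_distance("AAAA", "AAAA"), 0)
  expect_equal(p_distance("AAAA", "AAAT"), 0.25)
  expect_equal(p_distance("A-AA", "ACAA"), 0)
  expect_error(p_distance("---", "AAA"), "no comparable columns")
  expect_error(p_distance("AA", "AAA"), "differ in length")
})

test_that("the Dayhoff correction is zero at identity, monotone, and >= p", {
  expect_equal(dayhoff_distance("ARNDC", "ARNDC"), 0)
  rows <- list(
    c("ARNDCQEGHI", "ARNDCQEGHL"), # p = 0.1
    c("ARNDCQEGHI", "ARNKCQPGHL"), # p = 0.3
    c("ARNDCQEGHI", "GRNKCWPSHL")  # p = 0.5
  )
  d <- vapply(rows, function(r) dayhoff_distance(r[1], r[2]), numeric(1))
  p <- vapply(rows, function(r) p_distance(r[1], r[2]), numeric(1))
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("saturated pairs are flagged infinite with a warning", {
  a <- paste(rep("A", 50), collapse = "")
  b <- paste(rep("R", 50), collapse = "")
  expect_warning(d <- dayhoff_distance(a, b), "saturated")
  expect_true(is.infinite(d))
})

test_that("the Dayhoff inversion recovers the generating branch length", {
  # simulate a pair of sequences t substitutions/site apart under the model's
  # own transition matrix and check the estimated distance
  model <- malminer:::dayhoff_model()
  withr::local_seed(31)
  aa <- aa_alphabet()
  for (t_true in c(0.1, 0.5, 1.0)) {
    P <- Re(model$V %*% (exp(model$lambda * t_true) * model$Vi))
    x <- sample.int(20, 20000, replace = TRUE, prob = model$bf)
    y <- vapply(x, function(i) sample.int(20, 1, prob = pmax(P[i, ], 0)), integer(1))
    d <- dayhoff_distance(paste(aa[x], collapse = ""), paste(aa[y], collapse = ""))
    expect_equal(d, t_true, tolerance = 0.08, label = paste("t =", t_true))
  }
})

test_that("three-taxon NJ matches the closed-form branch lengths", {
  D <- matrix(c(0, 5, 9,
                5, 0, 10,
                9, 10, 0), 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(stats::as.dist(D))
  # v_A = (d_AB + d_AC - d_BC)/2 = 2, v_B = 3, v_C = 7
  bl <- stats::setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                        tr$tip.label)
  expect_equal(bl[["A"]], 2)
  expect_equal(bl[["B"]], 3)
  expect_equal(bl[["C"]], 7)
})

test_that("NJ recovers an additive four-taxon tree exactly", {
  true <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  D <- ape::cophenetic.phylo(true)
  tr <- neighbor_joining(D)
  expect_same_topology(tr, true)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
               tolerance = 1e-12)
})

test_that("equidistant taxa give a valid tree with equal branch lengths", {
  D <- matrix(2, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(D) <- 0
  tr <- neighbor_joining(stats::as.dist(D))
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), LETTERS[1:4])
  tip_edges <- tr$edge.length[tr$edge[, 2] <= 4]
  expect_true(all(abs(tip_edges - 1) < 1e-12))
})

test_that("two taxa yield a single split edge", {
  D <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr <- neighbor_joining(D)
  expect_equal(length(tr$tip.label), 2)
  expect_equal(sum(tr$edge.length), 0.4)
})

test_that("NJ topologies agree with ape's reference implementation", {
  withr::local_seed(41)
  for (k in 1:20) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n, rooted = FALSE)
    true$edge.length <- stats::runif(length(true$edge.length), 0.01, 1)
    D <- ape::cophenetic.phylo(true)
    mine <- neighbor_joining(D)
    reference <- ape::nj(D)
    expect_same_topology(mine, reference)
    expect_same_topology(mine, true)
  }
})

test_that("invalid distance matrices are rejected", {
  M <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(neighbor_joining(M), "symmetric")
  M2 <- matrix(c(0, -1, -1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(neighbor_joining(M2), "non-negative")
})

test_that("negative NJ branch lengths are clamped and counted", {
  # a non-additive matrix known to produce a negative internal estimate
  D <- matrix(c(0, 2, 2, 2,
                2, 0, 2, 2,
                2, 2, 0, 0.1,
                2, 2, 0.1, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports are deterministic per seed and sensible", {
  withr::local_seed(51)
  base <- random_protein(60)
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    idx <- sample(seq_along(v), k)
    for (i in idx) v[i] <- sample(setdiff(aa_alphabet(), v[i]), 1)
    paste(v, collapse = "")
  }
  clade1 <- mut(base, 3)
  clade2 <- mut(base, 25)
  seqs <- c(A = mut(clade1, 2), B = mut(clade1, 2),
            C = mut(clade2, 2), D = mut(clade2, 2),
            E = mut(clade2, 6), F = mut(clade2, 6))
  msa <- progressive_align(seqs)
  t1 <- bootstrap_support(msa, n_reps = 100, seed = 99, method = "p")
  t2 <- bootstrap_support(msa, n_reps = 100, seed = 99, method = "p")
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  # the deep A,B split is strongly supported
  expect_true(max(sup) >= 90)
  expect_error(bootstrap_support(msa, n_reps = 0), "n_reps")
})

test_that("a signal-free alignment does not produce uniform full support", {
  withr::local_seed(53)
  seqs <- stats::setNames(vapply(1:6, function(i) random_protein(40), character(1)),
                          LETTERS[1:6])
  msa <- progressive_align(seqs)
  tr <- suppressWarnings(bootstrap_support(msa, n_reps = 200, seed = 3, method = "p"))
  sup <- suppressWarnings(as.numeric(tr$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(any(sup < 100))
})

test_that("Newick output round-trips topology, lengths and supports", {
  withr::local_seed(61)
  true <- ape::rtree(6, rooted = FALSE)
  true$node.label <- c("", "97", "54", "100")
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(true, f)
  back <- read_newick(f)
  expect_same_topology(true, back)
  expect_equal(sort(back$edge.length), sort(true$edge.length), tolerance = 1e-9)
  expect_setequal(back$node.label, true$node.label)

  # two-taxon tree shape
  D <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  write_newick(neighbor_joining(D), f)
  expect_match(readLines(f), "^\\(A:0.2,B:0.2\\);$")
})

test_that("distance matrices support complete deletion as an alternative", {
  msa <- tibble::tibble(id = c("a", "b", "c"),
                        aligned = c("AR-DC", "ARN-C", "ARNDC"))
  Dp <- msa_distances(msa, method = "p", gap_handling = "pairwise")
  Dc <- msa_distances(msa, method = "p", gap_handling = "complete")
  expect_equal(as.numeric(Dc), rep(0, 3)) # only the agreeing columns remain
  expect_true(all(as.matrix(Dp) >= 0))
})
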