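test_that("progressive alignment: identical inputs give a gap-free
           alignment, a single insertion gives one gap run", {
  set.seed(41)
  s <- random_dna(120)
  aln <- align_progressive(c(a = s, b = s, c = s))
  expect_false(any(grepl("-", aln$seqs)))
  expect_equal(alignment_length(aln), 120L)

  ## one sequence with a 3-nt insertion: exactly one 3-column gap run in
  ## the other row
  ins <- paste0(substr(s, 1, 60), "GGG", substr(s, 61, 120))
  aln2 <- align_progressive(c(a = s, b = ins))
  expect_equal(alignment_length(aln2), 123L)
  gaps <- gregexpr("-+", aln2$seqs[["a"]])[[1]]
  expect_equal(length(gaps), 1L)
  expect_equal(attr(gaps, "match.length"), 3L)
  expect_false(grepl("-", aln2$seqs[["b"]]))

  ## alignment length never shrinks below the longest input
  pan <- small_panel()
  th <- pan$sequences[grepl("THCAS", names(pan$sequences))]
  aln3 <- align_progressive(th)
  expect_gte(alignment_length(aln3), max(nchar(th)))
  expect_error(align_progressive(c(a = "ACGT")), "at least two")
})

test_that("concatenation is column-wise with recoverable partitions", {
  a <- new_alignment(c(x = "ACGTACGTAC", y = "ACGTACGTAC"))
  b <- new_alignment(c(x = "TTTTTTTTTT", y = "TTTTCTTTTT"))
  cc <- concatenate_alignments(list(g1 = a, g2 = b))
  expect_equal(alignment_length(cc), 20L)
  expect_equal(alignment_partition(cc, "g1")$seqs[["x"]], a$seqs[["x"]])
  expect_equal(alignment_partition(cc, "g2")$seqs[["y"]], b$seqs[["y"]])
  ## missing sample: error by default, gap fill on request
  b2 <- new_alignment(c(x = "TTTTTTTTTT"))
  expect_error(concatenate_alignments(list(g1 = a, g2 = b2)), "absent")
  filled <- concatenate_alignments(list(g1 = a, g2 = b2), gap_fill = TRUE)
  expect_equal(substr(filled$seqs[["y"]], 11, 20), "----------")
})

test_that("JC69 distances match the closed form and an independent
           implementation", {
  ## identical rows
  aln0 <- new_alignment(c(a = "ACGTACGTAC", b = "ACGTACGTAC"))
  expect_equal(unname(jc69_distance(aln0)["a", "b"]), 0)

  ## p = 0.10 over 100 columns
  s <- strrep("ACGT", 25)
  t <- s
  for (i in seq(1, 37, 4)) substr(t, i, i) <- "G"  # 10 mismatches
  aln <- new_alignment(c(a = s, b = t))
  d <- jc69_distance(aln)
  expect_equal(unname(d["a", "b"]), -0.75 * log(1 - 4 * 0.1 / 3),
               tolerance = 1e-9)
  expect_equal(unname(d["a", "b"]), 0.1073256, tolerance = 1e-6)
  ## independent route: ape on the same alignment
  bin <- ape::as.DNAbin(strsplit(tolower(c(a = s, b = t)), ""))
  expect_equal(unname(d["a", "b"]),
               unname(as.matrix(ape::dist.dna(bin, model = "JC69"))["a", "b"]),
               tolerance = 1e-9)

  ## saturated pair: capped and flagged
  sat <- new_alignment(c(a = strrep("A", 40), b = strrep("C", 40)))
  ds <- jc69_distance(sat, saturation_cap = 5)
  expect_equal(unname(ds["a", "b"]), 5)
  expect_true(attr(ds, "saturated")["a", "b"])

  ## zero overlap: error naming the pair unless explicitly allowed
  z <- new_alignment(c(a = "ACGT----", b = "----ACGT"))
  expect_error(jc69_distance(z), "a.*b")
  dz <- jc69_distance(z, allow_zero_overlap = TRUE)
  expect_equal(unname(dz["a", "b"]), 5)
})

test_that("neighbor joining recovers additive matrices exactly", {
  ## fixed 4-taxon additive matrix from tree ((A:1,B:2):1,(C:3,D:1));
  D <- matrix(c(0, 3, 5, 3,
                3, 0, 6, 4,
                5, 6, 0, 4,
                3, 4, 4, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"),
                              c("A", "B", "C", "D")))
  tr <- nj_tree(D)
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  expect_equal(as.matrix(stats::cophenetic(tr))[rownames(D), colnames(D)],
               D, tolerance = 1e-9)
  expect_true(has_clade(tr, c("A", "B")))

  ## random additive matrices from random trees
  set.seed(53)
  for (n in c(5, 8, 12)) {
    gen <- ape::rtree(n, rooted = FALSE)
    gen$edge.length <- runif(nrow(gen$edge), 0.05, 1)
    Dm <- as.matrix(stats::cophenetic(gen))
    rec <- nj_tree(Dm)
    expect_setequal(oracle_split_keys(rec), oracle_split_keys(gen))
    expect_equal(as.matrix(stats::cophenetic(rec))[rownames(Dm), rownames(Dm)],
                 Dm, tolerance = 1e-8)
  }
})

test_that("neighbor joining agrees with ape's implementation on random
           (non-additive) matrices and validates its input", {
  set.seed(59)
  for (rep in 1:5) {
    n <- sample(5:10, 1)
    M <- matrix(runif(n * n, 0.1, 2), n, n)
    D <- (M + t(M)) / 2; diag(D) <- 0
    dimnames(D) <- list(letters[1:n], letters[1:n])
    mine <- nj_tree(D)
    apes <- ape::nj(D)
    expect_setequal(oracle_split_keys(mine), oracle_split_keys(apes))
  }
  ## three taxa: the unique unrooted topology
  D3 <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(D3)
  expect_equal(length(t3$tip.label), 3L)
  expect_equal(length(bipartitions(t3)), 0L)
  bad <- D3; bad[1, 2] <- 5
  expect_error(nj_tree(bad), "asymmetric")
  expect_error(nj_tree(D3[1:2, 1:2]), "at least 3")
})

test_that("trees survive a Newick round trip with identical splits", {
  pan <- small_panel()
  aln <- align_progressive(pan$sequences[grepl("THCAS",
                                               names(pan$sequences))])
  tr <- nj_tree(jc69_distance(aln))
  nwk <- ape::write.tree(tr)
  back <- ape::read.tree(text = nwk)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_setequal(oracle_split_keys(back), oracle_split_keys(tr))
})

test_that("bootstrap support is seeded, reproducible, and {0,1}-valued at
           a single replicate", {
  pan <- small_panel()
  aln <- align_progressive(pan$sequences[grepl("THCAS",
                                               names(pan$sequences))])
  b1 <- bootstrap_support(aln, n_replicates = 20, seed = 7)
  b2 <- bootstrap_support(aln, n_replicates = 20, seed = 7)
  expect_identical(b1$support, b2$support)
  expect_identical(b1$replicate_splits, b2$replicate_splits)
  one <- bootstrap_support(aln, n_replicates = 1, seed = 9)
  expect_true(all(one$support %in% c(0, 1)))
})

test_that("pooled gene-copy alignments keep rows disjoint and partitions
           addressable", {
  a <- new_alignment(c("x|g1" = "ACGT", "y|g1" = "ACGA"))
  b <- new_alignment(c("x|g2" = "TTTTT", "y|g2" = "TTTCT"))
  pooled <- pool_alignments(list(g1 = a, g2 = b))
  expect_equal(alignment_length(pooled), 9L)
  expect_equal(pooled$seqs[["x|g1"]], "ACGT-----")
  expect_equal(pooled$seqs[["y|g2"]], "----TTTCT")
  expect_error(pool_alignments(list(g1 = a, g2 = a)), "disjoint")
})
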