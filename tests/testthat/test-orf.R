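test_that("translation stops at the first stop codon and matches the
           standard genetic code", {
  expect_equal(translate_cds("ATGGCTTAA")$protein, "MA")
  expect_equal(translate_cds("ATGTGA")$protein, "M")
  set.seed(31)
  orf <- oracle_random_orf(60)
  body <- substr(orf, 1, 177)           # strip terminal stop
  tr <- translate_cds(body)
  expect_equal(nchar(tr$protein), 59L)
  expect_true(is.na(tr$first_stop))
  ## cross-check against Biostrings on random coding sequences
  for (i in 1:5) {
    cds <- oracle_random_orf(sample(20:80, 1))
    mine <- translate_cds(cds)
    bs <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_equal(paste0(mine$protein, "*"), bs)
  }
  part <- translate_cds("ATGGCTTA")
  expect_true(part$partial_codon)
  expect_equal(part$protein, "MA")
  expect_error(translate_cds("ATGX"), "A/C/G/T")
  expect_error(translate_cds("AT"), "codon")
})

test_that("pairwise aligner matches the exhaustive affine-gap DP oracle
           on short sequences", {
  set.seed(17)
  for (rep in 1:12) {
    a <- random_dna(sample(10:50, 1))
    b <- random_dna(sample(10:50, 1))
    for (type in c("overlap", "global")) {
      got <- pairwise_align(a, b, type = type)$score
      want <- oracle_gotoh(a, b, type = type)
      expect_equal(got, want, info = paste(type, a, b))
    }
  }
  ## related pair with a known indel: score and gap structure
  a <- random_dna(40)
  b <- paste0(substr(a, 1, 18), substr(a, 22, 40))
  aln <- pairwise_align(a, b, type = "global")
  expect_equal(aln$score, oracle_gotoh(a, b, type = "global"))
  expect_equal(nchar(gsub("[^-]", "", aln$b_aligned)), 3L)
})

test_that("integrity assessment: identity, frameshift deletion, premature
           stop", {
  set.seed(23)
  ref <- oracle_random_orf(200)
  self <- assess_integrity(ref, ref)
  expect_true(self$full_length)
  expect_equal(self$activity_call, "active")
  expect_false(self$frameshift)

  ## 4-nt deletion at position 153
  del4 <- paste0(substr(ref, 1, 152), substr(ref, 157, nchar(ref)))
  r4 <- assess_integrity(del4, ref)
  expect_true(r4$frameshift)
  expect_equal(r4$activity_call, "inactive")
  expect_equal(r4$indels$length, 4L)
  expect_true(r4$indels$in_sample)

  ## point mutation creating a stop at 60 % of the CDS
  stop_codon <- 120L
  mut <- ref
  substr(mut, 3 * stop_codon - 2, 3 * stop_codon) <- "TAA"
  rs <- assess_integrity(mut, ref)
  expect_false(rs$frameshift)
  expect_false(rs$full_length)
  expect_equal(rs$activity_call, "inactive")
  ## verify the reported stop position by scanning codons naively
  codons <- substring(mut, seq(1, nchar(mut), 3), seq(3, nchar(mut), 3))
  expect_equal(rs$first_stop, min(which(codons %in% c("TAA", "TAG", "TGA"))))
  expect_equal(rs$first_stop, stop_codon)
  expect_error(assess_integrity("", ref), "empty")
})

test_that("frameshift fires exactly for non-multiple-of-3 deletions", {
  set.seed(29)
  ref <- oracle_random_orf(150)
  for (len in c(1L, 2L, 3L, 4L, 5L, 6L, 9L)) {
    for (at in c(90L, 201L, 300L)) {
      del <- paste0(substr(ref, 1, at - 1), substr(ref, at + len, nchar(ref)))
      r <- assess_integrity(del, ref)
      expect_equal(r$frameshift, len %% 3L != 0L,
                   info = paste("len", len, "at", at))
    }
  }
})

test_that("integrity table reproduces the four activity groups on a
           synthetic panel", {
  pan <- small_panel()
  it <- integrity_table(pan$sequences, pan$references)
  it <- merge(it, pan$samples[c("sample_id", "true_chemotype")])
  expect_true(all(it$activity_call[it$gene == "THCAS" &
                                   it$true_chemotype %in% c("I", "II")] ==
                  "active"))
  expect_true(all(it$activity_call[it$gene == "THCAS" &
                                   it$true_chemotype == "III"] ==
                  "inactive"))
  expect_true(all(it$activity_call[it$gene == "CBDAS" &
                                   it$true_chemotype %in% c("II", "III")] ==
                  "active"))
  expect_true(all(it$activity_call[it$gene == "CBDAS" &
                                   it$true_chemotype == "I"] == "inactive"))
})
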