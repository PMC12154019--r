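test_that("a primer identical to a template substring binds exactly there", {
  set.seed(5)
  tmpl <- random_dna(300)
  p <- substr(tmpl, 101, 122)
  sites <- find_binding_sites(tmpl, p)
  plus <- sites[sites$strand == "+", ]
  expect_equal(plus$start, 101)
  expect_equal(plus$end, 122)
  expect_equal(plus$three_prime, 122)
})

test_that("binding-site scan agrees with the exhaustive all-offsets,
           all-strands oracle", {
  set.seed(12)
  for (rep in 1:8) {
    tmpl <- random_dna(sample(200:500, 1))
    ## primers: exact, mutated, reverse-complemented, degenerate
    base <- substr(tmpl, 51, 70)
    primers <- c(base,
                 local({ p <- base; substr(p, 7, 7) <- "N"; p }),
                 oracle_revcomp(substr(tmpl, 120, 141)),
                 random_dna(20))
    for (p in primers) {
      got <- find_binding_sites(tmpl, p)
      want <- oracle_binding_sites(tmpl, p)
      expect_equal(got[c("start", "end", "strand")],
                   want[order(want$start, want$strand), ],
                   ignore_attr = TRUE)
    }
  }
})

test_that("ARMS stringency: 3' mismatch refuses, one internal mismatch
           does not", {
  set.seed(3)
  tmpl <- random_dna(400)
  p <- substr(tmpl, 201, 220)           # 20-mer, 10 % = 2 internal allowed
  internal <- p
  substr(internal, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                    substr(p, 5, 5))[1]
  expect_equal(nrow(find_binding_sites(tmpl, internal)), 1L)
  terminal <- p
  substr(terminal, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                      substr(p, 20, 20))[1]
  plus <- subset(find_binding_sites(tmpl, terminal), strand == "+")
  expect_equal(nrow(plus), 0L)
  ## three internal mismatches exceed the 10 % budget
  many <- p
  for (i in c(3, 8, 12))
    substr(many, i, i) <- setdiff(c("A", "C", "G", "T"),
                                  substr(p, i, i))[1]
  expect_equal(nrow(find_binding_sites(tmpl, many)), 0L)
})

test_that("toggling the template base under the primer 3' end toggles the
           band for every allele-specific pair", {
  fx <- make_reference_fixtures()
  snp <- c(THCASd = 1349L, CBDASf = 645L)
  for (nm in names(snp)) {
    pair <- fx$assay[[nm]]
    tmpl <- fx$sequences[[paste0(pair$gene, "_active")]]
    expect_true(nrow(amplify(tmpl, pair)) > 0)
    toggled <- tmpl
    cur <- substr(toggled, snp[nm], snp[nm])
    substr(toggled, snp[nm], snp[nm]) <- if (cur == "G") "T" else "G"
    expect_equal(nrow(amplify(toggled, pair)), 0L)
  }
})

test_that("amplification respects orientation, size cap and template
           reverse-complementation", {
  fx <- make_reference_fixtures()
  pair <- fx$assay$THCASint
  tmpl <- fx$sequences[["THCAS_active"]]
  ## reverse-complementing the template leaves product lengths unchanged
  expect_equal(sort(amplify(revcomp(tmpl), pair)$length),
               sort(amplify(tmpl, pair)$length))
  ## divergent-only orientation gives nothing: a pair of two identical
  ## plus-strand primers has no minus-strand site
  fwd_only <- primer_pair("divergent", pair$forward, pair$forward,
                          gene = "THCAS", role = "internal_control",
                          expected_size = 291)
  expect_equal(nrow(amplify(tmpl, fwd_only)), 0L)
  ## size cap
  expect_equal(nrow(amplify(tmpl, pair, max_product_len = 100)), 0L)
  ## primer longer than template: empty, not an error
  expect_equal(nrow(find_binding_sites("ACGTACGTACGTACGTACGT",
                                       paste(rep("ACGT", 10), collapse = ""))),
               0L)
})

test_that("run_assay produces the published per-chemotype band patterns", {
  pan <- small_panel()
  bands <- band_table(pan$sequences, pan$assay)
  rows <- merge(bands, pan$samples[c("sample_id", "true_chemotype")])
  drug <- rows[rows$true_chemotype == "I", ]
  expect_true(all(drug$THCASd & drug$THCASint & !drug$CBDASf &
                  drug$CBDASint))
  inter <- rows[rows$true_chemotype == "II", ]
  expect_true(all(inter$THCASd & inter$THCASint & inter$CBDASf &
                  inter$CBDASint))
  fiber <- rows[rows$true_chemotype == "III", ]
  expect_true(all(!fiber$THCASd & fiber$THCASint & fiber$CBDASf &
                  fiber$CBDASint))
})

test_that("a missing gene gives absent bands plus a QC flag", {
  pan <- small_panel()
  one <- pan$sequences["S001|THCAS"]
  r <- run_assay(c(THCAS = unname(one)), pan$assay)
  expect_false(r$bands[["CBDASf"]])
  expect_false(r$bands[["CBDASint"]])
  expect_true("missing_CBDAS" %in% r$flags)
  empty <- run_assay(character(0), pan$assay)
  expect_true(all(!empty$bands))
  expect_setequal(empty$flags, c("missing_THCAS", "missing_CBDAS"))
})

test_that("allele-specificity validator reports discrimination and
           cross-template binding", {
  fx <- make_reference_fixtures()
  p <- fx$assay$THCASd$forward
  r <- validate_allele_specificity(p, fx$sequences[["THCAS_active"]],
                                   fx$sequences[["THCAS_inactive"]])
  expect_true(r$binds_active); expect_false(r$binds_inactive)
  expect_true(r$discriminating)
  same <- validate_allele_specificity(p, fx$sequences[["THCAS_active"]],
                                      fx$sequences[["THCAS_active"]])
  expect_true("non_discriminating" %in% same$flags)
  ## cross-species emulation: no binding on unrelated random sequences
  set.seed(77)
  hits <- vapply(1:10, function(i) {
    nrow(find_binding_sites(random_dna(2000), p)) > 0
  }, TRUE)
  expect_gte(sum(!hits), 9)
})
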