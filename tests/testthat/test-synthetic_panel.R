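test_that("same config and seed give byte-identical panels", {
  cfg <- panel_config(n_drug = 3, n_intermediate = 2, n_fiber = 2, seed = 1)
  expect_identical(make_panel(cfg), make_panel(cfg))
  ## and the generator leaves the caller's RNG stream untouched
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(make_panel(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("panel honours the configured composition and truth coding", {
  pan <- small_panel()
  expect_equal(nrow(pan$samples), 7L)
  expect_equal(as.integer(table(pan$samples$true_chemotype)[c("I", "II", "III")]),
               c(3L, 2L, 2L))
  map <- c(I = "Td", II = "TD", III = "tD")
  expect_equal(pan$samples$truth_genotype,
               unname(map[pan$samples$true_chemotype]))
  expect_false(any(grepl("[^ACGT]", pan$sequences)))
})

test_that("cannabinoid draws stay inside ranges and classes are separable
           at the fixed cutoffs", {
  pan <- small_panel()
  cfg <- pan$config
  lr <- compute_log_ratio(pan$samples$pct_thc, pan$samples$pct_cbd)
  for (i in seq_len(nrow(pan$samples))) {
    cls <- pan$samples$true_chemotype[i]
    expect_gte(pan$samples$pct_thc[i], cfg$thc_range[[cls]][1])
    expect_lte(pan$samples$pct_thc[i], cfg$thc_range[[cls]][2])
    expect_gte(pan$samples$pct_cbd[i], cfg$cbd_range[[cls]][1])
    expect_lte(pan$samples$pct_cbd[i], cfg$cbd_range[[cls]][2])
  }
  expect_true(all(lr[pan$samples$true_chemotype == "I"] > 0))
  expect_true(all(lr[pan$samples$true_chemotype == "III"] < -1))
  expect_true(all(lr[pan$samples$true_chemotype == "II"] > -1 &
                  lr[pan$samples$true_chemotype == "II"] < 0))
})

test_that("configuration guard rejects inseparable or malformed setups", {
  expect_error(panel_config(n_drug = -1), "non-negative")
  expect_error(panel_config(log_ratio_band = list(I = c(-0.5, 2),
                                                  II = c(-0.58, -0.1),
                                                  III = c(-1.61, -1.09))),
               "above 0")
  expect_error(panel_config(log_ratio_band = list(I = c(0.76, 3.14),
                                                  II = c(-0.58, -0.1),
                                                  III = c(-1.61, -0.9))),
               "below -1")
  expect_error(panel_config(thc_range = list(I = c(3, 2), II = c(0.5, 3.7),
                                             III = c(0.06, 0.15))),
               "invalid content range")
  expect_error(panel_config(frameshift_len = 5), "4 or 6")
  expect_warning(panel_config(frameshift_len = 6), "in frame")
  expect_error(panel_config(seq_length_thcas = 1500), "too short")
})

test_that("reference fixtures reproduce the four published band sizes and
           the ARMS no-band on the other allele", {
  fx <- make_reference_fixtures()
  sizes <- c(THCASd = 384L, THCASint = 291L, CBDASf = 346L, CBDASint = 169L)
  for (nm in names(sizes)) {
    pair <- fx$assay[[nm]]
    active <- fx$sequences[[paste0(pair$gene, "_active")]]
    inactive <- fx$sequences[[paste0(pair$gene, "_inactive")]]
    expect_equal(amplify(active, pair)$length, unname(sizes[nm]))
    if (pair$role == "target") {
      expect_equal(nrow(amplify(inactive, pair)), 0L)
    } else {
      expect_equal(amplify(inactive, pair)$length, unname(sizes[nm]))
    }
  }
})

test_that("restoring the frameshift deletion recovers a full-length CBDAS
           translation", {
  pan <- small_panel()
  cfg <- pan$config
  drug <- pan$samples$sample_id[pan$samples$true_chemotype == "I"][1]
  cds <- pan$sequences[[paste0(drug, "|CBDAS")]]
  ref <- pan$references[["CBDAS"]]
  before <- assess_integrity(cds, ref)
  expect_true(before$frameshift)
  expect_equal(before$activity_call, "inactive")
  fs <- cfg$frameshift_pos_cbdas
  restored <- paste0(substr(cds, 1, fs - 1),
                     substr(ref, fs, fs + cfg$frameshift_len - 1),
                     substr(cds, fs, nchar(cds)))
  after <- assess_integrity(restored, ref)
  expect_false(after$frameshift)
  expect_true(after$full_length)
  expect_equal(after$activity_call, "active")
})

test_that("panel round-trips through plain-text files", {
  pan <- small_panel()
  dir <- withr::local_tempdir()
  write_panel(pan, dir)
  expect_true(all(file.exists(file.path(
    dir, c("cannabinoids.csv", "truth.csv", "sequences.fasta",
           "assay.yaml")))))
  rec <- read_cannabinoid_table(file.path(dir, "cannabinoids.csv"))
  expect_equal(rec$sample_id, pan$samples$sample_id)
  expect_equal(rec$pct_thc, pan$samples$pct_thc, tolerance = 1e-6)
  assay <- read_assay(file.path(dir, "assay.yaml"))
  expect_s3_class(assay, "assay_definition")
  expect_equal(vapply(assay, `[[`, 0L, "expected_size"),
               vapply(pan$assay, `[[`, 0L, "expected_size"))
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "sequences.fasta"))
  expect_equal(length(seqs), length(pan$sequences))
  ## the re-read assay still amplifies the re-read sequences
  bands <- band_table(seqs, assay)
  expect_true(all(bands$THCASint) && all(bands$CBDASint))
})
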