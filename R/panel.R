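## ---- fixed assay geometry -------------------------------------------------
## Primer footprints (1-based, plus strand) on the engineered reference
## CDSs.  Chosen so the four bands come out at the published sizes:
##   THCASd   1330..1713  -> 384 nt (allele-specific 3' base at 1349)
##   THCASint  301..591   -> 291 nt
##   CBDASf    626..971   -> 346 nt (allele-specific 3' base at 645)
##   CBDASint 1201..1369  -> 169 nt
PCR_COORDS <- list(
  THCAS = list(
    d_fwd = c(1330L, 1349L), d_rev = c(1694L, 1713L),
    int_fwd = c(301L, 320L), int_rev = c(572L, 591L)),
  CBDAS = list(
    f_fwd = c(626L, 645L), f_rev = c(952L, 971L),
    int_fwd = c(1201L, 1220L), int_rev = c(1350L, 1369L))
)

STOP_CODONS <- c("TAA", "TAG", "TGA")
BASES <- c("A", "C", "G", "T")

## random stop-free ORF: ATG ... TAA with no internal stop codon
random_orf <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  nonstop <- setdiff(
    as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0)),
    STOP_CODONS)
  body <- sample(nonstop, len / 3L - 2L, replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}

## set one base; if that makes the containing codon a stop, repair another
## base of the same codon (set to C, which no stop codon contains)
set_base_safe <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  c0 <- ((pos - 1L) %/% 3L) * 3L + 1L
  if (substr(seq, c0, c0 + 2L) %in% STOP_CODONS) {
    fix <- setdiff(c0:(c0 + 2L), pos)[1L]
    substr(seq, fix, fix) <- "C"
  }
  seq
}

## expand a window to whole-codon boundaries
codon_window <- function(start, end) {
  c(((start - 1L) %/% 3L) * 3L + 1L, ceiling(end / 3L) * 3L)
}

#' Engineered reference sequences and marker assay
#'
#' Returns a fixed (non-random) set of active and inactive THCAS and
#' CBDAS reference coding sequences plus the four-primer-pair marker
#' assay, engineered so that in-silico amplification on the matching
#' templates reproduces the published band sizes exactly: THCASd 384 nt,
#' CBDASf 346 nt, THCASint 291 nt, CBDASint 169 nt.
#'
#' The allele conventions are arbitrary but consistent everywhere in the
#' package: at THCAS CDS position 1349 the active allele is G (inactive
#' T); at CBDAS position 645 the active allele is C (inactive G).  The
#' inactive THCAS additionally carries a premature stop at 60 percent of
#' its CDS; the inactive CBDAS carries a 4-nt frameshift deletion at
#' position 153.  The allele-specific forward primers end (3') exactly on
#' the SNP, so a template carrying the other allele gives no band.
#'
#' @return list with `sequences` (named character vector: `THCAS_active`,
#'   `THCAS_inactive`, `CBDAS_active`, `CBDAS_inactive`), `assay` (an
#'   `assay_definition` of four [primer_pair()]s) and `references`
#'   (active CDS per gene, for integrity analysis).
#' @export
make_reference_fixtures <- function() {
  seqs <- local_seed(101L, {
    thcas <- random_orf(1800L)
    cbdas <- random_orf(1632L)
    list(thcas = thcas, cbdas = cbdas)
  })
  thcas_a <- set_base_safe(seqs$thcas, 1349L, "G")
  cbdas_a <- set_base_safe(seqs$cbdas, 645L, "C")

  ## inactive THCAS: other allele + premature stop at codon 360 (60 %)
  thcas_i <- set_base_safe(thcas_a, 1349L, "T")
  substr(thcas_i, 1078L, 1080L) <- "TAA"
  ## inactive CBDAS: other allele + 4-nt deletion at position 153
  cbdas_i <- set_base_safe(cbdas_a, 645L, "G")
  cbdas_i <- paste0(substr(cbdas_i, 1L, 152L),
                    substr(cbdas_i, 157L, nchar(cbdas_i)))

  sub <- function(s, w) substr(s, w[1L], w[2L])
  co <- PCR_COORDS
  assay <- structure(list(
    THCASd = primer_pair(
      "THCASd",
      primer("THCASd_F", sub(thcas_a, co$THCAS$d_fwd),
             allele_specific = TRUE,
             note = "3' base on THCAS position 1349 (active allele G)"),
      primer("THCASd_R", revcomp(sub(thcas_a, co$THCAS$d_rev))),
      gene = "THCAS", role = "target", expected_size = 384L),
    THCASint = primer_pair(
      "THCASint",
      primer("THCASint_F", sub(thcas_a, co$THCAS$int_fwd)),
      primer("THCASint_R", revcomp(sub(thcas_a, co$THCAS$int_rev))),
      gene = "THCAS", role = "internal_control", expected_size = 291L),
    CBDASf = primer_pair(
      "CBDASf",
      primer("CBDASf_F", sub(cbdas_a, co$CBDAS$f_fwd),
             allele_specific = TRUE,
             note = "3' base on CBDAS position 645 (active allele C)"),
      primer("CBDASf_R", revcomp(sub(cbdas_a, co$CBDAS$f_rev))),
      gene = "CBDAS", role = "target", expected_size = 346L),
    CBDASint = primer_pair(
      "CBDASint",
      primer("CBDASint_F", sub(cbdas_a, co$CBDAS$int_fwd)),
      primer("CBDASint_R", revcomp(sub(cbdas_a, co$CBDAS$int_rev))),
      gene = "CBDAS", role = "internal_control", expected_size = 169L)
  ), class = "assay_definition")

  list(sequences = c(THCAS_active = thcas_a, THCAS_inactive = thcas_i,
                     CBDAS_active = cbdas_a, CBDAS_inactive = cbdas_i),
       assay = assay,
       references = c(THCAS = thcas_a, CBDAS = cbdas_a))
}

#' Configuration of a synthetic panel
#'
#' Describes the statistical and genetic structure of a generated panel.
#' Defaults reproduce the composition of the 85-sample reference study
#' (70 drug / 11 intermediate / 4 fiber) with per-chemotype cannabinoid
#' ranges and log-ratio bands read from its published table.
#'
#' Cannabinoid contents are drawn by first sampling the log10(THC/CBD)
#' ratio uniformly from the chemotype's `log_ratio_band` and then sampling
#' \%THC uniformly from the part of its range compatible with that ratio
#' and the \%CBD range; this keeps every draw inside the configured ranges
#' while guaranteeing the three classes stay linearly separable at the
#' fixed cutoffs (0, -1) — which the configuration validator enforces.
#'
#' @param n_drug,n_intermediate,n_fiber sample counts per chemotype.
#' @param thc_range,cbd_range named lists (`I`, `II`, `III`) of
#'   `c(min, max)` percent w/w intervals.
#' @param log_ratio_band named list of `c(min, max)` log10-ratio bands per
#'   chemotype.
#' @param seq_length_thcas,seq_length_cbdas CDS lengths in nucleotides
#'   (multiples of 3; at least 1716 / 1374 so the fixed assay geometry
#'   fits).
#' @param snp_pos_thcas,snp_pos_cbdas 1-based CDS coordinates of the
#'   discriminating SNPs (defaults 1349 and 645).
#' @param active_allele_thcas,active_allele_cbdas active-allele bases
#'   (defaults G and C); the inactive allele is T and G respectively.
#' @param frameshift_pos_cbdas,frameshift_len 1-based position and length
#'   (4 or 6 nt) of the deletion inactivating drug-type CBDAS.  A 6-nt
#'   deletion is in frame and triggers a warning since it cannot cause a
#'   frameshift.
#' @param premature_stop_frac fraction of the THCAS CDS at which the
#'   fiber-type premature stop codon is placed (default 0.60).
#' @param allele_divergence per-site rate of fixed substitutions
#'   separating the inactive from the active haplotype of each gene
#'   (default 0.01).  Inactive synthase alleles are diverged lineages,
#'   not point mutants of the active allele; this is what makes the
#'   active/inactive groups deep, well-supported clades.
#' @param background_mutation_rate per-site substitution probability
#'   applied per sample outside functional/primer windows (default
#'   0.001).
#' @param seed integer; fully determines the panel.
#' @return an object of class `panel_config`.
#' @export
panel_config <- function(n_drug = 70, n_intermediate = 11, n_fiber = 4,
                         thc_range = list(I = c(0.1, 3.7),
                                          II = c(0.5, 3.7),
                                          III = c(0.06, 0.15)),
                         cbd_range = list(I = c(0.001, 0.16),
                                          II = c(1.3, 6.5),
                                          III = c(0.86, 3.0)),
                         log_ratio_band = list(I = c(0.76, 3.14),
                                               II = c(-0.58, -0.10),
                                               III = c(-1.61, -1.09)),
                         seq_length_thcas = 1800, seq_length_cbdas = 1632,
                         snp_pos_thcas = 1349, snp_pos_cbdas = 645,
                         active_allele_thcas = "G",
                         active_allele_cbdas = "C",
                         frameshift_pos_cbdas = 153, frameshift_len = 4,
                         premature_stop_frac = 0.60,
                         allele_divergence = 0.01,
                         background_mutation_rate = 0.001,
                         seed = 1L) {
  cfg <- list(n_drug = as.integer(n_drug),
              n_intermediate = as.integer(n_intermediate),
              n_fiber = as.integer(n_fiber),
              thc_range = thc_range, cbd_range = cbd_range,
              log_ratio_band = log_ratio_band,
              seq_length_thcas = as.integer(seq_length_thcas),
              seq_length_cbdas = as.integer(seq_length_cbdas),
              snp_pos_thcas = as.integer(snp_pos_thcas),
              snp_pos_cbdas = as.integer(snp_pos_cbdas),
              active_allele_thcas = active_allele_thcas,
              active_allele_cbdas = active_allele_cbdas,
              frameshift_pos_cbdas = as.integer(frameshift_pos_cbdas),
              frameshift_len = as.integer(frameshift_len),
              premature_stop_frac = premature_stop_frac,
              allele_divergence = allele_divergence,
              background_mutation_rate = background_mutation_rate,
              seed = as.integer(seed))

  with(cfg, {
    if (any(c(n_drug, n_intermediate, n_fiber) < 0))
      stop("sample counts must be non-negative", call. = FALSE)
    for (cls in c("I", "II", "III")) {
      for (rng in list(thc_range[[cls]], cbd_range[[cls]])) {
        if (is.null(rng) || length(rng) != 2L || rng[1] > rng[2] ||
            rng[1] <= 0)
          stop("invalid content range for chemotype ", cls, call. = FALSE)
      }
      b <- log_ratio_band[[cls]]
      if (is.null(b) || length(b) != 2L || b[1] > b[2])
        stop("invalid log_ratio_band for chemotype ", cls, call. = FALSE)
    }
    ## separability guard at the fixed cutoffs (0, -1)
    if (log_ratio_band$I[1] <= 0)
      stop("drug-type log-ratio band must stay above 0", call. = FALSE)
    if (log_ratio_band$III[2] >= -1)
      stop("fiber-type log-ratio band must stay below -1", call. = FALSE)
    if (log_ratio_band$II[1] <= -1 || log_ratio_band$II[2] >= 0)
      stop("intermediate log-ratio band must lie inside (-1, 0)",
           call. = FALSE)
    ## a ratio draw anywhere in the band must leave a non-empty THC window
    for (cls in c("I", "II", "III")) {
      for (r in seq(log_ratio_band[[cls]][1], log_ratio_band[[cls]][2],
                    length.out = 25)) {
        lo <- max(thc_range[[cls]][1], cbd_range[[cls]][1] * 10^r)
        hi <- min(thc_range[[cls]][2], cbd_range[[cls]][2] * 10^r)
        if (lo > hi)
          stop("chemotype ", cls, " ranges incompatible with log-ratio ",
               round(r, 3), call. = FALSE)
      }
    }
    if (seq_length_thcas %% 3L != 0L || seq_length_cbdas %% 3L != 0L)
      stop("sequence lengths must be multiples of 3", call. = FALSE)
    if (seq_length_thcas < 1716L || seq_length_cbdas < 1374L)
      stop("sequence lengths too short for the fixed assay geometry",
           call. = FALSE)
    if (snp_pos_thcas > seq_length_thcas || snp_pos_cbdas > seq_length_cbdas)
      stop("SNP position outside the CDS", call. = FALSE)
    if (!frameshift_len %in% c(4L, 6L))
      stop("frameshift_len must be 4 or 6", call. = FALSE)
    if (allele_divergence < 0 || allele_divergence > 0.2 ||
        background_mutation_rate < 0 || background_mutation_rate > 0.2)
      stop("substitution rates must lie in [0, 0.2]", call. = FALSE)
    if (frameshift_len == 6L)
      warning("a 6-nt deletion is in frame and does not shift the ",
              "reading frame", call. = FALSE)
  })
  structure(cfg, class = "panel_config")
}

## masked windows (codon-expanded) where no background substitution may land
masked_positions <- function(gene, len, cfg) {
  co <- PCR_COORDS[[gene]]
  wins <- lapply(co, function(w) codon_window(w[1L], w[2L]))
  wins <- c(wins, list(start = c(1L, 3L), stop = c(len - 2L, len)))
  if (gene == "THCAS") {
    stop_codon <- floor(cfg$premature_stop_frac * (len %/% 3L))
    wins <- c(wins,
              list(snp = codon_window(cfg$snp_pos_thcas, cfg$snp_pos_thcas),
                   pstop = c(3L * stop_codon - 2L, 3L * stop_codon)))
  } else {
    fs <- c(cfg$frameshift_pos_cbdas,
            cfg$frameshift_pos_cbdas + cfg$frameshift_len - 1L)
    wins <- c(wins,
              list(snp = codon_window(cfg$snp_pos_cbdas, cfg$snp_pos_cbdas),
                   fs = codon_window(fs[1L], fs[2L])))
  }
  masked <- logical(len)
  for (w in wins) masked[w[1L]:min(w[2L], len)] <- TRUE
  masked
}

## seeded background substitutions outside masked sites, never creating an
## in-frame stop codon
background_substitute <- function(seq, rate, masked) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  hits <- which(stats::runif(n) < rate & !masked)
  for (pos in hits) {
    cur <- substr(seq, pos, pos)
    cand <- sample(setdiff(BASES, cur))
    c0 <- ((pos - 1L) %/% 3L) * 3L + 1L
    codon <- substr(seq, c0, c0 + 2L)
    off <- pos - c0 + 1L
    for (b in cand) {
      trial <- codon
      substr(trial, off, off) <- b
      if (!trial %in% STOP_CODONS) {
        substr(seq, pos, pos) <- b
        break
      }
    }
  }
  seq
}

#' Generate a synthetic chemotype/genotype panel
#'
#' Produces a self-consistent panel: per-sample cannabinoid contents
#' drawn inside the configured per-chemotype ranges, THCAS and CBDAS
#' coding sequences carrying the allelic structure that produces those
#' chemotypes, and the ground-truth labels.  Sequences of each gene
#' descend from a shared random ancestral CDS (re-drawn per panel seed)
#' whose functional positions and primer footprints are fixed to the
#' engineered reference of [make_reference_fixtures()], so the packaged
#' assay amplifies every panel.  Genetic structure per chemotype:
#'
#' * drug-type (I): active THCAS; CBDAS with inactive allele plus
#'   frameshift deletion;
#' * intermediate (II): active THCAS and active CBDAS;
#' * fiber-type (III): THCAS with inactive allele plus premature stop;
#'   active CBDAS.
#'
#' Background substitutions at `background_mutation_rate` fall only
#' outside functional/primer windows and never create an in-frame stop.
#' The same config and seed reproduce the panel byte for byte.
#'
#' @param config a [panel_config()].
#' @return object of class `cannatype_panel`: list with `samples` (data
#'   frame: `sample_id`, `true_chemotype`, `pct_thc`, `pct_cbd`,
#'   `truth_genotype`), `sequences` (named character vector,
#'   `"<sample>|<gene>"`), `assay`, `references` (the panel's active
#'   ancestral CDS per gene, the natural reference for
#'   [integrity_table()]) and `config`.
#' @export
make_panel <- function(config = panel_config()) {
  stopifnot(inherits(config, "panel_config"))
  fixtures <- make_reference_fixtures()
  cfg <- config

  local_seed(cfg$seed, {
    ## shared ancestors: random outside the fixed functional windows
    ancestor <- list()
    for (gene in c("THCAS", "CBDAS")) {
      len <- if (gene == "THCAS") cfg$seq_length_thcas else
        cfg$seq_length_cbdas
      anc <- random_orf(len)
      masked <- masked_positions(gene, len, cfg)
      ref <- fixtures$references[[gene]]
      for (w in PCR_COORDS[[gene]]) {
        cw <- codon_window(w[1L], w[2L])
        substr(anc, cw[1L], cw[2L]) <- substr(ref, cw[1L], cw[2L])
      }
      snp_pos <- if (gene == "THCAS") cfg$snp_pos_thcas else cfg$snp_pos_cbdas
      active <- if (gene == "THCAS") cfg$active_allele_thcas else
        cfg$active_allele_cbdas
      anc <- set_base_safe(anc, snp_pos, active)
      ## the inactive allele is a diverged haplotype lineage, shared by
      ## every sample carrying it (structural lesions are applied later)
      hap <- background_substitute(anc, cfg$allele_divergence, masked)
      ancestor[[gene]] <- list(seq = anc, inactive_hap = hap,
                               masked = masked)
    }

    chem <- rep(c("I", "II", "III"),
                c(cfg$n_drug, cfg$n_intermediate, cfg$n_fiber))
    n <- length(chem)
    ids <- sprintf("S%03d", seq_len(n))
    truth <- c(I = "Td", II = "TD", III = "tD")[chem]

    ## cannabinoids: ratio from the band, then THC from the compatible window
    pct_thc <- pct_cbd <- numeric(n)
    for (i in seq_len(n)) {
      cls <- chem[i]
      r <- stats::runif(1, cfg$log_ratio_band[[cls]][1],
                        cfg$log_ratio_band[[cls]][2])
      lo <- max(cfg$thc_range[[cls]][1], cfg$cbd_range[[cls]][1] * 10^r)
      hi <- min(cfg$thc_range[[cls]][2], cfg$cbd_range[[cls]][2] * 10^r)
      pct_thc[i] <- stats::runif(1, lo, hi)
      pct_cbd[i] <- pct_thc[i] / 10^r
    }

    ## sequences: background noise, then chemotype-defining lesions
    inactive_thcas <- setdiff(c("G", "T"), cfg$active_allele_thcas)[1L]
    inactive_cbdas <- setdiff(c("C", "G"), cfg$active_allele_cbdas)[1L]
    stop_codon_idx <- floor(cfg$premature_stop_frac *
                              (cfg$seq_length_thcas %/% 3L))
    seqs <- character(0)
    for (i in seq_len(n)) {
      th0 <- if (chem[i] == "III") ancestor$THCAS$inactive_hap else
        ancestor$THCAS$seq
      cb0 <- if (chem[i] == "I") ancestor$CBDAS$inactive_hap else
        ancestor$CBDAS$seq
      th <- background_substitute(th0, cfg$background_mutation_rate,
                                  ancestor$THCAS$masked)
      cb <- background_substitute(cb0, cfg$background_mutation_rate,
                                  ancestor$CBDAS$masked)
      if (chem[i] == "I") {
        cb <- set_base_safe(cb, cfg$snp_pos_cbdas, inactive_cbdas)
        cb <- paste0(substr(cb, 1L, cfg$frameshift_pos_cbdas - 1L),
                     substr(cb, cfg$frameshift_pos_cbdas + cfg$frameshift_len,
                            nchar(cb)))
      } else if (chem[i] == "III") {
        th <- set_base_safe(th, cfg$snp_pos_thcas, inactive_thcas)
        substr(th, 3L * stop_codon_idx - 2L, 3L * stop_codon_idx) <- "TAA"
      }
      seqs[paste0(ids[i], "|THCAS")] <- th
      seqs[paste0(ids[i], "|CBDAS")] <- cb
    }

    structure(list(
      samples = data.frame(sample_id = ids, true_chemotype = chem,
                           pct_thc = pct_thc, pct_cbd = pct_cbd,
                           truth_genotype = unname(truth),
                           stringsAsFactors = FALSE),
      sequences = seqs,
      assay = fixtures$assay,
      references = c(THCAS = ancestor$THCAS$seq, CBDAS = ancestor$CBDAS$seq),
      config = cfg), class = "cannatype_panel")
  })
}

#' @export
print.cannatype_panel <- function(x, ...) {
  tab <- table(x$samples$true_chemotype)
  cat("Synthetic panel:", nrow(x$samples), "samples (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  cat("seed:", x$config$seed, "; background mutation rate:",
      x$config$background_mutation_rate, "\n")
  invisible(x)
}

#' Write a panel to plain-text files
#'
#' Writes `cannabinoids.csv` (`sample_id,pct_thc,pct_cbd`), `truth.csv`,
#' `sequences.fasta` (one record per gene per sample, ids
#' `"<sample>|<gene>"`) and `assay.yaml` into a directory.
#'
#' @param panel a `cannatype_panel`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "cannatype_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("cannabinoids.csv", "truth.csv",
                            "sequences.fasta", "assay.yaml"))
  utils::write.csv(panel$samples[c("sample_id", "pct_thc", "pct_cbd")],
                   paths[1L], row.names = FALSE, quote = FALSE)
  utils::write.csv(panel$samples[c("sample_id", "true_chemotype",
                                   "truth_genotype")],
                   paths[2L], row.names = FALSE, quote = FALSE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(panel$sequences), paths[3L])
  write_assay(panel$assay, paths[4L])
  invisible(paths)
}

#' Serialize / read an assay definition (YAML)
#'
#' @param assay an `assay_definition`.
#' @param path file path.
#' @return `write_assay`: invisibly, `path`; `read_assay`: an
#'   `assay_definition`.
#' @export
write_assay <- function(assay, path) {
  stopifnot(inherits(assay, "assay_definition"))
  plain <- lapply(assay, function(p) {
    list(name = p$name, gene = p$gene, role = p$role,
         expected_size = p$expected_size,
         forward = unclass(p$forward), reverse = unclass(p$reverse))
  })
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_assay
#' @export
read_assay <- function(path) {
  plain <- yaml::read_yaml(path)
  pairs <- lapply(plain, function(p) {
    primer_pair(p$name,
                primer(p$forward$name, p$forward$sequence,
                       p$forward$allele_specific, p$forward$note %||% ""),
                primer(p$reverse$name, p$reverse$sequence,
                       p$reverse$allele_specific, p$reverse$note %||% ""),
                gene = p$gene, role = p$role,
                expected_size = p$expected_size)
  })
  names(pairs) <- vapply(pairs, `[[`, "", "name")
  structure(pairs, class = "assay_definition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a cannabinoid quantitation table
#'
#' @param path CSV with columns `sample_id`, `pct_thc`, `pct_cbd`.
#' @return validated data frame.
#' @export
read_cannabinoid_table <- function(path) {
  validate_cannabinoid_table(utils::read.csv(path, stringsAsFactors = FALSE))
}
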