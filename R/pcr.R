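#' Define a primer
#'
#' @param name primer name.
#' @param sequence 5'->3' nucleotide string; IUPAC ambiguity codes allowed.
#' @param allele_specific logical; `TRUE` when the 3'-terminal base sits on
#'   the discriminating SNP (ARMS primer).
#' @param note free-text annotation.
#' @return an object of class `primer`.
#' @export
primer <- function(name, sequence, allele_specific = FALSE, note = "") {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 15L)
    stop("primer '", name, "' is shorter than 15 nt", call. = FALSE)
  if (grepl("[^ACGTRYSWKMBDHVN]", sequence))
    stop("primer '", name, "' contains non-IUPAC characters", call. = FALSE)
  structure(list(name = name, sequence = sequence,
                 allele_specific = isTRUE(allele_specific), note = note),
            class = "primer")
}

#' Define a primer pair
#'
#' @param forward,reverse [primer()] objects.
#' @param gene `"THCAS"` or `"CBDAS"` — which gene copy the pair targets.
#' @param role `"target"` (allele-specific marker band) or
#'   `"internal_control"` (non-discriminating band confirming amplifiable
#'   template).
#' @param expected_size expected product length in nucleotides.
#' @param name assay/band name (e.g. `"THCASd"`).
#' @return an object of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse, gene = c("THCAS", "CBDAS"),
                        role = c("target", "internal_control"),
                        expected_size) {
  gene <- match.arg(gene)
  role <- match.arg(role)
  stopifnot(inherits(forward, "primer"), inherits(reverse, "primer"))
  if (!is.numeric(expected_size) || expected_size <= 0)
    stop("'expected_size' must be positive", call. = FALSE)
  structure(list(name = name, forward = forward, reverse = reverse,
                 gene = gene, role = role,
                 expected_size = as.integer(expected_size)),
            class = "primer_pair")
}

#' Find primer binding sites on a template
#'
#' Scans both strands of the template for sites where the primer could
#' prime synthesis under ARMS-style stringency: the 3'-terminal window of
#' the primer must match exactly (IUPAC-compatible) and the number of
#' internal mismatches may not exceed `max_internal_mismatch_fraction`
#' of the primer length.  A mismatched 3' base refuses extension, which is
#' what makes a primer whose last base sits on a SNP allele-specific.
#'
#' @param template nucleotide string (A/C/G/T only).
#' @param primer a [primer()] object, or a plain primer string.
#' @param max_internal_mismatch_fraction maximum tolerated fraction of
#'   mismatched positions outside the 3' window (default 0.10).
#' @param three_prime_exact_window number of 3'-terminal primer bases that
#'   must match exactly (default 1).
#' @return data frame with one row per site: `start`, `end` (1-based
#'   inclusive footprint on the plus strand), `strand` (`"+"` if the
#'   primer anneals to the minus strand and extends rightward along the
#'   plus strand, `"-"` for the converse), `three_prime` (template
#'   coordinate opposite the primer's 3' end), `mismatches`.
#' @export
find_binding_sites <- function(template, primer,
                               max_internal_mismatch_fraction = 0.10,
                               three_prime_exact_window = 1L) {
  template <- assert_acgt(template, "template")
  pseq <- if (inherits(primer, "primer")) primer$sequence else toupper(primer)
  k <- nchar(pseq)
  w <- as.integer(three_prime_exact_window)
  stopifnot(w >= 1L, w < k)
  tb <- seq_to_bits(template)
  n <- length(tb)
  if (k > n) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), three_prime = integer(),
                      mismatches = integer()))
  }
  max_internal <- floor(max_internal_mismatch_fraction * k)

  scan <- function(pbits, three_prime_at_right) {
    ## mismatch count per offset, vectorised over offsets
    noff <- n - k + 1L
    mism <- integer(noff)
    mism3 <- integer(noff)
    tail_idx <- if (three_prime_at_right) (k - w + 1L):k else 1L:w
    for (j in seq_len(k)) {
      bad <- bitwAnd(pbits[j], tb[j:(j + noff - 1L)]) == 0L
      if (j %in% tail_idx) mism3 <- mism3 + bad else mism <- mism + bad
    }
    hit <- mism3 == 0L & mism <= max_internal
    which(hit)
  }

  pb <- seq_to_bits(pseq)
  ## plus-strand priming: primer as written, 3' end at footprint right edge
  plus <- scan(pb, TRUE)
  ## minus-strand priming: compare reverse complement; primer 3' end then
  ## faces the left edge of the footprint in plus-strand coordinates
  pb_rc <- seq_to_bits(revcomp(pseq))
  minus <- scan(pb_rc, FALSE)

  res <- rbind(
    if (length(plus))
      data.frame(start = plus, end = plus + k - 1L, strand = "+",
                 three_prime = plus + k - 1L),
    if (length(minus))
      data.frame(start = minus, end = minus + k - 1L, strand = "-",
                 three_prime = minus)
  )
  if (is.null(res))
    res <- data.frame(start = integer(), end = integer(),
                      strand = character(), three_prime = integer())
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Predict amplicons for a primer pair on a template
#'
#' Enumerates every convergent combination of a plus-strand site of one
#' primer and a minus-strand site of the other (single-primer products
#' included, as in a real reaction) with product length up to
#' `max_product_len`.  The product spans from the 5' end of the
#' left (plus-strand) primer to the 5' end of the right (minus-strand)
#' primer, primers included.
#'
#' @param template nucleotide string.
#' @param pair a [primer_pair()].
#' @param max_product_len maximum product length considered (default 3000).
#' @param ... stringency parameters passed to [find_binding_sites()].
#' @return data frame of products sorted by `start`: columns `start`,
#'   `end`, `length`, `left_primer`, `right_primer`.
#' @export
amplify <- function(template, pair, max_product_len = 3000, ...) {
  stopifnot(inherits(pair, "primer_pair"))
  with_name <- function(p) {
    s <- find_binding_sites(template, p, ...)
    s$primer <- rep(p$name, nrow(s))
    s
  }
  sites <- rbind(with_name(pair$forward), with_name(pair$reverse))
  plus <- sites[sites$strand == "+", , drop = FALSE]
  minus <- sites[sites$strand == "-", , drop = FALSE]
  out <- data.frame(start = integer(), end = integer(), length = integer(),
                    left_primer = character(), right_primer = character())
  for (i in seq_len(nrow(plus))) {
    ok <- minus$start >= plus$start[i] & minus$end >= plus$end[i]
    len <- minus$end[ok] - plus$start[i] + 1L
    keep <- len <= max_product_len
    if (any(keep)) {
      out <- rbind(out, data.frame(
        start = plus$start[i], end = minus$end[ok][keep],
        length = len[keep],
        left_primer = plus$primer[i],
        right_primer = minus$primer[ok][keep]))
    }
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run a marker assay on one sample's gene sequences
#'
#' Runs every primer pair of the assay against the sample's sequence of
#' the pair's gene and scores a band as present when at least one
#' predicted product lies within `size_tolerance` of the expected size —
#' the binary read-out of an agarose gel.
#'
#' @param sample_seqs named character vector or `DNAStringSet` holding the
#'   sample's gene sequences, names `"THCAS"` / `"CBDAS"`.  Missing genes
#'   give an absent band plus a QC flag.
#' @param assay an `assay_definition` (list of [primer_pair()]s), e.g.
#'   from [make_reference_fixtures()].
#' @param size_tolerance relative tolerance on the expected product size
#'   (default 0.10, roughly agarose resolution).
#' @param ... passed to [amplify()].
#' @return list with `bands` (named logical per pair), `sizes` (named list
#'   of observed product lengths) and `flags` (character vector).
#' @export
run_assay <- function(sample_seqs, assay, size_tolerance = 0.10, ...) {
  stopifnot(inherits(assay, "assay_definition"))
  seqs <- as_named_chr(sample_seqs)
  bands <- logical(0)
  sizes <- list()
  flags <- character(0)
  for (pair in assay) {
    tmpl <- seqs[pair$gene]
    if (is.na(tmpl) || is.null(tmpl) || !nzchar(tmpl)) {
      bands[pair$name] <- FALSE
      sizes[[pair$name]] <- integer(0)
      flags <- c(flags, paste0("missing_", pair$gene))
      next
    }
    prod <- amplify(tmpl, pair, ...)
    sizes[[pair$name]] <- prod$length
    bands[pair$name] <- any(abs(prod$length - pair$expected_size) <=
                              size_tolerance * pair$expected_size)
  }
  list(bands = bands, sizes = sizes, flags = unique(flags))
}

#' Band patterns for a whole panel
#'
#' Applies [run_assay()] to every sample in a sequence set whose names
#' follow the `"<sample>|<gene>"` convention.
#'
#' @param sequences named character vector or `DNAStringSet`, names
#'   `"<sample_id>|<gene>"`.
#' @param assay an `assay_definition`.
#' @param sample_ids optional explicit sample ids (samples absent from
#'   `sequences` are scored with all bands absent and flagged).
#' @param ... passed to [run_assay()].
#' @return data frame: `sample_id`, one logical column per assay band,
#'   `flags`.
#' @export
band_table <- function(sequences, assay, sample_ids = NULL, ...) {
  seqs <- as_named_chr(sequences)
  nm <- names(seqs)
  if (is.null(nm) || any(!grepl("|", nm, fixed = TRUE)))
    stop("sequence names must follow '<sample>|<gene>'", call. = FALSE)
  sid <- sub("\\|.*$", "", nm)
  gene <- sub("^.*\\|", "", nm)
  if (is.null(sample_ids)) sample_ids <- unique(sid)
  rows <- lapply(sample_ids, function(s) {
    ss <- seqs[sid == s]
    names(ss) <- gene[sid == s]
    r <- run_assay(ss, assay, ...)
    cbind(data.frame(sample_id = s, stringsAsFactors = FALSE),
          as.data.frame(as.list(r$bands)),
          data.frame(flags = join_flags(r$flags)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Check that a primer discriminates two alleles
#'
#' Design-time check of the ARMS property: the primer should bind the
#' active-allele template and refuse the inactive one.  Also usable
#' against unrelated sequences to estimate cross-species specificity.
#'
#' @param primer a [primer()] or primer string.
#' @param active_template,inactive_template templates differing at the
#'   discriminating position.
#' @param ... stringency parameters for [find_binding_sites()].
#' @return list `binds_active`, `binds_inactive`, `discriminating`,
#'   `flags`.
#' @export
validate_allele_specificity <- function(primer, active_template,
                                        inactive_template, ...) {
  a <- nrow(find_binding_sites(active_template, primer, ...)) > 0L
  b <- nrow(find_binding_sites(inactive_template, primer, ...)) > 0L
  flags <- character(0)
  if (a && b) flags <- "non_discriminating"
  if (!a) flags <- c(flags, "no_binding_on_active")
  list(binds_active = a, binds_inactive = b,
       discriminating = a && !b, flags = flags)
}
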