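#' Translate a coding sequence up to the first stop codon
#'
#' Translation starts at position 1 and stops at the first stop codon or
#' at the end of the sequence; a trailing partial codon is ignored and
#' flagged.
#'
#' @param cds nucleotide string (A/C/G/T only), length >= 3.
#' @return list with `protein` (amino-acid string, stop excluded),
#'   `first_stop` (1-based codon index of the first stop, or `NA` if
#'   none), `n_codons` (codons scanned) and `partial_codon` (logical).
#' @examples
#' translate_cds("ATGGCTTAA")$protein  # "MA"
#' @export
translate_cds <- function(cds) {
  cds <- assert_acgt(cds, "cds")
  n <- nchar(cds)
  if (n < 3L) stop("cds shorter than one codon", call. = FALSE)
  n_codons <- n %/% 3L
  codons <- substring(cds, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
  aa <- Biostrings::GENETIC_CODE[codons]
  stop_at <- which(unname(aa) == "*")
  first_stop <- if (length(stop_at)) stop_at[1L] else NA_integer_
  keep <- if (is.na(first_stop)) aa else aa[seq_len(first_stop - 1L)]
  list(protein = paste(keep, collapse = ""),
       first_stop = first_stop,
       n_codons = n_codons,
       partial_codon = (n %% 3L) != 0L)
}

#' Pairwise alignment of two nucleotide sequences
#'
#' Global alignment with affine gaps and free end gaps ("overlap"): a gap
#' run of length L costs `gap_open + L * gap_extend`.  This is the scoring
#' used for integrity assessment and as the elementary step of the
#' progressive multiple aligner.
#'
#' @param a,b nucleotide strings.
#' @param type `"overlap"` (end gaps free, default) or `"global"`.
#' @param match,mismatch,gap_open,gap_extend scoring parameters
#'   (defaults +1 / -1 / -4 / -1, signs handled internally).
#' @return list with `score`, `a_aligned`, `b_aligned` (gapped strings of
#'   equal length).
#' @export
pairwise_align <- function(a, b, type = c("overlap", "global"),
                           match = 1, mismatch = -1,
                           gap_open = 4, gap_extend = 1) {
  type <- match.arg(type)
  a <- assert_acgt(a, "a"); b <- assert_acgt(b, "b")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = type, substitutionMatrix = mat,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
  list(score = Biostrings::score(aln),
       a_aligned = as.character(Biostrings::alignedPattern(aln)),
       b_aligned = as.character(Biostrings::alignedSubject(aln)))
}

## internal gap runs (start, length) of a gapped string, excluding runs
## touching either end of the alignment
internal_gap_runs <- function(gapped) {
  r <- rle(strsplit(gapped, "", fixed = TRUE)[[1]] == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & starts > 1L & ends < nchar(gapped)
  data.frame(start = starts[keep], length = r$lengths[keep])
}

#' Assess the structural integrity of a coding sequence
#'
#' Aligns a sample CDS to an active (complete-ORF) reference and decides
#' whether the sample copy could encode a functional enzyme on purely
#' structural grounds: an internal indel whose length is not a multiple
#' of three is a frameshift, and a translation shorter than
#' `length_threshold` of the reference protein (e.g. from a premature
#' stop) is a truncation.  `activity_call` is `"active"` only for a
#' full-length, frame-intact copy.  Catalytic-site substitutions that
#' inactivate an enzyme without disturbing the ORF are outside what this
#' check can see.
#'
#' @param sample_cds,reference_cds nucleotide strings; the reference must
#'   be a complete ORF.
#' @param length_threshold minimum translated-length fraction counted as
#'   full length (default 0.90).
#' @param ... scoring parameters for [pairwise_align()].
#' @return list: `protein`, `full_length`, `first_stop`, `frameshift`,
#'   `indels` (data frame of internal gap runs with `in_sample` marking
#'   deletions from the sample), `fraction_of_reference`, `activity_call`,
#'   `flags`.
#' @export
assess_integrity <- function(sample_cds, reference_cds,
                             length_threshold = 0.90, ...) {
  if (!nzchar(sample_cds) || !nzchar(reference_cds))
    stop("empty sequence", call. = FALSE)
  aln <- pairwise_align(sample_cds, reference_cds, type = "overlap", ...)
  del <- internal_gap_runs(aln$a_aligned)   # gaps in sample = deletions
  ins <- internal_gap_runs(aln$b_aligned)   # gaps in reference = insertions
  indels <- rbind(
    if (nrow(del)) cbind(del, in_sample = TRUE),
    if (nrow(ins)) cbind(ins, in_sample = FALSE))
  if (is.null(indels))
    indels <- data.frame(start = integer(), length = integer(),
                         in_sample = logical())
  frameshift <- any(indels$length %% 3L != 0L)

  tr_s <- translate_cds(sample_cds)
  tr_r <- translate_cds(reference_cds)
  ref_len <- nchar(tr_r$protein)
  if (ref_len == 0L)
    stop("reference translates to an empty protein", call. = FALSE)
  fraction <- nchar(tr_s$protein) / ref_len
  full_length <- !frameshift && fraction >= length_threshold
  flags <- c(if (frameshift) "frameshift",
             if (!is.na(tr_s$first_stop) && fraction < length_threshold)
               "premature_stop",
             if (tr_s$partial_codon) "partial_terminal_codon")
  list(protein = tr_s$protein,
       full_length = full_length,
       first_stop = tr_s$first_stop,
       frameshift = frameshift,
       indels = indels,
       fraction_of_reference = fraction,
       activity_call = if (full_length) "active" else "inactive",
       flags = if (is.null(flags)) character(0) else flags)
}

#' Integrity reports for a panel of gene sequences
#'
#' Runs [assess_integrity()] for every `"<sample>|<gene>"` sequence
#' against the matching active reference.
#'
#' @param sequences named character vector or `DNAStringSet`, names
#'   `"<sample_id>|<gene>"`.
#' @param references named list/vector of active reference CDSs, names
#'   matching the gene part (e.g. `THCAS`, `CBDAS`).
#' @param ... passed to [assess_integrity()].
#' @return data frame: `sample_id`, `gene`, `full_length`, `first_stop`,
#'   `frameshift`, `fraction_of_reference`, `activity_call`, `flags`.
#' @export
integrity_table <- function(sequences, references, ...) {
  seqs <- as_named_chr(sequences)
  refs <- as_named_chr(unlist(references))
  sid <- sub("\\|.*$", "", names(seqs))
  gene <- sub("^.*\\|", "", names(seqs))
  if (any(!gene %in% names(refs)))
    stop("no reference for gene(s): ",
         paste(setdiff(unique(gene), names(refs)), collapse = ", "),
         call. = FALSE)
  rows <- lapply(seq_along(seqs), function(i) {
    r <- assess_integrity(seqs[[i]], refs[[gene[i]]], ...)
    data.frame(sample_id = sid[i], gene = gene[i],
               full_length = r$full_length,
               first_stop = r$first_stop,
               frameshift = r$frameshift,
               fraction_of_reference = r$fraction_of_reference,
               activity_call = r$activity_call,
               flags = join_flags(r$flags),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
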