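#' Call one gene's allele symbol from its band pair
#'
#' Dominant-marker coding: presence of the allele-specific target band
#' gives the uppercase symbol (functional allele detected), absence with a
#' positive internal control gives the lowercase symbol.  When the
#' internal control also failed there is no evidence the template was
#' amplifiable; the lenient policy (default) still calls the lowercase
#' symbol but flags the failure, the strict policy returns `no_call`.
#'
#' @param target_band,internal_band logical band presences.
#' @param gene `"THCAS"` (symbols T/t) or `"CBDAS"` (symbols D/d).
#' @param policy `"lenient"` or `"strict"` handling of internal-control
#'   failure.
#' @return list with `symbol` and `flags`.
#' @export
call_gene <- function(target_band, internal_band,
                      gene = c("THCAS", "CBDAS"),
                      policy = c("lenient", "strict")) {
  gene <- match.arg(gene)
  policy <- match.arg(policy)
  upper <- if (gene == "THCAS") "T" else "D"
  lower <- tolower(upper)
  flags <- character(0)
  if (isTRUE(target_band)) {
    symbol <- upper
    if (!isTRUE(internal_band)) flags <- "internal_control_failed"
  } else if (isTRUE(internal_band)) {
    symbol <- lower
  } else {
    flags <- "internal_control_failed"
    symbol <- if (policy == "lenient") lower else "no_call"
  }
  list(symbol = symbol, flags = flags)
}

#' Combine allele symbols into a composite genotype and predicted chemotype
#'
#' The three composite genotypes observed in practice map directly to
#' chemotypes: `Td` (THCAS functional only) to I, `TD` (both functional)
#' to II, `tD` (CBDAS functional only) to III.  The fourth pattern `td`
#' (neither synthase detected) has no established chemotype and is
#' reported as `undetermined` with a QC flag.
#'
#' @param thcas_allele `"T"`, `"t"` or `"no_call"`.
#' @param cbdas_allele `"D"`, `"d"` or `"no_call"`.
#' @return list with `composite`, `predicted_chemotype`, `flags`.
#' @export
combine_and_predict <- function(thcas_allele, cbdas_allele) {
  if (thcas_allele == "no_call" || cbdas_allele == "no_call") {
    return(list(composite = "no_call",
                predicted_chemotype = "undetermined",
                flags = "no_call"))
  }
  stopifnot(thcas_allele %in% c("T", "t"), cbdas_allele %in% c("D", "d"))
  composite <- paste0(thcas_allele, cbdas_allele)
  map <- c(Td = "I", TD = "II", tD = "III")
  if (composite %in% names(map)) {
    list(composite = composite,
         predicted_chemotype = unname(map[composite]), flags = character(0))
  } else {
    list(composite = composite, predicted_chemotype = "undetermined",
         flags = "atypical_genotype")
  }
}

#' Genotype calls for a band-pattern table
#'
#' Turns the per-sample band table of [band_table()] (or hand-entered gel
#' read-outs in the same schema) into allele symbols, composite genotypes
#' and predicted chemotypes.
#'
#' @param bands data frame with columns `sample_id`, `THCASd`, `THCASint`,
#'   `CBDASf`, `CBDASint` (logical) and optionally `flags`.
#' @param policy passed to [call_gene()].
#' @return data frame: `sample_id`, `thcas`, `cbdas`, `composite`,
#'   `predicted_chemotype`, `flags`.
#' @export
call_genotypes <- function(bands, policy = c("lenient", "strict")) {
  policy <- match.arg(policy)
  need <- c("sample_id", "THCASd", "THCASint", "CBDASf", "CBDASint")
  if (!is.data.frame(bands) || !all(need %in% names(bands)))
    stop("'bands' must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  rows <- lapply(seq_len(nrow(bands)), function(i) {
    tt <- call_gene(bands$THCASd[i], bands$THCASint[i], "THCAS", policy)
    dd <- call_gene(bands$CBDASf[i], bands$CBDASint[i], "CBDAS", policy)
    cp <- combine_and_predict(tt$symbol, dd$symbol)
    upstream <- if ("flags" %in% names(bands)) bands$flags[i] else ""
    flags <- c(if (nzchar(upstream)) strsplit(upstream, ";")[[1]],
               if (length(tt$flags)) paste0("THCAS_", tt$flags),
               if (length(dd$flags)) paste0("CBDAS_", dd$flags),
               cp$flags)
    data.frame(sample_id = bands$sample_id[i],
               thcas = tt$symbol, cbdas = dd$symbol,
               composite = cp$composite,
               predicted_chemotype = cp$predicted_chemotype,
               flags = join_flags(flags),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
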