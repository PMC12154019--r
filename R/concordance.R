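#' Chemotype–genotype concordance table
#'
#' Joins chemotype calls with genotype predictions sample by sample and
#' summarises their agreement — the quantity of interest of the whole
#' marker system.  Predictions of `undetermined` (or `no_call`) never
#' match and are tallied separately.
#'
#' @param chemo_calls data frame with `sample_id` and `chemotype`
#'   (e.g. from [chemotype_calls()]).
#' @param geno_calls data frame with `sample_id`, `composite` and
#'   `predicted_chemotype` (e.g. from [call_genotypes()]).
#' @return object of class `concordance_table`: list with `table` (the
#'   per-sample join, columns `sample_id`, `chemotype`, `composite`,
#'   `predicted_chemotype`, `match`) and `summary` (list: `n_total`,
#'   `n_match`, `accuracy` in percent, `n_undetermined`, `by_chemotype`,
#'   `by_composite`).
#' @export
build_concordance <- function(chemo_calls, geno_calls) {
  if (!is.data.frame(chemo_calls) || nrow(chemo_calls) == 0L ||
      !is.data.frame(geno_calls) || nrow(geno_calls) == 0L)
    stop("empty input", call. = FALSE)
  need_c <- c("sample_id", "chemotype")
  need_g <- c("sample_id", "composite", "predicted_chemotype")
  stopifnot(all(need_c %in% names(chemo_calls)),
            all(need_g %in% names(geno_calls)))
  only_c <- setdiff(chemo_calls$sample_id, geno_calls$sample_id)
  only_g <- setdiff(geno_calls$sample_id, chemo_calls$sample_id)
  if (length(only_c) || length(only_g))
    stop("sample sets differ",
         if (length(only_c)) paste0("; chemotype only: ",
                                    paste(only_c, collapse = ", ")),
         if (length(only_g)) paste0("; genotype only: ",
                                    paste(only_g, collapse = ", ")),
         call. = FALSE)
  g <- geno_calls[match(chemo_calls$sample_id, geno_calls$sample_id), ]
  tab <- data.frame(sample_id = chemo_calls$sample_id,
                    chemotype = chemo_calls$chemotype,
                    composite = g$composite,
                    predicted_chemotype = g$predicted_chemotype,
                    match = chemo_calls$chemotype == g$predicted_chemotype,
                    stringsAsFactors = FALSE)
  n <- nrow(tab)
  n_match <- sum(tab$match)
  structure(list(
    table = tab,
    summary = list(
      n_total = n,
      n_match = n_match,
      accuracy = 100 * n_match / n,
      n_undetermined = sum(g$predicted_chemotype == "undetermined"),
      by_chemotype = table(tab$chemotype),
      by_composite = table(tab$composite))),
    class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Chemotype-genotype concordance: %.1f%% (%d/%d)\n",
              s$accuracy, s$n_match, s$n_total))
  cat("chemotypes: ",
      paste(names(s$by_chemotype), s$by_chemotype, sep = "=",
            collapse = ", "), "\n")
  cat("composite genotypes: ",
      paste(names(s$by_composite), s$by_composite, sep = "=",
            collapse = ", "), "\n")
  if (s$n_undetermined > 0)
    cat("undetermined predictions:", s$n_undetermined, "\n")
  invisible(x)
}
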