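#' Published 85-sample chemotype/genotype reference table
#'
#' The packaged reference dataset: 85 Cannabis sativa samples (46
#' cultivars) with their quantified \%THC and \%CBD contents (percent
#' w/w), the log ratio as printed in the source table, the assigned
#' chemotype, and the composite genotype (T/t, D/d) called from the
#' allele-specific THCAS/CBDAS markers.  Chemotype counts are 70 drug /
#' 11 intermediate / 4 fiber; chemotype and genotype agree for all 85
#' samples.
#'
#' Note that the printed `log_ratio_printed` column was computed by the
#' original authors from unrounded instrument values; recomputing it from
#' the printed 3-decimal contents reproduces most rows to within 0.005
#' but not those whose \%CBD sits at the 0.001–0.002 reporting limit.
#'
#' @return data frame with columns `sample_id`, `pct_thc`, `pct_cbd`,
#'   `log_ratio_printed`, `chemotype`, `composite`, `thcas`, `cbdas`.
#' @examples
#' t1 <- table1_panel()
#' table(t1$chemotype)
#' @export
table1_panel <- function() {
  path <- system.file("extdata", "table1_chemotype_genotype.csv",
                      package = "cannatype", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
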