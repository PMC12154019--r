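#' Log cannabinoid ratio
#'
#' The classifying statistic for Cannabis chemotypes:
#' `log10(%THC / %CBD)` with both contents floored at a small positive
#' value so that below-detection measurements (printed as zero or at the
#' reporting limit) do not produce infinities.
#'
#' @param pct_thc,pct_cbd numeric vectors of THC and CBD contents in
#'   percent w/w (non-negative).
#' @param floor positive content (percent w/w) substituted for any value
#'   below it before taking the ratio.  The default 0.001 is the smallest
#'   content the reference table reports.
#' @return numeric vector of log10 ratios, with attribute `"floored"`:
#'   a logical vector marking records where flooring was applied.
#' @examples
#' compute_log_ratio(0.928, 0.062)  # 1.175 at 3 d.p.
#' compute_log_ratio(0.744, 2.823)  # -0.579
#' @seealso [classify_fixed()], [chemotype_calls()]
#' @export
compute_log_ratio <- function(pct_thc, pct_cbd, floor = 0.001) {
  stopifnot(is.numeric(pct_thc), is.numeric(pct_cbd),
            length(pct_thc) == length(pct_cbd))
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0)
    stop("'floor' must be a single positive number", call. = FALSE)
  if (any(pct_thc < 0, na.rm = TRUE) || any(pct_cbd < 0, na.rm = TRUE))
    stop("cannabinoid contents must be non-negative", call. = FALSE)
  floored <- (pct_thc < floor) | (pct_cbd < floor)
  lr <- log10(pmax(pct_thc, floor) / pmax(pct_cbd, floor))
  attr(lr, "floored") <- floored
  lr
}

#' Fixed-cutoff chemotype classification
#'
#' Classifies log10(\%THC/\%CBD) values into the three chemotypes with two
#' fixed cutoffs: chemotype I (drug-type) above `upper_cut`, chemotype II
#' (intermediate) in `(lower_cut, upper_cut]`, chemotype III (fiber-type)
#' at or below `lower_cut`.  The defaults (0 and -1) are the conventional
#' thresholds used with log-ratio histograms of Cannabis populations.
#'
#' @param log_ratio numeric vector of log10 ratios (finite).
#' @param upper_cut,lower_cut classification cutoffs, `lower_cut < upper_cut`.
#' @return character vector of `"I"`, `"II"`, `"III"`.
#' @examples
#' classify_fixed(c(1.175, -0.579, -1.294))  # "I" "II" "III"
#' @export
classify_fixed <- function(log_ratio, upper_cut = 0, lower_cut = -1) {
  if (!is.numeric(log_ratio) || any(!is.finite(log_ratio)))
    stop("'log_ratio' must be finite numeric", call. = FALSE)
  if (!(lower_cut < upper_cut))
    stop("'lower_cut' must be below 'upper_cut'", call. = FALSE)
  ifelse(log_ratio > upper_cut, "I",
         ifelse(log_ratio > lower_cut, "II", "III"))
}

#' Chemotype calls for a cannabinoid table
#'
#' Computes the log-ratio statistic for each sample and classifies it,
#' either by the fixed cutoffs or by cutting a complete-linkage cluster
#' tree at k = 3 and labelling clusters by decreasing mean log ratio.
#'
#' @param records data frame with columns `sample_id`, `pct_thc`, `pct_cbd`.
#' @param method `"fixed_cutoff"` (default) or `"cluster"`.
#' @param upper_cut,lower_cut cutoffs for the fixed method.
#' @param floor flooring content for the log-ratio statistic
#'   (see [compute_log_ratio()]).
#' @param cluster_floor flooring content used for the 2-D clustering view
#'   (see [cluster_samples()]).
#' @return data frame with columns `sample_id`, `log_ratio`, `chemotype`,
#'   `method`, `flags`.
#' @export
chemotype_calls <- function(records, method = c("fixed_cutoff", "cluster"),
                            upper_cut = 0, lower_cut = -1,
                            floor = 0.001, cluster_floor = 0.01) {
  method <- match.arg(method)
  records <- validate_cannabinoid_table(records)
  lr <- compute_log_ratio(records$pct_thc, records$pct_cbd, floor = floor)
  flags <- ifelse(attr(lr, "floored"), "content_floored", "")
  if (method == "fixed_cutoff") {
    chem <- classify_fixed(as.numeric(lr), upper_cut, lower_cut)
  } else {
    cl <- cluster_samples(records, k = 3, floor = cluster_floor)
    chem <- cluster_chemotypes(cl)[records$sample_id]
  }
  data.frame(sample_id = records$sample_id,
             log_ratio = as.numeric(lr),
             chemotype = unname(chem),
             method = method,
             flags = flags,
             stringsAsFactors = FALSE)
}

validate_cannabinoid_table <- function(records) {
  need <- c("sample_id", "pct_thc", "pct_cbd")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("'records' must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(records) == 0L)
    stop("'records' is empty", call. = FALSE)
  if (anyDuplicated(records$sample_id))
    stop("duplicate sample_id in cannabinoid table: ",
         paste(unique(records$sample_id[duplicated(records$sample_id)]),
               collapse = ", "), call. = FALSE)
  records$sample_id <- as.character(records$sample_id)
  records
}

#' Hierarchical clustering of samples in cannabinoid space
#'
#' Agglomerative clustering (complete linkage, Euclidean distance) of the
#' samples as points `(log10 %THC, log10 %CBD)` after flooring — the same
#' construction as a clustered two-column log-content heatmap.
#'
#' The clustering floor (default 0.01) is intentionally higher than the
#' log-ratio floor: contents reported at the printing/quantitation limit
#' (0.001–0.002 percent) would otherwise be placed at log10 = -3 and the
#' spread inside the drug-type group would be an artifact of the reporting
#' resolution rather than of the chemistry.
#'
#' @param records data frame with `sample_id`, `pct_thc`, `pct_cbd`
#'   (unique ids).
#' @param k number of clusters for the reported partition (k >= 1).
#' @param floor quantitation floor applied to both contents before log10.
#' @return an object of class `chemotype_clustering`: list with elements
#'   `hclust` (the full merge tree), `k`, `partition` (named integer
#'   vector, cluster id per sample), `log_ratio` (named, computed with the
#'   same floor as [compute_log_ratio()]'s default) and `points`.
#' @export
cluster_samples <- function(records, k = 3, floor = 0.01) {
  records <- validate_cannabinoid_table(records)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("'k' must be a positive integer", call. = FALSE)
  if (nrow(records) < k)
    stop("need at least k records", call. = FALSE)
  pts <- cbind(log10(pmax(records$pct_thc, floor)),
               log10(pmax(records$pct_cbd, floor)))
  rownames(pts) <- records$sample_id
  colnames(pts) <- c("log10_thc", "log10_cbd")
  hc <- stats::hclust(stats::dist(pts, method = "euclidean"),
                      method = "complete")
  part <- stats::cutree(hc, k = k)
  lr <- compute_log_ratio(records$pct_thc, records$pct_cbd)
  structure(list(hclust = hc, k = k,
                 partition = part,
                 log_ratio = stats::setNames(as.numeric(lr),
                                             records$sample_id),
                 points = pts),
            class = "chemotype_clustering")
}

#' @export
print.chemotype_clustering <- function(x, ...) {
  cat("Chemotype clustering (complete linkage, Euclidean) of",
      length(x$partition), "samples\n")
  cat("k =", x$k, "; cluster sizes:",
      paste(table(x$partition), collapse = ", "), "\n")
  invisible(x)
}

#' Map clusters to chemotype labels
#'
#' For a k = 3 partition, clusters are labelled I, II, III in decreasing
#' order of mean log ratio (highest-THC cluster is chemotype I).
#'
#' @param clustering a [cluster_samples()] result with `k = 3`.
#' @return named character vector: chemotype label per sample.
#' @export
cluster_chemotypes <- function(clustering) {
  stopifnot(inherits(clustering, "chemotype_clustering"))
  if (clustering$k != 3L)
    stop("chemotype labelling needs k = 3", call. = FALSE)
  means <- tapply(clustering$log_ratio, clustering$partition, mean)
  ord <- order(means, decreasing = TRUE)  # cluster ids by decreasing THC bias
  lab <- stats::setNames(c("I", "II", "III"), names(means)[ord])
  stats::setNames(unname(lab[as.character(clustering$partition)]),
                  names(clustering$partition))
}

#' Per-cluster log-ratio ranges
#'
#' Reports, for each cluster of a [cluster_samples()] partition, the
#' minimum and maximum log10(\%THC/\%CBD), rounded half away from zero to
#' two decimals — the form in which chemotype group ranges are usually
#' quoted.
#'
#' @param clustering a [cluster_samples()] result.
#' @param digits decimals for the reported bounds.
#' @return data frame with columns `cluster`, `n`, `min`, `max`.
#' @export
derive_cluster_ranges <- function(clustering, digits = 2) {
  stopifnot(inherits(clustering, "chemotype_clustering"))
  sp <- split(clustering$log_ratio, clustering$partition)
  data.frame(cluster = as.integer(names(sp)),
             n = lengths(sp),
             min = round_half_away(vapply(sp, min, 0), digits),
             max = round_half_away(vapply(sp, max, 0), digits),
             row.names = NULL)
}
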