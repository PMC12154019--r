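#' End-to-end chemotype/genotype analysis
#'
#' Chains the whole pipeline in memory: chemotype calls from the
#' cannabinoid table, in-silico PCR band patterns from the sequences,
#' genotype calls from the bands, and the concordance of the two
#' classifications.
#'
#' @param cannabinoids data frame `sample_id`, `pct_thc`, `pct_cbd`.
#' @param sequences named character vector or `DNAStringSet` with names
#'   `"<sample>|<gene>"`.
#' @param assay an `assay_definition`.
#' @param method chemotype classification method, see [chemotype_calls()].
#' @param policy genotype-calling policy, see [call_genotypes()].
#' @param ... further arguments to [chemotype_calls()].
#' @return list with `chemotype`, `bands`, `genotype`, `concordance`.
#' @examples
#' panel <- make_panel(panel_config(n_drug = 4, n_intermediate = 2,
#'                                  n_fiber = 2, seed = 7))
#' res <- full_analysis(panel$samples, panel$sequences, panel$assay)
#' res$concordance$summary$accuracy  # 100
#' @export
full_analysis <- function(cannabinoids, sequences, assay,
                          method = "fixed_cutoff", policy = "lenient", ...) {
  chemo <- chemotype_calls(cannabinoids, method = method, ...)
  bands <- band_table(sequences, assay,
                      sample_ids = cannabinoids$sample_id)
  geno <- call_genotypes(bands, policy = policy)
  conc <- build_concordance(chemo, geno)
  list(chemotype = chemo, bands = bands, genotype = geno,
       concordance = conc)
}

## ---- command-line interface ----------------------------------------------
## thin shell over the package functions; `cannatype_cli()` is what the
## inst/cli/cannatype Rscript calls

cli_usage <- "usage: cannatype <command> [options]

commands:
  simulate     --out DIR [--seed N] [--n-drug N] [--n-intermediate N]
               [--n-fiber N]
  chemotype    --cannabinoids CSV --out DIR [--method fixed_cutoff|cluster]
  genotype     --fasta FASTA --assay YAML --out DIR [--policy lenient|strict]
  concordance  --chemotype CSV --genotype CSV --out DIR
  full         --cannabinoids CSV --fasta FASTA --assay YAML --out DIR
  help

All outputs are plain CSV; every run writes a manifest.json recording the
inputs, parameters, seed and package version."

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    key <- gsub("-", "_", substring(a, 3L))
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stop("missing value for --", key, call. = FALSE)
    flags[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

write_manifest <- function(dir, command, flags, extra = list()) {
  manifest <- c(list(command = command,
                     package = "cannatype",
                     version = as.character(utils::packageVersion("cannatype")),
                     created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                flags, extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

read_panel_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Command-line entry point
#'
#' Dispatches the subcommands of the `cannatype` command-line tool (see
#' `inst/cli/cannatype`).  Exposed as an R function so scripts and tests
#' can drive it without spawning a child process.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly (0 on success).
#' @export
cannatype_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[1L] %in% c("help", "--help", "-h")) {
    cat(cli_usage, "\n")
    return(invisible(0L))
  }
  command <- args[1L]
  flags <- parse_flags(args[-1L])
  out <- flags$out
  if (is.null(out)) stop("--out is required", call. = FALSE)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  switch(command,
    simulate = {
      cfg <- panel_config(
        n_drug = as.integer(flags$n_drug %||% 70),
        n_intermediate = as.integer(flags$n_intermediate %||% 11),
        n_fiber = as.integer(flags$n_fiber %||% 4),
        seed = as.integer(flags$seed %||% 1))
      panel <- make_panel(cfg)
      write_panel(panel, out)
      write_manifest(out, command, flags,
                     list(seed = cfg$seed, n_samples = nrow(panel$samples)))
    },
    chemotype = {
      records <- read_cannabinoid_table(req(flags, "cannabinoids"))
      calls <- chemotype_calls(records,
                               method = flags$method %||% "fixed_cutoff")
      utils::write.csv(calls, file.path(out, "chemotype.csv"),
                       row.names = FALSE)
      write_manifest(out, command, flags,
                     list(n_samples = nrow(calls),
                          counts = as.list(table(calls$chemotype))))
    },
    genotype = {
      seqs <- read_panel_fasta(req(flags, "fasta"))
      assay <- read_assay(req(flags, "assay"))
      bands <- band_table(seqs, assay)
      geno <- call_genotypes(bands, policy = flags$policy %||% "lenient")
      utils::write.csv(bands, file.path(out, "bands.csv"), row.names = FALSE)
      utils::write.csv(geno, file.path(out, "genotype.csv"),
                       row.names = FALSE)
      write_manifest(out, command, flags, list(n_samples = nrow(geno)))
    },
    concordance = {
      chemo <- utils::read.csv(req(flags, "chemotype"),
                               stringsAsFactors = FALSE)
      geno <- utils::read.csv(req(flags, "genotype"),
                              stringsAsFactors = FALSE)
      conc <- build_concordance(chemo, geno)
      utils::write.csv(conc$table, file.path(out, "concordance.csv"),
                       row.names = FALSE)
      write_manifest(out, command, flags,
                     list(accuracy = conc$summary$accuracy,
                          n_match = conc$summary$n_match,
                          n_total = conc$summary$n_total))
    },
    full = {
      records <- read_cannabinoid_table(req(flags, "cannabinoids"))
      seqs <- read_panel_fasta(req(flags, "fasta"))
      assay <- read_assay(req(flags, "assay"))
      res <- full_analysis(records, seqs, assay,
                           method = flags$method %||% "fixed_cutoff",
                           policy = flags$policy %||% "lenient")
      utils::write.csv(res$chemotype, file.path(out, "chemotype.csv"),
                       row.names = FALSE)
      utils::write.csv(res$bands, file.path(out, "bands.csv"),
                       row.names = FALSE)
      utils::write.csv(res$genotype, file.path(out, "genotype.csv"),
                       row.names = FALSE)
      utils::write.csv(res$concordance$table,
                       file.path(out, "concordance.csv"), row.names = FALSE)
      write_manifest(out, command, flags,
                     list(accuracy = res$concordance$summary$accuracy,
                          n_match = res$concordance$summary$n_match,
                          n_total = res$concordance$summary$n_total))
    },
    stop("unknown command: ", command, "\n", cli_usage, call. = FALSE)
  )
  invisible(0L)
}

req <- function(flags, key) {
  v <- flags[[key]]
  if (is.null(v)) stop("--", gsub("_", "-", key), " is required",
                       call. = FALSE)
  v
}
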