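## shared small fixtures, built once per test run

small_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_panel(panel_config(n_drug = 3, n_intermediate = 2,
                                        n_fiber = 2, seed = 11))
    cache
  }
})

## the paper-scale phylogeny selection: 4 drug / 5 intermediate / 3 fiber
phylo_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_panel(panel_config(n_drug = 4, n_intermediate = 5,
                                        n_fiber = 3, seed = 23))
    cache
  }
})

panel_gene_ids <- function(panel, chemotypes, gene) {
  ids <- panel$samples$sample_id[panel$samples$true_chemotype %in% chemotypes]
  paste0(ids, "|", gene)
}
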