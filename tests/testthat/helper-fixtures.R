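# Shared small fixtures, generated in code. The cached cohort is big enough
# to exercise every pipeline stage but small enough to keep the suite fast.

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(sim_config(
        n_families = 20, n_genes = 300, n_dase_genes = 30,
        delta = 1, tau = 0.3, bb_rho = 0.01,
        library_size_mean = 6e5, seed = 7))
    cache
  }
})

# tiny deterministic SNP table for filter/aggregation unit tests
toy_snps <- function() {
  data.table::data.table(
    sample_id = "s1",
    contig = "chr1",
    position = c(100L, 200L, 300L, 400L, 500L),
    refCount = c(5L, 0L, 2L, 4L, 2L),
    altCount = c(5L, 50L, 8L, 6L, 9L),
    gene_id = "geneA"
  )
}
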