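# One full pipeline run on the default study conditions (4 families x 15
# copies, pairwise divergence 0.08, 10% partials, seed 42, ~3 Mb), shared
# by the acceptance tests; computed once per test session.
.run_cache <- new.env(parent = emptyenv())

default_run <- function() {
  if (is.null(.run_cache$report)) {
    .run_cache$report <- run_pipeline(synth_config(seed = 42))
  }
  .run_cache$report
}

# a small, fast synthetic run for module-level tests
small_cfg <- function() {
  synth_config(seed = 7, n_contigs = 6, contig_length = 6e4,
               copies_per_family = 3, partial_copy_fraction = 0)
}

small_run <- function() {
  if (is.null(.run_cache$small)) {
    .run_cache$small <- run_pipeline(small_cfg())
  }
  .run_cache$small
}

small_run_genome <- function() {
  if (is.null(.run_cache$small_genome)) {
    .run_cache$small_genome <- simulate_genome(small_cfg())$genome
  }
  .run_cache$small_genome
}
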