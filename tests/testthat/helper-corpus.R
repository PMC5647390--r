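# Shared simulated corpora, generated once per test run.

.corpus_cache <- new.env()

## Default study corpus plus ORFs and the cascade result.
ta_default_run <- function() {
  if (is.null(.corpus_cache$default)) {
    cfg <- pipelineConfig()
    corpus <- generateScenario(defaultScenario(rng_seed = 20160913L),
                               cfg)
    orfs <- findOrfs(corpus$contigs, cfg)
    cascade <- cascadeSearch(orfs, corpus$seeds, cfg, corpus$profiles)
    .corpus_cache$default <- list(cfg = cfg, corpus = corpus,
                                  orfs = orfs, cascade = cascade)
  }
  .corpus_cache$default
}

locus_keys <- function(df) {
  paste(df$strain_id, df$contig_id, df$tox_start, df$tox_end)
}

truth_keys <- function(truth) {
  paste(truth$strain_id, truth$contig_id, truth$tox_start,
        truth$tox_end)
}

## A small corpus for fast pipeline-level tests: 6 strains, 2 families,
## a couple of decoys.
ta_small_run <- function() {
  if (is.null(.corpus_cache$small)) {
    cfg <- pipelineConfig()
    sc <- simulationScenario(
      n_strains = 6L, n_species = 2L, contig_len_nt = 8000L,
      families = list(
        plantedFamily("famA", center_divergence = 0.10, gap_nt = -4L,
                      carrier_fraction = 1.0),
        plantedFamily("famB", center_divergence = 0.20, gap_nt = 10L,
                      carrier_fraction = 0.5,
                      replicon_label = "plasmid")),
      decoy_spec = c(orphan_toxin = 1L, wide_gap = 1L,
                     opposite_strand = 1L, oversized_toxin = 1L,
                     undersized_antitoxin = 1L),
      rng_seed = 7L)
    corpus <- generateScenario(sc, cfg)
    orfs <- findOrfs(corpus$contigs, cfg)
    .corpus_cache$small <- list(cfg = cfg, scenario = sc,
                                corpus = corpus, orfs = orfs)
  }
  .corpus_cache$small
}

## Stepping-stone corpus: one deeply diverged family reachable through
## planted lineage intermediates.
ta_stepping_run <- function() {
  if (is.null(.corpus_cache$stepping)) {
    cfg <- pipelineConfig()
    sc <- simulationScenario(
      n_strains = 8L, n_species = 2L, contig_len_nt = 8000L,
      families = list(
        plantedFamily("deep", center_divergence = 0.22,
                      lineage_steps = 5L, member_jitter = 0.02,
                      gap_nt = 6L, carrier_fraction = 1.0)),
      rng_seed = 11L)
    corpus <- generateScenario(sc, cfg)
    orfs <- findOrfs(corpus$contigs, cfg)
    .corpus_cache$stepping <- list(cfg = cfg, corpus = corpus,
                                   orfs = orfs)
  }
  .corpus_cache$stepping
}
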