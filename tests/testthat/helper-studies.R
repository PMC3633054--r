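# The two simulated study conditions are expensive; compute each once and
# share across acceptance checks.
.study_cache <- new.env(parent = emptyenv())

cached_study <- function(n_species) {
  key <- paste0("n", n_species)
  if (is.null(.study_cache[[key]])) {
    cfg <- sim_config(n_species = n_species, seed = 20260920)
    .study_cache[[key]] <-
      run_simulation_study(cfg, comp_methods = c("ncd", "ibd"),
                           evo_models = "k2p", algos = c("nj", "upgma"))
  }
  .study_cache[[key]]
}

study_mean <- function(tab, comp, algo) {
  tab$mean[tab$comp == comp & tab$algo == algo]
}
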