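# small simulated datasets shared across test files
.sim_cache <- new.env(parent = emptyenv())

empty_tl <- function() apcohort:::empty_timeline()
age_band_label_pkg <- function(age) apcohort:::age_band_label(age)

cached_sim <- function(n = 8000, seed = 42) {
  key <- paste0("n", n, "s", seed)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_ehr(sim_config(n_patients = n,
                                                 seed = seed))
  }
  .sim_cache[[key]]
}
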