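# Shared simulations, built once per test run (lazy caches).

.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.sim_cache[[name]])) .sim_cache[[name]] <- force(expr)
  .sim_cache[[name]]
}

# small noise-free cohort: exact recovery expected
sim_clean <- function() cached("clean", simulate_study(synth_config(
  n_participants = 10, n_classes = 4, n_schools = 2, seed = 101,
  dropout_prob = 0, noise_sd_m = 0, speed_noise_sd_kmh = 0,
  low_compliance_frac = 0)))

# small cohort under the default noise conditions
sim_noisy <- function() cached("noisy", simulate_study(synth_config(
  n_participants = 10, n_classes = 4, n_schools = 2, seed = 202)))

sim_epochs <- function(sim) {
  key <- paste0("ep_", substr(digest_sim(sim), 1, 8))
  cached(key, align_epochs(sim$gps, sim$accel, sim$study_config))
}

digest_sim <- function(sim) {
  paste0(nrow(sim$gps), "_", nrow(sim$accel), "_", sim$config$seed)
}
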