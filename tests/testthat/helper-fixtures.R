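# Shared fixtures: ideal electrodes and small synthetic experiments.

# Perfectly selective electrode profile (no interferents).
no_interference <- function(ion = "K") selectivity_profile(ion)

# Bath containing only the scanned ion, for inversion-consistency checks.
pure_bath <- function(ion) {
  if (ion == "K") c(K = 3.4) else c(Na = 20)
}

# Site-level estimates -> per-preparation regional means.
prep_means_for <- function(datasets, ...) {
  est <- do.call(rbind, lapply(datasets, estimate_fluxes, ...))
  preparation_means(assign_regions(est))
}

# Simulate one control/treatment pair under a single RNG stream and return
# the region comparison table.
simulate_comparison <- function(ion, n_sites, seed, ...) {
  cal <- default_calibration(ion)
  ctrl <- default_experiment_config(ion, "control", n_sites = n_sites, ...)
  trt <- default_experiment_config(ion, "GPA2/GPB5", n_sites = n_sites, ...)
  set.seed(seed)
  compare_treatments(
    prep_means_for(simulate_experiment(ctrl, cal, seed = NULL)),
    prep_means_for(simulate_experiment(trt, cal,
                                       treatment_label = "GPA2/GPB5",
                                       seed = NULL)))
}
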