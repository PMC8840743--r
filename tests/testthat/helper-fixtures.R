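# Builders for small in-code fixtures.

peak_rec <- function(compound_id, mode, ph, dilution_factor = 1,
                     area = NA_real_, rt = NA_real_, mz = 200.05,
                     na_adduct = FALSE) {
  data.frame(compound_id = compound_id, mode = mode, ph = ph,
             dilution_factor = dilution_factor, area = area, rt = rt,
             mz = mz, na_adduct = na_adduct, stringsAsFactors = FALSE)
}

bind_recs <- function(...) do.call(rbind, list(...))

# A tiny noiseless, uncensored simulation shared by several tests.
noiseless_sim <- function(n = 20, seed = 42, ...) {
  cfg <- simulation_config(n_compounds = n, seed = seed, noise_cv = 0,
                           lod_area = 0, rt_jitter_sd = 0, ...)
  prof <- simulate_compounds(cfg)
  sim <- simulate_feature_table(prof, cfg)
  list(cfg = cfg, prof = prof, features = sim$features,
       standards = sim$standards)
}

# RF table row helper for baseline tests.
rf_row <- function(compound_id, rf, mean_rt, mode = "positive", ph = 2.7,
                   n_points_used = 5L) {
  data.frame(compound_id = compound_id, mode = mode, ph = ph, rf = rf,
             log_rf = log10(rf), mean_rt = mean_rt,
             n_points_used = n_points_used, stringsAsFactors = FALSE)
}
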