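test_that("simulation is fully reproducible under a fixed seed", {
  cfg <- simulation_config(n_compounds = 25, seed = 9)
  p1 <- simulate_compounds(cfg)
  p2 <- simulate_compounds(cfg)
  expect_identical(p1$compounds, p2$compounds)
  expect_identical(p1$true_log_rf, p2$true_log_rf)
  s1 <- simulate_feature_table(p1, cfg)
  s2 <- simulate_feature_table(p2, cfg)
  expect_identical(s1, s2)
  # and the global RNG state is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_compounds(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("generated response factors span several orders of magnitude", {
  cfg <- simulation_config(n_compounds = 200, seed = 5)
  prof <- simulate_compounds(cfg)
  pos <- prof$true_log_rf[prof$true_log_rf$mode == "positive", ]
  expect_gte(diff(range(pos$true_log_rf)), 4)
})

test_that("frac_neg_detectable = 0 suppresses all negative-mode signals", {
  cfg <- simulation_config(n_compounds = 30, seed = 2,
                           frac_neg_detectable = 0)
  prof <- simulate_compounds(cfg)
  expect_false(any(prof$true_log_rf$mode == "negative"))
  sim <- simulate_feature_table(prof, cfg)
  expect_false(any(sim$features$mode == "negative"))
})

test_that("noiseless areas equal concentration times the response factor", {
  sim <- noiseless_sim(n = 10, seed = 21)
  df <- merge(sim$features, sim$standards,
              by = c("compound_id", "dilution_factor"))
  df <- merge(df, sim$prof$true_log_rf, by = c("compound_id", "mode", "ph"))
  expect_true(all(!is.na(df$area)))
  expect_equal(df$area, df$concentration_M * 10^df$true_log_rf,
               tolerance = 1e-12)
})

test_that("an LOD above all expected areas censors every record", {
  cfg <- simulation_config(n_compounds = 10, seed = 3, lod_area = 1e30)
  prof <- simulate_compounds(cfg)
  sim <- simulate_feature_table(prof, cfg)
  expect_true(all(is.na(sim$features$area)))
})

test_that("raising the LOD never increases the number of detected records", {
  cfg_of <- function(lod) simulation_config(n_compounds = 40, seed = 13,
                                            lod_area = lod)
  prof <- simulate_compounds(cfg_of(0))
  detected <- vapply(c(0, 1e4, 1e6, 1e8, 1e10), function(lod) {
    sum(!is.na(simulate_feature_table(prof, cfg_of(lod))$features$area))
  }, numeric(1))
  expect_true(all(diff(detected) <= 0))
})

test_that("per-compound area regression recovers the true RF under noise", {
  cfg <- simulation_config(n_compounds = 100, seed = 31)
  prof <- simulate_compounds(cfg)
  sim <- simulate_feature_table(prof, cfg)
  rf <- suppressMessages(
    build_training_table(merge_split_peaks(sim$features), sim$standards))
  m <- merge(rf, prof$true_log_rf, by = c("compound_id", "mode", "ph"))
  rel_err <- abs(m$rf / 10^m$true_log_rf - 1)
  expect_gte(mean(rel_err <= 3 * cfg$noise_cv), 0.95)
})

test_that("log pos/neg area ratio correlates with positive-mode log RF", {
  cfg <- simulation_config(n_compounds = 200, seed = 17)
  prof <- simulate_compounds(cfg)
  sim <- simulate_feature_table(prof, cfg)
  desc <- build_descriptor_table(merge_split_peaks(sim$features))
  pos8 <- prof$true_log_rf[prof$true_log_rf$mode == "positive" &
                             prof$true_log_rf$ph == 8.0, ]
  df <- merge(desc, pos8, by = "compound_id")
  usable <- abs(df$ratio_ph8_0) < 900
  expect_gte(sum(usable), 30)
  expect_gt(cor(df$ratio_ph8_0[usable], df$true_log_rf[usable]), 0.4)
})

test_that("latent structure drives retention: RT increases with lipophilicity
           and the pH 10 shift follows basicity minus acidity", {
  cfg <- simulation_config(n_compounds = 200, seed = 23)
  prof <- simulate_compounds(cfg)
  rt27 <- prof$true_rt[prof$true_rt$ph == 2.7, ]
  rt10 <- prof$true_rt[prof$true_rt$ph == 10.0, ]
  df <- merge(merge(rt27, rt10, by = "compound_id"), prof$compounds,
              by = "compound_id")
  expect_gt(cor(df$true_rt.x, df$latent_lipophilicity), 0.5)
  shift <- df$true_rt.y - df$true_rt.x
  gap <- df$latent_basicity - df$latent_acidity
  unclamped <- df$true_rt.y > 0.2 & df$true_rt.x > 0.2
  expect_true(all(sign(shift[unclamped & abs(gap) > 1e-8]) ==
                    sign(gap[unclamped & abs(gap) > 1e-8])))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_compounds = 0), "n_compounds")
  expect_error(simulation_config(frac_neg_detectable = 1.5), "frac_neg")
  expect_error(simulation_config(noise_cv = -0.1), "noise_cv")
  expect_error(simulation_config(rt_range = c(5, 2)), "rt_range")
})
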