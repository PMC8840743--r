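# Descriptor table + RF table for a deterministic target that is a known
# function of the pH 8.0 ratio, built from a fully detected noiseless
# simulation.
ratio_driven_training <- function(n = 60, seed = 6,
                                  f = function(r) 14 + 0.5 * r) {
  sim <- noiseless_sim(n = n, seed = seed, frac_neg_detectable = 1)
  desc <- build_descriptor_table(merge_split_peaks(sim$features))
  rf <- data.frame(compound_id = desc$compound_id, mode = "positive",
                   ph = 8.0, log_rf = f(desc$ratio_ph8_0),
                   stringsAsFactors = FALSE)
  rf$rf <- 10^rf$log_rf
  rf$mean_rt <- desc$rt_ph8_0
  rf$n_points_used <- 5L
  list(desc = desc, rf = rf)
}

test_that("a constant training target yields constant predictions", {
  tr <- ratio_driven_training(n = 25, f = function(r) rep(15, length(r)))
  ms <- suppressMessages(train_model_set(tr$desc, tr$rf, seed = 1,
                                         num_trees = 100))
  expect_named(ms$models, "positive_pH8.0")
  pred <- predict_log_rf(ms, tr$desc, "positive", 8.0)
  expect_equal(unname(pred), rep(15, nrow(tr$desc)), tolerance = 1e-9)
})

test_that("training is deterministic under a fixed seed and learns a
           deterministic function of one descriptor", {
  tr <- ratio_driven_training(n = 60)
  ms1 <- suppressMessages(train_model_set(tr$desc, tr$rf, seed = 3))
  ms2 <- suppressMessages(train_model_set(tr$desc, tr$rf, seed = 3))
  p1 <- predict_log_rf(ms1, tr$desc, "positive", 8.0)
  p2 <- predict_log_rf(ms2, tr$desc, "positive", 8.0)
  expect_identical(p1, p2)
  r2 <- 1 - mean((p1 - tr$rf$log_rf)^2) / var(tr$rf$log_rf)
  expect_gte(r2, 0.9)
})

test_that("conditions with too few training compounds are skipped and
           prediction for them errors", {
  tr <- ratio_driven_training(n = 20)
  extra <- tr$rf[1:5, ]
  extra$mode <- "negative"
  rf <- rbind(tr$rf, extra)
  ms <- suppressMessages(train_model_set(tr$desc, rf, seed = 1,
                                         num_trees = 50))
  expect_false("negative_pH8.0" %in% names(ms$models))
  expect_error(predict_log_rf(ms, tr$desc, "negative", 8.0), "no model")
  expect_error(suppressMessages(train_model_set(tr$desc, rf[0, ], seed = 1)),
               "no condition")
})

test_that("forest predictions regress toward and stay inside the training
           spread", {
  tr <- ratio_driven_training(n = 60, seed = 14)
  ms <- suppressMessages(train_model_set(tr$desc, tr$rf, seed = 2,
                                         num_trees = 200))
  pred <- predict_log_rf(ms, tr$desc, "positive", 8.0)
  expect_true(all(is.finite(pred)))
  expect_gte(min(pred), min(tr$rf$log_rf))
  expect_lte(max(pred), max(tr$rf$log_rf))
})

test_that("permutation importance ranks the generating descriptor first and
           gives a near-zero score to pure noise", {
  tr <- ratio_driven_training(n = 60, seed = 26)
  ms <- suppressMessages(train_model_set(tr$desc, tr$rf, seed = 4))
  imp <- permutation_importance(ms, tr$desc, tr$rf, n_repeats = 10, seed = 5)
  expect_equal(nrow(imp), 12L)
  expect_setequal(imp$descriptor, descriptor_names())
  expect_equal(imp$descriptor[imp$rank == 1], "ratio_ph8_0")
  # determinism
  imp2 <- permutation_importance(ms, tr$desc, tr$rf, n_repeats = 10, seed = 5)
  expect_identical(imp, imp2)
  # a descriptor the target never depended on scores near zero: mz was not
  # used to build the target, so its importance must be dwarfed by the
  # generating descriptor's
  expect_lt(imp$importance[imp$descriptor == "mz"] /
              imp$importance[imp$descriptor == "ratio_ph8_0"], 0.05)
})

test_that("equal-RF baseline is the geometric mean and is invariant to
           duplication and order", {
  rf <- rbind(rf_row("a", 1e14, 5), rf_row("b", 1e16, 9))
  expect_equal(equal_rf_baseline(rf, "positive", 2.7), 1e15)
  expect_equal(equal_rf_baseline(rf_row("c", 3.0e16, 4), "positive", 2.7),
               3.0e16)
  rf3 <- rbind(rf_row("a", 1e12, 1), rf_row("b", 1e14, 2),
               rf_row("c", 1e16, 3))
  expect_equal(equal_rf_baseline(rf3, "positive", 2.7), 1e14)
  expect_equal(equal_rf_baseline(rbind(rf3, rf3), "positive", 2.7), 1e14)
  expect_equal(equal_rf_baseline(rf3[c(3, 1, 2), ], "positive", 2.7), 1e14)
  expect_error(equal_rf_baseline(rf3, "negative", 2.7), "no training")
})

test_that("closest-eluting baseline picks the nearest standard, breaking
           ties toward earlier elution", {
  rf <- rbind(rf_row("carbazole", 6.0e12, 13.6),
              rf_row("early", 2e15, 4.0), rf_row("late", 5e16, 6.0))
  expect_equal(closest_eluting_baseline(rf, 13.6, "positive", 2.7), 6.0e12)
  expect_equal(closest_eluting_baseline(rf, 13.9, "positive", 2.7), 6.0e12)
  expect_equal(closest_eluting_baseline(rf, 5.0, "positive", 2.7), 2e15)
  # membership: output always comes from the training multiset
  set.seed(55)
  q <- runif(50, 0, 20)
  expect_true(all(closest_eluting_baseline(rf, q, "positive", 2.7)
                  %in% rf$rf))
})

test_that("the simplified pH 8.0 linear model recovers exact and generative
           relationships", {
  tr <- ratio_driven_training(n = 30, seed = 33)
  fit <- fit_simplified_linear(tr$rf, tr$desc)
  expect_equal(fit$intercept, 14, tolerance = 1e-9)
  expect_equal(fit$slope, 0.5, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(predict(fit, 2), 15, tolerance = 1e-9)
  expect_error(predict(fit, 999), "sentinel")
  expect_error(fit_simplified_linear(tr$rf[1:2, ], tr$desc), "at least 3")

  # generative check: with no independent negative-mode variation the
  # pos/neg gap is affine in the positive log RF, so the fit is exact
  sim <- noiseless_sim(n = 40, seed = 44, frac_neg_detectable = 1,
                       neg_coupling = 1, basicity_rf_effect = 0,
                       acidity_rf_effect = 0, ph_trend_het = 0)
  desc <- build_descriptor_table(merge_split_peaks(sim$features))
  rf <- suppressMessages(build_training_table(
    merge_split_peaks(sim$features), sim$standards))
  fit2 <- fit_simplified_linear(rf, desc)
  cfg <- sim$cfg
  slope_truth <- 1 / (1 - cfg$neg_coupling * cfg$log_rf_sd_neg /
                        cfg$log_rf_sd_pos)
  expect_equal(fit2$slope, slope_truth, tolerance = 1e-6)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-9)
})

test_that("interpretive trees split on the generating descriptor and refine
           the constant model", {
  tr <- ratio_driven_training(
    n = 60, seed = 36, f = function(r) ifelse(r > stats::median(r), 16, 13))
  tree <- fit_interpretive_tree(tr$desc, tr$rf, "positive", 8.0,
                                max_depth = 2)
  expect_equal(tree_root_descriptor(tree), "ratio_ph8_0")
  txt <- format(tree)
  expect_true(any(grepl("ratio_ph8_0", txt)))

  # depth 0 gives the mean log RF
  leaf <- fit_interpretive_tree(tr$desc, tr$rf, "positive", 8.0,
                                max_depth = 0)
  expect_equal(unique(predict(leaf, tr$desc)), mean(tr$rf$log_rf))
  expect_true(is.na(tree_root_descriptor(leaf)))

  # refinement: tree training MSE never exceeds the constant model's
  mse <- function(p) mean((p - tr$rf$log_rf)^2)
  expect_lte(mse(predict(tree, tr$desc)), mse(predict(leaf, tr$desc)))
  expect_error(fit_interpretive_tree(tr$desc[1:5, ], tr$rf[1:5, ],
                                     "positive", 8.0), "training compound")
})
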