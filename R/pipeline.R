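#' End-to-end pipeline
#'
#' Chains the stages simulate -> calibrate -> featurize -> train ->
#' importance -> predict -> evaluate over a declarative run configuration,
#' writing every intermediate table as CSV so stages can also be run
#' independently with the CSVs as contracts. Identical configuration and
#' seed produce byte-identical outputs.
#'
#' @name pipeline
NULL

RUN_CONFIG_SCHEMA <- list(
  seed = NULL, output_dir = NULL,
  simulation = c("n_train", "n_test", "log_rf_mean_pos", "log_rf_sd_pos",
                 "log_rf_mean_neg", "log_rf_sd_neg", "frac_neg_detectable",
                 "rt_range", "noise_cv", "lod_area", "dilution_factors_train",
                 "dilution_factors_test", "conc_range_M", "ph_trend_pos",
                 "ph_trend_neg", "neg_coupling", "basicity_rf_effect",
                 "acidity_rf_effect", "rt_shift_scale", "rt_jitter_sd",
                 "na_adduct_prob", "neutral_mass_range"),
  training = c("num_trees", "folds", "mtry_grid", "min_node_grid",
               "min_training"),
  importance = c("n_repeats"),
  evaluation = c("threshold")
)

#' Default run configuration
#'
#' @param output_dir directory for all stage outputs
#' @param seed integer seed governing every random stage
#' @return a nested list understood by [run_pipeline()]
#' @export
default_run_config <- function(output_dir = tempfile("esiquant_run_"),
                               seed = 1) {
  list(
    seed = as.integer(seed),
    output_dir = output_dir,
    simulation = list(n_train = 150, n_test = 50),
    training = list(num_trees = 500, folds = 5, mtry_grid = c(3, 6, 9),
                    min_node_grid = c(2, 5), min_training = 10),
    importance = list(n_repeats = 5),
    evaluation = list(threshold = 10)
  )
}

validate_run_config <- function(config) {
  unknown <- setdiff(names(config), names(RUN_CONFIG_SCHEMA))
  if (length(unknown) > 0) {
    stop("unknown run-config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (section in c("simulation", "training", "importance", "evaluation")) {
    bad <- setdiff(names(config[[section]]), RUN_CONFIG_SCHEMA[[section]])
    if (length(bad) > 0) {
      stop("unknown run-config key(s) in ", section, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(config$seed) || is.null(config$output_dir)) {
    stop("run config must set seed and output_dir", call. = FALSE)
  }
  invisible(config)
}

#' Read a run configuration from a YAML file
#'
#' Keys absent from the file take their [default_run_config()] values;
#' unknown keys are rejected.
#'
#' @param path YAML file path
#' @return validated run configuration list
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  base <- default_run_config()
  for (key in names(user)) {
    if (is.list(base[[key]]) && is.list(user[[key]])) {
      for (sub in names(user[[key]])) base[[key]][[sub]] <- user[[key]][[sub]]
    } else {
      base[[key]] <- user[[key]]
    }
  }
  validate_run_config(base)
  base
}

run_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.1f s", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

# Per-(compound, condition) mean retention time of detected test features.
feature_mean_rt <- function(records) {
  det <- records[!is.na(records$area), , drop = FALSE]
  if (nrow(det) == 0) {
    return(data.frame(compound_id = character(), mode = character(),
                      ph = numeric(), mean_rt = numeric(),
                      stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(rt ~ compound_id + mode + ph, data = det,
                          FUN = mean)
  names(agg)[names(agg) == "rt"] <- "mean_rt"
  agg
}

#' Run the full pipeline
#'
#' @param config run configuration from [default_run_config()] or
#'   [read_run_config()]
#' @return invisibly, a list with the per-method error `summary` data frame,
#'   the `evaluation` records, the fitted `model_set` and the output paths
#' @export
run_pipeline <- function(config = default_run_config()) {
  validate_run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out_path <- function(name) file.path(config$output_dir, name)
  seed <- config$seed

  sim_args <- config$simulation
  n_train <- sim_args$n_train %||% 150
  n_test <- sim_args$n_test %||% 50
  sim_args$n_train <- NULL; sim_args$n_test <- NULL

  sim <- run_stage("simulate", {
    cfg_train <- do.call(simulation_config,
                         c(list(n_compounds = n_train, seed = seed), sim_args))
    cfg_test <- do.call(simulation_config,
                        c(list(n_compounds = n_test, seed = seed + 500000L),
                          sim_args))
    prof_train <- simulate_compounds(cfg_train)
    prof_test <- simulate_compounds(cfg_test)
    train <- simulate_feature_table(prof_train, cfg_train, seed_offset = 1)
    test <- simulate_feature_table(
      prof_test, cfg_test,
      dilution_factors = cfg_test$dilution_factors_test, seed_offset = 2)
    write_feature_table(train$features, out_path("features_train.csv"))
    write_feature_table(test$features, out_path("features_test.csv"))
    write_standards_table(train$standards, out_path("standards_train.csv"))
    write_standards_table(test$standards, out_path("standards_test.csv"))
    write_ground_truth_table(prof_train, out_path("truth_train.csv"))
    write_ground_truth_table(prof_test, out_path("truth_test.csv"))
    list(train = train, test = test)
  })

  rf_train <- run_stage("calibrate", {
    rf <- build_training_table(merge_split_peaks(sim$train$features),
                               sim$train$standards)
    write_rf_table(rf, out_path("rf_train.csv"))
    rf
  })

  desc <- run_stage("featurize", {
    d_train <- build_descriptor_table(merge_split_peaks(sim$train$features))
    d_test <- build_descriptor_table(merge_split_peaks(sim$test$features))
    write_csv_plain(d_train, out_path("descriptors_train.csv"))
    write_csv_plain(d_test, out_path("descriptors_test.csv"))
    list(train = d_train, test = d_test)
  })

  tr <- config$training
  model_set <- run_stage("train", {
    train_model_set(desc$train, rf_train, seed = seed,
                    num_trees = tr$num_trees, mtry_grid = tr$mtry_grid,
                    min_node_grid = tr$min_node_grid, folds = tr$folds,
                    min_training = tr$min_training)
  })

  run_stage("importance", {
    imp <- permutation_importance(model_set, desc$train, rf_train,
                                  n_repeats = config$importance$n_repeats,
                                  seed = seed)
    write_csv_plain(imp, out_path("importance.csv"))
  })

  preds <- run_stage("predict", {
    det <- sim$test$features[!is.na(sim$test$features$area), , drop = FALSE]
    cond_detected <- unique(det[, c("compound_id", "mode", "ph")])
    test_rt <- feature_mean_rt(sim$test$features)
    keys <- condition_keys()
    methods <- list()
    for (i in seq_len(nrow(keys))) {
      mode <- keys$mode[i]; ph <- keys$ph[i]
      label <- condition_label(mode, ph)
      here <- cond_detected[cond_detected$mode == mode &
                              cond_detected$ph == ph, , drop = FALSE]
      if (nrow(here) == 0) next
      dsub <- desc$test[desc$test$compound_id %in% here$compound_id, ,
                        drop = FALSE]
      if (!is.null(model_set$models[[label]])) {
        methods$lcms_descriptors <- rbind(
          methods$lcms_descriptors,
          data.frame(compound_id = dsub$compound_id, mode = mode, ph = ph,
                     rf_pred = 10^predict_log_rf(model_set, dsub, mode, ph),
                     stringsAsFactors = FALSE))
      }
      if (any(rf_train$mode == mode & rf_train$ph == ph)) {
        methods$equal_rf <- rbind(
          methods$equal_rf,
          data.frame(compound_id = here$compound_id, mode = mode, ph = ph,
                     rf_pred = equal_rf_baseline(rf_train, mode, ph),
                     stringsAsFactors = FALSE))
        rt_here <- merge(here, test_rt, by = c("compound_id", "mode", "ph"))
        methods$closest_eluting <- rbind(
          methods$closest_eluting,
          data.frame(compound_id = rt_here$compound_id, mode = mode, ph = ph,
                     rf_pred = closest_eluting_baseline(
                       rf_train, rt_here$mean_rt, mode, ph),
                     stringsAsFactors = FALSE))
      }
    }
    # concentration ranges across conditions for the descriptor models
    if (!is.null(methods$lcms_descriptors)) {
      est <- evaluate_quantification(sim$test$features, sim$test$standards,
                                     methods$lcms_descriptors)
      ranges <- do.call(rbind, lapply(
        split(est, paste(est$compound_id, est$dilution_factor, sep = "\r")),
        function(g) {
          agg <- aggregate_estimates(g$c_predicted)
          data.frame(compound_id = g$compound_id[1],
                     dilution_factor = g$dilution_factor[1],
                     n_conditions = nrow(g),
                     range_min = agg$range_min,
                     range_median = agg$range_median,
                     range_max = agg$range_max, stringsAsFactors = FALSE)
        }))
      ranges <- ranges[order(ranges$compound_id, ranges$dilution_factor), ,
                       drop = FALSE]
      write_csv_plain(ranges, out_path("concentration_ranges.csv"))
      pred_out <- methods$lcms_descriptors
      write_csv_plain(pred_out[order(pred_out$compound_id,
                                     condition_order(pred_out$mode,
                                                     pred_out$ph)), ],
                      out_path("predictions.csv"))
    }
    methods
  })

  summary_df <- run_stage("evaluate", {
    thr <- config$evaluation$threshold
    rows <- list(); all_records <- list()
    for (method in names(preds)) {
      ev <- evaluate_quantification(sim$test$features, sim$test$standards,
                                    preds[[method]])
      ev$method <- method
      all_records[[method]] <- ev
      s <- summarize_errors(ev$fold_error, threshold = thr)
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, mode = NA_character_, ph = NA_real_,
        mean_fold = s$mean_fold, median_fold = s$median_fold,
        max_fold = s$max_fold, frac_below_10 = s$frac_below_10, n = s$n,
        stringsAsFactors = FALSE)
      for (key in split(ev, paste(ev$mode, ev$ph, sep = "\r"))) {
        s <- summarize_errors(key$fold_error, threshold = thr)
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, mode = key$mode[1], ph = key$ph[1],
          mean_fold = s$mean_fold, median_fold = s$median_fold,
          max_fold = s$max_fold, frac_below_10 = s$frac_below_10, n = s$n,
          stringsAsFactors = FALSE)
      }
    }
    evaluation <- do.call(rbind, all_records)
    rownames(evaluation) <- NULL
    write_csv_plain(evaluation, out_path("evaluation.csv"))
    summary_df <- do.call(rbind, rows)
    write_csv_plain(summary_df, out_path("summary.csv"))
    attr(summary_df, "evaluation") <- evaluation
    summary_df
  })

  invisible(list(summary = summary_df,
                 evaluation = attr(summary_df, "evaluation"),
                 model_set = model_set,
                 output_dir = config$output_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
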