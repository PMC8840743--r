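#' Response-factor predictors
#'
#' One random-forest regressor per measurement condition predicts the log10
#' response factor from the twelve LC/MS descriptors. Two formula-defined
#' baselines are provided for comparison: the equal-response-factor baseline
#' (geometric mean RF of the training standards) and the closest-eluting
#' standard baseline (RF of the training standard with the nearest mean
#' retention time). A simplified linear model on the pH 8.0 pos/neg area
#' ratio and shallow interpretive regression trees support model inspection.
#'
#' @name predictors
#' @importFrom ranger ranger
#' @importFrom rpart rpart rpart.control
NULL

# Join a condition's response factors with the descriptor table; returns a
# data frame of descriptors plus log_rf, rownames = compound ids.
condition_training_frame <- function(descriptors, rf_table, mode, ph) {
  sub <- rf_table[rf_table$mode == mode & rf_table$ph == ph, , drop = FALSE]
  df <- merge(sub[, c("compound_id", "log_rf")], descriptors,
              by = "compound_id")
  df <- df[order(df$compound_id), , drop = FALSE]
  rownames(df) <- df$compound_id
  df[, c("log_rf", descriptor_names())]
}

# 5-fold CV over a small grid; returns the grid row with lowest CV RMSE
# (first such row on ties, so selection is deterministic under the seed).
tune_forest <- function(df, grid, folds, num_trees, seed) {
  n <- nrow(df)
  fold_id <- with_local_seed(seed, sample(rep_len(seq_len(folds), n)))
  rmse <- vapply(seq_len(nrow(grid)), function(g) {
    sq_err <- 0
    for (f in seq_len(folds)) {
      hold <- fold_id == f
      if (!any(hold) || sum(!hold) < 2) next
      fit <- ranger::ranger(
        dependent.variable.name = "log_rf", data = df[!hold, , drop = FALSE],
        num.trees = num_trees, mtry = grid$mtry[g],
        min.node.size = grid$min_node[g],
        seed = seed + g, num.threads = 1, verbose = FALSE)
      pred <- stats::predict(fit, df[hold, , drop = FALSE],
                             num.threads = 1)$predictions
      sq_err <- sq_err + sum((pred - df$log_rf[hold])^2)
    }
    sqrt(sq_err / n)
  }, numeric(1))
  cbind(grid[which.min(rmse), , drop = FALSE], cv_rmse = min(rmse))
}

#' Train the per-condition model set
#'
#' Fits one random-forest regressor of log10 RF on the twelve descriptors per
#' condition, tuning the number of candidate features per split and the
#' minimum leaf size by k-fold cross-validation over a small grid. Conditions
#' with fewer than `min_training` training compounds are skipped with a
#' message. Sentinel descriptor values (±999) are passed to the trees
#' untransformed.
#'
#' @param descriptors descriptor table from [build_descriptor_table()]
#' @param rf_table response-factor table from [build_training_table()]
#' @param seed integer seed; training is deterministic under it
#' @param num_trees trees per forest (default 500)
#' @param mtry_grid candidate features-per-split values
#' @param min_node_grid candidate minimum leaf sizes
#' @param folds cross-validation folds (default 5)
#' @param min_training minimum training compounds per condition (default 10)
#' @return an object of class `model_set` with elements `models` (named by
#'   condition label), `hyperparameters`, `training_ids` and `seed`
#' @export
train_model_set <- function(descriptors, rf_table, seed = 1,
                            num_trees = 500, mtry_grid = c(3, 6, 9),
                            min_node_grid = c(2, 5), folds = 5,
                            min_training = 10) {
  keys <- condition_keys()
  grid <- expand.grid(mtry = mtry_grid, min_node = min_node_grid)
  models <- list(); hyper <- list(); ids <- list()
  for (i in seq_len(nrow(keys))) {
    mode <- keys$mode[i]; ph <- keys$ph[i]
    label <- condition_label(mode, ph)
    df <- condition_training_frame(descriptors, rf_table, mode, ph)
    if (nrow(df) < min_training) {
      message(sprintf("skipping %s: %d training compound(s) < %d",
                      label, nrow(df), min_training))
      next
    }
    cond_seed <- seed + 1000L * i
    best <- tune_forest(df, grid, folds, num_trees, cond_seed)
    fit <- ranger::ranger(
      dependent.variable.name = "log_rf", data = df,
      num.trees = num_trees, mtry = best$mtry,
      min.node.size = best$min_node,
      seed = cond_seed, num.threads = 1, verbose = FALSE)
    models[[label]] <- fit
    hyper[[label]] <- best
    ids[[label]] <- rownames(df)
  }
  if (length(models) == 0) {
    stop("no condition had enough training compounds to fit a model",
         call. = FALSE)
  }
  structure(list(models = models, hyperparameters = hyper,
                 training_ids = ids, seed = seed),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("model_set: %d condition model(s), seed %d\n",
              length(x$models), x$seed))
  for (label in names(x$models)) {
    h <- x$hyperparameters[[label]]
    cat(sprintf("  %-18s n=%3d  mtry=%d  min.node=%d  cv RMSE=%.3f\n",
                label, length(x$training_ids[[label]]), h$mtry, h$min_node,
                h$cv_rmse))
  }
  invisible(x)
}

#' Predict log10 response factors for one condition
#'
#' @param model_set a [train_model_set()] result
#' @param descriptors descriptor table (rows for the compounds to predict)
#' @param mode,ph the condition; a model must exist for it
#' @return numeric vector of predicted log10 RF, named by compound id when
#'   the table carries one
#' @export
predict_log_rf <- function(model_set, descriptors, mode, ph) {
  stopifnot(inherits(model_set, "model_set"))
  label <- condition_label(mode, ph)
  fit <- model_set$models[[label]]
  if (is.null(fit)) {
    stop("no model available for condition ", label, call. = FALSE)
  }
  missing_cols <- setdiff(descriptor_names(), names(descriptors))
  if (length(missing_cols) > 0) {
    stop("descriptor table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pred <- stats::predict(fit, descriptors[, descriptor_names(), drop = FALSE],
                         num.threads = 1)$predictions
  if ("compound_id" %in% names(descriptors)) {
    names(pred) <- descriptors$compound_id
  }
  pred
}

#' Permutation variable importance
#'
#' Importance of a descriptor for one condition model is the mean increase in
#' squared prediction error on that model's training rows when the descriptor
#' column is randomly permuted, averaged over `n_repeats` permutations.
#'
#' @param model_set a [train_model_set()] result
#' @param descriptors descriptor table used in training
#' @param rf_table response-factor table used in training
#' @param n_repeats permutations per descriptor (default 10)
#' @param seed integer seed; the report is deterministic under it
#' @return data frame with columns `model`, `descriptor`, `importance` and
#'   `rank` (1 = most important), 12 rows per condition model
#' @export
permutation_importance <- function(model_set, descriptors, rf_table,
                                   n_repeats = 10, seed = 1) {
  stopifnot(inherits(model_set, "model_set"))
  keys <- condition_keys()
  out <- list()
  with_local_seed(seed, {
    for (i in seq_len(nrow(keys))) {
      label <- condition_label(keys$mode[i], keys$ph[i])
      fit <- model_set$models[[label]]
      if (is.null(fit)) next
      df <- condition_training_frame(descriptors, rf_table,
                                     keys$mode[i], keys$ph[i])
      df <- df[rownames(df) %in% model_set$training_ids[[label]], ,
               drop = FALSE]
      x <- df[, descriptor_names(), drop = FALSE]
      y <- df$log_rf
      base_mse <- mean((stats::predict(fit, x, num.threads = 1)$predictions
                        - y)^2)
      imp <- vapply(descriptor_names(), function(d) {
        delta <- vapply(seq_len(n_repeats), function(r) {
          xp <- x
          xp[[d]] <- xp[[d]][sample.int(nrow(xp))]
          mean((stats::predict(fit, xp, num.threads = 1)$predictions - y)^2) -
            base_mse
        }, numeric(1))
        mean(delta)
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        model = label, descriptor = descriptor_names(),
        importance = unname(imp),
        rank = rank(-imp, ties.method = "first"),
        stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Equal-response-factor baseline
#'
#' The back-transformed mean of the training standards' log10 response
#' factors (their geometric mean RF) is assigned to every compound.
#'
#' @param rf_table training response-factor table
#' @param mode,ph the condition
#' @return response factor in M^-1
#' @examples
#' rf <- data.frame(compound_id = c("a", "b"), mode = "positive", ph = 2.7,
#'                  rf = c(1e14, 1e16), log_rf = c(14, 16),
#'                  mean_rt = c(5, 10), n_points_used = 5L)
#' equal_rf_baseline(rf, "positive", 2.7)  # 1e15
#' @export
equal_rf_baseline <- function(rf_table, mode, ph) {
  assert_condition(mode, ph)
  sub <- rf_table[rf_table$mode == mode & rf_table$ph == ph, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("no training response factors for condition ",
         condition_label(mode, ph), call. = FALSE)
  }
  10^mean(log10(sub$rf))
}

#' Closest-eluting-standard baseline
#'
#' Each query compound is assigned the response factor of the training
#' standard whose mean retention time is nearest to the query retention
#' time; ties go to the earlier-eluting standard.
#'
#' @param rf_table training response-factor table (with `mean_rt`)
#' @param query_rt query retention time(s) in minutes
#' @param mode,ph the condition
#' @return response factor(s) in M^-1, one per query
#' @export
closest_eluting_baseline <- function(rf_table, query_rt, mode, ph) {
  assert_condition(mode, ph)
  sub <- rf_table[rf_table$mode == mode & rf_table$ph == ph &
                    !is.na(rf_table$mean_rt), , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("no training response factors with retention times for condition ",
         condition_label(mode, ph), call. = FALSE)
  }
  vapply(query_rt, function(q) {
    ord <- order(abs(sub$mean_rt - q), sub$mean_rt)
    sub$rf[ord[1]]
  }, numeric(1))
}

#' Simplified linear model on the pH 8.0 area ratio
#'
#' For compounds detected in both modes at pH 8.0, the log10 positive-mode
#' response factor is close to linear in the log10 pos/neg area ratio at the
#' same pH. This fits that line by OLS, excluding sentinel ratios.
#'
#' @param rf_table training response-factor table
#' @param descriptors descriptor table
#' @return object of class `simplified_rf_model` with `intercept`, `slope`,
#'   `r_squared` and `n`; predict with [predict.simplified_rf_model()]
#' @export
fit_simplified_linear <- function(rf_table, descriptors) {
  df <- condition_training_frame(descriptors, rf_table, "positive", 8.0)
  df <- df[abs(df$ratio_ph8_0) < 900, , drop = FALSE]
  if (nrow(df) < 3) {
    stop("need at least 3 compounds detected in both modes at pH 8.0",
         call. = FALSE)
  }
  fit <- stats::lm(log_rf ~ ratio_ph8_0, data = df)
  ss_tot <- sum((df$log_rf - mean(df$log_rf))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot
        else NA_real_
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = r2, n = nrow(df)),
            class = "simplified_rf_model")
}

#' Predict log10 RF from a pH 8.0 area ratio with the simplified model
#' @param object a [fit_simplified_linear()] result
#' @param ratio log10 pos/neg area ratio(s) at pH 8.0 (no sentinels)
#' @param ... unused
#' @export
predict.simplified_rf_model <- function(object, ratio, ...) {
  if (any(abs(ratio) >= 900)) {
    stop("simplified model is undefined for sentinel ratios", call. = FALSE)
  }
  object$intercept + object$slope * ratio
}

#' @export
print.simplified_rf_model <- function(x, ...) {
  cat(sprintf(
    "simplified linear model: log10 RF = %.3f + %.3f x ratio (R^2 %.3f, n %d)\n",
    x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Interpretive regression tree for one condition
#'
#' A single depth-limited regression tree on the twelve descriptors, meant
#' for inspection of what the forests learn rather than for prediction
#' accuracy. `max_depth = 0` yields a single leaf holding the mean log RF.
#'
#' @param descriptors descriptor table
#' @param rf_table training response-factor table
#' @param mode,ph the condition
#' @param max_depth maximum tree depth (default 3)
#' @param min_training minimum training compounds (default 10)
#' @return object of class `interpretive_tree`; print it for a nested
#'   (descriptor, threshold, children / leaf value) text rendering
#' @export
fit_interpretive_tree <- function(descriptors, rf_table, mode, ph,
                                  max_depth = 3, min_training = 10) {
  df <- condition_training_frame(descriptors, rf_table, mode, ph)
  if (nrow(df) < min_training) {
    stop(sprintf("only %d training compound(s) for %s (< %d)", nrow(df),
                 condition_label(mode, ph), min_training), call. = FALSE)
  }
  if (max_depth == 0) {
    obj <- list(fit = NULL, leaf_value = mean(df$log_rf), n = nrow(df),
                mode = mode, ph = ph, max_depth = 0)
  } else {
    fit <- rpart::rpart(
      log_rf ~ ., data = df, method = "anova",
      control = rpart::rpart.control(maxdepth = max_depth, minsplit = 5,
                                     minbucket = 2, cp = 1e-4, xval = 0))
    obj <- list(fit = fit, leaf_value = NULL, n = nrow(df),
                mode = mode, ph = ph, max_depth = max_depth)
  }
  structure(obj, class = "interpretive_tree")
}

#' Descriptor used at the root split of an interpretive tree
#' @param tree an `interpretive_tree`
#' @return descriptor name, or `NA` for a single-leaf tree
#' @export
tree_root_descriptor <- function(tree) {
  stopifnot(inherits(tree, "interpretive_tree"))
  if (is.null(tree$fit)) return(NA_character_)
  v <- as.character(tree$fit$frame$var[1])
  if (v == "<leaf>") NA_character_ else v
}

#' Predict with an interpretive tree
#' @param object an `interpretive_tree`
#' @param newdata descriptor table
#' @param ... unused
#' @export
predict.interpretive_tree <- function(object, newdata, ...) {
  if (is.null(object$fit)) return(rep(object$leaf_value, nrow(newdata)))
  unname(stats::predict(object$fit,
                        newdata[, descriptor_names(), drop = FALSE]))
}

#' @export
format.interpretive_tree <- function(x, ...) {
  header <- sprintf("interpretive tree (%s, n = %d, max depth %d)",
                    condition_label(x$mode, x$ph), x$n, x$max_depth)
  if (is.null(x$fit)) {
    return(c(header, sprintf("  leaf: log10 RF = %.3f", x$leaf_value)))
  }
  frame <- x$fit$frame
  node_ids <- as.integer(rownames(frame))
  lab <- labels(x$fit)
  render <- function(id, depth) {
    i <- match(id, node_ids)
    indent <- strrep("  ", depth + 1)
    if (as.character(frame$var[i]) == "<leaf>") {
      sprintf("%sleaf [%s]: log10 RF = %.3f (n = %d)", indent, lab[i],
              frame$yval[i], frame$n[i])
    } else {
      c(sprintf("%snode [%s]: split on %s", indent, lab[i],
                as.character(frame$var[i])),
        render(2L * id, depth + 1), render(2L * id + 1L, depth + 1))
    }
  }
  c(header, render(1L, 0))
}

#' @export
print.interpretive_tree <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}
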