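#' Quantification and evaluation
#'
#' Concentrations follow from peak areas and predicted response factors as
#' c = area / RF (the calibration intercept is assumed insignificant).
#' Prediction accuracy is expressed as a fold error,
#' max(c_pred / c_actual, c_actual / c_pred), summarized by its mean, median
#' and maximum and by the fraction of datapoints with fold error strictly
#' below 10. Multiplicative uncertainties from independent sources (e.g.
#' concentration and toxicity predictions in risk screening) combine in
#' quadrature on the relative scale.
#'
#' @name quantification
NULL

#' Estimate a molar concentration from a peak area and response factor
#'
#' @param area peak area (arbitrary counts, positive)
#' @param rf_pred predicted response factor in M^-1 (positive)
#' @return concentration in M: `area / rf_pred`
#' @examples
#' estimate_concentration(2.4e10, 1.2e17)  # 2e-7 M
#' @export
estimate_concentration <- function(area, rf_pred) {
  if (any(!is.finite(area) | area <= 0) ||
      any(!is.finite(rf_pred) | rf_pred <= 0)) {
    stop("area and rf_pred must be positive", call. = FALSE)
  }
  area / rf_pred
}

#' Aggregate per-condition concentration estimates into a range
#'
#' With one model per condition, a compound detected under several conditions
#' receives up to six concentration estimates; these are reported as a range
#' (min / median / max). The median of an even count is the arithmetic
#' midpoint of the two central values.
#'
#' @param per_condition named numeric vector (or list) of per-condition
#'   concentration estimates in M; nonempty, all positive
#' @return list with `per_condition`, `range_min`, `range_median`,
#'   `range_max`
#' @export
aggregate_estimates <- function(per_condition) {
  est <- unlist(per_condition)
  if (length(est) == 0) stop("no concentration estimates", call. = FALSE)
  if (any(!is.finite(est) | est <= 0)) {
    stop("concentration estimates must be positive", call. = FALSE)
  }
  list(per_condition = est, range_min = min(est),
       range_median = stats::median(est), range_max = max(est))
}

#' Fold error of a concentration prediction
#'
#' @param c_predicted,c_actual molar concentrations (positive); vectorized
#' @return `max(c_predicted / c_actual, c_actual / c_predicted)`, symmetric
#'   and >= 1, equal to 1 iff the inputs are equal
#' @examples
#' fold_error(2e-7, 1e-7)  # 2
#' @export
fold_error <- function(c_predicted, c_actual) {
  if (any(!is.finite(c_predicted) | c_predicted <= 0) ||
      any(!is.finite(c_actual) | c_actual <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  pmax(c_predicted / c_actual, c_actual / c_predicted)
}

#' Summarize fold errors
#'
#' @param fold_errors numeric vector of fold errors (each >= 1), one per
#'   datapoint (compound x concentration x condition)
#' @param threshold the "acceptable" fold threshold (default 10); the
#'   reported fraction uses a strict `<` comparison
#' @return list with `mean_fold`, `median_fold`, `max_fold`,
#'   `frac_below_10` and `n`
#' @examples
#' summarize_errors(c(1, 10, 100))  # mean 37, frac_below_10 = 1/3
#' @export
summarize_errors <- function(fold_errors, threshold = 10) {
  if (length(fold_errors) == 0) stop("no evaluation records", call. = FALSE)
  if (any(!is.finite(fold_errors) | fold_errors < 1)) {
    stop("fold errors must be finite and >= 1", call. = FALSE)
  }
  list(mean_fold = mean(fold_errors),
       median_fold = stats::median(fold_errors),
       max_fold = max(fold_errors),
       frac_below_10 = mean(fold_errors < threshold),
       n = length(fold_errors))
}

#' Combine multiplicative (fold) uncertainties
#'
#' Each fold factor f >= 1 is converted to a relative uncertainty u = f - 1,
#' the relative uncertainties are combined in quadrature following the law of
#' propagation of error for a product, and the result is converted back:
#' 1 + sqrt(sum(u^2)). The larger uncertainty dominates: combining a factor
#' of 10 with a factor of 1.2 still gives a factor of 10 (to rounding), while
#' two factors of 10 give a factor of 13.7.
#'
#' @param factors fold-uncertainty factors, each >= 1
#' @return combined fold-uncertainty factor
#' @examples
#' combine_uncertainty_factors(c(10, 10))   # 13.73
#' combine_uncertainty_factors(c(10, 1.2))  # 10.00
#' @export
combine_uncertainty_factors <- function(factors) {
  if (length(factors) == 0) stop("no uncertainty factors", call. = FALSE)
  if (any(!is.finite(factors) | factors < 1)) {
    stop("uncertainty factors must be >= 1", call. = FALSE)
  }
  1 + sqrt(sum((factors - 1)^2))
}

#' Evaluate response-factor predictions against known concentrations
#'
#' Builds one evaluation record per detected datapoint (compound x dilution x
#' condition): the predicted concentration is the peak area divided by the
#' predicted RF for that (compound, condition), the actual concentration
#' comes from the standards table, and the fold error compares the two.
#'
#' @param records peak-record data frame (split peaks merged)
#' @param standards standards table with the true concentrations
#' @param rf_pred data frame with columns compound_id, mode, ph, rf_pred
#' @return data frame with columns compound_id, mode, ph, dilution_factor,
#'   c_actual, c_predicted, fold_error
#' @export
evaluate_quantification <- function(records, standards, rf_pred) {
  records <- validate_feature_table(records)
  det <- records[!is.na(records$area), , drop = FALSE]
  df <- merge(det, standards, by = c("compound_id", "dilution_factor"))
  df <- merge(df, rf_pred[, c("compound_id", "mode", "ph", "rf_pred")],
              by = c("compound_id", "mode", "ph"))
  if (nrow(df) == 0) {
    return(data.frame(compound_id = character(), mode = character(),
                      ph = numeric(), dilution_factor = numeric(),
                      c_actual = numeric(), c_predicted = numeric(),
                      fold_error = numeric(), stringsAsFactors = FALSE))
  }
  df$c_predicted <- estimate_concentration(df$area, df$rf_pred)
  df$fold_error <- fold_error(df$c_predicted, df$concentration_M)
  out <- data.frame(compound_id = df$compound_id, mode = df$mode, ph = df$ph,
                    dilution_factor = df$dilution_factor,
                    c_actual = df$concentration_M,
                    c_predicted = df$c_predicted,
                    fold_error = df$fold_error, stringsAsFactors = FALSE)
  out <- out[order(out$compound_id, condition_order(out$mode, out$ph),
                   out$dilution_factor), , drop = FALSE]
  rownames(out) <- NULL
  out
}
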