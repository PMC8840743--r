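#' Calibration: response factors from dilution series
#'
#' The response factor of a compound under one condition is the slope of the
#' linear range of its calibration curve (peak area versus molar
#' concentration), fitted by ordinary least squares with a free intercept.
#' Quantification later ignores the intercept, which is assumed
#' insignificant.
#'
#' @name calibration
NULL

# Acceptance test for one candidate point set: the OLS fit must have
# R^2 >= r2_min and every point's back-calculated concentration
# (area - intercept)/slope must sit within max_backcalc_dev of nominal.
# The back-calculation check is what actually catches saturated top points:
# a high-leverage saturated point can dominate the fit and keep R^2 high
# while ruining accuracy at the low end.
calibration_fit_ok <- function(conc, area, r2_min, max_backcalc_dev) {
  fit <- stats::lm.fit(cbind(1, conc), area)
  slope <- fit$coefficients[2]
  if (!is.finite(slope) || slope <= 0) return(FALSE)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((area - mean(area))^2)
  if (ss_tot <= 0) return(FALSE)
  r2 <- 1 - ss_res / ss_tot
  back <- (area - fit$coefficients[1]) / slope
  r2 >= r2_min && all(abs(back / conc - 1) <= max_backcalc_dev)
}

# Linear-range selection: with points sorted by concentration, drop the
# highest-concentration point while more than 3 remain and the current set
# fails the acceptance test. Returns indices (into the sorted order) kept.
select_linear_range <- function(conc, area, r2_min = 0.99,
                                max_backcalc_dev = 0.3) {
  n <- length(conc)
  keep <- n
  while (keep > 3 && !calibration_fit_ok(conc[seq_len(keep)],
                                         area[seq_len(keep)],
                                         r2_min, max_backcalc_dev)) {
    keep <- keep - 1
  }
  seq_len(keep)
}

#' Fit a response factor from a calibration series
#'
#' Ordinary least squares of area on concentration with a free intercept,
#' restricted to an automatically selected linear range: points are dropped
#' from the top of the concentration range (where electrospray saturation is
#' the dominant nonlinearity) while the fit fails an accuracy criterion
#' (R^2 >= `r2_min` and back-calculated concentrations within
#' `max_backcalc_dev` of nominal) and more than three points remain.
#'
#' @param concentration molar concentrations of the detected dilutions
#' @param area corresponding peak areas
#' @param r2_min minimum R^2 for the linear range (default 0.99)
#' @param max_backcalc_dev maximum relative deviation of back-calculated
#'   from nominal concentration within the linear range (default 0.3)
#' @return list with `rf` (fitted slope, M^-1), `log_rf` (log10 of it),
#'   `intercept`, `r_squared`, `n_points_used`, and `points_used` (logical
#'   vector over the input points, in input order)
#' @examples
#' fit_response_factor(c(1e-7, 2e-7, 4e-7), c(1e9, 2e9, 4e9))$rf  # 1e16
#' @export
fit_response_factor <- function(concentration, area,
                                r2_min = 0.99, max_backcalc_dev = 0.3) {
  ok <- is.finite(concentration) & is.finite(area)
  concentration <- concentration[ok]
  area <- area[ok]
  if (length(concentration) < 3) {
    stop("insufficient data: calibration needs at least 3 detected points",
         call. = FALSE)
  }
  if (any(concentration <= 0) || any(area <= 0)) {
    stop("calibration points must have positive concentration and area",
         call. = FALSE)
  }
  if (anyDuplicated(concentration)) {
    stop("calibration concentrations must be distinct", call. = FALSE)
  }
  ord <- order(concentration)
  conc_s <- concentration[ord]
  area_s <- area[ord]
  kept_s <- select_linear_range(conc_s, area_s, r2_min, max_backcalc_dev)
  fit <- stats::lm.fit(cbind(1, conc_s[kept_s]), area_s[kept_s])
  slope <- unname(fit$coefficients[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("degenerate calibration: fitted slope is not positive",
         call. = FALSE)
  }
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((area_s[kept_s] - mean(area_s[kept_s]))^2)
  points_used <- logical(length(ok))
  points_used[which(ok)[ord[kept_s]]] <- TRUE
  list(rf = slope, log_rf = log10(slope),
       intercept = unname(fit$coefficients[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       n_points_used = length(kept_s), points_used = points_used)
}

#' Build the per-condition response-factor table for a set of standards
#'
#' For every (standard compound, condition) with at least three detected
#' dilutions that have known concentrations, fits the response factor and
#' attaches the mean retention time over detected dilutions. Split peaks
#' should be merged first (see [merge_split_peaks()]). Compound-conditions
#' that fail the preconditions (or produce a degenerate calibration) are
#' skipped with a message.
#'
#' @param records peak-record data frame
#' @param standards standards table (compound_id, dilution_factor,
#'   concentration_M)
#' @param r2_min,max_backcalc_dev passed to [fit_response_factor()]
#' @return response-factor data frame with columns compound_id, mode, ph,
#'   rf, log_rf, mean_rt, n_points_used
#' @export
build_training_table <- function(records, standards,
                                 r2_min = 0.99, max_backcalc_dev = 0.3) {
  records <- validate_feature_table(records)
  det <- records[!is.na(records$area), , drop = FALSE]
  out <- list()
  if (nrow(det) > 0) {
    det <- merge(det, standards, by = c("compound_id", "dilution_factor"))
    key <- paste(det$compound_id, det$mode, det$ph, sep = "\r")
    for (idx in split(seq_len(nrow(det)), key)) {
      g <- det[idx, , drop = FALSE]
      if (nrow(g) < 3) {
        message(sprintf("skipping %s (%s, pH %s): only %d detected dilution(s)",
                        g$compound_id[1], g$mode[1], g$ph[1], nrow(g)))
        next
      }
      fit <- tryCatch(
        fit_response_factor(g$concentration_M, g$area,
                            r2_min = r2_min,
                            max_backcalc_dev = max_backcalc_dev),
        error = function(e) {
          message(sprintf("skipping %s (%s, pH %s): %s", g$compound_id[1],
                          g$mode[1], g$ph[1], conditionMessage(e)))
          NULL
        })
      if (is.null(fit)) next
      out[[length(out) + 1L]] <- data.frame(
        compound_id = g$compound_id[1], mode = g$mode[1], ph = g$ph[1],
        rf = fit$rf, log_rf = fit$log_rf,
        mean_rt = mean_retention_time(g),
        n_points_used = fit$n_points_used, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(compound_id = character(), mode = character(),
                      ph = numeric(), rf = numeric(), log_rf = numeric(),
                      mean_rt = numeric(), n_points_used = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$compound_id, condition_order(res$mode, res$ph)), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
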