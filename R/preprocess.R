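#' Feature-table preprocessing
#'
#' Chromatographic artifacts sometimes split one compound's peak into two or
#' more integrated peaks within the same run. Such split peaks are merged by
#' summing their areas and averaging their retention times before any
#' calibration or descriptor work.
#'
#' @name preprocess
NULL

#' Merge split peaks
#'
#' Within each (compound, mode, pH, dilution) group, all detected records are
#' collapsed to a single record whose area is the sum of the member areas and
#' whose retention time is the arithmetic mean of the member retention times.
#' Groups with a single detected record pass through unchanged; not-detected
#' records take no part in merging and are retained as not-detected.
#'
#' The operation is idempotent and conserves total detected area per group.
#'
#' @param records peak-record data frame
#' @return peak-record data frame with at most one detected record per
#'   (compound, mode, pH, dilution) group
#' @examples
#' recs <- data.frame(
#'   compound_id = "c1", mode = "positive", ph = 2.7, dilution_factor = 1,
#'   area = c(1e6, 2e6), rt = c(5.0, 5.2), mz = 195.09, na_adduct = FALSE)
#' merge_split_peaks(recs)  # area 3e6, rt 5.1
#' @export
merge_split_peaks <- function(records) {
  records <- validate_feature_table(records)
  if (nrow(records) == 0) return(records)
  detected <- !is.na(records$area)
  und <- records[!detected, , drop = FALSE]
  det <- records[detected, , drop = FALSE]
  if (nrow(det) > 0) {
    key <- paste(det$compound_id, det$mode, det$ph, det$dilution_factor,
                 sep = "\r")
    groups <- split(seq_len(nrow(det)), key)
    merged <- lapply(groups, function(idx) {
      g <- det[idx, , drop = FALSE]
      if (nrow(g) == 1) return(g)
      out <- g[1, , drop = FALSE]
      out$area <- sum(g$area)
      out$rt <- mean(g$rt)
      out$mz <- mean(g$mz)
      out$na_adduct <- any(g$na_adduct)
      out
    })
    det <- do.call(rbind, merged)
  }
  sort_feature_table(rbind(det, und))
}

#' Mean retention time over detected dilutions
#'
#' The retention time assigned to a compound under one condition is the
#' arithmetic mean of its retention times over all dilutions where it was
#' detected.
#'
#' @param records peak-record data frame for one compound and condition (or
#'   any subset thereof); not-detected rows are ignored
#' @return mean retention time in minutes
#' @export
mean_retention_time <- function(records) {
  rt <- records$rt
  rt <- rt[!is.na(rt)]
  if (length(rt) == 0) {
    stop("retention time undefined: no detected record", call. = FALSE)
  }
  mean(rt)
}
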