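#' LC/MS descriptors
#'
#' Twelve descriptors summarize each compound's chromatographic and mass
#' spectrometric behaviour without any structural information: the log10
#' positive/negative peak-area ratio at each mobile-phase pH, the retention
#' time at each pH, two retention-time differences between pHs, the m/z of
#' the detected ion, sodium-adduct formation at pH 2.7, negative-mode
#' detectability, and the parity of the nominal mass. Ratios use the
#' sentinel -999 when the compound was not detected in positive mode at that
#' pH and +999 when it was not detected in negative mode; tree ensembles
#' handle such consistent out-of-range values without imputation. Missing
#' retention times (and differences involving them) use -999.
#'
#' @name descriptors
NULL

#' Fixed, ordered names of the twelve descriptors
#' @export
descriptor_names <- function() {
  c("ratio_ph2_7", "ratio_ph8_0", "ratio_ph10_0",
    "rt_ph2_7", "rt_ph8_0", "rt_ph10_0",
    "d_rt_8_minus_2_7", "d_rt_8_minus_10",
    "mz", "na_adduct", "detected_neg", "mz_parity")
}

SENTINEL_NEG <- -999
SENTINEL_POS <- 999

#' Log10 positive/negative peak-area ratio with detection sentinels
#'
#' @param pos_area positive-mode peak area, or `NA` if not detected
#' @param neg_area negative-mode peak area, or `NA` if not detected
#' @return `log10(pos_area / neg_area)` when both are present; -999 when the
#'   compound was not detected in positive mode; +999 when not detected in
#'   negative mode
#' @examples
#' log_area_ratio(1e6, 1e4)  # 2
#' log_area_ratio(NA, 5e5)   # -999
#' @export
log_area_ratio <- function(pos_area, neg_area) {
  if (is.na(pos_area) && is.na(neg_area)) {
    stop("undefined ratio: compound not detected in either mode",
         call. = FALSE)
  }
  if (is.na(pos_area)) return(SENTINEL_NEG)
  if (is.na(neg_area)) return(SENTINEL_POS)
  if (pos_area <= 0 || neg_area <= 0) {
    stop("areas must be positive when present", call. = FALSE)
  }
  log10(pos_area / neg_area)
}

#' Retention-time difference with a missing-value sentinel
#'
#' @param rt_a,rt_b retention times in minutes, or `NA` when unavailable
#' @return `rt_a - rt_b`, or -999 when either is missing
#' @export
rt_difference <- function(rt_a, rt_b) {
  if (is.na(rt_a) || is.na(rt_b)) return(SENTINEL_NEG)
  rt_a - rt_b
}

#' Parity of the nominal (integer) mass of the detected ion
#'
#' The nominal mass is the m/z rounded half away from zero; by the nitrogen
#' rule an odd nominal mass hints at an odd number of nitrogen atoms.
#'
#' @param mz m/z of the detected ion in Da (positive)
#' @return 1 if the nominal mass is odd, 0 if even
#' @examples
#' mz_parity(195.0877)  # 1
#' mz_parity(256.1200)  # 0
#' @export
mz_parity <- function(mz) {
  if (any(mz <= 0)) stop("m/z must be positive", call. = FALSE)
  as.integer(floor(mz + 0.5) %% 2)
}

# Per-pH area ratio for one compound. Uses the mean of per-dilution log10
# ratios over dilutions detected in both modes (robust to LOD censoring at
# the series tails, invariant to the shared concentration). If both modes
# were detected but never at the same dilution, falls back to the difference
# of dilution-normalized mean log areas, which coincides with the former on
# common dilutions. A pH with no detection at all gets -999 (treated like a
# missing positive-mode signal).
ratio_for_ph <- function(pos, neg) {
  if (nrow(pos) == 0 && nrow(neg) == 0) return(SENTINEL_NEG)
  if (nrow(pos) == 0) return(SENTINEL_NEG)
  if (nrow(neg) == 0) return(SENTINEL_POS)
  common <- intersect(pos$dilution_factor, neg$dilution_factor)
  if (length(common) > 0) {
    lp <- log10(pos$area[match(common, pos$dilution_factor)])
    ln <- log10(neg$area[match(common, neg$dilution_factor)])
    mean(lp - ln)
  } else {
    mean(log10(pos$area * pos$dilution_factor)) -
      mean(log10(neg$area * neg$dilution_factor))
  }
}

#' Build the twelve-descriptor vector for one compound
#'
#' @param records peak-record data frame for a single compound (all
#'   conditions and dilutions, split peaks already merged)
#' @return named numeric vector of length 12, in the fixed order of
#'   [descriptor_names()]
#' @export
build_descriptors <- function(records) {
  records <- validate_feature_table(records)
  if (length(unique(records$compound_id)) > 1) {
    stop("build_descriptors expects records for a single compound",
         call. = FALSE)
  }
  det <- records[!is.na(records$area), , drop = FALSE]
  if (nrow(det) == 0) {
    stop("compound not detected in any condition", call. = FALSE)
  }
  phs <- mobile_phase_ph()
  sub <- function(mode, ph) det[det$mode == mode & det$ph == ph, , drop = FALSE]

  ratios <- vapply(phs, function(ph) {
    ratio_for_ph(sub("positive", ph), sub("negative", ph))
  }, numeric(1))

  rts <- vapply(phs, function(ph) {
    pos <- sub("positive", ph); neg <- sub("negative", ph)
    if (nrow(pos) > 0) mean_retention_time(pos)
    else if (nrow(neg) > 0) mean_retention_time(neg)
    else NA_real_
  }, numeric(1))

  d_rt_8_2 <- rt_difference(rts[2], rts[1])
  d_rt_8_10 <- rt_difference(rts[2], rts[3])
  rts[is.na(rts)] <- SENTINEL_NEG

  pos_det <- det[det$mode == "positive", , drop = FALSE]
  neg_det <- det[det$mode == "negative", , drop = FALSE]
  mz <- if (nrow(pos_det) > 0) stats::median(pos_det$mz)
        else stats::median(neg_det$mz) + 2 * PROTON_MASS

  out <- c(ratios, rts, d_rt_8_2, d_rt_8_10, mz,
           as.numeric(any(det$ph == 2.7 & det$na_adduct)),
           as.numeric(nrow(neg_det) > 0), mz_parity(mz))
  names(out) <- descriptor_names()
  out
}

#' Build the descriptor table for all compounds in a feature table
#'
#' @param records peak-record data frame (split peaks already merged)
#' @return data frame with `compound_id` plus the twelve descriptor columns
#'   in fixed order, one row per compound detected anywhere
#' @export
build_descriptor_table <- function(records) {
  records <- validate_feature_table(records)
  det_ids <- sort(unique(records$compound_id[!is.na(records$area)]))
  rows <- lapply(det_ids, function(id) {
    build_descriptors(records[records$compound_id == id, , drop = FALSE])
  })
  out <- as.data.frame(do.call(rbind, rows))
  if (length(det_ids) == 0) {
    out <- as.data.frame(matrix(numeric(), ncol = 12,
                                dimnames = list(NULL, descriptor_names())))
  }
  cbind(data.frame(compound_id = det_ids, stringsAsFactors = FALSE), out)
}
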