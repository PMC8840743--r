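#' Measurement conditions
#'
#' Every acquisition is made under one of six conditions: electrospray
#' polarity (positive or negative) crossed with the aqueous mobile-phase pH
#' (2.7, 8.0 or 10.0). One response-factor model is trained per condition.
#'
#' @name conditions
NULL

#' Valid ionization modes, in canonical order (positive before negative).
#' @export
esi_modes <- function() c("positive", "negative")

#' Valid mobile-phase pH values, ascending.
#' @export
mobile_phase_ph <- function() c(2.7, 8.0, 10.0)

#' All six measurement conditions
#'
#' @return A data frame with columns `mode` and `ph`, one row per condition,
#'   in canonical order: positive mode first, pH ascending within mode.
#' @examples
#' condition_keys()
#' @export
condition_keys <- function() {
  data.frame(
    mode = rep(esi_modes(), each = 3L),
    ph = rep(mobile_phase_ph(), times = 2L),
    stringsAsFactors = FALSE
  )
}

#' Canonical label for a condition, e.g. "positive_pH2.7"
#'
#' @param mode ionization mode, "positive" or "negative"
#' @param ph mobile-phase pH, one of 2.7, 8.0, 10.0
#' @export
condition_label <- function(mode, ph) {
  assert_condition(mode, ph)
  sprintf("%s_pH%s", mode, format(ph, nsmall = 1))
}

#' Integer sort key for conditions (positive < negative, pH ascending)
#' @inheritParams condition_label
#' @export
condition_order <- function(mode, ph) {
  assert_condition(mode, ph)
  match(mode, esi_modes()) * 10L + match(ph, mobile_phase_ph())
}

# Internal validation; vectorized over mode/ph.
assert_condition <- function(mode, ph) {
  if (!all(mode %in% esi_modes())) {
    stop("invalid ionization mode: ",
         paste(unique(setdiff(mode, esi_modes())), collapse = ", "),
         " (must be 'positive' or 'negative')", call. = FALSE)
  }
  if (!all(ph %in% mobile_phase_ph())) {
    stop("invalid mobile-phase pH: ",
         paste(unique(ph[!ph %in% mobile_phase_ph()]), collapse = ", "),
         " (must be one of 2.7, 8, 10)", call. = FALSE)
  }
  invisible(TRUE)
}

# Mass of a proton in Da; converts between ion and neutral masses.
PROTON_MASS <- 1.00727646677
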