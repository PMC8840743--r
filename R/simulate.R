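#' Synthetic LC/ESI/HRMS data generator
#'
#' Generates feature tables with the statistical structure the quantification
#' method assumes: response factors spanning several orders of magnitude,
#' dual-polarity detection at three mobile-phase pHs, dilution series with
#' multiplicative (log-normal) area noise, censoring below a detection
#' threshold, and a positive correlation between the log positive/negative
#' area ratio and the positive-mode log response factor.
#'
#' Each compound carries three latent traits: lipophilicity (drives retention
#' time), basicity and acidity (drive the pH-dependent retention shift and
#' give small mode-specific boosts to ionization). Log10 response factors are
#' Gaussian per mode; the negative-mode draw is correlated with the
#' positive-mode draw so that the pos/neg gap correlates with the
#' positive-mode response factor, and response factors decline with pH in
#' positive mode.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' @param n_compounds number of compounds to generate
#' @param seed integer RNG seed; identical configs reproduce outputs exactly
#' @param log_rf_mean_pos,log_rf_sd_pos location/scale of log10 RF (M^-1) in
#'   positive mode
#' @param log_rf_mean_neg,log_rf_sd_neg same for negative mode
#' @param frac_neg_detectable fraction of compounds ionizing in negative mode
#' @param rt_range (min, max) retention time in minutes within the 20-min
#'   gradient
#' @param noise_cv coefficient of variation of multiplicative area noise
#'   (standard deviation of log area); 0 gives noiseless areas
#' @param lod_area minimum detectable area; realized areas below it are
#'   emitted as not-detected
#' @param dilution_factors_train,dilution_factors_test dilution series for
#'   standards and unknowns
#' @param conc_range_M (min, max) of the undiluted standard concentrations;
#'   stock concentrations are drawn log-uniformly in this range
#' @param ph_trend_pos,ph_trend_neg mean decline in log10 RF from pH 2.7 to
#'   pH 10.0 (log units over the full pH span), per mode
#' @param ph_trend_het compound-to-compound heterogeneity of the pH trend:
#'   each compound's trend is scaled by a log-normal multiplier with this
#'   log-scale standard deviation and unit mean (how strongly a compound's
#'   ionization responds to pH depends on its acid-base chemistry); 0 makes
#'   the trend identical for all compounds
#' @param neg_coupling correlation between the positive- and negative-mode
#'   base log RF draws, in \code{[0, 1]}
#' @param basicity_rf_effect,acidity_rf_effect log10-RF boost per unit latent
#'   basicity (positive mode) / acidity (negative mode); set both to 0 to
#'   decorrelate retention time from response factor entirely
#' @param rt_shift_scale minutes of retention-time shift from pH 2.7 to 10.0
#'   per unit of (basicity - acidity)
#' @param rt_jitter_sd run-to-run retention-time jitter (minutes)
#' @param na_adduct_prob probability a compound shows a sodium adduct at
#'   pH 2.7
#' @param neutral_mass_range (min, max) of neutral monoisotopic masses (Da);
#'   detected-ion m/z stays within the instrument scan range 65-975
#' @return a validated object of class `simulation_config`
#' @export
simulation_config <- function(n_compounds = 100,
                              seed = 1,
                              log_rf_mean_pos = 15.5,
                              log_rf_sd_pos = 1.0,
                              log_rf_mean_neg = 15.0,
                              log_rf_sd_neg = 0.7,
                              frac_neg_detectable = 0.4,
                              rt_range = c(1, 19),
                              noise_cv = 0.1,
                              lod_area = 1e5,
                              dilution_factors_train = c(1, 2, 4, 20, 40),
                              dilution_factors_test = c(1, 2, 10, 20, 100),
                              conc_range_M = c(1.7e-6, 2.4e-5),
                              ph_trend_pos = 0.5,
                              ph_trend_neg = 0,
                              ph_trend_het = 0.6,
                              neg_coupling = 0.4,
                              basicity_rf_effect = 0.3,
                              acidity_rf_effect = 0.3,
                              rt_shift_scale = 1.0,
                              rt_jitter_sd = 0.02,
                              na_adduct_prob = 0.3,
                              neutral_mass_range = c(100, 900)) {
  cfg <- list(
    n_compounds = as.integer(n_compounds), seed = as.integer(seed),
    log_rf_mean_pos = log_rf_mean_pos, log_rf_sd_pos = log_rf_sd_pos,
    log_rf_mean_neg = log_rf_mean_neg, log_rf_sd_neg = log_rf_sd_neg,
    frac_neg_detectable = frac_neg_detectable, rt_range = rt_range,
    noise_cv = noise_cv, lod_area = lod_area,
    dilution_factors_train = dilution_factors_train,
    dilution_factors_test = dilution_factors_test,
    conc_range_M = conc_range_M,
    ph_trend_pos = ph_trend_pos, ph_trend_neg = ph_trend_neg,
    ph_trend_het = ph_trend_het,
    neg_coupling = neg_coupling,
    basicity_rf_effect = basicity_rf_effect,
    acidity_rf_effect = acidity_rf_effect,
    rt_shift_scale = rt_shift_scale, rt_jitter_sd = rt_jitter_sd,
    na_adduct_prob = na_adduct_prob,
    neutral_mass_range = neutral_mass_range
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  stopifnot_cfg <- function(ok, msg) {
    if (!isTRUE(ok)) stop("invalid simulation config: ", msg, call. = FALSE)
  }
  stopifnot_cfg(cfg$n_compounds >= 1, "n_compounds must be >= 1")
  stopifnot_cfg(cfg$log_rf_sd_pos > 0 && cfg$log_rf_sd_neg > 0,
                "log RF scales must be positive")
  stopifnot_cfg(cfg$frac_neg_detectable >= 0 && cfg$frac_neg_detectable <= 1,
                "frac_neg_detectable must be in [0, 1]")
  stopifnot_cfg(cfg$neg_coupling >= 0 && cfg$neg_coupling <= 1,
                "neg_coupling must be in [0, 1]")
  stopifnot_cfg(cfg$na_adduct_prob >= 0 && cfg$na_adduct_prob <= 1,
                "na_adduct_prob must be in [0, 1]")
  stopifnot_cfg(cfg$noise_cv >= 0, "noise_cv must be >= 0")
  stopifnot_cfg(cfg$ph_trend_het >= 0, "ph_trend_het must be >= 0")
  stopifnot_cfg(cfg$lod_area >= 0, "lod_area must be >= 0")
  stopifnot_cfg(length(cfg$rt_range) == 2 && diff(cfg$rt_range) > 0 &&
                  cfg$rt_range[1] > 0, "rt_range must be increasing, > 0")
  stopifnot_cfg(length(cfg$conc_range_M) == 2 && all(cfg$conc_range_M > 0) &&
                  diff(cfg$conc_range_M) >= 0,
                "conc_range_M must be positive and non-decreasing")
  stopifnot_cfg(all(cfg$dilution_factors_train >= 1) &&
                  all(cfg$dilution_factors_test >= 1),
                "dilution factors must be >= 1")
  stopifnot_cfg(all(cfg$neutral_mass_range >= 66 + PROTON_MASS) &&
                  all(cfg$neutral_mass_range <= 974 - PROTON_MASS),
                "neutral_mass_range must keep ion m/z inside the 65-975 scan range")
  invisible(cfg)
}

# Evaluate expr with a locally seeded RNG, restoring global state after.
with_local_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% 2147483647L)
  expr
}

ph_scale <- function(ph) (ph - 2.7) / 7.3  # 0 at pH 2.7, 1 at pH 10.0

#' Draw latent compound profiles
#'
#' @param config a [simulation_config()]
#' @return an object of class `compound_profiles`: a list with
#'   \describe{
#'     \item{compounds}{per-compound traits, ion m/z values, stock
#'       concentration and sodium-adduct flag}
#'     \item{true_log_rf}{ground-truth log10 response factor per
#'       (compound, mode, pH); negative-mode rows exist only for compounds
#'       that ionize in negative mode}
#'     \item{true_rt}{ground-truth retention time per (compound, pH)}
#'   }
#' @export
simulate_compounds <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_compounds
  with_local_seed(config$seed, {
    ids <- sprintf("cmp%0*d", max(3L, nchar(n)), seq_len(n))
    lip <- stats::rnorm(n)
    bas <- stats::rnorm(n)
    aci <- stats::rnorm(n)
    neg_ion <- stats::runif(n) < config$frac_neg_detectable
    na_add <- stats::runif(n) < config$na_adduct_prob
    mass <- stats::runif(n, config$neutral_mass_range[1],
                         config$neutral_mass_range[2])
    stock <- 10^stats::runif(n, log10(config$conc_range_M[1]),
                             log10(config$conc_range_M[2]))

    pos_base <- stats::rnorm(n, config$log_rf_mean_pos, config$log_rf_sd_pos)
    eps <- stats::rnorm(n)
    neg_base <- config$log_rf_mean_neg +
      config$neg_coupling * (pos_base - config$log_rf_mean_pos) *
        (config$log_rf_sd_neg / config$log_rf_sd_pos) +
      sqrt(1 - config$neg_coupling^2) * config$log_rf_sd_neg * eps
    # per-compound, per-mode pH-trend multipliers (unit-mean log-normal)
    het <- config$ph_trend_het
    trend_mult_pos <- exp(het * stats::rnorm(n) - het^2 / 2)
    trend_mult_neg <- exp(het * stats::rnorm(n) - het^2 / 2)

    compounds <- data.frame(
      compound_id = ids, neutral_mass = mass,
      mz_pos = mass + PROTON_MASS, mz_neg = mass - PROTON_MASS,
      latent_lipophilicity = lip, latent_basicity = bas,
      latent_acidity = aci, neg_ionizable = neg_ion, na_adduct = na_add,
      stock_conc_M = stock, stringsAsFactors = FALSE
    )

    phs <- mobile_phase_ph()
    rt_base <- config$rt_range[1] + diff(config$rt_range) * stats::pnorm(lip)
    true_rt <- do.call(rbind, lapply(phs, function(ph) {
      rt <- rt_base + config$rt_shift_scale * (bas - aci) * ph_scale(ph)
      data.frame(compound_id = ids, ph = ph,
                 true_rt = pmax(rt, 0.2), stringsAsFactors = FALSE)
    }))

    lrf_pos <- do.call(rbind, lapply(phs, function(ph) {
      data.frame(compound_id = ids, mode = "positive", ph = ph,
                 true_log_rf = pos_base + config$basicity_rf_effect * bas -
                   config$ph_trend_pos * trend_mult_pos * ph_scale(ph),
                 stringsAsFactors = FALSE)
    }))
    lrf_neg <- if (any(neg_ion)) {
      do.call(rbind, lapply(phs, function(ph) {
        data.frame(compound_id = ids[neg_ion], mode = "negative", ph = ph,
                   true_log_rf = (neg_base + config$acidity_rf_effect * aci -
                                    config$ph_trend_neg * trend_mult_neg *
                                      ph_scale(ph))[neg_ion],
                   stringsAsFactors = FALSE)
      }))
    } else NULL
    true_log_rf <- rbind(lrf_pos, lrf_neg)
    ord <- order(true_log_rf$compound_id,
                 condition_order(true_log_rf$mode, true_log_rf$ph))
    true_log_rf <- true_log_rf[ord, , drop = FALSE]
    rownames(true_log_rf) <- NULL
    true_rt <- true_rt[order(true_rt$compound_id, true_rt$ph), , drop = FALSE]
    rownames(true_rt) <- NULL

    structure(list(compounds = compounds, true_log_rf = true_log_rf,
                   true_rt = true_rt, config = config),
              class = "compound_profiles")
  })
}

#' @export
print.compound_profiles <- function(x, ...) {
  cat(sprintf(
    "compound_profiles: %d compounds (%d negative-mode ionizable), seed %d\n",
    nrow(x$compounds), sum(x$compounds$neg_ionizable), x$config$seed))
  invisible(x)
}

#' Simulate a dilution-series feature table from latent profiles
#'
#' Expected area = concentration x 10^true_log_rf; realized area multiplies
#' in log-normal noise with standard deviation `noise_cv` on the log scale.
#' Realized areas below `lod_area` are emitted as not-detected records.
#'
#' @param profiles a [simulate_compounds()] result
#' @param config the [simulation_config()] used for the profiles
#' @param dilution_factors dilution series to acquire; defaults to the
#'   training series in `config`
#' @param seed_offset offset added to the config seed so repeated
#'   acquisitions of the same compounds (e.g. train vs test series) draw
#'   independent noise
#' @return list with elements `features` (peak-record data frame, including
#'   not-detected rows) and `standards` (compound_id, dilution_factor,
#'   concentration_M)
#' @export
simulate_feature_table <- function(profiles, config = profiles$config,
                                   dilution_factors =
                                     config$dilution_factors_train,
                                   seed_offset = 1) {
  stopifnot(inherits(profiles, "compound_profiles"))
  if (nrow(profiles$compounds) == 0) stop("profiles are empty", call. = FALSE)

  grid <- merge(profiles$true_log_rf,
                expand.grid(compound_id = profiles$compounds$compound_id,
                            dilution_factor = dilution_factors,
                            stringsAsFactors = FALSE),
                by = "compound_id")
  grid <- merge(grid, profiles$true_rt, by = c("compound_id", "ph"))
  grid <- merge(grid, profiles$compounds[, c("compound_id", "mz_pos",
                                             "mz_neg", "na_adduct",
                                             "stock_conc_M")],
                by = "compound_id")
  ord <- order(grid$compound_id, condition_order(grid$mode, grid$ph),
               grid$dilution_factor)
  grid <- grid[ord, , drop = FALSE]

  conc <- grid$stock_conc_M / grid$dilution_factor
  expected <- conc * 10^grid$true_log_rf

  with_local_seed(config$seed + 104729L * seed_offset, {
    area <- if (config$noise_cv > 0) {
      expected * exp(stats::rnorm(nrow(grid), 0, config$noise_cv))
    } else expected
    rt <- grid$true_rt + if (config$rt_jitter_sd > 0) {
      stats::rnorm(nrow(grid), 0, config$rt_jitter_sd)
    } else 0
    detected <- area >= config$lod_area
    features <- data.frame(
      compound_id = grid$compound_id, mode = grid$mode, ph = grid$ph,
      dilution_factor = grid$dilution_factor,
      area = ifelse(detected, area, NA_real_),
      rt = ifelse(detected, pmax(rt, 0.01), NA_real_),
      mz = ifelse(grid$mode == "positive", grid$mz_pos, grid$mz_neg),
      na_adduct = grid$mode == "positive" & grid$ph == 2.7 & grid$na_adduct,
      stringsAsFactors = FALSE
    )
    features <- sort_feature_table(validate_feature_table(features))

    standards <- expand.grid(compound_id = profiles$compounds$compound_id,
                             dilution_factor = dilution_factors,
                             stringsAsFactors = FALSE)
    standards <- merge(standards,
                       profiles$compounds[, c("compound_id", "stock_conc_M")],
                       by = "compound_id")
    standards$concentration_M <- standards$stock_conc_M /
      standards$dilution_factor
    standards <- standards[order(standards$compound_id,
                                 standards$dilution_factor),
                           c("compound_id", "dilution_factor",
                             "concentration_M")]
    rownames(standards) <- NULL
    list(features = features, standards = standards)
  })
}

#' Write the ground-truth log response factors of a profile set to CSV
#' @param profiles a [simulate_compounds()] result
#' @param path output path
#' @export
write_ground_truth_table <- function(profiles, path) {
  write_csv_plain(profiles$true_log_rf, path)
}
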