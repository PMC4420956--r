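#' Default exposure-response table
#'
#' One row per (exposure, outcome) pair with the relative risk per unit of
#' exposure change, the unit the risk refers to, whether the pathway acts on
#' mortality (via the life table) or morbidity (prevalence/event models),
#' and the lag class governing how fast the full effect is attained.
#' Mortality rows: winter-excess cardiovascular deaths 0.98 per degree C of
#' SIT; stroke 1.25 and myocardial infarction 1.30 per unit of the
#' secondhand-smoke index (1 = average smoker-household exposure);
#' cardiopulmonary 1.082 and lung cancer 1.059 per 10 ug/m3 PM2.5; lung
#' cancer 1.16 per 100 Bq/m3 radon. Morbidity rows: common mental disorders
#' 0.90 per degree C; childhood asthma harm classes II/III (1.53) and IV
#' (1.83) per 100 percentage points of mould prevalence. `sigma` is the
#' log-scale standard deviation used for Monte Carlo draws.
#'
#' @param rr_sigma default lognormal sigma applied to every row.
#' @return A tibble with columns `exposure`, `outcome`, `rr`, `unit_size`,
#'   `kind`, `lag_class`, `binary`, `sigma`.
#' @export
exposure_response <- function(rr_sigma = 0.1) {
  tibble(
    exposure = c("sit", "sts", "sts", "pm25", "pm25", "radon",
                 "sit", "mould", "mould", "mould"),
    outcome = c("winter_cv", "stroke", "mi", "cardiopulmonary",
                "lung_cancer", "lung_cancer",
                "cmd", "asthma_II", "asthma_III", "asthma_IV"),
    rr = c(0.98, 1.25, 1.30, 1.082, 1.059, 1.16, 0.90, 1.53, 1.53, 1.83),
    unit_size = c(1, 1, 1, 10, 10, 100, 1, 100, 100, 100),
    kind = c(rep("mortality", 6), rep("morbidity", 4)),
    lag_class = c("immediate", "cardiovascular", "cardiovascular",
                  "cardiovascular", "lung_cancer", "lung_cancer",
                  "immediate", "immediate", "immediate", "immediate"),
    binary = FALSE,
    sigma = rr_sigma
  )
}

#' Read an exposure-response table from CSV
#'
#' Accepts the schema written by [readr::write_csv()] from
#' [exposure_response()]; missing `binary`/`sigma` columns get defaults.
#'
#' @param path CSV file path.
#' @return A validated exposure-response tibble.
#' @export
read_exposure_response_csv <- function(path) {
  er <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("exposure", "outcome", "rr", "unit_size", "kind",
             "lag_class") %in% names(er))) {
    abort("exposure-response CSV is missing required columns")
  }
  if (!"binary" %in% names(er)) er$binary <- FALSE
  if (!"sigma" %in% names(er)) er$sigma <- 0.1
  if (any(er$rr <= 0)) abort("relative risks must be positive")
  as_tibble(er)
}

#' Scale a relative risk to an exposure change
#'
#' Log-linear scaling: `rr ^ (delta / unit_size)`, so a change of one unit
#' reproduces the tabulated risk, a zero change gives 1, and the scaling is
#' continuous and monotone in `delta`. For pathways flagged binary the
#' change must be -1, 0 or +1 (the flag switching off, unchanged, or on).
#'
#' @param rr relative risk per `unit_size` of exposure.
#' @param delta exposure change, in the same units as `unit_size`.
#' @param unit_size exposure units the tabulated risk refers to.
#' @param binary whether the exposure is a flag.
#' @return scaled relative risk (vectorised over `delta`).
#' @export
#' @examples
#' scale_rr(1.082, delta = 10, unit_size = 10)  # 1.082
#' scale_rr(0.98, delta = 0.3)                  # 0.98^0.3
scale_rr <- function(rr, delta, unit_size = 1, binary = FALSE) {
  if (any(!is.finite(delta))) abort("delta must be finite")
  if (any(rr <= 0)) abort("relative risk must be positive")
  if (binary && any(!delta %in% c(-1, 0, 1))) {
    abort("binary exposures only admit changes of -1, 0 or +1")
  }
  rr^(delta / unit_size)
}

#' Combine relative risks multiplicatively
#'
#' Outcomes affected by more than one exposure assume multiplicative
#' relative risks; an empty list is the null effect.
#'
#' @param rrs numeric vector of relative risks (all > 0).
#' @return the product; 1 for an empty input.
#' @export
combine_rrs <- function(rrs) {
  if (length(rrs) == 0) return(1)
  if (any(rrs <= 0)) abort("relative risks must be positive")
  prod(rrs)
}

#' Lag profile: fraction of the full effect attained
#'
#' Disease-specific time functions for the onset/cessation of effects after
#' an exposure change at year 0. Cold-related (winter cardiovascular)
#' effects are immediate (`f = 1` from `t = 0`), cardiovascular effects of
#' smoke and particles approach the full effect exponentially
#' (`1 - exp(-t/tau)`, default tau 2.5 y), and lung-cancer effects are zero
#' during a latency delay (default 5 y) then ramp linearly to the full
#' effect (default by 20 y). Shapes are configurable via
#' `params$health$lag`.
#'
#' @param lag_class `"immediate"`, `"cardiovascular"` or `"lung_cancer"`.
#' @param t years since the exposure change (vectorised, >= 0).
#' @param params parameter list from [hia_params()].
#' @return fractions in `[0, 1]`, non-decreasing in `t`.
#' @export
#' @examples
#' lag_profile("cardiovascular", 2.5)  # 1 - exp(-1)
lag_profile <- function(lag_class, t, params = hia_params()) {
  if (any(t < 0)) abort("t must be non-negative")
  lp <- params$health$lag
  switch(lag_class,
    immediate = rep(1, length(t)),
    cardiovascular = 1 - exp(-t / lp$tau_cv),
    lung_cancer = pmin(pmax((t - lp$lc_delay) /
                              (lp$lc_full - lp$lc_delay), 0), 1),
    abort(paste0("unknown lag class: ", lag_class))
  )
}
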