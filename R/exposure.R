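#' Infiltration air-change rate from envelope permeability
#'
#' Converts the 50 Pa permeability metric to an average infiltration rate
#' using the engineering "rule of 20": the air-change rate at 50 Pa
#' (`permeability x envelope area / volume`) divided by a configurable
#' divisor.
#'
#' @param stock dwelling tibble (needs `permeability`, `envelope_area`,
#'   `volume`).
#' @param params parameter list from [hia_params()].
#' @return numeric vector of infiltration rates (air changes per hour).
#' @export
infiltration_rate <- function(stock, params = hia_params()) {
  if (any(stock$volume <= 0)) abort("dwelling volume must be positive")
  if (any(stock$envelope_area <= 0)) abort("envelope area must be positive")
  if (any(stock$permeability < 0)) abort("permeability must be non-negative")
  stock$permeability * stock$envelope_area /
    (params$physics$infiltration_divisor * stock$volume)
}

#' Total air-change rate including purpose ventilation
#'
#' Infiltration plus the contributions of trickle vents and working extract
#' fans, floored at a minimum total rate representing occupant window
#' opening.
#'
#' @inheritParams infiltration_rate
#' @return numeric vector of total air-change rates (per hour).
#' @export
total_ach <- function(stock, params = hia_params()) {
  ph <- params$physics
  ach <- infiltration_rate(stock, params) +
    ph$trickle_vent_ach * stock$has_trickle_vents +
    ph$extract_fan_ach * (stock$has_extract_fans & stock$extract_fans_working)
  pmax(ach, ph$min_total_ach)
}

#' Ventilation heat loss from the air-change rate
#'
#' `0.33 W/K per m3/h` of air exchange (volumetric heat capacity of air),
#' applied to the total air-change rate times the dwelling volume.
#'
#' @inheritParams infiltration_rate
#' @return numeric vector in W/K.
#' @export
ventilation_heat_loss <- function(stock, params = hia_params()) {
  params$physics$vent_heat_coeff * total_ach(stock, params) * stock$volume
}

#' Single-zone steady-state indoor concentrations
#'
#' Well-mixed single-zone mass balance at steady state. The indoor-source
#' concentration is `(emission_rate / volume) / (total_ach + deposition)`;
#' the indoor concentration of outdoor origin is
#' `outdoor_conc x penetration x total_ach / (total_ach + deposition)`.
#'
#' @param emission_rate indoor source strength (mass per hour).
#' @param volume zone volume (m3).
#' @param total_ach total air-change rate (per hour, > 0).
#' @param penetration fraction of outdoor particles penetrating the envelope.
#' @param deposition first-order deposition/decay rate (per hour).
#' @param outdoor_conc outdoor concentration (mass per m3).
#' @return A list with `indoor_source_conc` and `outdoor_source_conc`.
#' @export
#' @examples
#' steady_state_concentration(480, 240, 0.4, penetration = 1,
#'                            deposition = 0.1, outdoor_conc = 0)
steady_state_concentration <- function(emission_rate, volume, total_ach,
                                       penetration = 1, deposition = 0,
                                       outdoor_conc = 0) {
  if (any(total_ach <= 0)) {
    abort("total_ach must be positive: a dwelling cannot have zero air exchange")
  }
  list(
    indoor_source_conc = (emission_rate / volume) / (total_ach + deposition),
    outdoor_source_conc = outdoor_conc * penetration *
      total_ach / (total_ach + deposition)
  )
}

#' Standardised internal temperature (SIT)
#'
#' Linear empirical relationship between total heat loss (fabric plus
#' ventilation, W/K) and the average of living-room and bedroom temperature
#' at 5 C outdoors: `SIT = s0 - s1 x H`. The two defaults are a two-point
#' calibration: the baseline stock mean (H = 369 W/K gives 17.8 C) and the
#' regulation-scenario shift (delta H = -80 W/K gives +0.3 C).
#'
#' @param stock dwelling tibble (needs `fabric_heat_loss`; ventilation heat
#'   loss is recomputed from the current ventilation state).
#' @param params parameter list from [hia_params()].
#' @return numeric vector of SIT in degrees C.
#' @export
compute_sit <- function(stock, params = hia_params()) {
  h <- stock$fabric_heat_loss + ventilation_heat_loss(stock, params)
  params$physics$sit_intercept - params$physics$sit_slope * h
}

#' Probability of a mould severity index above 1
#'
#' Logistic surrogate for surveyor-assessed mould risk: increasing in the
#' moisture load per air change and decreasing in indoor temperature. The
#' intercept is calibrated so the default baseline stock mean is 14.9%.
#'
#' @inheritParams compute_sit
#' @param sit standardised internal temperature (C); computed from the stock
#'   when omitted.
#' @param ach total air-change rate (per hour); computed when omitted.
#' @return numeric vector of probabilities.
#' @export
mould_risk <- function(stock, params = hia_params(), sit = NULL, ach = NULL) {
  ph <- params$physics
  if (is.null(ach)) ach <- total_ach(stock, params)
  if (is.null(sit)) sit <- compute_sit(stock, params)
  if (any(ach <= 0)) abort("total air-change rate must be positive")
  plogis(ph$mould_intercept + ph$mould_ach_coef * stock$moisture_load / ach -
           ph$mould_sit_coef * (sit - ph$mould_sit_ref))
}

baseline_mould_risk <- function(stock, params) mould_risk(stock, params)

# Exposure vector for one stock state. sts_norm is the baseline
# smoker-household mean of 1/ach, so that the baseline smoker mean is 1.
exposure_vector <- function(stock, params, sts_norm) {
  ph <- params$physics
  ach <- total_ach(stock, params)
  capture <- ph$extract_capture *
    (stock$has_extract_fans & stock$extract_fans_working)
  emission <- ph$pm_emission_rate * (1 - capture)

  # per-room indoor-source concentrations: room factors scale the
  # single-zone value (kitchen above, bedroom below); occupancy weights
  # 10/45/45% combine them into personal exposure
  cc <- steady_state_concentration(
    emission_rate = emission, volume = stock$volume, total_ach = ach,
    penetration = ph$pm_penetration, deposition = ph$pm_deposition,
    outdoor_conc = stock$outdoor_pm25)
  room_mix <- sum(ph$room_weights * ph$room_factors)
  sit <- compute_sit(stock, params)

  tibble(
    dwelling_id = stock$dwelling_id,
    sit = sit,
    sts = ifelse(stock$smoker_household, (1 / ach) / sts_norm, 0),
    pm25_indoor_source = cc$indoor_source_conc * room_mix,
    pm25_outdoor_source = cc$outdoor_source_conc,
    radon = stock$radon_source_strength / (ach + ph$radon_deposition),
    mould_risk = mould_risk(stock, params, sit = sit, ach = ach),
    heating_energy = (stock$fabric_heat_loss +
                        ventilation_heat_loss(stock, params)) *
      ph$degree_hours / stock$heating_efficiency / 1e6
  )
}

#' Pre- and post-retrofit exposure vectors for a dwelling stock
#'
#' Computes the five modelled exposures plus annual heating energy for the
#' pre-retrofit and post-retrofit states of every dwelling: standardised
#' internal temperature (C), secondhand tobacco smoke index (1 = baseline
#' average smoker-household exposure; 0 in non-smoking households),
#' indoor-source and outdoor-origin PM2.5 (ug/m3), radon (Bq/m3), mould
#' risk (probability of MSI > 1) and heating energy (MWh/year). The change
#' is instantaneous: the post state applies from year 0 with no transition.
#'
#' @param pre_stock baseline dwelling tibble.
#' @param post_stock scenario-applied dwelling tibble from
#'   [apply_measures()]; defaults to `pre_stock` (null intervention).
#' @param params parameter list from [hia_params()].
#' @return A tibble, one row per dwelling and state (`"pre"`/`"post"`).
#' @export
compute_exposures <- function(pre_stock, post_stock = pre_stock,
                              params = hia_params()) {
  if (!identical(pre_stock$dwelling_id, post_stock$dwelling_id)) {
    abort("pre and post stocks must contain the same dwellings in the same order")
  }
  smoker <- pre_stock$smoker_household
  inv_ach <- 1 / total_ach(pre_stock, params)
  sts_norm <- if (any(smoker)) mean(inv_ach[smoker]) else 1

  bind_rows(
    mutate(exposure_vector(pre_stock, params, sts_norm), state = "pre"),
    mutate(exposure_vector(post_stock, params, sts_norm), state = "post")
  ) %>%
    select("dwelling_id", "state", dplyr::everything())
}

#' Stock-mean exposure summary
#'
#' Stock-weighted means of each exposure by state, the shape of the
#' published baseline/scenario exposure comparison.
#'
#' @param exposures tibble from [compute_exposures()].
#' @param stock dwelling tibble supplying `stock_weight` (optional; equal
#'   weights when omitted).
#' @return A tibble with one row per state and one column per exposure.
#' @export
summarise_exposures <- function(exposures, stock = NULL) {
  w <- if (is.null(stock)) {
    rep(1, nrow(exposures))
  } else {
    stock$stock_weight[match(exposures$dwelling_id, stock$dwelling_id)]
  }
  exposures %>%
    mutate(.w = w) %>%
    group_by(.data$state) %>%
    summarise(across(c("sit", "sts", "pm25_indoor_source",
                       "pm25_outdoor_source", "radon", "mould_risk",
                       "heating_energy"),
                     ~ weighted.mean(.x, .data$.w)),
              .groups = "drop")
}
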