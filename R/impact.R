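#' Per-person exposure changes
#'
#' Joins each occupant to their dwelling's pre/post exposure vectors and
#' returns the exposure deltas the health model consumes. The PM2.5 change
#' is `theta x delta(indoor-source) + delta(outdoor-origin)`, where `theta`
#' is the relative toxicity assumed for indoor-generated particles
#' (default 1: equal toxicity).
#'
#' @param occupants tibble from [generate_population()].
#' @param exposures tibble from [compute_exposures()].
#' @param theta indoor-PM toxicity factor in `[0, 1]`.
#' @return A tibble per occupant with `delta_sit` (C), `delta_sts` (index
#'   units), `delta_pm` (ug/m3), `delta_radon` (Bq/m3), `delta_mould_pct`
#'   (percentage points of MSI > 1 risk).
#' @export
person_deltas <- function(occupants, exposures, theta = 1) {
  if (theta < 0 || theta > 1) abort("theta must lie in [0, 1]")
  wide <- exposures %>%
    tidyr::pivot_wider(id_cols = "dwelling_id", names_from = "state",
                       values_from = c("sit", "sts", "pm25_indoor_source",
                                       "pm25_outdoor_source", "radon",
                                       "mould_risk"))
  occupants %>%
    left_join(wide, by = "dwelling_id") %>%
    mutate(
      delta_sit = .data$sit_post - .data$sit_pre,
      delta_sts = .data$sts_post - .data$sts_pre,
      delta_pm = theta * (.data$pm25_indoor_source_post -
                            .data$pm25_indoor_source_pre) +
        (.data$pm25_outdoor_source_post - .data$pm25_outdoor_source_pre),
      delta_radon = .data$radon_post - .data$radon_pre,
      delta_mould_pct = 100 * (.data$mould_risk_post - .data$mould_risk_pre)
    ) %>%
    select("occupant_id", "dwelling_id", "sex", "age", "is_child",
           dplyr::starts_with("delta_"))
}

# Combined per-person RR for one mortality outcome, then the person-mean
# RR within each (sex, age) cell, which is the cohort-level hazard
# multiplier at full effect.
outcome_rr_cells <- function(deltas, outcome, er_table) {
  ers <- er_table %>%
    filter(.data$outcome == .env$outcome, .data$kind == "mortality")
  if (nrow(ers) == 0) abort(paste0("no mortality pathway for ", outcome))
  rr_i <- rep(1, nrow(deltas))
  for (k in seq_len(nrow(ers))) {
    delta <- switch(ers$exposure[k],
                    sit = deltas$delta_sit,
                    sts = deltas$delta_sts,
                    pm25 = deltas$delta_pm,
                    radon = deltas$delta_radon,
                    mould = deltas$delta_mould_pct,
                    abort(paste0("unknown exposure: ", ers$exposure[k])))
    rr_i <- rr_i * scale_rr(ers$rr[k], delta, ers$unit_size[k], ers$binary[k])
  }
  deltas %>%
    mutate(rr_i = rr_i) %>%
    group_by(.data$sex, .data$age) %>%
    summarise(rr = mean(.data$rr_i), .groups = "drop")
}

#' Morbidity impact derived from mortality life-years
#'
#' Years lived with disability (YLD) avoided are estimated from the
#' mortality life-years gained by cause-specific YLD:YLL ratios.
#'
#' @param delta_yll named numeric vector (or tibble with `outcome`,
#'   `delta_yll`) of life-years gained per mortality outcome.
#' @param yld_yll_ratios named non-negative ratios per outcome.
#' @return named vector of YLD avoided per outcome.
#' @export
morbidity_from_mortality <- function(delta_yll, yld_yll_ratios) {
  if (any(yld_yll_ratios < 0)) abort("YLD:YLL ratios must be non-negative")
  if (is.data.frame(delta_yll)) {
    delta_yll <- setNames(delta_yll$delta_yll, delta_yll$outcome)
  }
  ratios <- yld_yll_ratios[names(delta_yll)]
  if (anyNA(ratios)) abort("missing YLD:YLL ratio for some outcome")
  delta_yll * as.numeric(ratios)
}

#' QALY impact on common mental disorders from warmer homes
#'
#' Prevalence of common mental disorders (GHQ-12 score 4+) among adults
#' responds to indoor winter temperature with a relative risk of 0.90 per
#' degree C. The benefit decays exponentially and is truncated to exactly
#' zero from year 10 (`tau` defaults to `10/log(100)`, so the decay reaches
#' 1% of its initial value just before truncation).
#'
#' @param adults number of adults (or a vector of weights, paired with a
#'   vector `delta_sit`).
#' @param baseline_prevalence baseline CMD prevalence in adults.
#' @param delta_sit change in standardised internal temperature (C).
#' @param utility_weight QALY loss per prevalent case-year.
#' @param horizon follow-up years.
#' @param rr relative risk per degree C.
#' @param tau decay time constant (years).
#' @param duration years after which the effect is exactly zero.
#' @return total QALYs gained (negative for cooling).
#' @export
cmd_impact <- function(adults, baseline_prevalence, delta_sit,
                       utility_weight, horizon = 50, rr = 0.90,
                       tau = 10 / log(100), duration = 10) {
  if (baseline_prevalence < 0 || baseline_prevalence > 1) {
    abort("baseline_prevalence must lie in [0, 1]")
  }
  t <- 0:(horizon - 1)
  decay <- ifelse(t < duration, exp(-t / tau), 0)
  delta_cases <- sum(adults * baseline_prevalence *
                       (scale_rr(rr, delta_sit) - 1))
  -sum(decay) * delta_cases * utility_weight
}

#' QALY impact on childhood asthma from mould changes
#'
#' Asthma events in children scale with the change in mould prevalence
#' (percentage points of homes with MSI > 1) through per-harm-class
#' relative risks per 100 percentage points: hospital admissions (class II)
#' and GP consultations (class III) 1.53, minor symptoms (class IV) 1.83.
#'
#' @param children number of children (or weights paired with
#'   `delta_mould_pct`).
#' @param baseline_event_rates named per-class events per child-year.
#' @param delta_mould_pct change in mould prevalence (percentage points).
#' @param utility_weights named QALY loss per event, same classes.
#' @param horizon follow-up years.
#' @param rrs named relative risks per 100 percentage points.
#' @return total QALYs gained.
#' @export
asthma_impact <- function(children, baseline_event_rates, delta_mould_pct,
                          utility_weights, horizon = 50,
                          rrs = c(II = 1.53, III = 1.53, IV = 1.83)) {
  classes <- names(baseline_event_rates)
  unknown <- setdiff(classes, names(rrs))
  if (length(unknown) > 0) {
    abort(paste0("unknown asthma harm class: ", paste(unknown, collapse = ", ")))
  }
  if (any(baseline_event_rates < 0)) abort("event rates must be non-negative")
  total <- 0
  for (cl in classes) {
    delta_events <- sum(children * baseline_event_rates[[cl]] *
                          (scale_rr(rrs[[cl]], delta_mould_pct, 100) - 1))
    total <- total - horizon * delta_events * utility_weights[[cl]]
  }
  total
}

#' Aggregate pathway impacts into a health-impact result
#'
#' Mortality life-years gained enter with the configured average utility of
#' a life-year (default 1), morbidity terms add YLD avoided and the
#' prevalence-model QALYs, and everything is expressed per 10 000 persons
#' in the cohort. The net impact is the sum of the per-outcome entries.
#'
#' @param delta_yll named life-years gained per mortality outcome.
#' @param delta_yld named YLD avoided per mortality outcome.
#' @param cmd_qalys,asthma_qalys totals from [cmd_impact()] and
#'   [asthma_impact()].
#' @param persons cohort size (> 0).
#' @param horizon follow-up years.
#' @param scenario scenario name for labelling.
#' @param mortality_weight utility of a life-year gained.
#' @return An object of class `hia_result`.
#' @export
aggregate_qalys <- function(delta_yll, delta_yld, cmd_qalys, asthma_qalys,
                            persons, horizon = 50, scenario = NA_character_,
                            mortality_weight = 1) {
  if (persons <= 0) abort("persons must be positive")
  scale <- 1e4 / persons
  impacts <- tibble(
    outcome = c(names(delta_yll), "cmd", "asthma"),
    qaly_mortality = c(as.numeric(delta_yll) * mortality_weight, 0, 0) * scale,
    qaly_morbidity = c(as.numeric(delta_yld), cmd_qalys, asthma_qalys) * scale
  ) %>%
    mutate(qaly_per_10k = .data$qaly_mortality + .data$qaly_morbidity)
  structure(
    list(impacts = impacts, net_qaly_per_10k = sum(impacts$qaly_per_10k),
         persons = persons, horizon = horizon, scenario = scenario),
    class = "hia_result")
}

# Mortality outcomes and the life-table cause each one perturbs.
mortality_outcomes <- function() {
  tibble(
    outcome = c("winter_cv", "mi", "stroke", "cardiopulmonary", "lung_cancer"),
    cause = c("winter_cv", "mi", "stroke", "cardiopulmonary", "lung_cancer"),
    lag_class = c("immediate", "cardiovascular", "cardiovascular",
                  "cardiovascular", "lung_cancer")
  )
}

#' Run the full health impact analysis for one scenario
#'
#' Chains measure assignment, retrofit application, exposure computation and
#' the life-table/morbidity health models, returning per-outcome QALYs per
#' 10 000 persons over the follow-up horizon. Each mortality outcome is
#' evaluated on its own life-table run (pathway attribution); the net
#' impact is the sum over outcomes.
#'
#' @param stock dwelling tibble from [generate_stock()].
#' @param occupants occupant tibble from [generate_population()].
#' @param schedule mortality schedule from [generate_mortality()].
#' @param scenario scenario name (see [scenario_spec()]).
#' @param params parameter list from [hia_params()].
#' @param er_table exposure-response table, see [exposure_response()].
#' @param catalog measure catalogue, see [measure_catalog()].
#' @param theta indoor-PM toxicity factor; overrides `params$health$theta`.
#' @param high_risk_fraction winter-cardiovascular high-risk group size in
#'   `(0, 1]`; 1 = whole population equally at risk.
#' @return An object of class `hia_result` with per-outcome impacts, the
#'   exposure summary, and run metadata; see [tidy.hia_result()].
#' @export
#' @examples
#' params <- hia_params()
#' stock <- generate_stock(200, params, seed = 1)
#' occupants <- generate_population(stock, params, seed = 2)
#' schedule <- generate_mortality(params)
#' res <- run_hia(stock, occupants, schedule, "regulation", params)
#' res$net_qaly_per_10k
run_hia <- function(stock, occupants, schedule, scenario = "regulation",
                    params = hia_params(), er_table = exposure_response(),
                    catalog = measure_catalog(), theta = NULL,
                    high_risk_fraction = 1) {
  if (is.null(theta)) theta <- params$health$theta
  horizon <- params$health$horizon
  spec <- if (is.character(scenario)) scenario_spec(scenario) else scenario

  assignments <- assign_measures(stock, spec, catalog, params)
  post <- apply_measures(stock, assignments, catalog, params)
  exposures <- compute_exposures(stock, post, params)
  deltas <- person_deltas(occupants, exposures, theta)

  pop <- occupants %>%
    group_by(.data$sex, .data$age) %>%
    summarise(n = dplyr::n(), .groups = "drop")
  lt <- build_life_table(schedule, pop)

  mo <- mortality_outcomes()
  delta_yll <- setNames(numeric(nrow(mo)), mo$outcome)
  for (k in seq_len(nrow(mo))) {
    rr_cells <- outcome_rr_cells(deltas, mo$outcome[k], er_table)
    run <- if (mo$outcome[k] == "winter_cv" && high_risk_fraction < 1) {
      run_winter_stratified(lt, high_risk_fraction, rr_cells, horizon, params)
    } else {
      run_life_table(lt, mo$cause[k], rr_cells, mo$lag_class[k],
                     horizon, params)
    }
    delta_yll[mo$outcome[k]] <- run$delta_py
  }
  delta_yld <- morbidity_from_mortality(delta_yll, params$health$yld_yll)

  adults <- deltas %>% filter(!.data$is_child)
  cmd_er <- er_table %>% filter(.data$outcome == "cmd")
  cmd_q <- cmd_impact(
    adults = rep(1, nrow(adults)),
    baseline_prevalence = params$health$cmd$prevalence,
    delta_sit = adults$delta_sit,
    utility_weight = params$health$cmd$utility,
    horizon = horizon, rr = cmd_er$rr[1],
    tau = params$health$cmd$tau, duration = params$health$cmd$duration)

  children <- deltas %>% filter(.data$is_child)
  asthma_rrs <- er_table %>%
    filter(.data$exposure == "mould", grepl("^asthma_", .data$outcome))
  rrs <- setNames(asthma_rrs$rr, sub("^asthma_", "", asthma_rrs$outcome))
  asthma_q <- asthma_impact(
    children = rep(1, nrow(children)),
    baseline_event_rates = params$health$asthma$event_rates,
    delta_mould_pct = children$delta_mould_pct,
    utility_weights = params$health$asthma$utility_weights,
    horizon = horizon, rrs = rrs)

  out <- aggregate_qalys(delta_yll, delta_yld, cmd_q, asthma_q,
                         persons = nrow(occupants), horizon = horizon,
                         scenario = spec$name,
                         mortality_weight = params$health$mortality_weight)
  out$exposure_summary <- summarise_exposures(exposures, stock)
  out$theta <- theta
  out$high_risk_fraction <- high_risk_fraction
  out$n_dwellings <- nrow(stock)
  out
}
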