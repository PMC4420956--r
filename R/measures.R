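#' Retrofit measure catalogue
#'
#' One row per retrofit measure with its effect on the dwelling: change in
#' fabric heat loss (W/K, never positive for insulation), change in envelope
#' permeability (m3/m2/h), replacement heating-system efficiency, and flags
#' for the ventilation devices a measure installs or repairs. The default
#' fabric and permeability deltas are calibrated so that, at the configured
#' eligibility prevalences, the stock-mean shifts reproduce the published
#' regulation-scenario column (fabric heat loss 294 to 219 W/K, permeability
#' 16 to 11 m3/m2/h); they are configuration, not measured values.
#'
#' @return A tibble of measures: `name`, `fabric_delta`, `permeability_delta`,
#'   `efficiency_new`, `sets_trickle`, `sets_extract`, `repairs_extract`.
#' @export
measure_catalog <- function() {
  tibble(
    name = c("loft_insulation", "cavity_wall", "solid_wall", "double_glazing",
             "condensing_boiler", "gas_central_heating", "draught_proofing",
             "trickle_vents_install", "extract_fan_install",
             "extract_fan_refurbish"),
    fabric_delta = c(-45, -70, -105, -50, 0, 0, 0, 0, 0, 0),
    permeability_delta = c(-0.5, -4, -6, -4, 0, 0, -6, 0, 0, 0),
    efficiency_new = c(NA, NA, NA, NA, 0.88, 0.82, NA, NA, NA, NA),
    sets_trickle = c(rep(FALSE, 7), TRUE, FALSE, FALSE),
    sets_extract = c(rep(FALSE, 8), TRUE, FALSE),
    repairs_extract = c(rep(FALSE, 9), TRUE)
  )
}

validate_catalog <- function(catalog) {
  known <- measure_catalog()$name
  bad <- setdiff(catalog$name, known)
  if (length(bad) > 0) {
    abort(paste0("unknown measure name(s) in catalog: ",
                 paste(bad, collapse = ", ")))
  }
  insul <- c("loft_insulation", "cavity_wall", "solid_wall", "double_glazing")
  if (any(catalog$fabric_delta[catalog$name %in% insul] > 0)) {
    abort("insulation measures must not increase fabric heat loss")
  }
  vent <- c("trickle_vents_install", "extract_fan_install",
            "extract_fan_refurbish")
  if (any(catalog$fabric_delta[catalog$name %in% vent] != 0)) {
    abort("ventilation measures must have zero fabric heat-loss delta")
  }
  invisible(catalog)
}

#' Ventilation scenario specification
#'
#' The three policy settings examined alongside the fabric retrofits:
#' `"regulation"` installs trickle vents and extract fans wherever they are
#' absent; `"installer_discretion"` installs them only in homes exhibiting a
#' perceptible ventilation problem (baseline mould risk above the configured
#' threshold); `"no_added_ventilation"` installs none. Broken extract fans
#' are repaired, and trickle vents accompany glazing upgrades, in all three.
#' `"baseline"` applies no measures at all (null intervention).
#'
#' @param name one of `"regulation"`, `"installer_discretion"`,
#'   `"no_added_ventilation"`, `"baseline"`.
#' @return A list with the scenario name and policy flags.
#' @export
scenario_spec <- function(name = c("regulation", "installer_discretion",
                                   "no_added_ventilation", "baseline")) {
  name <- match.arg(name)
  list(
    name = name,
    add_vents_everywhere = name == "regulation",
    add_vents_problem_homes_only = name == "installer_discretion",
    repair_broken_fans = name != "baseline"
  )
}

#' Assign retrofit measures to each dwelling under a scenario
#'
#' Fabric and heating measures are assigned wherever the dwelling carries the
#' corresponding eligibility flag. Draught proofing additionally requires a
#' leaky envelope (permeability at or above the configured threshold,
#' default 7 m3/m2/h). Ventilation measures follow the scenario policy (see
#' [scenario_spec()]).
#'
#' @param stock dwelling tibble from [generate_stock()].
#' @param scenario a name accepted by [scenario_spec()] or its result.
#' @param catalog measure catalogue, see [measure_catalog()].
#' @param params parameter list from [hia_params()].
#' @return A tibble `(dwelling_id, measure)` in long form.
#' @export
assign_measures <- function(stock, scenario = "regulation",
                            catalog = measure_catalog(),
                            params = hia_params()) {
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  validate_catalog(catalog)
  if (scenario$name == "baseline") {
    return(tibble(dwelling_id = character(), measure = character()))
  }

  fabric_measures <- c("loft_insulation", "cavity_wall", "solid_wall",
                       "double_glazing", "condensing_boiler",
                       "gas_central_heating")
  rows <- purrr::map(fabric_measures, function(m) {
    tibble(dwelling_id = stock$dwelling_id[stock[[paste0("elig_", m)]]],
           measure = m)
  })

  dp <- stock$elig_draught_proofing &
    stock$permeability >= params$scenario$draught_proof_threshold
  rows <- c(rows, list(tibble(dwelling_id = stock$dwelling_id[dp],
                              measure = "draught_proofing")))

  # repairs happen in every retrofit scenario
  if (scenario$repair_broken_fans) {
    broken <- stock$has_extract_fans & !stock$extract_fans_working
    rows <- c(rows, list(tibble(dwelling_id = stock$dwelling_id[broken],
                                measure = "extract_fan_refurbish")))
  }

  # trickle vents accompany glazing upgrades in all scenarios
  glaze_trickle <- stock$elig_double_glazing & !stock$has_trickle_vents
  rows <- c(rows, list(tibble(dwelling_id = stock$dwelling_id[glaze_trickle],
                              measure = "trickle_vents_install")))

  vent_target <- if (scenario$add_vents_everywhere) {
    rep(TRUE, nrow(stock))
  } else if (scenario$add_vents_problem_homes_only) {
    baseline_mould_risk(stock, params) > params$scenario$problem_home_threshold
  } else {
    rep(FALSE, nrow(stock))
  }
  rows <- c(rows, list(
    tibble(dwelling_id = stock$dwelling_id[vent_target & !stock$has_trickle_vents],
           measure = "trickle_vents_install"),
    tibble(dwelling_id = stock$dwelling_id[vent_target & !stock$has_extract_fans],
           measure = "extract_fan_install")
  ))

  bind_rows(rows) %>% distinct() %>% arrange(.data$dwelling_id, .data$measure)
}

#' Apply assigned measures to a dwelling stock
#'
#' Pure function: returns a post-retrofit copy of the stock with fabric heat
#' loss and permeability updated additively (permeability floored at the
#' configured minimum), heating efficiency updated by replacement (an
#' upgrade never lowers the existing efficiency), ventilation-device flags
#' set by the installing/repairing measures, and ventilation heat loss
#' recomputed from the new air-change rate.
#'
#' @inheritParams assign_measures
#' @param assignments long tibble from [assign_measures()].
#' @return A post-retrofit dwelling tibble with the same schema as `stock`.
#' @export
apply_measures <- function(stock, assignments, catalog = measure_catalog(),
                           params = hia_params()) {
  validate_catalog(catalog)
  bad <- setdiff(assignments$measure, catalog$name)
  if (length(bad) > 0) {
    abort(paste0("assigned measure(s) missing from catalog: ",
                 paste(bad, collapse = ", ")))
  }
  post <- stock
  if (nrow(assignments) == 0) return(post)

  eff <- assignments %>%
    left_join(catalog, by = c(measure = "name")) %>%
    group_by(.data$dwelling_id) %>%
    summarise(
      fabric_delta = sum(.data$fabric_delta),
      permeability_delta = sum(.data$permeability_delta),
      efficiency_new = if (all(is.na(.data$efficiency_new))) NA_real_ else
        max(.data$efficiency_new, na.rm = TRUE),
      sets_trickle = any(.data$sets_trickle),
      sets_extract = any(.data$sets_extract),
      repairs_extract = any(.data$repairs_extract),
      .groups = "drop"
    )
  i <- match(eff$dwelling_id, post$dwelling_id)
  if (anyNA(i)) abort("assignments reference dwellings absent from the stock")

  post$fabric_heat_loss[i] <- pmax(
    post$fabric_heat_loss[i] + eff$fabric_delta, 1)
  post$permeability[i] <- pmax(
    post$permeability[i] + eff$permeability_delta,
    params$physics$permeability_floor)
  repl <- !is.na(eff$efficiency_new)
  post$heating_efficiency[i[repl]] <- pmax(
    post$heating_efficiency[i[repl]], eff$efficiency_new[repl])
  if (any(post$heating_efficiency <= 0 | post$heating_efficiency > 1)) {
    abort("resulting heating efficiency outside (0, 1]")
  }
  post$has_trickle_vents[i] <- post$has_trickle_vents[i] | eff$sets_trickle
  newfan <- eff$sets_extract
  post$has_extract_fans[i] <- post$has_extract_fans[i] | newfan
  post$extract_fans_working[i] <- post$extract_fans_working[i] | newfan |
    (eff$repairs_extract & post$has_extract_fans[i])
  post$ventilation_heat_loss <- ventilation_heat_loss(post, params)
  post
}
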