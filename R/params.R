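#' Default model parameters
#'
#' Returns the full nested parameter list used throughout the pipeline:
#' synthetic-stock generator targets, building-physics constants, scenario
#' rules, exposure-response defaults, life-table and morbidity settings, and
#' Monte Carlo defaults. Every value can be overridden with `...` (a nested
#' list merged recursively) or from a YAML file via [read_hia_config()].
#'
#' The generator targets for continuous dwelling fields are the stock-mean /
#' SD pairs of the 2010 English stock the model emulates (fabric heat loss
#' 294 (167) W/K, permeability 16 (5) m3/m2/h, heating-system efficiency
#' 76 (12) %). Physics constants marked "calibrated" were fitted once, on a
#' large generated stock, so that the baseline stock-mean exposures reproduce
#' the published baseline column (indoor-source PM2.5 9.4 ug/m3,
#' outdoor-origin indoor PM2.5 6.2 ug/m3, radon 22.9 Bq/m3, 14.9% of
#' dwellings with mould severity index > 1, SIT 17.8 C, heating energy
#' 22.9 MWh/y); they are configuration, not sourced measurements.
#'
#' @param ... nested named lists overriding any default, e.g.
#'   `hia_params(physics = list(pm_deposition = 0.3))`.
#' @return A nested named list of parameters.
#' @export
#' @examples
#' p <- hia_params(health = list(horizon = 20))
#' p$health$horizon
hia_params <- function(...) {
  defaults <- list(
    stock = list(
      total_stock = 18.99e6, # dwellings represented (1000s in source: 18 990)
      ceiling_height = 2.4,  # m
      dwelling_types = list(
        type = c("detached", "semidetached", "terrace", "flat"),
        share = c(0.23, 0.26, 0.29, 0.22),
        envelope_ratio = c(3.2, 3.0, 2.8, 2.6) # envelope area / floor area
      ),
      fields = list(
        floor_area        = list(mean = 87.026, sd = 30, lower = 25, upper = Inf),
        fabric_heat_loss  = list(mean = 294, sd = 167, lower = 0, upper = Inf),
        permeability      = list(mean = 16, sd = 5, lower = 0, upper = Inf),
        heating_efficiency = list(mean = 0.76, sd = 0.12, lower = 0, upper = 1),
        outdoor_pm25      = list(mean = 9.3136, sd = 2.5, lower = 0, upper = Inf),
        radon_source_strength = list(mean = 22.107, sd = 12, lower = 0, upper = Inf),
        moisture_load     = list(mean = 1, sd = 0.4, lower = 0, upper = Inf)
      ),
      flags = list(
        smoker_household = 0.20,      # free knob: prevalence not published
        has_trickle_vents = 0.35,
        has_extract_fans = 0.30,
        extract_fans_working = 0.85   # conditional on fans present
      ),
      # retrofit eligibility prevalences: installation counts / 18 990k stock
      eligibility = list(
        loft_insulation = 0.2801,
        cavity_wall = 0.3454,
        solid_wall = 0.3002,
        double_glazing = 0.1280,
        condensing_boiler = 0.5650,
        gas_central_heating = 0.0163,
        draught_proofing = 0.2038
      )
    ),
    population = list(
      household_size_probs = c(`1` = 0.29, `2` = 0.35, `3` = 0.16,
                               `4` = 0.13, `5` = 0.05, `6` = 0.02),
      sex_ratio_male = 0.5,
      child_age = 16
    ),
    mortality = list(
      makeham_a = 1e-4,
      gompertz_b = c(male = 3.2e-5, female = 2.2e-5),
      gompertz_theta = 0.095,
      constant_hazard = NULL,   # scalar override for testing
      max_age = 100L,
      winter_cv_share = 0.15,   # seasonal excess share of cardiovascular deaths
      cause_curves = list(
        cardiopulmonary = c(base = 0.12, rise = 0.33, mid = 70, scale = 12),
        mi = c(base = 0.05, rise = 0.10, mid = 65, scale = 15),
        stroke = c(base = 0.03, rise = 0.08, mid = 72, scale = 12),
        lung_cancer = c(peak = 0.07, mid = 72, width = 18)
      )
    ),
    physics = list(
      infiltration_divisor = 20,   # "rule of 20": ach50 -> infiltration ach
      min_total_ach = 0.30,        # occupant window-opening floor, /h
      vent_heat_coeff = 0.33,      # Wh/(m3 K): W/K per m3/h of air exchange
      trickle_vent_ach = 0.20,     # /h added by trickle vents
      extract_fan_ach = 0.20,      # /h added by working extract fans
      extract_capture = 0.65,      # fraction of cooking PM removed at source
      pm_deposition = 0.2,         # /h
      pm_penetration = 0.8,
      radon_deposition = 0,        # radioactive decay negligible at these ach
      pm_emission_rate = 2369.8,     # ug/h continuous-equivalent cooking source (calibrated)
      room_weights = c(kitchen = 0.10, lounge = 0.45, bedroom = 0.45),
      room_factors = c(kitchen = 3.25, lounge = 0.9, bedroom = 0.6),
      sit_intercept = 19.18375,    # C; SIT at zero heat loss (two-point calibration)
      sit_slope = 0.00375,         # C per W/K
      mould_intercept = -2.6651,      # logit scale (calibrated to 14.9% baseline)
      mould_ach_coef = 0.8,        # per unit moisture_load/ach
      mould_sit_coef = 0.35,       # per C
      mould_sit_ref = 17.8,
      degree_hours = 45855,        # K h / year (calibrated to 22.9 MWh/y baseline)
      permeability_floor = 3       # m3/m2/h minimum after retrofit
    ),
    scenario = list(
      draught_proof_threshold = 7,     # m3/m2/h: leaky-dwelling cut-off
      problem_home_threshold = 0.26952    # baseline mould risk above which a home
                                       # counts as a "problem home" (~6% of stock)
    ),
    health = list(
      horizon = 50L,
      lag = list(tau_cv = 2.5, lc_delay = 5, lc_full = 20),
      yld_yll = c(winter_cv = 0.05, mi = 0.18, stroke = 0.45,
                  cardiopulmonary = 0.55, lung_cancer = 0.20),
      mortality_weight = 1.0,   # average utility of a life-year gained
      cmd = list(prevalence = 0.16, utility = 0.10,
                 duration = 10, tau = 10 / log(100)),
      asthma = list(
        event_rates = c(II = 0.004, III = 0.04, IV = 0.25),  # per child-year
        utility_weights = c(II = 0.015, III = 0.003, IV = 5e-4) # QALY per event
      ),
      theta = 1.0   # relative toxicity of indoor-source PM2.5
    ),
    mc = list(
      n_iterations = 500L,
      centiles = c(2.5, 97.5),
      rr_sigma = 0.1,      # lognormal sd of RR draws (log scale)
      delta_sd = 0.1,      # sd of normal scale factors on retrofit deltas
      weight_kappa = 50    # beta concentration for utility-weight draws
    )
  )
  merge_params(defaults, list(...))
}

merge_params <- function(base, override) {
  if (length(override) == 0) return(base)
  if (is.null(names(override)) || any(names(override) == "")) {
    abort("parameter overrides must be fully named lists")
  }
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_params(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read or write a model configuration file
#'
#' Configuration files are YAML with the same nesting as [hia_params()].
#' Values present in the file override the shipped defaults; everything else
#' keeps its default, so a config file only needs the keys being changed.
#'
#' @param path file path.
#' @param base parameter list the file is merged into.
#' @return `read_hia_config()` returns a full parameter list;
#'   `write_hia_config()` returns `path` invisibly.
#' @export
read_hia_config <- function(path, base = hia_params()) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  override <- yaml::read_yaml(path)
  if (is.null(override)) override <- list()
  merge_params(base, override)
}

#' @rdname read_hia_config
#' @param params parameter list to serialise.
#' @export
write_hia_config <- function(params, path) {
  yaml::write_yaml(params, path)
  invisible(path)
}

# ---- truncated-normal moment matching ----------------------------------

#' Solve a truncated normal whose truncated moments match a target
#'
#' Continuous dwelling fields are drawn from normals truncated to a physical
#' interval (usually `[0, Inf)`). The published stock moments are the moments
#' of the *observed* (truncated) distribution, so the parent location/scale
#' are solved so the truncated mean and SD equal the configured targets.
#'
#' @param mean,sd target mean and standard deviation of the truncated draw.
#' @param lower,upper truncation bounds.
#' @return list with elements `mean` and `sd` of the parent normal.
#' @keywords internal
match_truncnorm <- function(mean, sd, lower = 0, upper = Inf) {
  if (sd < 0) abort("sd must be non-negative")
  if (sd == 0) return(list(mean = mean, sd = 0))
  if (mean <= lower || mean >= upper) {
    abort("target mean must lie strictly inside the truncation interval")
  }
  obj <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    m <- truncnorm::etruncnorm(a = lower, b = upper, mean = mu, sd = sigma)
    v <- truncnorm::vtruncnorm(a = lower, b = upper, mean = mu, sd = sigma)
    ((m - mean) / sd)^2 + ((sqrt(v) - sd) / sd)^2
  }
  fit <- optim(c(mean, log(sd)), obj,
               control = list(reltol = 1e-14, maxit = 5000))
  if (fit$value > 1e-10) {
    abort("could not match truncated-normal moments to the requested targets")
  }
  list(mean = fit$par[1], sd = exp(fit$par[2]))
}

#' Draw a truncated normal with given truncated moments
#'
#' @param n number of draws.
#' @inheritParams match_truncnorm
#' @return numeric vector of length `n`; with `sd = 0` a constant at `mean`.
#' @keywords internal
rtrunc_match <- function(n, mean, sd, lower = 0, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  par <- match_truncnorm(mean, sd, lower, upper)
  truncnorm::rtruncnorm(n, a = lower, b = upper, mean = par$mean, sd = par$sd)
}
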