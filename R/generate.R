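#' Generate a synthetic dwelling stock
#'
#' Draws `n_dwellings` dwellings whose continuous fields are independent
#' truncated-normal variables with the configured stock moments and whose
#' flags (smoker household, ventilation devices, retrofit eligibility) are
#' independent Bernoulli draws with the configured prevalences. Derived
#' geometry (volume, envelope area) follows the dwelling type and floor
#' area; ventilation heat loss is computed from the modelled air-change
#' rate. Under the default parameters a stock of a few thousand dwellings
#' reproduces the baseline English-stock means the model is calibrated to
#' (fabric heat loss 294 W/K, permeability 16 m3/m2/h, and the baseline
#' exposure column via [compute_exposures()]).
#'
#' @param n_dwellings number of dwellings to generate (>= 1).
#' @param params parameter list from [hia_params()].
#' @param seed integer seed; the output is a pure function of
#'   `(n_dwellings, params, seed)`.
#' @return A tibble with one row per dwelling: identifiers, type, geometry,
#'   fabric/ventilation heat loss (W/K), heating efficiency (0-1),
#'   permeability (m3/m2/h at 50 Pa), ventilation and occupancy flags,
#'   outdoor PM2.5 (ug/m3), radon source strength (Bq/m3 per ach), moisture
#'   load, `elig_*` retrofit-eligibility flags and the stock weight (real
#'   dwellings represented per synthetic dwelling).
#' @export
#' @examples
#' stock <- generate_stock(100, seed = 1)
#' mean(stock$fabric_heat_loss)
generate_stock <- function(n_dwellings, params = hia_params(), seed = 1L) {
  if (!is.numeric(n_dwellings) || length(n_dwellings) != 1 ||
      is.na(n_dwellings) || n_dwellings < 1) {
    abort("n_dwellings must be a single integer >= 1")
  }
  n <- as.integer(n_dwellings)
  sp <- params$stock
  for (f in names(sp$fields)) {
    if (sp$fields[[f]]$sd < 0) abort(paste0("negative sd configured for ", f))
  }

  withr::with_seed(seed, {
    types <- sample(sp$dwelling_types$type, n, replace = TRUE,
                    prob = sp$dwelling_types$share)
    ratio <- sp$dwelling_types$envelope_ratio[
      match(types, sp$dwelling_types$type)]

    draw <- function(f) {
      d <- sp$fields[[f]]
      rtrunc_match(n, d$mean, d$sd, d$lower, d$upper)
    }
    floor_area <- draw("floor_area")
    stock <- tibble(
      dwelling_id = sprintf("D%06d", seq_len(n)),
      dwelling_type = types,
      floor_area = floor_area,
      volume = floor_area * sp$ceiling_height,
      envelope_area = floor_area * ratio,
      fabric_heat_loss = draw("fabric_heat_loss"),
      permeability = draw("permeability"),
      heating_efficiency = draw("heating_efficiency"),
      outdoor_pm25 = draw("outdoor_pm25"),
      radon_source_strength = draw("radon_source_strength"),
      moisture_load = draw("moisture_load"),
      smoker_household = runif(n) < sp$flags$smoker_household,
      has_trickle_vents = runif(n) < sp$flags$has_trickle_vents,
      has_extract_fans = runif(n) < sp$flags$has_extract_fans,
      stock_weight = sp$total_stock / n
    )
    stock$extract_fans_working <- stock$has_extract_fans &
      runif(n) < sp$flags$extract_fans_working
    for (m in names(sp$eligibility)) {
      stock[[paste0("elig_", m)]] <- runif(n) < sp$eligibility[[m]]
    }
    stock$ventilation_heat_loss <- ventilation_heat_loss(stock, params)
    stock
  })
}

#' Generate a linked occupant population
#'
#' Each dwelling receives a household whose size is drawn from the
#' configured size distribution (default mean 2.36 persons per dwelling, the
#' people-to-dwellings ratio of the emulated stock). Ages are drawn from a
#' stationary-population pyramid implied by the mortality schedule of
#' [generate_mortality()]; sex is drawn independently.
#'
#' @param stock dwelling tibble from [generate_stock()].
#' @param params parameter list from [hia_params()].
#' @param seed integer seed.
#' @return A tibble of occupants: `occupant_id`, `dwelling_id`, `age`
#'   (integer years), `sex` ("male"/"female"), `is_child` (age below the
#'   configured threshold, default 16).
#' @export
generate_population <- function(stock, params = hia_params(), seed = 1L) {
  if (!is.data.frame(stock) || nrow(stock) == 0) {
    abort("stock must be a non-empty dwelling tibble")
  }
  pp <- params$population
  pyramid <- stationary_pyramid(params)

  withr::with_seed(seed, {
    sizes <- sample(as.integer(names(pp$household_size_probs)),
                    nrow(stock), replace = TRUE,
                    prob = pp$household_size_probs)
    n_people <- sum(sizes)
    ages <- sample(pyramid$age, n_people, replace = TRUE, prob = pyramid$weight)
    tibble(
      occupant_id = sprintf("P%07d", seq_len(n_people)),
      dwelling_id = rep(stock$dwelling_id, sizes),
      age = ages,
      sex = ifelse(runif(n_people) < pp$sex_ratio_male, "male", "female"),
      is_child = ages < pp$child_age
    )
  })
}

# Stationary age pyramid (survivorship of the sex-averaged schedule).
stationary_pyramid <- function(params) {
  sched <- generate_mortality(params)
  surv <- sched %>%
    group_by(.data$age) %>%
    summarise(rate = mean(.data$all_cause_rate), .groups = "drop") %>%
    arrange(.data$age) %>%
    mutate(l = exp(-cumsum(dplyr::lag(.data$rate, default = 0))))
  tibble(age = surv$age, weight = surv$l / sum(surv$l))
}

#' Generate sex-specific mortality schedules
#'
#' Builds deterministic all-cause and cause-partitioned mortality schedules
#' for single-year ages 0-100 (the last band is open, 100+). The default
#' all-cause force of mortality is Gompertz-Makeham,
#' `h(a) = A + B exp(theta a)`, with sex-specific `B`; a constant-hazard
#' override is available for testing. Cause fractions (myocardial
#' infarction, stroke, the broader cardiopulmonary group, lung cancer) are
#' smooth functions of age, and a configurable share of cardiovascular
#' deaths is flagged as seasonal winter excess -- the only component of
#' mortality modified by indoor winter temperature.
#'
#' @param params parameter list from [hia_params()]. Rates are forces of
#'   mortality (per person-year). A pre-computed schedule in the same layout
#'   can be loaded from CSV with [read_mortality_csv()].
#' @return A tibble with one row per sex and age: `all_cause_rate`,
#'   fraction columns `frac_mi`, `frac_stroke`, `frac_cardiopulmonary`
#'   (the full group, containing MI and stroke), `frac_lung_cancer`,
#'   `frac_winter_cv` (overlay within the cardiovascular causes) and a
#'   stationary `population` column per 100 000 births.
#' @export
generate_mortality <- function(params = hia_params()) {
  mp <- params$mortality
  ages <- 0:mp$max_age
  cc <- mp$cause_curves

  frac_cp <- cc$cardiopulmonary[["base"]] + cc$cardiopulmonary[["rise"]] *
    plogis((ages - cc$cardiopulmonary[["mid"]]) / cc$cardiopulmonary[["scale"]])
  frac_mi <- cc$mi[["base"]] + cc$mi[["rise"]] *
    plogis((ages - cc$mi[["mid"]]) / cc$mi[["scale"]])
  frac_stroke <- cc$stroke[["base"]] + cc$stroke[["rise"]] *
    plogis((ages - cc$stroke[["mid"]]) / cc$stroke[["scale"]])
  frac_lc <- cc$lung_cancer[["peak"]] *
    exp(-((ages - cc$lung_cancer[["mid"]]) / cc$lung_cancer[["width"]])^2)

  if (any(frac_mi + frac_stroke > frac_cp)) {
    abort("cause-fraction curves give MI + stroke above the cardiopulmonary group")
  }
  if (any(frac_cp + frac_lc > 1)) {
    abort("cause fractions sum above 1 in at least one age band")
  }

  out <- purrr::map(c("male", "female"), function(s) {
    rate <- if (!is.null(mp$constant_hazard)) {
      rep(mp$constant_hazard, length(ages))
    } else {
      mp$makeham_a + mp$gompertz_b[[s]] * exp(mp$gompertz_theta * ages)
    }
    if (any(rate < 0 | rate > 1)) {
      abort("all-cause rates must lie in [0, 1] per band")
    }
    l <- exp(-cumsum(c(0, rate[-length(rate)])))
    tibble(
      sex = s, age = ages,
      all_cause_rate = rate,
      frac_mi = frac_mi, frac_stroke = frac_stroke,
      frac_cardiopulmonary = frac_cp, frac_lung_cancer = frac_lc,
      frac_winter_cv = mp$winter_cv_share * frac_cp,
      population = 1e5 * l / sum(l)
    )
  })
  bind_rows(out)
}

#' Partition a mortality schedule into disjoint cause-specific rates
#'
#' Outcomes that are subcategories of others are removed from the larger
#' category to avoid double counting: the cardiopulmonary remainder is the
#' cardiopulmonary group minus MI and stroke (clipped at zero with a
#' warning if the configuration is inconsistent). The winter-excess
#' cardiovascular overlay is carved proportionally out of the three
#' cardiovascular components so that the partitioned rates sum exactly to
#' the all-cause rate.
#'
#' @param schedule tibble from [generate_mortality()].
#' @return A tibble per sex and age with disjoint rates: `rate_winter_cv`,
#'   `rate_mi`, `rate_stroke`, `rate_cardiopulmonary` (non-MI/stroke
#'   remainder), `rate_lung_cancer`, `rate_other`, plus `rate_all`; the six
#'   cause rates sum to `rate_all` to machine precision.
#' @export
partition_causes <- function(schedule) {
  other_cp_frac <- schedule$frac_cardiopulmonary -
    schedule$frac_mi - schedule$frac_stroke
  if (any(other_cp_frac < 0)) {
    warn("MI + stroke exceed the cardiopulmonary group in some bands; clipping at 0")
    other_cp_frac <- pmax(other_cp_frac, 0)
  }
  cv_total <- schedule$frac_mi + schedule$frac_stroke + other_cp_frac
  if (any(schedule$frac_winter_cv > cv_total + 1e-12)) {
    abort("winter-excess overlay exceeds the combined cardiovascular fractions")
  }
  # proportional carve-out of the winter overlay from the three CV components
  keep <- ifelse(cv_total > 0, 1 - schedule$frac_winter_cv / cv_total, 1)
  r <- schedule$all_cause_rate
  out <- tibble(
    sex = schedule$sex, age = schedule$age,
    rate_all = r,
    rate_winter_cv = r * schedule$frac_winter_cv,
    rate_mi = r * schedule$frac_mi * keep,
    rate_stroke = r * schedule$frac_stroke * keep,
    rate_cardiopulmonary = r * other_cp_frac * keep,
    rate_lung_cancer = r * schedule$frac_lung_cancer
  )
  out$rate_other <- r - out$rate_winter_cv - out$rate_mi - out$rate_stroke -
    out$rate_cardiopulmonary - out$rate_lung_cancer
  if (any(out$rate_other < -1e-12)) {
    warn("cause fractions exceed 1 after partition; clipping residual at 0")
    out$rate_other <- pmax(out$rate_other, 0)
  }
  out
}

#' Period life expectancy at birth from a mortality schedule
#'
#' Discrete annual life table with deaths at mid-year: annual death
#' probability `q = 1 - exp(-rate)`, person-years `l - d/2` per band, and a
#' closed-form geometric tail for the open 100+ band.
#'
#' @param schedule tibble from [generate_mortality()].
#' @param sex `"male"` or `"female"`.
#' @return life expectancy at birth in years.
#' @export
life_expectancy <- function(schedule, sex = "male") {
  rate <- schedule$all_cause_rate[schedule$sex == sex][order(
    schedule$age[schedule$sex == sex])]
  q <- 1 - exp(-rate)
  l <- cumprod(c(1, 1 - q))
  py <- l[-length(l)] * (1 - q / 2)
  q_tail <- q[length(q)]
  tail <- l[length(l)] * (1 - q_tail / 2) / q_tail
  sum(py) + tail
}
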