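# Shared test fixtures and independently-coded oracles.

# A minimal single-dwelling stock with closed-form-friendly geometry.
mini_stock <- function(n = 1, ...) {
  out <- tibble::tibble(
    dwelling_id = sprintf("D%06d", seq_len(n)),
    dwelling_type = "terrace",
    floor_area = 100,
    volume = 240,
    envelope_area = 300,
    fabric_heat_loss = 294,
    permeability = 16,
    heating_efficiency = 0.76,
    outdoor_pm25 = 10,
    radon_source_strength = 20,
    moisture_load = 1,
    smoker_household = FALSE,
    has_trickle_vents = FALSE,
    has_extract_fans = FALSE,
    extract_fans_working = FALSE,
    stock_weight = 1
  )
  for (m in c("loft_insulation", "cavity_wall", "solid_wall",
              "double_glazing", "condensing_boiler", "gas_central_heating",
              "draught_proofing")) {
    out[[paste0("elig_", m)]] <- FALSE
  }
  over <- list(...)
  for (nm in names(over)) out[[nm]] <- over[[nm]]
  out$ventilation_heat_loss <- ventilation_heat_loss(out, hia_params())
  out
}

# A toy mortality schedule in the generate_mortality() layout.
toy_schedule <- function(rates_male, rates_female = rates_male,
                         frac_mi = 0.2, frac_stroke = 0.1,
                         frac_cp = 0.5, frac_lc = 0.1, frac_w = 0) {
  mk <- function(s, r) {
    k <- length(r)
    tibble::tibble(
      sex = s, age = seq_len(k) - 1L, all_cause_rate = r,
      frac_mi = rep_len(frac_mi, k), frac_stroke = rep_len(frac_stroke, k),
      frac_cardiopulmonary = rep_len(frac_cp, k),
      frac_lung_cancer = rep_len(frac_lc, k),
      frac_winter_cv = rep_len(frac_w, k),
      population = rep(1, k)
    )
  }
  dplyr::bind_rows(mk("male", rates_male), mk("female", rates_female))
}

# Exhaustive survival-product enumeration of life-years gained, written as
# plain per-cohort loops (independent of the package's matrix engine).
#
# schedule: toy_schedule() tibble with frac_winter_cv = 0 (trivial partition);
# pop: tibble(sex, age, n); cause: name of a frac_* column suffix;
# rr_fun(sex, start_age) -> cohort relative risk at full effect;
# lag_frac: vector of attained effect fractions for t = 0..horizon-1.
brute_delta_py <- function(schedule, pop, cause, rr_fun, lag_frac, horizon) {
  frac_col <- paste0("frac_", cause)
  total <- 0
  for (i in seq_len(nrow(pop))) {
    s <- pop$sex[i]; a0 <- pop$age[i]; n <- pop$n[i]
    sch <- schedule[schedule$sex == s, ]
    sch <- sch[order(sch$age), ]
    max_age <- max(sch$age)
    rr <- rr_fun(s, a0)
    l_b <- 1; l_i <- 1; py_b <- 0; py_i <- 0
    for (t in 0:(horizon - 1)) {
      row <- sch[sch$age == min(a0 + t, max_age), ]
      r_all <- row$all_cause_rate
      r_c <- r_all * row[[frac_col]]
      m_t <- 1 + (rr - 1) * lag_frac[t + 1]
      r_imp <- r_all + r_c * (m_t - 1)
      q_b <- 1 - exp(-r_all)
      q_i <- 1 - exp(-r_imp)
      py_b <- py_b + l_b * (1 - q_b / 2)
      py_i <- py_i + l_i * (1 - q_i / 2)
      l_b <- l_b * (1 - q_b)
      l_i <- l_i * (1 - q_i)
    }
    total <- total + n * (py_i - py_b)
  }
  total
}

# Default-parameter fixtures shared across expensive tests (built once per
# test run; ~ a second).
fixture_env <- new.env(parent = emptyenv())
default_fixture <- function(n = 600, seed = 42L) {
  key <- paste0("fx_", n, "_", seed)
  if (is.null(fixture_env[[key]])) {
    p <- hia_params()
    stock <- generate_stock(n, p, seed = seed)
    occupants <- generate_population(stock, p, seed = seed + 1L)
    schedule <- generate_mortality(p)
    fixture_env[[key]] <- list(params = p, stock = stock,
                               occupants = occupants, schedule = schedule)
  }
  fixture_env[[key]]
}
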