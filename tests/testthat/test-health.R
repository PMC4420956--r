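# Exposure-response scaling, life-table engine and morbidity models.

test_that("scale_rr matches the log-linear closed form", {
  oracle <- function(rr, delta, unit) exp(log(rr) * delta / unit)
  expect_equal(scale_rr(1.082, 10, 10), oracle(1.082, 10, 10),
               tolerance = 1e-12)
  expect_equal(scale_rr(0.98, 0.3), oracle(0.98, 0.3, 1), tolerance = 1e-12)
  expect_equal(scale_rr(1.16, 57, 100), oracle(1.16, 57, 100),
               tolerance = 1e-12)
  expect_equal(scale_rr(1.5, 0), 1)                    # null change
  expect_equal(scale_rr(1.3, -1), 1 / 1.3)             # inverse on removal
  expect_error(scale_rr(-1, 1), "positive")
  expect_error(scale_rr(1.3, Inf), "finite")
  # binary pathways only admit off/unchanged/on
  expect_equal(scale_rr(1.3, 1, binary = TRUE), 1.3)
  expect_error(scale_rr(1.3, 0.5, binary = TRUE), "binary")
})

test_that("combine_rrs is the product with an empty-input identity", {
  expect_equal(combine_rrs(c(1.25, 1.30)), 1.625)
  expect_equal(combine_rrs(numeric(0)), 1)
  expect_equal(combine_rrs(c(2, 0.5)), 1)
  expect_error(combine_rrs(c(1.2, -1)), "positive")
})

test_that("lag profiles match their functional forms", {
  p <- hia_params()
  expect_equal(lag_profile("immediate", 0:5, p), rep(1, 6))
  expect_equal(lag_profile("cardiovascular", 2.5, p), 1 - exp(-1))
  expect_equal(lag_profile("cardiovascular", 0, p), 0)
  expect_equal(lag_profile("lung_cancer", c(0, 5, 12.5, 20, 40), p),
               c(0, 0, 0.5, 1, 1))
  lc <- lag_profile("lung_cancer", 0:49, p)
  expect_true(all(diff(lc) >= 0) && all(lc >= 0 & lc <= 1))
  expect_error(lag_profile("unknown", 1, p))
  expect_error(lag_profile("immediate", -1, p), "non-negative")
})

test_that("cause partition is disjoint and conserves the all-cause rate", {
  sched <- generate_mortality()
  part <- partition_causes(sched)
  total <- part$rate_winter_cv + part$rate_mi + part$rate_stroke +
    part$rate_cardiopulmonary + part$rate_lung_cancer + part$rate_other
  expect_lt(max(abs(total - part$rate_all)), 1e-12)
  expect_true(all(part[c("rate_winter_cv", "rate_mi", "rate_stroke",
                         "rate_cardiopulmonary", "rate_lung_cancer",
                         "rate_other")] >= 0))
  # hand-checked partition on a toy schedule without the winter overlay:
  # fractions 0.2 / 0.1 / 0.5 / 0.1 at rate 0.01 -> cp remainder 0.002
  toy <- toy_schedule(c(0.01, 0.01))
  tp <- partition_causes(toy)
  expect_equal(tp$rate_mi, rep(0.002, 4))
  expect_equal(tp$rate_stroke, rep(0.001, 4))
  expect_equal(tp$rate_cardiopulmonary, rep(0.002, 4))  # 0.5 - 0.2 - 0.1
  expect_equal(tp$rate_lung_cancer, rep(0.001, 4))
})

test_that("a unit multiplier leaves the life table exactly unchanged", {
  fx <- default_fixture()
  lt <- build_life_table(fx$schedule)
  run <- run_life_table(lt, "winter_cv", rr = 1, horizon = 50,
                        params = fx$params)
  expect_identical(run$delta_py, 0)
  expect_equal(run$cause_deaths_base, run$cause_deaths_imp)
})

test_that("run_life_table matches the brute-force enumeration on toy tables", {
  p <- hia_params()
  sched <- toy_schedule(c(0.02, 0.05, 0.10, 0.30, 0.90),
                        c(0.01, 0.04, 0.08, 0.25, 0.80))
  pop <- tidyr::expand_grid(sex = c("male", "female"), age = 0:4)
  pop$n <- c(10, 20, 30, 40, 50, 15, 25, 35, 45, 55)
  lt <- build_life_table(sched, pop)
  horizon <- 8L
  rr_tbl <- tidyr::expand_grid(sex = c("male", "female"), age = 0:4)
  rr_tbl$rr <- c(1.4, 1.2, 1.1, 0.9, 1.3, 1.25, 1.05, 0.8, 1.6, 1.0)
  rr_fun <- function(s, a) rr_tbl$rr[rr_tbl$sex == s & rr_tbl$age == a]

  for (spec in list(list(cause = "mi", lag = "cardiovascular"),
                    list(cause = "lung_cancer", lag = "lung_cancer"),
                    list(cause = "stroke", lag = "immediate"))) {
    lag_frac <- lag_profile(spec$lag, 0:(horizon - 1), p)
    got <- run_life_table(lt, spec$cause, rr_tbl, spec$lag, horizon, p)
    want <- brute_delta_py(sched, pop, spec$cause, rr_fun, lag_frac, horizon)
    expect_equal(got$delta_py, want, tolerance = 1e-9)
  }
})

test_that("life-years gained are monotone in the hazard multiplier", {
  fx <- default_fixture()
  lt <- build_life_table(fx$schedule)
  runs <- sapply(c(0.9, 0.95, 1, 1.05, 1.1), function(r)
    run_life_table(lt, "cardiopulmonary", r, "cardiovascular", 50,
                   fx$params)$delta_py)
  expect_true(all(diff(runs) < 0))        # higher hazard, fewer life-years
  expect_gt(runs[1], 0)
  expect_lt(runs[5], 0)
  # longer follow-up accumulates more impact
  short <- run_life_table(lt, "cardiopulmonary", 0.9, "cardiovascular", 10,
                          fx$params)$delta_py
  expect_gt(runs[1], short)
  expect_error(run_life_table(lt, "cardiopulmonary", -1), "positive")
  expect_error(run_life_table(lt, "cardiopulmonary", 1, horizon = 0),
               "horizon")
})

test_that("high-risk stratification at p = 1 equals the unadjusted run", {
  fx <- default_fixture()
  lt <- build_life_table(fx$schedule)
  base <- run_life_table(lt, "winter_cv", 0.95, "immediate", 50, fx$params)
  strat <- run_winter_stratified(lt, 1, 0.95, 50, fx$params)
  expect_identical(strat$delta_py, base$delta_py)
  expect_identical(strat$conservation_rel_error, 0)
})

test_that("concentrating winter risk shrinks the benefit towards zero", {
  fx <- default_fixture()
  lt <- build_life_table(fx$schedule)
  fractions <- c(1, 0.1, 0.01, 0.001)
  gains <- sapply(fractions, function(p)
    run_winter_stratified(lt, p, 0.9, 50, fx$params)$delta_py)
  expect_true(all(gains > 0))             # protective RR -> benefit
  expect_true(all(diff(gains) < 0))       # strictly decreasing with p
  expect_lt(gains[4], gains[1] / 10)      # vanishing at 0.1%
  # a harmful multiplier flips every sign
  losses <- run_winter_stratified(lt, 0.1, 1.1, 50, fx$params)$delta_py
  expect_lt(losses, 0)
  expect_error(run_winter_stratified(lt, 0), "fraction_p")
  expect_error(run_winter_stratified(lt, 1.2), "fraction_p")
})

test_that("stratification conserves base-year cardiovascular deaths", {
  fx <- default_fixture()
  lt <- build_life_table(fx$schedule)
  for (p in c(0.1, 0.01, 0.001)) {
    strat <- run_winter_stratified(lt, p, 0.9, 50, fx$params)
    expect_lt(strat$conservation_rel_error, 1e-8)
    # independent check of the reported stratified death count
    lam <- strat$lambda
    deaths <- function(kind) {
      sum(sapply(c("male", "female"), function(s) {
        r <- lt$rates[lt$rates$sex == s, ]
        r <- r[order(r$age), ]
        n <- lt$population$n[lt$population$sex == s][
          order(lt$population$age[lt$population$sex == s])]
        cv_nw <- r$rate_mi + r$rate_stroke + r$rate_cardiopulmonary
        if (kind == "unstratified") {
          q <- 1 - exp(-r$rate_all)
          sum(n * q * (cv_nw + r$rate_winter_cv) / r$rate_all)
        } else {
          r_low <- r$rate_all - r$rate_winter_cv
          r_high <- r_low + lam * r$rate_winter_cv / p
          q_h <- 1 - exp(-r_high); q_l <- 1 - exp(-r_low)
          sum(n * (p * q_h * (cv_nw + lam * r$rate_winter_cv / p) / r_high +
                     (1 - p) * q_l * cv_nw / r_low))
        }
      }))
    }
    expect_equal(deaths("stratified"), deaths("unstratified"),
                 tolerance = 1e-8)
  }
})

test_that("morbidity from mortality is linear in the ratios", {
  yll <- c(mi = 10, stroke = 5)
  ratios <- c(mi = 0.18, stroke = 0.45, cardiopulmonary = 0.55)
  expect_equal(morbidity_from_mortality(yll, ratios),
               c(mi = 1.8, stroke = 2.25))
  expect_equal(morbidity_from_mortality(2 * yll, ratios),
               2 * morbidity_from_mortality(yll, ratios))
  expect_error(morbidity_from_mortality(c(unknown = 1), ratios), "missing")
  expect_error(morbidity_from_mortality(yll, c(mi = -1, stroke = 1)),
               "non-negative")
})

test_that("CMD impact follows its decay-weighted closed form", {
  # one adult, prevalence 0.16, +1 C, utility 0.10
  q <- cmd_impact(1, 0.16, 1, 0.10, horizon = 50)
  t <- 0:49
  tau <- 10 / log(100)
  decay <- ifelse(t < 10, exp(-t / tau), 0)
  expect_equal(q, -sum(decay) * 0.16 * (0.9 - 1) * 0.10)
  expect_gt(q, 0)                          # warming reduces CMD
  expect_equal(cmd_impact(1, 0.16, 0, 0.10), 0)        # null change
  expect_equal(cmd_impact(1, 0.16, 1, 0.20), 2 * q)    # linear in weight
  # truncation: nothing accrues beyond year 10
  expect_equal(cmd_impact(1, 0.16, 1, 0.10, horizon = 10), q)
  expect_error(cmd_impact(1, 1.5, 1, 0.1), "prevalence")
})

test_that("asthma impact follows the per-class closed forms", {
  rates <- c(II = 0.004, III = 0.04, IV = 0.25)
  weights <- c(II = 0.015, III = 0.003, IV = 5e-4)
  # one child, +100 percentage points of mould: full tabulated RRs apply
  q <- asthma_impact(1, rates, 100, weights, horizon = 50)
  want <- -50 * sum(rates * (c(1.53, 1.53, 1.83) - 1) * weights)
  expect_equal(q, want)
  expect_lt(q, 0)                          # more mould, more asthma
  # -50 points scales the class-IV RR to 1.83^(-0.5)
  q2 <- asthma_impact(1, rates["IV"], -50, weights["IV"], horizon = 50)
  expect_equal(q2, -50 * 0.25 * (1.83^(-0.5) - 1) * 5e-4)
  expect_gt(q2, 0)
  expect_equal(asthma_impact(1, rates, 0, weights), 0)
  expect_error(asthma_impact(1, c(V = 0.1), 10, c(V = 0.1)), "harm class")
})

test_that("aggregate_qalys sums outcomes and scales per 10 000 persons", {
  yll <- c(winter_cv = 4, mi = -1)
  yld <- c(winter_cv = 0.2, mi = -0.18)
  res <- aggregate_qalys(yll, yld, cmd_qalys = 0.5, asthma_qalys = -0.1,
                         persons = 2000, scenario = "test")
  scale <- 1e4 / 2000
  expect_equal(res$net_qaly_per_10k,
               (4 + 0.2 - 1 - 0.18 + 0.5 - 0.1) * scale)
  expect_equal(res$net_qaly_per_10k, sum(res$impacts$qaly_per_10k))
  expect_setequal(res$impacts$outcome, c("winter_cv", "mi", "cmd", "asthma"))
  # utility of a life-year scales only the mortality component
  res2 <- aggregate_qalys(yll, yld, 0.5, -0.1, 2000, mortality_weight = 0.5)
  expect_equal(res2$impacts$qaly_mortality, res$impacts$qaly_mortality / 2)
  expect_equal(res2$impacts$qaly_morbidity, res$impacts$qaly_morbidity)
  expect_error(aggregate_qalys(yll, yld, 0, 0, persons = 0), "positive")
})

test_that("person deltas wire exposures to occupants correctly", {
  p <- hia_params()
  s <- dplyr::bind_rows(mini_stock(), mini_stock(fabric_heat_loss = 200))
  s$dwelling_id <- c("D000001", "D000002")
  occ <- tibble::tibble(
    occupant_id = c("P1", "P2", "P3"),
    dwelling_id = c("D000001", "D000002", "D000002"),
    age = c(40L, 8L, 70L), sex = c("male", "female", "female"),
    is_child = c(FALSE, TRUE, FALSE))
  post <- s
  post$fabric_heat_loss <- post$fabric_heat_loss - 80
  post$ventilation_heat_loss <- ventilation_heat_loss(post, p)
  ex <- compute_exposures(s, post, p)
  d <- person_deltas(occ, ex)
  expect_equal(nrow(d), 3)
  expect_equal(d$delta_sit, rep(0.3, 3))   # -80 W/K -> +0.3 C everywhere
  expect_equal(d$delta_pm, rep(0, 3))      # ventilation unchanged
  # theta scales only the indoor-source PM component
  d0 <- person_deltas(occ, ex, theta = 0)
  expect_equal(d0$delta_pm, rep(0, 3))
  expect_error(person_deltas(occ, ex, theta = 2), "theta")
})

test_that("run_hia baseline scenario is exactly null", {
  fx <- default_fixture()
  res <- run_hia(fx$stock, fx$occupants, fx$schedule, "baseline", fx$params)
  expect_equal(res$impacts$qaly_per_10k, rep(0, nrow(res$impacts)),
               tolerance = 0)
  expect_equal(res$net_qaly_per_10k, 0, tolerance = 0)
})

test_that("run_hia returns a coherent result object", {
  fx <- default_fixture()
  res <- run_hia(fx$stock, fx$occupants, fx$schedule, "regulation", fx$params)
  expect_s3_class(res, "hia_result")
  expect_setequal(res$impacts$outcome,
                  c("winter_cv", "mi", "stroke", "cardiopulmonary",
                    "lung_cancer", "cmd", "asthma"))
  expect_equal(res$net_qaly_per_10k, sum(res$impacts$qaly_per_10k))
  expect_equal(res$persons, nrow(fx$occupants))
  expect_equal(res$n_dwellings, nrow(fx$stock))
  # tidiers expose the same numbers
  expect_identical(tidy(res), res$impacts)
  expect_equal(glance(res)$net_qaly_per_10k, res$net_qaly_per_10k)
  expect_s3_class(autoplot(res), "ggplot")
})
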