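#' Monte Carlo settings
#'
#' @param n_iterations number of model iterations (default 500).
#' @param centiles lower/upper centiles of the reported credible interval
#'   (default 2.5 and 97.5).
#' @param seed master seed; each iteration derives its own substream from
#'   `(seed, iteration)` alone, so draws do not depend on evaluation order.
#' @param distributions parameter-distribution table, see
#'   [default_parameter_distributions()].
#' @return A list of class `mc_settings`.
#' @export
mc_settings <- function(n_iterations = 500L, centiles = c(2.5, 97.5),
                        seed = 1L,
                        distributions = default_parameter_distributions()) {
  if (n_iterations < 2) abort("n_iterations must be at least 2")
  if (!(centiles[1] > 0 && centiles[1] < centiles[2] && centiles[2] < 100)) {
    abort("centiles must satisfy 0 < lower < upper < 100")
  }
  structure(list(n_iterations = as.integer(n_iterations),
                 centiles = centiles, seed = as.integer(seed),
                 distributions = distributions),
            class = "mc_settings")
}

#' Default Monte Carlo parameter distributions
#'
#' Lognormal draws centred on each exposure-response relative risk (median
#' equal to the point estimate), normal scale factors on the retrofit
#' fabric / permeability / ventilation deltas (the determinants of the
#' exposure change), and beta draws for the utility weights. A dispersion
#' of zero makes a parameter degenerate at its centre.
#'
#' @param er_table exposure-response table.
#' @param params parameter list from [hia_params()].
#' @return A tibble with columns `parameter`, `dist`
#'   (`"lognormal"`/`"normal"`/`"beta"`), `center`, `dispersion`
#'   (lognormal sigma, normal sd, or beta concentration kappa).
#' @export
default_parameter_distributions <- function(er_table = exposure_response(),
                                            params = hia_params()) {
  rr_rows <- tibble(
    parameter = paste("rr", er_table$exposure, er_table$outcome, sep = "_"),
    dist = "lognormal", center = er_table$rr, dispersion = er_table$sigma)
  delta_rows <- tibble(
    parameter = c("delta_fabric_scale", "delta_permeability_scale",
                  "delta_vent_scale"),
    dist = "normal", center = 1, dispersion = params$mc$delta_sd)
  aw <- params$health$asthma$utility_weights
  util_rows <- tibble(
    parameter = c("utility_cmd", paste0("utility_asthma_", names(aw))),
    dist = "beta",
    center = c(params$health$cmd$utility, as.numeric(aw)),
    dispersion = params$mc$weight_kappa)
  bind_rows(rr_rows, delta_rows, util_rows)
}

#' Draw one joint parameter set
#'
#' Parameters are independent; the draw is reproducible from
#' `(settings$seed, iteration)` alone.
#'
#' @param settings from [mc_settings()].
#' @param iteration zero-based iteration index, below `n_iterations`.
#' @return named numeric vector of parameter values.
#' @export
sample_parameters <- function(settings, iteration) {
  if (iteration >= settings$n_iterations || iteration < 0) {
    abort("iteration must lie in [0, n_iterations)")
  }
  d <- settings$distributions
  sub_seed <- as.integer((as.numeric(settings$seed) * 48271 +
                            iteration * 16807 + 12345) %% 2147483629)
  withr::with_seed(sub_seed, {
    vals <- purrr::map2_dbl(seq_len(nrow(d)), d$dist, function(i, dist) {
      ctr <- d$center[i]; disp <- d$dispersion[i]
      if (disp == 0) return(ctr)
      switch(dist,
        lognormal = rlnorm(1, meanlog = log(ctr), sdlog = disp),
        normal = rnorm(1, mean = ctr, sd = disp),
        beta = rbeta(1, shape1 = ctr * disp, shape2 = (1 - ctr) * disp),
        abort(paste0("unknown distribution for parameter ", d$parameter[i]))
      )
    })
  })
  setNames(vals, d$parameter)
}

# Push a parameter draw into the model's configuration objects.
apply_draw <- function(draw, params, er_table, catalog) {
  key <- paste("rr", er_table$exposure, er_table$outcome, sep = "_")
  hit <- key %in% names(draw)
  er_table$rr[hit] <- as.numeric(draw[key[hit]])

  if ("delta_fabric_scale" %in% names(draw)) {
    catalog$fabric_delta <- catalog$fabric_delta * draw[["delta_fabric_scale"]]
  }
  if ("delta_permeability_scale" %in% names(draw)) {
    catalog$permeability_delta <- catalog$permeability_delta *
      draw[["delta_permeability_scale"]]
  }
  if ("delta_vent_scale" %in% names(draw)) {
    params$physics$trickle_vent_ach <- params$physics$trickle_vent_ach *
      draw[["delta_vent_scale"]]
    params$physics$extract_fan_ach <- params$physics$extract_fan_ach *
      draw[["delta_vent_scale"]]
  }
  if ("utility_cmd" %in% names(draw)) {
    params$health$cmd$utility <- draw[["utility_cmd"]]
  }
  aw <- params$health$asthma$utility_weights
  for (cl in names(aw)) {
    k <- paste0("utility_asthma_", cl)
    if (k %in% names(draw)) aw[[cl]] <- draw[[k]]
  }
  params$health$asthma$utility_weights <- aw
  list(params = params, er_table = er_table, catalog = catalog)
}

#' Build a Monte Carlo pipeline closure for the full model
#'
#' Returns a pure function of one parameter draw that re-runs the whole
#' scenario analysis (draw-perturbed retrofit deltas, exposure-response
#' risks and utility weights) and returns the per-outcome QALYs per 10 000
#' persons plus the net impact.
#'
#' @inheritParams run_hia
#' @return a function `draw -> named numeric vector`.
#' @export
hia_mc_pipeline <- function(stock, occupants, schedule,
                            scenario = "regulation", params = hia_params(),
                            er_table = exposure_response(),
                            catalog = measure_catalog(), theta = NULL,
                            high_risk_fraction = 1) {
  force(stock); force(occupants); force(schedule); force(scenario)
  function(draw) {
    cfg <- apply_draw(draw, params, er_table, catalog)
    res <- run_hia(stock, occupants, schedule, scenario,
                   params = cfg$params, er_table = cfg$er_table,
                   catalog = cfg$catalog, theta = theta,
                   high_risk_fraction = high_risk_fraction)
    c(setNames(res$impacts$qaly_per_10k, res$impacts$outcome),
      net = res$net_qaly_per_10k)
  }
}

#' Run the Monte Carlo uncertainty analysis
#'
#' Evaluates the pipeline once per iteration with an independent joint
#' parameter draw and summarises each output as its iteration mean plus the
#' empirical credible interval at the configured centiles (linear
#' interpolation between order statistics).
#'
#' @param pipeline function of one parameter draw returning a named numeric
#'   vector of outputs (see [hia_mc_pipeline()]).
#' @param settings from [mc_settings()].
#' @return An object of class `hia_mc`: `summary` (outcome, point, lower,
#'   upper, n), `draws` (per-iteration values) and the settings.
#' @export
run_monte_carlo <- function(pipeline, settings = mc_settings()) {
  rows <- purrr::map(seq_len(settings$n_iterations) - 1L, function(it) {
    draw <- sample_parameters(settings, it)
    out <- tryCatch(pipeline(draw), error = function(e) {
      abort(paste0("pipeline failed at iteration ", it, " (draw: ",
                   paste(names(draw), signif(draw, 4), sep = "=",
                         collapse = ", "), "): ", conditionMessage(e)))
    })
    tibble(iteration = it, outcome = names(out), value = as.numeric(out))
  })
  draws <- bind_rows(rows)
  probs <- settings$centiles / 100
  summary <- draws %>%
    group_by(.data$outcome) %>%
    summarise(point = mean(.data$value),
              lower = quantile(.data$value, probs[1], type = 7, names = FALSE),
              upper = quantile(.data$value, probs[2], type = 7, names = FALSE),
              n = dplyr::n(), .groups = "drop")
  if (any(summary$lower > summary$upper)) {
    abort("credible interval bounds are inverted")  # defensive; cannot happen
  }
  structure(list(summary = summary, draws = draws, settings = settings),
            class = "hia_mc")
}

#' Sensitivity of results to the size of the winter-risk group
#'
#' Re-evaluates the winter-cardiovascular pathway with the high-risk group
#' concentrated in decreasing fractions of the population (default 100%,
#' 10%, 1%, 0.1%). All other pathways are deterministic functions of
#' unchanged inputs, so their values are identical across fractions.
#'
#' @inheritParams run_hia
#' @param fractions high-risk fractions in `(0, 1]`, typically descending.
#' @return A tibble: one row per fraction and outcome plus a `net` row per
#'   fraction.
#' @export
sensitivity_high_risk <- function(stock, occupants, schedule,
                                  scenario = "installer_discretion",
                                  params = hia_params(),
                                  fractions = c(1, 0.1, 0.01, 0.001),
                                  er_table = exposure_response(),
                                  catalog = measure_catalog()) {
  purrr::map(fractions, function(p) {
    res <- run_hia(stock, occupants, schedule, scenario, params,
                   er_table = er_table, catalog = catalog,
                   high_risk_fraction = p)
    bind_rows(
      tibble(fraction = p, outcome = res$impacts$outcome,
             qaly_per_10k = res$impacts$qaly_per_10k),
      tibble(fraction = p, outcome = "net",
             qaly_per_10k = res$net_qaly_per_10k))
  }) %>% bind_rows()
}

#' Sensitivity of results to indoor-particle toxicity
#'
#' Scales the indoor-source component of the PM2.5 exposure change by
#' `theta` before exposure-response scaling: `theta = 1` assumes equal
#' toxicity to outdoor particles (the base analysis, reproduced exactly);
#' `theta = 0` removes the indoor-source PM effect entirely.
#'
#' @inheritParams run_hia
#' @return An `hia_result` for the given `theta`.
#' @export
sensitivity_pm_toxicity <- function(stock, occupants, schedule,
                                    scenario = "installer_discretion",
                                    params = hia_params(), theta = 0,
                                    er_table = exposure_response(),
                                    catalog = measure_catalog()) {
  if (theta < 0 || theta > 1) abort("theta must lie in [0, 1]")
  run_hia(stock, occupants, schedule, scenario, params,
          er_table = er_table, catalog = catalog, theta = theta)
}
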