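# Read a CSV with exact double parsing. vroom's fast float path can be off
# by one ulp on long mantissas, which breaks the bit-exact round-trip
# contract; reading as character and converting through R's correctly
# rounded strtod preserves every bit readr::write_csv emitted.
read_csv_exact <- function(path, character = character(0),
                           logical = character(0), integer = character(0)) {
  x <- readr::read_csv(
    path, col_types = readr::cols(.default = readr::col_character()))
  for (nm in names(x)) {
    x[[nm]] <- if (nm %in% character) {
      x[[nm]]
    } else if (nm %in% logical || startsWith(nm, "elig_")) {
      as.logical(x[[nm]])
    } else if (nm %in% integer) {
      as.integer(x[[nm]])
    } else {
      as.numeric(x[[nm]])
    }
  }
  x
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0(what, " is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Read and write the pipeline's CSV tables
#'
#' Stable, documented CSV schemas for the dwelling stock, occupant
#' population, mortality schedule, per-dwelling exposures and per-outcome
#' impacts. Files are UTF-8 with one header row and a decimal point;
#' numeric values round-trip exactly.
#'
#' @param x the tibble to write.
#' @param path file path.
#' @return readers return a validated tibble; writers return `path`
#'   invisibly.
#' @name hia_csv
NULL

#' @rdname hia_csv
#' @export
write_stock_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname hia_csv
#' @export
read_stock_csv <- function(path) {
  x <- read_csv_exact(
    path, character = c("dwelling_id", "dwelling_type"),
    logical = c("smoker_household", "has_trickle_vents",
                "has_extract_fans", "extract_fans_working"))
  check_columns(x, c("dwelling_id", "dwelling_type", "floor_area", "volume",
                     "envelope_area", "fabric_heat_loss", "permeability",
                     "heating_efficiency", "ventilation_heat_loss",
                     "smoker_household", "has_trickle_vents",
                     "has_extract_fans", "extract_fans_working",
                     "outdoor_pm25", "radon_source_strength",
                     "moisture_load", "stock_weight"), "stock.csv")
  lgl <- x$extract_fans_working & !x$has_extract_fans
  if (any(lgl)) abort("stock.csv row has working extract fans without fans")
  x
}

#' @rdname hia_csv
#' @export
write_population_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname hia_csv
#' @export
read_population_csv <- function(path) {
  x <- read_csv_exact(
    path, character = c("occupant_id", "dwelling_id", "sex"),
    logical = "is_child", integer = "age")
  check_columns(x, c("occupant_id", "dwelling_id", "age", "sex", "is_child"),
                "population.csv")
  x
}

#' @rdname hia_csv
#' @export
write_mortality_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname hia_csv
#' @export
read_mortality_csv <- function(path) {
  x <- read_csv_exact(path, character = "sex", integer = "age")
  check_columns(x, c("sex", "age", "all_cause_rate", "frac_mi",
                     "frac_stroke", "frac_cardiopulmonary",
                     "frac_lung_cancer", "frac_winter_cv", "population"),
                "mortality.csv")
  if (any(x$all_cause_rate < 0 | x$all_cause_rate > 1)) {
    abort("mortality.csv: all_cause_rate must lie in [0, 1]")
  }
  x
}

#' @rdname hia_csv
#' @export
write_exposures_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname hia_csv
#' @export
read_exposures_csv <- function(path) {
  x <- read_csv_exact(path, character = c("dwelling_id", "state"))
  check_columns(x, c("dwelling_id", "state", "sit", "sts",
                     "pm25_indoor_source", "pm25_outdoor_source", "radon",
                     "mould_risk", "heating_energy"), "exposures.csv")
  x
}

#' Generate and write the synthetic input tables
#'
#' Writes `stock.csv`, `population.csv` and `mortality.csv` to `outdir`
#' together with a `manifest.json` recording the seed, a parameter hash and
#' the row counts, so a run can be reproduced and verified byte for byte.
#'
#' @param n_dwellings number of dwellings to generate.
#' @param params parameter list from [hia_params()].
#' @param seed integer seed.
#' @param outdir output directory (created if needed).
#' @return the manifest as a list, invisibly.
#' @export
cmd_generate <- function(n_dwellings, params = hia_params(), seed = 1L,
                         outdir = ".") {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  stock <- generate_stock(n_dwellings, params, seed)
  occupants <- generate_population(stock, params, seed + 1L)
  schedule <- generate_mortality(params)
  write_stock_csv(stock, file.path(outdir, "stock.csv"))
  write_population_csv(occupants, file.path(outdir, "population.csv"))
  write_mortality_csv(schedule, file.path(outdir, "mortality.csv"))
  manifest <- list(seed = seed, parameter_hash = rlang::hash(params),
                   n_dwellings = nrow(stock), n_occupants = nrow(occupants),
                   n_mortality_rows = nrow(schedule))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run the scenario experiment end to end and write result tables
#'
#' For each requested scenario, chains measure assignment, retrofit
#' application, exposure modelling and the health engine, and writes
#' `impacts.csv` (one row per outcome per scenario). With `mc_iterations >
#' 0` a Monte Carlo run per scenario adds credible intervals and writes
#' `mc_summary.csv` and per-iteration `mc_results.csv`.
#'
#' @param stock,occupants,schedule input tibbles, or paths to the
#'   corresponding CSV files.
#' @param scenarios character vector of scenario names.
#' @param params parameter list from [hia_params()].
#' @param outdir output directory; `NULL` writes nothing.
#' @param mc_iterations Monte Carlo iterations (0 = deterministic only).
#' @param seed master seed for the Monte Carlo draws.
#' @return A list with `results` (per-scenario `hia_result`), `impacts`
#'   (combined tibble) and, with MC on, `mc` per scenario.
#' @export
cmd_run <- function(stock, occupants, schedule,
                    scenarios = c("regulation", "installer_discretion",
                                  "no_added_ventilation"),
                    params = hia_params(), outdir = NULL,
                    mc_iterations = 0L, seed = 1L) {
  if (is.character(stock)) stock <- read_stock_csv(stock)
  if (is.character(occupants)) occupants <- read_population_csv(occupants)
  if (is.character(schedule)) schedule <- read_mortality_csv(schedule)
  orphans <- setdiff(occupants$dwelling_id, stock$dwelling_id)
  if (length(orphans) > 0) {
    abort(paste0("population references unknown dwelling_id: ", orphans[1]))
  }

  results <- purrr::map(setNames(scenarios, scenarios), function(sc) {
    run_hia(stock, occupants, schedule, sc, params)
  })
  impacts <- purrr::imap(results, function(res, sc) {
    mutate(generics::tidy(res), scenario = sc)
  }) %>% bind_rows()

  mc <- NULL
  if (mc_iterations > 0) {
    settings <- mc_settings(
      n_iterations = mc_iterations, seed = seed,
      distributions = default_parameter_distributions(
        exposure_response(), params))
    mc <- purrr::map(setNames(scenarios, scenarios), function(sc) {
      run_monte_carlo(
        hia_mc_pipeline(stock, occupants, schedule, sc, params), settings)
    })
  }

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    readr::write_csv(impacts, file.path(outdir, "impacts.csv"))
    if (!is.null(mc)) {
      readr::write_csv(
        purrr::imap(mc, ~ mutate(.x$summary, scenario = .y)) %>% bind_rows(),
        file.path(outdir, "mc_summary.csv"))
      readr::write_csv(
        purrr::imap(mc, ~ mutate(.x$draws, scenario = .y)) %>% bind_rows(),
        file.path(outdir, "mc_results.csv"))
    }
  }
  invisible(list(results = results, impacts = impacts, mc = mc))
}
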