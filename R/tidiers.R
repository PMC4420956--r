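#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a health-impact result
#'
#' @param x an `hia_result` from [run_hia()].
#' @param ... unused.
#' @return A tibble with one row per outcome: `outcome`, `qaly_mortality`,
#'   `qaly_morbidity`, `qaly_per_10k` (all per 10 000 persons over the
#'   follow-up horizon).
#' @export
tidy.hia_result <- function(x, ...) x$impacts

#' One-row summary of a health-impact result
#'
#' @inheritParams tidy.hia_result
#' @return A one-row tibble: `scenario`, `net_qaly_per_10k`, `horizon`,
#'   `persons`, `n_dwellings`, `theta`, `high_risk_fraction`.
#' @export
glance.hia_result <- function(x, ...) {
  tibble(scenario = x$scenario, net_qaly_per_10k = x$net_qaly_per_10k,
         horizon = x$horizon, persons = x$persons,
         n_dwellings = x$n_dwellings %||% NA_integer_,
         theta = x$theta %||% NA_real_,
         high_risk_fraction = x$high_risk_fraction %||% NA_real_)
}

#' @export
print.hia_result <- function(x, ...) {
  cat("Health impact over", x$horizon, "years --", x$scenario,
      "scenario\n")
  cat(sprintf("  %d dwellings, %d persons\n",
              x$n_dwellings %||% NA_integer_, x$persons))
  df <- as.data.frame(x$impacts)
  df[-1] <- lapply(df[-1], round, 1)
  print(df, row.names = FALSE)
  cat(sprintf("  Net impact: %.1f QALYs per 10 000 persons\n",
              x$net_qaly_per_10k))
  invisible(x)
}

#' Tidy a Monte Carlo result
#'
#' @param x an `hia_mc` from [run_monte_carlo()].
#' @param ... unused.
#' @return The summary tibble: `outcome`, `point` (iteration mean),
#'   `lower`/`upper` (empirical credible bounds), `n` iterations.
#' @export
tidy.hia_mc <- function(x, ...) x$summary

#' One-row summary of a Monte Carlo result
#'
#' @inheritParams tidy.hia_mc
#' @return A one-row tibble with the net-impact point and interval.
#' @export
glance.hia_mc <- function(x, ...) {
  net <- x$summary[x$summary$outcome == "net", , drop = FALSE]
  tibble(net_point = net$point, net_lower = net$lower,
         net_upper = net$upper, n_iterations = x$settings$n_iterations)
}

#' @export
print.hia_mc <- function(x, ...) {
  cat("Monte Carlo health impact (", x$settings$n_iterations,
      " iterations, ", x$settings$centiles[1], "-",
      x$settings$centiles[2], " centiles)\n", sep = "")
  df <- as.data.frame(x$summary)
  df[c("point", "lower", "upper")] <-
    lapply(df[c("point", "lower", "upper")], round, 1)
  print(df, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot per-outcome QALY impacts
#'
#' @param object an `hia_result`.
#' @param ... unused.
#' @return a ggplot object: QALYs per 10 000 persons by outcome.
#' @export
autoplot.hia_result <- function(object, ...) {
  df <- object$impacts
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$outcome, .data$qaly_per_10k),
    y = .data$qaly_per_10k,
    fill = .data$qaly_per_10k > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "QALYs per 10 000 persons",
                  title = paste0("Health impact over ", object$horizon,
                                 " years: ", object$scenario)) +
    ggplot2::theme_minimal()
}

#' Plot Monte Carlo credible intervals per outcome
#'
#' @param object an `hia_mc`.
#' @param ... unused.
#' @return a ggplot object with points and interval bars.
#' @export
autoplot.hia_mc <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(
    x = stats::reorder(.data$outcome, .data$point), y = .data$point)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "QALYs per 10 000 persons",
                  title = "Monte Carlo credible intervals") +
    ggplot2::theme_minimal()
}
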