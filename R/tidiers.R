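#' Tidy per-cell posterior summaries of a fit
#'
#' One row per cell and parameter with posterior mean, sd and a central
#' credible interval.
#'
#' @param x A `txn_fit` object.
#' @param level Credible-interval level (default 0.95).
#' @param ... Unused.
#' @return A tibble: `cell_id`, `group`, `parameter`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`.
#' @export
tidy.txn_fit <- function(x, level = 0.95, ...) {
  a <- (1 - level) / 2
  x$cells |>
    tidyr::pivot_longer(
      cols = dplyr::all_of(c("tau_on", "tau_off", "switch_time", "alpha",
                             "copy_number", "sigma_eps2")),
      names_to = "parameter", values_to = "value"
    ) |>
    dplyr::summarise(
      estimate = mean(.data$value),
      std.error = sd(.data$value),
      conf.low = quantile(.data$value, a, names = FALSE),
      conf.high = quantile(.data$value, 1 - a, names = FALSE),
      .by = c("cell_id", "group", "parameter")
    )
}

#' One-row summary of a fit
#'
#' @param x A `txn_fit` object.
#' @param ... Unused.
#' @return A tibble with run-level facts: mode, cells, iterations kept, mean
#'   total log-likelihood, worst population-layer split R-hat and smallest
#'   effective sample size.
#' @export
glance.txn_fit <- function(x, ...) {
  ll <- x$cells |>
    dplyr::summarise(total = sum(.data$loglik), .by = "iteration")
  tibble::tibble(
    mode = x$mode,
    n_cells = length(unique(x$cells$cell_id)),
    n_groups = length(x$groups),
    n_stored = x$n_stored,
    mean_total_loglik = mean(ll$total),
    max_rhat = suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
    min_ess = suppressWarnings(min(x$diagnostics$ess, na.rm = TRUE)),
    seed = x$seed
  )
}

#' Heat-strip view of sorted per-cell on-rate posteriors
#'
#' Renders the [sorted_posterior_matrix()]: one horizontal strip per cell
#' (ascending posterior mean), shaded by normalized posterior mass, faceted
#' by group.
#'
#' @param object A `txn_fit` object.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.txn_fit <- function(object, bins = 100, ...) {
  spm <- sorted_posterior_matrix(object, bins = bins)
  mids <- (spm$breaks[-1] + spm$breaks[-length(spm$breaks)]) / 2
  df <- tibble::as_tibble(spm$matrix, rownames = "cell_id") |>
    tidyr::pivot_longer(-"cell_id", names_to = "bin", values_to = "mass") |>
    dplyr::mutate(rate = rep(mids, times = nrow(spm$matrix)),
                  rank = match(.data$cell_id, spm$order$cell_id),
                  group = spm$order$group[.data$rank])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rate, y = .data$rank,
                                   fill = .data$mass)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(direction = -1, name = "posterior mass") +
    ggplot2::facet_wrap(~group, scales = "free_y") +
    ggplot2::labs(x = "relative per-copy on-rate (arbitrary units)",
                  y = "cell (sorted by posterior mean)") +
    ggplot2::theme_minimal()
}

#' Plot observed onset curves
#'
#' @param data Long-format dataset (`cell_id`, `group`, `time`, `signal`).
#' @return A ggplot object with one line per cell, faceted by group.
#' @export
plot_onset_curves <- function(data) {
  data <- validate_timeseries_data(data)
  ggplot2::ggplot(data, ggplot2::aes(x = .data$time, y = .data$signal,
                                     group = .data$cell_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "time since transfection", y = "fluorescence signal") +
    ggplot2::theme_minimal()
}
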