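#' Read a long-format onset-curve dataset
#'
#' Reads a delimited text file with header columns `cell_id`, `group`,
#' `time`, `signal`, groups rows by cell, sorts by time, and validates
#' (strictly increasing times, no duplicate `(cell, time)` pairs, numeric
#' fields, >= 2 observations per cell).
#'
#' @param path CSV file path.
#' @return A validated tibble ordered by `(cell_id, time)`.
#' @export
read_timeseries <- function(path) {
  data <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE,
                    col_types = readr::cols(
                      cell_id = readr::col_character(),
                      group = readr::col_character(),
                      time = readr::col_double(),
                      signal = readr::col_double()
                    ))
  )
  prob <- readr::problems(data)
  if (nrow(prob) > 0) {
    stop("parse error in ", path, " at line(s) ",
         paste(utils::head(prob$row, 5), collapse = ", "), ": ",
         prob$expected[1], " expected", call. = FALSE)
  }
  validate_timeseries_data(data)
}

#' Write a long-format onset-curve dataset
#'
#' @param data Tibble with columns `cell_id`, `group`, `time`, `signal`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(data, path) {
  data <- validate_timeseries_data(data)
  readr::write_csv(data, path)
  invisible(path)
}

#' Moments of a lognormal distribution
#'
#' @param mu,sigma Location and scale of the underlying normal (`sigma >= 0`).
#' @return Named vector `c(mean, sd, cv)`:
#'   `mean = exp(mu + sigma^2/2)`, `sd = mean * sqrt(exp(sigma^2) - 1)`,
#'   `cv = sqrt(exp(sigma^2) - 1)` (depends on `sigma` only).
#' @export
lognormal_moments <- function(mu, sigma) {
  stopifnot(sigma >= 0)
  m <- exp(mu + sigma^2 / 2)
  cv <- sqrt(exp(sigma^2) - 1)
  c(mean = m, sd = m * cv, cv = cv)
}

#' Population-level summary of a fit
#'
#' Computes both reporting conventions for the on-phase transcription rate:
#' the *hierarchical* statistics (`hier_*`), obtained from the lognormal
#' moments evaluated at the posterior means of each group's population-layer
#' location and scale, and the *pooled* statistics (`pooled_*`), the sample
#' mean/sd/cv of the per-cell posterior-mean rates within each group.  In
#' standard (non-hierarchical) mode only the pooled convention is meaningful
#' and the hierarchical columns are `NA`.
#'
#' @param fit A [run_mcmc()] result.
#' @return A tibble with one row per group: `group`, `hier_mean`, `hier_sd`,
#'   `hier_cv`, `pooled_mean`, `pooled_sd`, `pooled_cv`, `n_cells`.
#' @export
summarize_population <- function(fit) {
  stopifnot(inherits(fit, "txn_fit"))
  pooled <- fit$cells |>
    dplyr::summarise(post_mean = mean(.data$tau_on),
                     .by = c("cell_id", "group")) |>
    dplyr::summarise(
      pooled_mean = mean(.data$post_mean),
      pooled_sd = sd(.data$post_mean),
      pooled_cv = sd(.data$post_mean) / mean(.data$post_mean),
      n_cells = dplyr::n(),
      .by = "group"
    )
  if (nrow(pooled) == 0 || any(pooled$n_cells == 0)) {
    stop("empty group in fit", call. = FALSE)
  }
  hier <- purrr::map_dfr(fit$groups, function(g) {
    mu_col <- paste0("mu_tau_on.", g)
    sd_col <- paste0("sigma_tau_on.", g)
    if (fit$mode != "hierarchical" ||
        !all(c(mu_col, sd_col) %in% names(fit$hyper))) {
      return(tibble::tibble(group = g, hier_mean = NA_real_,
                            hier_sd = NA_real_, hier_cv = NA_real_))
    }
    m <- lognormal_moments(mean(fit$hyper[[mu_col]]),
                           mean(fit$hyper[[sd_col]]))
    tibble::tibble(group = g, hier_mean = m[["mean"]], hier_sd = m[["sd"]],
                   hier_cv = m[["cv"]])
  })
  out <- dplyr::left_join(hier, pooled, by = "group")
  structure(out, class = c("population_summary", class(out)))
}

#' Between-construct transcription-rate ratio
#'
#' Ratio of group-level mean on-rates, `mean(X) / mean(Y)`.  Because the same
#' copy-number distribution underlies every group, this ratio is comparable
#' across constructs even though absolute per-copy rates are only defined up
#' to the common copy-number scale.  Uses the hierarchical means when
#' available, otherwise the pooled means.
#'
#' @param summary A [summarize_population()] result.
#' @param group_x,group_y Group labels (numerator / denominator).
#' @param convention `"hier"` or `"pooled"`; default picks `"hier"` when
#'   available.
#' @return Positive scalar ratio.
#' @export
construct_ratio <- function(summary, group_x, group_y,
                            convention = c("auto", "hier", "pooled")) {
  convention <- match.arg(convention)
  for (g in c(group_x, group_y)) {
    if (!g %in% summary$group) stop("unknown group: ", g, call. = FALSE)
  }
  use_hier <- switch(convention,
    auto = all(is.finite(summary$hier_mean)),
    hier = TRUE, pooled = FALSE)
  col <- if (use_hier) "hier_mean" else "pooled_mean"
  x <- summary[[col]][summary$group == group_x]
  y <- summary[[col]][summary$group == group_y]
  if (!is.finite(x) || !is.finite(y)) {
    stop("requested convention not available in summary", call. = FALSE)
  }
  x / y
}

#' Per-cell posterior histograms sorted by posterior mean
#'
#' For each cell, a normalized histogram of its stored on-rate samples on a
#' common grid (100 bins spanning the pooled 0.5-99.5 percentile range),
#' with rows ordered by ascending posterior mean — the matrix behind the
#' heat-strip views of per-cell estimates.
#'
#' @param fit A [run_mcmc()] result.
#' @param bins Number of histogram bins.
#' @return List with `matrix` (cells x bins, each row summing to 1),
#'   `breaks`, and `order` (tibble of `cell_id`, `group`, `post_mean` in row
#'   order).
#' @export
sorted_posterior_matrix <- function(fit, bins = 100) {
  stopifnot(inherits(fit, "txn_fit"), bins >= 2)
  samples <- fit$cells
  if (nrow(samples) == 0) stop("fit contains no stored samples", call. = FALSE)
  rng <- quantile(samples$tau_on, c(0.005, 0.995), names = FALSE)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5) * max(abs(rng[1]), 1) * 1e-6
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  ord <- samples |>
    dplyr::summarise(post_mean = mean(.data$tau_on),
                     .by = c("cell_id", "group")) |>
    dplyr::arrange(.data$post_mean)
  m <- t(vapply(ord$cell_id, function(id) {
    x <- samples$tau_on[samples$cell_id == id]
    x <- pmin(pmax(x, rng[1]), rng[2])
    h <- hist(x, breaks = breaks, plot = FALSE)$counts
    h / sum(h)
  }, numeric(bins)))
  rownames(m) <- ord$cell_id
  colnames(m) <- sprintf("bin%03d", seq_len(bins))
  list(matrix = m, breaks = breaks, order = ord)
}

#' @importFrom graphics hist
NULL

#' Write a fit to delimited-text sample tables with a JSON sidecar
#'
#' Persists the stored per-cell and population-layer samples as CSV (one row
#' per stored iteration) and the run metadata (config echo, seed, acceptance
#' rates, diagnostics) as JSON.
#'
#' @param fit A [run_mcmc()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "txn_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(fit$cells, file.path(dir, "cell_samples.csv"))
  readr::write_csv(fit$hyper, file.path(dir, "hyper_samples.csv"))
  meta <- list(
    mode = fit$mode, seed = fit$seed, groups = fit$groups,
    fixed = fit$fixed,
    config = fit$config[setdiff(names(fit$config), "proposal_scales")],
    proposal_scales = as.list(fit$config$proposal_scales),
    acceptance = fit$acceptance, diagnostics = fit$diagnostics,
    n_stored = fit$n_stored, windows = fit$windows
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a fit written by [write_fit()]
#'
#' @param dir Directory containing `cell_samples.csv`, `hyper_samples.csv`
#'   and `metadata.json`.
#' @return A `txn_fit` object (sufficient for summarizing and plotting).
#' @export
read_fit <- function(dir) {
  cells <- readr::read_csv(file.path(dir, "cell_samples.csv"),
                           show_col_types = FALSE)
  hyper <- readr::read_csv(file.path(dir, "hyper_samples.csv"),
                           show_col_types = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  structure(
    list(cells = cells, hyper = hyper,
         acceptance = tibble::as_tibble(meta$acceptance),
         diagnostics = tibble::as_tibble(meta$diagnostics),
         config = meta$config, fixed = meta$fixed, seed = meta$seed,
         mode = meta$mode, groups = meta$groups,
         windows = tibble::as_tibble(meta$windows),
         n_stored = meta$n_stored),
    class = "txn_fit"
  )
}
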