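# Minimal hand-built fit object for summary tests: constant chains whose
# population statistics are known exactly.
constant_fit <- function(mu = c(A = 1, B = 2), sigma = c(A = 0.5, B = 0.5),
                         tau_cells = NULL, n_iter = 10) {
  groups <- names(mu)
  cells <- purrr::map_dfr(groups, function(g) {
    taus <- if (is.null(tau_cells)) c(1, 1, 1) else tau_cells[[g]]
    purrr::map_dfr(seq_along(taus), function(i) {
      tibble::tibble(
        iteration = seq_len(n_iter),
        cell_id = paste0(g, i), group = g,
        tau_on = taus[i], tau_off = 0.1, switch_time = 5, alpha = 1,
        copy_number = 5, sigma_eps2 = 10, loglik = -10
      )
    })
  })
  hyper <- tibble::tibble(iteration = seq_len(n_iter))
  for (g in groups) {
    hyper[[paste0("mu_tau_on.", g)]] <- mu[[g]]
    hyper[[paste0("sigma_tau_on.", g)]] <- sigma[[g]]
  }
  structure(list(cells = cells, hyper = hyper, mode = "hierarchical",
                 groups = groups, n_stored = n_iter,
                 diagnostics = tibble::tibble(parameter = character(),
                                              rhat = numeric(),
                                              ess = numeric()),
                 acceptance = tibble::tibble(component = character(),
                                             rate = numeric()),
                 config = list(), fixed = list(), seed = 1),
            class = "txn_fit")
}

test_that("timeseries files round-trip and report malformed inputs", {
  b <- small_bench()
  path <- withr::local_tempfile(fileext = ".csv")
  write_timeseries(b$data, path)
  back <- read_timeseries(path)
  expect_equal(as.data.frame(back), as.data.frame(b$data))
  # shuffled rows sort back to the same dataset
  shuf <- b$data[sample(nrow(b$data)), ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(shuf, path2)
  expect_equal(as.data.frame(read_timeseries(path2)), as.data.frame(b$data))
  # duplicated time names the offending cell
  dup <- rbind(b$data, b$data[b$data$cell_id == "A02", ][1, ])
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dup, path3)
  expect_error(read_timeseries(path3), "A02")
  # missing column
  path4 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(b$data[, c("cell_id", "time", "signal")], path4)
  expect_error(read_timeseries(path4), "group")
})

test_that("lognormal moments follow the closed forms", {
  expect_equal(lognormal_moments(0, 0), c(mean = 1, sd = 0, cv = 0))
  p <- lognormal_params_from_mean_fano(10, 1)
  m <- lognormal_moments(p[["mu"]], p[["sigma"]])
  expect_equal(m[["mean"]], 10)
  expect_equal(m[["sd"]]^2, 10)
  # cv depends only on sigma
  expect_equal(lognormal_moments(0, 0.8)[["cv"]],
               lognormal_moments(5, 0.8)[["cv"]])
})

test_that("population summary computes both conventions consistently", {
  f <- constant_fit()
  s <- summarize_population(f)
  for (g in c("A", "B")) {
    m <- lognormal_moments(c(A = 1, B = 2)[[g]], 0.5)
    expect_equal(s$hier_mean[s$group == g], m[["mean"]])
    expect_equal(s$hier_sd[s$group == g], m[["sd"]])
  }
  # internal consistency cv = sd/mean to 1e-12 in both conventions
  expect_equal(s$hier_cv, s$hier_sd / s$hier_mean, tolerance = 1e-12)
  # pooled cv of identical cells is zero
  expect_equal(s$pooled_cv, c(0, 0))
  # pooled stats from distinct per-cell means
  f2 <- constant_fit(tau_cells = list(A = c(1, 2, 3), B = c(2, 4, 6)))
  s2 <- summarize_population(f2)
  expect_equal(s2$pooled_mean[s2$group == "A"], 2)
  expect_equal(s2$pooled_sd[s2$group == "A"], 1)
  expect_equal(s2$pooled_cv, s2$pooled_sd / s2$pooled_mean, tolerance = 1e-12)
})

test_that("construct ratios are reflexive, transitive and validated", {
  f <- constant_fit(mu = c(A = 1, B = 2, C = 3),
                    sigma = c(A = 0.5, B = 0.5, C = 0.5))
  s <- summarize_population(f)
  expect_equal(construct_ratio(s, "A", "A"), 1)
  expect_equal(construct_ratio(s, "C", "B") * construct_ratio(s, "B", "A"),
               construct_ratio(s, "C", "A"))
  expect_error(construct_ratio(s, "Z", "A"), "unknown group")
  # pooled convention selectable
  expect_equal(construct_ratio(s, "B", "A", convention = "pooled"), 1)
})

test_that("sorted posterior matrix is normalized and ordered", {
  f <- constant_fit(tau_cells = list(A = c(3, 1, 2), B = c(6, 5, 4)))
  spm <- sorted_posterior_matrix(f, bins = 20)
  expect_equal(rowSums(spm$matrix), rep(1, 6), ignore_attr = TRUE)
  expect_true(!is.unsorted(spm$order$post_mean))
  # single-cell input gives one row
  f1 <- constant_fit(mu = c(A = 1), sigma = c(A = 0.5),
                     tau_cells = list(A = 2))
  spm1 <- sorted_posterior_matrix(f1, bins = 10)
  expect_equal(nrow(spm1$matrix), 1)
})

test_that("fits persist to text files and summaries are pure functions of them", {
  b <- small_bench()
  d <- b$data[b$data$cell_id %in% c("A01", "B01"), ]
  cfg <- mcmc_config(n_iterations = 200, burn_in = 50, thin = 2, seed = 17)
  fit <- run_mcmc(d, fixed_bench, cfg)
  dir <- withr::local_tempdir()
  write_fit(fit, dir)
  expect_true(file.exists(file.path(dir, "cell_samples.csv")))
  back <- read_fit(dir)
  s1 <- summarize_population(back)
  s2 <- summarize_population(back)
  expect_identical(s1, s2)
  expect_equal(as.data.frame(s1), as.data.frame(summarize_population(fit)))
})

test_that("tidy, glance and autoplot work on a fit", {
  b <- small_bench()
  d <- b$data[b$data$cell_id %in% c("A01", "B01"), ]
  fit <- run_mcmc(d, fixed_bench,
                  mcmc_config(n_iterations = 200, burn_in = 50, thin = 2,
                              seed = 18))
  td <- tidy(fit)
  expect_true(all(c("cell_id", "parameter", "estimate", "conf.low",
                    "conf.high") %in% names(td)))
  expect_equal(nrow(td), 2 * 6)
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_cells, 2)
  p <- autoplot(fit, bins = 15)
  expect_s3_class(p, "ggplot")
  p2 <- plot_onset_curves(d)
  expect_s3_class(p2, "ggplot")
})

test_that("command-line interface runs the simulate/fit/summarize/compare pipeline", {
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "spec.json")
  jsonlite::write_json(list(
    n_cells_per_group = list(A = 2, B = 2),
    group_tau_on_means = list(A = 2, B = 4),
    obs_times = seq(1, 20, length.out = 15)
  ), cfg, auto_unbox = TRUE, digits = NA)
  sim_dir <- file.path(dir, "sim")
  expect_equal(cli_main(c("simulate", "--config", cfg, "--out-dir", sim_dir,
                          "--seed", "2")), 0L)
  expect_true(file.exists(file.path(sim_dir, "data.csv")))
  fit_dir <- file.path(dir, "fit")
  expect_equal(cli_main(c("fit", "--data", file.path(sim_dir, "data.csv"),
                          "--out-dir", fit_dir, "--mode", "hierarchical",
                          "--iterations", "150", "--burn-in", "50",
                          "--thin", "2", "--seed", "3")), 0L)
  fit_dir_s <- file.path(dir, "fit_s")
  expect_equal(cli_main(c("fit", "--data", file.path(sim_dir, "data.csv"),
                          "--out-dir", fit_dir_s, "--mode", "standard",
                          "--iterations", "150", "--burn-in", "50",
                          "--thin", "2", "--seed", "3")), 0L)
  sum_dir <- file.path(dir, "summ")
  expect_equal(cli_main(c("summarize", "--fit", fit_dir,
                          "--out-dir", sum_dir)), 0L)
  expect_true(file.exists(file.path(sum_dir, "summary.json")))
  meta_h <- jsonlite::read_json(file.path(fit_dir, "metadata.json"))
  meta_s <- jsonlite::read_json(file.path(fit_dir_s, "metadata.json"))
  expect_equal(meta_h$mode, "hierarchical")
  expect_equal(meta_s$mode, "standard")
  out_csv <- file.path(dir, "ratios.csv")
  expect_equal(cli_main(c("compare", file.path(sum_dir, "summary.json"),
                          "--out", out_csv)), 0L)
  ratios <- readr::read_csv(out_csv, show_col_types = FALSE)
  expect_true("B/A" %in% ratios$comparison)
  # unknown subcommand exits nonzero
  expect_equal(suppressMessages(cli_main("frobnicate")), 1L)
})
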