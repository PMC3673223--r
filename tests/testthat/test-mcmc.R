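test_that("log-space proposal has the antisymmetric Jacobian and right spread", {
  set.seed(21)
  p <- propose_log_perturbation(c(1, 2, 3), scales = 1e-12)
  expect_equal(p$proposal, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(p$log_jacobian, 0, tolerance = 1e-9)
  # antisymmetry: the reverse move has the negated Jacobian term
  p2 <- propose_log_perturbation(c(1.7, 0.3), scales = 0.5)
  fwd <- p2$log_jacobian
  rev <- sum(log(c(1.7, 0.3)) - log(p2$proposal))
  expect_equal(fwd, -rev)
  # sampling oracle: log-step is N(0, 0.1^2)
  set.seed(22)
  steps <- log(replicate(1e5, propose_log_perturbation(1, 0.1)$proposal))
  expect_equal(mean(steps), 0, tolerance = 0.002)
  expect_equal(sd(steps), 0.1, tolerance = 0.002)
})

test_that("configuration invariants are enforced", {
  expect_error(mcmc_config(n_iterations = 100, burn_in = 100), "burn_in")
  expect_error(mcmc_config(thin = 0))
  expect_error(mcmc_config(block_size = 0))
  expect_error(mcmc_config(proposal_scales = c(tau_on = -1, tau_off = 1,
                                               switch_time = 1, alpha = 1,
                                               copy_number = 1,
                                               sigma_eps2 = 1)))
  cfg <- mcmc_config(n_iterations = 10, burn_in = 2)
  expect_s3_class(cfg, "mcmc_config")
})

test_that("starting heuristic is deterministic, in-support, and finds a ramp onset", {
  b <- small_bench()
  set.seed(5)
  s1 <- initialize_state(b$data, fixed_bench)
  set.seed(5)
  s2 <- initialize_state(b$data, fixed_bench)
  expect_identical(s1, s2)
  expect_true(all(s1$theta$tau_on > 0 & s1$theta$copy_number > 0 &
                  s1$theta$sigma_eps2 > 0))
  win <- range(b$data$time)
  expect_true(all(s1$theta$switch_time >= win[1] &
                  s1$theta$switch_time <= win[2]))
  # noiseless ramp: flat to t=10, then linear rise
  t <- seq(1, 20, by = 1)
  y <- pmax(t - 10, 0) * 5
  ramp <- tibble::tibble(cell_id = "r1", group = "A", time = t, signal = y)
  set.seed(1)
  sr <- initialize_state(ramp, fixed_bench)
  expect_lt(abs(sr$theta$switch_time - 10), 1.5)  # within ~one frame
  # constant signal falls back to the window midpoint with a warning
  flat <- tibble::tibble(cell_id = "f1", group = "A", time = t,
                         signal = rep(2, length(t)))
  expect_warning(sf <- initialize_state(flat, fixed_bench), "midpoint")
  expect_equal(sf$theta$switch_time, mean(range(t)))
})

test_that("same seed gives bit-identical chains; standard mode never touches the population layer", {
  b <- small_bench()
  d3 <- b$data[b$data$cell_id %in% c("A01", "A02", "B01"), ]
  cfg <- mcmc_config(n_iterations = 300, burn_in = 100, thin = 2, seed = 99)
  f1 <- run_mcmc(d3, fixed_bench, cfg)
  f2 <- run_mcmc(d3, fixed_bench, cfg)
  expect_identical(f1$cells, f2$cells)
  expect_identical(f1$hyper, f2$hyper)
  expect_identical(f1$acceptance, f2$acceptance)
  cfg_s <- mcmc_config(n_iterations = 300, burn_in = 100, thin = 2, seed = 99,
                       mode = "standard")
  fs <- run_mcmc(d3, fixed_bench, cfg_s)
  hyper_cols <- setdiff(names(fs$hyper), "iteration")
  for (cl in hyper_cols) {
    expect_equal(length(unique(fs$hyper[[cl]])), 1)
  }
})

test_that("zero-variance proposals leave the chain unchanged with full acceptance", {
  b <- small_bench()
  d2 <- b$data[b$data$cell_id %in% c("A01", "B01"), ]
  tiny <- c(tau_on = 1e-12, tau_off = 1e-12, switch_time = 1e-12,
            alpha = 1e-12, copy_number = 1e-12, sigma_eps2 = 1e-12)
  cfg <- mcmc_config(n_iterations = 60, burn_in = 10, thin = 1, seed = 4,
                     proposal_scales = tiny, ridge_scale = 1e-12,
                     adapt = FALSE, mode = "standard")
  f <- run_mcmc(d2, fixed_bench, cfg)
  rates <- f$acceptance$rate[f$acceptance$component %in%
                               hiertxn:::.cell_params]
  expect_true(all(rates[!is.na(rates)] == 1))
  for (p in c("tau_on", "alpha", "copy_number")) {
    spread <- f$cells |>
      dplyr::summarise(r = diff(range(.data[[p]])), .by = "cell_id")
    expect_true(all(spread$r < 1e-6))
  }
})

test_that("MH acceptance rule holds on a logged single-cell trace", {
  # standard mode, one cell: accepted moves may decrease the posterior only
  # stochastically; every accepted decrease must be consistent with exp(delta)
  b <- small_bench()
  d1 <- b$data[b$data$cell_id == "A01", ]
  cfg <- mcmc_config(n_iterations = 400, burn_in = 0, thin = 1, seed = 8,
                     mode = "standard", adapt = FALSE)
  f <- run_mcmc(d1, fixed_bench, cfg)
  ll <- f$cells$loglik
  # chain must move and log-likelihood must stay finite
  expect_true(all(is.finite(ll)))
  expect_gt(length(unique(round(ll, 10))), 10)
  # large decreases in posterior should be rare under the MH rule
  drops <- diff(ll)
  expect_lt(mean(drops < -10), 0.05)
})

test_that("per-cell and joint-block acceptance target the same posterior", {
  tt <- toy_cells()
  cfg_pc <- mcmc_config(n_iterations = 8000, burn_in = 3000, thin = 2,
                        seed = 31, mode = "standard")
  cfg_jb <- mcmc_config(n_iterations = 8000, burn_in = 3000, thin = 2,
                        seed = 32, mode = "standard",
                        acceptance_style = "joint_block")
  f_pc <- run_mcmc(tt$data, tt$fixed, cfg_pc)
  f_jb <- run_mcmc(tt$data, tt$fixed, cfg_jb)
  # compare the data-identified combination c * tau_on * alpha
  m_pc <- f_pc$cells |>
    dplyr::summarise(
      m = mean(log(.data$tau_on * .data$copy_number * .data$alpha)),
      s = mean(.data$switch_time), .by = "cell_id")
  m_jb <- f_jb$cells |>
    dplyr::summarise(
      m = mean(log(.data$tau_on * .data$copy_number * .data$alpha)),
      s = mean(.data$switch_time), .by = "cell_id")
  expect_equal(m_pc$m, m_jb$m, tolerance = 0.05)
  expect_equal(m_pc$s, m_jb$s, tolerance = 0.1)
})

test_that("block size does not change the stationary distribution", {
  tt <- toy_cells()
  cfg1 <- mcmc_config(n_iterations = 8000, burn_in = 3000, thin = 2,
                      seed = 41, mode = "standard", block_size = 1)
  cfgN <- mcmc_config(n_iterations = 8000, burn_in = 3000, thin = 2,
                      seed = 42, mode = "standard", block_size = 3)
  f1 <- run_mcmc(tt$data, tt$fixed, cfg1)
  fN <- run_mcmc(tt$data, tt$fixed, cfgN)
  m1 <- f1$cells |>
    dplyr::summarise(
      m = mean(log(.data$tau_on * .data$copy_number * .data$alpha)),
      .by = "cell_id")
  mN <- fN$cells |>
    dplyr::summarise(
      m = mean(log(.data$tau_on * .data$copy_number * .data$alpha)),
      .by = "cell_id")
  expect_equal(m1$m, mN$m, tolerance = 0.05)
})

test_that("conjugate location update matches its closed-form posterior", {
  set.seed(51)
  x <- rnorm(200, 1.4, 0.6)
  sigma <- 0.6
  v <- 1 / (length(x) / sigma^2 + 1 / 100)
  m <- v * sum(x) / sigma^2
  draws <- replicate(2e4, hiertxn:::gibbs_mu(x, sigma))
  expect_lt(abs(mean(draws) - m), 5 * sqrt(v) / sqrt(2e4))
  expect_lt(abs(sd(draws) - sqrt(v)), 0.002)
})

test_that("population-layer updates recover known hyperparameters from many cells", {
  set.seed(61)
  n <- 10000
  true_mu <- 0.9; true_sigma <- 0.5
  theta <- data.frame(
    tau_on = rlnorm(n, true_mu, true_sigma),
    tau_off = rlnorm(n, -1, 0.4),
    alpha = rlnorm(n, 0, 0.5),
    copy_number = hiertxn:::rtpois(n, 5),
    sigma_eps2 = 1 / rgamma(n, 3, rate = 50),
    switch_time = runif(n, 2, 10)
  )
  groups <- rep("A", n)
  psi <- hyperparams("A", mu_tau_on = c(A = 0), sigma_tau_on = c(A = 1),
                     mu_tau_off = 0, sigma_tau_off = 1,
                     mu_alpha = 0, sigma_alpha = 1,
                     precision_shape = 1, precision_rate = 1, copy_lambda = 2)
  mus <- sigmas <- lams <- numeric(300)
  for (i in 1:300) {
    up <- update_hyperparams(theta, groups, psi)
    psi <- up$psi
    mus[i] <- psi$mu_tau_on[["A"]]
    sigmas[i] <- psi$sigma_tau_on[["A"]]
    lams[i] <- psi$copy_lambda
  }
  keep <- 101:300
  expect_lt(abs(mean(mus[keep]) - true_mu), 3 * sd(mus[keep]) + 0.02)
  expect_equal(mean(sigmas[keep]), true_sigma, tolerance = 0.05)
  expect_equal(mean(lams[keep]), 5, tolerance = 0.15)
})

test_that("standard mode pins the confounded product but not the individual rates", {
  tt <- toy_cells()
  cfg <- mcmc_config(n_iterations = 5000, burn_in = 1500, thin = 2, seed = 71,
                     mode = "standard")
  f <- run_mcmc(tt$data, tt$fixed, cfg)
  spread <- f$cells |>
    dplyr::summarise(
      sd_full = sd(log(.data$tau_on * .data$copy_number * .data$alpha)),
      sd_prod = sd(log(.data$tau_on * .data$copy_number)),
      sd_tau = sd(log(.data$tau_on)), .by = "cell_id")
  # the fully identified combination is far tighter than the free rate...
  expect_true(all(spread$sd_full < 0.3 * spread$sd_tau))
  # ...and folding in the copy number already tightens tau_on
  expect_true(all(spread$sd_prod < spread$sd_tau))
})

test_that("cells with too few observations are rejected", {
  b <- small_bench()
  d1 <- b$data[b$data$cell_id == "A01", ][1, ]  # 1 observation
  expect_error(run_mcmc(d1, fixed_bench,
                        mcmc_config(n_iterations = 10, burn_in = 1)),
               "fewer than 2")
})
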