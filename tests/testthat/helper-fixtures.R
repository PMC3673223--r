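# Shared fixtures and oracles, built in code at test time.

# Near-zero stand-in for rate parameters whose types require strict
# positivity but whose limiting (zero-rate) behaviour a test exercises.
EPS_RATE <- 1e-300

kin <- function(tau_off = 1, tau_on = 5, s = 10, alpha = 1, delta_M = 0.2,
                delta_P = 0.1, c = 1, kappa = 1, sig2 = 1) {
  cell_kinetics(changepoint_transcription(tau_off, tau_on, s),
                alpha = alpha, delta_M = delta_M, delta_P = delta_P,
                copy_number = c, kappa = kappa, sigma_eps2 = sig2)
}

fixed_bench <- list(delta_M = 0.2, delta_P = 0.1, kappa = 1)

# Small two-group benchmark reused across MCMC tests (cached per session).
.fixture_cache <- new.env()
small_bench <- function() {
  if (is.null(.fixture_cache$small)) {
    spec <- population_spec(
      n_cells_per_group = c(A = 4, B = 4),
      group_tau_on_means = c(A = 2, B = 4),
      obs_times = seq(0.5, 25, length.out = 25)
    )
    .fixture_cache$small <- make_benchmark(spec, seed = 3)
  }
  .fixture_cache$small
}

# Three fast-response cells with sharply identified switches, built for
# sampler-consistency checks: the posterior is unimodal and the combination
# c * tau_on * alpha is tightly data-determined.
toy_cells <- function(seed = 13) {
  set.seed(seed)
  truth <- tibble::tibble(
    cell_id = sprintf("T%02d", 1:3), group = "A",
    tau_on = 10, tau_off = 0.2, switch_time = c(5, 7, 9),
    alpha = 2, copy_number = c(3, 5, 7),
    sigma_eps2 = 9, delta_M = 1, delta_P = 0.5, kappa = 1
  )
  data <- purrr::map_dfr(1:3, function(i) {
    row <- truth[i, ]
    tr <- hiertxn:::ssa_at_times(hiertxn:::kinetics_from_row(row),
                                 seq(0.5, 25, length.out = 30))
    tibble::tibble(cell_id = row$cell_id, group = "A", time = tr$time,
                   signal = measure_signal(tr$P, 1, row$sigma_eps2))
  })
  list(data = data, truth = truth,
       fixed = list(delta_M = 1, delta_P = 0.5, kappa = 1))
}

# Independent brute-force Euler integration of the LNA moment ODEs
# (mean and covariance together), used as the step-refinement oracle.
# euler_oracle() applies one Richardson extrapolation step so the oracle's
# own discretization error is O(dt^2), well below the comparison tolerance.
euler_oracle <- function(mean0, cov0, t0, t1, k, dt = 2e-5) {
  e1 <- euler_moments(mean0, cov0, t0, t1, k, dt)
  e2 <- euler_moments(mean0, cov0, t0, t1, k, dt / 2)
  list(mean = 2 * e2$mean - e1$mean, cov = 2 * e2$cov - e1$cov)
}

euler_moments <- function(mean0, cov0, t0, t1, k, dt = 1e-6) {
  tr <- k$transcription
  # split at the changepoint so each segment is smooth (keeps the error
  # expansion regular for Richardson extrapolation)
  if (t0 < tr$switch_time && tr$switch_time < t1) {
    seg <- euler_moments(mean0, cov0, t0, tr$switch_time, k, dt)
    return(euler_moments(seg$mean, seg$cov, tr$switch_time, t1, k, dt))
  }
  m <- mean0
  S <- cov0
  nstep <- ceiling((t1 - t0) / dt)
  h <- (t1 - t0) / nstep
  t <- t0
  A <- matrix(c(-k$delta_M, k$alpha, 0, -k$delta_P), 2, 2)
  for (i in seq_len(nstep)) {
    tau <- if (t >= tr$switch_time) tr$tau_on else tr$tau_off
    ct <- k$copy_number * tau
    D <- diag(c(ct + k$delta_M * m[1], k$alpha * m[1] + k$delta_P * m[2]))
    m <- m + h * c(ct - k$delta_M * m[1], k$alpha * m[1] - k$delta_P * m[2])
    S <- S + h * (A %*% S + S %*% t(A) + D)
    t <- t + h
  }
  list(mean = m, cov = S)
}

# Dense joint-Gaussian likelihood oracle for the deterministic-linearization
# LNA: builds the full covariance of the state at all observation times from
# Sigma(t_i) and the analytic transition matrix, then evaluates the joint
# normal density of the signals directly.
dense_gaussian_loglik <- function(times, signals, k) {
  n <- length(times)
  expA <- function(dt) {
    eM <- exp(-k$delta_M * dt); eP <- exp(-k$delta_P * dt)
    off <- k$alpha * (eM - eP) / (k$delta_P - k$delta_M)
    matrix(c(eM, off, 0, eP), 2, 2)
  }
  means <- vector("list", n)
  covs <- vector("list", n)
  st <- moment_state(0)
  for (i in seq_len(n)) {
    st <- propagate_moments(st, times[i], k, nsub = 400)
    means[[i]] <- st$mean
    covs[[i]] <- st$cov
  }
  C <- matrix(0, 2 * n, 2 * n)
  for (i in seq_len(n)) {
    ii <- (2 * i - 1):(2 * i)
    C[ii, ii] <- covs[[i]]
    if (i < n) {
      for (j in (i + 1):n) {
        jj <- (2 * j - 1):(2 * j)
        Cij <- covs[[i]] %*% t(expA(times[j] - times[i]))
        C[ii, jj] <- Cij
        C[jj, ii] <- t(Cij)
      }
    }
  }
  Pidx <- seq(2, 2 * n, by = 2)
  mu_y <- k$kappa * vapply(means, function(m) m[2], numeric(1))
  S <- k$kappa^2 * C[Pidx, Pidx] + diag(k$sigma_eps2, n)
  L <- chol(S)
  z <- backsolve(L, signals - mu_y, transpose = TRUE)
  -0.5 * n * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}
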