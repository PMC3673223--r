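#' Changepoint transcription function
#'
#' Per-copy transcription proceeds at a basal level `tau_off` until a single
#' off-to-on switch at `switch_time`, after which it proceeds at the active
#' level `tau_on`.  The boundary belongs to the on-phase: the rate at
#' `t == switch_time` is `tau_on`.  No ordering between the two levels is
#' imposed; phases are labelled by time, not magnitude.
#'
#' @param tau_off Per-copy transcription rate in the off-phase
#'   (molecules / time / copy, > 0).
#' @param tau_on Per-copy transcription rate in the on-phase (> 0).
#' @param switch_time Time of the off-to-on transition (>= 0).
#' @return An object of class `changepoint_transcription`.
#' @examples
#' f <- changepoint_transcription(tau_off = 1, tau_on = 5, switch_time = 10)
#' transcription_rate_at(c(5, 10, 12), f)
#' @export
changepoint_transcription <- function(tau_off, tau_on, switch_time) {
  stopifnot(
    is.numeric(tau_off), length(tau_off) == 1, is.finite(tau_off), tau_off > 0,
    is.numeric(tau_on), length(tau_on) == 1, is.finite(tau_on), tau_on > 0,
    is.numeric(switch_time), length(switch_time) == 1, is.finite(switch_time),
    switch_time >= 0
  )
  structure(
    list(tau_off = tau_off, tau_on = tau_on, switch_time = switch_time),
    class = "changepoint_transcription"
  )
}

#' Evaluate the changepoint transcription rate
#'
#' @param t Time(s) at which to evaluate (finite, >= 0); vectorized.
#' @param f A [changepoint_transcription()] object.
#' @return `tau_off` where `t < switch_time`, `tau_on` where `t >= switch_time`.
#' @export
transcription_rate_at <- function(t, f) {
  stopifnot(inherits(f, "changepoint_transcription"))
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("`t` must be finite numeric", call. = FALSE)
  }
  ifelse(t >= f$switch_time, f$tau_on, f$tau_off)
}

#' Per-cell kinetic parameters
#'
#' Bundles every parameter of one cell's two-stage expression model and its
#' measurement equation: the changepoint transcription function, translation
#' rate `alpha`, degradation rates `delta_M` / `delta_P`, plasmid copy number
#' (a positive integer in simulation, any positive real in inference),
#' fluorescence-per-mole constant `kappa`, and the measurement error variance
#' `sigma_eps2`.
#'
#' @param transcription A [changepoint_transcription()] object.
#' @param alpha Translation rate per mRNA (1/time, > 0).
#' @param delta_M mRNA degradation rate (1/time, > 0).
#' @param delta_P Protein degradation rate (1/time, > 0).
#' @param copy_number Plasmid count `c` (> 0).
#' @param kappa Fluorescence per mole of protein (signal/molecule, > 0).
#' @param sigma_eps2 Measurement error variance (signal^2, > 0).
#' @return An object of class `cell_kinetics`.
#' @export
cell_kinetics <- function(transcription, alpha, delta_M, delta_P,
                          copy_number, kappa, sigma_eps2) {
  stopifnot(inherits(transcription, "changepoint_transcription"))
  vals <- c(alpha = alpha, delta_M = delta_M, delta_P = delta_P,
            copy_number = copy_number, kappa = kappa, sigma_eps2 = sigma_eps2)
  if (!all(is.finite(vals)) || !all(vals > 0)) {
    bad <- names(vals)[!(is.finite(vals) & vals > 0)]
    stop("cell_kinetics fields must be strictly positive and finite: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(transcription = transcription, alpha = alpha,
         delta_M = delta_M, delta_P = delta_P, copy_number = copy_number,
         kappa = kappa, sigma_eps2 = sigma_eps2),
    class = "cell_kinetics"
  )
}

#' Drift of the kinetic model
#'
#' Deterministic part of the mRNA/protein dynamics:
#' `(c * tau(t) - delta_M * M, alpha * M - delta_P * P)`.
#'
#' @param state Numeric 2-vector `(M, P)`, both >= 0.
#' @param t Time.
#' @param k A [cell_kinetics()] object.
#' @return Numeric 2-vector of time derivatives.
#' @export
kinetic_drift <- function(state, t, k) {
  stopifnot(inherits(k, "cell_kinetics"), length(state) == 2)
  tau <- transcription_rate_at(t, k$transcription)
  c(k$copy_number * tau - k$delta_M * state[1],
    k$alpha * state[1] - k$delta_P * state[2])
}

#' Instantaneous variance rates of the kinetic model
#'
#' Diffusion term of the chemical Langevin construction: the *sum* of birth
#' and death propensities per species,
#' `(c * tau(t) + delta_M * M, alpha * M + delta_P * P)`.
#'
#' @inheritParams kinetic_drift
#' @return Numeric 2-vector of variance rates (componentwise >= 0).
#' @export
kinetic_diffusion_var <- function(state, t, k) {
  stopifnot(inherits(k, "cell_kinetics"), length(state) == 2)
  if (any(state < 0)) stop("state must be nonnegative", call. = FALSE)
  tau <- transcription_rate_at(t, k$transcription)
  c(k$copy_number * tau + k$delta_M * state[1],
    k$alpha * state[1] + k$delta_P * state[2])
}

#' Assemble a per-cell time series tibble
#'
#' Validates one cell's fluorescence onset curve: strictly increasing times,
#' equal lengths, at least two observations.  Signals may be negative (after
#' background subtraction).
#'
#' @param cell_id Cell identifier.
#' @param group Construct / group label.
#' @param times Strictly increasing observation times (>= 0).
#' @param signals Fluorescence values, same length as `times`.
#' @return A tibble with columns `cell_id`, `group`, `time`, `signal`.
#' @export
cell_timeseries <- function(cell_id, group, times, signals) {
  if (length(times) != length(signals)) {
    stop("`times` and `signals` must have equal length", call. = FALSE)
  }
  if (length(times) < 2) stop("need at least 2 observations", call. = FALSE)
  if (any(!is.finite(times)) || any(times < 0) || any(diff(times) <= 0)) {
    stop("`times` must be nonnegative, finite and strictly increasing",
         call. = FALSE)
  }
  if (any(!is.finite(signals))) stop("`signals` must be finite", call. = FALSE)
  tibble::tibble(cell_id = as.character(cell_id), group = as.character(group),
                 time = as.numeric(times), signal = as.numeric(signals))
}

# Validate a long-format dataset of onset curves; returns it ordered by
# (cell_id, time).  Used by the likelihood, the fitter and the readers.
validate_timeseries_data <- function(data) {
  need <- c("cell_id", "group", "time", "signal")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  data <- dplyr::arrange(tibble::as_tibble(data), .data$cell_id, .data$time)
  check <- data |>
    dplyr::summarise(
      n = dplyr::n(),
      dup = anyDuplicated(.data$time) > 0,
      ngroup = dplyr::n_distinct(.data$group),
      .by = "cell_id"
    )
  if (any(check$dup)) {
    stop("duplicated observation times for cell(s): ",
         paste(check$cell_id[check$dup], collapse = ", "), call. = FALSE)
  }
  if (any(check$n < 2)) {
    stop("cell(s) with fewer than 2 observations: ",
         paste(check$cell_id[check$n < 2], collapse = ", "), call. = FALSE)
  }
  if (any(check$ngroup > 1)) {
    stop("cell(s) assigned to more than one group: ",
         paste(check$cell_id[check$ngroup > 1], collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(data$time) || !is.numeric(data$signal) ||
      any(!is.finite(data$time)) || any(!is.finite(data$signal))) {
    stop("`time` and `signal` must be finite numeric", call. = FALSE)
  }
  data
}
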