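#' Configuration of a virtual ventilated patient
#'
#' Describes a synthetic passive VC-ventilated patient: baseline
#' mechanics, a slowly varying elastance trajectory (multiplicative
#' log-normal walk across intervals), additive Gaussian pressure sensor
#' noise, and a per-breath probability of an asynchronous (effort-
#' distorted) breath. Defaults follow the ventilated-cohort medians the
#' protocol targets: weight 65 kg, elastance 33.8 cmH2O/L, resistance
#' 9.8 cmH2O.s/L, PEEP 10 cmH2O, 50 Hz sampling.
#'
#' @param weight Body weight, kg.
#' @param E0 Baseline elastance, cmH2O/L; must lie within `E_bounds`.
#' @param R Resistance, cmH2O.s/L (held constant).
#' @param PEEP Applied PEEP, cmH2O.
#' @param settings A [vc_settings()] object applied throughout.
#' @param log_walk_sd Per-interval SD of the log-elastance increments.
#' @param breath_E_sd Breath-to-breath multiplicative elastance
#'   variability (SD of per-breath log-elastance around the interval
#'   value). Real passive patients show a few percent of breath-to-breath
#'   variation; default 0.05.
#' @param noise_sd Pressure sensor noise SD, cmH2O.
#' @param asynchrony_rate Probability that a breath is asynchronous.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed; every random draw of the generator flows
#'   from it.
#' @param E_bounds Reflecting bounds of the elastance walk, cmH2O/L.
#' @return An object of class `virtual_patient_config`.
#' @export
virtual_patient_config <- function(weight = 65, E0 = 33.8, R = 9.8,
                                   PEEP = 10,
                                   settings = vc_settings(15, 6, 30, 0.3),
                                   log_walk_sd = 0.05, breath_E_sd = 0.05,
                                   noise_sd = 0.5,
                                   asynchrony_rate = 0.05, fs = 50,
                                   seed = 1L, E_bounds = c(8, 73)) {
  stopifnot(weight > 0, R >= 0, PEEP >= 0, fs > 0,
            log_walk_sd >= 0, breath_E_sd >= 0, noise_sd >= 0,
            asynchrony_rate >= 0, asynchrony_rate <= 1,
            inherits(settings, "vc_settings"))
  if (E_bounds[1L] <= 0 || E_bounds[2L] <= E_bounds[1L])
    stop("invalid elastance bounds")
  if (E0 < E_bounds[1L] || E0 > E_bounds[2L])
    stop("E0 outside the configured physiological bounds")
  structure(list(weight = weight, E0 = E0, R = R, PEEP = PEEP,
                 settings = settings, log_walk_sd = log_walk_sd,
                 breath_E_sd = breath_E_sd,
                 noise_sd = noise_sd, asynchrony_rate = asynchrony_rate,
                 fs = fs, seed = as.integer(seed), E_bounds = E_bounds),
            class = "virtual_patient_config")
}

#' Simulate a per-interval elastance trajectory
#'
#' Seeded multiplicative log-normal walk, reflected at the configured
#' physiological bounds: `log E_{k+1} = log E_k + eps_k`,
#' `eps_k ~ N(0, log_walk_sd^2)`, with out-of-bound log-values folded
#' back inside. Deterministic given the config seed.
#'
#' @param config A [virtual_patient_config()].
#' @param n_intervals Number of intervals.
#' @return Numeric vector of elastance values, one per interval, all
#'   within bounds.
#' @export
simulate_ers_trajectory <- function(config, n_intervals = 18L) {
  stopifnot(inherits(config, "virtual_patient_config"), n_intervals >= 1)
  set.seed(config$seed)
  lo <- log(config$E_bounds[1L]); hi <- log(config$E_bounds[2L])
  reflect <- function(z) {
    # fold into [lo, hi]
    span <- hi - lo
    z <- (z - lo) %% (2 * span)
    lo + ifelse(z > span, 2 * span - z, z)
  }
  logE <- numeric(n_intervals)
  logE[1L] <- log(config$E0)
  if (n_intervals > 1L) {
    steps <- rnorm(n_intervals - 1L, 0, config$log_walk_sd)
    for (k in 2:n_intervals) logE[k] <- reflect(logE[k - 1L] + steps[k - 1L])
  }
  exp(logE)
}

#' Generate a virtual-patient pressure--flow stream
#'
#' Concatenates VC breaths built by [build_vc_profile()] and
#' [simulate_pressure()], one interval at a time with the interval's
#' elastance from the trajectory. Expiration is passive relaxation at the
#' time constant `tau = R/E`, so expiratory airway pressure returns to
#' PEEP while expiratory flow decays exponentially. Additive Gaussian
#' noise is applied to the pressure channel. Asynchronous breaths,
#' injected with probability `asynchrony_rate`, carry a mid-inspiration
#' negative pressure deflection (an effort-like distortion) deep enough
#' to drive the model-fit APE above the 15% true-breath threshold.
#'
#' @param config A [virtual_patient_config()].
#' @param trajectory Optional per-interval elastance vector; derived from
#'   the config when omitted.
#' @param n_intervals Number of 10-min intervals to generate (ignored
#'   when `trajectory` is given).
#' @param interval_len Interval length, s.
#' @param path Optional CSV output path for the stream.
#' @param truth_path Optional JSON output path for the ground-truth
#'   sidecar.
#' @return List with `stream` (data frame `t_s`, `pressure_cmH2O`,
#'   `flow_Lps`) and `truth` (trajectory, settings, per-breath interval
#'   index and asynchrony indices).
#' @export
generate_patient_stream <- function(config, trajectory = NULL,
                                    n_intervals = 3L, interval_len = 600,
                                    path = NULL, truth_path = NULL) {
  stopifnot(inherits(config, "virtual_patient_config"))
  if (is.null(trajectory))
    trajectory <- simulate_ers_trajectory(config, n_intervals)
  n_intervals <- length(trajectory)
  set.seed(config$seed + 1L)

  st <- config$settings
  dt <- 1 / config$fs
  T_tot <- 60 / st$RR
  wf <- build_vc_profile(st, config$weight, dt)
  if (!wf$feasible) stop("infeasible settings schedule (no expiratory time)")
  n_breath <- round(T_tot / dt)
  n_insp <- length(wf$t)
  if (n_insp >= n_breath) stop("inspiration fills the whole breath period")
  V_T <- max(wf$volume)
  breaths_per_int <- floor(interval_len / T_tot + 1e-9)

  t_exp <- (seq_len(n_breath - n_insp)) * dt
  flow_breath <- function(tau) {
    c(wf$flow, -(V_T / tau) * exp(-t_exp / tau))
  }

  flows <- numeric(0); pressures <- numeric(0)
  breath_interval <- integer(0); asynchronous <- integer(0)
  breath_id <- 0L
  for (k in seq_len(n_intervals)) {
    E <- trajectory[k]
    tau <- max(config$R / max(E, 1e-6), 0.1)
    fb <- flow_breath(tau)
    vol <- c(wf$volume, V_T * exp(-t_exp / tau))
    for (b in seq_len(breaths_per_int)) {
      breath_id <- breath_id + 1L
      E_b <- E * exp(if (config$breath_E_sd > 0)
        rnorm(1, 0, config$breath_E_sd) else 0)
      pb_clean <- E_b * vol + config$R * fb + config$PEEP
      pb <- pb_clean
      if (runif(1) < config$asynchrony_rate) {
        asynchronous <- c(asynchronous, breath_id)
        # effort-like deflection over the central 80% of inspiration
        idx <- seq(max(2L, round(0.1 * n_insp)), round(0.9 * n_insp))
        amp <- 0.8 * (max(pb_clean[seq_len(n_insp)]) - config$PEEP)
        pb[idx] <- pb[idx] - amp * sin(pi * seq_along(idx) / length(idx))
      }
      pb <- pb + rnorm(n_breath, 0, config$noise_sd)
      flows <- c(flows, fb)
      pressures <- c(pressures, pb)
      breath_interval <- c(breath_interval, k)
    }
  }
  n <- length(flows)
  stream <- data.frame(t_s = (seq_len(n) - 1L) * dt,
                       pressure_cmH2O = pressures, flow_Lps = flows)
  truth <- list(trajectory = trajectory, R = config$R, PEEP = config$PEEP,
                weight = config$weight,
                settings = unclass(st),
                n_breaths = breath_id,
                breath_interval = breath_interval,
                asynchronous_breaths = asynchronous,
                seed = config$seed)
  if (!is.null(path)) write_pressure_flow(stream, path)
  if (!is.null(truth_path))
    jsonlite::write_json(truth, truth_path, digits = NA, auto_unbox = TRUE)
  list(stream = stream, truth = truth)
}

#' Configurations for a cohort of virtual patients
#'
#' Draws per-patient weight, baseline mechanics and PEEP from seeded
#' uniform ranges spanning a typical ventilated cohort, one derived seed
#' per patient.
#'
#' @param n Number of patients.
#' @param seed Cohort seed.
#' @param ... Overrides forwarded to [virtual_patient_config()].
#' @return List of `virtual_patient_config` objects.
#' @export
virtual_cohort_configs <- function(n = 20L, seed = 1L, ...) {
  set.seed(seed)
  weights <- runif(n, 40, 95)
  E0s <- runif(n, 10, 65)
  Rs <- runif(n, 3, 20)
  PEEPs <- sample(5:14, n, replace = TRUE)
  lapply(seq_len(n), function(i) {
    virtual_patient_config(weight = round(weights[i], 1),
                           E0 = round(E0s[i], 1), R = round(Rs[i], 1),
                           PEEP = PEEPs[i],
                           seed = seed * 1000L + i, ...)
  })
}
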