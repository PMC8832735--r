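#' Build the volume/flow profile of one volume-controlled breath
#'
#' Constructs the inspiratory flow and volume waveforms implied by a VC
#' setting combination. For the square waveform, flow is constant at the
#' set peak flow for `T_flow = V_T / Vmax`; for the (descending) ramp it
#' falls linearly from the peak flow to zero over `T_flow = 2 V_T / Vmax`,
#' so that both the set peak flow and the set tidal volume are honoured.
#' Zero flow is appended for the plateau hold; expiration is represented
#' by timing only (`T_exp`), not by a flow profile.
#'
#' All internal units are L, L/s, s and cmH2O; the peak flow is converted
#' from L/min at this boundary.
#'
#' @param settings A [vc_settings()] object.
#' @param weight Body weight, kg (converts `VT_perkg` to litres).
#' @param dt Sample period, s. Default 0.02 (50 Hz).
#'
#' @return An object of class `breath_waveform`: list with uniform grid `t`
#'   (s), `flow` (L/s), `volume` (L, running trapezoidal integral of flow,
#'   `V(0) = 0`), `pressure` (NULL until [simulate_pressure()]), `dt`, and
#'   timing fields `T_flow`, `T_insp`, `T_exp`, `feasible`. Infeasible
#'   timing (`T_flow + T_plat >= 60/RR`) is flagged, not an error.
#' @examples
#' wf <- build_vc_profile(vc_settings(20, 4, 30, 0.5), weight = 65)
#' max(wf$volume)  # 0.26 L
#' @export
build_vc_profile <- function(settings, weight, dt = 0.02) {
  stopifnot(inherits(settings, "vc_settings"), weight > 0, dt > 0)
  Vmax <- settings$peak_flow / 60            # L/min -> L/s
  V_T  <- settings$VT_perkg * weight / 1000  # mL/kg -> L
  T_flow <- switch(settings$waveform,
                   square = V_T / Vmax,
                   ramp   = 2 * V_T / Vmax)
  T_insp <- T_flow + settings$T_plat
  T_tot  <- 60 / settings$RR
  T_exp  <- T_tot - T_insp
  feasible <- T_exp > 0

  n <- floor(T_insp / dt + 1e-9) + 1L
  t <- (seq_len(n) - 1L) * dt
  flow <- switch(settings$waveform,
                 square = ifelse(t <= T_flow + 1e-12, Vmax, 0),
                 ramp   = Vmax * pmax(0, 1 - t / T_flow))
  volume <- pracma::cumtrapz(t, flow)[, 1L]

  structure(list(t = t, flow = flow, volume = volume, pressure = NULL,
                 dt = dt, T_flow = T_flow, T_insp = T_insp, T_exp = T_exp,
                 feasible = feasible, settings = settings, weight = weight),
            class = "breath_waveform")
}

#' Simulate airway pressure over a breath waveform
#'
#' Applies the single-compartment model pointwise:
#' `P_aw[i] = E_rs * volume[i] + R_rs * flow[i] + PEEP`.
#'
#' @param mech A [respiratory_mechanics()] object.
#' @param wf A `breath_waveform` with `flow` and `volume` populated, or any
#'   list with equal-length `flow` and `volume` vectors.
#' @return `wf` with the `pressure` element filled in.
#' @examples
#' wf <- build_vc_profile(vc_settings(20, 4, 30, 0.5), weight = 65)
#' wf <- simulate_pressure(respiratory_mechanics(43.5, 26.2, 13), wf)
#' max(wf$pressure)  # 37.41 cmH2O
#' @export
simulate_pressure <- function(mech, wf) {
  stopifnot(inherits(mech, "resp_mechanics"))
  if (is.null(wf$flow) || is.null(wf$volume))
    stop("waveform must have flow and volume populated")
  if (length(wf$flow) != length(wf$volume))
    stop("flow and volume grids have different lengths")
  wf$pressure <- mech$E_rs * wf$volume + mech$R_rs * wf$flow + mech$PEEP
  wf
}

#' Safety-relevant outcomes of one VC setting combination
#'
#' Computes peak airway pressure `P_MAX`, plateau pressure `P_PLAT`,
#' driving pressure `dP = P_PLAT - PEEP = E_rs * V_T`, inspiratory and
#' expiratory times and the I:E denominator (the `x` of a 1:x ratio) for a
#' setting combination under given mechanics.
#'
#' With `method = "closed_form"` (default, used by the protocol engine):
#' `P_PLAT = E_rs V_T + PEEP`; square `P_MAX = E_rs V_T + R_rs Vmax + PEEP`;
#' ramp `P_MAX` is the maximum of the model pressure at flow onset, at the
#' interior stationary point `t* = T_flow - R_rs/E_rs` (when it lies inside
#' the flow phase; skipped when `E_rs = 0`), and at end of flow. With
#' `method = "sampled"` the outcomes are read off a sampled, simulated
#' waveform; the two agree within one sample's pressure increment.
#'
#' @inheritParams build_vc_profile
#' @param mech A [respiratory_mechanics()] object.
#' @param method `"closed_form"` or `"sampled"`.
#' @return An object of class `ventilation_outcomes`: list with `P_MAX`,
#'   `P_PLAT`, `dP` (cmH2O), `IE_denom`, `T_insp`, `T_exp` (s), `feasible`
#'   (`T_exp > 0`).
#' @examples
#' compute_outcomes(respiratory_mechanics(43.5, 26.2, 13),
#'                  vc_settings(20, 4, 30, 0.5), weight = 65)
#' @export
compute_outcomes <- function(mech, settings, weight,
                             method = c("closed_form", "sampled"),
                             dt = 0.02) {
  method <- match.arg(method)
  stopifnot(inherits(mech, "resp_mechanics"),
            inherits(settings, "vc_settings"), weight > 0)
  Vmax <- settings$peak_flow / 60
  V_T  <- settings$VT_perkg * weight / 1000
  T_flow <- switch(settings$waveform, square = V_T / Vmax,
                   ramp = 2 * V_T / Vmax)
  T_insp <- T_flow + settings$T_plat
  T_exp  <- 60 / settings$RR - T_insp

  P_PLAT <- mech$E_rs * V_T + mech$PEEP
  dP     <- mech$E_rs * V_T

  if (method == "closed_form") {
    P_MAX <- if (settings$waveform == "square") {
      mech$E_rs * V_T + mech$R_rs * Vmax + mech$PEEP
    } else {
      ramp_peak_pressure(mech, Vmax, T_flow)
    }
  } else {
    wf <- simulate_pressure(mech, build_vc_profile(settings, weight, dt))
    P_MAX  <- max(wf$pressure)
    P_PLAT <- mech$E_rs * max(wf$volume) + mech$PEEP
    dP     <- P_PLAT - mech$PEEP
  }

  structure(list(P_MAX = P_MAX, P_PLAT = P_PLAT, dP = dP,
                 IE_denom = T_exp / T_insp, T_insp = T_insp, T_exp = T_exp,
                 feasible = T_exp > 0),
            class = "ventilation_outcomes")
}

# Closed-form peak pressure of a descending-ramp breath: evaluate the model
# at flow onset, end of flow and the interior stationary point
# t* = T_flow - R/E (volume gain and flow loss balance there).
ramp_peak_pressure <- function(mech, Vmax, T_flow) {
  E <- mech$E_rs; R <- mech$R_rs; P0 <- mech$PEEP
  cand <- c(R * Vmax + P0,                       # t = 0
            E * Vmax * T_flow / 2 + P0)          # end of flow, V = V_T
  if (E > 0) {
    tstar <- T_flow - R / E
    if (tstar > 0 && tstar < T_flow) {
      vol  <- Vmax * (tstar - tstar^2 / (2 * T_flow))
      flow <- Vmax * (1 - tstar / T_flow)
      cand <- c(cand, E * vol + R * flow + P0)
    }
  }
  max(cand)
}

#' @export
print.ventilation_outcomes <- function(x, ...) {
  cat(sprintf(
    "VC outcomes: P_MAX %.2f, P_PLAT %.2f, dP %.2f cmH2O; T_insp %.2f s, I:E 1:%.2f%s\n",
    x$P_MAX, x$P_PLAT, x$dP, x$T_insp, x$IE_denom,
    if (x$feasible) "" else " [infeasible timing]"))
  invisible(x)
}

#' Export a breath waveform as CSV
#'
#' Writes columns `t_s`, `flow_Lps`, `volume_L` and, when simulated,
#' `pressure_cmH2O`.
#'
#' @param wf A `breath_waveform`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(wf, path) {
  df <- data.frame(t_s = wf$t, flow_Lps = wf$flow, volume_L = wf$volume)
  if (!is.null(wf$pressure)) df$pressure_cmH2O <- wf$pressure
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
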