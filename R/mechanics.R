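#' Respiratory mechanics of the single-compartment lung model
#'
#' Bundles the patient-specific parameter triple driving the
#' single-compartment model `P_aw(t) = E_rs V(t) + R_rs V'(t) + PEEP`.
#'
#' @param E_rs Respiratory elastance, cmH2O/L. Must be >= 0.
#' @param R_rs Respiratory resistance, cmH2O.s/L. Must be >= 0.
#' @param PEEP Positive end-expiratory (offset) pressure, cmH2O. Must be >= 0.
#'
#' @return An object of class `resp_mechanics`: a named list with elements
#'   `E_rs`, `R_rs`, `PEEP`.
#' @examples
#' respiratory_mechanics(43.5, 26.2, 13)
#' @export
respiratory_mechanics <- function(E_rs, R_rs, PEEP) {
  stopifnot(is.numeric(E_rs), length(E_rs) == 1L, is.finite(E_rs),
            is.numeric(R_rs), length(R_rs) == 1L, is.finite(R_rs),
            is.numeric(PEEP), length(PEEP) == 1L, is.finite(PEEP))
  if (E_rs < 0) stop("E_rs must be nonnegative")
  if (R_rs < 0) stop("R_rs must be nonnegative")
  if (PEEP < 0) stop("PEEP must be nonnegative")
  structure(list(E_rs = E_rs, R_rs = R_rs, PEEP = PEEP),
            class = "resp_mechanics")
}

#' @export
print.resp_mechanics <- function(x, ...) {
  cat(sprintf("Respiratory mechanics: E_rs = %g cmH2O/L, R_rs = %g cmH2O.s/L, PEEP = %g cmH2O\n",
              x$E_rs, x$R_rs, x$PEEP))
  invisible(x)
}

#' One volume-controlled ventilation setting combination
#'
#' @param RR Respiratory rate, breaths/min.
#' @param VT_perkg Tidal volume, mL per kg body weight.
#' @param peak_flow Peak inspiratory flow, L/min.
#' @param T_plat Plateau (inspiratory hold) time, s.
#' @param waveform Inspiratory flow waveform, `"square"` (constant flow) or
#'   `"ramp"` (descending ramp from `peak_flow` to zero).
#'
#' @return An object of class `vc_settings`.
#' @seealso [enumerate_grid()] for the full setting grid.
#' @examples
#' vc_settings(RR = 20, VT_perkg = 4, peak_flow = 30, T_plat = 0.5)
#' @export
vc_settings <- function(RR, VT_perkg, peak_flow, T_plat = 0,
                        waveform = c("square", "ramp")) {
  waveform <- match.arg(waveform)
  stopifnot(is.numeric(RR), RR > 0, is.numeric(VT_perkg), VT_perkg > 0,
            is.numeric(peak_flow), peak_flow > 0, is.numeric(T_plat),
            T_plat >= 0)
  structure(list(RR = RR, VT_perkg = VT_perkg, peak_flow = peak_flow,
                 T_plat = T_plat, waveform = waveform),
            class = "vc_settings")
}

#' @export
print.vc_settings <- function(x, ...) {
  cat(sprintf("VC settings: RR %g /min, VT %g mL/kg, peak flow %g L/min, T_plat %g s, %s waveform\n",
              x$RR, x$VT_perkg, x$peak_flow, x$T_plat, x$waveform))
  invisible(x)
}
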