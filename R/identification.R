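#' Identify respiratory mechanics from one breath
#'
#' Integral-based identification of `E_rs` and `R_rs` over the inspiratory
#' phase of a breath. Integrating the single-compartment model from the
#' breath start `t0` to each inspiratory sample `t_i` gives one linear
#' equation per sample,
#'
#' `[ int_{t0}^{t_i} V dt,  V_i - V_0 ] [E_rs, R_rs]' = int_{t0}^{t_i} (P - PEEP) dt`,
#'
#' and the stacked system is solved by nonnegative least squares
#' (Lawson--Hanson, via [pracma::lsqnonneg()]). Cumulative integrals use
#' trapezoidal quadrature; one equation is formed per sample from the
#' second inspiratory sample onward. The median absolute percentage error
#' (APE) of the fitted pressure over inspiration is attached as the
#' model-fit statistic.
#'
#' @param breath A `segmented_breath` (see [segment_breaths()]) or any list
#'   with numeric `t`, `flow`, `pressure` vectors and optionally
#'   `insp_idx` (indices of the inspiratory phase; defaults to all
#'   samples). Volume is integrated from flow with `V(t0) = 0`.
#' @param PEEP Offset pressure used in the regression, cmH2O.
#'
#' @return An object of class `mechanics_estimate`: list with `E_rs`,
#'   `R_rs` (solver-enforced nonnegative), `APE` (percent), `n_equations`,
#'   `valid` (FALSE when the system is rank-deficient, e.g. zero flow).
#' @examples
#' wf <- build_vc_profile(vc_settings(15, 6, 30, 0.3), weight = 70)
#' wf <- simulate_pressure(respiratory_mechanics(30, 10, 5), wf)
#' identify_breath(wf, PEEP = 5)  # recovers E 30, R 10
#' @export
identify_breath <- function(breath, PEEP) {
  t <- breath$t
  flow <- breath$flow
  pressure <- breath$pressure
  if (is.null(pressure)) stop("breath has no pressure data")
  insp <- breath$insp_idx
  if (is.null(insp)) insp <- seq_along(t)
  if (length(insp) < 3L) stop("need at least 3 inspiratory samples")

  ti <- t[insp]; fi <- flow[insp]; pi <- pressure[insp]
  vol <- pracma::cumtrapz(ti, fi)[, 1L]
  if (any(vol < -1e-9)) stop("negative volume in inspiratory phase")

  int_V <- pracma::cumtrapz(ti, vol)[, 1L]
  int_P <- pracma::cumtrapz(ti, pi - PEEP)[, 1L]
  rows <- 2:length(ti)
  A <- cbind(int_V[rows], vol[rows] - vol[1L])
  b <- int_P[rows]

  invalid <- function() {
    structure(list(E_rs = NA_real_, R_rs = NA_real_, APE = NA_real_,
                   n_equations = length(rows), valid = FALSE),
              class = "mechanics_estimate")
  }
  if (qr(A)$rank < 2L) return(invalid())
  fit <- tryCatch(pracma::lsqnonneg(A, b), error = function(e) NULL)
  if (is.null(fit)) return(invalid())
  E_rs <- fit$x[1L]; R_rs <- fit$x[2L]

  P_sim <- E_rs * vol + R_rs * fi + PEEP
  structure(list(E_rs = E_rs, R_rs = R_rs,
                 APE = compute_ape(P_sim, pi),
                 n_equations = length(rows), valid = TRUE),
            class = "mechanics_estimate")
}

#' Median absolute percentage error between fitted and measured pressure
#'
#' `APE = median(|(P_sim - P_mea) / P_sim|) * 100`, evaluated over the
#' inspiratory samples. Samples where `P_sim = 0` are excluded from the
#' median (with a message).
#'
#' @param P_sim Model-fitted pressure series, cmH2O.
#' @param P_mea Measured pressure series, same length.
#' @return The APE, percent.
#' @examples
#' compute_ape(c(10, 20, 30), c(10, 25, 30))  # median{0, 25, 0} = 0
#' @export
compute_ape <- function(P_sim, P_mea) {
  if (length(P_sim) != length(P_mea))
    stop("P_sim and P_mea must have equal lengths")
  zero <- P_sim == 0
  if (any(zero)) {
    message(sum(zero), " sample(s) with P_sim = 0 excluded from APE")
    P_sim <- P_sim[!zero]; P_mea <- P_mea[!zero]
  }
  if (!length(P_sim)) return(NA_real_)
  median(abs((P_sim - P_mea) / P_sim)) * 100
}

#' @export
print.mechanics_estimate <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("Mechanics estimate: E_rs %.3f cmH2O/L, R_rs %.3f cmH2O.s/L (APE %.2f%%, %d eqs)\n",
                x$E_rs, x$R_rs, x$APE, x$n_equations))
  } else {
    cat("Mechanics estimate: invalid (rank-deficient system)\n")
  }
  invisible(x)
}

#' Serialise per-breath estimates to CSV
#'
#' @param estimates List of `mechanics_estimate` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_estimates_csv <- function(estimates, path) {
  df <- data.frame(
    breath_id = seq_along(estimates),
    E_rs = vapply(estimates, function(e) e$E_rs, numeric(1)),
    R_rs = vapply(estimates, function(e) e$R_rs, numeric(1)),
    APE = vapply(estimates, function(e) e$APE, numeric(1)),
    valid = vapply(estimates, function(e) e$valid, logical(1)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
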