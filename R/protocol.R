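#' Clinical safety thresholds for the elimination stage
#'
#' Defaults are the literature-recommended ranges: respiratory rate 6--35
#' breaths/min, tidal volume 4--8 mL/kg, peak pressure < 40 cmH2O
#' (strict), plateau pressure < 30 cmH2O (strict), I:E ratio between 1:1
#' and 1:3 (inclusive). PEEP is specified by the clinician and is not a
#' threshold axis.
#'
#' @param RR_range Inclusive respiratory-rate range, breaths/min.
#' @param VT_range Inclusive tidal-volume range, mL/kg.
#' @param Pmax_limit Strict upper limit on peak pressure, cmH2O.
#' @param Pplat_limit Strict upper limit on plateau pressure, cmH2O.
#' @param IE_range Inclusive range of the I:E denominator (the x in 1:x).
#'   Setting both ends infinite disables the timing criterion entirely.
#' @return An object of class `safety_thresholds`.
#' @export
safety_thresholds <- function(RR_range = c(6, 35), VT_range = c(4, 8),
                              Pmax_limit = 40, Pplat_limit = 30,
                              IE_range = c(1, 3)) {
  structure(list(RR_range = RR_range, VT_range = VT_range,
                 Pmax_limit = Pmax_limit, Pplat_limit = Pplat_limit,
                 IE_range = IE_range), class = "safety_thresholds")
}

#' Default VC setting grid specification
#'
#' The standard enumeration ranges and resolutions: RR 6--35 by 1, tidal
#' volume 4--8 mL/kg by 1, peak flow 5--150 L/min by 5, plateau time
#' 0--2 s by 0.1, square and ramp waveforms — 30 x 5 x 30 x 21 x 2 =
#' 189,000 combinations.
#'
#' @return Named list of grid axes.
#' @export
default_grid_spec <- function() {
  list(RR = 6:35, VT_perkg = 4:8, peak_flow = seq(5, 150, by = 5),
       T_plat = seq(0, 2, by = 0.1), waveform = c("square", "ramp"))
}

#' Enumerate every VC setting combination
#'
#' Cartesian product of the grid axes in the fixed order RR, tidal
#' volume, peak flow, plateau time, waveform (the first axis varying
#' fastest).
#'
#' @param grid_spec Named list of axes as in [default_grid_spec()].
#' @return Data frame with one row per combination and columns `RR`,
#'   `VT_perkg`, `peak_flow`, `T_plat`, `waveform`.
#' @examples
#' nrow(enumerate_grid())  # 189000
#' @export
enumerate_grid <- function(grid_spec = default_grid_spec()) {
  need <- c("RR", "VT_perkg", "peak_flow", "T_plat", "waveform")
  if (!all(need %in% names(grid_spec)))
    stop("grid_spec must name axes ", paste(need, collapse = ", "))
  if (any(vapply(grid_spec[need], length, integer(1)) == 0L))
    stop("empty grid axis")
  expand.grid(RR = grid_spec$RR, VT_perkg = grid_spec$VT_perkg,
              peak_flow = grid_spec$peak_flow, T_plat = grid_spec$T_plat,
              waveform = grid_spec$waveform,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

# Vectorised closed-form outcomes over a grid data frame (the V-stage
# work-horse; same formulas as compute_outcomes()).
grid_outcomes <- function(grid, E_rs, R_rs, PEEP, weight) {
  Vmax <- grid$peak_flow / 60
  V_T  <- grid$VT_perkg * weight / 1000
  sq <- grid$waveform == "square"
  T_flow <- ifelse(sq, V_T / Vmax, 2 * V_T / Vmax)
  T_insp <- T_flow + grid$T_plat
  T_exp  <- 60 / grid$RR - T_insp

  P_PLAT <- E_rs * V_T + PEEP
  dP     <- E_rs * V_T
  Pmax_sq <- E_rs * V_T + R_rs * Vmax + PEEP
  # ramp: onset, end of flow, interior stationary point t* = T_flow - R/E
  Pmax_rp <- pmax(R_rs * Vmax + PEEP, P_PLAT)
  if (E_rs > 0) {
    tstar <- T_flow - R_rs / E_rs
    interior <- !sq & tstar > 0 & tstar < T_flow
    if (any(interior)) {
      vol  <- Vmax * (tstar - tstar^2 / (2 * T_flow))
      flw  <- Vmax * (1 - tstar / T_flow)
      Pmax_rp[interior] <- pmax(Pmax_rp[interior],
                                (E_rs * vol + R_rs * flw + PEEP)[interior])
    }
  }
  grid$P_MAX  <- ifelse(sq, Pmax_sq, Pmax_rp)
  grid$P_PLAT <- P_PLAT
  grid$dP     <- dP
  grid$T_insp <- T_insp
  grid$T_exp  <- T_exp
  grid$IE_denom <- T_exp / T_insp
  grid$feasible <- T_exp > 0
  grid
}

# Logical pass mask of the elimination criteria for one outcomes frame.
pass_mask <- function(out, thr) {
  eps <- 1e-9
  ie <- thr$IE_range
  ok_timing <- if (all(is.infinite(ie))) {
    rep(TRUE, nrow(out))
  } else {
    out$T_exp > 0 & out$IE_denom >= ie[1L] - eps & out$IE_denom <= ie[2L] + eps
  }
  ok_timing &
    out$P_MAX  < thr$Pmax_limit &
    out$P_PLAT < thr$Pplat_limit &
    out$RR >= thr$RR_range[1L] - eps & out$RR <= thr$RR_range[2L] + eps &
    out$VT_perkg >= thr$VT_range[1L] - eps &
    out$VT_perkg <= thr$VT_range[2L] + eps
}

#' Eliminate unsafe setting combinations (E-stage)
#'
#' Keeps combinations whose forecast outcomes satisfy every safety
#' threshold: strict pressure limits, inclusive I:E range, feasible
#' timing, and the RR / tidal-volume ranges. When a pair of outcome
#' frames is supplied (the 5th/95th-percentile forecasts of the
#' stochastic protocol), both ends of the forecast range must pass.
#'
#' @param outcomes An outcomes data frame from the V-stage, or a list of
#'   two such frames `list(lo = , hi = )` sharing the same grid rows.
#' @param thresholds A [safety_thresholds()] object.
#' @return The surviving rows (for a pair: the `hi` grid columns with
#'   outcome columns from both ends suffixed `_lo`/`_hi`). An empty
#'   survivor set is a valid result.
#' @export
e_stage <- function(outcomes, thresholds = safety_thresholds()) {
  if (is.data.frame(outcomes)) {
    return(outcomes[pass_mask(outcomes, thresholds), , drop = FALSE])
  }
  lo <- outcomes$lo; hi <- outcomes$hi
  stopifnot(is.data.frame(lo), is.data.frame(hi), nrow(lo) == nrow(hi))
  keep <- pass_mask(lo, thresholds) & pass_mask(hi, thresholds)
  out <- hi[keep, c("RR", "VT_perkg", "peak_flow", "T_plat", "waveform",
                    "T_insp", "T_exp", "IE_denom", "feasible"), drop = FALSE]
  for (v in c("P_MAX", "P_PLAT", "dP")) {
    out[[paste0(v, "_lo")]] <- lo[[v]][keep]
    out[[paste0(v, "_hi")]] <- hi[[v]][keep]
  }
  out
}

#' Narrow survivors by a clinical objective (N-stage)
#'
#' The default (and currently only) objective minimises driving pressure:
#' all combinations whose driving pressure ties the survivor minimum are
#' retained. Since `dP = E_rs V_T`, this keeps exactly the lowest
#' surviving tidal-volume tier. For percentile-range outcomes the
#' 95th-percentile driving pressure (`dP_hi`) is used; `dP` being linear
#' in elastance, this selects the same tidal-volume tier as any
#' percentile.
#'
#' @param survivors Survivor data frame from [e_stage()].
#' @param objective Objective name; only `"min_dP"` is defined.
#' @return The narrowed data frame (empty in, empty out).
#' @export
n_stage <- function(survivors, objective = "min_dP") {
  if (!identical(objective, "min_dP"))
    stop("unknown narrowing objective: ", objective)
  if (!nrow(survivors)) return(survivors)
  dP <- if ("dP_hi" %in% names(survivors)) survivors$dP_hi else survivors$dP
  survivors[dP <= min(dP) + 1e-9, , drop = FALSE]
}

new_protocol_result <- function(protocol, grid_n, survivors_e, narrowed,
                                inputs, audit = NULL) {
  counts <- c(V = grid_n, E = nrow(survivors_e), N = nrow(narrowed))
  structure(list(protocol = protocol, stage_counts = counts,
                 survivors = narrowed,
                 pct_reduction = 100 * (1 - counts[["N"]] / counts[["V"]]),
                 audit = audit, inputs = inputs),
            class = "protocol_result")
}

#' Run the deterministic protocol for one interval (VENT)
#'
#' Forward-simulates every setting combination at the current interval
#' elastance (V-stage), eliminates unsafe combinations ([e_stage()]),
#' narrows by the clinical objective ([n_stage()]) and tabulates the
#' survivors with their single-valued outcomes (T-stage).
#'
#' @param summary An `interval_summary` (fields `Ers_N`, `Rrs_N`,
#'   `PEEP_N`).
#' @param weight Body weight, kg.
#' @param thresholds A [safety_thresholds()] object.
#' @param objective Narrowing objective, see [n_stage()].
#' @param grid_spec Setting grid, see [default_grid_spec()].
#' @param audit If TRUE (default), re-runs the elimination with the
#'   interval elastance perturbed by +-0.05 cmH2O/L (the precision of
#'   printed interval mechanics) and reports how many combinations change
#'   final status, bounding the sensitivity of the survivor count to
#'   input rounding.
#' @return A `protocol_result`: `stage_counts` (V, E, N — nonincreasing),
#'   `survivors` (T-stage table), `pct_reduction`, `audit`, `inputs`.
#' @examples
#' run_vent(interval_summary(43.5, 26.2, 13), weight = 65)
#' @export
run_vent <- function(summary, weight, thresholds = safety_thresholds(),
                     objective = "min_dP", grid_spec = default_grid_spec(),
                     audit = TRUE) {
  check_summary(summary)
  stopifnot(weight > 0)
  grid <- enumerate_grid(grid_spec)
  final_set <- function(E) {
    out <- grid_outcomes(grid, E, summary$Rrs_N, summary$PEEP_N, weight)
    keep <- pass_mask(out, thresholds)
    dP <- out$dP
    if (any(keep)) keep & (dP <= min(dP[keep]) + 1e-9) else keep
  }
  out <- grid_outcomes(grid, summary$Ers_N, summary$Rrs_N, summary$PEEP_N,
                       weight)
  surv_e <- e_stage(out, thresholds)
  narrowed <- n_stage(surv_e, objective)
  aud <- if (audit) {
    boundary_audit(final_set, summary$Ers_N)
  }
  new_protocol_result("VENT", nrow(grid), surv_e, narrowed,
                      inputs = list(summary = summary, weight = weight,
                                    thresholds = thresholds,
                                    objective = objective),
                      audit = aud)
}

#' Run the stochastic-forecast protocol for one interval (SiVENT)
#'
#' Forecasts the 5th and 95th percentile of the next-interval elastance
#' from the transition model, forward-simulates every setting combination
#' twice (once per percentile, with the interval resistance and PEEP),
#' and eliminates a combination unless both ends of its forecast pressure
#' range are safe. Narrowing and tabulation proceed as in [run_vent()],
#' with low--high outcome columns.
#'
#' @inheritParams run_vent
#' @param model An `ers_transition_model` whose support covers `Ers_N`.
#' @return A `protocol_result` with `forecast` (the percentile pair)
#'   attached to `inputs`.
#' @export
run_sivent <- function(summary, model, weight,
                       thresholds = safety_thresholds(),
                       objective = "min_dP",
                       grid_spec = default_grid_spec(), audit = TRUE) {
  check_summary(summary)
  stopifnot(weight > 0, inherits(model, "ers_transition_model"))
  grid <- enumerate_grid(grid_spec)
  x_grid <- default_x_grid(model)
  final_set <- function(E) {
    fc <- forecast_percentiles(model, E, levels = c(5, 95), x_grid = x_grid)
    lo <- grid_outcomes(grid, fc$values[1L], summary$Rrs_N, summary$PEEP_N,
                        weight)
    hi <- grid_outcomes(grid, fc$values[2L], summary$Rrs_N, summary$PEEP_N,
                        weight)
    keep <- pass_mask(lo, thresholds) & pass_mask(hi, thresholds)
    dP <- hi$dP
    if (any(keep)) keep & (dP <= min(dP[keep]) + 1e-9) else keep
  }
  fc <- forecast_percentiles(model, summary$Ers_N, levels = c(5, 95),
                             x_grid = x_grid)
  lo <- grid_outcomes(grid, fc$values[1L], summary$Rrs_N, summary$PEEP_N,
                      weight)
  hi <- grid_outcomes(grid, fc$values[2L], summary$Rrs_N, summary$PEEP_N,
                      weight)
  surv_e <- e_stage(list(lo = lo, hi = hi), thresholds)
  narrowed <- n_stage(surv_e, objective)
  aud <- if (audit) boundary_audit(final_set, summary$Ers_N)
  new_protocol_result("SiVENT", nrow(grid), surv_e, narrowed,
                      inputs = list(summary = summary, weight = weight,
                                    thresholds = thresholds,
                                    objective = objective, forecast = fc),
                      audit = aud)
}

check_summary <- function(summary) {
  if (!inherits(summary, "interval_summary"))
    stop("summary must be an interval_summary")
  if (!is.finite(summary$Ers_N) || summary$Ers_N <= 0)
    stop("invalid interval summary: Ers_N must be positive")
  invisible(TRUE)
}

# How many grid combinations change final (post-N-stage) status when the
# interval elastance moves by +-delta.
boundary_audit <- function(final_set, E, delta = 0.05) {
  base <- final_set(E)
  plus <- final_set(E + delta)
  minus <- final_set(max(E - delta, 1e-9))
  list(delta_E = delta,
       flips_plus = sum(base != plus), flips_minus = sum(base != minus),
       count = sum(base), count_plus = sum(plus), count_minus = sum(minus))
}

#' @export
print.protocol_result <- function(x, ...) {
  s <- x$inputs$summary
  cat(sprintf("%s protocol (E_rs %.2f, R_rs %.2f, PEEP %g, weight %g kg)\n",
              x$protocol, s$Ers_N, s$Rrs_N, s$PEEP_N, x$inputs$weight))
  if (!is.null(x$inputs$forecast))
    cat(sprintf("  forecast E_rs,N+1: %.2f (5%%) - %.2f (95%%) cmH2O/L\n",
                x$inputs$forecast$values[1L], x$inputs$forecast$values[2L]))
  cat(sprintf("  stage counts: V %d -> E %d -> N %d (%.1f%% reduction)\n",
              x$stage_counts[["V"]], x$stage_counts[["E"]],
              x$stage_counts[["N"]], x$pct_reduction))
  if (!is.null(x$audit))
    cat(sprintf("  boundary audit (+-%.2f cmH2O/L on E_rs): %d / %d combinations flip\n",
                x$audit$delta_E, x$audit$flips_plus, x$audit$flips_minus))
  invisible(x)
}

#' Write the T-stage recommendation table as CSV
#'
#' Columns: `RR`, `waveform`, `VT_mL_per_kg`, `peak_flow_Lpm`, `T_plat_s`,
#' `Pmax_lo`, `Pmax_hi`, `Pplat_lo`, `Pplat_hi`, `dP_lo`, `dP_hi`, `IE`.
#' For the deterministic protocol the low and high outcome columns
#' coincide.
#'
#' @param result A `protocol_result`.
#' @param path Output file path.
#' @return The written data frame, invisibly.
#' @export
write_recommendations <- function(result, path) {
  s <- result$survivors
  pick <- function(v) {
    lo <- if (paste0(v, "_lo") %in% names(s)) s[[paste0(v, "_lo")]] else s[[v]]
    hi <- if (paste0(v, "_hi") %in% names(s)) s[[paste0(v, "_hi")]] else s[[v]]
    list(lo = lo, hi = hi)
  }
  pm <- pick("P_MAX"); pp <- pick("P_PLAT"); dp <- pick("dP")
  df <- data.frame(RR = s$RR, waveform = s$waveform,
                   VT_mL_per_kg = s$VT_perkg, peak_flow_Lpm = s$peak_flow,
                   T_plat_s = s$T_plat,
                   Pmax_lo = pm$lo, Pmax_hi = pm$hi,
                   Pplat_lo = pp$lo, Pplat_hi = pp$hi,
                   dP_lo = dp$lo, dP_hi = dp$hi,
                   IE = s$IE_denom)
  if (!nrow(df)) warning("empty recommendation table", call. = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Interval-by-interval performance evaluation
#'
#' Runs both protocols on every usable interval of a record (up to
#' `horizon` seconds) and tabulates the survivor counts and percentage
#' reductions, plus median \[IQR\] aggregates.
#'
#' @param x Either a list of `interval_summary` objects or a pressure--flow
#'   stream data frame (processed with [process_stream()]).
#' @param model An `ers_transition_model` for the stochastic protocol.
#' @param weight Body weight, kg.
#' @param thresholds,objective,grid_spec Passed to the protocol runners.
#' @param horizon Evaluation horizon, s. Default 3 h.
#' @param interval Interval length, s. Default 600.
#' @return An object of class `performance_evaluation`: list with
#'   `intervals` (data frame: interval, Ers_N, Rrs_N, PEEP_N, vent_count,
#'   sivent_count, vent_pct, sivent_pct) and `aggregates` (median and
#'   IQR of each).
#' @export
evaluate_performance <- function(x, model, weight,
                                 thresholds = safety_thresholds(),
                                 objective = "min_dP",
                                 grid_spec = default_grid_spec(),
                                 horizon = 3 * 3600, interval = 600) {
  summaries <- if (is.data.frame(x)) {
    process_stream(x, interval_len = interval)
  } else x
  n_int <- floor(horizon / interval + 1e-9)
  summaries <- Filter(function(s) s$N <= n_int, summaries)
  if (!length(summaries)) stop("no usable intervals within the horizon")

  rows <- lapply(summaries, function(s) {
    v <- run_vent(s, weight, thresholds, objective, grid_spec, audit = FALSE)
    sv <- run_sivent(s, model, weight, thresholds, objective, grid_spec,
                     audit = FALSE)
    data.frame(interval = s$N, Ers_N = s$Ers_N, Rrs_N = s$Rrs_N,
               PEEP_N = s$PEEP_N,
               vent_count = v$stage_counts[["N"]],
               sivent_count = sv$stage_counts[["N"]],
               vent_pct = v$pct_reduction, sivent_pct = sv$pct_reduction)
  })
  tab <- do.call(rbind, rows)
  med_iqr <- function(v) c(median = median(v),
                           q25 = quantile(v, 0.25, names = FALSE),
                           q75 = quantile(v, 0.75, names = FALSE))
  aggregates <- list(vent_count = med_iqr(tab$vent_count),
                     sivent_count = med_iqr(tab$sivent_count),
                     vent_pct = med_iqr(tab$vent_pct),
                     sivent_pct = med_iqr(tab$sivent_pct))
  structure(list(intervals = tab, aggregates = aggregates),
            class = "performance_evaluation")
}

#' @export
print.performance_evaluation <- function(x, ...) {
  cat("Per-interval protocol performance:\n")
  print(x$intervals, row.names = FALSE)
  a <- x$aggregates
  cat(sprintf("Median [IQR] settings after protocol: VENT %g [%g-%g], SiVENT %g [%g-%g]\n",
              a$vent_count[1L], a$vent_count[2L], a$vent_count[3L],
              a$sivent_count[1L], a$sivent_count[2L], a$sivent_count[3L]))
  invisible(x)
}
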