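#' Segment a pressure--flow stream into breaths
#'
#' Scans a uniformly sampled airway pressure--flow record and applies the
#' breath-definition criteria:
#'
#' * inspiration onset: flow > 0.1 L/s and pressure > `peep_hint` + 2
#'   cmH2O, with positive flow sustained over the next 8 samples (0.16 s
#'   at 50 Hz);
#' * expiration onset: flow < -0.1 L/s, negative flow sustained over the
#'   next 8 samples;
#' * the candidate is kept only if peak inspiratory volume exceeds 40 mL,
#'   peak inspiratory pressure (PIP) exceeds `peep_hint` + 1 cmH2O during
#'   inspiration, and expiration is detected within 4.125 s of the
#'   inspiration onset.
#'
#' @param stream Data frame with columns `t_s`, `pressure_cmH2O`,
#'   `flow_Lps` (see [read_pressure_flow()]).
#' @param peep_hint Working PEEP estimate used by the onset criteria,
#'   cmH2O. Defaults to the minimum pressure in the stream.
#' @param pre_window Seconds of pre-inspiratory record attached to each
#'   breath for PEEP estimation. Default 0.2 s.
#'
#' @return A list of `segmented_breath` objects, each with local vectors
#'   `t`, `flow`, `pressure`, `volume` (integrated from inspiration
#'   onset), index sets `pre_idx`/`insp_idx`/`exp_idx`, global sample
#'   indices `insp_start`, `exp_start`, `end`, and fields `PIP`,
#'   `peak_insp_volume`, `PEEP_est`, `quality_flags`. Empty list when no
#'   breath qualifies.
#' @export
segment_breaths <- function(stream, peep_hint = NULL, pre_window = 0.2) {
  check_stream(stream)
  flow <- stream$flow_Lps
  pressure <- stream$pressure_cmH2O
  t <- stream$t_s
  n <- length(flow)
  if (is.null(peep_hint)) peep_hint <- min(pressure)

  sustained <- function(x) {
    # TRUE at i when x[i+1..i+8] all TRUE
    cs <- cumsum(c(0, as.numeric(x)))
    idx <- seq_len(n)
    ok <- rep(FALSE, n)
    has <- idx + 8L <= n
    ok[has] <- (cs[idx[has] + 8L + 1L] - cs[idx[has] + 1L]) == 8L
    ok
  }
  insp_cand <- flow > 0.1 & pressure > peep_hint + 2 & sustained(flow > 0)
  exp_cand  <- flow < -0.1 & sustained(flow < 0)
  insp_pos <- which(insp_cand)
  exp_pos  <- which(exp_cand)
  if (!length(insp_pos)) return(list())

  dt <- t[2L] - t[1L]
  npre <- round(pre_window / dt)
  breaths <- list()
  i <- insp_pos[1L]
  repeat {
    ex <- exp_pos[exp_pos > i]
    if (!length(ex)) break
    j <- ex[1L]
    nxt <- insp_pos[insp_pos > j]
    end <- if (length(nxt)) nxt[1L] - 1L else n

    insp_idx_g <- i:(j - 1L)
    vol_insp <- pracma::cumtrapz(t[insp_idx_g], flow[insp_idx_g])[, 1L]
    peak_vol <- max(vol_insp)
    PIP <- max(pressure[insp_idx_g])
    within_t <- (t[j] - t[i]) <= 4.125

    if (peak_vol > 0.040 && PIP > peep_hint + 1 && within_t) {
      lo <- max(1L, i - npre)
      sl <- lo:end
      volume <- c(rep(0, i - lo),
                  pracma::cumtrapz(t[i:end], flow[i:end])[, 1L])
      br <- structure(list(
        t = t[sl], flow = flow[sl], pressure = pressure[sl],
        volume = volume, dt = dt,
        pre_idx = if (i > lo) seq_len(i - lo) else integer(0),
        insp_idx = (i - lo + 1L):(j - lo),
        exp_idx = (j - lo + 1L):(end - lo + 1L),
        insp_start = i, exp_start = j, end = end,
        PIP = PIP, peak_insp_volume = peak_vol,
        PEEP_est = NA_real_, quality_flags = character(0)),
        class = "segmented_breath")
      br$PEEP_est <- estimate_peep(br)
      breaths[[length(breaths) + 1L]] <- br
    }
    nxt <- insp_pos[insp_pos > j]
    if (!length(nxt)) break
    i <- nxt[1L]
  }
  breaths
}

check_stream <- function(stream) {
  need <- c("t_s", "pressure_cmH2O", "flow_Lps")
  if (!all(need %in% names(stream)))
    stop("stream must have columns ", paste(need, collapse = ", "))
  if (!nrow(stream)) stop("empty stream")
  if (anyNA(stream[need])) stop("stream contains NA values")
  if (any(diff(stream$t_s) <= 0)) stop("time column must be strictly increasing")
  invisible(TRUE)
}

#' Estimate the applied PEEP of one breath
#'
#' Median airway pressure over the pre-inspiratory window, rounded to the
#' nearest integer cmH2O (matching the resolution at which PEEP is set
#' clinically). Falls back to the minimum pressure within the breath when
#' no pre-inspiratory samples are available.
#'
#' @param breath A `segmented_breath`.
#' @return PEEP estimate, integer-valued cmH2O.
#' @export
estimate_peep <- function(breath) {
  if (length(breath$pre_idx)) {
    round(median(breath$pressure[breath$pre_idx]))
  } else {
    round(min(breath$pressure))
  }
}

#' Apply the "true breath" quality criteria
#'
#' Flags breaths whose identification attempt indicates noise or
#' asynchrony: median model-fit error (APE) above `ape_threshold`,
#' estimated elastance `E_rs <= 0` (or an invalid fit), or elastance
#' outside the 5th--95th percentile of the patient's collected elastance
#' estimates. The reference collection is `history` when supplied
#' (e.g. the valid per-breath estimates of the patient's full record);
#' otherwise the valid positive estimates of this batch serve as the
#' collection. The percentile criterion is skipped, with a warning,
#' while the collection is shorter than `min_history`.
#'
#' @param breaths List of `segmented_breath` objects.
#' @param estimates List of `mechanics_estimate` objects, parallel to
#'   `breaths`.
#' @param history Numeric vector of collected `E_rs` estimates for this
#'   patient, the reference for the percentile criterion. `NULL` (the
#'   default) uses the valid positive estimates in `estimates`.
#' @param ape_threshold Rejection threshold on APE, percent. Default 15.
#' @param min_history Minimum collection size before the percentile
#'   criterion activates. Default 10.
#'
#' @return List with `breaths` (quality flags filled in), `accepted`
#'   (logical vector), `history` (the reference collection used).
#' @export
filter_true_breaths <- function(breaths, estimates, history = NULL,
                                ape_threshold = 15, min_history = 10) {
  stopifnot(length(breaths) == length(estimates))
  if (is.null(history)) {
    Es <- vapply(estimates, function(e)
      if (e$valid) e$E_rs else NA_real_, numeric(1))
    history <- Es[!is.na(Es) & Es > 0]
  }
  use_pct <- length(history) >= min_history
  if (!use_pct) {
    warning("elastance collection shorter than ", min_history,
            "; percentile criterion skipped", call. = FALSE)
  } else {
    pr <- quantile(history, c(0.05, 0.95), names = FALSE, type = 7)
  }
  accepted <- logical(length(breaths))
  for (k in seq_along(breaths)) {
    est <- estimates[[k]]
    flags <- character(0)
    if (!est$valid || est$E_rs <= 0) flags <- c(flags, "nonpositive_elastance")
    if (est$valid && !is.na(est$APE) && est$APE > ape_threshold)
      flags <- c(flags, "ape_exceeded")
    # tiny relative tolerance so a degenerate (constant) collection does
    # not reject numerically identical estimates
    if (use_pct && est$valid &&
        (est$E_rs < pr[1L] * (1 - 1e-6) || est$E_rs > pr[2L] * (1 + 1e-6)))
      flags <- c(flags, "outside_percentile")
    breaths[[k]]$quality_flags <- flags
    accepted[k] <- !length(flags)
  }
  list(breaths = breaths, accepted = accepted, history = history)
}

#' Aggregate true breaths of one interval into a summary
#'
#' Interval mechanics are the medians of the per-breath estimates; the
#' interval PEEP is the median of the per-breath PEEP estimates, rounded
#' to integer cmH2O.
#'
#' @param breaths List of accepted (`true`) `segmented_breath` objects.
#' @param estimates Parallel list of valid `mechanics_estimate` objects.
#' @param N Interval index.
#' @param interval_len Interval length, s. Default 600 (10 min).
#' @return An `interval_summary` (list with `N`, `Ers_N`, `Rrs_N`,
#'   `PEEP_N`, `n_true_breaths`, `interval_len`), or `NULL` when no breath
#'   is available (interval skipped).
#' @export
summarize_interval <- function(breaths, estimates, N = 1L,
                               interval_len = 600) {
  if (!length(breaths)) return(NULL)
  structure(list(
    N = N,
    Ers_N = median(vapply(estimates, function(e) e$E_rs, numeric(1))),
    Rrs_N = median(vapply(estimates, function(e) e$R_rs, numeric(1))),
    PEEP_N = round(median(vapply(breaths, function(b) b$PEEP_est, numeric(1)))),
    n_true_breaths = length(breaths),
    interval_len = interval_len), class = "interval_summary")
}

#' Build an interval summary directly from known mechanics
#'
#' Convenience constructor for protocol runs driven by already-known
#' interval medians (e.g. published tables or virtual-patient ground
#' truth) rather than a segmented stream.
#'
#' @param Ers_N,Rrs_N,PEEP_N Interval median mechanics.
#' @param N Interval index.
#' @param n_true_breaths Breath count backing the summary.
#' @param interval_len Interval length, s.
#' @return An `interval_summary`.
#' @examples
#' interval_summary(43.5, 26.2, 13)
#' @export
interval_summary <- function(Ers_N, Rrs_N, PEEP_N, N = 1L,
                             n_true_breaths = 1L, interval_len = 600) {
  stopifnot(Ers_N > 0, Rrs_N >= 0, PEEP_N >= 0)
  structure(list(N = N, Ers_N = Ers_N, Rrs_N = Rrs_N, PEEP_N = PEEP_N,
                 n_true_breaths = n_true_breaths,
                 interval_len = interval_len), class = "interval_summary")
}

#' @export
print.interval_summary <- function(x, ...) {
  cat(sprintf("Interval %d: E_rs %.2f cmH2O/L, R_rs %.2f cmH2O.s/L, PEEP %g cmH2O (%d true breaths)\n",
              x$N, x$Ers_N, x$Rrs_N, x$PEEP_N, x$n_true_breaths))
  invisible(x)
}

#' Process a full stream into per-interval summaries
#'
#' Two-pass retrospective pipeline. Pass one splits the record into
#' consecutive intervals, segments and identifies every breath; the
#' patient-specific elastance collection (all valid per-breath estimates
#' of the record) is assembled from it. Pass two applies the true-breath
#' criteria against that collection and aggregates interval medians.
#' The PEEP hint for segmentation is the previous interval's median
#' breath PEEP; the first interval uses the global pressure minimum.
#'
#' @param stream Data frame with `t_s`, `pressure_cmH2O`, `flow_Lps`.
#' @param interval_len Interval length, s. Default 600.
#' @param min_history Passed to [filter_true_breaths()].
#' @return List of `interval_summary` objects (skipped intervals omitted;
#'   their indices remain in `N`).
#' @export
process_stream <- function(stream, interval_len = 600, min_history = 10) {
  check_stream(stream)
  t0 <- stream$t_s[1L]
  dt <- median(diff(stream$t_s))
  # span counts the closing sample period, so an exact 18-interval record
  # yields 18 chunks
  total <- stream$t_s[nrow(stream)] - t0 + dt
  n_int <- max(1L, floor(total / interval_len + 1e-9))
  peep_hint <- min(stream$pressure_cmH2O)

  chunks <- vector("list", n_int)
  for (N in seq_len(n_int)) {
    sel <- stream$t_s >= t0 + (N - 1L) * interval_len &
           stream$t_s < t0 + N * interval_len
    chunk <- stream[sel, , drop = FALSE]
    if (nrow(chunk) < 20L) next
    breaths <- segment_breaths(chunk, peep_hint = peep_hint)
    if (!length(breaths)) next
    ests <- lapply(breaths, function(b) identify_breath(b, PEEP = b$PEEP_est))
    peep_hint <- round(median(vapply(breaths, function(b) b$PEEP_est,
                                     numeric(1))))
    chunks[[N]] <- list(breaths = breaths, ests = ests)
  }

  all_E <- unlist(lapply(chunks, function(ch) {
    if (is.null(ch)) return(numeric(0))
    Es <- vapply(ch$ests, function(e)
      if (e$valid) e$E_rs else NA_real_, numeric(1))
    Es[!is.na(Es) & Es > 0]
  }))

  summaries <- list()
  for (N in seq_len(n_int)) {
    ch <- chunks[[N]]
    if (is.null(ch)) next
    flt <- suppressWarnings(
      filter_true_breaths(ch$breaths, ch$ests, history = all_E,
                          min_history = min_history))
    keep <- flt$accepted
    summ <- summarize_interval(ch$breaths[keep], ch$ests[keep], N = N,
                               interval_len = interval_len)
    if (is.null(summ)) next
    summaries[[length(summaries) + 1L]] <- summ
  }
  summaries
}
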