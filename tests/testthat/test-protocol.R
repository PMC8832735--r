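test_that("the default setting grid enumerates 189,000 combinations", {
  grid <- enumerate_grid()
  expect_equal(nrow(grid), 189000L)
  expect_equal(length(unique(grid$RR)), 30L)
  expect_equal(length(unique(grid$VT_perkg)), 5L)
  expect_equal(length(unique(grid$peak_flow)), 30L)
  expect_equal(length(unique(grid$T_plat)), 21L)
  expect_equal(length(unique(grid$waveform)), 2L)
  expect_false(any(duplicated(grid)))

  single <- enumerate_grid(list(RR = 15, VT_perkg = 6, peak_flow = 30,
                                T_plat = 0.3, waveform = "square"))
  expect_equal(nrow(single), 1L)
  expect_error(enumerate_grid(list(RR = integer(0), VT_perkg = 6,
                                   peak_flow = 30, T_plat = 0.3,
                                   waveform = "square")), "empty")
})

test_that("elimination applies strict pressure limits and the inclusive I:E range", {
  # a combination sitting exactly at P_PLAT = 30 is eliminated
  s <- interval_summary(Ers_N = (30 - 10) / 0.26, Rrs_N = 0.1, PEEP_N = 10)
  res <- run_vent(s, weight = 65, audit = FALSE)
  vt4 <- res$survivors
  expect_equal(nrow(vt4), 0L)  # every VT tier has P_PLAT >= 30

  # disabling every threshold keeps all 189,000 (and 0% reduction)
  off <- safety_thresholds(RR_range = c(-Inf, Inf), VT_range = c(-Inf, Inf),
                           Pmax_limit = Inf, Pplat_limit = Inf,
                           IE_range = c(-Inf, Inf))
  grid <- enumerate_grid()
  out <- sivent:::grid_outcomes(grid, 43.5, 26.2, 13, 65)
  expect_equal(nrow(e_stage(out, off)), 189000L)

  # survivor count is nonincreasing in elastance
  n_at <- function(E) run_vent(interval_summary(E, 15, 10), 65,
                               audit = FALSE)$stage_counts[["E"]]
  expect_lte(n_at(60), n_at(30))
})

test_that("narrowing keeps exactly the minimum driving-pressure tier", {
  df <- data.frame(RR = 1:4, VT_perkg = c(4, 4, 5, 5), peak_flow = 30,
                   T_plat = 0, waveform = "square",
                   dP = c(11.31, 11.31, 14.14, 14.14))
  nr <- n_stage(df)
  expect_equal(nr$dP, c(11.31, 11.31))
  expect_equal(n_stage(df[3L, ]), df[3L, ])
  expect_equal(nrow(n_stage(df[0L, ])), 0L)
  expect_error(n_stage(df, objective = "max_ventilation"), "unknown")

  # within a full run the narrowed set is a single tidal-volume tier
  res <- run_vent(interval_summary(43.5, 26.2, 13), 65, audit = FALSE)
  expect_equal(unique(res$survivors$VT_perkg), 4)
})

test_that("stage counts are nonincreasing and reductions consistent", {
  set.seed(51)
  for (k in seq_len(5)) {
    s <- interval_summary(runif(1, 10, 65), runif(1, 2, 25), sample(2:14, 1))
    res <- run_vent(s, weight = runif(1, 40, 95), audit = FALSE)
    expect_true(all(diff(res$stage_counts) <= 0))
    expect_equal(res$pct_reduction,
                 100 * (1 - res$stage_counts[["N"]] / 189000))
  }
})

test_that("the vectorised engine matches a per-combination brute-force loop", {
  spec <- small_grid_spec()
  grid <- enumerate_grid(spec)
  mech <- respiratory_mechanics(43.5, 26.2, 13)
  thr <- safety_thresholds()

  brute <- vapply(seq_len(nrow(grid)), function(i) {
    st <- vc_settings(grid$RR[i], grid$VT_perkg[i], grid$peak_flow[i],
                      grid$T_plat[i], grid$waveform[i])
    o <- compute_outcomes(mech, st, weight = 65)
    o$feasible && o$IE_denom >= 1 - 1e-9 && o$IE_denom <= 3 + 1e-9 &&
      o$P_MAX < 40 && o$P_PLAT < 30
  }, logical(1))

  out <- sivent:::grid_outcomes(grid, 43.5, 26.2, 13, 65)
  expect_identical(sivent:::pass_mask(out, thr), brute)

  res <- run_vent(interval_summary(43.5, 26.2, 13), 65, grid_spec = spec,
                  audit = FALSE)
  expect_equal(res$stage_counts[["E"]], sum(brute))
  dPs <- out$dP[brute]
  expect_equal(res$stage_counts[["N"]], sum(dPs <= min(dPs) + 1e-9))
})

test_that("survivor counts do not depend on enumeration order", {
  spec <- small_grid_spec()
  rev_spec <- lapply(spec, rev)
  a <- run_vent(interval_summary(43.5, 26.2, 13), 65, grid_spec = spec,
                audit = FALSE)
  b <- run_vent(interval_summary(43.5, 26.2, 13), 65, grid_spec = rev_spec,
                audit = FALSE)
  expect_equal(a$stage_counts, b$stage_counts)
})

test_that("a degenerate forecast makes the stochastic protocol collapse onto the deterministic one", {
  s <- interval_summary(43.5, 26.2, 13)
  # one pair at (43.5 -> 43.5) with a tiny bandwidth: E5 = E95 = Ers_N
  m <- fit_transition_model(cbind(43.5, 43.5), bandwidth_rule = 1e-4)
  sv <- run_sivent(s, m, 65, audit = FALSE)
  v <- run_vent(s, 65, audit = FALSE)
  expect_equal(sv$stage_counts, v$stage_counts)
  expect_equal(sv$survivors$P_MAX_hi, v$survivors$P_MAX, tolerance = 1e-3)
})

test_that("stochastic survivors are a subset of deterministic survivors when the band brackets E", {
  set.seed(52)
  m <- fit_transition_model(make_lognormal_pairs(300, sd = 0.08))
  key <- function(df) paste(df$RR, df$VT_perkg, df$peak_flow, df$T_plat,
                            df$waveform)
  for (E in c(25, 43.5, 55)) {
    s <- interval_summary(E, 20, 12)
    fc <- forecast_percentiles(m, E)
    expect_true(fc$values[1L] <= E && E <= fc$values[2L])
    sv <- run_sivent(s, m, 65, audit = FALSE)
    v <- run_vent(s, 65, audit = FALSE)
    expect_lte(sv$stage_counts[["E"]], v$stage_counts[["E"]])
    expect_true(all(key(sv$survivors) %in% key(v$survivors)))
  }
})

test_that("a high forecast upper percentile empties the recommendation set", {
  # if E95 * V_Tmin + PEEP >= 30 even the smallest tidal volume is unsafe
  s <- interval_summary(60, 5, 13)
  m <- fit_transition_model(cbind(60, 80), bandwidth_rule = 5)
  fc <- forecast_percentiles(m, 60)
  expect_gt(fc$values[2L], (30 - 13) / (0.004 * 65))
  sv <- run_sivent(s, m, 65, audit = FALSE)
  expect_equal(sv$stage_counts[["N"]], 0L)
  expect_equal(sv$pct_reduction, 100)
})

test_that("the boundary audit reports status flips under elastance perturbation", {
  # place P_PLAT within 0.05 * V_T of the 30 cmH2O limit so +0.05 on E flips
  E0 <- (30 - 10) / 0.26 - 0.03
  res <- run_vent(interval_summary(E0, 0.1, 10), 65)
  expect_gt(res$audit$flips_plus, 0)
  expect_equal(res$audit$count, res$stage_counts[["N"]])
})

test_that("interval-by-interval evaluation tabulates both protocols", {
  set.seed(53)
  m <- fit_transition_model(make_lognormal_pairs(200, sd = 0.08))
  summaries <- lapply(1:18, function(N)
    interval_summary(40 + 0.2 * N, 12, 10, N = N))
  ev <- evaluate_performance(summaries, m, weight = 65)
  expect_equal(nrow(ev$intervals), 18L)
  expect_true(all(ev$intervals$sivent_count <= ev$intervals$vent_count))
  expect_equal(ev$aggregates$vent_count[["median"]],
               median(ev$intervals$vent_count))
  expect_equal(unname(ev$aggregates$sivent_count[c("q25", "q75")]),
               unname(quantile(ev$intervals$sivent_count, c(0.25, 0.75))))

  # constant mechanics give identical counts in every row
  const <- lapply(1:5, function(N) interval_summary(26, 7.2, 3, N = N))
  evc <- evaluate_performance(const, m, weight = 52)
  expect_equal(length(unique(evc$intervals$vent_count)), 1L)
  expect_error(evaluate_performance(list(), m, 65), "usable")
})

test_that("recommendation tables carry the tabulation columns", {
  s <- interval_summary(43.5, 26.2, 13)
  m <- fit_transition_model(cbind(43.5, 45), bandwidth_rule = 2)
  res <- run_sivent(s, m, 65, audit = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- write_recommendations(res, path)
  expect_named(df, c("RR", "waveform", "VT_mL_per_kg", "peak_flow_Lpm",
                     "T_plat_s", "Pmax_lo", "Pmax_hi", "Pplat_lo",
                     "Pplat_hi", "dP_lo", "dP_hi", "IE"))
  expect_true(all(df$Pmax_hi >= df$Pmax_lo))
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(df))
  # deterministic run: lo and hi coincide
  dfv <- write_recommendations(run_vent(s, 65, audit = FALSE), path)
  expect_equal(dfv$Pmax_lo, dfv$Pmax_hi)
})
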