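clean_config <- function(...) {
  virtual_patient_config(noise_sd = 0, breath_E_sd = 0, asynchrony_rate = 0,
                         log_walk_sd = 0, ...)
}

test_that("a clean VC stream segments into exactly its generated breaths", {
  # 20 breaths at RR 15 (4 s period) in one 80-s interval
  gen <- generate_patient_stream(clean_config(seed = 31), n_intervals = 1,
                                 interval_len = 80)
  breaths <- segment_breaths(gen$stream)
  expect_length(breaths, 20L)
  expect_true(all(vapply(breaths, function(b) b$insp_start < b$exp_start,
                         logical(1))))

  # constant pressure at PEEP, zero flow: onset condition never met
  quiet <- data.frame(t_s = seq(0, 10, 0.02),
                      pressure_cmH2O = 8, flow_Lps = 0)
  expect_length(segment_breaths(quiet, peep_hint = 8), 0L)

  expect_error(segment_breaths(data.frame(t_s = numeric(0),
                                          pressure_cmH2O = numeric(0),
                                          flow_Lps = numeric(0))), "empty")
})

test_that("a breath whose expiration starts 5 s after onset is rejected", {
  dt <- 0.02
  t <- seq(0, 8, dt)
  flow <- numeric(length(t))
  pressure <- rep(5, length(t))
  flow[t < 0.6] <- 0.5                       # inspiration, 0.3 L
  flow[t >= 5 & t < 6] <- -0.4               # expiration too late (5 s)
  pressure[t < 5] <- 5 + 20 * pmin(t[t < 5], 0.6)  # above PEEP + 2
  late <- data.frame(t_s = t, pressure_cmH2O = pressure, flow_Lps = flow)
  expect_length(segment_breaths(late, peep_hint = 5), 0L)

  # same breath with expiration at 1 s qualifies
  flow2 <- numeric(length(t))
  flow2[t < 0.6] <- 0.5
  flow2[t >= 1 & t < 2] <- -0.4
  ok <- data.frame(t_s = t, pressure_cmH2O = pressure, flow_Lps = flow2)
  expect_length(segment_breaths(ok, peep_hint = 5), 1L)
})

test_that("PEEP is estimated from the pre-inspiratory pressure median", {
  gen <- generate_patient_stream(clean_config(seed = 32, PEEP = 13),
                                 n_intervals = 1, interval_len = 80)
  breaths <- segment_breaths(gen$stream)
  peeps <- vapply(breaths[-1L], estimate_peep, numeric(1))
  expect_true(all(peeps == 13))

  # constant window -> that constant; noisy PEEP 10 +- 0.3 -> 10
  br <- list(pre_idx = 1:10, pressure = rep(7, 30))
  expect_equal(estimate_peep(br), 7)
  set.seed(33)
  br$pressure <- rnorm(30, 10, 0.3)
  expect_equal(estimate_peep(br), 10)
  # no pre-window: falls back to the breath's pressure minimum
  expect_equal(estimate_peep(list(pre_idx = integer(0),
                                  pressure = c(9.2, 12, 20))), 9)
})

test_that("true-breath criteria flag distorted, nonphysical and outlying estimates", {
  fake_est <- function(E, APE = 1, valid = TRUE) {
    structure(list(E_rs = E, R_rs = 10, APE = APE, n_equations = 50,
                   valid = valid), class = "mechanics_estimate")
  }
  fake_breath <- function() structure(list(quality_flags = character(0)),
                                      class = "segmented_breath")
  breaths <- replicate(14, fake_breath(), simplify = FALSE)
  ests <- c(lapply(rep(30, 11), fake_est),      # clean reference collection
            list(fake_est(30, APE = 20),        # distorted fit
                 fake_est(0),                   # boundary: E <= 0 rule
                 fake_est(80)))                 # far outside patient band
  flt <- filter_true_breaths(breaths, ests)
  expect_true(all(flt$accepted[1:11]))
  expect_identical(flt$breaths[[12L]]$quality_flags, "ape_exceeded")
  # a zero elastance violates both the sign rule and the patient band
  expect_true("nonpositive_elastance" %in% flt$breaths[[13L]]$quality_flags)
  expect_identical(flt$breaths[[14L]]$quality_flags, "outside_percentile")

  # short collection: percentile criterion skipped with a warning
  expect_warning(
    flt2 <- filter_true_breaths(breaths[1:3], ests[c(1, 2, 14)],
                                history = NULL),
    "percentile criterion skipped")
  expect_true(flt2$accepted[3L])
})

test_that("noise-free generator output is fully accepted and recovered", {
  gen <- generate_patient_stream(clean_config(seed = 34, E0 = 38.7, R = 4.5,
                                              PEEP = 7),
                                 n_intervals = 2)
  summaries <- process_stream(gen$stream)
  expect_length(summaries, 2L)
  for (s in summaries) {
    expect_equal(s$Ers_N, 38.7, tolerance = 5e-3)
    expect_equal(s$Rrs_N, 4.5, tolerance = 5e-3)
    expect_equal(s$PEEP_N, 7)
    # all generated breaths of the interval were accepted
    expect_equal(s$n_true_breaths, 150L)
  }
})

test_that("asynchronous breaths are flagged at about their injection rate", {
  cfg <- virtual_patient_config(seed = 35, asynchrony_rate = 0.2,
                                log_walk_sd = 0)
  gen <- generate_patient_stream(cfg, n_intervals = 2, interval_len = 400)
  n_breaths <- gen$truth$n_breaths
  expect_equal(n_breaths, 200L)
  breaths <- segment_breaths(gen$stream)
  expect_length(breaths, n_breaths)
  ests <- lapply(breaths, function(b) identify_breath(b, b$PEEP_est))
  flt <- filter_true_breaths(breaths, ests)
  flagged <- vapply(flt$breaths, function(b)
    "ape_exceeded" %in% b$quality_flags, logical(1))
  n_true <- length(gen$truth$asynchronous_breaths)
  # binomial fluctuation of the injected count around n * p
  expect_lt(abs(n_true - 200 * 0.2), 3 * sqrt(200 * 0.2 * 0.8) + 1)
  # APE flags recover the injected asynchronies (allowing a few borderline)
  expect_lt(abs(sum(flagged) - n_true), 0.1 * n_true + 3)
})

test_that("interval summaries take medians and skip empty intervals", {
  fake_est <- function(E) structure(list(E_rs = E, R_rs = 10, APE = 1,
                                         n_equations = 50, valid = TRUE),
                                    class = "mechanics_estimate")
  fake_breath <- function(p) structure(list(PEEP_est = p),
                                       class = "segmented_breath")
  s <- summarize_interval(lapply(c(8, 8, 9), fake_breath),
                          lapply(c(40, 43.5, 47), fake_est), N = 3L)
  expect_equal(s$Ers_N, 43.5)
  expect_equal(s$PEEP_N, 8)
  expect_equal(s$n_true_breaths, 3L)
  expect_null(summarize_interval(list(), list()))
})

test_that("segmentation is insensitive to leading and trailing partial breaths", {
  gen <- generate_patient_stream(clean_config(seed = 36), n_intervals = 1,
                                 interval_len = 80)
  full <- segment_breaths(gen$stream)
  # drop half of the first breath and the tail of the last
  trimmed <- gen$stream[gen$stream$t_s >= 2 & gen$stream$t_s <= 78.5, ]
  part <- segment_breaths(trimmed)
  expect_gte(length(part), length(full) - 2L)
  # interior breaths identical
  mid_full <- full[[5L]]; t_off <- trimmed$t_s[1L]
  mid_match <- Filter(function(b)
    abs(b$t[b$insp_idx[1L]] - mid_full$t[mid_full$insp_idx[1L]]) < 1e-9,
    part)
  expect_length(mid_match, 1L)
  expect_equal(mid_match[[1L]]$PIP, mid_full$PIP)
})
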