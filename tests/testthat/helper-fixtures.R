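# Shared fixtures built in code.

# A simulated breath with known mechanics: inspiration profile plus pressure.
make_breath <- function(E = 30, R = 10, PEEP = 5,
                        settings = vc_settings(15, 6, 30, 0.3),
                        weight = 70, dt = 0.02, noise_sd = 0) {
  wf <- build_vc_profile(settings, weight, dt)
  wf <- simulate_pressure(respiratory_mechanics(E, R, PEEP), wf)
  if (noise_sd > 0)
    wf$pressure <- wf$pressure + rnorm(length(wf$pressure), 0, noise_sd)
  wf
}

# Transition pairs with a known conditional law: x = y * exp(eps),
# eps ~ N(0, sd^2), y ~ U(lo, hi).
make_lognormal_pairs <- function(n, sd = 0.1, lo = 10, hi = 70) {
  y <- runif(n, lo, hi)
  x <- y * exp(rnorm(n, 0, sd))
  cbind(y = y, x = x)
}

# A reduced setting grid for brute-force comparisons.
small_grid_spec <- function() {
  list(RR = seq(6, 35, by = 3), VT_perkg = 4:8,
       peak_flow = seq(10, 150, by = 20), T_plat = seq(0, 2, by = 0.5),
       waveform = c("square", "ramp"))
}
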