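#' Fit the conditional kernel-density transition model of elastance
#'
#' Builds the stochastic model of elastance evolution from transition
#' pairs `(y_i = E_rs,N, x_i = E_rs,N+1)`. One bivariate Gaussian kernel
#' is placed on each pair; because elastance is physically nonnegative,
#' each axis kernel is truncated to `[0, Inf)` and renormalised by its
#' mass `p = 1 - Phi(0; centre, sigma)` on that half-line. The
#' conditional density of the next-interval elastance given the current
#' one is then a mixture of the truncated x-kernels with weights
#' proportional to the (truncated) y-kernel values at the conditioning
#' point.
#'
#' @param pairs Two-column matrix or data frame: column 1 `y` (current
#'   interval elastance `E_rs,N`), column 2 `x` (next interval
#'   `E_rs,N+1`), cmH2O/L; all values must be positive.
#' @param bandwidth_rule A global bandwidth rule name, or a numeric
#'   vector of length 1 or 2 giving the kernel standard deviations
#'   `(sigma_x, sigma_y)` directly. `"residual"` (the default) applies
#'   the normal-reference rule `0.9 min(sd, IQR/1.34) n^{-1/5}` to the
#'   residuals of a linear fit of next-interval on current-interval
#'   elastance — the scale on which the transition density actually
#'   varies — and uses it on both axes; `"silverman"` applies the same
#'   rule to each axis marginal (which over-smooths the conditional
#'   bands when successive elastances are strongly dependent, as they
#'   are). With fewer than 10 pairs the marginal rule is used
#'   regardless.
#'
#' @return An object of class `ers_transition_model`: list with `x`, `y`
#'   (kernel centres), `sigma2_x`, `sigma2_y` (per-kernel variances),
#'   `p_x`, `p_y` (truncation normalisers, each in (0, 1]), `n`,
#'   `bandwidth_rule`.
#' @examples
#' set.seed(1)
#' y <- runif(200, 10, 70)
#' x <- y * exp(rnorm(200, 0, 0.1))
#' m <- fit_transition_model(cbind(y, x))
#' forecast_percentiles(m, Ers_N = 40)
#' @export
fit_transition_model <- function(pairs, bandwidth_rule = "residual") {
  pairs <- as.matrix(pairs)
  if (!nrow(pairs)) stop("need at least one transition pair")
  if (ncol(pairs) != 2L) stop("pairs must have two columns (y = E_rs,N, x = E_rs,N+1)")
  if (any(!is.finite(pairs)) || any(pairs <= 0))
    stop("all elastance values must be positive and finite")
  y <- pairs[, 1L]; x <- pairs[, 2L]; n <- length(x)

  if (is.character(bandwidth_rule)) {
    rule <- match.arg(bandwidth_rule, c("residual", "silverman"))
    if (rule == "residual" && n >= 10L) {
      r <- residuals(stats::lm(x ~ y))
      h <- normal_reference_bw(r)
      if (is.finite(h) && h > 0) {
        sx <- sy <- h
      } else {
        sx <- silverman_bw(x); sy <- silverman_bw(y)
      }
    } else {
      sx <- silverman_bw(x); sy <- silverman_bw(y)
    }
  } else {
    stopifnot(is.numeric(bandwidth_rule), all(bandwidth_rule > 0))
    sx <- bandwidth_rule[1L]
    sy <- if (length(bandwidth_rule) > 1L) bandwidth_rule[2L] else sx
    rule <- "fixed"
  }

  structure(list(x = x, y = y,
                 sigma2_x = rep(sx^2, n), sigma2_y = rep(sy^2, n),
                 p_x = pnorm(x / sx), p_y = pnorm(y / sy),
                 n = n, bandwidth_rule = rule),
            class = "ers_transition_model")
}

silverman_bw <- function(v) {
  n <- length(v)
  if (n < 2L) return(max(abs(v)) * 0.1 + 1e-8)
  s <- min(sd(v), IQR(v) / 1.34)
  if (s <= 0) s <- sd(v)
  if (s <= 0) s <- abs(mean(v)) * 0.1 + 1e-8
  0.9 * s * n^(-1/5)
}

normal_reference_bw <- function(r) {
  s <- min(sd(r), IQR(r) / 1.34)
  if (!is.finite(s) || s <= 0) return(NA_real_)
  0.9 * s * length(r)^(-1/5)
}

#' @export
print.ers_transition_model <- function(x, ...) {
  cat(sprintf("Elastance transition model: %d kernel(s), bandwidth rule '%s' (sigma_x %.3f, sigma_y %.3f)\n",
              x$n, x$bandwidth_rule, sqrt(x$sigma2_x[1L]), sqrt(x$sigma2_y[1L])))
  invisible(x)
}

# Mixture weights of the truncated x-kernels at conditioning value y.
kernel_weights <- function(model, y) {
  w <- dnorm(y, model$y, sqrt(model$sigma2_y)) / model$p_y
  s <- sum(w)
  if (s == 0) stop("no support at y = ", y)
  w / s
}

#' Conditional density of next-interval elastance
#'
#' Evaluates `P(E_rs,N+1 = x | E_rs,N = y)` as the weighted mixture of
#' `[0, Inf)`-truncated Gaussian kernels in x, with weights proportional
#' to `phi(y; y_j, sigma2_y_j) / p_y_j`. The density integrates to 1 on
#' `[0, Inf)` by construction.
#'
#' @param model An `ers_transition_model`.
#' @param y Conditioning elastance `E_rs,N`, cmH2O/L (> 0).
#' @param x_grid Evaluation grid; default 1000 points over
#'   `[0, 1.5 max(x_i)]`.
#' @return List with `x` (grid) and `density`.
#' @export
conditional_density <- function(model, y, x_grid = NULL) {
  stopifnot(inherits(model, "ers_transition_model"), y > 0)
  if (is.null(x_grid)) x_grid <- default_x_grid(model)
  w <- kernel_weights(model, y)
  sx <- sqrt(model$sigma2_x)
  # columns: kernels; rows: grid. Truncated kernel density phi/p on x >= 0.
  dens <- outer(x_grid, seq_len(model$n),
                function(x, i) dnorm(x, model$x[i], sx[i]) / model$p_x[i]) %*% w
  dens <- as.vector(dens)
  dens[x_grid < 0] <- 0
  list(x = x_grid, density = dens)
}

default_x_grid <- function(model, n = 1000L) {
  seq(0, 1.5 * max(model$x), length.out = n)
}

#' Forecast percentiles of next-interval elastance
#'
#' Inverts the conditional CDF (cumulative trapezoid of
#' [conditional_density()], linearly interpolated) at the requested
#' percentile levels; the protocol uses the 5th and 95th.
#'
#' @param model An `ers_transition_model`.
#' @param Ers_N Current interval elastance, cmH2O/L.
#' @param levels Percentile levels, percent. Default `c(5, 95)`.
#' @param x_grid Optional evaluation grid (see [conditional_density()]).
#' @return An object of class `percentile_forecast`: list with `levels`
#'   and `values` (nondecreasing in level).
#' @examples
#' m <- fit_transition_model(cbind(30, 35), bandwidth_rule = 2)
#' forecast_percentiles(m, 30)  # approx 35 +/- 1.645 * 2
#' @export
forecast_percentiles <- function(model, Ers_N, levels = c(5, 95),
                                 x_grid = NULL) {
  stopifnot(all(levels > 0), all(levels < 100))
  o <- order(levels)
  cd <- conditional_density(model, Ers_N, x_grid)
  cdf <- pracma::cumtrapz(cd$x, cd$density)[, 1L]
  cdf <- cdf / cdf[length(cdf)]
  # strip flat duplicate CDF values so approx() can invert
  keep <- c(TRUE, diff(cdf) > 0)
  vals <- approx(cdf[keep], cd$x[keep], xout = levels[o] / 100,
                 rule = 2, ties = "ordered")$y
  structure(list(levels = levels[o], values = vals),
            class = "percentile_forecast")
}

#' @export
print.percentile_forecast <- function(x, ...) {
  cat("Elastance forecast (cmH2O/L):\n")
  cat(paste(sprintf("  %g%%: %.3f", x$levels, x$values), collapse = "\n"), "\n")
  invisible(x)
}

#' Empirical coverage of the forecast bands on held-out pairs
#'
#' For each test pair `(y_i, x_i)`, forecasts the `[5, 95]` and `[25, 75]`
#' percentile bands at `y_i` and reports the fraction of `x_i` falling
#' inside each band.
#'
#' @param model An `ers_transition_model`.
#' @param test_pairs Two-column matrix/data frame of held-out `(y, x)`
#'   pairs, disjoint from the training pairs.
#' @return List with `coverage_5_95`, `coverage_25_75` (fractions) and
#'   `n_test`.
#' @export
validate_coverage <- function(model, test_pairs) {
  test_pairs <- as.matrix(test_pairs)
  if (!nrow(test_pairs)) stop("empty test set")
  grid <- default_x_grid(model)
  inside <- matrix(NA, nrow(test_pairs), 2L)
  for (i in seq_len(nrow(test_pairs))) {
    fc <- forecast_percentiles(model, test_pairs[i, 1L],
                               levels = c(5, 25, 75, 95), x_grid = grid)
    xi <- test_pairs[i, 2L]
    inside[i, 1L] <- xi >= fc$values[1L] && xi <= fc$values[4L]
    inside[i, 2L] <- xi >= fc$values[2L] && xi <= fc$values[3L]
  }
  list(coverage_5_95 = mean(inside[, 1L]),
       coverage_25_75 = mean(inside[, 2L]),
       n_test = nrow(test_pairs))
}

#' Extract consecutive-interval transition pairs from interval summaries
#'
#' Pairs `(E_rs,N, E_rs,N+1)` are formed only from consecutive interval
#' indices; a gap (skipped interval) breaks the chain rather than pairing
#' across it.
#'
#' @param summaries List of `interval_summary` objects from one patient.
#' @return Two-column matrix (`y`, `x`); zero rows if fewer than two
#'   consecutive intervals exist.
#' @export
transition_pairs <- function(summaries) {
  if (length(summaries) < 2L) {
    return(matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("y", "x"))))
  }
  Ns <- vapply(summaries, function(s) s$N, numeric(1))
  Es <- vapply(summaries, function(s) s$Ers_N, numeric(1))
  o <- order(Ns); Ns <- Ns[o]; Es <- Es[o]
  consec <- which(diff(Ns) == 1)
  cbind(y = Es[consec], x = Es[consec + 1L])
}

#' Serialise / restore a transition model as JSON
#'
#' @param model An `ers_transition_model`.
#' @param path File path.
#' @return `write_transition_model()` returns `path` invisibly;
#'   `read_transition_model()` returns the restored model.
#' @export
write_transition_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transition_model
#' @export
read_transition_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$n <- as.integer(m$n)
  structure(m, class = "ers_transition_model")
}

#' Export a percentile look-up table
#'
#' Tabulates forecast percentiles over a grid of conditioning elastance
#' values, the look-up-table form in which the stochastic model is used
#' at the bedside.
#'
#' @param model An `ers_transition_model`.
#' @param Ers_grid Conditioning values; default 50 points spanning the
#'   training y-range.
#' @param levels Percentile levels, percent.
#' @param path Optional CSV output path.
#' @return Data frame with `Ers_N` and one column per level.
#' @export
percentile_table <- function(model, Ers_grid = NULL,
                             levels = c(5, 25, 50, 75, 95), path = NULL) {
  if (is.null(Ers_grid))
    Ers_grid <- seq(min(model$y), max(model$y), length.out = 50L)
  grid <- default_x_grid(model)
  out <- t(vapply(Ers_grid, function(yv)
    forecast_percentiles(model, yv, levels = levels, x_grid = grid)$values,
    numeric(length(levels))))
  df <- data.frame(Ers_N = Ers_grid, out)
  names(df)[-1L] <- paste0("p", levels)
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
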