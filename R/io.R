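#' Read a pressure--flow stream from CSV
#'
#' Expects columns `t_s`, `pressure_cmH2O` and a flow column tagged with
#' its unit: `flow_Lps` (L/s) or `flow_Lpm` (L/min, converted to L/s on
#' read). Gzip-compressed files are read transparently. Time must be
#' strictly increasing.
#'
#' @param path CSV (optionally `.gz`) file path.
#' @return Data frame with columns `t_s`, `pressure_cmH2O`, `flow_Lps`.
#' @export
read_pressure_flow <- function(path) {
  df <- read.csv(path)
  if (!all(c("t_s", "pressure_cmH2O") %in% names(df)))
    stop("missing column: need t_s and pressure_cmH2O in ", path)
  if ("flow_Lps" %in% names(df)) {
    # already L/s
  } else if ("flow_Lpm" %in% names(df)) {
    df$flow_Lps <- df$flow_Lpm / 60
    df$flow_Lpm <- NULL
  } else {
    stop("missing flow column: expected flow_Lps or flow_Lpm (unit tag) in ",
         path)
  }
  df <- df[c("t_s", "pressure_cmH2O", "flow_Lps")]
  if (anyNA(df)) {
    bad <- which(rowSums(is.na(df)) > 0)[1L]
    stop("NA values in stream (first at row ", bad, ")")
  }
  bad <- which(diff(df$t_s) <= 0)
  if (length(bad))
    stop("time column not strictly increasing (first violation after row ",
         bad[1L], ")")
  df
}

#' Write a pressure--flow stream as CSV
#'
#' @param stream Data frame with `t_s`, `pressure_cmH2O`, `flow_Lps`.
#' @param path Output path; a `.gz` suffix writes gzip-compressed.
#' @return `path`, invisibly.
#' @export
write_pressure_flow <- function(stream, path) {
  check_stream(stream)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.csv(stream[c("t_s", "pressure_cmH2O", "flow_Lps")], con,
            row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Bundles the setting grid, safety thresholds, interval scheme,
#' bandwidth rule, narrowing objective and seed of a protocol run. The
#' defaults reproduce the standard enumeration grid and threshold set,
#' so a bare configuration runs the reference protocol.
#'
#' @param grid_spec See [default_grid_spec()].
#' @param thresholds See [safety_thresholds()].
#' @param interval_len Interval length, s.
#' @param horizon Evaluation horizon, s.
#' @param bandwidth_rule Transition-model bandwidth rule.
#' @param objective Narrowing objective name.
#' @param seed Integer seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(grid_spec = default_grid_spec(),
                       thresholds = safety_thresholds(),
                       interval_len = 600, horizon = 3 * 3600,
                       bandwidth_rule = "silverman",
                       objective = "min_dP", seed = 1L) {
  cfg <- structure(list(version = 1L, grid_spec = grid_spec,
                        thresholds = thresholds,
                        interval_len = interval_len, horizon = horizon,
                        bandwidth_rule = bandwidth_rule,
                        objective = objective, seed = as.integer(seed)),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' Validate a run configuration against the schema
#'
#' @param cfg A `run_config` (or plain list in its shape).
#' @return `cfg`, invisibly, or an error describing the first violation.
#' @export
validate_run_config <- function(cfg) {
  need <- c("version", "grid_spec", "thresholds", "interval_len", "horizon",
            "bandwidth_rule", "objective", "seed")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("config missing field(s): ", paste(miss, collapse = ", "))
  if (cfg$version != 1L) stop("unsupported config version: ", cfg$version)
  axes <- c("RR", "VT_perkg", "peak_flow", "T_plat", "waveform")
  if (!all(axes %in% names(cfg$grid_spec)))
    stop("config grid_spec missing axis")
  thr <- cfg$thresholds
  if (!all(c("RR_range", "VT_range", "Pmax_limit", "Pplat_limit",
             "IE_range") %in% names(thr)))
    stop("config thresholds incomplete")
  if (cfg$interval_len <= 0 || cfg$horizon < cfg$interval_len)
    stop("config horizon must cover at least one interval")
  if (!is.character(cfg$objective)) stop("config objective must be a name")
  invisible(cfg)
}

#' Read / write a run configuration (YAML or JSON)
#'
#' The format is chosen from the file extension (`.yaml`/`.yml` or
#' `.json`). Read configurations are schema-validated.
#'
#' @param cfg A `run_config`.
#' @param path File path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns the validated `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  validate_run_config(cfg)
  plain <- unclass(cfg)
  plain$thresholds <- unclass(plain$thresholds)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(plain, path)
  } else {
    jsonlite::write_json(plain, path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  raw$thresholds <- do.call(safety_thresholds, raw$thresholds)
  cfg <- structure(raw, class = "run_config")
  validate_run_config(cfg)
  cfg
}
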