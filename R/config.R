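# Flat key = value run configuration shared by the CLI and
# export_scenario(). Unknown keys are rejected by name so a typo never
# silently falls back to a default.

CONFIG_KEYS <- c(
  # identity
  "scenario_name",
  # colony
  "production_rate", "cell_density", "radius_mm", "diffusion",
  "cell_width_um",
  # threshold ("calibrated" or a number in nM)
  "threshold_nM",
  # sweep
  "sweep_param", "sweep_grid", "sweep_r_min",
  # root-solve bracket
  "bracket_lo_mm", "bracket_hi_mm",
  # growth
  "theta_in", "theta0", "beta0", "alpha", "gamma", "Ks", "k_dec",
  "mu_max", "t_end", "dt_report", "Ks_alt",
  # coupling / output
  "coupling_mode", "out_csv", "plot")

input_error <- function(msg) {
  errorCondition(msg, class = c("qs_input_error", "error", "condition"))
}

#' Read a flat key = value run configuration
#'
#' Parses a plain-text file of `key = value` lines (blank lines and `#`
#' comments ignored). Keys must belong to the documented configuration
#' vocabulary; an unknown key is an error naming the offending key.
#'
#' @param path path to the config file
#' @return named list of raw string values
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(input_error(paste0("config file not found: ", path)))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0)
      stop(input_error(paste0("config line is not 'key = value': ", ln)))
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    if (!key %in% CONFIG_KEYS)
      stop(input_error(paste0("unknown config key: '", key, "'")))
    cfg[[key]] <- val
  }
  cfg
}

cfg_num <- function(cfg, key, default = NULL) {
  if (is.null(cfg[[key]])) {
    if (is.null(default))
      stop(input_error(paste0("missing required parameter: ", key)))
    return(default)
  }
  v <- suppressWarnings(as.numeric(cfg[[key]]))
  if (is.na(v))
    stop(input_error(paste0("parameter '", key, "' is not a number: ",
                            cfg[[key]])))
  v
}

cfg_colony <- function(cfg) {
  tryCatch(
    colony_parameters(
      production_rate = cfg_num(cfg, "production_rate"),
      cell_density = cfg_num(cfg, "cell_density"),
      radius_mm = cfg_num(cfg, "radius_mm"),
      diffusion_coefficient = cfg_num(cfg, "diffusion"),
      cell_width_um = cfg_num(cfg, "cell_width_um", 1)),
    error = function(e) {
      if (inherits(e, "qs_input_error")) stop(e)
      stop(input_error(conditionMessage(e)))
    })
}

cfg_threshold <- function(cfg) {
  raw <- cfg[["threshold_nM"]]
  if (is.null(raw))
    stop(input_error("missing required parameter: threshold_nM (a value in nM, or 'calibrated')"))
  if (identical(tolower(raw), "calibrated"))
    return(calibrate_threshold(reference_colony()))
  threshold_config(cfg_num(cfg, "threshold_nM"), note = "config file")
}

cfg_growth <- function(cfg) {
  tryCatch(
    growth_parameters(
      theta_in = cfg_num(cfg, "theta_in", 5e-3),
      theta0 = cfg_num(cfg, "theta0", 5e-3),
      beta0 = cfg_num(cfg, "beta0", 1e4),
      alpha = cfg_num(cfg, "alpha", 0),
      gamma = cfg_num(cfg, "gamma", 1e9),
      Ks = cfg_num(cfg, "Ks", 55.2e-4),
      k_dec = cfg_num(cfg, "k_dec", 0.01),
      mu_max = cfg_num(cfg, "mu_max", 0.3),
      t_end = cfg_num(cfg, "t_end", 240),
      dt_report = cfg_num(cfg, "dt_report", 0.5)),
    error = function(e) {
      if (inherits(e, "qs_input_error")) stop(e)
      stop(input_error(conditionMessage(e)))
    })
}

cfg_grid <- function(cfg) {
  raw <- cfg[["sweep_grid"]]
  if (is.null(raw)) return(NULL)
  vals <- suppressWarnings(as.numeric(strsplit(raw, ",", fixed = TRUE)[[1]]))
  if (anyNA(vals))
    stop(input_error(paste0("sweep_grid contains a non-number: ", raw)))
  vals
}
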