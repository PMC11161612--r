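# Packaged parameter sets: every scenario is self-contained code, so
# demos, tests and the CLI run with zero external input. Citations name
# the figure panel each scenario reproduces so exported CSVs are
# self-documenting.

#' The reference calibration colony
#'
#' The anchor scenario used throughout the package to pin the QS
#' threshold: P = 5000 molecules/cell/s, n = 1e6 cells/mL, Ws = 1 um,
#' D = 1e-6 cm^2/s, with the minimum thickness at that D equal to
#' 0.45 mm. [calibrate_threshold()] on this colony yields ~8.41 nM, the
#' implied threshold behind the packaged minimum-thickness table.
#'
#' @return a [colony_parameters()] object
#' @export
reference_colony <- function() {
  colony_parameters(production_rate = 5000, cell_density = 1e6,
                    radius_mm = 0.45, diffusion_coefficient = 1e-6,
                    cell_width_um = 1)
}

new_scenario <- function(name, citation, colony = NULL, threshold = NULL,
                         growth = NULL, growth_alt = NULL, sweep = NULL) {
  structure(list(name = name, citation = citation, colony = colony,
                 threshold = threshold, growth = growth,
                 growth_alt = growth_alt, sweep = sweep),
            class = "qs_scenario")
}

#' @export
print.qs_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%s)\n", x$name, x$citation))
  if (!is.null(x$sweep))
    cat(sprintf("  sweep over %s: %s\n", x$sweep$param,
                paste(format(x$sweep$grid, digits = 4), collapse = ", ")))
  if (!is.null(x$growth)) cat("  includes growth dynamics\n")
  invisible(x)
}

#' List the packaged scenarios
#'
#' Returns the named list of all packaged scenarios:
#' \describe{
#'   \item{fig2a_d_sweep}{autoinducer concentration at a 500 um biofilm
#'     while the diffusion coefficient runs from 1e-6 to 1e-5 cm^2/s}
#'   \item{fig2b_minthickness}{minimum biofilm thickness per diffusion
#'     coefficient, threshold calibrated so R_min(D = 1e-6) = 0.45 mm}
#'   \item{fig2c_p_sweep_1e5}{production-rate sweep \{500, 5000, 50000\}
#'     at 1e5 cells/mL and a 1 mm colony}
#'   \item{fig2d_p_sweep_1e6}{same sweep at 1e6 cells/mL}
#'   \item{fig2f_growth}{240 h batch growth coupled to autoinducer
#'     production (density-and-radius coupling, normalized curves)}
#'   \item{fig3_ks_pair}{the same growth run at half-saturation 55.2 vs
#'     17 (on the 1e-4 gCOD/mL scale)}
#' }
#' Thresholds marked "calibrated" are resolved against
#' [reference_colony()] at run time.
#'
#' @return named list of `qs_scenario` objects
#' @export
list_scenarios <- function() {
  ref <- reference_colony()
  base500 <- colony_parameters(5000, 1e6, 0.5, 1e-6, 1)
  scns <- list(
    new_scenario(
      "fig2a_d_sweep",
      "autoinducer concentration vs diffusion coefficient, 500 um biofilm (Fig. 2A)",
      colony = base500, threshold = "calibrated",
      sweep = list(param = "D", grid = seq(1e-6, 1e-5, by = 1e-6),
                   r_min = FALSE)),
    new_scenario(
      "fig2b_minthickness",
      "minimum biofilm thickness per diffusion coefficient (Fig. 2B)",
      colony = ref, threshold = "calibrated",
      sweep = list(param = "D", grid = seq(1e-6, 5e-6, by = 1e-6),
                   r_min = TRUE)),
    new_scenario(
      "fig2c_p_sweep_1e5",
      "production-rate sweep at 1e5 cells/mL, 1 mm colony (Fig. 2C)",
      colony = colony_parameters(5000, 1e5, 1, 1e-6, 1),
      threshold = "calibrated",
      sweep = list(param = "P", grid = c(500, 5000, 50000), r_min = FALSE)),
    new_scenario(
      "fig2d_p_sweep_1e6",
      "production-rate sweep at 1e6 cells/mL, 1 mm colony (Fig. 2D)",
      colony = colony_parameters(5000, 1e6, 1, 1e-6, 1),
      threshold = "calibrated",
      sweep = list(param = "P", grid = c(500, 5000, 50000), r_min = FALSE)),
    new_scenario(
      "fig2f_growth",
      "growth-phase curve with coupled autoinducer production, 240 h (Fig. 2F)",
      colony = ref, threshold = "calibrated",
      growth = growth_parameters()),
    new_scenario(
      "fig3_ks_pair",
      "time dynamics at half-saturation 55.2 (blue) vs 17 (red) (Fig. 3)",
      colony = ref, threshold = "calibrated",
      growth = growth_parameters(Ks = 55.2e-4),
      growth_alt = growth_parameters(Ks = 17e-4))
  )
  names(scns) <- vapply(scns, `[[`, "", "name")
  scns
}

#' Look up a packaged scenario by name
#'
#' @param name one of the names in [list_scenarios()]
#' @return a `qs_scenario`
#' @export
get_scenario <- function(name) {
  scns <- list_scenarios()
  if (!name %in% names(scns))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(scns), collapse = ", "), call. = FALSE)
  scns[[name]]
}

# resolve a scenario's threshold spec into a threshold_config
resolve_threshold <- function(sc) {
  if (inherits(sc$threshold, "threshold_config")) return(sc$threshold)
  if (identical(sc$threshold, "calibrated"))
    return(calibrate_threshold(reference_colony()))
  as_threshold(sc$threshold)
}

#' Run a packaged scenario end to end
#'
#' Sweep scenarios return a `sweep_table`; growth scenarios return the
#' coupled trajectory (a named list of two trajectories for paired
#' scenarios such as `fig3_ks_pair`).
#'
#' @param sc a `qs_scenario` or a scenario name
#' @param coupling_mode forwarded to [couple_autoinducer()] for growth
#'   scenarios
#' @return see Details
#' @examples
#' run_scenario("fig2b_minthickness")
#' @export
run_scenario <- function(sc, coupling_mode = "density_and_radius") {
  if (is.character(sc)) sc <- get_scenario(sc)
  stopifnot(inherits(sc, "qs_scenario"))
  thr <- resolve_threshold(sc)
  if (!is.null(sc$sweep))
    return(qs_sweep(sc$colony, thr, sc$sweep$param, sc$sweep$grid,
                    r_min = isTRUE(sc$sweep$r_min)))
  if (!is.null(sc$growth)) {
    run_one <- function(gp)
      couple_autoinducer(simulate_growth(gp), sc$colony,
                         coupling_mode = coupling_mode)
    if (is.null(sc$growth_alt)) return(run_one(sc$growth))
    return(list(primary = run_one(sc$growth), alt = run_one(sc$growth_alt)))
  }
  assess_feasibility(sc$colony, thr)
}

#' Export a scenario to the CLI config format
#'
#' Writes the flat `key = value` file the command-line interface reads,
#' so any packaged scenario can be re-run (and edited) from a shell.
#'
#' @param sc a `qs_scenario` or scenario name
#' @param path output file path
#' @return `path`, invisibly
#' @export
export_scenario <- function(sc, path) {
  if (is.character(sc)) sc <- get_scenario(sc)
  stopifnot(inherits(sc, "qs_scenario"))
  lines <- c(sprintf("# quorumsim scenario '%s': %s", sc$name, sc$citation),
             sprintf("scenario_name = %s", sc$name))
  cp <- sc$colony
  if (!is.null(cp))
    lines <- c(lines,
               sprintf("production_rate = %.15g", cp$P),
               sprintf("cell_density = %.15g", cp$n),
               sprintf("radius_mm = %.15g", cp$R * 10),
               sprintf("diffusion = %.15g", cp$D),
               sprintf("cell_width_um = %.15g", cp$Ws * 1e4))
  if (inherits(sc$threshold, "threshold_config"))
    lines <- c(lines, sprintf("threshold_nM = %.15g", sc$threshold$nM))
  else if (identical(sc$threshold, "calibrated"))
    lines <- c(lines, "threshold_nM = calibrated")
  if (!is.null(sc$sweep))
    lines <- c(lines,
               sprintf("sweep_param = %s", sc$sweep$param),
               sprintf("sweep_grid = %s",
                       paste(sprintf("%.15g", sc$sweep$grid), collapse = ",")),
               sprintf("sweep_r_min = %s",
                       if (isTRUE(sc$sweep$r_min)) "true" else "false"))
  gp <- sc$growth
  if (!is.null(gp))
    lines <- c(lines, sprintf("%s = %.15g", c(
      "theta_in", "theta0", "beta0", "alpha", "gamma", "Ks", "k_dec",
      "mu_max", "t_end", "dt_report"),
      unlist(gp[c("theta_in", "theta0", "beta0", "alpha", "gamma", "Ks",
                  "k_dec", "mu_max", "t_end", "dt_report")])))
  if (!is.null(sc$growth_alt))
    lines <- c(lines, sprintf("Ks_alt = %.15g", sc$growth_alt$Ks))
  writeLines(lines, path)
  invisible(path)
}
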