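# Parameter containers. User-facing units follow lab convention
# (mm, um, cells/mL, nM); everything is stored internally in CGS
# (cm, s, molecules) so the model formulas never mix unit systems.

#' Physical parameters of a spherical bacterial colony
#'
#' Bundles the five physical inputs of the colony concentration model:
#' per-cell autoinducer production rate, cell density, colony radius
#' (biofilm thickness), medium diffusion coefficient, and bacterial cell
#' width (the width of the Gaussian source representing one cell).
#'
#' Inputs are given in conventional units and converted to CGS on
#' construction: `radius_mm` (mm) is stored as `R` in cm,
#' `cell_width_um` (um) as `Ws` in cm, and `cell_density` (cells/mL) as
#' `n` in cells/cm^3 (numerically identical since 1 mL = 1 cm^3).
#'
#' @param production_rate P, autoinducer molecules per cell per second (> 0)
#' @param cell_density n, cells per mL (> 0)
#' @param radius_mm colony radius / biofilm thickness in mm (> 0, >= cell width)
#' @param diffusion_coefficient D in cm^2/s (> 0)
#' @param cell_width_um bacterial cell width in um (> 0), default 1 um
#' @return an object of class `colony_parameters` with CGS fields
#'   `P`, `n`, `R`, `D`, `Ws`
#' @examples
#' colony_parameters(5000, 1e6, 0.45, 1e-6)
#' @export
colony_parameters <- function(production_rate, cell_density, radius_mm,
                              diffusion_coefficient, cell_width_um = 1) {
  vals <- c(production_rate = production_rate, cell_density = cell_density,
            radius_mm = radius_mm, diffusion_coefficient = diffusion_coefficient,
            cell_width_um = cell_width_um)
  if (any(!is.finite(vals)))
    stop("colony parameters must all be finite: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "), call. = FALSE)
  if (any(vals <= 0))
    stop("colony parameters must all be strictly positive: ",
         paste(names(vals)[vals <= 0], collapse = ", "), call. = FALSE)
  R  <- radius_mm / 10          # mm -> cm
  Ws <- cell_width_um * 1e-4    # um -> cm
  if (R < Ws)
    stop("colony radius (", radius_mm, " mm) must be at least one cell width (",
         cell_width_um, " um)", call. = FALSE)
  structure(list(P = production_rate, n = cell_density, R = R,
                 D = diffusion_coefficient, Ws = Ws),
            class = "colony_parameters")
}

#' @export
print.colony_parameters <- function(x, ...) {
  cat("Colony parameters (stored in CGS):\n")
  cat(sprintf("  P  = %g molecules/cell/s\n", x$P))
  cat(sprintf("  n  = %g cells/cm^3\n", x$n))
  cat(sprintf("  R  = %g cm (%g mm)\n", x$R, x$R * 10))
  cat(sprintf("  D  = %g cm^2/s\n", x$D))
  cat(sprintf("  Ws = %g cm (%g um)\n", x$Ws, x$Ws * 1e4))
  invisible(x)
}

# replace one CGS field, revalidating (used by sweeps and root solving)
set_colony_field <- function(params, field, value) {
  stopifnot(inherits(params, "colony_parameters"))
  params[[field]] <- value
  if (any(unlist(params[c("P", "n", "R", "D", "Ws")]) <= 0))
    stop("colony parameters must stay strictly positive", call. = FALSE)
  params
}

#' Quorum-sensing threshold configuration
#'
#' The critical autoinducer concentration: quorum sensing is declared
#' when `N_threshold <= N_total` (non-strict, so a colony exactly at
#' threshold counts as sensing).
#'
#' @param nM threshold concentration in nanomolar (> 0)
#' @param note free-text provenance of the value
#' @return an object of class `threshold_config`
#' @seealso [calibrate_threshold()] for deriving the threshold that makes
#'   a reference colony exactly critical
#' @export
threshold_config <- function(nM = 10,
                             note = "default; calibrate_threshold() recovers the value implied by a reference colony (= 8.4 nM for the packaged reference)") {
  if (!is.numeric(nM) || length(nM) != 1 || !is.finite(nM) || nM <= 0)
    stop("threshold must be a single finite value > 0 (nM)", call. = FALSE)
  structure(list(nM = as.numeric(nM), note = as.character(note)),
            class = "threshold_config")
}

#' @export
print.threshold_config <- function(x, ...) {
  cat(sprintf("QS threshold: %g nM (%s)\n", x$nM, x$note))
  invisible(x)
}

# accept a bare number where a threshold_config is expected
as_threshold <- function(threshold) {
  if (inherits(threshold, "threshold_config")) return(threshold)
  threshold_config(threshold, note = "user-supplied")
}

#' Monod chemostat growth parameters
#'
#' Parameters of the single-species chemostat model
#' \deqn{d\theta/dt = (\theta_{in} - \theta)\alpha - \mu(\theta)\beta/\gamma}
#' \deqn{d\beta/dt  = (\mu(\theta) - \alpha - k_{dec})\beta}
#' with the Monod growth law \eqn{\mu(\theta) = \mu_{max}\theta/(K_s + \theta)}.
#' Substrate \eqn{\theta} is in gCOD/mL, cell density \eqn{\beta} in
#' cells/mL, rates in 1/h, and \eqn{\gamma} is the biomass yield in cells
#' per gCOD. Setting `alpha = 0` recovers a batch culture; in batch with
#' `k_dec = 0` the yield-weighted total `beta + gamma * theta` is
#' conserved exactly.
#'
#' The defaults describe a batch culture that traverses all four growth
#' phases (lag, log, stationary, death) within 240 h: cells grow on
#' 5e-3 gCOD/mL of substrate from a 1e4 cells/mL inoculum, peak near
#' `gamma * theta_in` = 5e6 cells/mL around 60 h, then decline at the
#' decay rate. `Ks` is expressed in the same units as `theta`
#' (gCOD/mL); the packaged scenarios use the half-saturation values
#' 55.2 and 17 on a 1e-4 gCOD/mL scale so that they are commensurate
#' with the default substrate level.
#'
#' @param theta_in influent substrate concentration, gCOD/mL
#' @param theta0 initial substrate concentration, gCOD/mL
#' @param beta0 initial cell density, cells/mL (>= 0)
#' @param alpha dilution (flow) rate, 1/h (0 = batch)
#' @param gamma biomass yield, cells per gCOD
#' @param Ks Monod half-saturation constant, same units as `theta`
#' @param k_dec first-order cell decay rate, 1/h
#' @param mu_max maximum specific growth rate, 1/h (>= 0)
#' @param t_end simulation horizon, h
#' @param dt_report reporting interval, h
#' @return an object of class `growth_parameters`
#' @examples
#' growth_parameters()              # packaged batch defaults, 240 h
#' growth_parameters(Ks = 17e-4)    # faster-growing variant
#' @export
growth_parameters <- function(theta_in = 5e-3, theta0 = 5e-3, beta0 = 1e4,
                              alpha = 0, gamma = 1e9, Ks = 55.2e-4,
                              k_dec = 0.01, mu_max = 0.3,
                              t_end = 240, dt_report = 0.5) {
  vals <- c(theta_in = theta_in, theta0 = theta0, beta0 = beta0, alpha = alpha,
            gamma = gamma, Ks = Ks, k_dec = k_dec, mu_max = mu_max,
            t_end = t_end, dt_report = dt_report)
  if (any(!is.finite(vals)))
    stop("growth parameters must all be finite: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "), call. = FALSE)
  if (any(vals < 0))
    stop("growth parameters must all be >= 0: ",
         paste(names(vals)[vals < 0], collapse = ", "), call. = FALSE)
  if (Ks <= 0) stop("Ks must be > 0", call. = FALSE)
  if (gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  if (t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  if (dt_report <= 0) stop("dt_report must be > 0", call. = FALSE)
  structure(as.list(vals), class = "growth_parameters")
}

#' @export
print.growth_parameters <- function(x, ...) {
  cat("Monod chemostat parameters:\n")
  cat(sprintf("  theta_in = %g, theta0 = %g gCOD/mL; beta0 = %g cells/mL\n",
              x$theta_in, x$theta0, x$beta0))
  cat(sprintf("  alpha = %g /h, gamma = %g cells/gCOD, Ks = %g gCOD/mL\n",
              x$alpha, x$gamma, x$Ks))
  cat(sprintf("  k_dec = %g /h, mu_max = %g /h; horizon %g h @ %g h\n",
              x$k_dec, x$mu_max, x$t_end, x$dt_report))
  invisible(x)
}
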