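# Coupling of the growth trajectory into the diffusion model: the
# static cell density n of the colony formula is replaced by the
# time-dependent beta(t); optionally the colony radius grows with the
# cube root of the population (fixed packing density).

#' Couple a growth trajectory to the autoinducer model
#'
#' At each reported time the colony centre concentration is evaluated
#' with the cell density set to \eqn{\beta(t)}. Per-cell production P is
#' held constant throughout. Two coupling modes are available:
#' * `"density_and_radius"` (default): the colony radius also grows,
#'   \eqn{R(t) = R_0 (\beta(t)/\beta_0)^{1/3}} — the sphere that keeps
#'   the packing density of the inoculum constant as cells multiply.
#' * `"density_only"`: the radius stays at \eqn{R_0}, so
#'   \eqn{N_{total}(t)} is exactly proportional to \eqn{\beta(t)}.
#'
#' In both modes the concentration at each instant is a monotone
#' function of \eqn{\beta}, so the autoinducer maximum occurs no earlier
#' than the population maximum — the signal peaks at the onset of the
#' death phase and then declines with the active-cell count.
#'
#' @param traj a `growth_trajectory` from [simulate_growth()]
#' @param base a [colony_parameters()] object supplying P, D, Ws and the
#'   reference radius \eqn{R_0} (its `n` is ignored in favour of
#'   \eqn{\beta(t)})
#' @param coupling_mode `"density_and_radius"` or `"density_only"`
#' @return a data frame of class `coupled_trajectory` with columns
#'   `time_h, substrate, cells, N_total_nM, cells_norm, N_norm`; the
#'   `_norm` columns are [normalize_series()] companions (all-zero if
#'   the culture is empty throughout)
#' @examples
#' traj <- simulate_growth(growth_parameters())
#' cpl <- couple_autoinducer(traj, colony_parameters(5000, 1e6, 0.45, 1e-6))
#' cpl[which.max(cpl$N_total_nM), "time_h"]
#' @export
couple_autoinducer <- function(traj, base,
                               coupling_mode = c("density_and_radius",
                                                 "density_only")) {
  stopifnot(inherits(traj, "growth_trajectory"),
            inherits(base, "colony_parameters"))
  coupling_mode <- match.arg(coupling_mode)
  beta <- traj$cells
  beta0 <- beta[1]
  R_t <- if (coupling_mode == "density_and_radius" && beta0 > 0)
    base$R * (beta / beta0)^(1 / 3)
  else
    rep(base$R, length(beta))
  N_nM <- mol_cm3_to_nM(ntotal_mol_cm3(base$P, beta, base$D, R_t, base$Ws))
  out <- data.frame(time_h = traj$time_h, substrate = traj$substrate,
                    cells = beta, N_total_nM = N_nM,
                    cells_norm = normalize_series(beta),
                    N_norm = normalize_series(N_nM))
  attr(out, "coupling_mode") <- coupling_mode
  attr(out, "base") <- base
  class(out) <- c("coupled_trajectory", "data.frame")
  out
}

#' Write a (coupled) trajectory to CSV
#'
#' Column layout `time_h,substrate,cells[,N_total_nM,cells_norm,N_norm]`
#' (the autoinducer columns are present only for coupled trajectories),
#' preceded by a `#` comment line with tool version and citation.
#'
#' @param traj a `growth_trajectory` or `coupled_trajectory`
#' @param path output file path
#' @param citation free-text provenance for the header comment
#' @return `path`, invisibly
#' @export
write_trajectory_csv <- function(traj, path, citation = "") {
  stopifnot(inherits(traj, "growth_trajectory") ||
              inherits(traj, "coupled_trajectory"))
  writeLines(csv_comment_header(citation), path)
  suppressWarnings(
    write.table(as.data.frame(traj), path, sep = ",", row.names = FALSE,
                col.names = TRUE, quote = FALSE, na = "", append = TRUE))
  invisible(path)
}
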