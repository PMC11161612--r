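# Decision layer: threshold comparison, calibration, minimum biofilm
# thickness by bisection, and single-parameter sweeps.

#' Assess quorum-sensing feasibility
#'
#' Computes the colony centre concentration via
#' [colony_concentration_closed_form()], converts to nM, and compares it
#' against the threshold. The comparison is non-strict: a colony exactly
#' at threshold is sensing (`N_threshold <= N_total`).
#'
#' @param params a [colony_parameters()] object
#' @param threshold a [threshold_config()] or a bare number in nM
#' @return an object of class `feasibility_result` with fields
#'   `N_total_nM`, `threshold_nM`, `feasible`, `params`
#' @examples
#' p <- colony_parameters(5000, 1e6, 0.45, 1e-6)
#' assess_feasibility(p, threshold_config(10))
#' @export
assess_feasibility <- function(params, threshold = threshold_config()) {
  stopifnot(inherits(params, "colony_parameters"))
  threshold <- as_threshold(threshold)
  N <- to_nanomolar(colony_concentration_closed_form(params))$value
  structure(list(N_total_nM = N, threshold_nM = threshold$nM,
                 feasible = threshold$nM <= N, params = params),
            class = "feasibility_result")
}

#' @export
print.feasibility_result <- function(x, ...) {
  cat(sprintf("QUORUM SENSING: %s\n", if (x$feasible) "YES" else "NO"))
  cat(sprintf("  N_total    = %.6g nM\n", x$N_total_nM))
  cat(sprintf("  N_threshold= %.6g nM\n", x$threshold_nM))
  invisible(x)
}

#' Calibrate the threshold to a reference colony
#'
#' Returns, as a [threshold_config()], the concentration produced by the
#' given colony, i.e. the threshold that makes that colony exactly
#' critical. Calibrating against a reference (D, R_min) pair and then
#' solving [minimum_thickness()] at other diffusion coefficients
#' reproduces a whole minimum-thickness table from one anchor point.
#'
#' @param params a [colony_parameters()] object
#' @return a [threshold_config()] with a provenance note recording the
#'   calibration colony
#' @examples
#' calibrate_threshold(colony_parameters(5000, 1e6, 0.45, 1e-6))  # ~8.4 nM
#' @export
calibrate_threshold <- function(params) {
  stopifnot(inherits(params, "colony_parameters"))
  N <- to_nanomolar(colony_concentration_closed_form(params))$value
  threshold_config(N, note = sprintf(
    "calibrated: N_total at P=%g, n=%g/mL, R=%g mm, D=%g cm^2/s, Ws=%g um",
    params$P, params$n, params$R * 10, params$D, params$Ws * 1e4))
}

# N_total in nM as a function of radius R in mm, other parameters fixed
ntotal_nM_of_Rmm <- function(params, R_mm) {
  mol_cm3_to_nM(ntotal_mol_cm3(params$P, params$n, params$D, R_mm / 10,
                               params$Ws))
}

#' Minimum biofilm thickness that triggers quorum sensing
#'
#' Solves \eqn{N_{total}(R) = N_{threshold}} for the colony radius R by
#' bisection. \eqn{N_{total}} is strictly increasing in R (leading term
#' \eqn{\propto R^2}), so the root is unique whenever the bracket
#' straddles the threshold. Bisection is used deliberately: the function
#' is cheap and monotone, and bisection converges unconditionally.
#'
#' @param params a [colony_parameters()] object; its own `R` is ignored
#' @param threshold a [threshold_config()] or a number in nM
#' @param bracket_mm length-2 bracket `(R_lo, R_hi)` in mm; the default
#'   lower end is one cell width, the upper end 100 mm
#' @param tol_mm absolute half-width at which bisection stops
#' @return the root R_min in mm; attributes `iterations` and
#'   `residual_nM` record the solve
#' @examples
#' p <- colony_parameters(5000, 1e6, 0.45, 1e-6)
#' thr <- calibrate_threshold(p)
#' minimum_thickness(colony_parameters(5000, 1e6, 0.45, 3e-6), thr)  # ~0.78 mm
#' @export
minimum_thickness <- function(params, threshold,
                              bracket_mm = c(params$Ws * 10, 100),
                              tol_mm = 1e-9) {
  stopifnot(inherits(params, "colony_parameters"))
  threshold <- as_threshold(threshold)
  if (length(bracket_mm) != 2 || any(!is.finite(bracket_mm)) ||
      bracket_mm[1] <= 0 || bracket_mm[2] <= bracket_mm[1])
    stop("bracket_mm must be two increasing positive values (mm)",
         call. = FALSE)
  lo <- bracket_mm[1]; hi <- bracket_mm[2]
  f_lo <- ntotal_nM_of_Rmm(params, lo) - threshold$nM
  f_hi <- ntotal_nM_of_Rmm(params, hi) - threshold$nM
  if (f_lo >= 0 && f_hi >= 0)
    stop(bracket_error(sprintf(
      "bracket does not straddle the root: lower endpoint R = %g mm already reaches the threshold (N - thr = %g nM)",
      lo, f_lo)))
  if (f_lo < 0 && f_hi < 0)
    stop(bracket_error(sprintf(
      "bracket does not straddle the root: upper endpoint R = %g mm stays below the threshold (N - thr = %g nM)",
      hi, f_hi)))
  if (f_lo >= 0)  # f_lo >= 0 > f_hi cannot occur for a monotone field
    stop(bracket_error("lower endpoint above threshold while upper is below; N_total(R) is increasing, check inputs"))
  it <- 0L
  while ((hi - lo) / 2 > tol_mm && it < 200L) {
    mid <- (lo + hi) / 2
    if (ntotal_nM_of_Rmm(params, mid) - threshold$nM < 0) lo <- mid else hi <- mid
    it <- it + 1L
  }
  root <- (lo + hi) / 2
  structure(root, iterations = it,
            residual_nM = ntotal_nM_of_Rmm(params, root) - threshold$nM)
}

bracket_error <- function(msg) {
  errorCondition(msg, class = c("qs_bracket_error", "error", "condition"))
}

#' Single-parameter feasibility sweep
#'
#' Evaluates feasibility along a grid of one parameter (diffusion
#' coefficient `D` in cm^2/s, production rate `P` in molecules/cell/s,
#' cell density `n` in cells/mL, or colony radius `R` in mm), holding
#' the others fixed. For `D` and `P` sweeps, `r_min = TRUE` additionally
#' solves the minimum thickness at each grid point.
#'
#' @param params a [colony_parameters()] baseline
#' @param threshold a [threshold_config()] or number in nM
#' @param sweep_param one of `"D"`, `"P"`, `"n"`, `"R"`
#' @param grid strictly increasing positive values in the parameter's
#'   user-facing unit
#' @param r_min also solve [minimum_thickness()] per point (only for
#'   `"D"` and `"P"` sweeps)
#' @param bracket_mm bracket passed through to [minimum_thickness()]
#' @return a data frame of class `sweep_table` with columns
#'   `param, value, N_total_nM, feasible, R_min_mm` (R_min_mm is `NA`
#'   where not requested)
#' @examples
#' p <- colony_parameters(5000, 1e6, 0.5, 1e-6)
#' qs_sweep(p, calibrate_threshold(colony_parameters(5000, 1e6, 0.45, 1e-6)),
#'          "D", seq(1e-6, 5e-6, 1e-6), r_min = TRUE)
#' @export
qs_sweep <- function(params, threshold, sweep_param = c("D", "P", "n", "R"),
                     grid, r_min = FALSE,
                     bracket_mm = c(params$Ws * 10, 100)) {
  stopifnot(inherits(params, "colony_parameters"))
  sweep_param <- match.arg(sweep_param)
  threshold <- as_threshold(threshold)
  if (length(grid) == 0) stop("sweep grid must be non-empty", call. = FALSE)
  bad <- which(!is.finite(grid) | grid <= 0)
  if (length(bad))
    stop("invalid sweep grid value at index ", bad[1], ": ", grid[bad[1]],
         call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE))
    stop("sweep grid must be strictly increasing", call. = FALSE)
  if (r_min && !sweep_param %in% c("D", "P"))
    stop("r_min solving is supported for D and P sweeps only", call. = FALSE)

  rows <- lapply(grid, function(v) {
    p_i <- switch(sweep_param,
                  D = set_colony_field(params, "D", v),
                  P = set_colony_field(params, "P", v),
                  n = set_colony_field(params, "n", v),
                  R = set_colony_field(params, "R", v / 10))
    res <- assess_feasibility(p_i, threshold)
    rmin <- if (r_min)
      as.numeric(minimum_thickness(p_i, threshold, bracket_mm)) else NA_real_
    data.frame(param = sweep_param, value = v, N_total_nM = res$N_total_nM,
               feasible = res$feasible, R_min_mm = rmin,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Write a sweep table to CSV
#'
#' Writes the `param,value,N_total_nM,feasible,R_min_mm` table with a
#' leading `#` comment line recording the tool version and scenario
#' citation, and empty fields where R_min was not solved.
#'
#' @param tab a `sweep_table` from [qs_sweep()]
#' @param path output file path
#' @param citation free-text provenance written into the header comment
#' @return `path`, invisibly
#' @export
write_sweep_csv <- function(tab, path, citation = "") {
  stopifnot(inherits(tab, "sweep_table"))
  writeLines(csv_comment_header(citation), path)
  suppressWarnings(
    write.table(as.data.frame(tab), path, sep = ",", row.names = FALSE,
                col.names = TRUE, quote = FALSE, na = "", append = TRUE))
  invisible(path)
}

csv_comment_header <- function(citation = "") {
  ver <- as.character(utils::packageVersion("quorumsim"))
  if (nzchar(citation)) sprintf("# quorumsim %s | %s", ver, citation)
  else sprintf("# quorumsim %s", ver)
}
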