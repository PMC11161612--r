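# Steady-state reaction-diffusion solutions for autoinducer release.
#
# A single cell is a Gaussian point source of width Ws releasing P
# molecules/s into a medium with diffusion coefficient D; the
# steady-state field is N(r) = P/(2 pi D r) * phi(r / (sqrt(2) Ws)) with
# phi the error function. A colony of density n inside radius R is the
# continuum superposition of such sources; its centre concentration has
# a closed form whose independent check is direct quadrature of the
# superposition integral.

#' Error-function radial profile
#'
#' The monotone profile \eqn{\phi(x) = (2/\sqrt{\pi}) \int_0^x e^{-h^2} dh}
#' (the error function) that shapes the near-field of a Gaussian point
#' source; \eqn{\phi(0) = 0} and \eqn{\phi(x) \to 1} as \eqn{x \to \infty}.
#'
#' @param x dimensionless argument, finite and >= 0 (vectorized)
#' @return \eqn{\phi(x)} in `[0, 1)`
#' @examples
#' erf_profile(c(0, 1, 10))
#' @export
erf_profile <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("erf_profile(): x must be finite numeric", call. = FALSE)
  if (any(x < 0))
    stop("erf_profile(): x must be >= 0", call. = FALSE)
  2 * pnorm(x * sqrt(2)) - 1
}

# switch to the series limit below this multiple of Ws to keep the
# field continuous (and finite) through r = 0
.ORIGIN_SWITCH <- 1e-6

#' Steady-state concentration around a single cell
#'
#' Evaluates \eqn{N(r) = P/(2\pi D r)\,\phi(r/(\sqrt{2} W_s))} for a
#' single Gaussian source. Below a small-radius switch point
#' (`r < 1e-6 * Ws`) the continuous \eqn{r \to 0} limit
#' \eqn{P/(\sqrt{2}\,\pi^{3/2} D W_s)} is returned instead, so the field
#' is continuous and monotonically non-increasing on `[0, Inf)`. In the
#' far field (\eqn{r \gg W_s}) the profile saturates and
#' \eqn{N(r) \to P/(2\pi D r)}.
#'
#' @param r radial position in cm, >= 0 (vectorized)
#' @param P production rate, molecules/cell/s (> 0)
#' @param D diffusion coefficient, cm^2/s (> 0)
#' @param Ws cell width in cm (> 0)
#' @return a [qs_concentration()] in molecules/cm^3
#' @examples
#' single_cell_concentration(1e-2, P = 5000, D = 1e-6, Ws = 1e-4)
#' @export
single_cell_concentration <- function(r, P, D, Ws) {
  if (any(!is.finite(c(P, D, Ws))) || any(c(P, D, Ws) <= 0))
    stop("P, D, Ws must be finite and > 0", call. = FALSE)
  if (!is.numeric(r) || any(!is.finite(r)) || any(r < 0))
    stop("r must be finite and >= 0 (cm)", call. = FALSE)
  out <- numeric(length(r))
  near <- r < .ORIGIN_SWITCH * Ws
  out[near] <- single_cell_origin(P, D, Ws)
  rf <- r[!near]
  out[!near] <- P / (2 * pi * D * rf) * erf_profile(rf / (sqrt(2) * Ws))
  qs_concentration(out, "molecules_per_cm3")
}

#' Concentration at the centre of a single cell
#'
#' The \eqn{r \to 0} value of the single-cell field. Two prefactor
#' conventions circulate for this limit:
#' * `"series"` (default): \eqn{P/(\sqrt{2}\,\pi^{3/2} D W_s)}, obtained by
#'   substituting the small-argument expansion
#'   \eqn{\phi(x) \approx 2x/\sqrt{\pi}} into the radial solution; this is
#'   the unique value that makes the field continuous at the origin and is
#'   what [single_cell_concentration()] uses.
#' * `"half"`: \eqn{P/((2\pi)^{3/2} D W_s)}, an alternative Taylor-expansion
#'   prefactor sometimes quoted for the same limit; it is exactly half the
#'   series value and is exposed here for comparison only.
#'
#' @param P,D,Ws as in [single_cell_concentration()]
#' @param form `"series"` (continuity-consistent, default) or `"half"`
#' @return concentration at the origin, molecules/cm^3 (bare numeric)
#' @export
single_cell_origin <- function(P, D, Ws, form = c("series", "half")) {
  form <- match.arg(form)
  if (any(!is.finite(c(P, D, Ws))) || any(c(P, D, Ws) <= 0))
    stop("P, D, Ws must be finite and > 0", call. = FALSE)
  switch(form,
         series = P / (sqrt(2) * pi^1.5 * D * Ws),
         half   = P / ((2 * pi)^1.5 * D * Ws))
}

# bracket of the closed form, as a function of R and Ws (both cm).
# The last term is kept exactly as the model states it, exponential
# inside the square root with exponent (R/(2 Ws))^2; it underflows to 0
# for every realistic colony (R/Ws >~ 30) and only matters near R ~ Ws.
closed_form_bracket <- function(R, Ws) {
  1 - (Ws^2 / R^2) * erf_profile(R / (sqrt(2) * Ws)) +
    sqrt((2 * Ws / (pi * R)) * exp(-(R / (2 * Ws))^2))
}

# numeric core: centre concentration in molecules/cm^3, vectorized over
# n and R so the growth coupling can evaluate whole trajectories at once.
# n = 0 rows are defined as 0.
ntotal_mol_cm3 <- function(P, n, D, R, Ws) {
  out <- P * n * R^2 / (2 * D) * closed_form_bracket(R, Ws)
  out[n == 0 | R == 0] <- 0
  out
}

#' Centre concentration of an n-cell colony (closed form)
#'
#' Total steady-state autoinducer concentration at the centre of a
#' spherical colony of radius R with uniform cell density n, each cell
#' producing at rate P:
#' \deqn{N_{total} = \frac{P n R^2}{2 D}\left[1
#'   - \frac{W_s^2}{R^2}\,\phi\!\left(\frac{R}{\sqrt{2} W_s}\right)
#'   + \sqrt{\frac{2 W_s}{\pi R}\, e^{-(R/(2 W_s))^2}}\right]}
#' The bracket tends to 1 as \eqn{W_s/R \to 0}, so the leading behaviour
#' is \eqn{P n R^2 / (2D)}: linear in P and n, quadratic in R, inverse in
#' D. [colony_concentration_quadrature()] evaluates the underlying
#' superposition integral directly and serves as an independent check.
#'
#' @param params a [colony_parameters()] object
#' @return a [qs_concentration()] in molecules/cm^3
#' @examples
#' p <- colony_parameters(5000, 1e6, 0.45, 1e-6)
#' to_nanomolar(colony_concentration_closed_form(p))  # ~ 8.4 nM
#' @export
colony_concentration_closed_form <- function(params) {
  stopifnot(inherits(params, "colony_parameters"))
  if (params$R / params$Ws < 10)
    warning("R/Ws = ", format(params$R / params$Ws, digits = 3),
            " < 10: the closed-form bracket is a wide-colony approximation",
            call. = FALSE)
  br <- closed_form_bracket(params$R, params$Ws)
  if (br <= 0)
    stop("closed-form bracket evaluated <= 0; parameters outside model validity",
         call. = FALSE)
  qs_concentration(params$P * params$n * params$R^2 / (2 * params$D) * br,
                   "molecules_per_cm3")
}

#' Centre concentration of an n-cell colony (quadrature)
#'
#' Direct adaptive quadrature of the continuum superposition integral
#' \deqn{N_{total} = \frac{P n}{D} \int_0^R r\,
#'   \phi\!\left(\frac{r}{\sqrt{2} W_s}\right) dr,}
#' the spherical-shell sum of single-cell fields evaluated at the colony
#' centre. Independent of the Taylor-series closed form, this is the
#' reference the closed form is validated against.
#'
#' @param params a [colony_parameters()] object (R = 0 permitted here and
#'   returns 0, the empty-colony limit)
#' @param rel_tol relative tolerance of the adaptive quadrature
#' @return a [qs_concentration()] in molecules/cm^3, with the
#'   quadrature's absolute error estimate attached as attribute
#'   `"abs_error"`
#' @export
colony_concentration_quadrature <- function(params, rel_tol = 1e-10) {
  stopifnot(inherits(params, "colony_parameters"))
  if (params$R == 0) return(qs_concentration(0, "molecules_per_cm3"))
  Ws <- params$Ws
  q <- tryCatch(
    stats::integrate(function(r) r * erf_profile(r / (sqrt(2) * Ws)),
                     lower = 0, upper = params$R,
                     rel.tol = rel_tol, subdivisions = 500L),
    error = function(e)
      stop("quadrature failed for R = ", params$R, " cm, Ws = ", Ws,
           " cm: ", conditionMessage(e), call. = FALSE))
  if (q$message != "OK")
    stop("quadrature did not converge: ", q$message,
         " (estimated abs error ", format(q$abs.error), ")", call. = FALSE)
  scale <- params$P * params$n / params$D
  out <- qs_concentration(scale * q$value, "molecules_per_cm3")
  attr(out, "abs_error") <- scale * q$abs.error
  out
}
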