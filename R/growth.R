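# Monod chemostat dynamics. The state is (theta, beta): substrate in
# gCOD/mL and cell density in cells/mL. Growth follows the Monod law;
# substrate is consumed at mu * beta / gamma so that in batch culture
# (alpha = 0) with no decay the yield-weighted total beta + gamma*theta
# is an exact invariant of the flow.

#' Monod specific growth rate
#'
#' \eqn{\mu(\theta) = \mu_{max}\,\theta / (K_s + \theta)}: zero at zero
#' substrate, \eqn{\mu_{max}/2} at the half-saturation constant, and
#' saturating below \eqn{\mu_{max}}.
#'
#' @param theta substrate concentration (>= 0, vectorized), gCOD/mL
#' @param mu_max maximum specific growth rate, 1/h
#' @param Ks half-saturation constant, same units as `theta`
#' @return growth rate in 1/h, in `[0, mu_max)`
#' @examples
#' monod_rate(55.2e-4, mu_max = 0.3, Ks = 55.2e-4)  # mu_max / 2
#' @export
monod_rate <- function(theta, mu_max, Ks) {
  if (!is.numeric(theta) || any(!is.finite(theta)))
    stop("monod_rate(): theta must be finite numeric", call. = FALSE)
  if (any(theta < 0))
    stop("monod_rate(): theta must be >= 0", call. = FALSE)
  if (Ks <= 0 || mu_max < 0)
    stop("monod_rate(): need Ks > 0 and mu_max >= 0", call. = FALSE)
  mu_max * theta / (Ks + theta)
}

integration_error <- function(msg) {
  errorCondition(msg, class = c("qs_integration_error", "error", "condition"))
}

#' Simulate chemostat growth
#'
#' Integrates
#' \deqn{d\theta/dt = (\theta_{in} - \theta)\,\alpha - \mu(\theta)\,\beta/\gamma}
#' \deqn{d\beta/dt = (\mu(\theta) - \alpha - k_{dec})\,\beta}
#' from \eqn{(\theta_0, \beta_0)} over `[0, t_end]` with a stiff-capable
#' adaptive integrator (deSolve's lsoda, rtol 1e-8). The integrator state
#' is never clipped; tiny negative substrate excursions are clamped to
#' zero only in the reported output (and inside the Monod rate
#' evaluation, where a negative argument would be unphysical).
#'
#' Useful limits: with `beta0 = 0` the substrate relaxes as
#' \eqn{\theta_{in} + (\theta_0 - \theta_{in}) e^{-\alpha t}}; with
#' `mu_max = 0` the cells wash out as
#' \eqn{\beta_0 e^{-(\alpha + k_{dec}) t}}; and whenever
#' `mu_max < alpha + k_dec` the culture washes out regardless of
#' substrate.
#'
#' @param gp a [growth_parameters()] object
#' @return a data frame of class `growth_trajectory` with columns
#'   `time_h`, `substrate`, `cells`, reported every `dt_report` hours
#' @examples
#' traj <- simulate_growth(growth_parameters())
#' traj[which.max(traj$cells), ]  # peak of the growth curve
#' @export
simulate_growth <- function(gp) {
  stopifnot(inherits(gp, "growth_parameters"))
  times <- seq(0, gp$t_end, by = gp$dt_report)
  if (times[length(times)] < gp$t_end) times <- c(times, gp$t_end)
  deriv <- function(t, y, parms) {
    th <- y[1]; b <- y[2]
    mu <- monod_rate(max(th, 0), gp$mu_max, gp$Ks)
    list(c((gp$theta_in - th) * gp$alpha - mu * b / gp$gamma,
           (mu - gp$alpha - gp$k_dec) * b))
  }
  atol <- max(1e-12 * max(gp$theta_in, gp$theta0, gp$beta0), 1e-16)
  sol <- tryCatch(
    deSolve::ode(y = c(theta = gp$theta0, beta = gp$beta0), times = times,
                 func = deriv, parms = NULL, method = "lsoda",
                 rtol = 1e-8, atol = atol),
    error = function(e) stop(integration_error(
      paste0("growth ODE integration failed: ", conditionMessage(e)))))
  sol <- as.data.frame(sol)
  if (anyNA(sol) || nrow(sol) < length(times)) {
    ok <- which(stats::complete.cases(sol))
    last_t <- if (length(ok)) sol$time[max(ok)] else NA_real_
    stop(integration_error(paste0(
      "growth ODE integration failed; last successful time = ", last_t, " h")))
  }
  out <- data.frame(time_h = sol$time,
                    substrate = pmax(sol$theta, 0),
                    cells = pmax(sol$beta, 0))
  attr(out, "growth_parameters") <- gp
  class(out) <- c("growth_trajectory", "data.frame")
  out
}

#' Normalize a series to [0, 1] by its maximum
#'
#' Divides by the series maximum so that the largest entry is exactly 1;
#' an all-zero series is returned unchanged (the degenerate no-signal
#' case). Used to overlay cell-density and autoinducer curves on one
#' comparative axis.
#'
#' @param values finite numeric vector with a positive maximum (or all
#'   zeros)
#' @return the scaled vector
#' @examples
#' normalize_series(c(2, 4, 8))
#' @export
normalize_series <- function(values) {
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("normalize_series(): values must be finite numeric", call. = FALSE)
  m <- max(values)
  if (m == 0 && all(values == 0)) return(values)
  if (m <= 0)
    stop("normalize_series(): series maximum must be positive", call. = FALSE)
  values / m
}
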