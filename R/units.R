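# Unit plumbing: concentrations are tagged with their unit so that a
# molecules-per-volume value can never be silently read as a molarity.

#' Avogadro's number (molecules per mole, 2019 SI exact value)
#' @export
AVOGADRO <- 6.02214076e23

#' Tagged concentration value
#'
#' A numeric vector tagged with its concentration unit, either
#' `"molecules_per_cm3"` (the native output of the diffusion model) or
#' `"nM"` (the unit thresholds are quoted in). Conversions are performed
#' by [to_nanomolar()] and [to_molecules_per_cm3()]; operating on the
#' wrong unit raises an error rather than returning a wrong number.
#'
#' @param value numeric vector, all entries >= 0
#' @param unit `"molecules_per_cm3"` or `"nM"`
#' @return an object of class `qs_concentration`
#' @examples
#' qs_concentration(6.02214076e11, "molecules_per_cm3")
#' @export
qs_concentration <- function(value, unit = c("molecules_per_cm3", "nM")) {
  unit <- match.arg(unit)
  if (!is.numeric(value) || any(!is.finite(value)))
    stop("concentration value must be finite numeric", call. = FALSE)
  if (any(value < 0))
    stop("concentration value must be >= 0", call. = FALSE)
  structure(list(value = as.numeric(value), unit = unit),
            class = "qs_concentration")
}

#' @export
print.qs_concentration <- function(x, ...) {
  cat(format(x$value, digits = 7), x$unit, "\n")
  invisible(x)
}

#' @rdname qs_concentration
#' @param x a `qs_concentration` object
#' @export
concentration_value <- function(x) {
  stopifnot(inherits(x, "qs_concentration"))
  x$value
}

# 1 nM = 1e-9 mol/L = 1e-9 * AVOGADRO molecules per 1000 cm^3
.MOL_CM3_PER_NM <- AVOGADRO * 1e-9 / 1000

#' Convert between molecules per cm^3 and nanomolar
#'
#' `to_nanomolar()` converts a concentration tagged
#' `molecules_per_cm3` into nM via Avogadro's number
#' (nM = molecules/cm^3 * 1000 / N_A * 1e9); `to_molecules_per_cm3()` is
#' its exact inverse. Round trips are exact to floating-point rounding
#' (well inside 1e-12 relative).
#'
#' @param x a [qs_concentration()] in the expected input unit
#' @return a [qs_concentration()] in the target unit
#' @examples
#' to_nanomolar(qs_concentration(6.02214076e11, "molecules_per_cm3"))  # 1 nM
#' @export
to_nanomolar <- function(x) {
  if (!inherits(x, "qs_concentration"))
    stop("to_nanomolar() expects a qs_concentration; tag the unit first",
         call. = FALSE)
  if (x$unit != "molecules_per_cm3")
    stop("unit error: to_nanomolar() expects molecules_per_cm3, got ", x$unit,
         call. = FALSE)
  qs_concentration(x$value / .MOL_CM3_PER_NM, "nM")
}

#' @rdname to_nanomolar
#' @export
to_molecules_per_cm3 <- function(x) {
  if (!inherits(x, "qs_concentration"))
    stop("to_molecules_per_cm3() expects a qs_concentration", call. = FALSE)
  if (x$unit != "nM")
    stop("unit error: to_molecules_per_cm3() expects nM, got ", x$unit,
         call. = FALSE)
  qs_concentration(x$value * .MOL_CM3_PER_NM, "molecules_per_cm3")
}

# internal numeric fast path used by the feasibility layer
mol_cm3_to_nM <- function(v) v / .MOL_CM3_PER_NM
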