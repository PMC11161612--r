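# Shared fixtures and independent oracles for the test suite.

# the anchor colony used throughout: P = 5000 molecules/cell/s,
# n = 1e6 cells/mL, R = 0.45 mm, D = 1e-6 cm^2/s, Ws = 1 um
ref_colony <- function(radius_mm = 0.45, diffusion = 1e-6)
  colony_parameters(5000, 1e6, radius_mm, diffusion, 1)

# error function by direct quadrature of its defining integral —
# independent of the pnorm identity used in the implementation
erf_by_quadrature <- function(x)
  vapply(x, function(xi)
    2 / sqrt(pi) * stats::integrate(function(h) exp(-h^2), 0, xi,
                                    rel.tol = 1e-12)$value,
    numeric(1))

# colony centre concentration by brute-force double quadrature: the
# radial superposition integral with the error function itself computed
# by quadrature (no shared code path with the package implementation)
colony_by_double_quadrature <- function(params) {
  Ws <- params$Ws
  params$P * params$n / params$D *
    stats::integrate(function(r) r * erf_by_quadrature(r / (sqrt(2) * Ws)),
                     0, params$R, rel.tol = 1e-9)$value
}

nM_value <- function(conc) to_nanomolar(conc)$value

# path of the installed CLI entry script
cli_script <- function() system.file("cli", "quorumsim.R", package = "quorumsim")

run_cli_subprocess <- function(args) {
  out <- suppressWarnings(system2(file.path(R.home("bin"), "Rscript"),
                                  c(cli_script(), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
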