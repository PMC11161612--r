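test_that("error-function profile matches its defining integral", {
  # independent quadrature of (2/sqrt(pi)) int_0^x exp(-h^2) dh
  xs <- c(0.1, 0.5, 1, 2, 3)
  expect_equal(erf_profile(xs), erf_by_quadrature(xs), tolerance = 1e-10)
  # frozen value from the quadrature oracle
  expect_equal(erf_profile(1), 0.8427007929, tolerance = 1e-9)

  expect_identical(erf_profile(0), 0)
  expect_equal(erf_profile(10), 1, tolerance = 1e-12)
  expect_true(all(diff(erf_profile(seq(0, 4, 0.05))) > 0))  # monotone

  expect_error(erf_profile(-0.1), ">= 0")
  expect_error(erf_profile(Inf), "finite")
  expect_error(erf_profile(NA_real_), "finite")
})

test_that("single-cell field matches direct evaluation and its far-field limit", {
  P <- 5000; D <- 1e-6; Ws <- 1e-4
  # at r = 1e-2 cm the profile is saturated, so N ~ P/(2 pi D r)
  v <- concentration_value(single_cell_concentration(1e-2, P, D, Ws))
  expect_equal(v, 7.957747e10, tolerance = 1e-6)
  expect_equal(v, P / (2 * pi * D * 1e-2), tolerance = 1e-12)

  # far-field invariant: N(r) * 2 pi D r / P -> 1 as r/Ws grows
  r_far <- Ws * c(1, 3, 100)
  scaled <- concentration_value(single_cell_concentration(r_far, P, D, Ws)) *
    2 * pi * D * r_far / P
  expect_true(all(diff(scaled) >= 0))
  expect_gt(scaled[2], scaled[1])
  expect_equal(scaled[3], 1, tolerance = 1e-12)

  # monotonically non-increasing in r, from the origin outwards
  # (grid starts at 1e-4 Ws, where the r^2/3 decrease of the profile is
  # well above floating-point noise in the error function)
  rs <- c(0, Ws * 10^seq(-4, 2, 0.25))
  Ns <- concentration_value(single_cell_concentration(rs, P, D, Ws))
  expect_true(all(diff(Ns) <= 0))
})

test_that("single-cell field is continuous across the small-radius switch", {
  P <- 5000; D <- 1e-6; Ws <- 1e-4
  r_switch <- 1e-6 * Ws
  below <- concentration_value(single_cell_concentration(r_switch * (1 - 1e-9), P, D, Ws))
  above <- concentration_value(single_cell_concentration(r_switch * (1 + 1e-9), P, D, Ws))
  expect_equal(below, above, tolerance = 1e-9)
  # and the origin value equals the series limit
  expect_equal(concentration_value(single_cell_concentration(0, P, D, Ws)),
               P / (sqrt(2) * pi^1.5 * D * Ws), tolerance = 1e-15)
})

test_that("the two origin-limit conventions differ by exactly a factor of two", {
  s <- single_cell_origin(5000, 1e-6, 1e-4, form = "series")
  h <- single_cell_origin(5000, 1e-6, 1e-4, form = "half")
  expect_equal(s / h, 2, tolerance = 1e-14)
})

test_that("closed-form colony concentration matches the quadrature oracle and scales linearly", {
  p <- ref_colony()
  cf <- concentration_value(colony_concentration_closed_form(p))
  # independent double-quadrature oracle (no shared code with the package)
  expect_equal(cf, colony_by_double_quadrature(p), tolerance = 1e-6)
  # and the packaged adaptive-quadrature evaluation of the same integral
  expect_equal(cf, concentration_value(colony_concentration_quadrature(p)),
               tolerance = 1e-6)
  # value on the scale of the leading term P n R^2 / (2D): ~5.06e12 /cm^3 ~ 8.4 nM
  expect_equal(cf, 5.0625e12, tolerance = 1e-3)
  expect_equal(nM_value(colony_concentration_closed_form(p)), 8.406,
               tolerance = 1e-3)

  # linearity: doubling P doubles, doubling D halves
  p2 <- colony_parameters(10000, 1e6, 0.45, 1e-6)
  expect_equal(concentration_value(colony_concentration_closed_form(p2)),
               2 * cf, tolerance = 1e-14)
  pD <- ref_colony(diffusion = 2e-6)
  expect_equal(concentration_value(colony_concentration_closed_form(pD)),
               cf / 2, tolerance = 1e-14)

  # Ws/R -> 0: bracket -> 1 so the leading term dominates
  p_thin <- colony_parameters(5000, 1e6, 100, 1e-6, cell_width_um = 0.01)
  expect_equal(concentration_value(colony_concentration_closed_form(p_thin)),
               5000 * 1e6 * 10^2 / (2 * 1e-6), tolerance = 1e-9)

  # narrow colonies trigger the approximation warning
  expect_warning(
    colony_concentration_closed_form(colony_parameters(5000, 1e6, 5e-3, 1e-6, 1)),
    "R/Ws")
})

test_that("quadrature evaluation handles limits and scales as R^2", {
  p <- ref_colony()
  p0 <- p; p0$R <- 0
  expect_equal(concentration_value(colony_concentration_quadrature(p0)), 0)

  # for R >> Ws the integral grows as R^2
  p2 <- ref_colony(radius_mm = 0.9)
  ratio <- concentration_value(colony_concentration_quadrature(p2)) /
    concentration_value(colony_concentration_quadrature(p))
  expect_equal(ratio, 4, tolerance = 1e-3)
})

test_that("closed form and quadrature agree across random parameter sets", {
  set.seed(42)
  n_sets <- 100
  ratio_RW <- exp(runif(n_sets, log(50), log(5000)))
  for (i in seq_len(n_sets)) {
    Ws_um <- exp(runif(1, log(0.5), log(5)))
    p <- colony_parameters(
      production_rate = exp(runif(1, log(500), log(50000))),
      cell_density = exp(runif(1, log(1e4), log(1e8))),
      radius_mm = ratio_RW[i] * Ws_um * 1e-3,
      diffusion_coefficient = exp(runif(1, log(1e-7), log(1e-5))),
      cell_width_um = Ws_um)
    cf <- suppressWarnings(concentration_value(colony_concentration_closed_form(p)))
    qd <- concentration_value(colony_concentration_quadrature(p))
    rel <- abs(cf - qd) / qd
    expect_lt(rel, 1e-2)
    if (ratio_RW[i] > 300) expect_lt(rel, 1e-3)
  }
})
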