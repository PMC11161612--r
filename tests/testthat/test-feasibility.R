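test_that("feasibility verdicts follow the non-strict threshold comparison", {
  p <- ref_colony()
  expect_true(assess_feasibility(p, 1e-9)$feasible)
  expect_false(assess_feasibility(p, 1e9)$feasible)

  # boundary: a colony at exactly its calibrated threshold is sensing
  thr <- calibrate_threshold(p)
  res <- assess_feasibility(p, thr)
  expect_true(res$feasible)
  expect_equal(res$N_total_nM, res$threshold_nM)
})

test_that("threshold calibration recovers the implied ~8.4 nM anchor and is linear in P", {
  thr <- calibrate_threshold(ref_colony())
  # cross-checked against the independent double-quadrature oracle
  oracle_nM <- colony_by_double_quadrature(ref_colony()) *
    1e12 / 6.02214076e23
  expect_equal(thr$nM, oracle_nM, tolerance = 1e-6)
  expect_equal(thr$nM, 8.406438, tolerance = 1e-6)

  thr2 <- calibrate_threshold(colony_parameters(10000, 1e6, 0.45, 1e-6))
  expect_equal(thr2$nM, 2 * thr$nM, tolerance = 1e-14)
})

test_that("minimum thickness solves the calibrated table and verifies its roots", {
  thr <- calibrate_threshold(ref_colony())
  # model-exact roots at D = 1..5e-6 cm^2/s under the 0.45 mm anchor
  expected <- c(0.45, 0.6363953, 0.7794216, 0.8999983, 1.0062286)
  for (i in 1:5) {
    pd <- ref_colony(diffusion = i * 1e-6)
    rmin <- minimum_thickness(pd, thr)
    expect_equal(as.numeric(rmin), expected[i], tolerance = 1e-5)
    # root verification: N_total(R_min) is at threshold
    N_at_root <- nM_value(colony_concentration_closed_form(
      colony_parameters(5000, 1e6, as.numeric(rmin), i * 1e-6)))
    expect_equal(N_at_root, thr$nM, tolerance = 1e-6)
  }
  # agreement with an off-the-shelf root finder on the same monotone map
  pd <- ref_colony(diffusion = 3e-6)
  u <- stats::uniroot(function(Rmm)
    nM_value(colony_concentration_closed_form(
      colony_parameters(5000, 1e6, Rmm, 3e-6))) - thr$nM,
    c(0.01, 10), tol = 1e-12)$root
  expect_equal(as.numeric(minimum_thickness(pd, thr)), u, tolerance = 1e-7)
})

test_that("bracket failures are reported with the failing side", {
  p <- ref_colony()
  thr <- calibrate_threshold(p)
  # upper endpoint below threshold
  expect_error(minimum_thickness(p, thr, bracket_mm = c(0.001, 0.1)),
               "upper endpoint", class = "qs_bracket_error")
  # lower endpoint already above threshold (threshold near zero)
  expect_error(minimum_thickness(p, threshold_config(1e-12),
                                 bracket_mm = c(0.2, 10)),
               "lower endpoint", class = "qs_bracket_error")
  expect_error(minimum_thickness(p, thr, bracket_mm = c(5, 1)), "increasing")
})

test_that("sweeps reproduce single assessments, order their grid, and stay monotone", {
  p <- colony_parameters(5000, 1e6, 0.5, 1e-6)
  thr <- calibrate_threshold(ref_colony())

  one <- qs_sweep(p, thr, "D", 1e-6)
  ref <- assess_feasibility(p, thr)
  expect_equal(one$N_total_nM, ref$N_total_nM)
  expect_equal(one$feasible, ref$feasible)

  tab <- qs_sweep(p, thr, "D", seq(1e-6, 1e-5, 1e-6))
  expect_equal(nrow(tab), 10)
  expect_true(all(diff(tab$value) > 0))
  # N decreasing in D => feasible flags monotone (TRUE then FALSE)
  expect_true(all(diff(tab$N_total_nM) < 0))
  expect_true(all(diff(as.integer(tab$feasible)) <= 0))

  # grid validation names the offending index
  expect_error(qs_sweep(p, thr, "D", c(1e-6, -1e-6)), "index 2")
  expect_error(qs_sweep(p, thr, "D", numeric(0)), "non-empty")
  expect_error(qs_sweep(p, thr, "D", c(2e-6, 1e-6)), "strictly increasing")
  expect_error(qs_sweep(p, thr, "n", c(1e5, 1e6), r_min = TRUE), "D and P")
})

test_that("minimum-thickness column of a D sweep matches the direct solves", {
  thr <- calibrate_threshold(ref_colony())
  tab <- qs_sweep(ref_colony(), thr, "D", seq(1e-6, 5e-6, 1e-6), r_min = TRUE)
  expect_equal(tab$R_min_mm, c(0.45, 0.6363953, 0.7794216, 0.8999983, 1.0062286),
               tolerance = 1e-5)
})

test_that("concentration depends on P and n only through their product", {
  thr <- calibrate_threshold(ref_colony())
  pairs <- list(c(500, 1e7), c(5000, 1e6), c(50000, 1e5), c(1.7e3, 5e6 / 1.7))
  Ns <- vapply(pairs, function(pr)
    assess_feasibility(colony_parameters(pr[1], pr[2], 0.45, 1e-6), thr)$N_total_nM,
    numeric(1))
  expect_equal(max(Ns) / min(Ns), 1, tolerance = 1e-14)

  # sweeps over P at fixed n and over n at fixed P with equal products agree
  sweep_P <- qs_sweep(colony_parameters(1, 1e6, 0.45, 1e-6), thr, "P",
                      c(500, 5000, 50000))
  sweep_n <- qs_sweep(colony_parameters(5000, 1, 0.45, 1e-6), thr, "n",
                      c(1e5, 1e6, 1e7))
  expect_equal(sweep_P$N_total_nM, sweep_n$N_total_nM, tolerance = 1e-14)
})

test_that("raising production or density never breaks feasibility", {
  thr <- calibrate_threshold(ref_colony())
  grid_P <- c(500, 5000, 50000)
  tab <- qs_sweep(colony_parameters(5000, 1e6, 0.45, 1e-6), thr, "P", grid_P)
  expect_true(all(diff(as.integer(tab$feasible)) >= 0))
  tab_n <- qs_sweep(colony_parameters(5000, 1e6, 0.45, 1e-6), thr, "n",
                    c(1e5, 1e6, 1e7))
  expect_true(all(diff(as.integer(tab_n$feasible)) >= 0))
})

test_that("sweep CSV carries header comment and empty missing R_min fields", {
  thr <- calibrate_threshold(ref_colony())
  tab <- qs_sweep(ref_colony(), thr, "D", c(1e-6, 2e-6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweep_csv(tab, path, citation = "unit test")
  lines <- readLines(path)
  expect_match(lines[1], "^# quorumsim .* \\| unit test$")
  expect_identical(lines[2], "param,value,N_total_nM,feasible,R_min_mm")
  expect_match(lines[3], ",$")  # R_min not requested -> empty trailing field
  back <- read.csv(path, comment.char = "#")
  expect_equal(back$N_total_nM, tab$N_total_nM, tolerance = 1e-12)
})
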