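test_that("normalization divides deflection by the pipette radius and removes the baseline", {
  tr <- aspiration_trace(time = 0:4 / 15, pressure = c(0, 0.1, 0.2, 0.3, 0.4),
                        deflection = c(0, 0.005, 0.01, 0.015, 0.02), r_i = 0.05)
  cv <- normalize_trace(tr)
  expect_equal(cv$lbar, c(0, 0.1, 0.2, 0.3, 0.4))
  expect_equal(cv$pressure, tr$pressure)

  # baseline offsets are subtracted so curves start at (0, 0)
  tr2 <- aspiration_trace(time = 0:4 / 15, pressure = c(0.02, 0.12, 0.22, 0.32, 0.42),
                         deflection = c(0.001, 0.006, 0.011, 0.016, 0.021), r_i = 0.05)
  cv2 <- normalize_trace(tr2)
  expect_equal(cv2$lbar[1L], 0)
  expect_equal(cv2$pressure[1L], 0)
  expect_equal(cv2$lbar, cv$lbar, tolerance = 1e-12)

  # element-wise oracle on randomized traces
  set.seed(42)
  for (i in 1:5) {
    d <- cumsum(abs(rnorm(20, 1e-3, 5e-4)))
    r_i <- runif(1, 0.02, 0.08)
    tr3 <- aspiration_trace(time = seq_len(20) / 15, pressure = seq(0, 1, length.out = 20),
                            deflection = d, r_i = r_i)
    expect_equal(normalize_trace(tr3)$lbar, (d - d[1L]) / r_i, tolerance = 1e-12)
  }
})

test_that("degenerate and non-monotone curves are flagged", {
  flat <- aspiration_trace(time = 0:4 / 15, pressure = seq(0, 0.4, 0.1),
                           deflection = rep(0.003, 5), r_i = 0.05)
  expect_true(normalize_trace(flat)$degenerate)

  jitter <- aspiration_trace(time = 0:5 / 15, pressure = seq(0, 0.5, 0.1),
                             deflection = c(0, 0.004, 0.002, 0.008, 0.012, 0.02),
                             r_i = 0.05)
  expect_true(normalize_trace(jitter)$nonmonotone)
})

test_that("trace validation rejects bad geometry and short traces", {
  expect_error(aspiration_trace(0:4, 0:4 / 10, 0:4 / 100, r_i = -1),
               class = "pamech_invalid_geometry")
  expect_error(aspiration_trace(0:2, c(0, 1, 2) / 10, c(0, 1, 2) / 100, r_i = 0.05),
               class = "pamech_insufficient_data")
})

test_that("SED of a linear curve is the triangle area", {
  # Dp = 10 * lbar: area to 0.4 is 0.5 * 0.4 * 4 = 0.8 kJ/m^3
  cv <- load_deflection_curve(seq(0, 0.5, 0.05), 10 * seq(0, 0.5, 0.05))
  expect_equal(compute_sed(cv, 0.4), 0.8, tolerance = 1e-12)
  expect_equal(compute_sed(cv, 0.2), 0.2, tolerance = 1e-12)
})

test_that("SED matches a dense-quadrature oracle on random piecewise-linear curves", {
  set.seed(7)
  for (i in 1:6) {
    lb <- sort(runif(12, 0, 0.6))
    lb <- c(0, lb[lb > 1e-3])
    pr <- c(0, cumsum(runif(length(lb) - 1L, 0, 0.4)))
    cv <- load_deflection_curve(lb, pr)
    lbar_max <- runif(1, 0.1, 0.9 * max(lb))
    # oracle: dense composite quadrature on the same linear interpolant,
    # with the interpolation knots included so the rule is exact
    grid <- sort(unique(c(seq(0, lbar_max, length.out = 1e5),
                          lb[lb < lbar_max], lbar_max)))
    py <- approx(lb, pr, xout = grid)$y
    oracle <- sum(diff(grid) * (py[-1] + py[-length(py)]) / 2)
    expect_equal(compute_sed(cv, lbar_max), oracle, tolerance = 1e-10)
  }
})

test_that("SED range errors name the shortfall and additivity holds", {
  cv <- load_deflection_curve(seq(0, 0.3, 0.05), seq(0, 0.6, 0.1))
  expect_error(compute_sed(cv, 0.4), class = "pamech_range_exceeded")
  expect_error(compute_sed(cv, 0.4), regexp = "short of")

  set.seed(11)
  for (i in 1:5) {
    lb <- c(0, sort(runif(15, 0, 0.5)), 0.55)
    pr <- cumsum(c(0, abs(rnorm(length(lb) - 1L, 0.05, 0.02))))
    cv <- load_deflection_curve(lb, pr)
    lhs <- compute_sed(cv, 0.4)
    mid <- compute_sed(cv, 0.2)
    # trapezoid of the interpolant over [0.2, 0.4]
    grid <- c(0.2, lb[lb > 0.2 & lb < 0.4], 0.4)
    py <- approx(lb, pr, xout = grid)$y
    upper <- sum(diff(grid) * (py[-1] + py[-length(py)]) / 2)
    expect_equal(lhs, mid + upper, tolerance = 1e-12)
  }
})

test_that("SED and slope scale linearly with pressure; zero curve gives zero", {
  cv <- load_deflection_curve(seq(0, 0.5, 0.025), seq(0, 1, 0.05)^1.3)
  for (c_scale in c(0.5, 3, 10)) {
    cv2 <- load_deflection_curve(cv$lbar, cv$pressure * c_scale)
    expect_equal(compute_sed(cv2, 0.4), c_scale * compute_sed(cv, 0.4))
    expect_equal(fit_trend(cv2, 1)$coefficients[2L],
                 c_scale * fit_trend(cv, 1)$coefficients[2L])
  }
  zero <- load_deflection_curve(seq(0, 0.5, 0.05), rep(0, 11))
  expect_identical(compute_sed(zero, 0.4), 0)

  # strictly increasing in lbar_max for positive-pressure curves
  pos <- load_deflection_curve(seq(0, 0.5, 0.05), 0.2 + seq(0, 1, 0.1))
  seds <- vapply(c(0.1, 0.2, 0.3, 0.4, 0.5), compute_sed, numeric(1), curve = pos)
  expect_true(all(diff(seds) > 0))
})

test_that("trend fits recover polynomials and respect nesting", {
  cv <- normalize_trace(linear_trace())
  expect_equal(fit_trend(cv, 1)$r2, 1.0, tolerance = 1e-12)

  set.seed(3)
  for (i in 1:5) {
    lb <- seq(0, 0.4, 0.02)
    pr <- 2 * lb + 3 * lb^2 + rnorm(length(lb), 0, 0.01)
    cv <- load_deflection_curve(lb, pr)
    r1 <- fit_trend(cv, 1)$r2
    r2 <- fit_trend(cv, 2)$r2
    expect_gte(r2, r1)  # nested least squares
    expect_true(r1 >= 0 && r2 <= 1)
  }

  short <- load_deflection_curve(c(0, 0.1, 0.2), c(0, 1, 2))
  expect_error(fit_trend(short, 2), class = "pamech_insufficient_data")
})

test_that("trace files round-trip through the delimited-text format", {
  tr <- linear_trace(specimen = "h7", region = "LV", group = "mutant")
  for (ext in c("csv", "tsv")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_trace(tr, path)
    back <- read_trace(path)
    expect_equal(back$deflection, tr$deflection, tolerance = 1e-12)
    expect_equal(back$pressure, tr$pressure, tolerance = 1e-12)
    expect_equal(back$r_i, tr$r_i)
    expect_identical(back$specimen, "h7")
    expect_identical(back$region, "LV")
    expect_identical(back$group, "mutant")
  }
})

test_that("per-test summaries populate the standard metric columns", {
  s <- sed_summary(linear_trace(slope = 0.025, p_max = 1.2))
  # lbar = 0.5 * pressure, so pressure = 2 * lbar: sed04 = 0.5*0.4*0.8
  expect_equal(s$slope, 2, tolerance = 1e-9)
  expect_equal(s$sed_04, 0.16, tolerance = 1e-9)
  expect_equal(s$sed_02, 0.04, tolerance = 1e-9)
  expect_equal(s$r2_lin, 1, tolerance = 1e-12)
})
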