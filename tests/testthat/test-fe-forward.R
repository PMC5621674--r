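# Finite-element forward model.  Full-density sweeps of all four reference
# conditions are exercised in the acceptance tests; here the mesh and the
# mechanics are checked on reduced problems where exact or classical
# references exist.

test_that("the default mesh matches the intended density and layering", {
  gp <- group_presets()
  m <- build_model(gp$control_RV$geom, material_law("neo-hookean", E = 2.42))
  expect_gte(m$n_elements, 600)
  expect_lte(m$n_elements, 2400)
  # interface sits exactly at the compact thickness
  expect_true(any(abs(m$zb + 0.066) < 1e-12))
  # trabecular elements carry density-scaled parameters
  mu <- material_law("neo-hookean", E = 2.42)$mu
  expect_equal(sort(unique(round(m$mu_e / mu, 6))), c(0.405, 1))

  # rho_tr = 1 removes the parameter jump
  g1 <- wall_geometry(0.066, 0.289, rho_tr = 1)
  m1 <- build_model(g1, material_law("neo-hookean", E = 2.42))
  expect_equal(length(unique(m1$mu_e)), 1L)
})

test_that("geometry validation catches impossible configurations", {
  expect_error(wall_geometry(0.06, 0.3, rho_tr = 1.2), class = "pamech_invalid_geometry")
  expect_error(wall_geometry(0, 0, rho_tr = 0.5), class = "pamech_invalid_geometry")
  expect_error(wall_geometry(0.06, 0.3, 0.5, r_i = 0.3, wall = 0.2, r_domain = 0.4),
               class = "pamech_invalid_geometry")
})

test_that("zero pressure gives an identically zero field and sweeps are deterministic", {
  m <- build_model(fast_geom(), material_law("neo-hookean", E = 2.42),
                   refine = fe_refine_fast)
  r1 <- solve_sweep(m, p_max = 0.4, step = 0.2)
  expect_identical(r1$pressure[1L], 0)
  expect_identical(r1$deflection[1L], 0)
  expect_true(all(abs(r1$fields[[1L]]) == 0))
  expect_true(all(diff(r1$deflection) > 0))
  r2 <- solve_sweep(m, p_max = 0.4, step = 0.2)
  expect_identical(r1$deflection, r2$deflection)  # bit-identical rerun
})

test_that("doubling the modulus halves the deflection", {
  g <- fast_geom()
  for (E in c(2, 8)) {
    ra <- solve_sweep(build_model(g, material_law("neo-hookean", E = E),
                                  refine = fe_refine_fast), p_max = 0.4, step = 0.2,
                      store_fields = FALSE)
    rb <- solve_sweep(build_model(g, material_law("neo-hookean", E = 2 * E),
                                  refine = fe_refine_fast), p_max = 0.4, step = 0.2,
                      store_fields = FALSE)
    expect_equal(rb$deflection[-1L], ra$deflection[-1L] / 2, tolerance = 0.02)
  }
})

test_that("neo-Hookean and linear-elastic responses agree in the small-strain limit", {
  g <- fast_geom()
  rn <- solve_sweep(build_model(g, material_law("neo-hookean", E = 2.42),
                                refine = fe_refine_fast), p_max = 0.2, step = 0.1,
                    store_fields = FALSE)
  rl <- solve_sweep(build_model(g, material_law("linear", E = 2.42),
                                refine = fe_refine_fast), p_max = 0.2, step = 0.1,
                    store_fields = FALSE)
  expect_equal(rl$deflection[-1L], rn$deflection[-1L], tolerance = 0.03)
})

test_that("a deep homogeneous model reproduces the classical aspiration relation", {
  # half-space punch relation E ~ 3 Dp Phi r_i / (2 pi L) with Phi ~ 2.0-2.1
  g <- wall_geometry(t_c = 0.25, t_tr = 0.25, rho_tr = 1, r_domain = 0.5)
  m <- build_model(g, material_law("linear", E = 10), refine = fe_refine_fast)
  res <- solve_sweep(m, p_max = 0.1, step = 0.05, store_fields = FALSE)
  L <- res$deflection[length(res$deflection)]
  phi_fe <- 2 * pi * L * 10 / (3 * 0.1 * g$r_i)
  expect_gt(phi_fe, 2.05 * 0.85)
  expect_lt(phi_fe, 2.05 * 1.15)
})

test_that("dilation shrinks with the bulk modulus and stays a small part of the bubble", {
  # signed volume change of the whole domain, integrated from the centroid
  # Jacobian determinant of every element, compared against the nominal
  # aspirated bubble volume pi/2 r_i^2 L.  At nu = 0.49 (kappa/mu = 50) the
  # dilation is an order 10% fraction; pushing nu toward 0.5 suppresses it.
  dv_ratio <- function(nu) {
    m <- build_model(fast_geom(), material_law("neo-hookean", E = 2.42, nu = nu),
                     refine = fe_refine_fast)
    res <- solve_sweep(m, p_max = 1.0, step = 0.2, stop_lbar = 0.45)
    k <- length(res$pressure)
    sol <- res$fields[[k]]
    dv <- 0
    for (e in seq_len(nrow(m$tri))) {
      Fc <- pamech:::fe_defgrad(m$nodes, m$tri, e, 1 / 3, 1 / 3, sol)
      J <- (Fc[1L] * Fc[4L] - Fc[2L] * Fc[3L]) * Fc[5L]
      X <- m$nodes[m$tri[e, 1:3], ]
      A <- abs((X[2L, 1L] - X[1L, 1L]) * (X[3L, 2L] - X[1L, 2L]) -
                 (X[3L, 1L] - X[1L, 1L]) * (X[2L, 2L] - X[1L, 2L])) / 2
      dv <- dv + (J - 1) * 2 * pi * mean(X[, 1L]) * A
    }
    dv / (pi / 2 * m$geom$r_i^2 * res$deflection[k])
  }
  r49 <- dv_ratio(0.49)
  r499 <- dv_ratio(0.499)
  expect_gt(r49, 0)
  expect_lt(r49, 0.2)
  expect_lt(r499, 0.6 * r49)
})

test_that("strain queries locate points and decay away from the pipette", {
  m <- build_model(fast_geom(), material_law("neo-hookean", E = 2.42),
                   refine = fe_refine_fast)
  res <- solve_sweep(m, p_max = 1.0, step = 0.2, stop_lbar = 0.45)
  expect_gte(max(res$lbar), 0.4)

  prof_d <- strain_profile(res, lbar = 0.4, direction = "depth")
  prof_r <- strain_profile(res, lbar = 0.4, direction = "radial")
  expect_equal(prof_d$relative[1L], 1)
  # decays to <= 10% of the apex value well before the fixed boundaries
  deep <- prof_d$distance > 0.6 * (m$geom$t_c + m$geom$t_tr)
  expect_true(all(abs(prof_d$relative[deep]) < 0.1))
  far <- prof_r$distance > 0.6 * m$geom$r_domain
  expect_true(all(abs(prof_r$relative[far]) < 0.1))

  # junction extremum appears only with trabecular porosity
  junction <- abs(prof_d$distance - m$geom$t_c) < 0.02
  inner <- prof_d$distance < m$geom$t_c - 0.02 & prof_d$distance > 0.02
  expect_gt(max(prof_d$strain[junction]), max(prof_d$strain[inner]))

  g1 <- wall_geometry(m$geom$t_c, m$geom$t_tr, rho_tr = 1)
  m1 <- build_model(g1, material_law("neo-hookean", E = 2.42),
                    refine = fe_refine_fast)
  r1 <- solve_sweep(m1, p_max = 1.2, step = 0.2, stop_lbar = 0.45)
  p1 <- strain_profile(r1, lbar = 0.4, direction = "depth")
  expect_lt(max(p1$strain[abs(p1$distance - m$geom$t_c) < 0.02]),
            max(prof_d$strain[junction]))

  expect_error(green_strain_at(res, 2, r = 1.0, z = 0), class = "pamech_out_of_domain")
})

test_that("a solid wall needs more pressure than its porous twin for the same height", {
  g <- fast_geom()
  rp <- solve_sweep(build_model(g, material_law("neo-hookean", E = 2.42),
                                refine = fe_refine_fast), p_max = 0.8, step = 0.2,
                    store_fields = FALSE)
  gs <- wall_geometry(g$t_c, g$t_tr, rho_tr = 1)
  rs <- solve_sweep(build_model(gs, material_law("neo-hookean", E = 2.42),
                                refine = fe_refine_fast), p_max = 0.8, step = 0.2,
                    store_fields = FALSE)
  expect_true(all(rs$deflection[-1L] < rp$deflection[-1L]))
})

test_that("the forward-curve cache returns identical results without resolving", {
  clear_fe_cache()
  g <- fast_geom()
  mat <- material_law("neo-hookean", E = 2.42)
  r1 <- forward_curve(g, mat, p_max = 0.4, step = 0.2, refine = fe_refine_fast)
  n1 <- pamech:::.pamech_cache$n_solves
  r2 <- forward_curve(g, mat, p_max = 0.4, step = 0.2, refine = fe_refine_fast)
  expect_identical(pamech:::.pamech_cache$n_solves, n1)
  expect_identical(r1$deflection, r2$deflection)
})
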