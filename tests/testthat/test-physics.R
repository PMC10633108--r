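test_that("ellipse geometry matches hand-derived values and circle limit", {
  # circle: d_h equals the diameter
  g <- circle_geometry(160)
  expect_equal(g$d_h, 160e-6, tolerance = 1e-9)

  # 200 x 160 um ellipse: pi*a*b/4 area, Ramanujan perimeter, 4A/P
  ge <- ellipse_geometry(200, 160)
  expect_equal(ge$area, 2.513274e-8, tolerance = 1e-6)
  expect_equal(ge$perimeter, 567.2334e-6, tolerance = 1e-6)
  expect_equal(ge$d_h, 4 * ge$area / ge$perimeter, tolerance = 1e-13)
  expect_equal(ge$d_h, 177.2303e-6, tolerance = 1e-6)

  # d_h bracketed by the axes; elliptical d_h below equal-area circle
  expect_true(ge$b <= ge$d_h && ge$d_h <= ge$a)
  gc <- circle_geometry(sqrt(200 * 160))
  expect_lt(ge$d_h, gc$d_h)

  expect_error(ellipse_geometry(160, 200), "major axis smaller")
  expect_error(ellipse_geometry(-1, -2), "positive")
  expect_error(ellipse_geometry(NaN, 100), "positive")
})

test_that("Laplace pressure: elliptical form, circle reduction, zero drive", {
  w <- water_equil()
  expect_equal(laplace_pressure(w, d156()), 903.24, tolerance = 1e-4)

  fl <- fluid_properties(998, 1.04, sigma_eff = 0.035294)
  expect_equal(laplace_pressure(fl, ellipse_geometry(200, 160)),
               794.115, tolerance = 1e-5)

  # circle limit 4 sigma / d
  g <- circle_geometry(200)
  expect_equal(laplace_pressure(fl, g), 4 * 0.035294 / 200e-6,
               tolerance = 1e-9)

  # vanishing drive as theta -> 90
  nearly_flat <- fluid_properties(998, 1.04, gamma_mN_m = 72.8,
                                  theta_deg = 89.999)
  expect_lt(laplace_pressure(nearly_flat, g), 0.1)
  expect_error(fluid_properties(998, 1.04, gamma_mN_m = 72.8,
                                theta_deg = 90), "theta")
  expect_error(laplace_pressure(fluid_properties(998, 1.04), d156()),
               "surface")
})

test_that("friction pressure follows the laminar Darcy-Weisbach closure", {
  w <- water_dyn()
  g <- d156()
  fr <- friction_pressure(w, g, u = 7.70e-3, L = 0.033)
  expect_equal(fr$Re, 1.1549, tolerance = 1e-4)
  expect_equal(fr$f_D, 55.417, tolerance = 1e-4)
  expect_equal(fr$dP, 346.16, tolerance = 1e-4)
  expect_false(fr$laminar_warning)

  # no flow, no friction
  fr0 <- friction_pressure(w, g, u = 0, L = 0.033)
  expect_identical(fr0$dP, 0)
  expect_true(is.na(fr0$f_D))

  # Darcy-Weisbach form equals 32 mu L u / d_h^2 identically
  set.seed(42)
  for (i in 1:50) {
    u <- runif(1, 1e-5, 0.05)
    L <- runif(1, 0.005, 0.1)
    fr <- friction_pressure(w, g, u, L)
    expect_equal(fr$dP, 32 * w$mu * L * u / g$d_h^2, tolerance = 1e-13)
    expect_equal(fr$f_D * fr$Re, 64, tolerance = 1e-13)
  }

  expect_error(friction_pressure(w, g, u = -1e-3, L = 0.03), "non-negative")
  expect_true(friction_pressure(w, g, u = 15, L = 0.03)$laminar_warning)
})

test_that("quasi-steady velocity closes the pressure balance and matches a
           bisection oracle over random draws", {
  w <- water_dyn()
  g <- d156()
  st <- quasi_steady_velocity(w, g, H = 0.030, L = 0.033)
  expect_equal(st$u, 7.698e-3, tolerance = 1e-3)
  expect_equal(st$gamma_w, 8 * st$u / g$d_h, tolerance = 1e-12)
  expect_equal(st$gamma_w, 394.0, tolerance = 1e-3)

  # at equilibrium height the velocity vanishes
  H_eq <- equilibrium_height(w, g)
  expect_equal(quasi_steady_velocity(w, g, H_eq, H_eq + 1e-3)$u, 0)

  # sweep: closure + oracle agreement + laminar identity
  ps <- draw_params(1000, seed = 7)
  for (i in seq_len(nrow(ps))) {
    fl <- fluid_properties(ps$rho[i], ps$mu_cP[i], sigma_eff = ps$sigma[i])
    gm <- ellipse_geometry(ps$d_um[i] * sqrt(ps$aspect[i]),
                           ps$d_um[i] / sqrt(ps$aspect[i]))
    H <- ps$h_frac[i] * equilibrium_height(fl, gm)
    st <- quasi_steady_velocity(fl, gm, H, H + 3e-3)
    expect_lte(abs(st$dP_laplace - st$dP_friction - st$dP_head),
               1e-9 * st$dP_laplace)
    expect_equal(st$u, bisect_velocity(fl, gm, H, H + 3e-3),
                 tolerance = 1e-9)
    if (st$Re > 0) expect_equal(st$f_D * st$Re, 64, tolerance = 1e-12)
  }

  expect_error(quasi_steady_velocity(w, g, H = 0, L = 0), "singular")
  expect_error(quasi_steady_velocity(w, g, H = 0.05, L = 0.01), "L >= H")
})

test_that("velocity is monotone in height, viscosity and surface drive", {
  g <- d156()
  u_of <- function(sigma, mu_cP, H) {
    fl <- fluid_properties(998, mu_cP, sigma_eff = sigma)
    quasi_steady_velocity(fl, g, H, H + 3e-3)$u
  }
  H <- seq(0.005, 0.06, length.out = 8)
  expect_true(all(diff(sapply(H, function(h) u_of(0.025, 1.04, h))) < 0))
  mus <- seq(1, 8, length.out = 8)
  expect_true(all(diff(sapply(mus, function(m) u_of(0.025, m, 0.02))) < 0))
  sigs <- seq(0.02, 0.05, length.out = 8)
  expect_true(all(diff(sapply(sigs, function(s) u_of(s, 1.04, 0.02))) > 0))
})

test_that("equilibrium height: hand value, viscosity-independence,
           diameter monotonicity", {
  w <- water_equil()
  expect_equal(equilibrium_height(w, d156()), 92.26e-3, tolerance = 1e-3)

  # no viscosity anywhere in the equilibrium balance
  w10 <- set_viscosity(w, w$mu * 10)
  expect_identical(equilibrium_height(w, d156()),
                   equilibrium_height(w10, d156()))

  h <- sapply(mean_diams, function(d) equilibrium_height(w, circle_geometry(d)))
  expect_true(all(diff(h) < 0))
})

test_that("contact angle from equilibrium round-trips and rejects
           infeasible observations", {
  w <- water_equil()
  for (theta in c(5, 30, 61, 80, 89)) {
    fl <- fluid_properties(998, 1.04, gamma_mN_m = 72.8, theta_deg = theta)
    for (d in mean_diams) {
      g <- circle_geometry(d)
      H_eq <- equilibrium_height(fl, g)
      expect_equal(contact_angle_from_equilibrium(H_eq, 72.8, 998, g),
                   theta, tolerance = 1e-6)
    }
  }
  g <- d156()
  expect_equal(contact_angle_from_equilibrium(0, 72.8, 998, g), 90)
  # implied cos(theta) = 1.2
  H_big <- 1.2 * 2 * 72.8e-3 * (1 / g$a + 1 / g$b) / (998 * 9.81)
  expect_error(contact_angle_from_equilibrium(H_big, 72.8, 998, g),
               "infeasible")
})

test_that("wall shear rate 8u/d_h sits in the physiological window at
           working velocities", {
  # at 10 mm/s the printed mean diameters all map into 100-800 1/s
  gw <- sapply(mean_diams, function(d)
    wall_shear_rate(0.010, circle_geometry(d)))
  expect_true(all(gw > 100 & gw < 800))
  expect_equal(wall_shear_rate(0.010, 156.3e-6), 8 * 0.010 / 156.3e-6)
})

test_that("fluid constructor validates and converts units", {
  expect_error(fluid_properties(-1, 1), "rho")
  expect_error(fluid_properties(998, 0), "mu")
  expect_error(fluid_properties(998, 1.04, gamma_mN_m = 72.8,
                                theta_deg = 61, sigma_eff = 0.07),
               "inconsistent")
  w <- fluid_properties(998, 1.04, gamma_mN_m = 72.8, theta_deg = 61)
  expect_equal(w$mu, 1.04e-3)
  expect_equal(sigma_eff(w), cos(61 * pi / 180) * 72.8e-3, tolerance = 1e-12)
  b <- fluid_properties(1055, 4.58, sigma_eff = 0.034)
  expect_equal(sigma_eff(b), 0.034)
})
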