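test_that("linear transient fit recovers the closed-form slope and
           intercept exactly on model data", {
  w <- water_dyn()
  g <- d156()
  H <- seq(0.008, 0.06, length.out = 40)
  vs <- model_velocity_series(w, g, H)      # L = H regime
  lf <- linear_transient_fit(vs, g, rho = 998)

  s_exp <- laplace_pressure(w, g) * g$d_h^2 / (32 * w$mu)
  c_exp <- -998 * 9.81 * g$d_h^2 / (32 * w$mu)
  expect_equal(lf$linear$slope, s_exp, tolerance = 1e-3)
  expect_equal(lf$linear$intercept, c_exp, tolerance = 1e-3)
  expect_equal(unname(coef(lf)["mu"]), w$mu, tolerance = 5e-3)
  expect_equal(unname(coef(lf)["sigma_eff"]), 0.025, tolerance = 5e-3)

  # doubling viscosity doubles mu-hat, leaves sigma-hat unchanged
  w2 <- set_viscosity(w, 2 * w$mu)
  lf2 <- linear_transient_fit(model_velocity_series(w2, g, H), g, 998)
  expect_equal(unname(coef(lf2)["mu"]), 2 * w$mu, tolerance = 5e-3)
  expect_equal(unname(coef(lf2)["sigma_eff"]), 0.025, tolerance = 5e-3)

  expect_error(linear_transient_fit(vs[1:3, ], g, 998), "insufficient")
  one_h <- model_velocity_series(w, g, rep(0.02, 6))
  expect_error(linear_transient_fit(one_h, g, 998), "single height")
})

test_that("the gravity intercept carries the viscosity information", {
  w <- water_dyn()
  g <- d156()
  vs <- model_velocity_series(w, g, seq(0.008, 0.06, length.out = 40))
  lf <- linear_transient_fit(vs, g, 998)
  # dropping the intercept changes the slope, hence the inferred physics:
  # slope alone only pins the ratio sigma/mu
  s0 <- unname(coef(stats::lm(u_raw ~ inv_H - 1, data = vs)))
  expect_gt(abs(s0 - lf$linear$slope) / lf$linear$slope, 0.01)

  # data rising faster than the gravity-free line (c >= 0) is flagged
  vs_flat <- vs
  vs_flat$u_raw <- vs_flat$u <- 1e-2 + 2e-4 * vs$inv_H / max(vs$inv_H)
  lff <- linear_transient_fit(vs_flat, g, 998)
  expect_true(lff$linear$intercept_flag)
  expect_true(is.na(coef(lff)["mu"]))
})

test_that("constrained fit matches the linear fit on noiseless linear-regime
           data and recovers truth across diameters", {
  w <- water_dyn()
  for (d in mean_diams) {
    g <- circle_geometry(d)
    H_eq <- equilibrium_height(w, g)
    H <- seq(0.008, 0.95 * H_eq, length.out = 40)
    vs <- model_velocity_series(w, g, H)
    cf <- capillary_fit(vs, g, rho = 998, L_dip = 1e-9)
    expect_equal(unname(coef(cf)["sigma_eff"]), 0.025, tolerance = 5e-3)
    expect_equal(unname(coef(cf)["mu"]), w$mu, tolerance = 5e-3)
    lf <- linear_transient_fit(vs, g, 998)
    expect_equal(coef(cf), coef(lf), tolerance = 5e-3)
  }

  # with a real dip depth the full model still recovers exactly
  g <- d156()
  vs_dip <- model_velocity_series(w, g, seq(0.008, 0.06, length.out = 40),
                                  L_dip = 3e-3)
  cf <- capillary_fit(vs_dip, g, rho = 998, L_dip = 3e-3)
  expect_equal(unname(coef(cf)["sigma_eff"]), 0.025, tolerance = 1e-3)
  expect_equal(unname(coef(cf)["mu"]), w$mu, tolerance = 1e-3)
})

test_that("constraint bounds are honest: inactive inside, pinned outside", {
  g <- d156()
  H <- seq(0.008, 0.055, length.out = 40)

  # truth inside the box: bound must stay inactive
  wb <- blood_like(mu_cP = 4.58)
  vs <- model_velocity_series(wb, g, H, L_dip = 3e-3)
  fit_in <- capillary_fit(vs, g, rho = 1055,
                          constraints = list(mu_cP = c(2, 6)), L_dip = 3e-3)
  expect_false(fit_in$constraints$any_active)
  expect_equal(unname(coef(fit_in)["mu"]), 4.58e-3, tolerance = 1e-3)

  # truth above the cap: estimate sits on the bound, flagged active
  thick <- blood_like(mu_cP = 8)
  vs8 <- model_velocity_series(thick, g, H, L_dip = 3e-3)
  fit_out <- capillary_fit(vs8, g, rho = 1055,
                           constraints = list(mu_cP = c(2, 6)), L_dip = 3e-3)
  expect_true(any(fit_out$constraints$active$mu))
  expect_equal(unname(coef(fit_out)["mu"]), 6e-3, tolerance = 1e-9)

  # PPP-like sample generated exactly at the cap reports the cap
  ppp <- fluid_properties(1025, 1.70, sigma_eff = 0.023)
  vsp <- model_velocity_series(ppp, g, H, L_dip = 3e-3)
  fit_ppp <- capillary_fit(vsp, g, rho = 1025,
                           constraints = list(mu_cP = c(NA, 1.7)),
                           L_dip = 3e-3)
  expect_equal(unname(coef(fit_ppp)["mu"]), 1.70e-3, tolerance = 2e-3)

  # fixed viscosity (equal bounds) fits sigma only
  wt <- water_dyn()
  vsw <- model_velocity_series(wt, g, H, L_dip = 3e-3)
  fit_fix <- capillary_fit(vsw, g, rho = 998,
                           constraints = list(mu_cP = c(1.04, 1.04)),
                           L_dip = 3e-3)
  expect_equal(unname(coef(fit_fix)["mu"]), 1.04e-3, tolerance = 1e-12)
  expect_equal(unname(coef(fit_fix)["sigma_eff"]), 0.025, tolerance = 1e-3)

  expect_error(capillary_fit(vs, g, rho = 1055,
                             constraints = list(mu_cP = c(6, 2))),
               "infeasible")
})

test_that("equilibrium-only fits return the surface drive but declare the
           viscosity not identifiable", {
  w <- water_equil()
  g <- d156()
  H_eq <- equilibrium_height(w, g)
  fit <- fit_from_equilibrium(H_eq, g, rho = 998)
  expect_equal(unname(coef(fit)["sigma_eff"]), sigma_eff(w),
               tolerance = 1e-9)
  expect_true(is.na(coef(fit)["mu"]))
  expect_identical(fit$mu_status, "not identifiable")
  expect_error(predict(fit, data.frame(H = 0.02)), "not identif")
  # H_eq round-trips through the fit
  expect_equal(fit$H_eq, H_eq, tolerance = 1e-12)
})

test_that("capfit methods behave like a standard model object", {
  w <- water_dyn()
  g <- d156()
  vs <- model_velocity_series(w, g, seq(0.008, 0.06, length.out = 30),
                              L_dip = 3e-3)
  fit <- capillary_fit(vs, g, rho = 998, sample_class = "water")

  expect_named(coef(fit), c("sigma_eff", "mu"))
  expect_length(residuals(fit), fit$n_points)
  expect_equal(fitted(fit) + residuals(fit), fit$pooled$u, tolerance = 1e-12)
  expect_lt(fit$residual_rms, 1e-5)

  # predict reproduces the generating velocities
  up <- predict(fit, data.frame(H = vs$H_mid))
  expect_equal(up, vs$u, tolerance = 1e-3)
  up2 <- predict(fit, data.frame(inv_H = 1 / vs$H_mid))
  expect_equal(up, up2, tolerance = 1e-12)

  expect_output(print(fit), "cos\\(theta\\)\\*gamma")
  expect_output(print(summary(fit)), "mu bounds")

  # simulate() from the fitted model reproduces the original physics
  trs <- simulate(fit, nsim = 1, cfg = sim_config(total_time = 10))
  tr_ref <- integrate_rise(w, g, sim_config(total_time = 10))
  expect_equal(trs[[1]]$height, tr_ref$height, tolerance = 1e-3)

  # plotting runs headless
  pf <- withr::local_tempfile(fileext = ".png")
  grDevices::png(pf)
  expect_silent(plot(fit))
  grDevices::dev.off()
  expect_true(file.exists(pf))
})

test_that("multiplier families are ordered and anchored at the baseline", {
  wb <- blood_like()
  g <- d156()
  vs <- model_velocity_series(wb, g, seq(0.008, 0.055, length.out = 40),
                              L_dip = 3e-3)
  fit <- capillary_fit(vs, g, rho = 1055, L_dip = 3e-3)
  fam <- multiplier_curves(fit)
  expect_equal(fam$multipliers, c(1, 2, 3, 4, 6))

  H <- seq(0.01, 0.05, length.out = 20)
  u1 <- fam$predict(1, H)
  expect_equal(u1, predict(fit, data.frame(H = H)), tolerance = 1e-12)
  prev <- u1
  for (m in c(2, 3, 4, 6)) {
    um <- fam$predict(m, H)
    expect_true(all(um < prev))
    prev <- um
  }
  # in the linear regime u scales as 1/mu
  lin_fit <- capillary_fit(model_velocity_series(wb, g,
                                                 seq(0.01, 0.05, length.out = 30)),
                           g, rho = 1055, L_dip = 1e-9)
  lin_fam <- multiplier_curves(lin_fit)
  expect_equal(lin_fam$predict(2, H), lin_fam$predict(1, H) / 2,
               tolerance = 1e-6)

  expect_error(multiplier_curves(fit, c(0.5, 2)), ">= 1")
})

test_that("stimulated series classify to the right multiplier and onset", {
  wb <- blood_like(sigma = 0.025)
  g <- d156()
  cfg <- sim_config(total_time = 40, time_step = 0.005)
  base_fit <- capillary_fit(
    model_velocity_series(wb, g, seq(0.008, 0.06, length.out = 50),
                          L_dip = cfg$dip_depth),
    g, rho = 1055, L_dip = cfg$dip_depth)
  fam <- multiplier_curves(base_fit)

  # unstimulated: terminal multiplier 1, no onset
  tr0 <- integrate_rise(wb, g, cfg)
  cl0 <- classify_stimulated_series(estimate_velocity(tr0), fam)
  expect_identical(cl0$terminal_multiplier, 1)
  expect_true(is.na(cl0$onset_time))

  # k = 6 ramp at t_on = 10 s: terminal 6, onset within 5 s
  sch <- viscosity_schedule(150, list(k = 6, t_on = 10))
  tr6 <- simulate_stimulated_rise(wb, g, sch, cfg)
  cl6 <- classify_stimulated_series(estimate_velocity(tr6), fam)
  expect_identical(cl6$terminal_multiplier, 6)
  expect_lt(abs(cl6$onset_time - 10), 5)

  # onset ordering follows the programmed onset times
  sch25 <- viscosity_schedule(150, list(k = 6, t_on = 25))
  tr25 <- simulate_stimulated_rise(wb, g, sch25, cfg)
  cl25 <- classify_stimulated_series(estimate_velocity(tr25), fam)
  expect_lt(cl6$onset_time, cl25$onset_time)

  empty <- model_velocity_series(wb, g, 0.02)[0, ]
  expect_error(classify_stimulated_series(empty, fam), "insufficient")
})

test_that("recovery reports compute signed percent deviations", {
  wb <- blood_like()
  g <- d156()
  vs <- model_velocity_series(wb, g, seq(0.01, 0.05, length.out = 30),
                              L_dip = 3e-3)
  fit <- capillary_fit(vs, g, rho = 1055, L_dip = 3e-3)
  rr <- recovery_report(list(sigma_eff = 0.034, mu = 4.58e-3), fit)
  expect_lt(rr$max_abs_pct, 0.5)

  fit$coefficients["mu"] <- 1.17e-3
  rr2 <- recovery_report(list(mu_cP = 1.04), fit)
  expect_equal(unname(rr2$deviations_pct["mu_cP"]), 12.5, tolerance = 1e-6)
  expect_error(recovery_report(list(bogus = 1), fit), "unknown parameter")
})

test_that("fit reports serialise to the documented JSON schema", {
  wb <- blood_like()
  g <- d156()
  vs <- model_velocity_series(wb, g, seq(0.01, 0.05, length.out = 30),
                              L_dip = 3e-3)
  fit <- capillary_fit(vs, g, rho = 1055,
                       constraints = list(mu_cP = c(2, 6)), L_dip = 3e-3,
                       sample_class = "WB")
  f <- withr::local_tempfile(fileext = ".json")
  write_fit_report(fit, f, seed = 42)
  rep <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(rep$sample_class, "WB")
  expect_equal(rep$mu_cP, 4.58, tolerance = 1e-2)
  expect_equal(rep$rho_kg_m3, 1055)
  expect_equal(rep$constraints$mu_cP, c(2, 6))
  expect_false(rep$constraints$active)
  expect_identical(rep$seed, 42L)

  # constraint JSON round trip
  cj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(WB = list(mu_cP = c(2, 6)),
                            PPP = list(mu_cP = list(NULL, 1.7))),
                       cj, auto_unbox = TRUE, digits = NA, null = "null")
  cons <- read_constraints(cj)
  expect_equal(cons$WB$mu_cP, c(2, 6))
  expect_equal(cons$PPP$mu_cP, c(NA, 1.7))
})
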