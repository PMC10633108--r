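# Shared fixtures: fluids, geometries and random parameter draws.

water_equil <- function() {
  fluid_properties(998, 1.04, gamma_mN_m = 72.8, theta_deg = 61)
}

# water with the transient-fit surface drive (dynamic wetting)
water_dyn <- function() {
  fluid_properties(998, 1.04, sigma_eff = 0.025)
}

blood_like <- function(sigma = 0.034, mu_cP = 4.58) {
  fluid_properties(1055, mu_cP, sigma_eff = sigma)
}

d156 <- function(length_mm = 100) circle_geometry(156.3, length_mm)

mean_diams <- c(156.3, 201.6, 261.2)

# random but physical parameter draws for property sweeps
draw_params <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    d_um = runif(n, 100, 300),
    aspect = runif(n, 1, 1.5),
    sigma = runif(n, 0.02, 0.05),
    mu_cP = runif(n, 0.8, 12),
    rho = runif(n, 950, 1200),
    h_frac = runif(n, 0.05, 0.95)
  )
}

# independent oracle: solve the pressure balance for u by bisection
bisect_velocity <- function(fluid, geom, H, L, g = 9.81) {
  dP_L <- laplace_pressure(fluid, geom)
  f <- function(u) dP_L - 32 * fluid$mu * L * u / geom$d_h^2 - fluid$rho * g * H
  if (f(0) <= 0) return(0)
  hi <- 1
  while (f(hi) > 0) hi <- hi * 2
  lo <- 0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
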