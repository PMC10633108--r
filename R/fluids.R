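#' Describe a fluid sample
#'
#' Bundles the physical properties of a liquid sample that enter the
#' capillary-rise pressure balance: density, dynamic viscosity, and the
#' surface drive at the meniscus.  The surface drive can be given either as
#' separate surface tension and contact angle, or (for samples such as blood
#' where the two cannot be identified separately) as the single combined term
#' \eqn{\sigma_{eff} = \cos\theta \cdot \gamma}.
#'
#' Arguments are in the units practitioners quote (cP, mN/m, degrees); the
#' returned object stores strict SI (Pa s, N/m) and every downstream function
#' works in SI.
#'
#' @param rho fluid density (kg m^-3).
#' @param mu_cP dynamic viscosity (cP; 1 cP = 1 mPa s).
#' @param gamma_mN_m liquid-air surface tension (mN m^-1), or `NULL`.
#' @param theta_deg liquid-wall contact angle (degrees, hydrophilic:
#'   0 <= theta < 90), or `NULL`.
#' @param sigma_eff combined surface drive cos(theta)*gamma (N m^-1), or
#'   `NULL`.  Exactly one of `sigma_eff` or the pair
#'   (`gamma_mN_m`, `theta_deg`) must be supplied for any Laplace-pressure
#'   computation.
#' @return An object of class `"fluid_properties"`: a list with elements
#'   `rho` (kg m^-3), `mu` (Pa s), `gamma` (N m^-1 or NA), `theta_deg`
#'   (degrees or NA), `sigma_eff` (N m^-1 or NA).
#' @examples
#' water <- fluid_properties(rho = 998, mu_cP = 1.04,
#'                           gamma_mN_m = 72.8, theta_deg = 61)
#' sigma_eff(water)
#' blood <- fluid_properties(rho = 1055, mu_cP = 4.58, sigma_eff = 0.034)
#' @export
fluid_properties <- function(rho, mu_cP, gamma_mN_m = NULL, theta_deg = NULL,
                             sigma_eff = NULL) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0)
    stop("'rho' must be a single positive number (kg/m^3)")
  if (!is.numeric(mu_cP) || length(mu_cP) != 1L || !is.finite(mu_cP) || mu_cP <= 0)
    stop("'mu_cP' must be a single positive number (cP)")
  gamma <- if (is.null(gamma_mN_m)) NA_real_ else gamma_mN_m * 1e-3
  theta <- if (is.null(theta_deg)) NA_real_ else theta_deg
  sig <- if (is.null(sigma_eff)) NA_real_ else sigma_eff
  if (!is.na(gamma) && gamma <= 0)
    stop("'gamma_mN_m' must be positive")
  if (!is.na(theta) && (theta < 0 || theta >= 90))
    stop("'theta_deg' must satisfy 0 <= theta < 90 (wetting wall)")
  if (!is.na(gamma) && !is.na(theta) && !is.na(sig)) {
    implied <- cos(theta * pi / 180) * gamma
    if (abs(sig - implied) > 1e-12 * max(abs(implied), 1e-300))
      stop("'sigma_eff' inconsistent with cos(theta)*gamma")
  }
  structure(list(rho = rho, mu = mu_cP * 1e-3, gamma = gamma,
                 theta_deg = theta, sigma_eff = sig),
            class = "fluid_properties")
}

#' Combined surface drive of a fluid
#'
#' Returns \eqn{\sigma_{eff} = \cos\theta \cdot \gamma} (N m^-1), either as
#' stored or computed from surface tension and contact angle.
#'
#' @param fluid a [fluid_properties()] object.
#' @return surface drive (N m^-1).
#' @export
sigma_eff <- function(fluid) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (!is.na(fluid$sigma_eff)) return(fluid$sigma_eff)
  if (!is.na(fluid$gamma) && !is.na(fluid$theta_deg))
    return(cos(fluid$theta_deg * pi / 180) * fluid$gamma)
  stop("fluid carries neither sigma_eff nor both gamma and theta; ",
       "supply surface information to compute Laplace pressure")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat("Fluid sample\n")
  cat(sprintf("  density:      %.1f kg/m^3\n", x$rho))
  cat(sprintf("  viscosity:    %.3f cP\n", x$mu * 1e3))
  if (!is.na(x$gamma))
    cat(sprintf("  surf.tension: %.1f mN/m\n", x$gamma * 1e3))
  if (!is.na(x$theta_deg))
    cat(sprintf("  contact ang.: %.1f deg\n", x$theta_deg))
  se <- tryCatch(sigma_eff(x), error = function(e) NA_real_)
  if (!is.na(se))
    cat(sprintf("  cos(theta)*gamma: %.4f N/m\n", se))
  invisible(x)
}

#' Replace the viscosity of a fluid
#'
#' Convenience for scaling studies (e.g. viscosity-multiplier families).
#'
#' @param fluid a [fluid_properties()] object.
#' @param mu new dynamic viscosity (Pa s).
#' @return a new `fluid_properties` object.
#' @export
set_viscosity <- function(fluid, mu) {
  stopifnot(inherits(fluid, "fluid_properties"), is.finite(mu), mu > 0)
  fluid$mu <- mu
  fluid
}

#' Glycerol-water calibration mixtures
#'
#' Literature properties (20 degrees C) of the glycerol-water mixtures used
#' to calibrate the capillary-rise method: 0, 20, 40 and 60 % w/w glycerol.
#' Contact angle on the hydrophilic (PVA-coated) capillary wall defaults to
#' the equilibrium value measured for pure water.
#'
#' @param theta_deg contact angle assumed for all mixtures (degrees).
#' @return data frame with columns `fraction_w`, `rho_kg_m3`, `mu_cP`,
#'   `gamma_mN_m`, `theta_deg`.
#' @export
glycerol_mixtures <- function(theta_deg = 61) {
  data.frame(
    fraction_w = c(0, 0.2, 0.4, 0.6),
    rho_kg_m3 = c(998, 1047, 1099, 1154),
    mu_cP = c(1.005, 1.76, 3.72, 10.8),
    gamma_mN_m = c(72.8, 71.0, 69.5, 67.5),
    theta_deg = theta_deg
  )
}

#' Default fixed densities by sample class
#'
#' Densities are fixed, never fitted; these are the literature values used
#' for each sample class (kg m^-3).
#'
#' @return named numeric vector.
#' @export
default_densities <- function() {
  c(water = 998, saline = 1005, plasma = 1025, whole_blood = 1055)
}

#' Read a fluid descriptor from JSON
#'
#' Accepts the descriptor schema
#' `{"rho_kg_m3", "mu_cP", "gamma_mN_m"|null, "theta_deg"|null,
#' "sigma_eff_N_m"|null}`.
#'
#' @param path JSON file path.
#' @return a [fluid_properties()] object.
#' @export
read_fluid <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  fluid_properties(rho = d$rho_kg_m3, mu_cP = d$mu_cP,
                   gamma_mN_m = d$gamma_mN_m, theta_deg = d$theta_deg,
                   sigma_eff = d$sigma_eff_N_m)
}

#' Write a fluid descriptor to JSON
#' @param fluid a [fluid_properties()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fluid <- function(fluid, path) {
  stopifnot(inherits(fluid, "fluid_properties"))
  jsonlite::write_json(list(
    rho_kg_m3 = fluid$rho, mu_cP = fluid$mu * 1e3,
    gamma_mN_m = if (is.na(fluid$gamma)) NULL else fluid$gamma * 1e3,
    theta_deg = if (is.na(fluid$theta_deg)) NULL else fluid$theta_deg,
    sigma_eff_N_m = if (is.na(fluid$sigma_eff)) NULL else fluid$sigma_eff
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
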