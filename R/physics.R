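#' Laplace pressure across the meniscus
#'
#' The capillary driving pressure in an elliptical bore,
#' \deqn{\Delta P_L = 2\,\sigma_{eff}\,(1/a + 1/b),}
#' with \eqn{\sigma_{eff} = \cos\theta\,\gamma} and a, b the full major and
#' minor axes.  For a circle of diameter d this reduces to the familiar
#' \eqn{4\cos\theta\,\gamma/d}.
#'
#' @param fluid a [fluid_properties()] object carrying surface information.
#' @param geom a [ellipse_geometry()] object.
#' @return Laplace pressure drop (Pa).
#' @examples
#' water <- fluid_properties(998, 1.04, gamma_mN_m = 72.8, theta_deg = 61)
#' laplace_pressure(water, circle_geometry(156.3))  # ~903 Pa
#' @export
laplace_pressure <- function(fluid, geom) {
  stopifnot(inherits(geom, "capillary_geometry"))
  2 * sigma_eff(fluid) * (1 / geom$a + 1 / geom$b)
}

#' Viscous friction pressure drop (Darcy-Weisbach, laminar)
#'
#' Computes the frictional pressure drop over a wetted length L at mean
#' superficial velocity u:
#' \deqn{\Delta P_F = f_D \frac{L}{d_h} \frac{\rho u^2}{2}, \quad
#'       f_D = 64/Re, \quad Re = \rho u d_h / \mu,}
#' which for laminar flow simplifies to \eqn{32 \mu L u / d_h^2}.
#'
#' @param fluid a [fluid_properties()] object.
#' @param geom a [ellipse_geometry()] object.
#' @param u mean superficial velocity (m s^-1, >= 0).
#' @param L total wetted fluid length (m, > 0).
#' @return list with `dP` (Pa), `Re`, `f_D` (NA when u = 0) and
#'   `laminar_warning` (TRUE when Re >= 2000, outside the model's regime).
#' @export
friction_pressure <- function(fluid, geom, u, L) {
  stopifnot(inherits(fluid, "fluid_properties"),
            inherits(geom, "capillary_geometry"))
  if (!is.finite(u) || u < 0) stop("'u' must be non-negative")
  if (!is.finite(L) || L <= 0) stop("'L' must be positive")
  if (u == 0)
    return(list(dP = 0, Re = 0, f_D = NA_real_, laminar_warning = FALSE))
  Re <- fluid$rho * u * geom$d_h / fluid$mu
  f_D <- 64 / Re
  dP <- f_D * (L / geom$d_h) * (fluid$rho * u^2 / 2)
  list(dP = dP, Re = Re, f_D = f_D, laminar_warning = Re >= 2000)
}

#' Wall shear rate of laminar tube flow
#'
#' \eqn{\gamma_w = 8u/d_h}, the wall velocity gradient that governs
#' platelet activation physiology.
#'
#' @param u mean superficial velocity (m s^-1).
#' @param geom a [ellipse_geometry()] object, or a numeric hydraulic
#'   diameter (m).
#' @return wall shear rate (s^-1).
#' @export
wall_shear_rate <- function(u, geom) {
  d_h <- if (inherits(geom, "capillary_geometry")) geom$d_h else geom
  8 * u / d_h
}

#' Instantaneous rise velocity from the quasi-steady pressure balance
#'
#' Solves \eqn{\Delta P_L = \Delta P_F(u) + \rho g H} for the instantaneous
#' meniscus velocity, neglecting inertia:
#' \deqn{u = \max\left(0,\; \frac{(\Delta P_L - \rho g H)\, d_h^2}
#'       {32 \mu L}\right).}
#' Above the equilibrium height the net pressure is negative and u clamps to
#' zero (the model does not describe meniscus retreat).
#'
#' @param fluid a [fluid_properties()] object.
#' @param geom a [ellipse_geometry()] object.
#' @param H meniscus height above the reservoir level (m, >= 0).
#' @param L total wetted length in the capillary (m, >= H, > 0).
#' @param g gravitational acceleration (m s^-2).
#' @return An object of class `"flow_state"`: list with `u` (m s^-1),
#'   `H`, `L` (m), `Re`, `f_D`, `gamma_w` (s^-1), `dP_laplace`,
#'   `dP_friction`, `dP_head` (Pa) and `laminar_warning`.  When u > 0 the
#'   three pressures close the balance to machine precision.
#' @examples
#' w <- fluid_properties(998, 1.04, sigma_eff = 0.025)
#' st <- quasi_steady_velocity(w, circle_geometry(156.3), H = 0.030, L = 0.033)
#' st$u * 1e3       # mm/s
#' st$gamma_w       # 8u/d_h
#' @export
quasi_steady_velocity <- function(fluid, geom, H, L, g = 9.81) {
  stopifnot(inherits(fluid, "fluid_properties"),
            inherits(geom, "capillary_geometry"))
  if (!is.finite(L) || L == 0)
    stop("singular state: wetted length L = 0 (regularize with a dip depth)")
  if (!is.finite(H) || H < 0 || L < H)
    stop("require L >= H >= 0")
  dP_L <- laplace_pressure(fluid, geom)
  dP_H <- fluid$rho * g * H
  u <- max(0, (dP_L - dP_H) * geom$d_h^2 / (32 * fluid$mu * L))
  fr <- friction_pressure(fluid, geom, u, L)
  structure(list(u = u, H = H, L = L, Re = fr$Re, f_D = fr$f_D,
                 gamma_w = wall_shear_rate(u, geom),
                 dP_laplace = dP_L, dP_friction = fr$dP, dP_head = dP_H,
                 laminar_warning = fr$laminar_warning),
            class = "flow_state")
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf("Flow state: u = %.3f mm/s at H = %.1f mm (L = %.1f mm)\n",
              x$u * 1e3, x$H * 1e3, x$L * 1e3))
  cat(sprintf("  Re = %.3g, gamma_w = %.0f 1/s\n", x$Re, x$gamma_w))
  cat(sprintf("  dP: Laplace %.1f = friction %.1f + head %.1f (Pa)\n",
              x$dP_laplace, x$dP_friction, x$dP_head))
  if (isTRUE(x$laminar_warning))
    cat("  warning: Re >= 2000, laminar closure not valid\n")
  invisible(x)
}

#' Equilibrium rise height
#'
#' Height at which the Laplace pressure balances the hydrostatic head:
#' \eqn{H_{eq} = \Delta P_L / (\rho g)}.  Independent of viscosity -- at
#' equilibrium there is no flow and hence no frictional resistance.
#'
#' @inheritParams quasi_steady_velocity
#' @return equilibrium height (m).
#' @examples
#' water <- fluid_properties(998, 1.04, gamma_mN_m = 72.8, theta_deg = 61)
#' equilibrium_height(water, circle_geometry(156.3)) * 1e3  # ~92.3 mm
#' @export
equilibrium_height <- function(fluid, geom, g = 9.81) {
  laplace_pressure(fluid, geom) / (fluid$rho * g)
}

#' Contact angle implied by an observed equilibrium height
#'
#' Inverts the equilibrium balance for the contact angle given a known
#' surface tension: \eqn{\cos\theta = \rho g H_{eq} /
#' (2\gamma(1/a + 1/b))}.  Round-trips with [equilibrium_height()].
#'
#' @param H_eq observed equilibrium height (m, >= 0).
#' @param gamma_mN_m known liquid-air surface tension (mN m^-1).
#' @param rho fluid density (kg m^-3).
#' @param geom a [ellipse_geometry()] object.
#' @param g gravitational acceleration (m s^-2).
#' @return contact angle (degrees); `H_eq = 0` maps to 90 degrees (no
#'   drive).
#' @export
contact_angle_from_equilibrium <- function(H_eq, gamma_mN_m, rho, geom,
                                           g = 9.81) {
  stopifnot(inherits(geom, "capillary_geometry"))
  if (!is.finite(H_eq) || H_eq < 0) stop("'H_eq' must be >= 0")
  gamma <- gamma_mN_m * 1e-3
  cos_theta <- rho * g * H_eq / (2 * gamma * (1 / geom$a + 1 / geom$b))
  if (cos_theta > 1 + 1e-12)
    stop("infeasible observation: H_eq too large for the stated ",
         "surface tension (implied cos(theta) = ", signif(cos_theta, 4), ")")
  if (cos_theta < 0)
    stop("infeasible observation: implied cos(theta) < 0")
  acos(min(cos_theta, 1)) * 180 / pi
}
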