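#' Linear transient fit of velocity against reciprocal height
#'
#' In the regime where the wetted length is dominated by the rise height
#' (L ~ H) the pressure balance predicts a straight line
#' \deqn{u = s \cdot \frac{1}{H} + c, \quad
#'       s = \frac{\Delta P_L d_h^2}{32\mu}, \quad
#'       c = -\frac{\rho g d_h^2}{32\mu},}
#' so ordinary least squares of u on 1/H identifies both the viscosity
#' (from the gravity intercept) and the surface drive (from the slope):
#' \eqn{\mu = -\rho g d_h^2/(32 c)} and \eqn{\sigma_{eff}} from the
#' elliptical Laplace inversion of \eqn{\Delta P_L = 32\mu s/d_h^2}.
#'
#' @param series a `velocity_series` (from [estimate_velocity()]).
#' @param geom the [ellipse_geometry()] of the capillary.
#' @param rho fixed fluid density (kg m^-3); densities are never fitted.
#' @param g gravitational acceleration (m s^-2).
#' @param weight_u_threshold velocities above this (m/s) are down-weighted
#'   by 1/u (early-time estimates carry larger timing noise).
#' @return a `"capfit"` object (`method = "linear"`) whose coefficients are
#'   `sigma_eff` (N/m) and `mu` (Pa s), with `slope`/`intercept` (SI) in
#'   the `linear` element.  A non-negative intercept means the gravity term
#'   was not resolved: the fit is flagged (`intercept_flag`) and `mu` is NA.
#' @export
linear_transient_fit <- function(series, geom, rho, g = 9.81,
                                 weight_u_threshold = 0.02) {
  stopifnot(inherits(geom, "capillary_geometry"))
  d <- series[is.finite(series$inv_H) & series$H_mid > 0, ]
  if (nrow(d) < 5)
    stop("insufficient data: need >= 5 usable velocity points, got ",
         nrow(d))
  if (length(unique(signif(d$inv_H, 12))) < 2)
    stop("insufficient data: velocity observed at a single height")
  u <- d$u_raw
  w <- ifelse(u > weight_u_threshold, weight_u_threshold / u, 1)
  fit <- stats::lm(u ~ inv_H, data = data.frame(u = u, inv_H = d$inv_H),
                   weights = w)
  s <- unname(stats::coef(fit)[2])
  c0 <- unname(stats::coef(fit)[1])
  intercept_flag <- c0 >= 0
  if (intercept_flag) {
    mu <- NA_real_
    sig <- NA_real_
  } else {
    mu <- -rho * g * geom$d_h^2 / (32 * c0)
    dP_L <- 32 * mu * s / geom$d_h^2
    sig <- dP_L / (2 * (1 / geom$a + 1 / geom$b))
  }
  new_capfit(sigma_eff = sig, mu = mu, rho = rho, g = g,
             geometries = list(geom), data = list(d),
             method = "linear", L_dip = 0,
             linear = list(slope = s, intercept = c0,
                           intercept_flag = intercept_flag),
             constraints = NULL)
}

.norm_constraints <- function(constraints) {
  mu_b <- c(1e-5, 1)       # Pa s; generous physical box
  sig_b <- c(1e-4, 0.2)    # N/m
  mu_given <- FALSE
  if (!is.null(constraints)) {
    if (!is.null(constraints$mu_cP)) {
      b <- constraints$mu_cP * 1e-3
      if (!is.na(b[1])) mu_b[1] <- b[1]
      if (!is.na(b[2])) mu_b[2] <- b[2]
      mu_given <- TRUE
    }
    if (!is.null(constraints$sigma_eff)) {
      b <- constraints$sigma_eff
      if (!is.na(b[1])) sig_b[1] <- b[1]
      if (!is.na(b[2])) sig_b[2] <- b[2]
    }
  }
  if (mu_b[1] > mu_b[2] || sig_b[1] > sig_b[2])
    stop("configuration error: infeasible constraint box")
  list(mu = mu_b, sigma = sig_b, mu_given = mu_given)
}

#' Fit the pressure-balance model to capillary-rise velocity data
#'
#' The package's central estimator.  Recovers the combined surface drive
#' \eqn{\sigma_{eff} = \cos\theta\,\gamma} and the dynamic viscosity
#' \eqn{\mu} of a sample by box-constrained least squares on velocity
#' residuals, pooling any number of capillaries (each with its own
#' measured geometry) against the full quasi-steady model
#' \deqn{u(H) = \max\!\left(0, \frac{(\Delta P_L(\sigma_{eff}) - \rho g H)
#'   \, d_h^2}{32 \mu (H + L_{dip})}\right).}
#' Density is fixed, never fitted.  Viscosity bounds expressing the
#' expected physiological range of a sample class (e.g. whole blood
#' between 2 and 6 cP) are applied as box constraints and the fit records
#' whether any bound is active.  The optimiser is Levenberg-Marquardt with
#' box bounds, seeded from the closed-form linear fit, so results are
#' deterministic.
#'
#' @param series a `velocity_series` or a list of them (pooled fit).
#' @param geometry a [ellipse_geometry()] or a list matching `series`.
#' @param rho fixed fluid density (kg m^-3); see [default_densities()].
#' @param constraints optional list with elements `mu_cP = c(lower, upper)`
#'   (cP, NA for an open side; equal bounds fix the viscosity) and/or
#'   `sigma_eff = c(lower, upper)` (N/m).  See [default_constraints()].
#' @param L_dip dip depth (m): the submerged strip length added to the
#'   rise height to form the wetted length.
#' @param g gravitational acceleration (m s^-2).
#' @param weight_u_threshold early-time down-weighting threshold (m/s);
#'   residuals at u above it get weight proportional to 1/u.
#' @param sample_class optional label recorded in reports.
#' @param start optional named start values `c(sigma_eff =, mu =)` (SI).
#' @return An object of class `"capfit"` with methods [print()],
#'   [summary()], [coef()], [predict.capfit()], [residuals()],
#'   [fitted()], [plot.capfit()] and [simulate.capfit()].  Coefficients:
#'   `sigma_eff` (N/m) and `mu` (Pa s).
#' @examples
#' w <- fluid_properties(998, 1.04, sigma_eff = 0.025)
#' geom <- circle_geometry(156.3)
#' tr <- integrate_rise(w, geom, sim_config(total_time = 20))
#' fit <- capillary_fit(estimate_velocity(tr), geom, rho = 998)
#' coef(fit)
#' @export
capillary_fit <- function(series, geometry, rho, constraints = NULL,
                          L_dip = 3e-3, g = 9.81,
                          weight_u_threshold = 0.02, sample_class = NULL,
                          start = NULL) {
  if (inherits(series, "velocity_series")) series <- list(series)
  if (inherits(geometry, "capillary_geometry"))
    geometry <- rep(list(geometry), length(series))
  if (length(geometry) != length(series))
    stop("need one geometry per velocity series")
  box <- .norm_constraints(constraints)

  dat <- list()
  for (j in seq_along(series)) {
    d <- series[[j]][is.finite(series[[j]]$inv_H) & series[[j]]$H_mid > 0, ]
    gj <- geometry[[j]]
    dat[[j]] <- data.frame(H = d$H_mid, u = d$u_raw,
                           inv_ab = 1 / gj$a + 1 / gj$b,
                           dh2 = gj$d_h^2,
                           cap = j)
  }
  dd <- do.call(rbind, dat)
  if (nrow(dd) < 5)
    stop("insufficient data: need >= 5 usable velocity points, got ",
         nrow(dd))
  w <- ifelse(dd$u > weight_u_threshold, weight_u_threshold / pmax(dd$u, 1e-12), 1)
  sw <- sqrt(w)

  model_u <- function(sig, mu) {
    pmax(0, (2 * sig * dd$inv_ab - rho * g * dd$H) * dd$dh2 /
           (32 * mu * (dd$H + L_dip)))
  }

  # Closed-form start: the full model is linear after the transform
  # u * (H + L_dip) = (sigma/mu) * (inv_ab * d_h^2 / 16)
  #                 + (1/mu) * (-rho * g * H * d_h^2 / 32),
  # so weighted OLS without intercept yields consistent start values even
  # when the dip depth breaks the u-vs-1/H linearisation.
  if (is.null(start)) {
    y <- dd$u * (dd$H + L_dip)
    x1 <- dd$inv_ab * dd$dh2 / 16
    x2 <- -rho * g * dd$H * dd$dh2 / 32
    cf <- tryCatch(stats::coef(stats::lm(y ~ x1 + x2 - 1, weights = w)),
                   error = function(e) c(NA_real_, NA_real_))
    sig0 <- unname(cf[1] / cf[2])
    mu0 <- unname(1 / cf[2])
    if (!is.finite(mu0) || mu0 <= 0) mu0 <- sqrt(prod(pmax(box$mu, 1e-5)))
    if (!is.finite(sig0) || sig0 <= 0) sig0 <- 0.03
  } else {
    sig0 <- start[["sigma_eff"]]
    mu0 <- start[["mu"]]
  }
  clip <- function(x, b) min(max(x, b[1]), b[2])
  sig0 <- clip(sig0, box$sigma)
  mu0 <- clip(mu0, box$mu)

  mu_fixed <- box$mu[1] == box$mu[2]
  if (mu_fixed) {
    resid_fn <- function(p) sw * (dd$u - model_u(p[1], box$mu[1]))
    nl <- minpack.lm::nls.lm(par = c(sig0), fn = resid_fn,
                             lower = box$sigma[1], upper = box$sigma[2],
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    sig <- nl$par[1]
    mu <- box$mu[1]
  } else {
    resid_fn <- function(p) sw * (dd$u - model_u(p[1], p[2]))
    nl <- minpack.lm::nls.lm(par = c(sig0, mu0), fn = resid_fn,
                             lower = c(box$sigma[1], box$mu[1]),
                             upper = c(box$sigma[2], box$mu[2]),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    sig <- nl$par[1]
    mu <- nl$par[2]
  }
  on_bound <- function(x, b) {
    tol <- 1e-6 * max(abs(b[is.finite(b)]), 1e-12)
    c(lower = abs(x - b[1]) <= tol, upper = abs(x - b[2]) <= tol)
  }
  active <- list(mu = if (mu_fixed) c(lower = TRUE, upper = TRUE)
                 else on_bound(mu, box$mu),
                 sigma_eff = on_bound(sig, box$sigma))
  u_hat <- model_u(sig, mu)
  new_capfit(sigma_eff = sig, mu = mu, rho = rho, g = g,
             geometries = geometry, data = series, method = "constrained",
             L_dip = L_dip,
             constraints = list(box = box, active = active,
                                any_active = (!mu_fixed && any(active$mu)) ||
                                  any(active$sigma_eff),
                                mu_fixed = mu_fixed),
             pooled = dd, fitted = u_hat, weights = w,
             sample_class = sample_class,
             convergence = list(info = nl$info, message = nl$message,
                                deviance = nl$deviance))
}

#' Surface drive from an equilibrium height alone
#'
#' Equilibrium rise is independent of viscosity (no flow, no friction), so
#' an equilibrium-only observation determines \eqn{\sigma_{eff}} but
#' leaves \eqn{\mu} explicitly not identifiable; the returned fit records
#' that status.
#'
#' @param H_eq observed equilibrium height (m).
#' @param geom a [ellipse_geometry()].
#' @param rho fluid density (kg m^-3).
#' @param g gravitational acceleration (m s^-2).
#' @return a `"capfit"` with `method = "equilibrium"` and `mu = NA`
#'   (`mu_status = "not identifiable"`).
#' @export
fit_from_equilibrium <- function(H_eq, geom, rho, g = 9.81) {
  stopifnot(inherits(geom, "capillary_geometry"), H_eq >= 0)
  sig <- rho * g * H_eq / (2 * (1 / geom$a + 1 / geom$b))
  new_capfit(sigma_eff = sig, mu = NA_real_, rho = rho, g = g,
             geometries = list(geom), data = list(), method = "equilibrium",
             L_dip = 0, constraints = NULL)
}

new_capfit <- function(sigma_eff, mu, rho, g, geometries, data, method,
                       L_dip, constraints, pooled = NULL, fitted = NULL,
                       weights = NULL, linear = NULL, sample_class = NULL,
                       convergence = NULL) {
  H_eq <- if (is.finite(sigma_eff)) {
    mean(vapply(geometries, function(gm)
      2 * sigma_eff * (1 / gm$a + 1 / gm$b) / (rho * g), 0))
  } else NA_real_
  resid <- if (!is.null(pooled) && !is.null(fitted)) pooled$u - fitted
  else NULL
  n_pts <- if (!is.null(pooled)) nrow(pooled)
  else sum(vapply(data, nrow, 0L))
  structure(list(
    coefficients = c(sigma_eff = sigma_eff, mu = mu),
    rho = rho, g = g, L_dip = L_dip, method = method,
    geometries = geometries, data = data, pooled = pooled,
    fitted.values = fitted, residuals = resid, weights = weights,
    H_eq = H_eq,
    residual_rms = if (!is.null(resid)) sqrt(mean(resid^2)) else NA_real_,
    n_points = n_pts, constraints = constraints, linear = linear,
    mu_status = if (is.finite(mu)) "identified" else
      if (identical(method, "equilibrium")) "not identifiable" else "flagged",
    sample_class = sample_class, convergence = convergence
  ), class = "capfit")
}

#' @export
coef.capfit <- function(object, ...) object$coefficients

#' @export
residuals.capfit <- function(object, ...) object$residuals

#' @export
fitted.capfit <- function(object, ...) object$fitted.values

#' Predict model velocities from a fitted pressure balance
#'
#' @param object a `"capfit"`.
#' @param newdata data frame with a column `H` (m) or `inv_H` (1/m).
#' @param geometry which geometry to evaluate on: an index into the fit's
#'   geometry list or a [ellipse_geometry()] (default: first fitted one).
#' @param multiplier viscosity multiplier applied to the fitted mu
#'   (e.g. 2 for a doubled-viscosity curve).
#' @param ... unused.
#' @return numeric vector of velocities (m/s).
#' @export
predict.capfit <- function(object, newdata, geometry = 1L, multiplier = 1,
                           ...) {
  if (!inherits(geometry, "capillary_geometry"))
    geometry <- object$geometries[[geometry]]
  if (multiplier < 1) stop("multiplier must be >= 1")
  H <- if (!is.null(newdata$H)) newdata$H else 1 / newdata$inv_H
  sig <- object$coefficients[["sigma_eff"]]
  mu <- object$coefficients[["mu"]] * multiplier
  if (!is.finite(mu))
    stop("viscosity not identified by this fit (", object$mu_status, ")")
  dP_L <- 2 * sig * (1 / geometry$a + 1 / geometry$b)
  pmax(0, (dP_L - object$rho * object$g * H) * geometry$d_h^2 /
         (32 * mu * (H + object$L_dip)))
}

#' @export
print.capfit <- function(x, ...) {
  cat("Capillary-rise pressure-balance fit (", x$method, ")\n", sep = "")
  if (!is.null(x$sample_class)) cat("  sample class:", x$sample_class, "\n")
  cat(sprintf("  cos(theta)*gamma: %.4f N/m\n",
              x$coefficients[["sigma_eff"]]))
  if (is.finite(x$coefficients[["mu"]]))
    cat(sprintf("  viscosity:        %.3f cP\n",
                x$coefficients[["mu"]] * 1e3))
  else
    cat("  viscosity:        ", x$mu_status, "\n", sep = "")
  cat(sprintf("  fixed density:    %.0f kg/m^3\n", x$rho))
  if (is.finite(x$H_eq))
    cat(sprintf("  implied H_eq:     %.1f mm\n", x$H_eq * 1e3))
  if (is.finite(x$residual_rms))
    cat(sprintf("  residual RMS:     %.3f mm/s on %d points\n",
                x$residual_rms * 1e3, x$n_points))
  if (!is.null(x$constraints) && isTRUE(x$constraints$any_active))
    cat("  note: a constraint bound is active\n")
  invisible(x)
}

#' @export
summary.capfit <- function(object, ...) {
  structure(list(fit = object), class = "summary.capfit")
}

#' @export
print.summary.capfit <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  if (!is.null(f$constraints)) {
    box <- f$constraints$box
    cat(sprintf("  mu bounds:    [%.3g, %.3g] cP%s\n",
                box$mu[1] * 1e3, box$mu[2] * 1e3,
                if (f$constraints$mu_fixed) " (fixed)"
                else if (any(f$constraints$active$mu)) " (ACTIVE)" else ""))
    cat(sprintf("  sigma bounds: [%.3g, %.3g] N/m%s\n",
                box$sigma[1], box$sigma[2],
                if (any(f$constraints$active$sigma_eff)) " (ACTIVE)" else ""))
  }
  if (!is.null(f$linear))
    cat(sprintf("  linear slope %.4g m^2/s, intercept %.4g m/s%s\n",
                f$linear$slope, f$linear$intercept,
                if (f$linear$intercept_flag)
                  " [non-physical intercept: gravity term unresolved]"
                else ""))
  cat(sprintf("  capillaries pooled: %d\n", length(f$geometries)))
  invisible(x)
}

#' Plot a fitted pressure balance as u versus 1/H
#'
#' Scatter of the fitted data in the paper-style diagnostic view
#' (instantaneous velocity against reciprocal height, mm units) with the
#' model curve overlaid.
#'
#' @param x a `"capfit"`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.capfit <- function(x, ...) {
  if (is.null(x$pooled)) stop("nothing to plot for this fit method")
  inv_mm <- 1 / (x$pooled$H * 1e3)
  graphics::plot(inv_mm, x$pooled$u * 1e3, xlab = "1/H (1/mm)",
                 ylab = "dH/dt (mm/s)", pch = 16, cex = 0.5,
                 col = "grey40", ...)
  grid_H <- seq(min(x$pooled$H), max(x$pooled$H), length.out = 200)
  graphics::lines(1 / (grid_H * 1e3),
                  predict(x, data.frame(H = grid_H)) * 1e3,
                  col = "firebrick", lwd = 2)
  invisible(x)
}

#' Simulate trajectories from a fitted model
#'
#' Integrates the rise ODE with the fitted (sigma_eff, mu) and fixed
#' density, on the fitted geometries.
#'
#' @param object a `"capfit"` with identified viscosity.
#' @param nsim number of capillaries to simulate (recycled over the fit's
#'   geometries).
#' @param seed passed to [sim_config()].
#' @param cfg a [sim_config()].
#' @param ... unused.
#' @return list of `rise_trajectory` objects.
#' @export
simulate.capfit <- function(object, nsim = 1, seed = NULL,
                            cfg = sim_config(), ...) {
  mu <- object$coefficients[["mu"]]
  if (!is.finite(mu))
    stop("viscosity not identified by this fit (", object$mu_status, ")")
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  fl <- fluid_properties(object$rho, mu * 1e3,
                         sigma_eff = object$coefficients[["sigma_eff"]])
  lapply(seq_len(nsim), function(i) {
    gm <- object$geometries[[(i - 1L) %% length(object$geometries) + 1L]]
    integrate_rise(fl, gm, cfg)
  })
}

#' Model curves at a family of viscosity multipliers
#'
#' For a fitted baseline, computes u(1/H) curves with the viscosity scaled
#' by each multiplier while the surface property stays fixed -- the
#' diagnostic family used to read a stimulation-induced viscosity increase
#' off velocity data.  Larger multipliers give lower velocity at every
#' height.
#'
#' @param baseline a `"capfit"` with identified viscosity.
#' @param multipliers viscosity multipliers (>= 1); the baseline multiplier
#'   1 is always included.
#' @param geometry geometry to evaluate on (index or object; default the
#'   baseline's first).
#' @return object of class `"multiplier_family"`: the baseline, sorted
#'   multipliers, the geometry and a `predict(m, H)` closure.
#' @export
multiplier_curves <- function(baseline, multipliers = c(2, 3, 4, 6),
                              geometry = 1L) {
  stopifnot(inherits(baseline, "capfit"))
  if (any(multipliers < 1)) stop("multipliers must be >= 1")
  if (!inherits(geometry, "capillary_geometry"))
    geometry <- baseline$geometries[[geometry]]
  m <- sort(unique(c(1, multipliers)))
  structure(list(baseline = baseline, multipliers = m, geometry = geometry,
                 predict = function(mult, H)
                   predict(baseline, data.frame(H = H), geometry = geometry,
                           multiplier = mult)),
            class = "multiplier_family")
}

#' @export
print.multiplier_family <- function(x, ...) {
  cat("Viscosity-multiplier curve family:",
      paste0(x$multipliers, "x", collapse = ", "), "\n")
  print(x$baseline)
  invisible(x)
}

#' Plot a viscosity-multiplier curve family
#'
#' @param x a `"multiplier_family"`.
#' @param H_range height range (m) to draw over.
#' @param series optional `velocity_series` scatter to overlay.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.multiplier_family <- function(x, H_range = c(0.005, NA), series = NULL,
                                   ...) {
  if (is.na(H_range[2]))
    H_range[2] <- 0.95 * x$baseline$H_eq
  Hs <- seq(H_range[1], H_range[2], length.out = 200)
  u1 <- x$predict(1, Hs) * 1e3
  graphics::plot(1 / (Hs * 1e3), u1, type = "l", lwd = 2,
                 xlab = "1/H (1/mm)", ylab = "dH/dt (mm/s)", ...)
  for (m in setdiff(x$multipliers, 1))
    graphics::lines(1 / (Hs * 1e3), x$predict(m, Hs) * 1e3,
                    col = "goldenrod3")
  if (!is.null(series))
    graphics::points(series$inv_H / 1e3, series$u * 1e3, pch = 16,
                     cex = 0.5, col = "grey40")
  invisible(x)
}

#' Classify a stimulated velocity series against a multiplier family
#'
#' Assigns every observation to the nearest family curve (smallest
#' absolute velocity residual; ties resolve to the smaller multiplier).
#' The onset estimate is the first time the best-matching multiplier
#' rises above baseline and stays there for `min_run` consecutive
#' observations; the terminal multiplier is the most common assignment
#' over the last few observations.
#'
#' @param series a `velocity_series`.
#' @param family a [multiplier_curves()] family (>= 2 multipliers).
#' @param min_run consecutive above-baseline observations required to call
#'   onset.
#' @param tail_n observations used for the terminal multiplier.
#' @return list with `assignments` (data frame `time`, `multiplier`,
#'   `residual`), `onset_time` (s, NA if never above baseline) and
#'   `terminal_multiplier`.
#' @export
classify_stimulated_series <- function(series, family, min_run = 3,
                                       tail_n = 5) {
  stopifnot(inherits(family, "multiplier_family"))
  if (length(family$multipliers) < 2)
    stop("family must contain at least 2 multipliers")
  d <- series[is.finite(series$inv_H) & series$H_mid > 0, ]
  if (nrow(d) == 0) stop("insufficient data: empty velocity series")
  pred <- vapply(family$multipliers,
                 function(m) family$predict(m, d$H_mid),
                 numeric(nrow(d)))
  pred <- matrix(pred, nrow = nrow(d))
  res <- abs(pred - d$u)
  best_i <- apply(res, 1, which.min)  # which.min takes the first: smaller m
  best <- family$multipliers[best_i]
  above <- best > 1
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & (r$lengths >= min_run | ends == length(above)))
  onset <- if (length(ok)) d$time[starts[ok[1]]] else NA_real_
  tail_best <- best[max(1, length(best) - tail_n + 1L):length(best)]
  tab <- table(tail_best)
  terminal <- as.numeric(names(tab)[which.max(tab)])
  list(assignments = data.frame(time = d$time, multiplier = best,
                                residual = res[cbind(seq_len(nrow(d)),
                                                     best_i)]),
       onset_time = onset, terminal_multiplier = terminal)
}

#' Percent deviation of recovered parameters from generating truth
#'
#' @param true_params named list/vector of generating values; recognised
#'   names: `sigma_eff` (N/m), `mu` (Pa s), `mu_cP` (cP).
#' @param fit a `"capfit"`.
#' @return list with `deviations_pct` (named, signed) and `max_abs_pct`.
#' @export
recovery_report <- function(true_params, fit) {
  stopifnot(inherits(fit, "capfit"))
  est <- c(sigma_eff = unname(fit$coefficients["sigma_eff"]),
           mu = unname(fit$coefficients["mu"]),
           mu_cP = unname(fit$coefficients["mu"]) * 1e3)
  dev <- c()
  for (nm in names(true_params)) {
    if (!nm %in% names(est)) stop("unknown parameter name: ", nm)
    dev[nm] <- 100 * (est[[nm]] - true_params[[nm]]) / true_params[[nm]]
  }
  list(deviations_pct = dev, max_abs_pct = max(abs(dev)))
}

#' Literature-expected viscosity bounds by sample class
#'
#' The constraint boxes used when fitting each sample class: water and
#' saline fixed at 1.04 cP, plasma below 1.7 cP, red cells and whole blood
#' between 2 and 6 cP.
#'
#' @return named list of `list(mu_cP = c(lower, upper))`, NA = open side.
#' @export
default_constraints <- function() {
  list(water = list(mu_cP = c(1.04, 1.04)),
       HBS = list(mu_cP = c(1.04, 1.04)),
       PPP = list(mu_cP = c(NA, 1.7)),
       PRP = list(mu_cP = c(NA, 1.7)),
       RBC = list(mu_cP = c(2, 6)),
       WB = list(mu_cP = c(2, 6)))
}

#' Read a constraint set from JSON
#'
#' Schema: object keyed by sample class, each with
#' `{"mu_cP": [lower|null, upper|null], "sigma_eff": [lower|null,
#' upper|null]}`.
#'
#' @param path JSON path.
#' @return named list of constraint lists.
#' @export
read_constraints <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(cl) {
    out <- list()
    for (nm in names(cl))
      out[[nm]] <- vapply(cl[[nm]],
                          function(v) if (is.null(v)) NA_real_ else as.numeric(v),
                          0)
    out
  })
}

#' Write a fit report to JSON
#'
#' Schema: `{sample_class, sigma_eff_N_m, mu_cP, rho_kg_m3, H_eq_mm,
#' residual_rms_mm_s, constraints: {mu_cP, sigma_eff, active}, n_points,
#' capillary_ids, seed}`.
#'
#' @param fit a `"capfit"`.
#' @param path output path.
#' @param seed seed recorded in the report.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, seed = NA_integer_) {
  stopifnot(inherits(fit, "capfit"))
  ids <- vapply(seq_along(fit$data), function(j) {
    cid <- attr(fit$data[[j]], "capillary_id")
    if (is.null(cid) || is.na(cid)) j else as.integer(cid)
  }, 0L)
  box <- fit$constraints$box
  jsonlite::write_json(list(
    sample_class = fit$sample_class %||% NA,
    sigma_eff_N_m = unname(fit$coefficients["sigma_eff"]),
    mu_cP = unname(fit$coefficients["mu"]) * 1e3,
    mu_status = fit$mu_status,
    rho_kg_m3 = fit$rho,
    H_eq_mm = fit$H_eq * 1e3,
    residual_rms_mm_s = fit$residual_rms * 1e3,
    constraints = if (is.null(box)) NULL else list(
      mu_cP = box$mu * 1e3, sigma_eff = box$sigma,
      active = isTRUE(fit$constraints$any_active)),
    n_points = fit$n_points,
    capillary_ids = ids,
    seed = seed
  ), path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}
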