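#' Simulation configuration
#'
#' Collects the numerical and noise settings for trajectory simulation.
#' The integrator is an explicit fixed-step 4th-order Runge-Kutta on
#' dH/dt with automatic substep refinement near the wetting front (each
#' macro step is subdivided so the height gain per substep stays below
#' `max_step_height`, which tames the 1/L startup singularity).
#'
#' @param time_step integrator macro step (s).
#' @param total_time simulated duration (s).
#' @param dip_depth submerged strip length L_dip (m); the wetted length is
#'   L = H + L_dip and the dipped portion is taken as filled at t = 0.
#' @param frame_rate recording rate (frames s^-1); trajectories are sampled
#'   at this rate, mirroring the imaging system.
#' @param seed integer seed controlling all simulation noise.
#' @param height_noise_sd multiplicative measurement noise on recorded
#'   heights (fraction; 0.01 = 1 %).
#' @param time_jitter_s half-width of uniform frame-timestamp jitter (s);
#'   jitter is shared by all capillaries within a frame and the jittered
#'   timestamps are what gets recorded.
#' @param g gravitational acceleration (m s^-2).
#' @param max_step_height maximum height gain per RK4 substep (m).
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(time_step = 0.001, total_time = 30, dip_depth = 3e-3,
                       frame_rate = 6, seed = 1L, height_noise_sd = 0.01,
                       time_jitter_s = 0.02, g = 9.81,
                       max_step_height = 5e-5) {
  stopifnot(time_step > 0, total_time > 0, dip_depth > 0, frame_rate > 0,
            height_noise_sd >= 0, time_jitter_s >= 0, g >= 0,
            max_step_height > 0)
  structure(list(time_step = time_step, total_time = total_time,
                 dip_depth = dip_depth, frame_rate = frame_rate,
                 seed = as.integer(seed),
                 height_noise_sd = height_noise_sd,
                 time_jitter_s = time_jitter_s, g = g,
                 max_step_height = max_step_height),
            class = "sim_config")
}

# Vectorised RK4 integration of dH/dt for a set of capillaries sharing one
# fluid and one viscosity schedule.  Returns heights at `record_times`
# (matrix, rows = times) plus the blockage time (NA if flow never gels).
.integrate_heights <- function(record_times, drive, coef, mu0, rho, g,
                               L_dip, cap_len, dt, dh_max,
                               mult_fun = NULL, block_mult = Inf) {
  n <- length(drive)
  H <- numeric(n)
  out <- matrix(NA_real_, nrow = length(record_times), ncol = n)
  blocked_at <- NA_real_
  blocked <- FALSE
  rate <- function(t, h) {
    m <- if (is.null(mult_fun)) 1 else mult_fun(t)
    h <- pmin(h, cap_len)
    u <- (drive - rho * g * h) * coef / (mu0 * m * (h + L_dip))
    u[u < 0 | h >= cap_len] <- 0
    if (blocked) u[] <- 0
    u
  }
  t <- record_times[1]
  if (t != 0) stop("record times must start at 0")
  out[1, ] <- H
  for (k in seq_along(record_times)[-1]) {
    t_next <- record_times[k]
    n_macro <- max(1L, ceiling((t_next - t) / dt))
    h_macro <- (t_next - t) / n_macro
    for (i in seq_len(n_macro)) {
      if (!blocked && !is.null(mult_fun) && mult_fun(t) >= block_mult) {
        blocked <- TRUE
        blocked_at <- t
      }
      u_now <- max(rate(t, H))
      n_sub <- max(1L, ceiling(u_now * h_macro / dh_max))
      h_sub <- h_macro / n_sub
      for (j in seq_len(n_sub)) {
        k1 <- rate(t, H)
        k2 <- rate(t + h_sub / 2, H + h_sub / 2 * k1)
        k3 <- rate(t + h_sub / 2, H + h_sub / 2 * k2)
        k4 <- rate(t + h_sub, H + h_sub * k3)
        H_new <- H + h_sub / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        if (any(H_new < H - 1e-12))
          stop("integration failure: non-monotone height; reduce time_step")
        H <- pmin(H_new, cap_len)
        t <- t + h_sub
      }
      t <- t_next - (n_macro - i) * h_macro  # absorb rounding drift
    }
    out[k, ] <- H
  }
  list(heights = out, blocked_at = blocked_at)
}

.new_trajectory <- function(time, height, capillary_id = 1L, strip_id = 1L,
                            blocked_at = NA_real_) {
  structure(data.frame(time = time, height = height),
            capillary_id = capillary_id, strip_id = strip_id,
            blocked_at = blocked_at,
            class = c("rise_trajectory", "data.frame"))
}

#' Integrate the capillary-rise ODE for one capillary
#'
#' Integrates dH/dt = u(H) with u from [quasi_steady_velocity()] and wetted
#' length L = H + dip_depth, starting from H(0) = 0 with the dipped portion
#' filled.  The trajectory is monotone non-decreasing, bounded by the strip
#' length, and approaches min(H_eq, strip length) at long times.
#'
#' @param fluid a [fluid_properties()] object.
#' @param geom a [ellipse_geometry()] object.
#' @param cfg a [sim_config()]; `height_noise_sd`/`time_jitter_s` are
#'   ignored here (this function is noiseless; see
#'   [simulate_strip_array()] for the noisy array generator).
#' @param schedule optional [viscosity_schedule()] applying a time-varying
#'   viscosity multiplier (thrombin-like stimulation).
#' @return a `rise_trajectory` data frame with columns `time` (s) and
#'   `height` (m), sampled at the frame rate; attributes `capillary_id`,
#'   `strip_id`, `blocked_at`.
#' @examples
#' w <- fluid_properties(998, 1.04, sigma_eff = 0.025)
#' tr <- integrate_rise(w, circle_geometry(156.3), sim_config(total_time = 10))
#' tail(tr, 3)
#' @export
integrate_rise <- function(fluid, geom, cfg = sim_config(), schedule = NULL) {
  stopifnot(inherits(fluid, "fluid_properties"),
            inherits(geom, "capillary_geometry"),
            inherits(cfg, "sim_config"))
  times <- seq(0, cfg$total_time, by = 1 / cfg$frame_rate)
  mult_fun <- NULL
  block <- Inf
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "stimulus_schedule"))
    mult_fun <- function(t) viscosity_multiplier(schedule, t)
    block <- schedule$blockage_multiplier
  }
  res <- .integrate_heights(times,
                            drive = laplace_pressure(fluid, geom),
                            coef = geom$d_h^2 / 32, mu0 = fluid$mu,
                            rho = fluid$rho, g = cfg$g,
                            L_dip = cfg$dip_depth, cap_len = geom$length,
                            dt = cfg$time_step, dh_max = cfg$max_step_height,
                            mult_fun = mult_fun, block_mult = block)
  .new_trajectory(times, drop(res$heights), blocked_at = res$blocked_at)
}

#' Gravity-free closed-form rise height (Washburn limit)
#'
#' With gravity switched off and the wetted length equal to the rise height
#' the pressure-balance ODE separates, giving
#' \eqn{H(t) = \sqrt{\Delta P_L d_h^2 t / (16\mu)}}.  Used as an
#' independent oracle for the numerical integrator.
#'
#' @param fluid a [fluid_properties()] object.
#' @param geom a [ellipse_geometry()] object.
#' @param t time(s) since dipping (s, >= 0).
#' @return height(s) (m).
#' @export
washburn_height <- function(fluid, geom, t) {
  stopifnot(all(t >= 0))
  sqrt(laplace_pressure(fluid, geom) * geom$d_h^2 * t / (16 * fluid$mu))
}

#' Dose-dependent viscosity ramp for stimulated blood
#'
#' Maps a thrombin loading dose to a smooth time-varying viscosity
#' multiplier
#' \deqn{\mu(t)/\mu_0 = 1 + (k - 1)\,\mathrm{logistic}((t - t_{on})/\tau),}
#' emulating the concentration-dependent slow-down of capillary rise after
#' stimulation.  The default dose mapping places the ramp onset within 10 s
#' at the highest dose and between 10 and 30 s at the lowest:
#' `t_on = 5 + 25 exp(-dose/30)` s and plateau
#' `k = 1 + 5 dose/(dose + 25)` (capped at 6).  The dose-to-(k, t_on)
#' mapping is a synthetic stand-in -- the effective thrombin concentration
#' in the rising column is not experimentally accessible -- and can be
#' overridden via `params`.
#'
#' @param dose stimulus loading dose (U mL^-1, >= 0); dose 0 gives k = 1
#'   (no stimulus).
#' @param params optional overrides: any of `k`, `t_on`, `tau`,
#'   `blockage_multiplier`.
#' @return list of class `"stimulus_schedule"` with fields `dose`, `k`,
#'   `t_on` (s), `tau` (s), `blockage_multiplier` (flow is frozen --
#'   gelation -- once the multiplier reaches this).
#' @export
viscosity_schedule <- function(dose, params = list()) {
  if (!is.finite(dose) || dose < 0) stop("'dose' must be >= 0")
  k <- if (dose == 0) 1 else min(6, 1 + 5 * dose / (dose + 25))
  t_on <- 5 + 25 * exp(-dose / 30)
  sch <- list(dose = dose, k = k, t_on = t_on, tau = 1.5,
              blockage_multiplier = 20)
  for (nm in names(params)) sch[[nm]] <- params[[nm]]
  stopifnot(sch$k >= 1, sch$t_on >= 0, sch$tau > 0,
            sch$blockage_multiplier > 1)
  structure(sch, class = "stimulus_schedule")
}

#' Viscosity multiplier of a stimulus schedule at time t
#'
#' @param schedule a [viscosity_schedule()] object.
#' @param t time(s) (s).
#' @return multiplier(s) mu(t)/mu0 (>= 1).
#' @export
viscosity_multiplier <- function(schedule, t) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  1 + (schedule$k - 1) * stats::plogis((t - schedule$t_on) / schedule$tau)
}

#' Simulate capillary rise under thrombin-like stimulation
#'
#' Identical to [integrate_rise()] but with the fluid viscosity replaced by
#' \eqn{\mu_0 \cdot} multiplier(t) from the schedule.  When the multiplier
#' reaches `blockage_multiplier` the column is treated as gelled: heights
#' freeze and the blockage time is recorded in the `blocked_at` attribute.
#'
#' @inheritParams integrate_rise
#' @param schedule a [viscosity_schedule()] object.
#' @return a `rise_trajectory` (see [integrate_rise()]).
#' @export
simulate_stimulated_rise <- function(fluid, geom, schedule,
                                     cfg = sim_config()) {
  integrate_rise(fluid, geom, cfg, schedule = schedule)
}

#' Multi-bore strip layout with realistic bore-to-bore variation
#'
#' Generates per-capillary elliptical geometries for an array of strips.
#' Within each strip the middle bores are slightly wider than the outer
#' two (melt-extrusion narrows the edges); on top of that profile each
#' bore's diameter gets independent lognormal jitter.  The ellipse axes are
#' set so their geometric mean equals the jittered diameter at the chosen
#' aspect ratio.
#'
#' @param n_strips number of strips (default 12).
#' @param capillaries_per_strip bores per strip (default 10).
#' @param mean_diameter_um target mean bore diameter(s) (um); a single
#'   value for all strips or one per strip.
#' @param length_mm strip length (mm).
#' @param aspect_ratio full-axis ratio a/b of the elliptical bores.
#' @param diameter_cv coefficient of variation of the lognormal
#'   bore-diameter jitter (default 0.094, the spread-to-mean ratio of the
#'   smallest printed diameter class).
#' @param edge_factor relative diameter of the two outer bores.
#' @param seed integer seed for the jitter draws.
#' @return list of class `"strip_layout"`: `n_strips`,
#'   `capillaries_per_strip`, `length` (m) and `geometries`, a list (by
#'   strip) of lists (by capillary) of [ellipse_geometry()] objects.
#' @export
strip_layout <- function(n_strips = 12, capillaries_per_strip = 10,
                         mean_diameter_um = 156.3, length_mm = 100,
                         aspect_ratio = 1.2, diameter_cv = 0.094,
                         edge_factor = 0.96, seed = 1L) {
  stopifnot(n_strips >= 1, capillaries_per_strip >= 1, aspect_ratio >= 1,
            diameter_cv >= 0, edge_factor > 0)
  mean_d <- rep_len(mean_diameter_um, n_strips)
  profile <- rep(1, capillaries_per_strip)
  if (capillaries_per_strip >= 3)
    profile[c(1, capillaries_per_strip)] <- edge_factor
  sdlog <- sqrt(log(1 + diameter_cv^2))
  geoms <- withr_seed(seed, {
    lapply(seq_len(n_strips), function(s) {
      jit <- if (diameter_cv > 0)
        exp(stats::rnorm(capillaries_per_strip, -sdlog^2 / 2, sdlog))
      else rep(1, capillaries_per_strip)
      d <- mean_d[s] * profile * jit
      lapply(d, function(di)
        ellipse_geometry(di * sqrt(aspect_ratio), di / sqrt(aspect_ratio),
                         length_mm))
    })
  })
  structure(list(n_strips = n_strips,
                 capillaries_per_strip = capillaries_per_strip,
                 length = length_mm * 1e-3, geometries = geoms),
            class = "strip_layout")
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Simulate a full strip array
#'
#' Produces one rise trajectory per capillary of the layout, with seeded
#' measurement noise emulating the imaging system: multiplicative Gaussian
#' height noise and uniform frame-timestamp jitter (shared across all
#' capillaries within a frame, as a camera exposes the whole array at
#' once).  Identical (layout, fluids, schedules, cfg) input produces
#' bitwise-identical output.
#'
#' @param layout a [strip_layout()].
#' @param fluids a single [fluid_properties()] for every strip, or a list
#'   of one per strip.
#' @param cfg a [sim_config()]; its `seed` drives all noise.
#' @param schedules optional stimulation: a single
#'   [viscosity_schedule()], a list of one per strip, or `NULL`.
#' @return long data frame of class `"trajectory_set"` with columns
#'   `time` (s), `strip_id`, `capillary_id`, `height` (m), `blocked`
#'   (logical); attribute `seed`.
#' @export
simulate_strip_array <- function(layout, fluids, cfg = sim_config(),
                                 schedules = NULL) {
  stopifnot(inherits(layout, "strip_layout"), inherits(cfg, "sim_config"))
  if (inherits(fluids, "fluid_properties"))
    fluids <- rep(list(fluids), layout$n_strips)
  if (length(fluids) != layout$n_strips)
    stop("configuration error: need one fluid per strip (got ",
         length(fluids), " for ", layout$n_strips, " strips)")
  if (inherits(schedules, "stimulus_schedule"))
    schedules <- rep(list(schedules), layout$n_strips)
  if (!is.null(schedules) && length(schedules) != layout$n_strips)
    stop("configuration error: need one schedule per strip or NULL")
  n_frames <- floor(cfg$total_time * cfg$frame_rate)
  base_times <- seq_len(n_frames) / cfg$frame_rate

  withr_seed(cfg$seed, {
    jitter <- if (cfg$time_jitter_s > 0)
      stats::runif(n_frames, -cfg$time_jitter_s, cfg$time_jitter_s)
    else numeric(n_frames)
    times <- c(0, base_times + jitter)
    pieces <- vector("list", layout$n_strips)
    for (s in seq_len(layout$n_strips)) {
      geoms <- layout$geometries[[s]]
      fl <- fluids[[s]]
      sch <- if (is.null(schedules)) NULL else schedules[[s]]
      mult_fun <- if (is.null(sch) || sch$k == 1) NULL else
        function(t) viscosity_multiplier(sch, t)
      block <- if (is.null(sch)) Inf else sch$blockage_multiplier
      res <- .integrate_heights(times,
        drive = vapply(geoms, function(g) laplace_pressure(fl, g), 0),
        coef = vapply(geoms, function(g) g$d_h^2 / 32, 0),
        mu0 = fl$mu, rho = fl$rho, g = cfg$g, L_dip = cfg$dip_depth,
        cap_len = vapply(geoms, function(g) g$length, 0),
        dt = cfg$time_step, dh_max = cfg$max_step_height,
        mult_fun = mult_fun, block_mult = block)
      h <- res$heights
      if (cfg$height_noise_sd > 0)
        h <- h * (1 + matrix(stats::rnorm(length(h), 0, cfg$height_noise_sd),
                             nrow = nrow(h)))
      blocked <- !is.na(res$blocked_at) & times >= res$blocked_at
      pieces[[s]] <- data.frame(
        time = rep(times, times = layout$capillaries_per_strip),
        strip_id = s,
        capillary_id = rep(seq_len(layout$capillaries_per_strip),
                           each = length(times)),
        height = as.vector(h),
        blocked = rep(blocked, times = layout$capillaries_per_strip))
    }
    structure(do.call(rbind, pieces), seed = cfg$seed,
              class = c("trajectory_set", "data.frame"))
  })
}

#' Extract one capillary's trajectory from a trajectory set
#'
#' @param set a `"trajectory_set"` data frame.
#' @param strip_id,capillary_id identifiers.
#' @return a `rise_trajectory`.
#' @export
get_trajectory <- function(set, strip_id, capillary_id) {
  d <- set[set$strip_id == strip_id & set$capillary_id == capillary_id, ]
  if (nrow(d) == 0) stop("no such (strip_id, capillary_id) in set")
  blocked_at <- if (any(d$blocked)) min(d$time[d$blocked]) else NA_real_
  .new_trajectory(d$time, d$height, capillary_id = capillary_id,
                  strip_id = strip_id, blocked_at = blocked_at)
}

#' Write trajectories to the shared CSV schema
#'
#' Long format with columns `time_s, strip_id, capillary_id, height_mm,
#' blocked` (0/1), preceded by a comment line recording the seed and
#' package version.  The schema is identical for simulated and tracked
#' trajectories, so either source feeds the fitting stage.
#'
#' @param set a `"trajectory_set"` (or single `rise_trajectory`).
#' @param path output CSV path.
#' @param seed seed to record in the header (defaults to the set's).
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(set, path, seed = attr(set, "seed")) {
  if (inherits(set, "rise_trajectory")) {
    set <- data.frame(time = set$time,
                      strip_id = attr(set, "strip_id"),
                      capillary_id = attr(set, "capillary_id"),
                      height = set$height,
                      blocked = !is.na(attr(set, "blocked_at")) &
                        set$time >= attr(set, "blocked_at"))
  }
  out <- data.frame(time_s = set$time, strip_id = set$strip_id,
                    capillary_id = set$capillary_id,
                    height_mm = set$height * 1e3,
                    blocked = as.integer(set$blocked))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# capflow %s seed=%s",
                     as.character(utils::packageVersion("capflow")),
                     if (is.null(seed)) "NA" else seed), con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Read trajectories from the shared CSV schema
#'
#' @param path CSV path written by [write_trajectories()] (or by the
#'   meniscus tracker).
#' @return a `"trajectory_set"` data frame (heights converted back to m).
#' @export
read_trajectories <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  need <- c("time_s", "strip_id", "capillary_id", "height_mm", "blocked")
  if (!all(need %in% names(d)))
    stop("trajectory CSV missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  structure(data.frame(time = d$time_s, strip_id = d$strip_id,
                       capillary_id = d$capillary_id,
                       height = d$height_mm * 1e-3,
                       blocked = d$blocked != 0),
            class = c("trajectory_set", "data.frame"))
}
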