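#' Default optics for the synthetic frame renderer
#'
#' @param scale_mm_per_px pixel scale (mm per pixel).  The real system's
#'   scale is not fixed; 0.1 mm/px is the package default and everything
#'   downstream reads the scale from the stack's sidecar metadata.
#' @param col_width_px rendered bore width (pixels).
#' @param gap_px gap between bores of a strip (pixels).
#' @param strip_gap_px gap between strips (pixels).
#' @param margin_px dry margin above the tallest rendered column (pixels).
#' @param bg,fg background (dry) and liquid (wet) grey levels (0-255).
#' @param noise_sd additive Gaussian pixel noise (grey levels).
#' @param seed seed for the pixel noise.
#' @return named list of optics settings.
#' @export
frame_optics <- function(scale_mm_per_px = 0.1, col_width_px = 4,
                         gap_px = 3, strip_gap_px = 10, margin_px = 8,
                         bg = 220, fg = 60, noise_sd = 0, seed = 1L) {
  stopifnot(scale_mm_per_px > 0, col_width_px >= 1, bg > fg, noise_sd >= 0)
  list(scale_mm_per_px = scale_mm_per_px, col_width_px = col_width_px,
       gap_px = gap_px, strip_gap_px = strip_gap_px, margin_px = margin_px,
       bg = bg, fg = fg, noise_sd = noise_sd, seed = as.integer(seed))
}

#' Render synthetic time-lapse frames of a strip array
#'
#' Draws each capillary as a vertical column: liquid renders dark from the
#' reservoir baseline up to the trajectory height, the meniscus edge is
#' anti-aliased by linear partial-pixel coverage, and dry bore plus
#' background stay light.  All capillaries of the set must share common
#' frame timestamps (as produced by [simulate_strip_array()]).
#'
#' @param set a `"trajectory_set"` data frame.
#' @param layout the [strip_layout()] the set was simulated on (defines
#'   the column ordering).
#' @param optics a [frame_optics()] list.
#' @return An object of class `"frame_stack"`: `frames` (list of integer
#'   matrices, grey 0-255), `timestamps` (s), `scale_mm_per_px`,
#'   `baseline_row` (pixel row of the reservoir surface; row 1 is the image
#'   top and heights grow upward from the baseline), and `registration`
#'   (data frame `strip_id, capillary_id, col_start, col_end`).
#' @export
render_frames <- function(set, layout, optics = frame_optics()) {
  stopifnot(inherits(set, "trajectory_set"), inherits(layout, "strip_layout"))
  times <- sort(unique(set$time))
  scale_m <- optics$scale_mm_per_px * 1e-3

  # registration: column ranges per capillary, strips left to right
  reg <- NULL
  col <- 1L
  for (s in seq_len(layout$n_strips)) {
    col <- col + optics$strip_gap_px
    for (k in seq_len(layout$capillaries_per_strip)) {
      reg <- rbind(reg, data.frame(strip_id = s, capillary_id = k,
                                   col_start = col,
                                   col_end = col + optics$col_width_px - 1L))
      col <- col + optics$col_width_px + optics$gap_px
    }
  }
  n_col <- col + optics$strip_gap_px
  h_max <- max(set$height)
  n_above <- ceiling(h_max / scale_m) + optics$margin_px
  baseline_row <- n_above + 1L
  n_row <- baseline_row + 2L  # two reservoir rows below the baseline

  # heights indexed [frame, capillary-in-registration-order]
  hmat <- matrix(NA_real_, nrow = length(times), ncol = nrow(reg))
  for (j in seq_len(nrow(reg))) {
    d <- set[set$strip_id == reg$strip_id[j] &
               set$capillary_id == reg$capillary_id[j], ]
    d <- d[order(d$time), ]
    if (nrow(d) != length(times))
      stop("trajectory set does not share common timestamps across ",
           "capillaries")
    hmat[, j] <- d$height
  }
  over <- hmat > layout$length + 1e-12
  if (any(over)) {
    bad <- which(apply(over, 2, any))[1]
    stop("render error: height exceeds the strip extent for strip ",
         reg$strip_id[bad], " capillary ", reg$capillary_id[bad])
  }

  frames <- withr_seed(optics$seed, {
    lapply(seq_along(times), function(f) {
      img <- matrix(optics$bg, nrow = n_row, ncol = n_col)
      img[(baseline_row):n_row, ] <- optics$fg  # reservoir band
      for (j in seq_len(nrow(reg))) {
        cols <- reg$col_start[j]:reg$col_end[j]
        h_px <- hmat[f, j] / scale_m
        n_full <- floor(h_px)
        if (n_full >= 1)
          img[(baseline_row - n_full):(baseline_row - 1L), cols] <- optics$fg
        frac <- h_px - n_full
        if (frac > 0)
          img[baseline_row - n_full - 1L, cols] <-
            optics$bg + (optics$fg - optics$bg) * frac
      }
      if (optics$noise_sd > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, optics$noise_sd),
                            nrow = n_row)
      matrix(as.integer(pmin(255, pmax(0, round(img)))), nrow = n_row)
    })
  })
  structure(list(frames = frames, timestamps = times,
                 scale_mm_per_px = optics$scale_mm_per_px,
                 baseline_row = baseline_row, registration = reg),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("Frame stack: %d frames of %d x %d px, %.3f mm/px, %d capillaries\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$scale_mm_per_px, nrow(x$registration)))
  invisible(x)
}

#' Write a frame stack as multi-page TIFF plus JSON sidecar
#'
#' @param stack a `"frame_stack"`.
#' @param tiff_path output TIFF path.
#' @param json_path sidecar path (default: `tiff_path` + ".json") holding
#'   timestamps, pixel scale and layout registration.
#' @return `tiff_path`, invisibly.
#' @export
write_frame_stack <- function(stack, tiff_path,
                              json_path = paste0(tiff_path, ".json")) {
  stopifnot(inherits(stack, "frame_stack"))
  tiff::writeTIFF(lapply(stack$frames, function(m) m / 255), tiff_path,
                  bits.per.sample = 8L)
  jsonlite::write_json(list(
    n_frames = length(stack$frames),
    timestamps_s = stack$timestamps,
    scale_mm_per_px = stack$scale_mm_per_px,
    baseline_row = stack$baseline_row,
    registration = stack$registration
  ), json_path, auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param tiff_path TIFF path.
#' @param json_path sidecar path.
#' @return a `"frame_stack"`.
#' @export
read_frame_stack <- function(tiff_path,
                             json_path = paste0(tiff_path, ".json")) {
  if (!file.exists(json_path))
    stop("missing sidecar JSON: ", json_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (length(pages) != meta$n_frames)
    stop("frame stack corrupt: TIFF has ", length(pages),
         " pages but sidecar declares ", meta$n_frames)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    matrix(as.integer(round(p * 255)), nrow = nrow(p))
  })
  structure(list(frames = frames, timestamps = meta$timestamps_s,
                 scale_mm_per_px = meta$scale_mm_per_px,
                 baseline_row = meta$baseline_row,
                 registration = as.data.frame(meta$registration)),
            class = "frame_stack")
}

# Sub-pixel meniscus position (pixels above baseline) from one intensity
# profile ordered upward from the baseline.  Wet/dry grey levels are
# calibrated from the profile itself (medians of the clearly-wet and
# clearly-dry regions), so a global intensity offset cancels.  The meniscus
# pixel is a partial-coverage pixel under the renderer's linear
# anti-aliasing, so inverting the coverage of the pixels flanking the
# threshold crossing recovers the edge position to a small fraction of a
# pixel.
.find_meniscus <- function(prof_up, min_contrast = 40) {
  wet0 <- min(prof_up)
  dry0 <- max(prof_up)
  if (dry0 - wet0 < min_contrast)
    return(list(h_px = 0, flag = "not_wetted"))
  span <- dry0 - wet0
  wet <- stats::median(prof_up[prof_up < wet0 + 0.25 * span])
  dry <- stats::median(prof_up[prof_up > dry0 - 0.25 * span])
  thr <- (wet + dry) / 2
  above <- which(prof_up > thr)
  if (length(above) == 0)
    return(list(h_px = NA_real_, flag = "carried"))  # wet to the top
  k <- above[1]
  cov <- function(i) max(0, min(1, (dry - prof_up[i]) / (dry - wet)))
  h <- if (k == 1L) cov(1) else (k - 2) + cov(k - 1) + cov(k)
  list(h_px = max(0, h), flag = "ok")
}

#' Recover height-time trajectories from a frame stack
#'
#' For each registered capillary and frame, the mean intensity profile over
#' the bore's pixel columns is scanned upward from the reservoir baseline;
#' the meniscus is located as the sub-pixel crossing of the midpoint
#' between the profile's own wet and dry levels (so tracking is invariant
#' to global intensity offsets).  A wetted capillary with no crossing
#' (column wet to the image top) carries the previous height forward with a
#' quality flag.
#'
#' @param stack a `"frame_stack"` with registration metadata.
#' @param min_contrast minimum wet/dry grey-level contrast below which a
#'   column is declared not wetted (height 0).
#' @return a `"trajectory_set"` data frame (columns `time`, `strip_id`,
#'   `capillary_id`, `height` in m, `blocked` = FALSE, `flag`).
#' @export
track_meniscus <- function(stack, min_contrast = 40) {
  stopifnot(inherits(stack, "frame_stack"))
  reg <- stack$registration
  if (is.null(reg) || nrow(reg) == 0)
    stop("configuration error: stack carries no layout registration")
  scale_m <- stack$scale_mm_per_px * 1e-3
  rows_up <- (stack$baseline_row - 1L):1L
  pieces <- vector("list", nrow(reg))
  for (j in seq_len(nrow(reg))) {
    cols <- reg$col_start[j]:reg$col_end[j]
    h <- numeric(length(stack$frames))
    flag <- character(length(stack$frames))
    prev <- 0
    for (f in seq_along(stack$frames)) {
      prof_up <- rowMeans(stack$frames[[f]][rows_up, cols, drop = FALSE])
      m <- .find_meniscus(prof_up, min_contrast)
      if (is.na(m$h_px)) {
        h[f] <- prev
      } else {
        h[f] <- m$h_px * scale_m
        prev <- h[f]
      }
      flag[f] <- m$flag
    }
    pieces[[j]] <- data.frame(time = stack$timestamps,
                              strip_id = reg$strip_id[j],
                              capillary_id = reg$capillary_id[j],
                              height = h, blocked = FALSE, flag = flag)
  }
  structure(do.call(rbind, pieces),
            class = c("trajectory_set", "data.frame"))
}

#' Instantaneous velocity from image-pair height differences
#'
#' Estimates dH/dt from pairs of frames: short pair spacing at early times
#' when the meniscus is fast, then spacing grown geometrically at later
#' times when the velocity is low and timing noise would otherwise
#' dominate.  Each estimate is assigned to the midpoint time, with the
#' paired reciprocal height evaluated at the midpoint height.
#'
#' @param traj a `rise_trajectory` (columns `time`, `height`), or any data
#'   frame with those columns.
#' @param scheme pair-spacing controls: `t_fast` (s; consecutive frames
#'   before this), `dt_max` (s; spacing cap), `t_ramp_end` (s; time by
#'   which spacing reaches `dt_max`).
#' @return An object of class `"velocity_series"`: data frame with columns
#'   `time` (s, pair midpoints), `u` (m/s, clamped at 0), `u_raw` (m/s,
#'   unclamped finite difference), `inv_H` (1/m at the midpoint height),
#'   `H_mid` (m), `clamped` (logical); attributes `capillary_id`,
#'   `strip_id`.  Pairs whose midpoint height is not positive are dropped
#'   (reciprocal height undefined).
#' @examples
#' tr <- data.frame(time = c(1, 1.5), height = c(0.010, 0.013))
#' estimate_velocity(tr)$u  # 6 mm/s
#' @export
estimate_velocity <- function(traj,
                              scheme = list(t_fast = 3, dt_max = 2,
                                            t_ramp_end = 30)) {
  t <- traj$time
  H <- traj$height
  if (length(t) < 2) stop("need at least 2 samples to estimate velocity")
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  frame_dt <- stats::median(diff(t))
  t_fast <- scheme$t_fast %||% 3
  dt_max <- scheme$dt_max %||% 2
  t_ramp <- scheme$t_ramp_end %||% 30
  target <- function(ti) {
    if (ti < t_fast) return(frame_dt)
    g <- (ti - t_fast) / max(t_ramp - t_fast, 1e-9)
    min(dt_max, frame_dt * (dt_max / frame_dt)^min(g, 1))
  }
  i <- 1L
  idx1 <- integer(0)
  idx2 <- integer(0)
  n <- length(t)
  while (i < n) {
    k <- max(1L, round(target(t[i]) / frame_dt))
    j <- min(i + k, n)
    idx1 <- c(idx1, i)
    idx2 <- c(idx2, j)
    i <- j
  }
  u_raw <- (H[idx2] - H[idx1]) / (t[idx2] - t[idx1])
  H_mid <- (H[idx1] + H[idx2]) / 2
  out <- data.frame(time = (t[idx1] + t[idx2]) / 2,
                    u = pmax(0, u_raw), u_raw = u_raw,
                    inv_H = ifelse(H_mid > 0, 1 / H_mid, NA_real_),
                    H_mid = H_mid, clamped = u_raw < 0)
  out <- out[H_mid > 0, ]
  structure(out, capillary_id = attr(traj, "capillary_id"),
            strip_id = attr(traj, "strip_id"),
            class = c("velocity_series", "data.frame"))
}

#' Velocity series for every capillary of a trajectory set
#'
#' @param set a `"trajectory_set"`.
#' @param scheme see [estimate_velocity()].
#' @return named list of `velocity_series`, one per (strip, capillary).
#' @export
estimate_velocities <- function(set,
                                scheme = list(t_fast = 3, dt_max = 2,
                                              t_ramp_end = 30)) {
  ids <- unique(set[, c("strip_id", "capillary_id")])
  out <- vector("list", nrow(ids))
  for (r in seq_len(nrow(ids))) {
    tr <- get_trajectory(set, ids$strip_id[r], ids$capillary_id[r])
    out[[r]] <- estimate_velocity(tr, scheme)
  }
  names(out) <- paste0("s", ids$strip_id, "c", ids$capillary_id)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exact model velocity series at given heights
#'
#' Evaluates the quasi-steady pressure-balance velocity at a set of
#' heights and packages the result as a `velocity_series` -- noiseless
#' model data free of finite-difference error, useful for linear-regime
#' identities and as a fitting oracle.
#'
#' @param fluid a [fluid_properties()].
#' @param geom a [ellipse_geometry()].
#' @param heights meniscus heights (m, > 0), all below the equilibrium
#'   height.
#' @param L_dip dip depth added to the wetted length (m); 0 gives the
#'   L = H linear regime.
#' @param g gravitational acceleration (m s^-2).
#' @return a `velocity_series` data frame.
#' @export
model_velocity_series <- function(fluid, geom, heights, L_dip = 0,
                                  g = 9.81) {
  stopifnot(all(heights > 0))
  u <- vapply(heights, function(h)
    quasi_steady_velocity(fluid, geom, h, h + max(L_dip, 1e-12), g)$u, 0)
  structure(data.frame(time = NA_real_, u = u, u_raw = u,
                       inv_H = 1 / heights, H_mid = heights,
                       clamped = FALSE),
            class = c("velocity_series", "data.frame"))
}
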