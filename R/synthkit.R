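# Synthetic world generator: biased persistent random walks around disk
# aggregates, density movies with Gaussian blobs, and directly sampled run
# databases with known ground-truth parameters.

#' Configuration for a synthetic developmental world
#'
#' Defines the ground truth of a synthetic field of view: disk aggregates
#' (optionally growing and later dispersing), cells performing a biased
#' persistent random walk whose run-duration means depend on the nearest
#' aggregate's area and on the direction of motion, and a density-dependent
#' traffic jam (probability of stopping and stop duration both increase with
#' local density).
#'
#' Durations of persistent runs are exponential with mean `tau_toward(A)` when
#' the cell's motion vector points within 90 degrees of the nearest aggregate
#' centroid and `tau_away(A)` otherwise, where `A` is the nearest aggregate's
#' area (um^2). At the end of a run the cell stops with probability
#' `p_stop(rho)` (exponential stop of mean `tau_stop(rho)` minutes) or reverses
#' (180-degree flip plus Gaussian noise). `rho` is the local synthetic density
#' (background plus Gaussian blobs, arbitrary units).
#'
#' Dispersal is emulated in two ways: an aggregate with a finite `disperse_at`
#' ramps its blob down to zero over `ramp_min` minutes, and, if `flip_time` is
#' set, the toward/away duration means are swapped for aggregates smaller than
#' `flip_area` from `flip_time` onward (cells then move away from small
#' aggregates for longer), with stop probabilities near those aggregates scaled
#' by `flip_pstop_factor`.
#'
#' @param fov numeric length-2, field of view (width, height) in um.
#' @param aggregates data.frame with columns `x`, `y` (centers, um), `r0`
#'   (initial radius, um), `growth` (radius growth rate, um/min), and
#'   `disperse_at` (min; `NA` for never). May have zero rows.
#' @param n_cells number of tracked cells.
#' @param frame_interval trajectory sampling interval (min).
#' @param duration total tracked time (min).
#' @param speed_mean,speed_sd persistent run speed distribution (um/min).
#' @param tau_toward,tau_away functions mapping aggregate area (um^2) to mean
#'   persistent run duration (min) for runs oriented toward/away from the
#'   nearest aggregate. With no aggregate present, the mean of the two
#'   evaluated at area 0 is used (direction is then undefined).
#' @param p_stop function mapping local density to the probability that a
#'   persistent run ends in a stop rather than a reversal.
#' @param tau_stop function mapping local density to the mean stop duration
#'   (min).
#' @param speed_factor function mapping local density to a multiplicative
#'   factor on the run speed (the density-dependent slowdown component of the
#'   traffic jam; the default, identically 1, disables it).
#' @param orientation_noise_sd sd (radians) of the Gaussian noise added to the
#'   orientation at reversals and state changes.
#' @param background_intensity,blob_amplitude,noise_sd density-movie background
#'   level, blob peak amplitude, and additive pixel noise sd (arbitrary units).
#' @param pixel_size movie pixel size (um/px).
#' @param movie_interval density movie frame interval (min).
#' @param flip_time,flip_area,flip_pstop_factor size-dependent dispersal cue:
#'   from `flip_time` (min) onward, aggregates with area below `flip_area`
#'   (um^2) have their toward/away means swapped and their local stop
#'   probability multiplied by `flip_pstop_factor`. `NA` disables.
#' @param ramp_min duration (min) of the linear blob ramp-down after
#'   `disperse_at`.
#' @param no_agg_distance boundary-distance sentinel (um) used when no
#'   aggregate is alive; should be on the scale of the largest observable
#'   boundary distance in the field of view.
#' @param agg_appear time (min) before which the configured aggregates exist
#'   only as density accumulations: the density blobs are present but no
#'   aggregate geometry is reported, emulating the pre-detection epoch in
#'   which incipient accumulations are visible in the density channel but are
#'   not yet segmentable aggregates.
#' @param seed integer RNG seed; all three generators are deterministic given
#'   the configuration.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(fov = c(500, 400),
                         aggregates = data.frame(
                           x = c(150, 360), y = c(150, 250),
                           r0 = c(40, 20), growth = c(0.01, 0.01),
                           disperse_at = c(NA, NA)
                         ),
                         n_cells = 200,
                         frame_interval = 1,
                         duration = 600,
                         speed_mean = 2.5, speed_sd = 0.5,
                         tau_toward = function(A) rep(10, length(A)),
                         tau_away = function(A) rep(7, length(A)),
                         p_stop = function(rho) pmin(0.45, 0.08 + 0.6 * rho),
                         tau_stop = function(rho) 6 + 16 * rho,
                         speed_factor = function(rho) rep(1, length(rho)),
                         orientation_noise_sd = 0.3,
                         background_intensity = 0.05,
                         blob_amplitude = 0.5,
                         noise_sd = 0.005,
                         pixel_size = 2,
                         movie_interval = 15,
                         flip_time = NA, flip_area = NA,
                         flip_pstop_factor = 0.5,
                         ramp_min = 60,
                         no_agg_distance = NO_AGGREGATE_DISTANCE,
                         agg_appear = 0,
                         seed = 1L) {
  cfg <- list(
    fov = as.numeric(fov), aggregates = aggregates, n_cells = n_cells,
    frame_interval = frame_interval, duration = duration,
    speed_mean = speed_mean, speed_sd = speed_sd,
    tau_toward = tau_toward, tau_away = tau_away,
    p_stop = p_stop, tau_stop = tau_stop, speed_factor = speed_factor,
    orientation_noise_sd = orientation_noise_sd,
    background_intensity = background_intensity,
    blob_amplitude = blob_amplitude, noise_sd = noise_sd,
    pixel_size = pixel_size, movie_interval = movie_interval,
    flip_time = flip_time, flip_area = flip_area,
    flip_pstop_factor = flip_pstop_factor, ramp_min = ramp_min,
    no_agg_distance = no_agg_distance, agg_appear = agg_appear,
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(
    length(cfg$fov) == 2, all(cfg$fov > 0),
    cfg$n_cells >= 1, cfg$frame_interval > 0, cfg$duration > 0,
    cfg$pixel_size > 0, cfg$movie_interval > 0
  )
  if (nrow(cfg$aggregates) > 0) {
    need <- c("x", "y", "r0", "growth", "disperse_at")
    if (!all(need %in% names(cfg$aggregates)))
      stop("configuration error: aggregates must have columns ",
           paste(need, collapse = ", "))
  }
  a_grid <- c(0, 10, 1000, 5000, 2e4)
  rho_grid <- c(0, cfg$background_intensity,
                cfg$background_intensity + cfg$blob_amplitude)
  tt <- cfg$tau_toward(a_grid); ta <- cfg$tau_away(a_grid)
  ps <- cfg$p_stop(rho_grid); ts <- cfg$tau_stop(rho_grid)
  sf <- cfg$speed_factor(rho_grid)
  if (!all(is.finite(sf)) || any(sf <= 0))
    stop("configuration error: speed_factor must be positive and finite")
  if (!all(is.finite(tt)) || !all(is.finite(ta)) ||
      !all(is.finite(ps)) || !all(is.finite(ts)))
    stop("configuration error: non-finite parameter function values")
  if (any(tt <= 0) || any(ta <= 0) || any(ts <= 0))
    stop("configuration error: run/stop duration means must be positive")
  if (any(ps < 0) || any(ps > 1))
    stop("configuration error: p_stop must lie in [0, 1]")
  invisible(cfg)
}

# Geometric state of the configured aggregates at time t: radius frozen at the
# dispersal trigger, blob amplitude ramping linearly to zero over ramp_min,
# aggregate removed from nearest-aggregate geometry once fully dispersed.
agg_state_at <- function(cfg, t) {
  ag <- cfg$aggregates
  if (nrow(ag) == 0) {
    return(data.frame(id = integer(), x = numeric(), y = numeric(),
                      radius = numeric(), area = numeric(), amp = numeric()))
  }
  t_grow <- ifelse(is.na(ag$disperse_at), t, pmin(t, ag$disperse_at))
  radius <- ag$r0 + ag$growth * t_grow
  frac <- ifelse(is.na(ag$disperse_at), 1,
                 pmax(0, 1 - pmax(0, t - ag$disperse_at) / cfg$ramp_min))
  alive <- frac > 0
  data.frame(id = seq_len(nrow(ag))[alive], x = ag$x[alive], y = ag$y[alive],
             radius = radius[alive], area = pi * radius[alive]^2,
             amp = (cfg$blob_amplitude * frac)[alive])
}

# Nearest aggregate (by boundary distance, ties to the larger area) for one
# point; NULL when no aggregate is alive.
nearest_agg_at <- function(cfg, x, y, t) {
  if (t < cfg$agg_appear) return(NULL)
  st <- agg_state_at(cfg, t)
  if (nrow(st) == 0) return(NULL)
  dc <- sqrt((st$x - x)^2 + (st$y - y)^2)
  bd <- dc - st$radius
  i <- order(bd, -st$area)[1]
  list(id = st$id[i], area = st$area[i], radius = st$radius[i],
       boundary_distance = bd[i], dist_centroid = dc[i],
       ux = if (dc[i] > 0) (st$x[i] - x) / dc[i] else 0,
       uy = if (dc[i] > 0) (st$y[i] - y) / dc[i] else 0)
}

# Synthetic local density (arbitrary units): background plus Gaussian blobs
# with sigma = radius / 2.
synth_density_at <- function(cfg, x, y, t) {
  st <- agg_state_at(cfg, t)
  rho <- rep(cfg$background_intensity, length(x))
  if (nrow(st) > 0) {
    for (i in seq_len(nrow(st))) {
      s2 <- (st$radius[i] / 2)^2
      rho <- rho + st$amp[i] *
        exp(-((x - st$x[i])^2 + (y - st$y[i])^2) / (2 * s2))
    }
  }
  rho
}

# Toward/away duration means at (area, t) with the size-dependent flip applied.
tau_pair_at <- function(cfg, area, t) {
  tt <- cfg$tau_toward(area)
  ta <- cfg$tau_away(area)
  if (!is.na(cfg$flip_time) && !is.na(cfg$flip_area) &&
      t >= cfg$flip_time && area > 0 && area < cfg$flip_area) {
    c(toward = ta, away = tt)
  } else {
    c(toward = tt, away = ta)
  }
}

p_stop_at <- function(cfg, rho, area, t) {
  p <- cfg$p_stop(rho)
  if (!is.na(cfg$flip_time) && !is.na(cfg$flip_area) &&
      t >= cfg$flip_time && area > 0 && area < cfg$flip_area) {
    p <- p * cfg$flip_pstop_factor
  }
  p
}

#' Expected reversal bias under a synthetic configuration
#'
#' Closed form for the value the run-level reversal-bias estimator converges
#' to under constant-speed, zero-stop conditions. Because toward and away runs
#' alternate one-for-one under pure reversals, run counts in the two strata are
#' equal and the mean duration of all persistent runs is the arithmetic mean
#' of the two conditional means, giving
#' `(tau_toward - tau_away) / ((tau_toward + tau_away) / 2)`.
#'
#' @param cfg a [synth_config()].
#' @param area nearest-aggregate area (um^2) at which to evaluate the duration
#'   means.
#' @param t time (min) at which to evaluate them (the size-dependent flip, if
#'   configured, applies from `flip_time` onward).
#' @return the expected reversal bias (dimensionless).
#' @export
expected_bias <- function(cfg, area = 0, t = 0) {
  tp <- tau_pair_at(cfg, area, t)
  unname((tp["toward"] - tp["away"]) / ((tp["toward"] + tp["away"]) / 2))
}

#' Generate synthetic tracked-cell trajectories
#'
#' Event-driven simulation of `n_cells` biased persistent random walkers (see
#' [synth_config()] for the behavioral model), sampled at `frame_interval`.
#' Boundaries reflect. Deterministic given the configuration seed.
#'
#' @param cfg a [synth_config()].
#' @return a data.frame with columns `cell_id`, `t_min`, `x_um`, `y_um`
#'   (a trajectory table). The attribute `"truth"` holds the ground-truth run
#'   segments (`cell_id`, `state`, `toward`, `t_start`, `t_end`, `end_event`)
#'   used by the test oracles.
#' @export
gen_trajectories <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(derive_seed(cfg$seed, 1L), {
    frames <- seq(0, cfg$duration, by = cfg$frame_interval)
    traj <- vector("list", cfg$n_cells)
    truth <- vector("list", cfg$n_cells)
    for (ci in seq_len(cfg$n_cells)) {
      x <- runif(1, 0, cfg$fov[1]); y <- runif(1, 0, cfg$fov[2])
      theta <- runif(1, 0, 2 * pi)
      t <- 0
      segs <- list()
      while (t < cfg$duration) {
        na <- nearest_agg_at(cfg, x, y, t)
        if (is.null(na)) {
          area <- 0
          tau <- mean(c(cfg$tau_toward(0), cfg$tau_away(0)))
          toward <- NA
        } else {
          area <- na$area
          toward <- (cos(theta) * na$ux + sin(theta) * na$uy) > 0
          tp <- tau_pair_at(cfg, area, t)
          tau <- if (toward) tp["toward"] else tp["away"]
        }
        dur <- rexp(1, 1 / tau)
        speed <- max(0.2 * cfg$speed_mean, rnorm(1, cfg$speed_mean, cfg$speed_sd)) *
          cfg$speed_factor(synth_density_at(cfg, x, y, t))
        t_end <- min(t + dur, cfg$duration)
        xu <- x + speed * cos(theta) * (t_end - t)
        yu <- y + speed * sin(theta) * (t_end - t)
        x1 <- reflect_fold(xu, cfg$fov[1])
        y1 <- reflect_fold(yu, cfg$fov[2])
        # reflections flip the direction of travel; carry the folded-frame
        # orientation forward so reversals flip the actual motion direction
        sx <- if (xu %% (2 * cfg$fov[1]) > cfg$fov[1]) -1 else 1
        sy <- if (yu %% (2 * cfg$fov[2]) > cfg$fov[2]) -1 else 1
        theta_out <- atan2(sy * sin(theta), sx * cos(theta))
        if (t_end >= cfg$duration) {
          segs[[length(segs) + 1]] <- list(
            state = "persistent", toward = toward, t0 = t, t1 = t_end,
            x0 = x, y0 = y, theta = theta, speed = speed,
            end_event = "track_end")
          t <- t_end
          break
        }
        rho <- synth_density_at(cfg, x1, y1, t_end)
        stopped <- runif(1) < p_stop_at(cfg, rho, area, t_end)
        segs[[length(segs) + 1]] <- list(
          state = "persistent", toward = toward, t0 = t, t1 = t_end,
          x0 = x, y0 = y, theta = theta, speed = speed,
          end_event = if (stopped) "state_change" else "reversal")
        x <- x1; y <- y1; t <- t_end; theta <- theta_out
        if (stopped) {
          sdur <- rexp(1, 1 / cfg$tau_stop(rho))
          t_end <- min(t + sdur, cfg$duration)
          segs[[length(segs) + 1]] <- list(
            state = "non-persistent", toward = NA, t0 = t, t1 = t_end,
            x0 = x, y0 = y, theta = theta, speed = 0,
            end_event = if (t_end >= cfg$duration) "track_end" else "state_change")
          t <- t_end
          theta <- theta + rnorm(1, 0, cfg$orientation_noise_sd)
        } else {
          theta <- theta + pi + rnorm(1, 0, cfg$orientation_noise_sd)
        }
      }
      s <- do.call(rbind, lapply(segs, function(g) {
        data.frame(state = g$state, toward = g$toward, t_start = g$t0,
                   t_end = g$t1, x0 = g$x0, y0 = g$y0, theta = g$theta,
                   speed = g$speed, end_event = g$end_event)
      }))
      # positions at frame times
      si <- findInterval(frames, s$t_start)
      dt <- frames - s$t_start[si]
      fx <- reflect_fold(s$x0[si] + s$speed[si] * cos(s$theta[si]) * dt,
                         cfg$fov[1])
      fy <- reflect_fold(s$y0[si] + s$speed[si] * sin(s$theta[si]) * dt,
                         cfg$fov[2])
      traj[[ci]] <- data.frame(cell_id = ci, t_min = frames,
                               x_um = fx, y_um = fy)
      truth[[ci]] <- cbind(cell_id = ci,
                           s[c("state", "toward", "t_start", "t_end",
                               "end_event")])
    }
    out <- do.call(rbind, traj)
    rownames(out) <- NULL
    tr <- do.call(rbind, truth)
    rownames(tr) <- NULL
    attr(out, "truth") <- tr
    out
  })
}

#' Generate a synthetic density movie
#'
#' Frame stack at `movie_interval` cadence: uniform background plus isotropic
#' Gaussian blobs at the configured aggregate centers (sigma = radius / 2),
#' blob amplitudes ramping to zero over `ramp_min` minutes after `disperse_at`,
#' plus additive Gaussian pixel noise. Deterministic given the seed.
#'
#' @param cfg a [synth_config()].
#' @return a [density_movie()] object.
#' @export
gen_density_movie <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(derive_seed(cfg$seed, 2L), {
    times <- seq(0, cfg$duration, by = cfg$movie_interval)
    nx <- max(2L, round(cfg$fov[1] / cfg$pixel_size))
    ny <- max(2L, round(cfg$fov[2] / cfg$pixel_size))
    px <- (seq_len(nx) - 1) * cfg$pixel_size
    py <- (seq_len(ny) - 1) * cfg$pixel_size
    gx <- matrix(px, ny, nx, byrow = TRUE)
    gy <- matrix(py, ny, nx)
    frames <- array(0, dim = c(ny, nx, length(times)))
    for (k in seq_along(times)) {
      f <- matrix(cfg$background_intensity, ny, nx)
      st <- agg_state_at(cfg, times[k])
      if (nrow(st) > 0) {
        for (i in seq_len(nrow(st))) {
          s2 <- (st$radius[i] / 2)^2
          f <- f + st$amp[i] *
            exp(-((gx - st$x[i])^2 + (gy - st$y[i])^2) / (2 * s2))
        }
      }
      if (cfg$noise_sd > 0) f <- f + rnorm(ny * nx, 0, cfg$noise_sd)
      frames[, , k] <- f
    }
    density_movie(frames, pixel_size = cfg$pixel_size,
                  frame_interval = cfg$movie_interval, t0 = 0,
                  times = times)
  })
}

#' Generate a run database directly (bypassing trajectory extraction)
#'
#' Samples run records whose covariates cover the cue space (positions uniform
#' over the field of view, orientations uniform, times uniform over the tracked
#' interval) and whose durations, end events, and speeds follow the same
#' distributions the trajectory generator produces. Intended for fast tests of
#' the statistics and the agent-based model.
#'
#' @param cfg a [synth_config()].
#' @param n_runs number of persistent run rows.
#' @param np_fraction number of non-persistent rows as a fraction of `n_runs`.
#' @param t_coarsen coarsening start used for time binning (defaults to
#'   `flip_time` if set, else the track duration).
#' @return a run database (see [run_database()]).
#' @export
gen_run_database <- function(cfg, n_runs = 5000, np_fraction = 0.3,
                             t_coarsen = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(t_coarsen)) {
    t_coarsen <- if (!is.na(cfg$flip_time)) cfg$flip_time else cfg$duration
  }
  with_seed(derive_seed(cfg$seed, 3L), {
    n <- n_runs
    t_mid <- runif(n, 0, cfg$duration)
    x <- runif(n, 0, cfg$fov[1]); y <- runif(n, 0, cfg$fov[2])
    orient <- runif(n, 0, 2 * pi)
    area <- numeric(n); bdist <- numeric(n); rel <- numeric(n)
    agg_id <- rep(NA_integer_, n); fate <- rep("unknown", n)
    tau <- numeric(n)
    for (i in seq_len(n)) {
      na <- nearest_agg_at(cfg, x[i], y[i], t_mid[i])
      if (is.null(na)) {
        area[i] <- 0; bdist[i] <- cfg$no_agg_distance; rel[i] <- NA_real_
        tau[i] <- mean(c(cfg$tau_toward(0), cfg$tau_away(0)))
      } else {
        area[i] <- na$area
        bdist[i] <- na$boundary_distance
        to_agg <- atan2(na$uy, na$ux)
        rel[i] <- angle_diff(orient[i], to_agg)
        agg_id[i] <- na$id
        fate[i] <- if (is.na(cfg$aggregates$disperse_at[na$id]))
          "stable" else "unstable"
        tp <- tau_pair_at(cfg, area[i], t_mid[i])
        tau[i] <- if (rel[i] < pi / 2) tp["toward"] else tp["away"]
      }
    }
    duration <- rexp(n, 1 / tau)
    speed <- pmax(0.2 * cfg$speed_mean, rnorm(n, cfg$speed_mean, cfg$speed_sd))
    rho <- vapply(seq_len(n),
                  function(i) synth_density_at(cfg, x[i], y[i], t_mid[i]),
                  numeric(1))
    p <- vapply(seq_len(n),
                function(i) p_stop_at(cfg, rho[i], area[i], t_mid[i]),
                numeric(1))
    speed <- speed * cfg$speed_factor(rho)
    ends <- ifelse(runif(n) < p, "state_change", "reversal")
    dtheta <- wrap_angle(rnorm(n, 0, cfg$orientation_noise_sd))
    gamma <- cos(2 * rnorm(n, 0, 0.6))
    pers <- data.frame(
      cell_id = sample.int(max(1L, n %/% 20L), n, replace = TRUE),
      state = "persistent",
      t_start = pmax(0, t_mid - duration / 2),
      t_end = pmin(cfg$duration, t_mid + duration / 2),
      duration = duration, mean_speed = speed,
      distance = speed * duration, orientation = wrap_angle(orient),
      end_event = ends, t_mid = t_mid, local_density = rho,
      alignment_gamma = gamma, delta_orientation = dtheta,
      boundary_distance = bdist, rel_angle = rel,
      nearest_aggregate_id = agg_id, nearest_aggregate_area = area,
      nearest_aggregate_fate = fate
    )
    m <- round(n * np_fraction)
    np <- NULL
    if (m > 0) {
      idx <- sample.int(n, m, replace = TRUE)
      sdur <- rexp(m, 1 / cfg$tau_stop(rho[idx]))
      np <- pers[idx, ]
      np$state <- "non-persistent"
      np$duration <- sdur
      np$t_start <- pmax(0, np$t_mid - sdur / 2)
      np$t_end <- pmin(cfg$duration, np$t_mid + sdur / 2)
      np$mean_speed <- 0; np$distance <- 0
      np$orientation <- NA_real_
      np$end_event <- "state_change"
      np$delta_orientation <- wrap_angle(rnorm(m, 0, cfg$orientation_noise_sd))
    }
    db <- rbind(pers, np)
    rownames(db) <- NULL
    run_database(db, t_start = 0, t_end = cfg$duration, t_coarsen = t_coarsen)
  })
}
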