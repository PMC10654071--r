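# World state, density feedback, and the main simulation loop.

#' Gaussian kernel density field of agent positions
#'
#' Positions are binned to the pixel grid and convolved with an isotropic
#' Gaussian kernel (exact separable convolution, zero padding); the field is
#' normalized to total 1 so that detection thresholds are on the same scale as
#' normalized experimental density frames.
#'
#' @param x,y agent positions (um).
#' @param fov field of view (width, height) in um.
#' @param pixel_size grid pixel size (um/px).
#' @param bandwidth kernel sd (um).
#' @return matrix (rows = y, cols = x) summing to 1.
#' @export
density_field <- function(x, y, fov, pixel_size, bandwidth) {
  stopifnot(length(x) >= 1, length(x) == length(y))
  nx <- max(2L, round(fov[1] / pixel_size))
  ny <- max(2L, round(fov[2] / pixel_size))
  ci <- pmin(pmax(round(x / pixel_size) + 1, 1), nx)
  ri <- pmin(pmax(round(y / pixel_size) + 1, 1), ny)
  counts <- matrix(0, ny, nx)
  counts[] <- tabulate(ri + (ci - 1) * ny, nbins = nx * ny)
  s <- bandwidth / pixel_size
  gy <- exp(-outer(seq_len(ny), seq_len(ny), "-")^2 / (2 * s^2))
  gx <- exp(-outer(seq_len(nx), seq_len(nx), "-")^2 / (2 * s^2))
  f <- gy %*% counts %*% gx
  f / sum(f)
}

#' Detect aggregates in a simulated density field
#'
#' Supra-threshold connected components (8-connectivity). Components smaller
#' than `pinpoint_min_area` are retained in the output but flagged unusable:
#' they are excluded from nearest-aggregate queries.
#'
#' @param field normalized density matrix.
#' @param threshold detection threshold.
#' @param pinpoint_min_area minimum usable area (um^2).
#' @param pixel_size um per pixel.
#' @return list with `table` (id, centroid, area, usable), `label` matrix, and
#'   `boundary` data.frame of usable-component boundary pixels.
#' @export
detect_sim_aggregates <- function(field, threshold, pinpoint_min_area = 300,
                                  pixel_size = 2) {
  lab <- label_components(field > threshold)
  n <- max(lab)
  if (n == 0) {
    return(list(table = data.frame(id = integer(), centroid_x = numeric(),
                                   centroid_y = numeric(), area = numeric(),
                                   usable = logical()),
                label = lab, boundary = NULL))
  }
  tab <- lapply(seq_len(n), function(i) {
    pix <- which(lab == i, arr.ind = TRUE)
    data.frame(id = i, centroid_x = mean(pix[, 2] - 1) * pixel_size,
               centroid_y = mean(pix[, 1] - 1) * pixel_size,
               area = nrow(pix) * pixel_size^2)
  })
  tab <- do.call(rbind, tab)
  tab$usable <- tab$area >= pinpoint_min_area
  bnd <- NULL
  for (i in tab$id[tab$usable]) {
    bp <- component_boundary(lab, i)
    bnd <- rbind(bnd, data.frame(id = i, x_um = (bp[, 2] - 1) * pixel_size,
                                 y_um = (bp[, 1] - 1) * pixel_size))
  }
  list(table = tab, label = lab, boundary = bnd)
}

# Nearest usable simulated aggregate for a set of agents. Returns bdist
# (signed), area, to_agg angle (NA when no aggregate).
sim_nearest_aggregate <- function(aggs, x, y, pixel_size,
                                  no_agg_distance = NO_AGGREGATE_DISTANCE) {
  np <- length(x)
  out <- data.frame(bdist = rep(no_agg_distance, np),
                    area = 0, rel_to = NA_real_, id = NA_integer_)
  tab <- aggs$table[aggs$table$usable, , drop = FALSE]
  if (nrow(tab) == 0) return(out)
  ri <- pmin(pmax(round(y / pixel_size) + 1, 1), nrow(aggs$label))
  ci <- pmin(pmax(round(x / pixel_size) + 1, 1), ncol(aggs$label))
  inside_id <- aggs$label[cbind(ri, ci)]
  # distance to boundary pixels, minimized per component
  bd <- matrix(Inf, np, nrow(tab))
  for (j in seq_len(nrow(tab))) {
    bp <- aggs$boundary[aggs$boundary$id == tab$id[j], ]
    d2 <- outer(x, bp$x_um, "-")^2 + outer(y, bp$y_um, "-")^2
    nearest <- knn_select(d2, 1L)[, 1]
    bd[, j] <- sqrt(d2[cbind(seq_len(np), nearest)])
    bd[inside_id == tab$id[j], j] <- -bd[inside_id == tab$id[j], j]
  }
  for (i in seq_len(np)) {
    j <- order(bd[i, ], -tab$area)[1]
    out$bdist[i] <- bd[i, j]
    out$area[i] <- tab$area[j]
    out$rel_to[i] <- atan2(tab$centroid_y[j] - y[i], tab$centroid_x[j] - x[i])
    out$id[i] <- tab$id[j]
  }
  out
}

# Alignment cue for a subset of agents: nematic alignment to all other agents
# within align_radius.
agent_alignment <- function(world, idx, align_radius) {
  g <- rep(NA_real_, length(idx))
  for (u in seq_along(idx)) {
    i <- idx[u]
    d2 <- (world$x - world$x[i])^2 + (world$y - world$y[i])^2
    nb <- which(d2 <= align_radius^2)
    nb <- nb[nb != i]
    if (length(nb) > 0)
      g[u] <- local_alignment(world$theta[i], world$theta[nb])
  }
  g
}

# Move persistent agents with reflecting boundaries, updating orientations on
# reflection.
advance_agents <- function(world, fov, dt) {
  mv <- world$state == "persistent"
  nx <- world$x + ifelse(mv, world$speed * cos(world$theta) * dt, 0)
  ny <- world$y + ifelse(mv, world$speed * sin(world$theta) * dt, 0)
  fx <- nx < 0 | nx > fov[1]
  fy <- ny < 0 | ny > fov[2]
  world$x <- reflect_fold(nx, fov[1])
  world$y <- reflect_fold(ny, fov[2])
  world$theta[fx] <- wrap_angle(pi - world$theta[fx])
  world$theta[fy] <- wrap_angle(-world$theta[fy])
  world$t_rem <- world$t_rem - dt
  world
}

# Refresh the density field, its agent-side standardization statistics, and
# the detected aggregates.
refresh_field <- function(world, cfg) {
  world$field <- density_field(world$x, world$y, cfg$fov, cfg$pixel_size,
                               cfg$kde_bandwidth)
  v <- bilinear_sample(world$field, world$x / cfg$pixel_size,
                       world$y / cfg$pixel_size)
  world$dens_mu <- mean(v)
  world$dens_sd <- max(sd(v), 1e-12)
  world$aggs <- detect_sim_aggregates(world$field, cfg$agg_threshold,
                                      cfg$pinpoint_min_area, cfg$pixel_size)
  world
}

# Raw cue table for the agents in `idx` against the current world.
agent_cues <- function(world, idx, cfg, use_aggregates = TRUE) {
  v <- bilinear_sample(world$field, world$x[idx] / cfg$pixel_size,
                       world$y[idx] / cfg$pixel_size)
  q <- data.frame(
    density = v, gamma = agent_alignment(world, idx, cfg$align_radius),
    bdist = cfg$no_agg_distance, rel = pi / 2, area = 0)
  dz <- (v - world$dens_mu) / world$dens_sd
  to_agg <- rep(NA_real_, length(idx))
  if (use_aggregates && !is.null(world$aggs)) {
    na <- sim_nearest_aggregate(world$aggs, world$x[idx], world$y[idx],
                                cfg$pixel_size, cfg$no_agg_distance)
    q$bdist <- na$bdist
    q$area <- na$area
    to_agg <- na$rel_to
    has <- !is.na(to_agg)
    q$rel[has] <- angle_diff(world$theta[idx][has], to_agg[has])
  }
  list(q = q, density_std = dz, to_agg = to_agg)
}

# Batched three-search resampling for the agents in `idx`.
resample_batch <- function(world, idx, index, cfg, bin, use_aggregates = TRUE) {
  ac <- agent_cues(world, idx, cfg, use_aggregates)
  phase <- index$bins$phase[bin]
  n <- length(idx)
  event <- character(n); next_state <- character(n)
  # search 1: state transition, within current-state strata
  for (s in unique(world$state[idx])) {
    g <- which(world$state[idx] == s)
    st <- index$strata[[paste(bin, s)]]
    qm <- standardize_query(st, ac$q[g, , drop = FALSE], ac$density_std[g],
                            search_cols(cfg, phase, "state"))
    r <- nn_draw(st, qm, cfg$knn_k)
    event[g] <- st$outcomes$end_event[r]
    next_state[g] <- ifelse(s == "persistent" & event[g] == "state_change",
                            "non-persistent", "persistent")
  }
  flip <- world$state[idx] == "persistent" & event == "reversal"
  new_theta <- numeric(n); speed <- numeric(n); duration <- numeric(n)
  for (s in unique(next_state)) {
    g <- which(next_state == s)
    st <- index$strata[[paste(bin, s)]]
    # search 2: reorientation
    qm <- standardize_query(st, ac$q[g, , drop = FALSE], ac$density_std[g],
                            search_cols(cfg, phase, "orientation"))
    r2 <- nn_draw(st, qm, cfg$knn_k)
    dth <- st$outcomes$delta_orientation[r2]
    th <- wrap_angle(world$theta[idx][g] + ifelse(flip[g], pi, 0) + dth)
    new_theta[g] <- th
    # search 3: speed and duration, with rel_angle after reorienting
    q3 <- ac$q[g, , drop = FALSE]
    has <- !is.na(ac$to_agg[g])
    q3$rel[has] <- angle_diff(th[has], ac$to_agg[g][has])
    qm3 <- standardize_query(st, q3, ac$density_std[g],
                             search_cols(cfg, phase, "duration"))
    r3 <- nn_draw(st, qm3, cfg$knn_k)
    speed[g] <- if (s == "non-persistent") 0 else st$outcomes$speed[r3]
    duration[g] <- st$outcomes$duration[r3]
  }
  world$state[idx] <- next_state
  world$theta[idx] <- new_theta
  world$speed[idx] <- speed
  # durations below the step are indistinguishable at the tracking cadence
  world$t_rem[idx] <- pmax(duration, cfg$dt)
  world
}

#' Initialize the simulated world
#'
#' Agents are placed uniformly at random with uniform orientations, then the
#' world is stepped for `init_duration` minutes using only the density and
#' alignment cues, resampling from database rows within the first
#' `init_sample_window` minutes. The initialization does not advance the main
#' clock. Call inside a seeded context ([run_simulation()] does).
#'
#' @param cfg a [sim_config()].
#' @param db a [run_database()].
#' @return a world state list.
#' @export
init_world <- function(cfg, db) {
  n <- cfg$n_agents
  world <- list(
    x = runif(n, 0, cfg$fov[1]), y = runif(n, 0, cfg$fov[2]),
    theta = runif(n, 0, 2 * pi),
    state = rep("persistent", n), speed = numeric(n), t_rem = numeric(n),
    t = cfg$t_start
  )
  t0 <- min(db$t_mid)
  early <- db[db$t_mid <= t0 + cfg$init_sample_window, ]
  early <- run_database(as.data.frame(early), t_start = t0,
                        t_end = t0 + cfg$init_sample_window)
  init_index <- suppressWarnings(
    build_search_index(early, cue_set = c("density", "gamma")))
  pers <- init_index$strata[[paste(1, "persistent")]]$outcomes
  draw <- sample.int(nrow(pers), n, replace = TRUE)
  world$speed <- pers$speed[draw]
  world$t_rem <- pers$duration[draw]
  world <- refresh_field(world, cfg)
  for (k in seq_len(ceiling(cfg$init_duration / cfg$dt))) {
    world <- advance_agents(world, cfg$fov, cfg$dt)
    ev <- which(world$t_rem <= 0)
    if (length(ev) > 0)
      world <- resample_batch(world, ev, init_index, cfg, 1,
                              use_aggregates = FALSE)
    if (k %% cfg$density_refresh == 0) world <- refresh_field(world, cfg)
  }
  world
}

#' Advance the world by one time step
#'
#' Persistent agents move `speed * dt` along their orientation (reflecting at
#' the boundary); agents whose remaining time reaches zero resample their next
#' behavior against the current field and aggregates; the field and the
#' aggregate list are refreshed every `density_refresh` minutes.
#'
#' @param world a world state from [init_world()].
#' @param cfg a [sim_config()].
#' @param index a [build_search_index()] result.
#' @return the advanced world.
#' @export
step_world <- function(world, cfg, index) {
  world <- advance_agents(world, cfg$fov, cfg$dt)
  world$t <- world$t + cfg$dt
  if ((world$t - cfg$t_start) %% cfg$density_refresh == 0)
    world <- refresh_field(world, cfg)
  ev <- which(world$t_rem <= 0)
  if (length(ev) > 0) {
    bin <- max(1L, findInterval(min(world$t, cfg$t_end - 1e-9),
                                index$bins$t_lo))
    world <- resample_batch(world, ev, index, cfg, bin)
  }
  world
}

#' Run a closed-loop simulation
#'
#' Builds the search index (rebinning the database to the configured time
#' bins), initializes the world, and advances it from `t_start` to `t_end`,
#' recording the density field and the detected aggregates every
#' `density_refresh` minutes. The recorded field movie is then segmented and
#' tracked with the same machinery used for experimental movies, and fates are
#' assigned.
#'
#' @param cfg a [sim_config()].
#' @param db a [run_database()].
#' @param store_movie keep the recorded field movie in the result.
#' @return list of class `sim_result` with `counts` (time series of usable
#'   aggregate count and total area), `aggregates` (an `aggregate_set` from
#'   the recorded movie, with fates), `world` (final state), `cfg`.
#' @export
run_simulation <- function(cfg, db, store_movie = FALSE) {
  db <- run_database(as.data.frame(db), t_start = cfg$t_start,
                     t_end = cfg$t_end, t_coarsen = cfg$t_coarsen,
                     pre_bin_width = cfg$time_bin_pre,
                     coarsening_bins = cfg$coarsening_bins)
  index <- build_search_index(db)
  with_seed(cfg$seed, {
    world <- init_world(cfg, db)
    snaps <- list(world$field)
    counts <- list(data.frame(t = world$t,
                              n_aggregates = sum(world$aggs$table$usable),
                              total_area = sum(world$aggs$table$area[
                                world$aggs$table$usable])))
    n_steps <- round((cfg$t_end - cfg$t_start) / cfg$dt)
    for (k in seq_len(n_steps)) {
      world <- step_world(world, cfg, index)
      if ((world$t - cfg$t_start) %% cfg$density_refresh == 0) {
        snaps[[length(snaps) + 1]] <- world$field
        counts[[length(counts) + 1]] <- data.frame(
          t = world$t, n_aggregates = sum(world$aggs$table$usable),
          total_area = sum(world$aggs$table$area[world$aggs$table$usable]))
      }
    }
    counts <- do.call(rbind, counts)
    movie <- density_movie(
      array(unlist(snaps), dim = c(dim(snaps[[1]]), length(snaps))),
      pixel_size = cfg$pixel_size, frame_interval = cfg$density_refresh,
      t0 = cfg$t_start)
    movie$normalized <- TRUE
    # fate tracking segments down to the movie-analysis floor so that real
    # aggregates dipping below the pinpoint size keep their identity; the
    # pinpoint filter still governs nearest-aggregate queries and counting
    set <- segment_and_track(movie, cfg$agg_threshold, a_seg_min = 100,
                             track_gap = 2)
    set <- label_fates(set)
    out <- list(counts = counts, aggregates = set, world = world, cfg = cfg)
    if (store_movie) out$movie <- movie
    class(out) <- "sim_result"
    out
  })
}

#' Summarize dispersal in a simulation
#'
#' Percent decrease in usable aggregate count between the coarsening start and
#' the end of the simulation, a logistic stability fit on the simulated
#' aggregates (area at the coarsening start versus fate), and the dispersal
#' fraction of aggregates below `area_max` (when given).
#'
#' @param sim a `sim_result`.
#' @param t_coarsen coarsening start (min); defaults to the configuration's.
#' @param area_max optional area cutoff (um^2) for the sub-threshold dispersal
#'   fraction.
#' @param min_age minimum aggregate age (min) at the coarsening start for a
#'   track to enter the fate statistics.
#' @return list with `pct_decrease`, `fit` (or `NULL` if single-class),
#'   `n_at_coarsen`, `n_at_end`, and optionally `sub_dispersal`.
#' @export
dispersal_summary <- function(sim, t_coarsen = NULL, area_max = NULL,
                              min_age = 60) {
  if (is.null(t_coarsen)) t_coarsen <- sim$cfg$t_coarsen
  cts <- sim$counts
  n0 <- cts$n_aggregates[which.min(abs(cts$t - t_coarsen))]
  n1 <- cts$n_aggregates[nrow(cts)]
  pct <- if (n0 > 0) 100 * (n0 - n1) / n0 else NA_real_
  st <- aggregates_at(sim$aggregates, t_coarsen,
                      min_area = sim$cfg$pinpoint_min_area)
  # fate statistics consider formed, stationary aggregates: alive at the
  # coarsening start and at least min_age minutes old by then (conditioning
  # only on pre-coarsening information), excluding tracks that ended by
  # fusing with a neighbor
  fl <- sim$aggregates$flags
  keep <- fl$agg_id[!fl$motile & fl$t_first <= t_coarsen - min_age]
  st <- st[st$agg_id %in% keep & st$fate %in% c("stable", "unstable"), ]
  fit <- NULL
  if (nrow(st) > 0 && length(unique(st$fate)) == 2)
    fit <- logistic_fate_vs_area(st$area_um2, st$fate)
  out <- list(pct_decrease = pct, fit = fit, n_at_coarsen = nrow(st),
              n_at_end = n1)
  if (!is.null(area_max)) {
    sub <- st[st$area_um2 < area_max, ]
    out$sub_dispersal <- if (nrow(sub) > 0) mean(sub$fate == "unstable")
    else NA_real_
  }
  out
}

#' Aggregates alive at a given time
#'
#' @param set an `aggregate_set` with fates.
#' @param t time (min); the nearest recorded frame is used.
#' @param min_area minimum area (um^2).
#' @return data.frame of per-aggregate rows (`agg_id`, `area_um2`, `fate`).
#' @export
aggregates_at <- function(set, t, min_area = 0) {
  k <- which.min(abs(set$times - t))
  rows <- set$tracks[set$tracks$frame == k & set$tracks$area_um2 >= min_area, ]
  merge(rows[, c("agg_id", "area_um2")],
        set$flags[, c("agg_id", "fate")], by = "agg_id")
}
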