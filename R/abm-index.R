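# Cue-matched nearest-neighbour resampling from the run database.

#' Simulation configuration
#'
#' Parameters of the closed-loop data-driven agent-based model. Agents move in
#' straight lines between reversals and stops; their next state, reorientation,
#' speed, and run duration are resampled from an experimental (or synthetic)
#' run database by nearest-neighbour search over standardized cue vectors,
#' performed within time bins and state strata. The density field is a
#' Gaussian kernel density estimate of agent positions, normalized to total 1,
#' refreshed every `density_refresh` simulated minutes, and thresholded to
#' detect in-simulation aggregates.
#'
#' @param fov field of view (width, height) in um.
#' @param n_agents number of agents.
#' @param dt time step (min).
#' @param t_start,t_end simulated interval (min).
#' @param t_coarsen coarsening start (min) used for time binning and for
#'   dropping the density cue.
#' @param kde_bandwidth Gaussian kernel bandwidth (um).
#' @param pixel_size density-grid pixel size (um/px).
#' @param agg_threshold aggregate detection threshold on the normalized
#'   (total = 1) density field. The default is expressed as a multiple of the
#'   uniform pixel mass via `threshold_rel` when `agg_threshold` is `NULL`.
#' @param threshold_rel threshold as a multiple of the uniform density level
#'   (used when `agg_threshold` is `NULL`).
#' @param pinpoint_min_area aggregates below this area (um^2) are excluded
#'   from nearest-aggregate queries.
#' @param time_bin_pre aggregation-phase time-bin width (min).
#' @param coarsening_bins number of coarsening-phase bins.
#' @param cue_flags list with logicals `area_in_state_search`,
#'   `area_in_duration_search`, `density_in_aggregation_phase`,
#'   `density_in_coarsening_phase`.
#' @param knn_k number of nearest neighbours among which the matched run is
#'   drawn uniformly (1 reproduces strict nearest-neighbour copying).
#' @param init_duration length (min) of the initialization phase run before
#'   the main clock starts.
#' @param init_sample_window only database rows from the first this-many
#'   minutes are used during initialization.
#' @param density_refresh interval (min) between density/aggregate updates.
#' @param align_radius neighbor radius (um) for the agent alignment cue.
#' @param no_agg_distance boundary-distance sentinel (um) when no usable
#'   aggregate exists; keep consistent with the run database's sentinel and on
#'   the scale of the largest observable boundary distance.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(fov = c(500, 400), n_agents = 2000, dt = 1,
                       t_start = 0, t_end = 600, t_coarsen = 300,
                       kde_bandwidth = 7, pixel_size = 2,
                       agg_threshold = NULL, threshold_rel = 3,
                       pinpoint_min_area = 300,
                       time_bin_pre = 100, coarsening_bins = 2,
                       cue_flags = list(), knn_k = 20,
                       init_duration = 90, init_sample_window = 20,
                       density_refresh = 15, align_radius = 12,
                       no_agg_distance = NO_AGGREGATE_DISTANCE, seed = 1L) {
  flags <- list(area_in_state_search = FALSE, area_in_duration_search = FALSE,
                density_in_aggregation_phase = TRUE,
                density_in_coarsening_phase = FALSE)
  flags[names(cue_flags)] <- cue_flags
  if (is.null(agg_threshold)) {
    npx <- round(fov[1] / pixel_size) * round(fov[2] / pixel_size)
    agg_threshold <- threshold_rel / npx
  }
  stopifnot(kde_bandwidth > 0, agg_threshold > 0, dt > 0,
            t_end > t_start, n_agents >= 1)
  structure(list(
    fov = fov, n_agents = n_agents, dt = dt, t_start = t_start, t_end = t_end,
    t_coarsen = t_coarsen, kde_bandwidth = kde_bandwidth,
    pixel_size = pixel_size, agg_threshold = agg_threshold,
    pinpoint_min_area = pinpoint_min_area, time_bin_pre = time_bin_pre,
    coarsening_bins = coarsening_bins, cue_flags = flags, knn_k = knn_k,
    init_duration = init_duration, init_sample_window = init_sample_window,
    density_refresh = density_refresh, align_radius = align_radius,
    no_agg_distance = no_agg_distance,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Map a simulation variant name to cue flags
#'
#' `"full"` uses the nearest-aggregate area in both the state and the
#' speed/duration searches, `"bias-only"` only in the speed/duration search,
#' `"jam-only"` only in the state search, `"no-area"` in neither.
#'
#' @param variant one of `"full"`, `"bias-only"`, `"jam-only"`, `"no-area"`.
#' @return a `cue_flags` list.
#' @export
variant_flags <- function(variant = c("full", "bias-only", "jam-only",
                                      "no-area")) {
  variant <- match.arg(variant)
  switch(variant,
    "full" = list(area_in_state_search = TRUE, area_in_duration_search = TRUE),
    "bias-only" = list(area_in_state_search = FALSE,
                       area_in_duration_search = TRUE),
    "jam-only" = list(area_in_state_search = TRUE,
                      area_in_duration_search = FALSE),
    "no-area" = list(area_in_state_search = FALSE,
                     area_in_duration_search = FALSE))
}

CUE_COLS <- c("density", "gamma", "bdist", "rel", "area")

# Raw cue columns from a run database, with the imputation rules:
# missing gamma -> stratum mean (applied later), missing rel_angle -> pi/2,
# missing boundary distance -> sentinel, missing area -> 0.
db_cues <- function(db) {
  data.frame(
    density = db$local_density,
    gamma = db$alignment_gamma,
    bdist = ifelse(is.na(db$boundary_distance), NO_AGGREGATE_DISTANCE,
                   db$boundary_distance),
    rel = ifelse(is.na(db$rel_angle), pi / 2, db$rel_angle),
    area = ifelse(is.na(db$nearest_aggregate_area), 0,
                  db$nearest_aggregate_area)
  )
}

#' Build the nearest-neighbour search index
#'
#' Per (time bin, state) stratum, cue vectors are z-score standardized (equal
#' weight per cue) and stored together with the stratum's outcome columns
#' (end event, reorientation, speed, duration). Cues with zero variance in a
#' stratum are dropped from that stratum's metric with a warning. The density
#' cue is standardized against the stratum's own values; at query time the
#' simulation supplies its densities already standardized against the
#' simulated field's statistics, reconciling the fluorescence and KDE scales.
#'
#' @param db a [run_database()] whose time bins match the simulation's.
#' @param cue_set character subset of `c("density","gamma","bdist","rel",
#'   "area")` to index (the per-search subsets are chosen at query time).
#' @return list of class `search_index` with one stratum per (bin, state).
#' @export
build_search_index <- function(db, cue_set = CUE_COLS) {
  stopifnot(inherits(db, "run_database"))
  bins <- time_bins(db)
  cues <- db_cues(db)
  keep <- db$end_event != "track_end"
  strata <- list()
  for (b in seq_len(nrow(bins))) {
    for (s in c("persistent", "non-persistent")) {
      sel <- which(keep & db$time_bin == b & db$state == s)
      if (length(sel) == 0)
        stop("empty run-database stratum: bin ", b, " (",
             bins$t_lo[b], "-", bins$t_hi[b], " min), state ", s)
      cc <- cues[sel, cue_set, drop = FALSE]
      for (col in names(cc)) {
        v <- cc[[col]]
        if (anyNA(v)) v[is.na(v)] <- mean(v, na.rm = TRUE)
        if (all(is.na(v))) v <- rep(0, length(v))
        cc[[col]] <- v
      }
      mu <- vapply(cc, mean, numeric(1))
      sdv <- vapply(cc, sd, numeric(1))
      usable <- names(cc)[is.finite(sdv) & sdv > 0]
      if (length(usable) < length(cue_set))
        warning("zero-variance cue(s) dropped in bin ", b, " state ", s, ": ",
                paste(setdiff(cue_set, usable), collapse = ", "))
      x <- sweep(sweep(as.matrix(cc[usable]), 2, mu[usable]), 2, sdv[usable],
                 "/")
      strata[[paste(b, s)]] <- list(
        bin = b, state = s, x = x, mu = mu, sd = sdv, usable = usable,
        outcomes = data.frame(
          end_event = db$end_event[sel],
          delta_orientation = ifelse(is.na(db$delta_orientation[sel]), 0,
                                     db$delta_orientation[sel]),
          speed = db$mean_speed[sel], duration = db$duration[sel]))
    }
  }
  structure(list(strata = strata, bins = bins, cue_set = cue_set),
            class = "search_index")
}

# Standardize raw query cues against a stratum. `density_std` entries, when
# not NA, are used as-is (already standardized on the simulation side).
standardize_query <- function(stratum, q_raw, density_std = NULL,
                              cols = stratum$usable) {
  cols <- intersect(cols, stratum$usable)
  qm <- matrix(0, nrow(q_raw), length(cols), dimnames = list(NULL, cols))
  for (col in cols) {
    v <- (q_raw[[col]] - stratum$mu[col]) / stratum$sd[col]
    if (col == "density" && !is.null(density_std)) {
      use <- !is.na(density_std)
      v[use] <- density_std[use]
    }
    v[is.na(v)] <- 0
    qm[, col] <- v
  }
  qm
}

# Draw one matched database row per query: uniform among the knn_k nearest.
nn_draw <- function(stratum, qm, k) {
  if (k > nrow(stratum$x))
    warning("stratum bin ", stratum$bin, " state ", stratum$state,
            " has fewer than k rows; using all")
  nn <- knn_query(stratum$x[, colnames(qm), drop = FALSE], qm, k)
  pick <- sample.int(ncol(nn), nrow(nn), replace = TRUE)
  nn[cbind(seq_len(nrow(nn)), pick)]
}

# Cue columns used by each of the three sequential searches.
search_cols <- function(cfg, phase, which_search) {
  base <- c("gamma", "bdist", "rel")
  dens_ok <- if (phase == "aggregation") cfg$cue_flags$density_in_aggregation_phase
  else cfg$cue_flags$density_in_coarsening_phase
  if (dens_ok) base <- c("density", base)
  if (which_search == "state" && cfg$cue_flags$area_in_state_search)
    base <- c(base, "area")
  if (which_search == "duration" && cfg$cue_flags$area_in_duration_search)
    base <- c(base, "area")
  base
}

#' Resample one agent's next behavior
#'
#' Three sequential nearest-neighbour searches: (1) against rows of the
#' agent's current state, the matched row's end event decides reversal versus
#' state change; (2) against rows of the next state, the matched row's
#' reorientation is copied (applied after adding pi on reversals); (3) with
#' the relative angle recomputed after reorienting, speed and duration are
#' copied jointly from one matched row. Non-persistent draws have speed 0.
#'
#' @param index a [build_search_index()] result.
#' @param cues named list/data.frame row with raw cue values `density`,
#'   `gamma`, `bdist`, `rel`, `area` (`density_std` optionally standardized).
#' @param state the agent's current state.
#' @param bin time-bin index.
#' @param cfg a [sim_config()] (for cue flags and `knn_k`).
#' @param orientation current orientation (radians).
#' @return list with `next_state`, `event`, `delta_orientation`,
#'   `orientation`, `speed`, `duration`.
#' @export
sample_next_behavior <- function(index, cues, state, bin, cfg,
                                 orientation = 0) {
  phase <- index$bins$phase[bin]
  q <- as.data.frame(cues[intersect(names(cues), CUE_COLS)])
  dz <- if (!is.null(cues$density_std)) cues$density_std else NULL

  s1 <- index$strata[[paste(bin, state)]]
  qm <- standardize_query(s1, q, dz, search_cols(cfg, phase, "state"))
  r1 <- nn_draw(s1, qm, cfg$knn_k)
  event <- s1$outcomes$end_event[r1]
  next_state <- if (state == "persistent" && event == "state_change")
    "non-persistent" else "persistent"

  s2 <- index$strata[[paste(bin, next_state)]]
  qm2 <- standardize_query(s2, q, dz, search_cols(cfg, phase, "orientation"))
  r2 <- nn_draw(s2, qm2, cfg$knn_k)
  dth <- s2$outcomes$delta_orientation[r2]
  flip <- state == "persistent" && event == "reversal"
  new_theta <- wrap_angle(orientation + (if (flip) pi else 0) + dth)

  # relative angle after reorienting
  q3 <- q
  if (!is.null(cues$to_agg) && !is.na(cues$to_agg))
    q3$rel <- angle_diff(new_theta, cues$to_agg)
  s3 <- index$strata[[paste(bin, next_state)]]
  qm3 <- standardize_query(s3, q3, dz, search_cols(cfg, phase, "duration"))
  r3 <- nn_draw(s3, qm3, cfg$knn_k)
  speed <- if (next_state == "non-persistent") 0 else s3$outcomes$speed[r3]
  list(next_state = next_state, event = event, delta_orientation = dth,
       orientation = new_theta, speed = speed,
       duration = s3$outcomes$duration[r3])
}
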