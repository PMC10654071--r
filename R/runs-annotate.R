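# Annotation of runs with cue covariates: local density, nematic alignment,
# nearest-aggregate geometry, and time binning into a run database.

#' Nematic (axial) mean angle
#'
#' Mean of axial angles with period pi: `0.5 * atan2(sum(sin 2a), sum(cos 2a))`.
#' The attribute `"resultant"` carries the mean resultant length of the doubled
#' angles; values near zero indicate a degenerate (isotropic) neighbor set.
#'
#' @param angles numeric vector of angles (radians); empty input returns `NA`.
#' @return the axial mean angle in (-pi/2, pi/2], with attribute `"resultant"`.
#' @export
nematic_mean <- function(angles) {
  angles <- angles[!is.na(angles)]
  if (length(angles) == 0) {
    out <- NA_real_
    attr(out, "resultant") <- NA_real_
    return(out)
  }
  s <- sum(sin(2 * angles)); c <- sum(cos(2 * angles))
  out <- 0.5 * atan2(s, c)
  attr(out, "resultant") <- sqrt(s^2 + c^2) / length(angles)
  out
}

#' Local alignment score
#'
#' `gamma = cos(2 * (theta_i - theta_bar))` where `theta_bar` is the nematic
#' mean of the neighbor orientations. Returns `NA` when there are no neighbors
#' or the neighbor set is directionally degenerate (resultant length below
#' `degenerate_tol`).
#'
#' @param theta_i focal cell orientation (radians).
#' @param neighbor_angles orientations of neighboring cells (radians).
#' @param degenerate_tol resultant-length threshold below which the mean angle
#'   is considered undefined.
#' @return gamma in `[-1, 1]`, or `NA`.
#' @export
local_alignment <- function(theta_i, neighbor_angles, degenerate_tol = 1e-8) {
  m <- nematic_mean(neighbor_angles)
  if (is.na(m) || attr(m, "resultant") < degenerate_tol) return(NA_real_)
  cos(2 * (theta_i - as.numeric(m)))
}

# Per-frame axial orientations from centered differences of smoothed positions.
frame_orientations <- function(traj, smooth_frames = 3) {
  out <- lapply(split(traj, traj$cell_id), function(d) {
    d <- d[order(d$t_min), ]
    n <- nrow(d)
    th <- rep(NA_real_, n)
    if (n >= 3) {
      sx <- moving_average(d$x_um, smooth_frames)
      sy <- moving_average(d$y_um, smooth_frames)
      k <- 2:(n - 1)
      dx <- sx[k + 1] - sx[k - 1]; dy <- sy[k + 1] - sy[k - 1]
      ok <- (dx^2 + dy^2) > 1e-12
      th[k][ok] <- atan2(dy[ok], dx[ok])
    }
    data.frame(cell_id = d$cell_id, t_min = d$t_min,
               x_um = d$x_um, y_um = d$y_um, theta = th)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$t_min), ]
}

#' Annotate runs with cue covariates
#'
#' Adds, per run: `local_density` (bilinear sample of the nearest normalized
#' density frame at the run midpoint), `alignment_gamma` (nematic alignment to
#' neighbors within `align_radius` um over the `align_window` min before the
#' run start, other cells only), `delta_orientation` (signed smallest angle
#' from the previous oriented run of the same cell, measured relative to the
#' flipped direction when the preceding event was a reversal),
#' `boundary_distance`
#' (signed distance to the nearest aggregate boundary at the run start,
#' negative inside), `rel_angle` (angle between the run orientation and the
#' direction to the nearest aggregate centroid), and the nearest aggregate's
#' id, area, and fate. Runs whose nearest aggregate is flagged as partially in
#' the field of view are dropped. When no aggregate exists at a run's time the
#' sentinel covariates are used (`boundary_distance = no_agg_distance`,
#' `area = 0`, `rel_angle = NA`).
#'
#' @param runs run data.frame from [segment_runs()].
#' @param density_movie a normalized [density_movie()] or `NULL`.
#' @param aggregates an aggregate set (see [nearest_aggregate()]) or `NULL`.
#' @param trajectories the full trajectory table (for the alignment cue) or
#'   `NULL`.
#' @param params a [run_params()] list.
#' @param t_coarsen,t_start,t_end time binning passed to [run_database()];
#'   `t_coarsen = NULL` places all runs in aggregation-phase bins.
#' @param fov optional field-of-view (width, height) in um; when given (with
#'   `trajectories`), runs during which the cell comes within
#'   `boundary_margin` um of the field edge are flagged `boundary_touch`.
#'   Reflecting-boundary artifacts masquerade as reversals, so bias statistics
#'   on synthetic worlds should exclude flagged runs.
#' @param boundary_margin wall margin (um) for the boundary-touch flag.
#' @return a [run_database()].
#' @export
annotate_runs <- function(runs, density_movie = NULL, aggregates = NULL,
                          trajectories = NULL, params = run_params(),
                          t_coarsen = NULL, t_start = NULL, t_end = NULL,
                          fov = NULL, boundary_margin = 5) {
  runs <- runs[order(runs$cell_id, runs$t_start), ]
  n <- nrow(runs)

  # local density at run midpoint, nearest frame in time
  runs$local_density <- NA_real_
  if (!is.null(density_movie)) {
    mt <- movie_times(density_movie)
    if (any(runs$t_mid < mt[1]))
      warning("runs before the first density frame use the nearest frame")
    fi <- vapply(runs$t_mid, function(t) which.min(abs(mt - t)), integer(1))
    ps <- density_movie$pixel_size
    for (k in unique(fi)) {
      sel <- fi == k
      runs$local_density[sel] <- bilinear_sample(
        density_movie$frames[, , k],
        runs$x_mid[sel] / ps, runs$y_mid[sel] / ps)
    }
  }

  # alignment gamma from neighboring tracked cells
  runs$alignment_gamma <- NA_real_
  if (!is.null(trajectories)) {
    fo <- frame_orientations(trajectories, params$smooth_frames)
    tvec <- fo$t_min
    for (i in seq_len(n)) {
      lo <- findInterval(runs$t_start[i] - params$align_window - 1e-9, tvec) + 1L
      hi <- findInterval(runs$t_start[i] + 1e-9, tvec)
      if (hi < lo) next
      nb <- fo[lo:hi, ]
      nb <- nb[nb$cell_id != runs$cell_id[i] & !is.na(nb$theta), ]
      if (nrow(nb) == 0) next
      d2 <- (nb$x_um - runs$x_start[i])^2 + (nb$y_um - runs$y_start[i])^2
      nb <- nb[d2 <= params$align_radius^2, ]
      if (nrow(nb) == 0) next
      th_i <- if (!is.na(runs$orientation[i])) runs$orientation[i] else next
      runs$alignment_gamma[i] <- local_alignment(th_i, nb$theta)
    }
  }

  # delta orientation from the previous oriented run of the same cell; turns
  # entering a run through a reversal are measured relative to the flipped
  # direction (pi subtracted), so values are comparable across event types
  runs$delta_orientation <- NA_real_
  prev_theta <- NA_real_; prev_cell <- NA; prev_end <- NA_character_
  for (i in seq_len(n)) {
    if (!identical(runs$cell_id[i], prev_cell)) {
      prev_cell <- runs$cell_id[i]
      prev_theta <- NA_real_; prev_end <- NA_character_
    }
    if (!is.na(runs$orientation[i])) {
      if (!is.na(prev_theta)) {
        flip <- if (identical(prev_end, "reversal")) pi else 0
        runs$delta_orientation[i] <-
          wrap_angle(runs$orientation[i] - prev_theta - flip)
      }
      prev_theta <- runs$orientation[i]
    }
    prev_end <- runs$end_event[i]
  }

  # nearest aggregate covariates at the run start
  runs$boundary_distance <- params$no_agg_distance
  runs$rel_angle <- NA_real_
  runs$nearest_aggregate_id <- NA_integer_
  runs$nearest_aggregate_area <- 0
  runs$nearest_aggregate_fate <- "unknown"
  drop <- rep(FALSE, n)
  if (!is.null(aggregates)) {
    qt <- aggregate_query_times(aggregates, runs$t_start)
    for (tq in unique(qt)) {
      sel <- which(qt == tq)
      na <- nearest_aggregate(aggregates, runs$x_start[sel],
                              runs$y_start[sel], tq)
      if (is.null(na)) next
      runs$boundary_distance[sel] <- na$boundary_distance
      runs$nearest_aggregate_id[sel] <- na$id
      runs$nearest_aggregate_area[sel] <- na$area
      runs$nearest_aggregate_fate[sel] <- na$fate
      to_agg <- atan2(na$uy, na$ux)
      to_agg[na$ux == 0 & na$uy == 0] <- NA  # at the centroid
      orient <- if ("orientation_start" %in% names(runs))
        ifelse(is.na(runs$orientation_start[sel]), runs$orientation[sel],
               runs$orientation_start[sel]) else runs$orientation[sel]
      runs$rel_angle[sel] <- angle_diff(orient, to_agg)
      drop[sel] <- drop[sel] | (na$partial_fov %in% TRUE)
      none <- is.na(na$id)
      if (any(none)) {
        runs$boundary_distance[sel][none] <- params$no_agg_distance
        runs$nearest_aggregate_area[sel][none] <- 0
        runs$nearest_aggregate_fate[sel][none] <- "unknown"
        runs$rel_angle[sel][none] <- NA_real_
      }
    }
    # nearest-aggregate distance at the run end: state transitions happen
    # where the run ends, so transition statistics stratify on this
    if (all(c("x_end", "y_end") %in% names(runs))) {
      runs$boundary_distance_end <- params$no_agg_distance
      qt2 <- aggregate_query_times(aggregates, runs$t_end)
      for (tq in unique(qt2)) {
        sel <- which(qt2 == tq)
        na <- nearest_aggregate(aggregates, runs$x_end[sel],
                                runs$y_end[sel], tq)
        if (is.null(na)) next
        bd <- ifelse(is.na(na$id), params$no_agg_distance,
                     na$boundary_distance)
        runs$boundary_distance_end[sel] <- bd
      }
    }
  }
  runs <- runs[!drop, ]

  # flag runs that graze the field edge (reflection artifacts)
  runs$boundary_touch <- FALSE
  if (!is.null(fov) && !is.null(trajectories)) {
    wall <- pmin(trajectories$x_um, fov[1] - trajectories$x_um,
                 trajectories$y_um, fov[2] - trajectories$y_um)
    for (ci in unique(runs$cell_id)) {
      d <- trajectories[trajectories$cell_id == ci, ]
      wd <- wall[trajectories$cell_id == ci][order(d$t_min)]
      tm <- sort(d$t_min)
      for (i in which(runs$cell_id == ci)) {
        fr <- tm >= runs$t_start[i] & tm <= runs$t_end[i]
        runs$boundary_touch[i] <- any(wd[fr] < boundary_margin)
      }
    }
  }
  if (is.null(t_start)) t_start <- min(runs$t_start)
  if (is.null(t_end)) t_end <- max(runs$t_end)
  run_database(runs, t_start = t_start, t_end = t_end, t_coarsen = t_coarsen)
}

#' Build a run database with time bins
#'
#' Assigns each run (by `t_mid`) to a time bin: aggregation-phase bins of
#' `pre_bin_width` minutes up to `t_coarsen`, then `coarsening_bins` bins of
#' equal length up to `t_end`.
#'
#' @param runs annotated run data.frame.
#' @param t_start,t_end analysis interval (min).
#' @param t_coarsen coarsening start (min); `NULL` or a value at/after `t_end`
#'   yields aggregation bins only.
#' @param pre_bin_width aggregation-phase bin width (min).
#' @param coarsening_bins number of coarsening-phase bins.
#' @return the runs with a `time_bin` column, class `run_database`, and
#'   attribute `time_bins` (data.frame `t_lo`, `t_hi`, `phase`).
#' @export
run_database <- function(runs, t_start, t_end, t_coarsen = NULL,
                         pre_bin_width = 100, coarsening_bins = 2) {
  if (is.null(t_coarsen) || t_coarsen >= t_end) t_coarsen <- t_end
  pre_edges <- unique(c(seq(t_start, t_coarsen, by = pre_bin_width), t_coarsen))
  bins <- data.frame(t_lo = head(pre_edges, -1), t_hi = tail(pre_edges, -1),
                     phase = "aggregation")
  if (t_coarsen < t_end && coarsening_bins >= 1) {
    ce <- seq(t_coarsen, t_end, length.out = coarsening_bins + 1)
    bins <- rbind(bins, data.frame(t_lo = head(ce, -1), t_hi = tail(ce, -1),
                                   phase = "coarsening"))
  }
  bins <- bins[bins$t_hi > bins$t_lo, ]
  rownames(bins) <- NULL
  idx <- findInterval(pmin(pmax(runs$t_mid, t_start), t_end - 1e-9),
                      c(bins$t_lo, t_end), rightmost.closed = TRUE)
  runs$time_bin <- pmin(pmax(idx, 1L), nrow(bins))
  attr(runs, "time_bins") <- bins
  class(runs) <- c("run_database", class(runs))
  runs
}

#' Time bins of a run database
#' @param db a [run_database()].
#' @return data.frame of bins (`t_lo`, `t_hi`, `phase`).
#' @export
time_bins <- function(db) attr(db, "time_bins")

# Toward/away classification of persistent runs from rel_angle.
# Returns "toward", "away", or NA (excluded).
toward_away <- function(rel_angle, split = "half") {
  out <- rep(NA_character_, length(rel_angle))
  if (split == "restricted45") {
    out[rel_angle < pi / 4] <- "toward"
    out[rel_angle > 3 * pi / 4] <- "away"
  } else {
    out[rel_angle < pi / 2] <- "toward"
    out[rel_angle > pi / 2] <- "away"
  }
  out
}
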