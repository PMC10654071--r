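# Coarse-graining of cell trajectories into persistent / non-persistent runs
# delimited by state changes and reversals.

#' Parameters for run extraction and annotation
#'
#' Calibration knobs for the trajectory coarse-graining. Defaults were
#' calibrated against the synthetic generator's ground truth at a 1-min frame
#' cadence; see the methods vignette for the calibration rationale.
#'
#' @param v_min minimum windowed mean speed (um/min) for a persistent frame.
#' @param d_min minimum windowed net displacement (um) for a persistent frame.
#' @param w_state state-classification window (min, centered).
#' @param dwell_min minimum bout length (frames); shorter bouts are merged into
#'   the flanking label, and reversals closer than this are suppressed.
#' @param smooth_frames moving-average window (frames) for position smoothing.
#' @param theta_rev minimum angle (radians) between pre/post displacement
#'   vectors for a reversal.
#' @param rev_halfwin half-window (frames) over which the pre/post displacement
#'   vectors are accumulated.
#' @param align_radius neighbor radius (um) for the local alignment score.
#' @param align_window how far back in time (min) neighbors are collected.
#' @param no_agg_distance boundary-distance sentinel (um) used when no
#'   aggregate exists.
#' @param toward_split `"half"` classifies runs with relative angle below pi/2
#'   as toward (and above as away); `"restricted45"` uses below pi/4 vs above
#'   3*pi/4, discarding intermediate orientations.
#' @return a list of class `run_params`.
#' @export
run_params <- function(v_min = 1.0, d_min = 1.0, w_state = 3,
                       dwell_min = 2, smooth_frames = 3,
                       theta_rev = 2 * pi / 3, rev_halfwin = 2,
                       align_radius = 12, align_window = 7,
                       no_agg_distance = NO_AGGREGATE_DISTANCE,
                       toward_split = c("half", "restricted45")) {
  p <- list(v_min = v_min, d_min = d_min, w_state = w_state,
            dwell_min = dwell_min, smooth_frames = smooth_frames,
            theta_rev = theta_rev, rev_halfwin = rev_halfwin,
            align_radius = align_radius, align_window = align_window,
            no_agg_distance = no_agg_distance,
            toward_split = match.arg(toward_split))
  class(p) <- "run_params"
  p
}

check_trajectories <- function(traj) {
  need <- c("cell_id", "t_min", "x_um", "y_um")
  if (!all(need %in% names(traj)))
    stop("trajectory table must have columns ", paste(need, collapse = ", "))
  invisible(traj)
}

# merge bouts shorter than dwell_min into their flanking label
merge_short_bouts <- function(lab, dwell_min) {
  repeat {
    r <- rle(lab)
    if (length(r$lengths) <= 1) return(lab)
    short <- which(r$lengths < dwell_min)
    if (length(short) == 0) return(lab)
    i <- short[which.min(r$lengths[short])]
    r$values[i] <- if (i == 1) r$values[2] else r$values[i - 1]
    lab <- inverse.rle(r)
  }
}

#' Classify trajectory frames as persistent or non-persistent
#'
#' A frame is persistent iff, over a centered window of `w_state` minutes on
#' smoothed positions, the windowed mean speed is at least `v_min` and the
#' windowed net displacement is at least `d_min`. Bouts shorter than
#' `dwell_min` frames are merged into the flanking label. Tracks shorter than
#' the window are labeled non-persistent with a warning.
#'
#' @param traj trajectory table (`cell_id`, `t_min`, `x_um`, `y_um`).
#' @param params a [run_params()] list.
#' @return data.frame (`cell_id`, `t_min`, `persistent`).
#' @export
classify_states <- function(traj, params = run_params()) {
  check_trajectories(traj)
  out <- lapply(split(traj, traj$cell_id), function(d) {
    d <- d[order(d$t_min), ]
    n <- nrow(d)
    dt <- if (n > 1) median(diff(d$t_min)) else 1
    hw <- max(1L, as.integer(round(params$w_state / dt / 2)))
    if (n < 2 * hw + 1) {
      warning("track ", d$cell_id[1], " shorter than the state window; ",
              "labeled non-persistent")
      return(data.frame(cell_id = d$cell_id, t_min = d$t_min,
                        persistent = FALSE))
    }
    # classification runs on raw positions: smoothing blurs the sharp 180-degree
    # turn at a reversal into an apparent 2-3 frame stop
    sx <- d$x_um
    sy <- d$y_um
    steps <- c(sqrt(diff(sx)^2 + diff(sy)^2), 0)
    cs <- cumsum(c(0, steps))
    lo <- pmax(seq_len(n) - hw, 1)
    hi <- pmin(seq_len(n) + hw, n)
    path <- cs[hi] - cs[lo]
    span <- d$t_min[hi] - d$t_min[lo]
    disp <- sqrt((sx[hi] - sx[lo])^2 + (sy[hi] - sy[lo])^2)
    lab <- (path / span) >= params$v_min & disp >= params$d_min
    lab <- merge_short_bouts(lab, params$dwell_min)
    data.frame(cell_id = d$cell_id, t_min = d$t_min, persistent = lab)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Detect reversals within persistent segments
#'
#' A reversal is emitted at frame `k` when the angle between the displacement
#' vectors accumulated over `rev_halfwin` frames before and after `k` exceeds
#' `theta_rev`. Consecutive candidates are clustered and the frame with the
#' largest angle is kept; events closer than `dwell_min` frames are suppressed
#' (first kept).
#'
#' @param traj trajectory table.
#' @param states output of [classify_states()].
#' @param params a [run_params()] list.
#' @return data.frame (`cell_id`, `t_min`) of reversal events.
#' @export
detect_reversals <- function(traj, states, params = run_params()) {
  check_trajectories(traj)
  st <- states[order(states$cell_id, states$t_min), ]
  out <- lapply(split(traj, traj$cell_id), function(d) {
    d <- d[order(d$t_min), ]
    n <- nrow(d)
    L <- params$rev_halfwin
    if (n < 2 * L + 1) return(NULL)
    pers <- st$persistent[st$cell_id == d$cell_id[1]]
    k <- (L + 1):(n - L)
    pre <- cbind(d$x_um[k] - d$x_um[k - L], d$y_um[k] - d$y_um[k - L])
    post <- cbind(d$x_um[k + L] - d$x_um[k], d$y_um[k + L] - d$y_um[k])
    ang <- vector_angle(pre, post)
    cand <- k[!is.na(ang) & ang > params$theta_rev & pers[k]]
    angs <- ang[match(cand, k)]
    # skip-frame test: single-frame displacements on either side of the gap
    # (k, k+1) resolve reversals flanked by runs as short as one frame
    kg <- 2:(n - 2)
    u <- cbind(d$x_um[kg] - d$x_um[kg - 1], d$y_um[kg] - d$y_um[kg - 1])
    w <- cbind(d$x_um[kg + 2] - d$x_um[kg + 1], d$y_um[kg + 2] - d$y_um[kg + 1])
    ang2 <- vector_angle(u, w)
    hit <- which(!is.na(ang2) & ang2 > params$theta_rev &
                   pers[kg] & pers[kg + 1])
    if (length(hit) > 0) {
      kk <- kg[hit]
      # place the event before or after the mixed step by its projection on
      # the outgoing direction
      proj <- rowSums((cbind(d$x_um[kk + 1] - d$x_um[kk],
                             d$y_um[kk + 1] - d$y_um[kk])) * w[hit, , drop = FALSE])
      at <- ifelse(proj > 0, kk, kk + 1L)
      cand <- c(cand, at)
      angs <- c(angs, ang2[hit])
      o <- order(cand)
      cand <- cand[o]; angs <- angs[o]
      dup <- duplicated(cand)
      if (any(dup)) {
        angs <- vapply(split(angs, cand), max, numeric(1))
        cand <- sort(unique(cand))
      }
    }
    if (length(cand) == 0) return(NULL)
    # cluster adjacent candidate frames, keep the max-angle frame
    grp <- cumsum(c(1, diff(cand) > 1))
    keep <- vapply(split(seq_along(cand), grp), function(ix) {
      ix[which.max(angs[ix])]
    }, integer(1))
    ev <- cand[keep]
    # dwell suppression
    if (length(ev) > 1) {
      sel <- ev[1]
      for (e in ev[-1]) if (e - sel[length(sel)] >= params$dwell_min)
        sel <- c(sel, e)
      ev <- sel
    }
    data.frame(cell_id = d$cell_id[1], t_min = d$t_min[ev])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(cell_id = integer(), t_min = numeric())
  rownames(out) <- NULL
  out
}

#' Segment trajectories into runs
#'
#' Runs tile each track; boundaries are state changes and reversal events.
#' Kinematics (duration, mean speed, net displacement, orientation of net
#' displacement for persistent runs) and the event ending each run are
#' recorded.
#'
#' @param traj trajectory table.
#' @param states output of [classify_states()].
#' @param reversals output of [detect_reversals()].
#' @param params a [run_params()] list.
#' @return data.frame of runs with columns `cell_id`, `state`, `t_start`,
#'   `t_end`, `duration`, `mean_speed`, `distance`, `orientation` (direction of
#'   net displacement), `orientation_start` (initial direction over the first
#'   frames, used for toward/away classification: the outgoing direction is
#'   what run durations are conditioned on, and unlike the net direction it is
#'   unaffected by later boundary reflections or undetected reversals),
#'   `end_event`, `t_mid`, and start/mid positions.
#' @export
segment_runs <- function(traj, states, reversals, params = run_params()) {
  check_trajectories(traj)
  out <- lapply(split(traj, traj$cell_id), function(d) {
    d <- d[order(d$t_min), ]
    n <- nrow(d)
    if (n < 2) return(NULL)
    pers <- states$persistent[states$cell_id == d$cell_id[1]][
      order(states$t_min[states$cell_id == d$cell_id[1]])]
    rev_t <- reversals$t_min[reversals$cell_id == d$cell_id[1]]
    sc <- which(diff(pers) != 0) + 1L       # first frame of a new state
    rv <- match(rev_t, d$t_min)
    b <- sort(unique(c(1L, n, sc, rv)))
    runs <- list()
    for (j in seq_len(length(b) - 1)) {
      i0 <- b[j]; i1 <- b[j + 1]
      dur <- d$t_min[i1] - d$t_min[i0]
      if (dur <= 0) next
      seg <- i0:i1
      path <- sum(sqrt(diff(d$x_um[seg])^2 + diff(d$y_um[seg])^2))
      dx <- d$x_um[i1] - d$x_um[i0]; dy <- d$y_um[i1] - d$y_um[i0]
      i2 <- min(i0 + 2L, i1)
      dx0 <- d$x_um[i2] - d$x_um[i0]; dy0 <- d$y_um[i2] - d$y_um[i0]
      state <- if (mean(pers[seg]) >= 0.5) "persistent" else "non-persistent"
      end_event <- if (i1 == n && !(i1 %in% sc) && !(i1 %in% rv)) "track_end"
        else if (i1 %in% rv) "reversal" else "state_change"
      runs[[j]] <- data.frame(
        cell_id = d$cell_id[1], state = state,
        t_start = d$t_min[i0], t_end = d$t_min[i1], duration = dur,
        mean_speed = path / dur, distance = sqrt(dx^2 + dy^2),
        orientation = if (state == "persistent") atan2(dy, dx) else NA_real_,
        orientation_start = if (state == "persistent" && dx0^2 + dy0^2 > 1e-12)
          atan2(dy0, dx0) else NA_real_,
        end_event = end_event, t_mid = (d$t_min[i0] + d$t_min[i1]) / 2,
        x_start = d$x_um[i0], y_start = d$y_um[i0],
        x_mid = d$x_um[i0] + dx / 2, y_mid = d$y_um[i0] + dy / 2,
        x_end = d$x_um[i1], y_end = d$y_um[i1])
    }
    do.call(rbind, runs)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Extract runs from a trajectory table
#'
#' Convenience wrapper chaining [classify_states()], [detect_reversals()], and
#' [segment_runs()].
#'
#' @inheritParams classify_states
#' @return a run data.frame (see [segment_runs()]).
#' @export
extract_runs <- function(traj, params = run_params()) {
  states <- classify_states(traj, params)
  revs <- detect_reversals(traj, states, params)
  segment_runs(traj, states, revs, params)
}
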