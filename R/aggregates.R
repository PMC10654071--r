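# Aggregate segmentation, tracking, and fate analysis of density movies.

#' Density movie container
#'
#' @param frames 3-D array (rows = y, cols = x, slices = frames) of
#'   nonnegative intensities.
#' @param pixel_size um per pixel.
#' @param frame_interval min between frames.
#' @param t0 time (min) of the first frame.
#' @param times optional explicit frame times; defaults to
#'   `t0 + (0:(n-1)) * frame_interval`.
#' @return an object of class `density_movie`.
#' @export
density_movie <- function(frames, pixel_size, frame_interval, t0 = 0,
                          times = NULL) {
  stopifnot(length(dim(frames)) == 3, pixel_size > 0, frame_interval > 0)
  if (is.null(times)) times <- t0 + (seq_len(dim(frames)[3]) - 1) * frame_interval
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, t0 = t0, times = times),
            class = "density_movie")
}

movie_times <- function(movie) movie$times

#' Normalize density-movie frames
#'
#' Each frame has its mean subtracted, is shifted by the resulting minimum so
#' all values are nonnegative, and is scaled to total intensity 1. The shift
#' makes the frame total well defined (a mean-subtracted frame sums to zero)
#' while preserving the frame-to-frame invariant total; frames differing only
#' by an additive offset normalize identically.
#'
#' @param movie a [density_movie()].
#' @return the movie with normalized frames.
#' @export
normalize_frames <- function(movie) {
  stopifnot(inherits(movie, "density_movie"))
  for (k in seq_len(dim(movie$frames)[3])) {
    f <- movie$frames[, , k]
    if (max(f) - min(f) < .Machine$double.eps * max(abs(f), 1))
      stop("constant frame ", k, " cannot be normalized")
    f <- f - mean(f)
    f <- f - min(f)
    movie$frames[, , k] <- f / sum(f)
  }
  movie$normalized <- TRUE
  movie
}

#' Scaled Otsu threshold from a reference frame
#'
#' The reference frame (nearest in time to `t_ref`, normally the midpoint
#' between aggregate initiation and coarsening start) is rescaled to `[0, 1]`,
#' Otsu's threshold is computed on a 256-bin histogram, and the result is
#' mapped back to the normalized-intensity scale:
#' `(a_max - a_min) * I_thresh + a_min`, so it can be applied to every frame.
#'
#' @param movie a normalized [density_movie()].
#' @param t_ref reference time (min).
#' @return the threshold on the normalized-intensity scale, with attributes
#'   `I_thresh`, `a_min`, `a_max`.
#' @export
compute_scaled_threshold <- function(movie, t_ref) {
  stopifnot(inherits(movie, "density_movie"))
  k <- which.min(abs(movie_times(movie) - t_ref))
  f <- movie$frames[, , k]
  a_min <- min(f); a_max <- max(f)
  if (a_max <= a_min) stop("reference frame is constant")
  g <- (f - a_min) / (a_max - a_min)
  i_thresh <- EBImage::otsu(g, range = c(0, 1), levels = 256)
  p_hi <- mean(g > i_thresh)
  if (p_hi < 1e-4 || p_hi > 1 - 1e-4)
    warning("reference-frame histogram looks unimodal; ",
            "Otsu threshold may be unreliable")
  out <- (a_max - a_min) * i_thresh + a_min
  attr(out, "I_thresh") <- i_thresh
  attr(out, "a_min") <- a_min
  attr(out, "a_max") <- a_max
  out
}

#' Segment and track aggregates across a movie
#'
#' Per frame, supra-threshold connected components (8-connectivity) with area
#' at least `a_seg_min` are detected. Components are linked across frames by
#' maximal pixel overlap with the previous frame, falling back to the nearest
#' previous centroid within `gate` um; splits and merges resolve to the
#' largest-overlap parent. A track is flagged `partial_fov` if any of its
#' components touches the image border.
#'
#' @param movie a normalized [density_movie()].
#' @param threshold segmentation threshold on the normalized-intensity scale.
#' @param a_seg_min minimum component area (um^2).
#' @param gate centroid linking gate (um).
#' @param track_gap number of frames an aggregate may drop below threshold and
#'   still be linked to its track (bridges flicker around the threshold).
#' @return an `aggregate_set`: list with `tracks` (per aggregate-frame rows),
#'   `flags` (per aggregate), `boundaries`, `label_stack`, `pixel_size`,
#'   `times`.
#' @export
segment_and_track <- function(movie, threshold, a_seg_min = 100, gate = 20,
                              track_gap = 1) {
  stopifnot(inherits(movie, "density_movie"))
  ps <- movie$pixel_size
  times <- movie_times(movie)
  nt <- dim(movie$frames)[3]
  ny <- dim(movie$frames)[1]; nx <- dim(movie$frames)[2]
  label_stack <- array(0L, dim = c(ny, nx, nt))
  tracks <- list()
  boundaries <- vector("list", nt)
  next_id <- 1L
  prev_global <- matrix(0L, ny, nx)
  touches <- integer(0)
  merges <- list()
  for (k in seq_len(nt)) {
    mask <- movie$frames[, , k] > as.numeric(threshold)
    lab <- label_components(mask)
    ncomp <- max(lab)
    assigned <- rep(NA_integer_, ncomp)
    if (ncomp > 0) {
      px_area <- tabulate(lab[lab > 0], nbins = ncomp) * ps^2
      keep <- which(px_area >= a_seg_min)
      # overlap with previous frame's global labels
      if (length(keep) > 0 && any(prev_global > 0)) {
        ov <- table(prev = prev_global[prev_global > 0 & lab > 0],
                    cur = lab[prev_global > 0 & lab > 0])
        if (length(ov) > 0) {
          od <- as.data.frame(ov, stringsAsFactors = FALSE)
          od$prev <- as.integer(as.character(od$prev))
          od$cur <- as.integer(as.character(od$cur))
          od <- od[od$Freq > 0 & od$cur %in% keep, ]
          od <- od[order(-od$Freq), ]
          used_prev <- integer(0)
          for (r in seq_len(nrow(od))) {
            cc <- od$cur[r]; pp <- od$prev[r]
            if (is.na(assigned[cc]) && !(pp %in% used_prev)) {
              assigned[cc] <- pp
              used_prev <- c(used_prev, pp)
            }
          }
          # tracks that overlap a component won by another track and receive
          # no component of their own this frame have merged into the winner
          for (r in seq_len(nrow(od))) {
            pp <- od$prev[r]
            if (!(pp %in% used_prev) && is.null(merges[[as.character(pp)]])) {
              merges[[as.character(pp)]] <- c(assigned[od$cur[r]], k)
            }
          }
        }
      }
      for (cc in keep) {
        pix <- which(lab == cc, arr.ind = TRUE)
        cx <- mean(pix[, 2] - 1) * ps
        cy <- mean(pix[, 1] - 1) * ps
        if (is.na(assigned[cc]) && k > 1) {
          # centroid gating against tracks seen within the bridging window
          prev_rows <- Filter(function(tr) tr$frame >= k - 1 - track_gap &&
                                tr$frame < k && !(tr$agg_id %in% assigned),
                              tracks)
          if (length(prev_rows) > 0) {
            dd <- vapply(prev_rows, function(tr)
              sqrt((tr$centroid_x_um - cx)^2 + (tr$centroid_y_um - cy)^2),
              numeric(1))
            j <- which.min(dd)
            if (dd[j] <= gate) assigned[cc] <- prev_rows[[j]]$agg_id
          }
        }
        if (is.na(assigned[cc])) {
          assigned[cc] <- next_id
          next_id <- next_id + 1L
        }
        gid <- assigned[cc]
        border <- any(pix[, 1] == 1 | pix[, 1] == ny |
                        pix[, 2] == 1 | pix[, 2] == nx)
        if (border) touches <- union(touches, gid)
        tracks[[length(tracks) + 1]] <- list(
          agg_id = gid, frame = k, t_min = times[k],
          centroid_x_um = cx, centroid_y_um = cy,
          area_um2 = px_area[cc])
      }
      glab <- matrix(0L, ny, nx)
      for (cc in keep) glab[lab == cc] <- assigned[cc]
      label_stack[, , k] <- glab
      prev_global <- glab
      bl <- lapply(keep, function(cc) {
        bp <- component_boundary(lab, cc)
        data.frame(agg_id = assigned[cc], x_um = (bp[, 2] - 1) * ps,
                   y_um = (bp[, 1] - 1) * ps)
      })
      boundaries[[k]] <- if (length(bl)) do.call(rbind, bl) else NULL
    } else {
      prev_global <- matrix(0L, ny, nx)
    }
  }
  tr <- do.call(rbind, lapply(tracks, as.data.frame))
  if (is.null(tr)) {
    tr <- data.frame(agg_id = integer(), frame = integer(), t_min = numeric(),
                     centroid_x_um = numeric(), centroid_y_um = numeric(),
                     area_um2 = numeric())
  }
  ids <- sort(unique(tr$agg_id))
  flags <- data.frame(
    agg_id = ids,
    t_first = vapply(ids, function(i) min(tr$t_min[tr$agg_id == i]), numeric(1)),
    t_last = vapply(ids, function(i) max(tr$t_min[tr$agg_id == i]), numeric(1)),
    partial_fov = ids %in% touches,
    merged_into = vapply(as.character(ids), function(i) {
      m <- merges[[i]]
      # a merge only stands if the track was never picked up again afterwards
      if (!is.null(m) && max(tr$frame[tr$agg_id == as.integer(i)]) < m[2])
        as.integer(m[1]) else NA_integer_
    }, integer(1)),
    motile = rep(NA, length(ids)), short_lived = rep(NA, length(ids)),
    fate = rep(NA_character_, length(ids))
  )
  set <- structure(list(tracks = tr, flags = flags, boundaries = boundaries,
                        label_stack = label_stack, pixel_size = ps,
                        times = times, movie_end = max(times)),
                   class = "aggregate_set")
  set$flags$motile <- vapply(ids, function(i)
    classify_motility(tr[tr$agg_id == i, ],
                      frame_interval = diff(times[1:2])), logical(1))
  set$flags$short_lived <- vapply(seq_along(ids), function(j)
    filter_short_lived(set$flags[j, ], set$movie_end), logical(1))
  set
}

#' Classify an aggregate track as motile or stationary
#'
#' Motile aggregates are those whose centroid moves at more than 3 um/min,
#' measured as the median frame-to-frame speed of a 3-frame smoothed centroid
#' series.
#'
#' @param track per-frame rows for one aggregate (columns `centroid_x_um`,
#'   `centroid_y_um`, `t_min`).
#' @param frame_interval min between frames.
#' @param speed_limit motility threshold (um/min).
#' @return `TRUE` if motile.
#' @export
classify_motility <- function(track, frame_interval, speed_limit = 3) {
  if (nrow(track) < 2) return(FALSE)
  track <- track[order(track$t_min), ]
  cx <- moving_average(track$centroid_x_um, 3)
  cy <- moving_average(track$centroid_y_um, 3)
  v <- sqrt(diff(cx)^2 + diff(cy)^2) / diff(track$t_min)
  median(v) > speed_limit
}

#' Flag short-lived aggregates
#'
#' An aggregate is short-lived if it was stationary and dispersed less than
#' 2 h after initial detection, or if it dispersed while counted as motile.
#' Aggregates alive at the end of the movie are never short-lived.
#'
#' @param flags_row one row of the `flags` table (needs `t_first`, `t_last`,
#'   `motile`).
#' @param movie_end time (min) of the last frame.
#' @return `TRUE` if short-lived.
#' @export
filter_short_lived <- function(flags_row, movie_end) {
  dispersed <- flags_row$t_last < movie_end
  if (!dispersed) return(FALSE)
  if (isTRUE(flags_row$motile)) return(TRUE)
  (flags_row$t_last - flags_row$t_first) < 120
}

#' Assign stable/unstable fates
#'
#' An aggregate is unstable iff its track disappears at least `margin` minutes
#' before the end of the movie; tracks still present closer to (or at) the end
#' are treated as stable (censoring-safe). Tracks that end by fusing with
#' another aggregate did not disperse and are labeled `"merged"`; they are
#' excluded from stability statistics.
#'
#' @param set an `aggregate_set`.
#' @param margin censoring margin (min).
#' @return the set with `fate` filled in.
#' @export
label_fates <- function(set, margin = 30) {
  stopifnot(inherits(set, "aggregate_set"))
  set$flags$fate <- ifelse(set$flags$t_last < set$movie_end - margin,
                           "unstable", "stable")
  set$flags$fate[!is.na(set$flags$merged_into)] <- "merged"
  set
}

#' Detect the start of the coarsening phase
#'
#' The candidate set is the unstable, stationary, not short-lived aggregates.
#' Their total area per frame is smoothed with a `smooth_window`-minute moving
#' average; the coarsening start is the time of the last global maximum after
#' which the smoothed series never again exceeds `recover_frac` of that
#' maximum.
#'
#' @param set an `aggregate_set` with fates assigned.
#' @param smooth_window smoothing window (min).
#' @param recover_frac non-recovery criterion (fraction of the maximum).
#' @return the coarsening start time (min), or `NA` if the candidate set is
#'   empty or the area never decreases.
#' @export
detect_coarsening_start <- function(set, smooth_window = 30,
                                    recover_frac = 0.95) {
  stopifnot(inherits(set, "aggregate_set"))
  fl <- set$flags
  cand <- fl$agg_id[fl$fate %in% "unstable" & !fl$motile & !fl$short_lived]
  if (length(cand) == 0) return(NA_real_)
  tr <- set$tracks[set$tracks$agg_id %in% cand, ]
  a_u <- vapply(set$times, function(t) sum(tr$area_um2[tr$t_min == t]),
                numeric(1))
  dt <- if (length(set$times) > 1) diff(set$times[1:2]) else 1
  w <- max(1L, 2L * as.integer(smooth_window / dt / 2) + 1L)
  s <- moving_average(a_u, w)
  m <- max(s)
  n <- length(s)
  cand_i <- which(s >= m * (1 - 1e-9))
  for (i in rev(cand_i)) {
    if (i == n) next
    after <- s[(i + 1):n]
    fall <- which(after < recover_frac * m)
    if (length(fall) == 0) next
    # "continually decrease": once below 95% of the maximum, never recover
    if (all(after[fall[1]:length(after)] < recover_frac * m)) {
      # refine the smoothed peak to the raw-series maximum nearby: centered
      # smoothing shifts a kinked peak early by up to its window width
      win <- max(1, i - w):min(n, i + w)
      return(set$times[win[which.max(a_u[win])]])
    }
  }
  NA_real_
}

#' Aggregate tracks with flags
#'
#' @param set an `aggregate_set`.
#' @return data.frame of per-frame rows joined with the per-aggregate flags.
#' @export
aggregate_tracks <- function(set) {
  merge(set$tracks, set$flags, by = "agg_id", sort = TRUE)
}

#' Nearest-aggregate query
#'
#' For each point, the nearest aggregate (smallest boundary distance, ties
#' broken by larger area) at time `t`, with the signed boundary distance
#' (negative inside), unit vector to the centroid, fate, and partial
#' field-of-view flag. Returns `NULL` when no aggregates exist at `t`.
#'
#' @param aggregates an `aggregate_set` or [disk_aggregates()] object.
#' @param x,y query coordinates (um).
#' @param t query time (min).
#' @param min_area ignore aggregates smaller than this area (um^2).
#' @return data.frame with one row per point (`id`, `area`,
#'   `boundary_distance`, `ux`, `uy`, `fate`, `partial_fov`), or `NULL`.
#' @export
nearest_aggregate <- function(aggregates, x, y, t, min_area = 0) {
  UseMethod("nearest_aggregate")
}

#' @export
nearest_aggregate.aggregate_set <- function(aggregates, x, y, t,
                                            min_area = 0) {
  set <- aggregates
  k <- which.min(abs(set$times - t))
  rows <- set$tracks[set$tracks$frame == k &
                       set$tracks$area_um2 >= min_area, ]
  if (nrow(rows) == 0) return(NULL)
  bnd <- set$boundaries[[k]]
  np <- length(x)
  res <- data.frame(id = rep(NA_integer_, np), area = NA_real_,
                    boundary_distance = NA_real_, ux = NA_real_, uy = NA_real_,
                    fate = NA_character_, partial_fov = NA)
  ps <- set$pixel_size
  ny <- dim(set$label_stack)[1]; nx <- dim(set$label_stack)[2]
  row_px <- pmin(pmax(round(y / ps) + 1, 1), ny)
  col_px <- pmin(pmax(round(x / ps) + 1, 1), nx)
  inside_id <- set$label_stack[cbind(row_px, col_px, k)]
  bd_mat <- matrix(Inf, np, nrow(rows))
  for (j in seq_len(nrow(rows))) {
    bp <- bnd[bnd$agg_id == rows$agg_id[j], ]
    for (i in seq_len(np)) {
      bd_mat[i, j] <- sqrt(min((bp$x_um - x[i])^2 + (bp$y_um - y[i])^2))
    }
  }
  sign_mat <- matrix(1, np, nrow(rows))
  for (j in seq_len(nrow(rows)))
    sign_mat[inside_id == rows$agg_id[j], j] <- -1
  signed <- bd_mat * sign_mat
  for (i in seq_len(np)) {
    j <- order(signed[i, ], -rows$area_um2)[1]
    fl <- set$flags[set$flags$agg_id == rows$agg_id[j], ]
    dcx <- rows$centroid_x_um[j] - x[i]; dcy <- rows$centroid_y_um[j] - y[i]
    dc <- sqrt(dcx^2 + dcy^2)
    res$id[i] <- rows$agg_id[j]
    res$area[i] <- rows$area_um2[j]
    res$boundary_distance[i] <- signed[i, j]
    res$ux[i] <- if (dc > 0) dcx / dc else 0
    res$uy[i] <- if (dc > 0) dcy / dc else 0
    res$fate[i] <- if (is.na(fl$fate)) "unknown" else fl$fate
    res$partial_fov[i] <- fl$partial_fov
  }
  res
}

#' Analytic disk-aggregate geometry for a synthetic configuration
#'
#' Wraps a [synth_config()] so its configured disk aggregates can be used as
#' the aggregate input of [annotate_runs()] without segmentation. Queries are
#' quantized to `time_step` minutes.
#'
#' @param cfg a [synth_config()].
#' @param time_step query-time quantization (min).
#' @return an object of class `disk_aggregates`.
#' @export
disk_aggregates <- function(cfg, time_step = 5) {
  stopifnot(inherits(cfg, "synth_config"))
  structure(list(cfg = cfg, time_step = time_step), class = "disk_aggregates")
}

#' @export
nearest_aggregate.disk_aggregates <- function(aggregates, x, y, t,
                                              min_area = 0) {
  cfg <- aggregates$cfg
  if (t < cfg$agg_appear) return(NULL)
  st <- agg_state_at(cfg, t)
  st <- st[st$area >= min_area, ]
  if (nrow(st) == 0) return(NULL)
  np <- length(x)
  dc <- sqrt(outer(x, st$x, "-")^2 + outer(y, st$y, "-")^2)
  bd <- sweep(dc, 2, st$radius)
  partial <- st$x - st$radius < 0 | st$x + st$radius > cfg$fov[1] |
    st$y - st$radius < 0 | st$y + st$radius > cfg$fov[2]
  fate <- ifelse(is.na(cfg$aggregates$disperse_at[st$id]), "stable", "unstable")
  res <- data.frame(id = integer(np), area = numeric(np),
                    boundary_distance = numeric(np), ux = numeric(np),
                    uy = numeric(np), fate = character(np),
                    partial_fov = logical(np))
  for (i in seq_len(np)) {
    j <- order(bd[i, ], -st$area)[1]
    d <- dc[i, j]
    res$id[i] <- st$id[j]
    res$area[i] <- st$area[j]
    res$boundary_distance[i] <- bd[i, j]
    res$ux[i] <- if (d > 0) (st$x[j] - x[i]) / d else 0
    res$uy[i] <- if (d > 0) (st$y[j] - y[i]) / d else 0
    res$fate[i] <- fate[j]
    res$partial_fov[i] <- partial[j]
  }
  res
}

# Times at which an aggregate object can be queried; run annotation groups
# queries by these to vectorize.
aggregate_query_times <- function(aggregates, t) {
  UseMethod("aggregate_query_times")
}

#' @export
aggregate_query_times.aggregate_set <- function(aggregates, t) {
  aggregates$times[vapply(t, function(ti)
    which.min(abs(aggregates$times - ti)), integer(1))]
}

#' @export
aggregate_query_times.disk_aggregates <- function(aggregates, t) {
  round(t / aggregates$time_step) * aggregates$time_step
}
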