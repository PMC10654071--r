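# Small fixtures shared across test files. Everything is generated in code;
# no data files.

# straight-line track at constant speed (um/min)
straight_track <- function(n = 60, speed = 3, theta = 0.3, cell_id = 1L,
                           x0 = 50, y0 = 50) {
  t <- 0:(n - 1)
  data.frame(cell_id = cell_id, t_min = t,
             x_um = x0 + speed * cos(theta) * t,
             y_um = y0 + speed * sin(theta) * t)
}

# track reversing direction exactly once at t = t_rev
reversing_track <- function(n = 120, t_rev = 60, speed = 2.5, cell_id = 1L) {
  t <- 0:(n - 1)
  x <- ifelse(t <= t_rev, speed * t, speed * t_rev - speed * (t - t_rev))
  data.frame(cell_id = cell_id, t_min = t, x_um = 200 + x, y_um = 100)
}

# track alternating blocks of motion and standstill
stop_go_track <- function(blocks = 4, block_min = 30, speed = 3,
                          cell_id = 1L) {
  t <- 0:(blocks * block_min)
  x <- numeric(length(t)); moving <- TRUE; xx <- 0
  for (i in seq_along(t)) {
    x[i] <- xx
    phase <- ((t[i]) %/% block_min) %% 2
    if (i < length(t)) xx <- xx + if (phase == 0) speed else 0
  }
  data.frame(cell_id = cell_id, t_min = t, x_um = 100 + x, y_um = 150,
             moving = (t %/% block_min) %% 2 == 0)
}

# minimal persistent-run table for direct statistics tests
runs_table <- function(durations, rel_angles, cell_id = NULL,
                       state = "persistent") {
  n <- length(durations)
  data.frame(
    cell_id = if (is.null(cell_id)) seq_len(n) else cell_id,
    state = state, duration = durations, rel_angle = rel_angles,
    mean_speed = 2.5, end_event = "reversal",
    t_mid = seq_len(n), boundary_distance = 10
  )
}

# single static Gaussian blob movie
blob_movie <- function(nx = 100, ny = 80, nt = 5, amp = 0.5, bg = 0.05,
                       cx = 100, cy = 80, sigma = 15, pixel_size = 2,
                       noise_sd = 0, seed = 1) {
  set.seed(seed)
  px <- (seq_len(nx) - 1) * pixel_size
  py <- (seq_len(ny) - 1) * pixel_size
  gx <- matrix(px, ny, nx, byrow = TRUE); gy <- matrix(py, ny, nx)
  f <- bg + amp * exp(-((gx - cx)^2 + (gy - cy)^2) / (2 * sigma^2))
  frames <- array(0, dim = c(ny, nx, nt))
  for (k in seq_len(nt))
    frames[, , k] <- f + if (noise_sd > 0) rnorm(nx * ny, 0, noise_sd) else 0
  density_movie(frames, pixel_size = pixel_size, frame_interval = 15)
}

# brute-force Otsu: exhaustive scan of the 256 candidate thresholds (bin
# midpoints of a 256-bin histogram on [0, 1]) maximizing between-class
# variance, computed directly from the pixel values
otsu_bruteforce <- function(g) {
  breaks <- seq(0, 1, length.out = 257)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  # bin pixels exactly as hist() does, then scan all candidate cuts
  bin <- findInterval(g, breaks, rightmost.closed = TRUE, left.open = TRUE)
  bin[bin == 0] <- 1L
  vals <- mids[bin]
  v <- rep(NA_real_, length(mids))
  for (i in seq_along(mids)) {
    lo <- vals[vals <= mids[i]]; hi <- vals[vals > mids[i]]
    if (length(lo) == 0 || length(hi) == 0) next
    v[i] <- length(lo) * length(hi) * (mean(hi) - mean(lo))^2
  }
  maxi <- which(v == max(v, na.rm = TRUE))
  (mids[maxi[1]] + mids[maxi[length(maxi)]]) / 2
}

# default-ish synthetic configuration, small enough for unit tests
small_cfg <- function(...) {
  dots <- list(...)
  defaults <- list(fov = c(300, 240), n_cells = 20, duration = 200,
                   aggregates = data.frame(x = 150, y = 120, r0 = 30,
                                           growth = 0, disperse_at = NA))
  do.call(synth_config, c(dots, defaults[!names(defaults) %in% names(dots)]))
}
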