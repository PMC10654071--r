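test_that("normalization yields unit-total frames and offset invariance", {
  m <- blob_movie(nt = 3)
  n <- normalize_frames(m)
  expect_equal(apply(n$frames, 3, sum), rep(1, 3), tolerance = 1e-9)
  m2 <- m; m2$frames <- m$frames + 0.37  # constant offset
  n2 <- normalize_frames(m2)
  expect_equal(n$frames, n2$frames, tolerance = 1e-12)
  mc <- m; mc$frames[, , 2] <- 0.2
  expect_error(normalize_frames(mc), "constant")
})

test_that("the scaled threshold reduces to Otsu under an identity rescale", {
  m <- normalize_frames(blob_movie(noise_sd = 0.01))
  thr <- compute_scaled_threshold(m, t_ref = 30)
  f <- m$frames[, , 3]
  expect_equal(attr(thr, "a_min"), min(f))
  expect_equal(attr(thr, "a_max"), max(f))
  expect_equal(as.numeric(thr),
               (max(f) - min(f)) * attr(thr, "I_thresh") + min(f))
  # threshold separates the two modes of a bimodal frame
  g <- (f - min(f)) / (max(f) - min(f))
  expect_gt(mean(g > attr(thr, "I_thresh")), 0)
  expect_gt(mean(g <= attr(thr, "I_thresh")), 0.5)
})

test_that("a single static blob yields one full-length track", {
  m <- normalize_frames(blob_movie(nt = 6, noise_sd = 0))
  thr <- compute_scaled_threshold(m, 40)
  set <- segment_and_track(m, thr)
  expect_equal(nrow(set$flags), 1)
  expect_equal(sum(set$tracks$agg_id == 1), 6)
  # noise-free: centroid within one pixel of the blob center at every frame
  expect_true(all(abs(set$tracks$centroid_x_um - 100) <= m$pixel_size))
  expect_true(all(abs(set$tracks$centroid_y_um - 80) <= m$pixel_size))
})

test_that("a slowly moving blob stays a single track", {
  nx <- 100; ny <- 80; nt <- 8; ps <- 2
  frames <- array(0, dim = c(ny, nx, nt))
  px <- (seq_len(nx) - 1) * ps; py <- (seq_len(ny) - 1) * ps
  gx <- matrix(px, ny, nx, byrow = TRUE); gy <- matrix(py, ny, nx)
  for (k in seq_len(nt)) {
    cx <- 60 + 2 * k  # 1 px per frame
    frames[, , k] <- 0.05 + 0.5 * exp(-((gx - cx)^2 + (gy - 80)^2) / 450)
  }
  m <- normalize_frames(density_movie(frames, ps, 15))
  set <- segment_and_track(m, compute_scaled_threshold(m, 60))
  expect_equal(nrow(set$flags), 1)
})

test_that("a ramped-down blob ends its track before the movie ends", {
  cfg <- synth_config(fov = c(300, 240), n_cells = 5, duration = 900,
                      aggregates = data.frame(x = c(90, 210), y = c(120, 120),
                                              r0 = c(35, 30), growth = 0,
                                              disperse_at = c(NA, 400)),
                      noise_sd = 0.003, seed = 6)
  m <- normalize_frames(gen_density_movie(cfg))
  set <- segment_and_track(m, compute_scaled_threshold(m, 200))
  expect_equal(nrow(set$flags), 2)
  expect_equal(sum(set$flags$t_last < 900), 1)
})

test_that("segmented area is monotone in the threshold", {
  m <- normalize_frames(blob_movie(noise_sd = 0.005))
  thr <- as.numeric(compute_scaled_threshold(m, 40))
  areas <- vapply(c(0.9, 1, 1.2) * thr, function(th) {
    s <- segment_and_track(m, th)
    sum(s$tracks$area_um2[s$tracks$frame == 3])
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("motility classification applies the 3 um/min rule", {
  mk <- function(v) data.frame(t_min = seq(0, 150, 15),
                               centroid_x_um = v * seq(0, 150, 15),
                               centroid_y_um = 0)
  expect_false(classify_motility(mk(0), 15))
  expect_true(classify_motility(mk(4), 15))
  expect_false(classify_motility(mk(2), 15))
})

test_that("short-lived flags follow the two-hour and motile-dispersal rules", {
  end <- 900
  row <- function(t0, t1, motile) data.frame(t_first = t0, t_last = t1,
                                             motile = motile)
  expect_true(filter_short_lived(row(0, 90, FALSE), end))    # < 2 h
  expect_false(filter_short_lived(row(0, 300, FALSE), end))  # long-lived
  expect_true(filter_short_lived(row(0, 300, TRUE), end))    # died motile
  expect_false(filter_short_lived(row(0, end, TRUE), end))   # never dispersed
})

test_that("fates are censoring-safe at the movie end", {
  m <- normalize_frames(blob_movie(nt = 10, noise_sd = 0))
  set <- segment_and_track(m, compute_scaled_threshold(m, 60))
  set$flags$t_last <- set$movie_end
  expect_equal(label_fates(set)$flags$fate, "stable")
  set$flags$t_last <- set$movie_end - 10
  expect_equal(label_fates(set, margin = 30)$flags$fate, "stable")
  set$flags$t_last <- set$movie_end - 180
  expect_equal(label_fates(set)$flags$fate, "unstable")
})

test_that("coarsening start is the last non-recovering maximum", {
  mk_set <- function(a_u) {
    times <- seq(0, by = 15, length.out = length(a_u))
    tr <- data.frame(agg_id = 1L, frame = seq_along(a_u), t_min = times,
                     centroid_x_um = 0, centroid_y_um = 0, area_um2 = a_u)
    structure(list(tracks = tr[tr$area_um2 > 0, ],
                   flags = data.frame(agg_id = 1L, t_first = 0,
                                      t_last = max(times[a_u > 0]),
                                      partial_fov = FALSE, motile = FALSE,
                                      short_lived = FALSE, fate = "unstable"),
                   times = times, movie_end = max(times)),
              class = "aggregate_set")
  }
  tri <- c(seq(100, 1000, length.out = 41), seq(975, 100, length.out = 36))
  set <- mk_set(tri)  # peak at t = 600
  expect_equal(detect_coarsening_start(set), 600, tolerance = 15)
  expect_true(is.na(detect_coarsening_start(mk_set(seq(100, 1000,
                                                       length.out = 60)))))
  set$flags$fate <- "stable"
  expect_true(is.na(detect_coarsening_start(set)))  # empty candidate set
})
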