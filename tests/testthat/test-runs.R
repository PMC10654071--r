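test_that("state classification separates motion from standstill", {
  st <- classify_states(straight_track(n = 60, speed = 3))
  expect_true(all(st$persistent))

  set.seed(1)
  jitter <- data.frame(cell_id = 1L, t_min = 0:59,
                       x_um = 50 + cumsum(rnorm(60, 0, 0.05)),
                       y_um = 50 + cumsum(rnorm(60, 0, 0.05)))
  expect_true(all(!classify_states(jitter)$persistent))

  expect_warning(classify_states(straight_track(n = 3)), "shorter")
})

test_that("alternating motion/stop blocks are labeled accurately", {
  d <- stop_go_track(blocks = 6, block_min = 30)
  st <- classify_states(d[c("cell_id", "t_min", "x_um", "y_um")])
  acc <- mean(st$persistent == d$moving)
  expect_gt(acc, 0.95)
  # every interior true boundary has a detected boundary within 2 frames
  bt <- which(diff(d$moving) != 0)
  bt <- bt[bt > 3 & bt < nrow(d) - 3]
  be <- which(diff(st$persistent) != 0)
  expect_true(all(vapply(bt, function(b) any(abs(be - b) <= 2), logical(1))))
})

test_that("reversal detection finds isolated reversals and nothing else", {
  d <- straight_track(n = 100)
  st <- classify_states(d)
  expect_equal(nrow(detect_reversals(d, st)), 0)

  d <- reversing_track(t_rev = 60)
  st <- classify_states(d)
  rv <- detect_reversals(d, st)
  expect_equal(nrow(rv), 1)
  expect_lte(abs(rv$t_min - 60), 1)
})

test_that("reversal recall and precision hold on generated tracks", {
  cfg <- synth_config(fov = c(500, 400), n_cells = 30, duration = 400,
                      tau_toward = function(A) rep(30, length(A)),
                      tau_away = function(A) rep(30, length(A)),
                      p_stop = function(rho) rep(0, length(rho)),
                      aggregates = data.frame(x = 250, y = 200, r0 = 40,
                                              growth = 0, disperse_at = NA),
                      seed = 7)
  traj <- gen_trajectories(cfg)
  truth <- attr(traj, "truth")
  st <- classify_states(traj)
  rv <- detect_reversals(traj, st)
  tr <- truth[truth$end_event == "reversal", ]
  hit <- vapply(seq_len(nrow(tr)), function(i) {
    any(abs(rv$t_min[rv$cell_id == tr$cell_id[i]] - tr$t_end[i]) <= 2)
  }, logical(1))
  expect_gt(mean(hit), 0.9)
  # false positives away from the reflecting boundary (wall bounces reverse
  # the displayed direction of motion and are not in the truth table)
  pos <- rv
  pos$x <- traj$x_um[match(paste(rv$cell_id, rv$t_min),
                           paste(traj$cell_id, traj$t_min))]
  pos$y <- traj$y_um[match(paste(rv$cell_id, rv$t_min),
                           paste(traj$cell_id, traj$t_min))]
  interior <- pos$x > 12 & pos$x < 488 & pos$y > 12 & pos$y < 388
  fp <- vapply(seq_len(nrow(rv)), function(i) {
    !any(abs(tr$t_end[tr$cell_id == rv$cell_id[i]] - rv$t_min[i]) <= 2)
  }, logical(1))
  expect_lt(mean(fp[interior]), 0.05)
})

test_that("runs tile each track", {
  cfg <- small_cfg(seed = 4)
  traj <- gen_trajectories(cfg)
  runs <- extract_runs(traj)
  for (ci in unique(runs$cell_id)) {
    r <- runs[runs$cell_id == ci, ]
    r <- r[order(r$t_start), ]
    expect_equal(r$t_start[-1], r$t_end[-nrow(r)])
    expect_equal(sum(r$duration), max(traj$t_min[traj$cell_id == ci]) -
                   min(traj$t_min[traj$cell_id == ci]))
  }
  expect_true(all(runs$duration > 0))
  expect_true(all(runs$distance >= 0))
})

test_that("a single reversal splits a clean track into two runs", {
  d <- reversing_track(n = 100, t_rev = 50)
  runs <- extract_runs(d)
  expect_equal(nrow(runs), 2)
  expect_equal(runs$end_event, c("reversal", "track_end"))
  expect_equal(sum(runs$duration), 99)
})

test_that("nematic mean respects axial symmetry", {
  expect_equal(as.numeric(nematic_mean(rep(0.7, 5))), 0.7)
  expect_equal(as.numeric(nematic_mean(c(0, pi))), 0)
  m <- nematic_mean(c(0, pi / 2))
  expect_lt(attr(m, "resultant"), 1e-8)
  expect_true(is.na(nematic_mean(numeric(0))))
})

test_that("alignment score hits its landmark values", {
  expect_equal(local_alignment(0.4, rep(0.4, 3)), 1)
  expect_equal(local_alignment(0.4 + pi / 2, rep(0.4, 3)), -1)
  expect_equal(local_alignment(0.4 + pi / 4, rep(0.4, 3)), 0,
               tolerance = 1e-12)
  expect_true(is.na(local_alignment(0.4, numeric(0))))
  expect_true(is.na(local_alignment(0.4, c(0, pi / 2))))  # degenerate set
})

test_that("annotation geometry matches an analytic disk", {
  cfg <- synth_config(fov = c(500, 400),
                      aggregates = data.frame(x = 200, y = 200, r0 = 50,
                                              growth = 0, disperse_at = NA))
  runs <- data.frame(cell_id = 1L, state = "persistent", t_start = 10,
                     t_end = 20, duration = 10, mean_speed = 2, distance = 20,
                     orientation = pi, orientation_start = pi,
                     end_event = "reversal", t_mid = 15,
                     x_start = 300, y_start = 200, x_mid = 290, y_mid = 200,
                     x_end = 280, y_end = 200)
  db <- annotate_runs(runs, aggregates = disk_aggregates(cfg))
  expect_equal(db$rel_angle, 0, tolerance = 1e-12)
  expect_equal(db$boundary_distance, 50)
  # a run starting at the centroid is inside: negative distance to contour
  runs$x_start <- 200
  runs$orientation <- 0; runs$orientation_start <- 0
  db <- annotate_runs(runs, aggregates = disk_aggregates(cfg))
  expect_equal(db$boundary_distance, -50)
  expect_equal(db$rel_angle, NA_real_)  # at the centroid direction undefined
})

test_that("rel_angle is uniform in an isotropic world", {
  cfg <- synth_config(fov = c(600, 500), n_cells = 40, duration = 250,
                      aggregates = data.frame(x = 300, y = 250, r0 = 40,
                                              growth = 0, disperse_at = NA),
                      tau_toward = function(A) rep(8, length(A)),
                      tau_away = function(A) rep(8, length(A)),
                      p_stop = function(rho) rep(0, length(rho)), seed = 13)
  traj <- gen_trajectories(cfg)
  db <- annotate_runs(extract_runs(traj), aggregates = disk_aggregates(cfg))
  rel <- db$rel_angle[db$state == "persistent" & !is.na(db$rel_angle)]
  ks <- suppressWarnings(ks.test(rel, "punif", 0, pi))
  expect_gt(ks$p.value, 0.01)
})

test_that("alignment gamma equals a direct neighbor scan", {
  cfg <- small_cfg(seed = 9, n_cells = 15, duration = 100)
  traj <- gen_trajectories(cfg)
  runs <- extract_runs(traj)
  db <- annotate_runs(runs, trajectories = traj)
  fo <- myxorun:::frame_orientations(traj, 3)
  idx <- which(!is.na(db$alignment_gamma))[1:20]
  for (i in idx[!is.na(idx)]) {
    nb <- fo[fo$t_min >= db$t_start[i] - 7 & fo$t_min <= db$t_start[i] &
               fo$cell_id != db$cell_id[i] & !is.na(fo$theta), ]
    nb <- nb[(nb$x_um - db$x_start[i])^2 + (nb$y_um - db$y_start[i])^2 <=
               12^2, ]
    expect_equal(db$alignment_gamma[i],
                 local_alignment(db$orientation[i], nb$theta))
  }
})

test_that("reorientation angles are stored relative to the flipped direction", {
  d <- reversing_track(n = 100, t_rev = 50)
  db <- annotate_runs(extract_runs(d))
  # a perfect 180-degree reversal has zero residual turn
  expect_equal(db$delta_orientation[2], 0, tolerance = 0.1)
})

test_that("time bins partition the analysis interval", {
  cfg <- small_cfg(seed = 1)
  db <- gen_run_database(cfg, n_runs = 300, t_coarsen = 150)
  bins <- time_bins(db)
  expect_equal(bins$t_lo[-1], bins$t_hi[-nrow(bins)])
  expect_equal(min(bins$t_lo), 0)
  expect_equal(max(bins$t_hi), cfg$duration)
  expect_true(all(db$time_bin %in% seq_len(nrow(bins))))
  expect_setequal(unique(bins$phase), c("aggregation", "coarsening"))
})
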