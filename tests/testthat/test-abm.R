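# Small, fast fixtures for the agent-based machinery; the scaled contrast
# experiment lives in test-acceptance.R.

abm_db_cfg <- function(seed = 3, ...) {
  synth_config(fov = c(400, 320), duration = 400,
               aggregates = data.frame(x = c(120, 280), y = c(160, 160),
                                       r0 = c(40, 18), growth = 0,
                                       disperse_at = NA),
               no_agg_distance = 200, seed = seed, ...)
}

tiny_sim_cfg <- function(...) {
  dots <- list(...)
  defaults <- list(fov = c(400, 320), n_agents = 300, t_start = 0, t_end = 60,
                   t_coarsen = 40, time_bin_pre = 40, coarsening_bins = 1,
                   threshold_rel = 2, no_agg_distance = 200,
                   init_duration = 20)
  do.call(sim_config, c(dots, defaults[!names(defaults) %in% names(dots)]))
}

test_that("a query equal to a stored row returns that row as 1-NN", {
  db <- gen_run_database(abm_db_cfg(), n_runs = 400)
  idx <- suppressWarnings(build_search_index(db))
  st <- idx$strata[["1 persistent"]]
  for (i in c(1, 7, 23)) {
    nn <- knn_query(st$x, st$x[i, , drop = FALSE], 1)
    expect_equal(nn[1, 1], i)
  }
})

test_that("zero-variance cues are dropped with a warning", {
  db <- gen_run_database(abm_db_cfg(), n_runs = 300)
  db$alignment_gamma <- 0.5
  expect_warning(idx <- build_search_index(db), "zero-variance")
  expect_false("gamma" %in% idx$strata[["1 persistent"]]$usable)
})

test_that("an empty stratum aborts with a diagnostic naming it", {
  db <- gen_run_database(abm_db_cfg(), n_runs = 300)
  db2 <- db[db$state == "persistent", ]
  attr(db2, "time_bins") <- time_bins(db)
  class(db2) <- class(db)
  expect_error(build_search_index(db2), "non-persistent")
})

test_that("exact search matches a per-query brute-force scan", {
  set.seed(14)
  dbm <- matrix(rnorm(2000 * 4), ncol = 4)
  q <- matrix(rnorm(100 * 4), ncol = 4)
  got <- knn_query(dbm, q, 7)
  for (i in seq_len(nrow(q))) {
    d <- sqrt(colSums((t(dbm) - q[i, ])^2))
    expect_equal(got[i, ], order(d)[1:7])
  }
})

test_that("a single-row stratum is copied verbatim", {
  db <- gen_run_database(abm_db_cfg(seed = 6), n_runs = 200)
  one <- db[c(which(db$state == "persistent")[1],
              which(db$state == "non-persistent")[1]), ]
  one$end_event <- c("reversal", "state_change")
  attr(one, "time_bins") <- data.frame(t_lo = 0, t_hi = 400,
                                       phase = "aggregation")
  one$time_bin <- 1L
  class(one) <- class(db)
  idx <- suppressWarnings(build_search_index(one))
  cfg <- tiny_sim_cfg()
  q <- list(density = 0.1, gamma = 0.2, bdist = 30, rel = 1, area = 500,
            to_agg = 0.5)
  set.seed(2)
  out <- suppressWarnings(
    sample_next_behavior(idx, q, "persistent", 1, cfg, orientation = 1))
  row <- one[one$state == "persistent", ]
  expect_equal(out$next_state, "persistent")  # all rows end in reversal
  expect_equal(out$duration, row$duration)
  expect_equal(out$speed, row$mean_speed)
  expect_equal(out$delta_orientation, row$delta_orientation)
})

test_that("the density field is a unit-mass kernel estimate", {
  f <- density_field(100, 100, c(300, 240), 2, 7)
  expect_equal(sum(f), 1)
  peak <- which(f == max(f), arr.ind = TRUE)
  expect_equal(unname((peak[1, 2] - 1) * 2), 100, tolerance = 2)
  expect_equal(unname((peak[1, 1] - 1) * 2), 100, tolerance = 2)
  # two distant agents: two equal local maxima
  f2 <- density_field(c(60, 240), c(120, 120), c(300, 240), 2, 7)
  expect_equal(sum(f2), 1)
  v1 <- f2[61, 31]; v2 <- f2[61, 121]
  expect_equal(v1, v2, tolerance = 1e-9)
  expect_equal(max(f2), v1, tolerance = 1e-9)
})

test_that("pinpoint aggregates are excluded from nearest-aggregate queries", {
  field <- matrix(0, 100, 100)
  field[10:12, 10:12] <- 1      # 9 px = 36 um^2 at 2 um/px: pinpoint
  field[60:80, 60:80] <- 1      # 441 px = 1764 um^2: usable
  field <- field / sum(field)
  aggs <- detect_sim_aggregates(field, threshold = 1e-6,
                                pinpoint_min_area = 300, pixel_size = 2)
  expect_equal(nrow(aggs$table), 2)
  expect_equal(sum(aggs$table$usable), 1)
  na <- myxorun:::sim_nearest_aggregate(aggs, 30, 30, 2)
  expect_equal(na$id, aggs$table$id[aggs$table$usable])
  # no supra-threshold pixels: sentinel cues
  empty <- detect_sim_aggregates(matrix(1, 50, 50) / 2500, threshold = 1,
                                 pinpoint_min_area = 300, pixel_size = 2)
  expect_equal(nrow(empty$table), 0)
  na2 <- myxorun:::sim_nearest_aggregate(empty, 30, 30, 2, 200)
  expect_equal(na2$bdist, 200)
  expect_equal(na2$area, 0)
})

test_that("raising the threshold never enlarges a component", {
  set.seed(3)
  f <- density_field(runif(500, 0, 300), runif(500, 0, 240), c(300, 240), 2, 7)
  lo <- detect_sim_aggregates(f, quantile(f, 0.95), 0, 2)
  hi <- detect_sim_aggregates(f, quantile(f, 0.99), 0, 2)
  expect_lte(sum(hi$table$area), sum(lo$table$area))
})

test_that("initialization conserves agents and is seed-stable", {
  db <- gen_run_database(abm_db_cfg(), n_runs = 1500)
  cfg <- tiny_sim_cfg()
  set.seed(5); w1 <- suppressWarnings(init_world(cfg, db))
  set.seed(5); w2 <- suppressWarnings(init_world(cfg, db))
  expect_equal(length(w1$x), cfg$n_agents)
  expect_identical(w1[c("x", "y", "theta", "state")],
                   w2[c("x", "y", "theta", "state")])
})

test_that("initialization keeps a bias-free, jam-free world uniform", {
  cfg0 <- abm_db_cfg(seed = 8,
                     tau_toward = function(A) rep(8, length(A)),
                     tau_away = function(A) rep(8, length(A)),
                     p_stop = function(rho) rep(0.1, length(rho)),
                     tau_stop = function(rho) rep(5, length(rho)))
  db <- gen_run_database(cfg0, n_runs = 1500)
  cfg <- tiny_sim_cfg(n_agents = 2000, init_duration = 60)
  set.seed(9)
  w <- suppressWarnings(init_world(cfg, db))
  grid <- table(cut(w$x, seq(0, 400, 100)), cut(w$y, seq(0, 320, 80)))
  expect_gt(chisq.test(grid)$p.value, 0.01)
})

test_that("stepping moves persistent agents and freezes stopped ones", {
  db <- gen_run_database(abm_db_cfg(), n_runs = 1500)
  cfg <- tiny_sim_cfg(n_agents = 2L)
  idx <- suppressWarnings(build_search_index(
    run_database(as.data.frame(db), 0, 60, 40, 40, 1)))
  w <- list(x = c(100, 200), y = c(100, 100), theta = c(0.4, 1),
            state = c("persistent", "non-persistent"), speed = c(2, 0),
            t_rem = c(50, 50), t = 0)
  w <- myxorun:::refresh_field(w, cfg)
  w2 <- step_world(w, cfg, idx)
  expect_equal(w2$x[1] - w$x[1], 2 * cos(0.4))
  expect_equal(w2$y[1] - w$y[1], 2 * sin(0.4))
  expect_equal(w2$x[2], w$x[2]); expect_equal(w2$y[2], w$y[2])
})

test_that("short simulations conserve agents and unit density mass", {
  db <- gen_run_database(abm_db_cfg(), n_runs = 1500)
  cfg <- tiny_sim_cfg(seed = 31)
  sim <- suppressWarnings(run_simulation(cfg, db, store_movie = TRUE))
  expect_equal(length(sim$world$x), cfg$n_agents)
  expect_true(all(sim$world$x >= 0 & sim$world$x <= 400))
  expect_equal(apply(sim$movie$frames, 3, sum),
               rep(1, dim(sim$movie$frames)[3]), tolerance = 1e-9)
})

test_that("simulations are byte-identical under a fixed seed", {
  db <- gen_run_database(abm_db_cfg(), n_runs = 1500)
  cfg <- tiny_sim_cfg(seed = 12)
  s1 <- suppressWarnings(run_simulation(cfg, db))
  s2 <- suppressWarnings(run_simulation(cfg, db))
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$world, s2$world)
})

test_that("dispersal summary arithmetic is exact", {
  sim <- list(counts = data.frame(t = c(0, 300, 600),
                                  n_aggregates = c(4, 10, 6),
                                  total_area = c(1, 2, 1.5)),
              cfg = list(t_coarsen = 300, pinpoint_min_area = 300),
              aggregates = structure(list(
                tracks = data.frame(agg_id = 1:2, frame = 2, t_min = 300,
                                    area_um2 = c(1000, 4000)),
                flags = data.frame(agg_id = 1:2, fate = c("unstable", "stable"),
                                   motile = FALSE, t_first = 0),
                times = c(0, 300, 600)), class = "aggregate_set"))
  class(sim) <- "sim_result"
  ds <- dispersal_summary(sim, area_max = 1500)
  expect_equal(ds$pct_decrease, 40)
  expect_equal(ds$sub_dispersal, 1)
  sim$counts$n_aggregates <- c(4, 10, 10)
  expect_equal(dispersal_summary(sim)$pct_decrease, 0)
})
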