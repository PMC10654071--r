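test_that("reversal bias follows its defining formula", {
  r <- runs_table(c(6, 6, 4, 4), c(0.3, 0.5, 2.8, 3.0))
  expect_equal(reversal_bias(r), (6 - 4) / 5)
  # identical toward/away samples cancel
  r2 <- runs_table(c(5, 7, 5, 7), c(0.3, 0.5, 2.8, 3.0))
  expect_equal(reversal_bias(r2), 0)
  # t_all includes runs outside the toward/away strata
  r3 <- runs_table(c(10, 2, 6, 6), c(0.3, 2.9, pi / 2, pi / 2))
  expect_equal(reversal_bias(r3), (10 - 2) / 6)
  # empty stratum: undefined, never zero
  r4 <- runs_table(c(5, 6), c(0.2, 0.4))
  expect_true(is.na(reversal_bias(r4)))
})

test_that("reversal bias is scale-free and respects the restricted split", {
  set.seed(2)
  r <- runs_table(rexp(200, 1 / 6), runif(200, 0, pi))
  expect_equal(reversal_bias(r), reversal_bias(transform(r, duration = duration * 13.7)))
  # restricted split discards mid-range orientations
  r5 <- runs_table(c(8, 8, 3, 3, 50, 50), c(0.2, 0.6, 2.9, 2.7, 1.4, 1.7))
  t_all <- mean(r5$duration)
  expect_equal(reversal_bias(r5, "restricted45"), (8 - 3) / t_all)
})

test_that("pooling equal-size toward/away strata reproduces t_all", {
  tw <- c(6, 8, 7); aw <- c(3, 5, 4)
  r <- runs_table(c(tw, aw), c(rep(0.3, 3), rep(2.9, 3)))
  expect_equal(mean(r$duration), (mean(tw) + mean(aw)) / 2)
  expect_equal(reversal_bias(r), (mean(tw) - mean(aw)) / mean(r$duration))
})

test_that("cluster bootstrap is deterministic and degenerates gracefully", {
  r <- runs_table(rep(5, 40), runif(40, 0, pi), cell_id = rep(1:8, each = 5))
  expect_warning(ci <- bootstrap_ci(function(d) mean(d$duration), r, B = 50,
                                    seed = 4),
                 "degenerate")
  expect_equal(unname(ci[1]), unname(ci[2]))
  set.seed(99)
  r2 <- runs_table(rexp(60, 1 / 5), runif(60, 0, pi),
                   cell_id = rep(1:10, each = 6))
  c1 <- bootstrap_ci(function(d) mean(d$duration), r2, B = 100, seed = 11)
  c2 <- bootstrap_ci(function(d) mean(d$duration), r2, B = 100, seed = 11)
  expect_identical(c1, c2)
  expect_error(bootstrap_ci(mean, r2[r2$cell_id == 1, ]), "two cells")
})

test_that("bootstrap intervals cover the true mean at near-nominal rate", {
  set.seed(31)
  true_mean <- 5
  covered <- vapply(seq_len(200), function(b) {
    d <- runs_table(rexp(80, 1 / true_mean), runif(80, 0, pi),
                    cell_id = rep(1:16, each = 5))
    ci <- bootstrap_ci(function(x) mean(x$duration), d, B = 200, seed = b)
    ci[1] <= true_mean && true_mean <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("windowed bias tracks a sign flip in the generator", {
  cfg <- synth_config(fov = c(400, 320), n_cells = 10, duration = 600,
                      aggregates = data.frame(x = c(120, 280),
                                              y = c(160, 160),
                                              r0 = c(40, 18), growth = 0,
                                              disperse_at = NA),
                      flip_time = 300, flip_area = 1500, seed = 17)
  db <- gen_run_database(cfg, n_runs = 6000)
  by_size <- function(runs) ifelse(
    runs$nearest_aggregate_area > 0,
    ifelse(runs$nearest_aggregate_area < 3000, "small", "large"),
    NA_character_)
  ws <- windowed_bias(db, stratifier = by_size, B = 0)
  small_pre <- ws$bias[ws$stratum == "small" & ws$t_center < 240]
  small_post <- ws$bias[ws$stratum == "small" & ws$t_center > 360]
  large <- ws$bias[ws$stratum == "large"]
  expect_gt(mean(small_pre, na.rm = TRUE), 0.2)
  expect_lt(mean(small_post, na.rm = TRUE), -0.2)
  expect_gt(mean(large, na.rm = TRUE), 0.2)
  expect_true(all(ws$ci_lo <= ws$bias & ws$bias <= ws$ci_hi, na.rm = TRUE) ||
                all(is.na(ws$ci_lo)))
})

test_that("jam metrics recover step-like stopping parameters from a run set", {
  bg <- 0.05; amp <- 0.5; edge <- bg + amp * exp(-2)
  cfg <- synth_config(fov = c(400, 320), n_cells = 10, duration = 500,
                      aggregates = data.frame(x = 200, y = 160, r0 = 45,
                                              growth = 0, disperse_at = NA),
                      p_stop = function(rho) ifelse(rho > edge, 0.4, 0.1),
                      tau_stop = function(rho) ifelse(rho > edge, 15, 6),
                      background_intensity = bg, blob_amplitude = amp,
                      seed = 23)
  db <- gen_run_database(cfg, n_runs = 4000, np_fraction = 0.3)
  jm <- jam_metrics(db, B = 0)
  val <- function(m, s) jm$value[jm$metric == m & jm$side == s]
  n_in <- jm$n[jm$metric == "p_stop" & jm$side == "inside"]
  ci <- binom.test(round(val("p_stop", "inside") * n_in), n_in)$conf.int
  expect_true(0.4 >= ci[1] && 0.4 <= ci[2])
  expect_equal(val("stop_duration", "inside"), 15, tolerance = 0.2 * 15)
  expect_equal(val("stop_duration", "outside"), 6, tolerance = 0.2 * 6)
  expect_equal(val("exit_rate", "outside"), 1 / 6, tolerance = 0.2 / 6)
})

test_that("logistic fit recovers parameters and matches glm", {
  set.seed(8)
  area <- runif(500, 0, 8000)
  y <- rbinom(500, 1, plogis(-4.5 + 1.5e-3 * area))
  fit <- logistic_fate_vs_area(area, y == 1)
  expect_false(fit$separated)
  expect_equal(fit$threshold_area, 3000, tolerance = 0.15 * 3000)
  ref <- glm(y ~ area, family = binomial)
  expect_equal(fit$beta0, unname(coef(ref)[1]), tolerance = 1e-4)
  expect_equal(fit$beta1, unname(coef(ref)[2]), tolerance = 1e-4)
})

test_that("logistic fit handles separation and symmetric overlap", {
  fit <- logistic_fate_vs_area(c(5000, 6000, 1000, 2000),
                               c(TRUE, TRUE, FALSE, FALSE))
  expect_true(fit$separated)
  expect_equal(fit$threshold_area, 3500)
  expect_gt(fit$threshold_area, 2000); expect_lt(fit$threshold_area, 5000)
  # symmetric overlap: threshold at the shared midpoint
  fit2 <- logistic_fate_vs_area(c(3000, 5000, 1000, 3000),
                                c(TRUE, TRUE, FALSE, FALSE))
  expect_false(fit2$separated)
  expect_equal(fit2$threshold_area, 3000, tolerance = 1)
  expect_error(logistic_fate_vs_area(c(1, 2), c(TRUE, TRUE)), "stable")
})

test_that("grid-search likelihood oracle agrees with the IRLS fit", {
  set.seed(5)
  area <- runif(60, 0, 6000)
  y <- rbinom(60, 1, plogis(-2 + 8e-4 * area))
  if (length(unique(y)) < 2) skip("degenerate draw")  # guarded by seed
  fit <- logistic_fate_vs_area(area, y == 1)
  loglik <- function(b0, b1) sum(y * (b0 + b1 * area) -
                                   log1p(exp(b0 + b1 * area)))
  # the fit is a stationary point: small perturbations never help
  base <- loglik(fit$beta0, fit$beta1)
  for (d in list(c(1e-4, 0), c(-1e-4, 0), c(0, 1e-8), c(0, -1e-8)))
    expect_lte(loglik(fit$beta0 + d[1], fit$beta1 + d[2]), base + 1e-10)
  # coarse grid around the fit confirms a global shape, to 1e-4 relative
  b0g <- fit$beta0 * seq(0.9, 1.1, length.out = 21)
  b1g <- fit$beta1 * seq(0.9, 1.1, length.out = 21)
  ll <- outer(b0g, b1g, Vectorize(loglik))
  best <- which(ll == max(ll), arr.ind = TRUE)
  expect_equal(b0g[best[1]], fit$beta0, tolerance = 2e-2)
  expect_equal(b1g[best[2]], fit$beta1, tolerance = 2e-2)
})
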