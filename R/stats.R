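# Reversal-bias statistic, traffic-jam metrics, bootstrap confidence
# intervals, and the logistic stability model.

#' Reversal bias of a set of persistent runs
#'
#' `(mean duration | toward) - (mean duration | away)` divided by the mean
#' duration of *all* persistent runs in the subset (including runs whose
#' orientation falls outside the toward/away strata under the restricted
#' split). Positive values indicate longer movement toward the nearest
#' aggregate before reversing.
#'
#' @param runs data.frame of runs with `state`, `duration`, `rel_angle`.
#' @param split toward/away convention; see [run_params()].
#' @return the bias, or `NA` if either stratum is empty.
#' @export
reversal_bias <- function(runs, split = "half") {
  p <- runs[runs$state == "persistent" & !is.na(runs$rel_angle), ]
  if (nrow(p) == 0) return(NA_real_)
  cls <- toward_away(p$rel_angle, split)
  n_t <- sum(cls %in% "toward"); n_a <- sum(cls %in% "away")
  if (n_t == 0 || n_a == 0) return(NA_real_)
  t_toward <- mean(p$duration[cls %in% "toward"])
  t_away <- mean(p$duration[cls %in% "away"])
  t_all <- mean(p$duration)
  (t_toward - t_away) / t_all
}

#' Cluster bootstrap confidence interval
#'
#' Percentile interval from `B` resamples of whole cells (all runs of a
#' sampled cell are kept together, reflecting within-cell autocorrelation).
#' Deterministic given `seed`.
#'
#' @param statistic function taking a run data.frame and returning a scalar.
#' @param runs run data.frame with a `cell_id` column.
#' @param B number of bootstrap resamples.
#' @param level confidence level.
#' @param seed integer seed.
#' @return named numeric `c(lo, hi)`; zero-width (with a warning) if the
#'   statistic is degenerate across resamples.
#' @export
bootstrap_ci <- function(statistic, runs, B = 1000, level = 0.95, seed = 1L) {
  cells <- unique(runs$cell_id)
  if (length(cells) < 2) stop("need at least two cells for the bootstrap")
  by_cell <- split(seq_len(nrow(runs)), match(runs$cell_id, cells))
  vals <- with_seed(seed, vapply(seq_len(B), function(b) {
    pick <- sample.int(length(cells), replace = TRUE)
    statistic(runs[unlist(by_cell[pick]), , drop = FALSE])
  }, numeric(1)))
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) return(c(lo = NA_real_, hi = NA_real_))
  a <- (1 - level) / 2
  ci <- quantile(vals, c(a, 1 - a), names = FALSE)
  if (diff(ci) == 0) warning("degenerate statistic: zero-width interval")
  c(lo = ci[1], hi = ci[2])
}

#' Reversal bias in sliding windows, by stratum
#'
#' Computes the reversal bias over runs whose midpoint falls in each sliding
#' window, optionally stratified, with cluster-bootstrap confidence intervals.
#'
#' @param db a [run_database()].
#' @param window window width (min).
#' @param step window step (min).
#' @param stratifier `"none"`, `"fate"` (stable vs unstable nearest aggregate;
#'   sentinel rows excluded), `"area"` (aggregate area above/below the overall
#'   median), or a function mapping the run data.frame to a character vector
#'   of stratum labels (`NA` excludes a run).
#' @param B bootstrap resamples per window (0 skips CIs).
#' @param level confidence level.
#' @param split toward/away convention.
#' @param seed integer seed for the bootstrap.
#' @return data.frame (`t_center`, `stratum`, `bias`, `ci_lo`, `ci_hi`,
#'   `n_toward`, `n_away`) of class `bias_series`.
#' @export
windowed_bias <- function(db, window = 60, step = 15, stratifier = "none",
                          B = 200, level = 0.95, split = "half", seed = 1L) {
  runs <- db[db$state == "persistent", ]
  strat <- if (is.function(stratifier)) stratifier(runs)
  else switch(stratifier,
    none = rep("all", nrow(runs)),
    fate = ifelse(runs$nearest_aggregate_fate %in% c("stable", "unstable"),
                  runs$nearest_aggregate_fate, NA_character_),
    area = {
      med <- median(runs$nearest_aggregate_area[runs$nearest_aggregate_area > 0],
                    na.rm = TRUE)
      ifelse(runs$nearest_aggregate_area > 0,
             ifelse(runs$nearest_aggregate_area <= med, "small", "large"),
             NA_character_)
    },
    stop("unknown stratifier: ", stratifier))
  centers <- seq(min(runs$t_mid) + window / 2, max(runs$t_mid) - window / 2,
                 by = step)
  if (length(centers) == 0) centers <- mean(range(runs$t_mid))
  out <- list()
  for (s in sort(unique(strat[!is.na(strat)]))) {
    rs <- runs[strat %in% s, ]
    for (tc in centers) {
      w <- rs[abs(rs$t_mid - tc) <= window / 2, ]
      cls <- toward_away(w$rel_angle[!is.na(w$rel_angle)], split)
      b <- reversal_bias(w, split)
      ci <- c(NA_real_, NA_real_)
      if (B > 0 && !is.na(b) && length(unique(w$cell_id)) >= 2) {
        ci <- suppressWarnings(bootstrap_ci(
          function(d) reversal_bias(d, split), w, B = B, level = level,
          seed = derive_seed(seed, round(tc))))
      }
      out[[length(out) + 1]] <- data.frame(
        t_center = tc, stratum = s, bias = b, ci_lo = ci[1], ci_hi = ci[2],
        n_toward = sum(cls %in% "toward"), n_away = sum(cls %in% "away"))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("bias_series", class(res))
  res
}

#' Traffic-jam metrics inside versus outside aggregates
#'
#' Stratifies runs by the sign of the boundary distance (inside iff negative)
#' and reports persistent run speeds, the probability that a persistent run
#' ends in a state change rather than a reversal, mean non-persistent
#' durations, and the exit rate (reciprocal mean non-persistent duration),
#' each with a cluster-bootstrap confidence interval.
#'
#' @param db a [run_database()] (or annotated run data.frame).
#' @param B bootstrap resamples (0 skips CIs).
#' @param level confidence level.
#' @param seed integer seed.
#' @return data.frame with one row per metric x side, columns `metric`,
#'   `side`, `value`, `ci_lo`, `ci_hi`, `n`.
#' @export
jam_metrics <- function(db, B = 200, level = 0.95, seed = 1L) {
  db <- db[!is.na(db$boundary_distance), ]
  # state transitions occur where a run ends; stratify persistent transition
  # metrics on the end-of-run distance when it is available
  bd <- if ("boundary_distance_end" %in% names(db) &&
            !anyNA(db$boundary_distance_end)) {
    ifelse(db$state == "persistent", db$boundary_distance_end,
           db$boundary_distance)
  } else db$boundary_distance
  side <- ifelse(bd < 0, "inside", "outside")
  fun <- list(
    speed = function(d) mean(d$mean_speed[d$state == "persistent"]),
    p_stop = function(d) {
      e <- d$end_event[d$state == "persistent" &
                         d$end_event %in% c("state_change", "reversal")]
      if (length(e) == 0) NA_real_ else mean(e == "state_change")
    },
    stop_duration = function(d) mean(d$duration[d$state == "non-persistent"]),
    exit_rate = function(d) 1 / mean(d$duration[d$state == "non-persistent"])
  )
  out <- list()
  for (sd_ in c("inside", "outside")) {
    d <- db[side == sd_, ]
    for (m in names(fun)) {
      v <- if (nrow(d) > 0) fun[[m]](d) else NA_real_
      ci <- c(NA_real_, NA_real_)
      if (B > 0 && is.finite(v) && length(unique(d$cell_id)) >= 2) {
        ci <- suppressWarnings(bootstrap_ci(fun[[m]], d, B = B, level = level,
                                            seed = derive_seed(seed, nchar(m))))
      }
      n <- if (m %in% c("stop_duration", "exit_rate"))
        sum(d$state == "non-persistent") else sum(d$state == "persistent")
      out[[length(out) + 1]] <- data.frame(metric = m, side = sd_, value = v,
                                           ci_lo = ci[1], ci_hi = ci[2], n = n)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# IRLS for the two-parameter logistic model with a small ridge penalty.
logistic_irls <- function(area, y, ridge = 1e-8, max_iter = 100, tol = 1e-10) {
  x <- cbind(1, area)
  beta <- c(0, 0)
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    xtw <- t(x * w)
    h <- xtw %*% x + diag(ridge, 2)
    beta_new <- drop(solve(h, xtw %*% z))
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  beta
}

#' Logistic model of aggregate stability versus area
#'
#' Maximum-likelihood fit of `P(stable) = 1 / (1 + exp(-(b0 + b1 * area)))` by
#' iteratively reweighted least squares with a 1e-8 ridge for numerical
#' stability. The stable-size threshold is the area at which the fitted curve
#' crosses 0.5, `-b0 / b1`. Complete separation is detected; the threshold is
#' then reported as the midpoint of the separating gap and flagged.
#'
#' @param areas aggregate areas (um^2), typically at the coarsening start.
#' @param stable logical (or `"stable"`/`"unstable"`) fate labels.
#' @return list of class `logistic_fit` with `beta0`, `beta1`,
#'   `threshold_area`, `n_stable`, `n_unstable`, `separated`.
#' @export
logistic_fate_vs_area <- function(areas, stable) {
  if (is.character(stable)) stable <- stable == "stable"
  ok <- is.finite(areas) & !is.na(stable)
  areas <- areas[ok]; y <- as.numeric(stable[ok])
  if (length(unique(y)) < 2)
    stop("need at least one stable and one unstable aggregate")
  separated <- max(areas[y == 0]) < min(areas[y == 1]) ||
    max(areas[y == 1]) < min(areas[y == 0])
  sc <- max(abs(areas))
  beta <- unname(logistic_irls(areas / sc, y,
                               max_iter = if (separated) 25 else 100))
  beta <- c(beta[1], beta[2] / sc)
  thr <- if (separated) {
    if (max(areas[y == 0]) < min(areas[y == 1]))
      (max(areas[y == 0]) + min(areas[y == 1])) / 2
    else (max(areas[y == 1]) + min(areas[y == 0])) / 2
  } else if (beta[2] != 0) -beta[1] / beta[2] else NA_real_
  structure(list(beta0 = beta[1], beta1 = beta[2], threshold_area = thr,
                 n_stable = sum(y == 1), n_unstable = sum(y == 0),
                 separated = separated),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic stability model: P(stable) = logistic(b0 + b1 * area)\n")
  cat(sprintf("  b0 = %.4g, b1 = %.4g per um^2\n", x$beta0, x$beta1))
  cat(sprintf("  stable-size threshold = %.1f um^2%s\n", x$threshold_area,
              if (x$separated) " (complete separation; midpoint of gap)" else ""))
  cat(sprintf("  n = %d stable, %d unstable\n", x$n_stable, x$n_unstable))
  invisible(x)
}
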