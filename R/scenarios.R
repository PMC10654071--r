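# Preset synthetic study conditions used by the package's validation suite,
# the acceptance script, and the documentation examples. Each preset fixes the
# ground truth once; the analysis and simulation code is then judged by how
# well it recovers that truth.

#' Parameter-recovery world: area-dependent reversal bias
#'
#' A 600 x 500 um world with four large stable disks (one per quadrant) and a
#' small disk in the center. Cells run toward their nearest aggregate for 10
#' min on average and away for 7 min when the aggregate is large, and the
#' reverse when it is small, giving a ground-truth reversal bias of +/- 0.35
#' by stratum. Stopping is rare and density-independent so the bias signal
#' dominates. The interior placement of the small disk keeps its basin away
#' from the reflecting boundary, whose artifacts otherwise contaminate the
#' away stratum.
#'
#' @param seed integer seed.
#' @param n_cells number of tracked cells.
#' @param duration tracked minutes.
#' @return a [synth_config()].
#' @export
bias_recovery_config <- function(seed = 11, n_cells = 250, duration = 600) {
  synth_config(
    fov = c(600, 500), n_cells = n_cells, duration = duration, seed = seed,
    aggregates = data.frame(x = c(130, 470, 130, 470, 300),
                            y = c(125, 125, 375, 375, 250),
                            r0 = c(40, 40, 40, 40, 30), growth = 0,
                            disperse_at = NA),
    tau_toward = function(A) ifelse(A > 3000, 10, 7),
    tau_away = function(A) ifelse(A > 3000, 7, 10),
    p_stop = function(rho) rep(0.1, length(rho)),
    tau_stop = function(rho) rep(5, length(rho))
  )
}

#' Parameter-recovery world: density-dependent traffic jam
#'
#' Two equal disks with direction-independent 9-min runs; the stopping
#' probability and stop duration step up inside the disks (the density at the
#' disk boundary equals the blob's e^-2 contour, so "inside the disk" and
#' "above the density step" coincide): p_stop 0.4 vs 0.1, stop means 20 vs 10
#' min.
#'
#' @inheritParams bias_recovery_config
#' @return a [synth_config()].
#' @export
jam_recovery_config <- function(seed = 5, n_cells = 180, duration = 500) {
  bg <- 0.05; amp <- 0.5
  edge <- bg + amp * exp(-2)
  synth_config(
    fov = c(500, 400), n_cells = n_cells, duration = duration, seed = seed,
    aggregates = data.frame(x = c(150, 350), y = c(150, 250), r0 = 45,
                            growth = 0, disperse_at = NA),
    tau_toward = function(A) rep(9, length(A)),
    tau_away = function(A) rep(9, length(A)),
    p_stop = function(rho) ifelse(rho > edge, 0.4, 0.1),
    tau_stop = function(rho) ifelse(rho > edge, 20, 10),
    background_intensity = bg, blob_amplitude = amp
  )
}

#' Scaled dispersal-contrast study: run-database world
#'
#' The synthetic world behind the scaled agent-based dispersal experiment:
#' four stable disks (areas roughly 6400, 5500, 4500, and 2800 um^2) in a
#' 500 x 400 um field. From minute 300 the toward/away duration means swap for
#' aggregates below `flip_area` = 4000 um^2 (cells then spend longer moving
#' away from small aggregates) and the local stopping probability near them
#' halves; the traffic jam is a step in density (p_stop 0.4/0.1, stops 15/5
#' min, speed halved inside blobs). The size threshold of 4000 um^2 keeps
#' "small" aggregates large enough (roughly 100-300 agents at the scaled
#' density) for their fates to be meaningful.
#'
#' @param seed integer seed.
#' @return a [synth_config()].
#' @export
dispersal_scenario_config <- function(seed = 3) {
  bg <- 0.05; amp <- 0.5
  edge <- bg + amp * exp(-2)
  synth_config(
    fov = c(500, 400), duration = 600, seed = seed,
    aggregates = data.frame(x = c(110, 390, 110, 390),
                            y = c(110, 110, 290, 290),
                            r0 = c(45, 42, 38, 30), growth = 0,
                            disperse_at = NA),
    p_stop = function(rho) ifelse(rho > edge, 0.4, 0.1),
    tau_stop = function(rho) ifelse(rho > edge, 15, 5),
    speed_factor = function(rho) ifelse(rho > edge, 0.5, 1),
    background_intensity = bg, blob_amplitude = amp,
    flip_time = 300, flip_area = 4000,
    no_agg_distance = 200
  )
}

#' Scaled dispersal-contrast study: simulation configuration
#'
#' Simulation settings for the scaled dispersal experiment: 2,000 agents in
#' 500 x 400 um, 10 h simulated (coarsening from minute 300), 10-um kernel
#' bandwidth and a detection threshold of 1.6x the uniform density level
#' (both calibrated once so that the simulation forms a persistent population
#' of aggregates spanning the size threshold by the coarsening start), 5-min
#' density refresh, and the boundary-distance sentinel shared with
#' [dispersal_scenario_config()].
#'
#' @param variant cue variant, see [variant_flags()].
#' @param seed integer seed.
#' @param ... overrides passed to [sim_config()].
#' @return a [sim_config()].
#' @export
dispersal_scenario_sim <- function(variant = "bias-only", seed = 1L, ...) {
  sim_config(fov = c(500, 400), n_agents = 2000, t_start = 0, t_end = 600,
             t_coarsen = 300, kde_bandwidth = 10, threshold_rel = 1.6,
             density_refresh = 5, no_agg_distance = 200,
             cue_flags = variant_flags(variant), seed = seed, ...)
}

#' Pooled sub-threshold dispersal over replicate simulations
#'
#' Runs `n_replicates` simulations differing only by seed and pools the fates
#' of the qualifying aggregates (alive at the coarsening start, at least
#' `min_age` minutes old, stationary, not ending by merging) below and above
#' `area_max`.
#'
#' @param db run database.
#' @param variant cue variant.
#' @param seeds integer vector of replicate seeds.
#' @param area_max the size threshold (um^2).
#' @param ... overrides passed to [dispersal_scenario_sim()].
#' @return list with `sub_n`, `sub_dispersed`, `areas`, `fates`,
#'   `pct_decrease` (per replicate), and a pooled `fit` (or `NULL`).
#' @export
run_dispersal_contrast <- function(db, variant, seeds = c(9, 10, 11),
                                   area_max = 4000, ...) {
  areas <- numeric(0); fates <- character(0); pct <- numeric(0)
  for (s in seeds) {
    cfg <- dispersal_scenario_sim(variant, seed = s, ...)
    sim <- suppressWarnings(run_simulation(cfg, db))
    ds <- dispersal_summary(sim, area_max = area_max)
    fl <- sim$aggregates$flags
    keep <- fl$agg_id[!fl$motile & fl$t_first <= cfg$t_coarsen - 60]
    st <- aggregates_at(sim$aggregates, cfg$t_coarsen,
                        min_area = cfg$pinpoint_min_area)
    st <- st[st$agg_id %in% keep & st$fate %in% c("stable", "unstable"), ]
    areas <- c(areas, st$area_um2)
    fates <- c(fates, st$fate)
    pct <- c(pct, ds$pct_decrease)
  }
  sub <- areas < area_max
  fit <- if (length(unique(fates)) == 2)
    logistic_fate_vs_area(areas, fates) else NULL
  list(sub_n = sum(sub), sub_dispersed = sum(fates[sub] == "unstable"),
       areas = areas, fates = fates, pct_decrease = pct, fit = fit)
}
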