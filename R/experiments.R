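## Scenario runner: each figure condition of the study is a named, fully
## seeded protocol (preset + wiring + trajectory set + analysis plan).

scenario_names <- c("fig1_intrinsic", "fig1_extrinsic", "fig2_directional",
                    "fig3_loop0", "fig3_loop180",
                    "fig4_control", "fig4_lesion",
                    "fig5_loop45", "fig5_loop90", "fig5_loop225", "fig5_loop270",
                    "fig6_norecurrence", "fig7_tempotron", "fig8_gradients")

#' Standard 2-s bidirectional track trajectories
#'
#' The canonical linear-track protocol: a rightward run from (-20, 0) to
#' (20, 0) at 20 cm/s over 2 s, and its exact reverse.
#'
#' @param config A `network_config` (for arena and dt).
#' @param duration Run duration (ms).
#' @param speed Running speed (cm/s).
#' @return List with `right` and `left` trajectories.
#' @export
track_trajectories <- function(config, duration = 2000, speed = 20) {
  ar <- config_arena(config)
  half <- speed * (duration / 1000) / 2
  list(
    right = make_straight_trajectory(c(-half, 0), 0, speed, duration,
                                     config$dt, ar),
    left = make_straight_trajectory(c(half, 0), pi, speed, duration,
                                    config$dt, ar)
  )
}

## simulate the same wiring along both track directions
run_both_directions <- function(config, duration = 2000, speed = 20,
                                network = NULL) {
  if (is.null(network)) network <- build_network(config)
  tr <- track_trajectories(config, duration, speed)
  list(network = network,
       fwd = simulate(config, tr$right, network),
       rev = simulate(config, tr$left, network))
}

#' Theta-compression summary of a run
#'
#' Computes [pair_metrics()] for the run and regresses the correlation-lag
#' phase on the field-centre distance ([theta_compression()]).
#'
#' @param record `spike_record` of the run.
#' @param max_dist Overlapping-pair distance bound (cm).
#' @param min_spikes Activity filter.
#' @return List: `slope` (rad/cm), `onset`, `R`, `n_pairs`, and the pair
#'   table as `pairs`.
#' @export
compression_analysis <- function(record, max_dist = 10, min_spikes = 5) {
  pm <- pair_metrics(record, max_dist = max_dist, min_spikes = min_spikes)
  fit <- theta_compression(pm$lag_phase, pm$dist)
  list(slope = fit$slope, onset = fit$onset, R = fit$R, n_pairs = fit$n,
       pairs = pm)
}

## fraction of extrinsic pairs within a logical subset
frac_extrinsic <- function(pm, subset = TRUE) {
  cls <- pm$class[subset & !is.na(pm$class)]
  if (!length(cls)) return(NA_real_)
  mean(cls == "extrinsic")
}

#' Extrinsicity/intrinsicity population summary for one loop direction
#'
#' Runs the wiring along both track directions, computes pairwise Ex/In,
#' classes each pair by preferred-direction geometry, and tabulates the
#' extrinsic fractions used in the directionality analyses.
#'
#' @param config `network_config` with `theta_dg` set.
#' @param network Optional pre-built network.
#' @param duration,speed Trajectory parameters.
#' @return List with the pair table and the extrinsic fractions by class.
#' @export
exin_analysis <- function(config, network = NULL, duration = 2000, speed = 20) {
  runs <- run_both_directions(config, duration, speed, network)
  pm <- pair_metrics(runs$fwd, runs$rev)
  cl <- classify_pairs(pm$psi_a, pm$psi_b, runs$fwd$trajectory$heading[1])
  list(
    pairs = cbind(pm, cl),
    frac_extrinsic = frac_extrinsic(pm),
    frac_extrinsic_best = frac_extrinsic(pm, cl$both_best),
    frac_extrinsic_worst = frac_extrinsic(pm, cl$both_worst),
    frac_extrinsic_similar = frac_extrinsic(pm, cl$similar),
    frac_extrinsic_dissimilar = frac_extrinsic(pm, cl$dissimilar),
    runs = runs
  )
}

#' Orientation of intrinsic and extrinsic pair populations
#'
#' For each classified pair the centre-difference vector is oriented along
#' the pair's within-cycle propagation direction (flipped when the
#' correlation-lag phase is negative). Returns the circular histogram peak
#' for the extrinsic and intrinsic populations; intrinsic pairs should peak
#' along the DG-loop direction, extrinsic pairs along the running direction.
#'
#' @param pairs Pair table from [exin_analysis()].
#' @param bin_deg Histogram bin width (degrees).
#' @return List with `peak_extrinsic` and `peak_intrinsic` orientations
#'   (radians) and the underlying histograms.
#' @export
pair_orientation_peaks <- function(pairs, bin_deg = 15) {
  ok <- !is.na(pairs$class) & is.finite(pairs$lag_phase)
  orient <- wrap_2pi(ifelse(pairs$lag_phase >= 0, pairs$orient,
                            pairs$orient + pi))
  edges <- seq(0, 2 * pi, by = bin_deg * pi / 180)
  peak <- function(o) {
    if (!length(o)) return(NA_real_)
    hcounts <- table(cut(o, edges, include.lowest = TRUE))
    centers <- edges[-1] - bin_deg * pi / 360
    centers[which.max(hcounts)]
  }
  list(peak_extrinsic = peak(orient[ok & pairs$class == "extrinsic"]),
       peak_intrinsic = peak(orient[ok & pairs$class == "intrinsic"]),
       orient = orient, ok = ok)
}

#' Landmark-detection protocol with the tempotron readout
#'
#' Reproduces the direction-invariance experiment: the DG loop is anchored
#' on a 40-cm path at y = +20 cm (and absent elsewhere), two tempotrons are
#' trained on the theta-cycle patterns evoked by 1-s non-moving stimuli at
#' the with-loop (0, 20) and no-loop (0, -20) locations, and both are then
#' tested on 1-s, 20-cm runs through their location at directions 0, 15,
#' ..., 345 degrees.
#'
#' @param seed Master seed (wiring, jitter, training shuffle).
#' @param directions_deg Test running directions (degrees).
#' @param n_jitter Jitter realisations per pattern.
#' @param epochs Training epoch budget.
#' @param duration Training/testing stimulus duration (ms).
#' @return List: `accuracy` data frame (direction, with_loop, no_loop),
#'   means per condition, and the trained models.
#' @export
tempotron_landmark_experiment <- function(seed = 1L,
                                          directions_deg = seq(0, 345, by = 15),
                                          n_jitter = 100, epochs = 100,
                                          duration = 1000) {
  cfg <- network_config("fig7", theta_dg = 0, loop_anchor = c(0, 20),
                        seed = as.integer(seed))
  net <- build_network(cfg)
  ar <- config_arena(cfg)
  loc_with <- c(0, 20)
  loc_no <- c(0, -20)
  train_one <- function(loc, seed_off) {
    tr <- make_straight_trajectory(loc, 0, 0, duration, cfg$dt, ar)
    rec <- simulate(cfg, tr, net)
    cp <- cycle_patterns(rec, loc)
    reals <- jittered_realizations(cp$patterns, n_jitter, 2,
                                   seed = seed + seed_off)
    train_pats <- do.call(c, reals)
    mdl <- tempotron(cp$n_afferents)
    mdl <- tempotron_train(mdl, train_pats, epochs = epochs,
                           seed = seed + seed_off + 1L)
    list(model = mdl, record = rec)
  }
  with_loop <- train_one(loc_with, 100L)
  no_loop <- train_one(loc_no, 200L)
  test_acc <- function(model, loc, dir_deg, seed_off) {
    phi <- dir_deg * pi / 180
    start <- loc - 10 * c(cos(phi), sin(phi))
    tr <- make_straight_trajectory(start, phi, 20, duration, cfg$dt, ar)
    rec <- simulate(cfg, tr, net)
    tempotron_evaluate(model, rec, loc, n_jitter = n_jitter, sd_ms = 2,
                       seed = seed + seed_off + dir_deg)
  }
  acc <- data.frame(direction = directions_deg)
  acc$with_loop <- vapply(directions_deg, function(d)
    test_acc(with_loop$model, loc_with, d, 300L), numeric(1))
  acc$no_loop <- vapply(directions_deg, function(d)
    test_acc(no_loop$model, loc_no, d, 400L), numeric(1))
  list(accuracy = acc,
       mean_with_loop = mean(acc$with_loop),
       mean_no_loop = mean(acc$no_loop),
       model_with_loop = with_loop$model,
       model_no_loop = no_loop$model)
}

#' Run a named scenario end to end
#'
#' Executes one figure condition (simulation plus its analysis plan) and
#' returns a summary list; every scenario is fully determined by
#' `(name, overrides, seed)`.
#'
#' @param name One of the scenario names (an unknown name raises an error
#'   listing the valid ones).
#' @param seed Master seed.
#' @param overrides Named list of `network_config` overrides.
#' @param duration Run duration (ms); the figure protocols use 2-s runs
#'   (1 s for the tempotron and gradient scenarios).
#' @return A summary list; components depend on the scenario's analysis
#'   plan (precession tables, averaged-correlogram peak lags, Ex/In
#'   fractions, compression slopes, tempotron accuracies, gradient maps).
#' @export
run_scenario <- function(name, seed = 1L, overrides = list(),
                         duration = 2000) {
  if (!name %in% scenario_names) {
    stop("unknown scenario '", name, "'; valid names: ",
         paste(scenario_names, collapse = ", "), call. = FALSE)
  }
  seed <- as.integer(seed)
  mk <- function(preset, ...) {
    do.call(network_config,
            c(list(preset = preset, seed = seed), list(...), overrides))
  }
  summarize_runs <- function(runs) {
    prec <- population_precession(runs$fwd)
    ## fixed cell order (along the rightward run) for both directions, so
    ## peak-lag signs are directly comparable between the two runs
    list(
      avg_ccg_fwd = averaged_correlogram(runs$fwd, ref_heading = 0),
      avg_ccg_rev = averaged_correlogram(runs$rev, ref_heading = 0),
      precession = prec,
      median_slope = stats::median(prec$slope, na.rm = TRUE)
    )
  }
  switch(
    name,
    fig1_intrinsic = ,
    fig1_extrinsic = {
      cfg <- mk(name)
      runs <- run_both_directions(cfg, duration)
      s <- summarize_runs(runs)
      s$peak_lag_fwd <- s$avg_ccg_fwd$peak_lag
      s$peak_lag_rev <- s$avg_ccg_rev$peak_lag
      s$sign_flips <- sign(s$peak_lag_fwd) != sign(s$peak_lag_rev)
      s$runs <- runs
      s
    },
    fig2_directional = {
      cfg <- mk("fig2")
      runs <- run_both_directions(cfg, duration)
      s <- summarize_runs(runs)
      prec <- s$precession
      best <- abs(circ_diff(prec$psi, 0)) < 30 * pi / 180
      worst <- abs(circ_diff(prec$psi, 0)) > 150 * pi / 180
      circ_mean <- function(x) wrap_2pi(Arg(mean(exp(1i * x))))
      s$best <- list(n = sum(best),
                     mean_phase = circ_mean(prec$mean_phase[best]),
                     mean_onset = circ_mean(prec$onset[best]))
      s$worst <- list(n = sum(worst),
                      mean_phase = circ_mean(prec$mean_phase[worst]),
                      mean_onset = circ_mean(prec$onset[worst]))
      s$runs <- runs
      s
    },
    fig3_loop0 = ,
    fig3_loop180 = {
      th <- if (name == "fig3_loop0") 0 else pi
      cfg <- mk("fig3", theta_dg = th)
      ex <- exin_analysis(cfg, duration = duration)
      ex$avg_ccg_fwd <- averaged_correlogram(ex$runs$fwd)
      ex$avg_ccg_rev <- averaged_correlogram(ex$runs$rev)
      ex
    },
    fig4_control = {
      cfg <- mk("fig4_control")
      runs <- run_both_directions(cfg, duration)
      compression_analysis(runs$fwd)
    },
    fig4_lesion = {
      cfg <- lesion_transform(mk("fig4_control"))
      tr <- track_trajectories(cfg, duration)
      rec <- simulate(cfg, tr$right)
      compression_analysis(rec)
    },
    fig5_loop45 = ,
    fig5_loop90 = ,
    fig5_loop225 = ,
    fig5_loop270 = {
      th <- as.numeric(sub("fig5_loop", "", name)) * pi / 180
      cfg <- mk("fig5", theta_dg = th)
      ex <- exin_analysis(cfg, duration = duration)
      ex$orientation <- pair_orientation_peaks(ex$pairs)
      ex
    },
    fig6_norecurrence = {
      cfg <- mk("fig6a")
      runs <- run_both_directions(cfg, duration)
      s <- summarize_runs(runs)
      s$sign_flips <- sign(s$avg_ccg_fwd$peak_lag) != sign(s$avg_ccg_rev$peak_lag)
      s$runs <- runs
      s
    },
    fig7_tempotron = tempotron_landmark_experiment(seed = seed),
    fig8_gradients = {
      ar_window <- c(500, 600)
      res <- list()
      for (variant in c("with_loop", "no_loop")) {
        cfg <- if (variant == "with_loop") mk("fig3", theta_dg = 0) else mk("fig2")
        tr <- make_straight_trajectory(c(0, 0), 0, 0, 1000, cfg$dt,
                                       config_arena(cfg))
        rec <- simulate(cfg, tr)
        res[[variant]] <- gradient_map(rec, window = ar_window)
      }
      res
    }
  )
}
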