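## Shared fixtures.  Full-scale simulations are expensive, so the acceptance
## tests share one lazily filled cache of runs; unit tests use the tiny
## network below.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

## a miniature network (100 CA3, 16 DG, 6 interneurons per layer) with
## weights scaled to the sparse 8-cm grid spacing; used wherever network
## behaviour, not the published operating point, is under test
tiny_config <- function(seed = 7L, ...) {
  network_config("fig3", seed = seed,
                 n_ca3_side = 10, n_dg_side = 4, N_I = 6,
                 A_pos = 9, A_dir = 5, B_pos = 40, B_dir = 30,
                 B_DG = 60, W0_ca3_inh = 10, W0_inh_ca3 = 4,
                 W0_dg_inh = 20, W0_inh_dg = 8, U_D = 0.6,
                 theta_dg = pi / 4, ...)
}

tiny_run <- function(duration = 500, seed = 7L, ...) {
  cfg <- tiny_config(seed = seed, ...)
  net <- build_network(cfg)
  tr <- make_straight_trajectory(c(-20, 0), 0, 40, duration, cfg$dt,
                                 arena(cfg$arena_width, cfg$arena_height))
  list(cfg = cfg, net = net, tr = tr, rec = simulate(cfg, tr, net))
}

## full-scale bidirectional runs over one wiring, cached by label
full_runs <- function(label, preset, theta_dg = 0, ...) {
  cached(label, {
    cfg <- network_config(preset, seed = 1L, theta_dg = theta_dg, ...)
    run_both_directions(cfg)
  })
}

circ_mean_phase <- function(x) wrap_2pi(Arg(mean(exp(1i * x))))

## circular absolute difference in degrees
circ_dist_deg <- function(a_deg, b_deg) {
  d <- abs((a_deg - b_deg) %% 360)
  min(d, 360 - d)
}
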