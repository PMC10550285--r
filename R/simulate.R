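#' Assemble grids and weight matrices for a configuration
#'
#' Builds the CA3 and DG place-cell grids (preferred directions drawn from
#' `config$seed` and `config$seed + 1`), the CA3 recurrent matrix, the two
#' DG-loop matrices, and the randomised inhibitory feedback matrices
#' (`config$seed + 2/3`). The result can be reused across simulations that
#' share wiring (e.g. forward and reverse runs over the same network).
#'
#' @param config A [network_config()].
#' @return A `network` list: `config`, `ca3`, `dg` (or `NULL`), and the
#'   weight blocks `W_cc`, `W_dc`, `W_cd`, `W_ic`, `W_id`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  arena <- config_arena(config)
  ca3 <- assign_preferred_directions(
    build_grid(arena, config$n_ca3_side, "CA3"), config$seed)
  has_dg <- config$n_dg_side > 0
  dg <- if (has_dg) {
    assign_preferred_directions(
      build_grid(arena, config$n_dg_side, "DG"), config$seed + 1L)
  }
  recur <- config$B_pos > 0 || config$B_dir > 0
  W_cc <- if (recur) {
    ca3_weights(ca3, config$B_pos, config$B_dir, config$K_CA3, config$sigma,
                config$asymmetry_on)
  } else matrix(0, 0, 0)
  loop <- has_dg && config$B_DG > 0 && !config$dg_lesion
  W_dc <- if (loop) {
    ca3_to_dg_weights(ca3, dg, config$B_DG, config$K_DG, config$sigma,
                      config$theta_dg, config$loop_anchor)
  } else matrix(0, 0, 0)
  W_cd <- if (loop) {
    dg_to_ca3_weights(dg, ca3, config$B_DG, config$K_DG, config$sigma,
                      config$theta_dg, config$loop_shift)
  } else matrix(0, 0, 0)
  n_ca3 <- config$n_ca3_side^2
  n_dg <- if (has_dg) config$n_dg_side^2 else 0L
  W_ic <- if (config$N_I > 0 && config$W0_inh_ca3 > 0) {
    inhibitory_weights(config$N_I, n_ca3, config$W0_inh_ca3, config$seed + 2L)
  } else matrix(0, 0, 0)
  W_id <- if (config$N_I > 0 && has_dg && config$W0_inh_dg > 0) {
    inhibitory_weights(config$N_I, n_dg, config$W0_inh_dg, config$seed + 3L)
  } else matrix(0, 0, 0)
  structure(
    list(config = config, ca3 = ca3, dg = dg,
         W_cc = W_cc, W_dc = W_dc, W_cd = W_cd, W_ic = W_ic, W_id = W_id),
    class = "network"
  )
}

#' @export
print.network <- function(x, ...) {
  cat(sprintf("<network> preset '%s': %d CA3, %d DG, %d+%d interneurons\n",
              x$config$preset, nrow(x$ca3$centers),
              if (is.null(x$dg)) 0 else nrow(x$dg$centers),
              x$config$N_I, if (is.null(x$dg)) 0 else x$config$N_I))
  invisible(x)
}

sim_prm <- function(config, n_dg, n_inh_ca3, n_inh_dg, max_spikes) {
  exc <- izhikevich_params("excitatory")
  inh <- izhikevich_params("inhibitory")
  list(
    n_ca3 = as.integer(config$n_ca3_side^2), n_dg = as.integer(n_dg),
    n_inh_ca3 = as.integer(n_inh_ca3), n_inh_dg = as.integer(n_inh_dg),
    dt = config$dt,
    tau_E = config$tau_E, tau_I = config$tau_I,
    tau_F = config$tau_F, tau_D = config$tau_D,
    V_E = config$V_E, V_I = config$V_I,
    theta_amp = config$theta_amp, theta_period = config$theta_period,
    mec_shift = config$mec_phase_deg * pi / 180,
    A_pos = config$A_pos, A_dir = config$A_dir,
    input_radius = config$input_radius,
    S0F = config$S0F, S1F = config$S1F, Phi_F = config$Phi_F,
    U_D = config$U_D, std_mode = config$std_mode,
    std_release = config$std_release,
    std_to_interneurons = config$std_to_interneurons,
    std_to_dg = config$std_to_dg,
    theta_to_inhibitory = config$theta_to_inhibitory,
    dg_lesion = config$dg_lesion,
    delay_steps = as.integer(round(config$tau_0 / config$dt)),
    max_spikes = max_spikes,
    dg_norm = if (identical(config$dg_norm, "per_block") && n_dg > 0) {
      as.numeric(n_dg)
    } else {
      as.numeric(config$n_ca3_side^2)
    },
    a_exc = exc$a, b_exc = exc$b, c_exc = exc$c, d_exc = exc$d,
    a_inh = inh$a, b_inh = inh$b, c_inh = inh$c, d_inh = inh$d
  )
}

#' Simulate the network along a trajectory
#'
#' Runs the full forward integration (compiled core) of all CA3 and DG place
#' cells plus the two interneuron populations at time step `config$dt`.
#' Sensory drive reaches only CA3; the theta drive is subtracted from every
#' neuron; short-term depression acts on every synapse with a CA3
#' presynaptic cell; spikes are delivered after the 2 ms transmission delay.
#' The result is bitwise reproducible given (config, trajectory).
#'
#' @param config A [network_config()].
#' @param trajectory A [make_straight_trajectory()] result sampled at
#'   `config$dt`.
#' @param network Optional pre-built [build_network()] result (reused wiring);
#'   built from `config` when missing.
#' @param max_spikes Abort threshold on total recorded spikes.
#' @param on_overflow `"error"` (default) aborts when `max_spikes` is
#'   exceeded; `"truncate"` returns the record up to that point (diagnostic
#'   use).
#' @return A `spike_record`: `spikes` data frame (`layer`, `id`, `t` in ms;
#'   ids are 1-based within each layer), the `ca3`/`dg` grids, `config`, and
#'   the simulation `duration`.
#' @export
simulate <- function(config, trajectory, network = NULL, max_spikes = 5e6,
                     on_overflow = c("error", "truncate")) {
  on_overflow <- match.arg(on_overflow)
  stopifnot(inherits(trajectory, "trajectory"))
  if (is.null(network)) network <- build_network(config) else {
    config <- network$config
  }
  if (abs(trajectory$dt - config$dt) > 1e-12) {
    stop("trajectory must be sampled at config$dt", call. = FALSE)
  }
  if (trajectory$arena$width != config$arena_width ||
      trajectory$arena$height != config$arena_height) {
    stop("trajectory arena does not match the configured arena", call. = FALSE)
  }
  n_ca3 <- config$n_ca3_side^2
  has_dg <- !is.null(network$dg)
  n_dg <- if (has_dg) config$n_dg_side^2 else 0L
  n_ic <- if (config$N_I > 0 && config$W0_ca3_inh > 0) config$N_I else 0L
  n_id <- if (config$N_I > 0 && has_dg && config$W0_dg_inh > 0) config$N_I else 0L
  traj <- cbind(trajectory$pos, trajectory$heading)
  out <- sim_core(network$W_cc, network$W_dc, network$W_cd,
                  network$W_ic, network$W_id,
                  config$W0_ca3_inh, config$W0_dg_inh,
                  network$ca3$centers, network$ca3$psi, traj,
                  c(sim_prm(config, n_dg, n_ic, n_id, max_spikes),
                    list(overflow_error = on_overflow == "error")))
  id <- out$id
  layer <- character(length(id))
  local_id <- integer(length(id))
  bounds <- cumsum(c(n_ca3, n_dg, n_ic, n_id))
  lab <- c("CA3", "DG", "InhCA3", "InhDG")
  prev <- 0L
  for (k in seq_along(bounds)) {
    sel <- id > prev & id <= bounds[k]
    layer[sel] <- lab[k]
    local_id[sel] <- id[sel] - prev
    prev <- bounds[k]
  }
  spikes <- data.frame(layer = layer, id = local_id, t = out$t,
                       stringsAsFactors = FALSE)
  spikes <- spikes[order(spikes$t, spikes$layer, spikes$id), , drop = FALSE]
  rownames(spikes) <- NULL
  structure(
    list(spikes = spikes, ca3 = network$ca3, dg = network$dg,
         config = config, trajectory = trajectory,
         duration = trajectory$t[length(trajectory$t)]),
    class = "spike_record"
  )
}

#' @export
print.spike_record <- function(x, ...) {
  tab <- table(x$spikes$layer)
  cat(sprintf("<spike_record> %.0f ms, %d spikes (%s)\n", x$duration,
              nrow(x$spikes),
              paste(sprintf("%s: %d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}

#' Spike times of one cell
#' @param record A `spike_record`.
#' @param id Cell id within the layer.
#' @param layer Layer name.
#' @return Numeric vector of spike times (ms).
#' @export
cell_spikes <- function(record, id, layer = "CA3") {
  s <- record$spikes
  s$t[s$layer == layer & s$id == id]
}

#' Write a spike record to CSV
#' @param record A `spike_record`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spikes_csv <- function(record, path) {
  utils::write.csv(record$spikes, path, row.names = FALSE)
  invisible(path)
}

#' Read spikes written by [write_spikes_csv()]
#' @param path CSV file with columns `layer`, `id`, `t`.
#' @return Data frame of spike events.
#' @export
read_spikes_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

## Pure-R reference integrator composing the exported step functions.  Only
## meant for tiny networks: the test suite uses it as the independent oracle
## for the compiled core.
simulate_reference <- function(config, trajectory, network = NULL) {
  if (is.null(network)) network <- build_network(config)
  cfg <- network$config
  n_ca3 <- cfg$n_ca3_side^2
  has_dg <- !is.null(network$dg)
  n_dg <- if (has_dg) cfg$n_dg_side^2 else 0L
  n_ic <- if (cfg$N_I > 0 && cfg$W0_ca3_inh > 0) cfg$N_I else 0L
  n_id <- if (cfg$N_I > 0 && has_dg && cfg$W0_dg_inh > 0) cfg$N_I else 0L
  n_tot <- n_ca3 + n_dg + n_ic + n_id
  exc_par <- izhikevich_params("excitatory")
  inh_par <- izhikevich_params("inhibitory")
  is_exc <- seq_len(n_tot) <= n_ca3 + n_dg
  a <- ifelse(is_exc, exc_par$a, inh_par$a); b <- ifelse(is_exc, exc_par$b, inh_par$b)
  cc <- ifelse(is_exc, exc_par$c, inh_par$c); dd <- ifelse(is_exc, exc_par$d, inh_par$d)
  v <- (-(5 - b) - sqrt((5 - b)^2 - 4 * 0.04 * 140)) / (2 * 0.04)
  u <- b * v
  gE <- numeric(n_tot); gI <- numeric(n_tot)
  sF <- rep(cfg$S0F, n_ca3); sD <- rep(1, n_ca3)
  delay_steps <- round(cfg$tau_0 / cfg$dt)
  qlen <- delay_steps + 2
  queue <- vector("list", qlen)
  idx_ca3 <- seq_len(n_ca3)
  idx_dg <- if (n_dg) n_ca3 + seq_len(n_dg) else integer(0)
  idx_ic <- if (n_ic) n_ca3 + n_dg + seq_len(n_ic) else integer(0)
  idx_id <- if (n_id) n_ca3 + n_dg + n_ic + seq_len(n_id) else integer(0)
  rec_id <- integer(0); rec_t <- numeric(0)
  n_steps <- length(trajectory$t)
  dt <- cfg$dt
  for (s in seq_len(n_steps)) {
    t <- (s - 1) * dt
    slot <- (s - 1) %% qlen + 1
    due <- queue[[slot]]; queue[slot] <- list(NULL)
    for (q in seq_len(NROW(due))) {
      j <- due$id[q]
      if (j <= n_ca3) {
        rel <- if (cfg$std_release == "emission") due$rel[q] else sD[j]
        if (length(network$W_cc)) gE[idx_ca3] <- gE[idx_ca3] + network$W_cc[, j] * rel / n_ca3
        if (length(network$W_dc) && !cfg$dg_lesion)
          gE[idx_dg] <- gE[idx_dg] +
            network$W_dc[, j] * (if (cfg$std_to_dg) rel else 1) / n_ca3
        if (n_ic) gE[idx_ic] <- gE[idx_ic] +
            cfg$W0_ca3_inh * (if (cfg$std_to_interneurons) rel else 1) / n_ca3
      } else if (j <= n_ca3 + n_dg) {
        dgn <- if (identical(cfg$dg_norm, "per_block")) n_dg else n_ca3
        if (length(network$W_cd)) gE[idx_ca3] <- gE[idx_ca3] + network$W_cd[, j - n_ca3] / dgn
        if (n_id) gE[idx_id] <- gE[idx_id] + cfg$W0_dg_inh / dgn
      } else if (j <= n_ca3 + n_dg + n_ic) {
        gI[idx_ca3] <- gI[idx_ca3] + network$W_ic[, j - n_ca3 - n_dg] / n_ic
      } else {
        gI[idx_dg] <- gI[idx_dg] + network$W_id[, j - n_ca3 - n_dg - n_ic] / n_id
      }
    }
    Js <- sensory_drive(trajectory$pos[s, ], trajectory$heading[s],
                        network$ca3, t, cfg$A_pos, cfg$A_dir, cfg$input_radius)
    Ith <- theta_drive(t, cfg$theta_amp, cfg$theta_period)
    ## intrinsic + stimulus terms explicit, synaptic terms semi-implicit
    ## (same scheme as the compiled core)
    Iext <- -Ith * ifelse(is_exc | cfg$theta_to_inhibitory, 1, 0)
    Iext[idx_ca3] <- Iext[idx_ca3] + Js * sF^2
    vstar <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + Iext)
    vn <- (vstar + dt * (gE * cfg$V_E + gI * cfg$V_I)) /
      (1 + dt * (gE + gI))
    un <- u + dt * a * (b * v - u)
    spiked <- v < 30 & vn >= 30
    if (any(spiked)) {
      w <- which(spiked)
      rec_id <- c(rec_id, w); rec_t <- c(rec_t, rep(t + dt, length(w)))
      dslot <- (s + delay_steps) %% qlen + 1
      ev <- data.frame(id = w, rel = ifelse(w <= n_ca3, sD[pmin(w, n_ca3)], 1))
      queue[[dslot]] <- rbind(queue[[dslot]], ev)
      vn[w] <- cc[w]; un[w] <- un[w] + dd[w]
    }
    v <- vn; u <- un
    gE <- gE * (1 - dt / cfg$tau_E); gI <- gI * (1 - dt / cfg$tau_I)
    sD <- std_step(sD, spiked[idx_ca3], dt, cfg$U_D, cfg$tau_D, cfg$std_mode)
    sF <- stf_step(sF, Js, dt, cfg$S0F, cfg$S1F, cfg$Phi_F, cfg$tau_F)
  }
  data.frame(id = rec_id, t = rec_t)
}
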