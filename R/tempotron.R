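#' Tempotron PSP kernel
#'
#' Double-exponential post-synaptic potential kernel
#' `K(dt) = V_0 (exp(-dt/tau) - exp(-dt/tau_r))` for `dt >= 0` (0 before the
#' spike), with decay `tau = 5` ms and rise `tau_r = 1.25` ms. `V_0` is the
#' factor normalising the kernel peak to exactly 1; the peak sits at
#' `t* = tau tau_r / (tau - tau_r) * log(tau / tau_r)`.
#'
#' @param dt Time since the afferent spike (ms, vectorised).
#' @param tau,tau_r Decay and rise time constants (ms).
#' @return Kernel values.
#' @export
psp_kernel <- function(dt, tau = 5, tau_r = 1.25) {
  V0 <- kernel_v0(tau, tau_r)
  ifelse(dt >= 0, V0 * (exp(-dt / tau) - exp(-dt / tau_r)), 0)
}

kernel_peak_time <- function(tau = 5, tau_r = 1.25) {
  tau * tau_r / (tau - tau_r) * log(tau / tau_r)
}

kernel_v0 <- function(tau = 5, tau_r = 1.25) {
  ts <- kernel_peak_time(tau, tau_r)
  1 / (exp(-ts / tau) - exp(-ts / tau_r))
}

#' Construct a tempotron readout neuron
#'
#' @param n_afferents Number of presynaptic place cells.
#' @param v_thresh Firing threshold (default 2).
#' @param tau,tau_r Kernel time constants (ms).
#' @param lr Learning rate (default 0.01).
#' @param cycle Pattern window length (ms, one theta cycle).
#' @param dt Trace sampling resolution (ms).
#' @param init `"zero"` (default) or `"uniform"` small random initial
#'   weights.
#' @param seed Seed for the random initialisation.
#' @return A `tempotron` object (list with `w` and the constants).
#' @export
tempotron <- function(n_afferents, v_thresh = 2, tau = 5, tau_r = 1.25,
                      lr = 0.01, cycle = 100, dt = 0.1,
                      init = c("zero", "uniform"), seed = 1L) {
  init <- match.arg(init)
  w <- if (init == "zero") {
    numeric(n_afferents)
  } else {
    withr::with_seed(seed, stats::runif(n_afferents, 0, 0.01))
  }
  structure(list(w = w, n_afferents = n_afferents, v_thresh = v_thresh,
                 tau = tau, tau_r = tau_r, V0 = kernel_v0(tau, tau_r),
                 lr = lr, cycle = cycle, dt = dt),
            class = "tempotron")
}

#' @export
print.tempotron <- function(x, ...) {
  cat(sprintf("<tempotron> %d afferents, threshold %g, |w| in [%.3g, %.3g]\n",
              x$n_afferents, x$v_thresh, min(x$w), max(x$w)))
  invisible(x)
}

## canonical pattern representation: list(aff = integer, t = numeric),
## sorted by time
as_pattern <- function(aff, t) {
  o <- order(t)
  list(aff = as.integer(aff[o]), t = as.numeric(t[o]))
}

#' Tempotron voltage trace and readout spike for one pattern
#'
#' Integrates the shunted soma potential: PSPs sum until the first upward
#' crossing of the threshold, after which later afferent arrivals evoke no
#' further PSPs for the rest of the pattern. Returns whether the readout
#' fired, the crossing time, and the time/height of the un-shunted voltage
#' maximum used by the learning rule.
#'
#' @param model A [tempotron()].
#' @param pattern List with `aff` (1-based afferent index per spike) and `t`
#'   (spike times, ms within the cycle).
#' @return List: `fired`, `t_spike` (`-1` if none), `t_max`, `v_max`, `dw`
#'   (per-afferent credit `sum K(t_max - t_f)`).
#' @export
voltage_trace <- function(model, pattern) {
  p <- as_pattern(pattern$aff, pattern$t)
  tempotron_eval(p$aff, p$t, model$w, model$tau, model$tau_r, model$V0,
                 model$v_thresh, model$cycle, model$dt)
}

#' Train the tempotron on (+) patterns
#'
#' All training patterns carry the (+) label: whenever a presented pattern
#' fails to elicit a readout spike, every afferent with spikes before the
#' un-shunted voltage maximum `t_max` is potentiated by
#' `lr * sum_{t_f < t_max} K(t_max - t_f)`. Patterns are presented in
#' random order each epoch (reproducible under `seed`); training stops
#' early once a full epoch elicits a spike for every pattern. There is no
#' depression step because no (-) patterns exist, so weights are
#' non-decreasing over training.
#'
#' @param model A [tempotron()].
#' @param patterns List of patterns (each `list(aff, t)`).
#' @param epochs Maximum number of epochs.
#' @param seed Seed for the per-epoch shuffling.
#' @return The trained model, with attributes `epochs_run` and
#'   `train_accuracy` (fraction of patterns firing at the end).
#' @export
tempotron_train <- function(model, patterns, epochs = 100, seed = 1L) {
  patterns <- lapply(patterns, function(p) as_pattern(p$aff, p$t))
  n <- length(patterns)
  empty <- vapply(patterns, function(p) length(p$aff) == 0, logical(1))
  if (any(empty)) {
    warning(sum(empty), " training pattern(s) contain no spikes; skipped")
    patterns <- patterns[!empty]
    n <- length(patterns)
  }
  epochs_run <- 0L
  withr::with_seed(seed, {
    for (e in seq_len(epochs)) {
      epochs_run <- e
      all_fired <- TRUE
      for (k in sample.int(n)) {
        p <- patterns[[k]]
        res <- tempotron_eval(p$aff, p$t, model$w, model$tau, model$tau_r,
                              model$V0, model$v_thresh, model$cycle, model$dt)
        if (!res$fired) {
          all_fired <- FALSE
          model$w <- model$w + model$lr * res$dw
        }
      }
      if (all_fired) break
    }
  })
  fired <- vapply(patterns, function(p) {
    tempotron_eval(p$aff, p$t, model$w, model$tau, model$tau_r, model$V0,
                   model$v_thresh, model$cycle, model$dt)$fired
  }, logical(1))
  attr(model, "epochs_run") <- epochs_run
  attr(model, "train_accuracy") <- mean(fired)
  model
}

#' Extract theta-cycle spike patterns from a box population
#'
#' The afferents are the CA3 cells whose field centres fall inside the
#' square box of side `box_size` centred at `box_center` (400 cells for the
#' default 20-cm box on the 1-cm CA3 lattice), indexed in cell-id order.
#' Spikes are subdivided into consecutive 100-ms theta cycles; each cycle is
#' one pattern with times relative to its cycle start.
#'
#' @param record A `spike_record`.
#' @param box_center Length-2 centre of the box (cm).
#' @param box_size Box side length (cm).
#' @param cycle Theta cycle length (ms).
#' @param n_cycles Number of cycles (defaults to the full record).
#' @return List: `patterns` (one per cycle), `afferents` (CA3 cell ids),
#'   `n_afferents`.
#' @export
cycle_patterns <- function(record, box_center, box_size = 20, cycle = 100,
                           n_cycles = NULL) {
  cen <- record$ca3$centers
  half <- box_size / 2
  ids <- which(cen[, 1] >= box_center[1] - half & cen[, 1] < box_center[1] + half &
               cen[, 2] >= box_center[2] - half & cen[, 2] < box_center[2] + half)
  if (is.null(n_cycles)) n_cycles <- floor(record$duration / cycle)
  s <- record$spikes[record$spikes$layer == "CA3" & record$spikes$id %in% ids, ]
  aff_of <- match(s$id, ids)
  patterns <- lapply(seq_len(n_cycles), function(c) {
    sel <- s$t >= (c - 1) * cycle & s$t < c * cycle
    as_pattern(aff_of[sel], s$t[sel] - (c - 1) * cycle)
  })
  list(patterns = patterns, afferents = ids, n_afferents = length(ids))
}

jitter_pattern <- function(pattern, sd_ms) {
  list(aff = pattern$aff, t = pattern$t + stats::rnorm(length(pattern$t), 0, sd_ms))
}

#' Jittered copies of a set of cycle patterns
#'
#' Every spike is independently jittered with Gaussian noise of standard
#' deviation `sd_ms` (2 ms in the landmark protocol); jittered times stay
#' assigned to their original cycle pattern.
#'
#' @param patterns List of patterns.
#' @param n_jitter Number of jittered realisations.
#' @param sd_ms Jitter standard deviation (ms).
#' @param seed Seed.
#' @return List of `n_jitter` lists of jittered patterns.
#' @export
jittered_realizations <- function(patterns, n_jitter = 100, sd_ms = 2,
                                  seed = 1L) {
  withr::with_seed(seed, {
    lapply(seq_len(n_jitter), function(r) {
      lapply(patterns, jitter_pattern, sd_ms = sd_ms)
    })
  })
}

#' Detection accuracy of a trained tempotron on a test run
#'
#' The test record (a 1-s trajectory through the trained location) is cut
#' into 10 theta-cycle patterns over the box afferents; each realisation
#' jitters every spike with `N(0, sd_ms^2)`, and a realisation counts as
#' detected when any of its 10 cycles elicits a readout spike. The accuracy
#' is the detected fraction over the realisations.
#'
#' @param model A trained [tempotron()].
#' @param record Test `spike_record`.
#' @param box_center Trained box centre (must match training).
#' @param box_size Box side (cm).
#' @param n_jitter Number of jitter realisations.
#' @param sd_ms Jitter SD (ms).
#' @param seed Seed (same seed, same accuracy).
#' @return Detection accuracy in `[0, 1]`.
#' @export
tempotron_evaluate <- function(model, record, box_center, box_size = 20,
                               n_jitter = 100, sd_ms = 2, seed = 1L) {
  cp <- cycle_patterns(record, box_center, box_size)
  if (cp$n_afferents != model$n_afferents) {
    stop("record/box mismatch: ", cp$n_afferents, " afferents in box but model has ",
         model$n_afferents, call. = FALSE)
  }
  reals <- jittered_realizations(cp$patterns, n_jitter, sd_ms, seed)
  detected <- vapply(reals, function(real) {
    for (p in real) {
      if (length(p$aff) == 0) next
      ps <- as_pattern(p$aff, p$t)
      if (tempotron_eval(ps$aff, ps$t, model$w, model$tau, model$tau_r,
                         model$V0, model$v_thresh, model$cycle,
                         model$dt)$fired) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  mean(detected)
}
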