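#' Theta phase of a spike time
#'
#' Phase zero sits at the maxima of the theta drive (`t = 0, 100, ...` ms)
#' and advances linearly over the 100-ms cycle: `phi = 2 pi (t mod 100)/100`.
#'
#' @param t Spike times (ms).
#' @param period Theta period (ms).
#' @return Phases in `[0, 2 pi)`.
#' @export
spike_phase <- function(t, period = 100) {
  2 * pi * ((t %% period) / period)
}

## Circular-linear regression (Kempter-style): find the slope a maximising
## the mean resultant length of (phase - a * x), by a coarse grid (1e-3 of
## the slope range) followed by golden-section refinement between the
## neighbouring grid points.  Returns slope, onset (circular intercept at
## x = 0, wrapped to [0, 2pi)), and the maximised resultant length.
circlin_fit <- function(phase, x, slope_range, grid_n = 1001) {
  stopifnot(length(phase) == length(x), length(phase) >= 2)
  grid <- seq(slope_range[1], slope_range[2], length.out = grid_n)
  R <- resultant_grid(phase, x, grid)
  k <- which.max(R)
  lo <- grid[max(1, k - 1)]
  hi <- grid[min(grid_n, k + 1)]
  opt <- stats::optimize(function(a) resultant_grid(phase, x, a),
                         lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-8 * diff(slope_range))
  a <- if (opt$objective >= R[k]) opt$maximum else grid[k]
  z <- mean(exp(1i * (phase - a * x)))
  list(slope = a, onset = wrap_2pi(Arg(z)), R = Mod(z))
}

#' Circular-linear regression of phase precession for one traversal
#'
#' Spike positions (projected on the running direction) are normalised so
#' the first spike maps to 0 and the last to 1; the precession slope is then
#' the slope (radians per field size) maximising the mean resultant length
#' of the phase residuals, searched over `[-4 pi, 4 pi]` (two cycles per
#' traversal). Cells with 5 or fewer spikes are excluded: the fit is
#' returned with `NA` values rather than an error.
#'
#' @param times Spike times (ms), sorted.
#' @param positions Spike positions projected on the running direction (cm
#'   or any monotone unit; only the normalised positions enter the fit).
#' @param min_spikes Minimum spike count for a fit (exclusive bound).
#' @param period Theta period (ms).
#' @return List: `slope` (rad per field size), `onset` (rad, at entry),
#'   `mean_phase` (circular mean of spike phases), `R` (resultant length),
#'   `n` (spike count). `NA` fit values when excluded.
#' @export
fit_precession <- function(times, positions, min_spikes = 5, period = 100) {
  n <- length(times)
  excluded <- list(slope = NA_real_, onset = NA_real_, mean_phase = NA_real_,
                   R = NA_real_, n = n)
  if (n <= min_spikes) return(excluded)
  span <- positions[n] - positions[1]
  if (abs(span) < .Machine$double.eps) return(excluded)
  x <- (positions - positions[1]) / span
  phase <- spike_phase(times, period)
  fit <- circlin_fit(phase, x, c(-4 * pi, 4 * pi))
  list(slope = fit$slope, onset = fit$onset,
       mean_phase = wrap_2pi(Arg(mean(exp(1i * phase)))),
       R = fit$R, n = n)
}

## interpolate trajectory position/heading at arbitrary times
traj_at <- function(trajectory, t) {
  ix <- pmin(pmax(findInterval(t, trajectory$t), 1), length(trajectory$t))
  list(pos = trajectory$pos[ix, , drop = FALSE],
       heading = trajectory$heading[ix])
}

#' Per-cell phase-precession table for a whole run
#'
#' Fits [fit_precession()] for every CA3 cell with more than `min_spikes`
#' spikes on the traversal, projecting the animal position at each spike
#' onto the running direction.
#'
#' @param record A `spike_record`.
#' @param min_spikes Activity filter (cells must exceed this count).
#' @return Data frame: `id`, field centre `x`/`y`, preferred direction
#'   `psi`, `slope`, `onset`, `mean_phase`, `R`, `n`.
#' @export
population_precession <- function(record, min_spikes = 5) {
  s <- record$spikes[record$spikes$layer == "CA3", ]
  counts <- table(s$id)
  ids <- as.integer(names(counts))[counts > min_spikes]
  traj <- record$trajectory
  dir <- c(cos(traj$heading[1]), sin(traj$heading[1]))
  rows <- lapply(ids, function(i) {
    tt <- sort(s$t[s$id == i])
    p <- traj_at(traj, tt)$pos
    proj <- p %*% dir
    f <- fit_precession(tt, as.numeric(proj), min_spikes)
    data.frame(id = i, x = record$ca3$centers[i, 1],
               y = record$ca3$centers[i, 2], psi = record$ca3$psi[i],
               slope = f$slope, onset = f$onset, mean_phase = f$mean_phase,
               R = f$R, n = f$n)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      psi = numeric(0), slope = numeric(0), onset = numeric(0),
                      mean_phase = numeric(0), R = numeric(0), n = integer(0))
  }
  out
}

#' Cross-correlogram of two spike trains
#'
#' Histogram of time lags `t_B - t_A` over all spike pairs, at 5-ms
#' resolution in a 200-ms window (`[-100, 100)` ms). The sign convention is
#' fixed by the caller's argument order. The analysis pipeline bins the lag
#' of each pair's first-encountered cell relative to the next cell along the
#' run, so a sequence played out in running order concentrates mass at
#' negative lags (and yields a positive correlation-lag phase).
#'
#' @param spikes_a,spikes_b Spike time vectors (ms).
#' @param bin Bin width (ms).
#' @param window Total window (ms).
#' @return A `crosscorr` list: `counts`, `centers` (bin centres, ms), `bin`,
#'   `n_pairs`, and `empty` flag.
#' @export
cross_correlogram <- function(spikes_a, spikes_b, bin = 5, window = 200) {
  half <- window / 2
  counts <- ccg_counts(as.numeric(spikes_a), as.numeric(spikes_b), bin, half)
  centers <- seq(-half + bin / 2, half - bin / 2, by = bin)
  structure(list(counts = as.numeric(counts), centers = centers, bin = bin,
                 n_pairs = sum(counts),
                 empty = length(spikes_a) == 0 || length(spikes_b) == 0),
            class = "crosscorr")
}

#' @export
print.crosscorr <- function(x, ...) {
  cat(sprintf("<crosscorr> %d bins of %g ms, %d spike pairs\n",
              length(x$counts), x$bin, x$n_pairs))
  invisible(x)
}

## Zero-phase 4-12 Hz band-pass of correlogram columns plus the analytic
## signal, via FFT: the histogram (sampled at 1/bin kHz) is zero-padded to
## three times its length, multiplied by the squared magnitude response of a
## second-order Butterworth band-pass (the frequency-domain equivalent of a
## forward-backward filter), and the analytic signal is formed by
## suppressing the negative frequencies.
analytic_bandpassed <- function(counts_mat, bin = 5, band_hz = c(4, 12)) {
  n <- nrow(counts_mat)
  fs <- 1000 / bin
  np <- 3L * n
  bf <- signal::butter(2, band_hz / (fs / 2), type = "pass")
  w <- 2 * pi * (seq_len(np) - 1) / np              # digital rad/sample
  ejw <- exp(-1i * w)
  H <- (signal::polyval(rev(bf$b), ejw) / signal::polyval(rev(bf$a), ejw))
  H2 <- Mod(H)^2                                    # zero-phase response
  h <- numeric(np)                                  # analytic-signal mask
  h[1] <- 1
  h[2:(np / 2)] <- 2
  h[np / 2 + 1] <- 1
  padded <- rbind(matrix(0, n, ncol(counts_mat)), counts_mat,
                  matrix(0, n, ncol(counts_mat)))
  X <- stats::mvfft(padded)
  z <- stats::mvfft(X * (H2 * h), inverse = TRUE) / np
  z[(n + 1):(2 * n), , drop = FALSE]                # analytic, original span
}

#' Correlation-lag phase of a cross-correlogram
#'
#' The correlogram is band-pass filtered in the theta band (4-12 Hz,
#' zero-phase second-order Butterworth applied in the frequency domain on a
#' three-fold zero-padded signal) and converted to its analytic signal; the
#' returned value is the analytic-signal phase at time lag 0, interpolated
#' between the two bin centres bracketing zero (-2.5 and +2.5 ms).
#'
#' @param hist A [cross_correlogram()] result, or a bare counts vector.
#' @param bin Bin width (ms), used when `hist` is a bare vector.
#' @param band_hz Pass band (Hz).
#' @return Phase in `(-pi, pi]` radians; `NA` for an all-zero histogram.
#' @export
correlation_lag <- function(hist, bin = 5, band_hz = c(4, 12)) {
  counts <- if (inherits(hist, "crosscorr")) hist$counts else as.numeric(hist)
  if (inherits(hist, "crosscorr")) bin <- hist$bin
  correlation_lag_many(matrix(counts, ncol = 1), bin, band_hz)[1]
}

## vectorised correlation-lag phase over columns of a counts matrix
correlation_lag_many <- function(counts_mat, bin = 5, band_hz = c(4, 12),
                                 chunk = 20000L) {
  p <- ncol(counts_mat)
  out <- rep(NA_real_, p)
  nonzero <- colSums(abs(counts_mat)) > 0
  lo <- nrow(counts_mat) %/% 2          # bin centre -bin/2
  for (start in seq(1, p, by = chunk)) {
    idx <- start:min(start + chunk - 1L, p)
    use <- idx[nonzero[idx]]
    if (!length(use)) next
    z <- analytic_bandpassed(counts_mat[, use, drop = FALSE], bin, band_hz)
    z1 <- z[lo, ]
    z2 <- z[lo + 1, ]
    phi <- Arg(z1) + 0.5 * Arg(z2 * Conj(z1))
    out[use] <- circ_diff(phi, 0)
  }
  out
}

#' Extrinsicity and intrinsicity of a place-field pair
#'
#' Given the pair's cross-correlograms for runs along the loop direction and
#' opposite to it (each with the per-run first-encountered cell as reference),
#' extrinsicity is the rescaled Pearson correlation of the two histograms,
#' `Ex = (r + 1)/2`, and intrinsicity the rescaled correlation of the
#' forward histogram with the time-flipped reverse histogram,
#' `In = (r' + 1)/2`. A pair is classified extrinsic iff `Ex > In`.
#'
#' @param hist_forward,hist_reverse [cross_correlogram()]s (or bare counts)
#'   from the two opposite runs.
#' @return List: `ex`, `in_` (both in `[0, 1]`, `NA` for a zero-variance
#'   histogram) and `class` (`"extrinsic"`/`"intrinsic"`/`NA`).
#' @export
ex_in <- function(hist_forward, hist_reverse) {
  hf <- if (inherits(hist_forward, "crosscorr")) hist_forward$counts else hist_forward
  hr <- if (inherits(hist_reverse, "crosscorr")) hist_reverse$counts else hist_reverse
  if (stats::sd(hf) == 0 || stats::sd(hr) == 0) {
    return(list(ex = NA_real_, in_ = NA_real_, class = NA_character_))
  }
  ex <- (stats::cor(hf, hr) + 1) / 2
  in_ <- (stats::cor(hf, rev(hr)) + 1) / 2
  list(ex = ex, in_ = in_,
       class = if (ex > in_) "extrinsic" else "intrinsic")
}

#' Theta-compression regression
#'
#' Circular-linear regression of correlation-lag phase against place-field
#' centre distance over a population of overlapping field pairs. The slope
#' `a` (radians/cm) measures how much theta phase advances per centimetre of
#' behavioural separation -- the strength of theta compression. The slope is
#' searched over +-0.5 rad/cm.
#'
#' @param lag_phase Correlation-lag phases (radians), one per pair.
#' @param distance Field-centre distances (cm).
#' @return List `slope` (rad/cm), `onset` (rad), `R`, `n`; all-`NA` when
#'   fewer than 3 usable pairs.
#' @export
theta_compression <- function(lag_phase, distance) {
  ok <- is.finite(lag_phase) & is.finite(distance)
  if (sum(ok) < 3) {
    return(list(slope = NA_real_, onset = NA_real_, R = NA_real_, n = sum(ok)))
  }
  fit <- circlin_fit(wrap_2pi(lag_phase[ok]), distance[ok], c(-0.5, 0.5))
  list(slope = fit$slope, onset = fit$onset, R = fit$R, n = sum(ok))
}

#' Directional classes of a place-field pair
#'
#' Compares the two cells' preferred heading directions with each other and
#' with the running direction (circular differences): a pair is `both_best`
#' when both cells' preferred directions lie within 30 degrees of the
#' trajectory, `both_worst` when both differ by more than 150 degrees,
#' `similar` when the two preferred directions are within 30 degrees of each
#' other, and `dissimilar` when they differ by more than 150 degrees. The
#' categories are not exclusive; pairs matching none are "other".
#'
#' @param psi_i,psi_j Preferred heading directions (radians, vectorised).
#' @param traj_dir Running direction (radians).
#' @return Data frame of logicals `both_best`, `both_worst`, `similar`,
#'   `dissimilar`.
#' @export
classify_pairs <- function(psi_i, psi_j, traj_dir) {
  di <- abs(circ_diff(psi_i, traj_dir))
  dj <- abs(circ_diff(psi_j, traj_dir))
  dij <- abs(circ_diff(psi_i, psi_j))
  lim_best <- 30 * pi / 180
  lim_worst <- 150 * pi / 180
  data.frame(both_best = di < lim_best & dj < lim_best,
             both_worst = di > lim_worst & dj > lim_worst,
             similar = dij < lim_best,
             dissimilar = dij > lim_worst)
}

## cells of a layer exceeding the activity filter, with their spike times
active_cells <- function(record, min_spikes = 5, layer = "CA3") {
  s <- record$spikes[record$spikes$layer == layer, ]
  counts <- table(s$id)
  ids <- as.integer(names(counts))[counts > min_spikes]
  trains <- lapply(ids, function(i) sort(s$t[s$id == i]))
  names(trains) <- ids
  list(ids = ids, trains = trains)
}

#' Pairwise theta-correlation metrics for a run (and optionally its reverse)
#'
#' Enumerates all pairs of active CA3 cells (more than `min_spikes` spikes)
#' with overlapping fields (centre distance below `max_dist`), orders each
#' pair by its projection on the forward running direction (cell A
#' encountered first), and computes per pair: the forward-run
#' cross-correlogram (`t_B - t_A`), its correlation-lag phase, the
#' centre-difference vector, and -- when a reverse-run record over the same
#' wiring is supplied -- the reverse-run correlogram (with roles swapped, so
#' each run references its own first-encountered cell) and the
#' extrinsicity/intrinsicity of the pair.
#'
#' @param record_fwd `spike_record` of the forward run.
#' @param record_rev Optional `spike_record` of the reverse run.
#' @param max_dist Maximum centre distance (cm) for an overlapping pair.
#' @param min_spikes Activity filter.
#' @return Data frame, one row per pair: ids, centre distance `dist`,
#'   centre-difference orientation `orient` (radians), `lag_phase`,
#'   preferred directions, and with a reverse run `ex`, `in_`, `class`.
#' @export
pair_metrics <- function(record_fwd, record_rev = NULL, max_dist = 10,
                         min_spikes = 5) {
  act_f <- active_cells(record_fwd, min_spikes)
  ids <- act_f$ids
  if (!is.null(record_rev)) {
    act_r <- active_cells(record_rev, min_spikes)
    ids <- intersect(ids, act_r$ids)
  }
  if (length(ids) < 2) {
    return(data.frame(id_a = integer(0), id_b = integer(0), dist = numeric(0),
                      orient = numeric(0), lag_phase = numeric(0)))
  }
  cen <- record_fwd$ca3$centers[ids, , drop = FALSE]
  pairs <- which(upper.tri(matrix(0, length(ids), length(ids))), arr.ind = TRUE)
  dx <- cen[pairs[, 2], 1] - cen[pairs[, 1], 1]
  dy <- cen[pairs[, 2], 2] - cen[pairs[, 1], 2]
  d <- sqrt(dx^2 + dy^2)
  keep <- d > 0 & d < max_dist
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs)) {
    return(data.frame(id_a = integer(0), id_b = integer(0), dist = numeric(0),
                      orient = numeric(0), lag_phase = numeric(0)))
  }
  heading <- record_fwd$trajectory$heading[1]
  dirv <- c(cos(heading), sin(heading))
  ## order pair so A is encountered first along the forward run
  proj <- (record_fwd$ca3$centers[ids, 1] * dirv[1] +
           record_fwd$ca3$centers[ids, 2] * dirv[2])
  swap <- proj[pairs[, 2]] < proj[pairs[, 1]]
  ia <- ifelse(swap, pairs[, 2], pairs[, 1])
  ib <- ifelse(swap, pairs[, 1], pairs[, 2])
  id_a <- ids[ia]
  id_b <- ids[ib]
  np <- length(id_a)
  ## histogram of t_A - t_B: the lag of the first-encountered cell relative
  ## to the next cell along the run (ccg_counts(x, y) bins y - x)
  counts_f <- matrix(0, 40, np)
  for (k in seq_len(np)) {
    counts_f[, k] <- ccg_counts(act_f$trains[[as.character(id_b[k])]],
                                act_f$trains[[as.character(id_a[k])]], 5, 100)
  }
  out <- data.frame(
    id_a = id_a, id_b = id_b,
    dist = sqrt((record_fwd$ca3$centers[id_b, 1] - record_fwd$ca3$centers[id_a, 1])^2 +
                (record_fwd$ca3$centers[id_b, 2] - record_fwd$ca3$centers[id_a, 2])^2),
    orient = atan2(record_fwd$ca3$centers[id_b, 2] - record_fwd$ca3$centers[id_a, 2],
                   record_fwd$ca3$centers[id_b, 1] - record_fwd$ca3$centers[id_a, 1]),
    psi_a = record_fwd$ca3$psi[id_a], psi_b = record_fwd$ca3$psi[id_b],
    lag_phase = correlation_lag_many(counts_f)
  )
  if (!is.null(record_rev)) {
    ex <- in_ <- rep(NA_real_, np)
    cls <- rep(NA_character_, np)
    for (k in seq_len(np)) {
      ## reverse run: B is encountered first, so the histogram is t_B - t_A
      hr <- ccg_counts(act_r$trains[[as.character(id_a[k])]],
                       act_r$trains[[as.character(id_b[k])]], 5, 100)
      hf <- counts_f[, k]
      if (stats::sd(hf) > 0 && stats::sd(hr) > 0) {
        ex[k] <- (stats::cor(hf, hr) + 1) / 2
        in_[k] <- (stats::cor(hf, rev(hr)) + 1) / 2
        cls[k] <- if (ex[k] > in_[k]) "extrinsic" else "intrinsic"
      }
    }
    out$ex <- ex
    out$in_ <- in_
    out$class <- cls
  }
  out
}

#' Population-averaged cross-correlogram of 4-cm pairs
#'
#' Averages the cross-correlograms of all active cell pairs whose field
#' centres are separated along the running direction by `sep` (within
#' `tol`), each referenced to its first-encountered cell. The peak lag is
#' taken on the theta-band filtered average.
#'
#' @param record A `spike_record`.
#' @param sep,tol Projected separation and tolerance (cm).
#' @param min_spikes Activity filter.
#' @param ref_heading Direction (radians) fixing the pair order: cell B of a
#'   pair lies `sep` cm from cell A along this direction. Defaults to the
#'   record's own running direction (the per-run convention); pass the same
#'   reference for runs in opposite directions to compare peak-lag signs in
#'   a fixed cell order.
#' @return List: `counts` (average), `centers` (ms), `peak_lag` (ms, from
#'   the band-passed average), `lag_phase`, `n_pairs`.
#' @export
averaged_correlogram <- function(record, sep = 4, tol = 0.5, min_spikes = 5,
                                 ref_heading = NULL) {
  act <- active_cells(record, min_spikes)
  ids <- act$ids
  heading <- if (is.null(ref_heading)) record$trajectory$heading[1] else ref_heading
  dirv <- c(cos(heading), sin(heading))
  cen <- record$ca3$centers[ids, , drop = FALSE]
  proj <- cen %*% dirv
  pairs <- which(upper.tri(matrix(0, length(ids), length(ids))), arr.ind = TRUE)
  dp <- proj[pairs[, 2]] - proj[pairs[, 1]]
  swap <- dp < 0
  ia <- ifelse(swap, pairs[, 2], pairs[, 1])
  ib <- ifelse(swap, pairs[, 1], pairs[, 2])
  keep <- abs(abs(dp) - sep) <= tol
  ia <- ia[keep]; ib <- ib[keep]
  total <- numeric(40)
  for (k in seq_along(ia)) {   # histogram of t_A - t_B (first rel. to next)
    total <- total + ccg_counts(act$trains[[ib[k]]], act$trains[[ia[k]]], 5, 100)
  }
  centers <- seq(-97.5, 97.5, by = 5)
  if (length(ia) == 0 || sum(total) == 0) {
    return(list(counts = total, centers = centers, peak_lag = NA_real_,
                lag_phase = NA_real_, n_pairs = length(ia)))
  }
  avg <- total / length(ia)
  z <- analytic_bandpassed(matrix(avg, ncol = 1))
  filt <- Re(z[, 1])
  core <- abs(centers) <= 50     # peak search within half a theta cycle
  list(counts = avg, centers = centers,
       peak_lag = centers[core][which.max(filt[core])],
       lag_phase = correlation_lag(avg), n_pairs = length(ia))
}

#' Spike-time gradient map for one theta cycle
#'
#' For every place-field centre with at least one spike inside the cycle
#' window, the arrow is the sum over its 8 lattice neighbours of the unit
#' vector toward the neighbour weighted by (neighbour mean spike time - own
#' mean spike time), so arrows point in the local travelling direction of
#' the sequence. Mean spike times are arithmetic means within the window.
#'
#' @param record A `spike_record`.
#' @param grid The CA3 `place_grid` (defaults to the record's).
#' @param window Length-2 cycle window `[t0, t1)` in ms.
#' @return Data frame: `id`, centre `x`/`y`, arrow components `gx`, `gy`.
#' @export
gradient_map <- function(record, grid = record$ca3, window) {
  s <- record$spikes[record$spikes$layer == "CA3" &
                     record$spikes$t >= window[1] & record$spikes$t < window[2], ]
  if (!nrow(s)) {
    return(data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      gx = numeric(0), gy = numeric(0)))
  }
  mt <- tapply(s$t, s$id, mean)
  n <- grid$n_side
  tmap <- rep(NA_real_, n * n)
  tmap[as.integer(names(mt))] <- mt
  has <- which(!is.na(tmap))
  offs <- expand.grid(ox = -1:1, oy = -1:1)
  offs <- offs[!(offs$ox == 0 & offs$oy == 0), ]
  rows <- lapply(has, function(i) {
    ix <- (i - 1) %% n + 1
    iy <- (i - 1) %/% n + 1
    gx <- gy <- 0
    for (k in seq_len(nrow(offs))) {
      jx <- ix + offs$ox[k]
      jy <- iy + offs$oy[k]
      if (jx < 1 || jx > n || jy < 1 || jy > n) next
      j <- (jy - 1) * n + jx
      if (is.na(tmap[j])) next
      unit <- c(offs$ox[k], offs$oy[k]) / sqrt(offs$ox[k]^2 + offs$oy[k]^2)
      wgt <- tmap[j] - tmap[i]
      gx <- gx + unit[1] * wgt
      gy <- gy + unit[2] * wgt
    }
    data.frame(id = i, x = grid$centers[i, 1], y = grid$centers[i, 2],
               gx = gx, gy = gy)
  })
  do.call(rbind, rows)
}
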