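test_that("spike phases wrap the 100-ms theta cycle", {
  expect_equal(spike_phase(0), 0)
  expect_equal(spike_phase(250), pi)
  expect_equal(spike_phase(c(100, 150)), c(0, pi))
})

test_that("precession fits recover synthetic slopes and handle exclusions", {
  ## generator-known ground truth: phi = (-pi x) mod 2pi over 6 spikes
  x <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  tt <- (((-pi * x) %% (2 * pi)) / (2 * pi)) * 100    # times with those phases
  f <- fit_precession(tt, x)
  expect_equal(f$slope, -pi, tolerance = 0.02)
  expect_equal(min(f$onset, 2 * pi - f$onset), 0, tolerance = 0.05)
  expect_equal(f$R, 1, tolerance = 1e-3)

  ## noiseless recovery across the slope range (dense grid-search oracle)
  for (a in c(-5, -2, -0.5, 0.5, 3)) {
    xs <- seq(0, 1, length.out = 25)
    ts <- ((a * xs) %% (2 * pi)) / (2 * pi) * 100
    fa <- fit_precession(ts, xs)
    expect_equal(fa$slope, a, tolerance = 0.1)
  }

  ## all spikes at one phase: zero slope, unit resultant
  f0 <- fit_precession(rep(25, 8), seq(0, 1, length.out = 8))
  expect_equal(f0$slope, 0, tolerance = 1e-6)
  expect_equal(f0$R, 1)

  ## five or fewer spikes: excluded sentinel, not an error
  few <- fit_precession(c(1, 2, 3), c(0, 0.5, 1))
  expect_true(is.na(few$slope))
  expect_equal(few$n, 3)
})

test_that("cross-correlograms bin spike-pair lags at 5 ms", {
  ## identical trains: maximum count in the bin containing zero lag
  a <- c(100, 230, 350, 480)
  h <- cross_correlogram(a, a)
  expect_equal(h$centers[which.max(h$counts)], 2.5)
  expect_equal(sum(h$counts), h$n_pairs)
  ## one pair with lag +20 lands in [20, 25)
  h2 <- cross_correlogram(100, 120)
  expect_equal(h2$counts[h2$centers == 22.5], 1)
  expect_equal(sum(h2$counts), 1)
  ## empty train: flagged all-zero histogram
  h3 <- cross_correlogram(numeric(0), a)
  expect_true(h3$empty)
  expect_equal(sum(h3$counts), 0)
})

test_that("independent Poisson trains give a flat correlogram", {
  set.seed(42)
  T_ms <- 20000
  a <- sort(runif(0.02 * T_ms, 0, T_ms))
  b <- sort(runif(0.02 * T_ms, 0, T_ms))
  h <- cross_correlogram(a, b)
  lambda <- length(a) * length(b) * 5 / T_ms   # expected count per bin
  expect_true(all(abs(h$counts - lambda) < 3 * sqrt(lambda) + 3))
})

test_that("correlation-lag phase matches the closed form for cosines", {
  centers <- seq(-97.5, 97.5, by = 5)
  ## even cosine: phase 0 at lag 0
  h0 <- cos(2 * pi * 8 * centers / 1000)
  expect_equal(correlation_lag(h0), 0, tolerance = 0.02)
  ## 15-ms shifted cosine: phase -2 pi f dt
  h15 <- cos(2 * pi * 8 * (centers - 15) / 1000)
  expect_equal(correlation_lag(h15), -2 * pi * 8 * 0.015, tolerance = 0.05)
  ## mirror flip negates the phase
  expect_equal(correlation_lag(rev(h15)), -correlation_lag(h15),
               tolerance = 0.02)
  ## one-bin shift changes the phase by ~2 pi f (5 ms)
  h20 <- cos(2 * pi * 8 * (centers - 20) / 1000)
  expect_equal(correlation_lag(h20) - correlation_lag(h15),
               -2 * pi * 8 * 0.005, tolerance = 0.03)
  ## degenerate input: undefined sentinel
  expect_true(is.na(correlation_lag(rep(0, 40))))
})

test_that("extrinsicity and intrinsicity follow their definitions", {
  ## symmetric identical histograms: Ex = In = 1
  sym <- c(rep(0, 17), 1, 2, 4, 4, 2, 1, rep(0, 17))
  r <- ex_in(sym, sym)
  expect_equal(r$ex, 1)
  expect_equal(r$in_, 1)
  ## reverse run = flip of forward: In = 1 and Ex < 1 for asymmetric input
  asym <- c(rep(0, 18), 1, 2, 5, 3, 1, rep(0, 17))
  r2 <- ex_in(asym, rev(asym))
  expect_equal(r2$in_, 1)
  expect_lt(r2$ex, 1)
  expect_equal(r2$class, "intrinsic")
  ## hand-computed toy: identical histograms are classified extrinsic
  toy <- c(0, 1, 2, 1, rep(0, 36))
  r3 <- ex_in(toy, toy)
  expect_equal(r3$ex, 1)
  expect_equal(r3$class, "extrinsic")
  expect_equal(r3$in_, (cor(toy, rev(toy)) + 1) / 2)
  ## zero-variance histogram: undefined sentinel
  expect_true(is.na(ex_in(rep(1, 40), toy)$ex))
  ## swapping the runs with flips applied to the other argument keeps Ex
  r4 <- ex_in(rev(asym), asym)
  expect_equal(r4$ex, r2$ex)
})

test_that("theta compression recovers a synthetic phase-distance slope", {
  d <- seq(2, 10, by = 0.25)
  fit <- theta_compression(0.2 * d, d)
  expect_equal(fit$slope, 0.2, tolerance = 1e-3)
  flat <- theta_compression(rep(0, 20), seq(1, 20))
  expect_equal(flat$slope, 0, tolerance = 1e-6)
  expect_true(is.na(theta_compression(c(0.1, 0.2), c(1, 2))$slope))
})

test_that("pair direction classes use 30/150-degree circular bounds", {
  cl <- classify_pairs(0, 0, 0)
  expect_true(cl$both_best && cl$similar)
  expect_false(cl$both_worst || cl$dissimilar)
  cl2 <- classify_pairs(0, pi, 0)
  expect_true(cl2$dissimilar)
  expect_false(cl2$both_best || cl2$both_worst)
  ## 140-degree circular difference: none of the classes
  cl3 <- classify_pairs(20 * pi / 180, 160 * pi / 180, 0)
  expect_false(any(unlist(cl3)))
  ## circular wrap: 350 vs 10 degrees are similar
  cl4 <- classify_pairs(350 * pi / 180, 10 * pi / 180, 0)
  expect_true(cl4$similar)
})

test_that("gradient maps point along the spike-time gradient", {
  g <- build_grid(arena(), 10)
  g$psi <- rep(0, 100)
  rec <- structure(list(
    spikes = data.frame(layer = "CA3", id = 1:100,
                        t = 500 + 5 * (g$centers[, 1] + 40)),
    ca3 = g, duration = 1000), class = "spike_record")
  gm <- gradient_map(rec, g, window = c(500, 1000))
  expect_equal(nrow(gm), 100)
  inner <- abs(gm$x) < 30 & abs(gm$y) < 30
  ang <- atan2(gm$gy[inner], gm$gx[inner])
  expect_true(all(abs(ang) < 1e-6))      # arrows point along +x
  ## uniform mean times: zero-magnitude arrows
  rec$spikes$t <- 550
  gm0 <- gradient_map(rec, g, window = c(500, 600))
  expect_true(all(abs(gm0$gx) < 1e-12 & abs(gm0$gy) < 1e-12))
  ## radially increasing times: arrows point outward
  rec$spikes$t <- 500 + 3 * sqrt(rowSums(g$centers^2))
  gmr <- gradient_map(rec, g, window = c(500, 1000))
  u <- cbind(gmr$x, gmr$y) / pmax(sqrt(gmr$x^2 + gmr$y^2), 1e-9)
  align <- (gmr$gx * u[, 1] + gmr$gy * u[, 2]) /
    pmax(sqrt(gmr$gx^2 + gmr$gy^2), 1e-9)
  expect_gt(mean(align[abs(gmr$x) < 30 & abs(gmr$y) < 30]), 0.9)
})
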