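test_that("PSP kernel is peak-normalised with the documented constants", {
  expect_equal(psp_kernel(0), 0)
  expect_equal(psp_kernel(-1), 0)
  tstar <- 6.25 / 3.75 * log(4)
  expect_equal(tstar, 2.3105, tolerance = 1e-4)
  expect_lt(abs(psp_kernel(tstar) - 1), 1e-12)
  ## independent numeric maximisation agrees
  opt <- optimize(psp_kernel, c(0, 20), maximum = TRUE)
  expect_equal(opt$maximum, tstar, tolerance = 1e-4)
  expect_equal(opt$objective, 1, tolerance = 1e-9)
  ## V0 from an independent scalar evaluation
  V0 <- 1 / (exp(-tstar / 5) - exp(-tstar / 1.25))
  expect_equal(V0, 2.1165, tolerance = 1e-3)
  expect_equal(psp_kernel(1), V0 * (exp(-0.2) - exp(-0.8)))
})

test_that("voltage traces cross threshold and shunt later arrivals", {
  m <- tempotron(3)
  ## all-zero weights: flat trace, no readout spike
  res0 <- voltage_trace(m, list(aff = c(1L, 2L), t = c(10, 20)))
  expect_false(res0$fired)
  expect_equal(res0$v_max, 0)

  ## single afferent with w = 3: peak 3 > 2, crossing before the PSP peak
  m$w <- c(3, 0, 0)
  res <- voltage_trace(m, list(aff = 1L, t = 10))
  expect_true(res$fired)
  expect_gt(res$t_spike, 10)
  expect_lt(res$t_spike, 10 + 6.25 / 3.75 * log(4))
  expect_equal(res$v_max, 3, tolerance = 1e-3)
  ## crossing time solves 3 K(dt) = 2 (scalar root)
  dt_cross <- uniroot(function(d) 3 * psp_kernel(d) - 2, c(0.01, 2.3))$root
  expect_equal(res$t_spike, 10 + dt_cross, tolerance = 0.1)

  ## spikes arriving after the crossing change nothing about the readout
  res2 <- voltage_trace(m, list(aff = c(1L, 2L, 3L), t = c(10, 50, 80)))
  expect_equal(res2$t_spike, res$t_spike)
})

test_that("training potentiates silent patterns and converges", {
  ## a pattern that already fires leaves the weights unchanged
  m <- tempotron(2)
  m$w <- c(5, 0)
  p <- list(aff = 1L, t = 30)
  m2 <- tempotron_train(m, list(p), epochs = 3)
  expect_identical(m2$w, m$w)

  ## single silent afferent: credit is K at the kernel peak, so
  ## delta w = lr * 1 on the first presentation
  m3 <- tempotron(1)
  res <- voltage_trace(m3, list(aff = 1L, t = 40))
  expect_equal(max(res$dw), 1, tolerance = 1e-3)

  ## convergence on jittered (+) patterns; weights never decrease
  base <- list(aff = as.integer(rep(1:20, 2)), t = c(seq(5, 43, 2), seq(50, 88, 2)))
  pats <- unlist(jittered_realizations(list(base), n_jitter = 60, sd_ms = 2,
                                       seed = 5L), recursive = FALSE)
  m4 <- tempotron(20)
  m5 <- tempotron_train(m4, pats, epochs = 100, seed = 9L)
  expect_gte(attr(m5, "train_accuracy"), 0.99)
  expect_true(all(m5$w >= m4$w))

  ## scaling all weights up never silences a firing pattern
  fired_before <- vapply(pats[1:10], function(p) voltage_trace(m5, p)$fired,
                         logical(1))
  m6 <- m5; m6$w <- 2 * m5$w
  fired_after <- vapply(pats[1:10], function(p) voltage_trace(m6, p)$fired,
                        logical(1))
  expect_true(all(fired_after[fired_before]))
})

test_that("cycle patterns carve the box population out of a record", {
  run <- tiny_run(duration = 500)
  cp <- cycle_patterns(run$rec, box_center = c(0, 0), box_size = 32)
  expect_equal(cp$n_afferents, 16)       # 4x4 cells of the 8-cm lattice
  expect_equal(length(cp$patterns), 5)
  for (k in seq_along(cp$patterns)) {
    p <- cp$patterns[[k]]
    expect_true(all(p$t >= 0 & p$t < 100))
    expect_true(all(p$aff >= 1 & p$aff <= 16))
  }
  ## evaluation is deterministic under a fixed seed
  m <- tempotron(16); m$w <- rep(0.5, 16)
  a1 <- tempotron_evaluate(m, run$rec, c(0, 0), box_size = 32,
                           n_jitter = 10, seed = 3L)
  a2 <- tempotron_evaluate(m, run$rec, c(0, 0), box_size = 32,
                           n_jitter = 10, seed = 3L)
  expect_identical(a1, a2)
  ## zero weights: zero accuracy
  z <- tempotron(16)
  expect_equal(tempotron_evaluate(z, run$rec, c(0, 0), box_size = 32,
                                  n_jitter = 5, seed = 1L), 0)
  expect_error(tempotron_evaluate(tempotron(7), run$rec, c(0, 0),
                                  box_size = 32, n_jitter = 2),
               "mismatch")
})
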