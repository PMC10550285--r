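test_that("theta drive and entorhinal gate have the documented phases", {
  expect_equal(theta_drive(0), 7)
  expect_equal(theta_drive(50), 0, tolerance = 1e-12)
  ## mean over one cycle is half the amplitude
  expect_equal(mean(theta_drive(seq(0, 100, by = 0.01)[-1])), 3.5,
               tolerance = 1e-3)
  ## entorhinal gate peaks 70 degrees after the theta peak
  tt <- seq(0, 100, by = 0.01)
  expect_equal(tt[which.max(mec_gate(tt))], 70 / 360 * 100, tolerance = 0.02)
  expect_equal(spike_phase(70 / 360 * 100), 70 * pi / 180)
})

test_that("sensory drive combines box field, direction gain and theta gate", {
  g <- build_grid(arena(), 80)
  g$psi <- rep(0, 6400)
  ## 5-cm box cutoff is sharp
  J <- sensory_drive(c(0, 0), 0, g, t = 70 / 3.6, A_pos = 1, A_dir = 0)
  d <- sqrt(rowSums(g$centers^2))
  expect_true(all(J[d > 5] == 0))
  expect_true(all(J[d <= 5] > 0))
  ## best vs worst direction amplitudes (at the gate peak, gate = 1),
  ## probed with the animal exactly on a field centre
  i <- which.min(d)
  at <- g$centers[i, ]
  Jb <- sensory_drive(at, 0, g, 70 / 3.6, A_pos = 2, A_dir = 3)
  Jw <- sensory_drive(at, pi, g, 70 / 3.6, A_pos = 2, A_dir = 3)
  expect_equal(Jb[i], 2 + 3, tolerance = 1e-9)
  expect_equal(Jw[i], 2 + 3 * exp(-2), tolerance = 1e-9)
})

test_that("facilitation relaxes to S0F and to the driven fixed point", {
  ## no drive: exponential relaxation to S0F with tau_F = 500 ms
  s <- 0
  for (k in 1:5000) s <- stf_step(s, 0, 0.1, S0F = 1, S1F = 2, Phi_F = 1e-3)
  expect_equal(s, 1 - exp(-1), tolerance = 1e-3)     # one tau_F elapsed
  for (k in 1:45000) s <- stf_step(s, 0, 0.1, 1, 2, 1e-3)
  expect_equal(s, 1, tolerance = 1e-4)
  ## constant drive: fixed point (S0F/tau + S1F Phi J)/(1/tau + Phi J)
  s <- 0
  for (k in 1:200000) s <- stf_step(s, 6.5, 0.1, 0, 2, 1e-3)
  expect_equal(s, (0 / 500 + 2 * 1e-3 * 6.5) / (1 / 500 + 1e-3 * 6.5),
               tolerance = 1e-6)
  expect_equal(s, 1.529, tolerance = 1e-3)
  ## Phi_F = 0 with S0F = S1F freezes the resource (lesion compensation)
  expect_equal(stf_step(1, 100, 0.1, 1, 1, 0), 1)
})

test_that("depression depletes on spikes and recovers with tau_D", {
  expect_equal(std_step(0.5, FALSE, 0.1, 0.9),
               0.5 + 0.1 * 0.5 / 500)
  expect_equal(std_step(0.4, TRUE, 0, 0), 0.4)          # U_D = 0 disables STD
  ## single-event closed form: deplete then recover
  s <- std_step(1, TRUE, 0.1, 0.9, mode = "multiplicative")
  for (k in 1:2499) s <- std_step(s, FALSE, 0.1, 0.9)
  expect_equal(s, 1 - 0.9 * exp(-250 / 500), tolerance = 1e-3)
  ## subtractive clamps at zero
  expect_equal(std_step(0.3, TRUE, 0, 0.7, mode = "subtractive"), 0)
})

test_that("Izhikevich dynamics: rest, bursting and reset", {
  ## (-70, -14) is a fixed point of the excitatory cell at I = 0
  st <- izhikevich_step(-70, -14, 0, 0.1)
  expect_equal(st$v, -70, tolerance = 1e-9)
  expect_equal(st$u, -14, tolerance = 1e-9)
  expect_equal(0.04 * 70^2 - 4.8 * 70 + 140, 0)   # nullcline residual

  ## sustained I = 10: burst firing (>= 2 spikes within 50 ms of the first)
  v <- -70; u <- -14; spikes <- c()
  for (k in 1:20000) {
    st <- izhikevich_step(v, u, 10, 0.1)
    if (st$spiked) spikes <- c(spikes, k * 0.1)
    v <- st$v; u <- st$u
  }
  expect_gte(length(spikes), 2)
  expect_gte(sum(spikes <= spikes[1] + 50), 2)

  ## reset contract: crossing sends v to c exactly
  st <- izhikevich_step(29, -20, 500, 0.1)
  expect_true(st$spiked)
  expect_equal(st$v, -60)
  expect_error(izhikevich_step(1e200, 0, 0, 0.1), "diverged")
})

test_that("conductances decay exponentially and jump on delivery", {
  ## pure decay: Euler factor per step, ~exp(-t/tau) over 120 ms
  g <- 2
  for (k in 1:1200) g <- conductance_step(g, matrix(0, 1, 1), integer(0), 1,
                                          0.1, tau = 12)
  expect_equal(g, 2 * (1 - 0.1 / 12)^1200, tolerance = 1e-10)
  expect_equal(g, 2 * exp(-10), tolerance = 0.05)   # ~4% Euler bias
  ## jump scales with W s / N_pre
  W <- matrix(c(6, 0, 2, 4), 2, 2)
  g2 <- conductance_step(c(0, 0), W, delivered = c(1L, 2L), s_D = c(0.5, 1),
                         dt = 0, tau = 12)
  expect_equal(g2, c((6 * 0.5 + 2 * 1) / 2, (0 + 4) / 2))
})
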