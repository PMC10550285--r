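grid4 <- assign_preferred_directions(build_grid(arena(), 4), seed = 2L)

test_that("CA3 weights follow the distance-direction factorisation", {
  g <- grid4
  ## B_dir = 0: self-weight is exactly B_pos
  W <- ca3_weights(g, B_pos = 3, B_dir = 0, K_CA3 = 1)
  expect_equal(unname(diag(W)), rep(3, 16))

  ## two aligned cells 2 cm apart with sigma = 2: (B_pos+B_dir) e^(-1/2)
  g2 <- build_grid(arena(8, 8), 4)   # 2-cm spacing
  g2$psi <- rep(0, 16)
  W2 <- ca3_weights(g2, B_pos = 1, B_dir = 1, K_CA3 = 1, sigma = 2)
  i <- 1; j <- 2                      # lattice neighbours along x
  expect_equal(W2[i, j], 2 * exp(-0.5), tolerance = 1e-12)

  ## rightward asymmetry: pre must lie strictly left of post
  Wa <- ca3_weights(g, 1, 0, 0, asymmetry_on = TRUE)
  x <- g$centers[, 1]
  expect_true(all(Wa[outer(x, x, "<=")] == 0))   # W[i,j]=0 unless x_j < x_i
  expect_true(any(Wa[outer(x, x, ">")] > 0))

  ## symmetric whenever the directional term is neutral
  Ws <- ca3_weights(g, 2, 0, 1)
  expect_identical(Ws, t(Ws))
  Wk <- ca3_weights(g, 2, 5, 0)
  expect_equal(Wk, t(Wk), tolerance = 1e-12)

  ## Gaussian decay with centre distance at fixed angles
  gl <- build_grid(arena(), 8); gl$psi <- rep(0, 64)
  Wl <- ca3_weights(gl, 1, 0, 0)
  d2m <- as.matrix(dist(gl$centers))
  o <- order(d2m[1, ])
  expect_true(all(diff(Wl[1, o]) <= 1e-12))

  expect_error(ca3_weights(build_grid(arena(), 4), 1, 1, 1), "preferred")
})

test_that("loop-path gain peaks on the path and decays off it", {
  cen <- rbind(c(0, 0), c(4, 0), c(0, 10), c(-20, 0))
  Cj <- loop_path_gain(cen, theta_dg = 0)
  expect_equal(Cj[1], 1)              # on a path sample point
  expect_equal(Cj[2], 1)              # x = 4 is also a sample (2k)
  expect_equal(Cj[3], exp(-100 / 8), tolerance = 1e-12)
  expect_equal(Cj[4], 1)              # path end x = -20
  ## brute-force oracle over the 21 path points
  pts <- cbind(2 * (-10:10), 0)
  brute <- max(exp(-((pts[, 1] - 0)^2 + (pts[, 2] - 10)^2) / 8))
  expect_equal(Cj[3], brute)
  ## anchored at (0, 20) the path spans x in [-20, 20] at y = 20
  Ca <- loop_path_gain(rbind(c(0, 20), c(20, 20), c(0, 0)), 0, anchor = c(0, 20))
  expect_equal(Ca[1:2], c(1, 1))
  expect_lt(Ca[3], 1e-10)
})

test_that("DG loop matrices implement gate, shift and direction gain", {
  ca3 <- assign_preferred_directions(build_grid(arena(), 20), seed = 5L)
  dg <- assign_preferred_directions(build_grid(arena(), 10), seed = 6L)

  Wcd <- ca3_to_dg_weights(ca3, dg, B_DG = 10, K_DG = 1, theta_dg = 0)
  expect_equal(dim(Wcd), c(100, 400))
  ## columns for CA3 cells far off the path are (near) zero
  far <- which(abs(ca3$centers[, 2]) > 15)
  expect_lt(max(Wcd[, far]), 1e-8)

  ## DG->CA3: a DG cell projects most strongly ~4 cm along theta_dg
  ## (argmax lands within half a lattice diagonal of the shifted centre)
  Wdc <- dg_to_ca3_weights(dg, ca3, B_DG = 10, K_DG = 0, theta_dg = 0)
  j <- which.min(rowSums(dg$centers^2))
  target <- dg$centers[j, ] + c(4, 0)
  i_star <- which.max(Wdc[, j])
  expect_lt(sqrt(sum((ca3$centers[i_star, ] - target)^2)),
            ca3$arena$width / ca3$n_side * sqrt(2) / 2 + 1e-9)

  ## K_DG = 0 removes the directional factor entirely
  dg_rot <- dg; dg_rot$psi <- wrap_2pi(dg$psi + 1)
  expect_equal(dg_to_ca3_weights(dg, ca3, 10, 0, theta_dg = 0),
               dg_to_ca3_weights(dg_rot, ca3, 10, 0, theta_dg = 0))

  ## theta_dg = 180 mirrors the targets of theta_dg = 0 in x for a
  ## direction-neutral grid (K_DG = 0): W180[mx(i), mx(j)] = W0[i, j]
  W0 <- dg_to_ca3_weights(dg, ca3, 10, 0, theta_dg = 0)
  W180 <- dg_to_ca3_weights(dg, ca3, 10, 0, theta_dg = pi)
  key <- function(m) paste(round(m[, 1], 6), round(m[, 2], 6))
  mx <- function(g) match(key(cbind(-g$centers[, 1], g$centers[, 2])),
                          key(g$centers))
  expect_equal(W180[mx(ca3), mx(dg)], unclass(W0), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("two-hop loop map displaces a bump by the shift length", {
  ## composition oracle: CA3 -> DG -> CA3 moves a unit bump +4 cm along x
  ca3 <- assign_preferred_directions(build_grid(arena(), 40), seed = 9L)
  dg <- assign_preferred_directions(build_grid(arena(), 20), seed = 10L)
  Wcd <- ca3_to_dg_weights(ca3, dg, 1, 1, theta_dg = 0)
  Wdc <- dg_to_ca3_weights(dg, ca3, 1, 1, theta_dg = 0)
  bump <- as.numeric(exp(-rowSums(ca3$centers^2) / 8))   # bump at the origin
  out <- as.numeric(Wdc %*% (Wcd %*% bump))
  centroid <- colSums(ca3$centers * out) / sum(out)
  expect_equal(unname(centroid[1]), 4, tolerance = 2)    # one grid spacing
  expect_equal(unname(centroid[2]), 0, tolerance = 1)
})

test_that("inhibitory weights are uniform, seeded, and bounded", {
  expect_equal(inhibitory_weights(5, 7, 0, 1L), matrix(0, 7, 5),
               ignore_attr = TRUE)
  W <- inhibitory_weights(250, 6400, 2, seed = 4L)
  expect_equal(dim(W), c(6400, 250))
  expect_true(all(W >= 0 & W <= 2))
  expect_equal(mean(W), 1, tolerance = 0.01)   # W0/2 by the LLN
  expect_identical(W, inhibitory_weights(250, 6400, 2, seed = 4L))
})
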