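## Synaptic weight construction.  All excitatory weights share the same
## structure: a Gaussian envelope over field-centre distance (width sigma)
## times a von-Mises-like gain in the difference of preferred heading
## directions, exp[K (cos(dpsi) - 1)].  Matrices are dense, shape
## (n_target, n_source); entry W[i, j] is the synapse from presynaptic j to
## postsynaptic i.

weight_matrix <- function(W, from, to) {
  attr(W, "from") <- from
  attr(W, "to") <- to
  W
}

## exp(-d^2 / 2 sigma^2) for all target/source centre pairs, as a matrix
gauss_envelope <- function(target_xy, source_xy, sigma) {
  d2 <- outer(target_xy[, 1], source_xy[, 1], "-")^2 +
        outer(target_xy[, 2], source_xy[, 2], "-")^2
  exp(-d2 / (2 * sigma^2))
}

dir_gain <- function(target_psi, source_psi, K) {
  if (K == 0) {
    matrix(1, length(target_psi), length(source_psi))
  } else {
    exp(K * (cos(outer(target_psi, source_psi, "-")) - 1))
  }
}

require_psi <- function(grid) {
  if (anyNA(grid$psi)) {
    stop("grid has no preferred directions; run assign_preferred_directions()",
         call. = FALSE)
  }
}

#' CA3 recurrent weight matrix
#'
#' `W[i, j] = J_ij * (B_pos + B_dir * exp[K_CA3 (cos(psi_i - psi_j) - 1)]) *
#' exp(-d(p_i, p_j)^2 / (2 sigma^2))`. With `asymmetry_on` the matrix is
#' gated by `J_ij = 1` iff `x_j < x_i` (place cells only project to their
#' rightward neighbours, the hard-wired variant of the intrinsic model);
#' otherwise `J_ij = 1` everywhere. Self-connections follow the same formula.
#'
#' @param grid CA3 `place_grid` with preferred directions.
#' @param B_pos,B_dir Positional / directional weight amplitudes.
#' @param K_CA3 Concentration of the directional gain.
#' @param sigma Gaussian envelope width (cm).
#' @param asymmetry_on Logical rightward-asymmetry switch.
#' @return Dense weight matrix (n x n).
#' @export
ca3_weights <- function(grid, B_pos, B_dir, K_CA3, sigma = 2,
                        asymmetry_on = FALSE) {
  require_psi(grid)
  W <- B_pos + B_dir * dir_gain(grid$psi, grid$psi, K_CA3)
  W <- W * gauss_envelope(grid$centers, grid$centers, sigma)
  if (asymmetry_on) {
    x <- grid$centers[, 1]
    W <- W * (outer(x, x, ">"))  # strict: ties get zero weight
  }
  weight_matrix(W, from = "CA3", to = "CA3")
}

#' Gate of the DG-loop path on outgoing CA3 projections
#'
#' The loop occupies a 40-cm-long path through `anchor` along direction
#' `theta_dg`, sampled at 21 points 2 cm apart
#' (`p_k = anchor + 2k (cos, sin)(theta_dg)`, `k = -10..10`). Each CA3 cell's
#' outgoing CA3->DG connections are scaled by the closest-point Gaussian
#' `C_j = max_k exp(-d(p_k, p_j)^2 / (2 sigma^2))`, so only cells on the path
#' feed the loop.
#'
#' @param centers n x 2 matrix of CA3 field centres.
#' @param theta_dg Loop direction (radians).
#' @param anchor Length-2 centre of the path (cm).
#' @param sigma Gaussian width (cm).
#' @param spacing Path point spacing (cm).
#' @param k_range Path point index range.
#' @return Numeric vector `C_j`, one gain per CA3 cell.
#' @export
loop_path_gain <- function(centers, theta_dg, anchor = c(0, 0), sigma = 2,
                           spacing = 2, k_range = -10:10) {
  px <- anchor[1] + spacing * k_range * cos(theta_dg)
  py <- anchor[2] + spacing * k_range * sin(theta_dg)
  g <- gauss_envelope(centers, cbind(px, py), sigma)
  apply(g, 1, max)
}

#' CA3 to DG weight matrix
#'
#' `W[i, j] = C_j * B_DG * exp[K_DG (cos(psi_i^DG - psi_j^CA3) - 1)] *
#' exp(-d(p_i^DG, p_j^CA3)^2 / (2 sigma^2))` with the loop-path gate `C_j`
#' from [loop_path_gain()].
#'
#' @param ca3,dg `place_grid`s with preferred directions.
#' @param B_DG,K_DG Loop weight amplitude and directional concentration.
#' @param sigma Gaussian width (cm).
#' @param theta_dg Loop direction (radians).
#' @param loop_anchor Centre of the gating path (cm).
#' @return Dense weight matrix (n_DG x n_CA3).
#' @export
ca3_to_dg_weights <- function(ca3, dg, B_DG, K_DG, sigma = 2, theta_dg = 0,
                              loop_anchor = c(0, 0)) {
  require_psi(ca3); require_psi(dg)
  Cj <- loop_path_gain(ca3$centers, theta_dg, loop_anchor, sigma)
  W <- B_DG * dir_gain(dg$psi, ca3$psi, K_DG) *
    gauss_envelope(dg$centers, ca3$centers, sigma)
  W <- sweep(W, 2, Cj, `*`)
  weight_matrix(W, from = "CA3", to = "DG")
}

#' DG to CA3 weight matrix
#'
#' DG cells project back to CA3 cells with field centres displaced by the
#' shift vector `shift * (cos(theta_dg), sin(theta_dg))` (4 cm along the
#' loop):
#' `W[i, j] = B_DG * exp[K_DG (cos(psi_i^CA3 - psi_j^DG) - 1)] *
#' exp(-d(p_i^CA3 - r, p_j^DG)^2 / (2 sigma^2))`. There are no DG->DG
#' connections anywhere in the model.
#'
#' @param dg,ca3 `place_grid`s with preferred directions.
#' @param B_DG,K_DG Loop weight amplitude and directional concentration.
#' @param sigma Gaussian width (cm).
#' @param theta_dg Loop direction (radians).
#' @param shift Displacement length (cm).
#' @return Dense weight matrix (n_CA3 x n_DG).
#' @export
dg_to_ca3_weights <- function(dg, ca3, B_DG, K_DG, sigma = 2, theta_dg = 0,
                              shift = 4) {
  require_psi(ca3); require_psi(dg)
  r <- shift * c(cos(theta_dg), sin(theta_dg))
  shifted <- cbind(ca3$centers[, 1] - r[1], ca3$centers[, 2] - r[2])
  W <- B_DG * dir_gain(ca3$psi, dg$psi, K_DG) *
    gauss_envelope(shifted, dg$centers, sigma)
  weight_matrix(W, from = "DG", to = "CA3")
}

#' Uniformly randomised inhibitory-to-excitatory weights
#'
#' All-to-all weights `W[i, j] = W0 * xi_ij` with `xi ~ U(0, 1)` i.i.d.,
#' reproducible given the seed. Used for the Inh->CA3 and Inh->DG blocks;
#' interneurons never connect to each other.
#'
#' @param n_pre,n_post Presynaptic (interneuron) and postsynaptic counts.
#' @param W0 Maximum synaptic strength (`W0 = 0` disables inhibition).
#' @param seed Integer seed.
#' @return Dense weight matrix (n_post x n_pre).
#' @export
inhibitory_weights <- function(n_pre, n_post, W0, seed) {
  stopifnot(W0 >= 0)
  W <- withr::with_seed(seed, {
    matrix(W0 * stats::runif(n_post * n_pre), nrow = n_post, ncol = n_pre)
  })
  weight_matrix(W, from = "Inh", to = "E")
}
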