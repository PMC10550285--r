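## Single-step update rules of the simulator, as plain R functions.  These
## are the reference definitions: the production integrator in src/sim.cpp
## applies exactly the same rules in the same order, and the two paths are
## cross-checked against each other on small networks in the test suite.

#' Oscillatory theta drive
#'
#' `I_theta(t) = amp * (1 + cos(2 pi t / period)) / 2`, maximal at `t = 0`,
#' `period`, ... . The drive is *subtracted* from every neuron's total input
#' current (`I = I_R + I_S - I_theta`), so spiking concentrates around the
#' theta trough of the drive.
#'
#' @param t Time in ms (vectorised).
#' @param amp Amplitude (default 7).
#' @param period Theta period in ms (default 100).
#' @return Drive current at `t`.
#' @examples
#' theta_drive(c(0, 50))  # 7 at the peak, 0 at the trough
#' @export
theta_drive <- function(t, amp = 7, period = 100) {
  amp * (1 + cos(2 * pi * t / period)) / 2
}

#' Theta-gated entorhinal input envelope
#'
#' `I_MEC(t) = (1 + cos(2 pi t / period - shift)) / 2`: the entorhinal drive
#' peaks `phase_deg` degrees (70 by default) after each theta-drive peak,
#' i.e. at spike phase 70 degrees under [spike_phase()].
#'
#' @param t Time in ms.
#' @param phase_deg Phase shift in degrees.
#' @param period Theta period in ms.
#' @return Gate value in `[0, 1]`.
#' @export
mec_gate <- function(t, phase_deg = 70, period = 100) {
  (1 + cos(2 * pi * t / period - phase_deg * pi / 180)) / 2
}

#' Sensory drive to the CA3 place cells
#'
#' Box place fields: a cell receives input only while the animal is within
#' `radius` (5 cm) of its field centre. The amplitude combines positional and
#' directional tuning, `A_i = A_pos + A_dir * exp(cos(heading - psi_i) - 1)`,
#' and is gated by the theta-modulated entorhinal envelope [mec_gate()].
#' Only CA3 cells receive sensory drive; DG cells and interneurons never do.
#'
#' @param pos Length-2 animal position (cm).
#' @param heading Heading angle (radians).
#' @param grid CA3 `place_grid` with preferred directions.
#' @param t Time (ms) for the theta gate.
#' @param A_pos,A_dir Positional and directional amplitudes.
#' @param radius Field radius (cm).
#' @return Numeric vector `J_S` of drive per cell (before facilitation).
#' @export
sensory_drive <- function(pos, heading, grid, t, A_pos, A_dir, radius = 5) {
  require_psi(grid)
  d2 <- (grid$centers[, 1] - pos[1])^2 + (grid$centers[, 2] - pos[2])^2
  amp <- A_pos + A_dir * exp(cos(heading - grid$psi) - 1)
  ifelse(d2 <= radius^2, amp * mec_gate(t), 0)
}

#' One Euler step of short-term facilitation
#'
#' `ds_F/dt = (S0F - s_F)/tau_F + (S1F - s_F) * Phi_F * J_S`. The effective
#' sensory current is the drive times the squared facilitation variable,
#' `I_S = J_S * s_F^2` (the square models supralinear presynaptic calcium).
#' With `Phi_F = 0` and `S0F = S1F` the resource is constant and `I_S`
#' reduces to a fixed release probability (the lesion-compensation setting).
#'
#' @param s_F Facilitation variable (vectorised over cells).
#' @param J_S Sensory drive from [sensory_drive()].
#' @param dt Time step (ms).
#' @param S0F,S1F Resting and driven fixed points.
#' @param Phi_F Facilitation rate per unit drive.
#' @param tau_F Recovery time constant (ms).
#' @return Updated `s_F`.
#' @export
stf_step <- function(s_F, J_S, dt, S0F, S1F, Phi_F, tau_F = 500) {
  s_F + dt * ((S0F - s_F) / tau_F + (S1F - s_F) * Phi_F * J_S)
}

#' One step of short-term depression
#'
#' Between spikes the release resource recovers as
#' `ds_D/dt = (1 - s_D)/tau_D`; on a presynaptic spike it is depleted
#' multiplicatively, `s_D <- s_D (1 - U_D)` (or subtractively with clamping
#' at 0 when `mode = "subtractive"`), with the depletion applied before this
#' step's recovery increment. STD applies to every synapse with a CA3
#' presynaptic cell; DG and inhibitory sources have `s_D` fixed at 1.
#'
#' @param s_D Resource in `[0, 1]` (vectorised).
#' @param spiked Logical, whether the presynaptic cell spiked this step.
#' @param dt Time step (ms).
#' @param U_D Depletion fraction in `[0, 1]`.
#' @param tau_D Recovery time constant (ms).
#' @param mode `"multiplicative"` or `"subtractive"`.
#' @return Updated `s_D`.
#' @export
std_step <- function(s_D, spiked, dt, U_D, tau_D = 500,
                     mode = c("multiplicative", "subtractive")) {
  mode <- match.arg(mode)
  dep <- if (mode == "multiplicative") s_D * (1 - U_D) else pmax(s_D - U_D, 0)
  s_D <- ifelse(spiked, dep, s_D)
  s_D + dt * (1 - s_D) / tau_D
}

#' One Euler step of the Izhikevich neuron
#'
#' `dv/dt = 0.04 v^2 + 5 v + 140 - u + I`, `du/dt = a (b v - u)`. A spike is
#' registered when `v` crosses 30 mV from below; the state is then reset to
#' `v = c`, `u = u + d`. The excitatory preset `(a, b, c, d) =
#' (0.035, 0.2, -60, 8)` yields burst firing; the inhibitory preset
#' `(0.02, 0.25, -65, 2)` yields fast spiking.
#'
#' @param v,u Membrane potential (mV) and recovery variable (vectorised).
#' @param I Input current.
#' @param dt Time step (ms).
#' @param a,b,c,d Izhikevich parameters.
#' @return List with updated `v`, `u` and logical `spiked`.
#' @export
izhikevich_step <- function(v, u, I, dt, a = 0.035, b = 0.2, c = -60, d = 8) {
  v_new <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + I)
  u_new <- u + dt * a * (b * v - u)
  if (any(!is.finite(v_new)) || any(!is.finite(u_new))) {
    stop("Izhikevich state diverged (non-finite v or u); reduce dt",
         call. = FALSE)
  }
  spiked <- v < 30 & v_new >= 30
  list(v = ifelse(spiked, c, v_new), u = ifelse(spiked, u_new + d, u_new),
       spiked = spiked)
}

#' Izhikevich parameter presets
#'
#' @param type `"excitatory"` (bursting place cells) or `"inhibitory"`
#'   (fast-spiking interneurons).
#' @return Named list `a`, `b`, `c`, `d`, `v_thresh`.
#' @export
izhikevich_params <- function(type = c("excitatory", "inhibitory")) {
  type <- match.arg(type)
  if (type == "excitatory") {
    list(a = 0.035, b = 0.2, c = -60, d = 8, v_thresh = 30)
  } else {
    list(a = 0.02, b = 0.25, c = -65, d = 2, v_thresh = 30)
  }
}

#' Conductance decay and spike-arrival jumps
#'
#' Exponential Euler-free decay rule used between deliveries:
#' `g <- g (1 - dt/tau)`, plus a jump `(1/N_pre) * sum_j W[, j] * s_D[j]`
#' for every presynaptic spike delivered this step (spikes arrive exactly
#' `tau_0 = 2` ms after emission). Currents follow from the conductances as
#' `I_E = (V_E - v) g_E`, `I_I = (V_I - v) g_I`.
#'
#' @param g Conductance vector (one entry per postsynaptic cell).
#' @param W Weight matrix block (n_post x n_pre).
#' @param delivered Integer indices of presynaptic cells whose spikes arrive
#'   this step (may be empty).
#' @param s_D Presynaptic release resources (1 for non-CA3 sources).
#' @param dt Time step (ms).
#' @param tau Conductance decay constant (ms).
#' @return Updated conductance vector.
#' @export
conductance_step <- function(g, W, delivered, s_D, dt, tau) {
  if (length(delivered)) {
    n_pre <- ncol(W)
    jump <- W[, delivered, drop = FALSE] %*% s_D[delivered] / n_pre
    g <- g + as.numeric(jump)
  }
  g <- g * (1 - dt / tau)
  if (any(g < 0)) stop("negative synaptic conductance", call. = FALSE)
  g
}
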