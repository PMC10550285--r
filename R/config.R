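## Parameter presets, one per simulated figure condition.
##
## The printed parameter table in the source model collapses runs of equal
## cells, so a few rows are ambiguous about where one value stops and the
## next begins (notably U_D, B_DG and the sensory amplitudes).  The presets
## below encode one consistent reading -- chosen so that each condition is a
## minimal change from its neighbours (e.g. the DG-lesion column only touches
## the sensory release parameters and silences the loop) -- and every scalar
## can be overridden through `network_config(...)`, so any other reading is
## reproducible from configuration.  Contested cells: U_D for the directional
## input condition (0.9 vs 0.7), the no-recurrence lesion STF row (set here to
## the constant-release values of the main lesion column).
.preset_table <- local({
  cols <- c("fig1_intrinsic", "fig1_extrinsic", "fig2", "fig3",
            "fig4_control", "fig4_lesion", "fig5", "fig6a",
            "fig6b_control", "fig6b_lesion", "fig7")
  m <- rbind(
    A_pos      = c(7.5, 7.5, 9.0, 6.5, 6.5, 9.5, 7.5, 6.5, 6.5, 6.5, 6.5),
    A_dir      = c(0,   0,   6,   6,   6,   9,   8,   6,   6,   6,   6),
    S0F        = c(1,   1,   0,   0,   0,   1.25, 0,  0.25, 0.25, 1.25, 0),
    S1F        = c(1,   1,   2,   2,   2,   1.25, 2,  1.5,  1.5,  1.25, 2),
    Phi_F      = c(0,   0,   1e-3, 1e-3, 1e-3, 0,  1e-3, 1e-3, 1e-3, 0, 1e-3),
    B_pos      = c(1100, 1100, 1100, 1100, 1100, 1100, 1100, 0, 0, 0, 1100),
    B_dir      = c(0,   0,   2000, 1500, 1500, 1500, 2000, 0, 0, 0, 1500),
    K_CA3      = c(0,   0,   1,   1,   1,   1,   1,   1,   1,   1,   1),
    asymmetry  = c(1,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0),
    U_D        = c(0,   0.9, 0.9, 0.7, 0.7, 0.7, 0.7, 0.7, 0.7, 0.7, 0.7),
    n_dg_side  = c(0,   0,   0,   40,  40,  40,  40,  40,  40,  40,  40),
    B_DG       = c(0,   0,   0,   3000, 3000, 0, 4000, 4000, 4000, 0, 4000),
    K_DG       = c(0,   0,   0,   1,   1,   1,   1,   1,   1,   1,   1),
    N_I        = c(250, 250, 250, 250, 250, 250, 250, 250, 250, 250, 250),
    W0_ca3_inh = c(50,  50,  50,  50,  50,  50,  50,  50,  50,  50,  50),
    W0_inh_ca3 = c(5,   5,   5,   5,   5,   5,   5,   5,   5,   5,   5),
    W0_dg_inh  = c(0,   0,   0,   350, 350, 350, 350, 350, 350, 350, 350),
    W0_inh_dg  = c(0,   0,   0,   35,  35,  35,  35,  35,  35,  35,  35)
  )
  colnames(m) <- cols
  m
})

#' Names of the built-in parameter presets
#' @return Character vector of preset names, one per simulated condition.
#' @export
preset_names <- function() colnames(.preset_table)

#' Build a network configuration
#'
#' Collects every scalar parameter of the model: sensory drive amplitudes and
#' short-term facilitation (STF) of the entorhinal input, CA3 recurrent weight
#' parameters and short-term depression (STD), DG-loop geometry and gain,
#' inhibitory feedback weights, synaptic time constants, and integration
#' settings. A `preset` selects one simulated condition; any field can then
#' be overridden by name.
#'
#' Fixed model constants carried by every configuration: Gaussian weight
#' width `sigma = 2` cm, `tau_F = tau_D = 500` ms, `tau_E = 12` ms,
#' `tau_I = 10` ms, transmission delay `tau_0 = 2` ms, reversal potentials
#' `V_E = 0` mV and `V_I = -80` mV, theta period 100 ms with drive amplitude
#' 7 and a +70 degree phase-shifted entorhinal gate, 5 cm box place fields.
#'
#' @param preset One of [preset_names()].
#' @param ... Named overrides of any configuration field.
#' @return A `network_config` (named list).
#' @examples
#' cfg <- network_config("fig4_control", theta_dg = pi)
#' cfg$B_DG
#' @export
network_config <- function(preset = "fig2", ...) {
  preset <- match.arg(preset, preset_names())
  p <- .preset_table[, preset]
  cfg <- list(
    preset = preset,
    ## arena and populations
    arena_width = 80, arena_height = 80,
    n_ca3_side = 80,
    n_dg_side = as.integer(p[["n_dg_side"]]),
    N_I = as.integer(p[["N_I"]]),
    ## sensory input and STF
    A_pos = p[["A_pos"]], A_dir = p[["A_dir"]],
    input_radius = 5,
    S0F = p[["S0F"]], S1F = p[["S1F"]], Phi_F = p[["Phi_F"]],
    tau_F = 500,
    mec_phase_deg = 70,
    ## CA3 recurrence and STD
    B_pos = p[["B_pos"]], B_dir = p[["B_dir"]], K_CA3 = p[["K_CA3"]],
    sigma = 2,
    asymmetry_on = p[["asymmetry"]] == 1,
    U_D = p[["U_D"]], tau_D = 500,
    std_mode = "subtractive",
    std_release = "delivery",
    std_to_interneurons = TRUE,
    std_to_dg = TRUE,     # depression on every CA3-source synapse, the
                          # strict reading; FALSE restricts it to the CA3
                          # recurrent collaterals and gives a stronger loop
    ## DG loop
    B_DG = p[["B_DG"]], K_DG = p[["K_DG"]],
    theta_dg = 0,
    loop_anchor = c(0, 0),
    loop_shift = 4,       # cm, DG->CA3 target displacement along theta_dg
    loop_spacing = 2,     # cm, spacing of the 21 gate path points
    dg_lesion = FALSE,
    dg_norm = "global",   # DG-source jumps divided by N_J (or "per_block")
    ## inhibition
    W0_ca3_inh = p[["W0_ca3_inh"]], W0_inh_ca3 = p[["W0_inh_ca3"]],
    W0_dg_inh = p[["W0_dg_inh"]], W0_inh_dg = p[["W0_inh_dg"]],
    ## synapses and theta drive
    tau_E = 12, tau_I = 10, tau_0 = 2,
    V_E = 0, V_I = -80,
    theta_amp = 7, theta_period = 100,
    theta_to_inhibitory = FALSE,
    ## integration
    dt = 0.1,
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
  structure(cfg, class = "network_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(cfg$dt > 0, "dt must be positive")
  for (f in c("tau_F", "tau_D", "tau_E", "tau_I", "tau_0")) {
    chk(cfg[[f]] > 0, paste(f, "must be positive"))
  }
  chk(cfg$U_D >= 0 && cfg$U_D <= 1, "U_D must lie in [0, 1]")
  chk(cfg$S0F >= 0 && cfg$S1F >= 0, "STF bounds must be non-negative")
  chk(cfg$n_ca3_side >= 1, "n_ca3_side must be >= 1")
  chk(cfg$n_dg_side >= 0, "n_dg_side must be >= 0")
  chk(length(cfg$loop_anchor) == 2, "loop_anchor must be a length-2 position")
  chk(is.logical(cfg$asymmetry_on) && is.logical(cfg$dg_lesion),
      "switches must be logical")
  chk(cfg$std_mode %in% c("multiplicative", "subtractive"),
      "std_mode must be 'multiplicative' or 'subtractive'")
  chk(cfg$std_release %in% c("emission", "delivery"),
      "std_release must be 'emission' or 'delivery'")
  chk(cfg$dg_norm %in% c("global", "per_block"),
      "dg_norm must be 'global' or 'per_block'")
  invisible(cfg)
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("<network_config> preset '%s'\n", x$preset))
  cat(sprintf("  CA3 %d^2 cells; DG %s; %d interneurons per layer\n",
              x$n_ca3_side,
              if (x$n_dg_side > 0) sprintf("%d^2 cells", x$n_dg_side) else "absent",
              x$N_I))
  cat(sprintf("  sensory A_pos=%g A_dir=%g, STF (S0=%g, S1=%g, Phi=%g)\n",
              x$A_pos, x$A_dir, x$S0F, x$S1F, x$Phi_F))
  cat(sprintf("  CA3 weights B_pos=%g B_dir=%g K=%g%s, STD U_D=%g\n",
              x$B_pos, x$B_dir, x$K_CA3,
              if (x$asymmetry_on) " (rightward asymmetry)" else "", x$U_D))
  if (x$n_dg_side > 0) {
    cat(sprintf("  DG loop B_DG=%g K_DG=%g theta_dg=%.0f deg anchor (%g, %g)%s\n",
                x$B_DG, x$K_DG, x$theta_dg * 180 / pi, x$loop_anchor[1],
                x$loop_anchor[2], if (x$dg_lesion) " [lesioned]" else ""))
  }
  invisible(x)
}

config_arena <- function(cfg) arena(cfg$arena_width, cfg$arena_height)

#' Read a configuration from a YAML or JSON file
#'
#' The file must contain a `preset` entry plus optional overrides of any
#' [network_config()] field; unknown keys are an error so that typos cannot
#' silently fall back to defaults. `theta_dg_deg` may be used instead of
#' `theta_dg` to give the loop direction in degrees.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A `network_config`.
#' @export
read_config <- function(path) {
  spec <- yaml::read_yaml(path)  # yaml reader also parses JSON
  if (is.null(spec$preset)) stop("config file must name a `preset`", call. = FALSE)
  preset <- spec$preset
  spec$preset <- NULL
  if (!is.null(spec$theta_dg_deg)) {
    spec$theta_dg <- spec$theta_dg_deg * pi / 180
    spec$theta_dg_deg <- NULL
  }
  if (!is.null(spec$loop_anchor)) spec$loop_anchor <- as.numeric(spec$loop_anchor)
  do.call(network_config, c(list(preset = preset), spec))
}

#' Simulated DG lesion
#'
#' Returns the configuration of the lesion counterpart of `config`: the DG
#' layer is silenced and the loss of loop drive is compensated by raising the
#' release probability of the sensory afferents -- short-term facilitation is
#' removed (`Phi_F = 0`, `S0F = S1F`) and the sensory amplitudes raised to
#' the lesion-condition values.
#'
#' @param config A `network_config` (typically the `fig4_control` preset).
#' @return The lesioned `network_config`.
#' @export
lesion_transform <- function(config) {
  stopifnot(inherits(config, "network_config"))
  config$dg_lesion <- TRUE
  config$B_DG <- 0
  config$S0F <- 1.25
  config$S1F <- 1.25
  config$Phi_F <- 0
  config$A_pos <- 9.5
  config$A_dir <- if (config$A_dir > 0) 9 else 0
  validate_config(config)
  config
}
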