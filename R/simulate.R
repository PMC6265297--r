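#' Passive-cell (oocyte) recording model
#'
#' Linear-membrane and instrumentation properties of the recorded cell:
#' linear membrane capacitance, clamp settling time constant, ohmic leak,
#' and Gaussian recording noise.  These produce the artifacts that P/N
#' subtraction and linear-capacitance regression are designed to remove.
#'
#' @param C_lin linear membrane capacitance, nF (>= 0).
#' @param tau_clamp clamp voltage settling time constant, ms (> 0).
#' @param g_leak linear leak conductance, uS (>= 0).
#' @param E_leak leak reversal potential, mV.
#' @param noise_sd Gaussian noise standard deviation, uA (>= 0).
#' @param seed RNG seed for the noise stream.
#' @return a `cell_model`.
#' @export
cell_model <- function(C_lin = 0.2, tau_clamp = 0.3, g_leak = 0.5,
                       E_leak = 0, noise_sd = 0, seed = 1L) {
  stopifnot(C_lin >= 0, tau_clamp > 0, g_leak >= 0, noise_sd >= 0)
  structure(list(C_lin = C_lin, tau_clamp = tau_clamp, g_leak = g_leak,
                 E_leak = E_leak, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cell_model")
}

# Clamp voltage and capacitive current along one sweep, analytic per
# segment: V_clamp relaxes exponentially (tau_clamp) to each new command
# level, so I_cap = C_lin * dV_clamp/dt is a decaying spike at each switch.
# Units: C_lin nF, V mV, t ms -> I_cap in uA after the 1e-3 factor
# (nF * mV / ms = 1e-3 uA).
clamp_waveforms <- function(protocol, step_index, cell, time) {
  seg <- protocol_segments(protocol, step_index)
  tau <- cell$tau_clamp
  V_clamp <- numeric(length(time))
  I_cap <- numeric(length(time))
  V_at_seg_start <- protocol$V_hold  # clamp assumed settled at hold
  t0 <- 0
  bounds <- cumsum(seg$duration)
  for (s in seq_len(nrow(seg))) {
    t1 <- bounds[s]
    idx <- which(time >= t0 & (time < t1 | (s == nrow(seg) & time <= t1 + 1e-9)))
    dt <- time[idx] - t0
    dV <- V_at_seg_start - seg$V[s]
    V_clamp[idx] <- seg$V[s] + dV * exp(-dt / tau)
    I_cap[idx] <- 1e-3 * cell$C_lin * (-dV / tau) * exp(-dt / tau)
    V_at_seg_start <- seg$V[s] + dV * exp(-seg$duration[s] / tau)
    t0 <- t1
  }
  list(V_clamp = V_clamp, I_cap = I_cap)
}

# Gating current of one sweep from the occupancy solution:
# I_g = N * e0 * sum_t z_t * (net forward flux) in uA
# (flux in ms^-1; C/ms -> uA needs 1e9).
gating_current <- function(scheme, occ_sol) {
  tr <- scheme$transitions
  e0 <- phys_constants(scheme$temperature_K)$e0
  n_t <- length(occ_sol$time)
  Ig <- numeric(n_t)
  # rates vary with command voltage, piecewise constant
  Vs <- occ_sol$voltage
  uV <- unique(Vs)
  for (V in uV) {
    idx <- which(Vs == V)
    rt <- transition_rates(scheme, V)
    flux <- numeric(length(idx))
    for (i in seq_len(nrow(rt))) {
      flux <- flux + rt$z_t[i] *
        (occ_sol$occ[idx, rt$from[i]] * rt$kf[i] -
         occ_sol$occ[idx, rt$to[i]] * rt$kb[i])
    }
    Ig[idx] <- scheme$N * e0 * flux * 1e9
  }
  Ig
}

#' Simulate a voltage-clamp sweep family
#'
#' Generates the macroscopic current for every step of a protocol:
#'
#' `I(t) = I_ionic + I_gating + I_cap + I_leak + noise`
#'
#' where the ionic current is `N * Po(t) * gamma * (V - Vrev)` (zero for
#' nonconducting schemes), the gating current is the summed z-weighted net
#' state flux, the capacitive transient follows the RC-smoothed clamp
#' voltage, and the leak is ohmic in the clamp voltage.  Channel kinetics
#' follow the command voltage so each segment is an exact master-equation
#' solution; the RC smoothing shapes only the linear artifact.  Outward
#' current is positive; a depolarizing step gives an upward ON gating
#' transient.
#'
#' Deterministic given (`scheme`, `protocol`, `cell`): the noise stream is
#' seeded from `cell$seed`, so identical inputs give identical traces.
#'
#' @param scheme a `gating_scheme`.
#' @param protocol a `voltage_protocol`; honors `n_repeats` (P/N subsweeps).
#' @param cell a `cell_model`.
#' @return a `sweep_set`: list with `time` (ms), `I` (samples x sweeps
#'   matrix, uA), `step_voltages` (per sweep), `repeat_index` (per sweep),
#'   `protocol`, and provenance metadata.
#' @export
simulate_sweeps <- function(scheme, protocol, cell = cell_model()) {
  dt <- 1 / protocol$sample_rate
  if (dt > cell$tau_clamp / 2)
    warning("sample interval exceeds tau_clamp/2: capacitance transient undersampled")
  n_steps <- length(protocol$step_voltages)
  n_rep <- protocol$n_repeats
  sols <- occupancies(scheme, protocol)
  time <- sols[[1L]]$time
  n_sweeps <- n_steps * n_rep
  I <- matrix(0, length(time), n_sweeps)
  sv <- rep(protocol$step_voltages, each = n_rep)
  ri <- rep(seq_len(n_rep), times = n_steps)
  e0 <- phys_constants(scheme$temperature_K)$e0
  set.seed(cell$seed)
  col <- 0L
  for (s in seq_len(n_steps)) {
    sol <- sols[[s]]
    cw <- clamp_waveforms(protocol, s, cell, time)
    Ii <- if (scheme$conducting) {
      po <- rowSums(sol$occ[, scheme$open_states, drop = FALSE])
      1e-3 * (scheme$N * scheme$gamma * 1e6) * po * (sol$voltage - scheme$Vrev)
    } else 0
    Ig <- gating_current(scheme, sol)
    Il <- 1e-3 * cell$g_leak * (cw$V_clamp - cell$E_leak)
    base <- Ii + Ig + cw$I_cap + Il
    for (r in seq_len(n_rep)) {
      col <- col + 1L
      noise <- if (cell$noise_sd > 0)
        stats::rnorm(length(time), 0, cell$noise_sd) else 0
      I[, col] <- base + noise
    }
  }
  structure(list(time = time, I = I, step_voltages = sv, repeat_index = ri,
                 protocol = protocol,
                 meta = list(scheme = scheme, cell = cell,
                             seed = cell$seed)),
            class = "sweep_set")
}

#' Write / read a sweep family as TSV plus a sidecar
#'
#' The TSV holds `time_ms` and one `I_step_<mV>[_r<k>]` column per sweep
#' (uA); the JSON sidecar records the protocol, scheme parameters, cell
#' model and seed so an analysis can be reproduced from the files alone.
#'
#' @param sweeps a `sweep_set`.
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return (write) the prefix, invisibly; (read) a `sweep_set`.
#' @export
write_sweep_set <- function(sweeps, prefix) {
  cn <- sprintf("I_step_%g", sweeps$step_voltages)
  if (max(sweeps$repeat_index) > 1L)
    cn <- sprintf("%s_r%d", cn, sweeps$repeat_index)
  df <- data.frame(time_ms = sweeps$time, sweeps$I)
  names(df) <- c("time_ms", cn)
  utils::write.table(df, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  pr <- sweeps$protocol
  sidecar <- list(
    protocol = pr[setdiff(names(pr), NULL)],
    step_voltages = sweeps$step_voltages,
    repeat_index = sweeps$repeat_index,
    seed = sweeps$meta$seed,
    cell = unclass(sweeps$meta$cell),
    scheme = if (!is.null(sweeps$meta$scheme)) list(
      states = sweeps$meta$scheme$states,
      transitions = sweeps$meta$scheme$transitions,
      open_states = sweeps$meta$scheme$open_states,
      N = sweeps$meta$scheme$N, gamma = sweeps$meta$scheme$gamma,
      Vrev = sweeps$meta$scheme$Vrev,
      conducting = sweeps$meta$scheme$conducting,
      temperature_K = sweeps$meta$scheme$temperature_K)
  )
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_sweep_set
#' @export
read_sweep_set <- function(prefix) {
  df <- utils::read.table(paste0(prefix, ".tsv"), sep = "\t", header = TRUE,
                          check.names = FALSE)
  sc <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  pr <- sc$protocol
  protocol <- structure(list(
    V_hold = pr$V_hold, step_voltages = pr$step_voltages,
    step_duration = pr$step_duration, V_tail = pr$V_tail,
    tail_duration = pr$tail_duration, pre_duration = pr$pre_duration,
    sample_rate = pr$sample_rate,
    n_repeats = as.integer(pr$n_repeats)), class = "voltage_protocol")
  structure(list(time = df$time_ms,
                 I = as.matrix(df[, -1L, drop = FALSE]),
                 step_voltages = sc$step_voltages,
                 repeat_index = sc$repeat_index,
                 protocol = protocol,
                 meta = list(cell = sc$cell, scheme = sc$scheme,
                             seed = sc$seed)),
            class = "sweep_set")
}
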