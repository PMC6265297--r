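#' Canonical study conditions
#'
#' These constructors freeze the synthetic-study conditions used by the
#' analysis scripts, the test-suite benchmarks and the acceptance script:
#' Table-style Boltzmann parameters for the wild-type-like channel and
#' for representative ester variants, recording protocols matching
#' two-electrode voltage-clamp practice, and a three-state charge scheme
#' whose Q-V decomposes into two components.
#'
#' Kinetic choices (documented in the methods vignette): the charge-split
#' fraction is 0.8 for conducting schemes, placing the transition barrier
#' near the activated state so that activation is fast and deactivation
#' tails relax over a few milliseconds at the repolarization potential,
#' as for Shaker; `k0 = 0.12` ms^-1 puts the slowest relaxation near
#' 5 ms so 30 ms steps equilibrate.
#'
#' @name study_conditions
NULL

#' Gating parameters of the worked examples (per-construct Boltzmann values)
#'
#' G-V Boltzmann midpoints (mV) and valences (e0) for the suppression
#' constructs analyzed in the worked examples: each site paired as amide
#' (aa) control vs alpha-hydroxy ester (ah) variant.
#'
#' @return data.frame (construct, site, kind, Vd, z).
#' @export
gating_parameter_table <- function() {
  path <- system.file("extdata", "gating_parameters.csv",
                      package = "vsgating", mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path))
    path <- file.path("inst", "extdata", "gating_parameters.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Wild-type-like two-state conducting scheme
#'
#' @param z,Vd Boltzmann truth (defaults: WT-like 3.4 e0, -25.9 mV).
#' @param k0,delta kinetic reference rate (ms^-1) and charge split.
#' @return a `gating_scheme`.
#' @export
wt_like_scheme <- function(z = 3.4, Vd = -25.9, k0 = 0.12, delta = 0.8) {
  build_two_state_scheme(z = z, Vd = Vd, k0 = k0, delta = delta,
                         N = 2.5e6, gamma = 2e-11, Vrev = 0)
}

#' Ionic recording protocol for G-V benchmarks
#'
#' Hold -80 mV, 5 mV steps, 30 ms test pulses, 10 kHz sampling.  The
#' repolarization potential defaults to -80 mV: with a two-state truth a
#' shallower tail leaves residual equilibrium open probability that
#' contaminates the tail readout (see the methods vignette).
#'
#' @param V_tail tail potential, mV.
#' @param step_voltages test voltages, mV.
#' @return a `voltage_protocol`.
#' @export
ionic_protocol <- function(V_tail = -80,
                           step_voltages = seq(-80, 60, by = 5)) {
  voltage_protocol(V_hold = -80, step_voltages = step_voltages,
                   step_duration = 30, V_tail = V_tail,
                   tail_duration = 30, pre_duration = 5, sample_rate = 10)
}

#' Three-state nonconducting charge scheme (two-component Q-V truth)
#'
#' Resting -> intermediate -> activated chain.  Defaults: z1 = 1.0 at
#' V1 = -120 mV and z2 = 2.5 at V2 = -20 mV, so the fraction of charge in
#' the hyperpolarized component is f1 = z1/(z1+z2) = 0.286 (roughly the
#' ~30% carried by the first S4 step in wild-type channels) and the
#' charge is fully saturated across the +50..+70 mV window used for the
#' linear-capacitance regression.
#'
#' @param z1,V1,k01 first-transition charge, midpoint (mV), rate (ms^-1).
#' @param z2,V2,k02 second-transition parameters.
#' @param N channel count (gating-current expression scale).
#' @return a nonconducting `gating_scheme`.
#' @export
charge_scheme <- function(z1 = 1.0, V1 = -120, k01 = 0.2,
                          z2 = 2.5, V2 = -20, k02 = 0.12, N = 1e10) {
  build_sequential_scheme(list(
    list(z_t = z1, Vd = V1, k0 = k01, delta = 0.5),
    list(z_t = z2, Vd = V2, k0 = k02, delta = 0.35)),
    N = N, conducting = FALSE)
}

#' Gating-current protocol
#'
#' Hold -100 mV, steps -150..+100 mV, 30 ms pulses.  Sampled at 200 kHz
#' so that trapezoidal integration resolves the fastest gating
#' transients (tau ~ 0.05-0.1 ms at the range extremes) to better than
#' 0.1%; the tail is lengthened to 60 ms so the slower component of the
#' OFF transient decays to numerical silence before the baseline window.
#'
#' @param by step increment, mV (5 for capacitance-grade Q-V curves).
#' @param sample_rate sampling rate, kHz.
#' @return a `voltage_protocol`.
#' @export
gating_protocol <- function(by = 5, sample_rate = 200) {
  voltage_protocol(V_hold = -100,
                   step_voltages = seq(-150, 100, by = by),
                   step_duration = 30, V_tail = -100,
                   tail_duration = 60, pre_duration = 2,
                   sample_rate = sample_rate)
}

#' Default recording cell for benchmarks
#'
#' @param noise_sd noise, uA.
#' @param seed RNG seed.
#' @param C_lin linear capacitance, nF.
#' @param g_leak leak conductance, uS.
#' @return a `cell_model`.
#' @export
study_cell <- function(noise_sd = 0, seed = 1L, C_lin = 200, g_leak = 1) {
  cell_model(C_lin = C_lin, tau_clamp = 0.3, g_leak = g_leak, E_leak = 0,
             noise_sd = noise_sd, seed = seed)
}

#' One-shot G-V recovery benchmark
#'
#' Simulates a two-state truth with P/N companion sweeps, performs P/N
#' subtraction, builds the tail G-V and fits a Boltzmann; returns truth
#' and recovered parameters.
#'
#' @param z,Vd truth parameters.
#' @param noise_sd recording noise, uA.
#' @param seed RNG seed.
#' @param n_sub P/N subpulse count.
#' @param method "tail" or "chord".
#' @return list (fit, gv, truth).
#' @export
gv_recovery_run <- function(z = 3.4, Vd = -25.9, noise_sd = 0, seed = 1L,
                            n_sub = 8L, method = c("tail", "chord")) {
  method <- match.arg(method)
  scheme <- wt_like_scheme(z = z, Vd = Vd)
  pr <- ionic_protocol()
  cell <- study_cell(noise_sd = noise_sd, seed = seed)
  test <- simulate_sweeps(scheme, pr, cell)
  sub_pr <- p_over_n_subpulses(pr, n = n_sub, V_sub_hold = -110)
  sub_cell <- cell; sub_cell$seed <- cell$seed + 1000003L
  sub <- simulate_sweeps(scheme, sub_pr, sub_cell)
  corrected <- p_over_n_subtract(test, sub)
  gv <- if (method == "tail") gv_from_tails(corrected)
        else gv_from_chord(corrected, Vrev = scheme$Vrev)
  fit <- fit_boltzmann(gv)
  list(fit = fit, gv = gv, truth = list(z = z, Vd = Vd))
}

#' One-shot gating-charge recovery benchmark
#'
#' Simulates the three-state nonconducting scheme with linear
#' capacitance and leak, runs the full charge pipeline (OFF integration,
#' +50..+70 mV capacitance regression, linear subtraction,
#' double-Boltzmann fit), and returns truth and recovered values.
#'
#' @param scheme a nonconducting `gating_scheme`; default [charge_scheme()].
#' @param protocol default [gating_protocol()].
#' @param cell default [study_cell()] (noiseless).
#' @param cap_range capacitance regression window, mV.
#' @return list (fit, qv, C_lin_hat, C_lin_true, truth).
#' @export
charge_recovery_run <- function(scheme = charge_scheme(),
                                protocol = gating_protocol(),
                                cell = study_cell(), cap_range = c(50, 70)) {
  sweeps <- simulate_sweeps(scheme, protocol, cell)
  qraw <- off_charges(sweeps)
  cap <- estimate_linear_capacitance(qraw, fit_range = cap_range)
  qv <- subtract_linear(qraw, cap$C_lin, V_tail = protocol$V_tail)
  fit <- fit_double_boltzmann(qv)
  tr <- scheme$transitions
  kT <- phys_constants(scheme$temperature_K)$kT_mV
  Vd_t <- kT / tr$z_t * log(tr$k0b / tr$k0f)
  list(fit = fit, qv = qv, C_lin_hat = cap$C_lin, C_lin_true = cell$C_lin,
       truth = list(f1 = tr$z_t[1] / sum(tr$z_t), V1 = Vd_t[1],
                    z1 = tr$z_t[1], V2 = Vd_t[2], z2 = tr$z_t[2]))
}
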