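#' P/N leak and capacitance subtraction
#'
#' Removes linear membrane components from a test sweep family using its
#' P/N companion: for each test step, the `n` subsweep responses (each
#' evoked by 1/`n` of the test excursion) are summed, scaled by the
#' subpulse sign, and subtracted from the test sweep.  Any purely linear
#' current (ohmic leak, linear capacitive transient) cancels exactly in
#' the noiseless limit; channel currents, which do not scale linearly
#' with voltage, survive.
#'
#' @param test `sweep_set` from the test protocol.
#' @param sub `sweep_set` from [p_over_n_subpulses()] (contains `n`
#'   subsweeps per test step).
#' @param n number of subpulses; defaults to the companion protocol's
#'   `n_repeats`.
#' @return a `sweep_set` of leak-subtracted traces (one per test step).
#' @export
p_over_n_subtract <- function(test, sub, n = sub$protocol$n_repeats) {
  if (length(test$time) != length(sub$time) ||
      max(abs(test$time - sub$time)) > 1e-9)
    stop("mismatched protocols: test and subpulse time bases differ")
  n_steps <- length(test$protocol$step_voltages)
  if (length(sub$step_voltages) != n_steps * n)
    stop("mismatched protocols: expected ", n, " subsweeps per test step")
  pn <- attr(sub$protocol, "pn")
  scale_sign <- if (!is.null(pn)) pn$scale_sign else 1
  # mean alignment over the pre-step segment: subpulses may run from a
  # different (hyperpolarized) holding level, leaving a DC leak offset
  # that must not survive the subtraction
  pre_idx <- test$time < test$protocol$pre_duration  # switch sample excluded
  out <- matrix(0, length(test$time), n_steps)
  for (s in seq_len(n_steps)) {
    test_cols <- which(test$step_voltages == test$protocol$step_voltages[s])
    sub_cols <- seq.int((s - 1L) * n + 1L, s * n)
    test_trace <- rowMeans(test$I[, test_cols, drop = FALSE])
    sub_sum <- scale_sign * rowSums(sub$I[, sub_cols, drop = FALSE])
    out[, s] <- (test_trace - mean(test_trace[pre_idx])) -
      (sub_sum - mean(sub_sum[pre_idx]))
  }
  structure(list(time = test$time, I = out,
                 step_voltages = test$protocol$step_voltages,
                 repeat_index = rep(1L, n_steps),
                 protocol = test$protocol,
                 meta = c(test$meta, list(leak_subtracted = TRUE))),
            class = "sweep_set")
}

#' Tail-current amplitude in a post-switch window
#'
#' Mean current over `[t_switch + window[1], t_switch + window[2]]` ms
#' minus the fully-deactivated baseline, estimated as the mean of the
#' final `baseline_frac` of the tail segment.  The 2-4 ms default window
#' is the conventional readout for normalized tail-current G-V curves.
#'
#' @param time time base, ms.
#' @param trace current trace, uA.
#' @param t_switch time of the step->tail voltage switch, ms.
#' @param window two-element window relative to `t_switch`, ms.
#' @param t_end end of the tail segment, ms; default: end of trace.
#' @param baseline_frac final fraction of the tail used as baseline.
#' @return amplitude, uA (signed).
#' @export
extract_tail_amplitude <- function(time, trace, t_switch, window = c(2, 4),
                                   t_end = max(time), baseline_frac = 0.1) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  if (t_switch + window[2] > max(time) + 1e-9)
    stop("tail window exceeds trace")
  win <- time >= t_switch + window[1] & time <= t_switch + window[2]
  base <- time >= t_end - baseline_frac * (t_end - t_switch) & time <= t_end
  mean(trace[win]) - mean(trace[base])
}

#' G-V curve from normalized tail currents
#'
#' Extracts the tail amplitude of every step (all tails at the common
#' repolarization potential, so amplitude is proportional to open
#' probability at the end of the step) and normalizes by the largest
#' absolute amplitude.
#'
#' @param sweeps leak-subtracted `sweep_set`.
#' @param window tail window relative to the switch, ms.
#' @return a `gv_curve`: data.frame (voltage, g, sd, n) with attributes
#'   `method = "tail"`.
#' @export
gv_from_tails <- function(sweeps, window = c(2, 4)) {
  pr <- sweeps$protocol
  ts <- tail_switch_time(pr)
  amps <- vapply(seq_len(ncol(sweeps$I)), function(j)
    extract_tail_amplitude(sweeps$time, sweeps$I[, j], ts, window), 0)
  # expression check: the largest amplitude must exceed what measurement
  # noise alone would produce (noise estimated from the pre-step segment)
  pre <- sweeps$time < pr$pre_duration
  n_win <- sum(sweeps$time >= ts + window[1] & sweeps$time <= ts + window[2])
  noise_amp <- if (sum(pre) > 2)
    stats::sd(sweeps$I[pre, ]) * sqrt(1 / max(n_win, 1) + 1 / max(sum(pre), 1))
  else 0
  if (max(abs(amps)) < max(5 * noise_amp, 1e-9))
    stop("no expression: all tail amplitudes within noise")
  ref <- amps[which.max(abs(amps))]
  g <- amps / ref
  out <- data.frame(voltage = sweeps$step_voltages, g = g,
                    sd = NA_real_, n = 1L)
  structure(out, class = c("gv_curve", "data.frame"), method = "tail")
}

#' G-V curve from chord conductance
#'
#' `G(V) = I_ss(V) / (V - Vrev)` using the steady-state current at the end
#' of each test step (mean of the last `ss_frac` of the step), normalized
#' to the maximum.  Used where rapid deactivation makes tail amplitudes
#' unreliable (e.g. strongly destabilized ester variants).  Steps within
#' `exclude_mV` of the reversal potential are dropped.
#'
#' @param sweeps leak-subtracted `sweep_set`.
#' @param Vrev reversal potential, mV (0 for symmetric high-K recording).
#' @param exclude_mV half-width of the excluded band around `Vrev`.
#' @param ss_frac final fraction of the step averaged as steady state.
#' @return a `gv_curve` with `method = "chord"`.
#' @export
gv_from_chord <- function(sweeps, Vrev = 0, exclude_mV = 5, ss_frac = 0.1) {
  pr <- sweeps$protocol
  t0 <- pr$pre_duration
  t1 <- tail_switch_time(pr)
  keep <- abs(sweeps$step_voltages - Vrev) > exclude_mV
  if (!any(keep)) stop("all steps within the excluded band around Vrev")
  # strictly before the switch: the boundary sample is already the tail
  win <- sweeps$time >= t1 - ss_frac * (t1 - t0) & sweeps$time < t1
  iss <- colMeans(sweeps$I[win, , drop = FALSE])
  g <- iss[keep] / (sweeps$step_voltages[keep] - Vrev)
  g <- g / max(abs(g)) * sign(g[which.max(abs(g))])
  out <- data.frame(voltage = sweeps$step_voltages[keep], g = g,
                    sd = NA_real_, n = 1L)
  structure(out, class = c("gv_curve", "data.frame"), method = "chord")
}

#' Fit a single Boltzmann to a G-V (or single-component Q-V) curve
#'
#' Least-squares fit of `G(V) = Gmax / (1 + exp(-z F (V - Vd) / RT))`.
#' Initialization: `Vd` from the interpolated half-maximum voltage and `z`
#' from the maximum slope of the normalized curve (for a Boltzmann the
#' peak slope is `z / (4 kT)`).  Non-convergence is reported through the
#' `converged` flag rather than an error.
#'
#' @param curve a `gv_curve` or data.frame with `voltage` and `g`.
#' @param temperature_K temperature, K.
#' @param weights optional per-point weights.
#' @return a `boltzmann_fit`: list (Gmax, Vd, z, residual, converged).
#' @export
fit_boltzmann <- function(curve, temperature_K = 295.15, weights = NULL) {
  V <- curve$voltage; g <- curve$g
  if (length(V) < 5L) stop("need at least 5 points to fit")
  kT <- phys_constants(temperature_K)$kT_mV
  gmax0 <- max(g)
  gn <- g / gmax0
  i_half <- which.min(abs(gn - 0.5))
  Vd0 <- stats::approx(gn[order(gn)], V[order(gn)], xout = 0.5,
                       ties = mean)$y
  if (is.na(Vd0)) Vd0 <- V[i_half]
  slope <- max(diff(gn) / diff(V))
  z0 <- max(min(4 * kT * slope, 10), 0.3)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      g ~ Gmax / (1 + exp(-z * (voltage - Vd) / kT)),
      data = data.frame(voltage = V, g = g, kT = kT),
      start = list(Gmax = gmax0, z = z0, Vd = Vd0),
      weights = if (is.null(weights)) rep(1, length(V)) else weights,
      lower = c(Gmax = 0, z = 1e-3, Vd = min(V) - 50),
      upper = c(Gmax = Inf, z = 50, Vd = max(V) + 50),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(Gmax = NA_real_, Vd = NA_real_, z = NA_real_,
                          residual = NA_real_, converged = FALSE,
                          temperature_K = temperature_K),
                     class = "boltzmann_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(Gmax = unname(cf["Gmax"]), Vd = unname(cf["Vd"]),
                 z = unname(cf["z"]),
                 residual = sqrt(sum(stats::resid(fit)^2)),
                 converged = fit$convInfo$isConv,
                 temperature_K = temperature_K),
            class = "boltzmann_fit")
}

#' Gating free-energy perturbation between two Boltzmann fits
#'
#' `ddG = (z F Vd)_aa - (z F Vd)_ah` in kcal/mol, with `F` = 23.061
#' kcal mol^-1 V^-1 and `Vd` in volts: the chemical (zero-voltage) free
#' energy of activation of the amide (amino acid, "aa") construct minus
#' that of the ester (alpha-hydroxy, "ah") variant.  A negative value
#' means the ester destabilizes the activated/open conformation.
#'
#' @param fit_aa `boltzmann_fit` for the amide (control) construct.
#' @param fit_ah `boltzmann_fit` for the ester variant.
#' @param label_aa,label_ah labels carried into the result.
#' @return a `delta_delta_g`: list (value, term_aa, term_ah, labels),
#'   kcal/mol.
#' @export
delta_delta_g <- function(fit_aa, fit_ah, label_aa = "aa", label_ah = "ah") {
  if (!isTRUE(fit_aa$converged) || !isTRUE(fit_ah$converged))
    stop("delta_delta_g requires converged Boltzmann fits")
  Fk <- phys_constants()$F_kcal
  term_aa <- fit_aa$z * Fk * (fit_aa$Vd / 1000)
  term_ah <- fit_ah$z * Fk * (fit_ah$Vd / 1000)
  structure(list(value = term_aa - term_ah, term_aa = term_aa,
                 term_ah = term_ah, label_aa = label_aa,
                 label_ah = label_ah),
            class = "delta_delta_g")
}

#' Single-exponential tail (deactivation) fit
#'
#' Fits `I(t) = A exp(-(t - t_start) / tau) + b` to the tail segment,
#' starting `blank` ms after the voltage switch to skip the clamp-settling
#' transient.  The reciprocal of `tau` estimates the deactivation rate at
#' the tail potential.  Non-decaying traces yield `converged = FALSE`.
#'
#' @param time time base, ms.
#' @param trace current trace, uA.
#' @param t_start time of the switch into the tail, ms.
#' @param t_end end of the fit window, ms; default end of trace.
#' @param blank initial blanked interval after the switch, ms.
#' @return an `exp_fit`: list (A, tau, b, window, converged).
#' @export
fit_exponential_tail <- function(time, trace, t_start, t_end = max(time),
                                 blank = 0.3) {
  idx <- time >= t_start + blank & time <= t_end
  tt <- time[idx] - (t_start + blank)
  y <- trace[idx]
  if (length(tt) < 5L) stop("tail window too short to fit")
  b0 <- mean(y[tt >= 0.9 * max(tt)])
  A0 <- y[1L] - b0
  span <- abs(A0)
  if (span < 1e-12 || stats::sd(y) < 1e-15) {
    return(structure(list(A = NA_real_, tau = NA_real_, b = b0,
                          window = c(t_start + blank, t_end),
                          converged = FALSE), class = "exp_fit"))
  }
  # tau guess: time to decay to 1/e of the initial amplitude
  frac <- (y - b0) / A0
  below <- which(frac < exp(-1))
  tau0 <- if (length(below)) max(tt[below[1L]], 1e-3) else max(tt) / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-tt / tau) + b,
                      data = data.frame(tt = tt, y = y),
                      start = list(A = A0, tau = tau0, b = b0),
                      lower = c(A = -Inf, tau = 1e-6, b = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$convInfo$isConv ||
      stats::coef(fit)["tau"] <= 0) {
    return(structure(list(A = NA_real_, tau = NA_real_, b = b0,
                          window = c(t_start + blank, t_end),
                          converged = FALSE), class = "exp_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(A = unname(cf["A"]), tau = unname(cf["tau"]),
                 b = unname(cf["b"]),
                 window = c(t_start + blank, t_end),
                 converged = TRUE), class = "exp_fit")
}
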