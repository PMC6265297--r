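#' Integrate OFF-transient gating charge
#'
#' Integrates `I - baseline` over the OFF (repolarization) window with the
#' trapezoid rule; the baseline is the mean of the final `baseline_frac`
#' of the tail segment, where the transient has fully decayed.  With
#' current in uA and time in ms the integral is in nC.
#'
#' @param time time base, ms.
#' @param trace current trace, uA.
#' @param off_window two-element c(start, end) of the OFF window, ms.
#' @param t_tail_end end of the tail segment used for the baseline;
#'   default: end of trace.
#' @param baseline_frac final fraction of the tail used as baseline.
#' @param noise_sd if supplied, warns when the current at the window end
#'   has not returned to within `3 * noise_sd` of baseline (truncated
#'   transient).
#' @return charge, nC (signed).
#' @export
integrate_off_charge <- function(time, trace, off_window,
                                 t_tail_end = max(time),
                                 baseline_frac = 0.2, noise_sd = NULL) {
  stopifnot(length(off_window) == 2L, off_window[2] > off_window[1])
  base_win <- time >= t_tail_end - baseline_frac * (t_tail_end - off_window[1])
  baseline <- mean(trace[base_win & time <= t_tail_end])
  idx <- time >= off_window[1] & time <= off_window[2]
  if (sum(idx) < 2L) stop("off_window contains fewer than 2 samples")
  if (!is.null(noise_sd)) {
    i_end <- trace[max(which(idx))]
    if (abs(i_end - baseline) > 3 * max(noise_sd, 1e-12))
      warning("OFF transient not decayed at window end; charge underestimated")
  }
  pracma::trapz(time[idx], trace[idx] - baseline)
}

#' Raw OFF charge for every step of a sweep family
#'
#' Convenience wrapper: integrates the OFF transient of each
#' (leak-subtracted or raw) sweep over the tail segment, after an optional
#' post-switch blank, and returns charge with the sign convention that
#' charge moved outward during the step is positive (the OFF integral is
#' negated).
#'
#' @param sweeps a `sweep_set`.
#' @param blank interval skipped after the switch, ms (0 keeps the full
#'   transient, required for exact linear-capacitance accounting).
#' @param baseline_frac final fraction of the tail used as baseline.
#' @return data.frame (voltage, Q_raw) with Q in nC.
#' @export
off_charges <- function(sweeps, blank = 0, baseline_frac = 0.2) {
  pr <- sweeps$protocol
  ts <- tail_switch_time(pr)
  t_end <- ts + pr$tail_duration
  Q <- vapply(seq_len(ncol(sweeps$I)), function(j)
    -integrate_off_charge(sweeps$time, sweeps$I[, j],
                          c(ts + blank, t_end), t_tail_end = t_end,
                          baseline_frac = baseline_frac), 0)
  data.frame(voltage = sweeps$step_voltages, Q_raw = Q)
}

#' Estimate linear membrane capacitance from the Q-V saturation limb
#'
#' At strongly depolarized steps the gating charge is saturated, so the
#' raw integrated OFF charge grows linearly in voltage with slope equal to
#' the linear membrane capacitance.  Ordinary least-squares regression of
#' raw charge on step voltage over `fit_range` (conventionally +50 to
#' +70 mV) yields the capacitance; nC per mV corresponds to uF, so the
#' slope is scaled by 1000 to report nF.
#'
#' @param qraw data.frame (voltage, Q_raw) from [off_charges()].
#' @param fit_range two-element voltage range, mV.
#' @param sat_tol warn if the regression residuals show curvature larger
#'   than this fraction of the fitted span (unsaturated gating charge).
#' @return list (C_lin in nF, intercept in nC, n_points).
#' @export
estimate_linear_capacitance <- function(qraw, fit_range = c(50, 70),
                                        sat_tol = 0.01) {
  idx <- qraw$voltage >= fit_range[1] & qraw$voltage <= fit_range[2]
  if (sum(idx) < 3L) stop("need >= 3 points inside fit_range")
  fit <- stats::lm(Q_raw ~ voltage, data = qraw[idx, ])
  res <- stats::resid(fit)
  # curvature relative to the fitted linear span flags unsaturated gating
  # charge leaking into the regression window
  span <- abs(stats::coef(fit)["voltage"]) * diff(range(qraw$voltage[idx])) + 1e-12
  if (max(abs(res)) / span > sat_tol)
    warning("nonlinear residuals in the capacitance fit range: gating charge may not be saturated")
  list(C_lin = unname(stats::coef(fit)["voltage"]) * 1000,
       intercept = unname(stats::coef(fit)[1L]),
       n_points = sum(idx))
}

#' Subtract linear capacitance to isolate nonlinear gating charge
#'
#' `Q(V) = Q_raw(V) - C_lin * (V - V_tail) / 1000` (nF * mV = pC, hence
#' the 1000), then normalized.  If the largest nonlinear charge falls
#' below `negligible_nC` the curve is flagged as a negative control
#' (no voltage-sensor expression).
#'
#' @param qraw data.frame (voltage, Q_raw).
#' @param C_lin linear capacitance, nF.
#' @param V_tail repolarization potential the OFF transient relaxes to, mV.
#' @param normalize "fit" (divide by a fitted single-Boltzmann Qmax,
#'   robust at a noisy saturated limb) or "max".
#' @param negligible_nC threshold for the negligible-charge flag.
#' @return a `qv_curve`: data.frame (voltage, Q_raw, Q, Q_norm) with
#'   attributes `C_lin`, `negligible`.
#' @export
subtract_linear <- function(qraw, C_lin, V_tail, normalize = c("fit", "max"),
                            negligible_nC = 1e-3) {
  normalize <- match.arg(normalize)
  Q <- qraw$Q_raw - C_lin * (qraw$voltage - V_tail) / 1000
  Q <- Q - min(Q)
  negligible <- max(abs(Q)) < negligible_nC
  Qmax <- max(abs(Q))
  if (!negligible && normalize == "fit") {
    bf <- tryCatch(
      fit_boltzmann(data.frame(voltage = qraw$voltage, g = Q)),
      error = function(e) NULL)
    if (!is.null(bf) && isTRUE(bf$converged) && bf$Gmax > 0)
      Qmax <- bf$Gmax
  }
  out <- data.frame(voltage = qraw$voltage, Q_raw = qraw$Q_raw, Q = Q,
                    Q_norm = if (negligible) Q * 0 else Q / Qmax)
  structure(out, class = c("qv_curve", "data.frame"), C_lin = C_lin,
            negligible = negligible)
}

#' Fit a double Boltzmann to a Q-V curve
#'
#' Least-squares fit of
#' `Q(V) = Q0 + Qmax [ f1 / (1 + exp(-z1 F (V - V1)/RT)) +
#'                    (1 - f1) / (1 + exp(-z2 F (V - V2)/RT)) ]`,
#' the standard description of gating charge moving in two sequential
#' steps (fractions `f1` and `1 - f1` centered at `V1 < V2`).  Two
#' nuisance terms reflect how measured Q-V curves are constructed: the
#' free offset `Q0` accounts for the curve being relative to the charge
#' already moved at the holding/repolarization level, and the floating
#' linear component `a (V - Vc)` absorbs any residual linear capacitance
#' left by an imperfect capacitance estimate (both are ~0 for clean
#' data).  Identifiability safeguards: midpoints are constrained near
#' the measured voltage range and valences to [0.5, 10] e0 -- a
#' "component" shallower than 0.5 e0 cannot be told apart from linear
#' background over a 250 mV window.
#' The fit is run from several starting midpoint pairs spaced over the
#' observed voltage quantiles and the best residual is kept; components
#' are reported in `V1 < V2` order.
#'
#' @param qv a `qv_curve` or data.frame with `voltage` and `Q_norm` (or
#'   `Q`).
#' @param temperature_K temperature, K.
#' @param n_starts number of multi-start midpoint pairs.
#' @return a `double_boltzmann_fit`: list (Qmax, f1, V1, z1, V2, z2,
#'   residual, converged).
#' @export
fit_double_boltzmann <- function(qv, temperature_K = 295.15, n_starts = 5L) {
  V <- qv$voltage
  y <- if (!is.null(qv$Q_norm)) qv$Q_norm else qv$Q
  if (length(V) < 8L) stop("need at least 8 points to fit")
  kT <- phys_constants(temperature_K)$kT_mV
  qs <- stats::quantile(V, probs = seq(0.15, 0.85, length.out = n_starts + 1L))
  Vc <- mean(range(V))
  model <- function(p, V)
    p["Q0"] + p["a"] * (V - Vc) + p["Qmax"] *
      (p["f1"] / (1 + exp(-p["z1"] * (V - p["V1"]) / kT)) +
       (1 - p["f1"]) / (1 + exp(-p["z2"] * (V - p["V2"]) / kT)))
  # identifiability bounds: a midpoint far outside the measured voltage
  # range cannot be distinguished from baseline/offset, and physical
  # gating components carry no more than a few elementary charges
  lower <- c(Qmax = 0, f1 = 0, V1 = min(V) - 30, z1 = 0.5,
             V2 = min(V) - 30, z2 = 0.5, Q0 = -Inf, a = -Inf)
  upper <- c(Qmax = Inf, f1 = 1, V1 = max(V) + 30, z1 = 10,
             V2 = max(V) + 30, z2 = 10, Q0 = Inf, a = Inf)
  # data-driven starts: candidate midpoints where the normalized curve
  # crosses fixed levels, f1 from the curve level between them
  yn <- (y - min(y)) / (max(y) - min(y) + 1e-12)
  cross <- function(level) {
    i <- which(yn >= level)[1L]
    if (is.na(i) || i == 1L) V[1L] else V[i]
  }
  starts <- lapply(seq_len(n_starts), function(k)
    c(V1 = unname(qs[k]), V2 = unname(qs[k + 1L]), f1 = 0.5))
  for (lv in list(c(0.2, 0.8), c(0.15, 0.6), c(0.4, 0.9))) {
    v1 <- cross(lv[1]); v2 <- cross(lv[2])
    if (v2 > v1) {
      gap <- yn[which.min(abs(V - (v1 + v2) / 2))]
      starts[[length(starts) + 1L]] <- c(V1 = v1, V2 = v2,
                                         f1 = min(max(gap, 0.05), 0.95))
    }
  }
  best <- NULL
  for (k in seq_along(starts)) {
    st <- c(Qmax = max(y), f1 = unname(starts[[k]]["f1"]),
            V1 = unname(starts[[k]]["V1"]), z1 = 1.5,
            V2 = unname(starts[[k]]["V2"]), z2 = 1.5, Q0 = 0, a = 0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = function(p) model(p, V) - y,
                         control = minpack.lm::nls.lm.control(maxiter = 500,
                                                             maxfev = 5000)),
      error = function(e) NULL)
    if (is.null(fit) || !(fit$info %in% 1:3)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(coef = fit$par, rss = rss)
  }
  if (is.null(best)) {
    return(structure(list(Qmax = NA_real_, f1 = NA_real_, V1 = NA_real_,
                          z1 = NA_real_, V2 = NA_real_, z2 = NA_real_,
                          Q0 = NA_real_, residual = NA_real_,
                          converged = FALSE),
                     class = "double_boltzmann_fit"))
  }
  cf <- best$coef
  f1 <- unname(cf["f1"]); V1 <- unname(cf["V1"]); z1 <- unname(cf["z1"])
  V2 <- unname(cf["V2"]); z2 <- unname(cf["z2"])
  if (V2 < V1) {  # ordering convention: component 1 is hyperpolarized
    tmp <- c(V1, z1, f1)
    V1 <- V2; z1 <- z2; f1 <- 1 - f1
    V2 <- tmp[1L]; z2 <- tmp[2L]
  }
  structure(list(Qmax = unname(cf["Qmax"]), f1 = f1, V1 = V1, z1 = z1,
                 V2 = V2, z2 = z2, Q0 = unname(cf["Q0"]),
                 a = unname(cf["a"]),
                 residual = sqrt(best$rss), converged = TRUE),
            class = "double_boltzmann_fit")
}

#' ON/OFF charge-conservation report
#'
#' For each step, integrates the gating transient during the step (ON) and
#' after repolarization (OFF) and reports the ratio `|Q_on / Q_off|`; in a
#' conservative gating model the sensor returns all its charge, so the
#' ratio is 1.  Ratios deviating by more than `tol` are flagged (e.g.
#' truncated OFF windows).  Steps with negligible charge are reported as
#' `NA` with `applicable = FALSE`.
#'
#' @param sweeps nonconducting `sweep_set` (leak-subtracted or
#'   artifact-free).
#' @param tol flag threshold on `|ratio - 1|`.
#' @param negligible_nC charge magnitude below which the ratio is not
#'   computed.
#' @return data.frame (voltage, Q_on, Q_off, ratio, flagged, applicable).
#' @export
charge_conservation_report <- function(sweeps, tol = 0.1,
                                       negligible_nC = 1e-4) {
  pr <- sweeps$protocol
  t_on0 <- pr$pre_duration
  ts <- tail_switch_time(pr)
  t_end <- ts + pr$tail_duration
  res <- lapply(seq_len(ncol(sweeps$I)), function(j) {
    tr <- sweeps$I[, j]
    # common baseline from the pre-step segment (input is assumed
    # leak-subtracted / artifact-free, so the settled current at hold is
    # the true zero); using the end-of-step mean instead would absorb the
    # slow tail of the ON transient into the baseline.
    baseline <- mean(tr[sweeps$time < t_on0])
    # ON window ends strictly before the repolarization switch: the
    # boundary sample already carries the OFF transient
    on_idx <- sweeps$time >= t_on0 & sweeps$time < ts
    Q_on <- pracma::trapz(sweeps$time[on_idx], tr[on_idx] - baseline)
    off_idx <- sweeps$time >= ts & sweeps$time <= t_end
    Q_off <- pracma::trapz(sweeps$time[off_idx], tr[off_idx] - baseline)
    applicable <- abs(Q_on) > negligible_nC && abs(Q_off) > negligible_nC
    ratio <- if (applicable) abs(Q_on / Q_off) else NA_real_
    data.frame(voltage = sweeps$step_voltages[j], Q_on = Q_on,
               Q_off = Q_off, ratio = ratio,
               flagged = applicable && abs(ratio - 1) > tol,
               applicable = applicable)
  })
  do.call(rbind, res)
}
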