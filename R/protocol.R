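#' Voltage-step protocol
#'
#' Describes a standard activation/gating-current protocol: hold, a
#' pre-pulse segment at the holding potential, a family of test steps, and
#' a fixed-voltage tail (repolarization) segment.  Defaults follow common
#' two-electrode voltage-clamp practice for Shaker-type channels: hold
#' -80 or -100 mV, test steps spanning -150..+100 mV, 30 ms test pulses,
#' 10 kHz sampling.
#'
#' @param V_hold holding potential, mV.
#' @param step_voltages test-step voltages, mV, strictly increasing.
#' @param step_duration test-pulse length, ms.
#' @param V_tail tail (repolarization) potential, mV.
#' @param tail_duration tail length, ms.
#' @param pre_duration pre-pulse at `V_hold` before the step, ms.
#' @param sample_rate sampling rate, kHz.
#' @param n_repeats sweeps acquired per step voltage (used by P/N
#'   companion protocols).
#' @return a `voltage_protocol`.
#' @export
voltage_protocol <- function(V_hold = -80,
                             step_voltages = seq(-150, 100, by = 10),
                             step_duration = 30, V_tail = -50,
                             tail_duration = 30, pre_duration = 5,
                             sample_rate = 10, n_repeats = 1L) {
  stopifnot(step_duration > 0, tail_duration > 0, pre_duration >= 0,
            sample_rate > 0, n_repeats >= 1L)
  if (is.unsorted(step_voltages, strictly = TRUE))
    stop("step_voltages must be strictly increasing")
  structure(list(V_hold = V_hold, step_voltages = step_voltages,
                 step_duration = step_duration, V_tail = V_tail,
                 tail_duration = tail_duration, pre_duration = pre_duration,
                 sample_rate = sample_rate, n_repeats = as.integer(n_repeats)),
            class = "voltage_protocol")
}

# Per-step segment table (voltage, duration) for one test step.
protocol_segments <- function(protocol, step_index) {
  V_step <- protocol$step_voltages[step_index]
  data.frame(
    V = c(protocol$V_hold, V_step, protocol$V_tail),
    duration = c(protocol$pre_duration, protocol$step_duration,
                 protocol$tail_duration)
  )
}

#' Time of the step-to-tail voltage switch
#'
#' Milliseconds from sweep start at which the test step ends and the
#' repolarization (tail) segment begins; the reference point for tail
#' windows and OFF-transient integration.
#'
#' @param protocol a `voltage_protocol`.
#' @return time, ms.
#' @export
tail_switch_time <- function(protocol) {
  protocol$pre_duration + protocol$step_duration
}

#' P/N leak-subtraction companion protocol
#'
#' Builds the subpulse protocol for P/N (classically P/8) leak and
#' capacitance subtraction: for each test step, `n` subsweeps are acquired
#' whose excursion from the subpulse holding level is 1/`n` of the test
#' excursion.  Because membrane leak and linear capacitance scale linearly
#' with voltage, the summed subsweep responses reproduce the linear
#' component of the test sweep and can be subtracted, leaving channel
#' current only.
#'
#' @param protocol the test `voltage_protocol`.
#' @param n number of subpulses (8 for P/8), >= 1.
#' @param scale_sign +1 for subpulses in the same direction as the test
#'   excursion, -1 for inverted ("P/-n") subpulses.
#' @param V_sub_hold holding level for the subpulses; defaults to the test
#'   protocol's holding potential.
#' @return a `voltage_protocol` with `n_repeats = n` and an `pn` attribute
#'   recording `n`, `scale_sign`, and the parent step voltages.
#' @export
p_over_n_subpulses <- function(protocol, n = 8L, scale_sign = 1,
                               V_sub_hold = protocol$V_hold) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  stopifnot(scale_sign %in% c(-1, 1))
  exc <- (protocol$step_voltages - protocol$V_hold) / n * scale_sign
  # built directly: subpulse voltages track the test-step ordering, which
  # is decreasing when scale_sign = -1
  sub <- structure(list(V_hold = V_sub_hold,
                        step_voltages = V_sub_hold + exc,
                        step_duration = protocol$step_duration,
                        V_tail = V_sub_hold,
                        tail_duration = protocol$tail_duration,
                        pre_duration = protocol$pre_duration,
                        sample_rate = protocol$sample_rate,
                        n_repeats = n),
                   class = "voltage_protocol")
  attr(sub, "pn") <- list(n = n, scale_sign = scale_sign,
                          test_steps = protocol$step_voltages)
  sub
}
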