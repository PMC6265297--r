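#' Gating schemes: Markov-state models of voltage-sensor movement
#'
#' A `gating_scheme` describes channel gating as a continuous-time Markov
#' chain whose transition rates depend exponentially on voltage (Eyring
#' form).  Each transition `j -> j+1` carries `z_t` elementary charges
#' across the membrane field, split between the forward and backward rate
#' by the fraction `delta`:
#'
#'   k_f(V) = k0f * exp( z_t * delta       * V / kT),
#'   k_b(V) = k0b * exp(-z_t * (1 - delta) * V / kT),
#'
#' with `kT = RT/F` in mV.  The per-transition equilibrium midpoint is
#' `Vd_t = (kT / z_t) * log(k0b / k0f)`.
#'
#' @name gating_scheme
NULL

new_gating_scheme <- function(states, transitions, open_states, N, gamma,
                              Vrev, conducting, temperature_K = 295.15) {
  stopifnot(length(states) >= 2L, all(open_states %in% states))
  structure(list(
    states = states,
    transitions = transitions,   # data.frame: from, to, z_t, k0f, k0b, delta
    open_states = open_states,
    N = N, gamma = gamma, Vrev = Vrev,
    conducting = conducting,
    temperature_K = temperature_K
  ), class = "gating_scheme")
}

#' Build a two-state gating scheme with a prescribed Boltzmann G-V
#'
#' Constructs a closed <-> open scheme whose equilibrium open probability is
#' exactly `1 / (1 + exp(-z F (V - Vd) / RT))`.  The kinetic reference rate
#' `k0` sets the relaxation speed at the midpoint; it does not affect the
#' equilibrium curve.
#'
#' @param z gating valence (e0 units), > 0.
#' @param Vd midpoint voltage, mV.
#' @param k0 rate at the midpoint, ms^-1, > 0.
#' @param N channel count.
#' @param gamma unitary conductance, S.
#' @param Vrev reversal potential, mV.
#' @param delta forward charge-split fraction in (0, 1).
#' @param conducting logical; `FALSE` emulates a W434F-like nonconducting
#'   channel whose voltage sensor still moves.
#' @param temperature_K temperature, K.
#' @return a `gating_scheme`.
#' @examples
#' sch <- build_two_state_scheme(z = 3.4, Vd = -25.9)
#' equilibrium_occupancies(sch, -25.9)  # 0.5 / 0.5
#' @export
build_two_state_scheme <- function(z, Vd, k0 = 1, N = 2.5e6, gamma = 2e-11,
                                   Vrev = 0, delta = 0.5, conducting = TRUE,
                                   temperature_K = 295.15) {
  if (!is.numeric(z) || z <= 0) stop("invalid parameter: z must be > 0")
  if (!is.numeric(k0) || k0 <= 0) stop("invalid parameter: k0 must be > 0")
  kT <- phys_constants(temperature_K)$kT_mV
  # choose zero-voltage rates so that k_f/k_b = exp(z (V - Vd)/kT)
  k0f <- k0 * exp(-z * delta * Vd / kT)
  k0b <- k0 * exp(z * (1 - delta) * Vd / kT)
  tr <- data.frame(from = "C", to = "O", z_t = z, k0f = k0f, k0b = k0b,
                   delta = delta, stringsAsFactors = FALSE)
  new_gating_scheme(c("C", "O"), tr, "O", N, gamma, Vrev, conducting,
                    temperature_K)
}

#' Build a sequential (linear-chain) gating scheme
#'
#' Builds an n-state chain `S1 <-> S2 <-> ... <-> Sn` from a list of
#' transitions, each given as `list(z_t=, Vd=, k0=)` (charge, equilibrium
#' midpoint in mV, midpoint rate in ms^-1) or as explicit
#' `list(z_t=, k0f=, k0b=)`.  The default three-state motif (resting,
#' intermediate, activated) emulates an S4 segment that moves in two
#' discrete steps, producing a two-component Q-V curve when the midpoints
#' are separated.
#'
#' @param transitions list of per-transition parameter lists (see above).
#' @param states optional state labels (length = transitions + 1).
#' @param open_states labels of conducting states; default: last state.
#' @param delta forward charge-split fraction applied to transitions that
#'   do not set their own.
#' @inheritParams build_two_state_scheme
#' @return a `gating_scheme`.
#' @examples
#' sch <- build_sequential_scheme(list(
#'   list(z_t = 1.0, Vd = -120, k0 = 2),
#'   list(z_t = 2.5, Vd =  +20, k0 = 1)), conducting = FALSE)
#' @export
build_sequential_scheme <- function(transitions, states = NULL,
                                    open_states = NULL, N = 1e10,
                                    gamma = 2e-11, Vrev = 0, delta = 0.5,
                                    conducting = TRUE,
                                    temperature_K = 295.15) {
  if (!length(transitions)) stop("disconnected chain: no transitions")
  kT <- phys_constants(temperature_K)$kT_mV
  n <- length(transitions) + 1L
  if (is.null(states)) {
    states <- if (n == 3L) c("R", "I", "A") else paste0("S", seq_len(n))
  }
  stopifnot(length(states) == n)
  rows <- lapply(seq_along(transitions), function(i) {
    tr <- transitions[[i]]
    if (is.null(tr$z_t) || tr$z_t <= 0)
      stop("invalid parameter: transition z_t must be > 0")
    d <- if (!is.null(tr$delta)) tr$delta else delta
    if (!is.null(tr$k0f) && !is.null(tr$k0b)) {
      k0f <- tr$k0f; k0b <- tr$k0b
    } else {
      if (is.null(tr$Vd)) stop("transition needs (Vd, k0) or (k0f, k0b)")
      k0 <- if (!is.null(tr$k0)) tr$k0 else 1
      k0f <- k0 * exp(-tr$z_t * d * tr$Vd / kT)
      k0b <- k0 * exp(tr$z_t * (1 - d) * tr$Vd / kT)
    }
    data.frame(from = states[i], to = states[i + 1L], z_t = tr$z_t,
               k0f = k0f, k0b = k0b, delta = d, stringsAsFactors = FALSE)
  })
  tr <- do.call(rbind, rows)
  if (sum(tr$z_t) <= 0) stop("total charge must be > 0")
  if (is.null(open_states)) open_states <- states[n]
  new_gating_scheme(states, tr, open_states, N, gamma, Vrev, conducting,
                    temperature_K)
}

#' Voltage-dependent transition rates
#'
#' @param scheme a `gating_scheme`.
#' @param V voltage, mV (scalar).
#' @return data.frame of transitions with columns `kf`, `kb` (ms^-1) at `V`.
#' @keywords internal
transition_rates <- function(scheme, V) {
  kT <- phys_constants(scheme$temperature_K)$kT_mV
  tr <- scheme$transitions
  tr$kf <- tr$k0f * exp(tr$z_t * tr$delta * V / kT)
  tr$kb <- tr$k0b * exp(-tr$z_t * (1 - tr$delta) * V / kT)
  if (any(!is.finite(tr$kf)) || any(!is.finite(tr$kb)))
    stop("non-finite transition rate at V = ", V, " mV")
  tr
}

#' Infinitesimal generator (rate matrix) at a voltage
#'
#' Rows sum to zero; `p'(t) = p(t) Q` with `p` a row vector of state
#' probabilities.
#'
#' @inheritParams transition_rates
#' @return square matrix, states x states.
#' @export
rate_matrix <- function(scheme, V) {
  st <- scheme$states
  Q <- matrix(0, length(st), length(st), dimnames = list(st, st))
  tr <- transition_rates(scheme, V)
  for (i in seq_len(nrow(tr))) {
    Q[tr$from[i], tr$to[i]] <- Q[tr$from[i], tr$to[i]] + tr$kf[i]
    Q[tr$to[i], tr$from[i]] <- Q[tr$to[i], tr$from[i]] + tr$kb[i]
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

#' Equilibrium state occupancies at a voltage
#'
#' For the linear chains built here, equilibrium follows from detailed
#' balance: relative weights are cumulative products of `kf/kb` along the
#' chain.
#'
#' @inheritParams transition_rates
#' @param V voltage(s), mV.
#' @return matrix, length(V) x states, rows summing to 1.
#' @export
equilibrium_occupancies <- function(scheme, V) {
  st <- scheme$states
  out <- matrix(NA_real_, length(V), length(st),
                dimnames = list(NULL, st))
  for (k in seq_along(V)) {
    tr <- transition_rates(scheme, V[k])
    w <- numeric(length(st)); names(w) <- st
    w[st[1L]] <- 1
    for (i in seq_len(nrow(tr)))
      w[tr$to[i]] <- w[tr$from[i]] * tr$kf[i] / tr$kb[i]
    out[k, ] <- w / sum(w)
  }
  out
}

#' Equilibrium open probability
#'
#' @inheritParams equilibrium_occupancies
#' @return numeric vector of Po(V).
#' @export
equilibrium_po <- function(scheme, V) {
  occ <- equilibrium_occupancies(scheme, V)
  rowSums(occ[, scheme$open_states, drop = FALSE])
}

#' Cumulative charge position of each state (e0 units)
#'
#' Charge moved to reach each state from the first state of the chain.
#'
#' @param scheme a `gating_scheme`.
#' @return named numeric vector over states.
#' @export
state_charges <- function(scheme) {
  st <- scheme$states
  q <- numeric(length(st)); names(q) <- st
  tr <- scheme$transitions
  for (i in seq_len(nrow(tr))) q[tr$to[i]] <- q[tr$from[i]] + tr$z_t[i]
  q
}

#' Equilibrium gating charge vs voltage (e0 per channel)
#'
#' `q(V) = sum_j q_j p_j(V)` with `q_j` the cumulative charge of state j;
#' saturates at the total transition charge as V -> +Inf.
#'
#' @inheritParams equilibrium_occupancies
#' @return numeric vector, e0 units per channel.
#' @export
equilibrium_charge <- function(scheme, V) {
  drop(equilibrium_occupancies(scheme, V) %*% state_charges(scheme))
}

# Propagate state probabilities over a constant-voltage segment.
# Returns occupancies at the requested times (ms, from segment start).
# Uses the eigendecomposition of the generator; the chains used here are
# small and generically diagonalizable.
propagate_segment <- function(scheme, p0, V, times) {
  Q <- rate_matrix(scheme, V)
  eg <- eigen(t(Q))
  # p(t)^T = Vr exp(L t) Vr^-1 p0^T
  Vr <- eg$vectors
  lam <- eg$values
  a <- solve(Vr, as.complex(p0))
  E <- exp(outer(lam, times))        # states x times
  out <- t(Re(Vr %*% (E * a)))       # a recycled down rows
  colnames(out) <- scheme$states
  # guard tiny negative round-off
  out[out < 0 & out > -1e-12] <- 0
  out
}

#' State-probability time courses over a voltage protocol
#'
#' Solves the master equation with piecewise-constant voltage, starting
#' from equilibrium at the holding potential and propagating each protocol
#' segment with the matrix exponential (via eigendecomposition of the
#' generator).  Probabilities stay in [0, 1] and sum to 1 to within 1e-9
#' at every sample.
#'
#' @param scheme a `gating_scheme`.
#' @param protocol a `voltage_protocol` (see [voltage_protocol()]).
#' @param step_index which test step of the protocol to run (scalar), or
#'   `NULL` to return a list over all steps.
#' @return list with `time` (ms), `voltage` (command mV per sample), and
#'   `occ` (samples x states matrix); or a list of such lists.
#' @export
occupancies <- function(scheme, protocol, step_index = NULL) {
  if (is.null(step_index)) {
    return(lapply(seq_along(protocol$step_voltages),
                  function(i) occupancies(scheme, protocol, i)))
  }
  seg <- protocol_segments(protocol, step_index)
  dt <- 1 / protocol$sample_rate
  time <- seq(0, sum(seg$duration), by = dt)
  voltage <- numeric(length(time))
  occ <- matrix(NA_real_, length(time), length(scheme$states),
                dimnames = list(NULL, scheme$states))
  p <- equilibrium_occupancies(scheme, protocol$V_hold)[1L, ]
  t0 <- 0
  eps <- dt / 2
  for (s in seq_len(nrow(seg))) {
    t1 <- t0 + seg$duration[s]
    # right-continuous: the sample at a voltage switch belongs to the new
    # segment (occupancy is continuous; rates and driving force switch)
    idx <- if (s < nrow(seg)) which(time >= t0 - eps & time < t1 - eps)
           else which(time >= t0 - eps & time <= t1 + eps)
    if (length(idx)) {
      occ[idx, ] <- propagate_segment(scheme, p, seg$V[s], time[idx] - t0)
      voltage[idx] <- seg$V[s]
    }
    p <- drop(propagate_segment(scheme, p, seg$V[s], seg$duration[s]))
    t0 <- t1
  }
  list(time = time, voltage = voltage, occ = occ)
}
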