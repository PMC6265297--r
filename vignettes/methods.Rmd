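---
title: "Models and methods behind vsgating"
author: "vsgating maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vsgating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsgating)
```

# Scope

`vsgating` re-implements, as a tested pipeline over synthetic data, the
complete analysis chain used to quantify how single backbone hydrogen
bonds contribute to voltage-sensor gating in Shaker-type potassium
channels: Markov-model simulation of two-electrode voltage-clamp (TEVC)
recordings with realistic artifacts, P/8 leak subtraction,
conductance–voltage (G–V) analysis with Boltzmann fits and
amide-vs-ester gating free energies, gating-charge (Q–V) isolation and
double-Boltzmann decomposition, deactivation kinetics, and per-residue
α/3₁₀ classification from backbone H-bond patterns with explicit
amide-to-ester (lost donor) semantics.

No raw recordings or trajectories are distributed with the package;
every analysis here runs on data the package itself generates, with
known ground truth.  What passing tests demonstrate is therefore that
the *analysis chain* is faithful — that it recovers what was put in,
under recording conditions emulating practice — not that any particular
biological value is reproduced.

# The gating model

Channel gating is a continuous-time Markov chain on a small set of
conformational states.  Each transition carries `z_t` elementary
charges across the membrane field and has Eyring-form rates

$$k_f(V) = k_{0f}\,e^{z_t \delta V / kT},\qquad
  k_b(V) = k_{0b}\,e^{-z_t (1-\delta) V / kT},$$

with the thermal voltage $kT \equiv RT/F \approx 25.4$ mV at the
default 295.15 K (22 °C, typical room-temperature oocyte recording;
recordings rarely state temperature, so it is an explicit parameter
everywhere).  The charge-split fraction $\delta$ locates the transition
barrier along the voltage coordinate; the per-transition equilibrium
midpoint is $V_d = (kT/z_t)\ln(k_{0b}/k_{0f})$, independent of
$\delta$.

Two canonical schemes define the study conditions:

* **Conducting two-state scheme** (`build_two_state_scheme`,
  `wt_like_scheme`): closed ⇌ open with the equilibrium open
  probability exactly $1/(1+e^{-z(V-V_d)/kT})$.  The wild-type-like
  truth uses the G–V parameters of the native channel
  ($z = 3.4$, $V_d = -25.9$ mV).  Kinetic parameters are not
  constrained by equilibrium data, so they were fixed once from
  qualitative physiology: $\delta = 0.8$ (barrier near the activated
  state) makes activation fast and deactivation tails relax over a few
  milliseconds at the repolarization potential, as observed for Shaker,
  and $k_0 = 0.12\ \mathrm{ms^{-1}}$ puts the slowest relaxation near
  5 ms so that 30 ms test pulses equilibrate.  The generic constructor
  default is $\delta = 0.5$.

* **Nonconducting three-state chain** (`charge_scheme`): resting ⇌
  intermediate ⇌ activated, emulating a W434F-like channel whose
  sensor moves normally but conducts nothing.  Defaults
  $z_1 = 1.0$ at $V_1 = -120$ mV and $z_2 = 2.5$ at $V_2 = -20$ mV put
  $f_1 = z_1/(z_1+z_2) = 0.286$ of the charge in the hyperpolarized
  component — the share carried by the first S4 step in wild-type
  channels — and saturate the gating charge well below the +50..+70 mV
  window used for capacitance regression (with a midpoint of +20 mV
  the residual gating slope in that window would corrupt the
  capacitance estimate by far more than its tolerance).  The asymmetric
  split $\delta_2 = 0.35$ keeps both the ON transient at +100 mV and
  the OFF transient at −100 mV on resolvable timescales
  (τ ≈ 0.05–0.1 ms).

State probabilities are propagated segment-by-segment through the
piecewise-constant protocol via the eigendecomposition of the generator
(exact for these small chains), holding probability normalization to
better than $10^{-9}$.  The sample that falls exactly on a voltage
switch is assigned to the *new* segment: occupancies are continuous but
rates and driving force are not, and this right-continuous convention
is what makes trapezoidal charge integrals start at the true initial
transient current.

# The synthetic recording

The simulated current is

$$I(t) = N P_o(t)\gamma (V - V_\mathrm{rev})
       + N e_0 \textstyle\sum_t z_t\,\mathrm{flux}_t(t)
       + C_\mathrm{lin}\dot V_\mathrm{clamp}
       + g_\mathrm{leak}(V_\mathrm{clamp} - E_\mathrm{leak})
       + \varepsilon,$$

outward positive, in µA/ms/mV/nF/µS units.  Channel kinetics follow the
command voltage, so every segment is an exact master-equation solution;
only the linear artifacts (capacitive spike, leak) follow the
RC-smoothed clamp voltage ($\tau_\mathrm{clamp}$ default 0.3 ms).  This
split keeps the propagation exact while still producing the settling
transients that motivate the 0.3 ms post-switch blank used in fits.
Noise is white Gaussian, seeded; identical configurations reproduce
traces bitwise.  The macroscopic (mean-current) approximation is
deliberate: every analysis operates on macroscopic currents, so
single-channel stochasticity would only add cost.  Whole-oocyte scale
is emulated with $N = 2.5\times 10^6$ channels of 20 pS (≈3 µA maximal
currents), $C_\mathrm{lin} = 200$ nF, $g_\mathrm{leak} = 1$ µS, and
$10^{10}$ channels for gating-current (W434F-like, high-expression)
recordings, giving ≈5.6 nC of total gating charge.

Gating-current protocols are sampled at 200 kHz rather than the 10 kHz
of ionic protocols, with 60 ms tails: the fastest OFF transients have
τ ≈ 0.05 ms, and resolving the per-step ON/OFF charge balance to 0.1%
requires several samples per time constant and complete decay before
the baseline window.  These are simulation-fidelity choices, not claims
about acquisition hardware.

# Ionic analysis

**P/8 subtraction.**  Each test step has a companion family of eight
subpulses of one-eighth the excursion; the summed subpulse response is
mean-aligned on the pre-step segment and subtracted.  Subpulses run
from a hyperpolarized holding level (−110 mV): a two-state channel with
$V_d \approx -26$ mV opens measurably at −62 mV, so subpulses taken
from the −80 mV holding potential would carry channel current scaled
eightfold into the subtraction — about a 1% distortion of the G–V top.
This is faithful to practice, where subtraction pulses are placed where
channels stay closed.  On a purely linear cell the subtraction cancels
to machine precision.

**Tail G–V.**  The tail amplitude is the *mean* current 2–4 ms after
the switch minus the fully-deactivated baseline (mean of the final 10%
of the tail).  A window mean is robust to noise; a point sample or
back-extrapolation would be fragile exactly where the method is needed
(fast-deactivating ester variants).  Amplitudes are normalized by the
largest absolute amplitude.  With a two-state truth the tail potential
matters: at −50 mV the channel retains an equilibrium open probability
of 0.038, which provably biases the recovered valence by about +10%.
The recovery benchmarks therefore repolarize to −80 mV (residual
$P_o = 7\times10^{-4}$); the choice is a property of the reduced
two-state model, not of the analysis, and the tail potential remains a
protocol parameter.

**Chord G–V.**  $G = I_{ss}/(V - V_\mathrm{rev})$ with
$V_\mathrm{rev} = 0$ (high-K recording solution) and a ±5 mV exclusion
band, for constructs whose deactivation is too fast for tail readouts.
Near the reversal potential the chord divides small constant
contamination by a small driving force, so the two methods agree to
$10^{-3}$ only on clean recordings; with artifacts the disagreement is
concentrated within ±10 mV of reversal and stays at the 1% level.

**Boltzmann fits and ΔΔG.**  $G(V) = G_\mathrm{max}/(1+e^{-z(V-V_d)/kT})$
by Levenberg–Marquardt, initialized from the interpolated half-maximum
and the maximal slope ($z_0 = 4kT\cdot\mathrm{slope}$).  The gating
perturbation of an ester substitution is
$\Delta\Delta G = (zFV_d)_{aa} - (zFV_d)_{ah}$ in kcal/mol with
$F = 23.061\ \mathrm{kcal\,mol^{-1}V^{-1}}$ — the difference in
chemical free energy of activation between the amide control and the
α-hydroxy variant.  Reported uncertainties propagate the fit standard
deviations to first order,
$\sigma(zFV_d) = F\sqrt{V_d^2\sigma_z^2 + z^2\sigma_{V_d}^2}$, combined
in quadrature across the pair; this is a convention choice, stated
because error propagation through the product is not unique.

**Deactivation.**  Tails are fit to a single exponential starting
0.3 ms after the switch (clamp settling blank).  Non-decaying traces
yield a flagged non-convergence, never a fabricated time constant.

# Gating-charge analysis

The OFF (repolarization) transient is integrated by the trapezoid rule
relative to a baseline from the final 20% of the tail.  Raw OFF charge
grows linearly with step voltage once gating charge saturates, so
ordinary least squares over +50..+70 mV estimates the linear membrane
capacitance, whose contribution $C_\mathrm{lin}(V - V_\mathrm{tail})$
is then subtracted to leave nonlinear gating charge.  A curvature check
on the regression residuals warns when gating charge is detectably
unsaturated in the window.

The Q–V curve is decomposed as

$$Q(V) = Q_0 + a(V - V_c) + Q_\mathrm{max}\left[
  \frac{f_1}{1+e^{-z_1(V-V_1)/kT}} +
  \frac{1-f_1}{1+e^{-z_2(V-V_2)/kT}}\right],$$

components reported with $V_1 < V_2$.  Two nuisance terms reflect how
measured Q–V curves are constructed: $Q_0$ because the curve is
relative to the charge already moved at the holding level (charge below
the most hyperpolarized step is invisible to the protocol), and the
floating linear term $a$ because any error in the capacitance estimate
leaves a residual linear component — the +50..+70 mV regression spans
20 mV but the subtraction extrapolates across 250 mV, amplifying
per-point noise roughly ninefold.  Identifiability safeguards: the fit
is multistarted from quantile-spaced and level-crossing-derived
midpoint pairs, midpoints are bounded within ±30 mV of the measured
range, and valences within [0.5, 10] $e_0$ — a "component" shallower
than 0.5 $e_0$ cannot be distinguished from linear background over a
250 mV window.  On noiseless data the nuisance terms fit to zero and
the generator truths are recovered to better than 1%.

The noisy benchmark adds per-acquisition charge noise of 2% of the
total gating charge and averages 16 acquisitions per step (simulated as
one sweep at one-quarter noise), which is standard practice for gating
currents; without averaging, the capacitance-regression leverage makes
the pipeline as described — five regression points, 20 mV window —
unable to bound the hyperpolarized component to better than tens of
percent.  That sensitivity is a property of the method worth knowing,
not something the package hides.

Charge conservation is audited per step as $|Q_\mathrm{on}/Q_\mathrm{off}|$
against a common pre-step baseline (the report expects leak-subtracted
or artifact-free input; leak that changes with voltage would otherwise
masquerade as unreturned charge).  In noiseless simulations every
applicable step balances to better than 0.1%; steps moving negligible
charge are reported as not-applicable rather than as spurious ratios.

# Backbone structure analysis

Multi-model PDB files are parsed (via `bio3d`) into per-frame backbone
coordinate sets.  Amide hydrogens are reconstructed at 1.01 Å from N
along the bisector of the preceding carbonyl directions — the standard
geometric placement — except for prolines, chain-initial residues, and
ester sites.  The hydrogen-bond criterion is the classic electrostatic
form

$$E = 27.888\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})\ \mathrm{kcal/mol},$$

with a bond recorded when $E < -0.5$ kcal/mol.  Donors without a
hydrogen return a no-energy sentinel, never a numeric zero.  Secondary
structure follows the minimal-helix convention: two consecutive
$i{+}k \to i$ turns start a helix of class G (k = 3, 3₁₀), H (k = 4,
α), or I (k = 5, π) with overlap priority H > G > I; isolated turns
are T, the rest coil.  The trajectory-analysis criterion behind
published helical-content profiles is rarely stated; these DSSP-style
rules are declared here as the package's convention, and the 60–80%
3₁₀-occupancy band reported for activated sensors is treated as
qualitative context, not a number the package claims to reproduce.

An amide-to-ester substitution at residue X removes the backbone N–H
donor *of residue X itself* — the amide preceding X's side chain —
leaving every acceptor, including X's own carbonyl, untouched.  On an
ideal α-helix this deletes exactly the X → X−4 bond and nothing else,
which the tests assert bond-by-bond.  Ideal fixtures are built by
internal-coordinate chain extension (NeRF) with standard backbone
geometry; the α fixture measures 1.56 Å rise and 3.6 residues/turn,
the 3₁₀ fixture 2.0 Å and 3.0.  A residue-number offset map links
Shaker S4 numbering to the activated-state structural template
(363 ↔ 291, 369 ↔ 297).

# Problem sizes and determinism

The shipped benchmarks use 29–51 voltage steps per family, 10 kHz
(ionic) or 200 kHz (charge) sampling, 20 seeds for noisy recovery
averages, and 12–15-residue ideal backbones — sizes chosen so the
whole test suite and the acceptance script each complete in well under
a minute while leaving every estimate comfortably inside its
tolerance.  All randomness flows from explicit integer seeds; rerunning
any script with the same seed reproduces every output byte-for-byte.

# Known limitations

* The two-state and three-state schemes are reduced models: they
  reproduce equilibrium curves exactly but compress Shaker's
  multi-step activation into one or two kinetic steps, so simulated
  time courses are caricatures (e.g. no Cole-Moore shift, no rising
  phase in gating current).
* The generator produces white noise only; real recordings carry 50/60
  Hz pickup, drift, and endogenous currents that the pipeline is not
  tested against.
* Series-resistance error is not modeled; the clamp is ideal apart
  from single-exponential settling.
* Chord conductances inherit any DC contamination amplified near the
  reversal potential; the ±5 mV exclusion band is a mitigation, not a
  cure.
* The secondary-structure rules are a declared convention; other
  assignment schemes (dihedral-based, DSSP variants with bridge
  detection) will disagree at helix termini.
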