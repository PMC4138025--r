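---
title: "Methods: an E/I firing-rate circuit as a theta-gamma coupling generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an E/I firing-rate circuit as a theta-gamma coupling generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wcpac)
```

## The model and its assumptions

`wcpac` implements a Wilson–Cowan-type firing-rate description of one
excitatory (E) and one inhibitory (I) neural population:

$$\tau_E \dot E = -E + f(w_{EE} E - w_{IE} I + \theta_E), \qquad
  \tau_I \dot I = -I + f(w_{EI} E + \theta_I),$$

with the logistic response $f(x) = 1/(1+e^{-\beta(x-1)})$. The state
variables are population-average activities, not membrane potentials or
spikes; everything a spiking network does below the population scale
(synchrony, finite-size noise, conduction delays) is outside the model. Three
structural assumptions matter:

* **Recurrent excitation** ($w_{EE}$) is the amplification that permits
  intrinsic oscillations; the reciprocal E–I loop alone cannot destabilize
  the fixed point here. If $w_{EE} \le 1$ the top-left Jacobian entry is
  negative at every state (the sigmoid slope never exceeds 1 at $\beta=4$),
  the equilibrium is unique and stable, and the circuit never oscillates —
  a property the test suite checks over a full input grid.
* **No I→I self-connection and no refractory saturation factor.** The
  equations are the minimal two-population skeleton.
* **Spontaneous activity:** $f(0) > 0$, so zero input still yields a small
  steady activity ($E^\* \approx 0.018$, $I^\* \approx 0.021$) rather than a
  silent stable state.

Subscripts on weights read source→target: $w_{EI}$ excites I, $w_{IE}$
inhibits E. We fixed this convention deliberately: with the alternative
(target–source) reading, raising $w_{EI}$ from 2 to 2.5 *enlarges* the
oscillatory input region, whereas stronger feed-forward recruitment of
inhibition should — and under our reading does — shrink it (712 → 441
oscillatory cells on a 0.02-step input grid over $[0,2]\times[0,1]$). At the
default weights the two readings are identical.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `w_EE` | 2.4 | — | recurrent excitation; must exceed 1 for any instability |
| `w_EI` | 2 | — | E→I drive; larger values shrink the oscillatory region |
| `w_IE` | 2 | — | I→E inhibition |
| `beta` | 4 | — | sigmoid steepness; 4 makes the peak slope exactly 1 |
| `threshold` | 1 | input units | sigmoid midpoint; fixed in the reference setup |
| `tau_E`, `tau_I` | 0.0032 | s | membrane time constants; set the gamma scale |

Two time conventions coexist and every result object records which one it
uses. *Natural units* ($\tau=1$) are used for all stability and bifurcation
analysis: with $\tau_E=\tau_I$ the Jacobian rescales uniformly, so
eigenvalue signs, stability labels and Hopf locations are $\tau$-invariant
(asserted as a test). *Seconds* are used for simulation presets:
$\tau=0.0032$ s turns the natural frequency 0.176 (cycles per natural time
unit at $\theta_E=0.5$) into the 55 Hz gamma rhythm, since $0.176/0.0032
\approx 55$.

## Equilibria, stability, and the oscillation window

Setting each derivative to zero gives the two nullclines in closed form:
$I = (w_{EE}E + \theta_E - f^{-1}(E))/w_{IE}$ (an inverse sigmoid) and
$I = f(w_{EI}E + \theta_I)$ (a sigmoid). Their difference $g(E)$ is smooth
with at most five roots, so equilibria are found by sign-change bracketing
on a 10,001-point grid in $E \in [10^{-6}, 1-10^{-6}]$ followed by
`uniroot` polishing to $10^{-14}$; residuals of both fixed-point equations
stay below $10^{-10}$. Exact zeros on grid points are deduplicated (the
symmetric case $\theta_E = 0.8$ puts the equilibrium exactly at $E=1/2$),
and a root where $g$ is tangent to zero is *flagged* degenerate rather than
rejected, because tangencies occur on measure-zero parameter sets during
sweeps. Eigenvalues come from the trace/determinant closed form
$\lambda = \mathrm{tr}/2 \pm \sqrt{\mathrm{tr}^2/4 - \Delta}$ and are
cross-checked against `eigen()` to $10^{-12}$; real parts within $10^{-8}$
of zero are labelled `nonhyperbolic`, never silently classified.

With equal time constants the Hopf condition is a trace zero with positive
discriminant, equivalent to the gain condition
$w_{EE}\,\beta E^\*(1-E^\*) = 2$. This fixes
$E^\* = \tfrac12\bigl(1 \pm \sqrt{1 - 8/(\beta w_{EE})}\bigr)$ — two values
symmetric about $1/2$ — and the nullclines then give the drive level in
closed form. `find_hopf_points()` instead tracks the equilibrium
numerically and bisects $\mathrm{Re}\,\lambda(\theta)$ to $10^{-12}$ in
$\theta$; the closed form serves as the independent oracle in the tests
(agreement to $10^{-9}$). A corollary of the $E^\*$ symmetry is that the
default window on $\theta_E$ is exactly symmetric about 0.8:
$(0.399986,\,1.200014)$, summing to 1.6 to machine precision. A trace zero
with $\Delta \le \mathrm{tr}^2/4$ (real eigenvalues, a non-Hopf mechanism
possible at larger $w_{EE}$) raises an error instead of being mislabelled,
and the tracker refuses intervals on which the equilibrium is not unique —
at $w_{EI}=2.5$ the branch gains companions above $\theta_E \approx 1.37$,
where the sweep-based window estimate takes over.

## Numerical integration

The integrator is fixed-step classical RK4, written in C++ for the inner
loop, with default $dt = \tau/100$ and a hard refusal above $\tau/20$.
Halving the step changes final states by less than $10^{-6}$ across the
preset experiments (tested). The square $[0,1]^2$ is forward-invariant for
the flow and the integrator respects it to $10^{-6}$ over every preset and
random drive battery we run. Determinism is part of the contract: identical
configurations give byte-identical trajectory files (the CSV writer formats
with 10 significant digits).

Problem sizes were chosen to keep every analysis well-resolved but fast:
constant-drive sweeps integrate 600 natural time units per grid point and
discard half. The long horizon is not cosmetic: one grid step (0.01) from a
window edge the eigenvalue real part is only $\sim$0.015–0.03, so the
near-edge ring-up/ring-down needs several hundred time constants to
separate a true limit cycle from a transient; with 300 discarded units the
simulated window edges agree with the eigenvalue-located Hopf points within
one 0.01 step on both axes. Region maps use 100 units per cell (their
purpose is area comparison, not edge-precision). Oscillation frequency is
estimated from interpolated upward mean-crossings — robust to the strongly
non-sinusoidal relaxation shape of the cycles — with the spectral peak used
only as a cross-check; the amplitude threshold for "oscillating" is a
post-transient peak-to-peak of $10^{-3}$, and near the supercritical onset
the simulated window is necessarily threshold-dependent, which is why the
eigenvalue root-finder is authoritative for window edges.

## Phase–amplitude coupling measurement

The slow drive is a cosine, so phase 0° is the drive peak, the descending
phase is (0°, 180°) and the ascending phase (180°, 360°); the drive phase is
known analytically and no estimator noise enters there. The fast envelope is
obtained by zero-phase Butterworth band-pass (order 4, default 40–100 Hz)
followed by the analytic-signal magnitude. Two implementation details:

* the series is first decimated to a working rate near $8\times$ the band's
  upper edge, because a Butterworth band-pass whose pass band is a tiny
  fraction of the Nyquist frequency (40–100 Hz against a 31 kHz simulation
  rate) is numerically singular; the trajectory is smooth so plain
  subsampling is lossless in the pass band;
* the analytic signal is built directly in the frequency domain (one FFT,
  zero negative frequencies, inverse FFT).

The modulation index bins the envelope by slow phase (18 bins), normalizes
bin means to a distribution and reports its Kullback–Leibler divergence from
uniform divided by $\log n_{\mathrm{bins}}$, giving a value in $[0,1]$ that
is invariant to positive rescaling of the envelope (tested to $10^{-12}$).
Empty bins are merged clockwise and flagged. **Limitation:** scale
invariance means the index measures only phase *concentration*; a
manipulation that weakens gamma while shortening its bursts (e.g. raising
$w_{EI}$) can leave the index flat or even raise it. When coupling strength
in the amplitude sense matters, read the index together with the envelope
peak, which the report also carries.

Observed regimes are classified from gamma bursts: stretches where the
envelope exceeds half its global maximum (and an absolute floor of 0.01
separating gamma from filter leakage) for at least two gamma periods, with
sub-period dips bridged. A global threshold is used rather than per-cycle
thresholds, which would split peak-locked bursts at cycle boundaries. The
decision rules: no bursts → subthreshold following; envelope's weakest
phase bin above both the floor and 20% of the strongest bin → persistent
gamma with theta-varying mean; otherwise the circular statistics of
burst-centre phases decide — a concentrated cluster within 90° of the peak
(resp. trough) is peak-locked (resp. trough-locked), and a dispersed
first harmonic with a concentrated second harmonic marks the biphasic
pattern (two antipodal clusters near ±90°). Burst thresholds are our
operationalization of a taxonomy originally judged by eye; the
prediction/observation agreement battery (five regimes × 20 random drives)
is the evidence that it carves the space at the right joints.

The preferred phase is the envelope-weighted circular mean of the slow
phase, reported only when the modulation index clears a 0.01 noise floor,
and is computed against two references: the drive itself ("source" phase)
and the theta-filtered activity of the analysed population ("local" phase,
Hilbert). The two differ materially on the $\theta_I$ axis, where coupling
that is trough-like in window terms appears shifted toward the ascending
phase at the source — an asymmetry of the window geometry, not an estimator
artifact, and the reason regime agreement is validated on the $\theta_E$
axis.

## Randomized drive generation

`sample_regime_drive()` draws sinusoid means/amplitudes uniformly from the
set that satisfies a regime's excursion rule with at least 0.05 clearance
from the window edges. For the biphasic regime the clearance is additionally
capped at 0.25 per side: a drive that sweeps the whole window in a few
milliseconds leaves less dwell time than a gamma period on each flank, so
the fast oscillation cannot ring up and the regime physically fails to
express — a genuine property of slow passage through a Hopf bifurcation,
not a classifier shortcoming.

## What the presets emulate — and what they do not

The presets encode the reference experiments: constant-drive sweeps and
their Hopf windows on both axes, the two-parameter oscillatory region at
grid step 0.01 with the $w_{EI}$ contrast, the five single-drive coupling
regimes at 4 Hz, and the two dual-drive behaviours (gamma on alternate theta
cycles under a 4 Hz/2 Hz drive pair; a 30° phase offset between two 4 Hz
drives placing the I population's preferred phase on the ascending
quadrant). Drive means and amplitudes for the coupling presets are our
documented choices satisfying each regime's excursion rule; run logs tag
every value `[paper]` or `[assumed]` accordingly.

The model is noiseless and autonomous apart from its deterministic drives.
Passing tests therefore demonstrate properties of the idealized circuit,
not of recorded brain signals: there is no spectral background, no
theta waveform asymmetry, no non-stationarity, and the modulation index has
no sampling distribution to correct against surrogates. Synaptic delays,
more than two populations, stochastic inputs, and analysis of empirical
recordings are out of scope.

## Known limitations

* Eigenvalue magnitudes at specific operating points depend on the time
  convention; only natural units are reported, and labels (not magnitudes)
  are the contract.
* The normalized modulation index is blind to absolute gamma amplitude (see
  above).
* The simulated window edge is threshold- and duration-dependent near the
  supercritical onset; use the eigenvalue root-finder for edges.
* Region maps classify by simulation from the origin; in multi-equilibrium
  pockets (large $w_{EE}$ or $w_{EI}$) the origin's basin decides the
  label, which is the experimentally relevant convention here but not a
  statement about all initial conditions.
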