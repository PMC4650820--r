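---
title: "Methods: two-layer multiplex Kuramoto dynamics of cortical activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-layer multiplex Kuramoto dynamics of cortical activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mkmcortex)
```

## The model

`mkmcortex` simulates a population of $n$ cortical regions, each an
oscillator near its limit cycle, interacting on a *two-layer multiplex
network*: one layer carries direct excitatory-excitatory (EE) coupling,
the other carries excitatory-inhibitory (EI) coupling whose synaptic
transmission delay $\tau$ survives phase reduction as a Sakaguchi phase
shift. In phase-deviation variables $\varphi_i$ the dynamics is

$$\dot\varphi_i \;=\; \omega_i
 \;+\; \frac{K}{\langle k^{EE}\rangle}\sum_j A^{EE}_{ij}\,
       \sin(\varphi_j-\varphi_i)
 \;+\; \frac{K}{\langle k^{EI}\rangle}\sum_j A^{EI}_{ij}\,
       \sin(\varphi_j-\varphi_i-\beta),$$

with $A^{EE}, A^{EI}$ the 0/1 adjacency matrices of the two layers,
$\langle k\rangle$ their mean degrees, $K \ge 0$ a global coupling
strength (physiologically tied to cerebral blood flow), $\beta =
\bar\omega\tau$ the phase shift standing in for the synaptic GABA level,
and $\omega_i$ the natural-frequency deviations, drawn from a symmetric
unimodal distribution (standard normal by default) and centered — a
rotating-frame transformation makes the zero-mean convention lossless.

Both layer sums are normalized by *their own* mean degree; a per-node
degree $k_i$ normalization would be the main alternative. Mean degree
was chosen because (i) it keeps the synchronized manifold exact
on regular graphs, (ii) it reproduces the mean-field critical coupling
$K_c = 1/(\pi g(0))$ for complete identical layers, and (iii) it leaves
the single-network Kuramoto model as the exact $\beta = 0$,
identical-layer limit (with effective coupling $2K$, since the two layer
sums add). The shift $\beta$ sits only in the EI layer: it encodes the
inhibitory transmission delay, and the EE channel has none.

Two exact consequences anchor the test suite:

* on regular layers the fully synchronized state rotates at
  $\dot\varphi = -K\sin\beta$: the frequency-suppression (slow-wave)
  mechanism at the transition into the synchronized regime, maximal at
  $\beta = \pi/2$;
* the map $(\beta,\omega,\varphi_0) \to (-\beta,-\omega,-\varphi_0)$
  negates trajectories exactly, and adding a constant to all $\omega_i$
  is a rotating-frame change that leaves the order parameter invariant.

## Order parameters

*Synchronization.* $r(t)e^{i\psi(t)} = n^{-1}\sum_j e^{i\varphi_j(t)}$,
with $\bar r$ its average over the post-burn-in window. At finite $n$
the incoherent state sits at the floor $r \sim n^{-1/2}$ (about 0.1 at
$n = 100$), not at zero.

*Chaos.* The largest Lyapunov exponent from twin trajectories: a
perturbed copy at initial separation $d_0$ ($10^{-8}$ by default) is
integrated with the identical stepper, and the separation is the
Euclidean norm of component-wise phase differences wrapped to
$(-\pi,\pi]$ — the standard metric on the phase torus, insensitive to
winding counts. Two estimators are exposed: the *direct* instantaneous
exponent $\lambda(t) = t^{-1}\log(d(t)/d_0)$, which saturates once
$d(t)$ reaches the torus scale $\sqrt{n}\,\pi$ and is kept for fidelity,
and the *renormalized* (Benettin) estimator — offset rescaled to $d_0$
every time unit, log stretch factors accumulated — whose post-burn-in
mean growth rate `lambda_final` is the quantity used everywhere a
number is needed. The two agree on non-saturating runs; tests check
this, plus a linear flow with a known exponent, the neutral direction
and the analytic transverse rate $-4K\cos\Delta^*$ of a locked pair.

*Frequency deviations.* $\Omega_i$ is the endpoint difference of the
*unwrapped* phase over the post-burn-in window divided by its length —
exact bookkeeping, $O(1/T_{\text{window}})$-insensitive to oscillatory
transients, with $\Omega$ the population mean and the spread
$\mathrm{sd}(\Omega_i)$ quantifying distribution narrowing. The state is
therefore stored unwrapped; an input-contract check rejects
modulo-wrapped phases.

## Phase diagram and classification

A sweep cell at $(K,\beta)$ averages $\bar r$, `lambda_final`, $\Omega$
and the spread over independent runs, each with fresh ER layers,
frequencies and initial phases (quenched averaging over *all* random
inputs), seeded from a master seed through a documented
linear-congruential counter scheme. Cells classify as **chaotic** when
$\lambda > 0.02$, else **synchronized** when $\bar r > 0.8$, else
**unsynchronized** when $\bar r < 0.3$, else "boundary". The thresholds
are package choices: 0.3 sits above the $n^{-1/2}$
incoherent floor at the default $n = 100$, 0.02 above the noise scale of
the finite-horizon Lyapunov estimate. In the cortical reading,
unsynchronized = background activity, synchronized = epileptiform
activity, chaotic (with synchronized clusters) = resting state.

The default protocol is $n = 100$ regions, two independent
Erdős–Rényi layers with $p = 0.1$ (mean degree $\approx 10$, safely
above the percolation threshold $1/(n-1)$), centered standard-normal
frequencies, classical RK4 with $dt = 0.01$ for $10^5$ steps with the
first $2\times10^4$ discarded (800 retained time units), and 10 runs per
cell (the automated checks use 5 runs per cell and, for the full
$6\times6$ sweep, $6\times10^4$ steps — 400 retained time units — which
keeps the sweep to a few minutes on one CPU without changing any of its
qualitative conclusions). These are the conditions every reported
number refers to.

### Critical coupling

`locate_critical_coupling()` bisects $K$ at $\beta = 0$ against the
crossing of $\bar r$ through a level. The default level is the
incoherent threshold 0.3, *not* the midpoint of the incoherent and
synchronized thresholds: on the supercritical branch
$r = \sqrt{1-K_c/K}$ of the mean-field Cauchy model, $r$ reaches the
midpoint 0.55 only at $1.43\,K_c$, so a midpoint criterion would
overestimate $K_c$ by over 40% by construction, while the onset level
0.3 crosses at $1.10\,K_c$. For complete identical layers the located
values land within a few percent plus finite-size noise of the
mean-field predictions $K_c = \gamma$ (Cauchy width $\gamma$) and
$K_c = \sqrt{2\pi}/\pi \approx 0.798$ (standard normal) — the halving
relative to the classical $2/(\pi g(0))$ comes from the two identical
layer sums adding.

### A finite-size caveat on the transition-window Lyapunov exponent

At the $\beta = 0$ transition the model shows weak finite-size chaos.
Its magnitude decreases with system size: under the default protocol the
run-averaged `lambda_final` near the transition is $\approx 0.10$–$0.12$
at $n = 100$, $\approx 0.06$–$0.11$ at $n = 200$ and $\approx 0.05$ at
$n = 400$. Reported transition-window ceilings therefore depend strongly
on $n$: quantitative statements about this exponent only make sense
relative to a stated system size, and the package always reports what
its stated $n = 100$ protocol produces.

## Wilson-Cowan layer and the phase-reduction check

The model above is a weak-coupling reduction of delay-coupled
Wilson-Cowan dynamics. Each region carries firing fractions
$(E_i, I_i)$ with

$$\dot E_i = -E_i + S_E\!\big(c_{ee}E_i - c_{ei}I_i + P
 + \varepsilon (W^{EE}E)_i - \varepsilon (W^{EI} I(t-\tau))_i\big),
 \qquad
 \dot I_i = -I_i + S_I\!\big(c_{ie}E_i - c_{ii}I_i + Q\big),$$

logistic $S(x) = 1/(1+e^{-a(x-\theta)})$. The inter-regional inputs are
weak ($\varepsilon$ small; inhibitory-inhibitory coupling, assumed very
weak, is dropped), and only the inhibitory channel is delayed — a
synaptic delay, distinct from axonal conduction delays, which are not
modeled.

The defaults $c_{ee}=16$, $c_{ei}=12$, $c_{ie}=15$, $c_{ii}=3$,
$a_E=1.3$, $a_I=2$, $\theta_E=4$, $\theta_I=3.7$, $P=1.25$, $Q=0$ are
the classical Wilson-Cowan oscillatory operating point, with a unique
exponentially stable limit cycle of period $T \approx 6.6$ relaxation
times. A unit sigmoid gain was considered and rejected: at gain 1 with
these synaptic weights the flow numerically settles to a fixed point, so
no oscillatory reduction exists there; the classical per-population
gains restore the cycle that the whole construction presupposes. Time is
in units of the relaxation time constant; only the dimensionless product
$\beta = \bar\omega\tau$ is matched between the two model levels.
Dropping $P$ to 0.2 gives the fixed-point regime used to exercise the
no-cycle error path.

*Delay integration.* Method of steps with RK4 inside each step; $\tau$
must sit on the step grid (snapped, with an error otherwise — this
avoids any ambiguity about interpolation across breaking points, which
align with grid nodes). The half-step stages need the delayed state at
past half-grid times, which a grid lookup cannot supply; those values
come from cubic Hermite interpolation on the stored grid using stored
derivatives, which preserves 4th-order convergence (verified by a
step-halving study). One subtlety: the history need not satisfy the
equations, so the solution's derivative jumps at $t = 0$, and the
interval $[-dt, 0]$ must be interpolated with the *history's* left-side
derivative rather than the RHS value — using the wrong side degrades
the scheme to 2nd order.

*Limit cycle, Floquet exponent, asymptotic phase.* The cycle is found by
Poincaré section ($E$ crossing its time mean upward) after a transient;
the period is the mean crossing interval, with a spread check and an
amplitude-decay check (a damped spiral crosses its mean with a clean
period too, so interval regularity alone cannot reject it). Orbital
stability is measured by splitting the deviation between a perturbed and
an on-cycle reference trajectory into flow-tangential (neutral) and
normal components and fitting the once-per-period (stroboscopic) normal
distances — within-period modulation and the quadratic tangential floor
otherwise bias the fit. The asymptotic phase of a state integrates the
uncoupled flow until the cycle is reached and reads the phase off the
last section-crossing time, $\theta = -\bar\omega t_c \bmod 2\pi$.

*The equivalence check.* Two delay-coupled regions started a quarter
period apart are simulated at $\varepsilon \in \{0.02, 0.01, 0.005\}$;
the phase difference $\Delta(t)$, extracted through asymptotic phases,
is compared against the matched two-oscillator reduction, which for the
symmetric pair is the Adler relaxation $\dot\Delta = -C\sin\Delta$ with
$C = 2\varepsilon(k_{ee} + k_{ei}\cos\beta)$. The single constant $C$ is
fitted by least squares at the largest $\varepsilon$ and rescaled
proportionally for the smaller ones; the maximal $|\Delta|$ discrepancy
over a fixed horizon (250 time units) then decreases with
$\varepsilon$. It does not reach zero: the comparison model keeps only
the first harmonic of the true interaction function, so a
shape-mismatch floor of order 0.1 rad remains; what vanishes with
$\varepsilon$ is the phase-reduction error proper. The delayed-channel
prediction is checked separately with a unidirectionally driven pair,
whose locked lag moves backward (towards $-\beta/2$ for equal channel
weights) once $\tau > 0$.

## Numerical and design notes

* Phases are stored unwrapped; wrapping happens only inside observables.
  RK4 is fixed-step; trajectories with non-finite phases abort with the
  step index.
* The compiled kernel evaluates edge sums in trig-factorized form
  ($O(n)$ sin/cos plus $O(|E|)$ additions per evaluation) and
  short-circuits complete layers via global sums; an independently coded
  velocity oracle and a pure-R twin-trajectory stepper cross-check it in
  the tests.
* ER layers are generated through igraph under fixed seeds;
  reproducibility is bit-exact for a given `(n, p, seed)`.
* All per-run seeds derive from one master seed via
  `derive_seeds()`; nothing numeric reads the clock.
* Degenerate inputs: a layer with no edges constructs (with a warning)
  but refuses integration, since its mean-degree normalization is
  undefined; `tau` off the step grid, wrapped-phase input to the
  frequency estimator, and an unbracketed bisection all raise typed
  errors rather than guessing.

## What the synthetic conditions do and do not show

All inputs are synthetic by design — the model's claims are about its
own dynamics, not about a data set. The ER-multiplex + standard-normal
conditions reproduce the three-phase structure and its frequency
phenomenology, and robustness holds above the percolation threshold and
across symmetric unimodal frequency distributions. What passing tests do
*not* show: behavior on empirical connectomes (weighted, modular,
spatially embedded), strong-coupling regimes where phase reduction
fails, strongly heterogeneous regions (frequency-modulated
interactions), axonal delays, or stochastic dynamics. Known limitations
worth naming: the finite-size dependence of transition-window Lyapunov
ceilings (above); near the synchronized/chaotic border, strongly
clustered chaotic states can combine $\bar r$ just above 0.8 with
clearly positive $\lambda$ at $n = 100$, so threshold-based exclusivity
statements are sharp only away from that border; and the Adler-form
comparison floor in the equivalence check.
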