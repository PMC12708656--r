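---
title: "Model, numerics and protocols for the transition to active nematic turbulence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, numerics and protocols for the transition to active nematic turbulence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(activenematic)
```

## The model

`activenematic` simulates a minimal hydrodynamic model of a two-dimensional,
incompressible, inertialess active nematic on a doubly periodic unit square.
The fluid is deep in the nematic phase: the director has unit norm, the
field is defect-free, and there is no flow alignment. Under these
assumptions the entire state reduces to a single scalar field, the director
angle $\theta(\mathbf r, t)$, with the director
$\mathbf n = (\cos\theta, \sin\theta)$.

Because inertia is absent, the flow is *slaved* to the director. Taking the
curl of the Stokes force balance (pressure drops out) and writing the
velocity through a stream function ($v_x = \partial_y\psi$,
$v_y = -\partial_x\psi$) gives, after nondimensionalizing lengths by the
system size $L$ and time by the active time $\tau_a = \eta/|\zeta|$,

$$-\nabla^4\psi \;=\; \frac{R}{2A}\,\nabla^4\theta
  + S\!\left[\tfrac12\left(\partial_x^2-\partial_y^2\right)\sin 2\theta
  - \partial^2_{xy}\cos 2\theta\right],$$

and the director angle evolves as

$$\partial_t\theta \;=\; -(\partial_y\psi)(\partial_x\theta)
  + (\partial_x\psi)(\partial_y\theta)
  - \tfrac12\nabla^2\psi + \tfrac1A\nabla^2\theta .$$

Three dimensionless groups appear: the **activity number**
$A = L^2/\ell_c^2$ with $\ell_c = \sqrt{K/(|\zeta| R)}$ the active length,
the **viscosity ratio** $R = \gamma/\eta$, and the **stress sign**
$S = \zeta/|\zeta|$ ($-1$ contractile, $+1$ extensile). Without flow
alignment the two signs are equivalent under $\theta \to \theta + \pi/2$ —
an exact symmetry the test suite verifies to rounding error. Throughout,
$R = 1$ and $S = -1$ unless stated, and $A$ is the sole bifurcation
parameter.

Two time units coexist. The equations above use $\tau_a$, which itself
changes with activity; results are reported in the nematic relaxation time
$\tau_r = \gamma L^2/K = A\,\tau_a$, which does not. Internally the
integrator always works in $\tau_r$ units (the director equation multiplied
by $A$), for two reasons: the reference time step is specified in $\tau_r$,
and the implicit diffusion coefficient becomes exactly 1, independent of
$A$, so activity ramps never change the implicit operator. Conversions:
$t[\tau_r] = t[\tau_a]/A$, $v[L/\tau_r] = A\,v[L/\tau_a]$, mean squared
velocities scale by $A^2$. `model_params(time_unit=)` selects the unit in
which fields and diagnostics are expressed.

## Spatial discretization and the Stokes solve

The grid is $n \times n$ on the unit square ($\Delta x = 1/n$; reference
resolution $n = 256$). The biharmonic Stokes problem is solved spectrally:
the right-hand side is assembled from $\sin 2\theta$, $\cos 2\theta$ and
$\theta$ in Fourier space, dealiased with the 2/3 rule, and divided by
$k^4$. The zero mode of $\psi$, left undetermined by the equation, is set
to zero; velocities involve only derivatives, so this is a pure gauge
choice. Derivatives of $\psi$ (velocity, vorticity, $\nabla^2\psi$) are
spectral.

Derivatives of $\theta$, by contrast, are second-order centered finite
differences. This mixed discretization mirrors the integrator: $\theta$ is
advanced with an alternating-direction-implicit (ADI) finite-difference
scheme, and using the same FD operators in the tendency keeps the scheme
and its fixed points exactly consistent (a uniform $\theta$ is an exact
fixed point to rounding error, as tested).

The compiled core calls FFTW3 directly with cached plans; the R-level
functions `velocity_from_stream()` and `vorticity_from_stream()` use R's
own FFT and serve as an independent cross-check in the tests.

## Time integration

One step of length $\Delta t$ is a Peaceman–Rachford pair of half-steps:
the diffusion term is implicit along $x$ in the first half-step and along
$y$ in the second (each a cyclic tridiagonal solve, Thomas elimination plus
a Sherman–Morrison correction for periodicity), while advection, the active
source $-\frac{A}{2}\nabla^2\psi$, and the cross-axis diffusion are
explicit. The stream function is recomputed from $\theta$ at the start of
each full step and held frozen across both half-steps (freezing per half
step would cost another Stokes solve per step for no observed accuracy
gain; with the source frozen the splitting is first-order accurate overall,
which the convergence test confirms with an error ratio near 2 under
$\Delta t$ halving).

The default step is $\Delta t = 1.8\times10^{-5}\,\tau_r$, held fixed
across activity ramps. Advection is explicit, so a CFL warning (not an
error) is emitted when $\max|v|\,\Delta t/\Delta x$ exceeds 1; the
reference parameter ranges stay below this at the default step.

Realizations are generated by additive Gaussian white noise on $\theta$
during a short initial transient. The amplitude convention is space–time
white noise: per node and step, standard deviation
$\sqrt{2 D \Delta t}/\Delta x$, which makes the physical noise level
grid-independent. The noise only breaks symmetry — results are insensitive
to the convention — but the convention is recorded here and in the output
metadata. Reference values: $D = 5\times10^{-4} L^2/\tau_r$ for
$10^{-2}\tau_r$ (ensembles), $D = 5\times10^{-6}$ for the tiny per-step
bursts used during low-activity ramps.

Two numerical-safety choices: $\theta$ is stored unwrapped (not mod $\pi$),
valid because the dynamics are defect-free; a warning fires if
nearest-neighbour angle differences exceed $\pi/2$, the signature of an
under-resolved field. And a resolution guard warns when $n \le 2\sqrt{A}$,
i.e. fewer than two grid points per active length $\ell_c/L = A^{-1/2}$;
scaled-down explorations may acknowledge it explicitly
(`check_resolution = FALSE`).

## Linear theory: the analytic anchor

Linearizing both equations about the aligned state for a single mode
$e^{i\mathbf k\cdot\mathbf r}$ gives the real growth rate (in $1/\tau_a$)

$$s(\mathbf k) = S\,\frac{k_x^2 - k_y^2}{2k^2} - \frac{(R+4)\,k^2}{4A},$$

implemented in `growth_rate()` and verified against an independently
assembled single-mode system to $10^{-10}$, and against the nonlinear
integrator at amplitude $10^{-6}$ to 2%. The optimal orientation (bend,
$k_x = 0$ for contractile stress with alignment along $x$) becomes marginal
at

$$A_c = \frac{(R+4)\,k_{\min}^2}{2}, \qquad k_{\min} = 2\pi
 \;\Rightarrow\; A_c = 10\pi^2 \approx 98.7 \ \ (R = 1).$$

This closed form anchors the first bifurcation; everything beyond it
(secondary pitchfork near $A \approx 330$, subcritical vortex transitions,
chaos) is measured, not derived.

## Lyapunov diagnostics

Chaos is quantified through shadow trajectories: each deviation field
$w^{(l)} = \tilde\theta^{(l)} - \theta$ is propagated by integrating the
perturbed field through the full nonlinear map alongside the reference —
not by a tangent-linear code — and renormalized to Euclidean norm
$\|w\| = 10^{-6}$ every $10^{-3}\tau_r$ (Gram–Schmidt orthonormalization
across deviations when several exponents are requested). The renormalization
interval is realized as a whole number of steps; the accumulated log growth
factors give

- the **maximal Lyapunov exponent** $\Lambda$ (total log growth over total
  time, `mle()`),
- **stretching numbers** $\alpha_k$ over windows of $5\times10^{-3}\tau_r$
  (`stretching_series()`); $\Lambda$ equals the time average of the
  $\alpha_k$ identically, which the tests assert as an algebraic fact,
- the ordered **spectrum** $\lambda_1 \ge \dots \ge \lambda_m$
  (`lyapunov_spectrum()`), with a drift check over the last quarter of the
  run as a convergence flag.

Varying the rescaling amplitude by a factor of ten changes the estimates by
well under 1% (tested). A finite-time estimate at integration time $T$
cannot resolve exponents below $\sim 3/T$ in magnitude; that resolution is
the package's tolerance whenever an exponent is claimed to "vanish" (the
Goldstone modes of broken translational symmetries).

The **chaotic fraction** $f_c$ — the order parameter of the transition —
is the probability mass of the chaotic peak in the pooled stretching-number
histogram of an ensemble. There is no canonical rule for separating the
peaks, so the threshold is a documented choice: the minimum of a
Gaussian-kernel density estimate (Silverman-style default bandwidth)
between the laminar peak at $\alpha \approx 0$ and the positive peak.
Unimodal distributions short-circuit to $f_c = 0$ (peak within two
bandwidths of zero) or $f_c = 1$ (positive peak).

## Protocols

`activity_ramp()` implements quasi-static continuation: change $A$ in
steps, relax, record the branch point just before the next increment, carry
the state forward. Branch MSVs are tail averages over the trailing 25% of
each window (smoothing limit-cycle states); each point also records the
within-window growth factors of the total and transverse MSV, the
instability detectors used to locate bifurcations of the current branch.
`hysteresis_loop()` composes an up and a down ramp sharing the turning
state and flags a jump at the first step at which the MSV *or either of
its components* changes by more than a threshold (default 50%) relative to
the previous step. Detecting on the components as well as the sum is
deliberate: the subcritical vortex transitions rearrange the flow pattern,
jumping $\langle v_x^2\rangle$ and $\langle v_y^2\rangle$ in opposite
directions, so the components move far more sharply than their sum. The
threshold is a documented choice; coarse desk-scale loops across the
weaker scaled-down transitions pass a smaller value (10%), safely above
the few-percent smooth drift per step of a laminar branch. `ensemble_transition_scan()`
runs independent noise-burst realizations per activity and aggregates MSV,
$\Lambda$, pooled $\alpha$ histograms and $f_c$; per-realization seeds
derive from a master seed by a counter scheme recorded in the output.

Reference protocol parameters (all config-exposed): bifurcation-diagram
ramp $\Delta A = 1$ per $2\tau_r$; hysteresis scan of the turbulence
transition $\Delta A = 100$ per $2.5\tau_r$; ensembles of 32 realizations
(64 in the transition region $A \ge 3800$) for $600\tau_r$ ($10\tau_r$
below $A = 3000$).

## Desk-scale problem sizes

The reference conditions ($256^2$, hundreds of $\tau_r$, tens of
realizations) are multi-day CPU work. The package's own test suite and
acceptance script therefore run the same pipelines at reduced scale,
chosen once as follows:

- **Primary threshold**: $n = 64$, seeded-mode runs of $0.2\tau_r$,
  bracketing in steps of $\Delta A = 5$ around the closed form.
- **Secondary pitchfork**: $n = 128$, shear branch established below the
  transition (at $A = 280$–$300$), ramp upward with $\Delta A = 10$ and
  $1\tau_r$ relaxation, per-step bursts at $D = 5\times10^{-6}$. The growth-factor detector
  locates the instability to within one step; the coarser
  "transverse MSV exceeds 1% of longitudinal" criterion used for the
  headline number lags the true onset by a few steps, as any
  finite-ramp measurement does.
- **Chaotic/laminar discrimination**: deviation runs of $1.5$–$3\tau_r$
  on a converged vortex state at $A = 500$ at $n = 64$ (which resolves
  the active length there; expect $\Lambda \le 0$ within $3/T$) and on
  the turbulent state at $A = 6000$ at $n = 96$ with the resolution
  guard acknowledged (expect $\Lambda \gg 3/T$), plus a three-point
  check that $\Lambda$ increases with $A$ deep in the chaotic regime.
- **Bistability**: a hysteresis mini-loop at $n = 64$ (which resolves
  $\ell_c$ up to $A = 1024$) across the two-vortex to three-vortex
  transition (subcritical, near $A \approx 941$ at reference scale),
  asserting that the up-jump occurs at strictly higher activity than the
  down-jump.

What these scaled runs do and do not show: they exercise every code path
at the same physics (the bifurcation structure is set by the low
wavenumbers, well resolved at these grids), but quantitative locations of
the nonlinear transitions shift by a few percent with resolution and ramp
schedule, and the long-transient statistics of the transition region
(chaotic fractions over $600\tau_r$ at $256^2$) are deliberately out of
desk scope. The synthetic-data generator (aligned states, noise bursts,
single modes) emulates the study's initial conditions exactly; it does not
emulate experimental imperfections such as defects, confinement, friction
or flow alignment, which the model itself excludes.

## Numerical edge cases

- Degenerate inputs: odd or tiny grids, $A \le 0$, $S \notin \{-1, +1\}$,
  zero wavevectors, non-finite fields and shape mismatches are rejected
  with errors; $D = 0$ noise is the identity.
- Divergence (CFL violation at extreme parameters) aborts with the failure
  time rather than returning NaNs.
- A deviation overflowing between renormalizations triggers automatic
  subdivision of the interval with a warning.
- Ties in the chaotic-fraction density minimum resolve to the first
  minimum; a zero-variance $\alpha$ sample is treated as a point mass.
- FFTW plans use the deterministic `FFTW_ESTIMATE` mode, so identical
  inputs give bitwise-identical trajectories across processes.

## Known limitations

- No topological defects, flow alignment, friction, confinement or
  variable nematic order: the model is the minimal one by design, and the
  package does not attempt to go beyond it.
- First-order splitting: accuracy is $O(\Delta t)$; the reference step is
  small enough that spatial error dominates at the reference resolution.
- The flow-state classifier and the vortex counter are documented
  heuristics supporting branch bookkeeping, not statements of the model.
- Quantitative bifurcation locations at desk scale carry the
  resolution/schedule caveats above.
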