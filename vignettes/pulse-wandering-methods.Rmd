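---
title: "Traveling pulses in a stochastic neural field: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Traveling pulses in a stochastic neural field: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuralpulse)
```

## The model

`neuralpulse` analyzes a one-dimensional scalar neural field

$$\partial_t u(x,t) = -u + \int_{-\infty}^{\infty} w(x-y)\,F(u(y,t))\,dy
  + I(x - vt) + \epsilon^{1/2} g(u)\,\xi(x,t),$$

a continuum description of a recurrent cortical network proposed as a
mechanism of direction selectivity.  Time is measured in units of the
membrane time constant.  The connectivity is an *offset Mexican hat*,

$$w(x) = a_e e^{-\sigma_e|x-x_0|} - a_i e^{-\sigma_i|x-x_0|},
  \qquad a_e > a_i > 0,\ \sigma_e > \sigma_i > 0,$$

local excitation with broad inhibition whose peak is displaced by $x_0$.
The displacement breaks reflection symmetry: instead of the stationary
bumps of the symmetric case, the field supports *traveling pulses* that
propagate in the direction of the offset, and these pulses can entrain
("lock") to a moving external stimulus — the direction-selective response.
All analytic constructions use the high-gain (Heaviside) firing rule
$F(u) = H(u - \kappa)$; the sigmoid rule is supported by the simulator
only, because the threshold-crossing constructions below have no closed
form for finite gain.

The package's defaults are the reference parameter set used throughout
its examples and acceptance experiments: $a_e = 5$, $a_i = 1$,
$\sigma_e = 0.42$, $\sigma_i = 0.1$, $x_0 = 3$, threshold $\kappa = 4$
(see `np_presets()`).

## Closed forms via piecewise-exponential algebra

Every analytic object in the package — the kernel, its window integrals
$W(\xi) = \int_{\xi-d_2}^{\xi-d_1} w$, pulse profiles, Evans-function
convolutions, adjoint null vectors, and the diffusivity integrands — is a
finite sum of exponentials on each piece of a partition of the line.  An
internal engine represents such functions explicitly and integrates them
exactly, so quadrature never enters the primary path; adaptive quadrature
appears only as an independent oracle in the test suite, where all closed
forms are required to agree with it to $10^{-8}$ or better.

## Free pulses

A pulse of speed $c$ and width $d$ satisfies the two threshold
conditions $U(0) = \kappa$, $U(d) = \kappa$, with

$$U(\xi) = \frac{e^{\xi/c}}{c}\int_\xi^\infty W(\xi')e^{-\xi'/c}\,d\xi',
  \qquad W(\xi) = \int_{\xi-d}^{\xi} w.$$

`solve_free_pulses()` finds all isolated $(c, d)$ roots with a damped
Newton iteration (SVD-truncated step, so rank-deficient Jacobians at
symmetric/degenerate points do not derail it) from a log-spaced
multistart grid over $c \in [0.05, 20]$, $d \in [0.1, 50]$ — a box that
brackets every branch at the reference parameters with a wide margin.
Roots closer than $10^{-6}$ are merged; every root must pass a hard
validity filter, the single-superthreshold-interval check, evaluated on a
dense grid.  At the reference parameters there are two branches: a
slow/wide pulse ($c = 3.896$, $d = 15.70$ at $\kappa = 4$) and a
fast/narrow one ($c = 6.303$, $d = 4.53$); the slow branch is the stable
one.  `branch_scan()` continues both branches across a threshold grid
(warm-started from the previous roots) until they terminate at a fold
between $\kappa = 5$ and $5.5$.  Two details worth noting:

* The slow branch's speed *increases* gently with $\kappa$ while the
  fast branch's decreases toward the fold.
* The stable speed at $\kappa = 4$ is $3.896$, which the source
  literature reports as the round value $4$; the package reports the
  computed value, confirmed by direct lattice integration of the field
  equation.

## Evans-function stability

Linearizing about a pulse in its co-moving frame gives an operator whose
essential spectrum is the vertical line $\mathrm{Re}\,\lambda = -1$
(`essential_spectrum()`; the residual spectrum is empty — both are fixed
analytic facts, asserted rather than recomputed).  Discrete eigenvalues
are the zeros of the Evans function built from half-line convolutions
$(w \star P_\lambda)(\xi)$ of the kernel (`evans_free()`,
`evans_locked()`).  `find_evans_roots()` samples the function on a
rectangle, seeds candidates where the zero contours of the real and
imaginary parts cross inside a grid cell, polishes by damped complex
Newton, and additionally sweeps the real axis in 1D (the function is
real there by conjugation symmetry).

`classify_stability()` searches a default box with
$\mathrm{Re}\,\lambda \in (-0.95, 3]$ and
$|\mathrm{Im}\,\lambda| \le \max(2\pi|v|/d, 2)$, *plus* a real-axis sweep
out to $\mathrm{Re}\,\lambda = 20$.  The generous real extent is
deliberate: the unstable eigenvalue of the fast free branch sits near
$1.88$ and that of very narrow locked pulses beyond $4$, so a cap at
$1$ would misclassify them.  A pulse is stable when every eigenvalue
other than the translation zero (free case; $|\lambda| < 10^{-6}$) has
$\mathrm{Re}\,\lambda < -10^{-6}$; eigenvalues inside that band yield the
verdict `"unknown"`.

As an independent check, `linearization_matrix()` builds the dense
finite-difference discretization of the linearized operator (central
differences, rank-one threshold-crossing terms with interpolated crossing
rows).  With $\Delta x = 0.02$ and the domain extending $\approx 30$
beyond each crossing, its eigenvalues match the Evans roots to better
than $10^{-3}$; the domain must be this generous because eigenfunctions
inherit the slowly decaying inhibitory tail ($1/\sigma_i = 10$ length
units).

## Stimulus-locked pulses

A rectangular stimulus of amplitude $I_0$ and width $d$ moving at speed
$v$ pins the pulse in the stimulus frame; the unknowns become the two
crossing points $(d_1, d_2)$.  The same tail-integral construction
applies with the stimulus added to the drive, and automatically
reproduces the sign-dependent piecewise forms (for $v < 0$ the integral
runs from $-\infty$).  `solve_locked_pulses()` multistarts over
$(d_1, d_2 - d_1)$, applies the same single-interval validity filter,
and reports invalid roots in an `n_invalid` attribute — those mark where
solutions are lost to multiple superthreshold regions as the drive
strengthens.  At $I_0 = 5$, $d = 5$, $v = 5$, $\kappa = 4$ the package
finds four candidates of which one is stable, in line with the at most
one stable / up to three unstable structure of the reference analysis.
`locking_tongues()` scans $(v, I_0)$ cells and tabulates
stable/unstable/invalid counts; per-cell failures are recorded in a
`status` column, never aborting the scan.  The stationary case $v = 0$
is out of scope.

## The Langevin simulator

`integrate_langevin()` integrates the Ito form equivalent to the
Stratonovich multiplicative noise,

$$dU = \left[-U + \epsilon C(0) g'(U)g(U) + w * F(U) + I\right]dt
 + \epsilon^{1/2} g(U)\,dW,$$

with explicit Euler–Maruyama steps.  Writing the Novikov drift
correction $\epsilon C(0) g'g$ out explicitly makes it testable in
isolation (the suite verifies both the per-site increment variance
$2C(0)\Delta t\,\epsilon g(U)^2$ and the correction term via a
regression across lattice sites).  Design choices:

* **Spatial noise** is the lattice white-noise limit: independent
  per-site Gaussian increments with $C(0) = 1/\Delta x$ (checked against
  the grid at load time; overriding it warns).  Finite correlation
  lengths are an extension point and are rejected rather than silently
  approximated.
* **Convolution** is spectral (circular FFT).  Free- and locked-pulse
  ensembles run on a periodic ring of circumference $102.4$ at
  $\Delta x = 0.1$; the ring is large enough that the measured
  deterministic speed is indistinguishable from the infinite-line value
  (the residual $-0.3\%$ bias is the first-order time-stepping error at
  $\Delta t = 0.01$ and vanishes under $\Delta t$ refinement).  A
  clamped-zero buffer boundary is available for non-periodic runs and is
  monitored for superthreshold contact.
* **Trials** evolve as columns of one lattice ensemble, packed two per
  complex FFT column, with a single seeded RNG stream; identical seeds
  give bit-identical output.  Noise draws are skipped where the
  multiplicative amplitude is below $10^{-9}$ per step — unused
  independent draws leave the law of the process unchanged.
* **Recording** extracts level-set crossing positions on the fly (the
  same interpolation rule as `level_crossings()`, with
  temporal-continuity selection among multiple crossings), so ensembles
  never store full space–time fields; a few full-field snapshot trials
  can be kept for plotting.

## Noise-modified pulse and wandering theory

For linear noise $g(U) = g_0 U$ the correction rescales the profile
decay to $\Gamma(\epsilon) = (1 - \epsilon C(0) g_0^2)/c_\epsilon$;
`effective_pulse()` re-solves the threshold conditions with this decay
(free case: unknowns $c_\epsilon$ and the width; locked case: speed
fixed at $v$, unknowns $(d_1, d_2)$).  At the reference noise
($\epsilon = 0.005$, $C(0) = 10$, $g_0 = 1$) the free pulse slows from
$3.896$ to $c_\epsilon = 3.692$ and widens from $15.70$ to $16.84$ —
and the simulated ensemble drifts at $3.698$, within $0.2\%$ of
$c_\epsilon$ ($+0.3\%$ discretization bias included).

Projecting the noise onto the translation mode with the adjoint null
vector $V$ gives the wandering laws: Brownian displacement with
$\langle\Delta^2\rangle = 2D(\epsilon)t$ for free pulses,
an Ornstein–Uhlenbeck process $d\Delta + A\Delta\,dt = d\hat W$ with
saturating variance $D/A$ for locked pulses
(`diffusivity()`, `ou_rate()`, `variance_curve()`).

**Free case.**  $V(\xi) = b(\Delta)H(\xi)e^{-\Gamma\xi} -
b(-\Delta)H(\xi-\Delta)e^{-\Gamma(\xi-\Delta)}$ in closed form, where
$b(z)$ is the exponentially discounted forward kernel mass
(`b_function()`).  The 2×2 self-consistency matrix is exactly rank 1
(relative determinant $\sim 10^{-16}$; a failure of this check is a hard
error signalling an invalid pulse context).  $D(\epsilon)$ is evaluated
fully in closed form from piecewise-exponential products, and the test
suite checks it against adaptive quadrature.

**Locked case — a genuinely open design point.**  With the stimulus
breaking translation symmetry there is *no* exact null vector at
$\lambda = 0$: the determinant of the self-consistency system equals the
Evans function at zero, which is nonzero for a locked pulse.  The
package therefore takes $V$ to be the adjoint eigenfunction at the slow
relaxation eigenvalue $\lambda_s$ — the real root of
$\det M(\lambda)$ nearest zero, with decay
$(1 - \epsilon C(0)g_0^2 + \lambda)/v$.  This choice keeps the two-jump
ansatz, makes $M(\lambda_s)$ rank 1 exactly, and renders the projection
formula self-consistent: because the linearization maps $U_0'$ to
$-I'$, the rate formula $A = \int V I' / \int V U_0'$ evaluates to
$-\lambda_s$ identically, and at $\epsilon \to 0$ it recovers the
locked pulse's Evans slow eigenvalue to machine precision.  A
least-singular-direction vector at $\lambda = 0$ was tried first and
rejected: its rate misestimated the measured relaxation by a factor
$\approx 2$ even for weak stimuli.

The ensemble validation of $A$ fits the exponential decay of the mean
displacement of the *leading* edge after an offset start.  The trailing
edge is unsuitable for a rate fit at desk scale: it carries slow
width-fluctuation transients that bias any practical fitting window
(observed $+30\%$ there versus $+12\%$ on the leading edge at 256
trials).

## Measurement protocol and estimators

Wave position is measured as the interpolated crossing of chosen levels,
by default $a \in \{0.6, 0.8, 1\}\kappa$ per edge (the number and
placement of levels is a package choice; the reference experiments state
only that several levels were sampled).  `ensemble_stats()` averages in
two stages — over levels, then over trials — and estimates the variance
as the level-average of the across-trial variance, so fixed geometric
offsets between levels do not inflate it and the curve estimates
$\langle\Delta(t)^2\rangle$.  Fits (`fit_wandering()`) use a
post-transient window, by default discarding the first quarter of the
record: the transients reflect relaxation of the mean pulse width.  The
OU saturation fit uses the full curve because $D$ and $A$ are only
jointly identifiable with the early-time rise.

Two empirical facts shape the test tolerances.  First, the trailing edge
of a pulse fluctuates much more than the leading edge — for the locked
pulse its asymptotic variance is larger by more than an order of
magnitude, which is why width fluctuations cannot be neglected there.
Second, at desk-scale trial counts (512–1024 versus the thousands of the
reference experiments) the trailing-edge variance curve is visibly
noisy; the linear-growth $R^2 \ge 0.98$ check is therefore asserted on
the leading edge and on the per-trial edge-averaged position (in which
width fluctuations cancel exactly), with a weaker $R^2 \ge 0.75$ bound
on the raw trailing curve.

## Study sizes used by the tests

The acceptance experiments run at: free-pulse diffusivity — 1024 trials at
$\kappa = 4$ (horizon $t = 48$) and 512 trials at $\kappa = 3.5, 4.5$
(horizon $t = 36$); locked wandering — 200 trials to
$t = 48$; all on the $102.4$-ring at $\Delta x = 0.1$,
$\Delta t = 0.01$.  Monte-Carlo comparisons against the perturbative
theory use a $25\%$ tolerance, reflecting both the $O(\epsilon^{1/2})$
accuracy of the reduction and sampling error at these ensemble sizes.
Estimator-recovery checks on synthetic Brownian/OU tracks (where truth
is known exactly) use $10\%$ at 512 trials.

## What the generator does and does not emulate

`synthetic_tracks()` generates level-set tracks with the exact
statistical structure the reduction predicts: one displacement process
per trial shared by all levels and edges, plus fixed level offsets and
optional measurement jitter.  It validates the estimators, not the field
model — it contains no width dynamics, no edge asymmetry, and no
level-crossing dropout, so passing recovery tests says the estimators
are consistent, not that the field behaves like the reduction.  That
question is answered separately by the Langevin ensembles.

## Known limitations

* Analytic constructions require the Heaviside firing rule and, for the
  wandering theory, linear or additive noise; the locked-case theory is
  implemented for positive stimulus speed (the mirror symmetry
  $x_0 \to -x_0$, $v \to -v$ maps the negative-speed case onto it, and
  is verified for the existence problem in the tests).
* The OU reduction describes the rigid displacement mode only; the
  observed edge asymmetry of locked-pulse variances lies outside it, and
  the package reports it as a measurement.
* Spatially correlated noise beyond the lattice white-noise limit is an
  extension point, not implemented.
* The stationary-stimulus case $v = 0$ and stimulus shapes other than a
  single rectangle are out of scope.
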