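---
title: "Methods: vector-symbolic SLAM on synthetic arenas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vector-symbolic SLAM on synthetic arenas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the model it implements, the
choices that were genuinely open, and what the test suite does and does not
establish. It states no empirical number that the tests or
`scripts/acceptance.R` do not themselves compute.

## 1. The representation

A continuous variable $x \in \mathbb{R}^m$ is represented by the spatial
semantic pointer $\phi(x) = \mathcal{F}^{-1}\{e^{iAx}\}$, with
$A \in \mathbb{R}^{d \times m}$ a fixed matrix of spatial frequencies whose
rows come in $\pm$ pairs around one all-zero row, so the spectrum is
conjugate-symmetric and $\phi(x)$ real. We require $d$ odd (the reference
configuration uses $d = 181$), which removes the Nyquist-row special case
entirely. The package-wide DFT convention puts the $1/d$ factor on the
inverse transform; under it every point encoding has unit Euclidean norm.
Binding is circular convolution and adds encoded positions:
$\phi(x) \mathbin{\circledast} \phi(x') = \phi(x + x')$ to machine precision
(this "shift property" is asserted at $10^{-9}$ across encoders and styles).
Discrete features are random *unitary* pointers (unit-modulus spectra) by
default, so that composite keys such as `BLUE ⊛ TRIANGLE` are norm-stable and
exactly invertible; this is a configuration flag, since nothing forces
feature pointers to be unitary.

**Length scale.** Phase rows are uniform in
$[-\pi/\ell, \pi/\ell]^m$, so the similarity kernel
$\phi(x)\cdot\phi(0)$ approaches $\prod_k \mathrm{sinc}(\pi x_k/\ell)$ as
$d \to \infty$; its main lobe has half-width $\ell$. The default is
$\ell = 0.15$ arena radii. Two a-priori constraints pin this choice: (i) the
lobe must span several decode-lattice cells (cell $= 0.024$ at the default
101-per-axis lattice) so that quadratic peak refinement works, and (ii) the
kernel mass $\nu \approx \ell^m$ must keep region-query similarities
$\sqrt{\nu/\mathrm{area}}$ above the random-similarity floor
$\sim 3/\sqrt{d}$ at $d = 181$, or area queries of the semantic map drown in
cross-talk. A value near $0.1$ satisfies (i) but leaves (ii) marginal; $0.15$
satisfies both.

## 2. Probability readout and decoding

The rectified similarity readout is implemented as
$\hat f(x) = (\phi(x)\cdot M/\nu - \xi)_+$ where $\nu$ is the kernel mass on
the evaluation lattice and $\xi \ge 0$ the correction for the mass gained by
clipping the kernel's negative side lobes, fitted by bisection so a single
point encoding integrates to one over the bounded arena (the computable
surrogate for the whole-space integral). Without the $1/\nu$ scaling a
narrow kernel integrates to $\ell^m \ll 1$, the fitted $\xi$ goes strongly
negative, and the "density" degenerates into a flat baseline — the form
implemented here is the one under which the rectification behaves as the
cited correction intends. Two caveats are honest limitations:

* translation invariance of $\xi$ is only approximate at finite $d$
  (similarity ripples differ between points); the default $\xi$ is exact for
  the calibration point, and `fit_xi()` refits it for any particular memory
  vector, which is also the literal definition of the correction for a
  sample mean;
* the sinc-kernel density estimate only beats a $\sqrt{n}$-bin histogram
  once $d$ is large enough that ripple noise sits below kernel structure
  (the test uses $d = 501$; at $d = 181$ the histogram wins narrowly).

MAP decoding takes the lattice argmax of the rectified field and refines it
with one quadratic-interpolation step per axis; ties break to the lowest
lattice index so decodes are deterministic. Lattice defaults: 101 per axis
for $m \le 2$, 31 for $m = 3$ (memory/time trade-off). Clean-up re-encodes
the decode; it is idempotent to lattice precision (~half a cell), not
exactly, because the refined argmax of a re-encoded point can shift by a
fraction of a cell.

## 3. The NEF runtime

LIF rates use the standard closed form with threshold at normalised current
1; spiking mode uses the exact zero-order-hold membrane update with
overshoot-corrected refractory timing, which matches rate mode to ~0.1% at
$dt = 1$ ms, and randomised initial voltages so population noise averages
instead of synchronising. Decoders are ridge-regressed with
$\sigma = 0.1 \times$ the peak rate (the de-facto standard). $dt = 1$ ms
throughout; synapses are first-order exponentials with
$\tau_\mathrm{syn} = 0.05$ s.

**Intercepts.** The stated operating point "10% of neurons active for a
random input" is applied to populations with SSP encoders (place-cell-like
and grid-cell-like tuning) and to the associative memory, where sparse,
key-selective intercepts are what lets the Voja rule specialise neurons
without cross-talk. For low-dimensional utility populations (the velocity
channel, the 3-D oscillator populations, 1-D decodes) the per-neuron
intercept quantiles are instead spread uniformly: with a fixed 0.1-active
intercept at $\dim \le 3$, the middle of the represented range is a dead
zone and even the identity function cannot be decoded.

**Learning rules.** Voja is the standard activity-gated encoder shift with
renormalisation (inactive rows bit-identical). PES is implemented
*activity-normalised*: $\Delta d_i = \kappa\,dt\,a_\mathrm{ref}
a_i/\sum_j a_j^2\; E$, so the decoded estimate converges toward the target
at rate $\kappa\,a_\mathrm{ref} \approx 4/\mathrm{s}$ at the reference
$\kappa = 10^{-2}$, independent of population size and sparsity. The raw
form's effective rate varies by orders of magnitude with the activity
distribution; in the SLAM loop it made the map track the drifting belief
faster than loop closure could pull the belief back, which defeats loop
closure entirely (see §5).

## 4. Path integration

Each Fourier coefficient of $\phi(x(t))$ rotates at
$\omega_j = A_j\cdot\dot x$; the implemented field adds the radial term
$(1-r^2)/r$ making the unit circle attracting, so the assembled estimate
stays near unit norm. Only the $\lfloor d/2\rfloor$ free coefficients are
simulated; the DC coefficient is pinned to 1 and the conjugate half is
mirrored on assembly.

* *Ideal tier*: RK4 at $dt = 1$ ms; with piecewise-constant velocities the
  rotation per step is exact up to RK4 truncation, so global error is
  $O(dt^4)$ (verified over $dt \in \{4,2,1\}$ ms). The radial gain is
  clamped below $r = 0.1$: loop-closure corrections can legitimately push a
  coefficient through the origin, where the exact field is singular.
* *Rate tier*: one shared 3-D population per oscillator representing
  $(\omega/\omega_s,\ \mathrm{Re},\ \mathrm{Im})$ at radius 1.5, recurrent
  decoders solved for $\tau f + \mathrm{id}$ on evaluation points
  concentrated on the attractor annulus, $\omega$ input-driven. The
  frequency scale $\omega_s = \tfrac12\max_j\lVert A_j\rVert$ spreads typical
  arena speeds over the represented range. All oscillators share tuning and
  decoders — the vector field is identical for each; only $\omega$ differs
  and $\omega$ is part of the represented state. Tracking quality is
  strongly neuron-limited: ~800 neurons per oscillator hold a 5-s segment
  at high similarity, and dead reckoning at reduced scales degrades within
  tens of seconds, which is the behaviour the full system's loop closure
  exists to fix.

Corrections enter as additive input currents on the half-spectrum
components at rate $1/\tau_\mathrm{syn}$, so a sustained correction acts as
a first-order pull toward the corrected estimate with gain
$\gamma = 0.2$ per $\tau_\mathrm{syn}$ (both config; the correction pathway's
gain and gating are not constrained by the architecture description).

## 5. Mapping and loop closure

Per timestep, landmarks within the view radius ($0.3\times$ arena radius,
closed ball, exact ground-truth displacements — sensory processing is out of
scope) are observed; one is attended per step, round-robin, to avoid
superposed key–value cross-talk during learning. The attended egocentric
encoding is bound with the *cleaned* self-position estimate to form the
allocentric location target, and the feature→location memory takes one
Voja + PES step with that target. A reverse location→feature memory can be
trained symmetrically (independent weights).

Loop closure: when the attended landmark's recall is confident (maximum
lattice similarity above $\theta = 0.5$), the alternative self-position
$\mathrm{recall}(B_i) \circledast \phi(x_i - x)^{-1}$ is formed and
$\gamma(\phi_{ME} - \hat\phi)$ fed back to the oscillators.

**Novelty gating.** Once a landmark's recall confidence exceeds
$\theta_\mathrm{learn} = 0.7$ its map entry stops training. The map then
stores the *past* (first-encounter) belief and recalls it on re-encounter,
which is precisely what makes the correction an anchor. With symmetric
continuous learning the map follows the drifting belief (the two pull on
each other at comparable rates) and loop closure improves dead reckoning
only marginally; with the gate, SLAM error stays flat over the run. The
margin above $\theta$ ensures an association is stored solidly before it
freezes. This gate is the package's design choice, fixed once; it implements
the "recall the past estimate" behaviour the architecture describes.

## 6. Synthetic worlds

Trajectories are per-axis Gaussian white noise, masked in the Fourier
domain to integer harmonics at or below the 0.2 Hz cutoff (an exactly
conjugate-symmetric mask — a floating-point boundary comparison here once
leaked a one-sided line), centred, and rescaled to stay inside
$0.95\times$ the arena radius; velocities are forward differences with the
last value repeated. The cutoff and scaling emulate foraging-style paths
that cross the arena several times per two minutes. Landmarks are uniform
in the arena; features are colour⊛shape composites. What the generator does
*not* emulate: occlusion, viewing direction, sensor noise on displacements,
non-stationary speed statistics, walls as obstacles (the wall region exists
only as a semantic map entry). A green localization test therefore
establishes the vector-symbolic pipeline's correctness, not robustness to
real perception.

The velocity channel encodes the true velocities in a spiking population
(500 neurons at reference scale) and decodes them through the synaptic
filter, after a 5$\tau$ warm-up so the filter's onset transient is not
counted as noise. Its error against the truth is dominated by the known
first-order lag; against the lag-matched reference, noise falls as
$\sim 1/\sqrt{n}$.

## 7. What the acceptance suite shows — and one honest red

The acceptance tests tie the implementation to the reference experiments at
reduced scale: algebra exactness, oscillator-vs-closed-form equivalence,
the NEF fidelity ladder, the worked three-landmark environment (map queries
decode to their published coordinates within 0.05 arena units; the area
query ranks exactly the in-area landmarks on top; the vector-to-landmark
error drops after first encounter), grid-cell field stability with vs
without loop closure, object-vector-cell offset clustering, head-direction
tuning of oscillator neurons, and 3-D generalization on the identical code
path.

One criterion is left red deliberately. The reference result "more than
ten-fold improvement in localization error" arises at full scale, where a
45,000-neuron *spiking* path integrator degrades catastrophically (its
estimate leaves the SSP manifold). At the prescribed reduced-scale testbed —
ideal-tier oscillators with a 0.25-scale spiking velocity channel, 60-s
paths — dead reckoning drifts far less, and the measured improvement ratio
is about 5× (SLAM ATE ~0.006–0.025 vs dead reckoning ~0.04–0.12 across
seeds). A 0.25-scale *rate-tier* integrator fails in the opposite way: it
drifts so fast that the map never stores good anchors. The ratio>10 check is
implemented exactly as prescribed and reports its measured value rather than
being loosened.

## 8. Numerical details worth knowing

* Confidence values are maximum lattice similarities of raw recalls; they
  can exceed 1 slightly (recall norms are not clamped).
* `map_decode` is invariant to positive rescaling of its input; decode
  failure (empty rectified field) falls back to the raw-similarity argmax
  with a flag, and clean-up then passes the input through unchanged.
* The involution inverse is exact for unitary pointers; for Gaussian
  pointers the unbinding similarity concentrates near $1/\sqrt2$ as $d$
  grows (its spread, not its mean, improves with $d$).
* All randomness flows through per-object integer seeds; every generator is
  reproducible from `(seed, config)` alone.
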