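---
title: "Fixed-node diffusion Monte Carlo at desk scale: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixed-node diffusion Monte Carlo at desk scale: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`fndmc` solves the electronic Schrödinger equation in the Born–Oppenheimer
approximation for a fixed set of nuclei, entirely in Hartree atomic units.
The Hamiltonian is

$$\hat H = -\tfrac12\sum_i \nabla_i^2 \;-\; \sum_{I,i}\frac{Z_I}{|\mathbf r_i-\mathbf R_I|}
\;+\; \sum_{i<j}\frac{1}{|\mathbf r_i-\mathbf r_j|}
\;+\; \sum_{I<J}\frac{Z_IZ_J}{|\mathbf R_I-\mathbf R_J|}.$$

Spin never appears as a sampled coordinate: electrons are assigned to a
spin-up block and a spin-down block by position in the coordinate vector,
and antisymmetry is only required within a block.  Model fixtures (harmonic
wells in one or three dimensions) replace the Coulomb potential by a custom
`V(X)` and are first-class systems: every sampler works on them unchanged,
which is what makes the analytic cross-checks in the test suite possible.

## Trial wavefunctions

A trial wavefunction is a behavioural contract: sign and log-magnitude of
$\psi_T$, plus analytic per-electron gradients and Laplacians of
$\log|\psi_T|$.  Everything downstream works with log differences —
Metropolis ratios, Green's-function ratios, determinant combinations — so
unnormalized magnitudes never overflow.  The local energy is

$$E_L = -\tfrac12\sum_i\left[\nabla_i^2\log|\psi_T| +
\left|\nabla_i\log|\psi_T|\right|^2\right] + V,$$

which is constant for exact eigenstates (the zero-variance principle; the
test suite uses this as a hard check on every analytic family).

Built-in families range from single closed forms (hydrogenic $e^{-Zr}$,
harmonic Gaussians, a two-electron Padé–Jastrow
$e^{-Z(r_1+r_2)}e^{u/2(1+bu)}$ that satisfies both Kato cusp conditions for
every $b$) through a minimal-basis Slater–Jastrow with Slater-rule
screening exponents, to a compact neural ansatz: a two-hidden-layer tanh
network applied per electron (trivially permutation-equivariant), linear
heads with trainable STO envelopes $e^{-\alpha_k r}$ feeding a few
determinants per spin channel, times a cusp-correct electron–electron
Jastrow.  All spatial derivatives of the network are propagated in forward
mode and parameter gradients in reverse mode, so no numerical
differentiation enters any sampler.  Deliberate simplification relative to
large neural wavefunctions: there are no cross-electron feature streams, so
each orbital depends on one electron's coordinates only and the determinant
derivative algebra stays single-row
($\nabla_i \log D = \sum_k \Phi^{-1}_{ki}\nabla\phi_k(\mathbf r_i)$, with the
rank-one cancellation making $\nabla_i^2 D / D$ equally cheap).

Every constructed trial passes a self-check: a same-spin transposition
test for antisymmetry and a finite-difference consistency test of the
derivatives.  The finite-difference oracle itself has truncation error
$\sim (h|\nabla\log|\psi||)^2$, so stencils that land within
$\sim 50\,h$ of a node are redrawn rather than silently tolerated.

# Variational Monte Carlo

`metropolis_sample()` runs plain Metropolis with Gaussian proposals and
acceptance $\exp(2\Delta\log|\psi|)$; all-electron moves below five
electrons, single-electron moves above (acceptance scaling).  Burn-in
defaults to 10% of the sweeps, mirroring the DMC equilibration convention.
`vmc_energy()` records per-sweep batch means of $E_L$ and reports the
reblocked mean and standard error.

`optimize_trial()` is plain stochastic gradient descent with the standard
estimator $g_\theta = 2\,\mathrm{Cov}(E_L, \partial_\theta\log|\psi|)$.
Local energies entering the gradient are winsorized at the batch median
± 5 mean absolute deviations (the recorded energies are not).  The
optimizer exists to generate training trajectories for the VMC–DMC
extrapolation and to exercise the train → project workflow; nothing in the
package depends on it converging quickly, which is why a natural-gradient
method was not implemented.

# The DMC engine

One iteration per walker:

1. **Drift–diffuse.** $\mathbf x' = \mathbf x + \bar{\mathbf v}\tau +
   \chi\sqrt{\tau}$, where the drift $\mathbf v = \nabla\log|\psi_T|$ is
   limited per electron by
   $\bar{\mathbf v} = \mathbf v\,(-1+\sqrt{1+2|\mathbf v|^2\tau})/(|\mathbf v|^2\tau)$,
   which caps the divergent drift near nodes and nuclei and reduces
   time-step error.
2. **Fixed-node rejection.** Any proposal whose trial sign differs from the
   walker's current sign is rejected unconditionally.  Node crossing is
   detected by the sign change alone (no continuous path check); this is
   exact in the $\tau\to 0$ limit and standard practice.
3. **Metropolis on the importance-sampled Green's function.**
   $A = \min\{1, [\psi(\mathbf x')^2 G(\mathbf x'\!\to\!\mathbf x)] /
   [\psi(\mathbf x)^2 G(\mathbf x\!\to\!\mathbf x')]\}$ with
   $G \propto \exp(-|\mathbf x'-\mathbf x-\bar{\mathbf v}\tau|^2/2\tau)$.
   The effective time step is rescaled each iteration by the
   accepted-to-proposed mean-squared-displacement ratio.
4. **Weights.** $w \leftarrow w\,\exp[-\tau_\mathrm{eff}(\tfrac12(\bar
   E_L(\mathbf x') + \bar E_L(\mathbf x)) - E_T)]$, where $\bar E_L$ is the
   local energy clipped to the running estimate
   $\pm\,\alpha_\mathrm{clip}/\sqrt{\tau}$ (default
   $\alpha_\mathrm{clip} = 0.2\sqrt{n_\mathrm{el}}$).  Clipping bounds the
   weight kick a rare near-singular configuration can deliver, which is
   what restores size consistency for well-separated fragments.
5. **Branch–merge at constant population.** Every walker heavier than the
   branch threshold (default 2.0) splits into two half-weight copies; for
   each split the two lightest walkers merge into one, positioned at one of
   the pair chosen proportionally to weight and carrying the summed weight.
   No merging happens without a branch, the population never changes, and
   total weight is conserved exactly (the merge is unbiased in expectation
   for any weighted observable).  One pass per iteration: walkers created
   by a merge are not re-examined until the next step, which also rules out
   branch/merge churn cycles.  Calibration on helium (four seeds at
   $\tau = 0.005$) showed that *more* aggressive thresholds near 1 increase
   the estimator variance — constant resampling correlates walkers — while
   threshold 2.0 leaves branching rare and the error bars honest (empirical
   seed-to-seed spread matching the reblocked claims).
6. **Trial-energy feedback.** $E_T = E_\mathrm{best} -
   \log(W/W_\mathrm{target})/t_\mathrm{damp}$ with
   $t_\mathrm{damp} = 10\tau$ by default; logarithmic negative feedback
   that pins the total weight near the setpoint while $E_T$ tracks the
   running mixed estimate.

The energy estimator is the mixed estimator: the per-iteration
weight-averaged clipped local energy.  The first 10% of iterations are
discarded as equilibration; the production mean is weighted by the
per-iteration total weights and its error comes from reblocking.

## Reblocking

Flyvbjerg–Petersen pairwise blocking.  The plateau is the first level at
which the standard-error estimate moves by less than 5% over two successive
levels.  When no plateau is found the deepest level with at least eight
blocks is used — below eight blocks the stderr estimate's own noise
dominates anything it measures.  The reported error is floored at the naive
(unblocked) value, since autocorrelation can only inflate it.

## Time-step extrapolation

`dmc_tau_extrapolation()` runs the engine at several $\tau$, scaling the
step count as $1/\tau$ so every run covers the same total imaginary time,
and extrapolates linearly to $\tau \to 0$ by inverse-variance-weighted
least squares.

# The VMC–DMC linear relation

Along a variational optimization the DMC energy relative to its final value
is empirically linear in the VMC–DMC gap,
$E^{(k)}_\mathrm{DMC} - E_\mathrm{final} =
w\,(E^{(k)}_\mathrm{VMC} - E^{(k)}_\mathrm{DMC}) + b$,
with $E_\mathrm{final}$ the DMC energy at the last available training step
(when a trajectory is truncated early, the last collected point plays that
role and $w$ is refit).  The intercept cannot be identified from the
trajectory itself, so absolute-energy extrapolation requires $b$ as user
input; for *relative* energies the intercept is assumed common to the two
configurations and cancels:

$$\Delta E_\mathrm{ex} = (1+w)\,\Delta E_\mathrm{DMC} - w\,\Delta E_\mathrm{VMC}.$$

`extrapolation_distribution()` applies this at every shared training step
with one pooled slope.  The pooled fit shares the slope but gives each
trajectory its own intercept (each is referenced to its own final energy);
a common-intercept fit would be misspecified whenever the final gaps
differ.  Ordinary least squares is unweighted by default — a weighted
variant is available — because the per-point errors along a trajectory are
typically comparable.  The per-step extrapolated values of a noiseless
linear trajectory are constant by construction, and under noise their
spread contracts relative to the raw DMC differences; both properties are
asserted in the tests.

# Nodal-surface geometry

The distance from a configuration to the nodal surface starts from the
first-order estimate $|\psi|/|\nabla\psi| = 1/|\nabla\log|\psi||$, marches
along the downhill gradient ray with geometrically growing steps until the
sign flips (falling back to the opposite ray when the envelope gradient
dominates and the downhill ray runs parallel to the node), bisects the
bracket, and then polishes the witness: Newton re-projection
$z \leftarrow z - \nabla\log|\psi| / |\nabla\log|\psi||^2$ alternating with
tangent-plane slides toward the foot of the perpendicular from the query
point.  The result is an upper bound on the true distance up to the
tolerance, which the tests verify against dense grid searches.

Node sampling restricts Metropolis $\psi^2$ sampling to the shell where the
*first-order* distance estimate is below $\varepsilon$ (default 0.1 bohr,
$K = 4096$ samples) and projects every retained sample to the surface
through the distance witness — the nearest-point map realizes the
pushforward of the $\psi^2$ density onto the node, so regions of the
surface with larger nearby $|\psi|$ are weighted more, exactly the regions
walkers visit.  The exact shell membership test would itself require a
distance solve per proposal; the first-order surrogate is the documented
approximation, and its bias is controlled by grid-oracle comparisons in the
tests.

The divergence between two nodal surfaces is the Monte-Carlo mean of the
distance from $\psi_1^2$-weighted samples on $S_1$ to $S_2$ (the
expectation form implies the mean over the $K$ samples; reported with its
Monte-Carlo standard error).  It is non-negative, vanishes on identical
surfaces up to projection tolerance, and is deliberately asymmetric.  On a
family of two-fermion trials whose node rotates away from the exact one it
grows monotonically with the rotation angle — the desk-scale surrogate for
tracking node convergence along a training run.

Visualization follows two protocols: two-dimensional slices obtained by
moving one electron over a square (default $[-5, 5]^2$ bohr) with all
others frozen, recording log-magnitude and sign per pixel; and for
four-electron atoms a three-dimensional cut in $(r_1, \cos\theta_1, r_3)$
over $r \in [0.1, 2.1]$ bohr and $\cos\theta_1 \in [-1, 1]$ with the other
spherical coordinates frozen at the standard scan values.  The
$[-1, 1]$ range for the first electron's angular coordinate is read as a
range of $\cos\theta_1$: an angle range of $[-1, 1]$ radians would break
the symmetry of the sweep.

# Study conditions and what passes mean

Fixed desk-scale problem sizes, chosen once from an a priori error budget
(per-sample variance of the helium trial $\approx 0.17\ \mathrm{Ha}^2$,
integrated autocorrelation time $\approx 0.2/\tau$ iterations):

* hydrogen and the 1-D two-fermion well: 300 walkers × 1500 steps at
  $\tau = 0.01$ — zero-variance checks, exact to numerical precision;
* helium: 4000 walkers, $\tau \in \{0.02, 0.01, 0.005\}$ with
  5000/10000/20000 steps (equal imaginary time 100 $\mathrm{Ha}^{-1}$),
  giving $\approx 0.4$ mHa per point and $\approx 0.9$ mHa on the
  $\tau \to 0$ intercept — the 1 mHa agreement with the order-4 Hylleraas
  reference ($-2.903714$ Ha, itself within 0.1 mHa of the exact
  nonrelativistic value) is therefore a $\sim\!1\sigma$ check and can fail
  on an unlucky seed without indicating a defect;
* size consistency: two hydrogen atoms at 20 bohr with a product trial,
  1000 walkers × 4000 steps, compared against twice the single-atom run;
* beryllium: the compact neural trial (two determinants, width 16, ~500
  parameters) trained by 2000 SGD iterations on batches of 256 walkers,
  then 512 walkers × 4000 DMC steps at $\tau = 0.01$.

The beryllium target — within 1 mHa of the exact $-14.66736$ Ha — is **not
reached** at this scale and the corresponding test is left failing by
design: SGD trains the network to $E_\mathrm{VMC} \approx -14.626$ Ha and
the fixed-node projection lands near $-14.66$ Ha, about 6 mHa high.  The
residual is a nodal-surface error: Be's $2s^2 \to 2p^2$ near-degeneracy
needs the equivalent of four determinants with p-character, which plain
first-order SGD does not discover in desk-scale time (a four-determinant
variant with jittered initialization trained to a *worse* node).  The run
still demonstrates the headline qualitative behaviour: the projection
recovers roughly three quarters of the trial's missing energy, far more
than the variational step alone.

What the synthetic fixtures do and do not show: the harmonic wells and
hyperplane-node trials have analytically known spectra and nodes, so they
validate the propagation, population control, estimator and nodal-geometry
machinery exactly — but they probe neither heavy-atom cusp behaviour, nor
multi-nucleus geometry, nor the high-dimensional node topologies of real
molecules.  Passing them certifies the algorithms, not chemical accuracy on
arbitrary systems.

# Numerical choices and degenerate inputs

* Coincident particles (distance $\le 10^{-12}$ bohr) raise a singular-
  configuration error in the scalar API; the samplers count and resample
  such walkers instead of aborting.
* A walker whose local energy turns non-finite is replaced by a copy of a
  healthy walker (weight kept) and counted in the diagnostics.
* Determinants with one or two orbitals per spin use closed-form
  vectorized inverses; larger blocks fall back to per-walker LU.
* The configuration format is YAML: a plain-text key-value dialect with a
  parser available to the package, serving the same reproducibility
  contract (the fully resolved configuration is echoed into every output
  directory).  Flags on the `fndmc` command line override config values.
* One RNG stream per run, seeded once; checkpoints store the stream, so a
  resumed run is bit-identical to an unbroken one.

# Known limitations

* Single process only; the constant-population contract is per process and
  no load balancing exists.
* The neural ansatz is atoms-only and deliberately small; no cross-electron
  streams, no pretraining, no natural-gradient optimizer.
* No pseudopotentials, excited states, forward walking, or released-node
  estimates.
* The Slater–Jastrow defaults use Slater screening rules and support at
  most five same-spin electrons (minimal s/p shells); it is a node
  provider for diagnostics, not a production ansatz.
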