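---
title: "Methods: perturbative field coupling through atomic polar tensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perturbative field coupling through atomic polar tensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `aptmd`, the choices that were
genuinely open when the package was designed, and what the synthetic test
systems do and do not establish about real condensed-phase simulations.

## The model

The interaction of an atomistic system with a homogeneous electric field
**E** is treated perturbatively, truncating the series expansion of the
Hamiltonian at first order in the field:

$$\mathcal{H}_\mathbf{E}(\mathbf r, \mathbf p)
 = \mathcal{H}_0(\mathbf r, \mathbf p) - \mathbf E \cdot \mathbf M(\mathbf r).$$

Hamilton's equations then give the force on atom $i$ as the zero-field
force plus the field-induced term

$$F_{i\xi} = -\frac{\partial E_\mathrm{pot}}{\partial r_{i\xi}}
 + \sum_\zeta \frac{\partial M_\zeta}{\partial r_{i\xi}} E_\zeta,$$

where $\partial M_\zeta / \partial r_{i\xi}$ is the atomic polar tensor
(APT) of atom $i$ — the transpose of which, contracted with the field,
is the field-induced force. Everything in the package follows from this
decomposition:

* the unperturbed potential is *any* force provider (`potentials` module);
* the APTs are *any* tensor provider (`apt` modules): analytic models,
  a finite-difference oracle, or a regressor trained at zero field;
* the dipole rate $\dot{\mathbf M} = \sum_{i\xi}
  (\partial \mathbf M/\partial r_{i\xi})\, v_{i\xi}$ is accumulated along
  trajectories and integrated into the itinerant dipole moment, from which
  polarization, dielectric constants and IR spectra follow.

Assumptions inherited from the truncation: the response is dipolar only
(no polarizability or hyperpolarizability, so very strong fields are out of
scope), and the field is homogeneous (no field-gradient/quadrupole
coupling).

**Index convention.** Tensors are stored as `tensors[i, zeta, xi]` =
$\partial M_\zeta/\partial r_{i\xi}$: row = dipole component, column =
displacement component. The field force is
`F[i, xi] = sum_zeta tensors[i, zeta, xi] * E[zeta]` and the dipole rate is
`Mdot[zeta] = sum_{i, xi} tensors[i, zeta, xi] * v[i, xi]`. One documented
convention removes the main index-transposition trap of this scheme; the
unit tests pin it with the point-charge limit, where both contractions
reduce to `q_i E` and `sum q_i v_i`.

## Units

Internal units are Å, fs, eV, elementary charge e, K. A field in V/Å is
numerically an eV e⁻¹ Å⁻¹, so the field–charge coupling carries no
conversion factor (test-asserted: charge e in a field (0,0,1) V/Å feels
exactly (0,0,1) eV/Å). Masses enter in g/mol and are converted by
1 g/mol = 103.642697 eV fs² Å⁻²; ε₀ = 5.526349×10⁻³ e² eV⁻¹ Å⁻¹;
kB = 8.617333×10⁻⁵ eV/K. Dipoles are e·Å, polarization e·Å⁻².

## Synthetic reference systems

The package ships three generated systems, chosen so that every observable
has an exact or closed-form reference:

* **Flexible toy water** (O,H,H; SPC/E charges qO = −0.8476 e, harmonic
  bonds r₀ = 1 Å and angle θ₀ = 109.47°, O–O Lennard-Jones, real-space
  damped-shifted-force Coulomb with Wolf damping 0.2 Å⁻¹ and a 6 Å
  cutoff). Forces are exactly differentiable, which the finite-difference
  property tests exploit. The Wolf/DSF choice replaces Ewald deliberately:
  at desk scale the point is an exactly testable, translation-invariant
  electrostatic term, not a production water model.
* **Ideal dipolar gas**: diatomics carrying ±q bound by a harmonic bond,
  with *no* intermolecular interactions. Its dielectric constant has the
  Langevin closed form $\varepsilon_r - 1 = N\mu^2/(3\varepsilon_0 V k_B T)$
  with $\mu = q r_0$, making it the analytic oracle for both the
  field-sweep and fluctuation routes. Default conditions for the
  consistency experiment: N = 200 molecules, L = 40 Å, q = 0.83 e,
  r₀ = 1 Å, T = 300 K, giving $\varepsilon_r - 1 \approx 5$; sweeps use
  the reference increment of 0.0026 V/Å.
* **Charged harmonic diatomics**: the analytic IR reference; the spectrum
  of a vibrationally excited ensemble must peak at
  $\sqrt{k/\mu_\mathrm{red}}/(2\pi c)$.

What these systems do *not* emulate: hydrogen-bond networks and collective
dipolar correlations (Kirkwood factors ≈ 1 here), electronic
polarizability (ε∞ = 1 for all toys), reciprocal-space electrostatics, and
the error structure of learned interatomic potentials. Passing tests
establish the correctness of the *scheme* — force coupling, integration,
statistics, spectra — not the fidelity of any particular water model.

## Thermostats and an ergodicity caveat

Finite-field sampling uses velocity-Verlet with the thermostat applied as
half-steps before and after each step (the splitting is stated because it
is otherwise an undocumented degree of freedom). Two stochastic thermostats
are provided:

* **CSVR** (canonical sampling through velocity rescaling; default time
  constant 1 ps): one global kinetic-energy rescaling per half-step. Its
  stationary distribution is canonical *given* microcanonically ergodic
  underlying dynamics — true for condensed, well-mixed systems like the
  water box.
* **Andersen** stochastic collisions. The ideal dipolar gas is integrable:
  molecules do not interact, and each molecule separately conserves the
  angular momentum component along the field axis, which puts a
  centrifugal barrier between high-angular-momentum molecules and field
  alignment. A global rescaling cannot cross that barrier, and in practice
  the gas settles ~30% below the Langevin alignment regardless of the
  CSVR time constant while its total kinetic energy remains perfectly
  canonical. Andersen collisions resample individual velocities from the
  Maxwell–Boltzmann distribution and therefore sample the canonical
  ensemble without any ergodicity assumption; all dipolar-gas equilibrium
  experiments use them (τ = 500 fs between collisions per atom). This is
  a property of the toy reference system, not of the field-coupling
  scheme.

Time steps: 1 fs under the field, 0.5 fs (or T/100 for stiff bonds) for
zero-field and conservation tests. NVE runs are used for spectra and
relaxation, matching standard practice of excluding thermostat
interference from dynamical observables.

Centre-of-mass momentum is tracked and reported but not removed during
field runs; with sum-rule-projected tensors the net field force vanishes
identically and the drift stays below 10⁻¹⁰ internal units per ps.

## Conserved quantity

Under a static field the monitored quantity is
$E_\mathrm{kin} + E_\mathrm{pot} - \mathbf E\cdot\mathbf M -
W_\mathrm{thermostat}$. Two dipole routes are available for the
$-\mathbf E \cdot \mathbf M$ term: the exact dipole function of an
analytic charge model (used by the conservation tests, drift
< 10⁻⁸ eV atom⁻¹ ps⁻¹), and the trapezoid-integrated itinerant dipole
(always available; carries O(dt²) integration error). Both are exposed
because the "right" choice depends on whether an exact dipole exists.

## Anchored dipole integration

$\dot{\mathbf M}$ is integrated with the trapezoid rule (second order,
matching the anchoring error analysis; the rule is fixed rather than
configurable). *Anchors* — independently computed reference dipoles —
reset the running integral exactly at their time stamps; anchor times
must coincide with stored frames, and no interpolation is performed, so
results are bit-reproducible. The error model: systematic error in the
rate signal accumulates linearly from the last anchor, so the time-mean
dipole error scales with anchor spacing; truncation error alone falls as
dt² (both are asserted in the acceptance tests, on an analytic
bond-charge trajectory whose dipole is known in closed form).

## Statistics

Time averages report SEM adjusted for statistical inefficiency,
`SEM = sd/sqrt(N_eff)` with `N_eff = N·dt_frame/(2·act)` capped at N.
The autocorrelation time `act` can be supplied (the reference analysis
uses a fixed literature value) or estimated by the initial-positive-
sequence rule (`integratedAutocorrelationTime()`); the estimator is used
in the self-consistency experiments so error bars track the actual
sampling quality. The sweep fit is a weighted least-squares line through
the origin (zero polarization at zero field is exact for these systems by
symmetry); `linearRegimeThreshold()` flags the first field whose mean
polarization deviates from the origin-line fit of the preceding points by
more than 2 SEM — the criterion is ours, since "start of nonlinearity"
has no canonical definition.

## IR spectra

The spectrum is the cosine transform of the vector autocorrelation of
$\dot{\mathbf M}$ (averaged over time origins, unbiased normalisation),
scaled by $\pi/(3 V c \varepsilon_0 k_B T)\cdot(1/2\pi)$, reported as the
product $\alpha(\omega)n(\omega)$ — the refractive index is never
separated out. Defaults: Hann window, 2 ps maximum lag; the window is a
documented choice, not physics, and an unwindowed Parseval identity is
test-asserted to 1%. The wavenumber grid runs to the Nyquist limit of the
frame spacing with resolution set by the maximum lag.

## Orientational relaxation

$\Theta$ is the angle between the OH-bisector (3-atom molecules, minimum-
image bond vectors) or the −q→+q bond vector (diatomics) and the field
axis; $\langle\Theta\rangle$ is the arithmetic molecular mean, 90° for an
isotropic ensemble. Relaxation fits use
$\Theta(t) = \Theta_\infty + (\Theta(0)-\Theta_\infty)e^{-t/\tau}$ with
$\Theta(0)$ fixed at the first sample: the offset form is adopted because
steady-state alignment under a field converges to a finite angle, and
fixing $\Theta(0)$ keeps the two remaining parameters identifiable on
short series. Constant series are rejected as unidentifiable rather than
returning an arbitrary τ.

## The APT regressor

The learned tensor model is a *linear* equivariant local expansion,

$$P_i \approx a_{s_i} I
 + \sum_{j\neq i}\sum_k d_{s_i s_j k}\, B_k(r_{ij})\, I
 + \sum_{j\neq i}\sum_k c_{s_i s_j k}\, B_k(r_{ij})
   \left(\hat r_{ij}\otimes\hat r_{ij} - I/3\right),$$

with Gaussian radial basis functions (centres evenly spaced up to the
cutoff, width = spacing) under a cosine cutoff, fit by ridge least squares
on all 9N tensor components. Design rationale: it keeps the defining
contract of equivariant graph-network tensor models — locality,
E(3)-equivariance, training at zero field only — while being exactly
analysable: on fixed-charge data it
must recover $q_i I$ to 10⁻⁸ (it does, with the default ridge of 10⁻¹⁰),
its equivariance is exact by construction, and its capacity grows
monotonically with the basis size on bond-charge data. The model interface
(`aptModel`: a `predict(system)` function) is pluggable, so a nonlinear
backend can replace it without touching the dynamics. Predictions are
sum-rule projected *at predict time, every step*; correcting at train time
instead would also be defensible, but predict-time projection guarantees
charge conservation regardless of the model's training.

Equivariance and periodic boundaries: rotating a periodic configuration is
only an exact symmetry of the minimum-image neighbour environment when no
competing image lies near the cutoff; the numerical equivariance tests
therefore use compact clusters far from the cell boundary, where the
property holds to 10⁻¹⁰ and better.

The acoustic sum-rule projection subtracts the componentwise mean tensor
from every atom. It is idempotent, and among all corrections restoring
the sum rule it is the closest in the Frobenius norm (orthogonal
projection onto an affine subspace) — both properties are unit-tested.

## Numerical choices

* Finite-difference APT step: h = 10⁻³ Å (truncation vs round-off balance
  for e·Å-scale dipoles in double precision); second-order convergence is
  Richardson-tested.
* Minimum image: lower-closed interval [−L/2, L/2), idempotent.
* Positions are never wrapped outside interaction kernels, so charge-model
  dipoles are continuous in time (the integration tests depend on this).
* Ridge default 10⁻¹⁰: large enough to keep the normal equations solvable
  when neighbour features vanish, small enough not to bias exactly
  representable targets beyond ~10⁻⁹; a zero ridge with a singular design
  raises an error advising ridge > 0.
* Extended-XYZ floats are written with `%.17g` so read/write round-trips
  are lossless.

## Problem sizes

The test suite and experiments run at sizes chosen to keep each experiment
statistically meaningful at interactive scale: dielectric consistency uses
200 dipoles with ~30 ps per field point and ~40 ps of zero-field
fluctuation sampling; conservation tests use 8 molecules for 10 ps at
dt = 0.2 fs; spectra use a few diatomics for 8 ps; the orientation
baseline uses 1.5×10⁵ Monte-Carlo orientations. Error bars are computed
from the data, so longer runs sharpen, but do not change, the comparisons.

## Known limitations

First-order (dipolar) field coupling only; homogeneous fields only; cubic
cells only; no constraints, rigid bodies or barostats; the regressor's
descriptors are strictly local, so systems with long-range charge
transfer or unscreened electrostatics are outside its design envelope;
toy electrostatics are real-space damped (no Ewald); ε∞ must be supplied
externally to the fluctuation route (the toys have no electronic
polarizability, so their ε∞ is exactly 1).
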