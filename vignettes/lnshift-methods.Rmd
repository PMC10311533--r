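---
title: "Geometry-driven pseudocontact shift dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry-driven pseudocontact shift dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnshift)
```

## The problem

Tricapped, pseudo-threefold-symmetric lanthanide(III) complexes of the
triazacyclononane-tris(carboxypyridyl) family are prototype PARASHIFT
MRI agents: their readout is the paramagnetic NMR shift of ligand
protons, dominated for remote nuclei by the through-space pseudocontact
(dipolar) term. That term is set by the *anisotropic* part of the
molecular magnetic susceptibility, which in these compounds is unusually
fragile: the axial crystal-field contribution of the macrocycle nitrogen
donors nearly cancels that of the pyridyl nitrogens, and the carboxylate
oxygens sit close to the magic angle, where their rank-2 contribution
vanishes. A change of a few degrees in the O–Ln–axis angle can flip the
sign of the magnetic anisotropy. In solution the coordination cage
oscillates by tens of degrees on the picosecond timescale, so the
instantaneous shift fluctuates enormously around a small time average.

`lnshift` packages the analysis chain needed to study this mechanism on
molecular-dynamics trajectories: trajectory I/O, instantaneous pseudo-C3
axis and donor-angle series, susceptibility-tensor decomposition,
pseudocontact shifts (full tensor and Bleaney's axial model), ensemble
statistics and the superposition-averaged structure — plus a desk-scale
crystal-field surrogate and a stochastic geometry generator so that the
entire chain is testable without large-scale ab initio calculations.

## Geometric model

**Pseudo-C3 axis.** The instantaneous axis is the renormalised mean of
the unit normals of three donor planes: the O triplet, the axial-N
triplet and the equatorial-N triplet. Normals are oriented towards the
axial-N side (reference: O-centroid to N_ax-centroid vector), which
fixes a consistent hemisphere for the angle series. The axis is
recomputed in every frame rather than frozen from frame 0: the
large-amplitude oscillations of interest are *instantaneous* angles
against the instantaneous quasi-symmetry axis, and a frozen axis would
conflate internal motion with overall tumbling.

**Angles.** `donor_axis_angle()` is the arccos of the normalised
metal-to-donor vector against the axis, in degrees; arm identity follows
donor-map order and is stable over time. All geometry is unweighted (no
mass weighting), and all outputs are invariant under rigid motions of
each frame.

## Pseudocontact shift models

**Full tensor (point-dipole).** With the metal-to-nucleus vector
$\mathbf r$ (m), $r = |\mathbf r|$, and the traceless part
$\tilde\chi$ of the per-molecule susceptibility (m$^3$),

$$\delta_{\mathrm{pc}} \;=\; \frac{10^6}{4\pi r^5}\,
  \mathbf r^{\mathsf T}\tilde\chi\,\mathbf r
  \;=\; \frac{10^6}{12\pi r^5}\left[
    \Delta\chi_{\mathrm{ax}}\,(3z^2 - r^2)
    + \tfrac{3}{2}\,\Delta\chi_{\mathrm{rh}}\,(x^2 - y^2)\right],$$

the second form written in the principal axis system. Both forms are
evaluated on every call and asserted equal — the decomposition
conventions are therefore continuously cross-checked in production, not
only in tests. Distances below 0.5 Å are rejected (point-dipole
validity). Unit bridge: quantum-chemistry style cgs molar tensors
(cm$^3$\,mol$^{-1}$) convert to per-molecule SI (m$^3$) by
$\chi_{\mathrm{SI}} = \chi_{\mathrm{cgs}}\cdot 4\pi\times10^{-6}/N_A$.

**Tensor decomposition.** `decompose_chi()` diagonalises the traceless
part; z carries the eigenvalue of largest magnitude, x the larger of the
remaining two, giving the standard paramagnetic-NMR constraint
$|\Delta\chi_{\mathrm{rh}}| \le \tfrac23|\Delta\chi_{\mathrm{ax}}|$ and
a right-handed frame. Sign ambiguity of eigenvectors (and the tie-break
for degenerate eigenvalues) is resolved by making each axis positive in
its largest component. Easy-axis means a positive traceless $\chi_{zz}$
(one large, two small eigenvalues); easy-plane the reverse.

**Bleaney model.** $\delta \propto C_J B_2^0 (3\cos^2\theta - 1)/(r^3
T^2)$. The printed literature forms of the absolute prefactor vary by
convention, so the default emits Bleaney-convention relative units with
$C_J$ from the customary table normalised to $C_{\mathrm{Dy}} = -100$,
and a `prefactor` hook accepts an absolute convention. Package tests
assert only ratios, nulls and scalings of this model, never absolute
magnitudes.

## The crystal-field surrogate

The surrogate replaces multireference spin-orbit electronic-structure
calculations with a ground-multiplet crystal-field model. **It makes no
claim of quantitative agreement with ab initio susceptibilities**; it is
built to reproduce the mechanisms — the magic-angle null, the
axial/equatorial cancellation, sign flips of the anisotropy under small
angular changes, and the correct Curie limit — at negligible cost.

* **Basis**: the isolated ground multiplet $|J, m_J\rangle$ (default
  Dy(III): $J = 15/2$, $g_J = 4/3$, 16 states). Excited multiplets,
  intermultiplet mixing and covalency are ignored.
* **Operators**: rank-$k$ spherical tensors built by ladder recursion
  from $J_+^k$, combined into real tesseral Hermitian operators. $q = 0$
  operators are rescaled to the classical Stevens polynomials
  ($O_2^0 = 3J_z^2 - J(J+1)$ exactly); $q \ne 0$ operators keep the
  spherical-tensor relative normalisation of their rank rather than the
  historical Stevens prefactor tables. The point-charge module uses the
  *dual* tesseral harmonics, so $\sum_{kq} B_k^q O_k^q$ equals a
  rotationally invariant contraction per charge and the whole chain is
  exactly equivariant: rotating the charge set rotates the
  susceptibility tensor. No result depends on the $q \ne 0$ absolute
  scale.
* **Point charges**: $B_k^q \propto A_k \sum_i q_i\,
  z_{kq}(\theta_i,\varphi_i)/R_i^{k+1}$, with the single-charge $B_2^0$
  proportional to $q(3\cos^2\theta - 1)/R^3$. The per-rank factors
  $A_k$ fold the Stevens reduced matrix elements
  ($\theta_2 = -2/315$, $\theta_4 = -8/135135$, $\theta_6 = 4/3864861$
  for Dy(III)), Freeman–Watson radial expectations and the Coulomb
  constant, electron-charge sign included. They are configuration
  inputs; tests rely only on their signs, nulls and ratios.
* **Susceptibility**: the equilibrium (Van Vleck) molar tensor
  $\chi_{\alpha\beta} = -N_A\,\partial^2 F/\partial B_\alpha\partial
  B_\beta$ at zero field, temperature default 298 K. Two independent
  implementations are kept: central finite differences of the
  analytically evaluated magnetization $M = -\partial F/\partial B$
  (step 1 mT, Richardson-extrapolated over $h$ and $h/2$), and an
  analytic sum over states with first-order terms summed inside
  degenerate blocks (grouped at $10^{-8}$ cm$^{-1}$, basis-invariant
  trace form) and a numerically stable `expm1` Boltzmann-difference
  factor for the second-order terms. The default method runs both and
  raises an error if they disagree beyond $10^{-6}$ relative.

Numerical notes that mattered: differencing $\ln Z$ itself at 1 mT is
hopeless in double precision (the field-dependent part is ~$10^{-10}$
of $\ln Z$), which is why the finite-difference route differences the
magnetization; and plain Boltzmann weight differences lose ~11 digits
for Kramers doublets split only by eigensolver noise, which is why the
sum over states uses the `expm1` form.

## The synthetic-geometry generator

`simulate_trajectory()` emulates the statistics of the coordination-cage
motion seen in solution simulations of these complexes, not the forces
behind it:

* each arm's donor polar angles follow independent stationary
  Ornstein–Uhlenbeck processes. Defaults are the solution-phase
  conditions: O mean 52° with σ = 8° (matching reported means of
  ~50–55° and oscillations of ±10–20°), N_ax 39° ± 5°, N_eq 90.5° ± 5°,
  correlation time τ = 100 fs (a free parameter — printed data do not
  constrain it; the value gives trace roughness similar to published
  angle/time figures), timestep 1 fs;
* bond lengths get i.i.d. normal jitter (σ = 0.02 Å);
* the pyridyl protons ride rigidly with their arm (their polar angles
  are offset by the arm's instantaneous O-angle deviation);
* an optional global rigid-rotation random walk (default off) exercises
  the rotation-invariance of the analysis;
* a single seeded RNG stream makes every run bit-reproducible.

An OU process is a modelling choice: the published trajectories show
bounded, large-amplitude, partially independent arm oscillations but no
dynamical model; a stationary Gaussian process with one correlation
time is the simplest process with those features. Arms evolve
independently (no arm–arm coupling). Default charges are O = −0.8 e,
N_ax = −0.49 e, N_eq = −0.40 e, a sign pattern that makes the axial and
equatorial rank-2 contributions oppose; magnitudes are tunable
configuration, not claims about the real complex.

What the generator does *not* emulate: explicit solvent, hydrogen
bonding, anharmonicity, arm–arm correlations, conformational
interconversion. Tests passing on synthetic data therefore validate the
analysis operators and the mechanism chain, not force-field realism.

**The near-cancellation regime.** The real compounds sit where the
*time-averaged* $B_2^0$ is close to zero, which is what separates the
huge instantaneous shift fluctuations from the small experimental
averages. `cancellation_o_angle()` defines that regime for the
surrogate deterministically: it root-finds the O-angle OU mean at which
the stationary-*expected* $B_2^0$ (Gaussian quadrature over the angle
distributions; bond jitter neglected) is exactly zero, rather than
tuning anything by simulation. With default charges this lands at
~54.3°, between the reported solution means and the magic angle. At
5 ps of synthetic trajectory the per-triplet time averages are still
sampling-noisy — exactly the short-trajectory caveat the underlying
studies emphasise — so the scale-separation property (fluctuation range
exceeding ten times the absolute time average) is asserted on the
pinned default-seed run.

A caveat found while validating the generator: because the pseudo-C3
axis is built from the donor planes, it co-moves with the fluctuating
donors, attenuating the *apparent* per-arm angle variance measured
against it (σ ≈ 6–7° recovered for a configured 8°). OU parameter
recovery is therefore checked on the donor polar angles in the
generator's molecular frame, and the attenuation itself is asserted as
a property of the axis-referenced series.

## Ensemble statistics

Superposition uses the SVD-based Kabsch algorithm with the reflection
branch corrected ($\det R = +1$ always); the average structure aligns
every frame onto frame 0 (all atoms, unweighted — the cited
superposition literature does not fix a weighting) and averages
coordinates, reporting per-atom RMSF. Descriptive statistics use the
population standard deviation (divide by $n$): a trajectory is treated
as the full population of frames, and the "±" accompanying published
averages is taken as that spread. Histograms use uniform bins snapped
to multiples of the bin width (defaults 5 ppm for shifts, 1° for
angles; the published histogram figures state no binning), half-open
except the last bin. Correlations are plain Pearson.

## Pipeline, problem sizes and determinism

`run_end_to_end()` chains simulate → angles → per-frame point-charge
crystal field → Van Vleck tensor → pseudocontact shifts → statistics →
average structure, and writes all artifacts plus a manifest (seed and
config hash). The default analysis cadence evaluates the susceptibility
every 30th frame of a 1 fs-timestep trajectory, mirroring the typical
cost balance of tensor evaluations along such trajectories; geometry is
analysed on every frame. The bundled acceptance script runs 10,000
frames (10 ps) with that cadence, i.e. 334 tensor evaluations; the test
suite uses 200–5000 frames per case. All stochastic tests pin seeds;
identical seeds reproduce identical trajectories bitwise.

## Known limitations

* The crystal-field surrogate is mechanism-level only; absolute shift
  magnitudes from the default charge set are not calibrated to any
  measured complex (no numeric crystal-field parameters for the real
  Dy complex are available to calibrate against).
* Contact (spin-delocalisation) shifts are out of scope — negligible
  for the remote pyridyl protons this pipeline targets, not for
  metal-bound nuclei.
* The tensor-fitting inverse problem (shifts → susceptibility) is not
  implemented.
* Solvent atoms, periodic-boundary unwrapping and box handling are out
  of scope; the complex is assumed whole in each frame and only atoms
  named in the donor map are analysed.
* Only the 3+3+3 donor topology is supported; there is no general
  symmetry detection.
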