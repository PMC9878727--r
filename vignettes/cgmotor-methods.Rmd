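---
title: "Coarse-grained model building for molecular motors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained model building for molecular motors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cgmotor)
```

# The problem

Coarse-grained (CG) simulation represents groups of atoms as single
interaction sites (beads), extending reachable scales by orders of
magnitude. For conjugated, fused-ring compounds such as second-generation
molecular motors and hemithioindigo-type switches, the standard Martini
recipe applies: tiny (T) beads carry the aromatic fragments, small (S)
beads the bulkier polar moieties, and virtual sites — massless beads
constructed geometrically from others each step — keep fused-ring
mappings consistent and provide pivots for stator–rotor dihedrals.

Nonbonded behaviour comes from the bead-type assignment; the *bonded*
model, in contrast, must be derived per molecule from an atomistic
reference. `cgmotor` implements that derivation loop and its validation
statistics in a form that runs entirely at desk scale: the atomistic
trajectory is replaced by a synthetic ensemble with planted ground truth,
and the CG engine by an internal Monte Carlo sampler, so that every stage
of the pipeline is testable against exact or closed-form answers.

# The bonded model

A `cg_topology` carries beads with size classes (default radii
regular 0.264 nm, small 0.230 nm, tiny 0.191 nm — overridable per bead)
and four bonded term types, with degrees and nm at every I/O boundary and
radians internally:

* bonds: $V = \tfrac12 k (r - r_0)^2$, or a fixed-length constraint;
* harmonic angles: $V = \tfrac12 k_f (\theta - \theta_0)^2$;
* quartic angles: $V = \sum_{n=0}^{4} C_n (\theta - \theta_0)^n$, the
  polynomial form able to carry a double well, used wherever an angle
  distribution is bimodal;
* proper dihedrals: $V = k_\phi (1 + \cos(n\phi - \phi_0))$, several
  cosine terms per quad allowed.

Virtual sites are placed as unweighted (cog) or weighted means of their
constructor beads after every move; they carry no independent degrees of
freedom. A bonded term may involve only virtual beads in exactly one
situation — a dihedral pivoting on a virtual site, as in the stator–rotor
torsion of the motor models. Topologies round-trip exactly through a
GROMACS-dialect `.itp` subset (`[moleculetype]`, `[atoms]`, `[bonds]`,
`[constraints]`, `[angles]` with function types 1 and 6, `[dihedrals]`
types 1/9, `[virtual_sitesn]` types 1/3).

# Forward mapping

`map_ensemble()` projects an atomistic ensemble through a
`mapping_scheme`: each real bead at the centre of geometry (default, the
Martini heavy-atom convention) or centre of mass of its atom group,
virtual beads filled afterwards from the topology rules. Mapping commutes
with rigid motions and preserves the frame count. Schemes are plain JSON
with 1-based atom indices; `check_scheme()` cross-checks scheme and
topology (bead counts and names, unconstructible virtual sites,
unassigned atoms) and reports findings machine-readably rather than
failing.

# Distribution statistics and the MAE

`extract_distributions()` histograms every bonded term (bin widths
0.001 nm for bonds, 1° for angles and dihedrals, configurable), with
linear moments for bonds and angles and circular moments for dihedrals
(wrapped to (−180°, 180°]). Angle modality is detected on a
kernel-smoothed density: maxima above 10 % of the global maximum,
separated by at least 15°, two of which mark a bimodal term. Dihedral
modes use the analogous circular detector on the binned density, since a
symmetric multi-well torsion has no meaningful circular mean.

Model quality is summarized as the mean absolute error of per-term
distribution means, computed per category — bonds (nm), unimodal angles
(degrees), bimodal angles (degrees, modes paired by nearest angle and
averaged). This "MAE over term means" reading is the only one that yields
numbers in nm and degrees; it is also exactly the quantity the refinement
loop controls. The default acceptance thresholds are 0.0025 nm, 5.5° and
11.4°.

# Fitting: Boltzmann inversion plus iterative matching

The initial guess is direct Boltzmann inversion of the mapped target
distributions, $V(x) = -k_BT \ln p(x)$:

* harmonic terms: $x_0$ = distribution mean, $k = k_BT/\sigma^2$
  ($k_B$ = 0.0083145 kJ mol⁻¹ K⁻¹; angle widths converted to radians);
  a vanishing $\sigma$ is reported as a constraint recommendation;
* quartic angles: least squares of the inverted, min-anchored profile on
  $\{1, x, x^2, x^3, x^4\}$ over bins above a density floor (10⁻⁴ of the
  maximum, to keep the log finite), with $\theta_0$ at the
  density-weighted mean;
* dihedrals: linear least squares on the basis
  $\{1 + \cos(n\phi - \phi_{0,n})\}$ with phases chosen in {0°, 180°} so
  amplitudes are non-negative.

**Angular Jacobian.** An angle sampled in 3-D carries the volume element
$\sin\theta$: the observed density is
$p(\theta) \propto \sin\theta\, e^{-\beta V(\theta)}$. The low-level fit
functions invert the literal density by default (`jacobian = "none"`),
but the pipeline (`boltzmann_invert()`) divides by $\sin\theta$ first
(`jacobian = "sine"`), the standard iterative-Boltzmann-inversion
practice; without it, a fitted quartic well re-sampled in 3-D would
acquire the Jacobian twice and its modes would drift. Harmonic terms need
no such care because the refinement loop matches moments directly.

`refine()` then iterates: sample the current model with the internal
sampler, extract distributions, score the MAE, and apply damped moment
updates to the harmonic terms,
$x_0 \leftarrow x_0 + d\,(\mu_\mathrm{target} - \mu_\mathrm{model})$ and
$k \leftarrow k\,(\sigma^2_\mathrm{model}/\sigma^2_\mathrm{target})^{d}$
with damping $d = 0.7$ by default (1 converges fastest on these small
systems; 0.7 is a safe general default, and both reach the same
parameters). Quartic and dihedral terms keep their direct inversion —
refinement adjusts, it never refits from scratch. The loop stops at the
MAE thresholds or `max_iterations`, returning the best iterate seen.
Because the updates match the very moments the MAE measures, convergence
is typically reached in 2–4 iterations.

# The Monte Carlo sampler

`sample_cg()` runs a single-molecule Metropolis chain on the bead
coordinates under the bonded energy: one step proposes a Gaussian
displacement (size `move_sigma`) of one randomly chosen movable bead.
Virtual sites are re-placed after every accepted move. The move size
adapts toward 40 % acceptance during burn-in only (default one tenth of
the production length) and is frozen afterwards; burn-in frames are never
recorded. Chains are bit-reproducible for a given seed, and a chain
rejecting 10⁴ consecutive proposals aborts with diagnostics rather than
silently producing a frozen ensemble.

Constrained bonds are sampled *on* the constraint surface: a move of a
constrained bead resamples the bond direction and renormalizes to exactly
$r_0$, so constraint violation is zero to machine precision. Only pendant
constraints are supported (a bead in at most one constrained bond);
constraint chains would need a coupled solver and are rejected at
validation. The direction-resampling proposal is symmetric only to first
order in the move size; for the bond-length statistics this package uses
constraints for, the residual bias is far below sampling noise.

Because sampling is in Cartesian coordinates, bond lengths carry the
radial $r^2$ weight: the stationary density is
$p(r) \propto r^2 e^{-\beta V(r)}$, so the length variance equals
$k_BT/k$ only up to a factor $1 - k_BT/(k r_0^2) + \dots$. At
$k = 1250$ kJ mol⁻¹ nm⁻², $r_0 = 0.35$ nm this correction is 3 %; in the
stiff regime ($k r_0^2/k_BT \gtrsim 100$) it is below 1 %. Tests
therefore compare moderate-stiffness bonds against the exact quadrature
oracle and reserve the bare equipartition closed form for stiff bonds.

**Enforced rotation** mimics the motor drive as a toy model: reference
positions of the rotor beads rotate rigidly about the axle direction at a
fixed rate (80°/ps in the standard protocol, completing a turn in
4.5 ps), and an isotropic harmonic restraint
(k = 280 kJ mol⁻¹ nm⁻², no mass weighting) couples each rotor bead to its
reference. "Pivot-free" is realized by centring the reference on the
rotor's instantaneous centroid. MC sweeps advance a fictitious clock
(0.002 ps per sweep by default) so rates in ps are meaningful; this is a
stated toy-model convention, not dynamics. The exact functional form of
the MD engine's pivot-free iso potential is not public in detail; the
simplified isotropic restraint reproduces its operational behaviour
(rotor tracks the schedule with a bounded steady lag).

**Switching** between stereoisomers is mimicked by continuing a finished
chain from its last coordinates under the other isomer's topology
(`switch_topology()`), recording per-frame energies as the relaxation
trace. Switch–switch-back recovers the original equilibrium.

# Free-energy estimators

* `ti_integrate()`: trapezoidal quadrature of per-λ means of
  $\langle\partial H/\partial\lambda\rangle$ (the decoupling protocol uses
  21 evenly spaced λ values), with per-λ standard errors propagated
  through the quadrature weights.
* `bar_estimate()`: solves
  $\sum_F f(\beta(W_F - \Delta G + M)) = \sum_R f(\beta(W_R + \Delta G - M))$,
  $f(x) = 1/(1+e^x)$, $M = \ln(n_F/n_R)/\beta$, by bracketed root finding
  with automatic bracket expansion, reporting the asymptotic variance. On
  delta-distributed work the root is exact
  ($W_F \equiv 10$, $W_R \equiv -6$ gives ΔG = 8 in closed form).
* `wham()`: self-consistent histogram reweighting on a fixed grid
  (default 300 bins), iterated to 10⁻⁷ relative tolerance on the window
  free energies; uncertainty from 100 bootstrap replicates, resampling
  each window's own time series with replacement (the conservative
  window-block choice). The profile is min-anchored at zero; comparisons
  against a known PMF are made after removing the arbitrary additive
  constant, since min-anchoring alone would transfer the noise of the
  minimum bin to every other bin. Windows whose sampled ranges leave a
  gap along the coordinate abort with a gap report.
* `log_p()`: $\log P = (\Delta G_{w\to vac} - \Delta G_{oct\to vac}) /
  (2.303\,R\,T)$ at $T = 310$ K by default, uncertainties combined in
  quadrature. The sign convention makes a hydrophobic solute (easier to
  strip from water than from octanol) positive. Both transfer directions
  are representable by flipping the inputs' signs.

# SASA validation

`sasa()` is a Shrake–Rupley implementation over a deterministic Fibonacci
sphere lattice (default 960 points, probe 0.14 nm): for each particle,
the accessible fraction of points on its probe-inflated sphere scales the
closed-form sphere area. Atomistic radii use the Rowland–Taylor values
(H 0.110, C 0.177, N 0.164, O 0.158, S 0.181 nm); CG radii come from the
bead classes. Virtual sites are excluded by default — they are
interaction constructs, not volume — with an include flag. The
cross-resolution check is the per-molecule percent difference of
ensemble-mean areas; 6 % is the acceptability edge used in practice. A
fixed point lattice makes results deterministic and translation-exact,
but rotating a molecule re-samples the occlusion pattern, so rotational
invariance holds only to the lattice resolution (≈0.3 % of area at 960
points), and doubling the point count moves totals by well under 0.5 %.

# Synthetic data: what it emulates, and what it does not

The generators stand in for the atomistic reference simulations and the
free-energy production runs:

* `toy_motor_topology()` plants a minimal motor: 8 real beads (4-bead
  stator chain, 4-bead rotor chain, axle bond between them), a virtual
  pivot at the stator's centre of geometry, five harmonic angles, one
  quartic double-well angle with modes at 80° and 130°
  (barrier 6 kJ/mol ≈ 2.4 k_BT, so both wells are populated and
  crossable), and one n = 2 dihedral through the virtual pivot — every
  term type the real motor/switch topologies use, at toy scale.
* `gen_reference_ensemble()` samples that truth and decorates each bead
  with pseudo-atoms whose centre of geometry equals the bead position
  *exactly* (offsets re-centred to zero mean), so mapping correctness and
  fitting correctness are tested independently; a `jitter = FALSE` rigid
  decoration exists for integration tests.
* `gen_umbrella_data()` draws window samples by inverse-CDF from the
  exact biased density of an analytic PMF at the protocol settings
  (0.1 nm spacing, k = 1500 kJ mol⁻¹ nm⁻²). The default 10⁴ samples per
  window represents the long, well-converged production windows of the
  umbrella protocol; at this size the WHAM reconstruction error
  (~0.3 kJ/mol RMS) is statistical, not systematic.
* `gen_work_samples()` draws Gaussian forward/reverse work obeying the
  fluctuation relation exactly, so the planted ΔG is the true answer.

What passing these tests does **not** show: chemistry. The pseudo-atoms
have no force field, the sampler has no nonbonded terms, solvent, or
dynamics, and the toy PMFs are analytic. The tests certify the
*machinery* — mapping, inversion, matching, estimators — against planted
truth; transferring to a real molecule still requires a genuine atomistic
reference and a Martini bead-type assignment, which are user inputs.

# Numerical choices and problem sizes

Reference and resampling chains use 10⁶ MC steps recording every 100th
frame; refinement iterations use 2×10⁵ steps. These sizes put sampling
noise on term means well below the acceptance thresholds while keeping
the full round-trip experiment under ten seconds. Other fixed choices:
density floor 10⁻⁴ of the maximum before any log-inversion; histogram
bins 0.001 nm / 1°; WHAM tolerance 10⁻⁷ with window-block bootstrap;
Fibonacci lattice of 960 SASA points; burn-in one tenth of the chain with
40 ± 10 % acceptance targeting.

# Known limitations

* Nonbonded energies (Lennard-Jones, Coulomb, the Martini interaction
  matrix) are out of scope; bead typing is user input.
* The sampler is Metropolis MC, not dynamics: time-stamped drivers use a
  fictitious clock and give no kinetic observables.
* Constraint support is limited to pendant constraints.
* Bimodal-angle MAE pairs modes by nearest angle; for distributions with
  more than two modes the pairing is still nearest-neighbour per
  reference mode.
* The quartic-angle convention is the polynomial
  $\sum C_n(\theta-\theta_0)^n$; topologies using a different quartic
  convention would need their coefficients transformed on import.
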