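---
title: "Phase-shift prediction and bonded-parameter fitting: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-shift prediction and bonded-parameter fitting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasefit)
```

## The problem

In CHARMM-style additive force fields every torsion angle $\phi$ contributes

$$V_\mathrm{dihedral} = \sum_t k_{\phi,t}\,\bigl[1 + \cos(n_t \phi - \delta_t)\bigr],$$

with multiplicities $n \in \{1,2,3,4,6\}$ and phase shifts $\delta \in
\{0^\circ, 180^\circ\}$. Parametrising small fused-ring molecules (the
motivating case is the bicyclic cores of beta-lactam antibiotics) is
notoriously fragile: a fitter that treats $\delta$ as a free parameter of the
torsion-profile fit can reproduce the reference energy profiles *perfectly*
and still place a cosine maximum at the molecule's equilibrium torsion. The
resulting simulation then relaxes away from the reference structure even
though every fitted curve "looked right".

`phasefit` implements the corrective workflow: **predict each phase from the
equilibrium geometry before any fitting, and never let the fitter touch it.**
Because the force field is additive and the reference geometry is (by
assumption) the global minimum, each cosine term should be at a local minimum
there. For a term with multiplicity $n$ at equilibrium torsion $\phi_0$ the
package evaluates $\cos(n\phi_0 - \delta)$ for both phases and keeps the
lower one (`predict_phase()`). When a type has several geometric instances
the criterion is summed over instances — the sum is what enters the energy.
Two further rules from the force-field literature are applied on top:

* an $n=2$ term across a bond of order 2 gets $\delta = 180^\circ$
  unconditionally (`apply_double_bond_rule()`);
* torsions that rotate a two-fold-symmetric terminal group (a carboxylate)
  get $n = 2$, whatever the database suggested
  (`apply_twofold_symmetry_rule()`).

Near-ties ($|\cos(n\phi_0) - \cos(n\phi_0 - 180^\circ)| <$ `tie_tol`,
default 0.05 on the cosine scale) are flagged ambiguous, and
`enumerate_alternatives()` produces the default assignment followed by all
flips of ambiguous/overridden decisions in increasing subset size, so each
candidate can be fitted and validated separately.

## Force-constant fitting

With $n$ and $\delta$ fixed, the torsion-profile objective is *linear* in the
force constants. `fit_group()` therefore solves a non-negative least-squares
problem (Lawson–Hanson active set) with one free additive offset per scan
(reference and MM energy zeros are unrelated; the offsets are eliminated by
per-scan centring). Scan rows whose min-subtracted target energy exceeds the
10 kcal/mol cutoff are excluded before fitting — exactly equivalent to
deleting those rows from the table. Terms whose basis column does not vary
over the included rows are reported as unidentifiable and keep their incoming
constants.

The fit is organised group-sequentially (`fit_workflow()`): four-membered-ring
torsions, partner-ring torsions, then carboxylate/improper groups last, with
double-bond torsions fitted first when present (fitting everything at once
can put the largest constant on a single bond instead of the double bond).
The whole sequence runs twice by default; the second pass reconciles coupled
groups. A scan is used by a group when its driven torsion is an instance of a
member *or couples to one* — operationally, when some member torsion moves by
more than 5 degrees across the scan's frames. Ring scans therefore inform
every ring group, while a rigid exocyclic rotation stays local.

Greedy multiplicity augmentation (`augment_multiplicities()`) tries each
missing $n$ on each member type with both the geometry-predicted phase and
its alternate, accepts the single best candidate whenever it reduces the
group RMSE by at least 10% (relative), and repeats until nothing qualifies.
Every trial is reported. The threshold quantifies "substantially improves";
it is exposed in the configuration.

### Identifiability and the reported condition number

Ring torsions co-vary: a closed ring has few soft degrees of freedom, so the
cosine columns of different ring-torsion types can be strongly collinear. In
a noiseless fit this is harmless (the solution is still unique and exact),
but with noisy data the *individual* constants along near-flat directions are
poorly determined even though their identified combinations — and the fitted
profile — are fine. This is a property of the physics, not of the solver:
it is the same degeneracy that makes two parameter sets of similar profile
quality but different force constants possible on a fused 5-ring.
`fit_group()` reports the condition number (`kappa`) of the centred design so
the degeneracy is visible; validation against the reference geometry, not
profile RMSE, is what discriminates such sets.

## Bonded parameters from the Hessian

Equilibrium bond lengths and angles are taken directly from the reference
geometry. This guarantees the acceptance envelope (every equilibrium within
0.03 Å and 3° of the reference geometry, `check_equilibria()`) by
construction, and matches the observed outcome that optimised equilibria sit
on the quantum geometry.

Force constants come from the Cartesian Hessian. Two methods are provided:

* **coupled** (default): decompose $H \approx \sum_q c_q B_q^\top B_q$ over
  the rank-1 curvature matrices of *all* internal coordinates by least
  squares (non-negative for bonds/angles/impropers; dihedral curvatures enter
  as free nuisance columns and are discarded). For a Hessian generated by a
  harmonic-consistent model at a strain-free minimum this decomposition is
  exact, because rank-1 matrices with distinct directions are linearly
  independent even when the underlying B-rows are redundant (rings).
* **uncoupled**: distort *one* internal coordinate with the others held fixed
  to first order (the pseudo-inverse distortion direction over the full
  Wilson B matrix) and match the quadratic energy. Coupling between internal
  curvatures is neglected. On non-redundant systems this is essentially
  exact (diatomic ~1%, a water-like bend ~5% against finite-difference
  reference Hessians); on redundant ring systems the "hold others fixed"
  constraint cannot be satisfied and errors grow to tens of percent — which
  is why the coupled decomposition is the default. A naive projection along
  the raw B-row direction (without holding the other internals) was rejected:
  bond stretching leaks into the angle directions and overestimates angle
  constants by ~70% even on the water-like case.

Parameter selection follows the penalty annotations: under the
`penalty-threshold` policy only entries with penalty strictly greater than 10
are optimised; the `all-bonded` policy selects every bonded parameter
regardless, motivated by the observation that database angles with *zero*
penalty can still sit tens of degrees from the reference geometry. Charges
are recorded in the selection report but never fitted (charge optimisation
needs water-interaction reference data, outside this package's scope).

## Validation surrogate

Full solvated molecular dynamics is out of scope; `validate_parameters()`
runs a desk-scale surrogate:

1. per-scan MM-vs-reference RMSE (free offset);
2. the location of the MM global minimum of each 1D profile must lie within
   15° of the reference torsion;
3. a multi-start conformer search: random torsion kicks on the scanned
   dihedrals (for ring bonds the downstream walk splits the ring at the first
   quadruple atom; the minimiser settles the distorted ring into a basin),
   followed by L-BFGS-B minimisation with analytic gradients, then GROMOS
   conformational clustering at a 0.2 Å RMSD cutoff on the ring heavy atoms
   (hydrogens and carboxylate excluded), with each cluster centroid's RMSD to
   the reference geometry;
4. verdict: pass iff all minima agree and the top cluster RMSD is at most
   0.15 Å. Two dominant clusters (fraction ≥ 0.2) are annotated as a
   conformational flip.

The 0.15 Å verdict threshold and the 0.2 dominant-cluster fraction are this
package's choices (the qualitative pass/fail judgement they encode has no
published numeric threshold); both are configurable via `run_config()`.
Cluster *populations* are deliberately not interpreted thermodynamically —
they reflect the basin volumes seen by the multi-start search, not free
energies.

On 2D grids `locate_minima()` additionally reports a flip barrier: the
minimax energy over monotone staircase paths between the two lowest minima
(diagonal steps allowed, so a diagonal valley is followed exactly), relative
to the higher minimum.

## The synthetic fixtures: what they emulate and what they do not

`make_fixture()` builds toy systems with known ground-truth parameters:
a five-atom chain, single 4- and 5-rings, fused 4+5 and 4+6 ring systems
(the 4+6 with one double bond), and a fused 4+5 system bearing a carboxylate.
All reference data (scan energies, Hessians) are generated from the
ground-truth MM model itself, so the noiseless recovery limit is exact and a
green test isolates protocol correctness from QM/MM model error — which no
real parametrisation can do. Conversely, these fixtures say nothing about
how well a cosine series approximates a genuine quantum torsion profile,
about charge quality, or about solvation; a green suite here is a statement
about the *fitting machinery*, not about force-field accuracy.

Design choices, made once:

* **Strain-free construction.** Non-flip templates are planar (rings) or
  all-trans (chain), with $b_0/\theta_0/\omega_0$ set to the exactly measured
  values, zero charges and zero Lennard-Jones depth. Every torsion sits at
  $0^\circ$ or $180^\circ$, which is an exact minimum of any cosine term with
  the geometry-predicted phase, so the built geometry is an exact stationary
  point (verified to max gradient $< 10^{-6}$ kcal/mol/Å).
* **Chemically plausible typing.** Single rings carry one atom type
  (cyclobutane/cyclopentane-style); fused templates use mirror-symmetric
  types. Symmetric instances then share one parameter, which is both what a
  real type assignment does and what keeps the fitting design
  well-conditioned.
* **Distinct multiplicities.** Ground-truth $n$ cycles over (2, 3, 4, 1)
  across type keys so that co-varying ring torsions carry functionally
  distinct cosine columns; double-bond and carboxylate torsions are fixed at
  $n = 2$ (8.5 kcal/mol on the double bond, small constants elsewhere, drawn
  once per seed from 0.3–2.2 kcal/mol).
* **Flip mode.** The fused-4+5 template can be built with $n=4$, $\delta=0$
  terms (k = 0.35 kcal/mol) on the two coupled 5-ring torsions and softened
  5-ring angles; minimisation then puckers the ring to about ±30°, with an
  exactly degenerate mirror conformer about 0.27 Å away (ring-heavy RMSD) and
  a staircase flip barrier below 1 kcal/mol — the "two near-degenerate
  conformers joined by a diagonal valley" situation.
* **Corrupted starting sets** (`perturb_params = TRUE`) bias about half of
  the angle equilibria by 5–20°, randomise every phase, set the carboxylate
  multiplicity to the database-like $n=3$, and stamp penalties above 10 on
  everything they touch — emulating a poor analogy-based initial guess.
* **Relaxed scans** restrain the driven torsion at 1000 kcal/mol/rad² and
  minimise everything else. On strongly strained grid cells the restraint is
  stiffened adaptively (up to 10⁵) so the frame honours the declared angle to
  well under the 1° reader tolerance. The recorded energy is always the
  restraint-free MM energy *of the stored frame*, so fitting consistency does
  not depend on how tightly the relaxation converged.

## Numerical choices

* Angles are degrees at every interface; torsions follow the IUPAC sign
  convention, values in $(-180, 180]$.
* Nonbonded model: 12-6 Lennard-Jones with Lorentz–Berthelot-style
  combination from (epsilon, rmin/2) plus plain Coulomb, no cutoff (systems
  here are ≤ ~30 atoms); 1-2 and 1-3 pairs excluded, 1-4 and beyond included
  unscaled. Urey–Bradley terms are not modelled (an accepted dialect
  restriction). Impropers are harmonic in the torsion measured on the stored
  quadruple order.
* A negative dihedral force constant is canonicalised by flipping the phase
  by 180°, which changes only the constant offset the fit absorbs.
* Minimisation wraps L-BFGS-B with analytic gradients (finite-difference
  checked in the test suite); convergence is max gradient component below
  the requested tolerance.
* The workflow's "RMSE non-increasing across iterations" check uses a
  tolerance of 10⁻⁹ kcal/mol plus a small absolute allowance for solver
  noise at converged fixed points, where per-scan RMSEs of order 10⁻⁸ jitter
  between iterations without meaning.
* Uniform fit weights; no Boltzmann weighting (only the 10 kcal/mol exclusion
  is prescribed; anything else would be invention). Exclusion happens at fit
  time and is configurable.

## Known limitations

* Individual ring-torsion constants in fused systems are only collectively
  identifiable from torsion scans (see the condition-number discussion
  above); with noisy data, report-level validation is the discriminator.
* The uncoupled Hessian method degrades on redundant internals by design;
  use the default coupled decomposition unless reproducing the simpler
  scheme is the point.
* The conformer-search surrogate explores basins, not thermodynamics; its
  cluster fractions are not populations.
* Phase prediction assumes the reference geometry is the global minimum; a
  local-minimum reference silently yields phases for *that* basin.
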