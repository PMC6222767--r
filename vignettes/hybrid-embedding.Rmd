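---
title: "Hybrid short/long-range electrostatic embedding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid short/long-range electrostatic embedding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmmbed)
```

## The model

Electrostatic-embedding QM/MM couples a quantum region (nuclear charges
$Z_A$ and electron density $\rho(\mathbf r)$) to an environment of MM point
charges $q_B$ through

$$E^{\mathrm{elec,I}} = \sum_A Z_A \phi(\mathbf r_A) - \int \rho(\mathbf r)\,\phi(\mathbf r)\,d\mathbf r,
\qquad \phi(\mathbf r) = \sum_B \frac{q_B}{|\mathbf r - \mathbf r_B|}.$$

The alternative is a multipolar representation of the QM subsystem:
generalized per-site moments $M_A^m$ (charge for $m=0$, Cartesian dipole
components for $m=1..3$) contracted with the local Taylor expansion
$F_A^m$ of the MM potential (potential, then field components), giving
$E^{\mathrm{elec,II}} = \sum_{A,m} M_A^m F_A^m$ with the interaction tensor
$T^0 = 1/r$, $T^1 = (\mathbf r_A-\mathbf r_B)/r^3$.

The hybrid scheme splits the environment by the distance of each charge to
its *closest QM atom*: charges within $r_\mathrm{off}$ are density embedded,
the rest multipole embedded. A switching function $S(r) \in [0,1]$ (Step,
Shift, Switch, LREC; closed forms in `?switch_value`) divides each inner
charge exactly into a density-embedded part $S(r_B)\,q_B$ and a
multipole-embedded complement, which makes the total energy continuous as
atoms cross the cutoff during dynamics or optimization.

Two families of moments are provided:

* **Mulliken** (`mulc`, `mulcd`): the density matrix is partitioned by
  basis-function ownership; charges are $q_A = Z_A - N_A$ and atomic dipoles
  are first moments of the atomic densities about their sites. These moments
  conserve the molecular monopole and dipole exactly (trace identities).
* **ESP-fitted** (`espc`, `espcd`): moments are the minimum-norm
  least-squares solution of $K M = \phi_s$ on a fitting grid, via SVD
  pseudo-inverse. The far-field charges can equivalently be *projected onto
  the grid*, $q_s = \sum_{A,m} F_{Am}(K^{-1})_{Am,s}$; the identity
  $\sum_{Am} M_{Am} F_{Am} = \sum_s q_s \phi_s$ holds algebraically for
  every target potential, which the test suite exercises as its master
  oracle on random geometries.

Two further baselines bracket the multipolar models: `truncation` (far
field dropped) and `truncation_mmlc` (far field added back classically,
with fixed force-field charges on the QM atoms — it corrects the energy but
by construction never polarizes the wavefunction), plus `mechanical`
embedding (both sides classical).

## Embedding operators and the SCF contract

For self-consistency each model must enter the one-electron Hamiltonian:

* scaled near-field charges enter as external point charges, always;
* `espc`/`espcd`: the projected grid charges $q_s$ depend only on the MM
  geometry, so the far field is a *static* set of external charges and the
  SCF is variationally exact — no response-kernel term exists;
* `mulc`/`mulcd`: the far-field energy is linear in the density matrix, so
  it contributes a constant one-electron matrix (built once per geometry)
  plus a nuclear shift;
* `truncation`: no far-field term.

Any backend implementing `converged_scf()` (returning first-cycle and
converged energies), `esp_on_points()`, `density_charge_interaction()`,
`excitation_energies()` and the density-matrix accessors can drive the
benchmark. The polarization energy is defined as
$E[\text{converged}] - E[\text{start density}]$ under a given operator,
which is non-positive by the variational principle; starting from the
all-charge reference density, its magnitude measures how far that operator
lets the wavefunction drift from the reference.

## The classical polarizable surrogate backend

The package ships a backend that fulfils this contract without quantum
chemistry, so the entire benchmark is a deterministic, fast, linear-algebra
computation. Its "density" for a QM region is a distributed set of point
populations: a core population per atom, bond-satellite populations
(default 0.30 e per bond for heavy atoms, 0.15 e for hydrogen, displaced
0.5 bohr along each covalent bond) and six small axial populations
(0.01 e at ±0.1 bohr) per atom. The satellites give the molecule permanent
atomic dipoles, quadrupoles and higher moments, so truncated multipolar
representations are genuinely approximate — without them every model would
be trivially exact and the benchmark meaningless.

Self-consistency is a variational linear response with two sets of
coordinates:

* **charge flow** $\Delta q_A$ against a charge-equilibration hardness
  matrix (element idempotentials on the diagonal, Klopman–Ohno screened
  Coulomb off-diagonal, total charge constrained), coupled to the external
  potential *averaged over the atomic cloud*;
* **induced dipoles** against isotropic element polarizabilities, realized
  as population shifts across the axial pair and coupled to the
  finite-difference potential across it.

Coupling through the distributed points rather than through site values
alone matters: an order-1 multipolar operator reproduces site potentials
and fields of the charges it represents essentially exactly, so a
site-coupled response could not distinguish ESPCD from the reference at
all. The distributed coupling senses the curvature of the embedding
potential, exactly as a real density does through its basis-set extent, and
yields small but honest non-zero deviations.

Excited states are fixed charge-transfer difference densities (0.1 e moved
between the most distant atom pair, from bond-displaced points) on top of
configurable gas-phase gaps (default 2.3 eV, spaced 0.4 eV); their energies
shift linearly in the embedding potential, as TDDFT states do under static
embedding charges. Hardness, polarizability, van der Waals and covalent
radii are tabulated per element in `element_table()`.

What the surrogate does *not* emulate: exchange/charge-penetration effects
of overlapping densities, basis-set sensitivity (the known instability of
Mulliken moments in diffuse bases will not reproduce here), non-linear
response, and state-specific solvation beyond the linear Stark shift.
Conclusions transferred to ab initio densities should be read as statements
about the *electrostatics and linear polarization* of the schemes.

## The synthetic benchmark systems

`generate_water_box()` packs rigid TIP3P-geometry waters (0.9572 Å O–H,
104.52° H–O–H, charges −0.834/+0.417 e) at random positions and
orientations around a solute, rejecting oxygens within 2.5 Å of each other
or 2.4 Å of the solute. With `orientation_bias = "anion"` a water at
distance $d$ from the solute is oriented with its dipole toward it with
probability $\exp(-(d - 2.4)/2.5)$ (plus a ~15° random tilt), emulating the
first-shell ordering that puts hydrogens on average closer to an anion than
oxygens — the feature that makes smooth charge scaling outperform hard
truncation. It does not emulate: liquid-state radial distribution beyond
the hard-core constraint, hydrogen-bond networks, thermal correlations
between configurations, or counter-ions (each ion would be its own charge
group). Configurations are independent re-seeded boxes, not MD snapshots;
RMSD semantics over configurations are unchanged.

The default desk-scale solute is the acetate anion (7 atoms, CHARMM-style
charges, net −1), standing in for a solvated organic anion; a larger
synthetic oxyluciferin-anion geometry ships in `inst/extdata/` for longer
runs. The benchmark scale used by the acceptance script — 10 configurations
of 200 waters in a 30 Å box, cutoff ladder truncated to the box — was
chosen as the smallest system that still has a substantial far field
(beyond 10 Å) around every near-field choice; the test suite uses smaller
boxes (15–100 waters) where only identities or orderings are asserted.

## Numerical choices

* **Units**: atomic units internally; angstrom and kcal/mol at the API.
  Conversion constants live in one place (`qmm_constants`).
* **Boundary convention**: $r = r_\mathrm{off}$ belongs to the near field
  (makes Step deterministic; smooth schemes are zero there anyway).
  Switch's inner radius defaults to $0.75\,r_\mathrm{off}$.
* **Group-mode inclusion** uses the minimum member distance (a group is
  near if *any* member is within the cutoff), so neutral groups are never
  split; atom-based cutoffs pair with smooth switching, group-based with
  Step, unless overridden.
* **ESP grid**: Merz–Kollman-style shells at 1.4/1.6/1.8/2.0 × Bondi radii,
  deterministic Fibonacci-sphere placement at 1 point/Å², points inside
  another atom's same-scale shell pruned. Grid choice is configurable;
  the published description of the "standard" grid underdetermines it.
* **SVD truncation** at $10^{-6}\sigma_\mathrm{max}$; the count of dropped
  singular values is reported by `glance()` on a fit. An optional
  total-charge constraint (Lagrange multiplier in the normal-equation
  metric) is available but off by default — the plain pseudo-inverse is the
  primary route.
* **Atomic dipole sign**: site dipoles are first moments of the (positive)
  atomic electron density; with the $T^1$ tensor above this is the unique
  convention under which the order-1 multipolar energy converges to the
  exact density–charge energy in the far field, which the test suite
  verifies via decay exponents.
* **Degenerate inputs**: empty MM sets partition to empty (not an error);
  coincident charge/site pairs raise singular-tensor errors; an
  underdetermined ESP fit errors rather than silently regularizing;
  single-atom regions have no charge flow (the constraint pins it).

## Design notes on the diagnostics

The far-field *order* diagnostic (error $\propto d^{-2}$ at order 0,
$d^{-3}$ at order 1) is measured with Mulliken moments, whose monopole and
dipole are exact by construction, using RMS error over a sphere of probe
directions (single probes can sit near nodal directions of the leading
error term). Fitted ESP moments carry least-squares residuals in the low
moments (~$10^{-4}$ e on the default grid), which leave shallower
$d^{-1}/d^{-2}$ tails; for them the suite asserts the order-1 fit's error
stays strictly below the order-0 fit's across the whole range instead. For
the continuity diagnostic, the Step discontinuity is demonstrated with the
truncation model, where the jump is the crossing charge's full interaction
energy; under ESPCD the Step "jump" is only the multipole representation
error of one charge at the cutoff and is itself tiny.

## Limitations

Non-periodic only; energies only (no gradients); quadrupoles and higher QM
moments are not used in the long range; the MM side is fixed point charges;
and all quantitative claims are made at the synthetic desk scale described
above — the scheme ordering (ESPCD ≳ MulCD > ESPC > truncation, smooth
switching ≥ Step) is the transferable result, not the absolute RMSD values.
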