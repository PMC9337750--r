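---
title: "Lattice-energy screening of cocrystal coformers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lattice-energy screening of cocrystal coformers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocryscreen)
```

## The screening problem

Cocrystallisation reformulates an active pharmaceutical ingredient (API) as a
multi-component crystal with a pharmaceutically acceptable partner (a
*coformer*). Whether a given API/coformer pair forms a cocrystal is, at the
level of thermodynamics, a question about free energies of competing solids:
the cocrystal is stable when

$$\Delta\Delta G_c \;=\; G_{[\mathrm{API}_n c_m]} - n\,G_{[\mathrm{API}]} - m\,G_{[c]} \;<\; 0 .$$

Free energies of crystal lattices are expensive, so this package follows the
standard desk-scale substitution: every $G$ is replaced by a static lattice
energy $U$ at 0 K, giving the screening metric

$$\Delta\Delta U_c \;=\; U_{[\mathrm{API}_n c_m],\min} - n\,U_{[\mathrm{API}],\min} - m\,U_{[c],\min},$$

where each $U_{\cdot,\min}$ is the lattice energy of the *best* structure of
that composition — either the minimum of a crystal-structure-prediction (CSP)
search or, when available and trusted, an experimentally determined form (the
`policy` argument of `run_screen()` chooses per run). Negative
$\Delta\Delta U_c$ favours cocrystallisation; increasingly positive values
make it increasingly unlikely. Two classification presets are built in:
`"screening"` excludes a coformer only when $\Delta\Delta U_c$ *strictly
exceeds* +5 kJ/mol (equality is retained — the wording "exceeding" decides
the boundary), and `"strict"` uses 0 kJ/mol. Both are deliberate
over-inclusions: lattice energies ignore entropic and thermal terms, and
metastable cocrystals are observed in practice, so a retain decision is cheap
insurance while an exclude decision saves bench work.

### Liquid coformers

If the coformer is liquid at the screening temperature $T$ (default 300 K),
the putative solid is a solvate and the neat-coformer reference is a liquid,
not a crystal. The missing term is the coformer's free energy of fusion,
estimated from melting data by the usual linear approximation

$$\Delta G_{\mathrm{fus}}(T) \;=\; \Delta H_{\mathrm{fus}}\left(1 - \frac{T}{T_{\mathrm{fus}}}\right),$$

which is negative above the melting point; `fusion_correction()` adds
$-m\,\Delta G_{\mathrm{fus}}$ to $\Delta\Delta U_c$, a *positive* shift for a
liquid coformer. For pyridine ($T_{\mathrm{fus}} = 231.5$ K,
$\Delta H_{\mathrm{fus}} = 8.3$ kJ/mol) at 300 K the shift is +2.5 kJ/mol:

```{r}
fusion_correction(fusion_data(T_fus = 231.5, dH_fus = 8.3, T = 300), m = 1)
```

An alternative $\tfrac{3}{2}RT$ estimate per coformer molecule (used in some
solvate studies) is available via `policy = "rt"`; the fusion form is the
default because it uses the compound's own melting data rather than an
ideal-gas argument.

## The lattice-energy model

The energy of a periodic structure is evaluated per asymmetric-unit formula
as

$$U = U_{\mathrm{exp6}} + U_{\mathrm{elec}} + \Delta U^{\mathrm{intra}} .$$

**Repulsion–dispersion.** Intermolecular atom–atom exp-6 (Buckingham) terms
$A e^{-Br} - C r^{-6}$, with geometric-mean combining for $A$ and $C$ and
arithmetic-mean for $B$, overridable per pair. The real-space cutoff defaults
to 15 Å; the last 10% of the cutoff is a CHARMM-style switching window so the
energy surface stays continuous as pairs cross the boundary (a hard
truncation makes numerically differentiated gradients useless), and a
uniform-density tail correction integrates the dispersion from the middle of
the switching window outwards, which also compensates the switched-off
fraction. A shipped C/H/N/O parameter file (`inst/params/default.yaml`,
Williams-type open-literature values) is a reasonable default for organic
molecules; any user file in the same YAML layout is accepted. Fixture tests
use fabricated, documented constants so engine validation never depends on
parameter provenance.

**Electrostatics.** Atomic point charges in vacuum, summed by Ewald
decomposition (real + reciprocal + self terms, intramolecular pairs
excluded, tinfoil boundary). The splitting parameter is derived from the
cutoff as $\alpha = \kappa/r_c$ with $\kappa = 4.8$, and the reciprocal
cutoff as $2\alpha\kappa$; the result is independent of $\kappa$ over
4.4–5.2 to better than $10^{-4}$ kJ/mol, which the tests assert. Under the
tinfoil convention a periodic box containing a single dipolar molecule
carries an exact finite-size energy $-\tfrac{2\pi}{3V}k_e p^2$; the tests
check this closed form and its $1/V$ decay rather than pretending the
isolated limit is reached at any finite box. Correctness
is anchored to the rock-salt and CsCl Madelung constants (1.7476 / 1.7627),
reproduced to four decimals against an independent neutral-cube direct
summation. The direct cube sum for CsCl famously converges to a
shape-dependent limit; the oracle therefore applies the standard cell
second-moment correction $-\tfrac{2\pi}{3V}\sum_i q_i r_i^2$ and a
Richardson extrapolation in $1/L^2$, which recovers the Ewald (tinfoil)
value without sharing any code with the Ewald path.

**Intramolecular energy and charges: the LAM database.** Conformational
energetics are delegated to a pluggable *conformational oracle* — any
deterministic function from (molecule, torsion angles) to (energy, atomic
charges). In production use this would wrap an electronic-structure code; in
this package's tests it is a synthetic closed form. The oracle is expensive
by assumption, so it is only ever evaluated on a uniform periodic grid over
the flexible torsions (`build_lam_grid()`, one call per node, energies
re-referenced to a zero minimum); every later query interpolates
multilinearly on the periodic grid (`evaluate_lam()`), exactly at nodes,
with zero oracle calls — this reuse contract is what makes screening many
coformers against one API affordable, and it is asserted by counter in the
tests. Databases persist as a JSON + CSV directory (`save_lam()`/
`load_lam()`) and are built at most once per molecule per screen; a
persisted database answers a whole re-run without a single oracle call.
Charges are tabulated and interpolated node-wise alongside the energy, so
conformation-dependent polarisation is represented at the same fidelity as
the energy; interpolation preserves the total molecular charge whenever the
nodes do.

A torsion is treated as flexible when the larger of the two energies from
±15° probes of the reference conformation is at most a threshold
(default 20 kJ/mol, configurable — the probing angle is standard practice
but published protocols rarely print the energy cutoff, so it must be an
explicit parameter here). Stiffer torsions stay frozen at their reference
values. An optional one-shot refinement halves the grid spacing along any
axis whose adjacent-node gap exceeds a convergence criterion
$\Delta^* = 5$ kJ/mol, a simplified stand-in for fully adaptive grid
placement: it captures the convergence criterion without the bookkeeping of
incremental node insertion.

## The search engine

Candidate structures are generated per space group from a seeded Halton
sequence with a Cranley–Patterson rotation (low-discrepancy coverage beats
pseudo-random sampling measurably; the suite compares star discrepancies).
Sampled variables: cell shape respecting the crystal system (free angles in
[60°, 120°)), cell scale solved from a sampled density within bounds
(default 0.4–4 g/cm³), fractional centroids, orientations uniform on the
quaternion sphere (Shoemake construction), and torsions on LAM grid nodes.
Candidates with any intermolecular contact below 0.6× the sum of covalent
radii are discarded and replaced — the exp-6 form is catastrophically
attractive at very short range, so a geometric guard is mandatory, and the
same sloped penalty protects every line search inside the minimiser.

Each candidate is relaxed by L-BFGS-B over the free cell parameters,
centroids, quaternions (projection-renormalised each evaluation) and
torsions. For rigid molecules the whole parameter-to-energy evaluation runs
in compiled code with a one-sided finite-difference gradient; if the exit
gradient still exceeds the tolerance (one-sided differences have a noise
floor that can stall stiff multi-molecule systems), a single polish restart
with central differences finishes the job. The converged flag requires the
central-difference gradient infinity norm to be at or below `gtol` (default
0.02 kJ/mol per unit parameter — loose enough for numerical gradients,
tight enough that re-minimising a converged structure changes the energy by
well under $10^{-8}$ kJ/mol, which the tests assert). Degenerate directions
(overall translation in P1, rotation about a linear molecule's axis) are
left free: their gradients vanish identically and L-BFGS-B simply never
moves along them.

Default scale is deliberately desk-sized: hundreds to a few thousand
candidates over a configurable space-group list (15 common groups ship with
explicit operator tables; any group can be supplied as operator triplets).
Production-scale settings — hundreds of thousands of minimisations over 59
groups — are reachable purely by configuration; the code path is identical.

After the search, duplicate minima are removed by a packing-similarity
cluster (`packing_rmsd()`): an $n$-molecule coordination shell (default 15)
is built around a central molecule in each structure, correspondences are
searched greedily (beam-limited, over symmetry-inequivalent central choices,
with and without inversion) within a centroid-distance tolerance, and the
matched clusters are superposed by Kabsch SVD on heavy atoms. Two minima are
duplicates when both their energies (within 1.0 kJ/mol) and their RMSD
(within 1.0 Å) agree; the greedy energy-ordered pass keeps the lower-energy
member and is idempotent. The directional correspondence search is
symmetrised by evaluating both orders and taking the minimum. The published
tolerances behind packing-similarity tools are not standardised, so all of
these knobs live in `cluster_config()` with pinned defaults. The
refinement-stage filter keeps all unique structures within 20 kJ/mol
(inclusive) of the global minimum, capped at the 500 lowest.

## The synthetic study system

The test suite never downloads anything; every input is generated:

* **Ionic prototypes** (`make_reference_lattice()`): rock-salt and CsCl
  cells with unit charges — closed-form oracles for the electrostatics.
* **A rigid diatomic crystal** (`make_diatomic_fixture()`): an X–Y molecule
  (bond 1.2 Å, no charges) under fabricated exp-6 constants
  ($A = 3.06\times10^5$ kJ/mol, $B = 3.6$ Å⁻¹, $C = 8200$ kJ·Å⁶/mol — pair
  minimum near 3 Å, ~5 kJ/mol deep, with a solid repulsive wall) and a
  reference structure from relaxing a hand-built dense P1 packing, verified
  to be a fixed point at generation time. Searches from 500 seeded
  candidates recover this minimum essentially always; the acceptance suite
  demands ≥95% of 20 seeds. The fixture cutoff is 6 Å so that ten thousand
  minimisations fit comfortably in a test run; cutoff only rescales the
  landscape, it does not change what the recovery test demonstrates.
* **An engineered cocrystal pair** (`make_toy_cocrystal_pair()`): two
  diatomics whose X–Y cross dispersion is scaled (1.25× for a former,
  0.3× for a non-former), so mixed packing is favourable or unfavourable *by
  construction*; the generation step verifies the promised ΔΔU ordering and
  errors out rather than emit a bad fixture. The cross-term scale was chosen
  to keep a strong repulsive wall at the overlap guard — stronger
  enhancement makes the potential collapse-prone and the fixture unusable.
* **Synthetic torsional oracles** (`make_torsion_oracle()`): quadratic and
  cosine closed forms with evaluation counters, standing in for
  isolated-molecule quantum chemistry.

What passing on these fixtures shows — and what it does not: the engine's
bookkeeping (symmetry, periodicity, interpolation, reuse, filtering,
ranking) is demonstrated exactly; the *chemistry* of real APIs is not.
Diatomics have no conformational polymorphism, fabricated constants are not
a validated force field, and point charges without multipoles underestimate
directional interactions such as hydrogen bonds. Screening a real API
additionally requires a quantum-chemical oracle and a validated exp-6
parameter set supplied by the user.

## Numerical choices and edge cases

* Energies are reported per asymmetric-unit formula (cell energy divided by
  the operator count), which makes P1 and higher-symmetry descriptions of
  the same packing agree to $10^{-6}$ kJ/mol (tested) and makes ΔΔU
  bookkeeping invariant to uniform reference shifts.
* Ties in the refinement filter and in coformer ranking are broken stably:
  input order for structures, lexicographic identifier for coformers.
* An overlapping candidate is replaced, not repaired; a candidate whose
  minimisation collapses is dropped with its reason recorded; a coformer
  whose searches fail is reported in the errors list without aborting the
  rest of the screen.
* Empty landscapes warn (search) or error with advice (global-minimum
  extraction); an all-excluded screen reports its hit rate as
  not-applicable rather than dividing by zero.
* The problem sizes in the tests (500 candidates × 20 seeds for recovery;
  tens of candidates for the end-to-end screens; L = 10–12 Evjen cubes)
  were chosen as the smallest sizes at which each property is demonstrated
  cleanly.

## Known limitations

Rigid-body + LAM torsions only (no full intramolecular relaxation during
lattice minimisation); point charges only (no atomic multipoles, no
polarisation); Z′ ≤ 1 per component; no free-energy, thermal or vibrational
corrections beyond the fusion term; no salts, disorder or partial
occupancy; CIF support is the core 1.1 subset a CSP pipeline needs, not a
dictionary-validated parser.
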