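# cocryscreen

Virtual screening of pharmaceutical cocrystal coformers by crystal structure
prediction (CSP) and lattice-energy ranking, at desk scale, in R.

## The problem

Cocrystallising an active pharmaceutical ingredient (API) with a second
neutral molecule (a *coformer*) can fix solubility or stability problems
without touching the API's covalent structure — but finding which of many
candidate coformers actually cocrystallise is an expensive experimental
campaign. A thermodynamic computation can prioritise it. For a cocrystal
API<sub>n</sub>c<sub>m</sub>, the package computes

```
ddU_c = U[APInCm],min − n·U[API],min − m·U[c],min
```

the lattice energy of the best predicted cocrystal structure minus the
stoichiometric sum of the best neat-component lattice energies (kJ/mol per
cocrystal formula; all at 0 K, static). Negative `ddU` says the mixed
crystal packs better than the separated solids. Coformers are ranked by
increasing `ddU`; a coformer whose `ddU` strictly exceeds +5 kJ/mol is
classified as unlikely (`"screening"` preset; a stricter `ddU ≤ 0` preset is
also built in). For coformers that are liquid at the screening temperature
(solvate formation), `ddU` is shifted by `−m·ΔH_fus·(1 − T/T_fus)`, the
fusion free-energy estimate from melting data — +2.5 kJ/mol for pyridine at
300 K.

Each `U` comes from the package's own CSP engine:

* **Energy model** — intermolecular exp-6 (Buckingham) atom–atom terms plus
  Ewald-summed point-charge electrostatics, plus a tabulated/interpolated
  intramolecular term for flexible torsions (the LAM database, built from a
  pluggable conformational-energy oracle and reused across all searches).
* **Global search** — seeded low-discrepancy sampling of cell, position,
  orientation and torsion variables in common space groups, followed by
  L-BFGS-B lattice-energy minimisation with compiled energy kernels.
* **Landscape assembly** — COMPACK-style packing-similarity clustering
  (heavy-atom RMSD of n-molecule coordination shells) to remove duplicate
  minima, and the usual refinement filter (all unique structures within
  20 kJ/mol of the minimum, capped at 500).

## Worked example

A complete screen on the package's engineered two-component fixture (rigid
diatomics whose cross-term dispersion is tuned so mixed packing wins):

```r
library(cocryscreen)

pair <- make_toy_cocrystal_pair(seed = 1)
cfg  <- search_config(list(), spacegroups = "P1", n_candidates = 40, seed = 8)

report <- run_screen(
  api       = list(molecule = pair$api),
  coformers = list(partner = list(molecule = pair$coformer, observed = TRUE)),
  config    = cfg,
  params    = pair$params)
report
#> <coformer screen> toyA - 1 coformer(s), threshold 5 kJ/mol
#>  rank coformer n m       ddU classification
#>     1  partner 1 1 -111.3499         retain
#> excluded: 0%  hits among retained: 100%
```

The searches found neat-A and neat-C minima at −125.42 kJ/mol each and a
cocrystal minimum at −362.19 kJ/mol per formula, so
`ddU = −362.19 − (−125.42) − (−125.42) = −111.35` kJ/mol: the mixed packing
is strongly favoured, as engineered, and the coformer is retained. The
`"non_former"` variant of the same fixture comes out above +5 and is
excluded.

The closed-form pieces are one-liners:

```r
cell_volume(unit_cell(27.0723, 5.1939, 24.1059, beta = 94.343))
#> [1] 3379.818   # A^3, matches the indexed monoclinic cell it came from

fusion_correction(fusion_data(T_fus = 231.5, dH_fus = 8.3, T = 300))$shift
#> [1] 2.455937   # kJ/mol, the pyridine solvate penalty (+2.5 to 1 decimal)
```

Screening-only mode takes a CSV of precomputed lattice energies
(`screen_from_table()`), and a thin CLI (`inst/cli/cocryscreen.R`) exposes
`search`, `screen` and `fixtures` subcommands.

## Scope

Rigid and semi-rigid (LAM-torsion) neutral molecules, Z′ = 1 per component,
point charges only, 0 K lattice energies. See the methods vignette
(`vignettes/cocryscreen-methods.Rmd`) for the models, defaults, numerical
choices and known limitations.
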