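---
title: "Predicting C–H activation regioselectivity from palladacycle intermediates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting C–H activation regioselectivity from palladacycle intermediates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Directing-group-assisted C–H activation with Pd(OAc)₂ proceeds by concerted
metalation–deprotonation (CMD): the Pd centre, held in place by a
coordinating heteroatom of the substrate, forms a σ-bond to an aromatic
carbon while an acetate ligand abstracts the proton. The product of this
rate-determining step is a palladacycle intermediate — a ring containing
the Pd, the activated carbon, the directing heteroatom and the atoms
between them, with the acetate bound κ² (both oxygens on Pd).

`regiopd` ranks candidate reaction sites by the energy of this
intermediate. That rests on three assumptions, inherited from the physical
model and stated here explicitly:

* the reaction is kinetically controlled by palladacycle formation;
* the Bell–Evans–Polanyi relation holds, so a lower intermediate energy
  implies a lower barrier — a correlation that is empirically imperfect,
  which is why sites within a finite energy window are reported together
  rather than forcing a unique answer;
* the intermediate geometry is square-planar at Pd(II), which is what the
  post-optimization validation enforces.

The package does not predict whether a reaction happens, its yield, or
competing mechanisms (e.g. electrophilic aromatic substitution).

## Workflow and tunable parameters

`run_prediction()` chains the stages below. Defaults are part of the study
conditions and are not meant to be tuned casually.

| Parameter | Default | Units | Role |
|---|---|---|---|
| path length (ortho mode) | 2–5 | bonds | palladacycle ring sizes 4–7 |
| `angle_tolerance` | 0.10 | relative | 2D ring-angle screen vs `(N−2)·180°/N`; boundary inclusive |
| `strain_threshold_kcal` (remote mode) | 10 | kcal/mol | MMFF94s out-of-plane + torsion sum of the CCl₂ dummy ring |
| conformers per complex | `3·N_rot + 3` | — | ETKDG embeddings; `N_rot` counted on the substrate only |
| `cluster_cutoff` | 1.0 | Å | heavy-atom RMSD clustering, medoid representatives |
| planarity gate | < 5 | degrees | angle between plane(Pd, C, X) and plane(Pd, O, O); strict |
| bond-perception factor | 1.25 | × Σ covalent radii | connectivity validation, metal bonds excluded |
| `threshold_kcal` | 1.0 | kcal/mol | prediction window around the global minimum |
| embedding seed | user (`seed`) | — | every stochastic step; fixed seed ⇒ bit-identical outputs |

Site and DG equivalence is decided on canonical SMILES: a site is marked by
attaching one explicit hydrogen carrying an isotope label (99), a donor by
coordinating a `*` dummy atom through a dative bond (a plain single bond
would break aromatic valence at, e.g., pyridine nitrogen). Stereochemistry
is ignored in these comparisons — sites equivalent on the constitutional
graph are treated as one — which is documented here as a deliberate
simplification; E/Z- or atropisomer-distinct sites are beyond the scope of
the equivalence test.

Donor qualification: N, O or S with at least one available lone pair,
computed from valence-electron bookkeeping; pyrrole-type aromatic nitrogen
(lone pair inside the sextet) and quaternary/protonated nitrogen do not
qualify. Phosphorus can be admitted via
`options(regiopd.donor_elements = c("N","O","S","P"))`.

## Geometry construction

Distance-geometry embedding knows nothing about metals, so the complex
builder supplies the geometry knowledge explicitly:

* Pd–ligand distance bounds from covalent radii ± 15%;
* square-planar cross bounds — trans partners near the sum of their
  Pd–ligand distances, cis partners near the right-angle diagonal. If these
  are infeasible (strongly strained rings), the embedder falls back to
  plain Pd–ligand bounds and then to stock ETKDG, probing each stage with a
  single cheap embedding first;
* each raw embedding is regularized by a short UFF minimization with the
  two trans L–Pd–L angles restrained to 180° (force constant 10⁴). UFF's
  generic Pd type has no d⁸ square-planar term, so without the restraints
  the coordination sphere relaxes toward tetrahedral and the planarity gate
  would reject everything. The same restrained optimizer backs the
  `forcefield` engine; single-point energies are plain UFF.

Conformers that still fail the planarity or connectivity gate after
engine optimization are dropped — with an external quantum engine this is
exactly the "optimization walked away from the intermediate" failure mode
the validation is designed to catch. A complex whose every conformer fails
is excluded and reported in the prediction's drop log, never silently
treated as high-energy. The embedding quota `3·N_rot + 3` is attempted, not
guaranteed: failed embeddings are not retried.

## Energy engines

The engine contract (`engine_spec()`) has two capabilities, `optimize` and
`singlepoint`. Externally, GFN1-xTB (ALPB solvent, default CH₂Cl₂) is the
intended optimizer and r²SCAN-3c (ORCA, CPCM) the single-point refiner;
both are discovered at run time and raise a typed configuration error when
absent, with engine-native units converted to kcal/mol at the adapter
boundary (1 Hartree = 627.5094740631 kcal/mol).

The `mock` engine makes the pipeline testable offline: its energy is the
sum of inverse pairwise interatomic distances of the given geometry — a
documented, deterministic, geometry-sensitive function — or a fixed value
per reaction site when an `energy_map` is supplied. The rigged form is what
the end-to-end tests use to verify that a site made strictly lowest by more
than the window is labelled *correct* and two sites within 0.5 kcal/mol are
labelled *semi-correct*.

Refinement (`refine()`) re-scores the best conformer of each
within-threshold complex with the single-point engine and re-applies the
window on the refined energies. Refined energies fully replace the
unrefined ones inside the window; complexes outside the window keep their
exclusion. Mixing levels across that boundary is a known approximation.
If the engine fails on a complex, that complex keeps its unrefined relative
rank (re-anchored to the refined minimum), with a warning.

## Numerical choices

* Ring angles are measured on the 2D coordinates of the ring closed through
  the Pd placeholder, including the angle at Pd (the polygon formula covers
  the whole ring; excluding Pd would leave the constraint underdetermined —
  `include_pd_angle = FALSE` is available for comparison). Relative
  deviation is `|measured − ideal| / ideal`; exactly 10% passes.
* The remote-mode strain score sums the MMFF94s out-of-plane and torsion
  terms only. In-plane angle bending at the carbene-like CCl₂ bridge is
  dominated by force-field typing artifacts of that deliberately
  non-physical fragment and would reject even the canonical fusable
  five-membered ring, so it is excluded from the score.
* Clustering representatives are medoids (the member minimizing total RMSD
  to its cluster), not coordinate means: conformers do not live in a vector
  space where averaging is meaningful. Clusters are formed Butina-style
  around maximal-neighbour leaders; membership radius is guaranteed with
  respect to the leader. RMSD is Kabsch-aligned over heavy atoms, without
  graph-automorphism symmetry correction (cost outweighs benefit at these
  ensemble sizes); failed alignments count as infinitely distant.
* Plane normals carry a sign ambiguity, so the planarity angle is folded
  into [0°, 90°]; the 5° criterion is strict (`<`), and the boundary
  behaviour is pinned by a unit test. Collinear atom triples raise a
  degenerate-geometry error and invalidate the conformer.
* Energy ties at `threshold_kcal = 0` return all tied sites, ordered by
  site atom index.
* All atom indices in inputs and outputs are 0-based in input-SMILES order;
  every results document states this.

## The offline test bed

`generate_fixtures()` is the package's synthetic study set: small
substrates with known symmetry structure (benzene, toluene,
2-phenylpyridine, N,N-dimethylbenzamide, nitrobenzene, acetanilide,
anisole, and the diamide/ketone worked-example substrate), each DG-bearing
fixture carrying a designated site and a mock-engine energy map that makes
that site's complex lowest by 10 kcal/mol. This emulates the *shape* of the
real problem — symmetry collapse, resonance-equivalent donors, competing
N/O donors, multi-ring substrates — but not its physics: mock energies are
rigged, conformer ensembles are small, and no solvation or electronic
effects enter. A green test suite therefore demonstrates that the
machinery (enumeration, filtering, deduplication, assembly, validation,
ranking, evaluation) is correct, not that the energy model is accurate on
real substrates; the latter depends on the external tight-binding/DFT
engines.

Problem sizes used by the tests were chosen to keep the suite expressive
yet quick: fixtures up to ~25 heavy atoms, conformer ensembles up to 18,
clustering oracles on ensembles of ≤ 30 synthetic geometries, 1000 random
tables for the sort oracle, and 10 random atom renumberings per invariance
check.

## Limitations

* The 2D angle screen inherits the layout heuristics of the underlying 2D
  coordinate generator; a ring the layout happens to draw regularly will
  pass even if 3D strain would be considerable (the remote-mode strain
  screen is the stricter alternative).
* UFF with generic Pd typing is a geometry regularizer, not a credible
  energy model for ranking; rankings intended for real decisions should use
  the tight-binding engine or better.
* Small palladacycles (3- and 4-membered rings) frequently fail embedding
  or validation; they are excluded with explicit warnings rather than
  scored.
* The bundled pattern table contains only the directing groups whose
  SMARTS and strengths are printed in the worked example; the full
  precomputed hierarchy is external data that users supply in the same TSV
  format.
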