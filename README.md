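# regiopd

Regioselectivity prediction for directing-group-assisted, Pd-mediated C–H
activation via the concerted metalation–deprotonation (CMD) mechanism.

## The problem

Selective functionalization of aromatic C–H bonds with Pd(OAc)₂ catalysts is
steered by directing groups (DGs): lone-pair heteroatoms that coordinate the
metal and place it next to one particular C–H bond. In the CMD mechanism the
rate-determining step forms a cyclic palladacycle intermediate — Pd
σ-bonded to the activated carbon, coordinated by the DG heteroatom and a
κ²-acetate. By the Bell–Evans–Polanyi principle the relative energy of this
intermediate tracks the activation barrier, so the reaction site whose
palladacycle is lowest in energy is the one predicted to react.

`regiopd` implements that workflow for computational and synthetic chemists:

1. **Enumerate** candidate (sp² C–H site, DG heteroatom) pairs from a
   substrate SMILES — either *ortho* pairs 2–5 bonds apart (palladacycle
   ring sizes 4–7) or, for remote DGs, the full Cartesian product of
   symmetry-unique sites and donors.
2. **Filter** geometrically: a 2D single-plane embedding of the ring closed
   through a Pd placeholder must keep every internal ring angle within 10%
   of the regular-polygon angle `(N−2)·180°/N`; in remote mode, a dummy
   palladacycle built with a CCl₂ bridge is embedded in 3D and kept only if
   the MMFF94s out-of-plane + torsion strain is ≤ 10 kcal/mol.
3. **Deduplicate** by graph symmetry (canonical SMILES with a labelled
   hydrogen or coordinated dummy atom) and DG resonance (nitro/carboxylate
   oxygens).
4. **Assemble** each surviving substrate–Pd(OAc) intermediate, generate
   `3·N_rot + 3` ETKDG conformers, cluster them at 1.0 Å heavy-atom RMSD
   (medoid representatives), and **optimize** the representatives with a
   pluggable energy engine (deterministic mock, UFF, external GFN1-xTB with
   ALPB solvent, or DFT single points for refinement). Optimized geometries
   are validated: unchanged connectivity away from the metal, and the Pd
   coordination sphere coplanar within 5°.
5. **Rank** sites by the best valid conformer energy per complex; every site
   within 1 kcal/mol of the global minimum is predicted. Against an observed
   site, predictions are labelled *correct* (unique hit), *semi-correct*
   (observed among several within the window) or *incorrect*.

A second, database-style predictor is included: a lookup table of SMARTS
patterns with precomputed DG strengths (kcal/mol). All patterns are matched
onto the substrate and ranked per site by the three-key priority — number of
heavy atoms matched (desc), sum of atomic numbers matched (desc), DG
strength (asc) — and the site(s) with the strongest assigned DG win.

Cheminformatics primitives (SMILES/SMARTS, canonical atom ranking, ETKDG,
MMFF94s/UFF) are delegated to RDKit through a bundled Python backend; the
workflow logic lives in R.

## Worked example: the lookup-table predictor

```r
library(regiopd)

tab <- load_pattern_table(system.file("extdata", "tomberg_patterns.tsv",
                                      package = "regiopd"))
predict_site_from_patterns("CCCN(C)C(=O)c1ccc(C(=O)c2ccccc2)cc1", tab)
#> <pattern_prediction> CCCN(C)C(=O)c1ccc(C(=O)c2ccccc2)cc1
#>   predicted site atom(s): 8, 20
#> # A tibble: 6 x 5
#>   site_atom assigned_strength_kcal smarts           n_heavy z_sum
#>       <int>                  <dbl> <chr>              <int> <int>
#> 1         8                   -2.7 [cH1]cC(N(C)A)=O       7    45
#> 2         9                   -1.7 [cH1]c-C(=O)c          5    32
#> 3        14                   -1.7 [cH1]c-C(=O)c          5    32
#> 4        18                   -1.7 [cH1]c-C(=O)c          5    32
#> 5        19                   -1.7 [cH1]c-C(=O)c          5    32
#> 6        20                   -2.7 [cH1]cC(N(C)A)=O       7    45
```

Six aromatic CH sites match a pattern (atom indices are 0-based, input
order). The two sites *ortho* to the tertiary amide (atoms 8 and 20) are
assigned the amide pattern `[cH1]cC(N(C)A)=O` — it matches 7 heavy atoms
(ΣZ = 45), beating the shorter amine pattern despite the latter's much
stronger −14.3 kcal/mol — and their −2.7 kcal/mol wins over the −1.7 of the
four ketone-*ortho* sites, so the amide directs the activation.

The QM-style pipeline runs the same way from a SMILES (here with the
deterministic mock engine; swap `engine_spec("xtb")` when the binary is
installed):

```r
pred <- run_prediction("c1ccc(-c2ccccn2)cc1",
                       engine = engine_spec("mock"), seed = 7)
tidy(pred)     # per-complex energies, relative energies, threshold flags
glance(pred)   # one-row summary
autoplot(pred) # relative-energy bar chart
```

A thin command-line wrapper is at `inst/cli/regiopd.R`
(`predict`, `patterns`, `nullmodel` subcommands).

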