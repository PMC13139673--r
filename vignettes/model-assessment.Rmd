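---
title: "Assessing predicted structures at their binding sites: methods and design"
author: "foldsite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing predicted structures at their binding sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldsite)
```

## The problem

Structure predictors (AlphaFold-family networks) and homology-modelling
servers now produce models of pharmacological targets for which few
experimental structures exist.  Whether such a model is usable for
docking and virtual screening is not a global question: what matters is
the *local* reliability of the binding pockets and whether a docking
setup built on the model can reproduce known ligand poses.  `foldsite`
implements that assessment as a reusable pipeline, developed around the
homotrimeric human P2X7 receptor (595 residues per subunit), whose
orthosteric ATP pocket and adjacent allosteric antagonist pocket are
shipped as built-in site definitions (`p2x7_sites()`).

Four quantities drive the assessment:

1. **Site confidence** — per-residue pLDDT aggregated over a site's key
   residues and their sequence neighbours.
2. **Model agreement** — Kabsch-superposed C-alpha RMSD between all
   model pairs.
3. **Redocking fidelity** — symmetry-corrected RMSD between a docked
   pose and the crystallographic pose, against the conventional 2.0
   angstrom criterion, plus the docking-grid definition itself.
4. **Interaction fingerprints** — which key residues form which contact
   types with a docked ligand.

## Site confidence

pLDDT (predicted local distance difference test, 0–100) is deposited in
the B-factor channel of predicted models.  Some predictors emit one
value per residue (all atoms of a residue share it), others one value
per atom.  `residue_confidence()` therefore uses a single convention —
the unweighted mean over a residue's atoms — which is exact for
residue-level files and the natural aggregate for atom-level files; a
`ca_only` mode is available for comparison.  Models read with
`predicted = FALSE` carry true B-factors and refuse these operations,
preventing a silent misreading of experimental structures.

`site_confidence()` aggregates a site in three steps: each key residue's
value is the mean over its *window* (the residue plus
`neighbor_offsets`, clipped at chain termini without error); windows are
averaged across chains (`chain_policy = "average_all"` by default, since
a homotrimer report prints one value per residue); and the site global
average is the plain mean of the key-residue values
(`aggregate_global_mean()`, reported at 2 decimals, computed at full
precision).  Each key residue's expected one-letter code is checked
against the model and a mismatch is an error: with author-numbered
models from different pipelines, numbering drift is the failure mode to
catch loudly.

Two conventions here were genuinely open, and we fixed them explicitly
rather than silently:

* **"Five adjacent residues"** does not determine a direction.  The
  default window is `c(-3, -2, -1, +1, +2)` — the five nearest sequence
  neighbours with the tie toward the N-terminus — and it is fully
  configurable, so any published convention can be matched exactly.
* **Are printed per-residue values bare or already windowed?**  Site
  reports of the kind this package reproduces are consistent with
  either reading.  We treat published per-residue tables as
  already-aggregated residue-level values: the worked examples plant
  them directly and evaluate with `neighbor_offsets = integer(0)`.
  Fresh analyses from raw models use the default window.
* The allosteric key-residue list is published with position 312 as
  valine in one place and alanine in another;
  `p2x7_sites(allosteric_variant = )` provides both, defaulting to
  V312, and takes no position on which is intended.

```{r}
ref <- p2x7_reference_plddt("AF2", "orthosteric")
aggregate_global_mean(ref$plddt)
rank_site_residues(data.frame(label = paste0(ref$aa, ref$resno),
                              resno = ref$resno, conf = ref$plddt))
```

## Superposition and model comparison

`kabsch()` is the closed-form SVD solution for the proper rotation and
translation minimising `sqrt(mean(|r_i - r_i_ref|^2))` over paired
points.  The reflection case is corrected by flipping the sign of the
smallest singular value, so the returned rotation always has
determinant +1 — a mirror image keeps a strictly positive RMSD, as it
must for chiral molecules.  Inputs with fewer than three non-collinear
points yield a correct RMSD but are flagged `non_unique`.

`pair_calpha()` pairs atoms on the intersection of (chain position,
residue number): models built from the same full-length sequence but
missing different regions (e.g. an unresolved 440–470 loop) pair on
what both resolve, and no sequence alignment is attempted — author
numbering is authoritative.  C-alpha-only pairing is the default (the
common convention for whole-model comparison); `selection = "all"`
matches all shared atom names.  For C3-symmetric homotrimers the chain
correspondence is not fixed by file order, so
`model_rmsd(trimer_symmetry = TRUE)` tries the cyclic chain shifts and
reports the minimum; `full_permutations = TRUE` extends the search to
all orderings for asymmetric edge cases.  `rmsd_matrix()` assembles the
all-pairs table with a zero diagonal; a pair that cannot be paired is
reported `NA`, never 0.  Reports round to 3 decimals.

## Symmetry-corrected ligand RMSD and redocking

Docked poses and the crystallographic ligand live in the same receptor
frame, so pose RMSD uses **no fitting**.  Chemically equivalent atoms
(the oxygens of a phosphate, the two arms of a symmetric aromatic) may
be indexed differently in two poses, inflating the naive RMSD; the
correction finds, per chemical element, the one-to-one atom
correspondence minimising the total sum of squared distances.  That is
a linear assignment problem, solved exactly by a hand-implemented
Hungarian (Munkres) method in its O(n^3) potential/augmenting-path
form (`solve_assignment()`); no installed R package provides linear
assignment, and the solver is validated in the test suite against
exhaustive permutation enumeration.  Among equally optimal assignments
the lexicographically smallest pair list is returned, making results
deterministic under ties (symmetric inputs produce exact ties
routinely).

Design choices:

* **Heavy atoms only by default** — docking outputs and crystal
  references rarely agree on hydrogen placement; `heavy_only = FALSE`
  restores hydrogens.  This is our declared default, not a claim about
  any published protocol.
* **Per-element matching, not graph-automorphism matching** — the
  correction is implemented exactly as stated for element classes; it
  can in principle pair chemically non-equivalent atoms of one element.
  A bond-graph-aware mode is a deliberate non-goal.
* The redocking verdict is **strict**: `sym_rmsd < threshold` (2.0
  angstrom default) is satisfactory; exactly 2.0 is not.
* `grid_from_ligand()` centres the docking box on the unweighted mean
  of the ligand's heavy-atom coordinates with edges 40 x 30 x 40
  angstrom by default — large enough to cover a pocket plus its
  surrounding interacting residues.

## Interaction fingerprints

`detect_interactions()` re-implements the geometric role of a
protein–ligand interaction profiler with explicit thresholds, all
exposed in `interaction_rules()`:

| contact | criterion | default |
|---|---|---|
| hydrogen bond (HB) | donor–acceptor heavy-atom distance; D–H...A angle only when hydrogens exist | 3.6 A, >= 100 deg |
| salt bridge (SB) | distance between opposite charged centers (Lys NZ, Arg guanidinium CZ, His ring vs. phosphate/carboxylate O, charged amines) | 5.5 A |
| hydrophobic (HI) | carbon–carbon contact between apolar atoms | 4.0 A |
| pi-stacking (pi-s) | ring-centroid distance with interplanar angle parallel or T-shaped | 5.5 A; <= 30 deg or 60–90 deg |

The detector is hydrogen-free by design: protonation is upstream of
this package, and the heavy-atom proxies above are the standard fallback
when hydrogens are absent.  Ligand chemistry (charges, apolar carbons,
aromatic rings) is inferred from the bond block when present, from
covalent-radius distances (<= 1.25 x the radius sum) when not, and can
be overridden by a `charge` column on the pose atoms.  Ring perception
collects the smallest cycle through each bond and keeps 5/6-cycles of
C/N that are coplanar within 0.2 angstrom.  Per residue and contact
kind, only the shortest contact is kept, which makes the record list
deterministic and maps directly onto fingerprint tables.
`fingerprint()` tabulates one row per key residue (an em-dash marks no
contact) and `compare_fingerprints()` aligns models side by side with a
per-model count of key residues hit.

The published analyses this layout mirrors used an external profiler
whose exact thresholds for that version are not stated; results on real
structures may therefore differ in borderline contacts, which is why
recovery is validated against *planted* geometry (below) rather than
against any published contact table.

## The synthetic generator and what passing tests mean

`make_trimer()` builds ideal alpha-helical poly-alanine chains (phi/psi
= -57/-47 via internal-coordinate placement) arranged with C3 symmetry,
and plants B-values per `conf_profile()`: a baseline, per-residue
overrides, optional per-atom Gaussian noise (values rounded to the PDB
B-factor precision of 2 decimals, and the truth records what was
actually written).  `make_transformed_copy()` applies a known rigid
motion plus optional coordinate noise and reports the exact fixed-frame
RMSD of the drawn displacements.  `make_pose_pair()` returns a pose and
an element-preserving permuted, uniformly displaced copy; its
symmetry-corrected ground truth comes from the exhaustive-permutation
oracle (`exhaustive_sym_rmsd()`) for classes of at most 6 atoms, and
analytically as the displacement norm for larger classes — valid
because the templates keep same-element atoms more than twice the
displacement apart, which makes the planted matching provably optimal
(any other matching pays at least one pair at distance >= spacing minus
displacement).  `make_interaction_scene()` places side-chain templates
and ligand fragments on icosahedron-vertex directions, 0.5 angstrom
inside the threshold for positive plants and 1.0 angstrom outside for
negative ones, with a steric re-placement loop.

What this does and does not show: the generator exercises numbering,
confidence semantics, geometry, symmetry and threshold logic exactly,
but its helices are not realistic folds, its ATP-like template is an
element-multiset stand-in with no chemical validity, and planted scenes
contain no competing near-threshold geometry.  Passing tests therefore
certify the *computations*, not agreement with any particular
experimental system.

## Numerical choices

* Kabsch/assignment/aggregation tolerances in tests are 1e-9 absolute
  unless the format dictates otherwise (PDB coordinates: 5e-4).
* Assignment tie-break: lexicographically smallest pair list, found by
  fixing rows in order against the known optimum with a relative
  tolerance of 1e-9.
* Altloc resolution keeps the highest-occupancy conformer; ties resolve
  toward altloc "A".
* Degenerate inputs: empty models, empty poses, empty value lists and
  non-square cost matrices are errors; collinear point sets are flagged
  rather than rejected; residues missing from a site are listed in the
  report, and only an entirely unresolvable site is an error.
* Reporting precision follows the conventional table layouts: 2
  decimals for pLDDT, 3 for RMSD; all internal computation is double
  precision.

## Problem sizes

The shipped test-suite and acceptance script run at sizes chosen to
exercise every code path while staying quick on one CPU: trimers of
20–320 residues, 50–60 oracle pose pairs plus 200–1000 bound checks,
100 rigid motions with a 10,000-transform random-search oracle, and
50–100 planted scenes.  All sizes are parameters of the corresponding
generator calls and scale up trivially.

## Limitations

* No sequence alignment: models must share author numbering.
* The interaction detector covers HB/SB/HI/pi-stacking only — no
  water-mediated contacts, halogen bonds, pi-cation or metal
  coordination — and estimates no binding affinity.
* No docking is performed; the package validates poses produced
  elsewhere and defines grids for external docking engines.
* pLDDT, pTM, ipTM and PAE are ingested, never recomputed; model
  quality scores of homology-modelling servers are out of scope.
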