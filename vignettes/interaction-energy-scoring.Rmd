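---
title: "Theory-based interaction energy component scoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Theory-based interaction energy component scoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iecscore)
library(dplyr)
```

## The problem

Classical docking scoring functions estimate protein–ligand binding
strength as a weighted sum of physically interpretable energy components —
van der Waals contacts, hydrogen bonds, electrostatics, hydrophobic burial,
desolvation, conformational entropy. Linear weights are cheap but rigid:
they cannot capture the non-additive interplay of those components across
diverse binding modes. A machine-learning scoring function (MLSF) keeps the
physically grounded descriptors but lets a non-linear classifier (SVM,
random forest, gradient-boosted trees) learn how the components combine to
separate active compounds from decoys in a virtual screen.

`iecscore` implements the full path from docked 3-D poses to a screened,
ranked compound list:

1. **Descriptor calculators** (`parse_receptor()`, `parse_ligand()`,
   `assign_types()`, `featurize()`) compute a Smina/Vina-style six-term
   block and an NNScore-2-style atom-type contact block directly from
   structures.
2. **A term taxonomy and combination framework** (`build_registry()`,
   `enumerate_formula()`, `enumerate_tree()`, `assemble()`, `ablate()`)
   organizes energy terms from 15 classical scoring functions into 12
   physicochemical interaction groups and enumerates theory-based feature
   combinations.
3. **A training protocol** (`split_screening()`, `tune()`,
   `train_final()`, `predict()`, `vote()`) with stratified splitting,
   seeded hyperparameter search and cross-validation.
4. **Screening metrics** (`f1_score()`, `roc_auc()`,
   `enrichment_factor()`, `evaluate_screen()`).
5. **A synthetic-data generator** (`make_complex()`,
   `make_screening_set()`) whose outputs have closed-form expected values,
   so every other layer is testable without any external download.

## Atom typing and charges

Atoms are mapped onto a fixed AutoDock-style heavy-atom alphabet
(`C`, aromatic `A`, `N`/`NA`, `O`/`OA`, `S`/`SA`, `P`, halogens, polar
hydrogen `HD`, `MET` for any metal). Per-type van der Waals radii
(X-Score/Vina-style: C 1.9 Å, N 1.8 Å, O 1.7 Å, S 2.0 Å, …), Lennard-Jones
well depths and desolvation parameters ship as a plain CSV
(`atom_type_params()`), so every numeric input to the kernels is auditable.

Nonpolar hydrogens are typed `H` and ignored by every pairwise term (the
united-heavy-atom convention of the Vina family); polar hydrogens are kept
because hydrogen-bond geometry needs them. Partial charges are Gasteiger
(PEOE) charges computed per molecule — chosen because they are fast,
deterministic and require no force-field setup, not because any upstream
tool is known to use them; structures that already carry charges (Mol2,
fixture sidecars) keep them. Receptors parsed from PDB have no
connectivity, so bonds are first inferred from covalent radii (sum plus
0.45 Å slack); this is an O(n²) step intended for binding-site-sized
receptors, not whole ribosomes.

Two typing choices are deliberately coarse and documented rather than
hidden: a nitrogen with no bound hydrogen is treated as an acceptor (`NA`),
one with a hydrogen as a donor (`N`); aromaticity requires either an
explicit aromatic bond order or a ring atom with a double bond.

## The descriptor blocks

All pairwise terms run over receptor–ligand atom pairs within a global
**8 Å cutoff** (closed boundary, `contacts()`), a Vina-family convention.
Let `r` be the center distance and `d = r − R_i − R_j` the surface
distance.

**Smina-style block** (six values):

* `smina:vdw` — the Vina steric triple
  `w₁·exp(−(d/0.5)²) + w₂·exp(−((d−3)/2)²) + w₃·d²·[d<0]` with the
  published default weights (−0.035579, −0.005156, 0.840245);
* `smina:hbond` — piecewise-linear, non-directional: 1 for `d ≤ −0.7`,
  0 for `d ≥ 0`, over complementary donor–acceptor typed pairs;
* `smina:elec` — Coulomb sum `Σ 332·q_i·q_j/(ε(r)·r)` with
  distance-dependent dielectric `ε(r) = 4r`;
* `smina:hydrophobic` / `smina:non_hydrophobic` — piecewise-linear: 1 for
  `d ≤ 0.5`, 0 for `d ≥ 1.5`, over pairs where both (neither) atoms are
  hydrophobic;
* `smina:sol` — Gaussian pair desolvation
  `Σ (S_i·V_j + S_j·V_i)·exp(−r²/(2σ²))`, σ = 3.6 Å, with per-type
  solvation parameters and volumes from the bundled radii.

These functional forms are this package's declared substitutes for a
six-term empirical decomposition; they are standard Vina-family kernels,
but no claim is made that they reproduce any external binary bit-for-bit.

**NNScore-2-style block** (fixed 363-column schema): a Lennard-Jones 6–12
sum over heavy pairs; the geometric hydrogen-bond count (H⋯A ≤ 2.5 Å,
donor–acceptor ≤ 3.5 Å, D–H⋯A angle ≥ 120°); the hydrophobic contact count
(r ≤ 4 Å); per-type-pair contact counts in two shells (close ≤ 2.5 Å,
semi-close 2.5–4 Å) and per-type-pair vacuum Coulomb sums (≤ 4 Å). Pair
keys are canonically ordered in the C locale and absent pairs are emitted
as zero, so the schema never varies between inputs — essential for
machine-learning feature tables.

**Auxiliary terms** (`aux` block): the rotatable-bond count (non-ring
single bonds between heavy atoms, each end with another heavy neighbor,
amides excluded — a ligand-entropy proxy), the quadratic clash penalty
`Σ d²` over interpenetrating pairs, a piecewise-linear metal–acceptor
attraction (plateau ≤ 2.2 Å, zero ≥ 4.0 Å), and an intramolecular 1-4+
Lennard-Jones sum as an internal-strain proxy.

Every kernel parameter lives in `kernel_params()` (YAML under `extdata`),
so deviations from the defaults are visible in one place.

## The interaction taxonomy and feature combinations

`build_registry()` loads the (scoring function, term) → interaction-group
taxonomy: 15 classical scoring functions whose terms fall into 12 groups
(vdW, H-bond, electrostatic, hydrophobic, solvation, entropy,
knowledge-based, clash, metal, internal, non-hydrophobic, atom-pair
counts). Six frequently used groups — vdW, H-bond, electrostatics,
hydrophobic, entropy, clash — are *varied*: a feature combination chooses
one scoring function's formula per varied group, while all terms of the
other six groups are retained in default.

Three strategy rows ship in `combination_options()`:

* **formula** — option sets chosen by formula diversity; the Cartesian
  product over the six groups yields 3·3·2·4·2·2 = **288** combinations;
* **tree_sum** / **tree_mean** — option sets guided by random-forest
  importance aggregated per (scoring function, group) by sum or mean
  (`tree_importance()`), yielding **24** and **12** combinations (36
  together, 324 in total with the formula row).

Terms from different scoring functions describing one interaction can tie
in importance; `options_from_importance()` retains all candidates within
1% relative difference of the group's best — the threshold is a package
choice, since "similar importance" has no canonical cut-off. The two tree
rows are exposed strictly by row id; their published naming is ambiguous
(the row labelled by one aggregation mode is described with the other
name in running text), and this package does not attempt to adjudicate.

Enumeration order is lexicographic by (group order, scoring-function
name) so runs are reproducible; `assemble()` projects a combination out of
a feature table and errors when a registry-defined column is missing, but
silently skips a chosen scoring function that simply has no term of a
group (that is what "choose Smina for entropy" must mean when Smina has no
entropy term). `ablate()` removes one group's columns for sensitivity
experiments.

## Training protocol

`split_screening()` performs the stratified 4:1 split (per class,
`round(n/5)` rows to the test part). Preprocessing (`preprocess_fit()` /
`preprocess_apply()`) removes exactly constant features (raw variance
< 1e-12) and standardizes the rest with *training* statistics; the
constant filter runs on raw values because after standardization every
kept feature has unit variance and a variance filter would be vacuous.
Applying the state never re-estimates statistics, so train/test leakage is
structurally impossible.

`tune()` draws exactly `steps` (default 100) candidates from the declared
spaces — SVM: C ∈ [0.1, 10], γ ∈ [0.001, 1]; random forest: 100–300 trees
in steps of 10, depth 6–100, `sqrt`/`log2` feature sampling, minimum leaf
3–10; gradient boosting: trees and depth as the forest, learning rate
[0.1, 0.5], L2 regularization [0.5, 3] — and scores each by stratified
k-fold (default tenfold) cross-validated F1 of the positive class at
threshold 0.5. F1 is the tuning objective because it is the primary
classification metric reported throughout; the search is a seeded random
search (recorded as such in the trace), which satisfies the
fixed-step-count protocol without a TPE dependency. One master seed
derives the split/search/fold/model seeds through a fixed counter scheme
(`derive_seed()`), making the whole pipeline bit-reproducible.

`vote()` implements the two ensembling modes (mean probability, majority
fraction); the default remains a single tuned model. No resampling is
applied to class imbalance by default.

## Metrics

`f1_score()` composes precision `TP/(TP+FP)` and recall `TP/(TP+FN)`;
degenerate denominators return 0 with a warning. `roc_auc()` is the exact
Mann–Whitney statistic computed from midranks (ties count one half).
`enrichment_factor()` uses `s = ceiling(fraction·N)` top-ranked molecules
— the rounding is a package choice since the defining ratio does not fix
it — and breaks score ties by input order (stable and conservative; EF can
genuinely depend on the tie policy, which is why it is pinned and
documented). Random rankings have expected EF 1.

## What the synthetic generator emulates — and what it does not

`make_complex()` builds toy complexes from a `plant_spec()`: isolated
interaction sites (hydrophobic C–C at the kernel plateau, linear N–H⋯O
hydrogen bonds at 1.9 Å, O–O clashes at d = −0.5 Å, charged C–C pairs)
spaced 25 Å apart so that, with the 8 Å cutoff, every term is exactly the
sum of independent single-pair contributions. Ground truth comes from a
separate closed-form evaluator that shares no code with the production
kernels, which turns the whole descriptor layer into an exactly testable
unit (agreement within 1e-9 on 100 seeded fixtures).

`make_screening_set()` draws active/decoy feature vectors from Gaussians
separated by a per-feature mean shift Δ with shared covariance. The
package default plants Δ on 5 informative features out of 50 — with
Δ = 2 that is a Mahalanobis separation of ~4.5 (best possible AUC ≈
0.999), a separation a well-behaved screening model should exploit while
45 noise features give it every chance to overfit. Defaults (200 actives,
1800 decoys) mirror a small screening campaign with ~10% actives.

Passing these tests shows the machinery is correct, deterministic and
leak-free. It does **not** show that real docking descriptors separate
real actives from property-matched decoys: synthetic fixtures have no
pose noise, no decoy bias, no activity-cliff structure, and Gaussian
class-conditional features are far kinder than real descriptor
distributions. Benchmark performance must be established on real screens.

## Numerical choices and degenerate inputs

* Cutoffs are closed (`r ≤ cutoff`); two atoms at exactly 8 Å are one
  contact.
* Overlapping atoms (r = 0) are an error in Coulomb sums rather than an
  infinity.
* Water residues are dropped at parse time; alternate locations other
  than blank/"A" are discarded; zero-atom ligand records are skipped with
  a recorded index.
* A ligand with no heavy atoms is an error for the descriptor blocks.
* Fixture problem sizes in the test-suite (25–60 receptor atoms, 8–15
  ligand atoms, screening sets of 300–2,000 rows, 100-step tuning at
  tenfold CV) were chosen as the smallest sizes at which each property is
  a meaningful check rather than a tautology.

## Known limitations

* The six Smina-style kernels are declared stand-ins for an unpublished
  term decomposition; absolute values should not be compared against
  external software output.
* Gasteiger charges on receptors rest on distance-inferred single-bond
  connectivity; charges near metal sites and unusual residues are crude.
* The external-term adapter (`ingest_external_terms()`) is the only route
  for the other 13 classical scoring functions; this package does not
  reimplement them.
* `options_from_importance()` ties (1%) and the EF rounding/tie policies
  are package choices, stated above, not inferences about any upstream
  implementation.
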