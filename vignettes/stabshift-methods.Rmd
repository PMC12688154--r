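---
title: "Methods: antisymmetric ΔΔG prediction with stabshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: antisymmetric ΔΔG prediction with stabshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabshift)
```

This vignette documents the scientific and numerical choices behind
`stabshift`: the model of the data, the descriptor definitions, the
selection and evaluation machinery, what the synthetic generators do and
do not emulate, and the decisions taken where the design was genuinely
open.

## The data model

A ΔΔG observation is a point mutation (structure id, chain, author
residue number with optional insertion code, wild-type and mutant amino
acid) measured at a pH and temperature, with a folding free-energy change
in kcal/mol. The sign convention of the input is passed through
unchanged: the package records ΔΔG verbatim and only ever negates it for
reverse records, so it is agnostic about whether positive means
stabilizing or destabilizing.

**Merging.** Curated stability datasets overlap heavily. Two records are
duplicates when they share the mutation key *and* the measuring
conditions; duplicates with identical ΔΔG collapse to one, and
duplicates with conflicting ΔΔG keep the value with the smallest |ΔΔG|
(reported ΔΔG values trend toward zero, and values closer to zero are
the more conservative choice under that trend), ties broken by first
occurrence. Whether conditions belong to the duplicate key is genuinely
ambiguous in the field's descriptions; here they do, so the same
substitution measured at two pH values remains two observations.
First-occurrence output order makes downstream seeded operations
reproducible.

**Antisymmetric augmentation.** ΔG is a thermodynamic state function,
so ΔΔG(A→B) = −ΔΔG(B→A). Every direct record gains one reverse sibling
(amino acids swapped, ΔΔG negated, conditions identical) sharing a
`pair_id`. Augmentation of an already-augmented dataset is an error, not
a no-op, because silently re-pairing records would corrupt pair identity.

**Pair-level resampling.** A record and its reverse twin are perfectly
dependent, so both the 90/10 train/test shuffle and cross-validation
folds treat the pair as the sampling unit. The split takes the first
⌈0.9·n⌉ shuffled pairs for training — the ceiling reproduces the
bookkeeping of a 7,876-pair input exactly (7,089 / 787). The shuffle
seed default of 42 is part of the method definition; fold-assignment and
model seeds are explicit arguments everywhere.

## Structural descriptors

All geometry operates on heavy atoms of the first PDB model, with
alternate locations resolved to the highest-occupancy conformer (ties →
altloc A) and waters/heteroatoms excluded.

* **Spatial shells.** The local environment is summarized over residues
  within 7, 10 and 13 Å of the mutation site, plus the whole structure.
  A residue is in a shell when the *minimum heavy-atom distance* to the
  site residue is within the radius. The field rarely states its
  distance convention; minimum heavy-atom distance is the most inclusive
  common choice, and a Cα-only mode exists behind a flag. Shells nest by
  construction and always contain the site.
* **Solvent accessibility.** Shrake–Rupley quadrature with a
  deterministic golden-spiral point set (default 960 points/atom, probe
  1.4 Å ≙ water). 960 points puts the single-atom error well under 1%.
  RSA divides by the theoretical maximum area of the amino acid (Tien et
  al. 2013 table) and clips to [0, 1.2]; residues with RSA < 0.25 are
  "buried" — 0.25 is the conventional burial threshold.
* **Secondary structure.** An eight-state vocabulary (3₁₀-, α-, π-helix,
  turn, β-strand, β-bridge, bend, loop). The baseline classifier maps
  backbone (φ, ψ) to an explicit, overridable region table
  (`rama_region_table()`); termini and residues with missing backbone
  atoms are loop. The table is a documented stand-in, not a DSSP clone —
  when a saved DSSP report is available its letters (G/H/I/T/E/B/S/other)
  take precedence.
* **Interactions.** Edges between residues by documented geometric
  criteria (defaults: donor–acceptor N/O ≤ 3.5 Å; SG–SG ≤ 2.5 Å;
  cation–anion group atoms ≤ 4.0 Å; heavy-atom distance ≤ vdW sum
  + 0.5 Å for sequence-non-adjacent residues; cation–ring centroid
  ≤ 5.0 Å; centroid–centroid ≤ 6.5 Å). A pair may carry several types —
  a salt bridge is both ionic and hydrogen-bonded. These cutoffs are
  configurable constants; no angular terms are applied.
* **Pharmacophores.** Each heavy atom is typed by a shipped
  (residue, atom-name) table into eight non-exclusive classes
  (hydrophobic, positive, negative, acceptor, donor, aromatic, sulphur,
  neutral); multi-label atoms count in every class. Untyped carbons are
  hydrophobic; unknown atoms neutral with a warning.
* **Hydrophobic clusters.** Connected components (size ≥ 2) of the
  contact graph over {A,V,L,I,M,F,W,C} with side-chain heavy atoms
  within 4.5 Å.
* **Flexibility.** A Cα Gaussian network model: Kirchhoff matrix from
  contacts within 7.3 Å, mean-square fluctuations from the diagonal of
  its Moore–Penrose pseudo-inverse, normalized to unit mean. This is a
  topology-only *baseline* for normal-mode flexibility, documented as
  such; it is invariant under rigid motion and is not calibrated to any
  external package's absolute scale.
* **Amino-acid categories.** Eight categories with an explicit shipped
  membership table; the four charge/polarity categories partition the
  alphabet (uncharged polar STNQCY; positive KRH; negative DE; nonpolar
  GAVLIPFMW) and the four others overlap it (aromatic FWYH, aliphatic
  GAVLI, heterocyclic HPW, sulfur-containing CM). The category *names*
  are standard; the memberships are this package's documented choice.

**Mutant structures.** The baseline mutant model renames the residue and
truncates its side chain at Cβ (removed entirely for glycine), leaving
every other atom bit-exact, and flags the structure side-chain-incomplete.
This keeps the pipeline runnable with zero external dependencies; a full
side-chain modelling tool can be plugged in upstream by supplying its
output structure instead.

## Feature groups and the registry

Features are assembled in four groups: (1) wild-type
structure/environment over the four regions plus site-level and energy
terms and the two condition features; (2) mutant − wild-type differences
of the same descriptors, excluding burial and disorder proportions
(essentially invariant under a point mutation); (3) mutation-type
encodings; (4) evolutionary profile features. The evolutionary window
half-width is 5, giving 2·(2·5+1) + 2 + 2 = 26 group-4 features; mutant
profile scores reuse the wild-type matrix with the mutant column read at
the site (standard practice — re-running a profile search per mutant is
supported via a hook but not required). For reverse records the mutant
structure plays the wild-type role and vice versa, which makes every
internally computed group-2 difference exactly antisymmetric within a
pair.

Column order is fixed by `feature_registry()`, never by input order, and
`registry_manifest()` is the bookkeeping source of truth for per-group
counts — the shipped registry's totals are asserted against the manifest,
not against any external count. Missing adapter-backed values (FoldX
terms, SIFT, B-factor, disorder) are masked `NA`, never zero-imputed; the
tree engine handles missingness natively, and a strict prediction mode
refuses masked inputs.

## Selection, training, tuning

Cross-validation trains on k−1 pair-folds and scores R² = 1 − SSE/SST on
the held-out fold (this is *not* a squared correlation and may be
negative). Zero-variance validation labels raise an error rather than a
sentinel, and folds with fewer than two pairs are rejected. RFE removes
exactly one feature per round — the lowest total-gain importance, ties
broken by removing the later registry column — and the optimal subset is
the round with the highest mean R², later rounds (fewer features)
winning ties; a `step` option exists for speed and defaults to 1.
Default fold count is 20, with 3–5 folds appropriate at desk scale.

Hyperparameter search maximizes mean pair-level CV R² over a declared
space. The default strategy is seeded uniform random search; the
`sampler` hook accepts any strategy (e.g. a Bayesian optimizer) without
changing the scoring harness. Default engine parameters: 300 rounds,
learning rate 0.08, depth 5, subsample 0.9, column subsample 0.9,
minimum child weight 3, L2 λ = 1, single-threaded for bit determinism.

## Evaluation

Eight comparison metrics: Pearson γ and RMSE σ over all, direct-only and
reverse-only records; γ<sub>dir,rev</sub>, the Pearson correlation
between paired direct/reverse predictions (−1 for an ideally
antisymmetric predictor); and δ, the mean per-pair prediction sum
(0 kcal/mol ideally). MMD² uses the biased V-statistic (diagonal terms
included) with an RBF kernel; the bandwidth coefficient defaults to
1/dimension — the convention of the common kernel implementations — and
is recorded in the result. Steiger's Z for two dependent correlations
sharing a target uses the Fisher-z statistic with the Dunn–Clark
covariance at the average correlation; the reported p is one-tailed
(upper), the convention consistent with published (z, p) pairs such as
(1.83, 0.03) and (0.92, 0.17). Calibration sorts by the true value into
equal-count bins (remainder spread over leading bins) and reports the
standard error of the residuals per bin.

## What the synthetic generators emulate — and what they do not

`make_helix_structure()` builds geometrically ideal α-helical backbones
(φ = −57°, ψ = −47°, standard bond lengths/angles, Cβ by tetrahedral
construction) — valid fixed-width PDB, correct dihedral classes, sensible
distances, but no packed core, no side chains beyond Cβ, no experimental
disorder. `make_profile_fixtures()` emits dialect-correct PSSM/AAindex
files with seeded random values carrying no evolutionary signal.
`make_ddg_table()` draws unique mutation records with ΔΔG ~ N(0.5, 1.5²)
kcal/mol, matching the near-zero-centred, mildly destabilizing shape of
curated datasets. `make_ddg_benchmark()` plants a linear signal:
direct labels w·f + ε over `n_informative` standard-normal features,
reverse rows with the informative block and label negated — the
antisymmetry is in the features, so a correct pipeline can reach
γ<sub>dir,rev</sub> ≈ −1.

Passing tests on these fixtures therefore demonstrate that the
*machinery* is correct — parsing, geometry, bookkeeping, leakage-free
resampling, signal recovery, antisymmetry propagation — not that the
package reproduces published predictive accuracy on experimental data,
which depends on real structures, profiles and energy terms.

The study-scale problem sizes used throughout the tests and the
acceptance script are: 7,876 synthetic records for the dataset
bookkeeping; a 500-pair / 40-feature / 5-informative / noise-0.2
benchmark with 3-fold pair-level CV for end-to-end recovery; 100 random
helix fixtures for shell-nesting properties; length-1000 vectors for the
metric oracles.

## Known limitations

* The mutant baseline carries no repacked side chain, so group-2
  differences under-represent real conformational change unless a
  modelled mutant structure is supplied.
* The dihedral secondary-structure table is a coarse stand-in for
  hydrogen-bond-pattern assignment; supply DSSP reports where available.
* Interaction criteria are distance-only; no angular hydrogen-bond terms.
* The GNM fluctuation scale is relative (unit mean), not comparable
  across packages in absolute units.
* Disorder is provider-backed: without a report, the baseline labels
  everything ordered and flags the value as baseline rather than
  guessing.
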