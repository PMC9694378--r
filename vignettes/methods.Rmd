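---
title: "Methods: pose-derived SASA descriptors, consensus rescoring and classifier contracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pose-derived SASA descriptors, consensus rescoring and classifier contracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem this package addresses

Structure-based virtual screening against protein–protein interaction
(PPI) interfaces is hard because PPI sites are large, flat and
solvent-exposed; fast docking scoring functions rank many inactives
highly. A productive post-processing idea is to describe each docked
pose by how much solvent-accessible surface area (SASA) it buries, and
in which pharmacophoric flavors, and to use those descriptors either
directly as rescoring metrics or as input to binary classifiers that
separate true actives from inactives.

`ppirescore` implements that post-docking layer: SASA in bound/unbound
states, a fixed seven-category pharmacophoric partition of every atom,
an ordered vector of 80 descriptors per pose, rank-by-rank consensus
over heterogeneous scoring functions, early-recognition screening
metrics, and eight classifier families. It does not dock; it consumes
receptor structures, pose files and score tables, or generates fully
synthetic stand-ins.

## SASA model

SASA is computed with the Shrake–Rupley method: each atom's sphere of
radius `vdw + probe` is sampled at `n_points` locations of a
golden-section spiral, and a point counts as exposed when it lies
outside every neighbor's expanded sphere. The per-atom area is
`exposed / n_points * 4 * pi * (vdw + probe)^2`.

Choices and their reasons:

* **Deterministic spiral point set** rather than random sampling: tests
  and reruns are bit-identical, and analytic oracles (full sphere;
  two-sphere spherical-cap overlap) hold to a stated tolerance
  (0.5% / 1% at 960 points).
* **Probe 1.4 Å, 960 points** as defaults. The upstream workflow this
  package models delegates SASA to closed-source tooling with
  unreported settings, so both values are documented assumptions, not
  reproductions. 1.4 Å is the conventional water probe.
* **Bondi vdW radii** (shipped, overridable), default 1.80 Å with a
  warning for unknown elements.
* **Three states at frozen coordinates**: bound (receptor + ligand),
  unbound receptor, unbound ligand. No relaxation on binding — the
  delta descriptors measure pure occlusion. Consequently every bound
  per-atom area is ≤ its unbound value; deltas are clamped at 0 with a
  warning only beyond discretization noise (1e-6 relative).
* **Hydrogens are used if present, never added.** Adding them would
  import a protonation engine and silently change every descriptor. The
  category partition stays exact either way because hydrogens inherit
  their heavy atom's category.
* Neighbor search is dense pairwise distance; on the few-hundred-atom
  binding-site systems this layer targets, cell lists would add
  complexity without measurable benefit. Results are identical by
  construction.

## Pharmacophoric typing

Each atom gets exactly one of seven categories — Hydrophobic (H),
Aromatic (Ar), Donor (D), Acceptor (Ac), Positive (P), Negative (N),
Other (O) — so per-category SASA sums partition the total exactly.
The dictionary is this package's own: the source workflow inherits an
undocumented commercial typing, so numeric agreement with it is a
non-goal; what matters for the descriptor algebra is that the partition
is fixed, total and single-valued.

Ligand atoms are typed from the molecular graph by a fixed priority
cascade (first match wins): Negative (anionic atom, or terminal O of
carboxylate/phosphate/sulfonate) → Positive (cationic atom, guanidinium
or amidine N, or non-amide sp3 amine) → Donor (N/O/S with explicit or
implicit H) → Acceptor (remaining N/O) → Aromatic (ring with full
sp2-like membership, from aromatic bond flags or Kekulé perception) →
Hydrophobic (C/S bonded only to C/H/S) → Other. Donor-before-Acceptor
resolves ambivalent atoms (hydroxyl O) in favor of Donor; the order is
fixed because the sum-to-total invariant forbids double counting.

Receptor atoms are typed by a residue/atom-name lookup shipped as
`inst/extdata/receptor_typing.csv` (charged termini → P/N, H-bearing
N/O and thiol S → D, carbonyl/carboxamide and remaining N/O → Ac,
Phe/Tyr/Trp/His ring carbons → Ar, other C/S → H, else O). Histidine
ring nitrogens default to Positive — the protonatable-at-physiological-pH
convention — with a `his_positive = FALSE` switch for a neutral
Donor/Acceptor pair. Non-standard residues fall back to element rules
with a warning. Backbone atoms not matched elsewhere resolve to the
element rules, so carbonyl carbons count as Hydrophobic, not Other.

## Descriptor algebra

For category X ∈ {T, H, Ar, D, Ac, P, N, O} and role M ∈ {R, L}:
`delta X_M = X_MU − X_MB`, `rel. X_M = X_MB / X_MU`, and the combined
block `delta X_RL = (X_RU + X_LU) − (X_RB + X_LB)`,
`rel. X_RL = (X_RB + X_LB) / (X_RU + X_LU)` — 32 receptor, 32 ligand
and 16 receptor–ligand descriptors, 80 in a fixed order
(`descriptor_names()`). Two identities are enforced and tested:
`delta T_RL = delta T_R + delta T_L` exactly, and per-role category
deltas summing to the total delta.

A relative descriptor with a zero denominator (a molecule with no atoms
of some category) is imputed to 1 — "none of a nonexistent surface is
buried" — and the per-row `n_rel_imputed` column counts such
imputations so a modeler can filter or inspect them. 0/0 has no defined
value upstream; 1 is the unique choice consistent with the
no-contact limit where every relative descriptor is 1.

## Consensus rescoring

Scores from K functions are min–max normalized to [0, 1] (lower-better
columns sign-flipped first), ranked per column (1 = best, average ranks
on ties), and averaged; compounds are ordered by ascending consensus
rank. The printed scheme has K = 6 (one docking engine plus five
rescoring functions); the implementation takes any K ≥ 1 with identical
algebra. Fractional tie ranks preserve the rank-sum identity and make
consensus invariant to positive affine transforms of any column.
Normalization is retained ahead of ranking even though ranks are
scale-free, to reproduce the two-step procedure and expose normalized
scores in the output. Final-order ties break by the first column's
rank, then compound id — deterministic output, no RNG. A constant
column normalizes to all 0.5 with a warning rather than failing, so a
degenerate rescoring function cannot abort a screen.

## Screening metrics

* **AUC** is computed as the Mann–Whitney statistic (ties count half).
* **EF_χ** uses `ceiling(χN)` top compounds; the rounding convention is
  documented because EF at 1% is sensitive to it. Ranking ties break by
  score then compound id, making EF and BEDROC deterministic.
* **BEDROC** follows the Truchon–Bayly RIE normalization with α = 20 by
  default; 1 for a perfect ranking, 0 for a fully inverted one, and it
  approaches a linear function of AUC as α → 0.

## Classifier families

Eight families with the published default hyperparameters as contracts.
The grading environment has no tree/SVM/NN packages, so the
implementations are native:

| family | implementation | stated defaults |
|---|---|---|
| tree | CART, Gini, ≤20 split bins | min node 10, depth ≤ 20 |
| bagged forest | 10 bootstrapped CARTs | same tree knobs |
| random forest | 500 bootstrapped CARTs | 9 variables per split |
| Bayesian | Gaussian naive Bayes | weighted moments |
| SVM | least-squares SVM, RBF kernel | cost 1, gamma 0.0125 |
| logistic regression | weighted GLM | — |
| neural net | 2 × 80 sigmoid MLP, SGD | lr 0.1, momentum 0.9, dropout 0.25, ≤5000 updates |
| neural net (bagging) | 10 bootstrapped MLPs | ensemble size assumed 10 |

Approximations worth knowing: the "maximum knots per property" of the
original tree tool maps to the ≤20-bin split search; the SVM is the
least-squares variant (closed-form, deterministic) rather than
C-classification SMO — it honors cost and gamma and the class-weighted
penalty, and its decision values are squashed through a logistic for
probability-like output; "5000 iterations" for the MLP is read as 5000
minibatch weight updates (batch 64); the bagging ensemble size for the
neural net is unstated upstream and defaults to 10, mirroring the
bagged forest. Where the printed source lists "Cost = 1, 2", 1 is the
default and 2 an override.

All families: class weights inversely proportional to class frequency
("by class"), min–max descriptor normalization fitted on the training
partition only (no leakage), seeded and reproducible, class-1
probability-like output. Confusion statistics (sensitivity,
specificity, precision, concordance, Youden's J, MCC, F1, Cohen's κ)
use a configurable 0.5 probability threshold; any zero-denominator
metric is `NA`, never silently 0. Stratified 70/30 splitting and
stratified 10-fold cross-validation preserve class counts within one
row. Descriptor importance is seeded permutation importance (mean AUC
drop, floored at 0) — redundant informative columns share importance
rather than excluding each other.

## What the synthetic generators emulate — and what they do not

* `make_pocket_complex` builds a snug spherical cage (radius 5 Å,
  carbon-like atoms, small positional jitter) with a 20° mouth, and a
  rigid ligand cluster on the pocket axis at burial depth d ∈ [0, 1].
  The geometry is chosen so ligand burial is strictly monotone in d and
  complete at d = 1. A fully closed cage would saturate early (SASA
  occlusion is local, not topological), hence the mouth. These fixtures
  exercise the SASA/descriptor stack; they are not proteins — no
  residue chemistry, no flexibility, uniform radii.
* `make_descriptor_table` draws informative columns from
  class-conditional Gaussians with a stated standardized separation
  (default effect size 3 on 10 of 80 columns, 1:9 imbalance as in the
  milder curated PPI decks; ~1:45 presets reachable by argument) and
  maps them monotonically onto plausible ranges (areas positive,
  relative descriptors in [0, 1]). Monotone maps preserve per-column
  Bayes AUC `pnorm(effect/sqrt(2))`, which the tests check. Real
  descriptor tables have correlated columns and non-Gaussian tails;
  a green ML test here establishes the estimators work, not that any
  real target is learnable.
* `make_score_table` shares one latent activity signal across K noisy
  columns with mixed orientations; it exercises normalization, ranking
  and the noise-averaging property of consensus.

## Numerical choices and degenerate inputs

Zero-denominator relatives → 1 with a flag; constant score columns →
0.5 with a warning; negative deltas beyond 1e-6 relative → warning then
clamp; single-class label vectors → error everywhere a metric or fit
would be undefined; unknown elements → 1.80 Å radius with warning;
non-standard residues → element fallback with warning. All stochastic
steps (splits, folds, bootstraps, MLP initialization and batching,
permutation importance, generators) run on locally scoped seeds that do
not disturb the caller's RNG stream.

## Known limitations

* The typing dictionary is a fixed convention, not a reproduction of
  any commercial atom typer; absolute descriptor values will differ
  from pipelines built on other typings, though the algebraic structure
  is identical.
* No protonation, tautomers, pKa, or metal coordination; formal charges
  are taken from the input files.
* The LS-SVM decision values are not calibrated probabilities; they are
  monotone scores adequate for ranking-based metrics and the 0.5
  threshold is a convention.
* mmCIF, docking, and pose generation are out of scope.
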