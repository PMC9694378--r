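# ppirescore

Post-docking rescoring toolkit for virtual screening on protein–protein
interaction (PPI) interfaces. PPI binding sites are large, flat and
solvent-exposed, and fast docking scoring functions rank poorly there.
`ppirescore` post-processes docked poses three complementary ways:

1. **SASA descriptors.** For each pose it computes Shrake–Rupley
   solvent-accessible surface area in three states at frozen
   coordinates — the bound complex, the unbound receptor (binding site)
   and the unbound ligand — partitions every atom into one of seven
   pharmacophoric categories (Hydrophobic, Aromatic, Donor, Acceptor,
   Positive, Negative, Other), and derives an ordered vector of **80
   descriptors**: per category X and role M ∈ {R, L},

   ```
   delta X_M  = X_MU − X_MB            (surface buried on binding)
   rel. X_M   = X_MB / X_MU            (low = deep burial)
   delta X_RL = (X_RU + X_LU) − (X_RB + X_LB)
   rel. X_RL  = (X_RB + X_LB) / (X_RU + X_LU)
   ```

   32 receptor + 32 ligand + 16 receptor–ligand descriptors per pose.
2. **Rank-by-rank consensus.** Heterogeneous score columns are min–max
   normalized to [0, 1], ranked per column, and each compound's
   consensus rank is the mean of its per-column ranks.
3. **Classification.** Eight classifier families (tree, bagged forest,
   random forest, naive Bayes, radial-kernel SVM, logistic regression,
   a 2×80 MLP, and a bagged MLP ensemble) train on descriptor tables
   with class weighting, stratified 70/30 splits and stratified 10-fold
   CV, and are scored by ROC AUC, EF1%/EF5%, BEDROC(α = 20) and the
   full confusion-matrix panel (sensitivity, specificity, precision,
   concordance, Youden's J, MCC, F1, Cohen's κ).

Inputs are PDB receptors, SDF/MOL2 pose files and CSV score/label
tables — or fully synthetic complexes and tables from the built-in
generators, which make the whole package testable offline. Docking
itself, and the internals of any commercial scoring function, are out
of scope.

## Worked example

```r
library(ppirescore)

# a synthetic pocket complex, ligand 60% buried
cpx <- make_pocket_complex(burial_depth = 0.6, seed = 42)
v <- pose_descriptors(cpx, n_points = 480)
round(v[c("T_LU", "T_LB", "delta T_L", "rel. T_L",
          "delta T_RL", "rel. T_RL")], 2)
#>       T_LU       T_LB  delta T_L   rel. T_L delta T_RL  rel. T_RL
#>     222.15      71.45     150.70       0.32     205.05       0.81
```

The unbound ligand exposes 222 Å²; in the pose only 71 Å² remain, i.e.
151 Å² (68%) are buried — `rel. T_L` = 0.32 flags a deeply inserted
ligand. The receptor–ligand view adds the wall area the ligand covers.

```r
# consensus rescoring of 6 noisy scoring functions, then screening metrics
st <- make_score_table(n_compounds = 200, K = 6, signal = 1.5, seed = 42)
cons <- consensus_rank(st$scores[-1], st$orientations,
                       compound_id = st$scores$compound_id)
m <- screen_metrics(st$labels, -cons$consensus_rank)
#> consensus: AUC 0.806, EF1% 5.00, EF5% 5.00, BEDROC 0.485
```

An EF1% of 5 means the top 1% of the consensus-ranked list is 5-fold
enriched in actives over random picking.

```r
# classifier on a synthetic 80-descriptor table (1:9 imbalance)
tab <- make_descriptor_table(n_active = 100, n_inactive = 900, seed = 42)
sp <- stratified_split(tab$label, 0.7, seed = 42)
fit <- fit_model(model_spec("random_forest", seed = 42, n_trees = 100),
                 tab[sp$train, descriptor_names()], tab$label[sp$train])
em <- predict_and_enrich(fit, tab[sp$test, descriptor_names()],
                         tab$label[sp$test])
#> random forest test: AUC 1.000, EF1% 10.0, BEDROC 1.000
```

EF1% = 10 is the ceiling for a 10%-active test set. The end-to-end
flow (descriptors → best pose → consensus → metrics → ML) runs under
one config with `run_pipeline()`; see `vignettes/methods.Rmd` for the
model choices and their assumptions, and `inst/cli/ppirescore.R` for
the command-line entry points.

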