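# confrag

Confidence-guided filtering of protein fragment libraries and local
structure prediction.

## What it does

Position-specific fragment libraries produced by remote-homology detection
mix, at every target residue, instances of a genuinely conserved local
motif with false hits. confrag decides, residue by residue, whether the
covering fragments agree well enough to trust — and if so, predicts the
backbone torsion angles (φ, ψ) from the cluster's representative fragment.

The pipeline, for each target position *i*:

1. **Cluster graph** — all fragments covering *i* become vertices; pairs
   whose query intervals overlap by ≥ 6 residues are joined by an edge
   weighted with their pairwise Cα-RMSD (Kabsch superposition over the
   overlap, residues paired by target index).
2. **Greedy outlier rejection** — while the average edge weight `W/|E|` is
   ≥ 1.5 Å, remove the vertex whose exclusion, probed in O(1) from cached
   sums as `(W − w(v)) / (|E| − deg(v))`, drops the average the most. If no
   removal strictly lowers it, the cluster is *diverging* and the position
   stays unassigned (a low-precision region).
3. **Confidence** — for a stable filtered cluster with recurrence *r*
   (vertex count) and consistency *c* (fraction of edges ≤ 1.5 Å), the
   confidence is `k = c · log10(r)`. `k ≥ 0.8` flags a reliable
   prediction; `k ≥ 1.0` is transitional, `k ≥ 1.5` credible.
4. **Prediction** — the centroid (minimum average RMSD to its adjacent
   vertices, among well-connected vertices) contributes its (φ, ψ) pair at
   position *i*.

Evaluation utilities score predictions against a native reference:
wraparound angular MAE (errors in [0, 180°]), confidence-stratified MAE
curves, per-residue local precision and coverage of the library
(compatibility = full-length Cα-RMSD < 1.5 Å), and an optimal-centroid
baseline that always picks the best-fitting covering fragment. A seeded
synthetic-scenario generator (native backbone from ideal-geometry torsions,
planted conserved motifs with tunable jitter, decoy outliers, coil gaps)
makes the whole pipeline testable without external data.

## Worked example

```r
library(confrag)

sc <- generate_scenario(scenario_spec(seed = 5))   # 38-residue target
pred <- predict_target(sc$library, sc$spec$target_length)
summary(pred)
#> confrag prediction over 38 residues
#>   stable: 38, diverging: 0, empty: 0
#>   assigned (phi,psi): 38; reliable (confidence >= 0.80): 25

pred[c(7, 19, 31), c("position", "recurrence", "consistency", "confidence",
                     "reliable", "phi", "psi")]
#>    position recurrence consistency confidence reliable  phi psi
#> 7         7         28   0.8161290  1.1810677     TRUE  -57 -47
#> 19       19          3   1.0000000  0.4771213    FALSE  -57 -47
#> 31       31         28   0.8386076  1.2135977     TRUE -120 120
```

Positions 7 and 31 are the centers of the planted helix and strand: large,
consistent clusters, confidence well above the 0.8 cutoff, and the
canonical torsion pairs (−57, −47) and (−120, +120) recovered exactly.
Position 19 lies in the variable linker, where only decoy fragments
accumulate: a tiny 3-fragment cluster survives, but with recurrence far
below 10 its confidence (0.48) stays under the reliable cutoff — exactly
the "severely penalized rare motif" behaviour the score is designed for.

```r
rep <- evaluate_predictions(pred, sc$native, cutoffs = c(0, 0.8),
                            library = sc$library, native_ca = sc$native$ca)
rep$per_cutoff
#>   cutoff n_phi n_psi  mae_phi  mae_psi
#> 1    0.0    38    38 14.98996 27.55105
#> 2    0.8    25    25  0.00000  0.00000
```

At cutoff 0 the MAE mixes exact conserved-region predictions with junk
from the linker; restricting to reliable residues leaves only exact ones.

A command-line wrapper with `simulate`, `filter`, `predict` and `evaluate`
subcommands is installed under `inst/cli/confrag`:

```sh
Rscript inst/cli/confrag simulate --seed 5 --out-library lib.tsv --out-native nat.tsv
Rscript inst/cli/confrag predict  --library lib.tsv --length 38 --out pred.tsv
Rscript inst/cli/confrag evaluate --assignments pred.tsv --native nat.tsv \
    --library lib.tsv --out report.tsv
```

File formats (TSV fragment library with a JSON mirror, native reference,
assignments, evaluation reports) are documented in `?read_fragment_library`
and friends; the methods vignette
(`vignettes/confidence-guided-fragment-filtering.Rmd`) covers the model,
its parameters, the generator's scope and the numerical conventions.

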