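# fisar

Structure–activity relationship (SAR) mining for **fluorine positional
isomers**: compounds that are identical except for where a fluorine sits.
Fluorine is ubiquitous in modern drug design, yet moving a single fluorine
around a ring can change binding to an aminergic GPCR by orders of
magnitude. `fisar` finds those cases systematically in bioactivity tables
(e.g. a ChEMBL export) and is aimed at computational and medicinal chemists
who want to quantify fluorine positional effects across a compound corpus.

## What it computes

1. **Potency standardization.** Heterogeneous measurements (K<sub>i</sub>,
   IC<sub>50</sub>, EC<sub>50</sub>, K<sub>b</sub>, K<sub>d</sub> and their
   log forms) are filtered (exact measurements, direct target relationship,
   top confidence) and placed on one scale,
   pPot = −log₁₀(potency in mol/L), with replicates aggregated per
   (compound, target).
2. **Fluorine-isomer analog sets (F_iSAR sets).** Each fluorinated compound
   is keyed by its *defluorinated scaffold*: the canonical structure with
   every F replaced by H, paired with the fluorine count. Compounds sharing
   a key and a target annotation — i.e. fluorine positional isomers active
   on the same target — form an analog set (minimum two distinct isomers).
3. **Activity cliffs.** Within each set, ΔpPot is measured against the most
   potent isomer. A set is an activity-cliff (AC) set when
   max |ΔpPot| ≥ 1.7 (≈50-fold potency change; deliberately below the usual
   100-fold MMP-cliff criterion because a fluorine shift is a minimal
   structural change). Sets with spread ≤ 0.3 (≈2-fold) are flat.
4. **Matched molecular pairs.** Single-cut fragmentation over acyclic single
   bonds (plus virtual hydrogen cuts) with transformation-size restrictions:
   shared core ≥ 2× the larger exchanged fragment, fragment size difference
   ≤ 8 heavy atoms, each fragment ≤ 13 heavy atoms.
5. **MMP network.** Sets sharing a scaffold key merge into multitarget
   nodes (shape = single/dual/multi-target, color = predominant receptor
   subfamily, border = AC flag); edges connect nodes whose defluorinated
   representatives form an MMP, typed `substructure` (H ↔ moiety) or
   `transformation`. Exported as GraphML + SIF + attribute TSVs for
   Cytoscape.

A synthetic library generator (`generate_library()`) plants scaffolds,
position effects, cliffs, decoys and noise with a ground-truth manifest, so
the entire pipeline is testable without database access. A small utility
(`compare_rankings()`) checks how well an external computed ranking (e.g.
ΔΔG from binding free-energy calculations) tracks experimental potencies.

## Worked example

Two bundled analog sets reproduce published potency vectors (a muscarinic
M1 set of five quinoline-scan isomers and a serotonin 5-HT2a
phenylpiperazine scan; structures are synthetic placeholders, potencies are
the published ones):

```r
library(fisar)
wx  <- worked_example_tables()
ann <- annotate_cliffs(wx$table_one)
dplyr::distinct(ann, set_id, target_id, max_abs_delta, is_ac, trend)
#> # A tibble: 2 × 5
#>   set_id          target_id max_abs_delta is_ac trend
#>   <chr>           <chr>             <dbl> <lgl> <chr>
#> 1 FS-a37ba4c1bd39 CHRM1              2.5  TRUE  significant
#> 2 FS-6e31f96cbf6b HTR2A              2.33 TRUE  significant
summarize_cliffs(ann)
#> Fluorine-isomer analog set summary
#>   sets: 2  (AC: 2, significant trend: 2, flat: 0)
#>   fold-change tiers:
#>     |dpPot| >= 1.00 ( 10.0-fold): 2 sets
#>     |dpPot| >= 1.48 ( 30.2-fold): 2 sets
#>     |dpPot| >= 1.70 ( 50.1-fold): 2 sets
```

The M1 set's ΔpPot vector is 0, −0.2, −0.5, −1.8, −2.5: the two weakest
isomers sit more than 50-fold below the best one, so the set is an AC set.
`autoplot(ann)` draws the per-set ΔpPot waterfalls.

End to end on a synthetic library:

```r
sim <- generate_library(synthetic_config(n_scaffolds = 8, seed = 42))
sim
#> Synthetic activity library: 53 records, 18 planted sets (4 with cliffs), 2 decoys
report <- run_pipeline(pipeline_config(out_dir = "fisar-out"), records = sim$records)
#> [ingest] 53 raw records
#> [aggregate] 53 potencies (53 records kept)
#> [scaffold] 24 structures, 23 fluorinated
#> [mine] 18 sets over 14 targets
#> [cliffs] 4 of 18 sets are AC sets
#> [network] 8 nodes, 2 edges
```

All 18 planted sets and all 4 planted cliffs are recovered; the 8 network
nodes (one per scaffold) and their stage tables land in `fisar-out/`,
including `network.graphml` ready for Cytoscape. For real data, point
`pipeline_config(input = ...)` at a CSV/TSV activity export (column names
remappable via `col_map`), or use the thin CLI at
`inst/scripts/fisar-pipeline.R`.

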