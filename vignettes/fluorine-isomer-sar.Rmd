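---
title: "Mining fluorine positional isomers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining fluorine positional isomers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fisar)
```

`fisar` quantifies what moving a fluorine atom does to binding potency. The
unit of analysis is the *fluorine-isomer analog set* (F_iSAR set): two or
more compounds, active on the same target, that are identical except for
the position(s) of fluorine substitution. This vignette explains the model
behind each stage, the tunable parameters, the numerical conventions, and
what the synthetic-data tests do and do not demonstrate.

## Potency standardization

All potency types are mapped to pPot, the negative decadic logarithm of the
molar potency: a K~i~ of 10 nM becomes pPot = 8. Log-scale inputs (pK~i~,
pIC~50~, pEC~50~, pK~b~, pK~d~) pass through unchanged, and `LogKi` is
treated as already being on the pK~i~ scale — its semantics are not
standardized across depositors, and this reading is the only one that keeps
it commensurate with the other log types. Mixing K~i~ and IC~50~ values on
one scale is itself an approximation (IC~50~ depends on assay conditions);
the record filters are the guard here, not the conversion.

Record filters (all defaults, all configurable): exact measurements only
(relation `=`), direct target relationship (`D`), top target confidence
(9), and a whitelist of well-defined potency types. Records with unknown
types or malformed values are dropped with a warning count rather than an
error, since a database export routinely contains both. Units are converted
through an explicit table (pM–M); an unrecognized unit string is an error,
never a silent assumption.

Replicates per (compound, target) are aggregated by the **median** pPot
(configurable to mean). The median is robust to the single discordant
replicate that is common in aggregated bioactivity data. Whether
deduplication should happen before or after log conversion is not decidable
from first principles; converting first and aggregating on the log scale is
used because potency errors are approximately log-normal.

## The defluorinated scaffold key

Two compounds are fluorine positional isomers exactly when they become the
same molecule after replacing every fluorine by hydrogen. The key is
therefore (canonical SMILES of the defluorinated structure, fluorine
count). Keying decisions:

- **Stereochemistry is retained** by default: enantiomers and
  diastereomers are different ligands pharmacologically and are not merged.
  `scaffold_key(strip_stereo = TRUE)` merges them when a coarser grouping
  is wanted.
- **Polyfluorinated groups** defluorinate atom-by-atom (CF~3~ → CH~3~), so
  e.g. 3-CF~3~ and 4-CF~3~ analogs group together (equal counts, same
  parent), while a CF~3~ and a mono-F analog never do.
- **Salts/mixtures**: the largest covalent fragment is kept before keying;
  ties break on the lexicographically smallest canonical SMILES so results
  are independent of input atom order.
- **Tautomers are not canonicalized**: tautomer merging is aggressive and
  error-prone, and over-merging would fabricate isomer relationships.
  Users with tautomer-noisy data should normalize upstream.
- Formal charges are preserved as given; no neutralization pass is applied,
  because correct (de)protonation is target- and assay-dependent.

All chemical perception — SMILES parsing, aromaticity, stereo, canonical
forms — is delegated to OpenBabel (via ChemmineOB). Graph edits
(defluorination, fragmentation) operate on V2000 molblock text and keep
OpenBabel's atom records verbatim, which preserves the fields and 2D
coordinates that carry stereochemistry through the edits.

## Cliff detection

Within a set, ΔpPot is computed against the most potent member (ties break
to the lexicographically smallest compound identifier), so the reference
carries 0 and all other deltas are ≤ 0. This matches how fluorine-scan
tables are usually reported and makes per-compound deltas directly
readable; because the reference is the maximum, the set-level spread
max |ΔpPot| equals the largest pairwise difference, so cliff calls would be
identical under all-pairwise comparison.

Thresholds, in log~10~ units of potency:

| parameter         | default | meaning                                     |
|-------------------|---------|---------------------------------------------|
| `ac_threshold`    | 1.7     | ≈50-fold change; a set with spread ≥ this is an activity-cliff set |
| `trend_threshold` | 0.3     | ≈2-fold change; a set with spread ≤ this is "flat" |

The cliff criterion is implemented as **≥** 1.7 (a spread of exactly 2.0
log units is a cliff). It sits deliberately below the conventional 100-fold
MMP-cliff criterion because exchanging H for F at a different position is
close to the smallest structural change possible; demanding 100-fold would
discard most genuine fluorine-position effects. "Trend" is classified from
the spread's existence (significant vs flat), not its direction — a
direction is not well defined for a set of more than two isomers.

`compare_rankings()` correlates experimental pPot with an external computed
ranking such as relative binding free energies. Correlations are computed
between pPot and −ΔΔG (lower predicted energy should track higher
potency); the sign convention is recorded in the result. Kendall's tau and
Spearman's rho require ≥ 3 compounds; constant inputs are degenerate and
reported as 0 with a flag rather than NA, so downstream tabulation stays
numeric.

## Matched molecular pairs

Fragmentation is single-cut over every **acyclic single bond between heavy
atoms** (the ring-bond test is graph-theoretic: a bond is cleavable when it
is a bridge), plus a **virtual hydrogen cut** at every heavy atom bearing a
hydrogen, which makes H ↔ moiety pairs first-class. Hydrogen cuts are
emitted for all atoms, not only ring atoms: restricting them would silently
remove pairs like benzene/toluene. Bonds to fluorine are cleavable, since
H ↔ F pairs are exactly the chemistry of interest here.

Pairs are found by indexing fragmentations on the canonical core (one
labeled attachment point) and admitting candidates by the
transformation-size rules: core ≥ 2 × the larger exchanged fragment,
fragment size difference ≤ 8 heavy atoms, each fragment ≤ 13 heavy atoms.
The hydrogen fragment counts 0 heavy atoms. A `per_fragment = TRUE` mode
relaxes the core rule to the smaller fragment (it then only needs to hold
in one of the two parents); the default conservative reading is used
everywhere else in the package. Multiple distinct cores relating the same
two compounds are all kept; the network layer collapses them to one edge.
The engine is verified in the test suite against a brute-force oracle that
compares all fragmentation pairs directly, and every emitted pair is
round-tripped by reattaching each fragment to the core and checking the
parent's canonical SMILES is recovered.

## Network construction

Target-based sets sharing a scaffold key merge into one multitarget node.
Node attributes: `shape_class` (single/dual/multi by target count),
`has_ac` (any member set is a cliff set), and `predominant_subfamily`, the
modal receptor subfamily of the node's targets with ties broken in the
fixed order serotoninergic > dopaminergic > adrenergic > histaminic >
muscarinic > other. Each node is represented for edge computation by its
**defluorinated parent structure**, which makes edges independent of the
arbitrary choice of a member isomer. Edges collapse all MMPs between two
representatives and are typed `substructure` when any underlying pair
exchanges a hydrogen for a moiety, else `transformation`. Singleton
(degree-0) nodes are exported — hiding them is a viewer concern, not a data
concern — and all visual encodings are exported as semantic attribute
values rather than concrete colors, leaving styling to the YAML style file
and the Cytoscape session.

## The synthetic library generator

`generate_library()` emulates the statistical structure of a fluorine-scan
corpus, not real chemistry distributions. Scaffolds are built from a
bundled grid of 8 amine/ether/amide tails × 6 (hetero)aromatic ring
systems; fluorine placements are enumerated over substitutable aromatic CH
positions with symmetry-duplicate isomers removed. Per (scaffold, target) a
base pPot is drawn uniformly from `base_ppot_range` (default 5–10, the
realistic span for optimized GPCR ligands), each fluorine position gets an
effect ~ N(0, `position_effect_sd`) (default 0.5 log units), and observed
values add N(0, `noise_sd`) measurement noise (default 0.1, a typical
inter-assay reproducibility).

Two guarantees make recovery tests exact:

- In a set designated as a cliff set (probability `planted_ac_fraction`),
  one position's effect is set to `max(other effects) −
  planted_ac_magnitude`, so the true spread is at least the planted
  magnitude.
- In non-cliff sets the effects are rescaled, when necessary, so the true
  spread stays below `flat_spread_max` (default 0.3, the flat-trend
  threshold; `Inf` disables the cap). Without the cap, unbounded normal
  effects would occasionally plant accidental cliffs and recovery against
  the manifest would not be exact by construction.

Decoys are non-isomeric singletons (alternating fluorinated and
non-fluorinated) built on a reserved tert-butyl tail family so their keys
cannot collide with planted scaffolds. Records are emitted as linear-scale
K~i~ values in nM (value = 10^(9 − pPot)), which round-trip through the
ingest conversion exactly at zero noise. All randomness flows from one
seeded generator, so a seed reproduces the library byte-for-byte.

What passing recovery tests shows: the grouping key, mining, annotation and
network stages are correct on data whose truth is known, at realistic set
sizes (2–4 isomers, the dominant sizes in fluorine-scan corpora) and noise.
What it does not show: robustness to real curation pathologies — tautomer
inconsistencies, charged/zwitterionic records, unit typos, duplicated
depositions with conflicting values — beyond the specific filters and
conversions described above. Database-wide counts depend on such curation
details and on the source snapshot, and are not reproducible at desk scale;
the test suite therefore anchors on the worked-example sets and on
planted-truth recovery (default problem sizes: 20 noise-free scaffolds,
and ~200 noisy sets over 40 scaffolds).

## Numerical conventions and degenerate inputs

- Set identifiers and node identifiers are content hashes (key + target),
  so re-runs and partial reruns agree; input row order never affects any
  output (asserted by tests).
- Empty inputs flow through every stage and produce structured empty
  outputs, including a valid empty GraphML.
- Floating-point: recovery at zero noise is asserted to 1e−9; the
  50-fold ⇔ cliff equivalence holds to the same tolerance.
- Potency ties for the set reference and subfamily ties use the documented
  deterministic tie-breaks.
- Pipeline outputs contain no timestamps; two runs on identical inputs are
  byte-identical (asserted by tests).

## Known limitations

- Fluorine only: no Cl/Br matched series, no general halogen scans.
- Single-cut MMPs only; no double/triple cuts, no transformation frequency
  statistics.
- OpenBabel's canonical SMILES is the identity oracle; molecules it cannot
  parse are rejected with their identifiers rather than repaired.
- The binding free-energy side of cliff rationalization (docking, MD,
  QM-polarized scoring) is out of scope; only the final
  computed-vs-experimental ranking comparison is supported via
  `compare_rankings()`.
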