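---
title: "Measurable compound list selection: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurable compound list selection: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mclselect)
```

This vignette is the package's own account of the science it
implements: the model and its assumptions, the parameters that matter,
what the synthetic generator does and does not emulate, and the choices
made where the design was genuinely open. It states no empirical result
that the test suite does not itself compute.

## The selection model

A measurable compound list (MCL) is a subset of a large compound table
that (i) covers the table's physicochemical/structural space as evenly
as possible and (ii) contains only structures an electrospray LC-HRMS
method can plausibly see. Both goals are operationalized on a
13-variable representation per compound:

| slot | variable | units | source |
|---|---|---|---|
| 1 | `mw` | Da (monoisotopic) | PubChem column or SMILES |
| 2 | `xlogp` | – | PubChem column or labelled surrogate |
| 3 | `tpsa` | Å² | column or Ertl N/O contributions |
| 4–5 | `hbd`, `hba` | counts | column or donor/N+O atom counts |
| 6–11 | `emd_CH2 … emd_CS` | – | computed from `mw` |
| 12 | `mobility_class` | code 1/2/3 | external predictor column |
| 13 | `log_ie` | log10, methyl-benzoate anchor | external predictor column |

The matrix is standardized (sample sd, n−1), decomposed by PCA, and the
selection cascade runs on the retained score space:
grid sampling → dissimilarity filter → ESI filters → per-class ranking.
The stage order follows the narrative order of the published workflow;
each stage is deterministic, so two runs on the same inputs produce
byte-identical lists.

### Assumptions

* The 13 variables, standardized, are a sufficient coordinate system
  for "coverage": two compounds close in this space are treated as
  redundant. Structural detail beyond the descriptor set (stereo,
  exact substitution patterns) is invisible to the sampler.
* LogIE predicted on a positive-mode scale is usable for *both*
  polarity filters: high values indicate ESI(+) compatibility, low
  values *plus at least one H-bond donor* indicate ESI(−) plausibility.
  This is a heuristic, inherited from the workflow the package
  implements, not a physical model of negative-mode ionization.
* Mobility class enters the PCA as an ordinal 1/2/3 code. Treating an
  ordinal as numeric is a modelling convenience; it preserves the
  ordering information and matches the published variable coding.

## Parameters, defaults, and why

* **EMD base units** (`default_emd_units()`): CH2, CO, CCl, CN, CF2,
  CS. Only three example units are documented in the source workflow
  (CO, CCl, CN); the remaining three are the standard Kendrick bases
  for alkyl, perfluorinated and sulfur chemistry. The set is fully
  configurable. The defect convention is round-to-nearest,
  `round(scaled) − scaled ∈ (−0.5, 0.5]`, chosen for symmetry; the
  half-integer case is forced onto +0.5 so the interval is half-open.
  Multi-atom labels are read literally as monoisotopic atom groups
  (CCl = 12 + 34.96885 Da).
* **Retained components** `k = 3`, **bins per axis** 20. Three PCs
  match the published observation that they explain the bulk (~84%) of
  the real descriptor variance; the bin count is a stand-in for the
  unpublished grid table and is configurable. "Symmetric gridding" is
  interpreted as *equal bin counts and equal bin widths on every
  retained axis over the observed score range*.
* **Distance threshold 0.15**, metric `continuous_tanimoto_on_features`
  on the standardized 13-vectors. The source text computes "Jaccard
  distances … using PCA variables", i.e. on the model variables rather
  than on binary fingerprints, which motivates the continuous Tanimoto
  default; classic binary Jaccard on the bundled non-hashed
  substructure keys is one config switch away. Note the source phrase
  "distance > 0.15 (i.e., a Roger/Tanimoto score > 0.85)" is internally
  inconsistent (distance > 0.15 ⇔ similarity < 0.85); this package
  retains structures with **distance strictly greater than the
  threshold** and does not guess further. Rogers–Tanimoto similarity
  (which rewards matching zeros) is deliberately *not* implemented.
* **ESI thresholds**: LogIE > 3.5 (positive), LogIE < 1.5 with
  `hbd ≥ 1` (negative), strict inequalities exactly as published, so
  boundary values are excluded.
* **Per-class count 50** → 150-entry lists per polarity over the three
  mobility classes, mirroring the published list sizes. Classes with
  fewer eligible members contribute all of them and a shortfall is
  recorded in the run report.
* **Per-cell cap**: unlimited by default. The published sampled count
  (17,743 of ~785k) implies multiple survivors per cell before the
  downstream filters, so capping is opt-in.
* **RPLC bounds** `(0, 50, 950, 1000)` on the cocamide retention-index
  scale: outside < 0 or > 1000, "maybe" inside the 50-unit margin
  bands, otherwise inside. The published classifier's internals are not
  restated anywhere; these bounds are an explicit, configurable
  stand-in consistent with the reported plausible range (5 < RI < 900).

## Numerical and determinism choices

* PCA is computed by SVD of the standardized matrix; explained
  variances are `d²/(n−1)`; `explained_ratio` is relative to the total
  variance over all 13 components, so the full set sums to 1. The sign
  of each component is fixed by making its largest-magnitude loading
  entry positive — loadings are then platform-independent.
* Grid bins are half-open `[e_i, e_{i+1})`; interior edge values belong
  to the higher bin and the maximum edge to the last bin. Out-of-range
  scores (new data projected into an old grid) clamp to the nearest
  boundary bin and increment a warning counter rather than erroring.
* All candidate orderings that feed the greedy dissimilarity filter are
  total: cell key (zero-padded, lexicographic), then distance to cell
  centroid, then compound id in C-locale (radix) order. Ranking ties on
  LogIE also break by id. This is what makes reruns byte-identical.
* The greedy filter keeps a candidate iff its distance to *every*
  previously kept candidate exceeds the threshold. The retained set
  therefore satisfies the all-pairs criterion, and every rejected
  candidate is within the threshold of some retained one (maximality);
  both properties are asserted against naive all-pairs oracles in the
  tests. Degenerate all-zero vectors have no defined distance and are
  skipped with a counter.
* Constant feature columns cannot be standardized and are rejected by
  name. Tables with duplicate ids are rejected citing the offending
  rows. Decimal commas are rejected rather than silently misparsed.

## The built-in chemistry layer

No R cheminformatics toolkit is assumed. A compact internal SMILES
parser (organic subset, bracket atoms, rings, branches; stereo ignored)
feeds: monoisotopic mass from an embedded atomic-mass table; H-bond
donors (N/O bearing H) and acceptors (N+O count); TPSA from the Ertl
N/O fragment contributions; and a 52-bit non-hashed substructure-key
fingerprint organized as six documented blocks (elements, element
counts, functional groups, rings/aromaticity, charge/unsaturation,
size). Masses, donor/acceptor counts and TPSA were validated at build
time against an independent RDKit computation on the embedded 45-SMILES
library; those values are frozen in the test suite. The internal XLogP
is a crude atom-contribution **surrogate**, used only when no
precomputed XLogP is supplied and flagged `"surrogate"` in provenance —
as are the baseline mobility/LogIE/RI predictors, which exist so the
pipeline runs end-to-end when the external predictor columns are
absent. They are labelled, documented linear/cutpoint forms, not
re-implementations of the published models.

## What the synthetic generator emulates — and what it does not

`generate_feature_table()` plants: Gaussian cluster structure in a 3-d
latent space mapped into the continuous descriptors (so PCA scores show
clusters); mobility classes drawn from configurable proportions;
LogIE drawn from three uniform segments placing known fractions above
3.5 and below 1.5 (defaults 30%/30%); and a configurable fraction of
donor-free structures (default 20%). Ground-truth eligibility labels
are computed inside the generator from its own draws — an independent
implementation of the same inequalities the ESI filter applies, which
is what makes the zero-mismatch acceptance check meaningful.

It does **not** emulate: real descriptor marginals or their heavy
tails, correlations between LogIE/mobility and the physicochemical
block, chemically valid SMILES for the synthetic rows (descriptor rows
only), or measurement error in predictor outputs. A green test on the
fixture therefore establishes that the *machinery* is correct — the
gridding, filtering, ranking, determinism and bookkeeping — not that
the thresholds are optimal for any particular real chemical space.
Scale is also reduced: tests run at 10³–10⁴ compounds, not 10⁵–10⁶;
the algorithms are O(n·kept) in the filter and O(n log n) elsewhere,
and the 10⁴ end-to-end run completes in seconds.

## Known limitations

* The published headline numbers (785,294 structures, 17,743 sampled,
  ~84% variance in 3 PCs) depend on an external descriptor deposit and
  external predictor models; they are inputs this package can consume
  (via the column map) but not reproduce from scratch, so no numeric
  acceptance target is asserted against them.
* The SMILES parser covers the organic subset plus common bracket
  atoms; exotic valences, polymers and organometallics are out of
  scope and fail loudly (collected and reported, or fatal under
  `--strict`).
* The six-fingerprint concatenation of the source workflow is not
  public; the bundled key set is a documented replacement, and any
  non-hashed scheme can be registered at run time.
* ClassyFire taxonomy and live PubChem availability queries are
  outside the core path; availability is served by a file-backed
  adapter so everything is testable offline.
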