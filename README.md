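# mclselect

Chemical-space sampling of **measurable compound lists (MCLs)** for
non-target LC-HRMS method development.

## The problem

Non-target analysis (NTA) by liquid chromatography–high-resolution mass
spectrometry tries to measure *everything* in a sample, but the methods
are tuned with a handful of internal standards. When those standards are
chemically similar to each other, the measurable region of the chemical
space collapses to their neighbourhood, and heterogeneous contaminant
spaces (hundreds of thousands of structures) are sampled with heavy
bias. `mclselect` builds candidate standard lists that instead cover the
chemical space *by construction* while staying compatible with
electrospray LC-HRMS in both ionization polarities.

## The method

Each compound is described by 13 variables:

* five physicochemical descriptors — monoisotopic mass *M*, XLogP,
  TPSA, H-bond donor and acceptor counts;
* six **elemental mass defects** (EMDs). For a base unit *u* with exact
  mass *m(u)* and nominal (integer) mass *n(u)*, the Kendrick-style
  defect of a compound of mass *M* is

  `EMD_u(M) = round(M · n(u)/m(u)) − M · n(u)/m(u)  ∈ (−0.5, 0.5]`,

  so homologues differing by whole units of *u* share one defect.
  Default units: CH2, CO, CCl, CN, CF2, CS;
* a predicted environmental **mobility class** coded 1 = Non-mobile,
  2 = Mobile, 3 = Very mobile;
* a predicted electrospray **ionization efficiency** on a log10 scale
  (LogIE, anchored to methyl benzoate in positive mode).

The matrix is mean-centred, scaled to unit variance, and decomposed by
PCA (SVD, deterministic sign convention). The retained score space
(default: first 3 PCs) is partitioned by a **symmetric grid** — the same
number of equal-width bins on every axis — and candidates are drawn
cell by cell, closest-to-centroid first. Survivors must then pass

1. a **dissimilarity filter**: greedy scan keeping a candidate only if
   its continuous Tanimoto distance to every kept candidate is > 0.15
   (Jaccard on non-hashed substructure-key fingerprints is available as
   an alternative metric);
2. an **ESI eligibility filter**: LogIE > 3.5 for ESI(+); LogIE < 1.5
   *and* H-bond donor count > 0 for ESI(−) (strict inequalities);
3. **grouping and ranking**: within each mobility class, candidates are
   ranked by descending LogIE and the top *n* per class taken (default
   50, giving 150-entry lists per polarity).

Coverage diagnostics (grid-cell occupancy vs. a reference "watch list",
RI-vs-mass regression, RPLC domain classification −1/0/1, patent and
literature availability) quantify what an emitted MCL does and does not
cover.

Descriptors may be supplied precomputed (e.g. from PubChem and external
mobility/IE/RI predictors — the intended mode) or computed from SMILES
by the built-in parser and descriptor engine; the internal XLogP and
RI/LogIE baselines are crude, clearly-labelled surrogates.

## Worked example

```r
library(mclselect)

rec <- compound_record("caffeine", "Cn1cnc2c1c(=O)n(C)c(=O)n2C")
pc  <- compute_physchem(rec)
#> caffeine: mw = 194.080376 Da, TPSA = 61.82 A^2, HBD = 0, HBA = 6

u <- emd_unit("CH2")
elemental_mass_defect(mol_monoisotopic_mass(parse_smiles("CCCCCC")), u)
#> -0.013399   # hexane
elemental_mass_defect(mol_monoisotopic_mass(parse_smiles("CCCCCCC")), u)
#> -0.013399   # heptane: same homologous series, same defect

# synthetic 5,000-compound space -> 150 + 150 candidate lists
gen <- generate_feature_table(fixture_spec(n = 5000, seed = 1))
X <- as.matrix(gen$features[, -1]); rownames(X) <- gen$features$id
Z <- apply_scaling(X, fit_scaling(X))
pca <- fit_pca(Z, 3)
S <- project_scores(Z, pca); rownames(S) <- gen$features$id
grid <- build_grid(S, 20)
res <- build_mcl(NULL, gen$features, S, grid,
                 selection_config(per_class_n = 50), scaled = Z)
res$report[c("n_input", "n_after_dissimilarity", "n_positive", "n_negative")]
#> n_input 5000; n_after_dissimilarity 3987; n_positive 150; n_negative 150
head(res$positive[, c("id", "mobility_class", "log_ie", "cell_index", "rank")], 3)
#>          id mobility_class   log_ie  cell_index rank
#> 1 SYN004800              1 5.995402 006:008:014    1
#> 2 SYN000358              1 5.991403 016:007:004    2
#> 3 SYN001298              1 5.980722 001:007:012    3
```

The report says: of 5,000 synthetic compounds, 3,987 survived the
grid-ordered dissimilarity filter, and the ESI filters plus per-class
ranking yielded exactly 50 candidates in each of the three mobility
classes per polarity. Ranks are contiguous within a polarity; LogIE
decreases within each class block.

## Command line

```sh
inst/cli/mcl simulate  --n 5000 --seed 1 --output fx
inst/cli/mcl space     --features fx_features.csv --model model.json --scores scores.csv
inst/cli/mcl sample    --features fx_features.csv --model model.json --out-dir mcl/
inst/cli/mcl report    --mcl-pos mcl/mcl_positive.csv --mcl-neg mcl/mcl_negative.csv \
                       --scores scores.csv --model model.json --output report.json
inst/cli/mcl featurize --input compounds.csv --output features.csv --config cfg.yaml
```

All thresholds, the column map, EMD units and grid parameters live in
one YAML config (see `default_config()`).

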