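# cycovar

Removal of unwanted covariance from single-cell mass cytometry (CyTOF)
data.

## The problem

Mass cytometry quantifies dozens of protein markers per cell, but has no
forward-scatter-style readout of cell size, and staining efficiency varies
cell to cell. Both confounders inflate every channel at once, so marker
intensities carry a large shared component that produces spurious
marker–marker correlations, obscures small cell populations (e.g.
apoptotic cells, which shrink), and biases comparisons between cell lines
and perturbations.

`cycovar` removes this unwanted covariance by regression on *surrogate*
channels of the confounders — channels expected to track cell size and
staining rather than biology:

* **mean DNA** — per-cell mean of the (standardized, asinh-scale) iridium
  DNA-intercalator channels;
* **mean BC** — per-cell mean of the highest (used) barcoding isotopes;
* abundant, condition-stable proteins such as **pan Akt** and
  **total ERK** (the loading controls of western blotting);
* optionally extra channels such as ruthenium stains.

## The model

For each marker *m*, cell *i* with surrogate vector *x&#8407;<sub>i</sub>*
and sample *j<sub>i</sub>*:

```
y_i^m = O^m(j_i) + S^m(x_i, j_i) + e_i^m
```

fit by ordinary least squares in one of three forms:

| form | intercept | slopes | typical use |
|---|---|---|---|
| `simple` | one | one vector | one cell line, many perturbations |
| `offset` | per sample | shared | batch-style offsets, common slope |
| `interaction` | per sample | per sample | cell lines with different size/marker relationships |

The corrected value is intercept plus residual, `y* = O(j_i) + e_i`,
which carries no linear dependence on any surrogate. Instead of the raw
surrogates, the regression can use the leading principal components of
the (z-scored) surrogate matrix — PC1 typically tracks cell size, PC2
staining efficiency. With globally centred surrogates the grand mean of
every marker is preserved; with per-sample centring (and `keep_offset`)
the per-sample means, hence between-sample log-fold changes, are
preserved.

The package also ships the evaluation surface (marker correlation
matrices, percent change in standard deviation, asinh-scale fold changes,
energy distance between conditions, KDE-valley threshold classification
with confusion counts), a synthetic confounded-data generator with
linear + quadratic cell-size artefacts for validation, minimal FCS/CSV
I/O, and a command-line interface.

## Worked example

Simulate a confounded two-condition dataset (4000 cells, 20 markers, 4
with a planted treatment effect, log-normal cell size driving linear and
quadratic artefacts plus 4 surrogate proxy channels), correct it, and
check what survives:

```r
library(cycovar)

cfg <- sim_config(n_cells_per_condition = 2000, n_datasets = 1, seed = 42)
sim <- simulate_dataset(cfg, 1)
ev  <- sim_event_table(sim)     # event_table + matching panel_config

pca_sucs(assemble_sucs(ev$table, ev$panel, centering = "global"))
#> pca_result over 4 surrogates
#> var explained (%): 93.6, 2.5, 2.1, 1.9

res <- run_rucova(ev$table, ev$panel,
                  model_spec(form = "simple", predictors = "pcs"))
#> corrected_table: 20 markers corrected
#> R^2 removed: median 0.227, range 0.041-0.349

detect_significant_markers(res$table, markers = colnames(sim$observed))
#> [1] "marker01" "marker08" "marker13" "marker19"
precision_recall(.Last.value, sim$signif_marker_ids)
#> precision    recall
#>         1         1
```

PC1 of the surrogate proxies carries 93.6% of their variance — the
planted size factor. The regression removes a median 23% of each
marker's variance (the artefact), after which exactly the four planted
treatment-responsive markers are recovered (precision = recall = 1).

The correction narrows distributions and erases the artificial
small-cell/large-cell separation:

```r
delta_sigma(ev$table$values[, "marker01"], res$table$values[, "marker01"])
#> -14.2          # percent change in SD after correction

large <- sim$cell_size > median(sim$cell_size)
mk <- ev$panel$markers_to_correct
e_distance(ev$table$values[large, mk], ev$table$values[!large, mk])   # 29.19
e_distance(res$table$values[large, mk], res$table$values[!large, mk]) #  0.04
```

## Command line

An `exec/cycovar` shim exposes the same pipeline:

```sh
cycovar correct  --input events.csv --panel panel.json --output corrected.csv \
                 --model interaction --predictors pcs --centering global
cycovar simulate --config sim.json --out-prefix sim      # observed/truth CSVs
cycovar validate --config sim.json --out-prefix val      # score table
cycovar metrics  --before before.csv --after after.csv \
                 --group-a line1 --group-b line2
```

Panel and simulation configs are JSON with keys named exactly as the
`panel_config()` / `sim_config()` arguments. Exit codes: 0 success,
2 configuration error, 3 data error, 4 numerical error.

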