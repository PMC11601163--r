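---
title: "Removing unwanted covariance from mass cytometry data: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Removing unwanted covariance from mass cytometry data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycovar)
```

## The model and its assumptions

Mass cytometry has no direct readout of cell size or staining efficiency,
yet both scale the signal of essentially every channel. `cycovar` treats
the problem as confounder regression on *surrogates*: measured channels
assumed to reflect the confounders and (approximately) nothing else. For
each marker $m$, cell $i$ with surrogate vector $x_i$ and sample $j_i$,

$$ y_i^m \;=\; O^m(j_i) \;+\; S^m(x_i, j_i) \;+\; \varepsilon_i^m, $$

fit by ordinary least squares on the asinh scale, and the corrected value
is the intercept plus residual, $y_i^{*m} = O^m(j_i) + \varepsilon_i^m$.
The working assumptions are:

* the confounders act (after asinh) approximately **linearly and
  additively** on every marker;
* the surrogates span the confounder space and carry little biology of
  their own — mean DNA-intercalator signal, mean barcode signal, and
  abundant loading-control proteins (pan Akt, total ERK) are chosen
  precisely because they should be condition-stable;
* biological effects of interest are **not** collinear with the
  surrogates within a least-squares stratum (a perturbation that truly
  changes cell size is partially absorbed — see *Limitations*).

Three model forms trade flexibility against the risk of absorbing
biology. `simple` fits one intercept and one slope vector across all
cells; `offset` gives each sample its own intercept but a common slope
(full-rank cell-means coding — one indicator column per sample, no
global intercept — so the per-sample offsets are read directly as
coefficients, with no arbitrary reference level); `interaction` fits each
sample independently, equivalent to concatenated per-sample simple fits
(the test suite checks this equivalence to 1e-10). Since the three
designs are nested, $R^2(\text{interaction}) \ge R^2(\text{offset}) \ge
R^2(\text{simple})$ on any dataset, a useful sanity check when choosing a
form.

## Centering semantics and what is preserved

What the correction *preserves* is governed entirely by how the
surrogates are centred before fitting:

* **global centering** — each surrogate column has zero grand mean, so
  for the simple model the fitted intercept is the marker's grand mean
  and correction preserves per-marker grand means exactly;
* **per-sample centering** — each surrogate has zero mean within every
  sample; with `keep_offset = TRUE` the per-sample marker means, and
  hence between-sample (log-)fold changes, are preserved exactly.

When principal components are used as predictors
(`predictors = "pcs"`), the same `centering` choice selects global vs
per-sample z-scoring of the surrogates before the PCA; the PC scores
themselves are column-centred by construction and are used as-is. Both
preservation properties are asserted at 1e-8 in the acceptance suite.

`keep_offset = FALSE` targets the case where the between-sample offsets
are themselves unwanted (e.g. batches): every per-sample intercept is
replaced by the **unweighted mean** of the intercepts. The underlying
convention is open — equally defensible would be the cell-weighted mean
or a designated reference sample — so the choice is flagged here: the
unweighted mean treats samples, not cells, as exchangeable units.

## The surrogate roster

| surrogate | definition | default |
|---|---|---|
| `mean_DNA` | mean of the iridium channels, each z-scored (asinh scale, all cells, $n-1$ denominator) before averaging | if DNA channels configured |
| `mean_BC` | per-cell mean of the `n_top_barcodes` largest barcode-channel values (channel identity may differ cell to cell) | `n_top_barcodes = 3` |
| antibody surrogates | asinh values of e.g. pan Akt, total ERK | — |
| extra surrogates | any further channel, e.g. ruthenium | — |

Two conventions here were genuinely open and are package choices:

* *Iridium normalization.* The per-channel z-score before averaging makes
  `mean_DNA` scale-free, so iridium isotopes with different absolute
  sensitivity contribute equally. Any per-channel affine normalization
  yields the same corrected output up to the fitted slope, so this choice
  affects interpretability of coefficients, not the correction.
* *Barcode count.* `n_top_barcodes = 3` matches the common k-of-n
  palladium scheme; it is configurable because panels differ.

The asinh cofactor defaults to 5, the mass-cytometry convention;
`markers_to_correct` may not overlap the surrogate roster, because
regressing a channel on itself returns a constant.

## Numerical choices

* OLS via QR decomposition; a design whose rank (relative tolerance
  1e-10) is deficient raises an error naming the collinear predictors
  rather than silently dropping them.
* PCA is correlation PCA: covariance of z-scored columns, $n-1$
  denominator, eigendecomposition; each loading column is sign-flipped so
  its largest-magnitude entry is positive, making output deterministic
  across linear-algebra backends. Rank deficiency after z-scoring warns
  and reports trailing zero variance.
* A sample stratum with fewer than (predictors + 2) cells fails loudly
  for the offset/interaction forms — silent pooling would change the
  model class.
* Zero intensities (detection-limit artifacts) are *not* excluded or
  imputed beforehand: the linear fit includes them, and the corrected
  value $O(j) - \sum \hat\alpha x$ is generally non-zero. This removes
  the covariance bias an imputation on uncorrected data would inherit.
* Energy distance uses squared Euclidean distance with within-group means
  over **all** ordered pairs including the zero diagonal (the V-statistic
  convention of the perturbation-atlas literature), which makes
  $E(A,A)=0$ exactly; groups are subsampled without replacement to
  `max_cells` (default 1000) under a caller-supplied seed.
* The bimodal gate is the minimum of a Gaussian KDE (Silverman's
  bandwidth, 512-point grid over the data range) between the two highest
  modes; a unimodal density is an error, not a guess. This valley rule is
  a stand-in for visual gating, not a claim of equivalence to any
  particular published threshold.

## What the synthetic generator emulates — and what it does not

`simulate_dataset()` states one world per configuration:

* ground-truth markers are multivariate normal *on the asinh scale* with
  block-equicorrelated structure (defaults: blocks 5/5/10 at $r = 0.5$,
  unit SD, baselines uniform in [2, 6]) in two conditions;
* `n_signif_markers` (default 4 of 20) gain `effect_size` (default 0.5)
  in the treated condition;
* each cell draws a log-normal size (default meanlog 5, sdlog 0.4);
  marker $m$ observes $y + a_m s + b_m s^2$ where $s$ is the centred log
  size on a **fixed reference scale of 0.4** — at the default spread $s$
  is simply the standardized log size, while a narrower configured
  spread proportionally weakens the artefact (no size variance, no
  artefact), which is the physically sensible limit;
* $a_m \sim U(0.2, 0.8)$, $b_m \sim U(0.05, 0.2)$ per marker; four
  surrogate proxy channels are affine in $s$ plus Gaussian noise
  (SD 0.3), so PC1 of the proxies tracks size.

Defaults are chosen once for clear signal separation at realistic CyTOF
scales (asinh-transformed intensities of a few units, thousands of cells
per condition) and mirror the desk-scale validation study: 10 datasets
of 2 x 5000 cells; the replicate count of the original full-scale study
(100) is available via `n_datasets`.

Features of real data deliberately *not* emulated: spillover, acquisition
-time drift, doublets, zero inflation, non-Gaussian marker distributions,
and any nonlinearity beyond the quadratic size term. A green validation
therefore establishes that the implementation removes the artefacts it
models — linear size effects exactly (planted slopes are recovered within
±0.05 at n = 5000 in the acceptance suite), quadratic ones only partially,
since a linear fit cannot represent $s^2$ (for near-normal $s$,
$\mathrm{cor}(s, s^2) \approx 0$) — not that it corrects every artefact
of a real instrument run. The quadratic term is kept in the default world
precisely as a stress test: correlation recovery must improve even when
the model is misspecified.

The differential-marker call used for scoring (Wilcoxon rank-sum,
Benjamini–Hochberg at $\alpha = 0.05$, plus an absolute asinh-scale
effect gate of 0.2) is likewise a stand-in chosen for robustness at CyTOF
sample sizes, where trivial effects are otherwise significant.

## Limitations

* Strictly linear correction: no robust/regularized variants, no basis
  expansion. Heavy-tailed artefacts or strong nonlinearity leave
  residual structure.
* If a genuine biological signal is collinear with the surrogates within
  a stratum (e.g. a treatment that truly enlarges cells), part of it is
  removed; the interaction model with samples chosen as the collinear
  unit, and inspection of before/after fold changes, are the available
  mitigations.
* Surrogates are assumed pre-gated, debarcoded input; no bead
  normalization, gating, or doublet handling is provided.
* FCS support is a minimal reader/writer (FCS 3.0/3.1, primary TEXT +
  numeric DATA segment, float/double types) sufficient for round-tripping
  corrected tables; exotic dialects should be converted to CSV upstream.
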