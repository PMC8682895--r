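---
title: "Modeling kinome array signals and scoring upstream kinase activity"
author: "kinact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling kinome array signals and scoring upstream kinase activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinact)
```

## The measurement and the model

A PamChip well exposes a lysate to ~140 immobilized reporter peptides;
the instrument images the chip at a grid of pump cycles and camera
exposure times (ms), and BioNavigator reduces each image to one
background-subtracted intensity per peptide. Within the last pump cycle
(the end point), accumulated phosphorylation is read repeatedly at
increasing exposure times, so in the camera's linear range the intensity
grows linearly with exposure time and the *slope* is proportional to the
amount of phosphorylated substrate. `kinact` therefore summarizes each
(peptide, well) by the ordinary-least-squares slope of signal versus
exposure time at the end point, and transforms it to the final signal
`log2(100 * slope)`. The factor 100 puts typical slopes
(0.01–10 signal units/ms) on a convenient positive log2 scale.

Assumptions worth keeping in mind: (i) linearity holds only inside the
camera's dynamic range — saturated points violate it, hence the optional
saturation filter; (ii) the slope is only meaningful when the fit is
good, hence the R² filter; (iii) a non-positive slope carries no kinetic
information and is clamped (see below).

## QC parameters

| parameter | default | units | role |
|---|---|---|---|
| `baseline` | 1 | signal units | clamp for negative signals and non-positive `100*slope`, keeps log2 finite |
| `minSignal` | 5 | signal units | detectability threshold at the end-point max exposure |
| `detectionFraction` | 1 | proportion | fraction of samples (within at least one group) that must exceed `minSignal` |
| `saturationLimit` | `Inf` (off) | signal units | camera ceiling; points at/above it are dropped |
| `r2Min` | 0.9 | — | strict R² threshold; a peptide failing it in *any* well is dropped panel-wide |

Design choices where the convention was genuinely open:

* **"Scaling negatives to the baseline" is clamping.** Any monotone map
  would do; clamping to a configurable baseline (default 1) is
  order-preserving, leaves clean data untouched, and makes `log2`
  defined. The same clamp handles non-positive `100*slope` before the
  final-signal transform, with a `clamped` flag in the fit table.
* **Detectability is a panel decision, not a well decision.** A peptide
  is kept iff its end-point max-exposure signal exceeds `minSignal` in
  at least `detectionFraction` of the samples of at least one group
  (boundary inclusive). Removal applies to all wells so every table
  downstream shares one peptide panel.
* **R² = 0 when the signal is flat.** When the total variance of y is
  zero the usual R² is 0/0; defining it as 0 routes flat peptides into
  the non-linearity filter, which is where they belong.
* **The R² comparison is strict** (`> r2Min` passes), matching the
  convention of reporting "R² > 0.9" panels.
* **Chip normalization is median-centering** of the final signal per
  barcode (mean offered); the median is robust to the handful of
  strongly differential peptides that would drag a mean.

## Differential phosphorylation

LFCs are computed on chip-normalized final signals, comparison minus
baseline. Two estimators are provided: *across-chip* (difference of
group means pooled over chips) and *within-chip* (per-chip difference of
group means, averaged over chips; the default, exact cancellation of
chip effects when every chip carries both groups). Peptide sets are
extracted at multiple cutoffs (default 0.2/0.3/0.4 log2 units,
two-sided, boundary inclusive) and the downstream kinase Z scores are
averaged across sets — using several cutoffs and averaging removes the
arbitrariness of any single threshold. Direction-restricted sets
(`up`/`down`) are available; with two-sided sets, swapping baseline and
comparison leaves the sets (and hence the kinase scores) unchanged,
while with directional sets it reverses them.

## The random-sampling kinase score

Given a mapping from peptides to upstream kinase families and a
differential set of size *n* from a pool of *N* QC-passing,
non-reference peptides, each family's observed mapped count is compared
to its distribution over B random *n*-subsets of the pool
(B = 2000 default), summarized by the sampling mean and the sample SD
(B−1 denominator): `Z = (observed − mean)/SD`. Choices:

* **Sampling is uniform without replacement** — the null is "a peptide
  set of this size chosen blindly from this chip", i.e. hypergeometric
  for each family; the empirical mean converges to `n*k/N` for a family
  with `k` substrates in the pool (a property the test suite checks
  against the closed form).
* **The pool is the post-QC, post-R², non-reference panel**, because
  the observed set was drawn from exactly that panel; using the full
  chip would bias μ upward for families mapped to filtered peptides.
* **Zero SD yields an undefined score** (NA, flagged, excluded from hit
  calling) rather than ±Inf.
* **Hit threshold is inclusive**, |mean Z| ≥ 2.
* **Determinism under parallelism.** Every cutoff set draws from its own
  RNG stream derived from the master seed by a fixed integer recurrence,
  so `workers = 1` and `workers = 4` produce bit-identical scores and a
  run is a pure function of (inputs, seed).

The mapping itself (which kinases can phosphorylate which reporter
sequences) is an *input*: the bundled
`synthetic_stk_mapping.tsv`/`synthetic_kinase_ppi.tsv` are
simulator-generated stand-ins shipped so examples and tests run offline;
real studies should supply curated predictor/literature unions in the
same two-column format.

## Network expansion

Hits are grown to depth 1 by default (hits plus direct interactors) over
a user-supplied kinase-kinase edge list; node names are case-folded and
passed through an editable alias table before joining, because family
level score names and PPI protein names rarely share a namespace.
Edges touching a hit are classed `hit_incident`. Degree, hit flag and
averaged Z per node support the usual rendering (size = degree,
colour = Z).

## Robustness protocol

`injectNoise()` perturbs the LFC vector with additive zero-mean Gaussian
noise of variance `var(LFC)/SNR` (uniform offered), and
`robustnessCurve()` re-runs set extraction and kinase scoring on the
noisy LFCs, reporting the Pearson correlation of averaged Z vectors
against the noiseless run per SNR. Seeded mode (default) is
bit-reproducible; an unseeded mode mirrors exploratory use. Noise is
injected at the LFC level (not the raw-signal level): the protocol asks
how stable the *kinase ranking* is to error in the measured group
differences, which the LFC vector carries entirely. "Ratio of
differences" could alternatively be read as linear-scale fold change;
the log2 scale was adopted because every downstream step consumes LFCs.

## What the simulator emulates — and what it does not

`simulateCrosstab()` writes a full crosstab file (meta line, well block,
(cycle × exposure) grid) with: per-well signals
`intercept + slope*t*c/c_max + N(0, noiseSd)`; planted log2 group
effects on the slope; multiplicative chip offsets; flat undetectable
peptides; step-shaped non-linear peptides; negative points (first cycle)
and saturated points; `ART_*` reference IDs. Defaults mirror a
demonstration-scale two-group study: 144-peptide panel with 11
reference, 12 undetectable and 2 non-linear peptides, 3 wells per group
on 4-well chips, exposure grid 10/20/50/100/200 ms, cycles
32–124, 20 differential peptides at LFC 0.5, chip offsets ±0.25 log2,
noise SD 1 signal unit (a high-quality run: the planted slopes span
log2 final signals of 4–8, so R² stays above 0.9 for linear peptides
with very high probability).

Not emulated: optical vignetting and spatial artifacts, washing-cycle
kinetics, saturating (Michaelis–Menten) accumulation, correlated noise
between neighbouring spots, and real kinase-substrate biology (the
synthetic mapping is random). Passing tests on fixtures therefore
demonstrate the *statistical machinery* — recovery of planted effects,
correctness of the null, determinism — not performance on real lysates.

## Numerical notes and degenerate inputs

* Crosstab numbers are written with 17 significant digits, so
  write/read round-trips doubles bit-exactly.
* OLS uses the closed-form Σ-formulas per (peptide, well); the suite
  cross-checks against `stats::lm` at 1e-10 relative tolerance.
* Single-well chips center to a degenerate constant with a warning;
  single-label datasets pass QC but are refused by `computeLFC()`.
* Empty peptide sets at a cutoff are retained with a warning; scoring a
  zero-size set is an error.
* Waterfall ordering is a stable sort (ties keep input order).
* The rank-sum global test uses the exact distribution up to 20 values
  per group and the tie-corrected normal approximation beyond.

## Problem sizes used by the checks

The bundled tests and the acceptance checks run at the demonstration
scale the package targets: 144-peptide panels, 6 wells, pools of 84–119
peptides, 2000 sampling iterations, SNR grid 1–32 with 9 noise
replicates. The whole suite completes in well under a minute on a
single core.

## Limitations

* Family-level scores inherit every bias of the mapping file; a family
  with very few substrates on the chip (small k) has a discrete,
  skewed null where |Z| ≥ 2 is a crude criterion.
* No per-peptide inferential statistics are attempted (the LFC
  magnitude is the only peptide-level criterion, by design).
* Tyrosine-kinase chips would need their own reference-peptide patterns
  and mapping; the defaults here target serine-threonine panels.
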