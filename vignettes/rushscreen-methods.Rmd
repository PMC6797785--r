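---
title: "Methods: simulating and analyzing a RUSH trafficking screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing a RUSH trafficking screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rushscreen)
```

## The assay and its readout

In a RUSH (retention using selective hooks) secretory-trafficking screen, a
fluorescent Golgi-enzyme cargo is held in the endoplasmic reticulum by a
streptavidin hook and released synchronously by adding biotin. Thirty minutes
after release, untreated cells show the cargo concentrated in a compact
juxtanuclear Golgi; compounds that block ER-to-Golgi transport leave it
diffuse in the ER, and compounds that fragment the Golgi scatter it into
puncta. Each well of a 384-well plate is imaged in three channels (DNA,
EGFP cargo, Golgi marker) at four positions, yielding roughly 300 measurable
cells per well. Every cell is gated into one of four phenotype classes —
ER-retained, ER+Golgi, Golgi, Golgi-disrupted — and the well-level class
fractions are the screen's unit of analysis.

`rushscreen` implements this analysis end to end and, because no image data
from such screens is bundled, pairs it with a synthetic image generator whose
ground truth makes every stage testable.

## The synthetic generator

`simulate_plate()` draws, for every well, a Poisson cell count (mean 300,
reduced by toxic compounds), per-cell phenotype labels from a mixture model,
and optionally renders fields. The mixture starts from a baseline (biotin
released: 96% Golgi; no biotin: 96% ER-retained; a 4% assay noise floor
spread over the remaining classes) and is shifted toward a compound's effect
phenotype with probability `max_effect * Hill(c; ec50, hill)`.

Effect classes mirror the mechanistic families a confirmation screen
distinguishes: pure ER retainers; steep, near-complete Golgi disruptors
(depolymerizer-like, Hill ≈ 2.5, plateau ≈ 0.95); shallow partial disruptors
(destabilizer-like, Hill ≈ 1, plateau ≈ 0.55); BFA-like compounds; toxic
compounds (cell-count loss only). For BFA-like compounds the
Golgi-disrupted share of affected cells is bell-shaped in dose
(`gd_weight * 4h(1-h)`): disruption is a transient intermediate, and at
saturating dose the Golgi is fully disassembled and cells are purely
ER-retained. This one choice reproduces two observed behaviours at once —
ER-retention and Golgi-disruption responses rising on the same concentration
range at intermediate doses, and the high-dose quantification artifact in
which no Golgi disruption is scored because no compact structures remain.

Cell appearance statistics of the original instrument are unpublished, so
sprite models were chosen for segmentability and are fully parameterized:
elliptical nuclei; a broad textured perinuclear Gaussian for diffuse ER
signal; compact *flat-intensity* disks (PSF-blurred) for inclusions. Flat
disks make "mean intensity inside the inclusion" a well-defined ground-truth
quantity: the half-maximum contour of a blurred step edge sits on the true
disk boundary, so generator truth and detector delineation can agree up to
noise. Golgi-disrupted cells draw `3 + Poisson(2)` puncta. The marker
channel mirrors the inclusion geometry.

Two well-level perturbations emulate screening reality:

* **Positional gradient** — a one-signed additive row+column ramp (0 at the
  first row/column, rising to `positional_gradient_amplitude`, default 0.1
  in screen configurations) on the ER-retained probability of biotin wells,
  with mass drawn from the Golgi class. It models an edge-correlated
  biotin-release/liquid-handling bias. Being one-signed, probabilities never
  clip, so the bias is *exactly* additive — the structure median polish
  removes.
* **Library nuisance activity** — each library compound carries a small
  half-normal ER-retention offset (sd 0.005, constant across replicates),
  reflecting the low-level bioactivity real libraries show. Its visible
  consequence is that the clean DMSO+biotin control scores slightly
  *negative* on the ER-retained class (the sample median sits above it),
  matching the sign structure reported for such screens.

Reproducibility: every well, field, cell and stage draws from an RNG
sub-stream keyed by `(seed, plate, well, replicate, stage)`
(`derive_seed()`), so plates regenerate bit-identically and wells are
order-insensitive.

What the generator does **not** emulate: optics-accurate PSFs, illumination
falloff, focus drift, debris, mitotic/apoptotic morphologies, cell-shape
variation beyond ellipse eccentricity, or spatially correlated biology.
Passing tests therefore demonstrate that the *analysis chain* is correct and
calibrated on data with the screen's statistical structure — not that it
would segment arbitrary real microscopy unchanged.

## Segmentation

`segment_nuclei()`: white top-hat (disk radius 8 px ≈ 1.5 nucleus radii) on
the DNA channel, Otsu threshold, area filter (≥ 20 px), optional watershed
split of touching nuclei. `collar_cell_regions()`: each nucleus dilated by
6 px, contested pixels assigned to the *nearest* nucleus by exact Euclidean
distance transforms, ties to the lower label; regions are disjoint, contain
their nuclei, and cover the dilated support exactly.

`detect_inclusions()`: pixel-wise maximum of white top-hats at disk radii
{2, 3} px, thresholded within the collar support by a robust rule
(median + 6·1.4826·MAD of the response) with an absolute floor of 0.12 —
the floor rejects texture ripple in diffuse-ER cells, whose top-hat response
stays below ~0.05 while true inclusions respond at ≥ 0.2. Candidate
components are then delineated at half-maximum of a lightly smoothed
(σ = 0.6 px) image above the local collar background — an FWHM-style rule
that tracks the physical structure boundary rather than the top-hat support.
By default a component straddling the midline between two cells stays whole
and belongs to the cell owning its peak (object-level assignment);
juxtanuclear inclusions frequently cross nearest-nucleus boundaries in
crowded fields, and cutting them there biases the intensity readout
(`inclusion_split_by_region = TRUE` restores strict pixel-level splitting).
The mean inclusion intensity is always measured on the **raw** cargo
channel, never the top-hat transform. Border-touching cells are flagged and
excluded from well summaries, standard high-content practice.

## Phenotype gating

A seed-fixed random forest (`ranger`, 300 trees) replaces interactive
machine-learning gating; it is trained one-shot from control wells:
DMSO-without-biotin and BFA+biotin wells label ER_retained, DMSO+biotin
labels Golgi, nocodazole+biotin labels Golgi_disrupted. The screen's named
controls provide no ER+Golgi examples, so these are synthesized from the
generator by default (`synthesize_training_cells()`), with an interface for
supplying hand-labeled cells instead — a documented deviation forced by the
control design. Features are the per-cell records (inclusion area, count,
mean/total intensity, collar mean, inclusion-to-collar ratio, nucleus and
collar geometry); cells without inclusions impute zero inclusion signal.
Ties in class probability break by the fixed class order ER_retained <
ER_plus_Golgi < Golgi < Golgi_disrupted. The training report carries a
stratified 80/20 held-out confusion matrix. Wells below 50 cells are flagged
low-count and excluded from hit calling (the cell count doubles as the
toxicity readout).

## Plate statistics

For each phenotype class, plate and replicate, well fractions form a 16×24
matrix; control and low-count wells are masked. `median_polish()` (Tukey,
row-first sweeps, even-length medians = mean of the central pair, masked
entries excluded from every median but still given residuals) removes
additive positional effects; the polish-then-robust-Z order is the standard
B-score-style pipeline, with `polish = FALSE` available. Residuals are then
scored as

RZ = (value − median(reference)) / (1.4826 × MAD(reference)),

where the reference is the population of *sample-well* residuals of that
replicate — most compounds are assumed inactive. Control wells are scored
against the same reference but never contribute to it (samples vastly
outnumber controls, so this choice is second-order). A compound is a hit in
a replicate when RZ < −2 or RZ > 2, strictly; replicate calls aggregate by
majority (configurable: any/all). Hits are annotated with triggering classes
and signs and sorted by the ER-retained score.

Numerical notes: a zero MAD flags the scores non-finite rather than
erroring; fully-masked rows/columns get zero effects and a flag; the RZ is
self-normalized, so even on an effect-free plate ~4.6% of wells per
replicate exceed |RZ| = 2 — replicate aggregation, not the threshold, is
what controls the false-positive rate. Because well-level binomial variance
varies across a strong gradient, per-replicate tails are somewhat heavier
than Gaussian; variance-stabilizing transforms were evaluated and not
adopted (they trade heteroscedasticity for non-additivity of the gradient,
and the fraction-scale pipeline is what the screen design prescribes).

## Dose-response analysis

`fit_4pl()` fits `r(c) = bottom + (top−bottom)/(1+(ic50/c)^hill)` by
Levenberg–Marquardt on log10 concentration with multi-start initialization
(IC50 quantile grid × shallow/steep Hill starts); non-convergence is
reported, never silently returned, and flat curves are flagged. The response
variable defaults to class fractions (bounded and stable), with RZ curves as
an alternative. Supported designs include the 8-point 3-fold series from
10 µM and the 10-point series from 30 µM down to 1.52 nM.

`detect_high_dose_collapse()` flags the quantification artifact in which
maximal disruption scores as "no disruption": the disrupted score drops by
> 50% from its maximum at a higher dose *while* the Golgi-signal readout
(mean inclusion intensity) is below 30% of its low-dose level. Genuine
non-monotonicity with preserved Golgi signal is never flagged.

`classify_family()` applies, after collapse correction: (a) ER rise with
flat disruption → homeostasis_or_energy; (b) disruption rise with flat ER →
microtubule-like, split depolymerizer- vs destabilizer-like by a plateau
criterion (disrupted plateau ≥ 0.75; a Hill-slope criterion is available) —
an explicitly heuristic rule, since the phenotype readout does not uniquely
determine that split; (c) both active with activity midpoints within a
3-fold window → bfa_like; (d) otherwise unclassified. Under a collapse flag
the disrupted activity midpoint is the log-quadratically interpolated *peak*
dose: a 4PL truncated to the rising flank of a transient systematically
underestimates the midpoint, while the peak tracks the underlying EC50.

## Problem sizes and design choices

The bundled analyses and tests use: 20 default fields (≈ 1,500 cells) for
segmentation recovery; one control plate (2×5 wells at full imaging scale)
plus one synthesized well for classifier training with per-class evaluation
wells; a full 384-well × 3-replicate screen at the label level (the
generator's ground-truth labels stand in for per-cell classification there,
isolating the normalization and hit-calling stages; the imaging path is
exercised at plate scale in the demo pipeline); 200 noisy-fit replications
and a 50-compound family panel for dose-response recovery. Replicate count
defaults to 3 (screen descriptions vary between two replicate experiments
and biological triplicates; triplicate is the analysis default here).

## Known limitations

* Sprite appearance is idealized; segmentation defaults are tuned to the
  generator and will need re-tuning for real instruments.
* The ER+Golgi class is trained from synthetic examples by default.
* The microtubule depolymerizer/destabilizer split is a labeled heuristic.
* Median polish on heavily non-additive matrices has non-unique fixed
  points; results match `stats::medpolish` exactly on additive-plus-outlier
  structure but can differ in effect allocation otherwise.
* No p-value/FDR machinery: hit calling is the RZ threshold rule only.
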