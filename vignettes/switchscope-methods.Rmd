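---
title: "Quantifying rare white-opaque switching: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rare white-opaque switching: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchscope)
```

## The scientific problem

White-opaque switching in *Candida albicans* is a textbook case of
heritable, bistable transcription states: genetically identical cells
maintain one of two stable identities through thousands of divisions, and
switch between them rarely and stochastically.  The master regulator Wor1
is expressed ~40-fold higher in opaque cells and positively regulates its
own long control region, so the transition of a single cell can be read
out as the rise of a nuclear-localized Wor1 fluorescent fusion.

Observing enough rare events to say anything quantitative requires
time-lapse microscopy of many microfluidic trap fields, single-cell
segmentation and pedigree tracking, and statistics that respect the
dependence structure of events within a lineage.  `switchscope`
implements that analysis chain, together with a flow-cytometry pipeline
for quantifying the steepness (ultrasensitivity) of Wor1 autoregulation
from a synthetic hormone-inducible system, and — because the raw
microscopy and flow data are large external deposits — a ground-truthed
synthetic-data generator that emulates both, so every stage is testable
end to end.

## The two-step switching model

The pedigree generator (`simulate_pedigrees()`) encodes the two-step
picture of stochastic switching:

1. **Predisposition** (first event): at any cell division, with
   probability `p_predispose`, the dividing pair acquires a heritable
   predisposed state.  Its span is drawn uniformly from 1–4 divisions;
   descendants within that many divisions of the establishment remain
   predisposed, after which the state expires.
2. **Activation** (second event): each division of a predisposed cell
   triggers, with probability `p_activate`, the committed activation of
   the master regulator.  Activation always captures the current
   mother-daughter pair jointly (the observed synchrony of pairs), and
   activated cells and all their descendants remain opaque.

This is deliberately the *minimal* mechanics consistent with the observed
pedigree patterns — direct pairs, occasional four-cell patterns, and
mixed-fate pedigrees in which switching groups separated by
non-switching divisions share a recent ancestor.  The true nature of the
first event is an open question; a per-division Bernoulli trial is one
admissible choice, and the package makes no mechanistic claim beyond it.

Cells divide with Gamma-distributed times (mean 95 min, sd 18 min,
chosen so a trap loaded with 2 cells reaches roughly 400 resident cells
by 12 h — about 8 doublings).  Traps have a fixed resident capacity
(default 400); once full, newborn cells are pushed out of the field and
leave the record.  Newborns of predisposed or activated lineages instead
displace a random unremarkable white resident.  This retention bias
mirrors how manually curated tracking follows event lineages, and keeps
the per-division event opportunity uniform across the movie.

**Calibration.** The defaults `p_predispose = 1.63e-4` and
`p_activate = 0.10` were fixed once, by simulation, so that the expected
number of zero-event traps in a default 168-trap experiment — measured
through the full pipeline (trace simulation, classification, grouping,
scheme-3 counting) — equals 134/168, the zero-class fraction the
statistics are built around.  This is openly a calibration, not a
prediction: the generator is made to reproduce the study conditions so
that the statistical machinery downstream can be validated against known
ground truth.  With these defaults, scheme-3 counts are
Poisson-consistent and scheme-2 counts reject the Poisson null in
essentially every replicate (the qualitative contrast the dependency
analysis rests on).  About a third of event-bearing pedigrees are
mixed-fate, somewhat more than the observed 7/34; pushing it lower by
reducing `p_activate` has little effect (pedigrees with a long
heritability span dominate the mixed-fate pool) and was not pursued,
since only the qualitative contrast and the 1–4-division separations are
contracts.

## Reporter kinetics

Switching traces follow a logistic rise from the white level (1, in
relative units — the study reports no absolute intensity scale) to the
opaque level (40), with a 10–90% rise time of 3 h.  In pedigree
simulations the rise midpoint sits `rise_offset_min` (60 min) after the
activating division; mother and daughter share one curve, which is what
makes their activation synchronous.  The standalone kinetics generator
(`make_switch_traces()`) instead draws the *birth-to-maximum* time from a
lognormal truncated to 5.4–17.2 h whose truncated mean and sd equal
9.9 h and 3.2 h exactly (the lognormal parameters are solved numerically
at configuration time), and anchors the curve so that the 95%-of-plateau
point — the operational "maximum" used by the classifier — falls at the
drawn time.  Traces carry multiplicative lognormal noise (cv 0.05 by
default).

## Imaging: registration, segmentation, quantification

The renderer draws cells as ellipses: a DIC-like channel with a bright
rim over a dark interior, and a GFP channel with a ~300-pixel nuclear
disc at the cell's current reporter level over cytoplasm at half that
level (nuclear level twice the cell background).  The nuclear disc is
sized so that the top-300-pixel average reads back the generating level
directly.  Typical white and opaque footprints are 1,750 and 2,500
pixels.

* **Registration** (`register_frames()`): consecutive-frame translation
  by FFT cross-correlation with parabolic subpixel refinement,
  accumulated to frame 0; corrected frames are zero-filled at uncovered
  borders.  Trap fields translate but do not rotate, so the general
  geometric transformation is deliberately reduced to translation.
* **Segmentation** (`segment_frame()`): the difference of white-top-hat
  and black-top-hat responses highlights cell rims; Otsu thresholding,
  dilation, hole filling, erosion and connected-component labeling yield
  candidate objects, filtered by area, perimeter and eccentricity
  ranges.  The structuring-element radii (defaults ~6 px, about a
  quarter of a cell radius) and the threshold rule are exposed in
  `segmentation_params()` because only the operator sequence, not its
  scales, is canonical.
* **Quantification**: `top_pixels_metric()` averages the 300 brightest
  pixels of an object in the fluorescence channel (objects smaller than
  `k` are averaged whole and flagged); `cell_length()` reports the
  moment-based major-axis length, the automated surrogate for a line
  drawn along the cell's long axis.  `extract_traces()` chains
  registration, per-frame segmentation and nearest-centroid linking into
  per-track traces; linking is an automated aid, with crowded-field
  ambiguity left to curated tables.
* The GFP channel is not background-subtracted before the top-pixel
  average; non-expressing white cells define the background level, and
  all levels are relative to it.

## Trace classification

`classify_switch()` calls a cell opaque-level when its LOESS-smoothed
trace (span 0.3, degree 1, via `lowess` with zero robustness iterations
— a linear smoother, so calls are monotone in the trace) exceeds the
geometric mean of the white and opaque reference levels for at least 3
consecutive frames.  The geometric mean is a scale-free midpoint in log
space; the persistence requirement suppresses single-frame noise.  Cells
above threshold from birth are `opaque`; cells that crossed during
observation are `switching`.

Kinetic quantities are read from a lightly smoothed trace (span 0.05)
with linear interpolation between frames: activation start (10% of the
white-to-opaque range), the 10–90% rise time, and the birth-to-maximum
time (first crossing of 95% of the cell's own plateau, the plateau being
the median of values above the 90% threshold).  The two spans differ
because state calling wants noise suppression while a 3 h rise sampled
at 12 min would be visibly broadened by a 36-frame window; with the
12-frame kinetic window the estimator biases are below 0.1 h for both
quantities (verified against generator ground truth).

## Event grouping and the three counting schemes

Cells of one activation event share a single rise curve, so their
absolute threshold-crossing times coincide.  `group_switching_cells()`
therefore connects parent-daughter switching cells only when those
crossing times agree within 2 frames (24 min) — the synchrony window —
and takes maximal connected sets as groups.  A mother that switched with
her third daughter is *not* merged with a first daughter that switched
at a different time; that is precisely the mixed-fate configuration.
Groups sharing a lineage-tree root of the recorded pedigree form one
*set* (no division-count cap; observed separations of 1–4 divisions
emerge from the heritability span, not from a threshold).

`count_events()` then implements the three schemes: (1) every
synchronous mother-daughter pair counts; (2) connected groups count
once; (3) sets count once.  The zero-class estimator
`estimate_lambda()` (`-log(n0/N)`, the ML rate for the zero/nonzero
dichotomy), `poisson_expected()` (with counts ≥ `k_max` pooled; default
`k_max = 4`) and `gof_monte_carlo()` (Pearson chi-squared with
multinomial Monte-Carlo p-values, 2,000 replicates, add-one estimator so
p is never exactly zero) complete the dependency analysis.

## Flow cytometry and robust Hill fitting

The plate generator draws intact cells, low-scatter debris and
high-scatter, high-autofluorescence aggregates, each event carrying its
ground-truth label.  For intact cells, induced protein follows a shared
saturating curve in hormone (basal 1, max 300, half-max 5 nM; free GFP
scaled 10-fold higher), with lognormal cell-to-cell spread (sd 0.25 on
the log scale).  The reporter's log10 forward-scatter-normalized level
follows a four-parameter log-logistic (Hill) response in log protein —
lower asymptote −1.7, upper 0.3, Hill coefficient 3.2 with half-max 40
protein units for the non-dimerizing fusion, 4.3 with half-max 8 for the
dimerizing fusion (a 5-fold half-max ratio).  The dimerizing fusion's
reporter declines as a power law above 2 nM hormone, so its fits use
only sub-threshold wells, exactly as the analysis prescribes.  Channel
noise is multiplicative lognormal (cv ≈ 5% on measurement channels);
these scales were chosen so that single-cell fits recover the generating
coefficients essentially unbiasedly, which is the property the
acceptance checks exercise.

`gate_events()` applies two rectangular gates in raw channel space
(scatter, and violet-670 autofluorescence vs GFP), removing ≥95% of
contaminants while keeping ≥95% of intact cells at the defaults; with
7,500 events per well the per-well pass counts land in the observed
127–8,905 range.  Gating on raw channels commutes with
forward-scatter normalization (`normalize_events()`), which appends
`gfp_n = gfp/fsc` and `mcherry_n = mcherry/fsc`.

`fit_hill()` fits `log10(y) = c + (d−c) / (1 + exp(−h(ln x − log K)))`
on pooled single-cell points (per-cell distributions, not per-well
medians; a per-well-median fit can be had by aggregating first).  The
predictor is clipped below at its 0.1th positive percentile before
logging.  An ordinary least-squares fit from a coarse multi-start grid
seeds a least-median-of-squares polish (multi-start Nelder-Mead on the
median of squared residuals).  The median-type loss is what makes the
fit resistant to the clumping and autofluorescence artifacts such
experiments produce; the implementation detail behind "robust median
estimation" is otherwise open, and least median of squares is the
package's choice.  The parameterization carries the natural log of the
half-max as a parameter, so rescaling all `x` by α shifts `log_K` by
exactly ln α and leaves `c`, `d`, `h` invariant — an exactness property
the tests assert on noiseless fits.  `summarize_fits()` aggregates
replicate strain-day fits per construct (mean ± sd of `h`, ratio of mean
half-max levels, Welch comparisons on `h` and `log K`); replicate fits
are aggregated per measurement day rather than pooled across days.

## What the generator does and does not emulate

The synthetic data reproduce the *statistical* structure the analysis
relies on: event rarity and lineage dependence, synchronous pair
activation, logistic reporter rises with the stated kinetics, class-
conditional cell sizes and lengths (the switching-length classes are
two-component round/elongated mixtures calibrated so 14% of mothers and
80% of daughters exceed the true white 95th percentile — a single
lognormal cannot give a white-like mode and these tail fractions
simultaneously), Hill-shaped reporter activation with debris and
aggregate subpopulations, and the high-concentration reporter decline.

They do not emulate photorealistic microscopy (no optics model, no
shading), pseudohyphal branching morphology, nuclear oscillations
(tolerated by smoothing, reproduced only as an optional modulation, off
by default), polyploidization, or instrument-specific absolute
fluorescence scales.  Passing tests therefore demonstrate that the
pipeline measures correctly what the generative model produces — not
that segmentation would survive arbitrary real-world image artifacts.

## Numerical choices and degenerate inputs

* Percentiles use linear interpolation between order statistics
  (`quantile` type 7); "longer than" is a strict inequality.
* Coordinates are 0-based (row, col); frame 0 is the experiment start;
  `time(frame) = frame × frame_interval`.
* Monte-Carlo p-values use the add-one estimator; fixed seeds make every
  stochastic stage bit-reproducible, and `run_pipeline()` derives each
  stage's seed from the global seed plus the stage name.
* Featureless frames register at (0, 0) with a warning; empty frames
  segment to zero objects; empty masks and degenerate predictors are
  errors; traces shorter than the persistence window are called white
  with a low-confidence flag; a fit that stalls returns
  `converged = FALSE` rather than raising.
* Problem sizes in the test-suite and acceptance computations are the
  study's own (168 traps, 248 length pairs, 21 kinetic traces, 8
  replicate strain-days of 10-well plates at 7,500 events/well);
  structural tests use smaller traps and plates because they exercise
  logic, not statistics.

## Known limitations

The generator's Bernoulli two-step mechanics are one admissible model of
an explicitly open hypothesis; rates are calibrated, not inferred.  The
tracking aid is nearest-centroid only and defers crowded traps to
curated tables.  The Poisson machinery covers the zero-class estimator
and Monte-Carlo chi-squared only — no negative-binomial or
zero-inflated alternatives.  Fits assume a monotone response below the
cutoff; the mechanism of the high-concentration decline is out of scope.
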