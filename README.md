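# switchscope

Single-cell analysis of rare, stochastic switching between heritable
transcriptional cell states — the white-opaque switch of *Candida
albicans* being the motivating system.  The package covers the full
analysis chain for time-lapse microfluidic experiments and for
flow-cytometry dose-response measurements of master-regulator
autoregulation, plus a ground-truthed synthetic-data generator so that
every stage can be exercised and validated without external image or
flow deposits.

## Who this is for

Quantitative biologists analyzing rare switching events in time-lapse
movies of trapped microbial populations (segmentation, per-cell
fluorescence traces, pedigree-aware event statistics), and anyone
fitting ultrasensitive transcriptional responses from single-cell flow
cytometry.

## What it computes

**Two-step switching statistics.**  Switching is modeled as two
stochastic steps: a heritable *predisposition* of a small lineage, then
*activation* of the master regulator (Wor1) in some of those cells,
always capturing a mother-daughter pair jointly.  Observed events per
trap are counted under three schemes — (1) every synchronous pair
independent, (2) connected groups merged, (3) whole mixed-fate
pedigrees merged — and compared with a Poisson null whose rate comes
from the zero class:

    lambda = -log(n0 / N)

with a Pearson chi-squared statistic and Monte-Carlo p-values
(multinomial simulation, 2,000 replicates).  Dependence between events
in a lineage shows up as scheme 2 rejecting the null while scheme 3 is
consistent with it.

**Trace kinetics.**  Per-cell reporter traces (the mean of the 300
brightest pixels of each cell in the GFP channel) are LOESS-smoothed and
classified; switching cells are timed from birth to maximal level and
their 10–90% rise measured.

**Robust Hill fits.**  Flow events are gated (scatter and
autofluorescence gates), normalized by forward scatter, and the pooled
single-cell response fitted with a four-parameter log-logistic (Hill)
curve on the log10 scale,

    log10(y) = c + (d - c) / (1 + exp(-h (ln x - log K)))

by least squares with a least-median-of-squares polish ("robust median"
loss).  Replicate strain-day fits aggregate to per-construct mean ± sd
of the Hill coefficient `h` and the half-max ratio between constructs.

## Worked example

```r
library(switchscope)

# --- a small trap experiment under the two-step model -------------------
cfg <- switch_model_config(n_traps = 24, rng_seed = 7)
experiment <- simulate_pedigrees(cfg)
traces     <- simulate_traces(experiment)
calls      <- classify_cells(traces, cfg$white_level, cfg$opaque_level)
groups     <- group_switching_cells(experiment$cells, calls)
tab        <- count_events(groups, scheme = 3, trap_ids = 1:24)
table(tab$count)
#>  0  1  2 
#> 17  6  1

# the Poisson null from the zero class (at the study scale, 134/168):
lam <- estimate_lambda(134, 168)
lam
#> [1] 0.2261242
gof_monte_carlo(tab, poisson_expected(estimate_lambda(17, 24), 24),
                reps = 2000, seed = 1)
#> Monte-Carlo chi-squared goodness-of-fit
#>           0    1    2    3  >=4
#> observed 17 6.00 1.00 0.00 0.00
#> expected 17 5.86 1.01 0.12 0.01
#> chi2 = 0.130, p = 1 (2000 replicates)

# --- the flow pipeline: gate -> normalize -> robust 4PL fit -------------
fcfg  <- flow_model_config(rng_seed = 7)
plate <- simulate_flow_plate(fcfg, strains = "Wor1-mGFP")
ev    <- normalize_events(gate_events(plate))
fit_hill(ev$gfp_n, ev$mcherry_n)
#> <hill_fit> c = -1.700, d = 0.297, K = 40.15 (log_K = 3.693), h = 3.215
#>   n = 69578, median |resid| = 0.0455, robust = median, converged = TRUE
```

The trap counts say: 17 of 24 traps saw no activation; treating each
mixed-fate pedigree as one event leaves the per-trap counts
Poisson-consistent (p = 1 at this small scale).  The Hill fit recovers an
ultrasensitive response (h ≈ 3.2, far above 1) with the half-max at
`K ≈ 40` normalized-GFP units; comparing constructs with
`summarize_fits()` yields the ~5-fold half-max ratio between the
non-dimerizing and dimerizing fusions.

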