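# galmodality

Phenomenological modelling and modality classification of galactose
(GAL) pathway induction in single yeast cells.

When yeast faces a glucose–galactose mixture, the GAL genes can come on
gradually in every cell (a unimodal response) or fully in only a
fraction of cells (a bimodal, bet-hedging response). Which of the two a
strain shows is captured by the relative position of two glucose
thresholds:

* **F90** — the glucose concentration at which 90% of cells are still
  induced (fraction regulation);
* **E10** — the glucose concentration at which the induced
  subpopulation's expression level has fallen to 10% of its maximum
  (level regulation).

The package implements the full desk-scale pipeline around this idea,
for anyone who wants to simulate, classify or reanalyze
flow-cytometry-style single-cell induction data:

* a two-Hill-curve model of induction. Induced fraction
  `f(g) = (αF90)^n / (g^n + (αF90)^n)` with `α = (0.9/0.1)^(1/n)`, and
  induced level
  `log10 ℓ(g) = (βE10)^n / (g^n + (βE10)^n) · 2.5 − 3` with
  `β = (0.6/0.4)^(1/n)`, plus a quadratic noise model
  `sd(x) = −0.2(x + 1.75)² + 0.4`;
* a seeded population simulator: 20,000-cell log-normal mixtures per
  condition across the standard twofold glucose titration (1% down to
  0.0039%), with uninduced and maximal-induction references, written and
  read as plain CSV event tables;
* the modality classifier: single-Gaussian histogram fit, fall back to a
  double Gaussian when the adjusted R² is below 0.99, bimodal iff the
  means are more than twice the larger SD apart and the minor component
  exceeds 0.15; profile and replicate aggregation rules included;
* metric extraction: quantile gating against the uninduced reference,
  E10/F90 read-off by log-linear interpolation, lower-bound flagging for
  level-suppressed strains, and Hill-coefficient fitting;
* a phase-diagram scan over (E10, F90, Hill coefficients) with exact
  slope-1 bounding lines delineating the unimodal, bimodal and ambiguous
  regimes, and a side-of-line modality predictor;
* a synthetic strain-panel/fixture generator with pre-induction-history
  effects (multiplicative F90 shifts) and a ground-truth manifest.

Everything is tidyverse-shaped: results come back as tibbles or carry
`tidy()`/`glance()` methods, and `autoplot()` covers models, profiles
and phase diagrams.

## Worked example

```r
library(galmodality)

# a strain whose level threshold sits above its fraction threshold
m <- gal_model(E10 = 0.25, F90 = 0.0625)
prof <- simulate_profile(m, n_cells = 20000, seed = 1)
analyze_profile(prof)
#> # A tibble: 1 × 7
#>   replicate_id modality n_bimodal   E10    F90 f90_lower_bound max_level_log
#>   <chr>        <chr>        <int> <dbl>  <dbl> <lgl>                   <dbl>
#> 1 rep1         bimodal          3 0.244 0.0627 FALSE                  -0.500
```

The strain is called bimodal (three of the nine titration conditions
show a resolved two-component histogram), and the thresholds measured
back from the 20,000-cell event tables — E10 = 0.244, F90 = 0.0627 —
recover the generating values 0.25 and 0.0625 to a few percent. The
maximal-induction reference sits at log10 level −0.5, the top of the
model's scaled range.

Swapping the two thresholds (`gal_model(E10 = 0.0625, F90 = 0.25)`)
produces a unimodal profile whose measured F90 is flagged as a lower
bound: expression shuts off before the fraction transition, so the
fraction threshold is concealed — the reason deleting the *MIG1*
repressor (which raises E10) converts unimodal strains to bimodal.

A phase diagram over the full published grid:

```r
pts <- scan_phase_grid(seed = 20) # 11 x 11 thresholds x 3 x 3 Hill values
dg <- delineate_regimes(pts)
predict_modality(dg, E10 = 0.5, F90 = 0.01) # "bimodal"
autoplot(dg)
```

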