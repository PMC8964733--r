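---
title: "Automated maximum-entropy range estimation: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated maximum-entropy range estimation: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxrange)
```

`maxrange` estimates where a species finds environmentally suitable
conditions inside its native regions, using nothing but presence-only
occurrence records and gridded environmental predictors. This vignette is
the package's own account of the science it implements: the model, the
workflow around it, the tunable parameters, the numerical choices, and
what the synthetic validation does and does not demonstrate.

## The modelling problem

Occurrence records for most plant species are presence-only: we know
where someone recorded the species, never where it is absent. The
package treats range estimation as a density-estimation problem on a
regular latitude/longitude grid (0.5°, roughly 56 km at the equator).
The *background* is every grid cell within the species' native regions —
botanical-country style polygons rasterized by cell-center containment —
and the model contrasts the environment at occupied cells against that
background.

### The maximum-entropy model

Let $f(x) \in [0,1]^J$ be a vector of features built from the
environmental variables at cell $x$. The model is the Gibbs density over
the $N$ background cells

$$ q_\beta(x) = \frac{e^{\beta^\top f(x)}}{\sum_{x'} e^{\beta^\top f(x')}}, $$

the maximum-entropy distribution subject to matching the presence means
of the features. The coefficients minimize the L1-penalized negative
presence log-likelihood

$$ \ell(\beta) = \log Z(\beta) - \beta^\top \bar f_{\text{pres}}
   + \sum_j \lambda_j |\beta_j|, $$

a convex objective solved by accelerated proximal gradient descent
(FISTA with backtracking and restart, implemented in C++) to a relative
objective tolerance of $10^{-7}$ within at most 10,000 iterations. The
per-feature penalty is

$$ \lambda_j = \mathrm{rm} \times \beta_{\text{class}(j)}(m) \times
   s_j / \sqrt{m}, $$

where $m$ is the presence count, $s_j$ the presence standard deviation
of feature $j$ (floored at 0.05 on the $[0,1]$ feature scale so that a
single presence point cannot zero out all penalties), and
$\beta_{\text{class}}$ the published per-feature-class default constants
(linear/quadratic/product interpolated over sample sizes
$(0,10,30,100) \to (1,1,0.2,0.05)$; hinge $0.5$; threshold
$(0,100) \to (2,1)$). The *regularization multiplier* (rm) scales the
whole penalty; larger values give sparser, smoother models.

Feature classes follow the six standard combinations `l`, `lq`, `h`,
`lqh`, `lqhp`, `lqhpt`: linear, quadratic, pairwise products, forward
and reverse hinges, and step thresholds, with hinge/threshold knots
evenly spaced over the background range of each min/max-scaled variable.
Scaling bounds are frozen at training time; prediction on new extents
clamps to $[0,1]$.

Two outputs are produced. The **raw** output is $q_\beta$ itself, a
relative occurrence rate summing to 1 over the training background. The
**cloglog** output is $1 - \exp(-e^{H} \cdot \text{raw})$, where $H$ is
the entropy of the raw distribution over the training background (kept
fixed for any prediction extent); it compresses extremes into $(0,1)$
and is best read as a relative suitability index. Because the transform
is strictly monotone, every ranking metric (AUC, AUC$_{PR}$, maximum
F1) is identical for the two outputs — a property the test suite
asserts.

## The workflow around the model

1. **Occurrence filtering.** Records with missing coordinates or flagged
   geospatial issues are dropped first. If at least 25 records fall in
   the 2000–2020 window, only those are kept (aligning occurrences to
   the period of the climate and land-cover layers); with fewer, all
   years are kept to maximize data. Records outside the native regions
   and exact duplicates of (lon, lat, year) are removed. The result is
   the *raw* data type.
2. **Data types.** Removing within-cell duplicates gives *presence
   cells*; spatial thinning at a minimum distance of two cell widths
   gives the *thinned* data. The three types represent increasing
   protection against pseudo-replication and clustered sampling effort.
3. **Eligibility.** A prediction is attempted only with ≥ 5 raw records
   across ≥ 3 cells and a native extent of ≥ 9 cells; the filtered data
   types additionally need ≥ 3 points each.
4. **Cross-validation.** Below 25 points, leave-one-out jackknife
   (k = n); from 25 up, spatial block partitioning (k = 4) that splits
   points at their median longitude and each half at its median
   latitude, assigning background cells to the same blocks by the stored
   split lines. The *degree of overfit* is the mean training AUC minus
   the mean testing AUC.
5. **Variable selection (Model 0).** The six feature combinations are
   cross-validated at rm = 1 on the raw data with all variables; the
   winner is chosen by AICc (K = nonzero coefficients, likelihood from
   the grid-standardized raw output), falling back to mean testing AUC
   when AICc is unavailable for at least half the candidates or has no
   unique minimum. Permutation importances on the winner and Spearman
   correlations over the background drive a greedy pruning: variables
   are admitted in order of decreasing importance iff
   $|\rho| < 0.7$ against everything already kept.
6. **Candidate grid (Models 1–3).** For each eligible data type, all
   6 combinations × 5 regularization multipliers {1, 2, 3, 5, 10} are
   cross-validated (30 candidates per type, at most 96 fitted models per
   species including Model 0). Per-type winners use the same
   AICc-then-AUC cascade; the overall winner maximizes the harmonic mean
   of presence-background AUC and AUC$_{PR}$.
7. **Evaluation and thresholds.** Metrics are computed from presence
   cells (positives) versus remaining native cells, or from a reference
   range when one exists. The no-omission threshold is the minimum
   predicted value over presence cells; the max-F1 threshold maximizes
   F1 over all observed score thresholds.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `cell_size` | 0.5° | modelling resolution (~56 km at the equator) |
| `year_lo`, `year_hi` | 2000, 2020 | temporal filter window |
| `min_recent` | 25 | in-window records needed to activate that filter |
| `min_records`, `min_cells`, `min_native` | 5, 3, 9 | Model 1 eligibility |
| `min_filtered` | 3 | Model 2/3 eligibility |
| `thin_dist_cells` | 2 | thinning distance in cell widths |
| `thin_reps` | 10 | randomized thinning restarts |
| `rho_max` | 0.7 | Spearman collinearity bound |
| `rms` | 1, 2, 3, 5, 10 | regularization multipliers |
| `n_knots` | 50 | hinge/threshold knots per variable |

`n_knots = 50` gives hinge responses close to the continuous limit;
the test-suite and example runs use 5 knots, which preserves every
structural property (counts, contracts, convergence) at a fraction of
the cost and, on the smooth synthetic layers, loses little flexibility.

## The synthetic worlds

Real occurrence data cannot ship with the package and true niches of
real species are unknowable, so validation rests on generated worlds
with a known ground truth:

- **Environment**: smooth standardized fields (sums of low-frequency
  sinusoids plus kernel-smoothed noise) for climate-like layers, and
  logistic transforms of such fields for land-cover fractions in
  $[0,1]$. Pairwise correlations span low to high; an explicitly
  correlated pair can be requested to exercise the pruning step.
- **Native regions**: unions of random rectangles of cells, with sizes
  and positions pinnable for exact-count tests.
- **Species**: suitability is
  $\mathrm{logistic}(c + \sum_i \beta_i x_i + \sum_i \gamma_i x_i^2)$
  over a small set of active variables (defaults: 2 active variables,
  $|\beta| \in [1.5, 2.5]$, $\gamma \in [-1.5, -0.5]$, giving bell-shaped
  responses with interior optima — the canonical shape niche theory
  expects). Records are cells drawn proportionally to suitability times
  an optional accessibility bias (distance decay from random hotspots,
  mimicking road/herbarium effort), jittered within the cell, dated
  uniformly, and optionally laced with labelled contaminants (missing
  coordinates, pre-2000 dates, out-of-region points, exact duplicates)
  so tests can assert that filters remove exactly those records.
- **Reference ranges**: native cells with true suitability at or above
  an inverse-ECDF quantile, standing in for expert-drawn maps.

What passing tests show: the estimator optimizes its objective, its
distributional contracts hold, the workflow enumerates and selects as
documented, and on worlds whose truth is a smooth function of the
supplied layers, the pipeline reliably recovers the niche (median
Spearman correlation between predicted suitability and truth ≥ 0.8 over
ten worlds of 60×40 cells with 80 presences, 2 active and 4 nuisance
variables). What they cannot show: behaviour under misspecification
that real data exhibit — niches driven by unmeasured variables,
non-equilibrium distributions, taxonomically confused records, or bias
fields correlated with the environment itself. Synthetic performance is
an upper bound, not a forecast.

## Numerical and design choices

- **Cell membership** uses half-open intervals $[edge, edge + cs)$ with
  the global east/north boundary closed; polygon rasterization uses
  cell-center containment (the common raster default; fractional
  coverage would blur eligibility counts).
- **Thinning distance** is anchored to the equatorial cell width: two
  0.5° cells = 111.32 km, measured as great-circle (haversine) distance.
  The thinning algorithm deletes the most-conflicted point with random
  tie-breaks, repeated over seeded restarts, keeping the run that
  retains most points; on instances small enough to enumerate, it
  attains the exhaustive maximum.
- **Duplicates** are identical (lon, lat, year) after rounding
  coordinates to $10^{-6}$ degrees. Records without a year are dropped
  only when the temporal filter is active.
- **Moran's I** uses binary queen contiguity over native cells, total
  weight sum $W$, no row standardization, zero-count native cells
  included.
- **Block partitioning** splits by rank (not by coordinate value), so
  fold sizes differ by at most 2 even with ties; the stored split lines
  are midpoints between the bounding coordinates of adjacent halves.
- **Jackknife testing AUC** with a single held-out presence is the
  fraction of background scored below it (ties counted half) — the
  natural n = 1 limit of the Mann–Whitney statistic.
- **AICc ties** within $10^{-9}$ count as "no unique minimum" and
  trigger the AUC fallback; the fallback compares all candidates, not
  only those lacking AICc. Harmonic-mean ties break by higher AUC, then
  fewer nonzero coefficients, then the data-type order raw, presence
  cells, thinned (prefer more filtering).
- **PR interpolation** is linear in recall between observed operating
  points, with the precision at vanishing recall taken from the highest
  threshold; the test oracle enumerates thresholds under the same
  convention, since nonlinear interpolation conventions differ between
  libraries.
- **Degenerate inputs**: constant variables are dropped with a warning
  before feature building; constant count fields make Moran's I error
  rather than return 0/0; a species failing eligibility produces a
  bundle with occurrences and native region only.
- **Spatial I/O**: grids, masks and predictions serialize as long-format
  CSV plus a JSON manifest keyed by the bundle variable names
  ("Maxent prediction", "Presence cells", "Native region", "Model 1–3");
  polygons are read from GeoJSON; fitted models serialize to JSON. These
  text formats keep bundles diffable and dependency-light.
- **Interface**: the package deliberately exposes an R API
  (`run_pipeline()` and the module functions) rather than a shell CLI —
  its users script analyses in R, and a thin wrapper script around
  `run_pipeline()` is trivial to write where batch execution is needed.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise the pipeline on
40×40-cell worlds (enumeration, evaluation) and ten 60×40-cell worlds
with 80 presences each (niche recovery), with 5 hinge/threshold knots
per variable — sizes chosen so a full run completes in well under a
minute per world on a single core while every count, contract and
selection rule is exercised at full fidelity. Larger grids change cost,
not logic.

## Known limitations

- The estimator fits the standard maximum-entropy formulation; it does
  not reproduce the Java Maxent tool bit-for-bit (different solver,
  knot placement and convergence criteria).
- Presence-background metrics depend on class balance and are comparable
  between models of one species, not across species; cross-species
  comparison needs reference ranges.
- No clamping/extrapolation diagnostics, categorical features, or
  reprojection between coordinate systems.
- The grid is plain lat/lon; "distance in cells" statements shrink in
  ground units toward the poles.
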