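---
title: "Rank-invariant agreement analysis: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-invariant agreement analysis: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankagree)
```

## The problem and the model

An ordinal instrument assigns each subject to one of C ordered
categories.  When the same subjects are assessed twice — by one rater on
two occasions (intra-rater) or by two raters on one occasion
(inter-rater) — the paired categories form a C×C contingency table, and
the reliability question splits into two qualitatively different parts:

* **Systematic disagreement**: the two assessments use the scale
  differently *as a group* — one shifted towards higher categories, or
  more concentrated on the central ones.  This is a property of the two
  marginal distributions.
* **Random (individual) disagreement**: subjects scatter around the
  systematic pattern — the residual, subject-level noise.

The rank-invariant approach quantifies these without assigning numeric
values to the categories: all statistics depend only on the ordering,
so any monotone relabelling of the levels leaves them unchanged.  That
is the reason this package does not compute weighted kappa or ICC-type
coefficients: those treat the category codes as interval-scaled numbers
and mix systematic and random components into a single index.

With cell counts $n_{ij}$ (row $i$: first assessment, column $j$:
second), marginals $a_i$, $b_j$, and $n$ subjects:

* **Percentage agreement** at point tolerance $k$:
  $PA_k = 100 \cdot \sum_{|i-j|\le k} n_{ij} / n$.  The package also
  searches for the smallest $k$ with $PA_k$ at or above the
  satisfactory threshold (70% by default); the search always terminates
  because $PA_{C-1} = 100$.
* **Relative position**
  $RP = \frac{1}{n^2}\left(\sum_{c<d} a_c b_d - \sum_{c>d} a_c b_d\right)
      = P(Y > X) - P(Y < X)$
  for independent draws $X$ from the first and $Y$ from the second
  marginal.  $RP \in [-1, 1]$; with the row/column convention below,
  positive RP means higher categories are used more often at the second
  assessment.
* **Relative concentration**
  $RC = \frac{2}{n^3}\left(\sum_c b_c A_{<c} A_{>c}
        - \sum_c a_c B_{<c} B_{>c}\right)$,
  with $A_{<c}, A_{>c}$ the first assessment's marginal counts strictly
  below/above $c$ (and $B$ likewise for the second): the probability
  that a second-assessment draw falls strictly between an unordered
  pair of first-assessment draws, minus the converse.
* **Augmented mean ranks**: each assessment ranks its subjects by own
  category, breaking ties by the paired assessment's category, with
  subjects in the same cell sharing the cell's mean rank:
  $R^{(1)}_{ij} = \sum_{p<i} a_p + \sum_{q<j} n_{iq} + (n_{ij}+1)/2$,
  symmetrically for $R^{(2)}_{ij}$.  Both rank sets sum to $n(n+1)/2$.
* **Relative rank variance**
  $RV = \frac{6}{n^3} \sum_{ij} n_{ij} (R^{(1)}_{ij} - R^{(2)}_{ij})^2$,
  zero exactly when the observed disagreement is fully explained by the
  marginal (systematic) pattern — in particular for every diagonal
  table, but also for tables like `[[2,1],[0,2]]` where the off-diagonal
  mass is a pure position shift.

## Normalisation choices

Two constants in these formulas are genuine conventions rather than
consequences of the probabilistic definitions, and the package pins them
by exhaustive enumeration oracles in its test suite (direct counting of
marginal pairs, ordered triples, and subject-level rankings on small
random tables):

* **RC uses the unordered-pair factor 2.** Under it the attainable
  extremes are ±0.5 (reached, e.g., when the first assessment sits
  entirely on the two end categories and the second entirely on a
  middle one).  The ±0.1 negligibility band — not the theoretical
  range — is what the classification rules consume, so the convention
  does not affect any flag.
* **RV uses $6/n^3$.** Under independence of the two assessments RV
  tends to 1 (the test suite checks this on large simulated samples),
  but adversarial rank-reversal tables can exceed 1; RV is therefore
  treated as a nonnegative measure with 0.1 as the negligibility
  cutoff, not as a quantity bounded by 1.

Other conventions: rows are always the first-listed assessment
(occasion 1 for intra-rater comparisons), so positive RP reads as
"higher at the second occasion"; sum-score tables span the full
theoretical range (35 categories for a 0–34 total) even when levels are
unobserved, which only matters for the point-tolerance metric; and
degenerate single-category tables return PA = 100 and RP = RC = RV = 0
rather than erroring.  All values are computed in full precision;
display rounding ("values with |x| ≤ 0.01 print as 0, otherwise two
decimals") applies only to formatted output.

## Inference and classification

The interval method is a **nonparametric percentile bootstrap over
subjects**: level pairs are resampled with replacement (the subject,
never the single assessment, is the resampling unit), the statistic is
recomputed B = 2000 times, and the level-α/2 percentiles are taken.
This is assumption-light and respects the range restrictions of the
statistics — RV intervals can never go negative.  In rare discrete edge
cases the percentile interval is widened to include the point estimate.
Seeding makes every interval exactly reproducible.

The CI-based classification, applied to RP, RC and RV with
negligibility band 0.1:

| |estimate| | 0 in CI | flag |
|---|---|---|
| ≥ 0.1 | no | `significant` |
| ≥ 0.1 | yes | `tendency` |
| < 0.1 | no | `negligible_significant` |
| < 0.1 | yes | `none` |

"Tendency" (an estimate beyond the band whose CI is asymmetric around
zero yet still includes it) is operationalised purely as the second row
— no additional asymmetry test is applied, since the combination
|estimate| ≥ 0.1 with 0 inside the CI already implies a CI lying mostly
on one side of zero.  No multiple-comparison adjustment is applied
across items or comparisons.

## The synthetic study generator

`synthetic_config()`/`generate_study()` emulate the paired-rater,
two-occasion reliability design: n subjects (default 60), a rater pool
(default A, B, C) whose unordered pairs receive subjects round-robin
(with three raters and 60 subjects each rater sees 40), and two
occasions.  Each subject carries a latent level per item drawn from the
item's marginal distribution; the generative parameters are:

* `shift_prob` (δ): the probability that a subject's latent level rises
  by **one** category (capped at the item maximum) at the second
  occasion.  Single-category shifts are the realistic systematic effect
  on 3-level items — e.g. spontaneous recovery early after stroke.
* `noise_prob` (ε): the probability that an individual recorded rating
  is perturbed by one category, direction symmetric, reflected at the
  scale bounds (so the marginals stay valid without renormalisation).
* `item_marginals`: default `c(0.15, 0.25, 0.60)` per 3-level item — a
  cohort dominated by mild-to-moderate impairment whose sum scores sit
  in the upper half of the range without piling onto the maximum, the
  typical shape of an acute-stroke reliability cohort.

`induced_marginals()` propagates a marginal through the shift and noise
kernels exactly, giving analytic reference distributions for
parameter-recovery tests: the population intra-rater RP implied by a
configuration is the RP formula applied to the two induced vectors.

What the generator deliberately does **not** model: item difficulty
hierarchies (no Rasch structure), rater-specific bias (noise is
exchangeable across raters), correlated errors across items, and
missing data.  Passing validation on synthetic studies therefore shows
that the estimators recover known shift/noise structure under a clean
design — not that any real instrument is reliable.

## Calibration design

Two simulation checks calibrate the machinery, both at the study size
of the motivating design (60 subjects, three raters in pairs, two
occasions, total-score analysis):

* **Shift recovery**: mean intra-rater RP over 200 replicates per
  δ ∈ {0, 0.1, 0.2, 0.3} with ε = 0 must be strictly increasing in δ.
* **Null calibration**: at δ = 0 the true RP is 0 and the 95% CI should
  exclude it at the nominal 5% rate (equivalently, cover it at 95%,
  ±3 percentage points; 200–500 replicates).  This check runs with
  ε = 0.1: with no noise *and* no shift the four assessments of every
  subject are identical, the statistic is a constant 0 and its interval
  degenerates to (0, 0) — there is no sampling variability to cover.
  Symmetric noise leaves the two occasions' marginal distributions
  identical, so true RP remains exactly 0.  The total score (C = 35) is
  used because item-level 3-category tables put discrete mass at
  RP = 0, which makes percentile intervals over-cover.

The oracle suite uses ≥200 random tables with C ≤ 5 and n ≤ 12
(exhaustive n³ triple enumeration stays instant there) at tolerance
1e-12; the bootstrap checks use B = 2000.

## Pipeline conventions

`run_analysis()` seeds a single RNG stream, so one seed makes the whole
report — every bootstrap interval in every comparison — reproducible;
`write_report()` omits the wall-clock timestamp from the JSON output so
that identical inputs and seed give byte-identical files (the
timestamp stays in the in-memory metadata).  Assessments missing one or
more items of a sum group are excluded from that group's sums with a
warning — the conservative convention, since a partial sum is not
comparable to a complete one — and subjects missing either side of a
comparison are dropped from it, again with a warning; subjects, not
assessments, are the exclusion unit.  The floor/ceiling check uses the
strict rule "more than 15% of subjects at the minimum/maximum", so a
proportion of exactly 15% is not flagged.

## Limitations

* The comparison machinery assumes at most two raters per subject per
  occasion (the paired design); pooled designs with three simultaneous
  raters are out of scope.
* Percentile-bootstrap intervals for heavily discrete item-level tables
  at small n are conservative; the classification flags inherit that.
* RC's ±0.5 extremes mean its values are not directly comparable to
  RP's on a common [-1, 1] footing; both are interpreted through the
  ±0.1 band only.
* The statistics condition on the observed marginals; they do not model
  covariate effects on disagreement.
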