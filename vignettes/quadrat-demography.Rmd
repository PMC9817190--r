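---
title: "Static life tables and survivorship curves from quadrat surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static life tables and survivorship curves from quadrat surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadpop)
```

## The problem and the modelling idea

Shrubs and small trees cannot be aged non-destructively, yet the questions
asked of their populations — is the stand recruiting, senescing, about to
collapse? — are demographic. `quadpop` implements the classical answer:
**space-for-time substitution**. A single census records the basal diameter
(BD, trunk diameter 5 cm above ground; more reliable than breast-height
diameter for multi-stemmed shrubs) of every woody individual in a set of
fixed-area quadrats. Contiguous BD classes (by default eight 2-cm classes)
are treated as age classes, and the standing size structure is read as if
it traced one cohort through time.

That substitution rests on two assumptions worth stating plainly:

1. **Stationarity** — recruitment and mortality schedules have been roughly
   constant for as long as the oldest standing individuals have lived, so
   today's class abundances are proportional to a cohort's survivors.
2. **Size tracks age monotonically** — growth is not so plastic that old
   suppressed individuals pile up in small classes.

Neither is testable from one census; results should be read as a
consistency check on a demographic hypothesis, not as measured rates.

## The static life table

Given class abundances $A_1 \dots A_n$ (stems per hectare) with $A_1 > 0$,
survivors are standardised to a radix (default 1000):
$l_x = A_x / A_1 \times 1000$. From these, deaths
$d_x = l_x - l_{x+1}$, stage-specific mortality $q_x = d_x / l_x$, span
life $L_x = (l_x + l_{x+1})/2$, total life $T_x = \sum_{i \ge x} L_i$, life
expectancy $e_x = T_x / l_x$, killing power
$K_x = \ln l_x - \ln l_{x+1}$, and survival rate $S_x = l_{x+1}/l_x$.

Conventions that the implementation pins down:

- **$q_x$ is $d_x/l_x$, a proportion.** Some presentations of this table
  write the mortality column as a percentage or in terms of $A_x$; the
  ratio-of-survivors definition is the one under which the remaining
  columns ($q_x = 1 - S_x$, $K_x = -\ln S_x$) are mutually consistent, and
  it is what `static_life_table()` computes.
- **Last class:** $d, q, K, S$ need $l_{n+1}$ and are reported `NA`. The
  final class is closed by $L_n = l_n/2$ (deaths spread uniformly over the
  class), which forces $T_n = l_n/2$ and $e_n = 0.5$ exactly — a
  convention, not an estimate.
- **Non-monotone censuses.** If $A_x$ rises anywhere, $d_x$, $q_x$ and
  $K_x$ go negative, which is a violation of the cohort reading rather
  than an arithmetic problem. The default is to compute the raw columns
  and attach a warning; `monotone = TRUE` first applies a decreasing
  isotonic regression (`stats::isoreg`) to $A$. Smoothing is off by
  default because silently altering the census hides exactly the signal
  (episodic recruitment) that a field ecologist may care about.
- Empty upper classes propagate `NA` through the log-based columns; the
  pipeline fits survivorship curves on the occupied classes only and
  refuses to proceed with fewer than three.

All columns are kept at full double precision; rounding to two decimals
happens only in `print()` and the human-readable report.

## Survivorship models and Deevey classification

Two curve families are fitted to $l_x$: exponential
$N_x = N_0 e^{-bx}$ and power $N_x = N_0 x^{-b}$. Both are estimated by
**ordinary least squares on the log scale** — $\ln l_x$ regressed on $x$ or
$\ln x$ — not by nonlinear least squares on the original scale. The log
scale is the scale on which these models are linear and on which the
survivorship plot is conventionally drawn; it also weights proportional
(not absolute) deviations, which is appropriate for survivor counts
spanning two orders of magnitude. $R^2$ is reported for that log-scale
regression, and the model F statistic uses the one-predictor identity
$F = (n-2)R^2/(1-R^2)$.

The better-determined model classifies the curve: exponential wins ⇒
Deevey type II (constant mortality), power wins ⇒ type III (mortality
concentrated in the youngest classes). Ties — including degenerate flat
series, where $R^2$ is undefined — resolve to the exponential model, the
more parsimonious reading. Type I (mortality concentrated late) cannot be
produced by either family; as a guard, `classify_deevey()` also reports
the sign of the quadratic coefficient of $\ln l_x$ on $x$ (positive =
convex, leaning II/III; strongly negative would hint at type I and should
prompt scepticism about the two-model scheme for that dataset).

## The survival-function suite

From the per-class rates $S_x$ the suite evaluates, at the end of class
$i$ with class interval $h$ (default 1 class unit):

$$S(i) = \prod_{k \le i} S_k, \quad F(i) = 1 - S(i), \quad
f(i) = \frac{S(i-1) - S(i)}{h}, \quad
\lambda(i) = \frac{2\,(1 - S(i))}{h\,(1 + S(i))}$$

with $S(0) \equiv 1$. The product telescopes to $S(i) = l_{i+1}/l_1$ — the
suite's strongest self-check, asserted in the tests to machine precision.
Whether the mortality and hazard formulas should receive the cumulative
$S(i)$ or the per-class $S_i$ is genuinely ambiguous in parts of the
ecological literature, where both appear under the same symbol. The
cumulative reading is the default here (it makes $F$ a distribution
function and $f$ its density, $F(i) = h\sum_{k\le i} f(k)$);
`mode = "per_class"` exposes the other reading unchanged. $h$ defaults to
one age-class unit rather than the 2 cm of BD because the table's time
axis is the class index; the parameter rescales $f$ and $\lambda$ only.

## Moving-average forecast

`time_series_forecast()` computes $M_t = \frac{1}{n}\sum_{k=t-n+1}^{t} X_k$
for each horizon $n$ (default 2, 4, 6, 8 classes). $M_t$ is reported only
for $t \ge n$ — earlier windows would index classes before the first —
and is `NA`, never zero-filled, elsewhere. The method treats the class
axis as the time axis, consistent with the space-for-time reading: under
inverted-J structures the long-horizon means exceed the standing counts of
the upper classes, quantifying the future flow of today's recruits into
larger sizes.

## Importance values and layer summaries

Relative importance values average three relative measures per layer
(density / basal area / coverage for shrubs; abundance / coverage /
frequency for herbs), each normalised to sum to 100 % across species —
the *mean*, not the sum, so the layer totals close at 100.00. Choices the
data forced or left open:

- Per-species mean BD and height are unweighted stem means; the totals row
  reports **stem-weighted** means, which is what makes a totals row
  consistent with pooling all stems.
- Shrub coverage defaults to summed crown-ellipse areas
  $\pi w_1 w_2 / 4$ from the two perpendicular crown widths, without
  overlap correction (`coverage_mode = "recorded"` accepts direct
  measurements instead). Overlap correction would need stem coordinates,
  which quadrat censuses do not record; summed-ellipse coverage can
  therefore exceed 100 % in dense stands, harmlessly for RIV, which only
  uses its relative share. A single recorded crown width is taken for
  both directions.
- Herb frequency counts occupied subquadrats over *all* subquadrats of the
  design, and mean coverage averages over all subquadrats with absences
  as zero — so species missing from many subquadrats are not flattered.
- Class histograms follow the half-open convention $(0, w)$,
  $[w, 2w), \dots$: a stem exactly on a boundary belongs to the upper
  class. `assign_age_class()` uses the same convention; diameters beyond
  the top boundary are an error by default (`overflow = "clamp"` pools
  them into the last class for exploratory work).

## The synthetic generator

`generate_survey()` exists so that every stage can be exercised, seeded
and end-to-end, without field data. It emulates the statistical structure
the analysis actually consumes — and nothing more:

- Stem counts per species are Poisson at the expected density over the
  sampled area, placed uniformly over quadrats. The pipeline never uses
  within-quadrat spatial structure, so no point process is simulated.
- BD comes from a truncated exponential (the inverted-J of an actively
  recruiting population), a uniform interval, or exact per-class counts
  (`bd_fixed_class_counts`), the latter making generator + histogram an
  exactly invertible pair for testing.
- Height is linear in BD with Gaussian noise (so height- and BD-class
  structures correlate, as they do in real shrub stands), crowns
  proportional to height; herbs arise per subquadrat from a presence
  probability with shifted-Poisson abundance and truncated-Gaussian cover.

What it does **not** emulate: spatial clumping, measurement error,
taxonomic misidentification, inter-annual variation, or any growth/death
dynamics. Passing tests therefore certify the arithmetic of the pipeline
under its own assumptions, not the field validity of space-for-time
substitution.

Determinism is part of the generator's contract: a `community_config`
requires a seed, and identical seeds give byte-identical CSVs; the
pipeline inherits end-to-end reproducibility from it.

## Problem sizes and numerical tolerances

The test suite checks exact identities (telescoping products, scale
invariance, OLS vs explicit normal equations) at tolerances of $10^{-9}$
to $10^{-12}$; published-table comparisons use half a unit in the last
printed decimal (0.005), the honest resolution of a 2-dp table. Simulation
checks use cohorts of $10^5$ stems multinomially distributed over eight
classes with decay 0.4 — at that size the sampling error of the fitted
decay is well inside $\pm 0.02$, and 100 seeded replicates run in seconds
— plus a 40-replicate model-recovery check for the Deevey classifier at
cohort size $2 \times 10^4$, where recovery is reliable but not yet
trivial. Large-sample distributional agreement of the BD generator is
checked with a chi-square statistic on a ~$10^5$-stem survey.

## Limitations

- The two-model scheme cannot emit Deevey type I; see the concavity
  diagnostic above.
- Static tables inherit every bias of space-for-time substitution;
  negative raw $d_x$ is reported, not repaired, unless smoothing is
  requested explicitly.
- The moving-average forecast has no error model and no uncertainty
  intervals; it is a descriptive smoother of the standing structure, not
  a projection matrix.
- RIV coverage for lianas and sprawling shrubs is taken at face value
  from crown widths, which overstates ground cover for such growth forms.
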